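gender,age,weight,height,R1,R2,R3,R4,R5,R6,R7,R8,PBF
F,60,59.5,162,307.0,23.4,297.6,23.9,24.4,30.5,261.9,217.7,31.1
M,23,49.3,158,370.5,22.4,362.1,22.7,23.5,29.3,257.4,262.9,27.8
M,28,58.5,180,307.3,24.5,312.3,25.4,26.4,32.3,261.8,255.7,12.6
M,28,58.5,180,312.5,25.9,322.2,26.5,27.3,34.2,259.6,252.4,13.8
F,51,56.9,161,341.1,23.6,340.6,25,27.2,34.4,230.1,227.7,29.6
F,29,79.3,163,278.9,26.4,278.5,26.9,27.3,33.5,200.1,184.2,40.6
M,59,77.2,176,244.8,22.2,260.4,22.5,22.8,29.1,192.7,190.7,22.9
M,45,87.8,180,235.7,20.3,237,20.9,21.3,26.4,221.2,215.6,23.0
M,57,75.0,163,235.4,20.6,244.9,21.2,21.5,28,192.6,192.7,32.2
M,31,78.4,171,216.9,19.8,222.7,20.3,20.7,25.8,167.4,160.7,21.6
F,42,55.8,152,282.8,26.6,291.5,27.4,28,33.4,216.2,212.7,31.4
F,51,68.3,162,307.4,20,306.3,20.7,21.3,27.2,193.7,188.8,33.9
F,54,70.5,168,290.0,28.1,296,28.7,29.1,35.2,208.6,203.3,30.2
M,55,60.7,165,284.7,23.3,274.9,23.8,24.3,30,222.6,219.1,21.9
M,50,79.7,166,241.6,26.7,241.9,27.3,27.6,33.7,193.0,199.4,30.7
F,33,50.0,156,322.0,25.3,327.5,25.9,26.7,32.1,241.9,243.1,24.7
M,43,64.2,170,292.4,23.1,283.7,23.8,24.3,29.8,236.6,245.9,21.7
M,43,66.4,175,303.7,21.1,320,22.3,21.9,28.1,237.3,229.1,21.1
M,51,63.5,168,255.3,26.1,259.1,26.7,27.5,32.1,304.4,206.0,27.6
M,48,76.6,172,264.2,22.2,272.3,23.5,22.3,29.9,205.5,203.4,27.5
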