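gender,age,weight,height,R1,R2,R3,R4,R5,R6,R7,R8,PBF
M,28,82.0,175,253.9,20.1,264.7,21,21.7,26.1,212.5,212.0,27.8
F,51,68.6,154,277.5,22.9,293.2,23.5,23.9,29.4,205.4,200.8,39.1
M,23,109.5,182,235.3,20.4,250.9,20.7,21.3,25.9,166.8,164.9,35.1
M,48,80.9,171,225.3,21.6,236.1,22,22.6,28.1,175.9,174.9,28.0
F,74,54.9,150.5,327.9,23.1,336.5,23.5,24.2,26.3,264.8,274.6,37.7
F,26,59.2,163,405.3,20.8,390.8,21.2,21.9,27.7,235.8,238.2,31.4
M,23,109.5,182,232.1,21.9,247.1,22.3,23,28.7,166,167.6,34.6
F,22,50.4,162.5,362.8,22.7,376.9,23.1,24.2,27.1,263,258.5,24.5
M,52,92.4,180,240.3,20.6,236.7,21.2,21.9,27.6,179.9,190.6,26.2
F,40,65,160,327.6,21.9,332.7,22.4,23.5,24.5,241.5,236.9,35.7
F,34,42.8,155,340.9,21.1,356,21.9,22.2,29.5,216.4,220.5,18.3
M,59,71,169,241.8,21.5,242.6,22.1,22.6,27.8,210.5,209.4,23.6
F,57,65,153,264.4,22.2,266.3,22.6,23.5,29.4,219.3,222.3,37.3
M,50,89,172,248.6,21.5,246,23.5,20.4,27.4,199.2,207.5,34.4
F,84,63.8,151.5,276.4,23.2,291.2,23.8,25.4,33.2,194.1,199.9,38.4
F,49,65,159.5,291.1,22.3,295.5,22.8,23.6,30.1,219.3,217.2,35.3
M,61,79.3,169,265.1,21.9,286.4,22.4,22.2,28.3,211.6,206.3,34.3
M,55,65.2,163,279.2,21.3,296.4,23.1,23.7,30.4,241.5,243.3,30.5
F,45,49.7,152.5,367.7,21.5,377.1,22.1,21.9,25.8,261.5,267.7,32.3
M,22,77.5,183,279.7,21.3,291.3,21.7,22.9,29.4,224,231.9,20.5
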