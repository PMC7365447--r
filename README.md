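# pbfit

Percentage body fat (PBF) prediction from segmental bioelectrical
impedance and anthropometry, for researchers working with eight-segment
BIA cohort data (gender, age, weight, height and the segmental impedances
R1–R8) who want an interpretable linear prediction equation rather than a
black-box regressor.

The package implements a three-stage pipeline:

1. **Candidate features.** The raw parameters are expanded into 64
   candidates: G (gender code), A, W, H, R1–R8, the squares Ri², the
   reciprocals 1/Ri, the pairwise products RiRj and the BIA indices
   H²/Ri.
2. **Feature selection.** An RReliefF variant ranks candidates using a
   neighbour metric that combines numeric and profile-shape similarity,
   C_ij = α·D_ij + β·S_ij, where D_ij is the min–max normalized Euclidean
   distance and S_ij = 1 − |r_ij| is one minus the absolute Pearson
   correlation of the two samples' parameter profiles (defaults α = 1/3,
   β = 2/3). Positively weighted features are then reduced by
   minimum-redundancy maximum-relevance (mRMR) selection with a
   cross-validated stop rule.
3. **Model solving.** The linear model

   PBF = ω₁G + ω₂A + ω₃W + ω₄H + ω₅R₁R₂ + ω₆R₂R₃ + ω₇R₄R₅ + ω₈R₂ +
   ω₉H²/R₂ + b

   is solved by a real-coded modified adaptive genetic algorithm (MAGA)
   that minimizes the mean relative error, with fitness
   fit = 1/(1 + object). MAGA sorts each generation into s fitness
   groups: the best group passes unchanged (and skips crossover and
   mutation), the worst group is discarded, and the middle groups are
   roulette-sampled. Plain GA and adaptive-GA (AGA) baselines share the
   same engine. A synthetic BIA cohort generator with known ground truth
   makes selection and coefficient recovery testable end to end.

## A worked example

Train on 200 samples of a synthetic cohort with known ground truth and
evaluate on the 20 held-out samples, mirroring the 200/20 study design
the package emulates:

```r
library(pbfit)

co    <- generate_cohort(synthetic_spec(n_samples = 220, seed = 1))
train <- as_pbf_cohort(as.data.frame(co)[1:200, ])
test  <- as_pbf_cohort(as.data.frame(co)[201:220, ])

fit <- fit_pbf(train, config = ga_config(seed = 1))
fit
#> Linear PBF model solved by MAGA
#> Coefficients:
#>            G            A            W            H         R1R2         R2R3
#> -5.474180000  0.044900000  0.295008000 -0.115047000 -0.000275140  0.000479097
#>         R4R5           R2        H2/R2            b
#>  0.010605300 -0.744455000 -0.000427543 36.644200000
#> Fitness:0.960663 (mean relative error 4.095%)
#> Stopped by max_generations after 400 generations (n = 200)

evaluate_predictions(predict(fit, test), test$PBF)
#> PBF prediction evaluation (n = 20)
#>   mean relative error: 0.04039 (4.039%)
#>   MSE (as printed, prediction dispersion): 16.86
#>   MSE (conventional): 1.566
#>   Pearson r: 0.9693
```

The training mean relative error of about 4.1% sits at the noise floor of
the generating model (PBF noise sd 1.5 on a mean of 27); on noise-free
cohorts the same configuration reaches the 1% convergence criterion and
stops early. The gender, age and weight coefficients recover the
generating model closely; the impedance-product coefficients are
individually less determined because those features are strongly
correlated, yet the held-out predictions remain accurate (r = 0.97). The
package also ships the printed 20-sample test table of the study it
mirrors as a fixture
(`read_cohort(system.file("extdata", "table3.csv", package = "pbfit"))`),
on which any fitted model can be evaluated with the same two calls.

A command-line interface covering the whole pipeline
(`simulate`, `select-features`, `train`, `predict`, `evaluate`) is
installed at `inst/cli/pbfit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pbfit.R", package = "pbfit"))')" \
    simulate --n 220 --seed 1 --out cohort.csv
```

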