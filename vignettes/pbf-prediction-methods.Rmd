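---
title: "Predicting percentage body fat from segmental bioimpedance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting percentage body fat from segmental bioimpedance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bioelectrical impedance analysis (BIA) estimates body composition from the
electrical resistance of body segments. An eight-segment measurement gives
the impedances R1–R8 of the left/right upper limbs, four trunk subdivisions
and the left/right lower limbs. Together with gender, age, weight and
height, these parameters predict percentage body fat (PBF) well — but the
raw parameters are redundant (left and right limbs are nearly identical)
and interact (products such as R1·R2 and the classic index height²/R track
fat-free mass better than single impedances do). `pbfit` implements a
complete pipeline for this setting:

1. expand the raw parameters into a 64-column candidate feature table;
2. rank the candidates with an RReliefF variant whose neighbour metric
   blends numeric and profile-shape similarity;
3. reduce the ranked set with minimum-redundancy maximum-relevance (mRMR)
   selection;
4. solve the coefficients of the resulting linear PBF model with a
   real-coded modified adaptive genetic algorithm (MAGA).

```{r setup}
library(pbfit)
```

## The candidate feature table

From gender code G (M = 1, F = 0), age A, weight W, height H and R1–R8,
`build_candidate_features()` constructs, in fixed order: the 12 first-order
columns, the 8 squares Ri², the 8 reciprocals 1/Ri, the 28 pairwise
products RiRj (i < j), and the 8 indices H²/Ri — 64 columns. The H²/Ri
family is included because the height-squared-over-resistance index is the
single most established BIA predictor of fat-free mass, and the reference
feature set of the PBF model uses H²/R2. Ethnicity is not generated: the
cohort tables this package mirrors do not contain it, and any extra numeric
covariate can be passed through the `extra` argument instead.

## The combined similarity distance

Relief-family algorithms reward features whose differences track target
differences among *near neighbours*, so the notion of "near" matters. Two
people can be numerically close in raw parameters yet have different PBF,
while two people with similar parameter *profiles* (the shape of the
vector across segments) can be metabolically alike. The neighbour metric
here is therefore a convex combination

$$C_{ij} = \alpha\, D_{ij} + \beta\, S_{ij}, \qquad \alpha + \beta = 1,$$

of a numeric part and a morphological part:

* $D_{ij}$: Euclidean distance between the parameter vectors, min–max
  normalized over all training pairs so the closest pair maps to 0 and the
  farthest to 1;
* $S_{ij} = 1 - |r_{ij}|$: one minus the absolute Pearson correlation of
  the two parameter profiles. Perfectly correlated *and* perfectly
  anti-correlated profiles both have $S = 0$ — the absolute value treats a
  sign-flipped profile as the same shape.

Defaults are $\alpha = 1/3$, $\beta = 2/3$. (Reported weightings for this
combination are not consistent — parameter sweeps favouring a 2:1 ratio
of $\alpha$ to $\beta$ circulate alongside the 1/3–2/3 assignment adopted
here — so both weights are configurable, and
`combined_distance_matrix()` makes an $\alpha/\beta$ sweep on your own
data a three-line loop.)

Because the parameters mix units (years, kg, cm, Ω), each column is
z-scored over the training set before either distance is computed; raw
Euclidean distance would otherwise be dominated by the largest-scaled
column. A `standardize = FALSE` switch exists for applying the formulas
verbatim. A zero-variance profile has no shape; its morphological distance
falls back to 1 (maximally dissimilar) with a warning rather than failing.
If all pairwise distances are equal, normalized distances are defined as 0.

## RReliefF with the combined distance

For each of `m_iterations` probe samples (default: every sample, drawn
without replacement), the `k_neighbors = 10` nearest neighbours under
$C_{ij}$ contribute with uniform weight $1/k$ to three accumulators: the
target-difference mass $N_{dC}$, the per-feature difference mass
$N_{dA}[A]$, and the joint mass $N_{dC\&dA}[A]$. Differences are absolute
differences scaled by the feature's (or target's) training-set range, the
standard choice for continuous attributes. The weight of feature $A$ is

$$W[A] = \frac{N_{dC\&dA}[A]}{N_{dC}} -
         \frac{N_{dA}[A] - N_{dC\&dA}[A]}{m - N_{dC}}.$$

A feature whose differences coincide with target differences gets a
positive weight; one whose differences are independent of the target gets
a weight near zero, and a constant feature gets exactly zero. The
threshold `sigma = 0` therefore keeps exactly the positively weighted
features — Relief weights at or below zero are the conventional signature
of irrelevance. Both neighbour count and threshold are configurable; a
degenerate (constant) target raises an error because both denominators
above collapse.

## mRMR reduction and the stop rule

Greedy forward selection: the first pick maximizes the mutual information
$I(f; c)$ with the target; the $q$-th pick maximizes
$I(f_i; c) - \frac{1}{q-1}\sum_{f_j \in \text{selected}} I(f_i; f_j)$.
Mutual information uses equal-frequency binning (`n_bins = 8`) and the
plug-in estimator — simple, deterministic and adequate at cohort sizes of
a few hundred. Ties break toward the lowest candidate-table column index,
which also makes the selection invariant to the order of the input list.

The stop rule compares a per-size accuracy trace $S_r$ and halts at the
first $r$ with $S_r \ge S_{r+1}$. Because PBF is continuous, "accuracy" is
operationalized as the 5-fold cross-validated accuracy of a
1-nearest-neighbour classifier on the PBF discretized into `n_classes = 4`
equal-frequency classes, computed on the selected columns (z-scored). The
classifier, fold count and class count are deliberately plain: the rule
only has to detect when an additional feature stops helping. All three are
configurable, and `max_features` caps the selection regardless.

## The linear PBF model and the genetic algorithm

The reference model is linear in the nine selected features,

$$\mathrm{PBF} = \omega_1 G + \omega_2 A + \omega_3 W + \omega_4 H +
\omega_5 R_1R_2 + \omega_6 R_2R_3 + \omega_7 R_4R_5 + \omega_8 R_2 +
\omega_9 H^2\!/R_2 + b,$$

and the coefficient vector is solved by minimizing the mean relative
error $\mathrm{object} = \frac{1}{m}\sum_i |f_i - F_i| / F_i$, reported as
the fitness $\mathrm{fit} = 1/(1 + \mathrm{object}) \in (0, 1]$. Three
strategies share the machinery:

* **GA** — roulette selection with probabilities
  $p(k) = \mathrm{fit}(k) / \sum_i \mathrm{fit}(i)$, fixed crossover and
  mutation probabilities (0.8 / 0.05);
* **AGA** — the same selection with adaptive probabilities
  $p_c = k_1 (f_{\max} - f') / (f_{\max} - f_{avg})$ for parents at or
  above the mean fitness (else $k_2$), likewise $p_m$ with $k_3/k_4$;
  defaults $k_1 = k_2 = 0.9$, $k_3 = k_4 = 0.1$, with the guard
  $p_c = k_2$, $p_m = k_4$ when $f_{\max} = f_{avg}$;
* **MAGA** — adaptive probabilities plus the grouped selection operator:
  sort the population of M = 96 by fitness into s = 8 groups of 12; the
  top group passes to the next generation untouched (and skips crossover
  and mutation); the bottom group is discarded; the remaining 84 slots are
  roulette-drawn, with replacement, from the 72 middle individuals with
  probabilities renormalized over the middle.

The grouped operator makes the best-fitness trace provably non-decreasing
(the elite group is never disturbed) while the discard step removes the
drag of the worst group; s must be at least 3 so the middle is non-empty,
and M must be divisible by s (a violation is a configuration error, not a
silent rounding).

### Operator mechanics and numerical conditioning

Genes are real-valued in $[-100, 100]$; individuals are initialized
uniformly and clipped back to the range after every operator. The
adaptivity *formulas* above are the classic ones; the operator *mechanics*
for real coding are the package's own choices, made for convergence on
this problem class:

* **Crossover**: per-gene extended blend (BLX-0.5),
  $c = \lambda p_1 + (1-\lambda) p_2$ with
  $\lambda \sim U(-0.5, 1.5)$. Plain convex blending only contracts the
  population; the extension lets children sample beyond the parent
  interval, which measurably speeds convergence along the valley of this
  objective.
* **Mutation**: a mutated gene takes, with probability 1/2, a Gaussian
  step whose standard deviation is the current spread of that gene over
  the fittest group — a self-scaling local refinement that shrinks as the
  population converges — and otherwise a log-uniform step of up to a tenth
  of the gene range, which restores diversity at all scales. A pure
  uniform redraw in the full range, the simplest textbook choice, was
  rejected: it cannot refine a near-converged population and stalls the
  search at mean relative errors orders of magnitude above the
  convergence criterion.
* **Conditioning**: the model features span four orders of magnitude (a
  gender code of 0/1 against impedance products near $10^4$) and are
  strongly correlated ($R_1R_2$ against $R_2R_3$). A direct search on the
  raw coefficients is numerically hopeless for *any* population-based
  optimizer at this budget. `evolve()` therefore searches the coefficients
  of an orthonormalized basis of the design matrix (QR decomposition,
  columns scaled to unit root mean square) and back-transforms the best
  individual to raw-scale coefficients. The gene range applies to the
  internal basis; on it, realistic PBF models sit comfortably inside
  $[-100, 100]$. A `condition = FALSE` switch runs the search on raw
  coefficients for didactic purposes.

Pairing shuffles the drawn individuals and crosses consecutive pairs; an
odd leftover passes through unchanged. One seeded generator drives the
entire run, so a run is reproducible from `(data, config)` alone.

Termination: the run stops when the best objective reaches
`termination_epsilon = 0.01` — the point at which predicted and actual
values agree to 1% on average, the natural reading of "error at most
0.01" for the only error the loop computes — or at 400 generations.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a hospital BIA cohort with
known ground truth, so that selection and coefficient recovery are
testable without any external data:

* gender Bernoulli(1/2); age uniform on 9–84 years; height normal by
  gender (172 ± 7 cm male, 159 ± 6 cm female) clipped to 149–190 cm;
  weight via a BMI draw (24.5 ± 3.2) times height², clipped to
  38.4–121.4 kg — the printed ranges of the cohorts this package mirrors;
* limb impedances log-normal around 255 Ω (male) / 320 Ω (female) with
  bilateral pairs agreeing within about 3%, lower limbs at about 0.8 of
  upper; trunk segments log-normal around 21.5–23 Ω with fixed
  R2 < R4 < R5 < R6 ordering — the magnitude pattern of printed segmental
  tables (limbs in the hundreds of ohms, trunk in the tens);
* PBF from a known coefficient vector on the reference features plus
  Gaussian noise (default sd 1.5 PBF points, a realistic residual scale
  for BIA regression equations), clipped to [3, 60]%. A spec whose model
  clips more than 1% of samples is rejected as infeasible rather than
  silently distorting the ground truth.

The default generating coefficients give females higher PBF, PBF rising
with age, weight and the impedance terms and falling with height, with a
population mean near 27% and a spread of about 4 points. What the
generator does *not* emulate: the joint dependence of impedance on age and
body water, measurement error in the impedance channels, and any
non-linearity in the true PBF relationship. Passing recovery tests on
these cohorts therefore demonstrates that the pipeline works when its
modelling assumptions hold; it is not evidence about hospital data.

`generate_planted_feature_task()` builds the candidate table but rewires
the target to depend on a chosen driver subset (2.5 PBF points per
standard deviation each), optionally appending independent noise columns
and 1%-jittered near-duplicates of the drivers — the ground truth for
selection-recovery and redundancy-avoidance experiments.

## Problem sizes and what the package's checks compute

The package's own test suite and the `scripts/acceptance.R` script work at
deliberately modest sizes chosen to exercise every property at desk
scale: cohorts of 200–220 samples (matching the emulated study design of
200 training and 20 test samples), 10 seeds for coefficient-recovery runs,
10 seeds per strategy for the GA/AGA/MAGA comparison on a fixed noisy
task, and 20 seeds for the planted-feature experiments. On these sizes a
single MAGA run of 400 generations takes a few seconds. Headline numbers
from the hospital-cohort literature (fitness 0.99, sub-0.1% mean relative
errors) are not reproduction targets: they depend on a full private
dataset and on operator details reported only by citation. The package's
claims are the property-level ones its tests compute — formula fidelity,
oracle agreement, the selection-operator contract, monotone elitism,
recovery of known ground truth, and the MAGA ≥ AGA ≥ GA ordering.

## Known limitations

* The as-printed "mean square error" of this literature,
  $\frac{1}{n}\sum_i (f_i - \bar f)^2$, is the dispersion of the
  predictions, not an error against observations. It is implemented
  verbatim as `mse_printed()` for comparability, flagged as such, and
  accompanied by `mse_conventional()` which is used for all internal
  quality reporting.
* Whether the gender variable of the feature-selection stage and of the
  fitted model are the same variable is assumed yes; the coding M = 1 /
  F = 0 is a documented convention, not a claim.
* The mutual-information estimator is the binned plug-in; it is biased
  upward at small samples, which is immaterial for ranking but means
  reported MI values should not be read as calibrated information
  estimates.
* mRMR's stop rule depends on a classifier heuristic; with very noisy
  targets it can stop early. `max_features` and the S_r trace in the
  returned object let the user override and inspect it.

## A worked example

```{r example, eval = FALSE}
co <- generate_cohort(synthetic_spec(n_samples = 220, seed = 1))
sel <- select_features(co, seed = 1)
sel

fit <- fit_pbf(co, config = ga_config(seed = 1))
summary(fit)
plot(fit)

test <- read_cohort(system.file("extdata", "table3.csv", package = "pbfit"))
evaluate_predictions(predict(fit, test), test$PBF)
```
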