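---
title: "Calibrated genomic prediction in multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated genomic prediction in multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcalib)
library(dplyr)
```

## The problem

Genomic selection trains a statistical model on a reference panel of plant
lines that have both genome-wide marker data and field phenotypes, then
predicts the trait values of selection candidates that have only been
genotyped. In a multi-environment trial each line is grown in several
environments, and prediction quality is judged by the mean squared error
(MSE) of out-of-fold predictions under cross-validation.

Feed-forward neural networks are attractive for this task because they can
capture non-additive signal, but with the small panels typical of breeding
programmes their tuning is fragile: after grid search and refitting, the
predictions often retain a systematic *affine* bias (they are shrunk toward
the mean, shifted, or both). `gpcalib` implements a post-processing
calibration for continuous outputs: a held-out slice of the training data
is predicted by the final network, an ordinary-least-squares line of
observed on predicted values is fitted on that slice, and the line is then
applied to the test-set predictions. The package ships the calibrated
protocol (`run_dl_m2()`), the conventional protocol (`run_dl_m1()`), and a
GBLUP mixed-model baseline (`run_gblup_cv()`), plus a synthetic trial
simulator so the whole benchmark is reproducible without external data.

## The models

### GBLUP with genotype-by-environment interaction

For line $j$ in environment $i$ the phenotype is modelled as

$$Y_{ij} = \mu + \mathrm{Loc}_i + g_j + gL_{ij} + \varepsilon_{ij},$$

with fixed environment effects, random line effects
$\mathbf g \sim N(0, \sigma^2_g \mathbf G)$, random interaction effects
$\mathbf{gL} \sim N(0, \sigma^2_{gL} (\mathbf I \otimes \mathbf G))$ and
i.i.d. residuals with variance $\sigma^2_e$. $\mathbf G$ is the VanRaden
genomic relationship matrix
$\mathbf G = \mathbf W \mathbf W^\top / (2\sum_k p_k(1-p_k))$, where
$\mathbf W$ holds allele counts centred by twice the allele frequency
(`vanraden_relationship()`; frequencies are estimated from the sample, and
an argument accepts external estimates).

The package fits this model by REML on an exactly equivalent ridge
parameterisation. Let $\mathbf L$ be a Cholesky factor of
$\mathbf G + \delta\mathbf I$ (`stabilized_cholesky()`; $\delta$ is the
smallest jitter in $\{0, 10^{-8}, 10^{-7}, \ldots\}$ that makes the
factorisation succeed — a realised $\mathbf G$ is rank-deficient whenever
markers are fewer than lines, and always loses one rank to centring). With

* `XE` — full one-hot environment incidence,
* `XG` — line incidence post-multiplied by $\mathbf L$,
* `XGE` — the column-wise Khatri–Rao product of `XE` and `XG`
  (environment-major),

i.i.d. ridge coefficients on `XG` and `XGE` induce exactly the
$\sigma^2_g\mathbf G$ and $\sigma^2_{gL}(\mathbf I\otimes\mathbf G)$
covariances above, because
$\mathtt{XG}\,\mathtt{XG}^\top = \mathbf Z(\mathbf G + \delta\mathbf I)\mathbf Z^\top$
and
$\mathtt{XGE}\,\mathtt{XGE}^\top = (\mathtt{XE}\,\mathtt{XE}^\top)\circ(\mathtt{XG}\,\mathtt{XG}^\top)$.
The same three blocks, concatenated, are the predictor matrix fed to the
neural networks, so every model in the benchmark sees identical
information. The Khatri–Rao construction is the standard one whose
cross-product reproduces the Kronecker covariance; the interaction block is
built from the Cholesky-transformed genotype block, consistent with how the
genotype block itself is defined.

REML details (`fit_gblup()`): the variance ratios
$\lambda_g = \sigma^2_g/\sigma^2_e$ and
$\lambda_{gL} = \sigma^2_{gL}/\sigma^2_e$ are profiled on the log scale —
Brent's method for one ratio, Nelder–Mead for two — with convergence
tolerance $10^{-8}$, at most 500 iterations, and ratios floored at
$10^{-10}$ so the mixed-model equations stay solvable. Each evaluation
Cholesky-factorises
$\mathbf H = \mathbf I + \lambda_g \mathbf K_g + \lambda_{gL}\mathbf K_{gL}$
($n \times n$), which is fast at the record counts this package targets
(up to a few thousand). Fixed effects are environment *cell means* (no
global intercept, no dropped reference level): this avoids an arbitrary
reference environment, and the networks likewise receive the full one-hot
block because they carry their own bias terms. A deterministic REML fit was
chosen over Monte-Carlo Bayesian estimation of the same model because it
targets the same estimands, is reproducible bit-for-bit, and makes
parameter-recovery testing meaningful; the package's tests validate the
BLUPs against dense mixed-model-equation solves at $10^{-8}$ and the
variance components against simulation truth.

### The network and its tuning grid

`train_mlp()` implements a dense feed-forward network: equal-width ReLU
hidden layers, a single linear output, inverted dropout after each hidden
layer (training only), Glorot-uniform initialisation, and Adam on
minibatch MSE. The tuning grid (`hyperparameter_grid()`) is fixed at eight
points: widths $\{1.5, 3\}\times$ the number of inputs, depths
$\{1, 4\}$, dropout $\{0.15, 0.30\}$, with learning rate $0.001$ and
exactly $1{,}000$ epochs in every entry. The grid order
(multiplier-major, then depth, then dropout) is part of the contract:
ties in the grid search resolve to the first entry.

Choices the protocol leaves open were fixed as follows: Adam as the
optimiser at the stated learning rate; batch size 32 (configurable via
`mlp_learner()`); one shared width for all hidden layers; widths rounded
half-up with a floor of one unit; dropout applied after hidden layers
only, not to the input; and inputs and response standardised by
training-set statistics (predictions are de-standardised), which keeps a
single learning rate usable across trait scales. Determinism is per seed:
one master seed fans out to shuffling, initialisation and dropout streams
via `derive_seed()`.

## The three protocols

All protocols share record-level 5-fold outer cross-validation
(`make_split_plan()`): records (line-environment cells) are shuffled and
dealt into five folds, so a line in the test fold usually stays in
training through its records in other environments. This mimics sparse
testing — predicting lines into environments where they were not grown —
and *not* cross-generation prediction. Assignment is uniform over records;
with balanced trials stratification would change almost nothing.

* **GBLUP** — fit on the four training folds, predict the fifth. No
  tuning, no calibration.
* **DL_M1 (conventional)** — split training 80/20 into inner-training
  (64% of all records) and validation (16%); train all eight grid entries
  on inner-training; pick the validation-MSE minimiser; *refit it on the
  full training set* (80%); predict the test fold.
* **DL_M2 (calibrated)** — split inner-training 80/20 again
  (inner-inner-training 51.2%, inner-validation 12.8%); grid-search at the
  deepest level; refit the winner on inner-training (64%); predict **both**
  the validation slice and the test fold; fit the OLS calibration line
  `observed ~ predicted` on the validation slice
  (`fit_calibration_line()`); report
  $\hat\beta_0 + \hat\beta_1\,\hat y_{\text{test}}$.

The tuning step uses a single 80/20 split rather than an inner k-fold
loop: the single-split procedure is the one the protocol descriptions fix
step by step, and it keeps the two DL protocols' training budgets
directly comparable. The calibration line is fitted pooled across
environments within a fold (one line per fold); per-environment lines
would use five times fewer points each at these panel sizes.

Two structural facts about DL_M2 are worth keeping in mind. Its final
model sees only 64% of the records versus DL_M1's 80%, so calibration has
to buy back a real handicap; and on its own validation points the OLS line
can never increase MSE (projection property — asserted exactly in the
tests). When the base learner is affinely biased, the calibrated
protocol's test MSE drops by the full bias term; when the learner is
already well calibrated the line is near-identity and the cost is only
the smaller training set. If the validation predictions are constant the
slope is undefined and the protocol falls back to the identity line with
a warning.

## The simulator

`simulate_markers()` draws per-marker allele frequencies uniformly from
`maf_range` and genotypes as Binomial(2, p) allele counts —
Hardy–Weinberg equilibrium, *independent* markers. `simulate_trial()`
generates $Y_{ij} = \mu + \mathrm{Loc}_i + g_j + gL_{ij} + \varepsilon_{ij}$
with additive marker effects behind $g$, per-environment marker effects
behind $gL$ (giving the $\mathbf I \otimes \mathbf G$ correlation
structure), and Gaussian noise. Marker effects are rescaled so the
*realised* genetic variance hits
$\sigma^2_g = h^2\sigma^2_e/(1-h^2)$ exactly in every dataset (the
heritability target is defined at `ge_ratio = 0`), and
$\sigma^2_{gL} = $ `ge_ratio` $\cdot\,\sigma^2_g$. Environment means
default to equally spaced values centred at zero with unit spacing.

The defaults — 300 lines, 1,000 markers, 3 environments, $h^2 = 0.5$,
`ge_ratio` 0.5, residual variance 1 — correspond to a mid-sized breeding
panel with moderate heritability and substantial but not dominant G-by-E.
What the simulator deliberately omits: linkage disequilibrium, dominance
and epistasis, pedigree/family structure, unbalanced designs and
environment-specific error variances. Consequently, passing tests show
the *methods* behave as specified (variance components recovered,
calibration inverts bias, protocols leak-free) — they do not show that
any method will rank first on a particular real dataset, where LD,
non-additive signal and small-sample noise change the picture.

## Testing strategy and problem sizes

The test suite validates each stage against an independent oracle: the
VanRaden matrix against a hand-computed 3-line example; BLUPs against
dense mixed-model-equation and closed-form ridge solves on toys of 6–12
records (tolerance $10^{-8}$); the calibration line against the
normal-equations solution and `lm()`; the protocols against injected
oracle learners with known, exactly invertible biases. Stochastic checks
run at sizes chosen to make the statistics stable while keeping the whole
suite around a minute: REML recovery uses 20 replicates of 300 lines
$\times$ 3 environments; the calibration-benefit experiment uses 20
replicates of the same size with a biased oracle learner as the base
model (a network base learner gives the same comparison, just slower);
the heritability check uses 2,000 lines to pin the variance ratio within
$\pm 0.05$.

## Known limitations

* REML, not MCMC: point estimates only, no posterior uncertainty on the
  variance components.
* The MLP is plain R matrix code: right-sized for panels of hundreds of
  lines; not intended for marker-level inputs of $10^5$ columns.
* One trait at a time; no multi-trait covariance.
* Record-level CV only — no leave-line-out or forward prediction.
* Balanced designs are not required, but heavily unbalanced data thin the
  per-environment cells of the report.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_lines = 120, n_markers = 400, n_env = 3, seed = 42)
markers <- simulate_markers(cfg)
trial <- simulate_trial(markers, cfg)

grm <- stabilized_cholesky(vanraden_relationship(markers))
design <- build_design(trial$phenotypes, grm$chol_factor, include_ge = TRUE)
plan <- make_split_plan(trial$phenotypes, k = 5, seed = 42, nested = TRUE)

gb <- run_gblup_cv(trial$phenotypes, design, plan)
m1 <- run_dl_m1(trial$phenotypes, design, plan)   # full grid, 1000 epochs
m2 <- run_dl_m2(trial$phenotypes, design, plan)

report <- build_report(list(gb, m1, m2))
report$cells
autoplot(report)
```
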