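---
title: "Methods: resource overlap, competition scoring and single-cell reproductive success"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resource overlap, competition scoring and single-cell reproductive success}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`phyllocomp` chains four models: a logistic growth model for microplate
curves, a constraint-based (flux balance) model for nutritional
requirements, a scalar competition score built from both, and a
fluorescence-dilution model for single-cell division counting. This
vignette records the assumptions behind each, the tunable parameters with
their defaults, the numerical choices, and what the synthetic-data tests do
and do not establish about real data.

## Logistic growth kinetics

Curves are modelled as
$N(t) = K / \left(1 + \frac{K - N_0}{N_0} e^{-\mu t}\right)$
with growth rate $\mu$ (per hour), carrying capacity $K$ (OD or RFU units)
and initial value $N_0$. Fitting assumes a single growth phase: diauxic
curves are out of scope. Before fitting, curves are normalised against the
no-carbon blank (`blank_correct()`; pointwise subtraction, negatives
clipped to zero — clipping is the reason zeros can appear in otherwise
positive data).

**Estimation.** `fit_logistic()` uses Levenberg-Marquardt least squares.
Plate-reader and fluorescence error grows with the signal, so for strictly
positive curves residuals are minimised on the log scale — the matched
estimator when the error is multiplicative — and on the linear scale when
clipped zeros are present. This choice is not cosmetic: with 5%
multiplicative noise on 25 points, linear-scale least squares recovers
$\mu$ within 10% in only ~83/100 curves, the log-scale fit in 100/100.
Starting values are $K \leftarrow \max(N)$, $N_0 \leftarrow$ first positive
reading, and $\mu \leftarrow$ the log-linear slope of the rising segment
(readings up to the first half-maximum crossing; using all sub-maximum
points lets plateau noise flatten the slope estimate and strand the
optimiser in a local minimum). A small multi-start over
$\mu_0 \in \{\hat\mu_0, 0.1, 0.5, 1\}$ guards the remaining cases. $K$ is
bounded in $(0, 2\max(N)]$. Flat or all-zero curves return a no-growth fit
(`converged = FALSE`, $\mu = K = 0$) rather than an error, because
no-growth wells are data, not failures.

**AUC.** The reported area under the curve is the analytic integral of the
fitted logistic over the observed interval, not the empirical trapezoid —
robust to sparse (24 h) sampling; both 24 h and 5 min grids are supported
without resampling.

**Carbon profiles.** `build_carbon_profile()` arranges $\mu$ and $K$ per
strain × carbon source into a matrix and z-scales each column. The sample
SD ($n-1$) is used, matching `scale()`'s convention; whether $\mu$ and $K$
should be scaled jointly or per column is genuinely open, and per-column
scaling was chosen (recorded in the object's `scaling` attribute).
Non-converged fits are coded $\mu = K = 0$ before scaling — no-growth cells
carry signal. Zero-variance columns are dropped with a warning. Strain
dissimilarity is the Euclidean distance between z-scored rows; the
complete-linkage merge tree is exposed alongside.

## Flux balance analysis and minimal media

A `metabolic_model` is a stoichiometric matrix with flux bounds, a biomass
reaction and exchange reactions mapped one-to-one to environment compounds.
FBA maximises biomass flux subject to $Sv = 0$; uptake is open (at the
medium's `uptake_bound`, default 10 flux units per compound) only for
medium compounds. Optima at the internal bound ceiling are reported as
model defects (unbounded rings).

Linear programs are solved with `boot::simplex`, with every solution
validated against the constraints; an internal two-phase simplex (Bland's
rule) takes over when the primary route fails validation, because
`boot::simplex` can silently return NaN on equality rows whose coefficients
are all negative. The two routes are cross-checked on random LPs in the
test suite.

**Minimal media.** The integer program — minimise the number of open uptake
compounds subject to biomass ≥ threshold (default 10% of the
medium-constrained maximum, with a $10^{-6}$ growth tolerance) — is solved
exactly by essentiality reduction: compounds whose single removal abolishes
growth are fixed open (every feasible set must contain them), and the
remainder is searched in ascending cardinality with LP feasibility as
oracle. Every set returned is a global minimum; alternative minima of the
same size are collected up to `max_alternatives` (default 50). On toy
models the enumeration provably equals exhaustive subset search (a suite
invariant).

**MRO.** Requirement sets are the union over alternative minimal media —
capturing the *maximal possible* overlap; a per-minimal-set pairing mode is
deliberately not implemented. The index is intersection over mean set size,
with a min-normalised variant behind `normalisation = "min"`, because the
normalisation convention in community metabolic modelling is not unique;
the choice is recorded in the result object. Inorganic nutrients are
included by default (whole-medium overlap); `carbon_only = TRUE` restricts
to carbon sources since shared salts compress the dynamic range. Built-in
media: `M5C` (glucose, fructose, malate, sorbitol, methanol), `L10C` (the
ten most abundant leaf metabolites) and `L8C` (L10C without citrate,
alanine and threonine, plus glucose); other leaf compositions must be
supplied as user `medium_spec()` objects.

## Competitive-ability score

$\mathrm{score} = (\mu_i - 1)/\sqrt{a_{ii} a_{ij}}$ with $a = 1/K$. The
numerator subtracts the dimensionless constant 1 from a per-hour rate; the
formula is implemented literally in that printed form, so scores are only
comparable within one experimental context and with consistent time units —
which is why cohorts are z-scaled (`zscore_scores()`, sample SD). Whether
the cohort should be replicate-level scores or strain means is not fixed by
the method; both work through the same function, and the caller's choice
defines the cohort. The geometric-mean denominator makes the score
symmetric in $a_{ii}$ and $a_{ij}$ and sign-faithful to $\mu_i - 1$.
`relative_auc_change()` (co-culture AUC over monoculture AUC) is the
model-free companion used for validation; on synthetic cohorts the two
agree at $r \ge 0.95$.

## CUSPER single-cell pipeline

The reporter's green pool is fixed at induction and halves per division, so
$RS = \log_2(\bar{x}_0 / x)$ counts divisions. Assumptions: no de novo GFP
synthesis, negligible photobleaching differences across fields of view, and
a $t_0$ sample that represents the founder intensity distribution
($\bar{x}_0$ is taken from the time-zero sample of each experiment after
background correction).

* **Background.** Mean background per field of view is subtracted.
  Corrected intensities ≤ 0 are cells dimmer than background — at least
  LOD-many divisions — and are floored at 1 a.u. and flagged rather than
  dropped.
* **LOD.** RS computed from background readings is high (background is
  dim); the limit of detection is the $\alpha = 0.05$ empirical quantile of
  that distribution (linear ECDF interpolation, `quantile` type 7), then
  snapped *down* to the nearest bin edge $k + 0.5$ so censoring aligns with
  binning. Whether background should enter as per-image means or pooled
  sampled values is unstated in standard protocols; pooled per-image
  sampled values are assumed.
* **Binning.** Half-open bins: $RS_0 : RS < 0.5$, $RS_k : k - 0.5 \le RS <
  k + 0.5$ (k = 1..4), $RS_{>4} : RS \ge 4.5$. Values at or above the
  working LOD are pooled into the top class and flagged censored. Negative
  RS (cells brighter than $\bar{x}_0$) goes to $RS_0$ and is counted in an
  attribute.
* **Founder reconstruction.** $g_k \propto f_k 2^{-k}$, fold increase
  $1/\sum_j f_j 2^{-j}$. The censored class needs a representative division
  count; the default 5 is its lower bound, making the fold increase
  conservative. It is configurable because any single value is a guess.
* **PERMANOVA.** Reimplemented with sequential (Type-I) sums of squares in
  the Gower-matrix formulation, factor order (time, treatment),
  unrestricted label permutations, $p = (1 + \#\{F^* \ge F\})/(n_{perm} +
  1)$; `vegan::adonis2` is the independent cross-check in the tests, which
  it matches to $10^{-10}$ on SS, $R^2$ and $F$. Units whose structure is
  all $RS_0/RS_1$ (initial populations) can be excluded from the
  multivariate comparison by the caller, as they reflect inoculation, not
  competition. Distances are Bray-Curtis via `vegan::vegdist`.

## Image quantification

The red (constitutive) channel identifies cells: intermodes thresholding
(iterative 3-bin mean smoothing of a 256-bin histogram until exactly two
local maxima survive; threshold = floor of the mode midpoint, ties flooring
to the lower intensity), 8-connected component labelling, area filter
0.5–2.5 µm² and border exclusion. "0.5–2.5 µm" is interpreted as *area* in
µm² (particle-analysis semantics); the alternative reading (major-axis
length) is flagged here but not implemented. The default `pixel_size` of
0.045 µm/px corresponds to a 100× widefield configuration and is a
configuration value, not a measured constant — synthetic tests use
0.1 µm/px for compact scenes. Manual curation against phase contrast is
replaced by an optional red-intensity floor; spectral unmixing,
illumination correction and tracking are out of scope. Per-cell green means
are measured through the red-derived mask, and background is sampled as one
random mask-free patch per image (seed-deterministic).

## Synthetic data: what it emulates, and what it does not

The generators produce logistic curves with multiplicative lognormal noise
(unit mean, given CV — positivity preserved, error scaling with signal),
fluorescence-dilution populations (division counts from a user pmf capped
at 8, descendants $2^k$ per founder at intensity $\mathrm{gfp\_mean}/2^k$
with lognormal CV `gfp_cv`, lognormal background), toy metabolic models
(one lumped biomass reaction, one uptake→precursor route per usable carbon,
biomass consuming a trace of every inorganic — the simplest structure with
controllable minimal media), and two-channel scenes of axis-aligned
ellipses over Gaussian background. Defaults: `noise_cv = 0.02` for
growth-curve studies (typical plate-reader repeatability), `gfp_cv = 0.05`
(no anchored literature value exists for cell-to-cell reporter CV at $t_0$;
this is a free configuration), background 100 a.u. at CV 0.2, scenes of
128×128 px with 6–10 cells at SNR well above 5.

Passing tests on these inputs establish internal consistency — exact
noise-free recovery, correct inversion of descendant weighting, correct set
arithmetic, calibrated permutation tests — not field performance. Real
images carry debris, uneven illumination and touching cells; real curves
carry lags and diauxie; real models carry gaps. None of those are emulated,
and claims about them are outside what this package's tests support.

## Problem sizes and numerical tolerances

Simulation studies in the tests and the acceptance script use sizes chosen
to make Monte Carlo error small relative to the tolerance being checked:
200 curves for fit-bias (<2% at CV 2%), 100 curves for the 10% recovery
band, 2000 founders (±3 binomial SE per bin) for the single-cell round
trip, 500 null data sets × 199 permutations for PERMANOVA type-I
calibration (rate within 0.05 ± 0.02), and 100 scenes for exact
segmentation recovery. LP feasibility uses a $10^{-6}$ growth tolerance;
fit convergence uses `ftol = ptol = 1e-12`; noise-free recovery is checked
to $10^{-6}$.

## Known limitations

* The minimal-media search is exponential in the number of non-essential
  medium compounds; it is exact and fast for the toy scale this package
  targets (≲ 15 medium compounds) but not tuned for genome-scale models
  with hundreds of exchanges.
* The SBML reader/writer covers the Level 3 FBC subset this pipeline emits
  (species, reactions, parameter bounds, one objective; exchanges by the
  `EX_` single-participant convention) — it is not a general SBML
  implementation.
* The competitive score inherits the unit ambiguity of its printed form
  ($\mu - 1$); interpret only within a z-scaled cohort.
* PERMANOVA permutations are unrestricted; nested or repeated-measures
  designs would need restricted permutation schemes that are not provided.
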