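---
title: "Dynamic functional network connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional network connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfnc)
```

## The problem

Resting-state fMRI studies of attention and impulsivity increasingly model
the brain's large-scale networks — default mode (DMN), executive control
(ECN) and salience (SN) — as a dynamically interacting system rather than a
static connectome. After group ICA, each subject is reduced to a T x C
matrix of component time courses (here C = 6: dDMN, pvDMN, pdDMN, rECN,
lECN, SN; T = 190 retained volumes at TR = 2.4 s). `dfnc` implements the
full downstream analysis:

1. **Conditioning** — linear detrend, running-median despiking, zero-phase
   Butterworth low-pass (0.15 Hz, order 5).
2. **Static FNC** — full-length Pearson correlation of every component
   pair (15 pairs for 6 components), Fisher z-transformed.
3. **Dynamic FNC** — a tapered sliding window (15-TR rectangle convolved
   with a sigma = 3 TR Gaussian, truncated at +/- 8 TRs, total support
   L = 31; slid in steps of 1 TR, giving 160 windows for T = 190), with the
   taper acting as observation weights in the windowed correlation.
   Optionally, each window's correlation comes from an L1-penalised
   precision fit (graphical lasso) with the penalty chosen per subject by
   cross-validated held-out log-likelihood.
4. **States** — k-means under the L1 (Manhattan) distance on all subjects'
   pooled windowed FNC vectors, k chosen by an elbow criterion over
   k = 2..8; per-subject mean dwell time (MDT), fraction time (FT) and
   number of transitions (NT).
5. **Meta-states** — each window expressed as weights on m maximally
   independent connectivity patterns (PCA + fixed-point ICA rotation),
   signed-quartile discretised; four dynamism indices per subject (number,
   changes, span, total distance).
6. **Behaviour** — Pearson screens of connectivity features against six
   behavioural measures (two YSR attention scales, four UPPS impulsivity
   facets), Benjamini–Hochberg FDR within declared families, and a motion
   QC screen of state occurrence against mean framewise displacement.

Because component time courses from developmental cohorts are rarely
shareable, the package ships a first-class synthetic-cohort generator so
that every stage is testable end to end.

## The synthetic cohort generator

`generate_cohort()` draws, per subject, a latent state sequence from a
first-order Markov chain (default self-transition 0.9, uniform off-diagonal
→ geometric dwell with mean 10 TRs = 24 s, in the range reported for
resting-state brain states) and emits, at each timepoint, an independent
zero-mean Gaussian vector with the active state's covariance. The default
state set (`make_default_states()`, separation 0.6) emulates the canonical
four-state repertoire: a posterior-DMN/ECN state with a decoupled SN; a
modular DMN-vs-ECN state with DMN–SN coupling; a globally hyperconnected
state; and an isolated pvDMN–SN synchronisation. Templates are repaired to
positive definite form by eigenvalue clipping at 1e-6 and rescaling to unit
diagonal.

Behavioural scores are generated as
`mean + sd * (sum_i rho_i z(feature_i) + sqrt(1 - sum rho_i^2) eps)` with
cohort means/SDs (e.g. YSR Attention Problems 57.19 +/- 6.85) and six
default planted effects linking ground-truth dynamic features to measures
(state-1 SN–lECN coupling to both attention scales at r = -.38/-.39,
state-3 dwell to ADHD manifestations and lack of perseverance at
.30/.33, switching and path length to ADHD manifestations at .24/.35).
Planted features come from the *true* latent sequences, so recovery by the
estimated pipeline is a genuine end-to-end test.

What the generator deliberately omits: within-state temporal
autocorrelation (emissions are i.i.d. given the state, keeping windowed
correlations unbiased estimators of the state matrices), scanner noise
spectra, head-motion artefacts, and subject-level variation in the state
covariances themselves. Consequences for interpreting green tests: passing
recovery tests show the estimators are correct under the model, not that
real BOLD data meet the model's assumptions.

A corollary worth stating explicitly: the conditioning chain exists for
real-data artefacts (drifts, spikes, high-frequency noise). Applied to the
generator's white Gaussian emissions, the 0.15 Hz low-pass only *removes*
effective degrees of freedom from each 31-TR window and blurs the state
structure. Synthetic recovery analyses (and the reproduction script)
therefore run the window estimator directly on the generated signals
(`condition = FALSE`); conditioning is validated by its own contract tests.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| window width | 15 | TRs | 36 s at TR 2.4 s; the standard compromise between temporal resolution and estimate stability |
| taper sigma | 3 | TRs | Gaussian smoothing of the rectangle's edges |
| taper truncation | 8 | TRs | makes L = 31 so that 190 timepoints give exactly 160 windows |
| step | 1 | TRs | dense window grid |
| cutoff | 0.15 | Hz | low-pass for FNC estimation; must be below Nyquist 1/(2 TR) ≈ 0.208 Hz |
| despike threshold / window | 3 / 7 | robust sigmas / TRs | running-median replacement; a column whose median residuals have zero MAD is left untouched |
| k range | 2..8 | states | model-selection span |
| replicates / max_iter | 10 / 200 | — | clustering restarts and Lloyd iteration cap |
| m | 4 | patterns | meta-state dimensionality, mirroring the four-state repertoire; not identified by theory, configurable |
| q | 0.05 | — | FDR threshold |
| glasso grid / folds | 10 log-spaced in [1e-3, 1] / 5 | — | per-subject penalty by contiguous-block CV over windows |

## Numerical and algorithmic choices

**Windowed correlation.** The taper enters as observation weights in the
weighted means, variances and covariances of each L-row slice. A window
with zero weighted variance in some component yields 0 for the affected
pairs with a warning. A flat unit window reproduces plain Pearson
correlation exactly.

**Zero-phase filtering.** `signal::filtfilt` applies zero initial
conditions, which leaves visible edge transients (a constant input is not
returned unchanged). `butterworth_lowpass()` therefore demeans and pads
both ends with odd (point-symmetric) reflections of length 9 x order before
the forward–backward pass, then trims — the effective amplitude response is
the squared one-pass Butterworth response, and a constant column passes
through to within 1e-9.

**Graphical lasso.** The penalised precision is fit by block coordinate
descent (each column update a cyclic-coordinate-descent lasso), penalising
off-diagonals only, so the covariance estimate keeps the sample diagonal.
At penalty 0 the sample estimate is returned; for penalties above the
largest absolute off-diagonal covariance the correlation estimate is
exactly diagonal. Cross-validation folds are contiguous blocks of windows,
respecting temporal ordering; the training covariance is the mean of the
training windows' weighted covariances and candidates are scored by
`log det(Theta) - tr(S_test Theta)` on held-out windows; ties go to the
smallest penalty.

**L1 k-means.** Assignment ties go to the lowest centroid index; the
centroid update is the componentwise median (the L1 minimiser); empty
clusters are re-seeded from the point farthest from its assigned centroid;
each replicate initialises from k distinct windows sampled uniformly under
a per-replicate seed; the best of 10 replicates by total within-cluster L1
dispersion is kept. The inner loop is compiled (Rcpp) because the pooled
problem is 12,800 windows x 15 pairs across seven values of k.

**Elbow rule.** The cluster index is I(k) = (mean within-cluster distance
to the assigned centroid) / (mean pairwise centroid distance), both in L1.
The chosen k maximises the perpendicular distance from (k, I(k)) to the
chord joining the curve's endpoints, ties to the smaller k. Two geometric
facts follow: the endpoints k_min and k_max can never be selected (their
chord distance is identically zero), so a recoverable planted state count
must be interior to the search range; and because splitting tight clusters
keeps lowering I(k), the rule is a *knee* detector, not a global optimum of
the index.

**Meta-states.** Pooled windowed vectors are centred, reduced to the top m
principal components, whitened, and rotated by symmetric fixed-point ICA
(logcosh contrast, tolerance 1e-8). Reproducibility conventions: each
pattern's largest-magnitude loading is made positive and patterns are
ordered by explained variance. Quartile boundaries for discretisation are
pooled across the whole cohort (not per subject) so meta-state vectors are
comparable between subjects; each weight maps to sign x (quartile of
magnitude), boundary ties to the lower quartile, exact zeros to +1 — an
8-level code in {-4..-1, 1..4} whose L1 geometry gives the span and
total-distance indices their +/-4-per-pattern range.

**Behavioural screens.** Per-state connectivity is the median over a
subject's windows in that state, Fisher-z transformed before correlation;
subjects who never entered a state are absent from that state's screen (in
metric tables they appear with FT = MDT = 0). Two-sided p-values come from
the t distribution with n - 2 degrees of freedom (n - 2 - c with c
covariates, both sides residualised). FDR families are declared explicitly:
the per-state FNC screen corrects across pairs x states x measures (360
with the defaults) even when fewer tests could be run. For state-metric and
meta-state families the package defaults to the literal number of tests
run, with `family_size` configurable where a larger declared family is
wanted.

## What the validation shows — and its limits

The package's tests plant known structure and measure recovery:

- Planted behavioural correlations (rho = 0.24–0.35, n = 80) are
  re-estimated within the sampling bound 2/sqrt(80) with coverage 0.96–0.98
  (measured by simulation).
- A planted rho = 0.35 effect tops its feature's six-measure screen in
  about 93% of replicates. That probability decays with family size — about
  0.82 across a 24-test family and 0.68 across 90 tests — so "the planted
  pair ranks first" is a claim about a single feature's screen, not about
  arbitrarily large families.
- Under the default study conditions (mean dwell 10 TRs against a 31-TR
  window), the elbow criterion recovers the planted four-state repertoire
  in roughly 80% of cohorts, and the majority vote over 20 cohorts is
  stably k = 4. The shortfall from perfect recovery is informative rather
  than a defect: a tapered window nearly three dwell lengths wide mixes
  states within windows, which blurs the cluster-index knee between k = 3,
  4 and 5. Regularising each window's estimate (graphical lasso with
  cross-validated penalty) does not systematically sharpen the knee under
  these conditions.

Problem sizes used by the default test run were chosen to exercise each
claim at the smallest scale where its statistics are meaningful: cohorts of
3–12 subjects for contract tests, 80 subjects for recovery claims, 20
cohorts for model-selection frequency, 1000 replicates for the FDR
expectation bound, and 1e5-timepoint single-state series for
law-of-large-numbers checks.

## Known limitations

- The generator's i.i.d. emissions understate the serial dependence of
  real BOLD; windowed estimates on real data have fewer effective degrees
  of freedom than the nominal window length suggests.
- m, the meta-state dimensionality, is a convention (default 4); the
  indices' scales change with m, so only within-cohort comparisons at
  fixed m are meaningful.
- The elbow rule cannot select the endpoints of the k range, and close
  repertoires (states sharing most of their structure) will be merged at
  short dwell times.
- Partial-correlation adjustment assumes linear covariate effects; no
  mixed models or site harmonisation are provided.
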