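---
title: "Maintenance and manipulation networks in working memory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maintenance and manipulation networks in working memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmnet)
```

## The task and its two demand codes

`wmnet` analyzes a delayed recognition alphabetization task (DRAT): a
subject encodes an array of 3--9 distinct consonants, mentally alphabetizes
it across a 5 s delay, and answers a letter--position probe. Two demands
operate concurrently on every trial:

* **Set size** — the number of letters, indexing *maintenance* load. Each
  subject is titrated to four consecutive sizes (relative levels 1--4)
  starting at their individual "Very Easy" size.
* **Sorting steps** — the minimum number of reordering operations needed to
  alphabetize the array, indexing *manipulation* load. It is the minimum
  over four counting rules: insertion, selection, merge-insertion and
  merge-selection.

The counting rules had to be pinned down precisely because "one step" is
underdetermined by prose descriptions of the algorithms. The package's
rules are:

* *insertion*: one step per element that is not a left-to-right running
  maximum — i.e. per element that must be extracted and reinserted into the
  sorted prefix. Elements already in relative order cost nothing.
* *selection*: one step per executed swap placing the alphabetically
  earliest remaining letter into position; swaps onto an already-correct
  position cost nothing. This equals `n - #cycles` of the sorting
  permutation, which is also the minimum transposition distance — the basis
  of one independent test oracle.
* *merge variants*: split at `ceiling(n/2)`, apply the base rule within
  each half, and charge one step per element of the second half merged in
  while the first half is non-empty. The combine charge is a visible-move
  count; no canonical cost exists, so this is a documented assumption.

Tests verify the selection rule exhaustively against breadth-first search
over all permutations up to n = 6, and the insertion rule against the
`n - LIS` remove-and-reinsert oracle.

## Titration

The screening stage is a staircase (+1 set size after a correct answer,
-2 after an error, clamped to the 3--9 stimulus range). Accuracy by size is
fitted with a logistic sigmoid with fixed asymptotes 1.0 and 0.5,

$$acc(s) = 0.5 + \frac{0.5}{1 + e^{(s - m)/k}},$$

after pinning low-trial sizes (fewer than 10 trials) at 50% and appending
peripheral anchors (sizes 1, 2 at 100%; 10, 11 at 50%). The asymptotes are
implied by those anchors. The fit is unweighted least squares; whether the
original analysis weighted by trial count is unknown, and the unweighted
choice is deliberate and simple. The *criterion* is the continuous size at
which the fitted curve crosses 82% accuracy; the two integer sizes with
fitted accuracy immediately above it become Very Easy and Easy, and the
next two Medium and Hard. The staircase is described in its source as
"2-down-1-up" while the quoted update rule is +1/-2; the package
implements the quoted rule and does not interpret the name.

## The synthetic cohort

No raw data are public, so the package ships a generator whose defaults
*are* the study conditions: 41 subjects (starting sizes 12/19/9/1 across
3--6), 4 runs x 30 trials, probe mix 40/40/20, 3 s array / 5 s delay / 4 s
probe window, truncated-exponential ITIs with ~5 s mean on [2, 10] s after
a 2 s lead-in, 254 volumes per run at TR = 2 s. Thirty trials at ~17 s do
not always fit 508 s, so ITIs are scaled down on the rare overruns; the
realized mean ITI stays close to 5 s. Non-response trials occur at random
at a 1.6% rate and are excluded from every analysis.

### Stimulus selection

Two printed statistics jointly constrain how stimuli must have been
sampled: the pooled correlation between absolute set size and sorting
steps (r = 0.51) and the collinearity of the two convolved parametric
regressors (VIF ~ 2.5, implying a within-run demand-code correlation near
0.7). Uniform random arrays produce r ~ 0.78 — both statistics cannot come
from unconstrained sampling. The generator therefore uses
*difficulty-standardized* selection: for each trial it draws 16 candidate
arrays and keeps the one whose minimum sorting steps is closest to a
target drawn from N(1 + level - 1.6 (start - 4), 2.0). Steps track
*relative* difficulty rather than absolute array size; the starting-size
term compensates the wider achievable step range of larger arrays. With
these values, measured across seeds: pooled r = 0.53 +/- 0.01, mean VIF
2.52/2.51 — inside both observed bands. These four numbers were fixed once
by calibration against the two printed statistics and are not free knobs.

### Behavior

Accuracy is Bernoulli with logit
$(\beta_0{+}u_0) + (\beta_1{+}u_1)\,level + (\beta_2{+}u_2)\,steps +
\beta_3\,level{\times}steps$ with fixed effects (4.10, -0.94, -0.49, 0.11);
RT is the linear analogue (1129.17, 284.36, 89.22, -29.14 ms) with a 350 ms
Gaussian residual, truncated at the 4000 ms response window. Covariate
coding is raw: level 1--4, steps uncentered — an assumption, since the
original coding is not stated. Random-effect SDs (0.60/0.15/0.10 logit;
150/40/20 ms) were chosen once as plausible between-subject spread; they
matter only for the mixed-model recovery tests, which compare estimates to
the generating values in SE units.

### BOLD

Each of 471 abstract ROIs (no atlas geometry) gets, per run, a 254-volume
series composed of:

* **task activation** on the 46 network nodes: HRF-convolved delay events
  with amplitude `0.15 + 0.25*level` (maintenance nodes) or
  `0.15 + 0.20*steps` (manipulation nodes);
* **within-network coupling**: a per-network latent series built from
  per-trial innovations, with positive lognormal node loadings
  (w = 0.95 maintenance, 0.60 manipulation, 25% jitter);
* **mean between-network coupling**: the two networks' innovations
  correlate at `rho(level) = -0.15 - 0.20 (level - 1)` — negative at every
  level, more negative at harder levels, identical for all subjects;
* **reconfiguration structure**: a gain-scaled, *level-specific* coupling
  pattern (zero mean across edges) plus a stable signed-loading global
  latent. The subject's reconfiguration gain rises with their criterion
  (slope 0.6, residual SD 0.25);
* **noise**: AR(1) innovations (phi = 0.3, SD 1) plus weak linear leakage
  of 8 smooth confound series (6 motion + WM + CSF random walks).

Latent innovation series are sample-orthogonalized to each run's demand
codes. Coupling noise is demand-independent by assumption; enforcing exact
orthogonality in the finite 30-trial runs keeps it from contaminating the
parametric activation estimates, which would otherwise dominate the
between-subject coefficient variance.

Two structural points were forced by the estimator itself, and are worth
recording. First, if the *mean* coupling decline scaled with the subject's
gain, rank-based state similarity would *increase* with gain (stronger
shared edge pattern), putting the reconfiguration--criterion correlation in
the wrong direction; the decline is therefore common to all subjects and
the gain instead scales the level-specific pattern component. Second,
without a stable gain-free edge pattern, leakage of each condition's
estimate into the others makes gain again raise state similarity; the
global latent supplies that stable baseline, which the gain-scaled pattern
then dilutes. Calibrated against the printed connectivity ranges, the
generator yields within-network cPPI means ~0.22 (maintenance) and ~0.12
(manipulation), a between-network mean of ~ -0.05 declining with level,
and a reconfiguration--criterion correlation near +0.7 at 12 subjects.

The structural generator writes symmetric FA matrices over the 46 nodes
with within-block mean 0.45, between-block 0.35, noise SD 0.03, clipped to
[0, 1].

## First-level GLM and diagnostics

Events (array 3 s, delay 5 s, response with RT duration; incorrect and
non-response trials duplicated as separate regressors) are placed on a
0.1 s microtime grid, convolved with a canonical double-gamma HRF (peak
6 s, undershoot 16 s, ratio 1/6, 32 s kernel), and sampled at volume
onsets. The two parametric delay modulators are mean-centered per run
*before* convolution and residualized against the convolved unmodulated
delay regressor *after* convolution (orthogonalization after convolution
is the software-convention choice). OLS is fitted per ROI per run with
confounds as nuisance columns; runs combine by inverse-variance fixed
effects, subjects by a one-sample t per ROI converted to z (capped at
+/-38 so zero-variance synthetic cases stay finite). VIF for a modulator is
1/(1 - R^2) against all other task columns, averaged across runs.
Prewhitening is deliberately absent: the generator's AR(1) is mild and the
group inference operates on subject-level coefficients, so null
calibration holds (tests assert a 3--7% false-positive band at |z| > 1.96).

## Networks, connectivity, and derived statistics

Equal-size networks take the top `floor(fraction * n_rois)` ROIs per
effect (5% of 471 = 23; `floor` reproduces that count where round-half-even
would give 24). If an ROI tops both lists it is assigned to the
larger-z effect and the other list backfills — an invented rule, needed
only in synthetic corner cases since disjoint truth communities make
overlap rare.

Task-state connectivity is correlational PPI: for nodes i, j the PPI terms
(demeaned timecourse x demeaned condition regressor) are correlated after
removing the condition regressor, both raw timecourses, and the 8 confound
columns; no deconvolution step is applied, matching the source method
description. Condition regressors are unmodulated delay events of one
level's trials (set-size level, or sorting-steps quartile after
within-subject rebinning to four equal-count levels — the "interpolation"
to equal trial counts is implemented as stable quartile binning). Each of
the 8 conditions is estimated per run and averaged across runs by Fisher
z. The implementation computes all pairs via Gram matrices after common
nuisance projection; tests pin it to a naive per-pair joint
residualization oracle at 1e-10.

From each condition matrix: mean within-network correlation per network
(upper triangle), signed mean between-network correlation (full cross
block), and

$$Segregation = \frac{\bar Z_w - \bar Z_b}{\bar Z_w},$$

with the signed between mean used in the ratio (the printed equation wins
over prose mentioning magnitudes; a magnitude variant and a node-level
variant are both exported). Reconfiguration across the four states of one
demand type is

$$1 - \frac{1}{n(n-1)} \sum_{x \neq y} \rho_{x,y}$$

with Spearman state similarities on a connection subset (between-network
block, or either within-network triangle); Pearson is available as an
option. Between-network reconfiguration is correlated with the criterion
across subjects (Pearson, with a Fisher r-to-z comparison between two
correlations on the same sample), and difficulty trends use a linear mixed
model with subject intercepts and a likelihood-ratio test of the level
term.

## Problem sizes and degenerate inputs

Tests and examples run at desk scale by choice: property suites use 60-ROI
parcellations with the same 23+23 truth communities and 12-subject
cohorts over 20 seeds; behavioral recovery uses full 41-subject cohorts
over 20 seeds; null calibration uses a 1046-ROI single cohort. Degenerate
inputs are first-class: all-zero design columns are dropped with a
warning, rank-deficient designs name their collinear columns, constant
timecourses flag their matrix entries as NA, a steps distribution with a
single value refuses to rebin, and a psychometric curve that never crosses
criterion refuses to titrate.

## What passing tests do and do not show

The generator emulates the *statistical structure* the analysis assumes —
titrated difficulty, the two correlated demand codes, concurrent
parametric activation, positive within / negative difficulty-scaled
between coupling, criterion-linked reconfiguration — not real BOLD. It has
no voxel geometry, no physiological noise beyond AR(1) + confound leakage,
no distance structure, and its non-network ROIs are pure noise. Green
tests therefore certify that the estimators recover what the generative
model puts in, at the study's dimensions; they do not certify the original
neural claims, which would require the unavailable cohort.
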