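---
title: "Directed transfer function connectivity: model, estimation and validation"
author: "dtfconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed transfer function connectivity: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtfconn)
```

## The problem and the model

Scalp EEG records the joint activity of many cortical sources at a few
electrodes. *Effective* connectivity asks a directed question of those
recordings: how strongly does activity at one channel drive activity at
another, and at which frequencies? This package implements the classic
parametric answer. A multichannel epoch $x(t) \in \mathbb{R}^k$ is modelled
as a stationary multivariate autoregressive (MVAR) process,

$$x(t) = \sum_{\ell=1}^{p} A_\ell\, x(t-\ell) + e(t),$$

with white Gaussian innovations $e(t)$. In the frequency domain the model
factorizes through the transfer matrix
$H(f) = \bar{A}(f)^{-1}$ with
$\bar{A}(f) = I - \sum_\ell A_\ell e^{-i 2\pi f \ell / f_s}$, and the
normalized squared directed transfer function

$$\gamma^2_{i \leftarrow j}(f) =
  \frac{|H_{ij}(f)|^2}{\sum_{m=1}^{k} |H_{im}(f)|^2}$$

measures the share of the total inflow to channel $i$ at frequency $f$
that originates from channel $j$. By construction each target row sums to
one at every frequency; this identity is asserted in the test suite for
random stable models and holds to machine precision.

The pipeline follows the short-time strategy standard for resting EEG:
many short (2 s) artifact-free epochs are treated as quasi-stationary
realizations of one process. Each epoch is fitted separately, the DTF is
aggregated into bands per epoch, and the subject-level statistic is the
element-wise *median* across epochs, which is robust to occasional
ill-conditioned epoch fits.

## Estimation choices

**Least squares, not normal equations.** `fitMVAR()` solves the stacked
lagged regression by an economy QR decomposition. The innovations
covariance uses the residual cross-product divided by $N - pk$
($N = T - p$); the Schwarz-criterion path uses the maximum-likelihood
divisor $N$ instead, as the criterion requires.

**Order selection.** `sbcScore()` implements
$\mathrm{SBC}(p) = \ln\det\hat\Sigma_e(p) + \frac{\ln N}{N}\,p k^2$ with a
common sample span $N = T - p_{\max}$ across candidate orders, so that
scores are comparable. `selectOrder()` minimizes per epoch over a default
range of 2–15 and takes the median across epochs (ties toward the smaller
order): one order per subject. The upper default of 15 keeps the parameter
count $pk^2$ under roughly a fifth of the available data points for
$k = 19$ channels and 1000-sample epochs. On simulated order-3 processes
the median-SBC rule recovers the true order in essentially every
replicate (see `test-acceptance.R`).

**Stability.** `checkStability()` returns the spectral radius of the
$pk \times pk$ companion matrix. Ground-truth networks must be stable at
construction (an unstable specification is an error unless `autoScale`
shrinks it to radius 0.95); fitted models only trigger a warning, since a
radius marginally above one can occur on short epochs and the caller
should decide.

**Structural zeros.** When every $A_\ell$ is triangular, $H(f)$ is
triangular too. A general pivoted solver can leave $O(10^{-16})$ residue
in those structurally-zero entries; the transfer-function code therefore
detects triangular coefficient stacks and inverts by substitution, so that
"no coupling" yields $\gamma^2 = 0$ exactly. Everything else goes through
the general complex solver, and a singular $\bar A(f)$ is reported with
the offending frequency.

## Frequency grid and bands

DTF is evaluated every 0.5 Hz from 1 to 50 Hz. Band aggregation takes the
mean of $\gamma^2$ over half-open intervals $[lo, hi)$ — delta 0.5–4,
theta 4–8, alpha 8–12, beta 12–30, broadband 0.5–30 Hz — so shared
boundaries (4, 8, 12 Hz) are never double-counted. Two consequences are
worth stating prominently:

* the nominal 0.5 Hz lower edge of delta and broadband falls below the
  grid, so both effectively begin at 1 Hz;
* the gamma range (30–50 Hz) lies on the grid but belongs to no band and
  is excluded from every downstream statistic, reflecting the common
  concern that scalp gamma is contaminated by muscle artifact.

Whether $\gamma$ or $\gamma^2$ is averaged within a band is a genuinely
open convention; this package averages $\gamma^2$ (the quantity whose
rows are normalized) and exposes a median-over-bins option.

## Permutation pruning

Estimated DTF is biased upward: finite-sample fits produce nonzero flow
everywhere. Each ordered channel pair is therefore tested against a
surrogate null. A surrogate epoch set permutes the *epoch order of each
channel independently*, which destroys cross-channel temporal alignment
while preserving every per-channel spectrum; the full fit-DTF-band-median
pipeline is re-run on each surrogate. The one-sided p-value uses the
add-one estimator $p = (1 + \#\{\text{surrogate} \ge
\text{observed}\})/(1 + n_{\mathrm{perm}})$, and entries with
$p \ge \alpha$ are set to exactly zero *before* node grouping. With fewer
than 19 surrogates no entry could ever reach $p < 0.05$, so that is an
error. The default is 500 surrogates; calibration runs in the test suite
use 200 (19 channels) and 100 (compact montage), where the measured null
survival rate is at the nominal level.

The order of operations — test the epoch-median statistic, prune, then
group into nodes — is one of several defensible readings of
"prune, then take medians"; it is fixed here because pruning the subject
statistic (rather than individual epochs) matches the one-number-per-edge
logic of the significance test. No multiple-testing correction is applied
at the pruning stage; correction enters only at the group-comparison
stage.

## Nodes and flow summaries

The 19 channels of the 10–20 montage are partitioned into seven anatomical
nodes (left/right frontal, left/right temporal, left/right
parieto-occipital, midline). Node-level connectivity is the *mean* of the
pruned channel-level values over member pairs — a sum would conflate node
sizes (3, 3, 2, 3, 3, 2, 3 channels). Within-node entries are stored but
excluded from summaries. For node $N$, inflow is the sum of off-diagonal
entries directed toward $N$, outflow the sum directed away, and nodal
strength their sum; the totals of inflow and outflow over nodes are equal
by construction, which the tests assert.

## Group comparison

Subjects — not epochs — are the unit of comparison, to avoid
pseudoreplication; each subject contributes one number per (band, node,
direction). `rankSumExact()` computes the two-sided Wilcoxon rank-sum
p-value by full enumeration of all $\binom{n_x+n_y}{n_x}$ rank
assignments whenever the combined sample size is at most 20, using
mid-ranks, so the enumeration is valid with and without ties; larger
samples fall back to the tie-corrected normal approximation. Bonferroni
correction is applied over the family of all (band, node) cells within a
direction, $m = 5 \times 7 = 35$ by default, and $m$ is configurable.

A small-sample caveat the package makes explicit: with six subjects per
group the most extreme exact two-sided p-value is $2/\binom{12}{6}
\approx 0.0022$, so with $m = 35$ no cell can reach Bonferroni-corrected
significance at $\alpha = 0.05$. Studies of this size that report
corrected node-level significance must be using a smaller family (for
example, per-band, $m = 7$). The end-to-end validation therefore runs on
the compact three-node scheme ($m = 15$), where corrected significance is
attainable exactly when the groups separate completely.

## The synthetic cohort generator

Because no clinical recordings ship with the package, every stage is
validated against simulated cohorts with known ground truth. The
generator draws each epoch independently (fresh innovations and a fresh
500-sample burn-in), matching the exchangeability the permutation scheme
assumes, and demeans per channel per epoch. Innovations are white
Gaussian with no $1/f$ shaping — exactly the model class DTF assumes —
and observation noise defaults to zero (the noise-free regime of DTF
theory), with a parameter exposed for robustness experiments.

The control template is a stable order-2 process on the 19-channel
montage (self-regression 0.55 at lag 1 and 0.25 at lag 2, a handful of
weak 0.1 background couplings; spectral radius about 0.85). Responders
share the control topology and differ only by seed. Nonresponders
additionally carry directed lag-1 couplings from the left temporal
channels into the right temporal channels, emulating a profile with
elevated right-temporal inflow and left-temporal outflow. No quantitative
effect size is available for such profiles, so the default weights (0.35
on the full montage, 0.4 on the compact one) were chosen once for
detectability in six-versus-six validation cohorts, not for clinical
realism. Simulated cohorts default to ten controls, six responders and
six nonresponders, 20 epochs of 2 s at 500 Hz per subject.

What passing these simulations shows — and does not show. They verify
that the estimation chain is correct and calibrated for data generated by
its own model class. They do not establish robustness to volume
conduction, reference choice, non-Gaussian or $1/f$ innovations, or
artifacts, none of which the generator emulates.

## Preprocessing and I/O

Recordings are read from EDF (a minimal 16-bit reader/writer is built in;
round-trip error is bounded by one digital quantum per channel). The
band-pass default is 0.5–70 Hz via a fourth-order Butterworth applied
forward-backward: the filter family is a standard clinical choice, and
zero-phase filtering matters because phase distortion would bias directed
estimates. Epoch placement is deterministic earliest-clean given a reject
mask, for reproducibility. Data are used as recorded (no re-referencing):
montage changes alter DTF, and the as-recorded default is flagged to
users as a configuration choice. Channel labels are validated against the
10–20 system, with legacy T3/T4/T5/T6 mapped to T7/T8/P7/P8.

## Numerical and degenerate-input policy

* Constant (zero-variance) channels are an error naming the channel, not
  silently dropped — channel sets define the node scheme.
* A rank-deficient lagged regressor matrix is an error.
* Non-positive-definite ML residual covariance yields an SBC of
  $+\infty$ with a warning, removing that order from contention.
* Order-selection ties round toward the smaller order (parsimony).
* All simulation, surrogate and cohort randomness flows from explicit
  seeds; identical seeds give bit-identical epoch sets and pipeline
  outputs.

## Validation problem sizes

The shipped validation suite uses 20 epochs of 2 s at 500 Hz per subject
throughout; 20-seed Monte-Carlo runs for direction recovery and order
selection; 10 seeds at 200 surrogates for the 19-channel null
calibration; 1000 replicates for rank-sum null calibration; and 20
effect-cohort plus 10 null-cohort replicates (compact montage, 100
surrogates, six subjects per group) for the end-to-end check. These sizes
give the Monte-Carlo acceptance thresholds comfortable margins while
keeping a full run in the minutes range.

## Known limitations

* Coefficients are assumed constant within an epoch; time variation is
  modelled only across epochs. No recursive/Kalman time-varying MVAR.
* No volume-conduction or lead-field modelling; scalp-level DTF does not
  localize sources.
* The gamma band is excluded by design; no graph-theoretic indices
  (efficiency, modularity) are computed.
* Whether clinical recordings were referential or bipolar affects DTF and
  cannot be recovered from the data files alone; the as-recorded default
  is a documented guess.
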