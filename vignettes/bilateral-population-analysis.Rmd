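---
title: "Dedicated and distributed arm coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dedicated and distributed arm coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilatpop)
```

## The scientific question

During a unimanual reach, motor cortical populations in *both*
hemispheres are active. Two organizational schemes can make the moving
arm decodable from such bilateral activity. Signals may consolidate in
**dedicated** sub-populations — units modulated almost exclusively for
one arm — so that the active sub-population itself identifies the arm.
Alternatively, signals for the two arms may be **distributed** across the
same units while occupying distinct (or shared) low-dimensional
subspaces of the population state space. `bilatpop` implements the
single-unit metrics, subspace geometry, decoding analyses and restricted
permutation inference needed to separate these two components in
bilateral premotor (PMd) and primary motor (M1) recordings collected
during an instructed-delay reaching task, together with a synthetic
session generator that embeds both components with known ground truth.

## Task structure and preprocessing

The task model is a blocked, unimanual, instructed-delay reach: a 500 ms
Rest hold with both hands at start targets, an instruction cue visible
for a delay drawn uniformly from 0.5–1.5 s, and a Move epoch that begins
when the reaching hand's speed crosses 10 cm/s. Hand assignments
alternate in blocks of two trials per target per arm, over six targets
and up to three stationary-hand start configurations (both-center,
left-eccentric, right-eccentric). The start configurations matter
analytically: whenever arm preference and modulation enter an analysis
jointly, they are computed from **different** configurations so that
sampling noise cannot couple them (`independent_metrics()`).

Spike preprocessing follows a fixed chain, in this order:

1. counts in non-overlapping 20 ms bins (a 50 Hz series, samples at bin
   centers);
2. square-root transform (variance stabilization for Poisson-like
   counts);
3. convolution with a Gaussian kernel, $\sigma = 50$ ms.

The kernel is truncated at $\pm 3\sigma$ and renormalized to unit mass,
including at the edges of the session trace, so constants are fixed
points of the smoothing and window edges are uncontaminated; smoothing is
applied to the full session trace before any windowing. Soft
normalization then maps each unit's rate $x_t$ to

$$z_t = \frac{x_t - \mu_{\mathrm{Rest}}}{\sigma_{\mathrm{Rest}} + 1},$$

where $\mu_{\mathrm{Rest}}$ pools the Rest-window samples of both arms
and $\sigma_{\mathrm{Rest}}$ is the mean of the two per-arm Rest
standard deviations. The per-arm rule matters because a blocked schedule
induces small arm-predictive offsets during Rest; computing the spread
within each arm keeps those offsets out of the denominator. (The
per-arm-versus-pooled choice is only specified for the standard
deviation; we pool the mean, which is the natural reading and makes
$z = 0$ the grand Rest state.) The constant 1 keeps the denominator at
least 1, so units silent at rest cannot blow up. An alternative
normalization (`mode = "range"`) divides by the unit's full firing-rate
range plus 5, de-emphasizing strongly modulated units; it is used as a
robustness check, not as the default.

Phase windows are 300 ms, edge-inclusive, hence exactly 16 samples at
50 Hz: Rest is the final 300 ms before the cue, Instruct is 200–500 ms
after the cue (the steady-state delay response), Move is the first
300 ms after movement onset. Alignment events are snapped to the nearest
bin center, which guarantees the 16-sample invariant for any event time.

Movement onset is the first post-go sample with hand speed above
10 cm/s; a reach ends at the first later sample where speed has dropped
below 20 cm/s *and* depth-axis velocity has reached zero, interpreted as
the first zero crossing or sign change because exact equality is
measure-zero on sampled data. Kinematics are smoothed per coordinate
with a cubic penalized-least-squares smoother on the uniform 240 Hz
sample grid (a banded second-difference penalty, the discrete equivalent
of the cubic smoothing spline), with smoothing parameter $p$ in the
convention where $p = 1$ interpolates and $p \to 0$ approaches a
straight line; the penalty weight is $(1-p)/p$ on the sample grid and
the default is $p = 0.005$, roughly a 15 ms equivalent bandwidth.
Duplicate units — full-session rate correlation above 0.9 within two
channels on the same probe — are reduced to a single member per pair.

## Single-unit metrics

Modulation is the mean squared soft-normalized rate over the
concatenated 16-sample windows of a phase,

$$M_{\mathrm{phase}} = \frac{1}{(\sigma_{\mathrm{Rest}}+1)^2}
  \,\mathbb{E}\!\left[(X_{\mathrm{phase}} - \mu_{\mathrm{Rest}})^2\right],$$

a unitless, variance-like score measured about the *Rest* mean, so both
offset shifts and variance increases count. Arm preference contrasts the
two arms' modulation,

$$AP = \frac{M_{\mathrm{contra}} - M_{\mathrm{ipsi}}}
            {M_{\mathrm{contra}} + M_{\mathrm{ipsi}}} \in [-1, 1],$$

with $+1$ meaning exclusively contralateral modulation. Any per-unit
normalization constant cancels between numerator and denominator, so
$AP$ is invariant to the normalization choice; when both modulations are
zero the preference is undefined and the unit is excluded from
preference-indexed analyses (and counted in reports). Units are pooled
across hemispheres by mapping each unit's hemisphere to its
contralateral arm.

Population summaries built on these metrics: the log-linear regression
of $\log_{10} M_{\mathrm{preferred}}$ on $|AP|$ within contra- and
ipsi-preferring subgroups (slope 1 = an order of magnitude from
arm-neutral to arm-dedicated; units weighted equally, bootstrap CI over
units), the cumulative-modulation curve over the sorted preference
spectrum, and the proportion of modulation inside the three regimes
contra-dedicated ($AP > 0.4$), ipsi-dedicated ($AP < -0.4$) and neutral
($-0.3 < AP < 0.3$), with the two gap bands completing the partition.
Significant modulation per unit and arm is flagged by a two-sample
t-test of per-trial means of the modulation time course $z_t^2$ between
a phase window and the Rest window, at $p < 0.05$.

## Subspace geometry

All population analyses operate on the $(16m \times n)$ matrix of $m$
concatenated trials by $n$ simultaneously recorded units. Because the
Rest mean is already subtracted by soft normalization, the data are
**not** re-centered before the singular value decomposition; captured
variance is nevertheless computed from the covariance of the component
scores, $V = \mathrm{Tr}(\mathrm{Cov}(XP))$, so means cannot inflate it.
Component signs follow a deterministic convention (largest-magnitude
coefficient positive); every downstream statistic is sign-invariant.

**Dimensionality** is selected by cross-validated reconstruction. For
each candidate $p$, each trial $i$ is left out, a $p$-dimensional model
is fit to the rest, and each unit $j$ of the held-out trial is
reconstructed from the other $n-1$ units: scores are estimated through
the Moore–Penrose pseudoinverse of the row-deleted coefficient matrix
and back-projected,
$\hat{X}^{(i)}_j = [\,P^{(-i)} (P^{(-i)}_{-j})^{+} (X^{(i)}_{-j})^{\top}]_j$.
The predicted residual error sum of squares (PRESS) accumulates the
squared errors and the selected dimensionality minimizes it. Nothing in
the construction rewards higher $p$, so the estimate is conservative.
The inner pseudoinverse exploits orthonormality: deleting row $j$ leaves
$P^\top P = I - p_j p_j^\top$, inverted by a rank-one update, with an
SVD fallback when $\lVert p_j\rVert \to 1$ (a unit owning a whole
component); the two routes agree to $10^{-10}$ and the update is only a
speed device. Pseudoinverse singular values below $10^{-10}$ of the
largest are treated as zero. Estimation uses centered-start-configuration
trials only. We focus on $p = 4$ components for all alignment and
distributed-subspace analyses (dimensionality estimates on both real and
synthetic data concentrate around 3–5); $p$ is configurable everywhere.

**Covariance alignment** measures how much of one dataset's
low-dimensional variance lives in another's low-dimensional subspace:

$$CA = \frac{\mathrm{Tr}(\mathrm{Cov}(X_A P_A P_A^\top P_B))}
            {\mathrm{Tr}(\mathrm{Cov}(X_A P_A))} \in [0, 1].$$

The double projection in the numerator is the defining feature: it
traces the *low-dimensional* representation of $A$ through $B$'s
subspace rather than comparing raw captured variances, so identical
organization gives exactly 1 regardless of signal magnitude and
orthogonal reorganization gives exactly 0. *Native* alignment (random
trial halves of one arm, all three start configurations pooled) sets the
estimation-noise ceiling; *cross* alignment (models fit per arm)
measures the divergence of the arms' subspaces. Both are Monte-Carlo
averaged over random partitions — 25 by default, enough to hold the
partition-noise standard error below about 0.02 CA units on synthetic
benchmarks — and over both projection directions (cross alignment is
reported per direction and as their mean; the directions agree closely
on synthetic data). Odd trial counts drop one trial at random per
partition. The time-resolved variant fits separate models to single
20 ms samples at every timepoint on disjoint random halves and evaluates
CA for every timepoint pair; block-diagonal structure in the resulting
map is the signature of phase-specific subspaces.

**Component structure.** For a single component $P_C$ evaluated on
held-out data, the right/left variance ratio
$V_{C,R/L} = \mathrm{Var}(X_R P_C)/\mathrm{Var}(X_L P_C)$ captures its
contribution to arm discrimination (reported on a log scale), and the
coefficient-weighted arm preference
$CAP_C = \sum_i A_i |P_{C,i}| / \sum_i |P_{C,i}|$ captures its
dependence on arm-dedicated units ($A$ from a held-out dataset). A
strong association between the two across components means subspace
separation rides on dedicated units. The **distributed subspace** is
probed conservatively: the population is split by preferred arm (from
held-out data; exact ties broken to the contralateral arm and flagged),
a 4-D model is fit to each subgroup's activity during *non-preferred*-arm
trials — trials on which dedicated activity is absent by definition —
and the raw captured variances of held-out non-preferred and preferred
trials are compared as the ratio non-preferred/preferred. Shared
structure with equal engagement gives a ratio near 1; purely
arm-specific structure leaves preferred-arm activity in the null space
and pushes the ratio far above 1; stronger preferred-arm engagement of a
shared subspace pulls it below 1. Train and test trials come from
different start configurations.

## Decoding

Target and arm classification use a Gaussian discriminant with one mean
per class, a single pooled within-class covariance, and uniform priors,
fit separately per arm so each arm gets its own covariance. Features are
one value per unit per trial: a 300 ms window mean for phase-level
models, a single 20 ms sample for time-resolved models. When units
outnumber trials the pooled covariance is singular and a small diagonal
shrinkage (coefficient 0.05 toward the average within-class variance) is
applied with a warning. Cross-temporal matrices are leave-one-out: a
model trained at one timepoint classifies the held-out trial at every
timepoint, and the averaged hit booleans form a train-by-test accuracy
map. Chance for balanced classes is $1/K$, and is verified empirically
by label shuffling in the test suite rather than assumed. The Rest-phase
analysis exploits the blocked schedule: classifiers trained on trials
whose arm repeats the previous trial are evaluated on held-out repeat
trials and on switch trials; an expectation-driven Rest state yields
above-chance repeat accuracy and below-chance switch accuracy. The
arm classifier pools all repeat trials with arm as the label (targets as
separate classes are kept for the configuration-crossed variant).

## Permutation and bootstrap inference

Hypothesis tests are permutation-based with restricted exchangeability:
only labels exchangeable under the specific null are permuted, e.g.
Phase labels within units in a crossed unit-by-phase design
(`permute_within_strata()` encapsulates the restriction, and a check
mode asserts per permutation that no label leaves its stratum).
P-values are the proportion of permutations at least as extreme as the
observed statistic — two-sided by absolute value unless declared
one-sided — floored at $1/n_{\mathrm{perm}}$ when the observed value
exceeds every permutation; the default is 10,000 permutations, so the
floor is $10^{-4}$. Factorial designs support main effects, simple
effects within a co-factor level, and interactions. The interaction null
permutes one factor's labels within strata of the other factor crossed
with the resampling unit, and its statistic is the dispersion across
co-factor levels of the centered level-mean profile — sensitive to sign
reversals that an unsigned per-level effect size would miss. Type-I
error of the whole chain is calibrated against generator null sessions
in the test suite. Bootstrap intervals are percentile intervals over the
declared resampling unit (units for slope fits, trials otherwise),
seeded. Ordinary parametric tests (t-tests and friends) are delegated to
`stats`; only the restricted permutation machinery is bespoke.

## The synthetic-session generator

`simulate_session()` produces sessions with the statistical structure
the analyses assume, plus ground truth. Each unit draws a true arm
preference $a \in [-1,1]$ from a mixture of a neutral bulk and
contra-dominant dedicated tails (the contralateral bias is a parameter
of the mixture, not hard-coded). The generative link between preference
and engagement is:

* preferred-arm modulation budget
  $V = V_0 \cdot 10^{s\,|a|}$, with $s$ the configured
  `modulation_slope` and $V_0$ the budget of an arm-neutral unit;
* non-preferred-arm budget $V \cdot (1-|a|)/(1+|a|)$, so the realized
  arm preference equals $a$ exactly;
* a fraction $f$ (`distributed_variance_fraction`) of the
  non-preferred-arm budget rides on **shared** latents whose loading
  vectors are identical for the two arms; the remainder is carried by
  **arm-specific** latents with independent loadings per arm. At
  $|a| = 1$ the non-preferred budget vanishes, so fully dedicated units
  have exactly zero loading on the other arm's latents.

Latents are phase-gated: raised-cosine envelopes rise 100 ms after the
cue and again around movement onset, and by default the Instruct and
Move epochs use independent loading patterns (`split_phases`), which is
what produces the block-diagonal structure of time-resolved alignment
maps; with `split_phases = FALSE` one fixed subspace spans the trial.
Within a bank, each latent carries an orthonormal target tuning (the
first latent is condition-independent — constant over targets — mirroring
the large target-independent component of motor cortical responses), a
mild bounded temporal wobble at a latent-specific frequency so latents
are linearly independent in time, and a geometrically decaying power
spectrum (ratio 0.45, mean power 1) that keeps the ordering of
instantaneous principal components stable within an epoch. Realized
latent scores are orthogonalized across banks on each arm's reference
windows and whitened there, and loadings are drawn as random directions
rescaled so each unit's spectrum-weighted drive power equals its budget
*exactly* — parameter recovery therefore tests the pipeline, not the
generator's sampling noise. Because a whole bank must stay linearly
independent over six targets, at most six latents per bank are allowed.

Noise comes in two fidelities: `"gaussian"` adds i.i.d. noise directly
to the square-root-scale rate samples (fast; used throughout the test
suite), `"poisson"` converts the rate process to spike times (per-bin
Poisson counts with uniform within-bin times, equivalent to 1 ms
thinning for the piecewise-constant rate) which then pass through the
full binning chain. An optional `rest_arm_offset` injects an
arm-predictive population state that follows the *expected* arm (the
previous trial's) before the cue and the actual arm after it,
reproducing the repeat/switch decoding dissociation; it is off by
default so that rank-controlled recovery tests see only the latent
banks. An optional `distributed_pref_gain` scales a unit's shared drive
on preferred-arm trials, emulating stronger preferred-arm engagement of
the shared subspace (ratios below 1).

Kinematics are generated at 240 Hz: the reaching hand follows a
sine-squared speed profile timed so speed crosses 10 cm/s exactly at the
scheduled onset, reaches 8 cm forward to one of six targets, holds, and
returns smoothly; the stationary hand carries stationary AR(1)
positional jitter with configurable mean speed (default 5 mm/s raw,
of the order observed in unrestrained reaching; smoothing reduces the
measured value further). With zero jitter the stationary hand is exactly
still.

What the generator does **not** emulate: biomechanics beyond the speed
profile, EMG, inter-hemispheric dynamics, non-Poisson spiking
statistics, electrode drift, or any systematic relationship between
stationary-hand micromovements and neural activity (a coupling term is
deliberately absent because no default could be justified). Passing
recovery tests on these sessions therefore demonstrates correctness of
the estimators under the assumed structure, not robustness to every
failure mode of real recordings.

## Numerical choices and degenerate inputs

* Gaussian kernel truncated at $\pm 3\sigma$, renormalized to unit mass
  (edge-renormalized, so constants are preserved).
* Alignment events snapped to the nearest bin center before windowing;
  a window of duration $d$ ms yields exactly $d/20 + 1$ samples.
* Pseudoinverse tolerance $10^{-10}$ relative to the largest singular
  value; subspace fits refuse $p$ above the numerical data rank and
  report the achievable rank.
* $CA$ is undefined (NA) when the source dataset has no low-dimensional
  variance; component variance ratios are infinite with a warning when
  the denominator variance is zero; CAP errors on an all-zero
  component; AP is NA when both modulations are zero.
* Exact preferred-arm ties break to the contralateral arm and carry a
  flag.
* Degenerate variance in the modulation flag yields "not significant"
  with a warning rather than an error.
* One master seed per simulated session; every stochastic draw
  (schedule, loadings, noise, kinematics) uses a named substream, so any
  component can be regenerated independently and bit-identically.

## Problem sizes used in the shipped validation

The test suite validates the estimators at deliberately modest sizes,
chosen so the full suite runs in minutes on one core while leaving the
statistical margins comfortable: 16–60 units and 12–72 trials per arm
for recovery tests; 20 seeded sessions for the dimensionality-recovery
rate; 200 null sessions (500 permutations each) for type-I calibration,
judged against a 99% binomial band; 25 null sessions with 12 trials per
class for chance-level decoding, where leave-one-out pessimism is
negligible; and 1000 random instances for the alignment bound and
scale-invariance properties. Real recordings are an order of magnitude
larger in units and trials; all estimators scale to that regime, only
their validation here is desk-scale.

## Known limitations

* The generator's arm-preference link fixes realized preference equal to
  the drawn preference; misspecification of that link (e.g. preference
  changing across phases within a unit) is not modeled.
* Instruct-epoch latents decay through the first ~100 ms after movement
  onset, so the early Move window transiently contains both epochs'
  structure when `split_phases` is on — as in real data, where phase
  transitions are not instantaneous. Rank-controlled dimensionality
  tests therefore use the single-subspace mode.
* Leave-one-out accuracy is pessimistically biased at very small
  trials-per-class counts; chance-level checks use enough trials for the
  bias to be negligible rather than correcting for it.
* The hierarchical session container is a directory of delimited text
  and JSON; very large sessions would deserve a binary array store.
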