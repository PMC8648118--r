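# bilatpop

Analysis of bilateral motor cortical population recordings during
unimanual reaching: how do premotor (PMd) and primary motor (M1)
populations in *both* hemispheres carry signals for the two arms?

Two organizational schemes can separate the arms' signals. A
**dedicated** component consolidates activity in units modulated almost
exclusively for one arm, so the active sub-population itself identifies
the arm. A **distributed** component mixes both arms' signals within the
same units, separated (or not) only at the level of population
subspaces. `bilatpop` implements the metrics and population analyses
needed to tell these apart in bilateral instructed-delay reaching
sessions, for systems neuroscientists working with simultaneous
multi-electrode recordings:

* preprocessing: 20 ms binning, square-root transform, 50 ms Gaussian
  smoothing, soft normalization, edge-inclusive 300 ms phase windows,
  duplicate-unit removal, kinematic smoothing and movement-onset
  detection;
* single-unit metrics: modulation
  `M = E[(x − μ_Rest)²] / (σ_Rest + 1)²` and arm preference
  `AP = (M_contra − M_ipsi) / (M_contra + M_ipsi)`, log-linear
  slope fits of `log10 M_pref` on `|AP|`, cumulative-modulation curves,
  regime proportions, modulation significance flags;
* subspace geometry: PCA by SVD (no re-centering beyond the rest-mean
  subtraction), cross-validated PRESS dimensionality with
  leave-one-trial × leave-one-unit reconstruction through the
  Moore–Penrose pseudoinverse, covariance alignment
  `CA = Tr(Cov(X_A P_A P_Aᵀ P_B)) / Tr(Cov(X_A P_A))` with its defining
  double projection, native/cross alignment, timepoint-pair alignment
  heatmaps, per-component variance ratios, coefficient-weighted arm
  preference `CAP = Σ A_i |P_i| / Σ |P_i|`, and distributed-subspace
  variance ratios;
* decoding: pooled-covariance linear discriminants with uniform priors,
  per arm, leave-one-out cross-temporal accuracy matrices, and
  repeat/switch Rest-phase classification;
* inference: restricted-exchangeability permutation tests (main, simple
  and interaction effects), p-values floored at `1/n_perm`, and seeded
  percentile bootstrap;
* a synthetic-session generator with exact per-unit variance budgets and
  full ground truth (true arm preferences, latent loadings, per-phase
  dimensionality) for parameter-recovery validation.

Results come back as tibbles (with `tidy()`/`glance()` methods for
fitted objects) and every result type has an `autoplot()` method.

## Worked example

Simulate a session with known structure, preprocess it, and run the core
analyses:

```r
library(bilatpop)

cfg <- sim_config(n_units_per_group = 10, trials_per_target_per_arm = 3,
                  start_configurations = 2, seed = 1)
session <- simulate_session(cfg, kinematics = FALSE)
session
#> <bilat_session> 40 units, 72 trials (gaussian mode)
#>   configurations: centered, left_ecc

prep <- preprocess_session(session)

# arm preference from one start configuration, modulation from the other
metrics <- independent_metrics(prep$z, session$trials, session$units,
                               "move", ap_configs = "centered",
                               m_configs = "left_ecc")
fit <- fit_loglinear_slope(metrics, subgroup = "contra", n_boot = 500)
fit
#> <slope_fit> contra-preferring units (n = 19)
#>   slope 0.983, intercept -0.276, 95% CI [0.960, 1.002]
```

The generator was configured with `modulation_slope = 1` (its default):
an order-of-magnitude increase in preferred-arm modulation from
arm-neutral to arm-dedicated units. The fitted slope of 0.983 with CI
[0.960, 1.002] recovers it.

```r
left  <- extract_phase_windows(prep$z, session$trials, "move", arms = "left")
right <- extract_phase_windows(prep$z, session$trials, "move", arms = "right")
al <- native_cross_alignment(left, right, p = 4, n_partitions = 15, seed = 1)
alignment_summary(al)
#> # A tibble: 3 × 3
#>   kind         mean_ca  sd_ca
#>   <chr>          <dbl>  <dbl>
#> 1 cross         0.0977 0.0200
#> 2 native_left   0.961  0.0152
#> 3 native_right  0.982  0.0154
```

Native alignment near 1 says each arm's subspace is estimated reliably;
cross alignment near 0.1 says the two arms' Move-phase subspaces have
diverged — expected here, because the default generator places most
non-baseline variance in arm-specific (dedicated) latents.

```r
dim_est <- estimate_dimensionality(
  extract_phase_windows(prep$z, session$trials, "move", arms = "left",
                        configs = "centered"), p_range = 1:10)
dim_est
#> <dimensionality_estimate> selected p = 8 (40 units, 18 trials)
```

The PRESS minimum at `p = 8` matches the generator's ground truth
(`session$ground_truth$dimensionality`: four shared plus four dedicated
latents active in the Move window). `autoplot(dim_est)` shows the PRESS
curve, `autoplot(al)` the alignment summary, and
`plot_arm_preference()` the preference distributions.

`run_pipeline()` chains all stages (simulate → preprocess → metrics →
subspace → decode → stats) from a single configuration list with the
canonical constants as defaults, and
`write_session_container()` / `read_session_container()` serialize
sessions as plain-text directories with provenance (config hash and
seed).

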