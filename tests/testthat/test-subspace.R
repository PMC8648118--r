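test_that("subspace models recover principal axes with orthonormal columns", {
  # variance only along the first coordinate axis
  x <- cbind(rnorm(50, 0, 3), matrix(rnorm(50 * 4, 0, 1e-4), ncol = 4))
  m <- fit_subspace(x, 1)
  expect_equal(abs(m$P[, 1]), c(1, 0, 0, 0, 0), tolerance = 1e-3)
  set.seed(8)
  x2 <- lowrank_data(80, 10, 10)
  m2 <- fit_subspace(x2, 4)
  expect_equal(crossprod(m2$P), diag(4), tolerance = 1e-8)
  # deterministic sign: largest coefficient positive
  expect_true(all(apply(m2$P, 2, function(p) p[which.max(abs(p))] > 0)))
  # rank error names the achievable rank
  expect_error(fit_subspace(lowrank_data(40, 8, 2), 5), "rank is 2")
})

test_that("captured variance matches the singular-value identity", {
  set.seed(9)
  x <- lowrank_data(96, 12, 12)
  x <- scale(x, scale = FALSE)       # centred so Cov and SVD align
  m <- fit_subspace(x, 4)
  v <- variance_captured(x, m)
  sv <- svd(x)$d
  expect_equal(v, sum(sv[1:4]^2) / (nrow(x) - 1), tolerance = 1e-10)
  # identity basis captures the total variance
  vi <- variance_captured(x, diag(12))
  expect_equal(vi, sum(apply(x, 2, var)), tolerance = 1e-10)
  # a zero-variance direction captures nothing
  x0 <- cbind(x, 0)
  expect_equal(variance_captured(x0, matrix(c(rep(0, 12), 1))), 0)
  # brute-force covariance oracle on a small case
  x6 <- matrix(rnorm(36), 6, 6)
  p4 <- qr.Q(qr(matrix(rnorm(24), 6, 4)))
  expect_equal(variance_captured(x6, p4),
               sum(diag(cov(x6 %*% p4))), tolerance = 1e-12)
  expect_error(variance_captured(x6, matrix(0, 5, 2)), "units")
})

test_that("left-out-unit reconstruction matches the least-squares oracle", {
  set.seed(10)
  # noiseless rank-3 data: reconstruction is exact for any left-out unit
  w <- matrix(rnorm(3 * 9), nrow = 3)
  x <- matrix(rnorm(64 * 3), ncol = 3) %*% w
  m <- fit_subspace(x, 3)
  xt <- matrix(rnorm(16 * 3), ncol = 3) %*% w   # same latent subspace
  for (j in c(1, 5, 9)) {
    rec <- reconstruct_left_out_unit(m, xt, j)
    expect_lt(max(abs(rec - xt[, j])), 1e-8)
  }
  # agreement with an explicit least-squares solve on noisy data
  xn <- x + matrix(rnorm(length(x), 0, 0.3), nrow(x))
  mn <- fit_subspace(xn, 3)
  xtn <- xt + matrix(rnorm(length(xt), 0, 0.3), nrow(xt))
  for (j in seq_len(9)) {
    rec <- reconstruct_left_out_unit(mn, xtn, j)
    scores <- qr.solve(mn$P[-j, ], t(xtn[, -j, drop = FALSE]))
    oracle <- as.numeric(mn$P[j, , drop = FALSE] %*% scores)
    expect_lt(max(abs(rec - oracle)), 1e-10)
  }
  # a unit with zero loadings reconstructs to zero regardless of its trace
  m0 <- mn
  m0$P[2, ] <- 0
  expect_true(all(reconstruct_left_out_unit(m0, xtn, 2) == 0))
})

test_that("PRESS equals a naive double-loop reimplementation", {
  naive_press <- function(tensor, p) {
    d <- dim(tensor)
    total <- 0
    for (i in seq_len(d[3])) {
      xtr <- tensor_matrix(tensor[, , -i, drop = FALSE])
      pp <- svd(xtr, nu = 0)$v[, seq_len(p), drop = FALSE]
      xte <- t(tensor[, , i])
      for (j in seq_len(d[1])) {
        pm <- pp[-j, , drop = FALSE]
        scores <- svd_pinv(pm) %*% t(xte[, -j, drop = FALSE])
        xhat <- as.numeric(pp[j, , drop = FALSE] %*% scores)
        total <- total + sum((xte[, j] - xhat)^2)
      }
    }
    total
  }
  svd_pinv <- function(a) {
    s <- svd(a)
    s$v %*% ((1 / s$d) * t(s$u))
  }
  set.seed(12)
  tens <- structure(array(rnorm(10 * 16 * 6), dim = c(10, 16, 6)),
                    class = "rate_tensor")
  est <- estimate_dimensionality(tens, p_range = 1:4)
  for (p in 1:4) {
    expect_equal(est$press$press[p], naive_press(tens, p),
                 tolerance = 1e-10)
  }
})

test_that("dimensionality selection is low for noise and permutation invariant", {
  set.seed(13)
  noise <- structure(array(rnorm(12 * 16 * 8), dim = c(12, 16, 8)),
                     class = "rate_tensor")
  est <- estimate_dimensionality(noise, p_range = 1:6)
  expect_lte(est$selected, 2)
  # permuting units leaves the selection unchanged
  perm <- sample(12)
  est2 <- estimate_dimensionality(
    structure(noise[perm, , ], class = "rate_tensor"), p_range = 1:6
  )
  expect_equal(est2$selected, est$selected)
  expect_equal(sort(est2$press$press), sort(est$press$press),
               tolerance = 1e-8)
  expect_error(estimate_dimensionality(noise[, , 1:3], p_range = 1:2),
               "too few trials")
  expect_error(estimate_dimensionality(noise, p_range = 1:20),
               "below the unit count")
})

test_that("covariance alignment satisfies its analytic identities", {
  set.seed(14)
  x <- lowrank_data(80, 10, 3, noise = 0.01)
  m <- fit_subspace(x, 3)
  # identical organization, arbitrary magnitude: alignment is 1
  m_scaled <- fit_subspace(4.2 * x, 3)
  expect_equal(covariance_alignment(x, m, m_scaled), 1, tolerance = 1e-8)
  expect_equal(covariance_alignment(x, m, m), 1, tolerance = 1e-12)
  # orthogonally reorganized activity: alignment is 0
  xa <- cbind(lowrank_data(60, 5, 2), matrix(0, 60, 5))
  xb <- cbind(matrix(0, 60, 5), lowrank_data(60, 5, 2))
  ca0 <- covariance_alignment(xa, fit_subspace(xa, 2), fit_subspace(xb, 2))
  expect_equal(ca0, 0, tolerance = 1e-12)
  # no low-dimensional variance: undefined
  expect_true(is.na(covariance_alignment(matrix(0, 10, 4),
                                         diag(4)[, 1:2], diag(4)[, 3:4])))
  # step-by-step trace computation oracle on a random small case
  pa <- qr.Q(qr(matrix(rnorm(6 * 2), 6)))
  pb <- qr.Q(qr(matrix(rnorm(6 * 2), 6)))
  xr <- matrix(rnorm(60), 10, 6)
  ta <- xr %*% pa
  oracle <- sum(diag(cov(ta %*% t(pa) %*% pb))) / sum(diag(cov(ta)))
  expect_equal(covariance_alignment(xr, pa, pb), oracle, tolerance = 1e-12)
})

test_that("alignment stays within [0,1] and is scale invariant", {
  set.seed(15)
  for (rep in 1:200) {
    n <- sample(5:10, 1)
    p <- sample(2:3, 1)
    xa <- matrix(rnorm(20 * n), 20, n)
    xb <- matrix(rnorm(20 * n), 20, n)
    ma <- fit_subspace(xa, p)
    mb <- fit_subspace(xb, p)
    ca <- covariance_alignment(xa, ma, mb)
    expect_gte(ca, 0)
    expect_lte(ca, 1 + 1e-12)
    c_pos <- runif(1, 0.1, 10)
    expect_equal(covariance_alignment(c_pos * xa, ma, mb), ca,
                 tolerance = 1e-9)
  }
})

test_that("native and cross alignment separate shared from dedicated structure", {
  mk <- function(f, apd) {
    cfg <- sim_config(n_units_per_group = 8, trials_per_target_per_arm = 2,
                      start_configurations = 2,
                      arm_pref_distribution = apd,
                      distributed_variance_fraction = f, seed = 5L)
    s <- simulate_session(cfg, kinematics = FALSE)
    pp <- preprocess_session(s)
    list(
      left = extract_phase_windows(pp$z, s$trials, "move", arms = "left"),
      right = extract_phase_windows(pp$z, s$trials, "move", arms = "right")
    )
  }
  # purely dedicated structure: cross far below native
  ded <- mk(0, list(neutral_sd = 0.15, dedicated_frac = 0.5,
                    dedicated_mean = 0.8, dedicated_sd = 0.08,
                    contra_bias = 0.5))
  al <- native_cross_alignment(ded$left, ded$right, p = 4,
                               n_partitions = 8, seed = 1)
  s1 <- alignment_summary(al)
  native <- mean(s1$mean_ca[s1$kind != "cross"])
  cross <- s1$mean_ca[s1$kind == "cross"]
  expect_lt(cross, native - 0.4)
  # fully shared structure: native and cross agree
  sh <- mk(1, neutral_arm_pref(0.05))
  al2 <- native_cross_alignment(sh$left, sh$right, p = 4,
                                n_partitions = 8, seed = 1)
  s2 <- alignment_summary(al2)
  expect_lt(abs(s2$mean_ca[s2$kind == "cross"] -
                  mean(s2$mean_ca[s2$kind != "cross"])), 0.05)
  # noise-free self comparison: native alignment of a model with itself is 1
  x <- tensor_matrix(ded$left)
  m <- fit_subspace(x, 4)
  expect_equal(covariance_alignment(x, m, m), 1, tolerance = 1e-12)
  tiny <- ded$left[, , 1:3]
  expect_error(
    native_cross_alignment(structure(tiny, class = "rate_tensor"),
                           ded$right, p = 2, n_partitions = 1),
    "too few trials"
  )
})

test_that("timepoint alignment shows blocks only when subspaces switch", {
  mkt <- function(split) {
    cfg <- sim_config(
      n_units_per_group = 6, trials_per_target_per_arm = 10,
      start_configurations = 1, split_phases = split,
      arm_pref_distribution = neutral_arm_pref(0.05),
      modulation_slope = 0, modulation_base = 1.5, noise_sd = 0.15,
      seed = 4L
    )
    s <- simulate_session(cfg, kinematics = FALSE)
    pp <- preprocess_session(s)
    ti <- extract_phase_windows(pp$z, s$trials,
                                list(event = "instruct_onset",
                                     offset = c(0.2, 0.5)), arms = "left")
    tm <- extract_phase_windows(pp$z, s$trials,
                                list(event = "movement_onset",
                                     offset = c(0.1, 0.4)), arms = "left")
    bind_rate_tensors(ti, tm)
  }
  am <- alignment_timecourse(mkt(TRUE), p = 4, n_partitions = 4, seed = 2)
  within <- mean(c(am[1:16, 1:16], am[17:32, 17:32]))
  across <- mean(c(am[1:16, 17:32], am[17:32, 1:16]))
  expect_gt(within, across + 0.3)
  expect_gte(mean(diag(am)), mean(am[row(am) != col(am)]))
  # a fixed subspace across the trial gives a uniform map
  am2 <- alignment_timecourse(mkt(FALSE), p = 4, n_partitions = 4, seed = 2)
  within2 <- mean(c(am2[1:16, 1:16], am2[17:32, 17:32]))
  across2 <- mean(c(am2[1:16, 17:32], am2[17:32, 1:16]))
  expect_lt(abs(within2 - across2), 0.08)
})

test_that("component variance ratios and weighted preferences behave", {
  set.seed(16)
  x <- matrix(rnorm(80), 20, 4)
  pc <- c(1, 0, 0, 0)
  expect_equal(component_variance_ratio(x, x, pc), 1)
  expect_equal(component_variance_ratio(3 * x, x, pc), 9, tolerance = 1e-12)
  expect_warning(
    r <- component_variance_ratio(x, matrix(0, 20, 4), pc),
    "zero denominator"
  )
  expect_true(is.infinite(r))
  # a component aligned with a right-arm-only latent
  lat <- rnorm(20)
  xr <- cbind(lat, matrix(rnorm(60, 0, 0.05), 20, 3))
  xl <- matrix(rnorm(80, 0, 0.05), 20, 4)
  expect_gt(component_variance_ratio(xr, xl, pc), 10)

  expect_equal(coefficient_weighted_arm_preference(c(1, 1, 0.5),
                                                   c(0.4, -0.6, 0)), 1)
  ap_grid <- seq(-1, 1, length.out = 21)
  expect_equal(coefficient_weighted_arm_preference(ap_grid, rep(0.3, 21)),
               0, tolerance = 1e-12)
  expect_equal(coefficient_weighted_arm_preference(c(0.8, -0.2),
                                                   c(0.5, 0.5)), 0.3)
  expect_error(coefficient_weighted_arm_preference(c(1, 0), c(0, 0)),
               "all-zero")
})

test_that("component structure ties variance ratios to dedicated units", {
  cfg <- sim_config(n_units_per_group = 8, trials_per_target_per_arm = 2,
                    start_configurations = 2,
                    arm_pref_distribution = list(
                      neutral_sd = 0.15, dedicated_frac = 0.5,
                      dedicated_mean = 0.8, dedicated_sd = 0.08,
                      contra_bias = 0.5
                    ),
                    distributed_variance_fraction = 0.2, seed = 17L)
  s <- simulate_session(cfg, kinematics = FALSE)
  pp <- preprocess_session(s)
  grab <- function(arm, cfgs) {
    tensor_matrix(extract_phase_windows(pp$z, s$trials, "move",
                                        arms = arm, configs = cfgs))
  }
  ap <- unit_phase_metrics(pp$z, s$trials, s$units, phases = "move",
                           configs = "centered")
  # left/right convention for the component analysis
  ap_lr <- compute_arm_preference(ap$m_right, ap$m_left)
  cs <- component_structure(grab("left", "left_ecc"),
                            grab("right", "left_ecc"),
                            grab("left", "centered"),
                            grab("right", "centered"),
                            ap_lr, p = 4)
  expect_equal(nrow(cs), 8L)
  # arm-discriminating components weight arm-dedicated units:
  # log ratio and coefficient-weighted preference correlate positively
  expect_gt(cor(cs$log10_ratio, cs$cap), 0.4)
})

test_that("distributed-subspace variance ratio separates the three regimes", {
  run_ratio <- function(f, apd, g = 1) {
    cfg <- sim_config(n_units_per_group = 15, trials_per_target_per_arm = 2,
                      start_configurations = 2, arm_pref_distribution = apd,
                      distributed_variance_fraction = f,
                      distributed_pref_gain = g, seed = 5L)
    s <- simulate_session(cfg, kinematics = FALSE)
    pp <- preprocess_session(s)
    mets <- unit_phase_metrics(pp$z, s$trials, s$units, phases = "move",
                               configs = "centered")
    pref <- assign_preferred_arm(mets, s$units)
    tensors <- list(
      left = extract_phase_windows(pp$z, s$trials, "move", arms = "left",
                                   configs = "centered"),
      right = extract_phase_windows(pp$z, s$trials, "move", arms = "right",
                                    configs = "centered"),
      left_test = extract_phase_windows(pp$z, s$trials, "move",
                                        arms = "left", configs = "left_ecc"),
      right_test = extract_phase_windows(pp$z, s$trials, "move",
                                         arms = "right", configs = "left_ecc")
    )
    distributed_subspace_variance_ratio(tensors, pref, p = 4)$ratio
  }
  shared <- run_ratio(1, neutral_arm_pref(0.1))
  expect_true(all(abs(shared - 1) < 0.15))
  dedicated <- run_ratio(0, list(neutral_sd = 0.2, dedicated_frac = 0.5,
                                 dedicated_mean = 0.7, dedicated_sd = 0.1,
                                 contra_bias = 0.5))
  expect_true(all(dedicated > 1.5))
  mixed <- run_ratio(0.5, neutral_arm_pref(0.1), g = 1.6)
  expect_true(all(mixed < 1))
})
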