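test_that("modulation is the mean squared normalized rate", {
  z <- array(rep(c(1, -1), 16), dim = c(1, 16, 2))
  tens <- structure(z, class = "rate_tensor")
  expect_equal(compute_modulation(tens)$modulation, 1)
  z0 <- structure(array(0, dim = c(2, 16, 3)), class = "rate_tensor")
  expect_equal(compute_modulation(z0)$modulation, c(0, 0))
  empty <- structure(array(0, dim = c(2, 16, 0)), class = "rate_tensor")
  expect_error(compute_modulation(empty), "empty window")
})

test_that("modulation equals variance about the rest mean over (sd+1)^2", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(64, mean = 10, sd = 3)          # raw rates
    mu <- 9.5; sdr <- 2.2
    z <- (x - mu) / (sdr + 1)
    tens <- structure(array(z, dim = c(1, 16, 4)), class = "rate_tensor")
    m <- compute_modulation(tens)$modulation
    oracle <- mean((x - mu)^2) / (sdr + 1)^2    # two-pass form
    expect_equal(m, oracle, tolerance = 1e-10)
  }
})

test_that("arm preference identities hold", {
  expect_equal(compute_arm_preference(4, 0), 1)
  expect_equal(compute_arm_preference(0, 3), -1)
  expect_equal(compute_arm_preference(2, 2), 0)
  expect_equal(compute_arm_preference(3, 1), 0.5)
  expect_true(is.na(compute_arm_preference(0, 0)))
  # invariant under common rescaling of the two modulations
  set.seed(2)
  mc <- runif(50); mi <- runif(50)
  expect_equal(compute_arm_preference(mc, mi),
               compute_arm_preference(7.3 * mc, 7.3 * mi))
})

test_that("arm preference is invariant to rescaling all firing rates", {
  s <- fixture_session()
  pp <- fixture_prep()
  ap1 <- unit_phase_metrics(pp$z, s$trials, s$units, phases = "move")
  r2 <- s$rates * 3.7
  attr(r2, "times") <- s$times
  attr(r2, "bin_width") <- s$bin_width
  rs2 <- compute_rest_statistics(r2, s$trials)
  # the per-unit normalization factor cancels between the two arms, so
  # arm preference is exactly invariant even though z itself is not
  z2 <- normalize_rates(r2, rs2)
  m2 <- unit_phase_metrics(z2, s$trials, s$units, phases = "move")
  expect_equal(ap1$arm_pref, m2$arm_pref, tolerance = 1e-10)
})

test_that("preferred-arm assignment uses hold-out modulation with contra ties", {
  units <- tibble::tibble(unit_id = c("a", "b", "c"),
                          hemisphere = c("L", "L", "R"))
  hm <- tibble::tibble(
    unit_id = c("a", "b", "c"), phase = "move",
    m_left = c(2, 1, 3), m_right = c(1, 1, 3)
  )
  out <- assign_preferred_arm(hm, units)
  expect_equal(out$pref_arm, c("left", "right", "left"))
  expect_equal(out$tie, c(FALSE, TRUE, TRUE))
  expect_error(assign_preferred_arm(hm[0, ], units), "hold-out")
})

test_that("log-linear slope behaves like ordinary least squares in log10", {
  set.seed(4)
  n <- 60
  ap <- runif(n, 0.05, 1)
  m <- 10^(0.8 * ap + rnorm(n, 0, 0.05))
  metrics <- tibble::tibble(arm_pref = ap, m_pref = m)
  fit <- fit_loglinear_slope(metrics, "contra", n_boot = 200)
  expect_equal(fit$slope, 0.8, tolerance = 0.1)
  # multiplying modulation by 10 shifts the intercept by 1, slope unchanged
  fit10 <- fit_loglinear_slope(dplyr::mutate(metrics, m_pref = m_pref * 10),
                               "contra", n_boot = 0)
  expect_equal(fit10$slope, fit$slope, tolerance = 1e-10)
  expect_equal(fit10$intercept, fit$intercept + 1, tolerance = 1e-10)
  # no structure: slope near zero, CI covers zero
  set.seed(7)
  m0 <- 10^rnorm(n, 0, 0.2)
  fit0 <- fit_loglinear_slope(tibble::tibble(arm_pref = ap, m_pref = m0),
                              "contra", n_boot = 400, seed = 2)
  expect_lt(fit0$ci[1], 0)
  expect_gt(fit0$ci[2], 0)
  # subgroups with too few units error
  expect_error(
    fit_loglinear_slope(metrics[1:2, ], "contra"),
    "fewer than 3"
  )
  expect_error(fit_loglinear_slope(metrics, "ipsi"), "fewer than 3")
})

test_that("tidiers expose slope fits as tibbles", {
  set.seed(4)
  metrics <- tibble::tibble(arm_pref = runif(20, 0.1, 1),
                            m_pref = runif(20, 0.5, 2))
  fit <- fit_loglinear_slope(metrics, "contra", n_boot = 100)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- glance(fit)
  expect_equal(gl$n_units, 20L)
  expect_lt(gl$conf.low, gl$conf.high)
})

test_that("cumulative modulation curves are monotone and end at one", {
  metrics <- tibble::tibble(
    arm_pref = c(-0.5, 0, 0.3, 1),
    m_contra = c(0, 0, 0, 5), m_ipsi = c(1, 1, 1, 1)
  )
  cc <- cumulative_modulation_curve(metrics, n_boot = 0)
  contra <- cc[cc$arm == "m_contra", ]
  # all contralateral modulation sits at arm preference +1
  expect_equal(contra$cum_prop, c(0, 0, 0, 1))
  ipsi <- cc[cc$arm == "m_ipsi", ]
  expect_equal(ipsi$cum_prop, c(0.25, 0.5, 0.75, 1))
  expect_true(all(diff(contra$cum_prop) >= 0))
  expect_equal(max(cc$cum_prop), 1)
  expect_error(
    cumulative_modulation_curve(
      tibble::tibble(arm_pref = c(0, 1), m_contra = c(0, 0),
                     m_ipsi = c(1, 1)),
      arms = "m_contra", n_boot = 0
    ),
    "total modulation is zero"
  )
})

test_that("regime proportions partition the modulation per arm", {
  metrics <- tibble::tibble(
    arm_pref = c(-0.9, -0.35, 0, 0.35, 0.9),
    m_contra = c(1, 2, 3, 4, 10), m_ipsi = c(5, 4, 3, 2, 1)
  )
  props <- regime_modulation_proportions(metrics)
  sums <- tapply(props$proportion, props$arm, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  # a population entirely at +1 concentrates everything contra-dedicated
  p1 <- regime_modulation_proportions(
    tibble::tibble(arm_pref = rep(1, 4), m_contra = runif(4),
                   m_ipsi = runif(4))
  )
  expect_equal(
    p1$proportion[p1$arm == "m_contra" & p1$regime == "contra_dedicated"], 1
  )
  expect_true(all(props$proportion >= 0 & props$proportion <= 1))
})

test_that("dedicated modulation concentrates more under dedicated structure", {
  run <- function(frac) {
    cfg <- sim_config(
      n_units_per_group = 6, trials_per_target_per_arm = 3,
      start_configurations = 2,
      arm_pref_distribution = list(neutral_sd = 0.15, dedicated_frac = frac,
                                   dedicated_mean = 0.85,
                                   dedicated_sd = 0.05, contra_bias = 1),
      seed = 61L
    )
    s <- simulate_session(cfg, kinematics = FALSE)
    pp <- preprocess_session(s)
    im <- independent_metrics(pp$z, s$trials, s$units, "move",
                              ap_configs = "centered",
                              m_configs = "left_ecc")
    props <- regime_modulation_proportions(im)
    props$proportion[props$arm == "m_contra" &
                       props$regime == "contra_dedicated"]
  }
  expect_gt(run(0.7), run(0.05))
})

test_that("significance flags identify the modulated arm and calibrate", {
  cfg <- sim_config(n_units_per_group = 4, trials_per_target_per_arm = 4,
                    start_configurations = 1,
                    arm_pref_distribution = dedicated_arm_pref(),
                    distributed_variance_fraction = 0,
                    modulation_base = 2, seed = 62L)
  s <- simulate_session(cfg, kinematics = FALSE)
  pp <- preprocess_session(s)
  fl <- flag_significant_modulation(pp$z, s$trials, s$units)
  # contra-dedicated generator: contra flags set, ipsi mostly not
  expect_true(all(fl$sig_contra))
  expect_lt(mean(fl$sig_ipsi), 0.35)
  expect_true(all(fl$category %in% c("contra_only", "bilateral")))
  # bilateral structure flags both arms
  cfgb <- sim_config(n_units_per_group = 4, trials_per_target_per_arm = 4,
                     start_configurations = 1,
                     arm_pref_distribution = neutral_arm_pref(),
                     distributed_variance_fraction = 1,
                     modulation_base = 2, seed = 63L)
  sb <- simulate_session(cfgb, kinematics = FALSE)
  ppb <- preprocess_session(sb)
  flb <- flag_significant_modulation(ppb$z, sb$trials, sb$units)
  expect_gt(mean(flb$category == "bilateral"), 0.8)
  # null sessions flag at roughly the nominal rate
  rates <- unlist(lapply(1:6, function(sd) {
    cfg0 <- sim_config(n_units_per_group = 6, trials_per_target_per_arm = 4,
                       start_configurations = 1, seed = 100L + sd)
    s0 <- simulate_null_session(cfg0)
    pp0 <- preprocess_session(s0)
    f0 <- flag_significant_modulation(pp0$z, s0$trials, s0$units)
    c(f0$sig_contra, f0$sig_ipsi)
  }))
  n <- length(rates)
  band <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(mean(rates), band[1] - 1e-9)
  expect_lte(mean(rates), band[2] + 1e-9)
})
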