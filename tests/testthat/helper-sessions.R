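# Shared fixtures, built once per test run. Sessions are deliberately
# small; tests that need specific structure build their own.

# generic session: 16 units, 2 start configurations, mixed arm prefs
fixture_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_units_per_group = 4,
                        trials_per_target_per_arm = 3,
                        start_configurations = 2, seed = 42L)
      cache <<- simulate_session(cfg, kinematics = FALSE)
    }
    cache
  }
})

fixture_prep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- preprocess_session(fixture_session())
    cache
  }
})

# configuration with no arm-preference structure at all
neutral_arm_pref <- function(sd = 0) {
  list(neutral_sd = sd, dedicated_frac = 0, dedicated_mean = 0.85,
       dedicated_sd = 0.08, contra_bias = 0.8)
}

# all units fully contra-dedicated
dedicated_arm_pref <- function() {
  list(neutral_sd = 0, dedicated_frac = 1, dedicated_mean = 1,
       dedicated_sd = 0, contra_bias = 1)
}

# random low-rank data matrix plus noise, for subspace tests
lowrank_data <- function(n_samples, n_units, rank, noise = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lat <- matrix(rnorm(n_samples * rank), ncol = rank)
  w <- matrix(rnorm(rank * n_units), nrow = rank)
  lat %*% w + if (noise > 0) {
    matrix(rnorm(n_samples * n_units, 0, noise), ncol = n_units)
  } else {
    0
  }
}

# smallest session with kinematics, one trial per target per arm
fixture_kin_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_units_per_group = 2,
                        trials_per_target_per_arm = 1,
                        start_configurations = 1, seed = 7L)
      cache <<- simulate_session(cfg, kinematics = TRUE)
    }
    cache
  }
})
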