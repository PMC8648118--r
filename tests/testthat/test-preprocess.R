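test_that("20 ms binning produces a 50 Hz series with bin-centre timestamps", {
  spikes <- list(u1 = c(0.01, 0.25, 0.50), u2 = numeric(0))
  r <- bin_and_smooth(spikes, t_start = 0, t_end = 1)
  times <- attr(r, "times")
  expect_equal(unique(round(diff(times), 10)), 0.02)
  expect_equal(times[1], 0.01)
  expect_true(all(r[2, ] == 0))        # empty unit: all-zero trace
})

test_that("a regular 50 Hz train is a fixed point of normalized smoothing", {
  spikes <- list(u = seq(0.01, 3.99, by = 0.02))  # one spike per bin
  r <- bin_and_smooth(spikes, t_start = 0, t_end = 3.99)
  expect_true(all(abs(r[1, ] - 1) < 1e-12))
})

test_that("a single spike reproduces the discretized gaussian kernel", {
  spikes <- list(u = 2.005)            # inside the bin centred at 2.01
  r <- bin_and_smooth(spikes, t_start = 0, t_end = 4)
  times <- attr(r, "times")
  centre <- which.min(abs(times - 2.01))
  k <- exp(-((-7:7) * 0.02)^2 / (2 * 0.05^2))
  k <- k / sum(k)
  got <- r[1, (centre - 7):(centre + 7)]
  expect_equal(unname(got), unname(k), tolerance = 1e-10)
  expect_true(all(r[1, seq_len(centre - 8)] == 0))
})

test_that("rest statistics follow the per-arm standard deviation rule", {
  s <- fixture_session()
  pp <- fixture_prep()
  rs <- pp$rest_stats
  expect_equal(rs$sd_rest, (rs$sd_left + rs$sd_right) / 2)
  # doubling all rates doubles both statistics
  r2 <- s$rates * 2
  attr(r2, "times") <- s$times
  attr(r2, "bin_width") <- s$bin_width
  rs2 <- compute_rest_statistics(r2, s$trials)
  expect_equal(rs2$mu_rest, rs$mu_rest * 2)
  expect_equal(rs2$sd_rest, rs$sd_rest * 2)
  # constant trace: mu = c, sd = 0
  rc <- matrix(3.5, nrow = 2, ncol = ncol(s$rates))
  attr(rc, "times") <- s$times
  rsc <- compute_rest_statistics(rc, s$trials)
  expect_equal(rsc$mu_rest, c(3.5, 3.5))
  expect_equal(rsc$sd_rest, c(0, 0))
  # single-arm trial tables are rejected
  expect_error(
    compute_rest_statistics(s$rates, s$trials[s$trials$arm == "left", ]),
    "no right-arm trials"
  )
})

test_that("toy per-arm standard deviations average correctly", {
  # two trials per arm; constant rate within each trial's rest window
  trials <- tibble::tibble(
    trial_id = 1:4, arm = c("left", "left", "right", "right"),
    instruct_onset = c(1, 2, 3, 4)
  )
  times <- seq(0.01, 4.5, by = 0.02)
  x <- numeric(length(times))
  lvl <- c(0, 2, 0, 4)   # left trials {0,2}, right trials {0,4}
  for (i in 1:4) {
    x[times >= trials$instruct_onset[i] - 0.3 &
        times <= trials$instruct_onset[i]] <- lvl[i]
  }
  r <- matrix(x, nrow = 1)
  attr(r, "times") <- times
  rs <- compute_rest_statistics(r, trials)
  k <- sum(times >= trials$instruct_onset[1] - 0.3 &
             times <= trials$instruct_onset[1])   # samples per window
  expect_equal(rs$sd_rest, (sd(c(rep(0, k), rep(2, k))) +
                              sd(c(rep(0, k), rep(4, k)))) / 2,
               tolerance = 1e-6)
})

test_that("soft normalization matches its closed form and never explodes", {
  r <- matrix(20, nrow = 2, ncol = 10)
  rs <- tibble::tibble(unit_id = c("a", "b"), mu_rest = c(10, 0),
                       sd_left = 0, sd_right = 0, sd_rest = c(4, 0))
  z <- normalize_rates(r, rs)
  expect_equal(z[1, 1], (20 - 10) / (4 + 1))   # = 2
  expect_equal(z[2, 1], 20)                    # silent at rest: denominator 1
  # x == mu gives exactly zero
  z0 <- normalize_rates(matrix(10, 1, 5),
                        tibble::tibble(unit_id = "a", mu_rest = 10,
                                       sd_left = 2, sd_right = 2,
                                       sd_rest = 2))
  expect_true(all(z0 == 0))
})

test_that("range normalization divides by the firing-rate range plus five", {
  r <- matrix(c(0, 5, 10, 15, 20), nrow = 1)
  rs <- tibble::tibble(unit_id = "a", mu_rest = 10, sd_left = 1,
                       sd_right = 1, sd_rest = 1)
  z <- normalize_rates(r, rs, mode = "range")
  expect_equal(as.numeric(z), (c(0, 5, 10, 15, 20) - 10) / (20 + 5))
})

test_that("edge-inclusive 300 ms windows hold exactly 16 samples", {
  s <- fixture_session()
  pp <- fixture_prep()
  for (ph in c("rest", "instruct", "move")) {
    tw <- extract_phase_windows(pp$z, s$trials, ph)
    expect_equal(dim(tw)[2], 16L)
    expect_equal(phase_window(ph)$n_samples, 16L)
  }
  # a window of duration d yields d/20 + 1 samples
  tw2 <- extract_phase_windows(pp$z, s$trials,
                               list(event = "instruct_onset",
                                    offset = c(0, 0.1)))
  expect_equal(dim(tw2)[2], 6L)
  # rest window ends exactly at the sample nearest instruction onset
  twr <- extract_phase_windows(pp$z, s$trials[1, ], "rest")
  expect_equal(attr(twr, "offsets")[16], 0)
  ev_idx <- which.min(abs(s$times - s$trials$instruct_onset[1]))
  expect_equal(unname(twr[, 16, 1]), unname(pp$z[, ev_idx]))
  # concatenation stacks to 16m rows
  tw3 <- extract_phase_windows(pp$z, s$trials, "move", arms = "left")
  m <- dim(tw3)[3]
  expect_equal(nrow(tensor_matrix(tw3)), 16L * m)
  # windows that fall off the recording error with the trial named
  bad <- s$trials[1, ]
  bad$movement_onset <- max(s$times) + 1
  expect_error(extract_phase_windows(pp$z, bad, "move"), "trial 1")
})

test_that("tensor_matrix stacks trials in order with unit columns", {
  tens <- array(seq_len(2 * 3 * 2), dim = c(2, 3, 2))
  dimnames(tens) <- list(c("a", "b"), NULL, NULL)
  tens <- structure(tens, class = "rate_tensor")
  m <- tensor_matrix(tens)
  expect_equal(dim(m), c(6L, 2L))
  expect_equal(m[1, ], c(a = 1, b = 2))
  expect_equal(m[4, ], c(a = 7, b = 8))     # first sample of trial 2
  expect_equal(tensor_matrix(tens, units = "b")[, 1], c(2, 4, 6, 8, 10, 12))
})

test_that("duplicate-unit rule removes one of each offending pair only", {
  units <- tibble::tibble(
    unit_id = c("a", "b", "c", "d"),
    hemisphere = "L", area = "PMd",
    channel = c(1, 2, 5, 6)
  )
  set.seed(5)
  base <- rnorm(500)
  rates <- rbind(
    a = base,
    b = base + rnorm(500, 0, 0.01),     # corr ~ 1, channel distance 1
    c = base + rnorm(500, 0, 0.01),     # corr ~ 1 but distance 3 from b
    d = rnorm(500)                      # uncorrelated, distance 1 from c
  )
  out <- dedupe_units(units, rates)
  expect_equal(out$units$unit_id, c("a", "c", "d"))
  expect_equal(out$removed$removed, "b")
  expect_equal(out$removed$duplicate_of, "a")
  # correlation 0.95 at channel distance 3: both kept
  units2 <- units[c(2, 3), ]
  out2 <- dedupe_units(units2, rates[c(2, 3), ])
  expect_equal(nrow(out2$removed), 0L)
  # low correlation at distance 1: both kept
  units3 <- units[c(3, 4), ]
  units3$channel <- c(5, 6)
  out3 <- dedupe_units(units3, rates[c(3, 4), ])
  expect_equal(nrow(out3$removed), 0L)
})

test_that("preprocessing is deterministic for identical inputs", {
  s <- fixture_session()
  a <- preprocess_session(s)
  b <- preprocess_session(s)
  expect_identical(a$z, b$z)
  expect_identical(a$rest_stats, b$rest_stats)
})
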