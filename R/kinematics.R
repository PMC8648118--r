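#' Simulate 240 Hz hand kinematics for a trial schedule
#'
#' Produces 3-D positions for both hands across the session. The reaching
#' hand follows a bell-shaped (sine-squared) speed profile from its start
#' position to the cued target, timed so that speed crosses the 10 cm/s
#' onset threshold exactly at the scheduled movement onset. The stationary
#' hand exhibits low-amplitude smooth positional jitter with configurable
#' mean speed (zero jitter gives a perfectly still hand).
#'
#' @param config A [sim_config()] object.
#' @param trials A trial table with `arm`, `target`, `config`,
#'   `movement_onset`, `reach_duration` and `trial_end` columns.
#' @return A `kinematics_set`: list with `time` (s), `sample_rate`, and
#'   `hands`, a list of `T x 3` position matrices (cm) named `left`/`right`.
#' @export
simulate_kinematics <- function(config, trials) {
  if (any(is.na(trials$movement_onset))) {
    stop("trial table has missing movement onsets", call. = FALSE)
  }
  sr <- config$kinematics$sample_rate
  peak <- config$kinematics$peak_speed
  jit <- config$kinematics$jitter_speed
  t_end <- max(trials$trial_end) + 0.5
  time <- seq(0, t_end, by = 1 / sr)
  nt <- length(time)
  tp <- target_positions()

  with_substream(config$seed, "kinematics", {
    hands <- lapply(c("left", "right"), function(hand) {
      # baseline: hand sits at its start position for the current trial
      base <- matrix(rep(start_position(hand, "centered"), each = nt),
                     nrow = nt, dimnames = list(NULL, c("x", "y", "z")))
      for (i in seq_len(nrow(trials))) {
        idx <- time >= (trials$rest_start[i] - config$phase_durations$iti / 2)
        s0 <- start_position(hand, trials$config[i])
        base[idx, ] <- matrix(rep(s0, each = sum(idx)), ncol = 3)
      }
      pos <- base
      # reaches of this hand
      for (i in which(trials$arm == hand)) {
        s0 <- start_position(hand, trials$config[i])
        tgt <- tp[trials$target[i], ]
        dist <- sqrt(sum((tgt - s0)^2))
        d_dur <- 2 * dist / peak
        # profile start chosen so speed crosses 10 cm/s at the onset
        lead <- (d_dur / pi) * asin(sqrt(10 / peak))
        t0 <- trials$movement_onset[i] - lead
        tau <- (time - t0) / d_dur
        # path length along the sine-squared speed profile
        arc <- peak * (d_dur * pmin(pmax(tau, 0), 1) / 2 -
                         d_dur * sin(2 * pi * pmin(pmax(tau, 0), 1)) / (4 * pi))
        frac <- pmin(arc / dist, 1)
        seg <- tau > 0 & time <= trials$trial_end[i]
        pos[seg, ] <- matrix(rep(s0, each = sum(seg)), ncol = 3) +
          outer(frac[seg], tgt - s0)
        # smooth return toward the next start position after the hold
        ret <- time > trials$trial_end[i] &
          time <= trials$trial_end[i] + 0.3
        if (any(ret)) {
          u <- raised_cosine_up(time[ret], trials$trial_end[i],
                                trials$trial_end[i] + 0.3)
          pos[ret, ] <- (1 - u) * matrix(rep(tgt, each = sum(ret)),
                                         ncol = 3) + u * pos[ret, ]
        }
      }
      if (jit > 0) {
        # stationary AR(1) positional noise calibrated to the requested
        # mean speed (mean of a 3-D normal speed = 1.5958 * per-axis sd)
        rho <- exp(-1 / (0.2 * sr))
        sd_p <- jit / (1.5958 * sr * sqrt(2 * (1 - rho)))
        for (j in 1:3) {
          e <- rnorm(nt, 0, sd_p * sqrt(1 - rho^2))
          x <- stats::filter(e, rho, method = "recursive")
          pos[, j] <- pos[, j] + as.numeric(x)
        }
      }
      pos
    })
    names(hands) <- c("left", "right")
    structure(
      list(time = time, sample_rate = sr, hands = hands),
      class = "kinematics_set"
    )
  })
}

# Uniform-grid cubic smoothing: penalized least squares with a
# second-difference roughness penalty solved through a banded sparse
# system. On a regular grid this is the discrete equivalent of the cubic
# smoothing spline, and runs in O(n) for session-length traces.
whittaker_smooth <- function(y, lambda) {
  n <- length(y)
  if (n < 4L || lambda <= 0) {
    return(y)
  }
  d2 <- Matrix::bandSparse(
    n - 2L, n,
    k = 0:2,
    diagonals = list(rep(1, n - 2L), rep(-2, n - 2L), rep(1, n - 2L))
  )
  a <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(d2)
  as.numeric(Matrix::solve(a, y))
}

#' Smooth raw kinematics and derive speed traces
#'
#' Applies cubic smoothing (second-difference penalized least squares on
#' the uniform 240 Hz sample grid) to each coordinate of each hand. The
#' smoothing parameter follows the penalized-least-squares convention in
#' which `p = 1` returns an interpolant and `p -> 0` approaches the
#' least-squares line; the penalty weight is `(1 - p) / p` on the sample
#' grid. Speeds are the norm of the central-difference velocity of the
#' smoothed trace, and are non-negative by construction.
#'
#' @param kin A `kinematics_set` (see [simulate_kinematics()]).
#' @param p Smoothing parameter in `(0, 1]`; default 0.005.
#' @return The input with added `smoothed` (list of position matrices) and
#'   `speed` (list of speed vectors, cm/s) elements.
#' @export
smooth_kinematics <- function(kin, p = 0.005) {
  stopifnot(inherits(kin, "kinematics_set"), p > 0, p <= 1)
  if (any(diff(kin$time) > 0.05 + 1e-9)) {
    stop("kinematic record has gaps exceeding 50 ms", call. = FALSE)
  }
  lambda <- (1 - p) / p
  kin$smoothed <- lapply(kin$hands, function(posm) {
    sm <- posm
    for (j in seq_len(ncol(posm))) {
      if (sd(posm[, j]) < 1e-14) next   # constant trace is its own smooth
      sm[, j] <- whittaker_smooth(posm[, j], lambda)
    }
    sm
  })
  kin$speed <- lapply(kin$smoothed, function(sm) {
    v <- apply(sm, 2, central_diff) * kin$sample_rate
    sqrt(rowSums(v^2))
  })
  kin
}

central_diff <- function(x) {
  n <- length(x)
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
}

#' Detect movement onset and reach end from hand speed
#'
#' Onset is the first sample after the go cue at which the reaching hand's
#' speed exceeds 10 cm/s. Reach end is the first post-onset sample at which
#' speed has dropped below 20 cm/s *and* the depth-direction velocity has
#' reached zero (first zero crossing or sign change; exact equality is
#' measure-zero on sampled data).
#'
#' @param kin A `kinematics_set`; smoothed speeds are computed on the fly
#'   if [smooth_kinematics()] has not been run.
#' @param trial A single row of a trial table (needs `arm`, `go_cue`,
#'   `trial_end`).
#' @param onset_threshold,end_threshold Speed thresholds (cm/s).
#' @param depth_axis Column of the position matrices pointing away from the
#'   body (default `"y"`).
#' @return A tibble with `onset`, `reach_end`, `duration` (s) and a
#'   `flagged` logical; flagged trials (threshold never crossed) carry `NA`
#'   times and are excluded downstream.
#' @export
detect_movement_onset <- function(kin, trial, onset_threshold = 10,
                                  end_threshold = 20, depth_axis = "y") {
  if (is.null(kin$speed)) kin <- smooth_kinematics(kin)
  hand <- trial$arm
  sp <- kin$speed[[hand]]
  posm <- kin$smoothed[[hand]]
  vdepth <- central_diff(posm[, depth_axis]) * kin$sample_rate
  horizon <- trial$trial_end + 0.2
  in_trial <- kin$time > trial$go_cue & kin$time <= horizon
  onset_idx <- which(in_trial & sp > onset_threshold)[1]
  if (is.na(onset_idx)) {
    return(tibble(onset = NA_real_, reach_end = NA_real_,
                  duration = NA_real_, flagged = TRUE))
  }
  after <- seq_along(sp) > onset_idx & kin$time <= horizon
  crossed <- c(FALSE, diff(sign(vdepth + 1e-12)) != 0) | abs(vdepth) < 1e-9
  end_idx <- which(after & sp < end_threshold & crossed)[1]
  onset <- kin$time[onset_idx]
  reach_end <- if (is.na(end_idx)) NA_real_ else kin$time[end_idx]
  tibble(
    onset = onset, reach_end = reach_end,
    duration = reach_end - onset, flagged = FALSE
  )
}
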