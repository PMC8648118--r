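#' Simulate a bilateral instructed-delay recording session
#'
#' Generates one synthetic session with the statistical structure the
#' downstream pipeline assumes: a blocked trial schedule (alternating
#' blocks of two trials per target per arm), per-unit baseline firing,
#' phase-gated target-tuned latent drive split into an arm-specific
#' *dedicated* component (magnitude scaling with the unit's arm
#' preference) and a *distributed* component shared between arms, plus
#' Poisson or Gaussian observation noise. Ground truth (true arm
#' preferences, latent loadings, per-phase latent dimensionality) is
#' attached for parameter-recovery testing.
#'
#' The generative rule links modulation to arm preference: a unit with true
#' arm preference `a` has preferred-arm modulation
#' `modulation_base * 10^(modulation_slope * |a|)` and non-preferred-arm
#' modulation scaled by `(1 - |a|) / (1 + |a|)`, so its realized arm
#' preference equals `a` up to noise. A fraction
#' `distributed_variance_fraction` of the non-preferred-arm budget is
#' carried by shared latents with loading vectors identical for the two
#' arms; the remainder is arm-specific.
#'
#' @param config A [sim_config()] object.
#' @param kinematics Generate 240 Hz hand kinematics alongside the neural
#'   data (default `TRUE`; skip for speed when only rates are needed).
#' @return A `bilat_session` list with elements `units` (tibble of unit
#'   metadata), `trials` (trial table), `rates` (units x bins matrix of
#'   square-root-scale rates, gaussian mode), `spikes` (list of spike-time
#'   vectors, poisson mode), `times` (bin centers, s), `kinematics`
#'   (a `kinematics_set` or `NULL`), `config`, and `ground_truth`.
#' @export
simulate_session <- function(config, kinematics = TRUE) {
  config <- validate_sim_config(unclass(config))
  build_session(config, null_session = FALSE, kinematics = kinematics)
}

#' Simulate a structureless (null) session
#'
#' Identical to [simulate_session()] except that all target- and
#' arm-dependent latent drive is removed: rates are baseline plus noise
#' while the trial labels and schedule are retained. Used for type-I error
#' calibration and chance-level decoding checks.
#'
#' @inheritParams simulate_session
#' @return A `bilat_session`; its ground truth carries zero loadings.
#' @export
simulate_null_session <- function(config, kinematics = FALSE) {
  config <- validate_sim_config(unclass(config))
  build_session(config, null_session = TRUE, kinematics = kinematics)
}

# ---------------------------------------------------------------------------

build_schedule <- function(config) {
  pd <- config$phase_durations
  tptpa <- config$trials_per_target_per_arm
  targets <- seq_len(config$target_count)
  rows <- list()
  with_substream(config$seed, "schedule", {
    for (cfg_label in config_labels(config$start_configurations)) {
      remaining <- list(left = rep(tptpa, length(targets)),
                        right = rep(tptpa, length(targets)))
      arm <- "left"
      block <- 1L
      while (any(remaining$left > 0) || any(remaining$right > 0)) {
        take <- pmin(remaining[[arm]], 2L)
        if (any(take > 0)) {
          tt <- sample(rep(targets, times = take))
          rows[[length(rows) + 1L]] <- tibble(
            config = cfg_label, arm = arm, target = tt, block = block
          )
          remaining[[arm]] <- remaining[[arm]] - take
        }
        arm <- if (arm == "left") "right" else "left"
        block <- block + 1L
      }
    }
    trials <- bind_rows(rows)
    m <- nrow(trials)
    delay <- runif(m, pd$instruct_min, pd$instruct_max)
    rt <- runif(m, pd$reaction_min, pd$reaction_max)
    trials$reach_duration <- reach_durations(trials, config)
    # sequential event times
    rest_start <- numeric(m)
    t0 <- 0.5
    instruct <- go <- mo <- tend <- numeric(m)
    for (i in seq_len(m)) {
      rest_start[i] <- t0
      instruct[i] <- rest_start[i] + pd$rest
      go[i] <- instruct[i] + delay[i]
      mo[i] <- go[i] + rt[i]
      tend[i] <- mo[i] + trials$reach_duration[i] + pd$hold
      t0 <- tend[i] + pd$iti
    }
    trials <- trials %>%
      mutate(
        trial_id = row_number(),
        rest_start = rest_start,
        instruct_onset = instruct,
        go_cue = go,
        movement_onset = mo,
        trial_end = tend,
        success = TRUE,
        prev_arm = dplyr::lag(arm)
      ) %>%
      select("trial_id", "config", "arm", "target", "block",
             "rest_start", "instruct_onset", "go_cue", "movement_onset",
             "reach_duration", "trial_end", "success", "prev_arm")
    trials
  })
}

reach_durations <- function(trials, config) {
  tp <- target_positions()
  vapply(seq_len(nrow(trials)), function(i) {
    s0 <- start_position(trials$arm[i], trials$config[i])
    d <- sqrt(sum((tp[trials$target[i], ] - s0)^2))
    2 * d / config$kinematics$peak_speed
  }, numeric(1))
}

build_units <- function(config) {
  groups <- expand.grid(
    hemisphere = c("L", "R"), area = c("PMd", "M1"),
    stringsAsFactors = FALSE
  )
  units <- purrr::pmap(groups, function(hemisphere, area) {
    tibble(
      hemisphere = hemisphere, area = area,
      channel = seq_len(config$n_units_per_group),
      depth = round(runif(config$n_units_per_group, 0, 3), 3),
      isolation = "single"
    )
  }) %>% list_rbind()
  units$unit_id <- sprintf("u%03d", seq_len(nrow(units)))
  ap <- config$arm_pref_distribution
  n <- nrow(units)
  dedicated <- runif(n) < ap$dedicated_frac
  a <- rnorm(n, 0, ap$neutral_sd)
  tail_sign <- ifelse(runif(n) < ap$contra_bias, 1, -1)
  a[dedicated] <- (tail_sign * rnorm(n, ap$dedicated_mean, ap$dedicated_sd))[dedicated]
  a <- pmin(1, pmax(-1, a))
  units$true_arm_pref <- a
  units$baseline_rate <- runif(n, config$baseline_rate_range[1],
                               config$baseline_rate_range[2])
  # contra arm for each unit given its hemisphere
  units$contra_arm <- ifelse(units$hemisphere == "L", "right", "left")
  units$pref_arm <- ifelse(units$true_arm_pref >= 0, units$contra_arm,
                           ifelse(units$contra_arm == "right", "left", "right"))
  units %>% select("unit_id", "hemisphere", "area", "channel", "depth",
                   "isolation", "true_arm_pref", "baseline_rate",
                   "contra_arm", "pref_arm")
}

raised_cosine_up <- function(t, t0, t1) {
  out <- ifelse(t <= t0, 0, ifelse(t >= t1, 1,
                                   0.5 - 0.5 * cos(pi * (t - t0) / (t1 - t0))))
  out
}

# Phase-gated envelopes plus time-since-anchor (for the per-latent
# temporal harmonics), per trial, on the session bin grid.
latent_envelopes <- function(times, trials) {
  n <- length(times)
  envI <- numeric(n); envM <- numeric(n)
  tauI <- numeric(n); tauM <- numeric(n)
  for (i in seq_len(nrow(trials))) {
    ins <- trials$instruct_onset[i]
    go <- trials$go_cue[i]
    mo <- trials$movement_onset[i]
    idx <- which(times >= trials$rest_start[i] - 0.2 &
                   times <= trials$trial_end[i] + 0.3)
    tt <- times[idx]
    up <- raised_cosine_up(tt, ins + 0.10, ins + 0.25)
    down <- 1 - raised_cosine_up(tt, go, mo + 0.10)
    envI[idx] <- up * down
    upm <- raised_cosine_up(tt, mo - 0.10, mo + 0.05)
    downm <- 1 - raised_cosine_up(tt, mo + 0.35, mo + 0.60)
    envM[idx] <- upm * downm
    tauI[idx] <- pmax(tt - (ins + 0.10), 0)
    tauM[idx] <- pmax(tt - (mo - 0.10), 0)
  }
  list(instruct = envI, move = envM, tau_instruct = tauI, tau_move = tauM)
}

# Indices of 20 ms bins inside the canonical phase window of each trial.
phase_bin_index <- function(times, trials, phase) {
  unlist(lapply(seq_len(nrow(trials)), function(i) {
    w <- switch(phase,
      rest = trials$instruct_onset[i] + c(-0.3, 0),
      instruct = trials$instruct_onset[i] + c(0.2, 0.5),
      move = trials$movement_onset[i] + c(0, 0.3)
    )
    which(times >= w[1] - 1e-9 & times <= w[2] + 1e-9)
  }))
}

# One latent bank: target-tuned, phase-gated scores on the bin grid,
# restricted to one arm (or both). Latents carry orthonormal target
# tunings plus a mild bounded temporal wobble (distinct frequency and
# random phase per latent) so they are linearly independent without
# their instantaneous power collapsing to zero anywhere. Scores are
# orthogonalized against any `ortho` bank on this bank's reference bins,
# whitened over those bins, and finally given a geometrically decaying
# power spectrum; the decaying spectrum keeps the ordering of
# single-timepoint principal components stable within an epoch. A
# unit's realized drive power over the reference windows then equals
# its spectrum-weighted squared loading norm exactly.
make_bank <- function(k, times, trials, env, tau, span, freq_offset,
                      arm, ref_idx, bin_arm, bin_trial, ortho = NULL,
                      spectrum_decay = 0.45) {
  if (k == 0L) {
    return(NULL)
  }
  if (k > 6L) {
    stop("at most six latents per bank (target-tuning rank)", call. = FALSE)
  }
  # orthonormal target tunings keep latent powers balanced across arms.
  # The first latent is condition-independent (constant tuning): the
  # largest component of motor cortical responses is a target-independent
  # mean shift, and routing it through the top spectrum slot reproduces
  # that without adding latent dimensions.
  basis <- matrix(rnorm(6 * k), nrow = 6)
  basis[, 1] <- 1
  tuning <- t(qr.Q(qr(basis)))
  phases <- runif(k, 0, 2 * pi)
  active <- if (is.null(arm)) rep(TRUE, length(times)) else bin_arm == arm
  active[is.na(active)] <- FALSE
  scores <- matrix(0, nrow = length(times), ncol = k)
  tr_ok <- !is.na(bin_trial)
  tgt <- rep(NA_integer_, length(times))
  tgt[tr_ok] <- trials$target[bin_trial[tr_ok]]
  sel <- which(active & tr_ok & env > 0)
  for (j in seq_len(k)) {
    freq <- freq_offset + j
    profile <- 1 + 0.25 * cos(pi * freq * tau[sel] / span + phases[j])
    scores[sel, j] <- env[sel] * profile * tuning[j, tgt[sel]]
  }
  ref <- intersect(ref_idx, which(active))
  if (!is.null(ortho)) {
    o_ref <- ortho[ref, , drop = FALSE]
    b <- solve(crossprod(o_ref) + diag(1e-10, ncol(o_ref)),
               crossprod(o_ref, scores[ref, , drop = FALSE]))
    act <- which(active)
    scores[act, ] <- scores[act, , drop = FALSE] -
      ortho[act, , drop = FALSE] %*% b
  }
  sv <- svd(scores[ref, , drop = FALSE])
  ok <- sv$d > 1e-6 * max(sv$d, .Machine$double.eps)
  if (sum(ok) < k) {
    stop("latent bank rank below requested dimension; reduce latent dims",
         call. = FALSE)
  }
  tr <- sv$v %*% diag(sqrt(length(ref)) / sv$d, nrow = k)
  spectrum <- spectrum_decay^(seq_len(k) - 1L)
  spectrum <- spectrum * k / sum(spectrum)    # mean latent power 1
  scores <- (scores %*% tr) %*% diag(sqrt(spectrum), nrow = k)
  list(scores = scores, tuning = tuning, spectrum = spectrum)
}

# Loadings with exact per-unit drive power: random directions scaled so
# the spectrum-weighted squared norm equals the unit's variance budget.
draw_loadings <- function(n, k, spectrum, budget) {
  w <- matrix(rnorm(n * k), nrow = n)
  wn <- sqrt(as.numeric(w^2 %*% spectrum))
  w * sqrt(pmax(budget, 0)) / pmax(wn, 1e-12)
}

build_session <- function(config, null_session, kinematics) {
  trials <- build_schedule(config)
  units <- with_substream(config$seed, "units", build_units(config))
  n <- nrow(units)

  bin <- 0.02
  t_end <- max(trials$trial_end) + 0.5
  times <- seq(bin / 2, t_end, by = bin)
  nb <- length(times)

  # map each bin to its trial (NA between trials) and trial arm
  bin_trial <- rep(NA_integer_, nb)
  for (i in seq_len(nrow(trials))) {
    bin_trial[times >= trials$rest_start[i] &
                times <= trials$trial_end[i]] <- i
  }
  bin_arm <- ifelse(is.na(bin_trial), NA_character_, trials$arm[bin_trial])

  env <- latent_envelopes(times, trials)
  move_idx <- phase_bin_index(times, trials, "move")
  instruct_idx <- phase_bin_index(times, trials, "instruct")

  # per-unit modulation budgets (z^2 units) on the Move window
  a <- abs(units$true_arm_pref)
  m_pref <- config$modulation_base * 10^(config$modulation_slope * a)
  m_nonpref <- m_pref * (1 - a) / (1 + a)
  f <- config$distributed_variance_fraction
  d_shared <- f * m_nonpref
  d_ded_pref <- m_pref - d_shared
  d_ded_nonpref <- m_nonpref - d_shared

  arm_budget <- function(arm) {
    ifelse(units$pref_arm == arm, d_ded_pref, d_ded_nonpref)
  }

  # amplitude scale from z units into the square-root rate domain
  sigma_rest <- if (config$noise_model == "gaussian") config$noise_sd else 0.17
  z_scale <- sigma_rest + 1

  drive <- matrix(0, nrow = n, ncol = nb)
  gt_loadings <- list()
  ks <- config$distributed_dim
  kd <- config$dedicated_dim

  if (!null_session) {
    with_substream(config$seed, "loadings", {
      epochs <- if (config$split_phases) c("instruct", "move") else "both"
      for (ep in epochs) {
        ep_env <- switch(ep,
          instruct = env$instruct,
          move = env$move,
          both = pmax(env$instruct, env$move)
        )
        ep_tau <- switch(ep,
          instruct = env$tau_instruct,
          move = env$tau_move,
          both = env$tau_instruct
        )
        span <- switch(ep, instruct = 0.8, move = 0.5, both = 1.2)
        ref_idx <- switch(ep,
          instruct = instruct_idx,
          move = move_idx,
          both = c(instruct_idx, move_idx)
        )
        gain <- if (ep == "instruct") config$instruct_gain else 1
        shared_scores <- NULL
        # shared bank: identical loadings for both arms by construction
        if (ks > 0) {
          bank <- make_bank(ks, times, trials, ep_env, ep_tau, span, 0,
                            NULL, ref_idx, bin_arm, bin_trial)
          shared_scores <- bank$scores
          w <- draw_loadings(n, ks, bank$spectrum, d_shared) *
            z_scale * gain
          contrib <- w %*% t(bank$scores)
          g <- config$distributed_pref_gain
          if (g != 1) {
            on_pref <- outer(units$pref_arm, bin_arm, `==`)
            on_pref[is.na(on_pref)] <- FALSE
            contrib <- contrib * (1 + (g - 1) * on_pref)
          }
          drive <- drive + contrib
          gt_loadings[[paste0("shared_", ep)]] <-
            list(loadings = w, tuning = bank$tuning)
        }
        # dedicated banks: separate latents and loadings per arm, using
        # higher temporal harmonics and orthogonalized against the shared
        # bank on each arm's reference bins
        if (kd > 0) {
          for (arm in c("left", "right")) {
            bank <- make_bank(kd, times, trials, ep_env, ep_tau, span, ks,
                              arm, ref_idx, bin_arm, bin_trial,
                              ortho = shared_scores)
            w <- draw_loadings(n, kd, bank$spectrum, arm_budget(arm)) *
              z_scale * gain
            drive <- drive + w %*% t(bank$scores)
            gt_loadings[[paste0("dedicated_", arm, "_", ep)]] <-
              list(loadings = w, tuning = bank$tuning)
          }
        }
      }
    })
  }

  if (!null_session && config$rest_arm_offset > 0) {
    # before the cue the offset tracks the arm the blocked schedule
    # predicts (the previous trial's); after the cue, the actual arm
    with_substream(config$seed, "rest_offset", {
      o <- rnorm(n)
      o <- o / sqrt(mean(o^2)) * config$rest_arm_offset * z_scale
      expected_arm <- ifelse(is.na(trials$prev_arm), trials$arm,
                             trials$prev_arm)
      ok <- which(!is.na(bin_trial))
      pre_cue <- times[ok] < trials$instruct_onset[bin_trial[ok]]
      eff_arm <- ifelse(pre_cue, expected_arm[bin_trial[ok]],
                        trials$arm[bin_trial[ok]])
      sgn <- ifelse(eff_arm == "left", 1, -1)
      drive[, ok] <- drive[, ok] + outer(o, sgn)
      gt_loadings[["rest_arm_offset"]] <- list(loadings = matrix(o))
    })
  }

  x_rest <- sqrt(units$baseline_rate * bin)
  session <- list(
    units = units %>% select(-"true_arm_pref", -"baseline_rate",
                             -"pref_arm"),
    trials = trials,
    times = times,
    bin_width = bin,
    config = config
  )

  if (config$noise_model == "gaussian") {
    noise <- with_substream(config$seed, "noise",
                            matrix(rnorm(n * nb, 0, config$noise_sd), nrow = n))
    session$rates <- drive + x_rest + noise
    rownames(session$rates) <- units$unit_id
    session$spikes <- NULL
  } else {
    # back to the rate domain: lambda = (sqrt-scale value)^2 / bin width
    xs <- pmax(drive + x_rest, 0)
    lambda <- xs^2 / bin
    session$spikes <- with_substream(config$seed, "noise", {
      sp <- vector("list", n)
      for (i in seq_len(n)) {
        counts <- rpois(nb, lambda[i, ] * bin)
        tot <- sum(counts)
        sp[[i]] <- if (tot == 0) numeric(0) else {
          sort(rep(times[counts > 0] - bin / 2, counts[counts > 0]) +
                 runif(tot, 0, bin))
        }
      }
      names(sp) <- units$unit_id
      sp
    })
    session$rates <- NULL
  }

  if (kinematics) {
    session$kinematics <- simulate_kinematics(config, trials)
  }

  # per-phase, per-arm latent dimensionality actually injected
  dims <- tidyr::expand_grid(
    phase = c("rest", "instruct", "move"), arm = c("left", "right")
  ) %>%
    mutate(true_dim = dplyr::case_when(
      null_session | phase == "rest" ~ 0L,
      TRUE ~ as.integer((ks > 0) * ks + (kd > 0) * kd)
    ))

  session$ground_truth <- list(
    units = units %>% select("unit_id", "hemisphere", "area",
                             "true_arm_pref", "baseline_rate", "contra_arm",
                             "pref_arm") %>%
      mutate(
        modulation_pref = if (null_session) 0 else m_pref,
        modulation_nonpref = if (null_session) 0 else m_nonpref,
        distributed_budget = if (null_session) 0 else d_shared
      ),
    loadings = gt_loadings,
    dimensionality = dims,
    null_session = null_session
  )
  structure(session, class = "bilat_session")
}

#' @export
print.bilat_session <- function(x, ...) {
  cat(sprintf(
    "<bilat_session> %d units, %d trials (%s mode)\n",
    nrow(x$units), nrow(x$trials), x$config$noise_model
  ))
  cat(sprintf("  configurations: %s\n",
              paste(unique(x$trials$config), collapse = ", ")))
  invisible(x)
}
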