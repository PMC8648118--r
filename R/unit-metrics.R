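#' Single-unit modulation from a windowed tensor
#'
#' Modulation is the mean squared soft-normalized rate over the
#' concatenated phase-window samples: a unitless, variance-like score of
#' deviation from Rest-phase baseline (deviation is measured from the Rest
#' mean, not the window mean, so offset shifts count as modulation).
#'
#' @param tensor A `rate_tensor` (units x samples x trials) of normalized
#'   rates, or a samples x units matrix.
#' @return A tibble with `unit_id` and `modulation` (non-negative).
#' @export
compute_modulation <- function(tensor) {
  if (inherits(tensor, "rate_tensor")) {
    if (dim(tensor)[3] == 0L) stop("empty window set", call. = FALSE)
    m <- apply(tensor^2, 1, mean)
    ids <- dimnames(tensor)[[1]] %||% sprintf("u%03d", seq_along(m))
  } else {
    x <- as.matrix(tensor)
    if (nrow(x) == 0L) stop("empty window set", call. = FALSE)
    m <- colMeans(x^2)
    ids <- colnames(x) %||% sprintf("u%03d", seq_along(m))
  }
  tibble(unit_id = ids, modulation = unname(m))
}

#' Arm preference from contra- and ipsilateral modulation
#'
#' `AP = (M_contra - M_ipsi) / (M_contra + M_ipsi)`, on `[-1, 1]`: +1 is
#' exclusive contralateral modulation, -1 exclusive ipsilateral. The
#' normalization constant used in the modulation calculation cancels, so
#' AP is invariant to any common rescaling of the two modulation values.
#' When both modulations are zero the preference is undefined and `NA` is
#' returned.
#'
#' @param m_contra,m_ipsi Non-negative modulation values (vectorized).
#' @return Numeric vector of arm preferences in `[-1, 1]` (or `NA`).
#' @export
compute_arm_preference <- function(m_contra, m_ipsi) {
  stopifnot(length(m_contra) == length(m_ipsi))
  tot <- m_contra + m_ipsi
  ifelse(tot == 0, NA_real_, (m_contra - m_ipsi) / tot)
}

#' Per-unit modulation and arm preference across phases
#'
#' Computes modulation for each unit, phase and arm (in both left/right
#' and contra/ipsi conventions, using each unit's hemisphere), and the
#' per-phase arm preference. Restrict `configs` to a subset of start
#' configurations to obtain metrics from independent trial sets (the
#' held-out-configuration design used whenever arm preference and
#' modulation enter an analysis jointly).
#'
#' @param z Normalized units x bins matrix.
#' @param trials Trial table.
#' @param units Unit metadata tibble (needs `unit_id`, `hemisphere`).
#' @param phases Phases to include.
#' @param configs Optional start-configuration filter.
#' @return A tibble with one row per unit x phase: `m_left`, `m_right`,
#'   `m_contra`, `m_ipsi`, `arm_pref`.
#' @export
unit_phase_metrics <- function(z, trials, units,
                               phases = c("rest", "instruct", "move"),
                               configs = NULL) {
  contra_arm <- ifelse(units$hemisphere == "L", "right", "left")
  res <- list()
  for (ph in phases) {
    m_by_arm <- lapply(c("left", "right"), function(arm) {
      tw <- extract_phase_windows(z, trials, ph, arms = arm,
                                  configs = configs)
      compute_modulation(tw)$modulation
    })
    names(m_by_arm) <- c("left", "right")
    m_contra <- ifelse(contra_arm == "right", m_by_arm$right, m_by_arm$left)
    m_ipsi <- ifelse(contra_arm == "right", m_by_arm$left, m_by_arm$right)
    res[[ph]] <- tibble(
      unit_id = units$unit_id, phase = ph,
      m_left = m_by_arm$left, m_right = m_by_arm$right,
      m_contra = m_contra, m_ipsi = m_ipsi,
      arm_pref = compute_arm_preference(m_contra, m_ipsi)
    )
  }
  bind_rows(res)
}

#' Assign each unit's preferred arm from held-out data
#'
#' The preferred arm is the arm with the larger hold-out modulation.
#' Exact ties are broken toward the contralateral arm (and flagged); the
#' assignment is invariant to common rescaling of firing rates because
#' only the comparison of the two modulations matters.
#'
#' @param holdout_metrics Tibble from [unit_phase_metrics()] computed on a
#'   held-out trial set (typically a different start configuration),
#'   filtered to one phase.
#' @param units Unit metadata tibble (for the hemisphere of each unit).
#' @return A tibble with `unit_id`, `pref_arm`, `tie`.
#' @export
assign_preferred_arm <- function(holdout_metrics, units) {
  if (nrow(holdout_metrics) == 0L) {
    stop("hold-out metrics are required to assign preferred arms",
         call. = FALSE)
  }
  contra_arm <- ifelse(units$hemisphere == "L", "right", "left")
  hm <- holdout_metrics %>%
    left_join(tibble(unit_id = units$unit_id, contra = contra_arm),
              by = "unit_id")
  hm %>%
    mutate(
      tie = .data$m_left == .data$m_right,
      pref_arm = dplyr::case_when(
        .data$m_left > .data$m_right ~ "left",
        .data$m_right > .data$m_left ~ "right",
        TRUE ~ .data$contra
      )
    ) %>%
    select("unit_id", "pref_arm", "tie")
}

#' Per-unit metrics from independent trial sets
#'
#' Assembles the table used by every analysis that combines arm
#' preference with modulation: arm preference (and the preferred-arm
#' label) measured on one set of start configurations, modulation on a
#' disjoint set, joined per unit with `m_pref` / `m_nonpref` columns.
#'
#' @param z Normalized units x bins matrix.
#' @param trials Trial table.
#' @param units Unit metadata tibble.
#' @param phase Task phase for both measurements.
#' @param ap_configs,m_configs Disjoint start-configuration subsets for
#'   the arm-preference and modulation datasets.
#' @return A tibble with one row per unit: `arm_pref`, `pref_arm`, `tie`,
#'   `m_left`, `m_right`, `m_contra`, `m_ipsi`, `m_pref`, `m_nonpref`.
#' @export
independent_metrics <- function(z, trials, units, phase = "move",
                                ap_configs, m_configs) {
  if (length(intersect(ap_configs, m_configs))) {
    warning("arm-preference and modulation configurations overlap; ",
            "the two measures will not be independent", call. = FALSE)
  }
  ap_set <- unit_phase_metrics(z, trials, units, phases = phase,
                               configs = ap_configs)
  m_set <- unit_phase_metrics(z, trials, units, phases = phase,
                              configs = m_configs)
  pref <- assign_preferred_arm(ap_set, units)
  ap_set %>%
    select("unit_id", "arm_pref") %>%
    left_join(select(m_set, "unit_id", "m_left", "m_right",
                     "m_contra", "m_ipsi"),
              by = "unit_id") %>%
    left_join(pref, by = "unit_id") %>%
    mutate(
      m_pref = ifelse(.data$pref_arm == "left", .data$m_left,
                      .data$m_right),
      m_nonpref = ifelse(.data$pref_arm == "left", .data$m_right,
                         .data$m_left)
    )
}

#' Log-linear fit of preferred-arm modulation on arm preference
#'
#' Ordinary least squares of `log10(M_preferred)` on `|AP|` within the
#' ipsi-preferring (`AP < 0`) or contra-preferring (`AP > 0`) subgroup. A
#' slope of 1 means an order-of-magnitude increase in modulation between
#' fully arm-neutral and fully arm-dedicated units. Arm preference and
#' modulation must come from disjoint trial sets; the bootstrap resamples
#' units.
#'
#' @param metrics Tibble with one row per unit holding `arm_pref` (from
#'   the independent dataset) and `m_pref` (preferred-arm modulation).
#' @param subgroup `"contra"` or `"ipsi"`.
#' @param n_boot Bootstrap resamples for the 95% CI (0 to skip).
#' @param seed Seed for the bootstrap.
#' @return A `slope_fit` object; see [tidy.slope_fit()].
#' @export
fit_loglinear_slope <- function(metrics, subgroup = c("contra", "ipsi"),
                                n_boot = 1000, seed = 1L) {
  subgroup <- match.arg(subgroup)
  df <- metrics %>%
    filter(!is.na(.data$arm_pref), .data$m_pref > 0) %>%
    filter(if (subgroup == "contra") .data$arm_pref > 0 else
      .data$arm_pref < 0)
  if (nrow(df) < 3L) {
    stop(sprintf("subgroup '%s' has fewer than 3 units", subgroup),
         call. = FALSE)
  }
  df <- df %>% mutate(abs_ap = abs(.data$arm_pref),
                      log_m = log10(.data$m_pref))
  fit <- lm(log_m ~ abs_ap, data = df)
  out <- list(
    subgroup = subgroup,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n_units = nrow(df),
    data = df
  )
  if (n_boot > 0) {
    bs <- bootstrap_interval(
      df, function(d) coef(lm(log_m ~ abs_ap, data = d))[2],
      n_boot = n_boot, seed = seed
    )
    out$ci <- c(bs$lower, bs$upper)
    out$se <- bs$se
  }
  structure(out, class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> %s-preferring units (n = %d)\n",
              x$subgroup, x$n_units))
  cat(sprintf("  slope %.3f, intercept %.3f", x$slope, x$intercept))
  if (!is.null(x$ci)) cat(sprintf(", 95%% CI [%.3f, %.3f]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' Cumulative modulation across the arm-preference spectrum
#'
#' Sorts units by arm preference (measured on an independent trial set)
#' and accumulates the proportion of total modulation accounted for by all
#' units at or below each preference value, separately per arm. The curve
#' is a monotone step function from 0 to 1. The bootstrap (over units)
#' gives a standard error at each step of the original curve.
#'
#' @param metrics Tibble with `arm_pref` plus one modulation column per
#'   arm (default `m_contra`, `m_ipsi`).
#' @param arms Names of the modulation columns to accumulate.
#' @param n_boot Bootstrap resamples for the SE (0 to skip).
#' @param seed Bootstrap seed.
#' @return A `cumulative_modulation` tibble: `arm_pref`, `arm`,
#'   `cum_prop`, `se`.
#' @export
cumulative_modulation_curve <- function(metrics,
                                        arms = c("m_contra", "m_ipsi"),
                                        n_boot = 500, seed = 1L) {
  df <- metrics %>% filter(!is.na(.data$arm_pref)) %>%
    arrange(.data$arm_pref)
  out <- list()
  for (a in arms) {
    tot <- sum(df[[a]])
    if (tot <= 0) stop("total modulation is zero", call. = FALSE)
    cum <- cumsum(df[[a]]) / tot
    se <- rep(NA_real_, nrow(df))
    if (n_boot > 0) {
      with_substream(seed, paste0("cumcurve_", a), {
        boot <- replicate(n_boot, {
          idx <- sample(nrow(df), replace = TRUE)
          d <- df[idx, ][order(df$arm_pref[idx]), ]
          bc <- cumsum(d[[a]]) / sum(d[[a]])
          # evaluate the bootstrap step curve on the original grid
          stats::approx(d$arm_pref, bc, xout = df$arm_pref,
                        method = "constant", yleft = 0, yright = 1,
                        ties = "ordered")$y
        })
        se <- apply(boot, 1, sd)
      })
    }
    out[[a]] <- tibble(arm_pref = df$arm_pref, arm = a,
                       cum_prop = cum, se = se)
  }
  structure(bind_rows(out), class = c("cumulative_modulation",
                                      class(tibble())))
}

#' Arm-preference regime boundaries
#'
#' The three regimes used to summarize the dedicated/neutral split of the
#' population: contra-dedicated (`AP > 0.4`), ipsi-dedicated
#' (`AP < -0.4`) and arm-neutral (`-0.3 < AP < 0.3`), plus the two gap
#' bands between them.
#'
#' @return A tibble with `regime`, `lower`, `upper` (open intervals where
#'   stated).
#' @export
regime_partition <- function() {
  tibble(
    regime = c("ipsi_dedicated", "gap_ipsi", "neutral", "gap_contra",
               "contra_dedicated"),
    lower = c(-1, -0.4, -0.3, 0.3, 0.4),
    upper = c(-0.4, -0.3, 0.3, 0.4, 1)
  )
}

classify_regime <- function(ap) {
  dplyr::case_when(
    is.na(ap) ~ NA_character_,
    ap > 0.4 ~ "contra_dedicated",
    ap < -0.4 ~ "ipsi_dedicated",
    ap > -0.3 & ap < 0.3 ~ "neutral",
    ap >= 0.3 ~ "gap_contra",
    TRUE ~ "gap_ipsi"
  )
}

#' Proportion of modulation within each arm-preference regime
#'
#' For each arm, the proportion of total population modulation carried by
#' units in each regime of the arm-preference spectrum (arm preference
#' from an independent trial set). The five regime proportions (three
#' named regimes plus the two gap bands) sum to 1 per arm.
#'
#' @inheritParams cumulative_modulation_curve
#' @return A tibble with `arm`, `regime`, `proportion`.
#' @export
regime_modulation_proportions <- function(metrics,
                                          arms = c("m_contra", "m_ipsi")) {
  df <- metrics %>% filter(!is.na(.data$arm_pref)) %>%
    mutate(regime = classify_regime(.data$arm_pref))
  out <- list()
  for (a in arms) {
    tot <- sum(df[[a]])
    props <- df %>% group_by(.data$regime) %>%
      summarise(proportion = sum(.data[[a]]) / tot, .groups = "drop") %>%
      mutate(arm = a)
    out[[a]] <- props
  }
  full <- tidyr::expand_grid(arm = arms,
                             regime = regime_partition()$regime)
  full %>%
    left_join(bind_rows(out), by = c("arm", "regime")) %>%
    mutate(proportion = ifelse(is.na(.data$proportion), 0,
                               .data$proportion))
}

#' Flag significantly modulated units
#'
#' Two-sample t-test of per-trial phase-window means of the modulation
#' time course (the squared soft-normalized rate) against the matching
#' per-trial Rest-window means, per unit and arm, at the given
#' significance level; both offset- and variance-type departures from the
#' Rest state register.
#' Units are then categorized as ipsi-only, contra-only, bilateral or
#' unmodulated. Degenerate variance (e.g. a silent unit) yields a
#' non-significant flag with a warning.
#'
#' @param z Normalized units x bins matrix.
#' @param trials Trial table.
#' @param units Unit metadata tibble.
#' @param phase Phase to compare against Rest.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `unit_id`, `p_contra`, `p_ipsi`, `sig_contra`,
#'   `sig_ipsi`, `category`.
#' @export
flag_significant_modulation <- function(z, trials, units, phase = "move",
                                        alpha = 0.05) {
  contra_arm <- ifelse(units$hemisphere == "L", "right", "left")
  trial_means <- function(ph, arm) {
    tw <- extract_phase_windows(z, trials, ph, arms = arm)
    apply(tw^2, c(1, 3), mean)   # units x trials, modulation per trial
  }
  res <- lapply(c("left", "right"), function(arm) {
    ph_m <- trial_means(phase, arm)
    rest_m <- trial_means("rest", arm)
    if (ncol(ph_m) < 2L || ncol(rest_m) < 2L) {
      stop("need at least two trials per condition", call. = FALSE)
    }
    vapply(seq_len(nrow(ph_m)), function(i) {
      if (sd(ph_m[i, ]) < 1e-12 && sd(rest_m[i, ]) < 1e-12) {
        warning("degenerate variance for a unit; flagged not significant",
                call. = FALSE)
        return(1)
      }
      t.test(ph_m[i, ], rest_m[i, ])$p.value
    }, numeric(1))
  })
  names(res) <- c("left", "right")
  p_contra <- ifelse(contra_arm == "right", res$right, res$left)
  p_ipsi <- ifelse(contra_arm == "right", res$left, res$right)
  tibble(
    unit_id = units$unit_id,
    p_contra = p_contra, p_ipsi = p_ipsi,
    sig_contra = p_contra < alpha, sig_ipsi = p_ipsi < alpha,
    category = dplyr::case_when(
      p_contra < alpha & p_ipsi < alpha ~ "bilateral",
      p_contra < alpha ~ "contra_only",
      p_ipsi < alpha ~ "ipsi_only",
      TRUE ~ "none"
    )
  )
}
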