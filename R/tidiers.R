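#' Tidy a log-linear slope fit
#'
#' @param x A `slope_fit` from [fit_loglinear_slope()].
#' @param ... Unused.
#' @return One-row tibble with term estimates and the bootstrap CI.
#' @method tidy slope_fit
#' @export
tidy.slope_fit <- function(x, ...) {
  tibble(
    subgroup = x$subgroup,
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(NA_real_, if (is.null(x$ci)) NA_real_ else x$ci[1]),
    conf.high = c(NA_real_, if (is.null(x$ci)) NA_real_ else x$ci[2])
  )
}

#' @rdname tidy.slope_fit
#' @method glance slope_fit
#' @export
glance.slope_fit <- function(x, ...) {
  tibble(subgroup = x$subgroup, slope = x$slope, intercept = x$intercept,
         n_units = x$n_units,
         conf.low = if (is.null(x$ci)) NA_real_ else x$ci[1],
         conf.high = if (is.null(x$ci)) NA_real_ else x$ci[2])
}

#' Tidy a permutation test
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return One-row tibble: observed statistic, p-value, permutation count.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(observed = x$observed, p.value = x$p, n_perm = x$n_perm,
         alternative = x$alternative)
}

#' Tidy a dimensionality estimate
#'
#' @param x A `dimensionality_estimate`.
#' @param ... Unused.
#' @return Tibble of PRESS per candidate dimension with a `selected`
#'   flag.
#' @method tidy dimensionality_estimate
#' @export
tidy.dimensionality_estimate <- function(x, ...) {
  x$press %>% mutate(selected = .data$p == x$selected)
}

#' @rdname tidy.dimensionality_estimate
#' @method glance dimensionality_estimate
#' @export
glance.dimensionality_estimate <- function(x, ...) {
  tibble(selected = x$selected, n_units = x$n_units, n_trials = x$n_trials,
         min_press = min(x$press$press))
}

#' Tidy a subspace model
#'
#' @param x A `subspace_model`.
#' @param ... Unused.
#' @return Long tibble of coefficients: `unit_id`, `component`, `weight`.
#' @method tidy subspace_model
#' @export
tidy.subspace_model <- function(x, ...) {
  ids <- rownames(x$P) %||% sprintf("u%03d", seq_len(nrow(x$P)))
  tibble(
    unit_id = rep(ids, x$p),
    component = rep(seq_len(x$p), each = nrow(x$P)),
    weight = as.numeric(x$P)
  )
}

#' @rdname tidy.subspace_model
#' @method glance subspace_model
#' @export
glance.subspace_model <- function(x, ...) {
  tibble(p = x$p, n_units = x$n_units, n_samples = x$n_samples)
}
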