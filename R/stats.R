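#' Permutation test with restricted exchangeability
#'
#' Builds the null distribution by re-evaluating a statistic on permuted
#' data, permuting only labels that are exchangeable under the null
#' hypothesis. The p-value is the proportion of permutations whose
#' statistic is at least as extreme as the observed one (two-sided by
#' absolute value unless declared one-sided); when the observed statistic
#' is more extreme than every permutation the p-value is floored at
#' `1 / n_perm`.
#'
#' @param data Input passed to `statistic` and `permute`.
#' @param statistic Function `data -> scalar`.
#' @param permute Function `data -> permuted data` encapsulating the
#'   exchangeability restriction; see [permute_within_strata()].
#' @param n_perm Number of permutations (default 10000).
#' @param alternative `"two.sided"` (extremity by absolute value),
#'   `"greater"` or `"less"`.
#' @param seed Seed for the permutation stream.
#' @return A `perm_test` with `observed`, `null` (numeric vector), `p`,
#'   `n_perm`, `alternative`.
#' @export
permutation_test <- function(data, statistic, permute, n_perm = 10000,
                             alternative = c("two.sided", "greater", "less"),
                             seed = 1L) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  observed <- statistic(data)
  if (!is.finite(observed)) {
    stop("statistic is not finite on the observed data", call. = FALSE)
  }
  null <- numeric(n_perm)
  with_substream(seed, "permutation_test", {
    for (b in seq_len(n_perm)) {
      null[b] <- statistic(permute(data))
    }
  })
  bad <- !is.finite(null)
  if (mean(bad) > 0.01) {
    stop("statistic non-finite on more than 1% of permutations",
         call. = FALSE)
  }
  null[bad] <- 0
  extreme <- switch(alternative,
    two.sided = abs(null) >= abs(observed),
    greater = null >= observed,
    less = null <= observed
  )
  p <- max(mean(extreme), 1 / n_perm)
  structure(
    list(observed = observed, null = null, p = p, n_perm = n_perm,
         alternative = alternative),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> observed %.4g, p = %.4g (%d permutations, %s)\n",
              x$observed, x$p, x$n_perm, x$alternative))
  invisible(x)
}

#' Permute one label column within strata
#'
#' Returns a function that shuffles `label` within every combination of
#' the `strata` columns, leaving all other columns untouched -- the
#' building block for restricted-exchangeability permutation schemes
#' (e.g. permuting Phase labels within units to respect a crossed
#' design). With `check = TRUE` every permutation asserts that no label
#' left its stratum.
#'
#' @param label Column name to permute.
#' @param strata Character vector of stratum columns (empty for free
#'   permutation).
#' @param check Assert the stratum invariant on each call (test mode).
#' @return A function `data.frame -> data.frame`.
#' @export
permute_within_strata <- function(label, strata = character(), check = FALSE) {
  force(label); force(strata); force(check)
  function(df) {
    out <- df
    if (length(strata) == 0L) {
      out[[label]] <- sample(out[[label]])
    } else {
      key <- interaction(df[strata], drop = TRUE)
      for (s in levels(key)) {
        idx <- which(key == s)
        out[[label]][idx] <- sample(df[[label]][idx])
      }
      if (check) {
        before <- tapply(as.character(df[[label]]), key,
                         function(v) sort(v))
        after <- tapply(as.character(out[[label]]), key,
                        function(v) sort(v))
        stopifnot(identical(before, after))
      }
    }
    out
  }
}

#' Validate an exchangeability declaration against a design
#'
#' Checks that the permuted factor is actually crossed within the
#' declared strata (each stratum holds more than one label value, so
#' permutation is meaningful, and the factor counts are balanced across
#' strata where balance is declared).
#'
#' @param df Design data frame.
#' @param label Factor to be permuted.
#' @param strata Stratum columns.
#' @param balanced Require equal label counts within every stratum.
#' @return Invisibly `TRUE`; otherwise an error naming the stratum.
#' @export
validate_permutation_scheme <- function(df, label, strata,
                                        balanced = TRUE) {
  key <- if (length(strata)) interaction(df[strata], drop = TRUE) else
    factor(rep("all", nrow(df)))
  tab <- table(key, df[[label]])
  single <- rownames(tab)[rowSums(tab > 0) < 2L]
  if (length(single)) {
    stop(sprintf("stratum '%s' has a single %s level: labels not exchangeable",
                 single[1], label), call. = FALSE)
  }
  if (balanced) {
    uneven <- rownames(tab)[apply(tab, 1, function(r) length(unique(r)) > 1L)]
    if (length(uneven)) {
      stop(sprintf("stratum '%s' is unbalanced in %s", uneven[1], label),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Default statistics for factorial effects.
stat_level_spread <- function(value, fac) {
  # between-level variability of the level means; reduces to |difference|
  # behaviour for two levels and generalizes to three (Phase)
  means <- tapply(value, fac, mean)
  sqrt(sum((means - mean(means))^2))
}

#' Factorial effects by restricted permutation
#'
#' Tests main effects, simple effects and 2 x 2 interactions on a crossed
#' design table by permuting only the labels exchangeable under each
#' effect's null. Main effect of A: A labels permuted within the
#' resampling unit (and within co-factor levels when `within_cofactor`
#' strata are declared). Simple effect of A at `B = b`: the same on the
#' subset. Interaction A x B: A labels permuted within strata of B (and
#' the resampling unit), with the statistic the spread of A's effect
#' across B levels.
#'
#' @param df Long design table (one row per observation).
#' @param value Name of the response column.
#' @param effects A list of effect declarations, each a list with
#'   `type` (`"main"`, `"simple"`, `"interaction"`), `factor`, and
#'   optionally `within` (co-factor for simple effects, second factor for
#'   interactions) and `at` (level for simple effects).
#' @param unit Name of the resampling-unit column (labels permute within
#'   it); `NULL` for free exchange across rows.
#' @param statistic Optional custom statistic `function(value, fac)` for
#'   main/simple effects (default: spread of level means).
#' @param n_perm Permutations per effect.
#' @param seed Seed.
#' @return A tibble with one row per effect: `effect`, `factor`,
#'   `observed`, `p`, `n_perm`.
#' @export
factorial_permutation_effects <- function(df, value, effects, unit = NULL,
                                          statistic = NULL, n_perm = 2000,
                                          seed = 1L) {
  stat <- statistic %||% stat_level_spread
  rows <- list()
  for (k in seq_along(effects)) {
    ef <- effects[[k]]
    type <- ef$type %||% "main"
    fac <- ef$factor
    dd <- df
    strata <- if (is.null(unit)) character() else unit
    label_name <- fac
    if (type == "simple") {
      if (is.null(ef$within) || is.null(ef$at)) {
        stop("simple effects need `within` and `at`", call. = FALSE)
      }
      dd <- df[df[[ef$within]] == ef$at, , drop = FALSE]
      stat_fun <- function(d) stat(d[[value]], d[[fac]])
    } else if (type == "interaction") {
      if (is.null(ef$within)) {
        stop("interactions need `within` (the second factor)", call. = FALSE)
      }
      strata <- c(strata, ef$within)
      lv <- sort(unique(df[[fac]]))
      stat_fun <- function(d) {
        # centred A-level-mean profile per B level; the interaction is the
        # dispersion of those profiles (sensitive to sign reversals that an
        # unsigned per-level effect size would miss)
        profs <- tapply(seq_len(nrow(d)), d[[ef$within]], function(idx) {
          m <- tapply(d[[value]][idx], factor(d[[fac]][idx], levels = lv),
                      mean)
          m - mean(m)
        })
        pm <- do.call(rbind, profs)
        sqrt(sum(sweep(pm, 2, colMeans(pm))^2))
      }
    } else {
      stat_fun <- function(d) stat(d[[value]], d[[fac]])
    }
    validate_permutation_scheme(dd, label_name, strata, balanced = FALSE)
    res <- permutation_test(
      dd, stat_fun,
      permute_within_strata(label_name, strata),
      n_perm = n_perm, alternative = "greater",
      seed = substream_seed(seed, paste0("effect", k))
    )
    rows[[k]] <- tibble(
      effect = type, factor = fac,
      within = if (is.null(ef$within)) NA_character_ else ef$within,
      at = if (is.null(ef$at)) NA_character_ else as.character(ef$at),
      observed = res$observed, p = res$p, n_perm = res$n_perm
    )
  }
  bind_rows(rows)
}

#' Bootstrap confidence interval and standard error
#'
#' Percentile bootstrap over the declared resampling unit (rows of a data
#' frame, or elements of a vector), seeded for reproducibility.
#'
#' @param data Data frame (rows resampled) or vector.
#' @param statistic Function of the resampled data returning a scalar.
#' @param n_boot Resamples (default 1000; below 100 triggers a warning).
#' @param level Confidence level (default 0.95).
#' @param seed Seed.
#' @return A tibble with `estimate`, `se`, `lower`, `upper`, `level`,
#'   `n_boot`.
#' @export
bootstrap_interval <- function(data, statistic, n_boot = 1000,
                               level = 0.95, seed = 1L) {
  if (n_boot < 100) {
    warning("fewer than 100 bootstrap resamples; interval will be crude",
            call. = FALSE)
  }
  take <- function(d, idx) {
    if (is.data.frame(d)) d[idx, , drop = FALSE] else d[idx]
  }
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  est <- statistic(data)
  with_substream(seed, "bootstrap", {
    boots <- vapply(seq_len(n_boot), function(b) {
      as.numeric(statistic(take(data, sample(n, replace = TRUE))))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- quantile(boots, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  tibble(
    estimate = as.numeric(est), se = sd(boots),
    lower = qs[1], upper = qs[2], level = level, n_boot = n_boot
  )
}
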