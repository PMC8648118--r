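#' Fit a principal-component subspace model
#'
#' Computes the top `p` right singular vectors of the concatenated
#' windowed data matrix `X` (`16m x n`). Because the Rest-phase mean has
#' already been subtracted during soft normalization, the data are *not*
#' re-centered before the decomposition. Columns are ordered by singular
#' value, with a deterministic sign convention (the largest-magnitude
#' coefficient of each component is positive).
#'
#' @param x Samples x units matrix (e.g. from [tensor_matrix()]).
#' @param p Number of components (default 4).
#' @param descriptor Optional free-form training descriptor (arm, phase,
#'   trial partition, normalization mode) carried in the model.
#' @return A `subspace_model` with orthonormal coefficients `P`
#'   (`n x p`), singular values `d`, and `p`.
#' @export
fit_subspace <- function(x, p = 4, descriptor = NULL) {
  x <- as.matrix(x)
  if (p < 1 || p > ncol(x)) {
    stop("p must lie between 1 and the number of units", call. = FALSE)
  }
  s <- svd(x, nu = 0, nv = min(ncol(x), nrow(x)))
  rank_x <- sum(s$d > 1e-10 * max(s$d, .Machine$double.eps))
  if (rank_x < p) {
    stop(sprintf("requested %d components but data rank is %d", p, rank_x),
         call. = FALSE)
  }
  coef <- s$v[, seq_len(p), drop = FALSE]
  for (j in seq_len(p)) {
    if (coef[which.max(abs(coef[, j])), j] < 0) coef[, j] <- -coef[, j]
  }
  rownames(coef) <- colnames(x)
  structure(
    list(P = coef, d = s$d[seq_len(p)], p = p,
         n_units = ncol(x), n_samples = nrow(x),
         descriptor = descriptor),
    class = "subspace_model"
  )
}

#' @export
print.subspace_model <- function(x, ...) {
  cat(sprintf("<subspace_model> %d components over %d units (%d samples)\n",
              x$p, x$n_units, x$n_samples))
  if (!is.null(x$descriptor)) cat("  ", x$descriptor, "\n")
  invisible(x)
}

coef_matrix <- function(model) {
  if (inherits(model, "subspace_model")) model$P else as.matrix(model)
}

#' Variance captured by a projection
#'
#' The trace of the covariance of the component scores `X P` -- raw
#' captured variance, not a proportion of total. Computed from the score
#' covariance so that uncentered means do not inflate the value.
#'
#' @param x Samples x units matrix.
#' @param model A `subspace_model` or a coefficient matrix (`n x p`).
#' @return A single non-negative number.
#' @export
variance_captured <- function(x, model) {
  p <- coef_matrix(model)
  x <- as.matrix(x)
  if (ncol(x) != nrow(p)) {
    stop(sprintf("data has %d units but projection expects %d",
                 ncol(x), nrow(p)), call. = FALSE)
  }
  trace_var(x %*% p)
}

#' Reconstruct a left-out unit from the remaining population
#'
#' Component scores for a test window are estimated from the other
#' `n - 1` units through the Moore--Penrose pseudoinverse of the
#' row-deleted coefficient matrix, then projected back into the ambient
#' space; the left-out unit's row of that back-projection is its
#' reconstruction. This is the inner step of the cross-validated
#' dimensionality estimate.
#'
#' @param model A `subspace_model` fit without the test trial.
#' @param x_test Samples x units matrix for the held-out trial.
#' @param j Index of the left-out unit.
#' @return Numeric vector: the reconstructed trace of unit `j`.
#' @export
reconstruct_left_out_unit <- function(model, x_test, j) {
  p_mat <- coef_matrix(model)
  x_test <- as.matrix(x_test)
  n <- nrow(p_mat)
  stopifnot(j >= 1, j <= n, ncol(x_test) == n)
  p_minus <- p_mat[-j, , drop = FALSE]
  if (qr(p_minus)$rank < ncol(p_mat)) {
    stop("row-deleted coefficient matrix is rank deficient", call. = FALSE)
  }
  scores <- pinv(p_minus) %*% t(x_test[, -j, drop = FALSE])
  as.numeric(p_mat[j, , drop = FALSE] %*% scores)
}

#' Estimate subspace dimensionality by cross-validated reconstruction
#'
#' For every candidate dimension `p`, every trial is left out in turn, a
#' model is fit to the remaining trials, and every unit of the held-out
#' trial is reconstructed from the other units (leave-one-trial-out x
#' leave-one-unit-out). The predicted residual error sum of squares
#' (PRESS) accumulates the squared reconstruction errors; the selected
#' dimensionality minimizes PRESS. There is no mathematical pressure
#' toward higher `p`, so the estimate is robust to overfitting.
#'
#' The inner pseudoinverse uses the orthonormality of the coefficients:
#' deleting row `j` leaves `P'P = I - p_j p_j'`, inverted by a rank-one
#' (Sherman--Morrison) update, with an SVD fallback when a unit nearly
#' owns a whole component.
#'
#' @param tensor A `rate_tensor` (units x samples x trials), normally from
#'   centered-start-configuration trials only.
#' @param p_range Candidate dimensions (default `1:10`).
#' @return A `dimensionality_estimate`: tibble of PRESS per `p` plus the
#'   selected dimension.
#' @export
estimate_dimensionality <- function(tensor, p_range = 1:10) {
  d <- dim(tensor)
  n <- d[1]; m <- d[3]
  if (m < 4L) stop("too few trials for leave-one-trial-out", call. = FALSE)
  if (max(p_range) >= n) {
    stop("candidate dimensions must be below the unit count", call. = FALSE)
  }
  press <- setNames(numeric(length(p_range)), p_range)
  pmax_ <- max(p_range)
  for (i in seq_len(m)) {
    x_train <- tensor_matrix(tensor[, , -i, drop = FALSE])
    x_test <- t(tensor[, , i])                       # samples x units
    s <- svd(x_train, nu = 0, nv = pmax_)
    v <- s$v
    for (pi in seq_along(p_range)) {
      p <- p_range[pi]
      pp <- v[, seq_len(p), drop = FALSE]
      press[pi] <- press[pi] + press_trial(pp, x_test)
    }
  }
  est <- tibble(p = as.integer(p_range), press = unname(press))
  structure(
    list(press = est, selected = est$p[which.min(est$press)],
         n_units = n, n_trials = m),
    class = "dimensionality_estimate"
  )
}

# Squared reconstruction error summed over left-out units for one trial.
press_trial <- function(pp, x_test) {
  n <- nrow(pp)
  p <- ncol(pp)
  err <- 0
  for (j in seq_len(n)) {
    pj <- pp[j, ]
    nj2 <- sum(pj^2)
    xmj <- x_test[, -j, drop = FALSE]
    if (nj2 < 1 - 1e-8) {
      # (P_{-j}' P_{-j})^{-1} = I + p_j p_j' / (1 - |p_j|^2)
      b <- t(pp[-j, , drop = FALSE]) %*% t(xmj)     # p x 16
      scores <- b + pj %*% (crossprod(pj, b) / (1 - nj2))
    } else {
      scores <- pinv(pp[-j, , drop = FALSE]) %*% t(xmj)
    }
    xhat <- as.numeric(pj %*% scores)
    err <- err + sum((x_test[, j] - xhat)^2)
  }
  err
}

#' @export
print.dimensionality_estimate <- function(x, ...) {
  cat(sprintf(
    "<dimensionality_estimate> selected p = %d (%d units, %d trials)\n",
    x$selected, x$n_units, x$n_trials
  ))
  invisible(x)
}

#' Covariance alignment between two subspaces
#'
#' The proportion of one dataset's low-dimensional variance that is also
#' captured in another dataset's low-dimensional subspace:
#' the data are projected into their own `p`-dimensional space, then that
#' low-dimensional representation is projected into the other model's
#' space (a *double* projection), and the ratio of the two traces is
#' returned. Identical organization gives 1 regardless of signal
#' magnitude; orthogonally reorganized activity gives 0; the value always
#' lies in `[0, 1]` and is invariant to positive rescaling of the data.
#'
#' @param x_a Samples x units matrix whose variance is being traced.
#' @param model_a Subspace model (or coefficient matrix) fit to `x_a`.
#' @param model_b Subspace model (or coefficients) defining the target
#'   space.
#' @return A single number in `[0, 1]`, or `NA` when `x_a` has no
#'   low-dimensional variance.
#' @export
covariance_alignment <- function(x_a, model_a, model_b) {
  pa <- coef_matrix(model_a)
  pb <- coef_matrix(model_b)
  stopifnot(nrow(pa) == nrow(pb), ncol(pa) == ncol(pb))
  ta <- as.matrix(x_a) %*% pa
  va <- trace_var(ta)
  if (va <= .Machine$double.eps) {
    return(NA_real_)
  }
  trace_var(ta %*% crossprod(pa, pb)) / va
}

#' Native and cross covariance alignment between arms
#'
#' *Native* alignment fits models to random halves of one arm's trials
#' and measures the alignment between the halves -- the ceiling set by
#' estimation noise. *Cross* alignment fits models to (random halves of)
#' each arm's trials and measures the alignment between arms. Both are
#' Monte-Carlo averaged over random partitions and over the two
#' projection directions.
#'
#' @param tensor_left,tensor_right `rate_tensor`s for left- and right-arm
#'   trials over the same units.
#' @param p Subspace dimension (default 4).
#' @param n_partitions Random partitions to average (default 25).
#' @param seed Seed for the partitioning.
#' @return An `alignment_result` tibble: `kind` (`native_left`,
#'   `native_right`, `cross`), `direction`, `ca` per partition, plus a
#'   summary attribute.
#' @export
native_cross_alignment <- function(tensor_left, tensor_right, p = 4,
                                   n_partitions = 25, seed = 1L) {
  halves <- function(m) {
    h <- floor(m / 2)
    idx <- sample(m, 2 * h)      # odd trial counts drop one at random
    list(a = idx[seq_len(h)], b = idx[h + seq_len(h)])
  }
  fit_half <- function(tensor, idx) {
    x <- tensor_matrix(tensor[, , idx, drop = FALSE])
    list(x = x, model = fit_subspace(x, p))
  }
  rows <- list()
  with_substream(seed, "native_cross", {
    for (r in seq_len(n_partitions)) {
      for (arm in c("left", "right")) {
        tensor <- if (arm == "left") tensor_left else tensor_right
        m <- dim(tensor)[3]
        if (m < 4L) stop("too few trials to halve", call. = FALSE)
        hh <- halves(m)
        fa <- fit_half(tensor, hh$a); fb <- fit_half(tensor, hh$b)
        rows[[length(rows) + 1L]] <- tibble(
          kind = paste0("native_", arm), partition = r,
          direction = c("a_in_b", "b_in_a"),
          ca = c(covariance_alignment(fa$x, fa$model, fb$model),
                 covariance_alignment(fb$x, fb$model, fa$model))
        )
      }
      hl <- halves(dim(tensor_left)[3]); hr <- halves(dim(tensor_right)[3])
      fl <- fit_half(tensor_left, hl$a); fr <- fit_half(tensor_right, hr$a)
      rows[[length(rows) + 1L]] <- tibble(
        kind = "cross", partition = r,
        direction = c("left_in_right", "right_in_left"),
        ca = c(covariance_alignment(fl$x, fl$model, fr$model),
               covariance_alignment(fr$x, fr$model, fl$model))
      )
    }
  })
  out <- bind_rows(rows)
  summary <- out %>%
    group_by(.data$kind) %>%
    summarise(mean_ca = mean(.data$ca), sd_ca = sd(.data$ca),
              .groups = "drop")
  structure(out, summary = summary,
            class = c("alignment_result", class(tibble())))
}

#' Summarize an alignment result
#' @param x An `alignment_result`.
#' @return Tibble of mean and SD of CA per kind.
#' @export
alignment_summary <- function(x) attr(x, "summary")

#' Covariance alignment between all pairs of timepoints
#'
#' For every pair of timepoints, trials are repeatedly split into two
#' disjoint random halves; a `p`-dimensional model is fit to one half at
#' the first timepoint and to the other half at the second, and the
#' covariance alignment of the first half's data in the second model's
#' space is computed. Each timepoint contributes a single 20 ms sample
#' per trial (separate models per timepoint). Averaging over repetitions
#' yields a time x time alignment matrix; block-diagonal structure
#' indicates phase-specific subspaces.
#'
#' @param tensor Event-locked `rate_tensor` (units x time x trials).
#' @param p Subspace dimension (default 4).
#' @param n_partitions Random partitions to average (default 10).
#' @param seed Partition seed.
#' @return An `alignment_matrix`: time x time matrix of mean CA with the
#'   sample offsets as dimnames.
#' @export
alignment_timecourse <- function(tensor, p = 4, n_partitions = 10,
                                 seed = 1L) {
  d <- dim(tensor)
  nt <- d[2]; m <- d[3]
  if (m < 4L) stop("too few trials to halve", call. = FALSE)
  acc <- matrix(0, nt, nt)
  cnt <- matrix(0, nt, nt)
  with_substream(seed, "alignment_timecourse", {
    h <- floor(m / 2)
    for (r in seq_len(n_partitions)) {
      idx <- sample(m, 2 * h)
      ia <- idx[seq_len(h)]; ib <- idx[h + seq_len(h)]
      xa <- lapply(seq_len(nt), function(t) t(tensor[, t, ia]))
      xb <- lapply(seq_len(nt), function(t) t(tensor[, t, ib]))
      ma <- lapply(xa, fit_subspace, p = p)
      mb <- lapply(xb, fit_subspace, p = p)
      for (t1 in seq_len(nt)) {
        for (t2 in seq_len(nt)) {
          ca <- covariance_alignment(xa[[t1]], ma[[t1]], mb[[t2]])
          if (!is.na(ca)) {
            acc[t1, t2] <- acc[t1, t2] + ca
            cnt[t1, t2] <- cnt[t1, t2] + 1
          }
        }
      }
    }
  })
  out <- acc / pmax(cnt, 1)
  offs <- attr(tensor, "offsets")
  if (!is.null(offs)) dimnames(out) <- list(offs, offs)
  structure(out, class = "alignment_matrix")
}

#' Per-component variance ratio between arms
#'
#' The ratio of the variances of held-out right- and left-arm activity
#' projected onto a single component. Ratios far from 1 (log far from 0)
#' mark components that discriminate between the arms.
#'
#' @param x_right,x_left Samples x units matrices of held-out data.
#' @param component Coefficient vector (`n x 1`) of one component.
#' @return The variance ratio (right over left); infinite with a warning
#'   when the left-arm variance is zero.
#' @export
component_variance_ratio <- function(x_right, x_left, component) {
  component <- as.numeric(component)
  vr <- var(as.numeric(as.matrix(x_right) %*% component))
  vl <- var(as.numeric(as.matrix(x_left) %*% component))
  if (vl <= .Machine$double.eps) {
    warning("zero denominator variance; ratio is infinite", call. = FALSE)
    return(Inf)
  }
  vr / vl
}

#' Coefficient-weighted arm preference of a component
#'
#' The average of the units' arm preferences weighted by the absolute
#' component coefficients: 1 when non-zero weights fall only on fully
#' right-dedicated units, 0 when equal weights cover a preference-
#' symmetric population. Captures how strongly a component depends on
#' arm-dedicated units.
#'
#' @param arm_pref Numeric vector of per-unit arm preferences (held-out
#'   dataset), length `n`.
#' @param component Coefficient vector of one component, length `n`.
#' @return A single number in `[-1, 1]`.
#' @export
coefficient_weighted_arm_preference <- function(arm_pref, component) {
  w <- abs(as.numeric(component))
  stopifnot(length(arm_pref) == length(w))
  if (sum(w) <= 0) stop("component has all-zero coefficients", call. = FALSE)
  sum(arm_pref * w) / sum(w)
}

#' Component structure of per-arm subspace models
#'
#' Fits a subspace model per arm on training trials and evaluates, for
#' each component, the right/left variance ratio on held-out trials and
#' the coefficient-weighted arm preference. This is the component-level
#' analysis linking subspace divergence to arm-dedicated units.
#'
#' @param train_left,train_right,test_left,test_right Samples x units
#'   matrices (train and test from disjoint trial sets).
#' @param arm_pref Held-out per-unit arm preferences.
#' @param p Components per model (default 5 are reported).
#' @return A tibble: `train_arm`, `component`, `variance_ratio`,
#'   `log10_ratio`, `cap`.
#' @export
component_structure <- function(train_left, train_right,
                                test_left, test_right, arm_pref, p = 5) {
  rows <- list()
  for (arm in c("left", "right")) {
    model <- fit_subspace(if (arm == "left") train_left else train_right, p)
    for (cidx in seq_len(p)) {
      pc <- model$P[, cidx]
      vr <- component_variance_ratio(test_right, test_left, pc)
      rows[[length(rows) + 1L]] <- tibble(
        train_arm = arm, component = cidx, variance_ratio = vr,
        log10_ratio = log10(vr),
        cap = coefficient_weighted_arm_preference(arm_pref, pc)
      )
    }
  }
  bind_rows(rows)
}

#' Variance ratio in the distributed subspace
#'
#' Splits the population into subgroups by preferred arm (from held-out
#' data), fits a `p`-dimensional model to each subgroup's activity during
#' trials of its *non-preferred* arm (a conservative way of isolating the
#' distributed component, since dedicated activity is absent on those
#' trials), and measures the raw captured variance of held-out
#' non-preferred and preferred trials in that space. The ratio is
#' non-preferred over preferred: near 1 when both arms share the
#' subspace with equal magnitude, far above 1 when the preferred arm's
#' activity falls in the null space (purely dedicated organization),
#' and below 1 when the preferred arm engages the shared subspace more
#' strongly.
#'
#' @param tensors Named list with `left` and `right` `rate_tensor`s per
#'   trial arm for the *training* configuration, and `left_test`,
#'   `right_test` for the held-out configuration.
#' @param pref Tibble from [assign_preferred_arm()] aligned to the tensor
#'   unit order.
#' @param p Subspace dimension (default 4).
#' @return A tibble: `subgroup`, `n_units`, `v_nonpref`, `v_pref`,
#'   `ratio`.
#' @export
distributed_subspace_variance_ratio <- function(tensors, pref, p = 4) {
  out <- list()
  for (grp_arm in c("left", "right")) {
    sel <- which(pref$pref_arm == grp_arm)
    if (length(sel) == 0L) {
      stop(sprintf("no units prefer the %s arm", grp_arm), call. = FALSE)
    }
    nonpref_arm <- if (grp_arm == "left") "right" else "left"
    x_train <- tensor_matrix(tensors[[nonpref_arm]])[, sel, drop = FALSE]
    model <- fit_subspace(x_train, p)
    x_np <- tensor_matrix(tensors[[paste0(nonpref_arm, "_test")]])[, sel,
                                                                   drop = FALSE]
    x_pr <- tensor_matrix(tensors[[paste0(grp_arm, "_test")]])[, sel,
                                                               drop = FALSE]
    v_np <- variance_captured(x_np, model)
    v_pr <- variance_captured(x_pr, model)
    out[[grp_arm]] <- tibble(
      subgroup = paste0(grp_arm, "_preferring"),
      n_units = length(sel),
      v_nonpref = v_np, v_pref = v_pr,
      ratio = ifelse(v_pr <= .Machine$double.eps, Inf, v_np / v_pr)
    )
  }
  bind_rows(out)
}
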