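#' Fit a pooled-covariance linear discriminant classifier
#'
#' Gaussian discriminant with one mean per class, a single pooled
#' within-class covariance, and uniform priors. Models are intended to be
#' fit separately per arm so each arm gets its own covariance. When the
#' pooled covariance is singular or near-singular (units outnumbering
#' trials), diagonal shrinkage toward the average within-class variance is
#' applied with a fixed small coefficient and a warning.
#'
#' @param x Trials x units feature matrix (one value per unit per trial:
#'   an instantaneous rate or a 300 ms window mean).
#' @param labels Class labels (targets, or arm identities), length
#'   `nrow(x)`.
#' @param shrinkage Diagonal shrinkage coefficient used when needed
#'   (default 0.05).
#' @return A `pooled_lda` model.
#' @export
fit_target_classifier <- function(x, labels, shrinkage = 0.05) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (!all(is.finite(x))) stop("features must be finite", call. = FALSE)
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("each class needs at least two trials", call. = FALSE)
  }
  means <- do.call(rbind, lapply(classes, function(k) {
    colMeans(x[labels == k, , drop = FALSE])
  }))
  centered <- x - means[match(labels, classes), , drop = FALSE]
  pooled <- crossprod(centered) / (nrow(x) - length(classes))
  shrunk <- FALSE
  ev_ok <- function(s) {
    e <- tryCatch(min(eigen(s, symmetric = TRUE,
                            only.values = TRUE)$values), error = function(...) -1)
    e > 1e-10 * max(diag(s), 1e-12)
  }
  if (!ev_ok(pooled)) {
    target <- mean(diag(pooled))
    if (target <= 0) target <- 1e-8
    pooled <- (1 - shrinkage) * pooled +
      shrinkage * diag(target, ncol(pooled))
    shrunk <- TRUE
    warning(sprintf(
      "singular pooled covariance: diagonal shrinkage %.2f applied",
      shrinkage
    ), call. = FALSE)
  }
  structure(
    list(classes = classes, means = means, sigma_inv = solve(pooled),
         shrunk = shrunk, n_features = ncol(x)),
    class = "pooled_lda"
  )
}

#' @export
predict.pooled_lda <- function(object, newdata, ...) {
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  stopifnot(ncol(x) == object$n_features)
  # linear discriminant per class; uniform priors drop out of the argmax
  a <- object$sigma_inv %*% t(object$means)              # n x K
  b <- -0.5 * colSums(t(object$means) * a)               # K
  scores <- x %*% a + matrix(b, nrow(x), length(b), byrow = TRUE)
  object$classes[max.col(scores, ties.method = "first")]
}

#' @export
print.pooled_lda <- function(x, ...) {
  cat(sprintf("<pooled_lda> %d classes, %d features%s\n",
              length(x$classes), x$n_features,
              if (x$shrunk) " (shrunk covariance)" else ""))
  invisible(x)
}

#' Leave-one-out accuracy of the pooled-covariance classifier
#'
#' @param x Trials x units feature matrix.
#' @param labels Class labels.
#' @param ... Passed to [fit_target_classifier()].
#' @return Proportion of held-out trials classified correctly.
#' @export
loo_accuracy <- function(x, labels, ...) {
  labels <- as.character(labels)
  hits <- vapply(seq_len(nrow(x)), function(i) {
    model <- suppressWarnings(
      fit_target_classifier(x[-i, , drop = FALSE], labels[-i], ...)
    )
    predict(model, x[i, , drop = FALSE]) == labels[i]
  }, logical(1))
  mean(hits)
}

#' Cross-temporal classification accuracy matrix
#'
#' For each training timepoint, a classifier is fit on all-but-one trial
#' using that timepoint's single-sample features, and the held-out trial
#' is classified at every test timepoint; iterating over held-out trials
#' and averaging the hit booleans yields a train-time x test-time
#' accuracy matrix. Diagonal blocks of high accuracy reveal phase-local
#' population codes; off-diagonal spread reveals cross-phase
#' generalization.
#'
#' @param tensor Event-locked `rate_tensor` (units x time x trials),
#'   typically one arm's trials.
#' @param labels Per-trial class labels (length = trial count).
#' @param shrinkage Passed to [fit_target_classifier()].
#' @return A `cross_temporal_matrix`: train x test accuracy matrix with
#'   `offsets` dimnames and a `chance` attribute (1 / number of classes).
#' @export
cross_temporal_accuracy <- function(tensor, labels, shrinkage = 0.05) {
  d <- dim(tensor)
  nt <- d[2]; m <- d[3]
  labels <- as.character(labels)
  stopifnot(length(labels) == m)
  acc <- matrix(0, nt, nt)
  for (i in seq_len(m)) {
    if (length(unique(labels[-i])) < length(unique(labels))) {
      stop("a class is absent from a training fold", call. = FALSE)
    }
    for (t1 in seq_len(nt)) {
      xtr <- t(tensor[, t1, -i, drop = TRUE])
      model <- suppressWarnings(
        fit_target_classifier(xtr, labels[-i], shrinkage = shrinkage)
      )
      feats <- t(tensor[, , i, drop = TRUE])             # time x units
      hits <- predict(model, feats) == labels[i]
      acc[t1, ] <- acc[t1, ] + hits
    }
  }
  out <- acc / m
  offs <- attr(tensor, "offsets")
  if (!is.null(offs)) dimnames(out) <- list(offs, offs)
  structure(out, chance = 1 / length(unique(labels)),
            class = "cross_temporal_matrix")
}

#' Rest-phase arm (and target) classification on repeat vs switch trials
#'
#' Under a blocked schedule the forthcoming arm is predictable whenever
#' the previous trial used the same arm. Classifiers are trained per
#' timepoint on repeat trials only (previous arm equal to current arm)
#' and evaluated on held-out repeat trials (leave-one-out) and on switch
#' trials (first trial of each block).
#'
#' @param tensor Event-locked `rate_tensor` spanning the Rest period for
#'   all trials.
#' @param trials Trial table aligned with the tensor (needs `arm`,
#'   `prev_arm`, and `target` when `task = "target"`).
#' @param task `"arm"` (default) or `"target"`.
#' @param shrinkage Passed to the classifier.
#' @return A tibble: `offset` (s), `set` (`repeat`/`switch`), `accuracy`,
#'   `chance`.
#' @export
rest_arm_classification <- function(tensor, trials, task = c("arm", "target"),
                                    shrinkage = 0.05) {
  task <- match.arg(task)
  labels <- if (task == "arm") trials$arm else as.character(trials$target)
  is_repeat <- !is.na(trials$prev_arm) & trials$prev_arm == trials$arm
  if (!any(!is_repeat)) stop("no switch trials in the schedule", call. = FALSE)
  if (!any(is_repeat)) stop("no repeat trials in the schedule", call. = FALSE)
  nt <- dim(tensor)[2]
  offs <- attr(tensor, "offsets") %||% seq_len(nt)
  rep_idx <- which(is_repeat)
  sw_idx <- which(!is_repeat)
  rows <- list()
  for (t1 in seq_len(nt)) {
    feats <- t(tensor[, t1, , drop = TRUE])              # trials x units
    rep_acc <- loo_accuracy(feats[rep_idx, , drop = FALSE],
                            labels[rep_idx], shrinkage = shrinkage)
    model <- suppressWarnings(
      fit_target_classifier(feats[rep_idx, , drop = FALSE],
                            labels[rep_idx], shrinkage = shrinkage)
    )
    sw_acc <- mean(predict(model, feats[sw_idx, , drop = FALSE]) ==
                     labels[sw_idx])
    rows[[t1]] <- tibble(
      offset = offs[t1], set = c("repeat", "switch"),
      accuracy = c(rep_acc, sw_acc),
      chance = 1 / length(unique(labels))
    )
  }
  bind_rows(rows)
}
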