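#' Bin, square-root transform and smooth spike trains
#'
#' Converts spike times into square-root-scale firing-rate traces: counts
#' in non-overlapping 20 ms bins, square root of the counts (variance
#' stabilization), then convolution with a Gaussian kernel of 50 ms
#' standard deviation (truncated at three standard deviations and
#' renormalized to unit mass, including at the trace edges, so a constant
#' trace is a fixed point of the smoothing). Output samples sit at bin
#' centers, giving an effective 50 Hz sampling rate.
#'
#' @param spikes Named list of non-decreasing spike-time vectors (s), or a
#'   `bilat_session`. Gaussian-mode sessions already carry rate matrices
#'   and are returned as they are.
#' @param t_start,t_end Session bounds (s); defaults cover all spikes.
#' @param bin_width Bin width in seconds (default 0.02).
#' @param kernel_sd Gaussian kernel standard deviation in seconds
#'   (default 0.05).
#' @return A units x bins matrix with attribute `times` (bin centers, s)
#'   and `bin_width`. An empty unit yields an all-zero row.
#' @export
bin_and_smooth <- function(spikes, t_start = NULL, t_end = NULL,
                           bin_width = 0.02, kernel_sd = 0.05) {
  if (inherits(spikes, "bilat_session")) {
    return(session_rates(spikes, bin_width = bin_width,
                         kernel_sd = kernel_sd))
  }
  stopifnot(is.list(spikes))
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  all_t <- unlist(spikes, use.names = FALSE)
  t_start <- t_start %||% 0
  t_end <- t_end %||% (if (length(all_t)) max(all_t) + bin_width else 1)
  breaks <- seq(t_start, t_end + bin_width, by = bin_width)
  centers <- head(breaks, -1L) + bin_width / 2
  k <- gaussian_kernel(kernel_sd, bin_width)
  rates <- t(vapply(spikes, function(st) {
    counts <- if (length(st)) {
      tabulate(findInterval(st, breaks, rightmost.closed = FALSE,
                            left.open = FALSE),
               nbins = length(centers))
    } else {
      integer(length(centers))
    }
    smooth_normalized(sqrt(counts), k)
  }, numeric(length(centers))))
  rownames(rates) <- names(spikes)
  attr(rates, "times") <- centers
  attr(rates, "bin_width") <- bin_width
  rates
}

# Gaussian kernel on the bin grid, truncated at +/- 3 sd, unit mass.
gaussian_kernel <- function(kernel_sd, bin_width) {
  r <- floor(3 * kernel_sd / bin_width)
  k <- exp(-((-r:r) * bin_width)^2 / (2 * kernel_sd^2))
  k / sum(k)
}

# Normalized convolution: at the edges the truncated kernel is
# renormalized by the local mass so constants stay constant.
smooth_normalized <- function(x, k) {
  num <- stats::filter(x, k, sides = 2)
  den <- stats::filter(rep(1, length(x)), k, sides = 2)
  out <- as.numeric(num / den)
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  for (i in which(is.na(out))) {
    lo <- max(1L, i - r); hi <- min(n, i + r)
    kk <- k[(lo - i + r + 1L):(hi - i + r + 1L)]
    out[i] <- sum(x[lo:hi] * kk) / sum(kk)
  }
  out
}

#' Full-session rate matrix for a session
#'
#' Dispatches on the session's noise model: Poisson-mode sessions are
#' binned, square-root transformed and smoothed via [bin_and_smooth()];
#' Gaussian-mode sessions already carry square-root-scale rate samples on
#' the 20 ms grid and are returned unchanged.
#'
#' @param session A `bilat_session`.
#' @inheritParams bin_and_smooth
#' @return A units x bins matrix with `times` and `bin_width` attributes.
#' @export
session_rates <- function(session, bin_width = 0.02, kernel_sd = 0.05) {
  stopifnot(inherits(session, "bilat_session"))
  if (!is.null(session$rates)) {
    out <- session$rates
    attr(out, "times") <- session$times
    attr(out, "bin_width") <- session$bin_width
    return(out)
  }
  bin_and_smooth(session$spikes, t_start = 0,
                 t_end = max(session$times) + bin_width / 2,
                 bin_width = bin_width, kernel_sd = kernel_sd)
}

#' Rest-phase statistics per unit
#'
#' Computes each unit's Rest-phase mean and standard deviation from the
#' 300 ms pre-instruction windows. The mean pools Rest samples from both
#' arms' trials; the standard deviation is computed separately for trials
#' of each arm and then averaged, so small arm-specific Rest offsets do
#' not inflate the spread estimate.
#'
#' @param rates Units x bins rate matrix (see [session_rates()]).
#' @param trials Trial table with `arm` and `instruct_onset`.
#' @return A tibble with `unit_id`, `mu_rest`, `sd_rest`, `sd_left`,
#'   `sd_right`.
#' @export
compute_rest_statistics <- function(rates, trials) {
  times <- attr(rates, "times")
  for (arm in c("left", "right")) {
    if (sum(trials$arm == arm) < 1L) {
      stop(sprintf("no %s-arm trials: Rest statistics undefined", arm),
           call. = FALSE)
    }
  }
  idx_by_arm <- lapply(c("left", "right"), function(arm) {
    tr <- trials[trials$arm == arm, , drop = FALSE]
    phase_bin_index(times, tr, "rest")
  })
  names(idx_by_arm) <- c("left", "right")
  pooled <- c(idx_by_arm$left, idx_by_arm$right)
  tibble(
    unit_id = rownames(rates) %||% sprintf("u%03d", seq_len(nrow(rates))),
    mu_rest = rowMeans(rates[, pooled, drop = FALSE]),
    sd_left = apply(rates[, idx_by_arm$left, drop = FALSE], 1, sd),
    sd_right = apply(rates[, idx_by_arm$right, drop = FALSE], 1, sd)
  ) %>%
    mutate(sd_rest = (.data$sd_left + .data$sd_right) / 2)
}

#' Soft-normalize firing rates
#'
#' `mode = "soft"` computes `z = (x - mu_rest) / (sd_rest + 1)`; the added
#' constant keeps the denominator at least 1 so units that are silent at
#' rest cannot explode. `mode = "range"` divides instead by the unit's
#' full firing-rate range over the session plus 5, which de-emphasizes
#' strongly modulated units.
#'
#' @param rates Units x bins matrix.
#' @param rest_stats Tibble from [compute_rest_statistics()].
#' @param mode `"soft"` (default) or `"range"`.
#' @return A matrix of normalized rates with the same attributes.
#' @export
normalize_rates <- function(rates, rest_stats, mode = c("soft", "range")) {
  mode <- match.arg(mode)
  stopifnot(nrow(rates) == nrow(rest_stats))
  den <- switch(mode,
    soft = rest_stats$sd_rest + 1,
    range = apply(rates, 1, function(x) diff(range(x))) + 5
  )
  z <- (rates - rest_stats$mu_rest) / den
  attr(z, "times") <- attr(rates, "times")
  attr(z, "bin_width") <- attr(rates, "bin_width")
  attr(z, "normalization") <- mode
  z
}

#' Canonical 300 ms phase windows
#'
#' Rest: the final 300 ms before instruction onset. Instruct: 200--500 ms
#' after instruction onset (the steady-state delay response). Move: the
#' first 300 ms after movement onset. Windows are edge-inclusive, so each
#' holds exactly 16 samples at 50 Hz.
#'
#' @param phase `"rest"`, `"instruct"` or `"move"`.
#' @return A list with `phase`, `event`, `offset` (s) and `n_samples`.
#' @export
phase_window <- function(phase = c("rest", "instruct", "move")) {
  phase <- match.arg(phase)
  spec <- switch(phase,
    rest = list(event = "instruct_onset", offset = c(-0.3, 0)),
    instruct = list(event = "instruct_onset", offset = c(0.2, 0.5)),
    move = list(event = "movement_onset", offset = c(0, 0.3))
  )
  c(list(phase = phase), spec,
    list(n_samples = as.integer(round(diff(spec$offset) / 0.02)) + 1L))
}

#' Extract phase-aligned windows into a rate tensor
#'
#' Slices the normalized session trace into edge-inclusive windows aligned
#' to each trial's phase event. The alignment event is snapped to the
#' nearest bin center, after which a 300 ms window always yields exactly
#' 16 samples. Trials can be filtered by arm and start configuration.
#'
#' @param z Normalized units x bins matrix (see [normalize_rates()]).
#' @param trials Trial table.
#' @param phase Phase name, or a list from [phase_window()], or a custom
#'   window `list(event =, offset = c(lo, hi))` in seconds.
#' @param arms,configs Optional filters on `trials$arm` / `trials$config`.
#' @return A `rate_tensor`: units x samples x trials array with attributes
#'   `trials` (the trial rows used), `offsets` (sample offsets, s) and
#'   `phase`.
#' @export
extract_phase_windows <- function(z, trials, phase = "move",
                                  arms = NULL, configs = NULL) {
  win <- if (is.character(phase)) phase_window(phase) else phase
  if (!is.null(arms)) trials <- trials[trials$arm %in% arms, , drop = FALSE]
  if (!is.null(configs)) {
    trials <- trials[trials$config %in% configs, , drop = FALSE]
  }
  if (nrow(trials) == 0L) stop("no trials selected", call. = FALSE)
  times <- attr(z, "times")
  bw <- attr(z, "bin_width") %||% 0.02
  steps <- seq(round(win$offset[1] / bw), round(win$offset[2] / bw))
  events <- trials[[win$event]]
  if (any(is.na(events))) {
    stop(sprintf("trial %s lacks event %s",
                 trials$trial_id[which(is.na(events))[1]], win$event),
         call. = FALSE)
  }
  out <- array(NA_real_, dim = c(nrow(z), length(steps), nrow(trials)))
  for (i in seq_len(nrow(trials))) {
    ev_idx <- which.min(abs(times - events[i]))
    idx <- ev_idx + steps
    if (idx[1] < 1L || idx[length(idx)] > ncol(z)) {
      stop(sprintf("window for trial %s exceeds recorded data",
                   trials$trial_id[i]), call. = FALSE)
    }
    out[, , i] <- z[, idx]
  }
  dimnames(out) <- list(rownames(z), NULL, NULL)
  structure(out,
            trials = trials, offsets = steps * bw,
            phase = win$phase %||% "custom", class = "rate_tensor")
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rate_tensor> %d units x %d samples x %d trials (%s)\n",
              d[1], d[2], d[3], attr(x, "phase")))
  invisible(x)
}

#' Concatenate a rate tensor into a samples-by-units matrix
#'
#' Stacks the per-trial windows of a `rate_tensor` into the
#' `(16 m) x n` matrix used by the population analyses (m trials of 16
#' samples, n units).
#'
#' @param tensor A `rate_tensor`.
#' @param units Optional unit subset (indices or names).
#' @return A numeric matrix, trials stacked in order.
#' @export
tensor_matrix <- function(tensor, units = NULL) {
  d <- dim(tensor)
  x <- aperm(tensor, c(2, 3, 1))
  m <- matrix(x, nrow = d[2] * d[3], ncol = d[1])
  colnames(m) <- dimnames(tensor)[[1]]
  if (!is.null(units)) m <- m[, units, drop = FALSE]
  m
}

#' Concatenate two rate tensors along the sample axis
#'
#' Joins event-locked tensors over the same units and trials (e.g. an
#' instruction-locked span followed by a movement-locked span) into one
#' tensor for time-resolved analyses.
#'
#' @param a,b `rate_tensor`s with identical unit and trial dimensions.
#' @param gap Seconds added to `b`'s offsets so the combined time axis
#'   stays monotone (default: one bin past the end of `a`).
#' @return A `rate_tensor` with `dim(a)[2] + dim(b)[2]` samples.
#' @export
bind_rate_tensors <- function(a, b, gap = NULL) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[3] == db[3])
  out <- array(NA_real_, dim = c(da[1], da[2] + db[2], da[3]))
  out[, seq_len(da[2]), ] <- a
  out[, da[2] + seq_len(db[2]), ] <- b
  offs_a <- attr(a, "offsets") %||% seq_len(da[2])
  offs_b <- attr(b, "offsets") %||% seq_len(db[2])
  gap <- gap %||% (max(offs_a) + 0.02 - min(offs_b))
  dimnames(out) <- list(dimnames(a)[[1]], NULL, NULL)
  structure(out,
            trials = attr(a, "trials"), offsets = c(offs_a, offs_b + gap),
            phase = paste(attr(a, "phase"), attr(b, "phase"), sep = "+"),
            class = "rate_tensor")
}

#' Remove duplicate units recorded on nearby channels
#'
#' Units whose full-session firing-rate traces correlate above the
#' threshold *and* that sit within two channels of each other on the same
#' probe (hemisphere x area) are treated as duplicate recordings of one
#' neuron; one member of each offending pair is removed (the
#' later-indexed one).
#'
#' @param units Unit metadata tibble with `unit_id`, `hemisphere`, `area`,
#'   `channel`.
#' @param rates Units x bins rate matrix (rows in `units` order).
#' @param cor_threshold Correlation threshold (default 0.9, exclusive).
#' @param channel_distance Maximum channel separation (default 2).
#' @return A list with `units` (filtered tibble), `keep` (logical), and
#'   `removed` (tibble reporting each removal and the unit it duplicated).
#' @export
dedupe_units <- function(units, rates, cor_threshold = 0.9,
                         channel_distance = 2) {
  stopifnot(nrow(units) == nrow(rates))
  n <- nrow(units)
  keep <- rep(TRUE, n)
  removed <- list()
  if (n >= 2L) {
    cc <- suppressWarnings(cor(t(rates)))
    cc[is.na(cc)] <- 0
    for (i in seq_len(n - 1L)) {
      if (!keep[i]) next
      for (j in seq((i + 1L), n)) {
        if (!keep[j]) next
        same_probe <- units$hemisphere[i] == units$hemisphere[j] &&
          units$area[i] == units$area[j]
        if (same_probe &&
              abs(units$channel[i] - units$channel[j]) <= channel_distance &&
              cc[i, j] > cor_threshold) {
          keep[j] <- FALSE
          removed[[length(removed) + 1L]] <- tibble(
            removed = units$unit_id[j], duplicate_of = units$unit_id[i],
            correlation = cc[i, j],
            channel_distance = abs(units$channel[i] - units$channel[j])
          )
        }
      }
    }
  }
  list(
    units = units[keep, , drop = FALSE],
    keep = keep,
    removed = if (length(removed)) bind_rows(removed) else tibble(
      removed = character(), duplicate_of = character(),
      correlation = numeric(), channel_distance = numeric()
    )
  )
}

#' Preprocess a session end to end
#'
#' Convenience wrapper: rates ([session_rates()]), Rest statistics
#' ([compute_rest_statistics()]) and normalization ([normalize_rates()])
#' in one call.
#'
#' @param session A `bilat_session`.
#' @param mode Normalization mode, `"soft"` or `"range"`.
#' @return A list with `rates`, `rest_stats` and `z`.
#' @export
preprocess_session <- function(session, mode = "soft") {
  rates <- session_rates(session)
  rest_stats <- compute_rest_statistics(rates, session$trials)
  z <- normalize_rates(rates, rest_stats, mode = mode)
  list(rates = rates, rest_stats = rest_stats, z = z)
}
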