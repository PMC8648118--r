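#' Default pipeline configuration
#'
#' All preprocessing and analysis constants with their canonical values:
#' 20 ms bins, 50 ms Gaussian smoothing, 10/20 cm/s movement thresholds,
#' the three 300 ms phase windows, 4-dimensional subspace models with
#' candidate dimensions 1--10, 25 Monte-Carlo partitions, and uniform-
#' prior LDA. `validate_config()` injects these defaults into any
#' partial configuration and rejects unknown keys and out-of-range
#' values.
#'
#' @return A nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, preprocess = TRUE, metrics = TRUE,
                  subspace = TRUE, decode = TRUE, stats = TRUE),
    sim = unclass(sim_config()),
    preprocess = list(
      bin_width = 0.02, kernel_sd = 0.05,
      onset_threshold = 10, end_threshold = 20,
      normalization = "soft",
      dedupe_cor = 0.9, dedupe_channels = 2
    ),
    subspace = list(p = 4, p_range = 1:10, n_partitions = 25),
    decode = list(shrinkage = 0.05),
    stats = list(n_perm = 2000, n_boot = 1000)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Merges a partial configuration with [default_pipeline_config()],
#' rejecting unknown keys and itemizing out-of-range constants.
#'
#' @param config A (possibly partial, possibly empty) nested list.
#' @return The completed configuration.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_pipeline_config()
  merged <- merge_config(defaults, config, path = "")
  errors <- character()
  pp <- merged$preprocess
  if (pp$bin_width <= 0) errors <- c(errors, "preprocess$bin_width must be > 0")
  if (pp$kernel_sd <= 0) errors <- c(errors, "preprocess$kernel_sd must be > 0")
  if (pp$onset_threshold <= 0 || pp$end_threshold <= pp$onset_threshold) {
    errors <- c(errors,
                "movement thresholds must satisfy 0 < onset < end")
  }
  if (!pp$normalization %in% c("soft", "range")) {
    errors <- c(errors, "preprocess$normalization must be 'soft' or 'range'")
  }
  if (merged$subspace$p < 1) errors <- c(errors, "subspace$p must be >= 1")
  if (merged$stats$n_perm < 1) errors <- c(errors, "stats$n_perm must be >= 1")
  merged$sim$seed <- merged$sim$seed %||% merged$seed
  sim_ok <- tryCatch({
    merged$sim <- unclass(validate_sim_config(merged$sim))
    TRUE
  }, error = function(e) {
    errors <<- c(errors, conditionMessage(e))
    FALSE
  })
  if (length(errors)) {
    stop(paste0("invalid configuration:\n  - ",
                paste(errors, collapse = "\n  - ")), call. = FALSE)
  }
  merged
}

merge_config <- function(defaults, override, path) {
  if (length(override) == 0L) return(defaults)
  extra <- setdiff(names(override), names(defaults))
  if (length(extra)) {
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")), call. = FALSE)
  }
  for (k in names(override)) {
    if (is.list(defaults[[k]]) && is.list(override[[k]]) &&
          !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], override[[k]],
                                    paste0(path, k, "$"))
    } else {
      defaults[[k]] <- override[[k]]
    }
  }
  defaults
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes simulate, preprocess, unit metrics, subspace, decoding and
#' permutation-stats stages as toggled in the configuration, collecting
#' every stage's outputs (and per-stage wall time) in one container.
#' Stages consume upstream results; disabling a required upstream stage
#' raises an error naming it. Re-running with an identical configuration
#' reproduces identical derived arrays.
#'
#' @param config A configuration list (see [validate_config()]); a
#'   `bilat_session` can be supplied instead of simulating.
#' @param session Optional pre-built session (skips the simulate stage).
#' @return A `bilat_pipeline` list with elements `session`, `prep`,
#'   `metrics`, `subspace`, `decode`, `stats`, `config`, `provenance`,
#'   `log`.
#' @export
run_pipeline <- function(config = list(), session = NULL) {
  config <- validate_config(config)
  st <- config$stages
  out <- list(config = config)
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, code) {
    t0 <- tic()
    res <- force(code)
    log[[name]] <<- tibble(stage = name, seconds = tic() - t0)
    res
  }

  if (is.null(session)) {
    if (!st$simulate) {
      stop("stage 'preprocess' requires upstream stage 'simulate' or a session",
           call. = FALSE)
    }
    session <- stage("simulate", simulate_session(
      validate_sim_config(config$sim), kinematics = FALSE
    ))
  }
  out$session <- session

  if (st$preprocess) {
    out$prep <- stage("preprocess",
                      preprocess_session(session,
                                         mode = config$preprocess$normalization))
  }

  need <- function(what, field) {
    if (is.null(out[[field]])) {
      stop(sprintf("stage '%s' requires upstream stage '%s'", what, field),
           call. = FALSE)
    }
  }

  if (st$metrics) {
    need("metrics", "prep")
    cfgs <- unique(session$trials$config)
    ap_cfg <- cfgs[1]
    m_cfg <- if (length(cfgs) > 1) cfgs[2] else cfgs[1]
    out$metrics <- stage("metrics", {
      ap_set <- unit_phase_metrics(out$prep$z, session$trials, session$units,
                                   configs = ap_cfg)
      m_set <- unit_phase_metrics(out$prep$z, session$trials, session$units,
                                  configs = m_cfg)
      list(ap_set = ap_set, m_set = m_set,
           ap_config = ap_cfg, m_config = m_cfg)
    })
  }

  if (st$subspace) {
    need("subspace", "prep")
    out$subspace <- stage("subspace", {
      z <- out$prep$z
      trials <- session$trials
      cfg_centered <- if ("centered" %in% trials$config) "centered" else
        unique(trials$config)[1]
      dim_est <- lapply(c("left", "right"), function(arm) {
        tw <- extract_phase_windows(z, trials, "move", arms = arm,
                                    configs = cfg_centered)
        estimate_dimensionality(tw, p_range = config$subspace$p_range)
      })
      names(dim_est) <- c("left", "right")
      tl <- extract_phase_windows(z, trials, "move", arms = "left")
      tr <- extract_phase_windows(z, trials, "move", arms = "right")
      align <- native_cross_alignment(tl, tr, p = config$subspace$p,
                                      n_partitions = config$subspace$n_partitions,
                                      seed = config$seed)
      list(dimensionality = dim_est, alignment = align)
    })
  }

  if (st$decode) {
    need("decode", "prep")
    out$decode <- stage("decode", {
      z <- out$prep$z
      trials <- session$trials
      res <- lapply(c("left", "right"), function(arm) {
        tw <- extract_phase_windows(z, trials, "move", arms = arm)
        feats <- t(apply(tw, c(1, 3), mean))
        acc <- loo_accuracy(feats, attr(tw, "trials")$target,
                            shrinkage = config$decode$shrinkage)
        tibble(arm = arm, phase = "move", accuracy = acc,
               chance = 1 / length(unique(attr(tw, "trials")$target)))
      })
      bind_rows(res)
    })
  }

  if (st$stats) {
    need("stats", "metrics")
    out$stats <- stage("stats", {
      mm <- out$metrics$m_set %>%
        filter(.data$phase == "move") %>%
        tidyr::pivot_longer(c("m_contra", "m_ipsi"),
                            names_to = "arm", values_to = "modulation") %>%
        mutate(log_m = log10(.data$modulation + 1e-6))
      factorial_permutation_effects(
        as.data.frame(mm), "log_m",
        effects = list(list(type = "main", factor = "arm")),
        unit = "unit_id", n_perm = config$stats$n_perm,
        seed = config$seed
      )
    })
  }

  out$log <- bind_rows(log)
  out$provenance <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("bilatpop")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(out, class = "bilat_pipeline")
}

#' @export
print.bilat_pipeline <- function(x, ...) {
  cat("<bilat_pipeline>\n  stages run:",
      paste(setdiff(names(x), c("config", "log", "provenance")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a session container to disk
#'
#' Serializes a session (and optionally its ground truth) to a directory
#' of delimited-text tables and JSON: `units.csv`, `trials.csv`,
#' `rates.csv` or `spikes.csv`, `kinematics/`, `ground_truth/` and
#' `provenance.json` (configuration hash and master seed). Everything is
#' plain text and round-trips at full printed double precision
#' (15 significant digits).
#'
#' @param session A `bilat_session`.
#' @param dir Target directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_session_container <- function(session, dir) {
  stopifnot(inherits(session, "bilat_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                           row.names = FALSE)
  wcsv(session$units, "units.csv")
  wcsv(session$trials, "trials.csv")
  if (!is.null(session$rates)) {
    rt <- as.data.frame(t(session$rates))
    rt <- cbind(time = session$times, rt)
    wcsv(rt, "rates.csv")
  }
  if (!is.null(session$spikes)) {
    sp <- purrr::imap(session$spikes, function(v, id) {
      if (length(v)) tibble(unit_id = id, t = v) else NULL
    }) %>% list_rbind()
    wcsv(sp, "spikes.csv")
  }
  if (!is.null(session$ground_truth)) {
    gtd <- file.path(dir, "ground_truth")
    dir.create(gtd, showWarnings = FALSE)
    utils::write.csv(session$ground_truth$units,
                     file.path(gtd, "units.csv"), row.names = FALSE)
    utils::write.csv(session$ground_truth$dimensionality,
                     file.path(gtd, "dimensionality.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(
      seed = session$config$seed,
      config = unclass(session$config),
      config_hash = rlang::hash(unclass(session$config)),
      bin_width = session$bin_width
    ),
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a session container
#'
#' Inverse of [write_session_container()]. Ground truth and kinematics
#' are restored when present.
#'
#' @param dir Container directory.
#' @return A `bilat_session`.
#' @export
read_session_container <- function(dir) {
  rcsv <- function(f) as_tibble(utils::read.csv(file.path(dir, f)))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  session <- list(
    units = rcsv("units.csv"),
    trials = rcsv("trials.csv"),
    bin_width = prov$bin_width,
    config = prov$config
  )
  if (file.exists(file.path(dir, "rates.csv"))) {
    rt <- utils::read.csv(file.path(dir, "rates.csv"))
    session$times <- rt$time
    session$rates <- t(as.matrix(rt[, -1, drop = FALSE]))
    rownames(session$rates) <- session$units$unit_id
  }
  if (file.exists(file.path(dir, "spikes.csv"))) {
    sp <- utils::read.csv(file.path(dir, "spikes.csv"))
    session$spikes <- split(sp$t, factor(sp$unit_id,
                                         levels = session$units$unit_id))
    session$times <- seq(prov$bin_width / 2,
                         max(session$trials$trial_end) + 0.5,
                         by = prov$bin_width)
  }
  gtd <- file.path(dir, "ground_truth")
  if (dir.exists(gtd)) {
    session$ground_truth <- list(
      units = as_tibble(utils::read.csv(file.path(gtd, "units.csv"))),
      dimensionality = as_tibble(utils::read.csv(
        file.path(gtd, "dimensionality.csv")
      ))
    )
  }
  structure(session, class = "bilat_session")
}
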