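#' Configuration for synthetic bilateral reaching sessions
#'
#' Builds the parameter list consumed by [simulate_session()]. Defaults
#' describe a desk-scale bilateral PMd/M1 recording during a blocked,
#' unimanual instructed-delay reaching task: six targets, two arms, three
#' stationary-hand start configurations, a 500 ms Rest hold and an
#' instruct delay drawn uniformly from 0.5--1.5 s.
#'
#' The generator embeds two kinds of latent structure. A *dedicated*
#' component gives each unit arm-specific latent drive whose magnitude
#' grows with the unit's arm preference (`modulation_slope` is the
#' increase in log10 modulation per unit of absolute arm preference). A
#' *distributed* component drives all units through target-tuned latents
#' whose loading vectors are identical for the two arms, so that it lives
#' in a shared subspace by construction.
#'
#' @param n_units_per_group Units per hemisphere (L/R) x area (PMd/M1) group.
#' @param trials_per_target_per_arm Trials per target, arm and start
#'   configuration. Scheduled in alternating blocks of two trials per target
#'   per arm.
#' @param arm_pref_distribution List describing the mixture over true arm
#'   preferences in `[-1, 1]`: a neutral bulk (`neutral_sd`, truncated
#'   normal at 0) plus dedicated tails (`dedicated_frac` of units at
#'   `+/- dedicated_mean` with spread `dedicated_sd`); `contra_bias` is the
#'   probability that a dedicated unit prefers the contralateral arm. Set
#'   `neutral_sd = 0` and `dedicated_frac = 0` for a population with no
#'   arm-preference structure at all.
#' @param modulation_slope Increase in log10 preferred-arm modulation per
#'   unit absolute arm preference (the dedicated link; 1 = an order of
#'   magnitude between fully neutral and fully dedicated units).
#' @param modulation_base Move-phase modulation (mean squared soft-normalized
#'   rate) of a fully arm-neutral unit.
#' @param dedicated_dim Number of arm-specific latents per arm (per phase
#'   epoch when `split_phases` is `TRUE`).
#' @param distributed_dim Number of shared (arm-independent) latents.
#' @param distributed_variance_fraction Fraction of each unit's
#'   non-preferred-arm modulation budget carried by the shared latents,
#'   in `[0, 1]`. 0 gives purely arm-specific (dedicated) structure, 1 puts
#'   all non-preferred-arm drive in the shared subspace.
#' @param distributed_pref_gain Multiplicative engagement gain applied to a
#'   unit's shared drive on trials of its preferred arm. 1 (default) gives
#'   equal shared magnitude for the two arms; values above 1 emulate
#'   stronger preferred-arm engagement of the shared subspace.
#' @param instruct_gain Amplitude of Instruct-epoch latents relative to
#'   Move-epoch latents.
#' @param split_phases If `TRUE` (default), Instruct and Move epochs use
#'   independent latent loading patterns, so the population subspace
#'   reorganizes at movement onset; if `FALSE` a single fixed subspace
#'   spans the whole trial.
#' @param phase_durations List of task timing constants (seconds): `rest`
#'   hold, `instruct_min`/`instruct_max` delay bounds, reaction-time bounds,
#'   terminal hold and inter-trial interval.
#' @param start_configurations Number of stationary-hand start
#'   configurations scheduled (1--3: both-center, left-eccentric,
#'   right-eccentric).
#' @param baseline_rate_range Range (spikes/s) for per-unit baseline rates.
#' @param noise_model `"gaussian"` (additive i.i.d. noise on the
#'   square-root-scale rate samples; fast, used throughout the test suite)
#'   or `"poisson"` (spike times drawn from the rate process; the
#'   preprocessing chain then bins, square-root transforms and smooths).
#' @param noise_sd Noise standard deviation on the square-root rate scale
#'   (gaussian mode).
#' @param rest_arm_offset Root-mean-square size (soft-normalized units) of
#'   a per-unit arm-specific offset active throughout each trial,
#'   including Rest. Emulates the arm-predictive population state that a
#'   blocked schedule induces before the cue; 0 (default) injects no
#'   Rest-phase arm structure. Because the offset is constant within each
#'   arm's trials it inflates neither per-arm Rest standard deviation.
#' @param kinematics List of kinematic constants: `peak_speed` (cm/s) of the
#'   bell-shaped reach profile, `jitter_speed` (cm/s mean speed of the
#'   stationary hand; of order 0.1--0.8), `sample_rate` (Hz).
#' @param seed Master seed; all stochastic draws derive from named
#'   substreams of this seed.
#'
#' @return A classed list (`sim_config`) of validated parameters.
#' @seealso [simulate_session()], [simulate_null_session()]
#' @export
sim_config <- function(n_units_per_group = 15,
                       trials_per_target_per_arm = 4,
                       arm_pref_distribution = list(
                         neutral_sd = 0.2,
                         dedicated_frac = 0.25,
                         dedicated_mean = 0.85,
                         dedicated_sd = 0.08,
                         contra_bias = 0.8
                       ),
                       modulation_slope = 1,
                       modulation_base = 0.5,
                       dedicated_dim = 4,
                       distributed_dim = 4,
                       distributed_variance_fraction = 0.3,
                       distributed_pref_gain = 1,
                       instruct_gain = 0.6,
                       split_phases = TRUE,
                       phase_durations = list(
                         rest = 0.5,
                         instruct_min = 0.5,
                         instruct_max = 1.5,
                         reaction_min = 0.25,
                         reaction_max = 0.40,
                         hold = 0.25,
                         iti = 0.4
                       ),
                       start_configurations = 3,
                       baseline_rate_range = c(2, 25),
                       noise_model = c("gaussian", "poisson"),
                       noise_sd = 0.2,
                       rest_arm_offset = 0,
                       kinematics = list(
                         peak_speed = 80,
                         jitter_speed = 0.5,
                         sample_rate = 240
                       ),
                       seed = 1L) {
  cfg <- list(
    n_units_per_group = n_units_per_group,
    trials_per_target_per_arm = trials_per_target_per_arm,
    arm_pref_distribution = arm_pref_distribution,
    modulation_slope = modulation_slope,
    modulation_base = modulation_base,
    dedicated_dim = dedicated_dim,
    distributed_dim = distributed_dim,
    distributed_variance_fraction = distributed_variance_fraction,
    distributed_pref_gain = distributed_pref_gain,
    instruct_gain = instruct_gain,
    split_phases = isTRUE(split_phases),
    phase_durations = phase_durations,
    target_count = 6L,
    start_configurations = start_configurations,
    baseline_rate_range = baseline_rate_range,
    noise_model = match.arg(noise_model),
    noise_sd = noise_sd,
    rest_arm_offset = rest_arm_offset,
    kinematics = kinematics,
    seed = seed
  )
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A list as produced by [sim_config()].
#' @return The validated configuration, classed `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_units_per_group)) {
    abort_config("n_units_per_group must be a positive integer")
  }
  if (!is_count(cfg$trials_per_target_per_arm)) {
    abort_config("trials_per_target_per_arm must be a positive integer")
  }
  f <- cfg$distributed_variance_fraction
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    abort_config("distributed_variance_fraction must lie in [0, 1]")
  }
  if (cfg$dedicated_dim < 0 || cfg$distributed_dim < 0) {
    abort_config("latent dimensions must be non-negative")
  }
  if (cfg$dedicated_dim + cfg$distributed_dim < 1) {
    abort_config("at least one latent dimension is required")
  }
  if (!is_count(cfg$start_configurations) || cfg$start_configurations > 3) {
    abort_config("start_configurations must be 1, 2 or 3")
  }
  if (cfg$modulation_base <= 0) {
    abort_config("modulation_base must be positive")
  }
  if (cfg$noise_sd < 0) abort_config("noise_sd must be non-negative")
  if (is.null(cfg$rest_arm_offset) || cfg$rest_arm_offset < 0) {
    abort_config("rest_arm_offset must be non-negative")
  }
  pd <- cfg$phase_durations
  for (k in c("rest", "instruct_min", "instruct_max", "reaction_min",
              "reaction_max", "hold", "iti")) {
    if (is.null(pd[[k]]) || pd[[k]] < 0) {
      abort_config("phase_durations$%s must be a non-negative number", k)
    }
  }
  if (pd$instruct_max < pd$instruct_min) {
    abort_config("instruct_max must be >= instruct_min")
  }
  br <- cfg$baseline_rate_range
  if (length(br) != 2L || any(br < 0) || br[2] < br[1]) {
    abort_config("baseline_rate_range must be an increasing non-negative pair")
  }
  ap <- cfg$arm_pref_distribution
  for (k in c("neutral_sd", "dedicated_frac", "dedicated_mean",
              "dedicated_sd", "contra_bias")) {
    if (is.null(ap[[k]]) || !is.numeric(ap[[k]])) {
      abort_config("arm_pref_distribution$%s missing", k)
    }
  }
  if (ap$dedicated_frac < 0 || ap$dedicated_frac > 1) {
    abort_config("dedicated_frac must lie in [0, 1]")
  }
  if (cfg$kinematics$jitter_speed < 0) {
    abort_config("jitter_speed must be non-negative")
  }
  if (cfg$kinematics$peak_speed <= 20) {
    abort_config("peak_speed must exceed the 20 cm/s reach-end threshold")
  }
  structure(cfg, class = "sim_config")
}

config_labels <- function(n) {
  c("centered", "left_ecc", "right_ecc")[seq_len(n)]
}

# Target geometry: six reach targets in a fronto-parallel plane 8 cm in
# front of the start bar, two heights x three lateral positions (cm).
target_positions <- function() {
  cbind(
    x = c(-12, 0, 12, -12, 0, 12),
    y = rep(8, 6),
    z = c(-3, -3, -3, 7, 7, 7)
  )
}

# Start position of each hand (cm) for a given configuration.
start_position <- function(hand, config) {
  ecc <- (hand == "left" && config == "left_ecc") ||
    (hand == "right" && config == "right_ecc")
  x <- if (hand == "left") -4 else 4
  if (ecc) x <- sign(x) * 15
  c(x = x, y = 0, z = 0)
}
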