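#' Simulation configuration for a synthetic photometry/PIT cohort
#'
#' Bundles every tunable parameter of the synthetic-data generator: the
#' session design constants of the behavioral task (trial counts, CS duration,
#' random-time reward schedule, intertrial intervals, PIT test structure) and
#' the signal/behavior parameters of the generative model (photobleaching,
#' shared motion artifact, calcium-transient kernel, food-port entry and
#' lever-press rates).
#'
#' Two presets matter. The standard behavioral design uses 8 presentations of
#' each CS per conditioning session with no probe restriction. The photometry
#' variant (`photometry = TRUE`) uses 4 of each CS per session (shorter
#' sessions limit photobleaching) and enforces a minimum 15-s probe period
#' between CS onset and the first reward delivery so CS-onset and
#' reward-evoked calcium transients can be dissociated.
#'
#' @param photometry logical; if `TRUE`, apply the photometry-variant session
#'   design (4 CSs of each type per session, 15-s minimum probe period).
#' @param ... named overrides for any configuration field (see Details).
#'
#' @details Fields and defaults:
#' \describe{
#'   \item{n_subjects}{cohort size (8).}
#'   \item{n_conditioning_sessions}{number of Pavlovian sessions (8).}
#'   \item{cs_per_type}{CS presentations of each type per session (8; 4 in the
#'     photometry variant).}
#'   \item{cs_duration_s}{CS duration, seconds (120).}
#'   \item{rt_mean_interval_s}{mean interval of the random-time reward
#'     schedule, seconds (30).}
#'   \item{min_probe_s}{minimum CS-onset-to-first-reward probe period, seconds
#'     (0; 15 in the photometry variant).}
#'   \item{iti_range_s}{uniform intertrial-interval range, seconds
#'     (c(120, 240), mean 180).}
#'   \item{pit_extinction_s}{lever-press extinction period opening the PIT
#'     test, seconds (300).}
#'   \item{pit_cs_reps}{presentations of each CS at the PIT test (4).}
#'   \item{pit_iti_s}{fixed PIT intertrial interval, seconds (240).}
#'   \item{sample_rate_hz}{per-channel photometry sampling rate (20); the two
#'     excitation channels are interleaved, offset by half a sample period.}
#'   \item{f0_470, f0_415}{baseline fluorescence of the signal and isosbestic
#'     channels, arbitrary units (100, 80).}
#'   \item{bleach_amp1, bleach_tau1_s, bleach_amp2, bleach_tau2_s}{two-term
#'     exponential photobleaching (0.3/400 s fast, 0.3/2500 s slow, roughly
#'     halving the signal over a 40-min session); the bleach factor
#'     multiplies both channel baselines.}
#'   \item{motion_sd, motion_tau_s}{standard deviation (fluorescence units, 10)
#'     and autocorrelation time (0.3 s) of the zero-mean motion artifact added
#'     to both channels.}
#'   \item{gain_415}{motion-artifact gain of the isosbestic channel relative
#'     to the signal channel (0.8).}
#'   \item{noise_sd}{white measurement noise, fluorescence units (0.5).}
#'   \item{tau_rise_s, tau_decay_s}{calcium transient kernel time constants
#'     (0.1, 0.5); the kernel is peak-normalized so transient amplitudes are
#'     in dF/F units.}
#'   \item{amp_cs, amp_retrieval}{peak dF/F of transients injected at CS onset
#'     (1) and reward retrieval (2).}
#'   \item{habituation_rate}{per-session multiplicative decay of the CS-onset
#'     transient in unpaired (CS-only) sessions (0.3): session s uses
#'     `amp_cs * (1 - habituation_rate)^(s - 1)`.}
#'   \item{entry_rate_base_per_min}{baseline food-port entry rate (2).}
#'   \item{entry_gain_per_session}{per-session growth of the CS-period entry
#'     rate multiplier `1 + entry_gain_per_session * session_index` (0.5).}
#'   \item{press_rate_base_per_min}{baseline per-lever press rate at the PIT
#'     test (5).}
#'   \item{tau_same, tau_diff}{fractional CS-period elevation of pressing on
#'     the Same and Different levers (1.0, 0.2).}
#'   \item{retrieval_latency_mean_s}{mean exponential latency from reward
#'     delivery to the retrieval food-port entry (1).}
#'   \item{qc_min_r2}{QC threshold on the isosbestic fit r-squared (0.6).}
#'   \item{qc_min_transient_rate_per_min}{QC threshold on the detected
#'     transient rate (0.1).}
#'   \item{window_pre_s, window_post_s}{peri-event baseline and response
#'     window lengths, seconds (3, 3).}
#'   \item{seed}{default seed used by [run_experiment()] (1).}
#' }
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(photometry = TRUE, n_subjects = 4)
#' cfg$cs_per_type
#' @export
sim_config <- function(photometry = FALSE, ...) {
  cfg <- list(
    seed = 1L,
    n_subjects = 8L,
    n_conditioning_sessions = 8L,
    cs_per_type = if (photometry) 4L else 8L,
    cs_duration_s = 120,
    rt_mean_interval_s = 30,
    min_probe_s = if (photometry) 15 else 0,
    iti_range_s = c(120, 240),
    pit_extinction_s = 300,
    pit_cs_reps = 4L,
    pit_iti_s = 240,
    sample_rate_hz = 20,
    f0_470 = 100,
    f0_415 = 80,
    bleach_amp1 = 0.3,
    bleach_tau1_s = 400,
    bleach_amp2 = 0.3,
    bleach_tau2_s = 2500,
    motion_sd = 10,
    motion_tau_s = 0.3,
    gain_415 = 0.8,
    noise_sd = 0.5,
    tau_rise_s = 0.1,
    tau_decay_s = 0.5,
    amp_cs = 1,
    amp_retrieval = 2,
    habituation_rate = 0.3,
    entry_rate_base_per_min = 2,
    entry_gain_per_session = 0.5,
    press_rate_base_per_min = 5,
    tau_same = 1.0,
    tau_diff = 0.2,
    retrieval_latency_mean_s = 1,
    qc_min_r2 = 0.6,
    qc_min_transient_rate_per_min = 0.1,
    window_pre_s = 3,
    window_post_s = 3,
    photometry = isTRUE(photometry)
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  nonneg <- c(
    "cs_duration_s", "min_probe_s", "pit_extinction_s", "pit_iti_s",
    "motion_sd", "motion_tau_s", "noise_sd", "amp_cs", "amp_retrieval",
    "habituation_rate", "entry_rate_base_per_min", "entry_gain_per_session",
    "press_rate_base_per_min", "tau_same", "tau_diff",
    "retrieval_latency_mean_s", "bleach_amp1", "bleach_amp2",
    "window_pre_s", "window_post_s"
  )
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0) {
      stop("sim_config field '", f, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  counts <- c("n_subjects", "n_conditioning_sessions", "cs_per_type",
              "pit_cs_reps")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v)) {
      stop("sim_config field '", f, "' must be a non-negative integer",
           call. = FALSE)
    }
    cfg[[f]] <- as.integer(v)
  }
  if (cfg$rt_mean_interval_s <= 0) {
    stop("rt_mean_interval_s must be > 0", call. = FALSE)
  }
  if (cfg$sample_rate_hz <= 0) stop("sample_rate_hz must be > 0", call. = FALSE)
  if (length(cfg$iti_range_s) != 2L || any(cfg$iti_range_s < 0) ||
      cfg$iti_range_s[1] > cfg$iti_range_s[2]) {
    stop("iti_range_s must be a non-decreasing pair of non-negative seconds",
         call. = FALSE)
  }
  if (cfg$tau_rise_s >= cfg$tau_decay_s) {
    stop("tau_rise_s must be smaller than tau_decay_s", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>",
      sprintf("%d subjects, %d conditioning sessions, %d CSs/type/session%s\n",
              x$n_subjects, x$n_conditioning_sessions, x$cs_per_type,
              if (x$photometry) " (photometry variant)" else ""))
  invisible(x)
}

#' Counterbalanced stimulus-outcome and lever-outcome assignments
#'
#' Assigns each subject a CS-to-outcome mapping (tone/noise vs sucrose/pellet)
#' and an independent lever-to-outcome mapping (left/right), alternating
#' across the subject index so that any even-sized cohort is exactly
#' counterbalanced: half the subjects have tone paired with sucrose and noise
#' with pellets, the other half the opposite, and lever assignments are
#' counterbalanced independently of the Pavlovian contingencies.
#'
#' @param subject_index zero-based subject index.
#' @return A `contingency` object: list with named character vectors
#'   `cs_to_outcome` (names `tone`, `noise`) and `lever_to_outcome`
#'   (names `left`, `right`), each a bijection onto
#'   `c("sucrose", "pellet")`.
#' @examples
#' make_contingency(0)
#' make_contingency(1)$cs_to_outcome
#' @export
make_contingency <- function(subject_index) {
  if (!is.numeric(subject_index) || length(subject_index) != 1L ||
      subject_index < 0 || subject_index != round(subject_index)) {
    stop("subject_index must be a single non-negative integer", call. = FALSE)
  }
  i <- as.integer(subject_index)
  outcomes <- c("sucrose", "pellet")
  cs_map <- if (i %% 2L == 0L) outcomes else rev(outcomes)
  lever_map <- if ((i %/% 2L) %% 2L == 0L) outcomes else rev(outcomes)
  structure(
    list(
      cs_to_outcome = stats::setNames(cs_map, c("tone", "noise")),
      lever_to_outcome = stats::setNames(lever_map, c("left", "right"))
    ),
    class = "contingency"
  )
}

#' @export
print.contingency <- function(x, ...) {
  cat("<contingency> ",
      paste(names(x$cs_to_outcome), x$cs_to_outcome, sep = "->", collapse = ", "),
      "; ",
      paste(names(x$lever_to_outcome), x$lever_to_outcome, sep = "->",
            collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

check_contingency <- function(contingency) {
  ok <- inherits(contingency, "contingency") &&
    setequal(unname(contingency$cs_to_outcome), c("sucrose", "pellet")) &&
    setequal(unname(contingency$lever_to_outcome), c("sucrose", "pellet")) &&
    !anyDuplicated(contingency$cs_to_outcome) &&
    !anyDuplicated(contingency$lever_to_outcome)
  if (!ok) stop("invalid contingency: each mapping must be a bijection onto {sucrose, pellet}",
                call. = FALSE)
  invisible(contingency)
}

#' Read or write a simulation configuration file
#'
#' The on-disk format is flat `key: value` text (a YAML mapping); keys are the
#' [sim_config()] field names. `iti_range_s` is written as a two-element
#' sequence. Unknown keys are an error, so typos fail fast.
#'
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a flat key: value mapping",
                          call. = FALSE)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
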