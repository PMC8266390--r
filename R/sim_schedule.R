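#' Random-time (RT) reward schedule
#'
#' Draws reward delivery times as a memoryless arrival process (exponential
#' inter-arrival waits at rate `1/mean_interval_s`) over the interval
#' `(min_probe_s, duration_s]`. This is the classical operant random-time
#' schedule: with a 2-min window and a 30-s mean interval the expected number
#' of deliveries is 4. A positive `min_probe_s` suppresses arrivals during the
#' opening probe period, as used in photometry sessions to dissociate CS-onset
#' from reward-evoked activity.
#'
#' @param duration_s window length in seconds (deliveries fall in
#'   `(min_probe_s, duration_s]`).
#' @param mean_interval_s mean inter-delivery interval, seconds (> 0).
#' @param min_probe_s opening delivery-free period, seconds.
#' @param seed optional integer seed; when given, the draw is a pure function
#'   of the arguments.
#' @return Sorted numeric vector of delivery times (seconds from window
#'   start); empty when `duration_s` is 0.
#' @examples
#' generate_rt_schedule(120, 30, seed = 1)
#' @export
generate_rt_schedule <- function(duration_s, mean_interval_s = 30,
                                 min_probe_s = 0, seed = NULL) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s < 0) {
    stop("duration_s must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(mean_interval_s) || mean_interval_s <= 0) {
    stop("mean_interval_s must be > 0", call. = FALSE)
  }
  if (duration_s == 0) return(numeric(0))
  if (min_probe_s < 0 || min_probe_s >= duration_s) {
    stop("min_probe_s must satisfy 0 <= min_probe_s < duration_s",
         call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  window <- duration_s - min_probe_s
  times <- numeric(0)
  t_last <- 0
  repeat {
    lambda <- window / mean_interval_s
    n_draw <- max(16L, ceiling(lambda + 6 * sqrt(lambda)))
    waits <- stats::rexp(n_draw, rate = 1 / mean_interval_s)
    times <- c(times, t_last + cumsum(waits))
    t_last <- times[length(times)]
    if (t_last > window) break
  }
  min_probe_s + times[times <= window]
}

# ITI sampler shared by the conditioning-session generators: uniform on the
# configured range (the task states only the 2-4 min range and its 3-min mean).
draw_itis <- function(n, config, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  stats::runif(n, config$iti_range_s[1], config$iti_range_s[2])
}

# Pseudorandom CS order: uniform shuffle, rejected until no run of more than
# two consecutive identical stimuli.
pseudorandom_order <- function(ids, max_run = 2L) {
  stopifnot(length(ids) >= 1L)
  repeat {
    ord <- sample(ids)
    runs <- rle(ord)$lengths
    if (max(runs) <= max_run) return(ord)
  }
}

new_schedule <- function(trials, session_kind, session_index,
                         extinction_end_s = NA_real_, session_end_s) {
  out <- tibble::as_tibble(trials)
  attr(out, "session_kind") <- session_kind
  attr(out, "session_index") <- as.integer(session_index)
  attr(out, "extinction_end_s") <- extinction_end_s
  attr(out, "session_end_s") <- session_end_s
  class(out) <- c("session_schedule", class(out))
  out
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule: %s, session %d, %d trials, ends %.0f s>\n",
              attr(x, "session_kind"), attr(x, "session_index"), nrow(x),
              attr(x, "session_end_s")))
  NextMethod()
}

#' Generate one Pavlovian conditioning session schedule
#'
#' Lays out `cs_per_type` presentations of each of the two CSs (tone, white
#' noise) in pseudorandom order (no more than two consecutive identical CSs),
#' separated by intertrial intervals drawn uniformly on `iti_range_s`. Each
#' 2-min CS carries reward deliveries from the random-time schedule
#' ([generate_rt_schedule()]), restricted to begin after `min_probe_s`; the
#' delivered outcome follows the subject's contingency. With
#' `unpaired = TRUE` the same trial layout is produced with no rewards
#' (the CS-only control design; rewards are given separately, see
#' [generate_reward_only_session()]).
#'
#' @param config a [sim_config()].
#' @param contingency a [make_contingency()] assignment.
#' @param session_index 1-based session number.
#' @param unpaired logical; omit all reward deliveries.
#' @param seed optional integer seed.
#' @return A `session_schedule` tibble, one row per CS trial, with columns
#'   `trial`, `cs_id`, `onset_s`, `offset_s`, `outcome_id` and the list-column
#'   `reward_times_s` (absolute seconds). Attributes: `session_kind`
#'   (`"conditioning"` or `"unpaired"`), `session_index`,
#'   `session_end_s`.
#' @export
generate_conditioning_session <- function(config, contingency, session_index,
                                          unpaired = FALSE, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_contingency(contingency)
  if (config$cs_per_type < 1L) {
    stop("cs_per_type must be >= 1 to build a conditioning session",
         call. = FALSE)
  }
  if (session_index < 1L || session_index > config$n_conditioning_sessions) {
    stop("session_index must be in 1..n_conditioning_sessions", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)

  cs_ids <- pseudorandom_order(rep(c("tone", "noise"), config$cs_per_type))
  n_trials <- length(cs_ids)
  itis <- draw_itis(n_trials, config)
  onsets <- numeric(n_trials)
  t_cursor <- 0
  for (i in seq_len(n_trials)) {
    onsets[i] <- t_cursor + itis[i]
    t_cursor <- onsets[i] + config$cs_duration_s
  }
  offsets <- onsets + config$cs_duration_s
  rewards <- lapply(seq_len(n_trials), function(i) {
    if (unpaired) return(numeric(0))
    onsets[i] + generate_rt_schedule(config$cs_duration_s,
                                     config$rt_mean_interval_s,
                                     config$min_probe_s)
  })
  new_schedule(
    list(
      trial = seq_len(n_trials),
      cs_id = cs_ids,
      onset_s = onsets,
      offset_s = offsets,
      outcome_id = unname(contingency$cs_to_outcome[cs_ids]),
      reward_times_s = rewards
    ),
    session_kind = if (unpaired) "unpaired" else "conditioning",
    session_index = session_index,
    session_end_s = t_cursor + 120
  )
}

#' Generate an outcome-selective PIT test schedule
#'
#' The PIT test opens with `pit_extinction_s` seconds of lever-press
#' extinction, after which each 2-min CS is presented `pit_cs_reps` times in
#' pseudorandom order, separated by a fixed `pit_iti_s` intertrial interval.
#' No rewards are delivered.
#'
#' @inheritParams generate_conditioning_session
#' @return A `session_schedule` tibble (`session_kind = "pit"`) with empty
#'   `reward_times_s`; attribute `extinction_end_s` marks the end of the
#'   opening extinction period.
#' @export
generate_pit_session <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  n_per <- config$pit_cs_reps
  if (n_per == 0L) {
    return(new_schedule(
      list(trial = integer(0), cs_id = character(0), onset_s = numeric(0),
           offset_s = numeric(0), outcome_id = character(0),
           reward_times_s = list()),
      session_kind = "pit", session_index = 1L,
      extinction_end_s = config$pit_extinction_s,
      session_end_s = config$pit_extinction_s
    ))
  }
  cs_ids <- pseudorandom_order(rep(c("tone", "noise"), n_per))
  n_trials <- length(cs_ids)
  onsets <- config$pit_extinction_s +
    (seq_len(n_trials) - 1L) * (config$cs_duration_s + config$pit_iti_s)
  offsets <- onsets + config$cs_duration_s
  new_schedule(
    list(
      trial = seq_len(n_trials),
      cs_id = cs_ids,
      onset_s = onsets,
      offset_s = offsets,
      outcome_id = NA_character_,
      reward_times_s = replicate(n_trials, numeric(0), simplify = FALSE)
    ),
    session_kind = "pit", session_index = 1L,
    extinction_end_s = config$pit_extinction_s,
    session_end_s = offsets[n_trials] + 60
  )
}

#' Generate a reward-only (unpaired reward) session schedule
#'
#' Emulates the non-contingent reward session of the unpaired control design:
#' for each outcome, `periods_per_outcome` 2-min reward periods under the
#' 30-s random-time schedule, period order pseudorandom, separated by
#' intertrial intervals drawn uniformly on `iti_range_s`. With 4 periods per
#' outcome and the default schedule, the expected delivery count is 16 per
#' outcome per session.
#'
#' @inheritParams generate_conditioning_session
#' @param periods_per_outcome number of 2-min reward periods per outcome (4).
#' @return A `session_schedule` tibble (`session_kind = "magazine"`), one row
#'   per reward period with `cs_id = NA` (no stimulus is presented).
#' @export
generate_reward_only_session <- function(config, periods_per_outcome = 4L,
                                         seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  outcomes <- pseudorandom_order(rep(c("sucrose", "pellet"),
                                     periods_per_outcome))
  n_trials <- length(outcomes)
  itis <- draw_itis(n_trials, config)
  onsets <- numeric(n_trials)
  t_cursor <- 0
  for (i in seq_len(n_trials)) {
    onsets[i] <- t_cursor + itis[i]
    t_cursor <- onsets[i] + config$cs_duration_s
  }
  offsets <- onsets + config$cs_duration_s
  rewards <- lapply(seq_len(n_trials), function(i) {
    onsets[i] + generate_rt_schedule(config$cs_duration_s,
                                     config$rt_mean_interval_s, 0)
  })
  new_schedule(
    list(
      trial = seq_len(n_trials),
      cs_id = NA_character_,
      onset_s = onsets,
      offset_s = offsets,
      outcome_id = outcomes,
      reward_times_s = rewards
    ),
    session_kind = "magazine", session_index = 1L,
    session_end_s = t_cursor + 120
  )
}

#' Simulate an instrumental (lever-press) training session
#'
#' Presses occur as a homogeneous arrival process at `press_rate_per_min`;
#' each press is reinforced with probability 1/20 (random-ratio-20). The
#' session terminates after 30 earned outcomes or 45 min (2700 s), whichever
#' comes first. A 60-presses-per-minute responder earns all 30 outcomes well
#' inside the time limit with overwhelming probability.
#'
#' @inheritParams generate_conditioning_session
#' @param lever_id `"left"` or `"right"`; the earned outcome follows the
#'   subject's lever contingency.
#' @param press_rate_per_min mean press rate (>= 0).
#' @param ratio reinforcement ratio (default 20: each press pays off with
#'   probability 1/20).
#' @param max_outcomes,max_duration_s termination conditions (30, 2700 s).
#' @return An event-log tibble (`time_s`, `event`, `label`) containing
#'   `session_start`, `lever_press`, `reward_delivery` and `session_end`
#'   events.
#' @export
generate_instrumental_session <- function(config, contingency, lever_id,
                                          press_rate_per_min, ratio = 20,
                                          max_outcomes = 30L,
                                          max_duration_s = 2700,
                                          seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_contingency(contingency)
  if (!lever_id %in% names(contingency$lever_to_outcome)) {
    stop("unknown lever_id: ", lever_id, call. = FALSE)
  }
  if (!is.numeric(press_rate_per_min) || press_rate_per_min < 0) {
    stop("press_rate_per_min must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  outcome <- unname(contingency$lever_to_outcome[lever_id])

  press_times <- arrival_times(press_rate_per_min / 60, 0, max_duration_s)
  reinforced <- if (length(press_times)) {
    stats::runif(length(press_times)) < 1 / ratio
  } else logical(0)
  earned <- cumsum(reinforced)
  if (any(earned >= max_outcomes)) {
    cut_idx <- which(earned == max_outcomes)[1]
    end_s <- press_times[cut_idx]
    keep <- seq_len(cut_idx)
  } else {
    end_s <- max_duration_s
    keep <- seq_along(press_times)
  }
  press_times <- press_times[keep]
  reinforced <- reinforced[keep]

  events <- dplyr::bind_rows(
    tibble::tibble(time_s = 0, event = "session_start", label = ""),
    tibble::tibble(time_s = press_times, event = "lever_press",
                   label = lever_id),
    tibble::tibble(time_s = press_times[reinforced],
                   event = "reward_delivery", label = outcome),
    tibble::tibble(time_s = end_s, event = "session_end", label = "")
  )
  as_event_log(events)
}

# Homogeneous Poisson arrival times at `rate` (per second) on [from, to).
arrival_times <- function(rate, from, to) {
  len <- to - from
  if (rate <= 0 || len <= 0) return(numeric(0))
  n <- stats::rpois(1L, rate * len)
  sort(stats::runif(n, from, to))
}
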