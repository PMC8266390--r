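#' Calcium transient kernel
#'
#' Double-exponential kernel `(1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`,
#' peak-normalized so that transient amplitudes are expressed directly in
#' dF/F units.
#'
#' @param t times since event onset (seconds); values at `t < 0` are 0.
#' @param tau_rise_s,tau_decay_s rise and decay time constants
#'   (`tau_rise_s < tau_decay_s`).
#' @return Kernel values, max 1.
#' @export
transient_kernel <- function(t, tau_rise_s, tau_decay_s) {
  stopifnot(tau_rise_s > 0, tau_decay_s > tau_rise_s)
  a <- tau_rise_s
  b <- tau_decay_s
  t_peak <- a * log((a + b) / a)
  k_max <- (1 - exp(-t_peak / a)) * exp(-t_peak / b)
  k <- ifelse(t < 0, 0, (1 - exp(-t / a)) * exp(-t / b))
  k / k_max
}

# Two-term exponential photobleaching factor, 1 at t = 0, decaying toward
# 1 - amp1 - amp2. Multiplies both channel baselines.
bleach_factor <- function(t, amp1, tau1, amp2, tau2) {
  (1 - amp1 - amp2) + amp1 * exp(-t / tau1) + amp2 * exp(-t / tau2)
}

# Zero-mean unit-variance AR(1) sequence with autocorrelation time tau_s at
# sampling interval dt.
ar1_series <- function(n, dt, tau_s) {
  if (n == 0L) return(numeric(0))
  if (tau_s <= 0) return(stats::rnorm(n))
  phi <- exp(-dt / tau_s)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1L, sd = sqrt(1 - phi^2))
  for (i in seq_len(n - 1L)) x[i + 1L] <- phi * x[i] + innov[i]
  x
}

#' Simulate an interleaved two-channel photometry recording
#'
#' Generates 415-nm (isosbestic) and 470-nm (calcium-dependent) fluorescence
#' streams for one session, acquired at `sample_rate_hz` per channel with the
#' two channels' acquisition times offset by half a sample period
#' (interleaved excitation). The generative model is
#' \deqn{F_{470}(t) = f0_{470} B(t) \bigl(1 + \sum_e a_e k(t - t_e)\bigr)
#'   + \sigma_m m(t) + \epsilon(t)}
#' \deqn{F_{415}(t) = f0_{415} B(t) + g_{415}\, \sigma_m m(t) + \epsilon(t)}
#' with `B(t)` the two-exponential photobleaching factor shared by both
#' channels, `m(t)` a zero-mean low-pass motion artifact shared across
#' channels, `k` the peak-normalized transient kernel
#' ([transient_kernel()]), and white measurement noise. Transients are
#' injected at CS onsets (amplitude `amp_cs`, decayed by `habituation_rate`
#' per session in unpaired sessions) and at reward retrievals (the first
#' food-port entry at or after each delivery, amplitude `amp_retrieval`).
#' No calcium term enters the 415 channel.
#'
#' The motion artifact is an AR(1) process anchored at the 415-channel sample
#' times and piecewise-linear in between, so the artifact seen by the
#' 470 channel (sampled midway between 415 samples) is exactly the linear
#' interpolation of the 415 samples; the de-interleaving step of the
#' preprocessing can therefore cancel a shared artifact exactly.
#'
#' @param schedule the session's `session_schedule`.
#' @param eventlog the session's `event_log` (used to locate reward
#'   retrievals; deliveries with no subsequent food-port entry simply
#'   contribute no transient).
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return A `two_channel_recording` tibble in long format: `time_s`,
#'   `channel` (415 or 470), `fluorescence`; attribute `sample_rate_hz`.
#' @export
simulate_photometry <- function(schedule, eventlog, config, seed = NULL) {
  stopifnot(inherits(schedule, "session_schedule"),
            inherits(config, "sim_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  fs <- config$sample_rate_hz
  dt <- 1 / fs
  dur <- attr(schedule, "session_end_s")
  n <- max(2L, floor(dur * fs))
  t415 <- (seq_len(n) - 1L) * dt
  t470 <- t415 + dt / 2

  # transient event times and amplitudes
  kind <- attr(schedule, "session_kind")
  session_index <- attr(schedule, "session_index")
  amp_cs <- config$amp_cs
  if (kind == "unpaired") {
    amp_cs <- amp_cs * (1 - config$habituation_rate)^(session_index - 1L)
  }
  cs_onsets <- schedule$onset_s[!is.na(schedule$cs_id)]
  retrievals <- derive_retrievals(schedule, eventlog)$time_s
  ev_times <- c(cs_onsets, retrievals)
  ev_amps <- c(rep(amp_cs, length(cs_onsets)),
               rep(config$amp_retrieval, length(retrievals)))

  transient_sum <- function(t_grid) {
    s <- numeric(length(t_grid))
    support <- 12 * config$tau_decay_s
    for (i in seq_along(ev_times)) {
      if (ev_amps[i] == 0) next
      idx <- which(t_grid >= ev_times[i] & t_grid <= ev_times[i] + support)
      if (length(idx)) {
        s[idx] <- s[idx] + ev_amps[i] *
          transient_kernel(t_grid[idx] - ev_times[i],
                           config$tau_rise_s, config$tau_decay_s)
      }
    }
    s
  }

  b415 <- bleach_factor(t415, config$bleach_amp1, config$bleach_tau1_s,
                        config$bleach_amp2, config$bleach_tau2_s)
  b470 <- bleach_factor(t470, config$bleach_amp1, config$bleach_tau1_s,
                        config$bleach_amp2, config$bleach_tau2_s)

  if (config$motion_sd > 0) {
    m415 <- ar1_series(n, dt, config$motion_tau_s)
    m470 <- (m415 + c(m415[-1L], m415[n])) / 2  # piecewise-linear midpoints
  } else {
    m415 <- m470 <- numeric(n)
  }

  f470 <- config$f0_470 * b470 * (1 + transient_sum(t470)) +
    config$motion_sd * m470 +
    if (config$noise_sd > 0) stats::rnorm(n, sd = config$noise_sd) else 0
  f415 <- config$f0_415 * b415 +
    config$gain_415 * config$motion_sd * m415 +
    if (config$noise_sd > 0) stats::rnorm(n, sd = config$noise_sd) else 0

  rec <- tibble::tibble(
    time_s = c(rbind(t415, t470)),
    channel = rep(c(415L, 470L), n),
    fluorescence = c(rbind(f415, f470))
  )
  attr(rec, "sample_rate_hz") <- fs
  class(rec) <- c("two_channel_recording", class(rec))
  rec
}

# First food-port entry at or after each reward delivery (bounded by the next
# delivery of the same trial, else the session end). Shared by the simulator
# (to place retrieval transients) and by derive_events().
derive_retrievals <- function(schedule, eventlog) {
  deliveries <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(schedule), "trial", "outcome_id",
                  "reward_times_s"),
    "reward_times_s"
  )
  if (!nrow(deliveries)) {
    return(tibble::tibble(time_s = numeric(0), delivery_time_s = numeric(0),
                          trial = integer(0)))
  }
  deliveries <- dplyr::arrange(deliveries, .data$trial, .data$reward_times_s)
  entries <- eventlog$time_s[eventlog$event == "foodport_entry"]
  end_s <- attr(schedule, "session_end_s")
  if (is.null(end_s)) end_s <- max(eventlog$time_s)
  out <- purrr::map_dfr(seq_len(nrow(deliveries)), function(i) {
    d <- deliveries$reward_times_s[i]
    same_trial <- deliveries$trial == deliveries$trial[i] &
      deliveries$reward_times_s > d
    bound <- if (any(same_trial)) min(deliveries$reward_times_s[same_trial])
             else end_s
    hit <- entries[entries >= d & entries < bound]
    if (!length(hit)) return(NULL)
    tibble::tibble(time_s = hit[1], delivery_time_s = d,
                   trial = deliveries$trial[i])
  })
  if (!nrow(out)) {
    out <- tibble::tibble(time_s = numeric(0), delivery_time_s = numeric(0),
                          trial = integer(0))
  }
  out
}
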