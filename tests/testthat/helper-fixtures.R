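# Build a corrected_trace directly from a zdff series (for alignment and QC
# tests that do not need the full preprocessing path).
make_trace <- function(time_s, zdff, dff = zdff, r_squared = 1,
                       sample_rate_hz = NULL) {
  out <- tibble::tibble(time_s = time_s, f470 = NA_real_, f415 = NA_real_,
                        fitted_415 = NA_real_, dff = dff, zdff = zdff)
  attr(out, "fit") <- structure(
    list(slope = 1, intercept = 0, r_squared = r_squared),
    class = "isosbestic_fit"
  )
  attr(out, "session_mean_dff") <- mean(dff)
  attr(out, "session_sd_dff") <- stats::sd(dff)
  attr(out, "sample_rate_hz") <- sample_rate_hz %||%
    (1 / stats::median(diff(time_s)))
  class(out) <- c("corrected_trace", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built event log from vectors.
make_log <- function(time_s, event, label = "") {
  tibble::tibble(time_s = time_s, event = event,
                 label = rep_len(label, length(time_s)))
}

# Minimal single-trial conditioning schedule for toy examples.
make_toy_schedule <- function(onset_s, offset_s, reward_times_s,
                              cs_id = "tone", outcome_id = "sucrose",
                              session_end_s = offset_s + 120,
                              session_kind = "conditioning",
                              session_index = 1L) {
  out <- tibble::tibble(
    trial = seq_along(onset_s),
    cs_id = rep_len(cs_id, length(onset_s)),
    onset_s = onset_s,
    offset_s = offset_s,
    outcome_id = rep_len(outcome_id, length(onset_s)),
    reward_times_s = reward_times_s
  )
  attr(out, "session_kind") <- session_kind
  attr(out, "session_index") <- session_index
  attr(out, "extinction_end_s") <- NA_real_
  attr(out, "session_end_s") <- session_end_s
  class(out) <- c("session_schedule", class(out))
  out
}

# dF/F straight from a raw recording, without Z-scoring (which rejects the
# zero-variance traces produced by exact-cancellation configurations).
compute_dff_from_recording <- function(rec) {
  p <- deinterleave(rec)
  fit <- fit_isosbestic(p$f470, p$f415)
  compute_dff(p$f470, p$f415, fit)
}
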