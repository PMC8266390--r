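#' De-interleave a two-channel recording onto a common timebase
#'
#' The 470-nm sample times become the master grid; the 415-nm stream is
#' linearly interpolated onto it. 470 samples outside the 415 support use
#' nearest-value extension.
#'
#' @param rec a `two_channel_recording` (long tibble with `time_s`,
#'   `channel`, `fluorescence`), e.g. from [simulate_photometry()] or
#'   [read_recording()].
#' @return Tibble with columns `time_s`, `f470`, `f415` (interpolated), one
#'   row per 470 sample.
#' @export
deinterleave <- function(rec) {
  stopifnot(all(c("time_s", "channel", "fluorescence") %in% names(rec)))
  ch470 <- rec[rec$channel == 470, , drop = FALSE]
  ch415 <- rec[rec$channel == 415, , drop = FALSE]
  if (nrow(ch470) < 2L || nrow(ch415) < 2L) {
    stop("both channels must be present with at least 2 samples each",
         call. = FALSE)
  }
  f415 <- stats::approx(ch415$time_s, ch415$fluorescence,
                        xout = ch470$time_s, rule = 2)$y
  tibble::tibble(time_s = ch470$time_s, f470 = ch470$fluorescence,
                 f415 = f415)
}

#' Least-squares isosbestic fit
#'
#' Ordinary least-squares linear regression fitting the 415-nm isosbestic
#' signal to the 470-nm signal over the whole session: the returned slope and
#' intercept map the 415 signal onto the scale of the 470 signal
#' (`fitted_415 = slope * f415 + intercept`), capturing shared photobleaching
#' and motion artifact.
#'
#' @param f470,f415 numeric vectors of equal length (>= 3) on a common
#'   timebase (see [deinterleave()]).
#' @return List of class `isosbestic_fit`: `slope`, `intercept`,
#'   `r_squared`.
#' @export
fit_isosbestic <- function(f470, f415) {
  if (length(f470) != length(f415) || length(f470) < 3L) {
    stop("f470 and f415 must have equal length >= 3", call. = FALSE)
  }
  sxx <- sum((f415 - mean(f415))^2)
  if (sxx == 0) {
    stop("degenerate isosbestic fit: 415 channel is constant", call. = FALSE)
  }
  sxy <- sum((f415 - mean(f415)) * (f470 - mean(f470)))
  syy <- sum((f470 - mean(f470))^2)
  slope <- sxy / sxx
  intercept <- mean(f470) - slope * mean(f415)
  r2 <- if (syy == 0) 1 else sxy^2 / (sxx * syy)
  structure(list(slope = slope, intercept = intercept, r_squared = r2),
            class = "isosbestic_fit")
}

#' @export
print.isosbestic_fit <- function(x, ...) {
  cat(sprintf("<isosbestic_fit> slope %.4g, intercept %.4g, r^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Fractional fluorescence change (dF/F)
#'
#' `dff_i = (f470_i - fitted415_i) / fitted415_i`, where
#' `fitted415 = slope * f415 + intercept` from the isosbestic fit. The
#' fitted reference must be strictly positive at every sample.
#'
#' @inheritParams fit_isosbestic
#' @param fit an `isosbestic_fit`.
#' @return Numeric dF/F series.
#' @export
compute_dff <- function(f470, f415, fit) {
  stopifnot(inherits(fit, "isosbestic_fit"))
  fitted <- fit$slope * f415 + fit$intercept
  bad <- which(fitted <= 0)
  if (length(bad)) {
    stop("fitted 415 reference is non-positive at sample ", bad[1],
         " (value ", signif(fitted[bad[1]], 4), ")", call. = FALSE)
  }
  (f470 - fitted) / fitted
}

#' Z-score a dF/F series over the whole session
#'
#' `(dff - mean(dff)) / sd_pop(dff)` with the population (divide-by-n)
#' standard deviation taken over the entire session, intertrial intervals
#' included.
#'
#' @param dff numeric dF/F series of length >= 2 with positive variance.
#' @return List: `zdff`, `session_mean_dff`, `session_sd_dff`.
#' @export
zscore_trace <- function(dff) {
  if (length(dff) < 2L) stop("dff must have length >= 2", call. = FALSE)
  mu <- mean(dff)
  sdp <- sqrt(mean((dff - mu)^2))
  if (sdp == 0) stop("cannot Z-score a zero-variance dF/F series",
                     call. = FALSE)
  list(zdff = (dff - mu) / sdp, session_mean_dff = mu, session_sd_dff = sdp)
}

#' Full photometry preprocessing: de-interleave, fit, dF/F, Z-score
#'
#' Convenience wrapper running [deinterleave()], [fit_isosbestic()],
#' [compute_dff()] and [zscore_trace()] on a raw recording.
#'
#' @inheritParams deinterleave
#' @return A `corrected_trace` tibble with columns `time_s`, `f470`, `f415`,
#'   `fitted_415`, `dff`, `zdff`; attributes `fit` (the `isosbestic_fit`),
#'   `session_mean_dff`, `session_sd_dff`, `sample_rate_hz`.
#' @examples
#' cfg <- sim_config(photometry = TRUE, n_subjects = 1)
#' ct <- make_contingency(0)
#' sch <- generate_conditioning_session(cfg, ct, 1, seed = 1)
#' log <- simulate_behavior(sch, cfg, ct, seed = 2)
#' rec <- simulate_photometry(sch, log, cfg, seed = 3)
#' trace <- correct_photometry(rec)
#' attr(trace, "fit")
#' @export
correct_photometry <- function(rec) {
  paired <- deinterleave(rec)
  fit <- fit_isosbestic(paired$f470, paired$f415)
  dff <- compute_dff(paired$f470, paired$f415, fit)
  z <- zscore_trace(dff)
  out <- tibble::tibble(
    time_s = paired$time_s,
    f470 = paired$f470,
    f415 = paired$f415,
    fitted_415 = fit$slope * paired$f415 + fit$intercept,
    dff = dff,
    zdff = z$zdff
  )
  attr(out, "fit") <- fit
  attr(out, "session_mean_dff") <- z$session_mean_dff
  attr(out, "session_sd_dff") <- z$session_sd_dff
  fs <- attr(rec, "sample_rate_hz")
  attr(out, "sample_rate_hz") <- if (is.null(fs)) {
    1 / stats::median(diff(paired$time_s))
  } else fs
  class(out) <- c("corrected_trace", class(out))
  out
}

# Local maxima of `x` exceeding `threshold`, greedily enforcing a minimum
# index separation, applied to a lightly smoothed copy of the trace so white
# measurement noise does not register as transients.
detect_transients <- function(dff, fs, min_separation_s = 1,
                              smooth_s = 0.25) {
  w <- max(1L, round(smooth_s * fs))
  if (w > 1L) {
    kern <- rep(1 / w, w)
    sm <- stats::filter(dff, kern, sides = 2)
    sm[is.na(sm)] <- 0
    sm <- as.numeric(sm)
  } else {
    sm <- dff
  }
  threshold <- 3 * stats::mad(dff, constant = 1.4826)
  n <- length(sm)
  if (n < 3L || threshold == 0) return(integer(0))
  is_peak <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                 sm[2:(n - 1)] >= sm[3:n], FALSE) & sm > threshold
  idx <- which(is_peak)
  if (!length(idx)) return(integer(0))
  min_gap <- min_separation_s * fs
  keep <- idx[order(-sm[idx])]
  chosen <- integer(0)
  for (i in keep) {
    if (!length(chosen) || all(abs(chosen - i) >= min_gap)) {
      chosen <- c(chosen, i)
    }
  }
  sort(chosen)
}

#' Session quality control
#'
#' A session passes QC when (a) the isosbestic fit is acceptable
#' (`r_squared >= min_r2`) and (b) transient calcium fluctuations are present
#' on the corrected 470 signal. Transients are local maxima of the dF/F
#' trace (smoothed over 0.25 s to reject single-sample noise) exceeding three
#' robust standard deviations (1.4826 x median absolute deviation of the raw
#' dF/F), separated by at least 1 s.
#'
#' @param trace a `corrected_trace` from [correct_photometry()].
#' @param min_r2 minimum acceptable isosbestic-fit r-squared.
#' @param min_transient_rate_per_min minimum detected transient rate.
#' @return One-row tibble: `transient_rate_per_min`, `n_transients`,
#'   `r_squared`, `passed`, and a list-column `reasons` holding a character
#'   vector drawn from `c("no_transients", "poor_fit")` (empty iff passed).
#' @export
qc_session <- function(trace, min_r2 = 0.6, min_transient_rate_per_min = 0.1) {
  stopifnot(inherits(trace, "corrected_trace"))
  fs <- attr(trace, "sample_rate_hz")
  dur_min <- (max(trace$time_s) - min(trace$time_s)) / 60
  idx <- detect_transients(trace$dff, fs)
  rate <- if (dur_min > 0) length(idx) / dur_min else 0
  r2 <- attr(trace, "fit")$r_squared
  reasons <- character(0)
  if (r2 < min_r2) reasons <- c(reasons, "poor_fit")
  if (rate < min_transient_rate_per_min) reasons <- c(reasons, "no_transients")
  tibble::tibble(
    transient_rate_per_min = rate,
    n_transients = length(idx),
    r_squared = r2,
    passed = length(reasons) == 0L,
    reasons = list(reasons)
  )
}
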