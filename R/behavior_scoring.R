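#' Event rate in a half-open time window
#'
#' Counts events of one kind with `start_s <= time < end_s` and divides by
#' the window length in minutes. Boundary events at `end_s` belong to the
#' next window (half-open convention).
#'
#' @param log an `event_log`.
#' @param kind event kind (e.g. `"foodport_entry"`, `"lever_press"`).
#' @param window numeric pair `c(start_s, end_s)` with `end_s > start_s`.
#' @param label optional label filter (e.g. a lever id).
#' @return Events per minute.
#' @export
entry_rate <- function(log, kind = "foodport_entry", window, label = NULL) {
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("window must be c(start_s, end_s) with end_s > start_s",
         call. = FALSE)
  }
  sel <- log$event == kind & log$time_s >= window[1] & log$time_s < window[2]
  if (!is.null(label)) sel <- sel & log$label == label
  sum(sel) / ((window[2] - window[1]) / 60)
}

# cs/(cs + pre), NA when both are zero (undefined; excluded from averages).
elevation_ratio <- function(cs, pre) {
  ifelse(cs + pre > 0, cs / (cs + pre), NA_real_)
}

# trial-level ratios -> mean within CS -> unweighted mean across CSs;
# undefined (NA) ratios drop out of the trial average.
summarise_ratio <- function(trials, value_col = "ratio") {
  usable <- trials[!is.na(trials[[value_col]]), , drop = FALSE]
  if (!nrow(usable)) return(NA_real_)
  per_cs <- tapply(usable[[value_col]], usable$cs_id, mean)
  mean(per_cs)
}

#' Pavlovian conditional approach: elevation ratios
#'
#' For each conditioning trial, computes the food-port entry rate during the
#' CS probe period (CS onset up to the first reward delivery, or CS offset if
#' no reward was delivered) and during the 2-min baseline immediately before
#' CS onset, and the elevation ratio
#' `cs_rate / (cs_rate + pre_rate)`. A ratio of 0.5 indicates no elevation;
#' trials where both rates are 0 are undefined and excluded from averages.
#' Trials whose 2-min pre window would precede the session start are flagged
#' and skipped.
#'
#' @param schedule a conditioning `session_schedule`.
#' @param log the matching `event_log`.
#' @param pre_window_s baseline window length before CS onset (120 s).
#' @return Tibble, one row per trial: `trial`, `cs_id`, `cs_rate_per_min`,
#'   `pre_rate_per_min`, `ratio`; attribute `summary` holds the
#'   trial-then-CS-averaged ratio (also available via
#'   [summarise_elevation()]).
#' @examples
#' cfg <- sim_config(n_subjects = 1)
#' ct <- make_contingency(0)
#' sch <- generate_conditioning_session(cfg, ct, 5, seed = 1)
#' log <- simulate_behavior(sch, cfg, ct, seed = 2)
#' pe <- pavlovian_elevation(sch, log)
#' summarise_elevation(pe)
#' @export
pavlovian_elevation <- function(schedule, log, pre_window_s = 120) {
  stopifnot(inherits(schedule, "session_schedule"))
  cs_trials <- schedule[!is.na(schedule$cs_id), , drop = FALSE]
  out <- purrr::map_dfr(seq_len(nrow(cs_trials)), function(i) {
    onset <- cs_trials$onset_s[i]
    if (onset - pre_window_s < 0) {
      rlang::inform(sprintf(
        "pavlovian_elevation: trial %d skipped (pre window precedes session start)",
        cs_trials$trial[i]))
      return(NULL)
    }
    rw <- cs_trials$reward_times_s[[i]]
    probe_end <- if (length(rw)) min(rw) else cs_trials$offset_s[i]
    if (probe_end <= onset) probe_end <- cs_trials$offset_s[i]
    cs_rate <- entry_rate(log, "foodport_entry", c(onset, probe_end))
    pre_rate <- entry_rate(log, "foodport_entry",
                           c(onset - pre_window_s, onset))
    tibble::tibble(
      trial = cs_trials$trial[i],
      cs_id = cs_trials$cs_id[i],
      cs_rate_per_min = cs_rate,
      pre_rate_per_min = pre_rate,
      ratio = elevation_ratio(cs_rate, pre_rate)
    )
  })
  if (!nrow(out)) stop("no scorable trials", call. = FALSE)
  attr(out, "summary") <- summarise_ratio(out)
  out
}

#' @rdname pavlovian_elevation
#' @param trials a per-trial ratio tibble (from [pavlovian_elevation()],
#'   [pit_foodport_score()], or one lever of [pit_lever_scores()]).
#' @export
summarise_elevation <- function(trials) summarise_ratio(trials)

#' Which lever is "Same" for a presented CS?
#'
#' The Same lever is the one whose training outcome matches the outcome
#' predicted by the presented CS under the subject's contingency; the other
#' available lever is Different.
#'
#' @param cs_id `"tone"` or `"noise"`.
#' @param contingency a [make_contingency()] assignment.
#' @return Lever id (`"left"` or `"right"`).
#' @export
classify_same_lever <- function(cs_id, contingency) {
  check_contingency(contingency)
  if (!cs_id %in% names(contingency$cs_to_outcome)) {
    stop("cs_id not mapped in contingency: ", cs_id, call. = FALSE)
  }
  outcome <- contingency$cs_to_outcome[[cs_id]]
  names(contingency$lever_to_outcome)[
    contingency$lever_to_outcome == outcome]
}

#' Outcome-selective PIT lever-press scoring
#'
#' For each PIT trial, counts lever presses during the 2-min CS and during
#' the 2-min baseline immediately before CS onset, split into Same (the
#' lever whose training outcome matches the presented CS) and Different
#' presses via [classify_same_lever()]. Per-trial elevation ratios
#' `CS / (CS + preCS)` are computed for each lever class, averaged across
#' trials within each CS and then across the two CSs. Windows are half-open;
#' trials whose pre window would overlap the session start are flagged and
#' skipped; 0/0 ratios are undefined and excluded.
#'
#' @param schedule a PIT `session_schedule`.
#' @param log the matching `event_log` with labeled `lever_press` events.
#' @param contingency the subject's [make_contingency()] assignment.
#' @param pre_window_s baseline window length (120 s).
#' @return One-row tibble: `same_ratio`, `different_ratio`; attribute
#'   `trials` holds the per-trial table (`trial`, `cs_id`, press counts and
#'   ratios per lever class).
#' @export
pit_lever_scores <- function(schedule, log, contingency, pre_window_s = 120) {
  stopifnot(inherits(schedule, "session_schedule"))
  check_contingency(contingency)
  cs_trials <- schedule[!is.na(schedule$cs_id), , drop = FALSE]
  skipped <- cs_trials$onset_s - pre_window_s < 0
  if (any(skipped)) {
    rlang::inform(sprintf(
      "pit_lever_scores: %d trial(s) skipped (pre window precedes session start)",
      sum(skipped)))
    cs_trials <- cs_trials[!skipped, , drop = FALSE]
  }
  if (!nrow(cs_trials)) stop("no scorable PIT trials", call. = FALSE)
  press_t <- split(log$time_s[log$event == "lever_press"],
                   log$label[log$event == "lever_press"])
  count_in <- function(lever, from, to) {
    t <- press_t[[lever]]
    if (is.null(t)) return(numeric(length(from)))
    vapply(seq_along(from), function(i) {
      sum(t >= from[i] & t < to[i])
    }, numeric(1))
  }
  same_lever <- vapply(cs_trials$cs_id, classify_same_lever, character(1),
                       contingency = contingency)
  diff_lever <- ifelse(same_lever == "left", "right", "left")
  on <- cs_trials$onset_s
  off <- cs_trials$offset_s
  cs_same <- pre_same <- cs_diff <- pre_diff <- numeric(nrow(cs_trials))
  for (lev in unique(same_lever)) {
    sel <- same_lever == lev
    cs_same[sel] <- count_in(lev, on[sel], off[sel])
    pre_same[sel] <- count_in(lev, on[sel] - pre_window_s, on[sel])
  }
  for (lev in unique(diff_lever)) {
    sel <- diff_lever == lev
    cs_diff[sel] <- count_in(lev, on[sel], off[sel])
    pre_diff[sel] <- count_in(lev, on[sel] - pre_window_s, on[sel])
  }
  trials <- tibble::tibble(
    trial = cs_trials$trial, cs_id = cs_trials$cs_id,
    cs_same = cs_same, pre_same = pre_same,
    cs_diff = cs_diff, pre_diff = pre_diff,
    same_ratio = elevation_ratio(cs_same, pre_same),
    diff_ratio = elevation_ratio(cs_diff, pre_diff)
  )
  out <- tibble::tibble(
    same_ratio = summarise_ratio(trials, "same_ratio"),
    different_ratio = summarise_ratio(trials, "diff_ratio")
  )
  attr(out, "trials") <- trials
  out
}

#' PIT conditional approach: food-port entry elevation
#'
#' Entries are counted over the full 2-min CS window and the 2-min baseline
#' before CS onset; the elevation ratio `CS / (CS + preCS)` is averaged
#' across trials and then across the two CSs, with undefined 0/0 trials
#' excluded.
#'
#' @inheritParams pit_lever_scores
#' @return Tibble, one row per trial (`trial`, `cs_id`, `cs_entries`,
#'   `pre_entries`, `ratio`); attribute `summary` holds the averaged ratio.
#' @export
pit_foodport_score <- function(schedule, log, pre_window_s = 120) {
  stopifnot(inherits(schedule, "session_schedule"))
  cs_trials <- schedule[!is.na(schedule$cs_id), , drop = FALSE]
  out <- purrr::map_dfr(seq_len(nrow(cs_trials)), function(i) {
    onset <- cs_trials$onset_s[i]
    if (onset - pre_window_s < 0) {
      rlang::inform(sprintf(
        "pit_foodport_score: trial %d skipped (pre window precedes session start)",
        cs_trials$trial[i]))
      return(NULL)
    }
    cs_n <- sum(log$event == "foodport_entry" & log$time_s >= onset &
                  log$time_s < cs_trials$offset_s[i])
    pre_n <- sum(log$event == "foodport_entry" &
                   log$time_s >= onset - pre_window_s & log$time_s < onset)
    tibble::tibble(trial = cs_trials$trial[i], cs_id = cs_trials$cs_id[i],
                   cs_entries = cs_n, pre_entries = pre_n,
                   ratio = elevation_ratio(cs_n, pre_n))
  })
  if (!nrow(out)) stop("no scorable PIT trials", call. = FALSE)
  attr(out, "summary") <- summarise_ratio(out)
  out
}
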