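test_that("retrievals and probe entries follow their definitions", {
  sch <- make_toy_schedule(onset_s = 90, offset_s = 210,
                           reward_times_s = list(c(100, 150)),
                           session_end_s = 260)
  log <- make_log(
    time_s = c(0, 90, 95, 103.2, 110, 151, 210, 260),
    event = c("session_start", "cs_on", "foodport_entry", "foodport_entry",
              "foodport_entry", "foodport_entry", "cs_off", "session_end"),
    label = c("", "tone", "", "", "", "", "tone", "")
  )
  ev <- derive_events(sch, log)
  # first entry at-or-after each delivery, bounded by the next delivery
  expect_equal(ev$reward_retrievals$time_s, c(103.2, 151))
  expect_equal(ev$reward_retrievals$delivery_time_s, c(100, 150))
  # probe entries: after onset, before the first delivery
  expect_equal(ev$probe_entries$time_s, 95)

  # entry exactly at the delivery time counts (inclusive boundary)
  log2 <- make_log(
    time_s = c(0, 90, 100, 210, 260),
    event = c("session_start", "cs_on", "foodport_entry", "cs_off",
              "session_end"),
    label = c("", "tone", "", "tone", "")
  )
  sch2 <- make_toy_schedule(90, 210, list(100), session_end_s = 260)
  expect_equal(derive_events(sch2, log2)$reward_retrievals$time_s, 100)

  # toy probe example: onset 120, first delivery 140, entries 30/90/125
  sch3 <- make_toy_schedule(120, 240, list(140), session_end_s = 300)
  log3 <- make_log(
    time_s = c(0, 30, 90, 120, 125, 240, 300),
    event = c("session_start", "foodport_entry", "foodport_entry", "cs_on",
              "foodport_entry", "cs_off", "session_end"),
    label = c("", "", "", "tone", "", "tone", "")
  )
  expect_equal(derive_events(sch3, log3)$probe_entries$time_s, 125)

  # mismatched markers are rejected
  bad <- make_log(c(0, 91, 210, 260),
                  c("session_start", "cs_on", "cs_off", "session_end"),
                  c("", "tone", "tone", ""))
  expect_error(derive_events(sch2, bad), "do not match")
})

test_that("peri-event extraction samples a fixed window on the trace grid", {
  tr <- make_trace(seq(0, 100, by = 0.1), zdff = rep(0, 1001))
  tens <- extract_peri_event(tr, c(10, 50), 3, 3)
  expect_equal(nrow(tens), 2)
  expect_equal(attr(tens, "n_dropped"), 0)
  rel <- attr(tens, "relative_time_s")
  expect_equal(range(rel), c(-3, 3))
  expect_true(all(tens == 0))

  # event too close to the recording edge is dropped and counted
  tens2 <- extract_peri_event(tr, c(1, 50), 3, 3)
  expect_equal(nrow(tens2), 1)
  expect_equal(attr(tens2, "n_dropped"), 1)

  empty <- extract_peri_event(tr, numeric(0))
  expect_equal(nrow(empty), 0)
  expect_error(extract_peri_event(tr, c(50, 10)), "sorted")
})

test_that("peak and AUC quantify the flanking windows", {
  # 1-s spacing, post window [0,1,1,0] -> trapezoid 2.0, peak 1.0
  tr <- make_trace(0:20, zdff = c(rep(0, 11), 1, 1, rep(0, 8)))
  tens <- extract_peri_event(tr, 10, 3, 3)
  q <- quantify_trials(tens)
  expect_equal(q$auc_post, 2)
  expect_equal(q$peak_post, 1)
  expect_equal(q$auc_pre, 0)
  expect_equal(q$peak_pre, 0)

  zero <- make_trace(0:20, zdff = rep(0, 21))
  qz <- quantify_trials(extract_peri_event(zero, 10))
  expect_equal(unlist(qz[c("peak_pre", "peak_post", "auc_pre", "auc_post")]),
               c(peak_pre = 0, peak_post = 0, auc_pre = 0, auc_post = 0))

  expect_error(quantify_trials(extract_peri_event(zero, numeric(0))),
               "empty")
})

test_that("trapezoidal AUC matches a fine-grid Riemann oracle", {
  withr::local_seed(202)
  for (i in seq_len(25)) {
    z <- stats::rnorm(121)
    tr <- make_trace(seq(0, 12, by = 0.1), zdff = z)
    q <- quantify_trials(extract_peri_event(tr, 6, 3, 3))
    rel <- seq(-3, 3, by = 0.1)
    vals <- z[31:91]
    # midpoint Riemann sum of the piecewise-linear interpolant
    riemann <- function(xs, ys) {
      # subdivide each sample interval so no Riemann cell straddles a kink
      grid <- seq(min(xs), max(xs), length.out = (length(xs) - 1) * 64 + 1)
      mid <- (grid[-1] + grid[-length(grid)]) / 2
      sum(stats::approx(xs, ys, xout = mid)$y) * diff(grid[1:2])
    }
    expect_equal(q$auc_pre, riemann(rel[rel <= 0], vals[rel <= 0]),
                 tolerance = 1e-8)
    expect_equal(q$auc_post, riemann(rel[rel >= 0], vals[rel >= 0]),
                 tolerance = 1e-8)
  }
})

test_that("AUC is symmetric for traces mirror-symmetric about the event", {
  z <- c(rep(0, 5), 1, 2, 3, 2, 1, 0.5, 1, 2, 3, 2, 1, rep(0, 5))
  # indices 6..16 symmetric about index 11
  tr <- make_trace(0:20, zdff = z)
  q <- quantify_trials(extract_peri_event(tr, 10, 3, 3))
  expect_equal(q$auc_pre, q$auc_post, tolerance = 1e-9)
})

test_that("aligning to random times in a null session is unbiased", {
  ct <- make_contingency(0)
  cfg <- sim_config(photometry = TRUE, amp_cs = 0, amp_retrieval = 0)
  sch <- generate_conditioning_session(cfg, ct, 1, seed = 301)
  log <- simulate_behavior(sch, cfg, ct, seed = 302)
  rec <- simulate_photometry(sch, log, cfg, seed = 303)
  tr <- correct_photometry(rec)
  withr::local_seed(304)
  times <- sort(stats::runif(250, 10, attr(sch, "session_end_s") - 10))
  q <- quantify_trials(extract_peri_event(tr, times, 3, 3))
  d <- q$peak_post - q$peak_pre
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 2 * se)
})

test_that("trial averages weight the two CSs equally", {
  q <- tibble::tibble(
    trial = 1:8,
    cs_id = c(rep("tone", 3), rep("noise", 5)),
    peak_post = c(1, 1, 1, 3, 3, 3, 3, 3)
  )
  out <- average_trials(q)
  expect_equal(out$peak_post, 2)  # 0.5/0.5 despite 3 vs 5 trials

  one_cs <- average_trials(q[q$cs_id == "tone", ])
  expect_equal(one_cs$peak_post, 1)
  expect_error(average_trials(q[0, ]), "no usable trials")
})

test_that("session binning follows the 1, 2, 3/4, 5/6, 7/8 scheme", {
  df <- tibble::tibble(subject = 1, session = 1:8, v = 1:8)
  out <- bin_sessions(df)
  expect_equal(out$v, c(1, 2, 3.5, 5.5, 7.5))
  expect_equal(as.character(out$bin), c("1", "2", "3/4", "5/6", "7/8"))

  # subject with both sessions of a bin missing is excluded...
  two <- dplyr::bind_rows(df,
                          tibble::tibble(subject = 2,
                                         session = c(1, 2, 3, 4, 7, 8),
                                         v = 0))
  expect_message(out2 <- bin_sessions(two), "excluded")
  expect_equal(attr(out2, "excluded"), 2)
  expect_false(2 %in% out2$subject)

  # ...but one usable session per bin suffices
  three <- dplyr::bind_rows(df,
                            tibble::tibble(subject = 3,
                                           session = c(1, 2, 4, 5, 8),
                                           v = c(10, 10, 40, 10, 10)))
  out3 <- bin_sessions(three)
  expect_true(3 %in% out3$subject)
  expect_equal(out3$v[out3$subject == 3 & out3$bin == "3/4"], 40)
})

test_that("CS-onset responses habituate across unpaired sessions", {
  ct <- make_contingency(0)
  cfg <- sim_config(photometry = TRUE, habituation_rate = 0.3)
  peaks <- vapply(1:5, function(session) {
    sch <- generate_conditioning_session(cfg, ct, session, unpaired = TRUE,
                                         seed = 400 + session)
    log <- simulate_behavior(sch, cfg, ct, seed = 500 + session)
    rec <- simulate_photometry(sch, log, cfg, seed = 600 + session)
    tr <- correct_photometry(rec)
    q <- quantify_trials(extract_peri_event(tr, sch$onset_s, 3, 3))
    mean(q$peak_post)
  }, numeric(1))
  slope <- stats::coef(stats::lm(peaks ~ seq_along(peaks)))[2]
  expect_lt(slope, 0)
})

test_that("retrieval peak recovers the configured transient amplitude", {
  # physiological amplitudes (2-14% dF/F): the session sd is then dominated
  # by measurement noise, so the Z-scored peak grows near-linearly with the
  # configured amplitude (at large amplitudes the transients themselves
  # inflate the session sd and the Z-peak saturates, though stays monotone)
  ct <- make_contingency(0)
  amps <- c(0.02, 0.05, 0.08, 0.11, 0.14)
  means <- vapply(seq_along(amps), function(i) {
    cfg <- sim_config(photometry = TRUE, amp_retrieval = amps[i])
    subj <- vapply(1:3, function(s) {
      sch <- generate_conditioning_session(cfg, ct, 1,
                                           seed = 1000 + 10 * i + s)
      log <- simulate_behavior(sch, cfg, ct, seed = 2000 + 10 * i + s)
      rec <- simulate_photometry(sch, log, cfg, seed = 3000 + 10 * i + s)
      tr <- correct_photometry(rec)
      retr <- derive_events(sch, log)$reward_retrievals$time_s
      q <- quantify_trials(extract_peri_event(tr, sort(retr), 3, 3))
      mean(q$peak_post)
    }, numeric(1))
    mean(subj)
  }, numeric(1))
  expect_identical(order(means), seq_along(amps))  # strictly increasing
  expect_gt(stats::cor(amps, means), 0.95)
})
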