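test_that("contingency assignments alternate and counterbalance a cohort", {
  c0 <- make_contingency(0)
  expect_equal(c0$cs_to_outcome, c(tone = "sucrose", noise = "pellet"))
  expect_equal(c0$lever_to_outcome, c(left = "sucrose", right = "pellet"))
  c1 <- make_contingency(1)
  expect_equal(c1$cs_to_outcome, c(tone = "pellet", noise = "sucrose"))

  cohort <- lapply(0:7, make_contingency)
  tone_sucrose <- vapply(cohort, function(x) x$cs_to_outcome[["tone"]],
                         character(1))
  expect_equal(sum(tone_sucrose == "sucrose"), 4)
  # lever assignment is counterbalanced independently of the CS assignment
  left_sucrose <- vapply(cohort, function(x) x$lever_to_outcome[["left"]],
                         character(1))
  tab <- table(tone_sucrose, left_sucrose)
  expect_true(all(tab == 2))
  expect_error(make_contingency(-1), "non-negative")
})

test_that("random-time schedule is memoryless with the configured mean", {
  expect_identical(generate_rt_schedule(0, 30), numeric(0))
  expect_error(generate_rt_schedule(-1, 30), "non-negative")
  expect_error(generate_rt_schedule(120, 0), "> 0")

  expect_identical(generate_rt_schedule(120, 30, seed = 42),
                   generate_rt_schedule(120, 30, seed = 42))

  withr::local_seed(7)
  counts <- vapply(seq_len(2000), function(i) {
    length(generate_rt_schedule(120, 30))
  }, numeric(1))
  # Poisson(4): se of the mean over 2000 draws is 2/sqrt(2000) ~ 0.045
  expect_lt(abs(mean(counts) - 4), 0.15)

  # probe restriction: no delivery before 15 s, expectation drops to 3.5
  withr::local_seed(8)
  probed <- replicate(500, generate_rt_schedule(120, 30, min_probe_s = 15),
                      simplify = FALSE)
  expect_true(all(vapply(probed, function(x) !length(x) || min(x) > 15,
                         logical(1))))
  expect_lt(abs(mean(lengths(probed)) - 3.5), 0.3)
})

test_that("conditioning sessions have the configured trial structure", {
  ct <- make_contingency(0)
  std <- sim_config()
  pho <- sim_config(photometry = TRUE)

  sch <- generate_conditioning_session(std, ct, 1, seed = 1)
  expect_equal(unname(table(sch$cs_id)[c("noise", "tone")]), c(8L, 8L),
               ignore_attr = TRUE)
  schp <- generate_conditioning_session(pho, ct, 3, seed = 2)
  expect_equal(sort(unique(as.vector(table(schp$cs_id)))), 4L)

  for (seed in 1:10) {
    s <- generate_conditioning_session(std, ct, 1, seed = seed)
    # non-overlapping, ordered CS windows with ITIs inside the range
    expect_true(all(diff(s$onset_s) > 0))
    gaps <- s$onset_s - c(0, s$offset_s[-nrow(s)])
    expect_true(all(gaps >= std$iti_range_s[1] - 1e-9 &
                      gaps <= std$iti_range_s[2] + 1e-9))
    # pseudorandom order: no run of more than two identical CSs
    expect_lte(max(rle(s$cs_id)$lengths), 2)
    # rewards inside their CS windows, outcomes follow the contingency
    for (i in seq_len(nrow(s))) {
      rw <- s$reward_times_s[[i]]
      expect_true(all(rw >= s$onset_s[i] & rw <= s$offset_s[i]))
    }
    expect_identical(unname(ct$cs_to_outcome[s$cs_id]), s$outcome_id)
  }

  # photometry variant: every first delivery respects the 15-s probe period
  for (seed in 1:10) {
    s <- generate_conditioning_session(pho, ct, 1, seed = seed)
    first_rel <- vapply(seq_len(nrow(s)), function(i) {
      rw <- s$reward_times_s[[i]]
      if (length(rw)) min(rw) - s$onset_s[i] else Inf
    }, numeric(1))
    expect_true(all(first_rel >= 15))
  }

  expect_error(generate_conditioning_session(std, ct, 99),
               "session_index")
})

test_that("sampled conditioning ITIs average three minutes", {
  withr::local_seed(11)
  itis <- photopit:::draw_itis(10000, sim_config())
  expect_lt(abs(mean(itis) - 180), 1.5)
  expect_true(all(itis >= 120 & itis <= 240))
})

test_that("PIT sessions have fixed ITIs, no rewards, and a 5-min extinction", {
  cfg <- sim_config()
  for (seed in 1:5) {
    s <- generate_pit_session(cfg, seed = seed)
    expect_equal(nrow(s), 8L)
    expect_equal(unname(table(s$cs_id)), c(4L, 4L), ignore_attr = TRUE)
    expect_true(all(lengths(s$reward_times_s) == 0))
    expect_equal(attr(s, "extinction_end_s"), 300)
    expect_equal(s$onset_s[1], 300)
    expect_equal(s$onset_s[-1] - s$offset_s[-nrow(s)], rep(240, nrow(s) - 1))
    expect_lte(max(rle(s$cs_id)$lengths), 2)
  }
  empty <- generate_pit_session(sim_config(pit_cs_reps = 0), seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "extinction_end_s"), 300)
})

test_that("instrumental sessions terminate at 30 outcomes or 45 minutes", {
  cfg <- sim_config()
  ct <- make_contingency(0)

  idle <- generate_instrumental_session(cfg, ct, "left", 0, seed = 1)
  expect_equal(max(idle$time_s), 2700)
  expect_equal(sum(idle$event == "reward_delivery"), 0L)

  for (seed in 1:10) {
    s <- generate_instrumental_session(cfg, ct, "right", 60, seed = seed)
    expect_equal(sum(s$event == "reward_delivery"), 30L)
    expect_lt(max(s$time_s), 2700)
    expect_true(all(s$label[s$event == "reward_delivery"] ==
                      ct$lever_to_outcome[["right"]]))
  }

  expect_identical(generate_instrumental_session(cfg, ct, "left", 20,
                                                 seed = 3),
                   generate_instrumental_session(cfg, ct, "left", 20,
                                                 seed = 3))
  expect_error(generate_instrumental_session(cfg, ct, "middle", 10),
               "unknown lever_id")
})

test_that("behavior simulation produces only markers when all rates are 0", {
  cfg <- sim_config(entry_rate_base_per_min = 0, press_rate_base_per_min = 0)
  ct <- make_contingency(0)
  sch <- generate_conditioning_session(cfg, ct, 1, seed = 1)
  log <- simulate_behavior(sch, cfg, ct, seed = 2)
  expect_setequal(unique(log$event),
                  c("session_start", "session_end", "cs_on", "cs_off",
                    "reward_delivery"))
  expect_equal(sum(log$event == "cs_on"), nrow(sch))
  expect_equal(sum(log$event == "cs_off"), nrow(sch))
})

test_that("baseline food-port entries are Poisson at the configured rate", {
  # CS-free expectation: unpaired schedule (no rewards -> no retrievals),
  # entry gain 0 so the rate is flat at 2/min over the whole session
  cfg <- sim_config(entry_gain_per_session = 0, entry_rate_base_per_min = 2)
  ct <- make_contingency(0)
  withr::local_seed(21)
  counts <- vapply(seq_len(300), function(i) {
    sch <- generate_conditioning_session(cfg, ct, 1, unpaired = TRUE)
    log <- simulate_behavior(sch, cfg, ct)
    expected <- 2 * attr(sch, "session_end_s") / 60
    sum(log$event == "foodport_entry") - expected
  }, numeric(1))
  # mean deviation from the Poisson expectation ~ 0 within 3 s.e.
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts)), 3 * se + 1e-9)
})

test_that("Same-lever pressing dominates when tau_same > tau_diff", {
  cfg <- sim_config(tau_same = 1, tau_diff = 0)
  ct <- make_contingency(0)
  withr::local_seed(31)
  diffs <- vapply(seq_len(60), function(i) {
    sch <- generate_pit_session(cfg)
    log <- simulate_behavior(sch, cfg, ct)
    same <- 0; different <- 0
    for (j in seq_len(nrow(sch))) {
      lever <- classify_same_lever(sch$cs_id[j], ct)
      other <- setdiff(c("left", "right"), lever)
      win <- log$time_s >= sch$onset_s[j] & log$time_s < sch$offset_s[j]
      same <- same + sum(win & log$event == "lever_press" &
                           log$label == lever)
      different <- different + sum(win & log$event == "lever_press" &
                                     log$label == other)
    }
    same - different
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(stats::t.test(diffs)$statistic, 3)
})

test_that("photometry simulator is exact in degenerate and single-transient cases", {
  ct <- make_contingency(0)
  flat <- sim_config(photometry = TRUE, f0_470 = 1, f0_415 = 1,
                     bleach_amp1 = 0, bleach_amp2 = 0, motion_sd = 0,
                     noise_sd = 0, amp_cs = 0, amp_retrieval = 0,
                     entry_rate_base_per_min = 0)
  sch <- generate_conditioning_session(flat, ct, 1, seed = 1)
  log <- simulate_behavior(sch, flat, ct, seed = 2)
  rec <- simulate_photometry(sch, log, flat, seed = 3)
  expect_true(all(abs(rec$fluorescence - 1) < 1e-12))

  # single CS transient: 470 max equals f0 * (1 + amp * max kernel-on-grid)
  one <- sim_config(photometry = TRUE, bleach_amp1 = 0, bleach_amp2 = 0,
                    motion_sd = 0, noise_sd = 0, amp_cs = 0.8,
                    amp_retrieval = 0, entry_rate_base_per_min = 0)
  sch1 <- make_toy_schedule(onset_s = 50, offset_s = 170,
                            reward_times_s = list(numeric(0)),
                            session_end_s = 200)
  log1 <- simulate_behavior(sch1, one, ct, seed = 4)
  rec1 <- simulate_photometry(sch1, log1, one, seed = 5)
  f470 <- rec1$fluorescence[rec1$channel == 470]
  t470 <- rec1$time_s[rec1$channel == 470]
  kmax_grid <- max(transient_kernel(t470[t470 >= 50] - 50,
                                    one$tau_rise_s, one$tau_decay_s))
  expect_equal(max(f470), one$f0_470 * (1 + 0.8 * kmax_grid),
               tolerance = 1e-12)

  cfg <- sim_config(photometry = TRUE)
  sch2 <- generate_conditioning_session(cfg, ct, 1, seed = 6)
  log2 <- simulate_behavior(sch2, cfg, ct, seed = 7)
  expect_identical(simulate_photometry(sch2, log2, cfg, seed = 8),
                   simulate_photometry(sch2, log2, cfg, seed = 8))
})

test_that("channels interleave at half a sample period with shared artifact", {
  ct <- make_contingency(0)
  cfg <- sim_config(photometry = TRUE, noise_sd = 0, amp_cs = 0,
                    amp_retrieval = 0, bleach_amp1 = 0, bleach_amp2 = 0,
                    gain_415 = 0.8, entry_rate_base_per_min = 0)
  sch <- generate_conditioning_session(cfg, ct, 1, seed = 1)
  log <- simulate_behavior(sch, cfg, ct, seed = 2)
  rec <- simulate_photometry(sch, log, cfg, seed = 3)
  t415 <- rec$time_s[rec$channel == 415]
  t470 <- rec$time_s[rec$channel == 470]
  expect_equal(stats::median(diff(t415)), 1 / cfg$sample_rate_hz)
  expect_equal(t470 - t415, rep(1 / (2 * cfg$sample_rate_hz), length(t415)))
  # gain_415 = f0_415/f0_470 makes the 470 trace affine in the interleaved
  # 415 trace; after de-interleaving the relation is exact
  paired <- deinterleave(rec)
  fit <- stats::lm(f470 ~ f415, data = paired)
  expect_lt(max(abs(stats::resid(fit))), 1e-8)
})
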