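test_that("saccade segments follow the main sequence", {
  # zero amplitude: identity case
  seg0 <- simulate_saccade_segment(0)
  expect_equal(seg0$x_deg, 0)
  expect_equal(seg0$v_deg_s, 0)

  for (amp in c(5, 12, 30, 55, -55)) {
    seg <- simulate_saccade_segment(amp, sampling_rate = 1000)
    # trapezoidal time-integral of velocity recovers the amplitude
    dt <- diff(seg$time_ms) / 1000
    integ <- sum(dt * (head(seg$v_deg_s, -1) + tail(seg$v_deg_s, -1)) / 2)
    expect_lt(abs(integ - amp), 0.1)
    # monotone flight from 0 to the signed amplitude
    expect_true(all(sign(amp) * diff(seg$x_deg) >= -1e-12))
    expect_equal(seg$x_deg[1], 0)
    expect_lt(abs(seg$x_deg[nrow(seg)] - amp), 1e-6)
    # unimodal velocity, zero at both ends
    v <- sign(amp) * seg$v_deg_s
    expect_equal(v[1], 0)
    expect_lt(abs(v[length(v)]), 1e-9)
    pk <- which.max(v)
    expect_true(all(diff(v[seq_len(pk)]) >= -1e-9))
    expect_true(all(diff(v[pk:length(v)]) <= 1e-9))
  }

  # duration law at defaults keeps the 55 deg saccade physiological
  expect_gt(saccade_duration(55), 80)
  expect_lt(saccade_duration(55), 200)
  expect_lt(saccade_peak_velocity(55), 750)
  # detectable peak for all amplitudes the validity rule can accept
  expect_true(all(saccade_peak_velocity(seq(5, 60, by = 5)) >= 60))
  # peak velocity is increasing in amplitude
  pv <- saccade_peak_velocity(seq(1, 60, by = 1))
  expect_true(all(diff(pv) > 0))

  expect_error(simulate_saccade_segment(10, sampling_rate = -200),
               "positive")
  expect_error(main_sequence_params(duration_slope = -1), "positive")
})

test_that("single trials carry exact ground truth and are reproducible", {
  cfg <- cohort_config(noise_sd = 0)
  sp <- list(latency_mean = 200, latency_sd = 0, accuracy = 1,
             rt_mean = 900, rt_sd = 0)
  sim <- simulate_trial(sp, "color", "right", cfg, seed = 5)
  expect_equal(sim$truth$true_latency, 200)
  expect_equal(sim$truth$true_saccade_onset, sim$event$t2_onset + 200)
  expect_equal(sim$truth$true_amplitude, 55)
  # fixation is exactly 0 before the saccade (no noise)
  pre <- sim$trace$x_deg[sim$trace$time_ms < sim$truth$true_saccade_onset]
  expect_equal(pre, rep(0, length(pre)))

  # same seed, bitwise-identical trace
  cfg2 <- cohort_config()
  a <- simulate_trial(sp, "landolt", "left", cfg2, seed = 99)
  b <- simulate_trial(sp, "landolt", "left", cfg2, seed = 99)
  expect_identical(a$trace$x_deg, b$trace$x_deg)
  expect_identical(a$event, b$event)

  # latency below the floor after max retries flags the trial degenerate
  sp_bad <- list(latency_mean = -500, latency_sd = 1, accuracy = 1,
                 rt_mean = 900, rt_sd = 0)
  simb <- simulate_trial(sp_bad, "color", "left", cfg, seed = 1)
  expect_true(simb$truth$degenerate)
  expect_true(is.na(simb$truth$true_latency))
})

test_that("block design balances task and side within every block", {
  cfg <- cohort_config(group_sizes = c(control = 3), seed = 21)
  coh <- simulate_cohort(cfg, traces = FALSE)
  ev <- coh$events
  expect_equal(nrow(ev), 3 * 96)
  for (s in unique(ev$subject)) {
    for (b in 1:3) {
      blk <- ev[ev$subject == s & ev$block == b, ]
      expect_equal(nrow(blk), 32)
      expect_equal(as.integer(table(blk$task)), c(16L, 16L))
      expect_equal(as.integer(table(blk$side)), c(16L, 16L))
      expect_equal(as.integer(table(blk$task, blk$side)), rep(8L, 4))
    }
  }
  # overall 50/50 task and side probabilities, exactly, by balance
  expect_equal(mean(ev$task == "color"), 0.5)
  expect_equal(mean(ev$side == "left"), 0.5)
})

test_that("cohorts have the configured composition and are seed-deterministic", {
  cfg <- cohort_config(seed = 13)
  coh <- simulate_cohort(cfg, traces = FALSE)
  expect_equal(nrow(coh$subjects), 47)
  expect_equal(as.integer(table(coh$subjects$group)[c("patient",
                                                      "control",
                                                      "relative")]),
               c(13, 24, 10))
  expect_equal(nrow(coh$truth), 47 * 96)

  coh2 <- simulate_cohort(cfg, traces = FALSE)
  expect_identical(coh$truth, coh2$truth)
  expect_identical(coh$events, coh2$events)

  # traced simulation is deterministic too
  small <- cohort_config(group_sizes = c(control = 1), n_trials = 4,
                         n_blocks = 1, seed = 8)
  a <- simulate_cohort(small)
  b <- simulate_cohort(small)
  expect_identical(a$traces, b$traces)

  expect_warning(
    simulate_cohort(cohort_config(group_sizes = c(control = 2,
                                                  relative = 0),
                                  n_trials = 4, n_blocks = 1, seed = 1),
                    traces = FALSE),
    "size 0")
})

test_that("degenerate variance collapses every latency to the group mean", {
  lm0 <- latency_model_default()
  lm0$between_sd <- 0
  lm0$within_sd <- 0
  cfg <- cohort_config(group_sizes = c(patient = 2, control = 2),
                       latency_model = lm0, n_trials = 8, n_blocks = 1,
                       noise_sd = 0, seed = 31)
  coh <- simulate_cohort(cfg, traces = FALSE)
  tr <- merge(coh$truth, lm0[, c("group", "task", "mean")],
              by = c("group", "task"))
  expect_equal(tr$true_latency, tr$mean)

  # and through the detector, up to quantization
  coht <- simulate_cohort(cfg, seed = 31)
  recs <- extract_latencies(coht)
  tl <- truth_latency_records(coht)
  expect_lt(max(abs(recs$latency - tl$latency)), 5 + 1e-9)
})

test_that("configured latency shifts propagate to recovered group means", {
  base <- cohort_config(group_sizes = c(control = 24), seed = 17)
  shifted_model <- latency_model_default()
  delta <- 40
  shifted_model$mean <- shifted_model$mean + delta
  shifted <- cohort_config(group_sizes = c(control = 24),
                           latency_model = shifted_model, seed = 17)
  m_of <- function(cfg) {
    coh <- simulate_cohort(cfg, traces = FALSE)
    s <- task_means(truth_latency_records(coh))
    c(mean(s$sl_color), se = sd(s$sl_color) / sqrt(nrow(s)))
  }
  a <- m_of(base); b <- m_of(shifted)
  se <- sqrt(a[2]^2 + b[2]^2)
  expect_lt(abs((b[1] - a[1]) - delta), 2 * se + 1e-9)
})

test_that("cohort parameters are recovered within sampling error", {
  cfg <- cohort_config(seed = 23)
  coh <- simulate_cohort(cfg, traces = FALSE)
  s <- task_means(truth_latency_records(coh))
  lm0 <- latency_model_default()
  for (g in c("patient", "control", "relative")) {
    for (tk in c("color", "landolt")) {
      conf <- lm0[lm0$group == g & lm0$task == tk, ]
      col <- if (tk == "color") "sl_color" else "sl_landolt"
      got <- s[s$group == g, col]
      se <- conf$between_sd / sqrt(length(got))
      expect_lt(abs(mean(got) - conf$mean), 2 * se + 3)
    }
  }
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_trials = 90, n_blocks = 4), "divisible")
  expect_error(cohort_config(n_trials = 18, n_blocks = 3),
               "divisible by 4")
  expect_error(cohort_config(noise_sd = -1), "non-negative")
  expect_error(cohort_config(group_sizes = c(5, 5)), "named")
  # unknown configuration keys are rejected up front
  expect_error(cohort_config(unknown_key = 1), "unused argument")

  # ex-Gaussian latency option produces right-skewed, floored latencies
  cfg <- cohort_config(group_sizes = c(control = 5),
                       latency_family = "exgaussian", seed = 3)
  coh <- simulate_cohort(cfg, traces = FALSE)
  lat <- coh$truth$true_latency
  expect_true(all(lat >= 80, na.rm = TRUE))
  expect_gt(mean((lat - mean(lat))^3) / sd(lat)^3, 0)  # skewed right
})
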