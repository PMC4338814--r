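test_that("subject summaries aggregate valid latencies per task", {
  recs <- data.frame(
    subject = rep(c("s1", "s2"), each = 4),
    group = "patient",
    task = rep(c("color", "color", "landolt", "landolt"), 2),
    trial = 1:8,
    latency = c(200, 220, 180, 190, 248, 248, 232, 232),
    valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    reason = "ok"
  )
  s <- task_means(recs)
  expect_equal(s$sl_color[s$subject == "s1"], 210)
  expect_equal(s$sld[s$subject == "s2"], 248 - 232)  # SLD identity

  # permuting record order leaves summaries unchanged
  s2 <- task_means(recs[sample(nrow(recs)), ])
  expect_equal(s, s2)

  # invalid latencies never enter the means
  recs$valid[1] <- FALSE
  expect_equal(task_means(recs)$sl_color[1], 220)

  # a subject missing one task entirely is excluded with a warning
  recs2 <- recs[!(recs$subject == "s2" & recs$task == "landolt"), ]
  expect_warning(s3 <- task_means(recs2), "missing a task")
  expect_equal(s3$subject, "s1")
})

test_that("percent reduction matches the reported worked examples", {
  expect_equal(round(percent_reduction(221, 178), 1), 19.5)
  expect_equal(round(percent_reduction(269, 209), 1), 22.3)
  expect_equal(round(percent_reduction(248, 232), 1), 6.5)
  expect_equal(percent_reduction(200, 200), 0)
  expect_error(percent_reduction(0, 10), "positive")
})

test_that("paired t equals the direct formula", {
  set.seed(3)
  a <- rnorm(13, 250, 50)
  b <- rnorm(13, 230, 50)
  got <- paired_t(a, b)
  want <- oracle_paired_t(a, b)
  expect_equal(got$statistic, want$t, tolerance = 1e-10)
  expect_equal(got$df, 12)             # n = 13 pairs -> df 12
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_error(paired_t(a, a), "zero variance")
})

test_that("Welch t has Satterthwaite df and collapses when appropriate", {
  set.seed(4)
  a <- rnorm(12, 250, 40); b <- rnorm(20, 220, 80)
  got <- welch_t(a, b)
  want <- oracle_welch_t(a, b)
  expect_equal(got$statistic, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)

  # swapping the samples flips the sign
  expect_equal(welch_t(b, a)$statistic, -got$statistic,
               tolerance = 1e-12)

  # equal variances and sizes: df collapses to n1 + n2 - 2
  a2 <- c(1, 2, 3, 4, 5); b2 <- a2 + 2   # identical spread
  expect_equal(welch_t(a2, b2)$df, 8)

  # one-tailed p at the reported SLD contrast scale:
  # t = 2.35 on df = 28.3 gives p ~ 0.013 one-tailed
  expect_equal(round(pt(2.35, 28.3, lower.tail = FALSE), 3), 0.013)
  expect_equal(round(pt(1.90, 15.4, lower.tail = FALSE), 3), 0.038)
})

test_that("RMS-pooled Cohen's d reproduces reported effect sizes", {
  expect_equal(round(cohens_d_paired(248, 56, 232, 51), 1), 0.3)
  expect_equal(round(cohens_d_paired(261, 100, 193, 27), 1), 0.9)
  expect_equal(round(cohens_d_paired(221, 49, 178, 30), 1), 1.1)
  expect_error(cohens_d_paired(1, 0, 2, 0), "not both zero")
})

test_that("Levene's test is a one-way ANOVA on absolute deviations", {
  set.seed(5)
  a <- rnorm(24, 261, 100); b <- rnorm(24, 193, 27)
  got <- levene_test(a, b)
  want <- oracle_levene(a, b)
  expect_equal(got$statistic, want$f, tolerance = 1e-10)
  expect_equal(got$df, c(1, 46))      # 24 + 24 observations
  expect_equal(got$p, want$p, tolerance = 1e-10)
  # identical samples: F = 0
  expect_equal(levene_test(a, a)$statistic, 0)
})

test_that("rank tests agree with exhaustive enumeration for small n", {
  set.seed(6)
  for (k in 1:5) {
    n <- sample(5:8, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- rank_tests(a, b, paired = TRUE)
    expect_equal(got$p, oracle_signed_rank_p(a - b), tolerance = 1e-12)
    a2 <- rnorm(sample(4:6, 1)); b2 <- rnorm(sample(4:6, 1))
    got2 <- rank_tests(a2, b2, paired = FALSE)
    expect_equal(got2$p, oracle_rank_sum_p(a2, b2), tolerance = 1e-12)
  }

  # all-positive paired differences of n = 3: V is the maximal rank sum
  expect_equal(rank_tests(c(4, 5, 6), c(1, 2, 3), paired = TRUE)$statistic,
               6)
  # fully separated unpaired samples: W = n1 * n2 or 0
  expect_equal(rank_tests(6:10, 1:5)$statistic, 25)
  expect_equal(rank_tests(1:5, 6:10)$statistic, 0)
  expect_error(rank_tests(c(1, 2), c(1, 2), paired = TRUE), "zero")
})

test_that("chi-squared independence matches the direct formula", {
  gender <- rbind(patient = c(3, 10), control = c(10, 14),
                  relative = c(2, 8))
  got <- chi_square_independence(gender)
  expect_equal(round(got$statistic, 2), 2.17)
  expect_equal(got$df, 2)

  tab <- matrix(c(12, 7, 5, 9), 2)
  want <- oracle_chisq(tab)
  got2 <- chi_square_independence(tab)
  expect_equal(got2$statistic, want$stat, tolerance = 1e-10)
  expect_equal(got2$df, want$df)

  # a table equal to its expected counts gives 0
  indep <- outer(c(10, 20), c(6, 4)) / 10
  expect_equal(chi_square_independence(indep)$statistic, 0)
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2)),
               "marginal")
})

test_that("mixed ANOVA matches the sums-of-squares decomposition", {
  d <- balanced_anova_fixture(seed = 42, n_per_group = 5, g = 3)
  got <- mixed_anova(d)
  want <- oracle_mixed_anova(d)
  expect_equal(got$group$statistic, want$F_group, tolerance = 1e-8)
  expect_equal(got$task$statistic, want$F_task, tolerance = 1e-8)
  expect_equal(got$interaction$statistic, want$F_inter, tolerance = 1e-8)
  expect_equal(got$group$df, want$df$group)
  expect_equal(got$task$df, want$df$task)
  expect_equal(got$interaction$df, want$df$inter)
  # the decomposition is exact on balanced layouts
  expect_equal(want$ss[["total"]],
               sum(want$ss[c("group", "subj", "task", "inter", "error")]),
               tolerance = 1e-8)

  # design-sized df triples: N = 47 in 3 groups -> (2,44), (1,44), (2,44)
  d2 <- data.frame(
    subject = rep(sprintf("s%02d", 1:47), 2),
    group = rep(rep(c("p", "c", "r"), c(13, 24, 10)), 2),
    task = rep(c("color", "landolt"), each = 47),
    value = rnorm(94, 900, 100)
  )
  got2 <- mixed_anova(d2)
  expect_equal(got2$group$df, c(2, 44))
  expect_equal(got2$task$df, c(1, 44))
  expect_equal(got2$interaction$df, c(2, 44))

  # balanced task deviations cancel: task and interaction F collapse to 0
  # while the within error term stays positive
  d3 <- data.frame(
    subject = rep(sprintf("s%02d", 1:12), 2),
    group = rep(rep(c("p", "c", "r"), each = 4), 2),
    task = rep(c("color", "landolt"), each = 12),
    value = c(rep(250, 12), 250 + rep(c(10, -10), 6))
  )
  got3 <- mixed_anova(d3)
  expect_equal(got3$task$statistic, 0)
  expect_equal(got3$interaction$statistic, 0)
})

test_that("Pearson correlation follows the closed form", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, x * 2)$effect, 1)
  set.seed(8)
  a <- rnorm(13); b <- rnorm(13)
  got <- pearson_r(a, b)
  r <- got$effect
  expect_equal(got$statistic, r * sqrt((13 - 2) / (1 - r^2)),
               tolerance = 1e-10)
  expect_equal(got$df, 11)             # n = 13 -> df 11
  # r = 0.17 at n = 13 gives t ~ 0.57 by the closed form
  expect_equal(round(0.17 * sqrt(11 / (1 - 0.17^2)), 2), 0.57)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("paired-t power comes from the noncentral t distribution", {
  # null effect: power equals alpha
  expect_equal(power_paired_t(0, 10, alpha = 0.05), 0.05,
               tolerance = 1e-10)
  # large reference effect
  expect_gte(power_paired_t(2, 10, alpha = 0.05), 0.99)
  # one-sided power agrees exactly with the base implementation
  for (d in c(0.3, 0.8, 1.5)) {
    for (n in c(5, 10, 24)) {
      expect_equal(power_paired_t(d, n, tails = "one.sided"),
                   stats::power.t.test(n = n, delta = d, sd = 1,
                                       type = "paired",
                                       alternative = "one.sided")$power,
                   tolerance = 1e-8)
    }
  }
  # two-sided: power.t.test drops the wrong-sign rejection region, so it
  # agrees with the exact noncentral-t form once that region is negligible
  expect_equal(power_paired_t(1.5, 10),
               stats::power.t.test(n = 10, delta = 1.5, sd = 1,
                                   type = "paired")$power,
               tolerance = 1e-6)
  # and for a null-adjacent effect the exact form exceeds it by the lower
  # tail mass
  expect_gt(power_paired_t(0.3, 5),
            stats::power.t.test(n = 5, delta = 0.3, sd = 1,
                                type = "paired")$power)
  # strictly increasing in n and |d|, approaching 1
  pn <- vapply(c(4, 8, 16, 32, 64), function(n) power_paired_t(0.5, n),
               numeric(1))
  expect_true(all(diff(pn) > 0))
  pd <- vapply(c(0.2, 0.5, 1, 2), function(d) power_paired_t(d, 12),
               numeric(1))
  expect_true(all(diff(pd) > 0))
  expect_gt(power_paired_t(1, 2000), 1 - 1e-12)

  # Monte Carlo rejection-rate oracle at d = 1, n = 10
  set.seed(9)
  reps <- 1e5
  diffs <- matrix(rnorm(reps * 10, mean = 1, sd = 1), nrow = reps)
  m <- rowMeans(diffs)
  s <- sqrt((rowSums(diffs^2) - 10 * m^2) / 9)
  tstat <- m / (s / sqrt(10))
  rej <- mean(abs(tstat) > qt(0.975, 9))
  expect_lt(abs(rej - power_paired_t(1, 10)), 0.01)
})

test_that("the cohort report covers all groups, contrasts and behaviour", {
  cfg <- cohort_config(seed = 91)
  coh <- simulate_cohort(cfg, traces = FALSE)
  s <- task_means(truth_latency_records(coh), events = coh$events)
  rep_ <- analyze_cohort(s)
  expect_setequal(names(rep_$groups), c("patient", "control", "relative"))
  for (g in names(rep_$groups)) {
    gr <- rep_$groups[[g]]
    expect_s3_class(gr$paired_t, "sl_test")
    expect_s3_class(gr$levene, "sl_test")
    expect_equal(gr$mean_sld, gr$mean_color - gr$mean_landolt)
  }
  expect_setequal(names(rep_$sld),
                  c("patient_vs_control", "patient_vs_relative",
                    "control_vs_relative"))
  # both tails are reported for the SLD contrasts
  pc <- rep_$sld$patient_vs_control
  expect_equal(pc$welch_two_sided$tails, "two.sided")
  expect_true(pc$welch_one_sided$tails %in% c("less", "greater"))
  expect_s3_class(rep_$behavior$rt_anova$group, "sl_test")
  expect_equal(rep_$behavior$rt_anova$task$df, c(1, 44))
})
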