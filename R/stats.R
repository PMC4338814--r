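#' Construct a test result
#'
#' Lightweight container for a statistical test: name, statistic, degrees
#' of freedom (possibly fractional, possibly a pair), p-value, tails and an
#' optional effect size.
#'
#' @param name Test label.
#' @param statistic Named or unnamed numeric statistic.
#' @param df Degrees of freedom (scalar or length-2).
#' @param p p-value in `[0, 1]`.
#' @param tails `"two.sided"`, `"less"` or `"greater"`.
#' @param effect Optional effect size.
#' @return An object of class `sl_test`.
#' @export
test_result <- function(name, statistic, df = NULL, p = NA_real_,
                        tails = "two.sided", effect = NULL) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  structure(list(name = name, statistic = unname(statistic), df = df,
                 p = p, tails = tails, effect = effect),
            class = "sl_test")
}

#' @export
print.sl_test <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else
    paste0(" (df ", paste(round(x$df, 2), collapse = ", "), ")")
  eff <- if (is.null(x$effect)) "" else
    sprintf(", effect = %.3g", x$effect)
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g [%s]%s\n",
              x$name, x$statistic, dfs, x$p, x$tails, eff))
  invisible(x)
}

#' Per-subject task means and the saccadic latency difference
#'
#' Aggregates valid latency records to one row per subject: mean saccadic
#' latency per task and their difference SLD = SL(color) - SL(landolt)
#' (positive SLD = latency reduction in the higher-demand Landolt task).
#' Behavioural columns (accuracy, mean response time per task) are attached
#' when a trial-event table is supplied. Subjects missing either task
#' entirely are excluded with a warning.
#'
#' @param records Latency records from [extract_latencies()] or
#'   [truth_latency_records()].
#' @param events Optional trial events with `correct` and `rt` columns.
#' @return A `data.frame` with columns `subject`, `group`, `sl_color`,
#'   `sl_landolt`, `sld` and, when `events` is given, `acc_color`,
#'   `acc_landolt`, `rt_color`, `rt_landolt`.
#' @export
task_means <- function(records, events = NULL) {
  valid <- records[records$valid, ]
  agg <- aggregate(latency ~ subject + group + task, data = valid, mean)
  wide <- reshape(agg, idvar = c("subject", "group"), timevar = "task",
                  direction = "wide")
  names(wide) <- sub("^latency\\.", "sl_", names(wide))
  missing_task <- !c("sl_color", "sl_landolt") %in% names(wide)
  if (any(missing_task))
    stop("no valid records at all for task(s): ",
         paste(c("color", "landolt")[missing_task], collapse = ", "),
         call. = FALSE)
  incomplete <- is.na(wide$sl_color) | is.na(wide$sl_landolt)
  if (any(incomplete)) {
    warning("excluding subject(s) missing a task: ",
            paste(wide$subject[incomplete], collapse = ", "))
    wide <- wide[!incomplete, ]
  }
  wide$sld <- wide$sl_color - wide$sl_landolt
  if (!is.null(events)) {
    acc <- aggregate(correct ~ subject + task, data = events, mean)
    acc <- reshape(acc, idvar = "subject", timevar = "task",
                   direction = "wide")
    names(acc) <- sub("^correct\\.", "acc_", names(acc))
    rt <- aggregate(rt ~ subject + task, data = events, mean)
    rt <- reshape(rt, idvar = "subject", timevar = "task",
                  direction = "wide")
    names(rt) <- sub("^rt\\.", "rt_", names(rt))
    wide <- merge(merge(wide, acc, by = "subject"), rt, by = "subject")
  }
  wide <- wide[order(wide$subject), ]
  rownames(wide) <- NULL
  wide
}

#' Percent latency reduction between tasks
#'
#' `100 * (mean_color - mean_landolt) / mean_color`: the percentage by
#' which mean saccadic latency drops in the higher-demand task.
#'
#' @param mean_color,mean_landolt Task mean latencies in ms; `mean_color`
#'   must be positive.
#' @return Reduction in percent.
#' @export
#' @examples
#' percent_reduction(221, 178)   # 19.5
percent_reduction <- function(mean_color, mean_landolt) {
  if (any(mean_color <= 0))
    stop("`mean_color` must be positive", call. = FALSE)
  100 * (mean_color - mean_landolt) / mean_color
}

#' Paired t-test
#'
#' Classic paired t on the differences `a - b`, df = n - 1.
#'
#' @param a,b Paired samples of equal length >= 2.
#' @param tails `"two.sided"` (default), `"less"` or `"greater"`.
#' @return An [test_result()] (`sl_test`).
#' @export
paired_t <- function(a, b, tails = "two.sided") {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (var(a - b) == 0)
    stop("zero variance of differences; paired t undefined", call. = FALSE)
  ht <- stats::t.test(a, b, paired = TRUE, alternative = tails)
  test_result("paired t-test", ht$statistic, unname(ht$parameter),
              ht$p.value, tails)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t with Welch--Satterthwaite fractional degrees of
#' freedom.
#'
#' @inheritParams paired_t
#' @export
welch_t <- function(a, b, tails = "two.sided") {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0)
    stop("zero variance in both samples", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = tails)
  test_result("Welch two-sample t-test", ht$statistic,
              unname(ht$parameter), ht$p.value, tails)
}

#' RMS-pooled Cohen's d for a paired contrast
#'
#' Standardized mean difference using the root-mean-square of the two
#' condition SDs: `d = (mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)`.
#' This summary-statistic form reproduces paired-design effect sizes
#' reported alongside condition means and SDs.
#'
#' @param mean_a,sd_a,mean_b,sd_b Condition means and SDs; SDs must be
#'   non-negative and not both zero.
#' @return The effect size d.
#' @export
#' @examples
#' cohens_d_paired(261, 100, 193, 27)   # ~0.93
cohens_d_paired <- function(mean_a, sd_a, mean_b, sd_b) {
  if (sd_a < 0 || sd_b < 0 || (sd_a == 0 && sd_b == 0))
    stop("SDs must be non-negative and not both zero", call. = FALSE)
  (mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)
}

#' Levene's test for equality of variances (two samples)
#'
#' One-way ANOVA on absolute deviations from the group centre; the classic
#' (mean-centred) form by default, with the median-centred Brown--Forsythe
#' variant available. df = (1, n1 + n2 - 2).
#'
#' @param a,b Samples of length >= 2.
#' @param center `"mean"` (classic Levene, default) or `"median"`.
#' @return An `sl_test` with F statistic and df pair.
#' @export
levene_test <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(length(a) >= 2, length(b) >= 2)
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  lt <- car::leveneTest(y, g, center = if (center == "mean") mean else
    median)
  test_result(sprintf("Levene's test (%s-centered)", center),
              lt[1, "F value"], c(lt[1, "Df"], lt[2, "Df"]),
              lt[1, "Pr(>F)"])
}

#' Wilcoxon rank tests
#'
#' Signed-rank test (paired, statistic V) or rank-sum test (unpaired,
#' statistic W). Exact p-values are used for n <= 25 without ties,
#' otherwise the normal approximation with tie correction.
#'
#' @param a,b Samples; equal lengths required when `paired`.
#' @param paired Use the signed-rank test.
#' @param tails Alternative hypothesis.
#' @return An `sl_test`.
#' @export
rank_tests <- function(a, b, paired = FALSE, tails = "two.sided") {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (paired) {
    stopifnot(length(a) == length(b))
    if (all(a - b == 0))
      stop("all paired differences are zero", call. = FALSE)
    d <- a - b
    exact <- length(d) <= 25 && !any(d == 0) &&
      !any(duplicated(abs(d)))
    ht <- stats::wilcox.test(a, b, paired = TRUE, exact = exact,
                             correct = !exact, alternative = tails)
    test_result("Wilcoxon signed rank test", ht$statistic, NULL,
                ht$p.value, tails)
  } else {
    exact <- max(length(a), length(b)) <= 25 &&
      !any(duplicated(c(a, b)))
    ht <- stats::wilcox.test(a, b, paired = FALSE, exact = exact,
                             correct = !exact, alternative = tails)
    test_result("Wilcoxon rank sum test", ht$statistic, NULL,
                ht$p.value, tails)
  }
}

#' Pearson chi-squared test of independence
#'
#' Pearson chi-squared on an r x c contingency table, without continuity
#' correction; df = (r - 1)(c - 1).
#'
#' @param table Matrix of non-negative counts, at least 2 x 2, with no
#'   zero row or column sums.
#' @return An `sl_test`.
#' @export
#' @examples
#' gender <- rbind(patient = c(3, 10), control = c(10, 14),
#'                 relative = c(2, 8))
#' chi_square_independence(gender)   # chi^2 = 2.17, df = 2
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need at least a 2 x 2 table", call. = FALSE)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result("Pearson chi-squared test", ht$statistic,
              unname(ht$parameter), ht$p.value)
}

#' Mixed-design ANOVA (between: group, within: task)
#'
#' Two-way mixed ANOVA with one between-subject factor (group) and one
#' two-level within-subject factor (task): the group effect is tested
#' against subjects-within-groups, task and the task x group interaction
#' against task x subjects-within-groups. With N subjects in g groups the
#' df are (g-1, N-g), (1, N-g) and (g-1, N-g). Subjects missing a task are
#' excluded.
#'
#' @param data Long-format `data.frame` with columns `subject`, `group`,
#'   `task`, `value` (one value per subject x task).
#' @return A named list of `sl_test` results: `group`, `task`,
#'   `interaction`.
#' @export
mixed_anova <- function(data) {
  stopifnot(all(c("subject", "group", "task", "value") %in% names(data)))
  cnt <- table(data$subject)
  complete <- names(cnt)[cnt == 2]
  data <- data[data$subject %in% complete, ]
  if (length(unique(data$group)) < 2)
    stop("need at least 2 groups", call. = FALSE)
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$task <- factor(data$task)
  fit <- stats::aov(value ~ group * task + Error(subject), data = data)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  row_of <- function(tab, nm) which(trimws(rownames(tab)) == nm)
  mk <- function(tab, nm, label) {
    i <- row_of(tab, nm)
    r <- row_of(tab, "Residuals")
    test_result(label, tab[i, "F value"], c(tab[i, "Df"], tab[r, "Df"]),
                tab[i, "Pr(>F)"])
  }
  list(group = mk(between, "group", "mixed ANOVA: group"),
       task = mk(within, "task", "mixed ANOVA: task"),
       interaction = mk(within, "group:task",
                        "mixed ANOVA: task x group"))
}

#' Pearson correlation test
#'
#' Pearson r with `t = r * sqrt((n - 2) / (1 - r^2))`, df = n - 2.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @param tails Alternative hypothesis.
#' @return An `sl_test`; the correlation is stored as `effect`.
#' @export
pearson_r <- function(x, y, tails = "two.sided") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson", alternative = tails)
  test_result("Pearson correlation", ht$statistic, unname(ht$parameter),
              ht$p.value, tails, effect = unname(ht$estimate))
}

#' Power of a paired t-test
#'
#' Exact power from the noncentral t distribution: with effect size d
#' (mean difference over SD of differences), n pairs and level alpha, the
#' test statistic under the alternative is noncentral t with df = n - 1
#' and noncentrality `d * sqrt(n)`.
#'
#' @param d Effect size (Cohen's d_z on the paired differences).
#' @param n Number of pairs, >= 2.
#' @param alpha Significance level in (0, 1).
#' @param tails `"two.sided"` (default) or `"one.sided"`.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' power_paired_t(d = 2, n = 10)   # > 0.99
power_paired_t <- function(d, n, alpha = 0.05, tails = "two.sided") {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  tails <- match.arg(tails, c("two.sided", "one.sided"))
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == "two.sided") {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp)
  }
}

#' Full statistical report for a two-task cohort
#'
#' Runs the complete latency-modulation analysis on per-subject summaries:
#' per-group task means, percent reduction, paired t, RMS-pooled Cohen's d
#' and Levene variance test; pairwise SLD contrasts between groups (Welch
#' t, both one- and two-tailed p reported, plus Cohen's d from the group
#' SLD summaries); and, when behavioural columns are present, Wilcoxon
#' signed-rank tests on accuracy per group and the mixed ANOVA on response
#' times.
#'
#' @param summaries Output of [task_means()].
#' @return A nested list of class `sl_report` (JSON-serializable via
#'   [write_report()]): `groups` (per-group latency stats), `sld`
#'   (pairwise contrasts), `behavior` (or `NULL`).
#' @export
analyze_cohort <- function(summaries) {
  canonical <- c("patient", "control", "relative")
  groups <- unique(summaries$group)
  groups <- c(intersect(canonical, groups), setdiff(groups, canonical))
  per_group <- lapply(groups, function(g) {
    s <- summaries[summaries$group == g, ]
    mc <- mean(s$sl_color); ml <- mean(s$sl_landolt)
    res <- list(
      n = nrow(s),
      mean_color = mc, sd_color = sd(s$sl_color),
      mean_landolt = ml, sd_landolt = sd(s$sl_landolt),
      mean_sld = mean(s$sld),
      percent_reduction = percent_reduction(mc, ml),
      cohens_d = cohens_d_paired(mc, sd(s$sl_color), ml,
                                 sd(s$sl_landolt))
    )
    res$paired_t <- if (nrow(s) >= 2 && var(s$sld) > 0)
      paired_t(s$sl_color, s$sl_landolt) else NULL
    res$levene <- if (nrow(s) >= 2)
      levene_test(s$sl_color, s$sl_landolt) else NULL
    res
  })
  names(per_group) <- groups

  pairs <- if (length(groups) >= 2) utils::combn(groups, 2,
                                                 simplify = FALSE)
  else list()
  sld <- lapply(pairs, function(p) {
    a <- summaries$sld[summaries$group == p[1]]
    b <- summaries$sld[summaries$group == p[2]]
    list(groups = p,
         welch_two_sided = welch_t(a, b, "two.sided"),
         welch_one_sided = welch_t(a, b,
                                   if (mean(a) >= mean(b)) "greater"
                                   else "less"),
         cohens_d = cohens_d_paired(mean(a), sd(a), mean(b), sd(b)))
  })
  names(sld) <- vapply(pairs, paste, collapse = "_vs_", character(1))

  behavior <- NULL
  if (all(c("acc_color", "acc_landolt", "rt_color", "rt_landolt") %in%
          names(summaries))) {
    acc_tests <- lapply(groups, function(g) {
      s <- summaries[summaries$group == g, ]
      if (all(s$acc_color - s$acc_landolt == 0)) return(NULL)
      rank_tests(s$acc_color, s$acc_landolt, paired = TRUE)
    })
    names(acc_tests) <- groups
    long <- data.frame(
      subject = rep(summaries$subject, 2),
      group = rep(summaries$group, 2),
      task = rep(c("color", "landolt"), each = nrow(summaries)),
      value = c(summaries$rt_color, summaries$rt_landolt)
    )
    behavior <- list(accuracy_signed_rank = acc_tests,
                     rt_anova = mixed_anova(long))
  }

  structure(list(groups = per_group, sld = sld, behavior = behavior),
            class = "sl_report")
}
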