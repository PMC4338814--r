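#' Build the two-feature classification table
#'
#' One feature vector per subject: mean saccadic latency in the Landolt
#' task and in the color task, with the group label preserved. Subjects
#' with a missing task mean are dropped with a warning; duplicated subject
#' ids are rejected.
#'
#' @param summaries Output of [task_means()].
#' @return A `data.frame` with columns `subject`, `group`, `sl_color`,
#'   `sl_landolt`.
#' @export
build_features <- function(summaries) {
  if (anyDuplicated(summaries$subject))
    stop("duplicated subject id(s)", call. = FALSE)
  keep <- is.finite(summaries$sl_color) & is.finite(summaries$sl_landolt)
  if (!all(keep)) {
    warning("dropping subject(s) with missing task mean: ",
            paste(summaries$subject[!keep], collapse = ", "))
  }
  out <- summaries[keep, c("subject", "group", "sl_color", "sl_landolt")]
  rownames(out) <- NULL
  out
}

#' Balanced-subsampling scheme for classification
#'
#' The three classification problems, each drawing a balanced 13 + 13
#' subsample per Monte Carlo iteration (patients are always the positive
#' class):
#' * `"P_vs_C"` — all 13 patients vs 13 controls sampled from 24.
#' * `"P_vs_RC"` — all 13 patients vs 13 sampled from the merged
#'   controls + relatives pool (34).
#' * `"PR_vs_C"` — 13 sampled from the merged patients + relatives pool
#'   (23) vs 13 controls sampled from 24.
#'
#' @param id Scheme id.
#' @param n_per_class Subsample size per class (default 13; the subsample
#'   always totals 26 subjects).
#' @return An object of class `sampling_scheme` with `id`,
#'   `positive_groups`, `negative_groups`, `n_per_class`.
#' @export
sampling_scheme <- function(id = c("P_vs_RC", "P_vs_C", "PR_vs_C"),
                            n_per_class = 13) {
  id <- match.arg(id)
  pools <- switch(id,
    P_vs_C  = list(pos = "patient", neg = "control"),
    P_vs_RC = list(pos = "patient", neg = c("control", "relative")),
    PR_vs_C = list(pos = c("patient", "relative"), neg = "control"))
  structure(list(id = id, positive_groups = pools$pos,
                 negative_groups = pools$neg, n_per_class = n_per_class),
            class = "sampling_scheme")
}

#' Draw one balanced subsample
#'
#' Samples `n_per_class` subjects without replacement from the scheme's
#' positive and negative pools.
#'
#' @param features Feature table from [build_features()].
#' @param scheme A [sampling_scheme()].
#' @param seed Optional seed for a reproducible draw.
#' @return The sampled rows of `features` with a `label` factor column
#'   (`"pos"` / `"neg"`).
#' @export
draw_subsample <- function(features, scheme, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- scheme$n_per_class
  pos_pool <- which(features$group %in% scheme$positive_groups)
  neg_pool <- which(features$group %in% scheme$negative_groups)
  if (length(pos_pool) < n || length(neg_pool) < n)
    stop(sprintf("pool smaller than %d (pos %d, neg %d)", n,
                 length(pos_pool), length(neg_pool)), call. = FALSE)
  pos <- if (length(pos_pool) == n) pos_pool else
    sample(pos_pool, n)
  neg <- if (length(neg_pool) == n) neg_pool else
    sample(neg_pool, n)
  out <- features[c(pos, neg), ]
  out$label <- factor(rep(c("pos", "neg"), each = n),
                      levels = c("pos", "neg"))
  rownames(out) <- NULL
  out
}

#' Leave-one-out cross-validated SVM predictions
#'
#' For each subject in the balanced subsample, trains a radial-basis-kernel
#' SVM on the remaining subjects and predicts the held-out one. Features
#' are standardized with training-fold statistics (the `scale` option of
#' \pkg{e1071}).
#'
#' @param sample26 Output of [draw_subsample()] (columns `sl_color`,
#'   `sl_landolt`, `label`).
#' @param cost SVM cost parameter (default 1).
#' @param gamma Radial kernel width; default `1 / n_features` = 0.5.
#' @param scale Standardize features within each training fold.
#' @return Factor of predicted labels, aligned with `sample26` rows.
#' @export
loocv_svm <- function(sample26, cost = 1, gamma = NULL, scale = TRUE) {
  x <- as.matrix(sample26[, c("sl_color", "sl_landolt")])
  y <- sample26$label
  if (any(apply(x, 2, stats::var) == 0))
    stop("degenerate (constant) feature", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  n <- nrow(x)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    fit <- e1071::svm(x[-i, , drop = FALSE], y[-i], kernel = "radial",
                      cost = cost, gamma = gamma, scale = scale)
    pred[i] <- stats::predict(fit, x[i, , drop = FALSE])
  }
  pred
}

# confusion counts with patients ("pos") as the positive class
confusion_counts <- function(truth, pred) {
  c(tp = sum(truth == "pos" & pred == "pos"),
    fp = sum(truth == "neg" & pred == "pos"),
    tn = sum(truth == "neg" & pred == "neg"),
    fn = sum(truth == "pos" & pred == "neg"))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; total must be > 0.
#' @return Named list with `accuracy`, `sensitivity`, `specificity`, all
#'   in percent.
#' @export
#' @examples
#' confusion_metrics(8, 5, 8, 5)   # 62% accuracy
confusion_metrics <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0))
    stop("counts must be non-negative", call. = FALSE)
  total <- tp + fp + tn + fn
  if (total == 0) stop("zero total count", call. = FALSE)
  list(accuracy = 100 * (tp + tn) / total,
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Monte Carlo balanced-subsample SVM classification
#'
#' Repeats [draw_subsample()] + [loocv_svm()] for the given number of
#' iterations and averages sensitivity, specificity and the confusion
#' counts across iterations. A running-mean accuracy trace is recorded as
#' a convergence diagnostic. Fully reproducible from the seed.
#'
#' @param features Feature table from [build_features()].
#' @param scheme A [sampling_scheme()] (or scheme id string).
#' @param iterations Number of Monte Carlo iterations (>= 1). The
#'   full-scale reference run uses 5e6; desk-scale runs of 1e3--1e4 are
#'   stable for this two-feature problem (watch `convergence`).
#' @param seed Integer seed.
#' @param cost,gamma,scale Passed to [loocv_svm()].
#' @param trace_every Record the running mean accuracy every this many
#'   iterations.
#'
#' @return An object of class `classification_result`: list with `scheme`,
#'   `iterations`, `sensitivity`, `specificity`, `accuracy` (mean
#'   percents), `confusion` (mean counts and integer-rounded counts),
#'   `convergence` (running-mean trace), `seed`.
#' @export
monte_carlo_svm <- function(features, scheme = sampling_scheme("P_vs_RC"),
                            iterations = 1e4, seed = NULL, cost = 1,
                            gamma = NULL, scale = TRUE,
                            trace_every = max(1, iterations %/% 100)) {
  if (is.character(scheme)) scheme <- sampling_scheme(scheme)
  stopifnot(iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  sums <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  sens_sum <- 0; spec_sum <- 0
  conv_at <- integer(0); conv_acc <- numeric(0)
  acc_sum <- 0
  for (it in seq_len(iterations)) {
    sub <- draw_subsample(features, scheme)
    pred <- loocv_svm(sub, cost = cost, gamma = gamma, scale = scale)
    cc <- confusion_counts(sub$label, pred)
    sums <- sums + cc
    sens_sum <- sens_sum + cc["tp"] / (cc["tp"] + cc["fn"])
    spec_sum <- spec_sum + cc["tn"] / (cc["tn"] + cc["fp"])
    acc_sum <- acc_sum + (cc["tp"] + cc["tn"]) / sum(cc)
    if (it %% trace_every == 0 || it == iterations) {
      conv_at <- c(conv_at, it)
      conv_acc <- c(conv_acc, 100 * acc_sum / it)
    }
  }
  mean_counts <- sums / iterations
  structure(
    list(scheme = scheme$id, iterations = iterations,
         sensitivity = unname(100 * sens_sum / iterations),
         specificity = unname(100 * spec_sum / iterations),
         accuracy = unname(100 * acc_sum / iterations),
         confusion = list(mean = as.list(mean_counts),
                          rounded = as.list(round(mean_counts))),
         convergence = data.frame(iteration = conv_at,
                                  running_accuracy = conv_acc),
         seed = seed),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    paste0("<classification_result> scheme %s, %d iterations\n",
           "  sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
           "  mean confusion: TP %.1f, FP %.1f, TN %.1f, FN %.1f\n"),
    x$scheme, x$iterations, x$sensitivity, x$specificity, x$accuracy,
    x$confusion$mean$tp, x$confusion$mean$fp, x$confusion$mean$tn,
    x$confusion$mean$fn))
  invisible(x)
}
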