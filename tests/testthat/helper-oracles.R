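# Independent oracles used across the suite. These re-derive expected
# values by exhaustive scan/enumeration or direct formula evaluation and
# deliberately share no code with the package implementation.

# --- exhaustive per-sample threshold-crossing saccade scan ----------------
# Walks the speed signal sample by sample: seeds wherever speed crosses the
# onset threshold, extends to the offset-threshold crossings by explicit
# backward/forward loops, then applies merge, mask, boundary-extension and
# size rules in the same plainly-coded way.
oracle_detect <- function(time_ms, x, speed, mask, cfg) {
  n <- length(speed)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (speed[i] >= cfg$onset_threshold) {
      s <- i
      while (s > 1L && speed[s - 1L] >= cfg$offset_threshold) s <- s - 1L
      e <- i
      while (e < n && speed[e + 1L] >= cfg$offset_threshold) e <- e + 1L
      runs[[length(runs) + 1L]] <- c(s, e)
      i <- e + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(runs) == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), amplitude = numeric(0),
                      peak_velocity = numeric(0)))
  runs <- unique(runs)
  # merge runs closer than merge_interval
  merged <- list(runs[[1]])
  if (length(runs) > 1) {
    for (k in 2:length(runs)) {
      last <- merged[[length(merged)]]
      if (time_ms[runs[[k]][1]] - time_ms[last[2]] < cfg$merge_interval) {
        merged[[length(merged)]] <- c(last[1], runs[[k]][2])
      } else {
        merged[[length(merged) + 1L]] <- runs[[k]]
      }
    }
  }
  # drop runs overlapping the mask
  merged <- Filter(function(r) !any(mask[r[1]:r[2]]), merged)
  if (length(merged) == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), amplitude = numeric(0),
                      peak_velocity = numeric(0)))
  ev <- do.call(rbind, lapply(merged, function(r) {
    s <- max(r[1] - 1L, 1L)   # crossing lies before the first >= sample
    e <- min(r[2] + 1L, n)
    data.frame(onset = time_ms[s], offset = time_ms[e],
               duration = time_ms[e] - time_ms[s],
               amplitude = x[e] - x[s],
               peak_velocity = max(speed[r[1]:r[2]]))
  }))
  ev <- ev[ev$duration >= cfg$min_duration &
             abs(ev$amplitude) >= cfg$min_amplitude, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# random piecewise-constant-velocity traces for detector equivalence tests
random_velocity_trace <- function(n = 300, fs = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, by = 1000 / fs, length.out = n)
  # a few velocity bursts on a noisy baseline
  speed <- abs(rnorm(n, 0, 12))
  for (k in seq_len(sample(0:4, 1))) {
    at <- sample(n - 30, 1)
    len <- sample(3:25, 1)
    speed[at:(at + len)] <- speed[at:(at + len)] + runif(1, 40, 600)
  }
  x <- cumsum(speed) / fs
  mask <- rep(FALSE, n)
  if (runif(1) < 0.3) {
    at <- sample(n, 1)
    mask[max(1, at - 2):min(n, at + 2)] <- TRUE
  }
  structure(
    data.frame(time_ms = t, x_deg = x, speed = speed, mask = mask),
    sampling_rate = fs, class = c("velocity_trace", "data.frame")
  )
}

# --- exact Wilcoxon enumeration ------------------------------------------
# Signed rank: all 2^n sign assignments on the ranks of |d| (assumes no
# zeros/ties, as in the fixtures used).
oracle_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Rank sum: all n1-subsets of the pooled ranks; W is the rank sum of the
# first sample minus n1(n1+1)/2.
oracle_rank_sum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  w_all <- apply(idx, 2, function(j) sum(r[j])) - n1 * (n1 + 1) / 2
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# --- direct-formula statistics -------------------------------------------
oracle_paired_t <- function(a, b) {
  d <- a - b; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

oracle_welch_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  se2 <- var(a) / n1 + var(b) / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / n1)^2 / (n1 - 1) + (var(b) / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(stat = sum((tab - e)^2 / e),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

oracle_levene <- function(a, b) {
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  z <- c(za, zb); g <- rep(1:2, c(length(a), length(b)))
  zg <- tapply(z, g, mean); ng <- tabulate(g)
  ssb <- sum(ng * (zg - mean(z))^2)
  ssw <- sum((z - zg[g])^2)
  df1 <- 1; df2 <- length(z) - 2
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df = c(df1, df2), p = pf(f, df1, df2, lower.tail = FALSE))
}

# Mixed-design ANOVA sums of squares on a balanced layout (equal group
# sizes, 2 tasks), by direct decomposition.
oracle_mixed_anova <- function(data) {
  grand <- mean(data$value)
  subj_means <- tapply(data$value, data$subject, mean)
  subj_group <- tapply(as.character(data$group), data$subject,
                       function(x) x[1])
  group_means <- tapply(data$value, data$group, mean)
  task_means_ <- tapply(data$value, data$task, mean)
  cell_means <- tapply(data$value, list(data$group, data$task), mean)
  ng <- table(subj_group)          # subjects per group
  N <- length(subj_means); g <- length(ng)

  ss_total <- sum((data$value - grand)^2)
  ss_between_subj <- 2 * sum((subj_means - grand)^2)
  ss_group <- 2 * sum(ng * (group_means[names(ng)] - grand)^2)
  ss_subj <- ss_between_subj - ss_group
  ss_task <- N * sum((task_means_ - grand)^2)
  ss_inter <- sum(outer(ng[rownames(cell_means)], c(1, 1)) *
                    (cell_means -
                       outer(group_means[rownames(cell_means)], c(0, 0),
                             "+") -
                       matrix(task_means_, nrow = g, ncol = 2,
                              byrow = TRUE) + grand)^2)
  ss_error <- ss_total - ss_group - ss_subj - ss_task - ss_inter
  list(
    F_group = (ss_group / (g - 1)) / (ss_subj / (N - g)),
    F_task = (ss_task / 1) / (ss_error / (N - g)),
    F_inter = (ss_inter / (g - 1)) / (ss_error / (N - g)),
    df = list(group = c(g - 1, N - g), task = c(1, N - g),
              inter = c(g - 1, N - g)),
    ss = c(total = ss_total, group = ss_group, subj = ss_subj,
           task = ss_task, inter = ss_inter, error = ss_error)
  )
}

# small balanced mixed-design fixture
balanced_anova_fixture <- function(seed = 42, n_per_group = 4, g = 3) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(n_per_group * g))
  grp <- rep(paste0("g", seq_len(g)), each = n_per_group)
  data.frame(
    subject = rep(subj, 2),
    group = rep(grp, 2),
    task = rep(c("color", "landolt"), each = n_per_group * g),
    value = rnorm(2 * n_per_group * g, mean = rep(c(250, 210),
                                                  each = n_per_group * g),
                  sd = 30)
  )
}
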