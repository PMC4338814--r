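#' Default latency model for the three-group, two-task design
#'
#' Per group x task, the model specifies the between-subject mean and SD of
#' the subject-level mean saccadic latency, the within-subject
#' (trial-to-trial) SD, and the between-task correlation of subject means.
#' Defaults reproduce the study conditions of the schizophrenia
#' latency-modulation design this package models: patients 248/232 ms
#' (color/Landolt), controls 261/193 ms, first-degree relatives 221/178 ms,
#' with the printed between-subject SDs. The between-task correlations
#' (0.88 / 0.05 / 0.63) are those implied by the reported paired t
#' statistics together with the per-task SDs, so simulated cohorts
#' reproduce both the marginal SDs and the dispersion of per-subject task
#' differences.
#'
#' @return A `data.frame` with columns `group`, `task`, `mean`,
#'   `between_sd`, `within_sd`, `task_cor`.
#' @export
latency_model_default <- function() {
  data.frame(
    group      = rep(c("patient", "control", "relative"), each = 2),
    task       = rep(c("color", "landolt"), 3),
    mean       = c(248, 232, 261, 193, 221, 178),
    between_sd = c(56, 51, 100, 27, 49, 30),
    within_sd  = rep(40, 6),
    task_cor   = rep(c(0.883, 0.053, 0.632), each = 2)
  )
}

#' Default behavioural (button-response) model
#'
#' Accuracy and response-time means per group x task. Values are chosen to
#' emulate the qualitative behavioural pattern of the design: ~95% correct
#' overall with slightly lower accuracy in the Landolt task for patients
#' and relatives; longer response times in the Landolt task in every group,
#' overall slower patients, and a larger relative Landolt slow-down in
#' patients (the task x group interaction).
#'
#' @return A `data.frame` with columns `group`, `task`, `accuracy`,
#'   `rt_mean` (ms), `rt_between_sd`, `rt_within_sd`.
#' @export
behavior_model_default <- function() {
  data.frame(
    group    = rep(c("patient", "control", "relative"), each = 2),
    task     = rep(c("color", "landolt"), 3),
    accuracy = c(0.96, 0.92, 0.97, 0.96, 0.97, 0.93),
    rt_mean  = c(1000, 1280, 800, 896, 820, 918),
    rt_between_sd = rep(150, 6),
    rt_within_sd  = rep(250, 6)
  )
}

#' Cohort simulation configuration
#'
#' Bundles everything [simulate_cohort()] needs: group sizes, the latency
#' and behaviour models, tracker noise and sampling rate, the balanced
#' block design, trial timing, and kinematic/geometry parameters.
#'
#' @param group_sizes Named integer vector of subjects per group; default
#'   `c(patient = 13, control = 24, relative = 10)`.
#' @param latency_model See [latency_model_default()].
#' @param behavior_model See [behavior_model_default()].
#' @param noise_sd Gaussian position-noise SD in degrees (default 0.3,
#'   consistent with a tracker of 0.5--1 degree spatial resolution).
#' @param sampling_rate Sampling rate in Hz (default 200).
#' @param n_trials,n_blocks Trials per subject and blocks; `n_trials` must
#'   be divisible by `n_blocks` and each block by 4 so task and side can be
#'   fully balanced within blocks (default 96 trials in 3 blocks of 32).
#' @param latency_floor Truncation floor for drawn latencies in ms
#'   (default 80; excludes anticipatory saccades).
#' @param latency_family `"gaussian"` (truncated) or `"exgaussian"`.
#' @param exgauss_tau Exponential tail parameter (ms) when
#'   `latency_family = "exgaussian"`.
#' @param fixation_duration,first_target_duration,post_duration Trial
#'   timing in ms: fixation dot, first (central) target, and recording tail
#'   after the saccade lands. The paradigm is a step paradigm (zero gap
#'   between first-target offset and second-target onset).
#' @param max_retries Redraw attempts for a latency below the floor before
#'   a trial is flagged degenerate.
#' @param geometry A [geometry_config()].
#' @param mainseq A [main_sequence_params()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(patient = 13, control = 24,
                                          relative = 10),
                          latency_model = latency_model_default(),
                          behavior_model = behavior_model_default(),
                          noise_sd = 0.3,
                          sampling_rate = 200,
                          n_trials = 96,
                          n_blocks = 3,
                          latency_floor = 80,
                          latency_family = c("gaussian", "exgaussian"),
                          exgauss_tau = 60,
                          fixation_duration = 500,
                          first_target_duration = 1000,
                          post_duration = 400,
                          max_retries = 100,
                          geometry = geometry_config(),
                          mainseq = main_sequence_params(),
                          seed = NULL) {
  latency_family <- match.arg(latency_family)
  if (is.null(names(group_sizes)) || any(names(group_sizes) == ""))
    stop("`group_sizes` must be a named vector", call. = FALSE)
  if (n_trials %% n_blocks != 0)
    stop("`n_trials` must be divisible by `n_blocks`", call. = FALSE)
  if ((n_trials / n_blocks) %% 4 != 0)
    stop("trials per block must be divisible by 4 to balance task x side",
         call. = FALSE)
  if (noise_sd < 0 || any(latency_model$between_sd < 0) ||
      any(latency_model$within_sd < 0))
    stop("all SDs must be non-negative", call. = FALSE)
  if (any(abs(latency_model$task_cor) > 1))
    stop("`task_cor` must lie in [-1, 1]", call. = FALSE)
  structure(
    list(group_sizes = group_sizes, latency_model = latency_model,
         behavior_model = behavior_model, noise_sd = noise_sd,
         sampling_rate = sampling_rate, n_trials = n_trials,
         n_blocks = n_blocks, latency_floor = latency_floor,
         latency_family = latency_family, exgauss_tau = exgauss_tau,
         fixation_duration = fixation_duration,
         first_target_duration = first_target_duration,
         post_duration = post_duration, max_retries = max_retries,
         geometry = geometry, mainseq = mainseq, seed = seed),
    class = "cohort_config"
  )
}

# Balanced randomized design: within every block each task and each side
# occurs equally often, with the task x side cross fully balanced.
block_design <- function(n_trials, n_blocks) {
  per_block <- n_trials / n_blocks
  cell <- per_block / 4
  out <- lapply(seq_len(n_blocks), function(b) {
    d <- expand.grid(task = c("color", "landolt"),
                     side = c("left", "right"),
                     stringsAsFactors = FALSE)
    d <- d[rep(seq_len(4), each = cell), ]
    d <- d[sample.int(nrow(d)), ]
    d$block <- b
    d
  })
  out <- do.call(rbind, out)
  out$trial <- seq_len(n_trials)
  rownames(out) <- NULL
  out[, c("trial", "block", "task", "side")]
}

# One latency draw; truncated-normal (or shifted ex-Gaussian) above floor.
draw_latency <- function(mean, sd, floor, family = "gaussian", tau = 60,
                         max_retries = 100) {
  for (i in seq_len(max_retries)) {
    l <- if (family == "gaussian") {
      rnorm(1, mean, sd)
    } else {
      mu <- mean - tau
      sigma <- sqrt(max(sd^2 - tau^2, (0.25 * sd)^2))
      rnorm(1, mu, sigma) + rexp(1, 1 / tau)
    }
    if (l >= floor) return(l)
  }
  NA_real_   # degenerate trial
}

#' Simulate a single trial
#'
#' Builds one gaze trace with ground truth: fixation at the centre through
#' the fixation-dot and first-target intervals, then (after a latency drawn
#' from the subject's latency distribution, truncated below at the floor) a
#' main-sequence saccade to the peripheral target, then fixation on the
#' target. Gaussian position noise is added throughout.
#'
#' @param subject_params List with `latency_mean`, `latency_sd`,
#'   `accuracy`, `rt_mean`, `rt_sd` for this subject and task.
#' @param task `"color"` or `"landolt"`.
#' @param side `"left"` or `"right"`.
#' @param config A [cohort_config()] (timing, noise, kinematics, geometry).
#' @param subject,trial,block Identifiers stored in the outputs.
#' @param seed Optional integer seed; the same seed reproduces the trial
#'   bitwise.
#'
#' @return A list with elements `trace` ([gaze_trace()]), `event` (one-row
#'   `data.frame`: identifiers, task, side, `t1_onset`, `t2_onset`,
#'   `correct`, `rt`) and `truth` (one-row `data.frame`: `true_latency`,
#'   `true_saccade_onset`, `true_amplitude`, `degenerate`).
#' @export
simulate_trial <- function(subject_params, task, side,
                           config = cohort_config(),
                           subject = "S01", trial = 1L, block = 1L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geo <- config$geometry
  fs <- config$sampling_rate
  step <- 1000 / fs
  ecc <- geo$target_eccentricity
  amp <- if (side == "right") ecc else -ecc

  lat <- draw_latency(subject_params$latency_mean,
                      subject_params$latency_sd,
                      config$latency_floor, config$latency_family,
                      config$exgauss_tau, config$max_retries)
  degenerate <- is.na(lat)
  t2_onset <- config$fixation_duration + config$first_target_duration
  onset <- if (degenerate) NA_real_ else t2_onset + lat
  dur <- saccade_duration(abs(amp), config$mainseq)

  total <- t2_onset + (if (degenerate) 0 else lat) + dur +
    config$post_duration
  t <- seq(0, total, by = step)
  x <- numeric(length(t))
  if (!degenerate) {
    u <- (t - onset) / dur
    x <- amp * raised_cosine_progress(u)
  }
  if (config$noise_sd > 0) {
    x <- x + rnorm(length(t), 0, config$noise_sd)
    y <- rnorm(length(t), 0, config$noise_sd)
  } else {
    y <- numeric(length(t))
  }
  trace <- gaze_trace(t, x, y, sampling_rate = fs, subject = subject,
                      trial = trial)

  correct <- as.logical(rbinom(1, 1, subject_params$accuracy))
  rt <- max(200, rnorm(1, subject_params$rt_mean, subject_params$rt_sd))
  event <- data.frame(
    subject = subject, trial = trial, block = block, task = task,
    side = side, t1_onset = config$fixation_duration, t2_onset = t2_onset,
    response = ifelse(correct, "match", "nonmatch"), correct = correct,
    rt = rt, stringsAsFactors = FALSE
  )
  truth <- data.frame(
    subject = subject, trial = trial, task = task, side = side,
    true_latency = lat, true_saccade_onset = onset, true_amplitude = amp,
    degenerate = degenerate, stringsAsFactors = FALSE
  )
  list(trace = trace, event = event, truth = truth)
}

#' Simulate a synthetic cohort
#'
#' Generates a full multi-group dataset with known ground truth: subject
#' task means drawn from the group-level bivariate latency model, balanced
#' randomized blocks, and (optionally) one gaze trace per trial.
#'
#' @param config A [cohort_config()].
#' @param traces If `FALSE`, skip gaze-trace synthesis and return events and
#'   ground truth only (fast path for statistical replication studies; the
#'   detector stage is then bypassed via [truth_latency_records()]).
#' @param seed Overrides `config$seed` when non-`NULL`.
#'
#' @return An object of class `sl_cohort`: a list with `config`, `subjects`
#'   (`data.frame`: `subject`, `group`), `events`, `truth` (row per trial)
#'   and `traces` (named list of [gaze_trace()]s, or `NULL`).
#' @export
#' @examples
#' cfg <- cohort_config(group_sizes = c(patient = 2, control = 2),
#'                      n_trials = 8, n_blocks = 1, seed = 7)
#' coh <- simulate_cohort(cfg, traces = FALSE)
#' table(coh$subjects$group)
simulate_cohort <- function(config = cohort_config(), traces = TRUE,
                            seed = NULL) {
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)

  sizes <- config$group_sizes
  if (any(sizes == 0)) {
    warning("omitting group(s) with size 0: ",
            paste(names(sizes)[sizes == 0], collapse = ", "))
    sizes <- sizes[sizes > 0]
  }
  lm_tab <- config$latency_model
  bm_tab <- config$behavior_model

  prefix <- toupper(substr(names(sizes), 1, 1))
  subjects <- data.frame(
    subject = unlist(lapply(seq_along(sizes), function(i)
      sprintf("%s%02d", prefix[i], seq_len(sizes[i])))),
    group = rep(names(sizes), sizes),
    stringsAsFactors = FALSE
  )

  events_list <- list()
  truth_list <- list()
  trace_list <- if (traces) list() else NULL

  for (si in seq_len(nrow(subjects))) {
    subj <- subjects$subject[si]
    grp <- subjects$group[si]
    lm_g <- lm_tab[lm_tab$group == grp, ]
    bm_g <- bm_tab[bm_tab$group == grp, ]
    if (nrow(lm_g) != 2)
      stop("latency model must have one color and one landolt row for ",
           grp, call. = FALSE)
    lc <- lm_g[lm_g$task == "color", ]
    ll <- lm_g[lm_g$task == "landolt", ]

    # correlated subject-level task means
    z1 <- rnorm(1)
    z2 <- rnorm(1)
    rho <- lc$task_cor
    zc <- z1
    zl <- rho * z1 + sqrt(1 - rho^2) * z2
    mu_subj <- c(color   = lc$mean + lc$between_sd * zc,
                 landolt = ll$mean + ll$between_sd * zl)

    rt_int <- rnorm(1, 0, bm_g$rt_between_sd[1])

    design <- block_design(config$n_trials, config$n_blocks)
    for (ti in seq_len(nrow(design))) {
      task <- design$task[ti]
      lm_t <- if (task == "color") lc else ll
      bm_t <- bm_g[bm_g$task == task, ]
      sp <- list(latency_mean = mu_subj[[task]],
                 latency_sd = lm_t$within_sd,
                 accuracy = bm_t$accuracy,
                 rt_mean = bm_t$rt_mean + rt_int,
                 rt_sd = bm_t$rt_within_sd)
      if (traces) {
        sim <- simulate_trial(sp, task, design$side[ti], config,
                              subject = subj, trial = design$trial[ti],
                              block = design$block[ti])
        trace_list[[paste(subj, design$trial[ti], sep = "_")]] <- sim$trace
      } else {
        sim <- simulate_trial_fast(sp, task, design$side[ti], config,
                                   subject = subj,
                                   trial = design$trial[ti],
                                   block = design$block[ti])
      }
      sim$event$group <- grp
      sim$truth$group <- grp
      events_list[[length(events_list) + 1L]] <- sim$event
      truth_list[[length(truth_list) + 1L]] <- sim$truth
    }
  }

  structure(
    list(config = config,
         subjects = subjects,
         events = do.call(rbind, events_list),
         truth = do.call(rbind, truth_list),
         traces = trace_list),
    class = "sl_cohort"
  )
}

# Latency/behaviour draws without trace synthesis; RNG consumption differs
# from simulate_trial (no per-sample noise), so traces = FALSE is its own
# deterministic stream, not a replay of the traced one.
simulate_trial_fast <- function(subject_params, task, side, config,
                                subject, trial, block) {
  geo <- config$geometry
  amp <- if (side == "right") geo$target_eccentricity else
    -geo$target_eccentricity
  lat <- draw_latency(subject_params$latency_mean,
                      subject_params$latency_sd,
                      config$latency_floor, config$latency_family,
                      config$exgauss_tau, config$max_retries)
  t2_onset <- config$fixation_duration + config$first_target_duration
  correct <- as.logical(rbinom(1, 1, subject_params$accuracy))
  rt <- max(200, rnorm(1, subject_params$rt_mean, subject_params$rt_sd))
  list(
    event = data.frame(subject = subject, trial = trial, block = block,
                       task = task, side = side,
                       t1_onset = config$fixation_duration,
                       t2_onset = t2_onset,
                       response = ifelse(correct, "match", "nonmatch"),
                       correct = correct, rt = rt,
                       stringsAsFactors = FALSE),
    truth = data.frame(subject = subject, trial = trial, task = task,
                       side = side, true_latency = lat,
                       true_saccade_onset = if (is.na(lat)) NA_real_ else
                         t2_onset + lat,
                       true_amplitude = amp, degenerate = is.na(lat),
                       stringsAsFactors = FALSE)
  )
}

#' @export
print.sl_cohort <- function(x, ...) {
  cat(sprintf(
    "<sl_cohort> %d subjects (%s), %d trials each, traces: %s\n",
    nrow(x$subjects),
    paste(sprintf("%s=%d", names(table(x$subjects$group)),
                  as.integer(table(x$subjects$group))), collapse = ", "),
    x$config$n_trials, if (is.null(x$traces)) "no" else "yes"))
  invisible(x)
}

#' Latency records taken directly from simulation ground truth
#'
#' Converts a cohort's `truth` table into the same latency-record schema
#' that [extract_latencies()] produces from detected saccades, bypassing
#' the detector. Used for latency-level replication studies where trace
#' synthesis and detection would only add a known, sub-sample quantization
#' error.
#'
#' @param cohort An `sl_cohort`.
#' @param floor,ceiling Validity bounds in ms.
#' @return A `data.frame` of latency records (`subject`, `group`, `task`,
#'   `trial`, `latency`, `valid`, `reason`).
#' @export
truth_latency_records <- function(cohort, floor = 80, ceiling = 1000) {
  tr <- cohort$truth
  lat <- tr$true_latency
  valid <- !is.na(lat) & lat >= floor & lat <= ceiling
  reason <- rep("ok", nrow(tr))
  reason[is.na(lat)] <- "none_found"
  reason[!is.na(lat) & lat < floor] <- "anticipatory"
  reason[!is.na(lat) & lat > ceiling] <- "out_of_bounds"
  data.frame(subject = tr$subject, group = tr$group, task = tr$task,
             trial = tr$trial, latency = lat, valid = valid,
             reason = reason, stringsAsFactors = FALSE)
}
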