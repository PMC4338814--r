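#' Saccade detection configuration
#'
#' Dual velocity-threshold detector settings: events are seeded where eye
#' speed exceeds `onset_threshold` and extended to the nearest crossings of
#' `offset_threshold`. Defaults are 60 and 15 deg/s. The small-event
#' filters (`min_duration`, `min_amplitude`) and `merge_interval` suppress
#' noise-driven micro-events at 200 Hz.
#'
#' @param onset_threshold Seed threshold in deg/s; must exceed
#'   `offset_threshold`.
#' @param offset_threshold Boundary threshold in deg/s; must be positive.
#' @param min_duration Minimum event duration in ms (default 10).
#' @param min_amplitude Minimum unsigned amplitude in degrees (default 1).
#' @param merge_interval Events closer than this (offset to next onset, ms)
#'   are merged (default 20).
#'
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(onset_threshold = 60, offset_threshold = 15,
                             min_duration = 10, min_amplitude = 1,
                             merge_interval = 20) {
  if (!(onset_threshold > offset_threshold && offset_threshold > 0))
    stop("need onset_threshold > offset_threshold > 0", call. = FALSE)
  structure(
    list(onset_threshold = onset_threshold,
         offset_threshold = offset_threshold,
         min_duration = min_duration, min_amplitude = min_amplitude,
         merge_interval = merge_interval),
    class = "detection_config"
  )
}

#' Detect saccades with a dual velocity threshold
#'
#' Finds maximal runs of samples with speed at or above the offset
#' threshold that contain at least one sample at or above the onset
#' threshold (equivalent to seeding at the onset-threshold crossing and
#' extending backward/forward to the offset-threshold crossings; the
#' backward extension stops at the last sample below the offset threshold,
#' so onset ties resolve toward the earlier sample). Events closer than
#' `merge_interval` are merged, events overlapping masked (artifact)
#' samples are dropped, and events shorter than `min_duration` or smaller
#' than `min_amplitude` are discarded.
#'
#' @param vel A `velocity_trace` from [preprocess_trace()] or [velocity()].
#' @param cfg A [detection_config()].
#'
#' @return A `data.frame` of saccade events: `onset`, `offset` (ms),
#'   `duration` (ms), `amplitude` (deg, signed), `peak_velocity` (deg/s).
#'   Zero rows when nothing crosses the onset threshold.
#' @export
#' @examples
#' seg <- simulate_saccade_segment(30)
#' tr <- gaze_trace(seg$time_ms, seg$x_deg, sampling_rate = 200)
#' detect_saccades(preprocess_trace(tr))
detect_saccades <- function(vel, cfg = detection_config()) {
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), amplitude = numeric(0),
                      peak_velocity = numeric(0))
  n <- nrow(vel)
  if (n == 0) return(empty)
  speed <- vel$speed
  above <- speed >= cfg$offset_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) return(empty)
  seeded <- vapply(seq_along(starts), function(i)
    any(speed[starts[i]:ends[i]] >= cfg$onset_threshold), logical(1))
  starts <- starts[seeded]; ends <- ends[seeded]
  if (length(starts) == 0) return(empty)

  # merge events whose gap is below merge_interval
  if (length(starts) > 1) {
    tm <- vel$time_ms
    merged_s <- starts[1]; merged_e <- ends[1]
    for (i in 2:length(starts)) {
      gap <- tm[starts[i]] - tm[merged_e[length(merged_e)]]
      if (gap < cfg$merge_interval) {
        merged_e[length(merged_e)] <- ends[i]
      } else {
        merged_s <- c(merged_s, starts[i])
        merged_e <- c(merged_e, ends[i])
      }
    }
    starts <- merged_s; ends <- merged_e
  }

  # drop events overlapping artifact-masked samples
  ok <- vapply(seq_along(starts), function(i)
    !any(vel$mask[starts[i]:ends[i]]), logical(1))
  starts <- starts[ok]; ends <- ends[ok]
  if (length(starts) == 0) return(empty)

  # boundary refinement: the offset-threshold crossing lies between the
  # last sub-threshold sample and the run, so extend one sample outward on
  # each side (ties toward the earlier sample -> conservative latency)
  bstarts <- pmax(starts - 1L, 1L)
  bends <- pmin(ends + 1L, n)
  ev <- data.frame(
    onset = vel$time_ms[bstarts],
    offset = vel$time_ms[bends],
    duration = vel$time_ms[bends] - vel$time_ms[bstarts],
    amplitude = vel$x_deg[bends] - vel$x_deg[bstarts],
    peak_velocity = vapply(seq_along(starts), function(i)
      max(speed[starts[i]:ends[i]]), numeric(1))
  )
  ev <- ev[ev$duration >= cfg$min_duration &
             abs(ev$amplitude) >= cfg$min_amplitude, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Extract the saccadic latency of one trial
#'
#' Saccadic latency is the delay from second-target onset to the onset of
#' the first detected saccade that goes toward the target: its sign must
#' match the target side and its unsigned amplitude must reach
#' `direction_fraction` of the target eccentricity (permissive, because
#' large gaze shifts carry head components the eye-only signal omits).
#' Latencies outside `[floor, ceiling]` are flagged invalid (anticipatory /
#' out-of-bounds); trials with no qualifying saccade are flagged
#' `none_found` or `wrong_direction`.
#'
#' @param events Saccade events from [detect_saccades()].
#' @param trial One-row trial event `data.frame` with `t2_onset`, `side`,
#'   and identifier columns (`subject`, `group`, `task`, `trial`).
#' @param floor,ceiling Validity bounds in ms (defaults 80 and 1000).
#' @param direction_fraction Minimum amplitude as a fraction of target
#'   eccentricity (default 0.2).
#' @param eccentricity Target eccentricity in degrees (default 55).
#'
#' @return A one-row latency-record `data.frame`: `subject`, `group`,
#'   `task`, `trial`, `latency` (ms, `NA` if none found), `valid`,
#'   `reason` (`"ok"`, `"none_found"`, `"wrong_direction"`,
#'   `"anticipatory"`, `"out_of_bounds"`).
#' @export
saccadic_latency <- function(events, trial, floor = 80, ceiling = 1000,
                             direction_fraction = 0.2,
                             eccentricity = 55) {
  if (is.null(trial$t2_onset) || is.na(trial$t2_onset))
    stop("trial must carry a second-target onset time", call. = FALSE)
  rec <- data.frame(
    subject = trial$subject,
    group = if (!is.null(trial$group)) trial$group else NA_character_,
    task = trial$task, trial = trial$trial,
    latency = NA_real_, valid = FALSE, reason = "none_found",
    stringsAsFactors = FALSE
  )
  after <- events[events$onset > trial$t2_onset, , drop = FALSE]
  if (nrow(after) == 0) return(rec)
  want_sign <- if (trial$side == "right") 1 else -1
  match_dir <- sign(after$amplitude) == want_sign &
    abs(after$amplitude) >= direction_fraction * eccentricity
  if (!any(match_dir)) {
    rec$reason <- "wrong_direction"
    return(rec)
  }
  first <- after[which(match_dir)[1], ]
  lat <- first$onset - trial$t2_onset
  rec$latency <- lat
  if (lat < floor) {
    rec$reason <- "anticipatory"
  } else if (lat > ceiling) {
    rec$reason <- "out_of_bounds"
  } else {
    rec$valid <- TRUE
    rec$reason <- "ok"
  }
  rec
}

#' Run preprocessing, detection and latency extraction over a cohort
#'
#' For every trial trace: preprocess ([preprocess_trace()]), detect
#' ([detect_saccades()]), and extract the latency ([saccadic_latency()]).
#'
#' @param cohort An `sl_cohort` simulated with `traces = TRUE`, or any list
#'   with `events` and a named `traces` list (`"subject_trial"` keys).
#' @param cfg A [detection_config()].
#' @param window,ceiling_velocity,guard_samples Preprocessing settings; see
#'   [preprocess_trace()].
#' @param floor,ceiling Latency validity bounds in ms.
#' @param direction_fraction See [saccadic_latency()].
#'
#' @return A latency-record `data.frame`, one row per trial.
#' @export
extract_latencies <- function(cohort, cfg = detection_config(),
                              window = 20, ceiling_velocity = 750,
                              guard_samples = 2, floor = 80,
                              ceiling = 1000, direction_fraction = 0.2) {
  if (is.null(cohort$traces))
    stop("cohort has no traces; simulate with traces = TRUE or use ",
         "truth_latency_records()", call. = FALSE)
  ecc <- cohort$config$geometry$target_eccentricity
  ev <- cohort$events
  out <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    key <- paste(ev$subject[i], ev$trial[i], sep = "_")
    tr <- cohort$traces[[key]]
    vt <- preprocess_trace(tr, window = window, ceiling = ceiling_velocity,
                           guard_samples = guard_samples)
    sac <- detect_saccades(vt, cfg)
    out[[i]] <- saccadic_latency(sac, ev[i, ], floor = floor,
                                 ceiling = ceiling,
                                 direction_fraction = direction_fraction,
                                 eccentricity = ecc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-subject quality-control summary of latency records
#'
#' Counts valid and invalid trials per subject, by invalidity reason. The
#' counts partition the records: they sum to the number of trials.
#'
#' @param records A latency-record `data.frame`.
#' @return A `data.frame` with one row per subject x reason (including
#'   `"ok"`), columns `subject`, `reason`, `n`.
#' @export
qc_summary <- function(records) {
  tab <- as.data.frame(table(subject = records$subject,
                             reason = records$reason),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[order(tab$subject, tab$reason), ]
  rownames(tab) <- NULL
  tab
}
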