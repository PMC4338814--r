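#' Construct a gaze trace
#'
#' A gaze trace holds time-stamped horizontal/vertical eye positions in
#' degrees of visual angle on a strictly uniform time grid, plus sampling
#' metadata. This is the raw signal every downstream stage consumes.
#'
#' @param time_ms Sample times in ms; strictly increasing, uniformly spaced
#'   at `1000 / sampling_rate`.
#' @param x_deg,y_deg Horizontal / vertical eye position in degrees.
#' @param sampling_rate Sampling rate in Hz.
#' @param subject,trial Optional identifiers carried as attributes.
#'
#' @return A `data.frame` of class `gaze_trace` with columns `time_ms`,
#'   `x_deg`, `y_deg` and attributes `sampling_rate`, `subject`, `trial`.
#' @export
gaze_trace <- function(time_ms, x_deg, y_deg = rep(0, length(time_ms)),
                       sampling_rate, subject = NA_character_,
                       trial = NA_integer_) {
  n <- length(time_ms)
  stopifnot(length(x_deg) == n, length(y_deg) == n, n >= 1)
  if (sampling_rate <= 0)
    stop("`sampling_rate` must be positive", call. = FALSE)
  if (n > 1) {
    dt <- diff(time_ms)
    if (any(dt <= 0))
      stop("`time_ms` must be strictly increasing", call. = FALSE)
    step <- 1000 / sampling_rate
    if (any(abs(dt - step) > 1e-6 * step))
      stop("`time_ms` must be uniformly spaced at 1000/sampling_rate ms",
           call. = FALSE)
  }
  structure(
    data.frame(time_ms = time_ms, x_deg = x_deg, y_deg = y_deg),
    sampling_rate = sampling_rate, subject = subject, trial = trial,
    class = c("gaze_trace", "data.frame")
  )
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> %d samples @ %g Hz (subject %s, trial %s)\n",
              nrow(x), attr(x, "sampling_rate"),
              attr(x, "subject"), attr(x, "trial")))
  invisible(x)
}

# Moving average with shrinking windows at the edges; NA samples are
# excluded from the local mean (positions masked as artifacts upstream do
# not leak into their neighbours). Even windows extend one sample further
# forward than backward (the stats::filter convention).
moving_average <- function(x, n_samples) {
  n <- length(x)
  k <- as.integer(n_samples)
  if (k <= 1) return(x)
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  good <- !is.na(x)
  xz <- ifelse(good, x, 0)
  cs <- c(0, cumsum(xz))
  cn <- c(0, cumsum(as.numeric(good)))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- ifelse(cnt > 0, tot / cnt, NA_real_)
  out
}

#' Smooth a gaze trace with a centred moving average
#'
#' Applies a moving average of the given temporal width to both position
#' channels. A 20 ms window at 200 Hz spans 4 samples. Edges use shrinking
#' windows so no samples are trimmed near target onset; missing (masked)
#' samples are excluded from the local mean.
#'
#' @param trace A [gaze_trace()].
#' @param window Window width in ms; default 20 ms. A window shorter than
#'   one sample period returns the trace unchanged with a warning.
#'
#' @return A smoothed `gaze_trace`.
#' @export
smooth_trace <- function(trace, window = 20) {
  fs <- attr(trace, "sampling_rate")
  n_samples <- round(window * fs / 1000)
  if (n_samples < 1) {
    warning("smoothing window shorter than one sample period; trace unchanged")
    return(trace)
  }
  trace$x_deg <- moving_average(trace$x_deg, n_samples)
  trace$y_deg <- moving_average(trace$y_deg, n_samples)
  trace
}

#' Compute the eye-speed signal of a gaze trace
#'
#' Horizontal eye speed (deg/s) from central differences of the horizontal
#' position channel; the endpoints use one-sided differences. Targets in the
#' two-task paradigm are horizontal, so latency is defined on horizontal
#' gaze shifts and only the horizontal channel enters detection.
#'
#' @param trace A [gaze_trace()] with at least 3 samples.
#' @return A `data.frame` of class `velocity_trace` with columns `time_ms`,
#'   `x_deg` (the position the speed was derived from), `speed` (deg/s,
#'   non-negative) and `mask` (logical artifact flag, all `FALSE` here).
#' @export
velocity <- function(trace) {
  if (!inherits(trace, "gaze_trace"))
    stop("`trace` must be a gaze_trace", call. = FALSE)
  n <- nrow(trace)
  if (n < 3) stop("velocity needs at least 3 samples", call. = FALSE)
  fs <- attr(trace, "sampling_rate")
  dt <- 1 / fs                       # seconds per sample
  x <- trace$x_deg
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  mid <- 2:(n - 1)
  v[mid] <- (x[mid + 1] - x[mid - 1]) / (2 * dt)
  speed <- abs(v)
  mask <- is.na(speed)
  speed[mask] <- 0
  structure(
    data.frame(time_ms = trace$time_ms, x_deg = x, speed = speed,
               mask = mask),
    sampling_rate = fs, subject = attr(trace, "subject"),
    trial = attr(trace, "trial"),
    class = c("velocity_trace", "data.frame")
  )
}

#' Mask physiologically implausible velocity samples
#'
#' Samples whose speed exceeds the ceiling (default 750 deg/s, above human
#' saccadic peak velocities) are flagged as artifacts, together with a guard
#' margin of neighbouring samples, so blink spikes and tracker glitches are
#' excluded from saccade detection. Masked samples keep their values; the
#' `mask` column marks them and detection drops events that overlap it.
#'
#' @param vel A `velocity_trace` from [velocity()].
#' @param ceiling Artifact ceiling in deg/s; must be positive.
#' @param guard_samples Number of neighbouring samples masked on each side
#'   of an over-ceiling sample.
#'
#' @return The `velocity_trace` with an updated `mask` column.
#' @export
artifact_filter <- function(vel, ceiling = 750, guard_samples = 2) {
  if (ceiling <= 0) stop("`ceiling` must be positive", call. = FALSE)
  hit <- vel$speed > ceiling
  mask <- hit
  if (guard_samples > 0 && any(hit)) {
    n <- length(hit)
    for (g in seq_len(guard_samples)) {
      mask <- mask | c(rep(FALSE, g), hit[seq_len(n - g)]) |
        c(hit[-seq_len(g)], rep(FALSE, g))
    }
  }
  vel$mask <- vel$mask | mask
  vel
}

#' Preprocess a gaze trace into a detection-ready velocity signal
#'
#' Fixed pipeline: visual-angle positions in, artifact masking of
#' over-ceiling raw velocities (so spikes do not leak into neighbouring
#' samples through the smoother), moving-average smoothing, then the speed
#' signal by central differences. This order is logged in the returned
#' object's `"pipeline"` attribute so it can be audited.
#'
#' @param trace A [gaze_trace()] (positions already in degrees).
#' @param window Smoothing window in ms (default 20).
#' @param ceiling Artifact velocity ceiling in deg/s (default 750).
#' @param guard_samples Guard margin around artifact samples (default 2).
#'
#' @return A `velocity_trace` with artifact mask, ready for
#'   [detect_saccades()].
#' @export
#' @examples
#' seg <- simulate_saccade_segment(20)
#' tr <- gaze_trace(seg$time_ms, seg$x_deg, sampling_rate = 200)
#' vt <- preprocess_trace(tr)
#' max(vt$speed)
preprocess_trace <- function(trace, window = 20, ceiling = 750,
                             guard_samples = 2) {
  raw_vel <- velocity(trace)
  raw_vel <- artifact_filter(raw_vel, ceiling = ceiling,
                             guard_samples = guard_samples)
  x <- trace$x_deg
  x[raw_vel$mask] <- NA_real_
  masked_trace <- trace
  masked_trace$x_deg <- x
  sm <- smooth_trace(masked_trace, window = window)
  vt <- velocity(sm)
  vt$mask <- vt$mask | raw_vel$mask
  attr(vt, "pipeline") <-
    c("visual_angle", "artifact_filter", "smooth", "velocity")
  vt
}
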