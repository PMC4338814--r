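#' Main-sequence kinematic parameters
#'
#' Saccade kinematics for the simulator follow the oculomotor main sequence:
#' duration grows linearly with amplitude, and peak velocity is a
#' saturating, increasing function of amplitude. The velocity profile is a
#' raised cosine (smooth, unimodal, integrable in closed form), whose peak
#' for a saccade of amplitude A and duration D is `2 A / D`. The linear
#' duration law is therefore capped from below by the saturating
#' peak-velocity law `vmax(A) = vmax_asymptote * (1 - exp(-A /
#' vmax_angular_constant))`: `D(A) = max(slope * A + intercept, 2 A /
#' vmax(A))`.
#'
#' Defaults (2.5 ms/deg slope, 25 ms intercept, 700 deg/s asymptote, 14 deg
#' angular constant) are standard oculomotor values chosen so that even the
#' 55-degree target saccade peaks below the 750 deg/s artifact ceiling used
#' in preprocessing (55 deg -> 162.5 ms, ~677 deg/s).
#'
#' @param duration_slope ms of duration per degree of amplitude.
#' @param duration_intercept Duration intercept in ms.
#' @param vmax_asymptote Asymptotic peak velocity in deg/s.
#' @param vmax_angular_constant Angular constant of the saturating
#'   peak-velocity law, in degrees.
#'
#' @return An object of class `main_sequence_params`.
#' @export
main_sequence_params <- function(duration_slope = 2.5,
                                 duration_intercept = 25,
                                 vmax_asymptote = 700,
                                 vmax_angular_constant = 14) {
  vals <- c(duration_slope, duration_intercept, vmax_asymptote,
            vmax_angular_constant)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all main-sequence parameters must be positive", call. = FALSE)
  structure(
    list(duration_slope = duration_slope,
         duration_intercept = duration_intercept,
         vmax_asymptote = vmax_asymptote,
         vmax_angular_constant = vmax_angular_constant),
    class = "main_sequence_params"
  )
}

#' Saccade duration and peak velocity from the main sequence
#'
#' @param amplitude Saccade amplitude(s) in degrees (unsigned).
#' @param params A [main_sequence_params()].
#' @return `saccade_duration`: duration in ms. `saccade_peak_velocity`:
#'   peak velocity in deg/s (0 for zero amplitude).
#' @export
saccade_duration <- function(amplitude, params = main_sequence_params()) {
  stopifnot(all(amplitude >= 0))
  d_lin <- params$duration_slope * amplitude + params$duration_intercept
  vmax <- params$vmax_asymptote *
    (1 - exp(-amplitude / params$vmax_angular_constant))
  d_cap <- ifelse(amplitude > 0, 2 * amplitude / vmax * 1000, d_lin)
  pmax(d_lin, d_cap)
}

#' @rdname saccade_duration
#' @export
saccade_peak_velocity <- function(amplitude,
                                  params = main_sequence_params()) {
  d <- saccade_duration(amplitude, params) / 1000
  ifelse(amplitude > 0, 2 * amplitude / d, 0)
}

# Closed-form raised-cosine displacement: fraction of amplitude covered
# after fraction u in [0,1] of the saccade duration.
raised_cosine_progress <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u - sin(2 * pi * u) / (2 * pi)
}

#' Simulate one saccade segment
#'
#' Samples position and velocity of a single saccade of the given amplitude
#' on a uniform grid. The velocity profile is a raised cosine
#' `v(t) = Vp/2 * (1 - cos(2 pi t / D))`, so position moves monotonically
#' from 0 to the signed amplitude and velocity starts and ends at zero with
#' a single peak `Vp = 2|A|/D` at mid-flight.
#'
#' @param amplitude Signed amplitude in degrees; `0` yields a single
#'   all-zero sample.
#' @param params A [main_sequence_params()].
#' @param sampling_rate Sampling rate in Hz; must be positive.
#'
#' @return A `data.frame` with columns `time_ms`, `x_deg`, `v_deg_s` and
#'   attributes `duration_ms`, `peak_velocity`.
#' @export
#' @examples
#' seg <- simulate_saccade_segment(55)
#' attr(seg, "duration_ms")      # 162.5
#' attr(seg, "peak_velocity")    # ~677 deg/s
simulate_saccade_segment <- function(amplitude,
                                     params = main_sequence_params(),
                                     sampling_rate = 200) {
  if (sampling_rate <= 0)
    stop("`sampling_rate` must be positive", call. = FALSE)
  a_abs <- abs(amplitude)
  if (a_abs == 0) {
    out <- data.frame(time_ms = 0, x_deg = 0, v_deg_s = 0)
    attr(out, "duration_ms") <- 0
    attr(out, "peak_velocity") <- 0
    return(out)
  }
  dur <- saccade_duration(a_abs, params)
  vp <- 2 * a_abs / (dur / 1000)
  step <- 1000 / sampling_rate
  t <- seq(0, dur + step - 1e-9, by = step)   # cover the full flight
  u <- pmin(t / dur, 1)
  x <- sign(amplitude) * a_abs * raised_cosine_progress(u)
  v <- sign(amplitude) * vp / 2 * (1 - cos(2 * pi * u))
  v[u >= 1] <- 0
  out <- data.frame(time_ms = t, x_deg = x, v_deg_s = v)
  attr(out, "duration_ms") <- dur
  attr(out, "peak_velocity") <- vp
  out
}
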