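#' Screen/tracker geometry configuration
#'
#' Describes the physical recording setup: viewing distance, target size and
#' eccentricity, and the vertical offset of the eye relative to the screen
#' centre. Defaults match a head-mounted video-oculography setup with
#' peripheral targets at 55 degrees and an 80 cm viewing distance.
#'
#' @param viewing_distance Viewing distance in cm. Must be positive.
#' @param target_size Target edge length in cm (square targets).
#' @param target_eccentricity Horizontal eccentricity of peripheral targets
#'   in degrees of visual angle; must lie in (0, 90).
#' @param eye_height_offset Vertical offset of the eye relative to the
#'   central target, in cm.
#'
#' @return An object of class `geometry_config`.
#' @export
#' @examples
#' geo <- geometry_config()
#' geo$target_eccentricity
geometry_config <- function(viewing_distance = 80,
                            target_size = 6,
                            target_eccentricity = 55,
                            eye_height_offset = 0) {
  stopifnot(is.numeric(viewing_distance), length(viewing_distance) == 1)
  if (viewing_distance <= 0)
    stop("`viewing_distance` must be positive", call. = FALSE)
  if (target_eccentricity <= 0 || target_eccentricity >= 90)
    stop("`target_eccentricity` must lie in (0, 90) degrees", call. = FALSE)
  structure(
    list(viewing_distance = viewing_distance,
         target_size = target_size,
         target_eccentricity = target_eccentricity,
         eye_height_offset = eye_height_offset),
    class = "geometry_config"
  )
}

#' Convert an on-screen offset to visual angle
#'
#' Transforms a linear offset on the stimulus plane into degrees of visual
#' angle via `atan(offset / distance)`. The transform is odd:
#' `to_visual_angle(-x, d) == -to_visual_angle(x, d)`.
#'
#' @param offset_cm On-screen offset(s) from the line of sight, in cm.
#' @param viewing_distance Viewing distance in cm; must be positive.
#'
#' @return Visual angle(s) in degrees, same length as `offset_cm`.
#' @export
#' @examples
#' to_visual_angle(0, 80)              # 0
#' to_visual_angle(80, 80)             # 45
#' 2 * to_visual_angle(3, 80)          # ~4.3, a 6 cm target at 80 cm
to_visual_angle <- function(offset_cm, viewing_distance) {
  if (!is.numeric(viewing_distance) || length(viewing_distance) != 1 ||
      viewing_distance <= 0)
    stop("`viewing_distance` must be a positive scalar", call. = FALSE)
  atan(offset_cm / viewing_distance) * 180 / pi
}

#' Angular size subtended by a target
#'
#' Full visual angle of an object of the given linear size centred on the
#' line of sight: `2 * atan(size/2 / distance)`.
#'
#' @inheritParams to_visual_angle
#' @param size_cm Linear size of the object in cm.
#' @return Angle in degrees.
#' @export
target_visual_angle <- function(size_cm, viewing_distance) {
  2 * to_visual_angle(size_cm / 2, viewing_distance)
}
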