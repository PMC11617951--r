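#' Flight-mill geometry
#'
#' Describes the rotating arm and the sectored coding wheel read by the
#' dual-channel photointerrupter. Each opaque/transparent edge produces one
#' timestamped transition, so a wheel with eight opaque sectors yields 16
#' transitions per full rotation of the 90 mm arm.
#'
#' @param arm_radius Arm radius in metres. Default 0.09.
#' @param transitions_per_rotation Number of sensor transitions per full
#'   rotation. Must be an even integer of at least 2 (opaque/transparent
#'   sectors come in pairs). Default 16.
#' @return An object of class `mill_geometry` with fields `arm_radius`,
#'   `transitions_per_rotation` and the derived `distance_per_transition`.
#' @examples
#' g <- mill_geometry()
#' distance_per_transition(g)  # 0.03534292 m, displayed rounded as 0.035
#' @export
mill_geometry <- function(arm_radius = 0.09, transitions_per_rotation = 16L) {
  if (!is.numeric(arm_radius) || length(arm_radius) != 1L || !is.finite(arm_radius) ||
      arm_radius <= 0) {
    stop("invalid geometry: arm_radius must be a positive number", call. = FALSE)
  }
  n <- transitions_per_rotation
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 || n != round(n) ||
      (n %% 2) != 0) {
    stop("invalid geometry: transitions_per_rotation must be an even integer >= 2",
         call. = FALSE)
  }
  structure(
    list(
      arm_radius = as.numeric(arm_radius),
      transitions_per_rotation = as.integer(n),
      distance_per_transition = 2 * pi * arm_radius / n
    ),
    class = "mill_geometry"
  )
}

#' Arc distance represented by one sensor transition
#'
#' The distance travelled by the tethered insect between two consecutive
#' transitions: one sector edge of the coding wheel, i.e.
#' `2 * pi * arm_radius / transitions_per_rotation`. With the default geometry
#' this is 0.0353 m, so a count of transitions in one second converts directly
#' to a speed in m/s (72 transitions/s = 2.54 m/s).
#'
#' @param geometry A [mill_geometry()].
#' @return Distance in metres.
#' @export
distance_per_transition <- function(geometry = mill_geometry()) {
  stopifnot(inherits(geometry, "mill_geometry"))
  geometry$distance_per_transition
}

#' @export
print.mill_geometry <- function(x, ...) {
  cat(sprintf(
    "<mill_geometry> arm radius %.3f m, %d transitions/rotation (%.6f m each)\n",
    x$arm_radius, x$transitions_per_rotation, x$distance_per_transition
  ))
  invisible(x)
}
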