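#' Specify a circular visual target
#'
#' Describes a circular high-contrast disk as presented to the modeled eye:
#' its diameter, whether it stands vertically (facing the eye) or lies
#' horizontally on the floor, the horizontal distance from the eye to the
#' target center, and -- for horizontal targets -- the altitude of the eye
#' above the target plane.
#'
#' Distances are measured horizontally from the eye to the target center for
#' both orientations. For a horizontal target the eye looks obliquely down at
#' the disk from `altitude_cm` (default 15 cm, a typical low flight height),
#' which foreshortens its angular image; for a vertical target the disk is
#' centered on a horizontal gaze axis.
#'
#' @param diameter_cm Target disk diameter in cm.
#' @param orientation `"vertical"` or `"horizontal"`.
#' @param distance_cm Horizontal eye-to-center distance in cm. May be `NULL`
#'   when the spec is used as a template for [detection_distance()].
#' @param altitude_cm Eye height above the target plane in cm; used only for
#'   horizontal targets. Default 15.
#' @return An object of class `target_spec`.
#' @examples
#' target_spec(30, "vertical", distance_cm = 50)
#' target_spec(15, "horizontal", distance_cm = 25, altitude_cm = 15)
#' @export
target_spec <- function(diameter_cm,
                        orientation = c("vertical", "horizontal"),
                        distance_cm = NULL,
                        altitude_cm = 15) {
  orientation <- match.arg(orientation)
  if (!is.numeric(diameter_cm) || length(diameter_cm) != 1L ||
      !is.finite(diameter_cm) || diameter_cm <= 0) {
    stop("invalid target: 'diameter_cm' must be a positive number",
         call. = FALSE)
  }
  if (!is.null(distance_cm) &&
      (!is.numeric(distance_cm) || length(distance_cm) != 1L ||
       !is.finite(distance_cm) || distance_cm <= 0)) {
    stop("invalid target: 'distance_cm' must be a positive number or NULL",
         call. = FALSE)
  }
  if (orientation == "horizontal" &&
      (!is.numeric(altitude_cm) || length(altitude_cm) != 1L ||
       !is.finite(altitude_cm) || altitude_cm <= 0)) {
    stop("invalid target: 'altitude_cm' must be positive for horizontal targets",
         call. = FALSE)
  }
  structure(
    list(
      diameter_cm = diameter_cm,
      orientation = orientation,
      distance_cm = distance_cm,
      altitude_cm = if (orientation == "horizontal") altitude_cm else NA_real_
    ),
    class = "target_spec"
  )
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("Circular target: %g cm diameter, %s", x$diameter_cm,
              x$orientation))
  if (!is.null(x$distance_cm)) cat(sprintf(", %g cm away", x$distance_cm))
  if (x$orientation == "horizontal") {
    cat(sprintf(", eye altitude %g cm", x$altitude_cm))
  }
  cat("\n")
  invisible(x)
}
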