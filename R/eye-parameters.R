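#' Angular geometry and thresholds of the modeled eye patch
#'
#' Bundles the parameters of the ommatidial eye model: the hexagonal lattice of
#' ommatidial viewing axes, the angular width of each receptive field, the
#' stimulation thresholds that define detection, and the resolution of the
#' distance sweep and polygon discretization.
#'
#' The modeled eye is a patch of `1 + sum(6 * (1:n_rings))` ommatidia (37 with
#' the default three rings) whose viewing axes form a hexagonal lattice with
#' nearest-neighbor angular spacing `interommatidial_angle_deg`, centered on
#' the gaze direction. Each ommatidium responds to the fraction of its circular
#' receptive field (full width `receptive_field_deg`) covered by the target's
#' angular image.
#'
#' Two summation rules are available for the total eye stimulation that
#' defines detection:
#' \describe{
#'   \item{`"excess"` (default)}{each ommatidium whose stimulation meets
#'     `individual_threshold_pct` contributes its stimulation *in excess* of
#'     that threshold; detection when the summed excess reaches
#'     `total_threshold_pct`. With the default parameters this rule reproduces
#'     detection distances of roughly 72/36 cm for 30/15 cm vertical disks and
#'     42/24 cm for the same disks lying on the floor viewed from 15 cm
#'     altitude.}
#'   \item{`"sum"`}{each supra-threshold ommatidium contributes its full
#'     stimulation percentage. This is the naive reading of
#'     threshold-then-sum; it yields systematically larger detection
#'     distances.}
#' }
#'
#' @param interommatidial_angle_deg Angular spacing between adjacent
#'   ommatidial axes, degrees. Default 8.
#' @param receptive_field_deg Full angular width of one ommatidium's circular
#'   receptive field, degrees. Default 40 (radius 20 degrees).
#' @param n_rings Number of hexagonal rings around the central axis. Default 3,
#'   giving 37 ommatidia.
#' @param individual_threshold_pct Minimum stimulation (percent of receptive
#'   field area) for an ommatidium to count toward the total. Default 20.
#' @param total_threshold_pct Total stimulation required for detection,
#'   percentage points. Default 100.
#' @param polygon_resolution Number of vertices used to discretize circles and
#'   target outlines. Default 360.
#' @param scan_step_cm Distance-sweep resolution in cm. Default 1.
#' @param scan_max_cm Upper bound of the distance sweep in cm. Default 500.
#' @param summation_rule `"excess"` or `"sum"`; see Details.
#'
#' @return An object of class `eye_parameters`.
#' @seealso [ommatidial_array()], [detection_distance()]
#' @examples
#' eye_parameters()
#' eye_parameters(n_rings = 1, receptive_field_deg = 30)
#' @export
eye_parameters <- function(interommatidial_angle_deg = 8,
                           receptive_field_deg = 40,
                           n_rings = 3,
                           individual_threshold_pct = 20,
                           total_threshold_pct = 100,
                           polygon_resolution = 360,
                           scan_step_cm = 1,
                           scan_max_cm = 500,
                           summation_rule = c("excess", "sum")) {
  summation_rule <- match.arg(summation_rule)
  check_positive <- function(value, field) {
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
        value <= 0) {
      stop("invalid eye parameter '", field, "': must be a positive number",
           call. = FALSE)
    }
  }
  check_positive(interommatidial_angle_deg, "interommatidial_angle_deg")
  check_positive(receptive_field_deg, "receptive_field_deg")
  check_positive(total_threshold_pct, "total_threshold_pct")
  check_positive(scan_step_cm, "scan_step_cm")
  check_positive(scan_max_cm, "scan_max_cm")
  if (!is.numeric(n_rings) || length(n_rings) != 1L || n_rings < 0 ||
      n_rings != round(n_rings)) {
    stop("invalid eye parameter 'n_rings': must be a non-negative integer",
         call. = FALSE)
  }
  if (!is.numeric(individual_threshold_pct) ||
      length(individual_threshold_pct) != 1L ||
      individual_threshold_pct < 0 || individual_threshold_pct > 100) {
    stop("invalid eye parameter 'individual_threshold_pct': must lie in [0, 100]",
         call. = FALSE)
  }
  if (!is.numeric(polygon_resolution) || length(polygon_resolution) != 1L ||
      polygon_resolution < 16 ||
      polygon_resolution != round(polygon_resolution)) {
    stop("invalid eye parameter 'polygon_resolution': must be an integer >= 16",
         call. = FALSE)
  }
  structure(
    list(
      interommatidial_angle_deg = interommatidial_angle_deg,
      receptive_field_deg = receptive_field_deg,
      n_rings = as.integer(n_rings),
      individual_threshold_pct = individual_threshold_pct,
      total_threshold_pct = total_threshold_pct,
      polygon_resolution = as.integer(polygon_resolution),
      scan_step_cm = scan_step_cm,
      scan_max_cm = scan_max_cm,
      summation_rule = summation_rule
    ),
    class = "eye_parameters"
  )
}

#' @export
print.eye_parameters <- function(x, ...) {
  n_omm <- 1L + if (x$n_rings > 0) sum(6L * seq_len(x$n_rings)) else 0L
  cat("Ommatidial eye parameters\n")
  cat(sprintf("  lattice: %d rings (%d ommatidia), spacing %g deg\n",
              x$n_rings, n_omm, x$interommatidial_angle_deg))
  cat(sprintf("  receptive field: %g deg full width\n", x$receptive_field_deg))
  cat(sprintf("  thresholds: individual %g%%, total %g (rule: %s)\n",
              x$individual_threshold_pct, x$total_threshold_pct,
              x$summation_rule))
  cat(sprintf("  sweep: %g to %g cm by %g cm, polygons at %d vertices\n",
              x$scan_step_cm, x$scan_max_cm, x$scan_step_cm,
              x$polygon_resolution))
  invisible(x)
}

#' Hexagonal lattice of ommatidial viewing axes
#'
#' Builds the viewing-axis offsets of the modeled eye patch: a central axis at
#' the gaze direction plus `n_rings` concentric hexagonal rings with
#' nearest-neighbor angular spacing equal to the interommatidial angle. Ring
#' `k` holds `6 * k` axes, so the default three rings give 37 ommatidia with
#' ring populations 1, 6, 12, 18.
#'
#' Offsets are expressed in the gaze-centered tangent plane used throughout
#' the eye model (azimuthal-equidistant: angular distances from the gaze axis
#' are preserved), in degrees.
#'
#' @param params An [eye_parameters()] object.
#' @return A data frame of class `ommatidial_array` with columns `index`,
#'   `ring`, `x_deg`, `y_deg`.
#' @examples
#' axes <- ommatidial_array(eye_parameters())
#' nrow(axes)          # 37
#' table(axes$ring)    # 1 6 12 18
#' @export
ommatidial_array <- function(params = eye_parameters()) {
  stopifnot(inherits(params, "eye_parameters"))
  spacing <- params$interommatidial_angle_deg
  dirs <- rbind(cos((0:5) * pi / 3), sin((0:5) * pi / 3))
  xs <- 0
  ys <- 0
  rings <- 0L
  if (params$n_rings > 0) {
    for (k in seq_len(params$n_rings)) {
      for (i in 0:5) {
        corner <- k * spacing * dirs[, i + 1L]
        step <- spacing * dirs[, ((i + 2L) %% 6L) + 1L]
        j <- 0:(k - 1L)
        xs <- c(xs, corner[1L] + j * step[1L])
        ys <- c(ys, corner[2L] + j * step[2L])
        rings <- c(rings, rep(k, k))
      }
    }
  }
  out <- data.frame(
    index = seq_along(xs),
    ring = as.integer(rings),
    x_deg = xs,
    y_deg = ys
  )
  class(out) <- c("ommatidial_array", "data.frame")
  out
}
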