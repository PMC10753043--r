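#' Project a target into gaze-centered angular coordinates
#'
#' Computes the angular image of a circular target as seen by an eye gazing at
#' the target center. The image is the outline of the disk mapped through an
#' azimuthal-equidistant projection about the gaze direction: each boundary
#' direction is placed at its true angular distance from the gaze axis, along
#' its true bearing in the plane orthogonal to the gaze. Angular distances from
#' the gaze axis are therefore exact, and receptive-field overlaps can be
#' computed as planar polygon areas in degree units.
#'
#' A vertical disk centered on the gaze axis maps to a circle of angular
#' radius `atan(radius / distance)`. A horizontal (floor-lying) disk viewed
#' from above is foreshortened into a vertically compressed, egg-shaped
#' outline -- the optical distortion of oblique viewing. The image's `y`
#' axis is the projection of "up" (for horizontal targets the gaze is
#' depressed by `atan(altitude / distance)` below the horizon; the image is
#' centered near, not exactly at, the gaze axis because the disk center and
#' the image centroid do not coincide under perspective).
#'
#' @param target A [target_spec()] with a non-`NULL` `distance_cm`.
#' @param params An [eye_parameters()] object; only `polygon_resolution` is
#'   used here.
#' @return An object of class `angular_image`: a list with `outline` (data
#'   frame of `x_deg`, `y_deg` vertices, `polygon_resolution` rows) and
#'   `source` (the target).
#' @examples
#' img <- project_target(target_spec(30, "vertical", distance_cm = 15))
#' range(sqrt(img$outline$x_deg^2 + img$outline$y_deg^2))  # 45 degrees
#' @export
project_target <- function(target, params = eye_parameters()) {
  stopifnot(inherits(target, "target_spec"), inherits(params, "eye_parameters"))
  if (is.null(target$distance_cm)) {
    stop("target has no 'distance_cm'; supply one or use detection_distance()",
         call. = FALSE)
  }
  r <- target$diameter_cm / 2
  d <- target$distance_cm
  n <- params$polygon_resolution
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]

  # World frame: x forward (toward target), y lateral, z vertical; eye at origin.
  if (target$orientation == "vertical") {
    pts <- cbind(d, r * cos(t), r * sin(t))
    gaze <- c(1, 0, 0)
  } else {
    h <- target$altitude_cm
    if (d < r) {
      stop("degenerate geometry: eye lies over the horizontal target disk ",
           "(distance ", d, " cm < radius ", r, " cm)", call. = FALSE)
    }
    pts <- cbind(d + r * cos(t), r * sin(t), -h)
    gaze <- c(d, 0, -h)
    gaze <- gaze / sqrt(sum(gaze^2))
  }
  dirs <- pts / sqrt(rowSums(pts^2))

  # Gaze-centered basis: "up" is vertical projected off the gaze axis.
  up <- c(0, 0, 1) - gaze[3L] * gaze
  up <- up / sqrt(sum(up^2))
  right <- c(gaze[2L] * up[3L] - gaze[3L] * up[2L],
             gaze[3L] * up[1L] - gaze[1L] * up[3L],
             gaze[1L] * up[2L] - gaze[2L] * up[1L])

  ang <- acos(pmin(1, pmax(-1, dirs %*% gaze))) * 180 / pi
  px <- dirs %*% right
  py <- dirs %*% up
  nrm <- sqrt(px^2 + py^2)
  nrm[nrm < 1e-12] <- 1  # boundary point on the gaze axis maps to the origin

  structure(
    list(
      outline = data.frame(
        x_deg = as.vector(ang * px / nrm),
        y_deg = as.vector(ang * py / nrm)
      ),
      source = target
    ),
    class = "angular_image"
  )
}

#' @export
print.angular_image <- function(x, ...) {
  a <- polygon_area(list(x = x$outline$x_deg, y = x$outline$y_deg))
  cat(sprintf(
    "Angular image: %d-vertex outline, area %.2f deg^2, extent x [%.2f, %.2f], y [%.2f, %.2f] deg\n",
    nrow(x$outline), a, min(x$outline$x_deg), max(x$outline$x_deg),
    min(x$outline$y_deg), max(x$outline$y_deg)))
  invisible(x)
}
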