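#' Stimulation of a single ommatidium by an angular image
#'
#' Fraction (percent) of one ommatidium's receptive field covered by the
#' target's angular image. The receptive field is a disk of radius
#' `receptive_field_deg / 2` centered on the ommatidial axis offset; the
#' overlap is computed by polygon clipping at `polygon_resolution` vertices,
#' with exact fast paths when the image is certainly contained in or disjoint
#' from the receptive field (bounding-circle tests).
#'
#' @param image An [project_target()] result (or any `angular_image`).
#' @param axis A single ommatidial axis: any list/row with `x_deg`, `y_deg`.
#' @param params An [eye_parameters()] object.
#' @return Stimulation percentage in `[0, 100]`. A degenerate (zero-area)
#'   image yields 0.
#' @examples
#' img <- project_target(target_spec(30, "vertical", distance_cm = 100))
#' ommatidium_stimulation(img, list(x_deg = 0, y_deg = 0))
#' @export
ommatidium_stimulation <- function(image, axis, params = eye_parameters()) {
  stopifnot(inherits(image, "angular_image"))
  poly <- list(x = image$outline$x_deg, y = image$outline$y_deg)
  stimulation_pct(poly, axis$x_deg, axis$y_deg,
                  params$receptive_field_deg / 2, params$polygon_resolution)
}

# poly: list(x, y); overlap of poly with the RF disk at (ax, ay), as % of disk.
stimulation_pct <- function(poly, ax, ay, rf_radius, resolution) {
  if (length(poly$x) < 3L) return(0)
  rf_area <- pi * rf_radius^2
  dist2 <- (poly$x - ax)^2 + (poly$y - ay)^2
  # Image polygon inside the RF disk: the disk is convex, so vertex containment
  # suffices; the polygon's area is the exact overlap (no discretized disk).
  if (max(dist2) <= rf_radius^2) {
    return(min(100, 100 * polygon_area(poly) / rf_area))
  }
  # Certainly disjoint: image lies inside the circle about its centroid through
  # its farthest vertex; if that circle misses the RF disk, overlap is 0.
  cc <- polygon_centroid_radius(poly)
  if (sqrt((cc$cx - ax)^2 + (cc$cy - ay)^2) > cc$r + rf_radius) return(0)
  rf_poly <- circle_polygon(ax, ay, rf_radius, resolution)
  overlap <- polygon_intersection_area(poly, rf_poly)
  # Normalize by the discretized disk so full coverage reports exactly 100.
  min(100, 100 * overlap / polygon_area(rf_poly))
}

#' Whole-eye stimulation map and detection verdict
#'
#' Evaluates every ommatidium of the eye patch against a target's angular
#' image and applies the detection rule: ommatidia stimulated at or above
#' `individual_threshold_pct` contribute to the total (their excess over the
#' threshold under the default `"excess"` rule, their full stimulation under
#' `"sum"`); the target is detected when the total reaches
#' `total_threshold_pct`.
#'
#' @param image An `angular_image`.
#' @param eye An [ommatidial_array()]; defaults to the array implied by
#'   `params`.
#' @param params An [eye_parameters()] object.
#' @return An object of class `stimulation_map`: list with
#'   `per_ommatidium_pct` (one value per ommatidium), `total_pct`, `detected`,
#'   and the inputs' metadata.
#' @examples
#' img <- project_target(target_spec(30, "vertical", distance_cm = 50))
#' eye_stimulation(img)
#' @export
eye_stimulation <- function(image, eye = NULL, params = eye_parameters()) {
  stopifnot(inherits(image, "angular_image"))
  if (is.null(eye)) eye <- ommatidial_array(params)
  if (nrow(eye) == 0L) stop("eye array is empty", call. = FALSE)
  poly <- list(x = image$outline$x_deg, y = image$outline$y_deg)
  rf_radius <- params$receptive_field_deg / 2
  s <- vapply(
    seq_len(nrow(eye)),
    function(i) stimulation_pct(poly, eye$x_deg[i], eye$y_deg[i], rf_radius,
                                params$polygon_resolution),
    numeric(1)
  )
  new_stimulation_map(s, params, image$source)
}

new_stimulation_map <- function(per_pct, params, source = NULL) {
  eps <- 1e-9  # inclusive thresholds, stable under floating point
  above <- per_pct >= params$individual_threshold_pct - eps
  total <- if (params$summation_rule == "excess") {
    sum(per_pct[above] - params$individual_threshold_pct)
  } else {
    sum(per_pct[above])
  }
  structure(
    list(
      per_ommatidium_pct = per_pct,
      total_pct = total,
      detected = total >= params$total_threshold_pct - eps,
      params = params,
      source = source
    ),
    class = "stimulation_map"
  )
}

#' @export
print.stimulation_map <- function(x, ...) {
  cat(sprintf(
    "Stimulation map: %d ommatidia, %d above %g%%, total %.1f (%s rule) -> %s\n",
    length(x$per_ommatidium_pct),
    sum(x$per_ommatidium_pct >= x$params$individual_threshold_pct - 1e-9),
    x$params$individual_threshold_pct, x$total_pct, x$params$summation_rule,
    if (x$detected) "detected" else "not detected"))
  invisible(x)
}

#' Maximum distance at which a target is resolved
#'
#' Sweeps the eye-to-target distance from `scan_step_cm` to `scan_max_cm` in
#' `scan_step_cm` increments, evaluating the whole-eye stimulation at each
#' distance, and reports the largest distance at which the target is detected.
#' The full sweep trace is returned so non-monotone stimulation profiles
#' (possible for oblique horizontal targets) are visible. For horizontal
#' targets, distances at which the eye would sit over the disk
#' (`distance <= radius`) are excluded from the sweep.
#'
#' @param target A [target_spec()]; its `distance_cm` is ignored.
#' @param eye An [ommatidial_array()], or `NULL` to build it from `params`.
#' @param params An [eye_parameters()] object.
#' @return An object of class `detection_result`: list with `max_distance_cm`
#'   (`NA` if never detected), `sweep` (data frame `distance_cm`, `total_pct`,
#'   `detected`), `target`, `params`.
#' @examples
#' \donttest{
#' res <- detection_distance(target_spec(15, "vertical"))
#' res$max_distance_cm
#' }
#' @export
detection_distance <- function(target, eye = NULL, params = eye_parameters()) {
  stopifnot(inherits(target, "target_spec"), inherits(params, "eye_parameters"))
  if (is.null(eye)) eye <- ommatidial_array(params)
  distances <- seq(params$scan_step_cm, params$scan_max_cm,
                   by = params$scan_step_cm)
  if (target$orientation == "horizontal") {
    distances <- distances[distances > target$diameter_cm / 2]
  }
  rf_radius <- params$receptive_field_deg / 2
  totals <- numeric(length(distances))
  detected <- logical(length(distances))
  for (i in seq_along(distances)) {
    tgt <- target_spec(target$diameter_cm, target$orientation,
                       distance_cm = distances[i],
                       altitude_cm = if (target$orientation == "horizontal")
                         target$altitude_cm else 15)
    img <- project_target(tgt, params)
    m <- eye_stimulation(img, eye, params)
    totals[i] <- m$total_pct
    detected[i] <- m$detected
  }
  max_d <- if (any(detected)) max(distances[detected]) else NA_real_
  structure(
    list(
      max_distance_cm = max_d,
      sweep = data.frame(distance_cm = distances, total_pct = totals,
                         detected = detected),
      target = target,
      params = params
    ),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  print(x$target)
  if (is.na(x$max_distance_cm)) {
    cat("Not resolved at any swept distance\n")
  } else {
    cat(sprintf("Resolved up to %g cm\n", x$max_distance_cm))
  }
  invisible(x)
}
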