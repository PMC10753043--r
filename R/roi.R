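#' Build a target region-of-interest cuboid
#'
#' Expands a target's floor-plan footprint by a buffer (default 10 cm) on each
#' side in X and Y and extrudes it from the floor to 30 cm for horizontal
#' targets or 60 cm for vertical targets. Cuboids extending past the arena are
#' clipped with a warning. For vertical targets the target plane's y position
#' (footprint center) is retained so visits can be labeled upwind/downwind.
#'
#' @param x_range,y_range Length-2 cm extents of the target footprint.
#' @param orientation `"vertical"` or `"horizontal"` (sets the height).
#' @param buffer_cm Buffer added per side in X and Y. Default 10.
#' @param label Cuboid label (target id). Default `"target"`.
#' @param arena An [arena_bounds()] object used for clipping.
#' @param height_cm Override for the cuboid height; by default 30
#'   (horizontal) or 60 (vertical).
#' @return An object of class `roi_cuboid`: list with `x`, `y`, `z` ranges,
#'   `label`, `orientation`, `plane_y`.
#' @examples
#' build_cuboid(c(45, 75), c(80, 120), "horizontal")  # 50 x 60 x 30 cm
#' @export
build_cuboid <- function(x_range, y_range,
                         orientation = c("vertical", "horizontal"),
                         buffer_cm = 10, label = "target",
                         arena = arena_bounds(), height_cm = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(length(x_range) == 2L, length(y_range) == 2L,
            diff(x_range) > 0, diff(y_range) > 0, buffer_cm >= 0)
  if (is.null(height_cm)) {
    height_cm <- if (orientation == "horizontal") 30 else 60
  }
  x <- c(x_range[1L] - buffer_cm, x_range[2L] + buffer_cm)
  y <- c(y_range[1L] - buffer_cm, y_range[2L] + buffer_cm)
  z <- c(arena$z[1L], arena$z[1L] + height_cm)
  clipped_x <- c(max(x[1L], arena$x[1L]), min(x[2L], arena$x[2L]))
  clipped_y <- c(max(y[1L], arena$y[1L]), min(y[2L], arena$y[2L]))
  clipped_z <- c(z[1L], min(z[2L], arena$z[2L]))
  if (!identical(c(clipped_x, clipped_y, clipped_z), c(x, y, z))) {
    warning("cuboid '", label, "' extends past the arena; clipped to fit")
  }
  structure(
    list(x = clipped_x, y = clipped_y, z = clipped_z, label = label,
         orientation = orientation, plane_y = mean(y_range)),
    class = "roi_cuboid"
  )
}

#' No-target control cuboid
#'
#' Builds the behavioral-baseline control: a cuboid with the same dimensions
#' as a reference cuboid (canonically the large horizontal target's), placed
#' at the downwind end of the arena (low y), centered laterally.
#'
#' @param reference An [build_cuboid()] result whose dimensions are copied.
#' @param arena An [arena_bounds()] object.
#' @param margin_cm Distance of the cuboid's downwind face from the downwind
#'   wall. Default 5.
#' @return An `roi_cuboid` labeled `"no-target"`.
#' @export
no_target_cuboid <- function(reference, arena = arena_bounds(),
                             margin_cm = 5) {
  stopifnot(inherits(reference, "roi_cuboid"))
  dx <- diff(reference$x)
  dy <- diff(reference$y)
  x0 <- mean(arena$x) - dx / 2
  y0 <- arena$y[1L] + margin_cm
  structure(
    list(x = c(x0, x0 + dx), y = c(y0, y0 + dy), z = reference$z,
         label = "no-target", orientation = reference$orientation,
         plane_y = NA_real_),
    class = "roi_cuboid"
  )
}

#' @export
print.roi_cuboid <- function(x, ...) {
  cat(sprintf(
    "Cuboid '%s' (%s): x [%g, %g], y [%g, %g], z [%g, %g] cm\n",
    x$label, x$orientation, x$x[1L], x$x[2L], x$y[1L], x$y[2L], x$z[1L],
    x$z[2L]))
  invisible(x)
}

points_in_cuboid <- function(points, cuboid) {
  # half-open [min, max) so boundary points are never double counted by
  # adjacent regions
  points$x >= cuboid$x[1L] & points$x < cuboid$x[2L] &
    points$y >= cuboid$y[1L] & points$y < cuboid$y[2L] &
    points$z >= cuboid$z[1L] & points$z < cuboid$z[2L]
}

#' Segment a track into visits of a cuboid
#'
#' A visit is a maximal run of consecutive track points lying inside the
#' cuboid (half-open `[min, max)` on every axis); runs of fewer than 2 points
#' (a 20 ms crossing at 50 fps) are discarded. For vertical-target cuboids
#' each visit is labeled `"upwind"` or `"downwind"` by the side of the target
#' plane on which the visit's mean y falls.
#'
#' @param track A cleaned [flight_track()].
#' @param cuboid An [build_cuboid()] result.
#' @param min_points Minimum points per visit. Default 2.
#' @return A list of `roi_visit` objects, each carrying the visit's points
#'   and its metrics (see [visit_metrics()]).
#' @export
segment_visits <- function(track, cuboid, min_points = 2L) {
  stopifnot(inherits(track, "flight_track"), inherits(cuboid, "roi_cuboid"))
  p <- track$points
  if (nrow(p) == 0L) return(list())
  inside <- points_in_cuboid(p, cuboid)
  if (!any(inside)) return(list())
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_points
  out <- list()
  for (i in which(keep)) {
    q <- p[starts[i]:ends[i], , drop = FALSE]
    rownames(q) <- NULL
    side <- NA_character_
    if (cuboid$orientation == "vertical" && is.finite(cuboid$plane_y)) {
      side <- if (mean(q$y) >= cuboid$plane_y) "upwind" else "downwind"
    }
    visit <- structure(
      list(track_id = track$track_id, label = cuboid$label,
           entry_frame = q$frame[1L], exit_frame = q$frame[nrow(q)],
           points = q, side = side),
      class = "roi_visit"
    )
    visit$metrics <- visit_metrics(visit, track$frame_rate_hz)
    out[[length(out) + 1L]] <- visit
  }
  out
}

#' Per-visit flight metrics
#'
#' Computes the behavioral metrics of one visit: duration
#' `(n_points - 1) / frame_rate`, 3D path length (sum of consecutive
#' Euclidean steps), tortuosity (path length over the entry-to-exit chord;
#' reported `NA` when the chord is shorter than 0.1 cm), and mean speed
#' (path length over duration).
#'
#' @param visit An `roi_visit` (or any list with a `points` data frame).
#' @param frame_rate_hz Frames per second. Default 50.
#' @return A list with `duration_s`, `path_length_cm`, `tortuosity`,
#'   `mean_speed_cms`.
#' @export
visit_metrics <- function(visit, frame_rate_hz = 50) {
  q <- visit$points
  if (nrow(q) < 2L) stop("a visit needs at least 2 points", call. = FALSE)
  duration <- (nrow(q) - 1L) / frame_rate_hz
  steps <- sqrt(diff(q$x)^2 + diff(q$y)^2 + diff(q$z)^2)
  path <- sum(steps)
  chord <- sqrt((q$x[nrow(q)] - q$x[1L])^2 + (q$y[nrow(q)] - q$y[1L])^2 +
                  (q$z[nrow(q)] - q$z[1L])^2)
  tortuosity <- if (chord < 0.1) NA_real_ else path / chord
  list(duration_s = duration, path_length_cm = path,
       tortuosity = tortuosity, mean_speed_cms = path / duration)
}

#' Summarize visits of one target
#'
#' Aggregates the visits of a single cuboid into the per-target summary:
#' visit count, total time, total 3D distance, mean tortuosity and mean speed
#' over visits, plus the landing density per 100 cm^2 of target surface from
#' an externally supplied landing count. For vertical targets the visit
#' count, time and distance are additionally broken down into upwind and
#' downwind components.
#'
#' @param visits List of `roi_visit` objects sharing one cuboid label.
#' @param landings Integer number of mosquitoes that landed on the target.
#' @param target_area_cm2 Target surface area in cm^2 (must be positive).
#' @param label Target label; defaults to the label shared by the visits.
#' @return A one-row data frame of class `target_summary`.
#' @examples
#' summarize_target(list(), landings = 4, target_area_cm2 = 1200)
#' @export
summarize_target <- function(visits, landings = 0, target_area_cm2,
                             label = NULL) {
  if (!is.numeric(target_area_cm2) || target_area_cm2 <= 0) {
    stop("'target_area_cm2' must be positive", call. = FALSE)
  }
  labels <- unique(vapply(visits, function(v) v$label, character(1)))
  if (length(labels) > 1L) {
    stop("visits span multiple cuboid labels: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  metric <- function(vs, name) vapply(vs, function(v) v$metrics[[name]],
                                      numeric(1))
  sides <- vapply(visits, function(v) v$side %||% NA_character_, character(1))
  summary_of <- function(vs) {
    if (length(vs) == 0L) {
      return(list(n = 0L, time = 0, dist = 0))
    }
    list(n = length(vs), time = sum(metric(vs, "duration_s")),
         dist = sum(metric(vs, "path_length_cm")))
  }
  all_s <- summary_of(visits)
  up_s <- summary_of(visits[!is.na(sides) & sides == "upwind"])
  down_s <- summary_of(visits[!is.na(sides) & sides == "downwind"])
  tort <- if (all_s$n > 0) metric(visits, "tortuosity") else numeric(0)
  speed <- if (all_s$n > 0) metric(visits, "mean_speed_cms") else numeric(0)
  out <- data.frame(
    label = if (!is.null(label)) label else
      if (length(labels) == 1L) labels else NA_character_,
    n_visits = all_s$n,
    total_time_s = all_s$time,
    total_distance_cm = all_s$dist,
    mean_tortuosity = if (all(is.na(tort))) NA_real_ else
      mean(tort, na.rm = TRUE),
    mean_speed_cms = if (length(speed) == 0L) NA_real_ else mean(speed),
    landings = as.integer(landings),
    landing_density_per_100cm2 = 100 * landings / target_area_cm2,
    n_visits_upwind = up_s$n, total_time_upwind_s = up_s$time,
    total_distance_upwind_cm = up_s$dist,
    n_visits_downwind = down_s$n, total_time_downwind_s = down_s$time,
    total_distance_downwind_cm = down_s$dist
  )
  class(out) <- c("target_summary", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' 2D density heatmap of track points
#'
#' Bins the points of one or more tracks over a plane of the arena into a
#' square-cell count grid (Fig-1E-style occupancy maps). The grid covers the
#' full arena extent of the chosen plane; cells are half-open so every point
#' inside the arena falls in exactly one cell and the grid total equals the
#' number of points binned.
#'
#' @param tracks A list of [flight_track()] objects (or a single one).
#' @param plane `"XY"` (floor plan) or `"YZ"` (side view).
#' @param bin_cm Cell edge length, cm. Default 2.
#' @param arena An [arena_bounds()] object.
#' @return A numeric matrix of counts; rows advance along the first named
#'   axis, with `dimnames` giving the lower edge of each cell.
#' @export
heatmap_density <- function(tracks, plane = c("XY", "YZ"), bin_cm = 2,
                            arena = arena_bounds()) {
  plane <- match.arg(plane)
  if (!is.numeric(bin_cm) || bin_cm <= 0) {
    stop("'bin_cm' must be positive", call. = FALSE)
  }
  if (inherits(tracks, "flight_track")) tracks <- list(tracks)
  axes <- if (plane == "XY") c("x", "y") else c("y", "z")
  lim1 <- arena[[axes[1L]]]
  lim2 <- arena[[axes[2L]]]
  breaks1 <- seq(lim1[1L], lim1[2L] + bin_cm, by = bin_cm)
  breaks2 <- seq(lim2[1L], lim2[2L] + bin_cm, by = bin_cm)
  grid <- matrix(0, nrow = length(breaks1) - 1L, ncol = length(breaks2) - 1L,
                 dimnames = list(utils::head(breaks1, -1L),
                                 utils::head(breaks2, -1L)))
  for (tr in tracks) {
    p <- tr$points
    if (nrow(p) == 0L) next
    i <- findInterval(p[[axes[1L]]], breaks1, rightmost.closed = FALSE)
    j <- findInterval(p[[axes[2L]]], breaks2, rightmost.closed = FALSE)
    ok <- i >= 1L & i <= nrow(grid) & j >= 1L & j <= ncol(grid)
    if (any(ok)) {
      tab <- table(factor(i[ok], levels = seq_len(nrow(grid))),
                   factor(j[ok], levels = seq_len(ncol(grid))))
      grid <- grid + unclass(tab)
    }
  }
  grid
}
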