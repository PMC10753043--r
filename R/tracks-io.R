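#' Wind-tunnel arena extents
#'
#' The default working volume is the 120 cm wide x 120 cm tall x 200 cm long
#' wind-tunnel arena, with x lateral (0-120), y along the airflow with upwind
#' positive (0-200), z vertical (0-120) and the origin at the
#' downwind-floor-left corner. All coordinates are in cm.
#'
#' @param x,y,z Length-2 numeric ranges, cm.
#' @return A named list of ranges of class `arena_bounds`.
#' @export
arena_bounds <- function(x = c(0, 120), y = c(0, 200), z = c(0, 120)) {
  for (axis in list(x = x, y = y, z = z)) {
    if (!is.numeric(axis) || length(axis) != 2L || diff(axis) <= 0) {
      stop("arena bounds must be increasing length-2 numeric ranges",
           call. = FALSE)
    }
  }
  structure(list(x = x, y = y, z = z), class = "arena_bounds")
}

#' Construct a flight track
#'
#' A track is an ordered sequence of 3D positions sampled at a fixed frame
#' rate, with a per-point status flag recording whether the point was observed
#' or filled in by gap interpolation.
#'
#' @param track_id Identifier (coerced to character).
#' @param points Data frame with columns `frame`, `x`, `y`, `z` and optional
#'   `status` (`"observed"` or `"interpolated"`; defaults to observed).
#' @param frame_rate_hz Sampling rate, frames per second. Default 50.
#' @return An object of class `flight_track`.
#' @export
flight_track <- function(track_id, points, frame_rate_hz = 50) {
  stopifnot(is.data.frame(points))
  required <- c("frame", "x", "y", "z")
  missing <- setdiff(required, names(points))
  if (length(missing) > 0L) {
    stop("track points lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(points$status)) points$status <- rep("observed", nrow(points))
  points <- points[order(points$frame), c(required, "status")]
  if (anyDuplicated(points$frame)) {
    stop("track '", track_id, "' has duplicated frame indices", call. = FALSE)
  }
  rownames(points) <- NULL
  structure(
    list(track_id = as.character(track_id), frame_rate_hz = frame_rate_hz,
         points = points),
    class = "flight_track"
  )
}

#' @export
print.flight_track <- function(x, ...) {
  p <- x$points
  cat(sprintf(
    "Flight track '%s': %d points, frames %d-%d @ %g fps (%d interpolated)\n",
    x$track_id, nrow(p), min(p$frame), max(p$frame), x$frame_rate_hz,
    sum(p$status == "interpolated")))
  invisible(x)
}

#' Read 3D flight tracks from delimited text
#'
#' Reads a CSV/TSV table with header columns `track_id`, `frame`, `x`, `y`,
#' `z` (cm) and returns one [flight_track()] per id, points sorted by frame.
#' Rows with non-finite coordinates or non-integer frames are rejected with
#' their line numbers.
#'
#' @param file Path to the table.
#' @param frame_rate_hz Sampling rate to attach to each track. Default 50.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab from
#'   the header line.
#' @return A named list of `flight_track` objects.
#' @export
read_tracks <- function(file, frame_rate_hz = 50, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(file, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("track_id", "frame", "x", "y", "z")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("track file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  frame <- num("frame")
  x <- num("x")
  y <- num("y")
  z <- num("z")
  bad <- !is.finite(frame) | frame != round(frame) |
    !is.finite(x) | !is.finite(y) | !is.finite(z)
  if (any(bad)) {
    # +1 for the header line, so numbers refer to lines in the file
    stop("malformed track rows at line(s): ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(track_id = raw$track_id, frame = as.integer(frame),
                   x = x, y = y, z = z)
  tracks <- lapply(split(df, df$track_id), function(d) {
    flight_track(d$track_id[1L],
                 d[, c("frame", "x", "y", "z")],
                 frame_rate_hz = frame_rate_hz)
  })
  tracks[order(names(tracks))]
}

#' Write flight tracks as delimited text
#'
#' Writes the same dialect [read_tracks()] reads (CSV with header
#' `track_id,frame,x,y,z`); the status flag is appended as a sixth column and
#' ignored by the reader.
#'
#' @param tracks A list of [flight_track()] objects (or a single one).
#' @param file Output path.
#' @export
write_tracks <- function(tracks, file) {
  if (inherits(tracks, "flight_track")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    cbind(track_id = tr$track_id, tr$points)
  }))
  utils::write.csv(rows, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
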