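#' Track-cleaning configuration
#'
#' Parameters of the three cleaning stages applied to raw tracks: outlier
#' removal (arena-bounds check plus an isolated-spike speed test), linear
#' interpolation across short gaps, and per-axis cubic smoothing-spline
#' smoothing.
#'
#' @param max_gap_frames Longest run of missing frames that is interpolated;
#'   longer gaps split the track. Default 5.
#' @param outlier_speed_cms A point is a spike when the speed implied to both
#'   of its neighbors exceeds this, cm/s. Default 400 (about 17x the mean
#'   flight speed).
#' @param smoothing_parameter Smoothing-spline curvature penalty per axis,
#'   expressed on the frame scale (so its effect is independent of track
#'   length); 0 leaves the track unchanged. The default 10 gives an
#'   equivalent kernel bandwidth of about `10^(1/4) ~ 1.8` frames -- it
#'   roughly halves sub-frame tracking jitter while leaving
#'   constant-velocity flight unchanged (straight lines are in the penalty
#'   null space) and preserving maneuvers slower than ~25 Hz.
#' @param arena_bounds An [arena_bounds()] object; points outside are removed.
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(max_gap_frames = 5,
                            outlier_speed_cms = 400,
                            smoothing_parameter = 10,
                            arena_bounds = mozsight::arena_bounds()) {
  if (!is.numeric(max_gap_frames) || max_gap_frames < 0) {
    stop("'max_gap_frames' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(outlier_speed_cms) || outlier_speed_cms <= 0) {
    stop("'outlier_speed_cms' must be positive", call. = FALSE)
  }
  structure(
    list(max_gap_frames = as.integer(max_gap_frames),
         outlier_speed_cms = outlier_speed_cms,
         smoothing_parameter = smoothing_parameter,
         arena_bounds = arena_bounds),
    class = "cleaning_config"
  )
}

#' Remove erroneous track points
#'
#' Drops points outside the arena bounds and isolated spikes: interior points
#' whose implied speed to *both* neighbors exceeds `outlier_speed_cms`
#' (endpoints are dropped when the speed to their only neighbor exceeds it).
#' Speeds are frame-aware (`distance / (dframes / rate)`), so existing gaps do
#' not create false positives. Removal leaves gaps that
#' [interpolate_gaps()] handles; the operation is idempotent on smooth flight.
#'
#' @param track A [flight_track()].
#' @param config A [cleaning_config()].
#' @return The filtered `flight_track` (possibly with zero points).
#' @export
filter_outliers <- function(track, config = cleaning_config()) {
  stopifnot(inherits(track, "flight_track"))
  p <- track$points
  b <- config$arena_bounds
  inside <- p$x >= b$x[1L] & p$x <= b$x[2L] &
    p$y >= b$y[1L] & p$y <= b$y[2L] &
    p$z >= b$z[1L] & p$z <= b$z[2L]
  p <- p[inside, , drop = FALSE]
  n <- nrow(p)
  if (n >= 2L) {
    dt <- diff(p$frame) / track$frame_rate_hz
    step <- sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2)
    fast <- step / dt > config$outlier_speed_cms   # between point i and i+1
    spike <- logical(n)
    if (n == 2L) {
      # a two-point track with an impossible jump is unusable evidence of both
      spike[] <- fast[1L]
    } else {
      spike[1L] <- fast[1L]
      spike[n] <- fast[n - 1L]
      mid <- 2:(n - 1L)
      spike[mid] <- fast[mid - 1L] & fast[mid]
    }
    p <- p[!spike, , drop = FALSE]
  }
  track$points <- p
  rownames(track$points) <- NULL
  track
}

#' Interpolate short gaps and split at long ones
#'
#' Fills gaps of at most `max_gap_frames` missing frames by per-axis linear
#' interpolation (filled points are flagged `"interpolated"`); longer gaps
#' split the track into separate tracks whose ids gain a `.1`, `.2`, ...
#' suffix when splitting occurs.
#'
#' @param track A [flight_track()].
#' @param config A [cleaning_config()].
#' @return A list of `flight_track` objects (length 1 when nothing splits).
#' @export
interpolate_gaps <- function(track, config = cleaning_config()) {
  stopifnot(inherits(track, "flight_track"))
  p <- track$points
  if (nrow(p) == 0L) return(list())
  gap <- diff(p$frame) - 1L
  split_after <- which(gap > config$max_gap_frames)
  piece_id <- cumsum(c(0L, seq_len(nrow(p) - 1L) %in% split_after)) + 1L
  pieces <- split(p, piece_id)
  out <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    q <- pieces[[i]]
    frames <- q$frame[1L]:q$frame[nrow(q)]
    if (length(frames) > nrow(q)) {
      filled <- data.frame(
        frame = frames,
        x = stats::approx(q$frame, q$x, xout = frames)$y,
        y = stats::approx(q$frame, q$y, xout = frames)$y,
        z = stats::approx(q$frame, q$z, xout = frames)$y,
        status = "interpolated"
      )
      filled$status[frames %in% q$frame] <- q$status
      q <- filled
    }
    id <- if (length(pieces) > 1L) paste0(track$track_id, ".", i) else
      track$track_id
    out[[i]] <- flight_track(id, q, track$frame_rate_hz)
  }
  out
}

#' Smooth a track with per-axis cubic smoothing splines
#'
#' Fits a penalized cubic smoothing spline to each coordinate as a function of
#' frame index and evaluates it at the original frames, damping tracking
#' jitter while leaving straight constant-speed flight unchanged. A
#' `smoothing_parameter` of 0 returns the input exactly. Tracks shorter than
#' 4 points are returned unsmoothed with a warning.
#'
#' @param track A [flight_track()].
#' @param config A [cleaning_config()].
#' @return The smoothed `flight_track` (same frames, same length).
#' @export
smooth_track <- function(track, config = cleaning_config()) {
  stopifnot(inherits(track, "flight_track"))
  lambda <- config$smoothing_parameter
  if (lambda <= 0) return(track)
  p <- track$points
  if (nrow(p) < 4L) {
    warning("track '", track$track_id, "' has fewer than 4 points; ",
            "returned unsmoothed")
    return(track)
  }
  # smooth.spline defines lambda on frames rescaled to [0, 1]; dividing by
  # the cubed frame range keeps the user's penalty on the frame scale, so the
  # same value smooths equally on short and long tracks
  lambda_norm <- lambda / diff(range(p$frame))^3
  for (axis in c("x", "y", "z")) {
    fit <- stats::smooth.spline(p$frame, p[[axis]], lambda = lambda_norm,
                                all.knots = TRUE, keep.data = FALSE)
    p[[axis]] <- stats::predict(fit, p$frame)$y
  }
  track$points <- p
  track
}

#' Run the full cleaning pipeline
#'
#' Applies [filter_outliers()], [interpolate_gaps()] and [smooth_track()] in
#' that order to each input track and returns the flattened list of cleaned
#' tracks (outlier removal can create gaps; long gaps split tracks).
#'
#' @param tracks A list of [flight_track()] objects (or a single one).
#' @param config A [cleaning_config()].
#' @param smooth Logical; apply the smoothing stage. Default `TRUE`.
#' @return A named-by-id list of cleaned `flight_track` objects.
#' @export
clean_tracks <- function(tracks, config = cleaning_config(), smooth = TRUE) {
  if (inherits(tracks, "flight_track")) tracks <- list(tracks)
  out <- list()
  for (tr in tracks) {
    pieces <- interpolate_gaps(filter_outliers(tr, config), config)
    for (piece in pieces) {
      if (nrow(piece$points) == 0L) next
      if (smooth) piece <- smooth_track(piece, config)
      out[[piece$track_id]] <- piece
    }
  }
  out
}
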