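#' Configuration of the synthetic-track simulator
#'
#' Parameters of the correlated-random-walk flight simulator and of the
#' corruption stage that emulates tracking defects (missing frames, spurious
#' points). The mean flight speed defaults to 24 cm/s, a typical wind-tunnel
#' flight speed for host-seeking anophelines; arena and frame rate default to
#' the 120 x 120 x 200 cm tunnel sampled at 50 fps.
#'
#' @param frame_rate_hz Sampling rate. Default 50.
#' @param mean_speed_cms Mean flight speed, cm/s. Default 24.
#' @param speed_sd_cms Per-frame speed standard deviation (speeds are drawn
#'   from a normal truncated at zero). Default 6.
#' @param persistence Direction persistence of the correlated random walk in
#'   `[0, 1]`: each new heading is the unit-normalized mix
#'   `p * previous + (1 - p) * random`. 1 gives straight flight. Default 0.95.
#' @param arena An [arena_bounds()] object; walls reflect.
#' @param duration_s Track duration, s. Must be positive.
#' @param rng_seed Seed fixing the full output stream. Default 1.
#' @param gap_rate Per-frame probability that a missing-frame gap starts.
#'   Default 0.01.
#' @param gap_length_range Length-2 integer range of gap lengths (frames),
#'   sampled uniformly. Default `c(1, 8)` so both interpolable and
#'   track-splitting gaps occur.
#' @param spike_rate Per-frame probability that a point is displaced into a
#'   spurious spike. Default 0.005.
#' @param spike_magnitude_cm Displacement of spike points, cm. Default 50.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(frame_rate_hz = 50,
                              mean_speed_cms = 24,
                              speed_sd_cms = 6,
                              persistence = 0.95,
                              arena = arena_bounds(),
                              duration_s = 30,
                              rng_seed = 1,
                              gap_rate = 0.01,
                              gap_length_range = c(1, 8),
                              spike_rate = 0.005,
                              spike_magnitude_cm = 50) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("'duration_s' must be positive", call. = FALSE)
  }
  if (mean_speed_cms <= 0 || speed_sd_cms < 0) {
    stop("speeds must be positive", call. = FALSE)
  }
  if (persistence < 0 || persistence > 1) {
    stop("'persistence' must lie in [0, 1]", call. = FALSE)
  }
  for (rate in c(gap_rate, spike_rate)) {
    if (rate < 0 || rate > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(frame_rate_hz = frame_rate_hz, mean_speed_cms = mean_speed_cms,
         speed_sd_cms = speed_sd_cms, persistence = persistence,
         arena = arena, duration_s = duration_s, rng_seed = rng_seed,
         gap_rate = gap_rate,
         gap_length_range = as.integer(gap_length_range),
         spike_rate = spike_rate, spike_magnitude_cm = spike_magnitude_cm),
    class = "simulation_config"
  )
}

with_sim_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Simulate one correlated-random-walk flight track
#'
#' Generates a clean 3D track: headings follow a correlated random walk (new
#' heading is the normalized mix of the previous heading and an isotropic
#' random direction, weighted by `persistence`), per-frame speeds are drawn
#' from a truncated normal about `mean_speed_cms`, and arena walls reflect
#' the trajectory. Fully deterministic given `rng_seed`.
#'
#' @param config A [simulation_config()].
#' @param track_id Identifier for the generated track. Default `"sim"`.
#' @param start Optional start position `c(x, y, z)`; defaults to the arena
#'   center.
#' @return A clean [flight_track()].
#' @examples
#' tr <- simulate_track(simulation_config(duration_s = 2))
#' nrow(tr$points)  # 101 frames
#' @export
simulate_track <- function(config = simulation_config(), track_id = "sim",
                           start = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n <- round(config$duration_s * config$frame_rate_hz) + 1L
  b <- config$arena
  if (is.null(start)) {
    start <- c(mean(b$x), mean(b$y), mean(b$z))
  }
  with_sim_seed(config$rng_seed, {
    pos <- matrix(NA_real_, n, 3L)
    pos[1L, ] <- start
    dir <- random_unit_vector()
    lo <- c(b$x[1L], b$y[1L], b$z[1L])
    hi <- c(b$x[2L], b$y[2L], b$z[2L])
    for (i in 2:n) {
      dir <- config$persistence * dir +
        (1 - config$persistence) * random_unit_vector()
      dir <- dir / sqrt(sum(dir^2))
      speed <- -1
      while (speed <= 0) {
        speed <- stats::rnorm(1L, config$mean_speed_cms, config$speed_sd_cms)
      }
      p <- pos[i - 1L, ] + dir * speed / config$frame_rate_hz
      # reflect at the walls
      for (k in 1:3) {
        if (p[k] < lo[k]) {
          p[k] <- 2 * lo[k] - p[k]
          dir[k] <- -dir[k]
        } else if (p[k] > hi[k]) {
          p[k] <- 2 * hi[k] - p[k]
          dir[k] <- -dir[k]
        }
      }
      pos[i, ] <- p
    }
    flight_track(track_id,
                 data.frame(frame = seq_len(n), x = pos[, 1L], y = pos[, 2L],
                            z = pos[, 3L]),
                 config$frame_rate_hz)
  })
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3L)
    s <- sqrt(sum(v^2))
    if (s > 1e-12) return(v / s)
  }
}

#' Corrupt a clean track with gaps and spikes
#'
#' Emulates the defects the cleaning pipeline targets: deletes runs of frames
#' (gaps, lengths sampled from `gap_length_range`) and displaces isolated
#' points by `spike_magnitude_cm` in a random direction (spurious points).
#' Spikes are kept isolated -- at least two intact frames from every gap,
#' every other spike and the track ends -- so each defect is attributable.
#' Every corrupted frame index is recorded.
#'
#' @param track A clean [flight_track()].
#' @param config A [simulation_config()] (uses the corruption fields and
#'   `rng_seed + 1` so corruption is independent of track generation).
#' @return A list with `track` (corrupted), `gap_frames` (integer vector of
#'   deleted frames), `spike_frames` (integer vector of displaced frames).
#' @export
corrupt_track <- function(track, config = simulation_config()) {
  stopifnot(inherits(track, "flight_track"),
            inherits(config, "simulation_config"))
  p <- track$points
  n <- nrow(p)
  with_sim_seed(config$rng_seed + 1L, {
    gap_frames <- integer(0)
    if (config$gap_rate > 0 && n > 4L) {
      starts <- which(stats::runif(n) < config$gap_rate)
      starts <- starts[starts > 1L & starts < n]
      for (s in starts) {
        len_span <- config$gap_length_range[2L] - config$gap_length_range[1L]
        len <- config$gap_length_range[1L] + sample.int(len_span + 1L, 1L) - 1L
        frames <- p$frame[s] + 0:(len - 1L)
        # keep gaps whole and isolated (>= 2 intact frames apart, never
        # touching the last frame) so each recorded gap keeps its drawn
        # length instead of being trimmed or coalescing into a longer one
        if (max(frames) < p$frame[n] && (length(gap_frames) == 0L ||
            min(abs(outer(gap_frames, frames, "-"))) > 2L)) {
          gap_frames <- c(gap_frames, frames)
        }
      }
      gap_frames <- sort(as.integer(gap_frames))
    }
    spike_frames <- integer(0)
    if (config$spike_rate > 0 && n > 4L) {
      candidates <- which(stats::runif(n) < config$spike_rate)
      candidates <- candidates[candidates > 2L & candidates < n - 1L]
      for (s in candidates) {
        frame <- p$frame[s]
        near_gap <- any(abs(gap_frames - frame) <= 2L)
        near_spike <- any(abs(spike_frames - frame) <= 2L)
        if (!near_gap && !near_spike) {
          spike_frames <- c(spike_frames, frame)
        }
      }
      for (frame in spike_frames) {
        i <- match(frame, p$frame)
        p[i, c("x", "y", "z")] <- p[i, c("x", "y", "z")] +
          config$spike_magnitude_cm * random_unit_vector()
      }
      spike_frames <- as.integer(spike_frames)
    }
    keep <- !(p$frame %in% gap_frames)
    out <- track
    out$points <- p[keep, , drop = FALSE]
    rownames(out$points) <- NULL
    list(track = out, gap_frames = gap_frames, spike_frames = spike_frames)
  })
}

#' Construct tracks with a planned visit schedule
#'
#' Builds piecewise-linear constant-speed tracks that enter given cuboids a
#' planned number of times for planned dwell times, together with the exact
#' ground truth of every visit. One track is built per plan entry. Each visit
#' enters through the cuboid's downwind (low-y) face, flies a serpentine
#' polyline through the interior (5 cm inside each face) whose in-cuboid path
#' length equals `dwell_s * mean_speed_cms` exactly, and exits back through
#' the same face; at constant speed the in-cuboid time therefore equals
#' `dwell_s` up to one frame of quantization. Ground-truth metrics are
#' computed directly from the constructed points by the closed forms that
#' define the visit metrics, independent of the segmentation code.
#'
#' @param cuboids Named list of disjoint [build_cuboid()] results.
#' @param visit_plan Data frame with columns `label`, `n_visits`, `dwell_s`.
#' @param config A [simulation_config()]; supplies speed, frame rate and
#'   duration.
#' @return A list with `tracks` (list of clean [flight_track()]) and `truth`
#'   (data frame: one row per track x cuboid with `n_visits`, `total_time_s`,
#'   `total_path_cm`).
#' @export
make_visit_scenario <- function(cuboids, visit_plan,
                                config = simulation_config()) {
  stopifnot(is.data.frame(visit_plan),
            all(c("label", "n_visits", "dwell_s") %in% names(visit_plan)))
  labels <- vapply(cuboids, function(cb) cb$label, character(1))
  names(cuboids) <- labels
  b <- config$arena
  rate <- config$frame_rate_hz
  speed <- config$mean_speed_cms
  # staging point well away from every cuboid: downwind-top corner region
  staging <- c(mean(b$x), b$y[1L] + 5, b$z[2L] - 10)
  for (cb in cuboids) {
    if (all(staging >= c(cb$x[1L], cb$y[1L], cb$z[1L])) &&
        all(staging < c(cb$x[2L], cb$y[2L], cb$z[2L]))) {
      stop("no staging point outside all cuboids; move cuboids away from ",
           "the downwind-top region", call. = FALSE)
    }
  }
  tracks <- list()
  truth <- list()
  for (row in seq_len(nrow(visit_plan))) {
    label <- as.character(visit_plan$label[row])
    n_visits <- visit_plan$n_visits[row]
    dwell_s <- visit_plan$dwell_s[row]
    cb <- cuboids[[label]]
    if (is.null(cb)) stop("no cuboid labeled '", label, "'", call. = FALSE)
    waypoints <- list(staging)
    if (n_visits > 0) {
      margin <- 5
      entry_depth <- margin  # inside path on the entry and exit legs
      inx <- cb$x + c(margin, -margin)
      inz <- cb$z + c(margin, -margin)
      y_in <- cb$y[1L] + margin
      outside <- c(mean(cb$x), cb$y[1L] - 10, mean(inz))
      # one extra frame of path compensates the half-frame quantization of
      # the entry and exit crossings, centering realized dwell on the plan
      inside_length <- speed * dwell_s - 2 * entry_depth + speed / rate
      if (inside_length <= 0) {
        stop("dwell_s too short: each visit needs at least ",
             round(2 * entry_depth / speed, 2), " s at ", speed, " cm/s",
             call. = FALSE)
      }
      for (v in seq_len(n_visits)) {
        zig <- serpentine_polyline(inx, inz, y_in, inside_length,
                                   start_x = mean(cb$x))
        last <- zig[[length(zig)]]
        waypoints <- c(waypoints, list(outside), zig,
                       list(c(last[1L], cb$y[1L] - 10, last[3L])))
      }
    }
    waypoints <- c(waypoints, list(staging))
    path <- do.call(rbind, waypoints)
    # sample the polyline at constant speed (drop zero-length segments first)
    seg <- sqrt(rowSums(diff(path)^2))
    path <- path[c(TRUE, seg > 1e-9), , drop = FALSE]
    seg <- seg[seg > 1e-9]
    if (nrow(path) < 2L) {
      # empty plan: a short hover leg near the staging point
      path <- rbind(path[1L, ], path[1L, ] + c(8, 0, 0))
      seg <- 8
    }
    cum <- c(0, cumsum(seg))
    total_len <- cum[length(cum)]
    needed_s <- total_len / speed
    if (needed_s > config$duration_s) {
      stop("visit plan infeasible: needs ", round(needed_s, 1),
           " s but duration_s is ", config$duration_s, call. = FALSE)
    }
    n_frames <- floor(needed_s * rate) + 1L
    s_at <- pmin((seq_len(n_frames) - 1L) / rate * speed, total_len)
    pts <- cbind(
      stats::approx(cum, path[, 1L], xout = s_at)$y,
      stats::approx(cum, path[, 2L], xout = s_at)$y,
      stats::approx(cum, path[, 3L], xout = s_at)$y
    )
    id <- paste0("plan_", row, "_", label)
    tr <- flight_track(id, data.frame(frame = seq_len(n_frames),
                                      x = pts[, 1L], y = pts[, 2L],
                                      z = pts[, 3L]), rate)
    tracks[[id]] <- tr
    truth[[id]] <- scenario_truth(tr, cuboids)
  }
  truth_df <- do.call(rbind, lapply(names(truth), function(id) {
    do.call(rbind, lapply(names(truth[[id]]), function(lb) {
      t <- truth[[id]][[lb]]
      data.frame(track_id = id, label = lb, n_visits = t$n_visits,
                 total_time_s = t$total_time_s,
                 total_path_cm = t$total_path_cm)
    }))
  }))
  list(tracks = tracks, truth = truth_df)
}

# Axis-aligned serpentine of exact total length inside the x/z box at fixed y:
# x sweeps alternate between the box edges, with small z steps between sweeps.
serpentine_polyline <- function(inx, inz, y, target_length, start_x) {
  pos <- c(start_x, y, mean(inz))
  pts <- list(pos)
  remaining <- target_length
  x_targets <- rep(c(inx[1L], inx[2L]), length.out = 10000L)
  dz <- 3
  z_dir <- 1
  k <- 0L
  move_to <- function(p, q, remaining) {
    len <- sqrt(sum((q - p)^2))
    if (len >= remaining) {
      list(point = p + (q - p) * remaining / len, used = remaining,
           done = TRUE)
    } else {
      list(point = q, used = len, done = FALSE)
    }
  }
  while (remaining > 1e-9) {
    k <- k + 1L
    # x sweep
    step <- move_to(pos, c(x_targets[k], y, pos[3L]), remaining)
    pos <- step$point
    pts <- c(pts, list(pos))
    remaining <- remaining - step$used
    if (step$done || remaining <= 1e-9) break
    # z step, bouncing inside the box
    z_next <- pos[3L] + z_dir * dz
    if (z_next > inz[2L] || z_next < inz[1L]) {
      z_dir <- -z_dir
      z_next <- pos[3L] + z_dir * dz
    }
    step <- move_to(pos, c(pos[1L], y, z_next), remaining)
    pos <- step$point
    pts <- c(pts, list(pos))
    remaining <- remaining - step$used
  }
  pts
}

# Ground truth by direct arithmetic on the constructed points.
scenario_truth <- function(track, cuboids) {
  p <- track$points
  out <- list()
  for (cb in cuboids) {
    inside <- points_in_cuboid(p, cb)
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values & runs$lengths >= 2L)
    time_s <- 0
    path <- 0
    for (i in keep) {
      idx <- starts[i]:ends[i]
      time_s <- time_s + (length(idx) - 1L) / track$frame_rate_hz
      path <- path + sum(sqrt(diff(p$x[idx])^2 + diff(p$y[idx])^2 +
                                diff(p$z[idx])^2))
    }
    out[[cb$label]] <- list(n_visits = length(keep), total_time_s = time_s,
                            total_path_cm = path)
  }
  out
}
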