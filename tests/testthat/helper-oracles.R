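# Independent oracles and fixture builders shared across tests.

# Analytic area of the lens of intersection of two circles (radii r1, r2,
# center distance d).
lens_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
}

# Analytic stimulation (percent of the receptive field, radius rf_r at
# distance d from the image center) by a circular image of radius rho.
lens_stim_pct <- function(rho, rf_r, d) 100 * lens_area(rho, rf_r, d) / (pi * rf_r^2)

# Monte-Carlo stimulation oracle: fraction of points uniform in the RF disk
# that fall inside the image outline (point-in-polygon via mgcv::in.out).
mc_stim_pct <- function(image, ax, ay, rf_r, n = 1e5, seed = 99) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  r <- rf_r * sqrt(runif(n))
  t <- runif(n, 0, 2 * pi)
  pts <- cbind(ax + r * cos(t), ay + r * sin(t))
  bnd <- as.matrix(image$outline)
  100 * mean(mgcv::in.out(bnd, pts))
}

# A vertical target whose angular image is a circle of angular radius
# rho_deg when viewed from `distance` cm.
target_with_angular_radius <- function(rho_deg, distance = 50) {
  target_spec(2 * distance * tan(rho_deg * pi / 180), "vertical",
              distance_cm = distance)
}

# Constant-velocity straight track: n points from `from` toward unit
# direction `dir` at `speed_cms`, 50 fps.
line_track <- function(n, from = c(10, 10, 10), dir = c(0, 1, 0),
                       speed_cms = 24, rate = 50, id = "line") {
  dir <- dir / sqrt(sum(dir^2))
  step <- speed_cms / rate
  i <- seq_len(n) - 1
  flight_track(id, data.frame(
    frame = seq_len(n),
    x = from[1] + i * step * dir[1],
    y = from[2] + i * step * dir[2],
    z = from[3] + i * step * dir[3]
  ), rate)
}

# Drop the given frames from a track (simulating missing coordinates).
drop_frames <- function(track, frames) {
  track$points <- track$points[!track$points$frame %in% frames, ]
  rownames(track$points) <- NULL
  track
}
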