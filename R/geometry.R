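# Planar polygon primitives used by the eye model. All polygons are lists with
# numeric components x and y holding vertices in order, without a repeated
# closing vertex (the polyclip convention).

circle_polygon <- function(cx, cy, r, n) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = cx + r * cos(t), y = cy + r * sin(t))
}

polygon_area <- function(p) {
  x <- p$x
  y <- p$y
  if (length(x) < 3L) return(0)
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_centroid_radius <- function(p) {
  cx <- mean(p$x)
  cy <- mean(p$y)
  list(cx = cx, cy = cy, r = sqrt(max((p$x - cx)^2 + (p$y - cy)^2)))
}

# Area of intersection of two simple polygons (Vatti clipping via polyclip).
polygon_intersection_area <- function(a, b) {
  pieces <- polyclip::polyclip(a, b, op = "intersection")
  if (length(pieces) == 0L) return(0)
  sum(vapply(pieces, polygon_area, numeric(1)))
}
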