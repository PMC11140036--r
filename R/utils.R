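# Internal geometry / indexing helpers shared across modules.

# Pixel coordinate convention, used everywhere: (x, y) with 0-based integers,
# origin at the image top-left, x rightward, y downward. A pixel (x, y) lives
# at mat[y + 1, x + 1] of the row-major image matrix.

# Encode (x, y) pairs as single integer keys for fast set membership.
# `w` must exceed every x in play; callers pass image width (or bbox width).
pix_key <- function(xy, w) xy[, 1L] + xy[, 2L] * w

# Integer Bresenham raster of the segment (x0,y0)-(x1,y1), endpoints included.
# Produces an 8-connected one-pixel-thick digital line.
raster_line <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  n <- max(dx, dy) + 1L
  xs <- integer(n); ys <- integer(n)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    xs[i] <- x; ys[i] <- y
    if (x == x1 && y == y1) { xs <- xs[1:i]; ys <- ys[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  cbind(x = xs, y = ys)
}

# Smallest circular difference between two angles in degrees, in [0, 180].
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

empty_pixels <- function() {
  cbind(x = integer(0), y = integer(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
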