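# Synthetic ground-truth fixtures: binary images with cells of known
# polarity, so every pipeline stage is testable without real micrographs.
#
# Rasterization rule (used consistently so that geometric oracles match):
# a pixel (integer coordinates) belongs to a disk of center c and radius r
# iff its center lies within the continuous disk, i.e. |p - c|^2 <= r^2.

disk_pixels <- function(center, radius) {
  cx <- center[[1L]]; cy <- center[[2L]]
  xs <- seq.int(floor(cx - radius), ceiling(cx + radius))
  ys <- seq.int(floor(cy - radius), ceiling(cy + radius))
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= radius^2
  cbind(x = g$x[keep], y = g$y[keep])
}

# Unit vector of a bearing in degrees (ccw, 90 = north on screen): image y
# grows downward, so the y component is negated.
bearing_vec <- function(bearing_deg) {
  t <- bearing_deg * pi / 180
  c(cos(t), -sin(t))
}

#' Disk-with-hole ground-truth cell
#'
#' Emulates a spectrin-labeled hair-cell surface: a filled disk (the chunk)
#' with a circular unlabeled inclusion (the cave, like the fonticulus) whose
#' center sits `offset` pixels from the disk center along the true bearing.
#' The hole must be fully interior: `offset + cave_radius < radius`.
#'
#' @param center numeric `(x, y)` disk center in pixels.
#' @param radius disk radius in pixels.
#' @param offset cave-center displacement from the disk center, in pixels
#'   (0 gives a concentric hole, which downstream measurement flags
#'   unmeasurable).
#' @param bearing_deg true polarity bearing in degrees (counterclockwise,
#'   90 = north).
#' @param cave_radius hole radius in pixels.
#' @return `list(chunk =, cave =)` of (x, y) pixel matrices.
#' @export
make_disk_cell <- function(center, radius, offset, bearing_deg,
                           cave_radius = 3) {
  if (offset + cave_radius >= radius) {
    stop("cave not fully interior: need offset + cave_radius < radius")
  }
  cave_center <- c(center[[1L]], center[[2L]]) + offset * bearing_vec(bearing_deg)
  cave <- disk_pixels(cave_center, cave_radius)
  disk <- disk_pixels(center, radius)
  # shift to non-negative coordinates before keying (centers may sit near 0)
  x0 <- min(disk[, 1L]); y0 <- min(disk[, 2L])
  w <- max(disk[, 1L]) - x0 + 2L
  key <- function(p) (p[, 1L] - x0) + (p[, 2L] - y0) * w
  chunk <- disk[!(key(disk) %in% key(cave)), , drop = FALSE]
  list(chunk = chunk, cave = cave)
}

#' U-shaped (open-concavity) ground-truth cell
#'
#' Emulates a phalloidin-labeled stereocilia bundle or an ommatidium: an
#' annulus with an angular mouth cut out toward the true bearing, leaving an
#' open concavity that only plastic wrap can enclose. With wrap enabled and
#' the largest cave selected, the measured angle approximates the mouth
#' bearing.
#'
#' @param center numeric `(x, y)` in pixels.
#' @param outer_radius,inner_radius annulus radii in pixels.
#' @param bearing_deg direction the mouth faces (counterclockwise degrees,
#'   90 = north).
#' @param mouth_half_angle half-width of the mouth sector in degrees.
#' @return (x, y) pixel matrix of the chunk.
#' @export
make_u_cell <- function(center, outer_radius = 12, inner_radius = 6,
                        bearing_deg = 90, mouth_half_angle = 45) {
  ring <- disk_pixels(center, outer_radius)
  dx <- ring[, 1L] - center[[1L]]
  dy <- ring[, 2L] - center[[2L]]
  r2 <- dx^2 + dy^2
  ring <- ring[r2 > inner_radius^2, , drop = FALSE]
  ang <- (atan2(-(ring[, 2L] - center[[2L]]), ring[, 1L] - center[[1L]]) *
            180 / pi) %% 360
  keep <- circ_diff_deg(ang, bearing_deg) > mouth_half_angle
  ring[keep, , drop = FALSE]
}

#' Fused doublet ground-truth cell pair
#'
#' Two disk-with-hole cells rasterized so their disks abut along an image
#' axis, producing a single 8-connected chunk whose bounding-box aspect
#' ratio reaches 2, the default doublet-splitting trigger.
#'
#' @param truth_a,truth_b lists with fields `radius`, `offset`,
#'   `bearing_deg`, `cave_radius` (as in [make_disk_cell()]); both disks get
#'   the same radius treatment but may differ in polarity.
#' @param center numeric `(x, y)`: midpoint between the two cell centers.
#' @param fusion_axis `"horizontal"` (side by side) or `"vertical"`.
#' @return `list(chunk =, centers =)`: the fused pixel matrix and the two
#'   cell centers.
#' @export
make_doublet <- function(truth_a, truth_b, center = c(40, 40),
                         fusion_axis = c("horizontal", "vertical")) {
  fusion_axis <- match.arg(fusion_axis)
  ra <- truth_a$radius; rb <- truth_b$radius
  sep <- ra + rb + 1                     # abutting pixel footprints
  d <- if (fusion_axis == "horizontal") c(1, 0) else c(0, 1)
  ca <- floor(c(center[[1L]], center[[2L]]) - d * sep / 2)
  cb <- ca + d * sep
  a <- make_disk_cell(ca, ra, truth_a$offset, truth_a$bearing_deg,
                      truth_a$cave_radius %||% 3)
  b <- make_disk_cell(cb, rb, truth_b$offset, truth_b$bearing_deg,
                      truth_b$cave_radius %||% 3)
  chunk <- rbind(a$chunk, b$chunk)
  list(chunk = chunk, centers = list(ca, cb))
}

#' Paint pixel sets into a binary image
#'
#' @param pixel_sets list of (x, y) matrices to set to foreground.
#' @param width,height canvas dimensions.
#' @return a [binary_image].
#' @export
pixels_to_image <- function(pixel_sets, width, height) {
  m <- matrix(0L, height, width)
  for (p in pixel_sets) {
    ok <- p[, 1L] >= 0L & p[, 1L] < width & p[, 2L] >= 0L & p[, 2L] < height
    p <- p[ok, , drop = FALSE]
    m[cbind(p[, 2L] + 1L, p[, 1L] + 1L)] <- 1L
  }
  binary_image(m)
}

# von Mises sampler (Best & Fisher 1979 rejection algorithm).
# mu in degrees (ccw); returns degrees in [0, 360). kappa ~ 0 => uniform.
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u3 - 0.5) * acos(f) * 180 / pi) %% 360
    }
  }
  out
}

#' Generate a synthetic tissue image with known polarity
#'
#' Places `n` non-overlapping disk-with-hole cells at rejection-sampled
#' positions, draws bearings from the requested distribution, and returns
#' the rasterized binary image together with a ground-truth table. Optional
#' background speckles of bounded size exercise size exclusion. Fully
#' reproducible for a fixed seed.
#'
#' The default geometry is the stated world of a high-magnification confocal
#' mask: cell radii 17-20 px (area 880-1260 px, comfortably above the
#' default 500 px noise floor even after the cave is subtracted), cave
#' radius 6 px (about 110 px, above the default 15 px cave floor, roughly a
#' third of the cell diameter like a hair cell's fonticulus) and cave
#' offset 8-10 px (eccentric, about half the radius, as the fonticulus sits
#' toward the cell's lateral edge). At this geometry the rasterization error
#' of the measured angle stays below 2 degrees, so recovered bearings are
#' dominated by biology, not discretization.
#'
#' @param n number of cells.
#' @param bearing either a single number (fixed bearing for every cell),
#'   `"uniform"`, or `list(mu =, kappa =)` for von Mises draws.
#' @param seed integer random seed.
#' @param width,height canvas size in pixels.
#' @param radius_range,offset_range inclusive integer ranges sampled per cell.
#' @param cave_radius hole radius in pixels.
#' @param n_speckles,speckle_max_px number and maximum pixel size of noise
#'   speckles.
#' @param margin keep cell disks at least this far inside the border (so the
#'   default border exclusion does not fire); set 0 to allow border contact.
#' @return `list(image = binary_image, truth = data.frame(id, x, y,
#'   bearing_deg, radius, offset, shape))`.
#' @export
make_tissue <- function(n, bearing = "uniform", seed = 1,
                        width = 1024, height = 1024,
                        radius_range = c(17, 20), offset_range = c(8, 10),
                        cave_radius = 6, n_speckles = 0, speckle_max_px = 400,
                        margin = 12) {
  set.seed(seed)
  if (n == 0L) {
    return(list(image = pixels_to_image(list(), width, height),
                truth = data.frame(id = integer(0), x = numeric(0),
                                   y = numeric(0), bearing_deg = numeric(0),
                                   radius = numeric(0), offset = numeric(0),
                                   shape = character(0))))
  }
  bearings <- if (is.numeric(bearing) && length(bearing) == 1L) {
    rep(bearing %% 360, n)
  } else if (identical(bearing, "uniform")) {
    stats::runif(n, 0, 360)
  } else if (is.list(bearing)) {
    rvonmises_deg(n, bearing$mu, bearing$kappa)
  } else stop("bearing must be a number, \"uniform\", or list(mu=, kappa=)")
  rchoice <- seq(radius_range[1], radius_range[2])
  ochoice <- seq(offset_range[1], offset_range[2])
  radii <- rchoice[sample.int(length(rchoice), n, replace = TRUE)]
  offsets <- ochoice[sample.int(length(ochoice), n, replace = TRUE)]
  centers <- matrix(NA_real_, n, 2)
  max_attempts <- 200L * n
  attempts <- 0L
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place ", n, " cells in ", width, "x", height,
           " after ", max_attempts, " attempts; use larger dimensions")
    }
    r <- radii[placed + 1L]
    lo <- r + margin
    cand <- c(stats::runif(1, lo, width - 1 - lo),
              stats::runif(1, lo, height - 1 - lo))
    if (placed > 0L) {
      prev <- centers[seq_len(placed), , drop = FALSE]
      dmin <- sqrt(min((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2))
      if (dmin < r + max(radii[seq_len(placed)]) + 3) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  cells <- lapply(seq_len(n), function(i) {
    make_disk_cell(centers[i, ], radii[i], offsets[i], bearings[i],
                   cave_radius)$chunk
  })
  if (n_speckles > 0L) {
    sr <- pmax(1, floor(sqrt(speckle_max_px / pi)))
    for (k in seq_len(n_speckles)) {
      repeat {
        r <- sample(seq_len(sr), 1L)
        cand <- c(stats::runif(1, r + 1, width - r - 2),
                  stats::runif(1, r + 1, height - r - 2))
        dmin <- sqrt(min((centers[, 1] - cand[1])^2 +
                         (centers[, 2] - cand[2])^2))
        if (dmin > max(radii) + r + 4) break
      }
      cells <- c(cells, list(disk_pixels(cand, r)))
    }
  }
  truth <- data.frame(id = seq_len(n), x = centers[, 1], y = centers[, 2],
                      bearing_deg = bearings, radius = radii,
                      offset = offsets, shape = "disk_with_hole")
  list(image = pixels_to_image(cells, width, height), truth = truth)
}
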