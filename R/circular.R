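# Fisher circular descriptive statistics and rose (windmill) diagrams.

#' Circular descriptive statistics
#'
#' Standard Fisher statistics for angular data. With angles \eqn{\theta_i} in
#' radians, \eqn{C = \sum\cos\theta_i}, \eqn{S = \sum\sin\theta_i},
#' \eqn{R = \sqrt{C^2 + S^2}}: the mean angle is \eqn{atan2(S, C)}, the
#' resultant mean length is \eqn{RML = R/n} (1 = perfect alignment, 0 = full
#' dispersion), the circular variance is \eqn{1 - RML}, and the circular
#' standard deviation is \eqn{\sqrt{-2\ln RML}} converted to degrees.
#'
#' Angles supplied on a clockwise and/or signed axis are interpreted under
#' `conv`, and the mean is reported on that same axis. When the resultant
#' length vanishes (e.g. antipodal pairs), the mean is undefined: `NaN` is
#' returned with a warning and the SD is infinite.
#'
#' @param angles numeric vector of angles in degrees (on the `conv` axis).
#' @param conv an [angle_convention()].
#' @return `list(mean_angle, rml, circ_variance, circ_sd)`; `circ_sd` in
#'   degrees.
#' @export
circular_summary <- function(angles, conv = angle_convention()) {
  if (length(angles) == 0L) stop("need at least one angle")
  theta <- unconvert_axis(angles, conv) * pi / 180
  C <- sum(cos(theta)); S <- sum(sin(theta))
  r <- sqrt(C^2 + S^2) / length(theta)
  if (r < 1e-12) {
    warning("resultant mean length is zero: mean angle undefined")
    return(list(mean_angle = NaN, rml = 0, circ_variance = 1, circ_sd = Inf))
  }
  mean_ccw <- (atan2(S, C) * 180 / pi) %% 360
  list(mean_angle = convert_axis(mean_ccw, conv),
       rml = min(r, 1),
       circ_variance = 1 - min(r, 1),
       circ_sd = sqrt(max(-2 * log(min(r, 1)), 0) + 0) * 180 / pi)
}

#' Chunk summary statistics
#'
#' The per-run summary table: Processed Count (cells with a measured angle),
#' Bad Count (cells where no angle could be measured), Total Count, Processed
#' %, and the circular statistics of the measured angles.
#'
#' @param measurements measurement data frame from [measure_all()] (or any
#'   data frame with an `angle` column).
#' @param bad_count number of unmeasurable chunks.
#' @param conv an [angle_convention()].
#' @return a `summary_stats` list with fields `processed_count`, `bad_count`,
#'   `total_count`, `processed_pct`, `mean_angle`, `rml`, `circ_variance`,
#'   `circ_sd`. Angular fields are `NaN`/`NA` when nothing was measured.
#' @export
chunk_summary <- function(measurements, bad_count = 0L,
                          conv = angle_convention()) {
  p <- nrow(measurements)
  b <- as.integer(bad_count)
  total <- p + b
  ang <- if (p > 0L) circular_summary(measurements$angle, conv) else {
    list(mean_angle = NaN, rml = NaN, circ_variance = NaN, circ_sd = NaN)
  }
  structure(c(list(
    processed_count = p, bad_count = b, total_count = total,
    processed_pct = if (total > 0L) 100 * p / total else 0), ang),
    class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    paste0("Chunk summary: processed %d, bad %d, total %d (%.2f%%)\n",
           "  mean angle %.3f deg, RML %.5f, circ. variance %.5f, ",
           "circ. SD %.3f deg\n"),
    x$processed_count, x$bad_count, x$total_count, x$processed_pct,
    x$mean_angle, x$rml, x$circ_variance, x$circ_sd))
  invisible(x)
}

#' Rose (windmill) diagram
#'
#' Bins angles into half-open sectors `[k*w, (k+1)*w)` of width `w` degrees
#' and optionally renders a polar wedge plot (SVG) with the mean angle drawn
#' as a black radial line. Works stand-alone on any numeric angle data set,
#' whether or not it was produced by this package.
#'
#' @param angles numeric vector of angles in degrees; values are reduced
#'   modulo 360 for binning.
#' @param bin_width sector width in degrees; must divide 360 evenly.
#' @param path optional output path for an SVG rendering.
#' @param conv an [angle_convention()] (used for the mean-angle line).
#' @return invisibly, `list(counts, breaks)`: `counts[k]` is the number of
#'   angles in `[(k-1)*w, k*w)`.
#' @export
rose_diagram <- function(angles, bin_width = 15, path = NULL,
                         conv = angle_convention()) {
  if (bin_width <= 0 || 360 %% bin_width != 0) {
    stop("bin_width must divide 360 evenly")
  }
  nbins <- as.integer(360 / bin_width)
  a <- unconvert_axis(angles, conv)          # ccw screen angles for drawing
  counts <- if (length(a)) {
    tabulate(floor(a / bin_width) + 1L, nbins = nbins)
  } else integer(nbins)
  mean_deg <- if (length(a) > 0L) {
    s <- suppressWarnings(circular_summary(angles, conv))
    if (is.nan(s$mean_angle)) NULL else unconvert_axis(s$mean_angle, conv)
  } else NULL
  if (!is.null(path)) {
    writeLines(rose_svg(counts, bin_width, mean_deg), path)
  }
  invisible(list(counts = counts, breaks = seq(0, 360, by = bin_width)))
}

# Build the SVG markup for a rose diagram. Screen-angle mapping: a data
# angle of t degrees (ccw, 0 = east, 90 = north-on-screen) is drawn at
# canvas direction (cos t, -sin t) since SVG y grows downward.
rose_svg <- function(counts, bin_width, mean_deg = NULL, size = 480) {
  cx <- size / 2; cy <- size / 2
  rmax <- size / 2 - 40
  peak <- max(counts, 1L)
  pt <- function(t, r) {
    c(cx + r * cos(t * pi / 180), cy - r * sin(t * pi / 180))
  }
  wedges <- character(0)
  for (k in seq_along(counts)) {
    if (counts[k] == 0L) next
    r <- rmax * counts[k] / peak
    t0 <- (k - 1L) * bin_width; t1 <- k * bin_width
    p0 <- pt(t0, r); p1 <- pt(t1, r)
    large <- if (bin_width > 180) 1 else 0
    wedges <- c(wedges, sprintf(
      paste0("<path d=\"M %.2f %.2f L %.2f %.2f ",
             "A %.2f %.2f 0 %d 0 %.2f %.2f Z\" ",
             "fill=\"#4477aa\" fill-opacity=\"0.75\" ",
             "stroke=\"#223355\" stroke-width=\"1\"/>"),
      cx, cy, p0[1], p0[2], r, r, large, p1[1], p1[2]))
  }
  rings <- sprintf(
    "<circle cx=\"%.1f\" cy=\"%.1f\" r=\"%.2f\" fill=\"none\" stroke=\"#cccccc\"/>",
    cx, cy, rmax * c(0.25, 0.5, 0.75, 1))
  axes <- sprintf(
    "<line x1=\"%.1f\" y1=\"%.1f\" x2=\"%.2f\" y2=\"%.2f\" stroke=\"#dddddd\"/>",
    cx, cy, cx + rmax * cos(seq(0, 330, 30) * pi / 180),
    cy - rmax * sin(seq(0, 330, 30) * pi / 180))
  mean_line <- if (!is.null(mean_deg)) {
    p <- pt(mean_deg, rmax)
    sprintf(paste0("<line x1=\"%.1f\" y1=\"%.1f\" x2=\"%.2f\" y2=\"%.2f\" ",
                   "stroke=\"#000000\" stroke-width=\"2.5\"/>"),
            cx, cy, p[1], p[2])
  } else character(0)
  labels <- sprintf(
    paste0("<text x=\"%.1f\" y=\"%.1f\" font-size=\"14\" ",
           "text-anchor=\"middle\" fill=\"#333333\">%d</text>"),
    cx + (rmax + 18) * cos(c(0, 90, 180, 270) * pi / 180),
    cy - (rmax + 18) * sin(c(0, 90, 180, 270) * pi / 180) + 5,
    c(0L, 90L, 180L, 270L))
  c(sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">"),
            size, size, size, size),
    sprintf("<rect width=\"%d\" height=\"%d\" fill=\"white\"/>", size, size),
    axes, rings, wedges, mean_line, labels, "</svg>")
}
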