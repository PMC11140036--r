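# Annotated output images: pseudo-colored exclusion categories, directional
# arrows, id/angle labels, and the transparent overlay variant.

#' Default pseudo-color palette
#'
#' Colors for the annotated output, one per category, each a length-3
#' RGB vector in 0-255. Defaults: size-excluded cells pink, border-excluded
#' blue, unmeasurable red, wrap (bridging) pixels yellow, text orange,
#' arrows green. Any entry can be overridden.
#'
#' @param ... named overrides, e.g. `arrow = c(0, 200, 0)`.
#' @return named list of RGB vectors.
#' @export
default_palette <- function(...) {
  pal <- list(
    size_excluded   = c(255, 105, 180),
    border_excluded = c(0, 0, 255),
    unmeasurable    = c(255, 0, 0),
    wrap            = c(255, 255, 0),
    text            = c(255, 165, 0),
    arrow           = c(0, 255, 0)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(pal))
  if (length(bad)) stop("unknown palette entries: ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    v <- over[[nm]]
    if (!is.numeric(v) || length(v) != 3L || any(v < 0 | v > 255)) {
      stop("palette entry '", nm, "' must be 3 RGB values in 0-255")
    }
    pal[[nm]] <- v
  }
  pal
}

# 5x7 bitmap glyphs for annotation text (digits, '.', '-', ':').
# Each glyph is 7 strings of 5 characters; '#' = set pixel.
.glyphs <- local({
  g <- list(
    "0" = c(" ### ", "#   #", "#  ##", "# # #", "##  #", "#   #", " ### "),
    "1" = c("  #  ", " ##  ", "  #  ", "  #  ", "  #  ", "  #  ", " ### "),
    "2" = c(" ### ", "#   #", "    #", "   # ", "  #  ", " #   ", "#####"),
    "3" = c(" ### ", "#   #", "    #", "  ## ", "    #", "#   #", " ### "),
    "4" = c("   # ", "  ## ", " # # ", "#  # ", "#####", "   # ", "   # "),
    "5" = c("#####", "#    ", "#### ", "    #", "    #", "#   #", " ### "),
    "6" = c(" ### ", "#    ", "#    ", "#### ", "#   #", "#   #", " ### "),
    "7" = c("#####", "    #", "   # ", "  #  ", "  #  ", "  #  ", "  #  "),
    "8" = c(" ### ", "#   #", "#   #", " ### ", "#   #", "#   #", " ### "),
    "9" = c(" ### ", "#   #", "#   #", " ####", "    #", "    #", " ### "),
    "." = c("     ", "     ", "     ", "     ", "     ", "  ## ", "  ## "),
    "-" = c("     ", "     ", "     ", " ### ", "     ", "     ", "     "),
    ":" = c("     ", "  ## ", "  ## ", "     ", "  ## ", "  ## ", "     "),
    " " = c("     ", "     ", "     ", "     ", "     ", "     ", "     ")
  )
  lapply(g, function(rows) {
    do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]] == "#"))
  })
})

# Draw helpers operate on an h x w x 4 numeric array (RGBA, 0-255) in place.
set_pixels <- function(arr, xy, rgb, alpha = 255) {
  if (nrow(xy) == 0L) return(arr)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  ok <- xy[, 1L] >= 0L & xy[, 1L] < w & xy[, 2L] >= 0L & xy[, 2L] < h
  xy <- xy[ok, , drop = FALSE]
  for (k in 1:3) arr[cbind(xy[, 2L] + 1L, xy[, 1L] + 1L, k)] <- rgb[k]
  arr[cbind(xy[, 2L] + 1L, xy[, 1L] + 1L, 4L)] <- alpha
  arr
}

draw_text <- function(arr, x, y, text, rgb) {
  chars <- strsplit(text, "")[[1]]
  cx <- round(x)
  for (ch in chars) {
    glyph <- .glyphs[[ch]]
    if (!is.null(glyph)) {
      on <- which(glyph, arr.ind = TRUE)
      xy <- cbind(cx + on[, 2L] - 1L, round(y) + on[, 1L] - 1L)
      arr <- set_pixels(arr, xy, rgb)
    }
    cx <- cx + 6L
  }
  arr
}

# Arrow from the chunk centroid along `theta_ccw` (degrees, ccw, 0 = east,
# 90 = north on screen), of length 0.8 x the chunk bbox diagonal, with a
# simple two-stroke head.
draw_arrow <- function(arr, origin, theta_ccw, length_px, rgb) {
  t <- theta_ccw * pi / 180
  x0 <- round(origin[[1L]]); y0 <- round(origin[[2L]])
  x1 <- round(origin[[1L]] + length_px * cos(t))
  y1 <- round(origin[[2L]] - length_px * sin(t))
  arr <- set_pixels(arr, raster_line(x0, y0, x1, y1), rgb)
  head_len <- max(3, round(length_px * 0.25))
  for (da in c(150, -150)) {
    th <- (theta_ccw + da) * pi / 180
    hx <- round(x1 + head_len * cos(th))
    hy <- round(y1 - head_len * sin(th))
    arr <- set_pixels(arr, raster_line(x1, y1, hx, hy), rgb)
  }
  arr
}

annotate_measurement <- function(arr, chunk, angle_axis, theta_ccw, palette) {
  bb <- chunk_bbox(chunk)
  diag_len <- sqrt((bb["x_max"] - bb["x_min"] + 1)^2 +
                   (bb["y_max"] - bb["y_min"] + 1)^2)
  cc <- chunk_centroid(chunk)
  arr <- draw_arrow(arr, cc, theta_ccw, 0.8 * diag_len, palette$arrow)
  label <- sprintf("%d: %.3f", chunk$id, angle_axis)
  arr <- draw_text(arr, cc[["x"]] - 3 * nchar(label), cc[["y"]] + 4,
                   label, palette$text)
  arr
}

#' Write the annotated output image
#'
#' Renders the binary image in RGB with every chunk in exactly one category:
#' processed chunks stay white and get their id number, angle text and a
#' directional arrow; excluded chunks are pseudo-colored by category
#' (size-excluded, border-excluded, unmeasurable); bridging wrap pixels are
#' drawn in the wrap color. Output dimensions equal input dimensions.
#'
#' @param image the analyzed [binary_image].
#' @param measurements measurement data frame from [measure_all()].
#' @param chunks named list of chunk lists by category:
#'   `processed`, `size_excluded`, `border_excluded`, `unmeasurable`.
#' @param palette a [default_palette()]-style list.
#' @param path output PNG path.
#' @param conv the [angle_convention()] the measurement angles are on.
#' @return `path`, invisibly.
#' @export
write_annotated <- function(image, measurements, chunks,
                            palette = default_palette(), path,
                            conv = angle_convention()) {
  h <- image_height(image); w <- image_width(image)
  arr <- array(0, dim = c(h, w, 4L))
  arr[, , 4L] <- 255
  fg <- foreground_pixels(image)
  arr <- set_pixels(arr, fg, c(255, 255, 255))
  for (cat in c("size_excluded", "border_excluded", "unmeasurable")) {
    for (ch in chunks[[cat]] %||% list()) {
      arr <- set_pixels(arr, ch$pixels, palette[[cat]])
    }
  }
  for (ch in c(chunks$processed %||% list(), chunks$unmeasurable %||% list())) {
    arr <- set_pixels(arr, ch$wrap_pixels, palette$wrap)
  }
  by_id <- stats::setNames(chunks$processed %||% list(),
                           vapply(chunks$processed %||% list(),
                                  function(ch) ch$id, 0L))
  for (i in seq_len(nrow(measurements))) {
    ch <- by_id[[as.character(measurements$chunk_id[i])]]
    theta_ccw <- unconvert_axis(measurements$angle[i], conv)
    arr <- annotate_measurement(arr, ch, measurements$angle[i], theta_ccw,
                                palette)
  }
  png::writePNG(arr[, , 1:3] / 255, path)
  invisible(path)
}

#' Write the transparent overlay image
#'
#' An RGBA PNG containing only the id numbers, angle text and directional
#' arrows on a fully transparent background, sized to the source micrograph
#' so it can be composited over the original (zero-transparent overlay
#' semantics).
#'
#' @param measurements measurement data frame from [measure_all()].
#' @param chunks list of processed chunks (for arrow scaling).
#' @param width,height output dimensions (the source image's).
#' @param palette a [default_palette()]-style list.
#' @param path output PNG path.
#' @param conv the [angle_convention()] the measurement angles are on.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(measurements, chunks, width, height,
                          palette = default_palette(), path,
                          conv = angle_convention()) {
  arr <- array(0, dim = c(height, width, 4L))
  by_id <- stats::setNames(chunks, vapply(chunks, function(ch) ch$id, 0L))
  for (i in seq_len(nrow(measurements))) {
    ch <- by_id[[as.character(measurements$chunk_id[i])]]
    theta_ccw <- unconvert_axis(measurements$angle[i], conv)
    arr <- annotate_measurement(arr, ch, measurements$angle[i], theta_ccw,
                                palette)
  }
  png::writePNG(arr / 255, path)
  invisible(path)
}
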