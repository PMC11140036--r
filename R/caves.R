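# Cave detection: plastic-wrap bridging, enclosed background components,
# cave filtering and selection.

new_cave <- function(pixels, origin = "natural") {
  structure(list(pixels = pixels, size = nrow(pixels),
                 centroid = c(x = mean(pixels[, 1L]), y = mean(pixels[, 2L])),
                 origin = origin),
            class = "cave")
}

#' @export
print.cave <- function(x, ...) {
  cat(sprintf("<cave: %d px, centroid (%.2f, %.2f), %s>\n",
              x$size, x$centroid[1], x$centroid[2], x$origin))
  invisible(x)
}

#' Bridge open concavities ("plastic wrap")
#'
#' Indentations open to the background (e.g. the mouth of a U-shaped
#' stereocilia bundle) are not enclosed caves and would otherwise be
#' invisible to cave detection. This operation closes them: it takes the
#' convex hull of the chunk's pixel coordinates and, for every hull edge
#' whose one-pixel-thick digital line spans a genuine perimeter break (at
#' least one line pixel is neither a chunk pixel nor 8-adjacent to one),
#' adds the line's non-chunk pixels as bridging "wrap" pixels. The adjacency
#' condition keeps hull chords that merely graze the rim of a digitally
#' convex shape from depositing spurious pixels. Wrap
#' pixels count as cell mass for the centroid and act as cave boundary, but
#' never as cave interior. Applying the operation twice adds nothing
#' further, and a convex chunk is left untouched.
#'
#' @param chunk a chunk.
#' @param image the [binary_image] the chunk came from.
#' @return the chunk with its `wrap_pixels` filled in.
#' @export
plastic_wrap <- function(chunk, image) {
  pts <- rbind(chunk$pixels, chunk$wrap_pixels)
  if (nrow(pts) < 3L) return(chunk)
  hull <- grDevices::chull(pts[, 1L], pts[, 2L])
  if (length(hull) < 3L) return(chunk)   # collinear
  w <- image_width(image)
  own <- pix_key(pts, w)
  # pixels 8-adjacent to (or part of) the chunk/wrap mass: a hull chord that
  # merely grazes the rim of a digitally convex shape stays within this halo
  # and is not a perimeter break
  halo <- unique(c(outer(own, c(-w - 1L, -w, -w + 1L, -1L, 0L, 1L,
                                w - 1L, w, w + 1L), "+")))
  add <- empty_pixels()
  nh <- length(hull)
  for (i in seq_len(nh)) {
    a <- pts[hull[i], ]
    b <- pts[hull[if (i == nh) 1L else i + 1L], ]
    seg <- raster_line(a[1L], a[2L], b[1L], b[2L])
    keys <- pix_key(seg, w)
    # bridge only edges spanning a genuine gap: some pixel on the line is
    # neither chunk/wrap nor adjacent to it
    if (any(!(keys %in% halo))) {
      add <- rbind(add, seg[!(keys %in% own), , drop = FALSE])
    }
  }
  if (nrow(add) > 0L) {
    add <- add[!duplicated(pix_key(add, w)), , drop = FALSE]
    chunk$wrap_pixels <- rbind(chunk$wrap_pixels, add)
  }
  chunk
}

# Background pixels of `image` enclosed by barrier coordinates `barrier`
# (an x,y matrix): flood-fill 4-connected from the rim of the padded
# bounding box through everything that is not a barrier pixel; black pixels
# never reached are enclosed. Pixels of *other* chunks are passable, so a
# pocket sealed only jointly with a neighboring chunk does not count.
enclosed_background <- function(barrier, image) {
  w <- image_width(image); h <- image_height(image)
  x0 <- max(min(barrier[, 1L]) - 1L, -1L); x1 <- min(max(barrier[, 1L]) + 1L, w)
  y0 <- max(min(barrier[, 2L]) - 1L, -1L); y1 <- min(max(barrier[, 2L]) + 1L, h)
  bw <- x1 - x0 + 1L; bh <- y1 - y0 + 1L
  # local matrix [bh, bw]; TRUE = blocked
  block <- matrix(FALSE, bh, bw)
  block[cbind(barrier[, 2L] - y0 + 1L, barrier[, 1L] - x0 + 1L)] <- TRUE
  seen <- block
  rim <- unique(c(which(row(seen) == 1L | row(seen) == bh |
                        col(seen) == 1L | col(seen) == bw)))
  frontier <- rim[!seen[rim]]
  seen[frontier] <- TRUE
  while (length(frontier) > 0L) {
    fr <- (frontier - 1L) %% bh + 1L
    fc <- (frontier - 1L) %/% bh + 1L
    nr <- c(fr - 1L, fr + 1L, fr, fr)
    nc <- c(fc, fc, fc - 1L, fc + 1L)
    ok <- nr >= 1L & nr <= bh & nc >= 1L & nc <= bw
    ni <- unique((nc[ok] - 1L) * bh + nr[ok])
    ni <- ni[!seen[ni]]
    seen[ni] <- TRUE
    frontier <- ni
  }
  inner <- which(!seen)               # never reached, not barrier
  if (length(inner) == 0L) return(empty_pixels())
  px <- cbind(x = (inner - 1L) %/% bh + x0, y = (inner - 1L) %% bh + y0)
  # keep only true background pixels of the image (drop enclosed white
  # pixels belonging to other chunks)
  inside <- px[, 1L] >= 0L & px[, 1L] < w & px[, 2L] >= 0L & px[, 2L] < h
  px <- px[inside, , drop = FALSE]
  px[unclass(image)[cbind(px[, 2L] + 1L, px[, 1L] + 1L)] == 0L, , drop = FALSE]
}

#' Find caves enclosed within a chunk
#'
#' A cave is a 4-connected component of black pixels fully contained within
#' the body of the chunk: unreachable from outside the chunk's filled region
#' without crossing chunk or wrap pixels. Components that touch a wrap pixel
#' and were not already enclosed before wrapping are tagged
#' `origin = "wrap_created"`; a component merging natural and wrap-created
#' pockets inherits `wrap_created`.
#'
#' @param chunk a chunk (wrap already applied, if enabled).
#' @param image the source [binary_image].
#' @return list of cave objects in raster order of first pixel.
#' @export
find_caves <- function(chunk, image) {
  barrier <- rbind(chunk$pixels, chunk$wrap_pixels)
  enc <- enclosed_background(barrier, image)
  if (nrow(enc) == 0L) return(list())
  # component split (4-connected) of the enclosed set
  x0 <- min(enc[, 1L]); y0 <- min(enc[, 2L])
  bw <- max(enc[, 1L]) - x0 + 1L; bh <- max(enc[, 2L]) - y0 + 1L
  m <- matrix(0L, bh, bw)
  m[cbind(enc[, 2L] - y0 + 1L, enc[, 1L] - x0 + 1L)] <- 1L
  lab <- label_components(m, connectivity = 4L)
  has_wrap <- nrow(chunk$wrap_pixels) > 0L
  # keys offset by +1 so that out-of-image neighbor coordinates cannot
  # collide with real pixels
  kw <- image_width(image) + 2L
  key <- function(xy) (xy[, 1L] + 1L) + (xy[, 2L] + 1L) * kw
  if (has_wrap) {
    pre <- enclosed_background(chunk$pixels, image)
    pre_keys <- key(pre)
    wrap_keys <- key(chunk$wrap_pixels)
  }
  lapply(seq_len(max(lab)), function(i) {
    idx <- which(lab == i)
    px <- cbind(x = (idx - 1L) %/% bh + x0, y = (idx - 1L) %% bh + y0)
    px <- px[order(px[, 2L], px[, 1L]), , drop = FALSE]
    origin <- "natural"
    if (has_wrap) {
      keys <- key(px)
      new_px <- !all(keys %in% pre_keys)
      nb <- c(key(cbind(px[, 1L] + 1L, px[, 2L])),
              key(cbind(px[, 1L] - 1L, px[, 2L])),
              key(cbind(px[, 1L], px[, 2L] + 1L)),
              key(cbind(px[, 1L], px[, 2L] - 1L)))
      touches_wrap <- any(nb %in% wrap_keys)
      if (new_px && touches_wrap) origin <- "wrap_created"
    }
    new_cave(px, origin)
  })
}

#' Size-filter caves
#'
#' Removes caves smaller than `min_px` or larger than `max_px` before the
#' cave of interest is selected, e.g. to ignore speckle pockets introduced by
#' thresholding.
#'
#' @param caves list of caves.
#' @param min_px,max_px pixel-count limits, or `NULL` for no limit.
#' @return filtered list of caves.
#' @export
filter_caves <- function(caves, min_px = NULL, max_px = NULL) {
  if (!is.null(min_px) && !is.null(max_px) && min_px > max_px) {
    stop("min_px must not exceed max_px")
  }
  keep <- vapply(caves, function(cv) {
    cv$size >= (min_px %||% 0) && cv$size <= (max_px %||% Inf)
  }, NA)
  caves[keep]
}

#' Select the directional cave of interest
#'
#' One cave per chunk serves as the directional marker. `"largest"` picks the
#' biggest cave; the compass criteria pick the cave whose centroid is most in
#' that direction in image coordinates (north = smallest y, since y grows
#' downward). Ties break by larger size, then smaller centroid y, then
#' smaller centroid x, then detection order.
#'
#' @param caves list of (already size-filtered) caves.
#' @param criterion one of `"largest"`, `"northmost"`, `"southmost"`,
#'   `"eastmost"`, `"westmost"`.
#' @return the selected cave, or `NULL` for an empty list (the chunk is then
#'   unmeasurable and counts toward the Bad Count).
#' @export
select_cave <- function(caves,
                        criterion = c("largest", "northmost", "southmost",
                                      "eastmost", "westmost")) {
  criterion <- match.arg(criterion)
  if (length(caves) == 0L) return(NULL)
  size <- vapply(caves, function(cv) cv$size, 0)
  cx <- vapply(caves, function(cv) cv$centroid[["x"]], 0)
  cy <- vapply(caves, function(cv) cv$centroid[["y"]], 0)
  primary <- switch(criterion,
    largest = -size, northmost = cy, southmost = -cy,
    eastmost = -cx, westmost = cx)
  ord <- order(primary, -size, cy, cx, seq_along(caves))
  caves[[ord[1L]]]
}

#' Cave centroid
#'
#' Arithmetic mean of the cave's pixel coordinates.
#'
#' @param cave a cave.
#' @return named numeric `(x, y)`.
#' @export
cave_centroid <- function(cave) cave$centroid
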