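# Chunk detection: connected foreground components and their filters.

new_chunk <- function(id, pixels, status = "candidate",
                      wrap_pixels = empty_pixels(), split_origin = "none") {
  structure(list(id = as.integer(id), pixels = pixels, status = status,
                 wrap_pixels = wrap_pixels, split_origin = split_origin),
            class = "chunk")
}

#' @export
print.chunk <- function(x, ...) {
  bb <- chunk_bbox(x)
  cat(sprintf(
    "<chunk %d: %d px (+%d wrap), bbox [%d..%d]x[%d..%d], status %s>\n",
    x$id, nrow(x$pixels), nrow(x$wrap_pixels),
    bb[1], bb[3], bb[2], bb[4], x$status))
  invisible(x)
}

#' Chunk geometry accessors
#'
#' `chunk_size()` is the foreground pixel count (wrap pixels excluded, as used
#' by size filtering). `chunk_bbox()` is the tight inclusive bounding box
#' `(x_min, y_min, x_max, y_max)` of the pixels plus any wrap pixels.
#' `chunk_centroid()` is the arithmetic mean of the pixel coordinates,
#' *including* wrap pixels, which count as cell mass once bridging has run.
#'
#' @param chunk a chunk as returned by [find_chunks()].
#' @return `chunk_size()`: integer; `chunk_bbox()`: named numeric length 4;
#'   `chunk_centroid()`: named numeric `(x, y)`.
#' @export
chunk_size <- function(chunk) nrow(chunk$pixels)

#' @rdname chunk_size
#' @export
chunk_bbox <- function(chunk) {
  p <- rbind(chunk$pixels, chunk$wrap_pixels)
  c(x_min = min(p[, 1L]), y_min = min(p[, 2L]),
    x_max = max(p[, 1L]), y_max = max(p[, 2L]))
}

#' @rdname chunk_size
#' @export
chunk_centroid <- function(chunk) {
  p <- rbind(chunk$pixels, chunk$wrap_pixels)
  c(x = mean(p[, 1L]), y = mean(p[, 2L]))
}

# Label connected components of a 0/1 matrix. Vectorized frontier BFS:
# each sweep advances every pixel of the current frontier at once.
# Ids follow raster-scan order of each component's first-encountered pixel.
label_components <- function(mat, connectivity = 8L) {
  h <- nrow(mat); w <- ncol(mat)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 8L) {
    cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    cbind(dr = c(-1L, 0L, 0L, 1L), dc = c(0L, -1L, 1L, 0L))
  }
  idx <- which(mat == 1L)
  if (length(idx) == 0L) return(lab)
  r <- (idx - 1L) %% h + 1L
  c_ <- (idx - 1L) %/% h + 1L
  seeds <- idx[order(r, c_)]          # raster order: by row, then column
  next_id <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    next_id <- next_id + 1L
    lab[s] <- next_id
    frontier <- s
    while (length(frontier) > 0L) {
      fr <- (frontier - 1L) %% h + 1L
      fc <- (frontier - 1L) %/% h + 1L
      nr <- rep(fr, each = nrow(offs)) + offs[, 1L]
      nc <- rep(fc, each = nrow(offs)) + offs[, 2L]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      ni <- unique((nc[ok] - 1L) * h + nr[ok])
      ni <- ni[mat[ni] == 1L & lab[ni] == 0L]
      lab[ni] <- next_id
      frontier <- ni
    }
  }
  lab
}

#' Find chunks (connected foreground components)
#'
#' Aggregates abutting white pixels into chunks using 8-connectivity by
#' default, so diagonally touching pixels join one chunk. Ids are assigned in
#' raster-scan order of each component's first-encountered pixel, starting
#' at 1.
#'
#' @param image a [binary_image].
#' @param connectivity 8 (default) or 4.
#' @return list of chunk objects (possibly empty).
#' @export
find_chunks <- function(image, connectivity = 8L) {
  stopifnot(inherits(image, "binary_image"))
  lab <- label_components(unclass(image), connectivity)
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0L)
  h <- nrow(lab)
  px <- cbind(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
  lapply(seq_len(k), function(i) {
    sel <- lab[idx] == i
    p <- px[sel, , drop = FALSE]
    new_chunk(i, p[order(p[, 2L], p[, 1L]), , drop = FALSE])
  })
}

#' Size-based chunk exclusion
#'
#' Chunks with fewer than `min_px` or more than `max_px` pixels are excluded
#' from analysis (status `size_excluded`); counts use the chunk's own pixels,
#' since bridging pixels are only added later in the pipeline. Either limit
#' may be `NULL` (no limit).
#'
#' @param chunks list of chunks.
#' @param min_px,max_px pixel-count limits, or `NULL`.
#' @return `list(kept =, excluded =)` of chunk lists.
#' @export
apply_size_filter <- function(chunks, min_px = NULL, max_px = NULL) {
  if (!is.null(min_px) && !is.null(max_px) && min_px > max_px) {
    stop("min_px must not exceed max_px")
  }
  sizes <- vapply(chunks, chunk_size, 0L)
  bad <- (!is.null(min_px) & sizes < (min_px %||% -Inf)) |
         (!is.null(max_px) & sizes > (max_px %||% Inf))
  excluded <- lapply(chunks[bad], function(ch) { ch$status <- "size_excluded"; ch })
  list(kept = chunks[!bad], excluded = excluded)
}

#' Border-proximity chunk exclusion
#'
#' A chunk is excluded (status `border_excluded`) if any of its pixels lies
#' within `margin` pixels of the image border: x < margin, y < margin,
#' x >= width - margin or y >= height - margin. A margin of 0 excludes
#' nothing. This filters cells that did not fully enter the imaging frame.
#'
#' @param chunks list of chunks.
#' @param width,height image dimensions in pixels.
#' @param margin border margin in pixels (>= 0).
#' @return `list(kept =, excluded =)` of chunk lists.
#' @export
apply_border_filter <- function(chunks, width, height, margin) {
  stopifnot(margin >= 0)
  if (margin > min(width, height) / 2) {
    warning("border margin ", margin, " exceeds half the smaller image ",
            "dimension; every chunk will be excluded")
  }
  bad <- vapply(chunks, function(ch) {
    p <- ch$pixels
    any(p[, 1L] < margin | p[, 2L] < margin |
        p[, 1L] >= width - margin | p[, 2L] >= height - margin)
  }, NA)
  excluded <- lapply(chunks[bad], function(ch) { ch$status <- "border_excluded"; ch })
  list(kept = chunks[!bad], excluded = excluded)
}

#' Split a fused cell doublet in half
#'
#' Two touching or overlapping cells form one elongated chunk. If the chunk's
#' bounding box is at least `ratio` times wider than tall, it is split at the
#' vertical midline `x = x_min + floor(width / 2)` (pixels strictly left of
#' the line form the first half, the rest the second); symmetrically for
#' chunks at least `ratio` times taller than wide. Otherwise the chunk is
#' returned unchanged. Halves are treated as discrete cells downstream and
#' are never re-split, so aggregates of three or more cells cannot be
#' separated this way. The heuristic is most accurate for doublets aligned
#' with the image axes and degrades toward 45 degrees.
#'
#' @param chunk a candidate chunk.
#' @param ratio aspect-ratio trigger, > 1 (typical values 1.5-2).
#' @param next_id first id to assign to the halves if a split happens.
#' @return list of 1 (no split) or 2 chunks.
#' @export
split_doublets <- function(chunk, ratio, next_id = chunk$id) {
  stopifnot(ratio > 1)
  bb <- chunk_bbox(chunk)
  w <- bb["x_max"] - bb["x_min"] + 1
  h <- bb["y_max"] - bb["y_min"] + 1
  p <- chunk$pixels
  halves <- if (w / h >= ratio) {
    cut <- bb["x_min"] + floor(w / 2)
    list(first = p[p[, 1L] < cut, , drop = FALSE],
         second = p[p[, 1L] >= cut, , drop = FALSE],
         origin = c("left-half", "right-half"))
  } else if (h / w >= ratio) {
    cut <- bb["y_min"] + floor(h / 2)
    list(first = p[p[, 2L] < cut, , drop = FALSE],
         second = p[p[, 2L] >= cut, , drop = FALSE],
         origin = c("top-half", "bottom-half"))
  } else {
    return(list(chunk))
  }
  if (nrow(halves$first) == 0L || nrow(halves$second) == 0L) {
    return(list(chunk))               # degenerate 1-px-wide bbox
  }
  list(new_chunk(next_id, halves$first, split_origin = halves$origin[1]),
       new_chunk(next_id + 1L, halves$second, split_origin = halves$origin[2]))
}

# Pipeline helper: split every kept chunk once, assigning fresh ids to halves
# after the current maximum id.
apply_doublet_split <- function(chunks, ratio, all_ids) {
  next_id <- if (length(all_ids)) max(all_ids) + 1L else 1L
  out <- list()
  for (ch in chunks) {
    res <- split_doublets(ch, ratio, next_id)
    if (length(res) == 2L) next_id <- next_id + 2L
    out <- c(out, res)
  }
  out
}
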