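# Independent oracles used by property and acceptance tests. These are
# deliberately written as naive scalar algorithms, sharing no code with the
# package implementation.

# Stack-based scalar flood-fill labeling, raster-scan seed order.
oracle_label <- function(mat, connectivity = 8L) {
  h <- nrow(mat); w <- ncol(mat)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 8L) {
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
         c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  }
  nid <- 0L
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (mat[r, cc] != 1L || lab[r, cc] != 0L) next
    nid <- nid + 1L
    stack <- list(c(r, cc))
    lab[r, cc] <- nid
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        rr <- p[1] + o[1]; c2 <- p[2] + o[2]
        if (rr >= 1L && rr <= h && c2 >= 1L && c2 <= w &&
            mat[rr, c2] == 1L && lab[rr, c2] == 0L) {
          lab[rr, c2] <- nid
          stack[[length(stack) + 1L]] <- c(rr, c2)
        }
      }
    }
  }
  lab
}

# Direct trigonometric circular statistics via complex arithmetic.
oracle_circ <- function(angles_deg) {
  z <- sum(exp(1i * angles_deg * pi / 180))
  n <- length(angles_deg)
  rml <- Mod(z) / n
  list(mean_angle = (Arg(z) * 180 / pi) %% 360, rml = rml,
       circ_variance = 1 - rml,
       circ_sd = sqrt(-2 * log(rml)) * 180 / pi)
}

# Scalar 4-connected flood fill from a pixel through non-barrier pixels;
# TRUE if the fill can escape outside the barrier's padded bounding box.
oracle_escapes <- function(x, y, barrier) {
  bkeys <- paste(barrier[, 1L], barrier[, 2L])
  x0 <- min(barrier[, 1L]) - 1L; x1 <- max(barrier[, 1L]) + 1L
  y0 <- min(barrier[, 2L]) - 1L; y1 <- max(barrier[, 2L]) + 1L
  seen <- new.env(hash = TRUE)
  stack <- list(c(x, y))
  while (length(stack) > 0L) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (p[1] < x0 || p[1] > x1 || p[2] < y0 || p[2] > y1) return(TRUE)
    k <- paste(p[1], p[2])
    if (!is.null(seen[[k]])) next
    seen[[k]] <- TRUE
    if (k %in% bkeys) next
    for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      stack[[length(stack) + 1L]] <- p + o
    }
  }
  FALSE
}

# Smallest circular difference in degrees.
circ_err <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# Decode a hex-text fixture into a binary file; returns the temp path.
hex_fixture <- function(name) {
  hexpath <- system.file("extdata", name, package = "polarcell")
  h <- paste(readLines(hexpath, warn = FALSE), collapse = "")
  out <- tempfile(fileext = ".tif")
  bytes <- strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)), 16L)
  writeBin(as.raw(bytes), out)
  out
}

# Match measured cells to ground-truth cells by nearest centroid; returns
# per-truth-row measured angle (NA if unmatched).
match_truth <- function(measurements, truth, max_dist = 10) {
  vapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((measurements$chunk_x - truth$x[i])^2 +
              (measurements$chunk_y - truth$y[i])^2)
    j <- which.min(d)
    if (length(j) == 0L || d[j] > max_dist) NA_real_ else measurements$angle[j]
  }, 0)
}
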