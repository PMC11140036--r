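# Minimal baseline TIFF codec.
#
# No TIFF-capable R package is available in the target environment, so this
# file implements the small subset of TIFF 6.0 the package needs: reading
# single-plane 8-bit grayscale images (uncompressed or LZW, horizontal
# predictor 1 or 2, II or MM byte order, multi-strip), and writing
# uncompressed 8-bit grayscale. Anything else is rejected with a message
# naming the preprocessing required.

read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  le <- switch(order_tag, II = TRUE, MM = FALSE,
               stop("not a TIFF file: ", path))
  u16 <- function(off) read_uint(raw, off, 2L, le)
  u32 <- function(off) read_uint(raw, off, 4L, le)
  if (u16(3L) != 42L) stop("not a TIFF file: ", path)
  ifd <- u32(5L)
  n_entries <- u16(ifd + 1L)
  tags <- list()
  for (i in seq_len(n_entries) - 1L) {
    e <- ifd + 3L + i * 12L
    tag <- u16(e); type <- u16(e + 2L); count <- u32(e + 4L)
    size <- c(1L, 1L, 2L, 4L, 8L)[type]  # BYTE ASCII SHORT LONG RATIONAL
    if (is.na(size)) next
    voff <- if (size * count <= 4L) e + 8L else u32(e + 8L) + 1L
    vals <- if (type == 3L) {
      vapply(seq_len(count) - 1L, function(k) u16(voff + 2L * k), 0)
    } else if (type == 4L) {
      vapply(seq_len(count) - 1L, function(k) u32(voff + 4L * k), 0)
    } else if (type == 1L) {
      as.integer(raw[voff + seq_len(count) - 1L])
    } else next
    tags[[as.character(tag)]] <- vals
  }
  g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
  if (u32(ifd + 3L + n_entries * 12L) != 0L) {
    stop("multi-page TIFF is unsupported: extract a single plane first")
  }
  w <- g(256); h <- g(257)
  if (is.null(w) || is.null(h)) stop("TIFF missing image dimensions")
  spp <- g(277, 1L)
  bps <- g(258, 1L)
  if (spp != 1L) {
    stop("multi-channel (", spp, " samples/pixel) TIFF is unsupported: ",
         "split channels to single-plane grayscale first")
  }
  if (!identical(as.integer(bps), 8L)) {
    stop("only 8-bit grayscale TIFF is supported (got ", bps,
         "-bit): convert to 8-bit first")
  }
  comp <- g(259, 1L)
  photo <- g(262, 1L)
  if (!photo %in% c(0L, 1L)) {
    stop("non-grayscale TIFF (photometric ", photo, ") is unsupported")
  }
  pred <- g(317, 1L)
  offs <- g(273); cnts <- g(279)
  if (is.null(offs) || is.null(cnts)) stop("TIFF missing strip layout")
  rps <- min(g(278, h), h)
  out <- integer(w * h)
  row0 <- 0L
  for (s in seq_along(offs)) {
    strip <- raw[offs[s] + seq_len(cnts[s])]
    nrow_s <- min(rps, h - row0)
    bytes <- switch(as.character(comp),
      "1" = as.integer(strip),
      "5" = lzw_decode(strip, w * nrow_s),
      stop("TIFF compression ", comp,
           " is unsupported: save uncompressed or LZW")
    )
    if (length(bytes) < w * nrow_s) stop("truncated TIFF strip data")
    m <- matrix(bytes[seq_len(w * nrow_s)], nrow = nrow_s, ncol = w,
                byrow = TRUE)
    if (pred == 2L) m <- t(apply(m, 1L, function(r) cumsum(r) %% 256L))
    out[(row0 * w) + seq_len(w * nrow_s)] <- t(m)
    row0 <- row0 + nrow_s
  }
  mat <- matrix(out, nrow = h, ncol = w, byrow = TRUE)
  if (photo == 0L) mat <- 255L - mat  # min-is-white
  mat
}

read_uint <- function(raw, off, nbytes, le) {
  b <- as.integer(raw[off + seq_len(nbytes) - 1L])
  if (le) b <- rev(b)
  v <- 0
  for (x in b) v <- v * 256 + x
  v
}

# TIFF-variant LZW (MSB-first bit packing, 9-bit initial codes, clear = 256,
# EOI = 257, "early change" code-width bumps).
lzw_decode <- function(strip, max_out) {
  bits <- matrix(as.integer(rawToBits(strip)), nrow = 8L)[8:1, , drop = FALSE]
  bits <- as.integer(bits)            # MSB-first bit stream
  nbits <- length(bits)
  pos <- 1L
  width <- 9L
  dict <- vector("list", 4096L)
  for (i in 1:256) dict[[i]] <- i - 1L
  dsize <- 258L
  out <- integer(max_out + 256L)
  oi <- 0L
  prev <- NULL
  pow <- 2^(16:0)
  repeat {
    if (pos + width - 1L > nbits) break
    code <- sum(bits[pos:(pos + width - 1L)] * pow[(18L - width):17L])
    pos <- pos + width
    if (code == 256L) {               # clear
      dsize <- 258L; width <- 9L; prev <- NULL
      next
    }
    if (code == 257L) break           # end of information
    if (is.null(prev)) {
      entry <- dict[[code + 1L]]
    } else if (code < dsize) {
      entry <- dict[[code + 1L]]
      dsize <- dsize + 1L
      dict[[dsize]] <- c(prev, entry[1L])
    } else {
      entry <- c(prev, prev[1L])
      dsize <- dsize + 1L
      dict[[dsize]] <- entry
    }
    ne <- length(entry)
    out[oi + seq_len(ne)] <- entry
    oi <- oi + ne
    prev <- entry
    if (dsize >= 2L^width - 1L && width < 12L) width <- width + 1L
  }
  out[seq_len(min(oi, max_out))]
}

# Uncompressed little-endian single-strip grayscale writer.
write_tiff_gray <- function(mat, path) {
  storage.mode(mat) <- "integer"
  h <- nrow(mat); w <- ncol(mat)
  pix <- as.raw(as.integer(t(mat)))
  u16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  u32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con); u16(42L); u32(8L)      # header, IFD at 8
  entries <- list(                                        # tag, type, value
    c(256L, 4L, w), c(257L, 4L, h), c(258L, 3L, 8L), c(259L, 3L, 1L),
    c(262L, 3L, 1L), c(273L, 4L, 0L),                     # offset patched below
    c(277L, 3L, 1L), c(278L, 4L, h), c(279L, 4L, length(pix))
  )
  data_off <- 8L + 2L + 12L * length(entries) + 4L
  entries[[6]][3] <- data_off
  u16(length(entries))
  for (e in entries) {
    u16(e[1]); u16(e[2]); u32(1L)
    if (e[2] == 3L) { u16(e[3]); u16(0L) } else u32(e[3])
  }
  u32(0L)                                                 # no next IFD
  writeBin(pix, con)
  invisible(path)
}
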