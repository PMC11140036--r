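#' Binary image container
#'
#' A `binary_image` wraps an integer matrix with values in \{0, 1\}, where 1 is
#' foreground (white, cell surface) and 0 is background (black). The matrix is
#' indexed `[y + 1, x + 1]`: the origin (x = 0, y = 0) is the top-left pixel,
#' x grows rightward and y grows downward, matching screen/raster conventions
#' of the microscopy tools this package interoperates with.
#'
#' @param pixels integer or numeric matrix of 0/1 values; rows are image rows
#'   (y), columns are image columns (x).
#' @return an object of class `binary_image`.
#' @examples
#' img <- binary_image(matrix(c(0, 1, 1, 0), 2, 2))
#' image_width(img)
#' @export
binary_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("binary image must be at least 1x1")
  }
  storage.mode(pixels) <- "integer"
  if (!all(pixels == 0L | pixels == 1L)) {
    stop("binary image values must all be 0 or 1")
  }
  structure(pixels, class = "binary_image")
}

#' @rdname binary_image
#' @param x a `binary_image`.
#' @export
image_width <- function(x) ncol(x)

#' @rdname binary_image
#' @export
image_height <- function(x) nrow(x)

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image %d x %d px, %d foreground px>\n",
              image_width(x), image_height(x), sum(x == 1L)))
  invisible(x)
}

# Coordinates (0-based x,y matrix) of all foreground pixels, raster order
# (left-to-right within top-to-bottom rows).
foreground_pixels <- function(img) {
  idx <- which(t(unclass(img)) == 1L) - 1L  # transpose => raster order
  w <- ncol(img)
  cbind(x = idx %% w, y = idx %/% w)
}

#' Read a grayscale or binary mask image
#'
#' Reads a single-plane PNG or TIFF and binarizes it. Images that are already
#' binary (only values \{0, 1\} or \{0, 255\} on the 8-bit scale) pass through
#' losslessly. Other grayscale images are thresholded: values at or above the
#' threshold become foreground. Multi-channel (RGB/RGBA) and multi-plane
#' inputs are rejected: split channels and z-project to a single 8-bit plane
#' upstream (e.g. in Fiji) before analysis.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file. PNG must be 8-bit;
#'   TIFF must be 8-bit grayscale, uncompressed or LZW.
#' @param threshold `"auto"` (Otsu's method) or a cutoff intensity in
#'   `[0, 255]`; pixels with intensity `>= threshold` map to foreground.
#' @param invert if `TRUE`, swap foreground and background after binarizing
#'   (for masks drawn with black cells on white, e.g. inverted LUTs).
#' @return a [binary_image].
#' @export
read_mask <- function(path, threshold = "auto", invert = FALSE) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  gray <- switch(ext,
    png = read_png_gray(path),
    tif = ,
    tiff = read_tiff_gray(path),
    stop("unsupported image format '.", ext, "': use single-plane PNG or TIFF")
  )
  binarize_gray(gray, threshold, invert)
}

read_png_gray <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch == 2L) {
      arr <- arr[, , 1L]  # gray + alpha: alpha carries no mask information
    } else {
      stop("multi-channel (", nch, "-channel) image is unsupported: split ",
           "channels and convert to single-plane 8-bit grayscale first")
    }
  }
  round(arr * 255)
}

binarize_gray <- function(gray, threshold = "auto", invert = FALSE) {
  vals <- sort(unique(as.vector(gray)))
  if (all(vals %in% c(0, 1))) {
    bin <- gray                      # already 0/1
  } else if (all(vals %in% c(0, 255))) {
    bin <- gray / 255                # already binary on the 8-bit scale
  } else {
    thr <- if (identical(threshold, "auto")) otsu_threshold(gray) else {
      if (!is.numeric(threshold) || length(threshold) != 1L ||
          threshold < 0 || threshold > 255) {
        stop("`threshold` must be \"auto\" or a number in [0, 255]")
      }
      threshold
    }
    bin <- (gray >= thr) * 1
  }
  if (invert) bin <- 1 - bin
  binary_image(bin)
}

# Otsu's method on the 0..255 histogram: threshold t maximizing between-class
# variance; foreground is >= t. Returns a cutoff in [1, 255].
otsu_threshold <- function(gray) {
  h <- tabulate(as.vector(gray) + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)                       # pixels with value <= t-1 if cut at t
  mu0 <- cumsum(h * lev)
  mu_t <- mu0[256]
  w1 <- n - w0
  between <- numeric(255)
  for (t in 1:255) {
    a <- w0[t]; b <- w1[t]
    if (a == 0 || b == 0) { between[t] <- 0; next }
    m0 <- mu0[t] / a
    m1 <- (mu_t - mu0[t]) / b
    between[t] <- a * b * (m0 - m1)^2
  }
  which.max(between)  # cut value: foreground >= this level
}

#' Write a binary mask image
#'
#' Writes a [binary_image] as an 8-bit grayscale PNG or TIFF with foreground
#' as 255 and background as 0, so that [read_mask()] round-trips losslessly.
#'
#' @param image a [binary_image].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(image, path) {
  stopifnot(inherits(image, "binary_image"))
  gray <- unclass(image) * 255L
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(gray / 255, path),
    tif = ,
    tiff = write_tiff_gray(gray, path),
    stop("unsupported output format '.", ext, "'")
  )
  invisible(path)
}
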