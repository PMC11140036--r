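# Image reading, binarization and annotated/overlay output.

write_gray_png <- function(mat, path = tempfile(fileext = ".png")) {
  png::writePNG(mat / 255, path)
  path
}

test_that("read_mask binarizes grayscale with explicit and pass-through semantics", {
  # saturated / empty inputs
  p <- write_gray_png(matrix(255, 4, 5))
  expect_true(all(read_mask(p) == 1L))
  p <- write_gray_png(matrix(0, 4, 5))
  expect_true(all(read_mask(p) == 0L))
  # threshold semantics: >= threshold is foreground
  m <- matrix(c(10, 200, 10, 200), 2, 2)
  p <- write_gray_png(m)
  img <- read_mask(p, threshold = 128)
  expect_identical(unclass(img), matrix(c(0L, 1L, 0L, 1L), 2, 2))
  img <- read_mask(p, threshold = 128, invert = TRUE)
  expect_identical(unclass(img), matrix(c(1L, 0L, 1L, 0L), 2, 2))
  # {0, 255} images pass through losslessly regardless of threshold
  p <- write_gray_png(matrix(c(0, 255), 2, 4))
  expect_identical(unclass(read_mask(p, threshold = 999)),
                   matrix(c(0L, 1L), 2, 4))
})

test_that("Otsu auto-threshold separates a bimodal image", {
  m <- matrix(c(rep(20, 50), rep(31, 3), rep(230, 47)), 10, 10)
  p <- write_gray_png(m)
  img <- read_mask(p, threshold = "auto")
  expect_identical(sum(img == 1L), 47L)
})

test_that("multi-channel input is rejected with a preprocessing hint", {
  p <- tempfile(fileext = ".png")
  png::writePNG(array(runif(4 * 5 * 3), c(4, 5, 3)), p)
  expect_error(read_mask(p), "split channels")
})

test_that("mask write/read round trip reproduces the pixel grid", {
  set.seed(7)
  img <- binary_image(matrix(rbinom(30 * 20, 1, 0.4), 30, 20))
  for (ext in c(".png", ".tif")) {
    p <- tempfile(fileext = ext)
    write_mask(img, p)
    expect_identical(unclass(read_mask(p)), unclass(img), info = ext)
  }
})

test_that("TIFF reader matches an independent reference encoder", {
  # fixtures written once by Python tifffile from the recomputable pattern
  # value(x, y) = (3x + 7y^2) mod 251
  expected <- outer(0:127, 0:127, function(y, x) (3 * x + 7 * y * y) %% 251)
  for (f in c("plain_tif.hex", "lzw_tif.hex", "lzw_pred_tif.hex")) {
    m <- polarcell:::read_tiff_gray(hex_fixture(f))
    expect_identical(dim(m), c(128L, 128L), info = f)
    expect_true(all(m == expected), info = f)
  }
})

test_that("unsupported TIFF flavors are rejected, not misread", {
  # RGB PNG masquerading via tifffile is not available offline; craft a
  # 3-sample TIFF header by patching SamplesPerPixel in our own output
  p <- tempfile(fileext = ".tif")
  polarcell:::write_tiff_gray(matrix(0L, 4, 4), p)
  raw <- readBin(p, "raw", file.info(p)$size)
  # entry 7 (277 SamplesPerPixel) value word: patch 1 -> 3
  off <- 8 + 2 + 6 * 12 + 8
  raw[off + 1] <- as.raw(3)
  writeBin(raw, p)
  expect_error(read_mask(p), "multi-channel")
})

make_category_fixture <- function() {
  # one good cell, one tiny speckle, one border-touching cell
  good <- make_disk_cell(c(30, 30), 10, 4, 0, 2)$chunk
  speck <- cbind(x = 55:57, y = rep(55, 3))
  border <- make_disk_cell(c(75, 8), 8, 3, 90, 2)$chunk
  img <- pixels_to_image(list(good, speck, border), 96, 96)
  cfg <- default_config(min_chunk_px = 50, border_margin_px = 10,
                        min_cave_px = NULL)
  list(img = img, res = run_single(img, cfg), cfg = cfg)
}

test_that("annotated image colors categories and preserves dimensions", {
  fx <- suppressMessages(make_category_fixture())
  p <- tempfile(fileext = ".png")
  write_annotated(fx$img, fx$res$measurements, fx$res$chunks,
                  default_palette(), p)
  arr <- png::readPNG(p)
  expect_identical(dim(arr)[1:2], c(96L, 96L))
  rgb255 <- round(arr * 255)
  pix_color <- function(xy) rgb255[xy[2] + 1, xy[1] + 1, ]
  # speckle rendered pink (size-excluded), border cell blue
  expect_equal(pix_color(c(55, 55)), c(255, 105, 180))
  border_ch <- fx$res$chunks$border_excluded[[1]]
  expect_equal(pix_color(border_ch$pixels[5, ]), c(0, 0, 255))
  # one processed chunk -> exactly one id label and arrow in their colors
  expect_identical(length(fx$res$chunks$processed), 1L)
  expect_gt(sum(rgb255[, , 1] == 0 & rgb255[, , 2] == 255 &
                  rgb255[, , 3] == 0), 0)   # arrow green present
  expect_gt(sum(rgb255[, , 1] == 255 & rgb255[, , 2] == 165 &
                  rgb255[, , 3] == 0), 0)   # text orange present
  # every chunk lands in exactly one category
  ncat <- vapply(fx$res$chunks, length, 0L)
  expect_identical(sum(ncat), 3L)
})

test_that("overlay is transparent and arrows honor the north convention", {
  # empty results -> fully transparent canvas
  p <- tempfile(fileext = ".png")
  empty <- measure_all(list(), list())$measurements
  write_overlay(empty, list(), 20, 20, default_palette(), p)
  arr <- png::readPNG(p)
  expect_true(all(arr[, , 4] == 0))

  # one measurement at 90 degrees: arrow extends strictly upward
  cell <- make_disk_cell(c(32, 40), 12, 5, 90)
  img <- pixels_to_image(list(cell$chunk), 64, 72)
  cfg <- default_config(min_chunk_px = NULL, border_margin_px = 0,
                        min_cave_px = NULL)
  res <- suppressMessages(run_single(img, cfg))
  expect_equal(res$measurements$angle, 90, tolerance = 1e-6)
  p <- tempfile(fileext = ".png")
  write_overlay(res$measurements, res$chunks$processed, 64, 72,
                default_palette(arrow = c(10, 250, 10)), p)
  arr <- round(png::readPNG(p) * 255)
  green <- which(arr[, , 1] == 10 & arr[, , 2] == 250 & arr[, , 3] == 10 &
                   arr[, , 4] == 255, arr.ind = TRUE)
  expect_gt(nrow(green), 0)
  cc <- chunk_centroid(res$chunks$processed[[1]])
  expect_true(all(green[, 1] - 1 <= cc[["y"]]))       # nothing below centroid
  expect_true(any(green[, 1] - 1 < cc[["y"]] - 5))    # extends well upward
})
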