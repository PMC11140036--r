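# Connected-component chunk detection, exclusion filters, doublet splitting.

img_from_coords <- function(xy, w = 8, h = 8) {
  pixels_to_image(list(xy), w, h)
}

test_that("find_chunks handles connectivity and raster-order ids", {
  # single pixel
  ch <- find_chunks(img_from_coords(cbind(3, 4)))
  expect_length(ch, 1)
  expect_identical(chunk_size(ch[[1]]), 1L)
  expect_equal(chunk_centroid(ch[[1]]), c(x = 3, y = 4))
  # diagonal abutment joins under 8-connectivity...
  ch <- find_chunks(img_from_coords(cbind(c(0, 1), c(0, 1))))
  expect_length(ch, 1)
  # ...but not under 4-connectivity
  ch <- find_chunks(img_from_coords(cbind(c(0, 1), c(0, 1))), connectivity = 4)
  expect_length(ch, 2)
  # separated pixels are distinct chunks, ids in raster order
  ch <- find_chunks(img_from_coords(cbind(c(5, 0), c(5, 0))))
  expect_length(ch, 2)
  expect_identical(ch[[1]]$id, 1L)
  expect_equal(ch[[1]]$pixels[1, ], c(x = 0, y = 0))
  # all-black image -> empty list
  expect_length(find_chunks(binary_image(matrix(0L, 5, 5))), 0)
})

test_that("labeling matches the scalar flood-fill oracle on random images", {
  set.seed(11)
  for (i in 1:12) {
    mat <- matrix(rbinom(64 * 64, 1, runif(1, 0.2, 0.7)), 64, 64)
    expect_identical(polarcell:::label_components(mat, 8L), oracle_label(mat, 8L))
  }
  # conservation: chunk sizes sum to the white pixel count
  img <- binary_image(matrix(rbinom(64 * 64, 1, 0.5), 64, 64))
  chunks <- find_chunks(img)
  expect_identical(sum(vapply(chunks, chunk_size, 0L)), sum(img == 1L))
})

test_that("size filter uses strict bounds on pixel counts", {
  mk <- function(n) polarcell:::new_chunk(n, cbind(x = seq_len(n), y = rep(1L, n)))
  chunks <- list(mk(400), mk(500), mk(501))
  sf <- apply_size_filter(chunks, min_px = 500)
  expect_length(sf$excluded, 1)           # the 400 px chunk only
  expect_identical(sf$excluded[[1]]$id, 400L)
  expect_identical(sf$excluded[[1]]$status, "size_excluded")
  # no limits set -> all kept
  sf <- apply_size_filter(chunks)
  expect_length(sf$kept, 3)
  # max bound
  sf <- apply_size_filter(chunks, max_px = 500)
  expect_identical(sf$excluded[[1]]$id, 501L)
  expect_error(apply_size_filter(chunks, min_px = 10, max_px = 5), "min_px")
})

test_that("border filter excludes any chunk with a pixel inside the margin", {
  near <- polarcell:::new_chunk(1L, cbind(x = c(5L, 30L), y = c(50L, 60L)))
  inside <- polarcell:::new_chunk(2L, cbind(x = 10L, y = 10L))
  bf <- apply_border_filter(list(near, inside), 1024, 1024, 10)
  expect_length(bf$excluded, 1)
  expect_identical(bf$excluded[[1]]$id, 1L)
  expect_identical(bf$excluded[[1]]$status, "border_excluded")
  # boundary: x = margin is kept, x = margin - 1 is not
  at <- polarcell:::new_chunk(3L, cbind(x = 10L, y = 500L))
  expect_length(apply_border_filter(list(at), 1024, 1024, 10)$excluded, 0)
  # margin 0 excludes nothing, even chunks touching the edge
  edge <- polarcell:::new_chunk(4L, cbind(x = 0L, y = 0L))
  expect_length(apply_border_filter(list(edge), 64, 64, 0)$excluded, 0)
  # far side: x >= width - margin
  farx <- polarcell:::new_chunk(5L, cbind(x = 1014L, y = 500L))
  expect_length(apply_border_filter(list(farx), 1024, 1024, 10)$excluded, 1)
  expect_warning(apply_border_filter(list(inside), 15, 15, 10), "margin")
})

test_that("border rule is translation-consistent inside the safe zone", {
  set.seed(5)
  base <- make_disk_cell(c(20, 20), 6, 2, 45, 1)$chunk
  for (i in 1:10) {
    dx <- sample(0:50, 1); dy <- sample(0:50, 1)
    moved <- polarcell:::new_chunk(1L, cbind(base[, 1] + dx, base[, 2] + dy))
    if (min(moved$pixels) >= 10 && max(moved$pixels) < 90) {
      expect_length(apply_border_filter(list(moved), 100, 100, 10)$excluded, 0)
    }
  }
})

solid_rect <- function(w, h, x0 = 0L, y0 = 0L) {
  g <- expand.grid(x = x0 + seq_len(w) - 1L, y = y0 + seq_len(h) - 1L)
  polarcell:::new_chunk(1L, cbind(x = g$x, y = g$y))
}

test_that("doublet splitting halves elongated chunks at the bbox midline", {
  # 40x10 horizontal rectangle, ratio 2 -> two 20x10 halves
  res <- split_doublets(solid_rect(40, 10), 2)
  expect_length(res, 2)
  expect_identical(chunk_size(res[[1]]), 200L)
  expect_identical(chunk_size(res[[2]]), 200L)
  expect_equal(unname(chunk_bbox(res[[1]])), c(0, 0, 19, 9))
  expect_equal(unname(chunk_bbox(res[[2]])), c(20, 0, 39, 9))
  expect_identical(res[[1]]$split_origin, "left-half")
  # oracle: brute-force pixel partition at the midline
  parent <- solid_rect(40, 10)
  left <- parent$pixels[parent$pixels[, 1] < 20, ]
  expect_identical(res[[1]]$pixels[order(res[[1]]$pixels[, 2],
                                         res[[1]]$pixels[, 1]), ],
                   left[order(left[, 2], left[, 1]), ])
  # square never splits
  expect_length(split_doublets(solid_rect(10, 10), 2), 1)
  # vertical rectangle splits horizontally
  res <- split_doublets(solid_rect(10, 40), 2)
  expect_length(res, 2)
  expect_equal(unname(chunk_bbox(res[[1]])), c(0, 0, 9, 19))
  expect_identical(res[[1]]$split_origin, "top-half")
  # halves partition the parent pixel set
  expect_identical(nrow(res[[1]]$pixels) + nrow(res[[2]]$pixels), 400L)
  # thin line still halves cleanly
  line <- polarcell:::new_chunk(1L, cbind(x = rep(3L, 8), y = 0:7))
  res <- split_doublets(line, 2)
  expect_length(res, 2)
  expect_identical(chunk_size(res[[1]]), 4L)
})

test_that("chunk centroid averages pixels plus wrap pixels", {
  ch <- polarcell:::new_chunk(1L, cbind(x = c(0L, 2L), y = c(0L, 0L)))
  expect_equal(chunk_centroid(ch), c(x = 1, y = 0))
  sq <- solid_rect(3, 3)
  expect_equal(chunk_centroid(sq), c(x = 1, y = 1))
  # wrap pixels are part of the cell mass
  ch <- polarcell:::new_chunk(1L, cbind(x = 0L, y = 0L),
                              wrap_pixels = cbind(x = 2L, y = 0L))
  expect_equal(chunk_centroid(ch), c(x = 1, y = 0))
})
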