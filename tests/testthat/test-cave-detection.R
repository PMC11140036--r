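# Plastic wrap, cave detection, filtering and selection.

wrap_first_chunk <- function(img, wrap = TRUE) {
  ch <- find_chunks(img)[[1]]
  if (wrap) plastic_wrap(ch, img) else ch
}

test_that("plastic wrap leaves convex chunks alone and is idempotent", {
  disk <- polarcell:::disk_pixels(c(15, 15), 8)
  img <- pixels_to_image(list(disk), 32, 32)
  ch <- wrap_first_chunk(img)
  expect_identical(nrow(ch$wrap_pixels), 0L)
  # tiny chunks are never wrapped
  dot <- pixels_to_image(list(cbind(x = c(3L, 4L), y = c(3L, 3L))), 8, 8)
  expect_identical(nrow(wrap_first_chunk(dot)$wrap_pixels), 0L)
})

test_that("plastic wrap bridges a U-shape mouth and an L-shape diagonal", {
  u <- make_u_cell(c(20, 20), 10, 5, bearing_deg = 90)
  img <- pixels_to_image(list(u), 40, 40)
  ch0 <- wrap_first_chunk(img, wrap = FALSE)
  expect_length(find_caves(ch0, img), 0)      # open mouth: nothing enclosed
  ch <- plastic_wrap(ch0, img)
  expect_gt(nrow(ch$wrap_pixels), 0)
  # bridging pixels sit across the mouth: above the arms' top pixel rows
  expect_lte(min(ch$wrap_pixels[, 2]), min(u[, 2]) + 1)
  # idempotence
  ch2 <- plastic_wrap(ch, img)
  expect_identical(nrow(ch2$wrap_pixels), nrow(ch$wrap_pixels))

  # L-shape: one bridging line along the hull's diagonal edge
  lpx <- rbind(cbind(x = 2L, y = 2:12), cbind(x = 3:12, y = 12L))
  limg <- pixels_to_image(list(lpx), 16, 16)
  lch <- wrap_first_chunk(limg)
  expect_gt(nrow(lch$wrap_pixels), 0)
  # oracle: wrap pixels lie on the raster of the hull edge joining the two
  # L tips (2,2) -> (12,12)
  seg <- polarcell:::raster_line(2L, 2L, 12L, 12L)
  seg_keys <- paste(seg[, 1], seg[, 2])
  expect_true(all(paste(lch$wrap_pixels[, 1], lch$wrap_pixels[, 2])
                  %in% seg_keys))
})

test_that("find_caves detects enclosed holes with the right origin", {
  # 5x5 solid square with black center pixel -> one natural 1-px cave
  sq <- solid <- expand.grid(x = 10:14, y = 10:14)
  solid <- solid[!(solid$x == 12 & solid$y == 12), ]
  img <- pixels_to_image(list(cbind(x = solid$x, y = solid$y)), 25, 25)
  caves <- find_caves(find_chunks(img)[[1]], img)
  expect_length(caves, 1)
  expect_identical(caves[[1]]$size, 1L)
  expect_identical(caves[[1]]$origin, "natural")
  expect_equal(cave_centroid(caves[[1]]), c(x = 12, y = 12))

  # U-shape: no caves unwrapped, one wrap-created cave wrapped
  u <- make_u_cell(c(20, 20), 10, 5, bearing_deg = 90)
  img <- pixels_to_image(list(u), 40, 40)
  ch <- wrap_first_chunk(img)
  caves <- filter_caves(find_caves(ch, img), min_px = 15)
  expect_length(caves, 1)
  expect_identical(caves[[1]]$origin, "wrap_created")
  # the mouth cave centroid lies north of the chunk centroid
  expect_lt(cave_centroid(caves[[1]])[["y"]], chunk_centroid(ch)[["y"]])
})

test_that("a pocket sealed only jointly with a neighboring chunk is no cave", {
  # two facing C-shapes almost enclosing the gap between them
  left <- make_u_cell(c(12, 16), 7, 3, bearing_deg = 0, mouth_half_angle = 30)
  right <- cbind(x = 22L, y = 8:24)   # wall closing the mouth from outside
  img <- pixels_to_image(list(left, right), 32, 32)
  chunks <- find_chunks(img)
  expect_length(chunks, 2)
  for (ch in chunks) {
    caves <- find_caves(ch, img)     # no wrap: each alone encloses nothing
    natural <- Filter(function(cv) cv$size > 2, caves)
    expect_length(natural, 0)
  }
})

test_that("cave enclosure matches the scalar escape oracle", {
  set.seed(21)
  for (i in 1:6) {
    img <- make_tissue(1, bearing = runif(1, 0, 360), seed = i, width = 80,
                       height = 80, radius_range = c(17, 18),
                       margin = 20)$image
    ch <- find_chunks(img)[[1]]
    caves <- find_caves(ch, img)
    expect_length(caves, 1)
    barrier <- rbind(ch$pixels, ch$wrap_pixels)
    # every cave pixel is trapped; a pixel just outside the disk escapes
    cp <- caves[[1]]$pixels[1, ]
    expect_false(oracle_escapes(cp[[1]], cp[[2]], barrier))
    expect_true(oracle_escapes(min(barrier[, 1]) - 1L, min(barrier[, 2]),
                               barrier))
  }
})

test_that("cave size filtering is strict and optional", {
  mk <- function(n) polarcell:::new_cave(cbind(x = seq_len(n), y = rep(1L, n)))
  caves <- list(mk(3), mk(15), mk(16))
  kept <- filter_caves(caves, min_px = 15)
  expect_identical(vapply(kept, function(cv) cv$size, 0L), c(15L, 16L))
  expect_length(filter_caves(caves), 3)
  expect_length(filter_caves(caves, max_px = 15), 2)
  expect_error(filter_caves(caves, min_px = 9, max_px = 3), "min_px")
})

test_that("cave selection honors criteria and documented tie-breaks", {
  mk_at <- function(n, cx, cy) {
    polarcell:::new_cave(cbind(x = cx + seq_len(n) - mean(seq_len(n)), y = cy))
  }
  caves <- list(mk_at(5, 10, 10), mk_at(9, 30, 3))
  expect_identical(select_cave(caves, "largest")$size, 9L)
  expect_equal(select_cave(caves, "northmost")$centroid[["y"]], 3)
  expect_equal(select_cave(caves, "southmost")$centroid[["y"]], 10)
  expect_equal(select_cave(caves, "eastmost")$centroid[["x"]], 30)
  expect_equal(select_cave(caves, "westmost")$centroid[["x"]], 10)
  expect_null(select_cave(list(), "largest"))
  # tie on size -> smaller centroid y wins; tie on y -> smaller x
  t1 <- list(mk_at(4, 10, 20), mk_at(4, 10, 5))
  expect_equal(select_cave(t1, "largest")$centroid[["y"]], 5)
  t2 <- list(mk_at(4, 50, 5), mk_at(4, 10, 5))
  expect_equal(select_cave(t2, "largest")$centroid[["x"]], 10)
})

test_that("displaced-hole disk: largest and northmost agree", {
  cell <- make_disk_cell(c(20, 20), 12, 6, 90, 3)
  img <- pixels_to_image(list(cell$chunk), 40, 40)
  ch <- wrap_first_chunk(img)
  caves <- find_caves(ch, img)
  expect_identical(select_cave(caves, "largest")$centroid,
                   select_cave(caves, "northmost")$centroid)
})

test_that("cave centroids are plain coordinate means", {
  expect_equal(cave_centroid(polarcell:::new_cave(cbind(x = 4L, y = 4L))),
               c(x = 4, y = 4))
  four <- polarcell:::new_cave(cbind(x = c(0L, 0L, 2L, 2L), y = c(0L, 2L, 0L, 2L)))
  expect_equal(cave_centroid(four), c(x = 1, y = 1))
  line <- polarcell:::new_cave(cbind(x = 1:3, y = 7L))
  expect_equal(cave_centroid(line), c(x = 2, y = 7))
})
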