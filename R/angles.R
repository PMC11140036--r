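# Polarity angle measurement: chunk centroid -> cave centroid direction,
# expressed on a configurable circular axis.

#' Angle axis convention
#'
#' Angles are measured from the chunk centroid toward the cave centroid.
#' The reference direction 0 degrees points east (image +x). Under the
#' default counterclockwise convention 90 degrees points north *on screen*
#' (toward smaller y, since image y grows downward). The range is either
#' `[0, 360)` or `(-180, 180]`, and the direction of increase can be flipped
#' to clockwise.
#'
#' @param range `"unsigned_360"` (default) or `"signed_180"`.
#' @param direction `"counterclockwise"` (default) or `"clockwise"`.
#' @return an `angle_convention` object.
#' @export
angle_convention <- function(range = c("unsigned_360", "signed_180"),
                             direction = c("counterclockwise", "clockwise")) {
  structure(list(range = match.arg(range), direction = match.arg(direction)),
            class = "angle_convention")
}

#' Raw polarity angle of a chunk/cave centroid pair
#'
#' The direction of the vector from the chunk centroid to the cave centroid,
#' as `atan2(y_chunk - y_cave, x_cave - x_chunk)` in degrees on `[0, 360)`.
#' The y difference is negated because image y grows downward, so that 90
#' degrees points north on screen under the counterclockwise convention.
#'
#' @param chunk_centroid,cave_centroid numeric `(x, y)` in pixels.
#' @return angle in degrees in `[0, 360)`, or `NA` if the centroids
#'   coincide (the chunk is then unmeasurable).
#' @export
raw_angle <- function(chunk_centroid, cave_centroid) {
  dx <- cave_centroid[[1L]] - chunk_centroid[[1L]]
  dy <- chunk_centroid[[2L]] - cave_centroid[[2L]]   # negated image y
  if (abs(dx) < 1e-9 && abs(dy) < 1e-9) return(NA_real_)
  (atan2(dy, dx) * 180 / pi) %% 360
}

#' Express an angle on a configured axis
#'
#' Applies the direction flip first (clockwise maps theta to
#' `(360 - theta) mod 360`), then the range mapping (`signed_180` maps values
#' above 180 to `value - 360`).
#'
#' @param theta angle in degrees in `[0, 360)` (counterclockwise, 0 = east).
#' @param conv an [angle_convention()].
#' @return angle in degrees on the configured axis.
#' @export
convert_axis <- function(theta, conv = angle_convention()) {
  stopifnot(inherits(conv, "angle_convention"))
  if (conv$direction == "clockwise") theta <- (360 - theta) %% 360
  if (conv$range == "signed_180") theta <- ifelse(theta > 180, theta - 360, theta)
  theta
}

# Inverse of convert_axis: back to counterclockwise [0, 360).
unconvert_axis <- function(theta, conv = angle_convention()) {
  theta <- theta %% 360
  if (conv$direction == "clockwise") theta <- (360 - theta) %% 360
  theta
}

#' Measure all chunk/cave pairs
#'
#' Produces one measurement per chunk with a selected cave. Chunks without a
#' cave, or whose cave centroid coincides with the chunk centroid (e.g. a
#' perfectly concentric hole), are returned as unmeasurable and count toward
#' the Bad Count.
#'
#' @param chunks list of processed chunks (filtered, wrapped).
#' @param selected_caves list parallel to `chunks`: the selected cave of each
#'   chunk, or `NULL`.
#' @param conv an [angle_convention()].
#' @return `list(measurements = data.frame(chunk_id, chunk_x, chunk_y,
#'   cave_x, cave_y, angle), bad_chunks = list)`.
#' @export
measure_all <- function(chunks, selected_caves, conv = angle_convention()) {
  stopifnot(length(chunks) == length(selected_caves))
  rows <- list()
  bad <- list()
  for (i in seq_along(chunks)) {
    ch <- chunks[[i]]
    cv <- selected_caves[[i]]
    theta <- if (is.null(cv)) NA_real_ else {
      raw_angle(chunk_centroid(ch), cave_centroid(cv))
    }
    if (is.na(theta)) {
      ch$status <- "unmeasurable"
      bad <- c(bad, list(ch))
      next
    }
    cc <- chunk_centroid(ch)
    vc <- cave_centroid(cv)
    ch$status <- "processed"
    rows <- c(rows, list(data.frame(
      chunk_id = ch$id, chunk_x = cc[["x"]], chunk_y = cc[["y"]],
      cave_x = vc[["x"]], cave_y = vc[["y"]],
      angle = convert_axis(theta, conv))))
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chunk_id = integer(0), chunk_x = numeric(0),
               chunk_y = numeric(0), cave_x = numeric(0),
               cave_y = numeric(0), angle = numeric(0))
  }
  list(measurements = measurements, bad_chunks = bad)
}
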