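# Full analysis pipeline: single image and batch orchestration.

# Core per-image analysis on an in-memory binary image.
# Stage order: find chunks -> size filter -> doublet split -> border filter
# -> plastic wrap -> centroid -> caves -> cave filter/selection -> angles.
analyze_image <- function(image, cfg = default_config()) {
  stopifnot(inherits(image, "binary_image"), inherits(cfg, "run_config"))
  conv <- config_convention(cfg)
  chunks <- find_chunks(image)
  all_ids <- vapply(chunks, function(ch) ch$id, 0L)

  sf <- apply_size_filter(chunks, cfg$min_chunk_px, cfg$max_chunk_px)
  kept <- sf$kept
  if (cfg$doublet_enabled && length(kept)) {
    kept <- apply_doublet_split(kept, cfg$doublet_ratio, all_ids)
  }
  bf <- apply_border_filter(kept, image_width(image), image_height(image),
                            cfg$border_margin_px)
  kept <- bf$kept
  if (cfg$plastic_wrap) {
    kept <- lapply(kept, plastic_wrap, image = image)
  }
  selected <- lapply(kept, function(ch) {
    caves <- find_caves(ch, image)
    caves <- filter_caves(caves, cfg$min_cave_px, cfg$max_cave_px)
    select_cave(caves, cfg$cave_criterion)
  })
  meas <- measure_all(kept, selected, conv)
  processed_ids <- meas$measurements$chunk_id
  by_status <- list(
    processed = Filter(function(ch) ch$id %in% processed_ids, kept),
    size_excluded = sf$excluded,
    border_excluded = bf$excluded,
    unmeasurable = meas$bad_chunks
  )
  summary <- chunk_summary(meas$measurements, length(meas$bad_chunks), conv)
  list(measurements = meas$measurements, summary = summary,
       chunks = by_status, image = image, config = cfg)
}

results_table <- function(measurements) {
  data.frame(chunk_id = measurements$chunk_id,
             x = round(measurements$chunk_x, 3),
             y = round(measurements$chunk_y, 3),
             angle = round(measurements$angle, 3))
}

summary_table <- function(s) {
  data.frame(processed_count = s$processed_count, bad_count = s$bad_count,
             total_count = s$total_count,
             processed_pct = round(s$processed_pct, 3),
             mean_angle = round(s$mean_angle, 3),
             rml = round(s$rml, 5), circ_variance = round(s$circ_variance, 5),
             circ_sd = round(s$circ_sd, 3))
}

write_table <- function(df, path) {
  utils::write.csv(format(df, trim = TRUE, scientific = FALSE), path,
                   row.names = FALSE, quote = FALSE)
}

#' Analyze a single binary image
#'
#' Runs the full pipeline on one mask: chunk detection, size filtering,
#' optional doublet splitting, border exclusion, optional plastic wrap, cave
#' detection/filtering/selection, angle measurement, and summary statistics.
#' When `out_dir` is given, the enabled artifacts are written there:
#' `results.csv` (one row per processed chunk: id, centroid, angle),
#' `summary.csv`, `rose.svg`, `annotated.png`, `overlay.png`, and the
#' effective `config.json`.
#'
#' @param image_path path to a PNG/TIFF mask, or a [binary_image].
#' @param cfg a [default_config()]-style `run_config`.
#' @param out_dir optional output directory (created if missing).
#' @return invisibly, `list(measurements, summary, chunks, image, config)`;
#'   `chunks` groups chunks by category (processed / size_excluded /
#'   border_excluded / unmeasurable).
#' @export
run_single <- function(image_path, cfg = default_config(), out_dir = NULL) {
  image <- if (inherits(image_path, "binary_image")) image_path else {
    read_mask(image_path, cfg$threshold, cfg$invert)
  }
  res <- analyze_image(image, cfg)
  message(sprintf(
    "processed %d | size-excluded %d | border-excluded %d | unmeasurable %d",
    length(res$chunks$processed), length(res$chunks$size_excluded),
    length(res$chunks$border_excluded), length(res$chunks$unmeasurable)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    conv <- config_convention(cfg)
    if (cfg$output_results) {
      write_table(results_table(res$measurements),
                  file.path(out_dir, "results.csv"))
    }
    if (cfg$output_summary) {
      write_table(summary_table(res$summary), file.path(out_dir, "summary.csv"))
    }
    if (cfg$output_rose) {
      rose_diagram(res$measurements$angle, cfg$rose_bin_width,
                   file.path(out_dir, "rose.svg"), conv)
    }
    if (cfg$output_annotated) {
      write_annotated(image, res$measurements, res$chunks, cfg$palette,
                      file.path(out_dir, "annotated.png"), conv)
    }
    if (cfg$output_overlay) {
      write_overlay(res$measurements, res$chunks$processed,
                    image_width(image), image_height(image), cfg$palette,
                    file.path(out_dir, "overlay.png"), conv)
    }
    write_config(cfg, file.path(out_dir, "config.json"))
  }
  invisible(res)
}

#' Batch-analyze multiple binary images
#'
#' Analyzes each image with one shared configuration and pools the per-cell
#' measurements into a single data set (a `source_image` column records the
#' origin). The pooled summary and rose diagram are computed over the
#' concatenated raw angles, not over per-image means. Unreadable images are
#' logged and skipped; the result's `status` is 2 if any failed, else 0.
#'
#' @param image_paths character vector of mask paths (>= 1).
#' @param cfg a `run_config`.
#' @param out_dir optional output directory for pooled artifacts
#'   (`results.csv`, `summary.csv`, `rose.svg`, `per_image_summary.csv`,
#'   `config.json`) plus one `annotated_<name>.png` per image.
#' @return invisibly, `list(measurements, summary, per_image, failed,
#'   status)`.
#' @export
run_batch <- function(image_paths, cfg = default_config(), out_dir = NULL) {
  stopifnot(length(image_paths) >= 1L)
  conv <- config_convention(cfg)
  pooled <- list(); per_image <- list(); failed <- character(0)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in image_paths) {
    res <- tryCatch(run_single(p, cfg, out_dir = NULL), error = function(e) {
      message("skipping unreadable image ", p, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) { failed <- c(failed, p); next }
    m <- res$measurements
    if (nrow(m) > 0L) m$source_image <- basename(p) else m$source_image <- character(0)
    pooled <- c(pooled, list(m))
    pi_row <- summary_table(res$summary)
    pi_row <- cbind(data.frame(source_image = basename(p)), pi_row)
    per_image <- c(per_image, list(pi_row))
    if (!is.null(out_dir) && cfg$output_annotated) {
      nm <- sub("\\.[^.]+$", "", basename(p))
      write_annotated(res$image, res$measurements, res$chunks, cfg$palette,
                      file.path(out_dir, paste0("annotated_", nm, ".png")),
                      conv)
    }
  }
  measurements <- if (length(pooled)) do.call(rbind, pooled) else {
    cbind(measure_all(list(), list(), conv)$measurements,
          data.frame(source_image = character(0)))
  }
  bad_total <- sum(vapply(per_image, function(r) r$bad_count, 0))
  summary <- chunk_summary(measurements, bad_total, conv)
  per_image_df <- if (length(per_image)) do.call(rbind, per_image) else NULL
  if (!is.null(out_dir)) {
    if (cfg$output_results) {
      rt <- results_table(measurements)
      rt$source_image <- measurements$source_image
      write_table(rt, file.path(out_dir, "results.csv"))
    }
    if (cfg$output_summary) {
      write_table(summary_table(summary), file.path(out_dir, "summary.csv"))
      if (!is.null(per_image_df)) {
        write_table(per_image_df, file.path(out_dir, "per_image_summary.csv"))
      }
    }
    if (cfg$output_rose) {
      rose_diagram(measurements$angle, cfg$rose_bin_width,
                   file.path(out_dir, "rose.svg"), conv)
    }
    write_config(cfg, file.path(out_dir, "config.json"))
  }
  invisible(list(measurements = measurements, summary = summary,
                 per_image = per_image_df, failed = failed,
                 status = if (length(failed)) 2L else 0L))
}
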