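# Run configuration: defaults, file loading, flag overrides, validation.

#' Default run configuration
#'
#' The defaults reproduce the settings used for the cochlear hair-cell
#' workflow this tool was designed around: chunks under 500 px removed as
#' noise, a 10 px border exclusion zone, plastic wrap on, doublet splitting
#' at aspect ratio 2, caves of 15 px or less ignored, largest cave selected,
#' angles on a counterclockwise 0-360 axis where 90 points north. Every
#' field can be overridden (e.g. `doublet_ratio = 1.5` for utricle-style
#' tissue, `cave_criterion = "northmost"`).
#'
#' @param ... named overrides of any configuration field.
#' @return a validated `run_config` list.
#' @field min_chunk_px,max_chunk_px chunk size limits in pixels (`NULL` = none).
#' @export
default_config <- function(...) {
  cfg <- list(
    min_chunk_px = 500, max_chunk_px = NULL,
    border_margin_px = 10,
    doublet_enabled = TRUE, doublet_ratio = 2.0,
    plastic_wrap = TRUE,
    min_cave_px = 15, max_cave_px = NULL,
    cave_criterion = "largest",
    angle_range = "unsigned_360", angle_direction = "counterclockwise",
    rose_bin_width = 15,
    palette = default_palette(),
    output_results = TRUE, output_summary = TRUE, output_rose = TRUE,
    output_annotated = TRUE, output_overlay = TRUE,
    threshold = "auto", invert = FALSE,
    seed = NULL
  )
  modify_config(cfg, list(...))
}

modify_config <- function(cfg, over) {
  if (length(over) == 0L) return(validate_config(cfg))
  if (is.null(names(over)) || any(names(over) == "")) {
    stop("configuration overrides must be named")
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  for (nm in names(over)) cfg[nm] <- list(over[[nm]])
  validate_config(cfg)
}

validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  num_or_null <- function(v) is.null(v) || (is.numeric(v) && length(v) == 1L && v >= 0)
  chk(num_or_null(cfg$min_chunk_px), "min_chunk_px must be a number >= 0 or NULL")
  chk(num_or_null(cfg$max_chunk_px), "max_chunk_px must be a number >= 0 or NULL")
  if (!is.null(cfg$min_chunk_px) && !is.null(cfg$max_chunk_px)) {
    chk(cfg$min_chunk_px <= cfg$max_chunk_px, "min_chunk_px must be <= max_chunk_px")
  }
  chk(is.numeric(cfg$border_margin_px) && cfg$border_margin_px >= 0,
      "border_margin_px must be >= 0")
  chk(isTRUE(cfg$doublet_enabled) || isFALSE(cfg$doublet_enabled),
      "doublet_enabled must be TRUE/FALSE")
  chk(is.numeric(cfg$doublet_ratio) && cfg$doublet_ratio > 1,
      "doublet_ratio must be > 1")
  chk(isTRUE(cfg$plastic_wrap) || isFALSE(cfg$plastic_wrap),
      "plastic_wrap must be TRUE/FALSE")
  chk(num_or_null(cfg$min_cave_px), "min_cave_px must be a number >= 0 or NULL")
  chk(num_or_null(cfg$max_cave_px), "max_cave_px must be a number >= 0 or NULL")
  if (!is.null(cfg$min_cave_px) && !is.null(cfg$max_cave_px)) {
    chk(cfg$min_cave_px <= cfg$max_cave_px, "min_cave_px must be <= max_cave_px")
  }
  chk(cfg$cave_criterion %in%
        c("largest", "northmost", "southmost", "eastmost", "westmost"),
      "cave_criterion must be largest/northmost/southmost/eastmost/westmost")
  chk(cfg$angle_range %in% c("unsigned_360", "signed_180"),
      "angle_range must be unsigned_360 or signed_180")
  chk(cfg$angle_direction %in% c("counterclockwise", "clockwise"),
      "angle_direction must be counterclockwise or clockwise")
  chk(is.numeric(cfg$rose_bin_width) && cfg$rose_bin_width > 0 &&
        360 %% cfg$rose_bin_width == 0,
      "rose_bin_width must divide 360 evenly")
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = "run_config")
}

config_convention <- function(cfg) {
  angle_convention(cfg$angle_range, cfg$angle_direction)
}

#' Load a run configuration
#'
#' Resolution order: command-line style overrides beat config-file values,
#' which beat the built-in defaults. The configuration file is JSON with the
#' field names of [default_config()]; unknown keys or out-of-range values
#' raise a validation error naming the offending fields.
#'
#' @param path optional JSON configuration file.
#' @param overrides named list of overriding values (e.g. parsed CLI flags).
#' @return a validated `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(vals$palette)) {
      vals$palette <- do.call(default_palette, as.list(vals$palette))
    }
    cfg <- modify_config(cfg, vals)
  }
  modify_config(cfg, overrides)
}

# Echo the effective configuration (for provenance) into the output dir.
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}
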