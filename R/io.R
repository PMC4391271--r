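# IO module: on-disk formats (16-bit grayscale TIFF + JSON sidecars, CSV flow
# traces) and the end-to-end pipeline driver.

write_json_file <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)

#' Write a synthetic segment's artifact set
#'
#' Writes `<stem>_bf.tif` and `<stem>_ef.tif` (16-bit grayscale),
#' `<stem>_image.json` (pixel-size sidecar), `<stem>_truth.json` (ground
#' truth incl. fibers), `<stem>_flow.csv` (`time_s`, `cumulative_mass_g`) and
#' `<stem>_meta.json` (pressure gradient, segment length, density, type,
#' seed).
#'
#' @param segment an `xylem_segment`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem; defaults to `plant<NN>_<type>`.
#' @return The stem path, invisibly.
#' @export
write_segment <- function(segment, dir,
                          stem = sprintf("plant%02d_%s", segment$plant,
                                         segment$segment_type)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, stem)
  if (!is.null(segment$image_pair)) {
    tiff::writeTIFF(segment$image_pair$bf, paste0(base, "_bf.tif"),
                    bits.per.sample = 16L)
    tiff::writeTIFF(segment$image_pair$ef, paste0(base, "_ef.tif"),
                    bits.per.sample = 16L)
    write_json_file(list(pixel_size_um = segment$image_pair$pixel_size,
                         height = nrow(segment$image_pair$bf),
                         width = ncol(segment$image_pair$bf)),
                    paste0(base, "_image.json"))
  }
  tr <- as.data.frame(segment$truth)
  write_json_file(list(vessels = tr,
                       fibers = attr(segment$truth, "fibers"),
                       true_kht = segment$true_kht,
                       true_kh = segment$true_kh,
                       efficiency = segment$efficiency),
                  paste0(base, "_truth.json"))
  if (!is.null(segment$flow_trace)) {
    utils::write.csv(data.frame(time_s = segment$flow_trace$time_s,
                                cumulative_mass_g =
                                  segment$flow_trace$cumulative_mass_g),
                     paste0(base, "_flow.csv"), row.names = FALSE)
  }
  write_json_file(list(pressure_gradient_mpa = segment$config$pressure_gradient,
                       segment_length_m = segment$config$segment_length,
                       water_density = segment$config$water_density,
                       segment_type = segment$segment_type,
                       pixel_size_um = segment$config$pixel_size,
                       seed = segment$config$seed),
                  paste0(base, "_meta.json"))
  invisible(base)
}

read_json_file <- function(path, what) {
  if (!file.exists(path)) stopf("missing %s file: %s", what, path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a co-registered BF/EF image pair from disk
#'
#' Expects `<stem>_bf.tif`, `<stem>_ef.tif` and a pixel-size sidecar
#' (`<stem>_image.json`, falling back to `<stem>_meta.json`).
#'
#' @param path_stem path prefix (no suffix).
#' @return An [image_pair()].
#' @export
read_image_pair <- function(path_stem) {
  for (f in paste0(path_stem, c("_bf.tif", "_ef.tif")))
    if (!file.exists(f)) stopf("missing image file: %s", f)
  side <- paste0(path_stem, "_image.json")
  if (!file.exists(side)) side <- paste0(path_stem, "_meta.json")
  meta <- read_json_file(side, "pixel-size sidecar")
  ps <- meta$pixel_size_um
  if (is.null(ps) || !is_number(ps) || ps <= 0)
    stopf("sidecar %s lacks a positive pixel_size_um", side)
  bf <- tiff::readTIFF(paste0(path_stem, "_bf.tif"))
  ef <- tiff::readTIFF(paste0(path_stem, "_ef.tif"))
  image_pair(bf, ef, ps)
}

#' Read a flow trace (CSV + metadata JSON)
#'
#' @param csv_path CSV with columns `time_s`, `cumulative_mass_g`.
#' @param meta metadata: a list or a path to a JSON file providing
#'   `pressure_gradient_mpa`, `segment_length_m`, `water_density`.
#' @return A [flow_trace()].
#' @export
read_flow_trace <- function(csv_path, meta) {
  if (!file.exists(csv_path)) stopf("missing flow file: %s", csv_path)
  if (is.character(meta)) meta <- read_json_file(meta, "flow metadata")
  for (k in c("pressure_gradient_mpa", "segment_length_m", "water_density"))
    if (is.null(meta[[k]])) stopf("flow metadata lacks key '%s'", k)
  df <- utils::read.csv(csv_path)
  if (!all(c("time_s", "cumulative_mass_g") %in% names(df)))
    stopf("%s must have columns time_s, cumulative_mass_g", csv_path)
  flow_trace(df$time_s, df$cumulative_mass_g,
             meta$pressure_gradient_mpa, meta$segment_length_m,
             meta$water_density)
}

#' Read a segment's artifact set back from disk
#'
#' Counterpart of [write_segment()]; tolerates missing images (un-rendered
#' segments) and missing truth (real data).
#'
#' @param dir directory, as in [write_segment()].
#' @param stem file-name stem.
#' @return An `xylem_segment`-like list.
#' @export
read_segment <- function(dir, stem) {
  base <- file.path(dir, stem)
  meta <- read_json_file(paste0(base, "_meta.json"), "segment metadata")
  pair <- if (file.exists(paste0(base, "_bf.tif"))) read_image_pair(base)
  truth <- NULL; true_kht <- NA_real_; true_kh <- NA_real_
  if (file.exists(paste0(base, "_truth.json"))) {
    tj <- read_json_file(paste0(base, "_truth.json"), "ground truth")
    truth <- as.data.frame(tj$vessels)
    if (nrow(truth)) {
      attr(truth, "fibers") <- as.data.frame(tj$fibers)
      class(truth) <- c("xylem_truth", "data.frame")
    }
    true_kht <- tj$true_kht %||% NA_real_
    true_kh <- tj$true_kh %||% NA_real_
  }
  trace <- if (file.exists(paste0(base, "_flow.csv")))
    read_flow_trace(paste0(base, "_flow.csv"), meta)
  plant <- suppressWarnings(as.integer(sub("plant(\\d+)_.*", "\\1", stem)))
  structure(list(plant = if (is.na(plant)) 0L else plant,
                 segment_type = meta$segment_type,
                 truth = truth, image_pair = pair, flow_trace = trace,
                 true_kht = true_kht, true_kh = true_kh,
                 config = NULL, meta = meta),
            class = "xylem_segment")
}

pipeline_defaults <- function() {
  list(seed = 1L, out_dir = "xylemtrace_run", n_plants = 2L, render = TRUE,
       from = "auto", apical = list(), basal = list(),
       segmentation = list(), classification = list(),
       hydraulics = list(window_fraction = 0.5), log_level = "info")
}

#' Run the full pipeline: simulate, measure, classify, summarize, report
#'
#' Drives all stages on a synthetic cohort and writes the per-stage
#' artifacts: per-segment TIFF/JSON/CSV files, `vessels_measured.csv`,
#' `vessels_classified.csv`, `hydraulics.csv`, `report.json`, `report.md`,
#' and the resolved configuration (`config.json`) for provenance. Re-running
#' with identical inputs reproduces identical tabular outputs. Progress is
#' logged to standard error; stage errors are re-raised with the stage name.
#'
#' @param config a named list (or path to a YAML file) overriding any of:
#'   `seed`, `out_dir`, `n_plants`, `render`, `from`, `apical`/`basal`
#'   (generator overrides), `segmentation`, `classification`, `hydraulics`,
#'   `log_level`. Unknown keys are rejected.
#' @return The [compare_bf_ef()] report, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    stopf("unknown pipeline configuration key(s): %s",
          paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, config)
  log <- function(...) if (cfg$log_level != "quiet") message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  log(sprintf("[simulate] %d plants, seed %d", cfg$n_plants, cfg$seed))
  segs <- stage("simulate", {
    ca <- do.call(generator_config,
                  c(list(segment_type = "apical"), cfg$apical))
    cb <- do.call(generator_config,
                  c(list(segment_type = "basal"), cfg$basal))
    generate_cohort(cfg$n_plants, ca, cb, seed = cfg$seed,
                    render = cfg$render)
  })
  seg_dir <- file.path(out, "segments")
  stage("simulate", for (s in segs) write_segment(s, seg_dir))

  log("[segment/classify] measuring vessels")
  analysis <- stage("segment", do.call(analyze_cohort, c(
    list(segs, from = cfg$from, seg_params = cfg$segmentation,
         class_params = cfg$classification),
    cfg$hydraulics)))

  measured_cols <- c("segment", "id", "centroid_x_um", "centroid_y_um",
                     "area_um2", "diameter_um", "wall_completeness",
                     "stain_fraction")
  utils::write.csv(analysis$vessels[, measured_cols],
                   file.path(out, "vessels_measured.csv"), row.names = FALSE)
  utils::write.csv(analysis$vessels,
                   file.path(out, "vessels_classified.csv"),
                   row.names = FALSE)
  utils::write.csv(format(analysis$segments, digits = 7, scientific = TRUE,
                          trim = TRUE),
                   file.path(out, "hydraulics.csv"), row.names = FALSE)

  log("[report] building BF-vs-EF comparison")
  report <- stage("report", compare_bf_ef(analysis))
  write_json_file(report[c("parameters", "counts", "ratios", "regression",
                           "vessel_level", "n_segments")],
                  file.path(out, "report.json"))
  writeLines(utils::capture.output(print(report)),
             file.path(out, "report.md"))
  cfg$version <- as.character(utils::packageVersion("xylemtrace"))
  write_json_file(cfg, file.path(out, "config.json"))
  log(sprintf("[done] artifacts in %s", normalizePath(out)))
  invisible(report)
}
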