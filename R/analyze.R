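# Pipeline composition: from a synthetic (or loaded) segment to classified
# vessel records, hydraulic summaries, and cohort-level tables.

# Measurement-free vessel table straight from ground truth (used when images
# were not rendered, or to isolate downstream stages from segmentation error).
truth_records <- function(truth, config = NULL) {
  out <- data.frame(
    id = truth$id,
    bundle_id = truth$bundle_id,
    centroid_x_um = truth$x_um,
    centroid_y_um = truth$y_um,
    area_um2 = pi * (truth$diameter_um / 2)^2,
    diameter_um = truth$diameter_um,
    wall_completeness = truth$wall_completeness,
    stain_fraction = truth$stain_fraction,
    stringsAsFactors = FALSE)
  if (!is.null(config))
    attr(out, "pith_center_um") <-
      c((config$image_shape[2] - 1) / 2,
        (config$image_shape[1] - 1) / 2) * config$pixel_size
  out
}

#' Analyze one segment: measure, classify, summarize
#'
#' Runs the measurement and classification stages on a segment and computes
#' its hydraulic summary. With `from = "images"` the vessel table comes from
#' the rendered image pair via [measure_vessels()]; with `from = "truth"` it
#' is derived directly from the ground-truth geometry (no imaging error);
#' `"auto"` uses images when present.
#'
#' @param segment an `xylem_segment` (from [generate_cohort()] or
#'   [read_segment()]).
#' @param from `"auto"`, `"images"` or `"truth"`.
#' @param seg_params segmentation parameter overrides ([detect_lumens()]).
#' @param class_params classification overrides ([classify_all()]), e.g.
#'   `list(theta_bf = 0.9)`.
#' @param window_fraction steady-flow window for [estimate_flow_rate()].
#' @param eta dynamic viscosity, MPa s.
#' @return List with `records` (classified vessel table), `summary`
#'   (`hydraulic_summary`), `segment_type`, `plant`.
#' @export
analyze_segment <- function(segment, from = c("auto", "images", "truth"),
                            seg_params = list(), class_params = list(),
                            window_fraction = 0.5, eta = ETA_WATER_20C) {
  from <- match.arg(from)
  if (from == "auto")
    from <- if (!is.null(segment$image_pair)) "images" else "truth"
  records <- switch(from,
    images = {
      if (is.null(segment$image_pair))
        stopf("segment has no rendered image pair")
      measure_vessels(segment$image_pair, seg_params)
    },
    truth = truth_records(segment$truth, segment$config))
  records <- do.call(classify_all, c(list(records), class_params))
  summary <- summarize_segment(records, segment$flow_trace, eta,
                               window_fraction)
  list(records = records, summary = summary,
       segment_type = segment$segment_type, plant = segment$plant)
}

#' Analyze a cohort of segments into per-segment and vessel tables
#'
#' @param segments list of `xylem_segment` objects.
#' @param ... passed to [analyze_segment()].
#' @return An object of class `xylem_cohort_analysis`: a list with
#'   `segments` (one row per segment: identifiers, `kh`, and the
#'   per-criterion `kht`, `khs`, `khts`, `mean_d`, counts and `ratio`
#'   columns) and `vessels` (all classified vessel records, tagged by
#'   segment). Feed it to [compare_bf_ef()].
#' @export
analyze_cohort <- function(segments, ...) {
  rows <- vector("list", length(segments))
  vt <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    a <- analyze_segment(segments[[i]], ...)
    s <- a$summary
    rows[[i]] <- data.frame(
      segment = i, plant = a$plant, segment_type = a$segment_type,
      kh = s$kh,
      kht_bf = s$kht_bf, kht_ef = s$kht_ef,
      total_lumen_area_bf = s$total_lumen_area_bf,
      total_lumen_area_ef = s$total_lumen_area_ef,
      khs_bf = s$khs_bf, khs_ef = s$khs_ef,
      khts_bf = s$khts_bf, khts_ef = s$khts_ef,
      mean_d_bf = s$mean_d_bf, mean_d_ef = s$mean_d_ef,
      n_px_bf = s$n_px_bf, n_mx_bf = s$n_mx_bf, n_total_bf = s$n_total_bf,
      n_px_ef = s$n_px_ef, n_mx_ef = s$n_mx_ef, n_total_ef = s$n_total_ef,
      ratio_bf = s$ratio_bf, ratio_ef = s$ratio_ef,
      stringsAsFactors = FALSE)
    r <- a$records
    r$segment <- i
    vt[[i]] <- r
  }
  structure(list(segments = do.call(rbind, rows),
                 vessels = do.call(rbind, vt)),
            class = "xylem_cohort_analysis")
}

#' @export
print.xylem_cohort_analysis <- function(x, ...) {
  cat(sprintf("<xylem_cohort_analysis> %d segments, %d vessels\n",
              nrow(x$segments), nrow(x$vessels)))
  invisible(x)
}

#' Match measured vessel records to ground-truth vessels
#'
#' Greedy nearest-centroid matching within `max_dist_um`; each truth vessel
#' is used at most once.
#'
#' @param records measured vessel table (`centroid_x_um`, `centroid_y_um`).
#' @param truth an `xylem_truth` table.
#' @param max_dist_um maximum centre distance for a match (default 3).
#' @return Integer vector along `records`: the matched row index in `truth`,
#'   or `NA` if none within range.
#' @export
match_vessels <- function(records, truth, max_dist_um = 3) {
  n <- nrow(records)
  out <- rep(NA_integer_, n)
  if (n == 0 || nrow(truth) == 0) return(out)
  d2 <- outer(records$centroid_x_um, truth$x_um, "-")^2 +
    outer(records$centroid_y_um, truth$y_um, "-")^2
  lim <- max_dist_um^2
  for (k in seq_len(min(n, nrow(truth)))) {
    i <- which.min(apply(d2, 1, min, na.rm = TRUE))
    j <- which.min(d2[i, ])
    if (!is.finite(d2[i, j]) || d2[i, j] > lim) break
    out[i] <- j
    d2[i, ] <- Inf
    d2[, j] <- Inf
  }
  out
}
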