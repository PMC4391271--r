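# Segmentation module: lumen detection in the BF channel, wall-completeness
# and stained-perimeter-fraction measurement on radial annuli.

#' Co-registered bright-field / epifluorescence image pair
#'
#' @param bf,ef numeric matrices of identical shape (rows = image height).
#' @param pixel_size micrometres per pixel, > 0.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(bf, ef, pixel_size) {
  if (!is.matrix(bf) || !is.matrix(ef)) stopf("bf and ef must be matrices")
  if (!identical(dim(bf), dim(ef)))
    stopf("bf and ef must have identical shape (got %dx%d vs %dx%d)",
          nrow(bf), ncol(bf), nrow(ef), ncol(ef))
  if (!is_number(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be > 0")
  structure(list(bf = bf, ef = ef, pixel_size = pixel_size),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %d x %d px at %.3g um/px (%.0f x %.0f um)\n",
              nrow(x$bf), ncol(x$bf), x$pixel_size,
              nrow(x$bf) * x$pixel_size, ncol(x$bf) * x$pixel_size))
  invisible(x)
}

#' @export
plot.image_pair <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, main) {
    graphics::plot(c(0, ncol(m)), c(0, nrow(m)), type = "n", asp = 1,
                   axes = FALSE, xlab = "", ylab = "", main = main)
    graphics::rasterImage(grDevices::as.raster(m), 0, 0, ncol(m), nrow(m))
  }
  show(x$bf, "bright field")
  show(x$ef, "epifluorescence")
  invisible(x)
}

default_seg_params <- function(pixel_size) {
  list(smooth_sigma = 0.3,      # um, pre-threshold Gaussian smoothing
       psf_sigma = 0.3,         # um, microscope PSF width (acquisition metadata)
       min_area = 4, max_area = 1000,   # um^2 lumen size gate
       min_solidity = 0.8,
       n_boundary = 360,
       wall_width = 2,          # um, radial annulus width
       k_bf = 3, k_ef = 6,      # threshold multipliers (robust background SD)
       watershed_tolerance = 1,
       refine = TRUE)
}

seg_params <- function(pixel_size, params = list()) {
  p <- default_seg_params(pixel_size)
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) stopf("unknown segmentation parameter(s): %s",
                             paste(unknown, collapse = ", "))
  utils::modifyList(p, params)
}

# Shoelace area of the convex hull of pixel centres, corrected to pixel-count
# scale (Pick): interior + boundary/2 + 1.
hull_pixel_area <- function(rows, cols) {
  if (length(rows) < 3) return(length(rows))
  h <- grDevices::chull(cols, rows)
  xs <- cols[h]; ys <- rows[h]
  n <- length(h)
  j <- c(n, seq_len(n - 1))
  a <- abs(sum(xs * ys[j] - xs[j] * ys)) / 2
  per <- sum(sqrt(diff(c(xs, xs[1]))^2 + diff(c(ys, ys[1]))^2))
  a + per / 2 + 1
}

# Resample a closed polygon (n x 2, not closed) to m points at equal arc
# length along the contour.
resample_closed <- function(pts, m) {
  P <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)
  keep <- c(TRUE, seg > 0)
  P <- P[keep, , drop = FALSE]
  if (nrow(P) < 3) return(matrix(rep(pts[1, ], each = m), m, 2))
  cs <- c(0, cumsum(sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)))
  s <- (seq_len(m) - 1) / m * cs[length(cs)]
  cbind(approx(cs, P[, 1], s)$y, approx(cs, P[, 2], s)$y)
}

make_region <- function(label, rows, cols, pixel_size, n_boundary, H, W,
                        area = NULL) {
  area <- area %||% (length(rows) * pixel_size^2)
  centroid <- c(x = (mean(cols) - 1) * pixel_size,
                y = (mean(rows) - 1) * pixel_size)
  r0 <- min(rows); c0 <- min(cols)
  mask <- matrix(0L, max(rows) - r0 + 3L, max(cols) - c0 + 3L)
  mask[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- 1L
  oc <- EBImage::ocontour(EBImage::Image(mask))[[1]]   # 0-based (row, col)
  bd_rows <- oc[, 1] + r0 - 1L   # back to 1-based global
  bd_cols <- oc[, 2] + c0 - 1L
  boundary <- resample_closed(
    cbind((bd_cols - 1) * pixel_size, (bd_rows - 1) * pixel_size), n_boundary)
  colnames(boundary) <- c("x_um", "y_um")
  structure(list(label = label, rows = rows, cols = cols,
                 area_um2 = area, centroid_um = centroid,
                 boundary = boundary,
                 equivalent_diameter = 2 * sqrt(area / pi),
                 pixel_size = pixel_size, image_dim = c(H, W)),
            class = "lumen_region")
}

#' @export
print.lumen_region <- function(x, ...) {
  cat(sprintf("<lumen_region %d> area %.1f um^2, D %.2f um, centroid (%.1f, %.1f) um\n",
              x$label, x$area_um2, x$equivalent_diameter,
              x$centroid_um[1], x$centroid_um[2]))
  invisible(x)
}

#' Detect vessel lumens in a bright-field raster
#'
#' Candidate bright regions are found by global Otsu thresholding after
#' Gaussian smoothing; holes are filled, touching lumens are split by
#' watershed on the distance transform, and regions are filtered by area and
#' solidity. Each surviving region's outline is then refined by a local
#' half-height re-threshold (midpoint between the lumen interior and the
#' surrounding wall/ground intensity), and its area is corrected for the
#' systematic inward bias of any fixed-level contour of a blurred convex disc
#' (noncentral-chi-square inversion using the total blur width) — a bias that
#' fourth-power conductivities would amplify. Labels are ordered by centroid,
#' row-major; the boundary is resampled to `n_boundary` points at equal arc
#' length.
#'
#' All thresholds are derived from the data, so the output is invariant to
#' positive rescaling of the intensities.
#'
#' @param bf numeric matrix, bright-field intensities.
#' @param pixel_size micrometres per pixel.
#' @param params named list overriding any of: `smooth_sigma` (um, 0.3),
#'   `psf_sigma` (um, 0.3; the microscope's PSF width from acquisition
#'   metadata, used in the blur-bias correction), `min_area`/`max_area`
#'   (um^2, 4/1000), `min_solidity` (0.8), `n_boundary` (360), `wall_width`
#'   (um, 2), `watershed_tolerance` (1), `refine` (TRUE).
#' @return A list of `lumen_region` objects (possibly empty).
#' @export
detect_lumens <- function(bf, pixel_size, params = list()) {
  if (!is_number(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be > 0")
  if (!is.matrix(bf) || !length(bf)) stopf("bf must be a non-empty matrix")
  p <- seg_params(pixel_size, params)
  if (diff(range(bf)) == 0) return(list())
  H <- nrow(bf); W <- ncol(bf)

  img <- EBImage::Image(bf)
  sm <- if (p$smooth_sigma > 0)
    EBImage::gblur(img, sigma = p$smooth_sigma / pixel_size) else img
  smm <- EBImage::imageData(sm)
  th <- EBImage::otsu(sm, range = range(smm))
  bin <- EBImage::fillHull(sm > th)

  # drop sub-minimum components before the (costly) watershed
  lab0 <- EBImage::bwlabel(bin)
  lab0m <- EBImage::imageData(lab0)
  sizes <- tabulate(lab0m[lab0m > 0])
  min_px <- max(1, floor(p$min_area / pixel_size^2))
  keep0 <- which(sizes >= min_px)
  if (!length(keep0)) return(list())
  binm <- matrix(lab0m %in% keep0, H, W)
  lab <- EBImage::watershed(EBImage::distmap(EBImage::Image(binm)),
                            tolerance = p$watershed_tolerance, ext = 1)
  labm <- EBImage::imageData(lab)

  idx_all <- which(labm > 0)
  groups <- split(idx_all, labm[idx_all])
  regions <- list()
  # brightness gate: a lumen interior must stand clearly above the ground
  # (rejects threshold artefacts on low-contrast/noise-only rasters)
  bg_med <- median(smm)
  bg_rsd <- robust_sd(smm)
  for (g in groups) {
    if (median(smm[g]) < bg_med + 4 * bg_rsd) next
    rows <- (g - 1L) %% H + 1L
    cols <- (g - 1L) %/% H + 1L
    area <- length(rows) * pixel_size^2
    if (p$refine) {
      ref <- refine_region(smm, labm, rows, cols, labm[g[1]], p, pixel_size)
      rows <- ref$rows; cols <- ref$cols; area <- ref$area_um2
    }
    if (area < p$min_area || area > p$max_area) next
    sol <- length(rows) / hull_pixel_area(rows, cols)
    if (sol < p$min_solidity) next
    regions[[length(regions) + 1L]] <-
      make_region(0L, rows, cols, pixel_size, p$n_boundary, H, W, area)
  }
  if (!length(regions)) return(list())
  ord <- order(vapply(regions, function(r) round(r$centroid_um["y"], 3),
                      numeric(1)),
               vapply(regions, function(r) round(r$centroid_um["x"], 3),
                      numeric(1)))
  regions <- regions[ord]
  for (i in seq_along(regions)) regions[[i]]$label <- i
  regions
}

# Local refinement of one detected lumen within its padded bounding box.
# Two steps: (1) re-threshold at the midpoint between the region's interior
# median and the median of the surrounding wall ring (recovers the pixel set
# lost to the global threshold); (2) correct the half-level area for blur:
# the half-height contour of a Gaussian-blurred disc lies strictly inside the
# true circle (tangential mixing at a convex edge depresses the edge-level
# set), an effect that fourth-power conductivities amplify. The blurred disc
# has the exact radial profile M(r) = P(chi2_2((r/s)^2) <= (R/s)^2) with
# s the total blur width, so the true radius follows from the apparent one
# by a noncentral-chi-square quantile inversion.
refine_region <- function(smm, labm, rows, cols, label, p, pixel_size) {
  H <- nrow(smm); W <- ncol(smm)
  pad <- ceiling(p$wall_width / pixel_size) + 2L
  rr <- max(1L, min(rows) - pad):min(H, max(rows) + pad)
  cc <- max(1L, min(cols) - pad):min(W, max(cols) + pad)
  sub <- smm[rr, cc, drop = FALSE]
  sublab <- labm[rr, cc, drop = FALSE]
  npx_area <- function(r) length(r) * pixel_size^2
  mask <- matrix(FALSE, length(rr), length(cc))
  mask[cbind(rows - rr[1] + 1L, cols - cc[1] + 1L)] <- TRUE
  bw <- 2L * floor(p$wall_width / pixel_size / 2) + 3L
  brush <- EBImage::makeBrush(bw, "disc")
  ours <- sublab == 0 | sublab == label     # exclude other labels' pixels
  ring <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(mask * 1), brush)) > 0 & !mask & sublab == 0
  if (!any(ring)) return(list(rows = rows, cols = cols,
                              area_um2 = npx_area(rows)))
  # plateau: upper quantile of the interior (the median dips for small lumens
  # whose edge band reaches the centre); wall reference: lower quantile of
  # the ring, approximating the wall-centre minimum rather than the ring
  # median, which background bleed-through biases upward
  plateau <- quantile(sub[mask], 0.9, names = FALSE)
  wall_ref <- quantile(sub[ring], 0.05, names = FALSE)
  t_loc <- (plateau + wall_ref) / 2
  binloc <- sub > t_loc & ours
  ll <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(binloc * 1)))
  cr <- round(mean(rows)) - rr[1] + 1L
  cctr <- round(mean(cols)) - cc[1] + 1L
  lab_at <- if (cr >= 1 && cr <= nrow(ll) && cctr >= 1 && cctr <= ncol(ll))
    ll[cr, cctr] else 0
  if (lab_at == 0) {
    # centroid off the refined mask (odd shapes): take the component with the
    # largest overlap with the original mask
    ov <- table(ll[mask & ll > 0])
    if (!length(ov)) return(list(rows = rows, cols = cols,
                                 area_um2 = npx_area(rows)))
    lab_at <- as.integer(names(ov)[which.max(ov)])
  }
  keep <- EBImage::imageData(EBImage::fillHull(
    EBImage::Image((ll == lab_at) * 1))) > 0
  area <- blur_corrected_area(sum(keep), p, pixel_size)
  w <- which(keep)
  list(rows = (w - 1L) %% nrow(keep) + 1L + rr[1] - 1L,
       cols = (w - 1L) %/% nrow(keep) + 1L + cc[1] - 1L,
       area_um2 = area)
}

# Invert the half-level contour of a Gaussian-blurred disc: given the
# apparent (mask) radius r_t and the total blur width s (PSF plus smoothing
# in quadrature), the true radius R satisfies
#   0.5 = pchisq((R/s)^2, df = 2, ncp = (r_t/s)^2).
blur_corrected_area <- function(n_px, p, pixel_size) {
  area_raw <- n_px * pixel_size^2
  s <- sqrt(p$psf_sigma^2 + p$smooth_sigma^2)
  if (s <= 0 || n_px < 3) return(area_raw)
  r_t <- sqrt(area_raw / pi)
  R <- s * sqrt(stats::qchisq(0.5, df = 2, ncp = (r_t / s)^2))
  if (!is.finite(R) || R <= 0) return(area_raw)
  pi * R^2
}

#' Threshold the epifluorescence channel into a stained-signal mask
#'
#' Emulates the exposure-time tuning that keeps the intense signal of
#' dye-stained secondary walls while suppressing autofluorescence: the
#' background level is the raster median and pixels exceeding it by `k_ef`
#' robust standard deviations form the mask.
#'
#' @param ef numeric matrix, epifluorescence intensities.
#' @param k_ef threshold multiplier (default 6).
#' @return A logical matrix, `TRUE` where stained signal is present.
#' @export
apply_exposure_normalization <- function(ef, k_ef = 6) {
  if (!is.matrix(ef) || !length(ef)) stopf("ef must be a non-empty matrix")
  if (diff(range(ef)) == 0)
    return(matrix(FALSE, nrow(ef), ncol(ef)))
  ef > median(ef) + k_ef * robust_sd(ef)
}

# Radial sampling geometry shared by the two perimeter measures: for each
# boundary sample, points every half pixel along the outward normal from the
# lumen edge through an annulus `wall_width` deep.
ray_indices <- function(region, wall_width) {
  ps <- region$pixel_size
  b <- region$boundary
  ctr <- region$centroid_um
  dx <- b[, 1] - ctr["x"]; dy <- b[, 2] - ctr["y"]
  nrm <- sqrt(dx^2 + dy^2); nrm[nrm == 0] <- 1
  off <- seq(0, wall_width, by = ps / 2)
  X <- outer(off, dx / nrm) + rep(b[, 1], each = length(off))
  Y <- outer(off, dy / nrm) + rep(b[, 2], each = length(off))
  rows <- round(Y / ps) + 1L
  cols <- round(X / ps) + 1L
  H <- region$image_dim[1]; W <- region$image_dim[2]
  inb <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  list(rows = rows, cols = cols, inb = inb,
       n_samples = nrow(b), n_off = length(off))
}

annulus_fraction <- function(raster, region, wall_width, hit) {
  ri <- ray_indices(region, wall_width)
  if (!all(ri$inb))
    warnf("measurement annulus clipped at the image edge (region %d)",
          region$label)
  hits <- logical(ri$n_samples)
  for (s in seq_len(ri$n_samples)) {
    ok <- ri$inb[, s]
    if (!any(ok)) next
    hits[s] <- hit(raster[cbind(ri$rows[ok, s], ri$cols[ok, s])])
  }
  mean(hits)
}

#' Measure secondary-wall completeness around a lumen
#'
#' For each boundary sample the radial annulus (width `wall_width`) outward of
#' the lumen edge is examined; the sample counts as "walled" when the minimum
#' intensity in its annulus falls below the dark-wall threshold (background
#' median minus `k_bf` robust standard deviations). Returns the walled
#' fraction of the perimeter.
#'
#' @param bf bright-field matrix the region was detected in.
#' @param region a `lumen_region`.
#' @param params list overriding `wall_width` (um) and `k_bf`.
#' @param threshold optional precomputed dark-wall threshold (intensity);
#'   avoids recomputing the background statistics per vessel.
#' @return Fraction in \[0, 1\].
#' @export
measure_wall_completeness <- function(bf, region, params = list(),
                                      threshold = NULL) {
  p <- seg_params(region$pixel_size, params)
  thr <- threshold %||% (median(bf) - p$k_bf * robust_sd(bf))
  annulus_fraction(bf, region, p$wall_width, function(v) min(v) < thr)
}

#' Measure the stained fraction of a wall perimeter
#'
#' Same annulus geometry as [measure_wall_completeness()]; a boundary sample
#' counts as stained when any mask pixel lies in its radial annulus.
#'
#' @param stain_mask logical matrix from [apply_exposure_normalization()].
#' @param region a `lumen_region` co-registered with the mask.
#' @param params list overriding `wall_width` (um).
#' @return Fraction in \[0, 1\].
#' @export
measure_stain_fraction <- function(stain_mask, region, params = list()) {
  p <- seg_params(region$pixel_size, params)
  annulus_fraction(stain_mask, region, p$wall_width, function(v) any(v))
}

#' Measure all vessels in an image pair
#'
#' Composition of lumen detection, wall-completeness and stain-fraction
#' measurement. Deterministic for fixed inputs.
#'
#' @param pair an [image_pair()].
#' @param params segmentation parameter overrides (see [detect_lumens()];
#'   `k_ef` controls the stain mask).
#' @return A `data.frame` with one row per detected lumen: `id`,
#'   `centroid_x_um`, `centroid_y_um`, `area_um2`, `diameter_um`,
#'   `wall_completeness`, `stain_fraction`.
#' @export
measure_vessels <- function(pair, params = list()) {
  stopifnot(inherits(pair, "image_pair"))
  p <- seg_params(pair$pixel_size, params)
  regions <- detect_lumens(pair$bf, pair$pixel_size, params)
  mask <- apply_exposure_normalization(pair$ef, p$k_ef)
  thr_bf <- median(pair$bf) - p$k_bf * robust_sd(pair$bf)
  out <- data.frame(
    id = integer(0), centroid_x_um = numeric(0), centroid_y_um = numeric(0),
    area_um2 = numeric(0), diameter_um = numeric(0),
    wall_completeness = numeric(0), stain_fraction = numeric(0))
  for (r in regions) {
    out[nrow(out) + 1L, ] <- list(
      r$label, unname(r$centroid_um["x"]), unname(r$centroid_um["y"]),
      r$area_um2, r$equivalent_diameter,
      measure_wall_completeness(pair$bf, r, params, threshold = thr_bf),
      measure_stain_fraction(mask, r, params))
  }
  # the pith sits at the section centre; downstream type assignment uses it
  # as the origin of the inner->outer axis
  attr(out, "pith_center_um") <- c((ncol(pair$bf) - 1) / 2,
                                   (nrow(pair$bf) - 1) / 2) * pair$pixel_size
  out
}
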