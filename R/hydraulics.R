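# Hydraulics module: experimental conductivity from balance traces,
# theoretical (Hagen-Poiseuille) conductivity from vessel diameters, and the
# derived specific conductivities, ratios and resistivities.

#' Dynamic viscosity of water at 20 degrees C, in MPa s
#' @export
ETA_WATER_20C <- 1.002e-9

#' Cumulative-mass flow trace
#'
#' @param time_s strictly increasing sampling times, seconds (>= 3 samples).
#' @param cumulative_mass_g balance readings, grams.
#' @param pressure_gradient MPa across the segment (> 0).
#' @param segment_length metres (> 0).
#' @param water_density kg m^-3 (> 0).
#' @return An object of class `flow_trace`.
#' @export
flow_trace <- function(time_s, cumulative_mass_g, pressure_gradient,
                       segment_length, water_density = 998.2) {
  if (length(time_s) != length(cumulative_mass_g))
    stopf("time_s and cumulative_mass_g must have equal length")
  if (length(time_s) < 3) stopf("a flow trace needs at least 3 samples")
  if (any(diff(time_s) <= 0)) stopf("time_s must be strictly increasing")
  if (!is_number(pressure_gradient) || pressure_gradient <= 0)
    stopf("pressure_gradient must be > 0")
  if (!is_number(segment_length) || segment_length <= 0)
    stopf("segment_length must be > 0")
  if (!is_number(water_density) || water_density <= 0)
    stopf("water_density must be > 0")
  structure(list(time_s = as.numeric(time_s),
                 cumulative_mass_g = as.numeric(cumulative_mass_g),
                 pressure_gradient = pressure_gradient,
                 segment_length = segment_length,
                 water_density = water_density),
            class = "flow_trace")
}

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("<flow_trace> %d samples over %g s, dP %g MPa, L %g m\n",
              length(x$time_s), max(x$time_s), x$pressure_gradient,
              x$segment_length))
  invisible(x)
}

#' @export
plot.flow_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$cumulative_mass_g, type = "l",
                 xlab = "time (s)", ylab = "cumulative mass (g)", ...)
  invisible(x)
}

#' Estimate the steady volumetric flow rate from a trace
#'
#' Ordinary least-squares slope of cumulative mass versus time over the final
#' `window_fraction` of the samples (excluding any initial transient),
#' converted to volume via the water density.
#'
#' @param trace a [flow_trace()].
#' @param window_fraction fraction of trailing samples to fit (default 0.5).
#' @return Volumetric flow rate, m^3 s^-1.
#' @export
estimate_flow_rate <- function(trace, window_fraction = 0.5) {
  stopifnot(inherits(trace, "flow_trace"))
  if (!is_number(window_fraction) || window_fraction <= 0 ||
      window_fraction > 1)
    stopf("window_fraction must lie in (0, 1]")
  n <- length(trace$time_s)
  k <- ceiling(window_fraction * n)
  if (k < 3) stopf("fewer than 3 samples in the steady-flow window")
  idx <- (n - k + 1):n
  slope_gs <- unname(coef(lm(trace$cumulative_mass_g[idx] ~
                               trace$time_s[idx]))[2])
  if (!is.finite(slope_gs) || slope_gs <= 0)
    stopf("no positive steady flow in the fitted window")
  slope_gs / 1000 / trace$water_density
}

#' Experimental hydraulic conductivity
#'
#' `Kh = F * L / dP`, with the flow rate `F` in m^3 s^-1, segment length `L`
#' in metres and pressure gradient `dP` in MPa.
#'
#' @param flow_rate m^3 s^-1 (> 0).
#' @param segment_length metres (> 0).
#' @param pressure_gradient MPa (> 0).
#' @return Kh in m^4 MPa^-1 s^-1.
#' @export
compute_kh <- function(flow_rate, segment_length, pressure_gradient) {
  for (v in c(flow_rate, segment_length, pressure_gradient))
    if (!is_number(v) || v <= 0)
      stopf("flow_rate, segment_length and pressure_gradient must all be > 0")
  flow_rate * segment_length / pressure_gradient
}

#' Equivalent circular diameter from a lumen area
#'
#' Vessels are treated as ideal capillaries of circular cross section:
#' `D = 2 * sqrt(area / pi)`.
#'
#' @param area_um2 lumen area(s), square micrometres (> 0).
#' @return Diameter(s), micrometres.
#' @export
diameter_from_area <- function(area_um2) {
  if (any(!is.finite(area_um2) | area_um2 <= 0))
    stopf("area must be > 0")
  2 * sqrt(area_um2 / pi)
}

#' Theoretical hydraulic conductivity (Hagen-Poiseuille sum)
#'
#' `Kht = sum(pi * D^4 / (128 * eta))` over the conductive vessels, with
#' diameters converted from micrometres to metres and the dynamic viscosity
#' `eta` in MPa s (water at 20 degrees C by default).
#'
#' @param diameters_um vessel inner diameters, micrometres (may be empty).
#' @param eta dynamic viscosity, MPa s.
#' @return Kht in m^4 MPa^-1 s^-1 (0 for an empty set).
#' @export
compute_kht <- function(diameters_um, eta = ETA_WATER_20C) {
  if (!is_number(eta) || eta <= 0) stopf("eta must be > 0")
  if (!length(diameters_um)) return(0)
  bad <- which(!is.finite(diameters_um) | diameters_um <= 0)
  if (length(bad)) stopf("non-positive diameter at index %d", bad[1])
  sum(pi * (diameters_um * 1e-6)^4 / (128 * eta))
}

#' Specific conductivity
#'
#' Conductivity divided by the total vessel-lumen area.
#'
#' @param K conductivity, m^4 MPa^-1 s^-1 (>= 0).
#' @param total_lumen_area m^2 (> 0).
#' @return m^2 s^-1 MPa^-1.
#' @export
specific_conductivity <- function(K, total_lumen_area) {
  if (!is_number(total_lumen_area) || total_lumen_area <= 0)
    stopf("total_lumen_area must be > 0")
  if (!is_number(K) || K < 0) stopf("K must be >= 0")
  K / total_lumen_area
}

#' Relative contribution of experimental to theoretical conductivity
#'
#' @param kh,kht conductivities (kht > 0).
#' @return Percent, `100 * kh / kht`.
#' @export
relative_contribution <- function(kh, kht) {
  if (!is_number(kht) || kht <= 0) stopf("kht must be > 0")
  if (!is_number(kh) || kh < 0) stopf("kh must be >= 0")
  100 * kh / kht
}

#' Lumen resistivity (reciprocal conductivity)
#'
#' @param kh conductivity, m^4 MPa^-1 s^-1 (> 0).
#' @return Resistivity, MPa s m^-4.
#' @export
resistivity <- function(kh) {
  if (any(!is.finite(kh) | kh <= 0)) stopf("kh must be > 0")
  1 / kh
}

#' Summarize the hydraulics of one segment
#'
#' Computes the experimental conductivity from the flow trace and, separately
#' over the bright-field-conductive and epifluorescence-conductive vessel
#' subsets: the Hagen-Poiseuille theoretical conductivity, total lumen area,
#' specific conductivities, mean diameter, per-type counts and the relative
#' contribution `100 * Kh / Kht`. A criterion with zero conductive vessels
#' yields `Kht = 0` and missing (NA) specific conductivities and ratio.
#'
#' @param records classified vessel table (see [classify_all()]).
#' @param trace a [flow_trace()] or `NULL` (then `Kh` and derived fields are
#'   NA).
#' @param eta dynamic viscosity, MPa s.
#' @param window_fraction steady-flow window for [estimate_flow_rate()].
#' @return An object of class `hydraulic_summary` (a list).
#' @export
summarize_segment <- function(records, trace = NULL, eta = ETA_WATER_20C,
                              window_fraction = 0.5) {
  kh <- NA_real_
  if (!is.null(trace))
    kh <- tryCatch(
      compute_kh(estimate_flow_rate(trace, window_fraction),
                 trace$segment_length, trace$pressure_gradient),
      error = function(e) {
        # a flow too weak for the balance yields no usable slope; such
        # segments are reported without an experimental conductivity
        warnf("no usable steady flow (%s); Kh recorded as missing",
              conditionMessage(e))
        NA_real_
      })
  out <- list(kh = kh)
  for (crit in c("bf", "ef")) {
    sel <- records[[paste0("conductive_", crit)]]
    d <- records$diameter_um[sel]
    kht <- compute_kht(d, eta)
    area_m2 <- sum(records$area_um2[sel]) * 1e-12
    out[[paste0("kht_", crit)]] <- kht
    out[[paste0("total_lumen_area_", crit)]] <- area_m2
    out[[paste0("khs_", crit)]] <-
      if (!is.na(kh) && area_m2 > 0) specific_conductivity(kh, area_m2)
      else NA_real_
    out[[paste0("khts_", crit)]] <-
      if (area_m2 > 0) specific_conductivity(kht, area_m2) else NA_real_
    out[[paste0("mean_d_", crit)]] <- if (any(sel)) mean(d) else NA_real_
    out[[paste0("n_px_", crit)]] <- sum(sel & records$type == "PX")
    out[[paste0("n_mx_", crit)]] <- sum(sel & records$type == "MX")
    out[[paste0("n_total_", crit)]] <- sum(sel)
    out[[paste0("ratio_", crit)]] <-
      if (!is.na(kh) && kht > 0) relative_contribution(kh, kht) else NA_real_
  }
  structure(out, class = "hydraulic_summary")
}

#' @export
print.hydraulic_summary <- function(x, ...) {
  cat("<hydraulic_summary>\n")
  cat(sprintf("  Kh        %.4e m^4 MPa^-1 s^-1\n", x$kh))
  for (crit in c("bf", "ef")) {
    cat(sprintf("  [%s] n = %d (PX %d, MX %d), Kht %.4e, Khs %.4g, Khts %.4g, Kh/Kht %.1f%%\n",
                toupper(crit), x[[paste0("n_total_", crit)]],
                x[[paste0("n_px_", crit)]], x[[paste0("n_mx_", crit)]],
                x[[paste0("kht_", crit)]], x[[paste0("khs_", crit)]],
                x[[paste0("khts_", crit)]], x[[paste0("ratio_", crit)]]))
  }
  invisible(x)
}
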