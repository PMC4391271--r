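#' Configuration for the synthetic vascular-bundle generator
#'
#' Bundles every tunable of the synthetic-data module: image geometry, vessel
#' counts and diameter distributions, wall/staining class fractions, optical
#' parameters (PSF, noise), and the hydraulic measurement set-up (pressure
#' gradient, segment length, balance sampling). Defaults emulate the study
#' conditions for *Arabidopsis thaliana* inflorescence-stem segments:
#' per-segment lignified vessel counts of 61 (protoxylem, PX) and 40
#' (metaxylem incl. secondary xylem, MX), 35 % of lignified vessels
#' non-conductive, flow recorded every 20 s for 30 min under a 0.04 MPa
#' gradient across a 0.03 m segment, and a mean experimental-to-theoretical
#' conductivity ratio of 0.33 with CV 0.69.
#'
#' @param segment_type `"basal"` or `"apical"`; selects the diameter regime.
#' @param seed integer seed attached to the config (used by [render_pair()]
#'   for its noise stream and as the default for [build_ground_truth()]).
#' @param pixel_size microscope sampling, micrometres per pixel.
#' @param image_shape integer `c(height, width)` in pixels.
#' @param n_bundles number of collateral vascular bundles placed on a ring.
#' @param px_count_mean,mx_count_mean expected per-segment vessel counts per
#'   type. Realized counts are Poisson around a per-segment mean that itself
#'   varies between plants (see `count_dispersion`): stems differ widely in
#'   vigour, and the metaxylem file length especially so.
#' @param count_dispersion `c(PX, MX)` lognormal sdlog of the shared
#'   per-segment vigour factor applied to the two count means. The defaults
#'   (0.19, 0.71) reproduce per-segment count SDs of about 14 and 33 around
#'   means of 61 and 40 — the dispersion reported for inflorescence stems.
#' @param diameter_params list with elements `PX` and `MX`, each
#'   `c(median, gsd)` of a lognormal inner-diameter distribution in
#'   micrometres. `NULL` selects the per-`segment_type` defaults.
#' @param diameter_scale_cv coefficient of variation of a per-segment scale
#'   factor on both diameter medians (plants differ in vessel calibre;
#'   default 0.10, the between-segment CV of reported mean diameters).
#' @param frac_walled_nonconductive mean fraction of fully lignified vessels
#'   that are nevertheless non-conductive (not yet connected / embolized):
#'   a single number, or `c(PX = , MX = )` for type-specific means (the
#'   defaults 0.295 and 0.425 are the reported per-type shares of
#'   lignified-but-nonfunctional vessels). The realized fraction varies
#'   between segments (stems differ in maturation state): each segment draws
#'   its own fraction(s) from a Beta distribution with this mean and
#'   concentration `frac_nonconductive_concentration`.
#' @param frac_nonconductive_concentration Beta concentration (a + b) of the
#'   per-segment non-conductive fraction; larger is less variable, `Inf`
#'   fixes the fraction. Default 16 (SD about 0.11 at a mean of 0.35).
#' @param frac_expanding fraction of vessels that are immature (expanding or
#'   not yet lignified), i.e. lack a complete secondary wall.
#' @param stain_fraction_conductive,stain_fraction_nonconductive intervals
#'   from which the true stained perimeter fraction is drawn; must be
#'   disjoint about 0.5 (conductive above, non-conductive below).
#' @param fiber_density expected number of stainable fibers per bundle,
#'   rendered as confounding texture near the PX cluster.
#' @param psf_sigma Gaussian point-spread sigma, micrometres.
#' @param noise_sd additive Gaussian intensity noise (images scaled to
#'   \[0, 1\]).
#' @param pressure_gradient MPa across the segment.
#' @param segment_length metres.
#' @param sampling_interval balance sampling interval, seconds.
#' @param duration flow recording duration, seconds.
#' @param water_density kg m^-3 used for mass-to-volume conversion of the
#'   dilute KCl perfusate.
#' @param balance_noise_sd additive Gaussian noise on each cumulative-mass
#'   reading, grams.
#' @param transient_tau time constant (s) of the initial exponential flow
#'   transient; `0` disables it.
#' @param efficiency_params `c(mean, cv)` of the lognormal (truncated to
#'   (0, 1]) per-segment ratio of experimental to theoretical conductivity.
#' @param ring_radius radius (micrometres) of the ring on which bundles sit;
#'   may be 0 for a single centred bundle.
#' @param wall_width rendered secondary-wall thickness, micrometres (also the
#'   default measurement annulus width).
#'
#' @return An object of class `xylem_config` (a validated list).
#' @seealso [build_ground_truth()], [render_pair()], [generate_cohort()]
#' @export
#' @examples
#' cfg <- generator_config("apical", seed = 7, n_bundles = 2,
#'                         px_count_mean = 10, mx_count_mean = 6)
#' cfg$diameter_params$PX
generator_config <- function(segment_type = c("basal", "apical"),
                             seed = 1L,
                             pixel_size = 0.25,
                             image_shape = c(2304L, 2304L),
                             n_bundles = 8,
                             px_count_mean = 61,
                             mx_count_mean = 40,
                             count_dispersion = c(PX = 0.19, MX = 0.71),
                             diameter_params = NULL,
                             diameter_scale_cv = 0.10,
                             frac_walled_nonconductive = c(PX = 0.295,
                                                           MX = 0.425),
                             frac_nonconductive_concentration = 4,
                             frac_expanding = 0.08,
                             stain_fraction_conductive = c(0.60, 0.98),
                             stain_fraction_nonconductive = c(0.02, 0.45),
                             fiber_density = 15,
                             psf_sigma = 0.3,
                             noise_sd = 0.01,
                             pressure_gradient = 0.04,
                             segment_length = 0.03,
                             sampling_interval = 20,
                             duration = 1800,
                             water_density = 998.2,
                             balance_noise_sd = 2e-4,
                             transient_tau = 60,
                             efficiency_params = c(mean = 0.33, cv = 0.69),
                             ring_radius = 110,
                             wall_width = 2) {
  segment_type <- match.arg(segment_type)
  if (is.null(diameter_params)) {
    diameter_params <- switch(segment_type,
      apical = list(PX = c(median = 7.2,  gsd = 1.30),
                    MX = c(median = 11.5, gsd = 1.30)),
      basal  = list(PX = c(median = 10.5, gsd = 1.30),
                    MX = c(median = 17.0, gsd = 1.30)))
  }
  cfg <- list(
    segment_type = segment_type, seed = as.integer(seed),
    pixel_size = pixel_size, image_shape = as.integer(image_shape),
    n_bundles = n_bundles,
    px_count_mean = px_count_mean, mx_count_mean = mx_count_mean,
    count_dispersion = count_dispersion,
    diameter_params = diameter_params,
    diameter_scale_cv = diameter_scale_cv,
    frac_walled_nonconductive = frac_walled_nonconductive,
    frac_nonconductive_concentration = frac_nonconductive_concentration,
    frac_expanding = frac_expanding,
    stain_fraction_conductive = stain_fraction_conductive,
    stain_fraction_nonconductive = stain_fraction_nonconductive,
    fiber_density = fiber_density, psf_sigma = psf_sigma,
    noise_sd = noise_sd,
    pressure_gradient = pressure_gradient,
    segment_length = segment_length,
    sampling_interval = sampling_interval, duration = duration,
    water_density = water_density, balance_noise_sd = balance_noise_sd,
    transient_tau = transient_tau,
    efficiency_params = efficiency_params,
    ring_radius = ring_radius, wall_width = wall_width)
  validate_config(cfg)
  class(cfg) <- "xylem_config"
  cfg
}

validate_config <- function(cfg) {
  if (!is_number(cfg$pixel_size) || cfg$pixel_size <= 0)
    stopf("pixel_size must be a positive number")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 8L))
    stopf("image_shape must be c(height, width) with at least 8 px each")
  for (f in c("n_bundles", "px_count_mean", "mx_count_mean", "fiber_density"))
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0) stopf("%s must be >= 0", f)
  if (cfg$n_bundles != round(cfg$n_bundles) || cfg$n_bundles < 1)
    stopf("n_bundles must be a positive integer")
  fw <- cfg$frac_walled_nonconductive
  if (!is.numeric(fw) || !length(fw) %in% c(1L, 2L) ||
      any(fw < 0 | fw >= 1) ||
      (length(fw) == 2L && !all(c("PX", "MX") %in% names(fw))))
    stopf("frac_walled_nonconductive must be one fraction in [0, 1) or c(PX = , MX = )")
  if (!is_number(cfg$frac_expanding) || cfg$frac_expanding < 0 ||
      cfg$frac_expanding >= 1)
    stopf("frac_expanding must lie in [0, 1)")
  cd <- cfg$count_dispersion
  if (!is.numeric(cd) || length(cd) != 2L || any(cd < 0))
    stopf("count_dispersion must be c(PX, MX) with values >= 0")
  if (!is_number(cfg$diameter_scale_cv) || cfg$diameter_scale_cv < 0)
    stopf("diameter_scale_cv must be >= 0")
  if (!(is.numeric(cfg$frac_nonconductive_concentration) &&
        length(cfg$frac_nonconductive_concentration) == 1L &&
        cfg$frac_nonconductive_concentration > 0))
    stopf("frac_nonconductive_concentration must be > 0")
  sc <- cfg$stain_fraction_conductive
  sn <- cfg$stain_fraction_nonconductive
  if (length(sc) != 2L || sc[1] > sc[2] || sc[1] <= 0.5 || sc[2] > 1)
    stopf("stain_fraction_conductive must be an interval within (0.5, 1]")
  if (length(sn) != 2L || sn[1] > sn[2] || sn[1] < 0 || sn[2] > 0.5)
    stopf("stain_fraction_nonconductive must be an interval within [0, 0.5]")
  for (f in c("pressure_gradient", "segment_length", "sampling_interval",
              "duration", "water_density", "wall_width"))
    if (!is_number(cfg[[f]]) || cfg[[f]] <= 0) stopf("%s must be > 0", f)
  for (f in c("psf_sigma", "noise_sd", "balance_noise_sd", "transient_tau",
              "ring_radius"))
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0) stopf("%s must be >= 0", f)
  ep <- cfg$efficiency_params
  if (length(ep) != 2L || ep[1] <= 0 || ep[1] >= 1 || ep[2] <= 0)
    stopf("efficiency_params must be c(mean, cv) with mean in (0, 1), cv > 0")
  dp <- cfg$diameter_params
  if (!all(c("PX", "MX") %in% names(dp)))
    stopf("diameter_params must contain PX and MX entries")
  for (t in c("PX", "MX"))
    if (length(dp[[t]]) != 2L || any(dp[[t]] <= 0) || dp[[t]][2] < 1)
      stopf("diameter_params$%s must be c(median > 0, gsd >= 1)", t)
  invisible(cfg)
}

#' @export
print.xylem_config <- function(x, ...) {
  cat(sprintf("<xylem_config> %s segment, seed %d\n", x$segment_type, x$seed))
  cat(sprintf("  image %d x %d px at %.3g um/px, %d bundle(s), ring %g um\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size,
              x$n_bundles, x$ring_radius))
  cat(sprintf("  vessel count means: PX %.3g, MX %.3g; %s%% lignified non-conductive, %g%% expanding\n",
              x$px_count_mean, x$mx_count_mean,
              paste(100 * x$frac_walled_nonconductive, collapse = "/"),
              100 * x$frac_expanding))
  cat(sprintf("  diameters (um): PX %.3g (gsd %.3g), MX %.3g (gsd %.3g)\n",
              x$diameter_params$PX[1], x$diameter_params$PX[2],
              x$diameter_params$MX[1], x$diameter_params$MX[2]))
  cat(sprintf("  flow: %g MPa over %g m, every %g s for %g s\n",
              x$pressure_gradient, x$segment_length,
              x$sampling_interval, x$duration))
  invisible(x)
}
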