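# Shared fixtures: all synthetic, generated in code at test time.

# One small bundle (6 PX + 4 MX expected) in a 200 x 200 um field; fast to
# render yet structurally complete.
small_config <- function(segment_type = "apical", seed = 1, pixel_size = 0.25,
                         noise_sd = 0.01, ...) {
  generator_config(segment_type, seed = seed, pixel_size = pixel_size,
                   image_shape = as.integer(round(c(200, 200) / pixel_size)),
                   n_bundles = 1, ring_radius = 0,
                   px_count_mean = 6, mx_count_mean = 4, fiber_density = 6,
                   noise_sd = noise_sd, ...)
}

# A single vessel centred in a 60 x 60 um field.
single_vessel_fixture <- function(d = 16, stain_fraction = 0.75,
                                  wall_state = "full",
                                  wall_completeness = NULL,
                                  pixel_size = 0.25, noise_sd = 0,
                                  fibers = NULL) {
  cfg <- generator_config("apical", seed = 1, pixel_size = pixel_size,
                          image_shape = as.integer(round(c(60, 60) / pixel_size)),
                          n_bundles = 1, ring_radius = 0,
                          px_count_mean = 0, mx_count_mean = 0,
                          fiber_density = 0, noise_sd = noise_sd)
  tr <- vessel_truth(30, 30, d, wall_state,
                     wall_completeness = wall_completeness,
                     stain_fraction = stain_fraction,
                     conductive = wall_state == "full" & stain_fraction > 0.5,
                     fibers = fibers)
  list(truth = tr, pair = render_pair(tr, cfg), config = cfg)
}

# Compare measured records against truth by nearest-centroid matching.
match_table <- function(records, truth) {
  idx <- match_vessels(records, truth)
  cbind(records, truth[idx, c("type", "wall_state", "conductive",
                              "stain_fraction", "diameter_um")] |>
          stats::setNames(paste0("true_", c("type", "wall_state",
                                            "conductive", "stain_fraction",
                                            "diameter_um"))))
}
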