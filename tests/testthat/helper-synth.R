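# shared fixtures: small geometries and scenes used across test files

small_geom <- function(pixels = 192, pixel_size = 1, n_planes = 5,
                       n_fields = 1) {
  geometry_from_pixels(pixels, pixel_size = pixel_size, n_planes = n_planes,
                       n_fields = n_fields)
}

# nucleus-record data frame straight from intensity vectors
nucleus_records <- function(caspase, pi, well_id = "W1") {
  data.frame(nucleus_id = seq_along(caspase), organoid_id = 1L,
             well_id = well_id, plane = 1L, area = 75,
             mean_caspase = caspase, mean_pi = pi)
}

# a standard demonstration field: a few organoids plus debris
demo_scene <- function(seed = 7, n_organoids = 3, n_debris = 6,
                       background = c(5, 2), ...) {
  synthetic_scene(small_geom(), n_organoids = n_organoids,
                  nuclei_per_organoid = c(12, 20), n_debris = n_debris,
                  background = background, seed = seed, ...)
}

# 96-well-style layout with negative, positive and DMSO controls
demo_layout <- function(doses = 10^seq(-2, 2, length.out = 8),
                        n_reps = 3) {
  ctrl <- data.frame(
    well = sprintf("A%d", 1:9),
    treatment = rep(c("none", "dmso", "staurosporine"), each = 3),
    dose = 0,
    control_role = rep(c("untreated", "vehicle_dmso", "staurosporine"),
                       each = 3))
  trt <- data.frame(
    well = sprintf("B%d", seq_len(length(doses) * n_reps)),
    treatment = "drugX",
    dose = rep(doses, each = n_reps),
    control_role = "none")
  rbind(ctrl, trt)
}
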