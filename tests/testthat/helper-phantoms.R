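# Shared fixtures: compact phantoms built in code. Geometry mirrors the
# default study layout (segmented tendon tube, four vials, large noise
# box) on a reduced field of view so whole-pipeline tests stay fast.

tendon_segments <- function(center = c(36, 20.3), radius = 4,
                            z0 = 4, seg_len = 30,
                            conc = c(INS = 112.9, MID = 77.3, MTJ = 55.3)) {
  regions <- names(conc)
  out <- list()
  for (i in seq_along(regions)) {
    r <- regions[i]
    out[[r]] <- compartment_spec(
      r, "cylinder", center_mm = center, radius_mm = radius,
      z_range_mm = z0 + c(i - 1, i) * seg_len,
      concentration_mM = conc[[r]],
      relaxation = tendon_relaxation(r),
      h1_pd = 100, h1_t2star_ms = c(INS = 1.9, MID = 2.0, MTJ = 2.3)[[r]])
  }
  out
}

small_vials <- function(conc = c(50, 75, 100, 125)) {
  xs <- c(10, 26, 46, 62)
  out <- list()
  for (i in seq_along(conc)) {
    role <- paste0("VIAL_", c(50, 75, 100, 125)[i])
    out[[role]] <- compartment_spec(
      role, "cylinder", center_mm = c(xs[i], 48), radius_mm = 5,
      z_range_mm = c(20, 56), concentration_mM = conc[i],
      relaxation = phantom_relaxation(), h1_pd = 100, h1_t2star_ms = 30)
  }
  out
}

noise_box <- function() {
  list(NOISE = compartment_spec(
    "NOISE", "box", box_mm = list(c(44, 72), c(2, 30), c(84, 120)),
    concentration_mM = 0))
}

# Segmented-tendon study phantom on a 72 x 72 x 120 mm field of view;
# the noise box holds 14*14*18 = 3528 sodium voxels.
small_spec <- function(tendon = tendon_segments(), vials = small_vials(),
                       ...) {
  phantom_spec(fov_mm = c(72, 72, 120),
               compartments = c(tendon, vials, noise_box()), ...)
}

# Uniform (unsegmented) tendon variant for exact-inversion checks.
small_uniform_spec <- function(concentration = 82.2, center = c(36, 20.3),
                               radius = 4, z_range = c(4, 94), ...) {
  tendon <- list(TENDON = compartment_spec(
    "TENDON", "cylinder", center_mm = center, radius_mm = radius,
    z_range_mm = z_range, concentration_mM = concentration,
    relaxation = tendon_relaxation("Total"), h1_pd = 100,
    h1_t2star_ms = 2.1))
  phantom_spec(fov_mm = c(72, 72, 120),
               compartments = c(tendon, small_vials(), noise_box()), ...)
}

noise_free <- function(spec_fn = small_spec, ...)
  spec_fn(sensitivity_model = "UNIFORM", target_snr = NULL,
          h1_noise_sigma = 0, ...)
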