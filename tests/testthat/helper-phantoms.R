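# Shared phantom builders for the segmentation and feature tests.

# Noiseless two-level phantom: lesion SUV 10 on background 2, no texture,
# no blur, no noise. The analytic fixed point of the adaptive threshold is
# B + 0.5 (10 - B) = 6 with B = 2.
two_level_phantom <- function(seed = 7L) {
  generate_phantom(phantom_spec(lesion_mean_suv = 10,
                                background_mean_suv = 2,
                                heterogeneity_sd = 0, psf_fwhm_mm = 0,
                                noise_sd = 0, seed = seed))
}

# Moderate-difficulty phantom: TBR 4, moderate blur and noise.
moderate_phantom <- function(seed) {
  generate_phantom(phantom_spec(lesion_mean_suv = 8,
                                background_mean_suv = 2,
                                heterogeneity_sd = 0.8, psf_fwhm_mm = 6,
                                noise_sd = 0.3, seed = seed))
}

# Build a small suv_volume directly from an array (unit-ish voxels).
tiny_volume <- function(values, voxel_dims = c(1, 1, 1)) {
  suv_volume(values, voxel_dims)
}

# Random discretised volume fixture: integer levels in 1..n_levels on a
# full mask, returned as a discretised_volume via a matching SUV volume.
random_disc <- function(seed, dm = c(4, 4, 4), n_levels = 3L,
                        bin_width = 1) {
  set.seed(seed)
  lev <- array(sample.int(n_levels, prod(dm), replace = TRUE), dm)
  vol <- tiny_volume((lev - 0.5) * bin_width)
  mask <- array(TRUE, dm)
  discretise_fbs(vol, mask, discretisation_config(bin_width = bin_width))
}
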