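#' Specification of a synthetic FDG-PET lesion phantom
#'
#' Describes a single ellipsoidal FDG-avid lesion on uniform background
#' activity, with within-lesion Gaussian texture, Gaussian PSF blur
#' (mimicking reconstruction smoothing) and additive Gaussian noise.
#' Defaults use the voxel grid of a clinical time-of-flight PET
#' reconstruction (2.73 x 2.73 x 3.27 mm voxels).
#'
#' @param grid_shape Grid dimensions in voxels.
#' @param voxel_dims Voxel edge lengths in mm.
#' @param lesion_centre Lesion centre in (1-based) grid coordinates;
#'   default grid centre.
#' @param lesion_radii Ellipsoid semi-axes in mm.
#' @param lesion_mean_suv,background_mean_suv Mean SUV inside / outside the
#'   lesion; their ratio is the tumour-to-background ratio (TBR).
#' @param heterogeneity_sd SD (SUV) of the zero-mean Gaussian texture added
#'   inside the lesion before blurring.
#' @param psf_fwhm_mm Full width at half maximum of the Gaussian point
#'   spread function, in mm (0 disables blurring).
#' @param noise_sd SD (SUV) of i.i.d. Gaussian noise added after blurring.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 26L),
                         voxel_dims = c(2.73, 2.73, 3.27),
                         lesion_centre = NULL,
                         lesion_radii = c(10, 10, 10),
                         lesion_mean_suv = 8,
                         background_mean_suv = 2,
                         heterogeneity_sd = 1.0,
                         psf_fwhm_mm = 6.0,
                         noise_sd = 0.3,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(lesion_centre)) lesion_centre <- (grid_shape + 1) / 2
  spec <- structure(list(
    grid_shape = grid_shape, voxel_dims = as.numeric(voxel_dims),
    lesion_centre = as.numeric(lesion_centre),
    lesion_radii = as.numeric(lesion_radii),
    lesion_mean_suv = lesion_mean_suv,
    background_mean_suv = background_mean_suv,
    heterogeneity_sd = heterogeneity_sd,
    psf_fwhm_mm = psf_fwhm_mm, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3L, all(spec$grid_shape > 0),
            all(spec$voxel_dims > 0), all(spec$lesion_radii > 0),
            spec$lesion_mean_suv > 0, spec$background_mean_suv > 0,
            spec$heterogeneity_sd >= 0, spec$psf_fwhm_mm >= 0,
            spec$noise_sd >= 0)
  if (spec$lesion_mean_suv <= spec$background_mean_suv)
    stop("lesion_mean_suv must exceed background_mean_suv")
  if (any(spec$lesion_radii <= spec$voxel_dims))
    stop("every lesion radius must exceed one voxel dimension")
  ax <- c("i", "j", "k")
  for (a in 1:3) {
    ext <- spec$lesion_radii[a] / spec$voxel_dims[a]
    if (spec$lesion_centre[a] - ext < 3 ||
        spec$lesion_centre[a] + ext > spec$grid_shape[a] - 2)
      stop(sprintf(
        "lesion (plus a 2-voxel margin) exceeds the grid on axis %s", ax[a]))
  }
  invisible(spec)
}

#' Generate a synthetic PET phantom with ground truth
#'
#' Builds the SUV volume (background + ellipsoidal lesion + within-lesion
#' texture, PSF blur, additive noise, clipped at 0) and the ground-truth
#' lesion mask. The truth mask is the pre-blur ellipsoid, so it serves as
#' the oracle for segmentation accuracy.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (an [suv_volume()]) and `truth`, a list with
#'   `mask` (logical array), `volume_mm3` and `tbr`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  dm <- spec$grid_shape
  # voxel-centre coordinates relative to the lesion centre, in mm
  dx <- (seq_len(dm[1]) - spec$lesion_centre[1]) * spec$voxel_dims[1]
  dy <- (seq_len(dm[2]) - spec$lesion_centre[2]) * spec$voxel_dims[2]
  dz <- (seq_len(dm[3]) - spec$lesion_centre[3]) * spec$voxel_dims[3]
  q <- outer(outer((dx / spec$lesion_radii[1])^2,
                   (dy / spec$lesion_radii[2])^2, `+`),
             (dz / spec$lesion_radii[3])^2, `+`)
  mask <- q <= 1
  vol <- with_seed(spec$seed, {
    v <- array(spec$background_mean_suv, dm)
    n_les <- sum(mask)
    v[mask] <- spec$lesion_mean_suv +
      if (spec$heterogeneity_sd > 0) stats::rnorm(n_les, 0, spec$heterogeneity_sd) else 0
    v <- gaussian_blur(v, spec$psf_fwhm_mm, spec$voxel_dims)
    if (spec$noise_sd > 0)
      v <- v + array(stats::rnorm(prod(dm), 0, spec$noise_sd), dm)
    pmax(v, 0)
  })
  truth <- structure(list(
    mask = mask,
    volume_mm3 = sum(mask) * prod(spec$voxel_dims),
    tbr = spec$lesion_mean_suv / spec$background_mean_suv),
    class = "lesion_truth")
  list(volume = suv_volume(vol, spec$voxel_dims), truth = truth)
}
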