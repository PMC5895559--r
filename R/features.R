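# Fixed-bin-size SUV discretisation and the ten image features: volume,
# SUVmax, energy, skewness, kurtosis, entropy (first order), GLCM
# dissimilarity (second order), GLSZM grey-level non-uniformity and zone
# percentage, and NGTDM coarseness (higher order). Matrices are computed
# in 3D; formulas follow the image-biomarker standardisation conventions.

#' Discretisation configuration (fixed bin size)
#'
#' SUVs are mapped to integer grey levels with a constant bin width
#' (default 0.5 SUV) anchored at SUV 0, so bins are comparable across
#' lesions and masks: `level = floor((SUV - anchor)/width) + 1`, with
#' half-open bins (a value on an edge goes to the higher bin).
#'
#' @param bin_width Bin width in SUV (> 0).
#' @param anchor Lower edge of the first bin (SUV).
#' @export
discretisation_config <- function(bin_width = 0.5, anchor = 0) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  structure(list(bin_width = bin_width, anchor = anchor),
            class = "discretisation_config")
}

#' Texture configuration
#'
#' @param distance Offset distance for GLCM/NGTDM neighbourhoods (>= 1).
#' @param glcm_symmetric Use symmetric co-occurrence matrices.
#' @param kurtosis_excess Report excess kurtosis (m4/m2^2 - 3) rather than
#'   raw kurtosis.
#' @param glnu_normalised Normalise GLSZM grey-level non-uniformity by the
#'   total zone count (`sum z_i^2 / N_z`); `FALSE` gives the unnormalised
#'   `sum z_i^2`.
#' @export
texture_config <- function(distance = 1L, glcm_symmetric = TRUE,
                           kurtosis_excess = TRUE, glnu_normalised = TRUE) {
  if (distance < 1L) stop("distance must be >= 1")
  structure(list(distance = as.integer(distance),
                 glcm_symmetric = glcm_symmetric,
                 kurtosis_excess = kurtosis_excess,
                 glnu_normalised = glnu_normalised,
                 zone_connectivity = 26L,
                 aggregation = "per-direction-then-average"),
            class = "texture_config")
}

#' Discretise masked SUVs to grey levels at fixed bin size
#'
#' @param vol An [suv_volume()].
#' @param mask Logical array congruent with the volume.
#' @param cfg A [discretisation_config()].
#' @return Object of class `discretised_volume`: integer `bins` array (0
#'   outside the mask), `n_levels`, the `mask` and the config.
#' @export
discretise_fbs <- function(vol, mask, cfg = discretisation_config()) {
  if (!any(mask)) stop("mask is empty")
  bins <- array(0L, dim(vol$values))
  b <- floor((vol$values[mask] - cfg$anchor) / cfg$bin_width) + 1
  if (any(b < 1))
    stop("discretisation produced levels below 1; lower the anchor")
  bins[mask] <- as.integer(b)
  structure(list(bins = bins, n_levels = max(b), mask = mask, config = cfg),
            class = "discretised_volume")
}

#' First-order features
#'
#' Volume (voxel count times voxel volume), SUVmax, energy (sum of squared
#' SUVs), skewness and kurtosis of the masked SUVs using population
#' moments, and Shannon entropy (base 2) of the discretised grey-level
#' histogram. Zero-variance masks yield NaN skewness/kurtosis with a
#' warning.
#'
#' @inheritParams discretise_fbs
#' @param disc The matching [discretise_fbs()] result.
#' @param tcfg A [texture_config()].
#' @return Named list: volume_mm3, suv_max, energy, skewness, kurtosis,
#'   entropy.
#' @export
first_order_features <- function(vol, mask, disc, tcfg = texture_config()) {
  if (!any(mask)) stop("mask is empty")
  x <- vol$values[mask]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < 1e-24) {
    warning("zero variance in mask; skewness/kurtosis undefined")
    skw <- NaN; krt <- NaN
  } else {
    skw <- mean((x - m)^3) / m2^1.5
    krt <- mean((x - m)^4) / m2^2 - if (tcfg$kurtosis_excess) 3 else 0
  }
  p <- tabulate(disc$bins[mask])
  p <- p[p > 0] / sum(p)
  list(volume_mm3 = sum(mask) * prod(vol$voxel_dims),
       suv_max = max(x),
       energy = sum(x^2),
       skewness = skw,
       kurtosis = krt,
       entropy = -sum(p * log2(p)) + 0)
}

# Symmetric grey-level co-occurrence matrix for one direction offset,
# normalised to probabilities; NULL when the direction has no in-mask pair.
glcm_matrix <- function(disc, offset, symmetric = TRUE) {
  dm <- dim(disc$bins)
  nl <- disc$n_levels
  vox <- which(disc$mask)
  co <- arrayInd(vox, dm)
  ni <- co[, 1] + offset[1]; nj <- co[, 2] + offset[2]
  nk <- co[, 3] + offset[3]
  ok <- ni >= 1 & ni <= dm[1] & nj >= 1 & nj <= dm[2] & nk >= 1 & nk <= dm[3]
  if (!any(ok)) return(NULL)
  nlidx <- (nk[ok] - 1) * dm[1] * dm[2] + (nj[ok] - 1) * dm[1] + ni[ok]
  keep <- disc$mask[nlidx]
  if (!any(keep)) return(NULL)
  a <- disc$bins[vox[ok][keep]]
  b <- disc$bins[nlidx[keep]]
  M <- matrix(0, nl, nl)
  tb <- table(factor(a, levels = 1:nl), factor(b, levels = 1:nl))
  M <- M + unclass(tb)
  if (symmetric) M <- M + t(M)
  M / sum(M)
}

#' GLCM dissimilarity
#'
#' For each of the 13 unique 3D directions at Chebyshev distance
#' `tcfg$distance`, builds a symmetric co-occurrence matrix over in-mask
#' voxel pairs, computes `sum p(i,j) |i-j|`, and returns the unweighted
#' mean over directions with at least one pair.
#'
#' @param disc A [discretise_fbs()] result.
#' @param tcfg A [texture_config()].
#' @export
glcm_dissimilarity <- function(disc, tcfg = texture_config()) {
  offs <- half_offsets() * tcfg$distance
  vals <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    M <- glcm_matrix(disc, offs[r, ], tcfg$glcm_symmetric)
    if (is.null(M)) next
    nl <- nrow(M)
    D <- abs(outer(1:nl, 1:nl, `-`))
    vals <- c(vals, sum(M * D))
  }
  if (length(vals) == 0L)
    stop("no in-mask voxel pairs in any direction")
  mean(vals)
}

#' GLSZM features: grey-level non-uniformity and zone percentage
#'
#' Zones are maximal 26-connected sets of equal grey level within the mask.
#' With `z_i` zones at level i, `N_z` total zones and `N_v` masked voxels:
#' GLNU = `sum z_i^2 / N_z` (or unnormalised per config) and zone
#' percentage = `N_z / N_v`.
#'
#' @inheritParams glcm_dissimilarity
#' @return List with `glnu` and `zone_percentage`.
#' @export
glszm_features <- function(disc, tcfg = texture_config()) {
  lab <- label_components(disc$mask, values = disc$bins)
  nz <- max(lab)
  if (nz == 0L) stop("mask is empty")
  zone_level <- disc$bins[match(seq_len(nz), lab)]
  z <- table(zone_level)
  glnu <- sum(as.numeric(z)^2)
  if (tcfg$glnu_normalised) glnu <- glnu / nz
  list(glnu = glnu, zone_percentage = nz / sum(disc$mask))
}

#' NGTDM coarseness
#'
#' For every masked voxel with at least one masked 26-neighbour, the
#' neighbourhood average grey level (excluding the centre) is compared with
#' the voxel's level; with `s_i` the summed absolute differences at level i
#' and `p_i` the level fractions, coarseness is `1 / (eps + sum p_i s_i)`
#' with eps = 1e-12 guarding the flat-region singularity.
#'
#' @inheritParams glcm_dissimilarity
#' @export
ngtdm_coarseness <- function(disc, tcfg = texture_config()) {
  if (!any(disc$mask)) stop("mask is empty")
  b0 <- disc$bins
  b0[!disc$mask] <- 0L
  mnum <- array(as.numeric(disc$mask), dim(disc$mask))
  nsum <- array(0, dim(b0)); ncnt <- array(0, dim(b0))
  offs <- neighbour_offsets() * tcfg$distance
  for (r in seq_len(nrow(offs))) {
    nsum <- nsum + shift_padded(b0, offs[r, ], 0)
    ncnt <- ncnt + shift_padded(mnum, offs[r, ], 0)
  }
  valid <- disc$mask & ncnt >= 1
  if (!any(valid)) stop("no masked voxel has a masked neighbour")
  avg <- nsum[valid] / ncnt[valid]
  lev <- disc$bins[valid]
  contrib <- abs(lev - avg)
  N <- sum(valid)
  s_i <- tapply(contrib, lev, sum)
  n_i <- tapply(contrib, lev, length)
  1 / (1e-12 + sum((n_i / N) * s_i))
}

#' Extract the full ten-feature vector for one lesion mask
#'
#' Computes all ten features on the unthresholded mask under fixed-bin-size
#' discretisation.
#'
#' @inheritParams discretise_fbs
#' @param tcfg A [texture_config()].
#' @param method_name Optional segmentation method annotation.
#' @return Object of class `feature_vector`: named list with volume_mm3,
#'   suv_max, energy, skewness, kurtosis, entropy, dissimilarity, glnu,
#'   zone_percentage, coarseness.
#' @export
extract_features <- function(vol, mask, dcfg = discretisation_config(),
                             tcfg = texture_config(), method_name = NULL) {
  disc <- discretise_fbs(vol, mask, dcfg)
  fo <- first_order_features(vol, mask, disc, tcfg)
  gz <- glszm_features(disc, tcfg)
  fv <- c(fo, list(dissimilarity = glcm_dissimilarity(disc, tcfg)),
          gz, list(coarseness = ngtdm_coarseness(disc, tcfg)))
  fv <- fv[c("volume_mm3", "suv_max", "energy", "skewness", "kurtosis",
             "entropy", "dissimilarity", "glnu", "zone_percentage",
             "coarseness")]
  structure(fv, class = "feature_vector", method_name = method_name,
            dcfg = dcfg, tcfg = tcfg)
}

#' @export
print.feature_vector <- function(x, ...) {
  m <- attr(x, "method_name")
  cat("Feature vector", if (!is.null(m)) paste0(" [", m, "]"), "\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Write a feature table as CSV
#'
#' One row per (patient, segmentation method) with the ten feature columns.
#'
#' @param features Data frame of features.
#' @param path Output CSV path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
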