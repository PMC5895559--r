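# Internal helpers: seeded evaluation, seed splitting, 3D array shifts,
# 26-connectivity components, Sobel gradient, separable Gaussian blur.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic splitting scheme used throughout the package so that every
#' stage of a pipeline run (cohort generation, per-patient phantoms, ...)
#' gets its own reproducible stream. Always returns a positive integer
#' below 2^31.
#'
#' @param master Integer master seed.
#' @param stage Integer stage index (any non-negative integer).
#' @return A single integer seed.
#' @export
stage_seed <- function(master, stage) {
  s <- ((as.numeric(master) %% 1e6) * 2039 + as.numeric(stage) * 9973 + 1) %%
    2147483647
  as.integer(s + 1)
}

# out[i,j,k] = a[clamp(i+d1), clamp(j+d2), clamp(k+d3)]  (replicate edges)
shift_clamped <- function(a, d) {
  dm <- dim(a)
  a[pmin(pmax(seq_len(dm[1]) + d[1], 1L), dm[1]),
    pmin(pmax(seq_len(dm[2]) + d[2], 1L), dm[2]),
    pmin(pmax(seq_len(dm[3]) + d[3], 1L), dm[3]), drop = FALSE]
}

# Shift with zero padding (value `fill` outside the grid).
shift_padded <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- lapply(1:3, function(ax) {
    idx <- seq_len(dm[ax]) + d[ax]
    idx[idx >= 1 & idx <= dm[ax]]
  })
  dst <- lapply(1:3, function(ax) src[[ax]] - d[ax])
  if (any(vapply(src, length, 1L) == 0)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# All 26 neighbour offsets, and the 13 unique (half-space) directions.
neighbour_offsets <- function() {
  o <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
}

half_offsets <- function() {
  o <- neighbour_offsets()
  keep <- o[, 1] > 0 |
    (o[, 1] == 0 & o[, 2] > 0) |
    (o[, 1] == 0 & o[, 2] == 0 & o[, 3] > 0)
  o[keep, , drop = FALSE]
}

# Label 26-connected components of `mask`; if `values` is given, voxels are
# connected only when their values are equal (used for size-zone labelling).
# Returns an integer array, 0 outside the mask.
label_components <- function(mask, values = NULL) {
  dm <- dim(mask)
  vox <- which(mask)
  lab <- array(0L, dm)
  if (length(vox) == 0L) return(lab)
  idx <- array(0L, dm)
  idx[vox] <- seq_along(vox)
  co <- arrayInd(vox, dm)
  offs <- half_offsets()
  e1 <- integer(0); e2 <- integer(0)
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    ni <- co[, 1] + d[1]; nj <- co[, 2] + d[2]; nk <- co[, 3] + d[3]
    ok <- ni >= 1 & ni <= dm[1] & nj >= 1 & nj <= dm[2] & nk >= 1 & nk <= dm[3]
    if (!any(ok)) next
    nl <- (nk[ok] - 1) * dm[1] * dm[2] + (nj[ok] - 1) * dm[1] + ni[ok]
    sl <- vox[ok]
    good <- mask[nl]
    if (!is.null(values)) good <- good & (values[nl] == values[sl])
    if (!any(good)) next
    e1 <- c(e1, idx[sl[good]])
    e2 <- c(e2, idx[nl[good]])
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(e1)) g <- igraph::add_edges(g, rbind(e1, e2))
  lab[vox] <- as.integer(igraph::components(g)$membership)
  lab
}

# Keep only the largest 26-connected component (ties: lowest label, i.e.
# the component containing the lexicographically first voxel).
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (!any(lab > 0L)) return(array(FALSE, dim(mask)))
  tb <- tabulate(lab[lab > 0L])
  lab == which.max(tb)
}

# 1D convolution along one axis via shifted copies, replicate padding.
conv_axis <- function(a, w, axis) {
  r <- (length(w) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (t in seq_along(w)) {
    if (w[t] == 0) next
    d <- c(0L, 0L, 0L)
    d[axis] <- t - r - 1L
    out <- out + w[t] * shift_clamped(a, d)
  }
  out
}

# 3D Sobel gradient magnitude (index space): central difference along one
# axis, [1,2,1] smoothing along the other two.
sobel_gradient <- function(a) {
  sm <- c(1, 2, 1); dv <- c(-1, 0, 1)
  g2 <- array(0, dim(a))
  for (ax in 1:3) {
    g <- a
    for (ax2 in 1:3) g <- conv_axis(g, if (ax2 == ax) dv else sm, ax2)
    g2 <- g2 + g^2
  }
  sqrt(g2)
}

# Separable Gaussian blur with FWHM in mm, voxel dims in mm, truncated 3 sd.
gaussian_blur <- function(a, fwhm_mm, voxel_dims) {
  if (fwhm_mm <= 0) return(a)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    s <- sigma_mm / voxel_dims[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(seq(-r, r), sd = s)
    a <- conv_axis(a, w / sum(w), ax)
  }
  a
}
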