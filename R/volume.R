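#' SUV volume container
#'
#' A 3D grid of standardised uptake values (SUV) together with its voxel
#' dimensions in mm. All downstream operations (segmentation, feature
#' extraction) take this container.
#'
#' @param values 3D numeric array of non-negative SUVs.
#' @param voxel_dims Length-3 numeric, voxel edge lengths in mm.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(values, voxel_dims) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(values < 0))
    stop("SUVs must be non-negative")
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stop("`voxel_dims` must be three positive lengths (mm)")
  structure(list(values = values, voxel_dims = voxel_dims),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("SUV volume %s, voxels %.2f x %.2f x %.2f mm, SUV range [%.2f, %.2f]\n",
              paste(dim(x$values), collapse = "x"),
              x$voxel_dims[1], x$voxel_dims[2], x$voxel_dims[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Bounding box in voxel indices
#'
#' Inclusive low corner, exclusive high corner, 0-based (so a box spanning
#' the whole of a 32-voxel axis is low 0, high 32).
#'
#' @param low,high Length-3 integer corners.
#' @param grid_shape Optional grid dimensions for containment validation.
#' @return Object of class `bounding_box`.
#' @export
bounding_box <- function(low, high, grid_shape = NULL) {
  low <- as.integer(low); high <- as.integer(high)
  if (length(low) != 3L || length(high) != 3L)
    stop("box corners must have length 3")
  if (any(high <= low))
    stop("box must satisfy low < high on every axis")
  if (any(low < 0L))
    stop("box low corner must be >= 0")
  if (!is.null(grid_shape) && any(high > grid_shape))
    stop("box exceeds the grid")
  structure(list(low = low, high = high), class = "bounding_box")
}

# 1-based index ranges of a box.
box_ranges <- function(box) {
  lapply(1:3, function(ax) (box$low[ax] + 1L):box$high[ax])
}

box_dims <- function(box) box$high - box$low

# Extract the sub-array of a volume (or plain array) inside a box.
crop_box <- function(values, box) {
  r <- box_ranges(box)
  values[r[[1]], r[[2]], r[[3]], drop = FALSE]
}

# Place a sub-array mask back into a full-grid logical array.
embed_box <- function(sub, box, grid_shape) {
  out <- array(FALSE, grid_shape)
  r <- box_ranges(box)
  out[r[[1]], r[[2]], r[[3]]] <- sub
  out
}

# Logical array marking the outermost voxel layer of a sub-array.
shell_mask <- function(dm) {
  sh <- array(FALSE, dm)
  sh[c(1L, dm[1]), , ] <- TRUE
  sh[, c(1L, dm[2]), ] <- TRUE
  sh[, , c(1L, dm[3])] <- TRUE
  sh
}

#' Bounding box around a ground-truth lesion mask
#'
#' Dilates the tight box of the mask by a fixed margin (default 8 voxels),
#' clipped to the grid. This stands in for the manual box placement of a
#' clinical workflow.
#'
#' @param mask Logical 3D array.
#' @param margin Dilation in voxels per side.
#' @return A [bounding_box()].
#' @export
truth_bounding_box <- function(mask, margin = 8L) {
  if (!any(mask)) stop("mask is empty")
  dm <- dim(mask)
  co <- arrayInd(which(mask), dm)
  lo <- pmax(apply(co, 2, min) - 1L - margin, 0L)
  hi <- pmin(apply(co, 2, max) + margin, dm)
  bounding_box(lo, hi, dm)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b Logical arrays of identical shape.
#' @return 2|A&B| / (|A|+|B|); NaN when both masks are empty.
#' @export
dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Read / write SUV volumes and masks as NIfTI
#'
#' Thin wrappers over RNifti preserving voxel dimensions in the header.
#' Masks are stored as 0/1 volumes.
#'
#' @param vol An [suv_volume()]; `mask` a logical 3D array.
#' @param voxel_dims Voxel dimensions for `write_mask`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_suv_volume` returns an [suv_volume()]; `read_mask` a
#'   logical array; the writers return `path` invisibly.
#' @export
write_suv_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_suv_volume
#' @export
read_suv_volume <- function(path) {
  img <- RNifti::readNifti(path)
  suv_volume(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3])
}

#' @rdname write_suv_volume
#' @export
write_mask <- function(mask, voxel_dims, path) {
  img <- RNifti::asNifti(array(as.numeric(mask), dim(mask)))
  RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_suv_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim(img))
}

#' Bounding box JSON round trip
#'
#' Boxes are exchanged as `{"low": [i,j,k], "high": [i,j,k]}` (0-based,
#' low inclusive / high exclusive).
#'
#' @param box A [bounding_box()].
#' @param path JSON file path.
#' @export
write_box_json <- function(box, path) {
  jsonlite::write_json(list(low = box$low, high = box$high), path,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_box_json
#' @export
read_box_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bounding_box(x$low, x$high)
}
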