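#' Binary voxel mask with physical geometry
#'
#' A `mask_volume` is the substrate of all geometric measurements: a 3D
#' array of 0/1 voxels plus the physical spacing (mm per axis) and the
#' scanner-space position of the first voxel centre. The index-to-mm
#' mapping is axis-aligned under the right-anterior-superior (RAS)
#' convention: voxel `(i, j, k)` (1-based R indices) has its centre at
#' `origin + (c(i, j, k) - 1) * spacing`. The midsagittal plane is the
#' `x = 0` plane of this frame unless an explicit plane is supplied.
#'
#' @param voxels 3D array (or object coercible to one) of values in
#'   \{0, 1\} (logical arrays are accepted).
#' @param spacing numeric length-3, mm per axis; all entries > 0.
#' @param origin numeric length-3, mm coordinates of the centre of voxel
#'   `(1, 1, 1)`.
#' @return An object of class `mask_volume`: a list with elements
#'   `voxels` (logical 3D array), `spacing`, and `origin`.
#' @examples
#' a <- array(0L, c(4, 4, 4)); a[2, 2, 2] <- 1L
#' m <- mask_volume(a, spacing = c(1, 1, 2))
#' mask_count(m)
#' @export
mask_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array, got ", length(dim(voxels)), " dimensions")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite lengths (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite mm coordinates")
  v <- voxels
  if (!is.logical(v)) {
    uv <- unique(as.vector(v))
    if (!all(uv %in% c(0, 1)))
      stop("mask voxels must be exactly 0 or 1; found other values ",
           "(use `binarize_threshold` when reading non-binary volumes)")
    v <- array(v == 1, dim(voxels))
  }
  structure(list(voxels = v, spacing = spacing, origin = origin),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mask_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm, %d foreground\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              mask_count(x)))
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param m a [mask_volume()].
#' @return integer count of 1-voxels.
#' @export
mask_count <- function(m) sum(m$voxels)

#' Physical volume of a mask in cubic millimetres
#' @param m a [mask_volume()].
#' @return numeric, `mask_count(m) * prod(spacing)`.
#' @export
mask_volume_mm3 <- function(m) mask_count(m) * prod(m$spacing)

#' Millimetre coordinates of all foreground voxel centres
#' @param m a [mask_volume()].
#' @return an n x 3 numeric matrix of RAS mm coordinates.
#' @export
mask_coords <- function(m) {
  idx <- which(m$voxels, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, m$spacing, `*`), 2, m$origin, `+`)
}

# shared-grid check used by every pairwise geometric operation
check_same_grid <- function(a, b, name_a = "a", name_b = "b") {
  stopifnot(inherits(a, "mask_volume"), inherits(b, "mask_volume"))
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop(sprintf("grid mismatch: %s is %s but %s is %s",
                 name_a, paste(dim(a$voxels), collapse = "x"),
                 name_b, paste(dim(b$voxels), collapse = "x")))
  if (max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6)
    stop(sprintf("grid mismatch: %s and %s differ in spacing or origin",
                 name_a, name_b))
  invisible(TRUE)
}

check_nonempty <- function(m, name) {
  if (mask_count(m) == 0L)
    stop(sprintf("mask `%s` is empty; a nonempty mask is required", name))
  invisible(TRUE)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Reads a `.nii` / `.nii.gz` volume and converts it to a [mask_volume()].
#' The voxel spacing is taken from the NIfTI header; the origin is the RAS
#' position of the first voxel centre from the stored affine. Volumes with
#' values other than \{0, 1\} are rejected unless `binarize_threshold` is
#' given, in which case voxels with intensity strictly greater than the
#' threshold become foreground.
#'
#' @param path path to a NIfTI-1 file.
#' @param binarize_threshold optional numeric; see Details.
#' @return a [mask_volume()].
#' @export
read_mask <- function(path, binarize_threshold = NULL) {
  if (!file.exists(path)) stop("cannot read mask: file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop("mask file is not a 3D volume: ", path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  aff <- RNifti::xform(img)
  origin <- as.numeric(aff[1:3, 4])
  if (!is.null(binarize_threshold)) {
    arr <- array(as.numeric(arr > binarize_threshold), dim(arr))
  } else if (!all(unique(as.vector(arr)) %in% c(0, 1))) {
    stop("volume is not binary: ", path,
         " (supply `binarize_threshold` to binarize it)")
  }
  mask_volume(arr, spacing = spacing, origin = origin)
}

#' Write a mask to a NIfTI-1 file
#'
#' Foreground voxels are written as 1, background as 0; spacing and origin
#' are stored in the NIfTI header (axis-aligned RAS affine).
#'
#' @param m a [mask_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path) {
  stopifnot(inherits(m, "mask_volume"))
  arr <- array(as.integer(m$voxels), dim(m$voxels))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- m$spacing
  aff <- diag(c(m$spacing, 1))
  aff[1:3, 4] <- m$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# logical array of boundary foreground voxels: foreground with at least one
# 6-neighbour (or grid edge) outside the mask; extreme points of the voxel
# set always lie on the boundary, so exact max-pairwise searches may be
# restricted to it
boundary_voxels <- function(m) {
  v <- m$voxels
  d <- dim(v)
  interior <- array(TRUE, d)
  shift_ok <- function(ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- (1 + by):n; idx_src[[ax]] <- 1:(n - by) }
    else        { idx_dst[[ax]] <- 1:(n + by); idx_src[[ax]] <- (1 - by):n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      v[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift_ok(ax, by)
  v & !interior
}
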