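# Brute-force geometric oracles: exhaustive voxel-centre pair searches,
# independent of the distance-transform implementation. Only for small masks.

all_pair_dists <- function(A, B) {
  # |A| x |B| matrix of Euclidean distances between coordinate rows
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

bf_min_dist <- function(a, b) {
  min(all_pair_dists(mask_coords(a), mask_coords(b)))
}

bf_oedema_extension <- function(tumour, oedema) {
  outside <- oedema$voxels & !tumour$voxels
  if (!any(outside)) return(0)
  om <- mask_volume(outside, oedema$spacing, oedema$origin)
  d <- all_pair_dists(mask_coords(om), mask_coords(tumour))
  max(apply(d, 1, min))
}

bf_feret <- function(a) {
  pts <- mask_coords(a)
  if (nrow(pts) < 2) return(0)
  max(all_pair_dists(pts, pts))
}

# random sparse mask on a given grid with n foreground voxels
random_mask <- function(dim, n, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- array(FALSE, dim)
  v[sample(prod(dim), n)] <- TRUE
  mask_volume(v, spacing, origin)
}

# single-voxel mask helper
voxel_mask <- function(dim, at, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- array(FALSE, dim)
  v[at[1], at[2], at[3]] <- TRUE
  mask_volume(v, spacing, origin)
}
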