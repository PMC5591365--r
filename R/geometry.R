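#' Minimum surface distance between two masks
#'
#' Minimum over foreground voxels of `a` of the Euclidean distance (mm,
#' honouring anisotropic spacing) from the voxel centre to the nearest
#' foreground voxel centre of `b`. Returns 0 when the masks overlap. This
#' is the measurement behind the periventricular rule: enhancing tumour
#' within 10 mm of the ventricles.
#'
#' Distances are voxel-centre to voxel-centre, computed with an exact
#' anisotropic Euclidean distance transform; sub-voxel surface offsets are
#' not modelled, so results carry an error bound of at most one voxel
#' diagonal relative to continuous geometry.
#'
#' @param a,b [mask_volume()] objects on the same grid; both nonempty.
#' @return distance in mm (>= 0).
#' @export
min_surface_distance <- function(a, b) {
  check_same_grid(a, b)
  check_nonempty(a, deparse(substitute(a)))
  check_nonempty(b, deparse(substitute(b)))
  if (any(a$voxels & b$voxels)) return(0)
  d2 <- cpp_edt_sq(as.vector(b$voxels), dim(b$voxels), b$spacing)
  sqrt(min(d2[a$voxels]))
}

#' Maximum (Feret) diameter of a mask in 3D
#'
#' The maximum Euclidean distance in mm between centres of any two
#' foreground voxels — the 3D maximal tumour diameter. Computed exactly by
#' pairwise search restricted to boundary voxels (which contain the extreme
#' points). `mode = "axial"` instead returns the maximum in-plane diameter
#' over axial (z) slices, the way a radiologist measures on a single slice.
#'
#' @param a a nonempty [mask_volume()].
#' @param mode `"3d"` (default) or `"axial"`.
#' @return diameter in mm (0 for a single voxel).
#' @export
feret_diameter <- function(a, mode = c("3d", "axial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "mask_volume"))
  check_nonempty(a, deparse(substitute(a)))
  if (mode == "3d") {
    bm <- mask_volume(boundary_voxels(a), a$spacing, a$origin)
    return(cpp_max_pairwise(mask_coords(bm)))
  }
  d <- dim(a$voxels)
  best <- 0
  for (k in seq_len(d[3])) {
    sl <- a$voxels[, , k]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    pts <- cbind(sweep(idx - 1, 2, a$spacing[1:2], `*`), 0)
    best <- max(best, cpp_max_pairwise(pts))
  }
  best
}

#' Maximum extension of oedema beyond the enhancing tumour
#'
#' Maximum over oedema voxels of the Euclidean distance (mm) to the nearest
#' tumour voxel centre: how far the peritumoural oedema reaches beyond the
#' contrast-enhancing margin. 0 when the oedema mask is empty or lies
#' entirely inside the tumour.
#'
#' @param tumour nonempty [mask_volume()] of enhancing tumour.
#' @param oedema [mask_volume()] of oedema on the same grid (may be empty).
#' @return extension in mm (>= 0).
#' @export
oedema_extension <- function(tumour, oedema) {
  check_same_grid(tumour, oedema, "tumour", "oedema")
  check_nonempty(tumour, "tumour")
  outside <- oedema$voxels & !tumour$voxels
  if (!any(outside)) return(0)
  d2 <- cpp_edt_sq(as.vector(tumour$voxels), dim(tumour$voxels),
                   tumour$spacing)
  sqrt(max(d2[outside]))
}

#' Does the tumour extend into a region?
#'
#' TRUE iff the tumour and region masks share at least `min_voxels`
#' foreground voxels. Used for corpus callosum and eloquent-region
#' involvement ("extends into"); the default of one voxel is the most
#' sensitive reading and is configurable.
#'
#' @param tumour,region [mask_volume()] objects on the same grid.
#' @param min_voxels minimum overlap count (>= 1) to call involvement.
#' @return logical.
#' @export
involvement <- function(tumour, region, min_voxels = 1L) {
  check_same_grid(tumour, region, "tumour", "region")
  min_voxels <- as.integer(min_voxels)
  if (is.na(min_voxels) || min_voxels < 1L)
    stop("`min_voxels` must be an integer >= 1")
  sum(tumour$voxels & region$voxels) >= min_voxels
}

#' Define a plane by a point and a normal
#'
#' @param point numeric length-3, a point on the plane (mm, RAS).
#' @param normal numeric length-3, plane normal; normalised internally.
#' @return list with unit `normal` and `point`, class `mm_plane`.
#' @export
midline_plane <- function(point = c(0, 0, 0), normal = c(1, 0, 0)) {
  normal <- as.numeric(normal); point <- as.numeric(point)
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn == 0) stop("plane normal must be nonzero")
  structure(list(point = point, normal = normal / nn), class = "mm_plane")
}

#' Does the tumour cross the midsagittal plane?
#'
#' TRUE iff the tumour has at least one voxel centre strictly on each side
#' of the plane (signed distance > 0 and < 0); centres exactly on the plane
#' count for neither side. This is the bilateral-location criterion.
#'
#' @param tumour nonempty [mask_volume()].
#' @param midline a [midline_plane()]; defaults to the scanner `x = 0`
#'   plane of the RAS frame.
#' @return logical.
#' @export
crosses_midline <- function(tumour, midline = midline_plane()) {
  stopifnot(inherits(tumour, "mask_volume"), inherits(midline, "mm_plane"))
  check_nonempty(tumour, "tumour")
  pts <- mask_coords(tumour)
  s <- as.vector((pts - matrix(midline$point, nrow(pts), 3, byrow = TRUE)) %*%
                   midline$normal)
  any(s > 0) && any(s < 0)
}

#' Assemble a region atlas
#'
#' Bundles the anatomical reference masks (ventricles, corpus callosum,
#' eloquent regions — motor/sensory cortex, language cortex, insula, basal
#' ganglia as one union mask) and the midsagittal plane, all co-registered
#' with the subject masks.
#'
#' @param ventricles,corpus_callosum,eloquent [mask_volume()] objects on a
#'   common grid.
#' @param midline a [midline_plane()].
#' @return list of class `region_atlas`.
#' @export
region_atlas <- function(ventricles, corpus_callosum, eloquent,
                         midline = midline_plane()) {
  check_same_grid(ventricles, corpus_callosum, "ventricles", "corpus_callosum")
  check_same_grid(ventricles, eloquent, "ventricles", "eloquent")
  stopifnot(inherits(midline, "mm_plane"))
  structure(list(ventricles = ventricles, corpus_callosum = corpus_callosum,
                 eloquent = eloquent, midline = midline),
            class = "region_atlas")
}

#' Extract the five raw grading measurements for one subject
#'
#' Composes the geometric operations into the continuous/boolean
#' measurements that the grading rules threshold: distance from enhancing
#' tumour to ventricles, corpus callosum involvement, bilaterality (midline
#' crossing), eloquent involvement, maximal diameter, and oedema extension.
#' Deterministic for fixed input.
#'
#' @param tumour nonempty [mask_volume()] of contrast-enhancing tumour.
#' @param oedema [mask_volume()] of associated oedema (same grid).
#' @param atlas a [region_atlas()] on the same grid.
#' @param subject_id identifier copied into the output row.
#' @param diameter_mode `"3d"` or `"axial"`, see [feret_diameter()].
#' @param involvement_min_voxels overlap threshold for [involvement()].
#' @return one-row data.frame with columns `subject_id`,
#'   `ventricle_distance_mm`, `corpus_callosum_involved`, `bilateral`,
#'   `eloquent_involved`, `max_diameter_mm`, `oedema_extension_mm`.
#' @export
extract_features <- function(tumour, oedema, atlas, subject_id = "subject",
                             diameter_mode = c("3d", "axial"),
                             involvement_min_voxels = 1L) {
  diameter_mode <- match.arg(diameter_mode)
  stopifnot(inherits(atlas, "region_atlas"))
  check_same_grid(tumour, atlas$ventricles, "tumour", "atlas")
  check_nonempty(tumour, "tumour")
  data.frame(
    subject_id = as.character(subject_id),
    ventricle_distance_mm = min_surface_distance(tumour, atlas$ventricles),
    corpus_callosum_involved =
      involvement(tumour, atlas$corpus_callosum, involvement_min_voxels),
    bilateral = crosses_midline(tumour, atlas$midline),
    eloquent_involved =
      involvement(tumour, atlas$eloquent, involvement_min_voxels),
    max_diameter_mm = feret_diameter(tumour, diameter_mode),
    oedema_extension_mm = oedema_extension(tumour, oedema),
    stringsAsFactors = FALSE
  )
}
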