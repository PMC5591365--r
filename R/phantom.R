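#' Specify a geometric phantom with analytic ground truth
#'
#' A phantom is an ellipsoidal "tumour" plus the surrounding structures
#' needed to exercise every grading measurement: an oedema shell of
#' commanded thickness, a ventricle slab at a commanded gap from the
#' tumour surface, optional boxes overlapping the tumour for corpus
#' callosum and eloquent regions, and a commanded side relative to the
#' midline. All commanded lengths are snapped to the voxel lattice
#' (semi-axes to whole voxels per axis, gap to whole voxels along x) so
#' that the implied ground-truth features are exact on the lattice rather
#' than discretisation-limited; the snapped values are what the returned
#' spec records.
#'
#' @param semi_axes_mm ellipsoid semi-axes (3 positive lengths, mm).
#' @param oedema_thickness_mm commanded oedema shell thickness (>= 0).
#' @param ventricle_gap_mm commanded gap between tumour surface and the
#'   ventricle slab; values <= 0 make them overlap (distance 0).
#' @param callosum_overlap,eloquent_overlap should the region box overlap
#'   the tumour?
#' @param span_midline should the tumour straddle the `x = 0` plane?
#' @param spacing voxel spacing in mm (3 positive values).
#' @param grid_shape optional integer length-3; auto-sized to fit the
#'   phantom when `NULL`. A grid too small for the commanded geometry is
#'   rejected.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes_mm = c(20, 15, 10),
                         oedema_thickness_mm = 10,
                         ventricle_gap_mm = 5,
                         callosum_overlap = FALSE,
                         eloquent_overlap = FALSE,
                         span_midline = FALSE,
                         spacing = c(1, 1, 1),
                         grid_shape = NULL) {
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(semi_axes_mm) == 3)
  if (any(semi_axes_mm <= 0)) stop("semi-axes must be positive")
  if (oedema_thickness_mm < 0) stop("oedema thickness must be >= 0")
  # snap to the lattice so ground truth is exact
  ax <- pmax(1, round(semi_axes_mm / spacing)) * spacing
  gap <- round(ventricle_gap_mm / spacing[1]) * spacing[1]
  thick <- round(oedema_thickness_mm / spacing[1]) * spacing[1]
  slab_vox <- 3L
  pad <- 2L
  need <- c(
    # x: oedema margin | tumour | gap | slab | pad
    ceiling((thick + ax[1]) / spacing[1]) + 1 + ceiling((ax[1] + max(gap, 0)) / spacing[1]) + slab_vox + pad,
    # y, z: tumour + oedema + region box room
    ceiling(2 * (ax[2] + thick) / spacing[2]) + 2 * pad + 4,
    ceiling(2 * (ax[3] + thick) / spacing[3]) + 2 * pad + 4
  )
  if (is.null(grid_shape)) grid_shape <- as.integer(need)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < need))
    stop(sprintf("grid %s too small for phantom (needs at least %s)",
                 paste(grid_shape, collapse = "x"),
                 paste(as.integer(need), collapse = "x")))
  structure(list(semi_axes_mm = ax, oedema_thickness_mm = thick,
                 ventricle_gap_mm = gap,
                 callosum_overlap = isTRUE(callosum_overlap),
                 eloquent_overlap = isTRUE(eloquent_overlap),
                 span_midline = isTRUE(span_midline),
                 spacing = spacing, grid_shape = grid_shape),
            class = "phantom_spec")
}

#' Rasterise a phantom and return masks, atlas, and ground truth
#'
#' Builds the subject masks (tumour, oedema) and region atlas (ventricles,
#' corpus callosum, eloquent, midline) commanded by a [phantom_spec()],
#' together with the analytically implied feature values:
#' `ventricle_distance_mm = max(gap, 0)`, `max_diameter_mm = 2 * max
#' semi-axis`, `oedema_extension_mm = thickness`, and the three booleans
#' as commanded. The tumour centre sits on a voxel centre and the
#' ventricle slab's near face is aligned to the rasterised tumour's
#' extreme voxel plane, so the length ground truths are exact for the
#' voxel-centre metric.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `tumour`, `oedema` ([mask_volume()]s),
#'   `atlas` ([region_atlas()]), and `truth` (one-row data.frame in the
#'   [extract_features()] column layout).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape; sp <- spec$spacing
  ax <- spec$semi_axes_mm
  # tumour centre index: leave oedema room on -x, region/pad room elsewhere
  ci <- c(ceiling((spec$oedema_thickness_mm + ax[1]) / sp[1]) + 2L,
          as.integer(ceiling(d[2] / 2)),
          as.integer(ceiling(d[3] / 2)))
  # origin: tumour centre at x = +spacing/2 when spanning the midline
  # (voxel centres then straddle x = 0); strictly positive x otherwise
  ox <- if (spec$span_midline) sp[1] / 2 - (ci[1] - 1) * sp[1] else sp[1] / 2
  origin <- c(ox, 0, 0)

  idx <- arrayInd(seq_len(prod(d)), d)
  off <- sweep(idx, 2, ci, `-`)
  off <- sweep(off, 2, sp, `*`)
  r2 <- (off[, 1] / ax[1])^2 + (off[, 2] / ax[2])^2 + (off[, 3] / ax[3])^2
  tum <- array(r2 <= 1 + 1e-9, d)
  tumour <- mask_volume(tum, sp, origin)

  # oedema: all voxels within the commanded thickness of the tumour set
  if (spec$oedema_thickness_mm > 0) {
    d2 <- cpp_edt_sq(as.vector(tum), d, sp)
    oed <- array(d2 <= spec$oedema_thickness_mm^2 + 1e-6, d)
  } else oed <- tum
  oedema <- mask_volume(oed, sp, origin)

  # ventricle slab: near face exactly `gap` beyond the extreme tumour
  # voxel plane (gap is a whole number of voxels, so the face lies on the
  # lattice and the minimum centre-to-centre distance equals the gap)
  ix_max <- max(idx[tum, 1])
  gap_vox <- as.integer(round(spec$ventricle_gap_mm / sp[1]))
  v_start <- ix_max + max(gap_vox, 0L)
  v_end <- min(v_start + 2L, d[1])
  if (gap_vox < 0L) v_start <- max(1L, ix_max + gap_vox)
  vent <- array(FALSE, d)
  vent[v_start:v_end, , ] <- TRUE
  ventricles <- mask_volume(vent, sp, origin)

  box <- function(overlap, axis) {
    b <- array(FALSE, d)
    if (overlap) {
      b[ci[1] + (-1:1), ci[2] + (-1:1), ci[3] + (-1:1)] <- TRUE
    } else {
      # a 2-voxel plate on the far edge of `axis`, outside tumour reach
      sel <- lapply(d, seq_len)
      sel[[axis]] <- (d[axis] - 1L):d[axis]
      b[sel[[1]], sel[[2]], sel[[3]]] <- TRUE
    }
    b
  }
  callosum <- mask_volume(box(spec$callosum_overlap, 2L), sp, origin)
  eloquent <- mask_volume(box(spec$eloquent_overlap, 3L), sp, origin)
  if (!spec$callosum_overlap && any(callosum$voxels & tum))
    stop("phantom grid leaves no room for a disjoint corpus callosum box")
  if (!spec$eloquent_overlap && any(eloquent$voxels & tum))
    stop("phantom grid leaves no room for a disjoint eloquent box")

  truth <- data.frame(
    subject_id = "phantom",
    ventricle_distance_mm = max(spec$ventricle_gap_mm, 0),
    corpus_callosum_involved = spec$callosum_overlap,
    bilateral = spec$span_midline,
    eloquent_involved = spec$eloquent_overlap,
    max_diameter_mm = 2 * max(ax),
    oedema_extension_mm = spec$oedema_thickness_mm,
    stringsAsFactors = FALSE
  )
  list(tumour = tumour, oedema = oedema,
       atlas = region_atlas(ventricles, callosum, eloquent, midline_plane()),
       truth = truth)
}

#' Draw a random phantom specification
#'
#' Samples commanded geometry uniformly over ranges typical of
#' supratentorial glioblastoma at 1 mm isotropic resolution: semi-axes
#' 4-18 mm, oedema thickness 0-15 mm, ventricle gap -3 to 15 mm, and
#' independent fair draws of the three booleans. Used for randomised
#' phantom-recovery suites.
#'
#' @param seed integer seed for reproducibility.
#' @param spacing voxel spacing (default 1 mm isotropic).
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, spacing = c(1, 1, 1)) {
  set.seed(seed)
  phantom_spec(
    semi_axes_mm = stats::runif(3, 4, 18),
    oedema_thickness_mm = sample(0:15, 1),
    ventricle_gap_mm = sample(-3:15, 1),
    callosum_overlap = stats::runif(1) < 0.5,
    eloquent_overlap = stats::runif(1) < 0.5,
    span_midline = stats::runif(1) < 0.5,
    spacing = spacing
  )
}
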