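#' Surface shell of a brain mask
#'
#' The band of brain voxels within `thickness_mm` of the brain surface:
#' the brain mask minus the mask eroded by `round(thickness_mm / spacing)`
#' voxels per axis (box structuring element). Vessels incompletely
#' suppressed by the black-blood sequence concentrate near the surface, so
#' zeroing this band removes a major false-positive source.
#'
#' @param brain_mask non-empty binary 3D grid.
#' @param thickness_mm shell thickness in mm (0 gives an empty shell).
#' @param spacing voxel sizes (mm), length 3.
#' @return Binary integer grid, a subset of `brain_mask`; the shell and the
#'   eroded interior partition the brain mask.
#' @export
make_surface_shell <- function(brain_mask, thickness_mm, spacing) {
  assert_binary(brain_mask, "brain mask")
  if (sum(brain_mask != 0) == 0) stop("brain mask is empty")
  stopifnot(thickness_mm >= 0, length(spacing) == 3, all(spacing > 0))
  radii <- as.integer(round(thickness_mm / spacing))
  bm <- as_int_mask(brain_mask)
  if (all(radii == 0L)) return(array(0L, dim(bm)))
  eroded <- cpp_erode_box(bm, radii)
  if (sum(eroded) == 0)
    stop(sprintf("shell thickness %.1f mm exceeds the brain radius: erosion is empty",
                 thickness_mm))
  array(as.integer(bm == 1L & eroded == 0L), dim(bm))
}

#' Masks used for false-positive suppression
#'
#' @param surface_shell binary brain-boundary band ([make_surface_shell()]).
#' @param choroid_mask binary choroid-plexus mask on the same grid.
#' @param vessel_mask optional binary vessel mask added to the suppression
#'   union (for phantoms the generator's ground-truth vessels; for real
#'   data a vessel segmentation, when available).
#' @param shell_thickness_mm thickness used to build the shell (recorded).
#' @param overlap_fraction_threshold fraction theta in (0,1\] of a
#'   component's voxels inside the masks at or above which the component is
#'   dropped in `component_filter` mode.
#' @return An object of class `suppression_masks`.
#' @export
suppression_masks <- function(surface_shell, choroid_mask, vessel_mask = NULL,
                              shell_thickness_mm = 2,
                              overlap_fraction_threshold = 0.5) {
  assert_binary(surface_shell, "surface shell")
  assert_binary(choroid_mask, "choroid mask")
  assert_same_grid(surface_shell, choroid_mask, "surface shell", "choroid mask")
  if (is.null(vessel_mask)) {
    vessel_mask <- array(0L, dim(surface_shell))
  } else {
    assert_binary(vessel_mask, "vessel mask")
    assert_same_grid(surface_shell, vessel_mask, "surface shell", "vessel mask")
  }
  stopifnot(overlap_fraction_threshold > 0, overlap_fraction_threshold <= 1)
  structure(list(surface_shell = as_int_mask(surface_shell),
                 choroid_mask = as_int_mask(choroid_mask),
                 vessel_mask = as_int_mask(vessel_mask),
                 shell_thickness_mm = shell_thickness_mm,
                 overlap_fraction_threshold = overlap_fraction_threshold),
            class = "suppression_masks")
}

#' Binarization and small-component filtering configuration
#'
#' @param probability_threshold foreground threshold, strictly in (0,1).
#' @param min_component_voxels components smaller than this are dropped.
#' @param mode `"zero_probability"` zeroes the foreground probability inside
#'   the suppression masks before thresholding; `"component_filter"`
#'   thresholds first and drops whole components whose in-mask voxel
#'   fraction reaches the threshold theta.
#' @return An object of class `binarization_config`.
#' @export
binarization_config <- function(probability_threshold = 0.5,
                                min_component_voxels = 2L,
                                mode = c("zero_probability", "component_filter")) {
  mode <- match.arg(mode)
  if (probability_threshold <= 0 || probability_threshold >= 1)
    stop("probability_threshold must lie strictly inside (0, 1)")
  stopifnot(min_component_voxels >= 0)
  structure(list(probability_threshold = probability_threshold,
                 min_component_voxels = as.integer(min_component_voxels),
                 mode = mode),
            class = "binarization_config")
}

#' Suppress false positives in a foreground probability map
#'
#' Operates solely on the foreground channel. Suppression never adds a
#' voxel (the output is a subset of the thresholded input) and is
#' idempotent for fixed masks and configuration.
#'
#' @param prob_map 3D foreground probability grid.
#' @param masks a [suppression_masks()] on the same grid.
#' @param cfg a [binarization_config()].
#' @return Binary integer prediction grid.
#' @export
suppress <- function(prob_map, masks, cfg = binarization_config()) {
  stopifnot(inherits(masks, "suppression_masks"), inherits(cfg, "binarization_config"))
  assert_same_grid(prob_map, masks$surface_shell, "probability map", "suppression masks")
  union_mask <- masks$surface_shell == 1L | masks$choroid_mask == 1L |
    masks$vessel_mask == 1L
  if (cfg$mode == "zero_probability") {
    p <- prob_map
    p[union_mask] <- 0
    bin <- array(as.integer(p >= cfg$probability_threshold), dim(p))
  } else {
    bin <- array(as.integer(prob_map >= cfg$probability_threshold), dim(prob_map))
    lab <- cpp_label_components(bin, 26L)
    nlab <- max(lab)
    if (nlab > 0) {
      tot <- tabulate(lab[lab > 0L], nbins = nlab)
      inm <- tabulate(lab[lab > 0L & union_mask], nbins = nlab)
      drop <- which(inm / tot >= masks$overlap_fraction_threshold)
      if (length(drop)) bin[lab %in% drop] <- 0L
    }
  }
  drop_small_components(bin, cfg$min_component_voxels)
}

drop_small_components <- function(bin, min_voxels) {
  if (min_voxels <= 1L || sum(bin) == 0) return(bin)
  lab <- cpp_label_components(bin, 26L)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  small <- which(sizes < min_voxels)
  if (length(small)) bin[lab %in% small] <- 0L
  bin
}
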