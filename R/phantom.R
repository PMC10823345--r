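#' Specification of a synthetic black-blood-style phantom
#'
#' Describes a toy 3D volume emulating the appearance of contrast-enhanced
#' black-blood T1-weighted brain MRI at desk scale: a mid-grey brain ellipsoid
#' on a dark background, bright quasi-spherical metastasis-like lesions (a
#' subset carrying a darker non-enhancing necrotic core which the ground
#' truth excludes), bright tubular vessel distractors, a bright
#' choroid-plexus-like ellipsoidal region, and additive Gaussian noise.
#'
#' @param grid_shape integer vector of 3 positive voxel counts.
#' @param voxel_spacing numeric vector of 3 positive voxel sizes in mm.
#' @param n_lesions non-negative number of lesions to place.
#' @param lesion_diameter_range `c(min_mm, max_mm)` for the sampled lesion
#'   diameters (mm), `min_mm <= max_mm`, both positive.
#' @param necrosis_probability probability in \[0,1\] that a lesion carries a
#'   necrotic core.
#' @param necrosis_core_fraction core radius as a fraction of the lesion
#'   radius, strictly inside (0,1).
#' @param n_vessels number of random-walk vessel tubes.
#' @param vessel_radius_mm dilation radius of the vessel centrelines (mm).
#' @param choroid_region list with `centre_vox` (3 voxel coordinates; `NULL`
#'   places it periventricularly, slightly anterior/inferior of the grid
#'   centre) and `semi_axes_mm` (3 semi-axes in mm).
#' @param intensity_levels named list with levels `background`, `brain`,
#'   `lesion_rim`, `necrotic_core`, `vessel`, `choroid`. The necrotic core
#'   must be darker than the lesion rim (non-enhancing).
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed integer seed; the whole phantom is a deterministic function of
#'   the spec including this seed.
#' @param placement_margin_mm minimal distance kept between a lesion surface
#'   and the brain surface (mm), so lesions stay clear of the surface shell
#'   used by postprocessing.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_spacing = c(1, 1, 1),
                         n_lesions = 4,
                         lesion_diameter_range = c(4, 12),
                         necrosis_probability = 0.3,
                         necrosis_core_fraction = 0.45,
                         n_vessels = 3,
                         vessel_radius_mm = 1,
                         choroid_region = list(centre_vox = NULL,
                                               semi_axes_mm = c(8, 4, 4)),
                         intensity_levels = list(background = 0, brain = 60,
                                                 lesion_rim = 200,
                                                 necrotic_core = 35,
                                                 vessel = 180, choroid = 190),
                         noise_sigma = 4,
                         seed = 1L,
                         placement_margin_mm = 4) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            length(voxel_spacing) == 3, all(voxel_spacing > 0),
            n_lesions >= 0, length(lesion_diameter_range) == 2,
            necrosis_probability >= 0, necrosis_probability <= 1,
            necrosis_core_fraction > 0, necrosis_core_fraction < 1,
            n_vessels >= 0, vessel_radius_mm > 0, noise_sigma >= 0)
  if (lesion_diameter_range[1] > lesion_diameter_range[2])
    stop("lesion_diameter_range must satisfy min_mm <= max_mm")
  if (any(lesion_diameter_range <= 0))
    stop("zero- or negative-volume lesions requested: diameters must be positive")
  if (intensity_levels$necrotic_core >= intensity_levels$lesion_rim)
    stop("necrotic core must be darker than the lesion rim (non-enhancing)")
  if (is.null(choroid_region$centre_vox))
    choroid_region$centre_vox <- round(grid_shape * c(0.5, 0.38, 0.38))
  semi_vox <- choroid_region$semi_axes_mm / voxel_spacing
  if (any(2 * semi_vox >= grid_shape))
    stop("choroid semi-axes do not fit inside the grid")
  structure(list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 n_lesions = as.integer(n_lesions),
                 lesion_diameter_range = lesion_diameter_range,
                 necrosis_probability = necrosis_probability,
                 necrosis_core_fraction = necrosis_core_fraction,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius_mm = vessel_radius_mm,
                 choroid_region = choroid_region,
                 intensity_levels = intensity_levels,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 placement_margin_mm = placement_margin_mm),
            class = "phantom_spec")
}

#' Volume of a binary mask in cubic millimetres
#'
#' @param mask binary 3D grid.
#' @param spacing numeric vector of 3 positive voxel sizes (mm).
#' @return `voxel count * prod(spacing)` in mm^3.
#' @examples
#' lesion_volume(array(1, c(10, 10, 1)), c(1, 1, 1))
#' @export
lesion_volume <- function(mask, spacing) {
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive voxel sizes in mm")
  sum(mask != 0) * prod(spacing)
}

#' Generate a synthetic phantom volume with known ground truth
#'
#' Places non-touching ellipsoidal lesions (mild random anisotropy, axis
#' scale factors in \[0.8, 1.25\]) by rejection sampling with a minimum
#' 2-voxel gap, carves necrotic cores out of the ground truth for lesions
#' drawn as necrotic, walks bright vessel tubes through the brain, paints the
#' choroid-plexus region, and adds Gaussian noise last. All randomness runs
#' through one seeded generator; the global RNG state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @param max_retries placement attempts per lesion before failing.
#' @return An object of class `phantom_volume`: list with `intensity` (3D
#'   array), binary integer masks `brain_mask`, `gt_mask`, `necrosis_mask`,
#'   `vessel_mask`, `choroid_mask`, the labelled `lesion_labels` grid, the
#'   lesion `catalog` (tibble), `spacing` and the generating `spec`.
#'   The ground truth excludes necrotic cores and is confined to the brain.
#' @export
generate_phantom <- function(spec, max_retries = 400L) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec, max_retries))
}

place_lesions <- function(spec, gs, sp, brain_interior, occupancy, max_retries) {
  gap <- c(2L, 2L, 2L)
  lesion_labels <- array(0L, gs)
  necrosis <- array(0L, gs)
  geometry <- vector("list", spec$n_lesions)
  has_necrosis <- logical(spec$n_lesions)
  for (i in seq_len(spec$n_lesions)) {
    placed <- FALSE
    for (attempt in seq_len(max_retries)) {
      d_mm <- runif(1, spec$lesion_diameter_range[1], spec$lesion_diameter_range[2])
      axis_scale <- runif(3, 0.8, 1.25)
      semi_mm <- (d_mm / 2) * axis_scale
      semi_vox <- pmax(semi_mm / sp, 0.6)
      # sample centres only where the whole ellipsoid sits inside the
      # interior and its gap-dilated extent clears existing occupancy; this
      # keeps the rejection rate workable for large lesions
      rad <- as.integer(ceiling(semi_vox))
      allowed <- cpp_erode_box(brain_interior, rad)
      blocked <- cpp_dilate_box(occupancy, rad + gap)
      allowed_idx <- which(allowed == 1L & blocked == 0L)
      if (!length(allowed_idx)) next
      cidx <- allowed_idx[sample.int(length(allowed_idx), 1)]
      cvox <- arrayInd(cidx, gs)[1, ]
      les <- ellipsoid_mask(gs, cvox, semi_vox)
      if (sum(les) == 0) next
      if (any(les == 1L & brain_interior == 0L)) next
      les_dil <- cpp_dilate_box(les, gap)
      if (any(les_dil == 1L & occupancy == 1L)) next
      lesion_labels[les == 1L] <- i
      occupancy <- array(as.integer(occupancy == 1L | les_dil == 1L), gs)
      nec <- runif(1) < spec$necrosis_probability
      has_necrosis[i] <- nec
      if (nec) {
        core_semi_vox <- pmax(semi_vox * spec$necrosis_core_fraction, 0.5)
        core <- ellipsoid_mask(gs, cvox, core_semi_vox)
        core <- core * les
        if (sum(les) - sum(core) < 1L) {
          # lesion too small to carry a resolvable core and keep an enhancing rim
          nec <- FALSE
          has_necrosis[i] <- FALSE
        } else {
          necrosis[core == 1L] <- 1L
        }
      }
      geometry[[i]] <- list(centre_vox = cvox, semi_axes_mm = semi_mm,
                            diameter_mm = d_mm, necrotic = nec,
                            core_fraction = spec$necrosis_core_fraction)
      placed <- TRUE
      break
    }
    if (!placed)
      return(list(failed = i))
  }
  list(failed = NULL, lesion_labels = lesion_labels, necrosis = necrosis,
       geometry = geometry, has_necrosis = has_necrosis, occupancy = occupancy)
}

generate_phantom_impl <- function(spec, max_retries) {
  gs <- spec$grid_shape
  sp <- spec$voxel_spacing
  centre <- (gs + 1) / 2

  brain <- ellipsoid_mask(gs, centre, 0.44 * gs)

  ch_semi_vox <- pmax(spec$choroid_region$semi_axes_mm / sp, 0.5)
  choroid <- ellipsoid_mask(gs, spec$choroid_region$centre_vox, ch_semi_vox)
  choroid <- choroid * brain

  # lesions must keep a margin from the brain surface and a >=2-voxel gap
  # from each other and from the choroid region
  margin_vox <- pmax(1L, as.integer(ceiling(spec$placement_margin_mm / sp)))
  brain_interior <- cpp_erode_box(brain, margin_vox)
  gap <- c(2L, 2L, 2L)
  occupancy <- cpp_dilate_box(choroid, gap)

  interior_idx <- which(brain_interior == 1L)
  if (spec$n_lesions > 0 && length(interior_idx) == 0)
    stop("brain interior is empty at the requested placement margin")

  # rejection-sample the whole lesion configuration; if one lesion cannot be
  # placed (earlier placements may have blocked the space), restart afresh
  placement <- NULL
  failed_lesion <- 0L
  for (restart in seq_len(5L)) {
    placement <- place_lesions(spec, gs, sp, brain_interior, occupancy, max_retries)
    if (!is.null(placement$failed)) { failed_lesion <- placement$failed; next }
    break
  }
  if (!is.null(placement$failed))
    stop(sprintf("failed to place lesion %d after %d attempts (5 restarts); grid too crowded for %d lesions of %.1f-%.1f mm",
                 failed_lesion, max_retries, spec$n_lesions,
                 spec$lesion_diameter_range[1], spec$lesion_diameter_range[2]))
  lesion_labels <- placement$lesion_labels
  necrosis <- placement$necrosis
  geometry <- placement$geometry
  has_necrosis <- placement$has_necrosis
  occupancy <- placement$occupancy

  gt <- array(as.integer(lesion_labels > 0L & necrosis == 0L), gs)

  # vessels: Bernoulli-step random walks dilated to the vessel radius,
  # clipped to the brain and kept clear of lesions and choroid
  vessel <- array(0L, gs)
  if (spec$n_vessels > 0) {
    brain_idx <- which(brain == 1L)
    n_steps <- as.integer(2 * max(gs))
    for (v in seq_len(spec$n_vessels)) {
      pos <- arrayInd(brain_idx[sample.int(length(brain_idx), 1)], gs)[1, ]
      drift <- sample(c(-1L, 0L, 1L), 3, replace = TRUE)
      if (all(drift == 0L)) drift[sample.int(3, 1)] <- 1L
      for (s in seq_len(n_steps)) {
        jitter <- sample(c(-1L, 0L, 1L), 3, replace = TRUE, prob = c(0.2, 0.6, 0.2))
        step <- drift + jitter
        pos <- pos + pmax(pmin(step, 1L), -1L)
        if (any(pos < 1L) || any(pos > gs)) break
        if (brain[pos[1], pos[2], pos[3]] == 0L) break
        vessel[pos[1], pos[2], pos[3]] <- 1L
      }
    }
    vr <- pmax(0L, as.integer(round(spec$vessel_radius_mm / sp)))
    if (any(vr > 0L)) vessel <- cpp_dilate_box(vessel, vr)
    vessel <- vessel * brain
    vessel[occupancy == 1L] <- 0L
  }

  lv <- spec$intensity_levels
  intensity <- array(lv$background, gs)
  intensity[brain == 1L] <- lv$brain
  intensity[choroid == 1L] <- lv$choroid
  intensity[vessel == 1L] <- lv$vessel
  intensity[lesion_labels > 0L] <- lv$lesion_rim
  intensity[necrosis == 1L] <- lv$necrotic_core
  if (spec$noise_sigma > 0)
    intensity <- intensity + array(rnorm(prod(gs), 0, spec$noise_sigma), gs)

  catalog <- phantom_catalog(lesion_labels, gt, necrosis, has_necrosis, sp)
  structure(list(intensity = intensity, brain_mask = brain, gt_mask = gt,
                 necrosis_mask = necrosis, vessel_mask = vessel,
                 choroid_mask = choroid, lesion_labels = lesion_labels,
                 catalog = catalog, geometry = geometry,
                 spacing = sp, spec = spec),
            class = "phantom_volume")
}

phantom_catalog <- function(lesion_labels, gt, necrosis, has_necrosis, sp) {
  n <- max(0L, max(lesion_labels))
  voxvol <- prod(sp)
  rows <- lapply(seq_len(n), function(i) {
    idx <- which(lesion_labels == i & gt == 1L)
    vol <- length(idx) * voxvol
    coords <- arrayInd(idx, dim(lesion_labels))
    cen <- colMeans((coords - 0.5) * rep(sp, each = nrow(coords)))
    d <- equivalent_diameter(vol)
    tibble::tibble(lesion_id = i, cx_mm = cen[1], cy_mm = cen[2], cz_mm = cen[3],
                   solid_volume_mm3 = vol, equivalent_diameter_mm = d,
                   has_necrosis = has_necrosis[i], size_class = size_class(d))
  })
  if (n == 0)
    return(tibble::tibble(lesion_id = integer(), cx_mm = numeric(),
                          cy_mm = numeric(), cz_mm = numeric(),
                          solid_volume_mm3 = numeric(),
                          equivalent_diameter_mm = numeric(),
                          has_necrosis = logical(), size_class = character()))
  do.call(rbind, rows)
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %s voxels @ %s mm, %d lesion(s), %d with necrosis\n",
              paste(dim(x$intensity), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              nrow(x$catalog), sum(x$catalog$has_necrosis)))
  invisible(x)
}

nifti_write <- function(arr, file, spacing, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, file, datatype = datatype)
  invisible(file)
}

#' Write a phantom to disk as NIfTI volumes plus catalog and manifest
#'
#' The intensity grid is written in double precision, each mask as unsigned
#' 8-bit, all with voxel dimensions taken from the phantom spacing; the
#' lesion catalog goes to CSV and a JSON manifest records the files and the
#' generating spec (including the seed), so the phantom can be regenerated
#' or re-read bit-identically.
#'
#' @param volume a `phantom_volume`.
#' @param directory output directory (created if missing).
#' @return The manifest, invisibly.
#' @seealso [read_phantom()]
#' @export
write_phantom <- function(volume, directory) {
  stopifnot(inherits(volume, "phantom_volume"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", directory))
  files <- list(intensity = "intensity.nii.gz", brain_mask = "brain_mask.nii.gz",
                gt_mask = "gt_mask.nii.gz", necrosis_mask = "necrosis_mask.nii.gz",
                vessel_mask = "vessel_mask.nii.gz", choroid_mask = "choroid_mask.nii.gz")
  res <- try({
    nifti_write(volume$intensity, file.path(directory, files$intensity),
                volume$spacing, "double")
    for (m in names(files)[-1])
      nifti_write(volume[[m]], file.path(directory, files[[m]]),
                  volume$spacing, "uint8")
    write.csv(volume$catalog, file.path(directory, "catalog.csv"), row.names = FALSE)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop(sprintf("failed writing phantom under '%s': %s", directory,
                 attr(res, "condition")$message))
  spec <- volume$spec
  spec$choroid_region$centre_vox <- as.numeric(spec$choroid_region$centre_vox)
  manifest <- list(files = files, catalog = "catalog.csv",
                   spec = unclass(spec))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read back a phantom written by [write_phantom()]
#'
#' @param directory directory containing `manifest.json`.
#' @return A `phantom_volume` (without the internal geometry/label metadata;
#'   grids, catalog, spacing and spec round-trip exactly).
#' @export
read_phantom <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("no manifest.json under '%s'", directory))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  s <- manifest$spec
  spec <- phantom_spec(grid_shape = s$grid_shape, voxel_spacing = s$voxel_spacing,
                       n_lesions = s$n_lesions,
                       lesion_diameter_range = s$lesion_diameter_range,
                       necrosis_probability = s$necrosis_probability,
                       necrosis_core_fraction = s$necrosis_core_fraction,
                       n_vessels = s$n_vessels, vessel_radius_mm = s$vessel_radius_mm,
                       choroid_region = list(centre_vox = s$choroid_region$centre_vox,
                                             semi_axes_mm = s$choroid_region$semi_axes_mm),
                       intensity_levels = as.list(s$intensity_levels),
                       noise_sigma = s$noise_sigma, seed = s$seed,
                       placement_margin_mm = s$placement_margin_mm)
  rd <- function(f, int = FALSE) {
    a <- as.array(RNifti::readNifti(file.path(directory, f)))
    if (int) array(as.integer(a), dim(a)) else a
  }
  catalog <- tibble::as_tibble(read.csv(file.path(directory, manifest$catalog),
                                        stringsAsFactors = FALSE))
  structure(list(intensity = rd(manifest$files$intensity),
                 brain_mask = rd(manifest$files$brain_mask, TRUE),
                 gt_mask = rd(manifest$files$gt_mask, TRUE),
                 necrosis_mask = rd(manifest$files$necrosis_mask, TRUE),
                 vessel_mask = rd(manifest$files$vessel_mask, TRUE),
                 choroid_mask = rd(manifest$files$choroid_mask, TRUE),
                 lesion_labels = NULL, catalog = catalog, geometry = NULL,
                 spacing = spec$voxel_spacing, spec = spec),
            class = "phantom_volume")
}
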