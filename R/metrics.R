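#' Equivalent sphere diameter of a volume
#'
#' @param volume_mm3 positive volume(s) in mm^3.
#' @return Diameter(s) in mm: `(6 V / pi)^(1/3)`.
#' @examples
#' equivalent_diameter(4 / 3 * pi * 5^3)  # 10 mm
#' @export
equivalent_diameter <- function(volume_mm3) {
  if (any(volume_mm3 <= 0)) stop("volume must be positive")
  (6 * volume_mm3 / pi)^(1 / 3)
}

#' Size class of a lesion diameter
#'
#' Lesions up to and including 10 mm equivalent diameter are "small",
#' larger ones "large" (the 10 mm boundary is inclusive to small).
#'
#' @param diameter_mm positive diameter(s) in mm.
#' @return Character vector of `"small"` / `"large"`.
#' @export
size_class <- function(diameter_mm) {
  if (any(diameter_mm <= 0)) stop("diameter must be positive")
  ifelse(diameter_mm <= 10, "small", "large")
}

#' Connected components of a binary mask
#'
#' @param mask binary 3D grid.
#' @param spacing voxel sizes in mm (length 3).
#' @param connectivity 26 (faces, edges, corners; default) or 6 (faces).
#' @return An object of class `component_set`: the labelled integer grid
#'   (`labels`, ids dense from 1) and a `summary` tibble with per-component
#'   id, voxel count, volume (mm^3), centroid (mm) and equivalent sphere
#'   diameter (mm).
#' @export
label_components <- function(mask, spacing = c(1, 1, 1), connectivity = 26L) {
  assert_binary(mask, "mask")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  stopifnot(length(spacing) == 3, all(spacing > 0))
  m <- as_int_mask(mask)
  lab <- cpp_label_components(m, as.integer(connectivity))
  n <- max(lab)
  voxvol <- prod(spacing)
  if (n == 0) {
    summ <- tibble::tibble(id = integer(), voxels = integer(),
                           volume_mm3 = numeric(), cx_mm = numeric(),
                           cy_mm = numeric(), cz_mm = numeric(),
                           equivalent_diameter_mm = numeric())
  } else {
    idx <- which(lab > 0L)
    ids <- lab[idx]
    coords <- arrayInd(idx, dim(lab))
    voxels <- tabulate(ids, nbins = n)
    cen <- vapply(1:3, function(a)
      tapply((coords[, a] - 0.5) * spacing[a], ids, mean), numeric(n))
    cen <- matrix(cen, nrow = n)
    vol <- voxels * voxvol
    summ <- tibble::tibble(id = seq_len(n), voxels = voxels, volume_mm3 = vol,
                           cx_mm = cen[, 1], cy_mm = cen[, 2], cz_mm = cen[, 3],
                           equivalent_diameter_mm = equivalent_diameter(vol))
  }
  structure(list(labels = lab, summary = summ, spacing = spacing,
                 connectivity = as.integer(connectivity)),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d component(s), %d-connectivity\n",
              nrow(x$summary), x$connectivity))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' Match predicted lesions to ground-truth lesions
#'
#' Any-overlap matching: a ground-truth component counts as detected when
#' it overlaps the union of predicted components by at least
#' `min_overlap_voxels`; each predicted component is assigned to the
#' ground-truth component it overlaps most (ties to the lower ground-truth
#' id), and predicted components with no qualifying overlap are false
#' positives. True positives are counted on the ground-truth side for
#' sensitivity and on the prediction side for precision, which keeps
#' split and merge cases well defined.
#'
#' @param gt,pred `component_set`s on the same grid.
#' @param min_overlap_voxels minimal overlap to qualify as a match.
#' @return An object of class `match_result` with a `matches` tibble
#'   (gt_id, pred_id, overlap_voxels) and the id vectors `TP_gt`, `FN`,
#'   `TP_pred`, `FP`.
#' @export
match_lesions <- function(gt, pred, min_overlap_voxels = 1L) {
  stopifnot(inherits(gt, "component_set"), inherits(pred, "component_set"))
  assert_same_grid(gt$labels, pred$labels, "ground truth", "prediction")
  n_gt <- nrow(gt$summary); n_pred <- nrow(pred$summary)
  both <- gt$labels > 0L & pred$labels > 0L
  if (any(both)) {
    ov <- table(gt = gt$labels[both], pred = pred$labels[both])
    ovm <- matrix(0, n_gt, n_pred)
    ovm[cbind(as.integer(rownames(ov))[row(ov)], as.integer(colnames(ov))[col(ov)])] <- as.numeric(ov)
  } else {
    ovm <- matrix(0, n_gt, n_pred)
  }
  gt_total <- if (n_pred > 0) rowSums(ovm) else numeric(n_gt)
  TP_gt <- which(gt_total >= min_overlap_voxels)
  FN <- setdiff(seq_len(n_gt), TP_gt)
  matches <- tibble::tibble(gt_id = integer(), pred_id = integer(),
                            overlap_voxels = numeric())
  TP_pred <- integer(0); FP <- integer(0)
  for (p in seq_len(n_pred)) {
    if (n_gt > 0 && max(ovm[, p]) >= min_overlap_voxels) {
      gbest <- which.max(ovm[, p])  # ties resolve to the lower gt id
      TP_pred <- c(TP_pred, p)
      matches <- rbind(matches,
                       tibble::tibble(gt_id = as.integer(gbest), pred_id = p,
                                      overlap_voxels = ovm[gbest, p]))
    } else {
      FP <- c(FP, p)
    }
  }
  structure(list(matches = matches, TP_gt = as.integer(TP_gt),
                 FN = as.integer(FN), TP_pred = as.integer(TP_pred),
                 FP = as.integer(FP), n_gt = n_gt, n_pred = n_pred),
            class = "match_result")
}

#' Pooled lesion-level detection metrics
#'
#' Sensitivity `|TP_gt| / (|TP_gt| + |FN|)`, precision
#' `|TP_pred| / (|TP_pred| + |FP|)`, false positives per scan and missed
#' lesions per patient, pooled over scans and stratified by size class
#' (small: equivalent diameter <= 10 mm). Ground-truth components and the
#' true-positive predictions they absorb are classed by the ground-truth
#' component's own equivalent diameter; false positives by theirs.
#'
#' @param match_results list of `match_result`s, one per scan.
#' @param gt_sets,pred_sets matching lists of `component_set`s.
#' @param n_patients number of patients (defaults to the number of scans).
#' @return An object of class `detection_metrics`: a tibble with one row
#'   per class (`small`, `large`, `all`). With zero ground-truth lesions in
#'   a class its sensitivity is `NA`, not 0.
#' @export
detection_metrics <- function(match_results, gt_sets, pred_sets,
                              n_patients = length(match_results)) {
  stopifnot(length(match_results) >= 1,
            length(match_results) == length(gt_sets),
            length(match_results) == length(pred_sets))
  n_scans <- length(match_results)
  per_comp <- list()
  for (i in seq_along(match_results)) {
    mr <- match_results[[i]]
    gts <- gt_sets[[i]]$summary
    prs <- pred_sets[[i]]$summary
    if (nrow(gts)) {
      cls <- size_class(gts$equivalent_diameter_mm)
      per_comp[[length(per_comp) + 1]] <- tibble::tibble(
        kind = ifelse(gts$id %in% mr$TP_gt, "TP_gt", "FN"), class = cls)
    }
    if (nrow(prs)) {
      # class TPs by their matched ground-truth lesion, FPs by themselves
      cls_pred <- character(nrow(prs))
      for (p in prs$id) {
        if (p %in% mr$TP_pred) {
          gid <- mr$matches$gt_id[mr$matches$pred_id == p][1]
          cls_pred[p] <- size_class(gts$equivalent_diameter_mm[gts$id == gid])
        } else {
          cls_pred[p] <- size_class(prs$equivalent_diameter_mm[prs$id == p])
        }
      }
      per_comp[[length(per_comp) + 1]] <- tibble::tibble(
        kind = ifelse(prs$id %in% mr$TP_pred, "TP_pred", "FP"), class = cls_pred)
    }
  }
  comp <- if (length(per_comp)) do.call(rbind, per_comp)
          else tibble::tibble(kind = character(), class = character())
  one_class <- function(cls) {
    sub <- if (identical(cls, "all")) comp else comp[comp$class == cls, ]
    tp_g <- sum(sub$kind == "TP_gt"); fn <- sum(sub$kind == "FN")
    tp_p <- sum(sub$kind == "TP_pred"); fp <- sum(sub$kind == "FP")
    tibble::tibble(
      class = cls, n_gt = tp_g + fn, tp_gt = tp_g, fn = fn,
      tp_pred = tp_p, fp = fp,
      sensitivity = if (tp_g + fn > 0) tp_g / (tp_g + fn) else NA_real_,
      precision = if (tp_p + fp > 0) tp_p / (tp_p + fp) else NA_real_,
      fp_per_scan = fp / n_scans,
      missed_bm_per_patient = fn / n_patients)
  }
  structure(rbind(one_class("small"), one_class("large"), one_class("all")),
            class = c("detection_metrics", class(tibble::tibble())))
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty masks have DSC 1 by
#' convention (reported with a message).
#'
#' @param seg_a,seg_b binary grids on the same lattice.
#' @return DSC in \[0,1\].
#' @export
dsc <- function(seg_a, seg_b) {
  assert_same_grid(seg_a, seg_b, "first segmentation", "second segmentation")
  a <- seg_a != 0; b <- seg_b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    message("both segmentations empty; DSC = 1 by convention")
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

#' Per-lesion and global segmentation quality
#'
#' For every ground-truth lesion, the Dice coefficient between that lesion
#' and the union of predicted components assigned to it (0 for missed
#' lesions); mean DSC overall and per size class, plus the global
#' all-voxel DSC.
#'
#' @param match a [match_lesions()] result.
#' @param gt,pred the `component_set`s it was computed from.
#' @return An object of class `segmentation_metrics`: list with the
#'   `per_lesion` tibble, `mean_dsc`, `mean_dsc_small`, `mean_dsc_large`
#'   and `global_dsc`.
#' @export
segmentation_metrics <- function(match, gt, pred) {
  stopifnot(inherits(match, "match_result"))
  gts <- gt$summary
  rows <- lapply(seq_len(nrow(gts)), function(g) {
    gmask <- gt$labels == g
    pids <- match$matches$pred_id[match$matches$gt_id == g]
    pmask <- if (length(pids)) array(pred$labels %in% pids, dim(pred$labels))
             else array(FALSE, dim(pred$labels))
    d <- if (sum(gmask) + sum(pmask) == 0) 1 else 2 * sum(gmask & pmask) / (sum(gmask) + sum(pmask))
    tibble::tibble(gt_id = g, dsc = d,
                   size_class = size_class(gts$equivalent_diameter_mm[g]))
  })
  per <- if (length(rows)) do.call(rbind, rows)
         else tibble::tibble(gt_id = integer(), dsc = numeric(), size_class = character())
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  structure(list(per_lesion = per,
                 mean_dsc = mean_or_na(per$dsc),
                 mean_dsc_small = mean_or_na(per$dsc[per$size_class == "small"]),
                 mean_dsc_large = mean_or_na(per$dsc[per$size_class == "large"]),
                 global_dsc = dsc(gt$labels > 0L, pred$labels > 0L)),
            class = "segmentation_metrics")
}

#' Volumetric agreement between paired measurements
#'
#' Pearson product-moment correlation and Bland-Altman analysis
#' (differences `pred - gt`; limits of agreement at mean +/- 1.96 sample
#' standard deviations).
#'
#' @param gt_volumes,pred_volumes paired numeric vectors (same units,
#'   conventionally cm^3; missed lesions pair with 0 predicted volume,
#'   false positives are excluded).
#' @return An object of class `volume_agreement` with `pearson_r` (`NA`
#'   when either list has zero variance) and `bland_altman`
#'   (`mean_difference`, `sd_difference`, `loa_low`, `loa_high`).
#' @export
volume_agreement <- function(gt_volumes, pred_volumes) {
  stopifnot(length(gt_volumes) == length(pred_volumes))
  n <- length(gt_volumes)
  if (n < 3) stop("need at least 3 paired volumes")
  r <- if (sd(gt_volumes) == 0 || sd(pred_volumes) == 0) NA_real_
       else cor(gt_volumes, pred_volumes)
  d <- pred_volumes - gt_volumes
  m <- mean(d); s <- sd(d)
  structure(list(pearson_r = r, n = n,
                 bland_altman = list(mean_difference = m, sd_difference = s,
                                     loa_low = m - 1.96 * s,
                                     loa_high = m + 1.96 * s),
                 differences = d, means = (gt_volumes + pred_volumes) / 2),
            class = "volume_agreement")
}

#' @export
print.volume_agreement <- function(x, ...) {
  cat(sprintf("<volume_agreement> n=%d, Pearson r=%s, mean diff=%.4g [LoA %.4g, %.4g]\n",
              x$n, ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r)),
              x$bland_altman$mean_difference, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  invisible(x)
}
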