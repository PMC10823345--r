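#' Volumetric response-assessment configuration
#'
#' The progression threshold follows spherical geometry: a 20% diameter
#' increase of a perfect sphere corresponds to a `1.2^3 - 1 = 72.8%` volume
#' increase, so the volumetric progressive-disease rule fires at a relative
#' total-volume change of at least 0.728 (boundary inclusive), or at any
#' new lesion.
#'
#' @param pd_volume_increase_threshold fractional volume increase defining
#'   progression (default `0.728`).
#' @param new_lesion_min_voxels minimal size of an unmatched follow-up
#'   component to count as a new lesion (keeps single-voxel noise from
#'   forcing progression).
#' @param correspondence_max_centroid_distance_mm maximal centroid distance
#'   for linking non-overlapping lesions across timepoints.
#' @return An object of class `response_config`.
#' @export
response_config <- function(pd_volume_increase_threshold = 0.728,
                            new_lesion_min_voxels = 2L,
                            correspondence_max_centroid_distance_mm = 5) {
  stopifnot(pd_volume_increase_threshold > 0, new_lesion_min_voxels >= 1,
            correspondence_max_centroid_distance_mm > 0)
  structure(list(pd_volume_increase_threshold = pd_volume_increase_threshold,
                 new_lesion_min_voxels = as.integer(new_lesion_min_voxels),
                 correspondence_max_centroid_distance_mm =
                   correspondence_max_centroid_distance_mm),
            class = "response_config")
}

#' Fractional volume increase equivalent to a diameter increase
#'
#' For a sphere, a fractional diameter increase `delta` scales the volume
#' by `(1 + delta)^3`, i.e. a fractional volume increase of
#' `(1 + delta)^3 - 1`. `diameter_to_volume_ratio(0.20)` is `0.728`, the
#' volumetric progression threshold.
#'
#' @param delta fractional diameter increase, `> -1`.
#' @return Fractional volume increase.
#' @examples
#' diameter_to_volume_ratio(0.20)  # 0.728
#' @export
diameter_to_volume_ratio <- function(delta) {
  if (any(delta <= -1)) stop("delta must be greater than -1")
  (1 + delta)^3 - 1
}

#' Link lesions across two co-registered timepoints
#'
#' Greedy one-to-one linking by descending spatial overlap, then by
#' centroid distance (up to the configured maximum) for non-overlapping
#' pairs. Remaining baseline lesions are resolved; remaining follow-up
#' components of at least `new_lesion_min_voxels` are new lesions, smaller
#' ones are sub-threshold.
#'
#' @param baseline,followup `component_set`s on the same grid.
#' @param cfg a [response_config()].
#' @return An object of class `correspondence_map`.
#' @export
correspond_lesions <- function(baseline, followup, cfg = response_config()) {
  stopifnot(inherits(baseline, "component_set"), inherits(followup, "component_set"))
  assert_same_grid(baseline$labels, followup$labels, "baseline", "follow-up")
  nb <- nrow(baseline$summary); nf <- nrow(followup$summary)
  links <- tibble::tibble(baseline_id = integer(), followup_id = integer(),
                          overlap_voxels = numeric(), centroid_distance_mm = numeric())
  free_b <- seq_len(nb); free_f <- seq_len(nf)
  both <- baseline$labels > 0L & followup$labels > 0L
  if (any(both) && nb && nf) {
    ov <- table(b = baseline$labels[both], f = followup$labels[both])
    ovm <- matrix(0, nb, nf)
    ovm[cbind(as.integer(rownames(ov))[row(ov)], as.integer(colnames(ov))[col(ov)])] <- as.numeric(ov)
    while (length(free_b) && length(free_f)) {
      sub <- ovm[free_b, free_f, drop = FALSE]
      mx <- max(sub)
      if (mx <= 0) break
      pos <- which(sub == mx, arr.ind = TRUE)
      pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE][1, ]
      bi <- free_b[pos[1]]; fi <- free_f[pos[2]]
      dist <- centroid_distance(baseline$summary[bi, ], followup$summary[fi, ])
      links <- rbind(links, tibble::tibble(baseline_id = as.integer(bi),
                                           followup_id = as.integer(fi),
                                           overlap_voxels = mx,
                                           centroid_distance_mm = dist))
      free_b <- setdiff(free_b, bi); free_f <- setdiff(free_f, fi)
    }
  }
  # non-overlapping pairs: nearest centroids within the distance budget
  if (length(free_b) && length(free_f)) {
    bf0 <- free_b; ff0 <- free_f
    dmat <- outer(bf0, ff0, Vectorize(function(b, f)
      centroid_distance(baseline$summary[b, ], followup$summary[f, ])))
    while (length(free_b) && length(free_f)) {
      sub <- dmat[match(free_b, bf0), match(free_f, ff0), drop = FALSE]
      mn <- min(sub)
      if (mn > cfg$correspondence_max_centroid_distance_mm) break
      pos <- which(sub == mn, arr.ind = TRUE)[1, , drop = TRUE]
      bi <- free_b[pos[1]]; fi <- free_f[pos[2]]
      links <- rbind(links, tibble::tibble(baseline_id = as.integer(bi),
                                           followup_id = as.integer(fi),
                                           overlap_voxels = 0,
                                           centroid_distance_mm = mn))
      free_b <- setdiff(free_b, bi); free_f <- setdiff(free_f, fi)
    }
  }
  fsum <- followup$summary
  new_ids <- free_f[fsum$voxels[match(free_f, fsum$id)] >= cfg$new_lesion_min_voxels]
  sub_ids <- setdiff(free_f, new_ids)
  structure(list(links = links, resolved = as.integer(free_b),
                 new_lesions = as.integer(new_ids),
                 subthreshold = as.integer(sub_ids)),
            class = "correspondence_map")
}

centroid_distance <- function(row_a, row_b) {
  sqrt((row_a$cx_mm - row_b$cx_mm)^2 + (row_a$cy_mm - row_b$cy_mm)^2 +
       (row_a$cz_mm - row_b$cz_mm)^2)
}

#' Classify treatment response from a baseline/follow-up pair
#'
#' Volumetric modified RANO-BM rule over total solid enhancing volume
#' (necrosis is excluded by the ground-truth convention):
#' progressive disease (PD) when any new lesion appears or when the
#' relative total-volume change reaches the threshold (boundary
#' inclusive); complete response (CR) when the follow-up volume is exactly
#' zero with no new lesion; partial response / stable disease (PR_SD)
#' otherwise.
#'
#' @param baseline,followup `component_set`s of the two timepoints.
#' @param correspondence a [correspond_lesions()] map (computed if `NULL`).
#' @param cfg a [response_config()].
#' @return An object of class `response_result` with `category`
#'   (`"CR"`, `"PR_SD"` or `"PD"`), machine-readable `reasons`, the total
#'   volumes (mm^3) and the `relative_change`.
#' @export
classify_response <- function(baseline, followup, correspondence = NULL,
                              cfg = response_config()) {
  if (is.null(correspondence)) correspondence <- correspond_lesions(baseline, followup, cfg)
  v_base <- sum(baseline$summary$volume_mm3)
  v_follow <- sum(followup$summary$volume_mm3)
  if (v_base <= 0)
    stop("baseline total volume is zero: response is undefined; handle new-lesion-only follow-up separately")
  rel <- (v_follow - v_base) / v_base
  has_new <- length(correspondence$new_lesions) > 0
  reasons <- character(0)
  if (has_new) reasons <- c(reasons, "new_lesion")
  if (rel >= cfg$pd_volume_increase_threshold)
    reasons <- c(reasons, "volume_increase_ge_threshold")
  if (length(reasons)) {
    category <- "PD"
  } else if (v_follow == 0) {
    category <- "CR"; reasons <- "total_disappearance"
  } else {
    category <- "PR_SD"; reasons <- "neither"
  }
  structure(list(category = category, reasons = reasons,
                 baseline_volume_mm3 = v_base, followup_volume_mm3 = v_follow,
                 relative_change = rel,
                 n_new_lesions = length(correspondence$new_lesions)),
            class = "response_result")
}

#' @export
print.response_result <- function(x, ...) {
  cat(sprintf("<response_result> %s (%s); V %.1f -> %.1f mm^3 (%+.1f%%), %d new lesion(s)\n",
              x$category, paste(x$reasons, collapse = "+"),
              x$baseline_volume_mm3, x$followup_volume_mm3,
              100 * x$relative_change, x$n_new_lesions))
  invisible(x)
}

response_levels <- c("CR", "PR_SD", "PD")

#' Confusion matrix and percent agreement between two raters
#'
#' @param ratings_a,ratings_b equal-length vectors of categories among
#'   `CR`, `PR_SD`, `PD` (rater A in rows, rater B in columns).
#' @return List with the 3x3 `confusion` matrix, `percent_agreement`
#'   (0-100) and `n`.
#' @export
confusion_and_agreement <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must have equal length")
  if (length(ratings_a) < 1) stop("need at least one rating pair")
  bad <- setdiff(unique(c(ratings_a, ratings_b)), response_levels)
  if (length(bad))
    stop(sprintf("unknown categories: %s", paste(bad, collapse = ", ")))
  fa <- factor(ratings_a, levels = response_levels)
  fb <- factor(ratings_b, levels = response_levels)
  confusion <- table(rater_a = fa, rater_b = fb)
  n <- length(ratings_a)
  list(confusion = confusion,
       percent_agreement = 100 * sum(diag(confusion)) / n, n = n)
}

#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single rater
#'
#' Computed from the two-way ANOVA decomposition
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with the
#' F-based 95% confidence interval of McGraw and Wong.
#'
#' @param ratings numeric matrix, `n` subjects (rows) by `k` raters
#'   (columns), no missing cells.
#' @param conf_level confidence level for the interval.
#' @return List of class `icc_result`: `icc`, `icc_ci95`, mean squares and
#'   dimensions. With zero residual error the ICC is 1 with a degenerate
#'   interval (reported with a message); with no subject variability at
#'   all the ICC is undefined and returned as `NA`.
#' @export
icc_2_1 <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (anyNA(ratings)) stop("missing cells are not supported")
  gm <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  mse <- max(mse, 0)  # numerical floor
  out <- function(icc, lo, hi)
    structure(list(icc = icc, icc_ci95 = c(lo, hi), msr = msr, msc = msc,
                   mse = mse, n = n, k = k, conf_level = conf_level),
              class = "icc_result")
  if (msr < 1e-14 && mse < 1e-14 && msc < 1e-14)
    return(out(NA_real_, NA_real_, NA_real_))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (mse < 1e-14 && msc <= mse) {
    message("zero residual and rater variance: ICC = 1 with degenerate interval")
    return(out(1, 1, 1))
  }
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
       ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
           (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
           (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  out(icc, lower, upper)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.3f [%.3f, %.3f], n=%d subjects, k=%d raters\n",
              x$icc, x$icc_ci95[1], x$icc_ci95[2], x$n, x$k))
  invisible(x)
}

#' Full rater-agreement summary for response categories
#'
#' Combines the 3x3 confusion matrix, percent agreement and ICC(2,1) under
#' ordinal numeric coding CR = 1, PR_SD = 2, PD = 3.
#'
#' @inheritParams confusion_and_agreement
#' @return An object of class `agreement_stats`.
#' @export
agreement_stats <- function(ratings_a, ratings_b) {
  ca <- confusion_and_agreement(ratings_a, ratings_b)
  coding <- c(CR = 1, PR_SD = 2, PD = 3)
  icc <- tryCatch(icc_2_1(cbind(coding[ratings_a], coding[ratings_b])),
                  error = function(e) NULL)
  structure(list(confusion = ca$confusion,
                 percent_agreement = ca$percent_agreement, n = ca$n,
                 icc = if (is.null(icc)) NA_real_ else icc$icc,
                 icc_ci95 = if (is.null(icc)) c(NA_real_, NA_real_) else icc$icc_ci95),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> %.1f%% agreement over %d pairs; ICC(2,1) = %s\n",
              x$percent_agreement, x$n,
              ifelse(is.na(x$icc), "NA",
                     sprintf("%.3f [%.3f, %.3f]", x$icc, x$icc_ci95[1], x$icc_ci95[2]))))
  print(x$confusion)
  invisible(x)
}
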