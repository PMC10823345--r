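#' Stratified patient-level K-fold split balancing lesion-size strata
#'
#' Patients are shuffled (seeded), sorted by descending (large-lesion
#' count, small-lesion count) and greedily assigned, each to the fold that
#' minimizes the deviation of the per-fold small-lesion proportion from the
#' global proportion while keeping fold sizes balanced. Deterministic for a
#' fixed seed; every patient lands in exactly one fold.
#'
#' @param patients data frame with columns `patient_id`, `n_small`,
#'   `n_large` (per-patient lesion counts by size class).
#' @param k number of folds.
#' @param seed integer seed for the tie-breaking shuffle.
#' @return An object of class `fold_spec`: `assignments` tibble
#'   (patient_id, fold), per-fold `summary` tibble, `k`, `seed`.
#' @export
stratified_kfold <- function(patients, k = 5L, seed = 1L) {
  patients <- as.data.frame(patients)
  stopifnot(all(c("patient_id", "n_small", "n_large") %in% names(patients)))
  n <- nrow(patients)
  if (n < k) stop(sprintf("fewer patients (%d) than folds (%d)", n, k))
  ord <- withr::with_seed(as.integer(seed), sample.int(n))
  pts <- patients[ord, ]
  pts <- pts[order(-pts$n_large, -pts$n_small), ]
  tot_small <- sum(pts$n_small); tot_large <- sum(pts$n_large)
  global_prop <- if (tot_small + tot_large > 0) tot_small / (tot_small + tot_large) else 0.5
  fold_small <- numeric(k); fold_large <- numeric(k); fold_n <- integer(k)
  assign <- integer(n)
  target_small <- tot_small / k; target_large <- tot_large / k
  for (i in seq_len(n)) {
    # patient counts stay balanced (differ by at most one); among the
    # least-filled folds, pick the one whose stratum totals move closest to
    # their fair per-fold share
    cand0 <- which(fold_n == min(fold_n))
    score <- vapply(cand0, function(f) {
      abs(fold_small[f] + pts$n_small[i] - target_small) +
        abs(fold_large[f] + pts$n_large[i] - target_large)
    }, numeric(1))
    cand <- cand0[score == min(score)]
    f <- cand[1]
    assign[i] <- f
    fold_small[f] <- fold_small[f] + pts$n_small[i]
    fold_large[f] <- fold_large[f] + pts$n_large[i]
    fold_n[f] <- fold_n[f] + 1L
  }
  # deterministic swap refinement: exchange patients between folds while it
  # reduces the total deviation of fold proportions from the global one
  dev_total <- function(fs, fl) {
    prop <- ifelse(fs + fl > 0, fs / (fs + fl), global_prop)
    sum(abs(prop - global_prop))
  }
  for (pass in seq_len(50)) {
    improved <- FALSE
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        fa <- assign[a]; fb <- assign[b]
        if (fa >= fb) next
        ds <- pts$n_small[a] - pts$n_small[b]
        dl <- pts$n_large[a] - pts$n_large[b]
        if (ds == 0 && dl == 0) next
        fs2 <- fold_small; fl2 <- fold_large
        fs2[fa] <- fs2[fa] - ds; fs2[fb] <- fs2[fb] + ds
        fl2[fa] <- fl2[fa] - dl; fl2[fb] <- fl2[fb] + dl
        if (dev_total(fs2, fl2) < dev_total(fold_small, fold_large) - 1e-12) {
          assign[c(a, b)] <- c(fb, fa)
          fold_small <- fs2; fold_large <- fl2
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  assignments <- tibble::tibble(patient_id = pts$patient_id, fold = assign)
  assignments <- assignments[order(match(assignments$patient_id, patients$patient_id)), ]
  summary <- tibble::tibble(fold = seq_len(k), n_patients = fold_n,
                            n_small = fold_small, n_large = fold_large,
                            small_prop = ifelse(fold_small + fold_large > 0,
                                                fold_small / (fold_small + fold_large),
                                                NA_real_))
  structure(list(assignments = assignments, summary = summary, k = as.integer(k),
                 seed = as.integer(seed), global_small_prop = global_prop),
            class = "fold_spec")
}

#' @export
print.fold_spec <- function(x, ...) {
  cat(sprintf("<fold_spec> %d folds over %d patients (global small proportion %.2f)\n",
              x$k, nrow(x$assignments), x$global_small_prop))
  print(x$summary)
  invisible(x)
}

#' Assemble a reproducible pipeline run configuration
#'
#' Bundles every stage's configuration plus one run seed from which all
#' stage sub-seeds are derived deterministically, so a saved `run_config`
#' replays to an identical report.
#'
#' @param n_patients number of synthetic patients.
#' @param phantom a [phantom_spec()] template (per-patient seeds are
#'   derived from the run seed).
#' @param network a [network_config()].
#' @param k folds for the patient-level split.
#' @param train_steps optimizer steps per fold.
#' @param lr Adam learning rate.
#' @param validation_fraction fraction of training patients held out for
#'   validation monitoring.
#' @param shell_thickness_mm surface-shell thickness for postprocessing.
#' @param binarization a [binarization_config()].
#' @param response a [response_config()].
#' @param oracle_mode skip training and use the ground truth as the
#'   prediction (end-to-end plumbing check).
#' @param response_stage also simulate one follow-up per test patient
#'   (seeded growth / disappearance / new-lesion scenarios), classify the
#'   response from the ground-truth pair and from the predicted pair, and
#'   report their agreement.
#' @param seed run seed.
#' @param out_dir optional directory for the JSON report and logs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_patients = 10L,
                       phantom = phantom_spec(),
                       network = network_config(n_levels = 2, base_channels = 8,
                                                large_kernel_edge = 7,
                                                parallel_kernel_edge = 3),
                       k = 5L, train_steps = 100L, lr = 1e-3,
                       validation_fraction = 0.10,
                       shell_thickness_mm = 2,
                       binarization = binarization_config(),
                       response = response_config(),
                       oracle_mode = FALSE, response_stage = FALSE,
                       seed = 1L, out_dir = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(network, "network_config"),
            n_patients >= k, validation_fraction >= 0, validation_fraction < 1)
  structure(list(n_patients = as.integer(n_patients), phantom = phantom,
                 network = network, k = as.integer(k),
                 train_steps = as.integer(train_steps), lr = lr,
                 validation_fraction = validation_fraction,
                 shell_thickness_mm = shell_thickness_mm,
                 binarization = binarization, response = response,
                 oracle_mode = isTRUE(oracle_mode),
                 response_stage = isTRUE(response_stage),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

phantom_for_patient <- function(config, i) {
  sp <- config$phantom
  sp$seed <- derive_seed(config$seed, i)
  generate_phantom(sp)
}

#' Train a network for one run configuration
#'
#' Builds the network from the run seed, holds out
#' `validation_fraction` of the training patients (patient level) for
#' monitoring, and runs [train_network()]. With `steps = 0` the returned
#' parameters equal the seeded initialization.
#'
#' @param phantoms list of `phantom_volume`s to train on.
#' @param config a [run_config()].
#' @return List with the trained `net`, the training `log`, and the indices
#'   of the validation patients.
#' @export
run_training <- function(phantoms, config) {
  stopifnot(inherits(config, "run_config"), length(phantoms) >= 1)
  n <- length(phantoms)
  n_val <- floor(config$validation_fraction * n)
  val_idx <- if (n_val > 0)
    withr::with_seed(derive_seed(config$seed, 7717L), sample.int(n, n_val))
  else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  vols <- lapply(phantoms[tr_idx], `[[`, "intensity")
  gts <- lapply(phantoms[tr_idx], `[[`, "gt_mask")
  validation <- if (length(val_idx))
    list(volumes = lapply(phantoms[val_idx], `[[`, "intensity"),
         gt_masks = lapply(phantoms[val_idx], `[[`, "gt_mask"))
  else NULL
  net <- build_network(config$network, seed = derive_seed(config$seed, 31L))
  fit <- train_network(net, vols, gts, steps = config$train_steps, lr = config$lr,
                       validation = validation)
  list(net = fit$net, log = fit$log, validation_patients = val_idx)
}

predict_and_postprocess <- function(net, phantom, config) {
  prob <- predict_volume(net, phantom$intensity)
  shell <- make_surface_shell(phantom$brain_mask, config$shell_thickness_mm,
                              phantom$spacing)
  masks <- suppression_masks(shell, phantom$choroid_mask,
                             vessel_mask = phantom$vessel_mask,
                             shell_thickness_mm = config$shell_thickness_mm)
  suppress(prob, masks, config$binarization)
}

#' Run the full phantom-to-metrics pipeline
#'
#' Generates a synthetic cohort, splits it into stratified patient-level
#' folds, trains one network per fold on the training folds, predicts the
#' held-out fold, postprocesses with each phantom's true brain and choroid
#' masks, and pools lesion-level detection and segmentation metrics across
#' folds. In `oracle_mode` the ground truth stands in for the prediction,
#' which exercises every stage downstream of the network.
#'
#' @param config a [run_config()].
#' @return A report list (also written as JSON when `out_dir` is set):
#'   per-fold and pooled metric blocks, fold assignments and the effective
#'   configuration. Replaying the same config gives a byte-identical JSON
#'   report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  phantoms <- lapply(seq_len(config$n_patients), function(i)
    phantom_for_patient(config, i))
  cat_df <- tibble::tibble(
    patient_id = seq_len(config$n_patients),
    n_small = vapply(phantoms, function(p) sum(p$catalog$size_class == "small"), numeric(1)),
    n_large = vapply(phantoms, function(p) sum(p$catalog$size_class == "large"), numeric(1)))
  folds <- stratified_kfold(cat_df, k = config$k, seed = derive_seed(config$seed, 101L))
  fold_blocks <- list()
  all_matches <- list(); all_gt <- list(); all_pred <- list()
  response_ratings <- list()
  for (f in seq_len(config$k)) {
    test_idx <- folds$assignments$patient_id[folds$assignments$fold == f]
    train_idx <- setdiff(seq_len(config$n_patients), test_idx)
    net <- NULL
    if (!config$oracle_mode) {
      fit <- run_training(phantoms[train_idx], config)
      net <- fit$net
    }
    mrs <- list(); gts <- list(); prs <- list()
    for (j in seq_along(test_idx)) {
      ph <- phantoms[[test_idx[j]]]
      pred_mask <- if (config$oracle_mode) ph$gt_mask
                   else predict_and_postprocess(net, ph, config)
      gt_cs <- label_components(ph$gt_mask, ph$spacing)
      pred_cs <- label_components(pred_mask, ph$spacing)
      mrs[[j]] <- match_lesions(gt_cs, pred_cs)
      gts[[j]] <- gt_cs; prs[[j]] <- pred_cs
      if (config$response_stage) {
        pid <- test_idx[j]
        fu <- simulate_scenario_followup(ph, derive_seed(config$seed, 500L + pid))
        fu_pred <- if (config$oracle_mode) fu$gt_mask
                   else predict_and_postprocess(net, fu, config)
        fu_gt_cs <- label_components(fu$gt_mask, ph$spacing)
        fu_pr_cs <- label_components(fu_pred, ph$spacing)
        rating_gt <- tryCatch(
          classify_response(gt_cs, fu_gt_cs, cfg = config$response)$category,
          error = function(e) NA_character_)
        rating_pred <- tryCatch(
          classify_response(pred_cs, fu_pr_cs, cfg = config$response)$category,
          error = function(e) NA_character_)
        response_ratings[[length(response_ratings) + 1]] <-
          tibble::tibble(patient_id = pid, rating_gt = rating_gt,
                         rating_pred = rating_pred)
      }
    }
    dm <- detection_metrics(mrs, gts, prs)
    seg <- mapply(segmentation_metrics, mrs, gts, prs, SIMPLIFY = FALSE)
    fold_blocks[[f]] <- list(
      fold = f, test_patients = test_idx,
      detection = as.data.frame(dm),
      mean_dsc = mean(vapply(seg, `[[`, numeric(1), "mean_dsc"), na.rm = TRUE))
    all_matches <- c(all_matches, mrs); all_gt <- c(all_gt, gts); all_pred <- c(all_pred, prs)
  }
  pooled <- detection_metrics(all_matches, all_gt, all_pred,
                              n_patients = config$n_patients)
  seg_all <- mapply(segmentation_metrics, all_matches, all_gt, all_pred,
                    SIMPLIFY = FALSE)
  per_lesion <- do.call(rbind, lapply(seg_all, `[[`, "per_lesion"))
  report <- list(
    config = serializable_config(config),
    folds = fold_blocks,
    pooled = list(detection = as.data.frame(pooled),
                  mean_dsc = mean(per_lesion$dsc),
                  mean_dsc_small = mean(per_lesion$dsc[per_lesion$size_class == "small"]),
                  mean_dsc_large = mean(per_lesion$dsc[per_lesion$size_class == "large"]),
                  n_lesions = nrow(per_lesion)))
  if (config$response_stage && length(response_ratings)) {
    rr <- do.call(rbind, response_ratings)
    ok <- !is.na(rr$rating_gt) & !is.na(rr$rating_pred)
    ag <- if (any(ok)) agreement_stats(rr$rating_gt[ok], rr$rating_pred[ok]) else NULL
    report$response <- list(
      ratings = as.data.frame(rr),
      percent_agreement = if (is.null(ag)) NA else ag$percent_agreement,
      icc = if (is.null(ag)) NA else ag$icc,
      confusion = if (is.null(ag)) NULL
                  else as.data.frame.matrix(unclass(ag$confusion)))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

serializable_config <- function(config) {
  out <- unclass(config)
  out$out_dir <- NULL  # run content, not run location

  out$phantom <- unclass(out$phantom)
  out$phantom$choroid_region$centre_vox <- as.numeric(out$phantom$choroid_region$centre_vox)
  out$network <- unclass(out$network)
  out$binarization <- unclass(out$binarization)
  out$response <- unclass(out$response)
  out
}

# one seeded follow-up scenario per patient: progression by growth,
# progression by a new lesion, stability, shrinkage, or complete response
simulate_scenario_followup <- function(phantom, seed) {
  n <- length(phantom$geometry)
  scenario <- withr::with_seed(seed, sample(c("pd_growth", "pd_new", "stable",
                                              "partial", "cr"), 1))
  switch(scenario,
    pd_growth = simulate_followup(phantom, rep(1.3, n), seed = seed),
    pd_new = tryCatch(
      simulate_followup(phantom, rep(1, n), add_lesion_mm = 5, seed = seed),
      error = function(e) simulate_followup(phantom, rep(1.3, n), seed = seed)),
    stable = simulate_followup(phantom, rep(1, n), seed = seed),
    partial = simulate_followup(phantom, rep(0.7, n), seed = seed),
    cr = simulate_followup(phantom, rep(0, n), seed = seed))
}

#' Simulate a follow-up phantom from a baseline
#'
#' Redraws each baseline lesion at the same centre with its radii scaled by
#' a per-lesion growth factor (0 removes the lesion), optionally adds a new
#' lesion, and regenerates vessels, noise and intensities with a fresh
#' seed. The two phantoms share the brain/choroid geometry and grid, i.e.
#' they behave as co-registered timepoints.
#'
#' @param baseline a `phantom_volume` from [generate_phantom()] (with
#'   geometry metadata).
#' @param growth_factors numeric vector, one factor per baseline lesion.
#' @param add_lesion_mm diameter of one new lesion to add (NULL for none).
#' @param seed seed for noise and new-lesion placement.
#' @return A `phantom_volume` of the follow-up timepoint.
#' @export
simulate_followup <- function(baseline, growth_factors, add_lesion_mm = NULL,
                              seed = 1L) {
  stopifnot(inherits(baseline, "phantom_volume"),
            !is.null(baseline$geometry),
            length(growth_factors) == length(baseline$geometry))
  withr::with_seed(as.integer(seed), {
    gs <- dim(baseline$intensity)
    sp <- baseline$spacing
    labels <- array(0L, gs)
    necrosis <- array(0L, gs)
    has_nec <- logical(0)
    geom <- list()
    nid <- 0L
    for (i in seq_along(baseline$geometry)) {
      g <- baseline$geometry[[i]]
      f <- growth_factors[i]
      if (f <= 0) next
      semi_vox <- pmax(g$semi_axes_mm * f / sp, 0.6)
      les <- ellipsoid_mask(gs, g$centre_vox, semi_vox)
      les <- les * baseline$brain_mask
      if (sum(les) == 0) next
      nid <- nid + 1L
      labels[les == 1L] <- nid
      nec_i <- FALSE
      if (isTRUE(g$necrotic)) {
        core <- ellipsoid_mask(gs, g$centre_vox, pmax(semi_vox * g$core_fraction, 0.5))
        core <- core * les
        if (sum(les) - sum(core) >= 1L) {
          necrosis[core == 1L] <- 1L
          nec_i <- TRUE
        }
      }
      has_nec <- c(has_nec, nec_i)
      geom[[nid]] <- list(centre_vox = g$centre_vox, semi_axes_mm = g$semi_axes_mm * f,
                          diameter_mm = g$diameter_mm * f, necrotic = nec_i,
                          core_fraction = g$core_fraction)
    }
    if (!is.null(add_lesion_mm)) {
      margin_vox <- pmax(1L, as.integer(ceiling(baseline$spec$placement_margin_mm / sp)))
      interior <- cpp_erode_box(baseline$brain_mask, margin_vox)
      occupied <- cpp_dilate_box(array(as.integer(labels > 0L | baseline$choroid_mask == 1L), gs),
                                 c(2L, 2L, 2L))
      free_idx <- which(interior == 1L & occupied == 0L)
      placed <- FALSE
      for (attempt in seq_len(200)) {
        cvox <- arrayInd(free_idx[sample.int(length(free_idx), 1)], gs)[1, ]
        les <- ellipsoid_mask(gs, cvox, pmax(add_lesion_mm / 2 / sp, 0.6))
        if (sum(les) == 0 || any(les == 1L & interior == 0L)) next
        if (any(cpp_dilate_box(les, c(2L, 2L, 2L)) == 1L & occupied == 1L)) next
        nid <- nid + 1L
        labels[les == 1L] <- nid
        has_nec <- c(has_nec, FALSE)
        geom[[nid]] <- list(centre_vox = cvox, semi_axes_mm = rep(add_lesion_mm / 2, 3),
                            diameter_mm = add_lesion_mm, necrotic = FALSE,
                            core_fraction = baseline$spec$necrosis_core_fraction)
        placed <- TRUE
        break
      }
      if (!placed) stop("failed to place the new follow-up lesion")
    }
    gt <- array(as.integer(labels > 0L & necrosis == 0L), gs)
    lv <- baseline$spec$intensity_levels
    intensity <- array(lv$background, gs)
    intensity[baseline$brain_mask == 1L] <- lv$brain
    intensity[baseline$choroid_mask == 1L] <- lv$choroid
    intensity[baseline$vessel_mask == 1L] <- lv$vessel
    intensity[labels > 0L] <- lv$lesion_rim
    intensity[necrosis == 1L] <- lv$necrotic_core
    if (baseline$spec$noise_sigma > 0)
      intensity <- intensity + array(rnorm(prod(gs), 0, baseline$spec$noise_sigma), gs)
    catalog <- phantom_catalog(labels, gt, necrosis, has_nec, sp)
    structure(list(intensity = intensity, brain_mask = baseline$brain_mask,
                   gt_mask = gt, necrosis_mask = necrosis,
                   vessel_mask = baseline$vessel_mask,
                   choroid_mask = baseline$choroid_mask, lesion_labels = labels,
                   catalog = catalog, geometry = geom, spacing = sp,
                   spec = baseline$spec),
              class = "phantom_volume")
  })
}
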