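test_that("component labelling matches a breadth-first flood-fill oracle", {
  m <- array(0L, c(14, 8, 8))
  m[2:4, 2:4, 2:4] <- 1L
  m[8:10, 2:4, 2:4] <- 1L
  cs <- label_components(m, c(1, 1, 1))
  expect_equal(nrow(cs$summary), 2)
  expect_equal(cs$summary$voxels, c(27L, 27L))
  # two voxels touching only at a corner: one 26-component, two 6-components
  corner <- array(0L, c(4, 4, 4))
  corner[1, 1, 1] <- 1L; corner[2, 2, 2] <- 1L
  expect_equal(nrow(label_components(corner)$summary), 1)
  expect_equal(nrow(label_components(corner, connectivity = 6)$summary), 2)
  expect_equal(max(bfs_label(corner, 26)), 1)
  expect_equal(max(bfs_label(corner, 6)), 2)
  # empty mask, non-binary input
  expect_equal(nrow(label_components(array(0L, c(3, 3, 3)))$summary), 0)
  expect_error(label_components(array(2L, c(3, 3, 3))), "binary")
  # random masks against the oracle (component count and voxel partition)
  withr::with_seed(9, {
    for (trial in 1:20) {
      r <- array(as.integer(runif(10^3) < 0.25), c(10, 10, 10))
      for (conn in c(6L, 26L)) {
        lab <- label_components(r, connectivity = conn)
        oracle <- bfs_label(r, conn)
        expect_equal(nrow(lab$summary), max(oracle))
        # same partition up to relabelling
        expect_equal(length(unique(paste(lab$labels, oracle))) - 1,
                     max(oracle))
      }
    }
  })
})

test_that("equivalent diameter inverts the sphere volume formula", {
  expect_equal(equivalent_diameter(523.6), 10, tolerance = 1e-4)
  expect_equal(equivalent_diameter(4.18879), 2, tolerance = 1e-4)
  v <- 77.7
  expect_equal(equivalent_diameter(8 * v), 2 * equivalent_diameter(v))
  expect_error(equivalent_diameter(0), "positive")
  expect_equal(size_class(c(10, 10.1, 7.3)), c("small", "large", "small"))
  expect_error(size_class(-1), "positive")
})

test_that("lesion matching handles identity, misses and split predictions", {
  d <- c(20, 10, 6)
  gt <- array(0L, d)
  gt[2:4, 2:4, 2:4] <- 1L     # GT 1
  gt[10:12, 2:4, 2:4] <- 1L   # GT 2
  gt_cs <- label_components(gt)
  # exact prediction
  m <- match_lesions(gt_cs, gt_cs)
  expect_equal(m$TP_gt, c(1L, 2L))
  expect_length(m$FP, 0)
  # empty prediction
  m0 <- match_lesions(gt_cs, label_components(array(0L, d)))
  expect_equal(m0$FN, c(1L, 2L))
  expect_length(m0$TP_pred, 0)
  # one 9-voxel overlap with GT1 plus two spurious blobs
  pred <- array(0L, d)
  pred[2:4, 2:4, 2] <- 1L        # 9 voxels on GT 1
  pred[16:17, 2:3, 2:3] <- 1L    # spurious
  pred[16:17, 7:8, 2:3] <- 1L    # spurious
  pr_cs <- label_components(pred)
  m1 <- match_lesions(gt_cs, pr_cs)
  expect_length(m1$TP_gt, 1); expect_length(m1$FN, 1); expect_length(m1$FP, 2)
  expect_equal(m1$matches$overlap_voxels, 9)
  dm <- detection_metrics(list(m1), list(gt_cs), list(pr_cs))
  expect_equal(dm$sensitivity[dm$class == "all"], 0.5)
  expect_equal(dm$precision[dm$class == "all"], 1 / 3)
})

test_that("pooled detection metrics follow the counting formulas", {
  # 10 ground-truth blobs along x, 7 detected, 2 spurious predictions
  d <- c(62, 18, 6)
  gt <- array(0L, d); pred <- array(0L, d)
  for (i in 0:9) gt[(6 * i + 1):(6 * i + 2), 2:3, 2:3] <- 1L
  for (i in 0:6) pred[(6 * i + 1):(6 * i + 2), 2:3, 2:3] <- 1L
  pred[2:3, 10:11, 2:3] <- 1L
  pred[40:41, 14:15, 2:3] <- 1L
  gt_cs <- label_components(gt); pr_cs <- label_components(pred)
  m <- match_lesions(gt_cs, pr_cs)
  dm <- detection_metrics(list(m), list(gt_cs), list(pr_cs))
  all_row <- dm[dm$class == "all", ]
  expect_equal(all_row$sensitivity, 0.7)
  expect_equal(all_row$precision, 7 / 9)
  expect_equal(all_row$fp_per_scan, 2)
  expect_equal(all_row$missed_bm_per_patient, 3)
  # perfect prediction on every scan
  dm_perf <- detection_metrics(list(match_lesions(gt_cs, gt_cs)),
                               list(gt_cs), list(gt_cs))
  expect_equal(dm_perf$sensitivity[dm_perf$class == "all"], 1)
  expect_equal(dm_perf$fp_per_scan[dm_perf$class == "all"], 0)
  # fp averaging across scans: 3 and 1 give 2.0
  dm2 <- detection_metrics(list(m, m), list(gt_cs, gt_cs), list(pr_cs, pr_cs))
  expect_equal(dm2$fp_per_scan[dm2$class == "all"], 2)
  # zero ground truth: sensitivity is missing, not zero
  empty_cs <- label_components(array(0L, d))
  m_none <- match_lesions(empty_cs, pr_cs)
  dm0 <- detection_metrics(list(m_none), list(empty_cs), list(pr_cs))
  expect_true(is.na(dm0$sensitivity[dm0$class == "all"]))
})

test_that("match bookkeeping is conserved on random masks (oracle fuzz)", {
  withr::with_seed(31, {
    for (trial in 1:100) {
      d <- c(10, 10, 10)
      gt <- array(as.integer(runif(1000) < 0.12), d)
      pred <- array(as.integer(runif(1000) < 0.12), d)
      gt_cs <- label_components(gt); pr_cs <- label_components(pred)
      m <- match_lesions(gt_cs, pr_cs)
      expect_equal(length(m$TP_gt) + length(m$FN), nrow(gt_cs$summary))
      expect_equal(length(m$TP_pred) + length(m$FP), nrow(pr_cs$summary))
      if (nrow(m$matches)) expect_true(all(m$matches$overlap_voxels >= 1))
      # oracle: explicit overlap matrix from the two labelled grids
      if (nrow(gt_cs$summary) && nrow(pr_cs$summary)) {
        ovm <- matrix(0, nrow(gt_cs$summary), nrow(pr_cs$summary))
        for (g in seq_len(nrow(ovm))) for (p in seq_len(ncol(ovm)))
          ovm[g, p] <- sum(gt_cs$labels == g & pr_cs$labels == p)
        expect_equal(sort(m$TP_gt), which(rowSums(ovm) >= 1))
        expect_equal(sort(m$FP), which(colSums(ovm) == 0))
      }
      # pooled sensitivity lies between the class sensitivities
      dm <- detection_metrics(list(m), list(gt_cs), list(pr_cs))
      s <- dm$sensitivity
      if (!anyNA(s)) {
        expect_gte(s[3] + 1e-12, min(s[1], s[2]))
        expect_lte(s[3] - 1e-12, max(s[1], s[2]))
      }
    }
  })
})

test_that("Dice takes its closed-form values and is symmetric", {
  a <- array(0L, c(6, 6, 6)); a[1:3, , ] <- 1L
  expect_equal(dsc(a, a), 1)
  b <- array(0L, c(6, 6, 6)); b[4:6, , ] <- 1L
  expect_equal(dsc(a, b), 0)
  # |A| = 100, |B| = 150, overlap 75 -> 0.6
  a2 <- array(0L, c(30, 30, 1)); a2[1:4, 1:25, 1] <- 1L
  b2 <- array(0L, c(30, 30, 1)); b2[2:7, 1:25, 1] <- 1L
  expect_equal(sum(a2), 100); expect_equal(sum(b2), 150)
  expect_equal(sum(a2 & b2), 75)
  expect_equal(dsc(a2, b2), 0.6)
  expect_equal(dsc(b2, a2), dsc(a2, b2))
  expect_message(z <- dsc(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))), "convention")
  expect_equal(z, 1)
  expect_error(dsc(a, array(0L, c(5, 5, 5))), "grid")
})

test_that("per-lesion segmentation metrics score misses as zero", {
  d <- c(20, 10, 6)
  gt <- array(0L, d); gt[2:4, 2:4, 2:4] <- 1L; gt[10:12, 2:4, 2:4] <- 1L
  pred <- array(0L, d); pred[2:4, 2:4, 2:4] <- 1L
  gt_cs <- label_components(gt); pr_cs <- label_components(pred)
  sm <- segmentation_metrics(match_lesions(gt_cs, pr_cs), gt_cs, pr_cs)
  expect_equal(sort(sm$per_lesion$dsc), c(0, 1))
  expect_equal(sm$mean_dsc, 0.5)
  expect_equal(sm$global_dsc, 2 * 27 / (54 + 27))
})

test_that("volume agreement reproduces hand-computed Bland-Altman limits", {
  va <- volume_agreement(c(1, 2, 3), c(2, 4, 6))
  expect_equal(va$pearson_r, 1)
  va2 <- volume_agreement(c(10, 20, 30), c(12, 18, 30))
  expect_equal(va2$bland_altman$mean_difference, 0)
  expect_equal(va2$bland_altman$sd_difference, 2)
  expect_equal(va2$bland_altman$loa_low, -3.92)
  expect_equal(va2$bland_altman$loa_high, 3.92)
  va3 <- volume_agreement(c(5, 7, 9, 11), c(5, 7, 9, 11))
  expect_equal(va3$bland_altman$loa_low, 0)
  expect_equal(va3$bland_altman$loa_high, 0)
  expect_true(is.na(volume_agreement(c(1, 1, 1), c(1, 2, 3))$pearson_r))
  expect_error(volume_agreement(c(1, 2), c(1, 2)), "at least 3")
})
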