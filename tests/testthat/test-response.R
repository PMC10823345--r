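test_that("diameter-volume conversion follows spherical geometry", {
  expect_equal(diameter_to_volume_ratio(0.20), 0.728, tolerance = 1e-12)
  expect_equal(diameter_to_volume_ratio(0), 0)
  expect_equal(diameter_to_volume_ratio(1), 7)
  expect_error(diameter_to_volume_ratio(-1), "greater than -1")
  # inverse recovers the diameter change
  for (delta in c(-0.5, -0.1, 0, 0.2, 0.7, 2)) {
    ratio <- diameter_to_volume_ratio(delta)
    expect_equal((1 + ratio)^(1 / 3) - 1, delta, tolerance = 1e-12)
  }
})

test_that("lesion correspondence links, resolves and flags new lesions", {
  d <- c(30, 30, 10)
  base <- array(0L, d)
  base[2:5, 2:5, 2:5] <- 1L
  base[20:23, 2:5, 2:5] <- 1L
  base_cs <- label_components(base)
  # identical sets: all linked, nothing new
  cm <- correspond_lesions(base_cs, base_cs)
  expect_equal(nrow(cm$links), 2)
  expect_length(cm$new_lesions, 0)
  expect_length(cm$resolved, 0)
  # follow-up adds a far blob and loses one baseline lesion
  fu <- array(0L, d)
  fu[2:5, 2:5, 2:5] <- 1L
  fu[20:23, 20:23, 2:5] <- 1L   # far from both baseline lesions
  fu_cs <- label_components(fu)
  cm2 <- correspond_lesions(base_cs, fu_cs)
  expect_equal(nrow(cm2$links), 1)
  expect_length(cm2$new_lesions, 1)
  expect_length(cm2$resolved, 1)
  # a single-voxel leftover is sub-threshold, not a new lesion
  fu3 <- array(0L, d)
  fu3[2:5, 2:5, 2:5] <- 1L
  fu3[25, 25, 8] <- 1L
  cm3 <- correspond_lesions(base_cs, label_components(fu3))
  expect_length(cm3$new_lesions, 0)
  expect_length(cm3$subthreshold, 1)
  # nearby non-overlapping components link by centroid distance
  fu4 <- array(0L, d)
  fu4[7:9, 2:5, 2:5] <- 1L     # shifted off lesion 1, centroid ~4.5 mm away
  fu4[20:23, 2:5, 2:5] <- 1L
  cm4 <- correspond_lesions(base_cs, label_components(fu4))
  expect_equal(nrow(cm4$links), 2)
  expect_error(correspond_lesions(base_cs, label_components(array(0L, c(4, 4, 4)))),
               "grid")
})

test_that("the response rule matches an independent enumeration on the full grid", {
  # masks built with exact voxel counts so relative changes hit the
  # boundary exactly; oracle is a literal restatement of the rule
  oracle <- function(rel, has_new, v_follow_zero) {
    if (has_new || rel >= 0.728) "PD"
    else if (v_follow_zero) "CR"
    else "PR_SD"
  }
  gs <- c(40L, 40L, 20L)
  base <- prefix_blob(gs, c(2L, 2L, 2L), c(12L, 12L, 12L), 1000L)
  base_cs <- label_components(base)
  cfg <- response_config()
  for (rel in c(-1, -0.5, 0, 0.727, 0.728, 0.729, 2)) {
    for (has_new in c(FALSE, TRUE)) {
      n_follow <- as.integer(round((1 + rel) * 1000))
      fu <- prefix_blob(gs, c(2L, 2L, 2L), c(15L, 15L, 15L), n_follow)
      if (has_new) fu[37:38, 37:38, 16:17] <- 1L
      fu_cs <- label_components(fu)
      res <- classify_response(base_cs, fu_cs, cfg = cfg)
      expect_equal(res$category, oracle(rel, has_new, n_follow == 0),
                   info = sprintf("rel=%g new=%d", rel, has_new))
      # reasons are consistent with the category
      if (res$category == "PD") {
        expect_true(any(c("new_lesion", "volume_increase_ge_threshold") %in% res$reasons))
        if (has_new) expect_true("new_lesion" %in% res$reasons)
      } else if (res$category == "CR") {
        expect_equal(res$reasons, "total_disappearance")
        expect_equal(res$followup_volume_mm3, 0)
      } else {
        expect_equal(res$reasons, "neither")
      }
      if (!has_new)
        expect_equal(res$relative_change, rel, tolerance = 1e-9)
    }
  }
  # zero baseline volume is an error, not a silent classification
  empty_cs <- label_components(array(0L, gs))
  expect_error(classify_response(empty_cs, base_cs, cfg = cfg), "baseline")
})

test_that("boundary volume cases from the volumetric rule classify correctly", {
  gs <- c(40L, 40L, 20L)
  base_cs <- label_components(prefix_blob(gs, c(2L, 2L, 2L), c(12L, 12L, 12L), 1000L))
  # 1000 -> 1728 mm^3 with no new lesion: exactly +72.8%, PD inclusive
  fu_cs <- label_components(prefix_blob(gs, c(2L, 2L, 2L), c(15L, 15L, 15L), 1728L))
  res <- classify_response(base_cs, fu_cs)
  expect_equal(res$category, "PD")
  expect_equal(res$reasons, "volume_increase_ge_threshold")
  # total disappearance: CR
  res_cr <- classify_response(base_cs, label_components(array(0L, gs)))
  expect_equal(res_cr$category, "CR")
  # moderate growth plus a new lesion: PD by the new lesion
  fu2 <- prefix_blob(gs, c(2L, 2L, 2L), c(15L, 15L, 15L), 1500L)
  fu2[37:38, 37:38, 16:17] <- 1L
  res_new <- classify_response(base_cs, label_components(fu2))
  expect_equal(res_new$category, "PD")
  expect_true("new_lesion" %in% res_new$reasons)
  expect_false("volume_increase_ge_threshold" %in% res_new$reasons)
})

test_that("confusion matrix and percent agreement count categories", {
  a <- c("CR", "PR_SD", "PD", "PD")
  expect_equal(confusion_and_agreement(a, a)$percent_agreement, 100)
  expect_equal(sum(confusion_and_agreement(a, a)$confusion
                   [upper.tri(diag(3)) | lower.tri(diag(3))]), 0)
  single <- confusion_and_agreement("CR", "PD")
  expect_equal(single$percent_agreement, 0)
  expect_error(confusion_and_agreement(c("CR", "PD"), "CR"), "equal length")
  expect_error(confusion_and_agreement("CR", "XX"), "unknown")
  # marginals equal each rater's category counts
  b <- c("CR", "PD", "PD", "PR_SD")
  cm <- confusion_and_agreement(a, b)$confusion
  expect_equal(as.numeric(rowSums(cm)), as.numeric(table(factor(a, c("CR", "PR_SD", "PD")))))
  expect_equal(as.numeric(colSums(cm)), as.numeric(table(factor(b, c("CR", "PR_SD", "PD")))))
})

test_that("ICC(2,1) reproduces the hand-worked ANOVA example", {
  res <- icc_2_1(cbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  # MSR = 10/3, MSC = 2, MSE = 0 -> ICC = (10/3)/(10/3 + 1) = 10/13
  expect_equal(res$msr, 10 / 3)
  expect_equal(res$msc, 2)
  expect_equal(res$mse, 0, tolerance = 1e-12)
  expect_equal(round(res$icc, 3), 0.769)
  # identical raters over distinct subjects
  expect_message(perfect <- icc_2_1(cbind(1:5, 1:5)), "degenerate")
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$icc_ci95, c(1, 1))
  # affine transforms of all cells leave the ICC unchanged
  withr::with_seed(2, {
    m <- matrix(rnorm(12), 6, 2)
    expect_equal(icc_2_1(3 * m + 7)$icc, icc_2_1(m)$icc, tolerance = 1e-12)
  })
  expect_error(icc_2_1(matrix(1, 1, 2)), "at least 2")
  expect_true(is.na(icc_2_1(matrix(5, 4, 2))$icc))
})

test_that("ICC agrees with an aov-based two-way ANOVA oracle", {
  withr::with_seed(8, {
    for (trial in 1:25) {
      n <- sample(4:10, 1); k <- sample(2:4, 1)
      m <- matrix(rnorm(n * k), n, k)
      res <- icc_2_1(m)
      long <- data.frame(y = as.vector(m),
                         subject = factor(rep(seq_len(n), k)),
                         rater = factor(rep(seq_len(k), each = n)))
      tab <- anova(lm(y ~ subject + rater, data = long))
      msr <- tab["subject", "Mean Sq"]; msc <- tab["rater", "Mean Sq"]
      mse <- tab["Residuals", "Mean Sq"]
      icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
      expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
    }
  })
})

test_that("agreement_stats combines confusion, agreement and ordinal ICC", {
  a <- c("CR", "PR_SD", "PD", "PD", "PR_SD")
  b <- c("CR", "PR_SD", "PD", "PR_SD", "PR_SD")
  st <- agreement_stats(a, b)
  expect_equal(st$percent_agreement, 80)
  expect_equal(sum(st$confusion), 5)
  expect_true(st$icc <= 1)
  expect_equal(st$icc, icc_2_1(cbind(c(1, 2, 3, 3, 2), c(1, 2, 3, 2, 2)))$icc)
})
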