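test_that("built networks have one parameter group per level and seeded init", {
  cfg <- network_config(n_levels = 4, base_channels = 2, large_kernel_edge = 5,
                        parallel_kernel_edge = 3)
  net <- build_network(cfg, seed = 5)
  for (l in 1:4) {
    expect_true(sprintf("enc%d.dwL.w", l) %in% names(net$params))
    expect_true(sprintf("enc%d.dwS.w", l) %in% names(net$params))
  }
  for (l in 1:3) expect_true(sprintf("dec%d.merge.W", l) %in% names(net$params))
  expect_identical(net$params, build_network(cfg, seed = 5)$params)
  expect_false(identical(net$params, build_network(cfg, seed = 6)$params))
  # channel widths double per level
  expect_equal(dim(net$params[["enc2.dwL.w"]])[4], 4)
  expect_equal(dim(net$params[["enc4.dwL.w"]])[4], 16)
})

test_that("forward respects the shape contract and softmax normalization", {
  net <- build_network(tiny_net_config(), seed = 2)
  x <- array(rnorm(16^3), c(16, 16, 16))
  out <- net_forward(net, x, training_mode = TRUE)
  expect_equal(dim(out$prob), c(16, 16, 16, 2))
  expect_lt(max(abs(out$prob[, , , 1] + out$prob[, , , 2] - 1)), 1e-6)
  expect_length(out$aux, 1)
  expect_equal(dim(out$aux[[1]])[1:3], c(8, 8, 8))
  # inference mode: only the full-resolution map
  expect_null(net_forward(net, x, training_mode = FALSE)$aux)
  # a four-level network yields three auxiliary maps
  cfg4 <- network_config(n_levels = 4, base_channels = 2, large_kernel_edge = 5,
                         parallel_kernel_edge = 3)
  out4 <- net_forward(build_network(cfg4, seed = 1),
                      array(0, c(40, 40, 40)), training_mode = TRUE)
  expect_length(out4$aux, 3)
  expect_true(all(is.finite(out4$prob)))
})

test_that("shape violations produce informative errors", {
  net <- build_network(tiny_net_config(), seed = 1)
  expect_error(net_forward(net, array(0, c(15, 16, 16))), "multiples of 2")
  big_k <- network_config(n_levels = 2, base_channels = 2, large_kernel_edge = 13,
                          parallel_kernel_edge = 5)
  expect_error(net_forward(build_network(big_k, seed = 1), array(0, c(16, 16, 16))),
               "level 2")
})

test_that("fusing folds normalization and pads the small kernel in place", {
  # all-zero large branch + centred delta small branch with identity
  # normalization fuses to a single centred 1 and acts as identity inside
  C <- 2; K <- 7; k <- 3
  eps <- 1e-5
  delta <- array(0, c(k, k, k, C)); delta[2, 2, 2, ] <- 1
  idn <- list(gamma = rep(1, C), beta = rep(0, C), mean = rep(0, C),
              var = rep(1 - eps, C))
  blk <- block_params(array(0, c(K, K, K, C)), delta, idn, idn)
  f <- fuse_reparameterize(blk, eps = eps)
  expect_equal(f$b, rep(0, C))
  expect_equal(f$w[4, 4, 4, ], rep(1, C))
  expect_equal(sum(f$w != 0), C)
  x <- array(rnorm(12^3 * C), c(12, 12, 12, C))
  y <- rlkunet:::block_forward(blk, x, eps = eps, fused = TRUE)
  expect_equal(y, x)

  # an off-centre small-kernel entry lands at the same offset from the
  # fused kernel's centre
  delta2 <- array(0, c(k, k, k, C)); delta2[3, 2, 2, ] <- 1  # +1 along x
  blk2 <- block_params(array(0, c(K, K, K, C)), delta2, idn, idn)
  f2 <- fuse_reparameterize(blk2, eps = eps)
  expect_equal(f2$w[5, 4, 4, ], rep(1, C))
  expect_equal(sum(f2$w != 0), C)
})

test_that("fused and multi-branch forwards agree to double precision", {
  for (seed in 1:5) {
    blk <- random_block(seed, channels = 2, K = 9, k = 3)
    x <- withr::with_seed(seed + 100, array(rnorm(16^3 * 2), c(16, 16, 16, 2)))
    y_multi <- rlkunet:::block_forward(blk, x, fused = FALSE)
    y_fused <- rlkunet:::block_forward(blk, x, fused = TRUE)
    expect_lt(max(abs(y_multi - y_fused)), 1e-10)
  }
  expect_error(fuse_reparameterize(random_block(1, K = 9, k = 4)), "odd")
  bad <- random_block(2)
  bad$bn_large$var[1] <- 0
  expect_error(block_params(bad$large_kernel, bad$small_kernel, bad$bn_large,
                            bad$bn_small), "positive")
})

test_that("a fused full network reproduces multi-branch inference", {
  net <- build_network(tiny_net_config(), seed = 8)
  # give the running statistics non-trivial values via a few training steps
  x <- array(rnorm(16^3), c(16, 16, 16))
  gt <- array(0L, c(16, 16, 16)); gt[6:10, 6:10, 6:10] <- 1L
  fit <- train_network(net, list(x), list(gt), steps = 5)
  p1 <- predict_volume(fit$net, x)
  p2 <- predict_volume(fuse_network(fit$net), x)
  expect_lt(max(abs(p1 - p2)), 1e-10)
})

test_that("perturbations beyond the kernel radius cannot reach a voxel", {
  C <- 1; K <- 13
  blk <- random_block(42, channels = C, K = K, k = 5)
  x <- withr::with_seed(1, array(rnorm(16^3 * C), c(16, 16, 16, C)))
  y0 <- rlkunet:::block_forward(blk, x)
  v <- c(8, 8, 8)
  r <- (K - 1) / 2
  x_far <- x; x_far[v[1] + r + 1, v[2], v[3], 1] <- x_far[v[1] + r + 1, v[2], v[3], 1] + 5
  y_far <- rlkunet:::block_forward(blk, x_far)
  expect_identical(y_far[v[1], v[2], v[3], 1], y0[v[1], v[2], v[3], 1])
  x_near <- x; x_near[v[1] + r, v[2], v[3], 1] <- x_near[v[1] + r, v[2], v[3], 1] + 5
  y_near <- rlkunet:::block_forward(blk, x_near)
  expect_false(isTRUE(all.equal(y_near[v[1], v[2], v[3], 1], y0[v[1], v[2], v[3], 1])))
})

test_that("multiscale targets preserve foreground under max-pooling", {
  m <- array(0L, c(16, 16, 16)); m[5, 9, 12] <- 1L
  tg <- mhf_targets(m, 2)
  expect_true(sum(tg[[1]]) >= 1 && sum(tg[[2]]) >= 1)
  empty <- mhf_targets(array(0L, c(8, 8, 8)), 2)
  expect_equal(sum(empty[[1]]) + sum(empty[[2]]), 0)
  # 4^3 cube aligned to the pooling lattice becomes a 2^3 block, matching a
  # brute-force max-pool oracle
  cube <- array(0L, c(16, 16, 16)); cube[5:8, 5:8, 5:8] <- 1L
  tg1 <- mhf_targets(cube, 1)[[1]]
  oracle <- array(0L, c(8, 8, 8))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    oracle[i, j, k] <- max(cube[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                                (2 * k - 1):(2 * k)])
  expect_identical(tg1, oracle)
  expect_equal(sum(tg1), 8)
  expect_error(mhf_targets(array(0L, c(6, 6, 6)), 2), "divisible")
})

test_that("composite loss components take their closed-form values", {
  d <- c(8, 8, 8)
  gt <- array(0L, d); gt[1:8, 1:8, 1:4] <- 1L  # half foreground
  onehot <- array(0, c(d, 2))
  onehot[, , , 2] <- gt; onehot[, , , 1] <- 1 - gt
  t_perf <- rlkunet:::ce_dice_terms(onehot, gt, dice_smooth = 1e-5)
  expect_equal(t_perf$dice_loss, 0)
  all_bg <- array(0, c(d, 2)); all_bg[, , , 1] <- 1
  t_miss <- rlkunet:::ce_dice_terms(all_bg, gt, dice_smooth = 1e-12)
  expect_equal(t_miss$dice_loss, 1, tolerance = 1e-9)
  half <- array(0.5, c(d, 2))
  t_half <- rlkunet:::ce_dice_terms(half, gt, dice_smooth = 1e-12)
  expect_equal(t_half$dice_loss, 0.5, tolerance = 1e-9)
  # composite aggregates with geometric decay
  out <- list(prob = onehot, aux = list(array(0.5, c(4, 4, 4, 2))))
  aux_t <- mhf_targets(gt, 1)
  loss <- composite_loss(out, gt, aux_t, aux_loss_decay = 0.5)
  terms <- attr(loss, "terms")
  expect_equal(terms$weight, c(1, 0.5))
  expect_gte(as.numeric(loss), 0)
  expect_error(composite_loss(list(prob = onehot), array(0L, c(4, 4, 4))), "match")
})

test_that("analytic gradients agree with central finite differences", {
  for (mode in c("deep_supervision", "gating")) {
    cfg <- tiny_net_config(mhf_mode = mode)
    net <- build_network(cfg, seed = 3)
    x <- withr::with_seed(70, array(rnorm(16^3), c(16, 16, 16)))
    gt <- array(0L, c(16, 16, 16)); gt[4:7, 5:9, 6:10] <- 1L
    aux <- mhf_targets(gt, 1)
    lg <- rlkunet:::loss_and_grads(net, x, gt, aux)
    sel <- c("enc1.dwL.w", "enc1.bnL.gamma", "enc2.pw_in.W", "dec1.merge.W",
             "head.W", "aux1.W", "down1.w")
    for (name in sel) {
      idx <- withr::with_seed(nchar(name), sample(length(net$params[[name]]), 1))
      h <- 1e-5
      np <- net; np$params[[name]][idx] <- np$params[[name]][idx] + h
      nm <- net; nm$params[[name]][idx] <- nm$params[[name]][idx] - h
      num <- (rlkunet:::loss_and_grads(np, x, gt, aux)$loss -
              rlkunet:::loss_and_grads(nm, x, gt, aux)$loss) / (2 * h)
      ana <- lg$grads[[name]][idx]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("a short optimization run halves the loss on an easy phantom", {
  sp <- small_phantom_spec(77, n_lesions = 2, necrosis_probability = 0,
                           noise_sigma = 2)
  ph <- generate_phantom(sp)
  net <- build_network(tiny_net_config(base_channels = 8), seed = 4)
  fit <- train_network(net, list(ph$intensity), list(ph$gt_mask), steps = 200,
                       lr = 1e-3)
  expect_lte(tail(fit$log$loss, 1), 0.5 * fit$log$loss[1])
  expect_equal(nrow(fit$log), 200)
  # determinism of the whole recipe
  fit2 <- train_network(build_network(tiny_net_config(base_channels = 8), seed = 4),
                        list(ph$intensity), list(ph$gt_mask), steps = 5, lr = 1e-3)
  fit3 <- train_network(build_network(tiny_net_config(base_channels = 8), seed = 4),
                        list(ph$intensity), list(ph$gt_mask), steps = 5, lr = 1e-3)
  expect_identical(fit2$log$loss, fit3$log$loss)
})

test_that("checkpoints round-trip parameters and configuration", {
  net <- build_network(tiny_net_config(), seed = 10)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, net$params)
  expect_equal(back$config, net$config)
  x <- array(rnorm(16^3), c(16, 16, 16))
  expect_identical(predict_volume(back, x), predict_volume(net, x))
})
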