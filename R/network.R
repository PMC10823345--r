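#' Network architecture configuration
#'
#' Hyperparameters of the large-kernel 3D U-Net. The encoder stacks
#' `n_levels` blocks of the form pointwise expand -> parallel depthwise
#' large- and small-kernel branches, each batch-normalized, summed -> GELU
#' -> pointwise project, with stride-2 depthwise downsampling between
#' levels; the decoder mirrors it with trilinear upsampling, skip
#' concatenation and 3x3x3 depthwise refinement. The two depthwise branches
#' can be algebraically fused into one kernel for inference
#' ([fuse_network()]). Multiscale foreground highlighting (MHF) adds an
#' auxiliary two-channel softmax head at every coarser decoder scale.
#'
#' @param n_levels number of encoder (= decoder) resolution levels, >= 2.
#' @param in_channels input channels (1 for a single MRI contrast).
#' @param out_channels output channels (2: background, foreground).
#' @param base_channels channels at the first level, doubling per level.
#' @param large_kernel_edge odd edge of the depthwise large kernel.
#' @param parallel_kernel_edge odd edge of the parallel small branch,
#'   strictly smaller than `large_kernel_edge`.
#' @param mhf_enabled enable the multiscale foreground heads.
#' @param mhf_mode `"deep_supervision"` (auxiliary losses against
#'   max-pooled foreground targets) or `"gating"` (additionally multiplies
#'   decoder features by `1 + p_fg` of their scale's foreground map).
#' @param aux_loss_decay geometric weight `decay^s` of the auxiliary loss at
#'   scale `s`, in (0, 1].
#' @param bn_eps,bn_momentum batch-normalization variance floor and running
#'   statistics momentum.
#' @param dice_smooth smoothing constant of the soft-Dice loss.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_levels = 4L, in_channels = 1L, out_channels = 2L,
                           base_channels = 16L, large_kernel_edge = 13L,
                           parallel_kernel_edge = 5L, mhf_enabled = TRUE,
                           mhf_mode = c("deep_supervision", "gating"),
                           aux_loss_decay = 0.5, bn_eps = 1e-5,
                           bn_momentum = 0.1, dice_smooth = 1e-5) {
  mhf_mode <- match.arg(mhf_mode)
  stopifnot(n_levels >= 2, base_channels >= 1, out_channels == 2,
            aux_loss_decay > 0, aux_loss_decay <= 1, bn_eps > 0)
  if (large_kernel_edge %% 2 == 0 || parallel_kernel_edge %% 2 == 0)
    stop("kernel edges must be odd")
  if (parallel_kernel_edge >= large_kernel_edge)
    stop("parallel_kernel_edge must be smaller than large_kernel_edge")
  structure(list(n_levels = as.integer(n_levels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_channels = as.integer(base_channels),
                 large_kernel_edge = as.integer(large_kernel_edge),
                 parallel_kernel_edge = as.integer(parallel_kernel_edge),
                 mhf_enabled = isTRUE(mhf_enabled), mhf_mode = mhf_mode,
                 aux_loss_decay = aux_loss_decay, bn_eps = bn_eps,
                 bn_momentum = bn_momentum, dice_smooth = dice_smooth),
            class = "network_config")
}

level_channels <- function(config) config$base_channels * 2L^(seq_len(config$n_levels) - 1L)

#' Build a network with deterministic seeded initialization
#'
#' @param config a [network_config()].
#' @param seed integer seed for the weight initialization (He-style normal
#'   for pointwise and depthwise kernels; batch-norm at identity).
#' @return An object of class `rlk_net` holding `params` (named list of
#'   arrays), `buffers` (running batch-norm statistics) and the config.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  withr::with_seed(as.integer(seed), build_network_impl(config, seed))
}

build_network_impl <- function(config, seed) {
  L <- config$n_levels
  C <- level_channels(config)
  K <- config$large_kernel_edge
  k <- config$parallel_kernel_edge
  p <- list(); b <- list()
  he <- function(fan_in, n) rnorm(n, 0, sqrt(2 / fan_in))
  for (l in seq_len(L)) {
    cin <- if (l == 1) config$in_channels else C[l - 1]
    cl <- C[l]
    p[[sprintf("enc%d.pw_in.W", l)]] <- matrix(he(cin, cin * cl), cin, cl)
    p[[sprintf("enc%d.pw_in.b", l)]] <- numeric(cl)
    p[[sprintf("enc%d.dwL.w", l)]] <- array(he(K^3, K^3 * cl), c(K, K, K, cl))
    p[[sprintf("enc%d.dwS.w", l)]] <- array(he(k^3, k^3 * cl), c(k, k, k, cl))
    for (br in c("bnL", "bnS")) {
      p[[sprintf("enc%d.%s.gamma", l, br)]] <- rep(1, cl)
      p[[sprintf("enc%d.%s.beta", l, br)]] <- numeric(cl)
      b[[sprintf("enc%d.%s.mean", l, br)]] <- numeric(cl)
      b[[sprintf("enc%d.%s.var", l, br)]] <- rep(1, cl)
    }
    p[[sprintf("enc%d.pw_out.W", l)]] <- matrix(he(cl, cl * cl), cl, cl)
    p[[sprintf("enc%d.pw_out.b", l)]] <- numeric(cl)
    if (l < L) {
      p[[sprintf("down%d.w", l)]] <- array(0.125 + rnorm(8 * cl, 0, 0.02), c(2, 2, 2, cl))
      p[[sprintf("down%d.b", l)]] <- numeric(cl)
    }
  }
  for (l in seq_len(L - 1)) {
    cl <- C[l]
    p[[sprintf("dec%d.up_mix.W", l)]] <- matrix(he(C[l + 1], C[l + 1] * cl), C[l + 1], cl)
    p[[sprintf("dec%d.up_mix.b", l)]] <- numeric(cl)
    p[[sprintf("dec%d.merge.W", l)]] <- matrix(he(2 * cl, 2 * cl * cl), 2 * cl, cl)
    p[[sprintf("dec%d.merge.b", l)]] <- numeric(cl)
    p[[sprintf("dec%d.dw.w", l)]] <- array(he(27, 27 * cl), c(3, 3, 3, cl))
    p[[sprintf("dec%d.dw.b", l)]] <- numeric(cl)
  }
  p[["head.W"]] <- matrix(he(C[1], C[1] * 2), C[1], 2)
  p[["head.b"]] <- numeric(2)
  if (config$mhf_enabled) {
    for (s in seq_len(L - 1)) {
      cs <- C[s + 1]
      p[[sprintf("aux%d.W", s)]] <- matrix(he(cs, cs * 2), cs, 2)
      p[[sprintf("aux%d.b", s)]] <- numeric(2)
    }
  }
  structure(list(config = config, params = p, buffers = b, fused = FALSE,
                 seed = as.integer(seed)),
            class = "rlk_net")
}

#' @export
print.rlk_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<rlk_net> %d levels, base %d channels, kernels %d/%d, %s, %s params\n",
              x$config$n_levels, x$config$base_channels,
              x$config$large_kernel_edge, x$config$parallel_kernel_edge,
              if (x$fused) "fused" else "multi-branch", format(np, big.mark = ",")))
  invisible(x)
}

# ---- elementary layers (forward + backward) --------------------------------

pw_fwd <- function(x4, W, bias) {
  d <- dim(x4); n <- prod(d[1:3])
  y <- matrix(x4, n, d[4]) %*% W
  y <- sweep(y, 2, bias, `+`)
  array(y, c(d[1:3], ncol(W)))
}

pw_bwd <- function(x4, W, gy4) {
  d <- dim(x4); n <- prod(d[1:3])
  gym <- matrix(gy4, n, ncol(W))
  xm <- matrix(x4, n, d[4])
  list(gx = array(gym %*% t(W), d), gW = crossprod(xm, gym), gb = colSums(gym))
}

gelu <- function(x) x * pnorm(x)
gelu_bwd <- function(x, gy) gy * (pnorm(x) + x * dnorm(x))

bn_fwd <- function(x4, gamma, beta, rmean, rvar, eps, training, momentum) {
  d <- dim(x4); n <- prod(d[1:3])
  xm <- matrix(x4, n, d[4])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean; v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = array(y, d), cache = list(xhat = xhat, invstd = invstd, dims = d),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(cache, gamma, gy4) {
  d <- cache$dims; n <- prod(d[1:3])
  gym <- matrix(gy4, n, d[4])
  gbeta <- colSums(gym)
  ggamma <- colSums(gym * cache$xhat)
  # batch-statistics backward
  gx <- sweep(gym, 2, gbeta / n) - sweep(cache$xhat, 2, ggamma / n, `*`)
  gx <- sweep(gx, 2, gamma * cache$invstd, `*`)
  list(gx = array(gx, d), ggamma = ggamma, gbeta = gbeta)
}

flip_kernel <- function(w) {
  d <- dim(w)
  w[d[1]:1, d[2]:1, d[3]:1, , drop = FALSE]
}

dw_fwd <- function(x4, w, bias = NULL) {
  if (is.null(bias)) bias <- numeric(dim(w)[4])
  cpp_dwconv3(x4, w, bias)
}

dw_bwd <- function(x4, w, gy4) {
  gx <- cpp_dwconv3(gy4, flip_kernel(w), numeric(dim(w)[4]))
  g <- cpp_dwconv3_grad(x4, gy4, dim(w))
  list(gx = gx, gw = g$gw, gb = g$gb)
}

concat4 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1:3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

softmax2 <- function(z4) {
  m <- pmax(z4[, , , 1], z4[, , , 2])
  e1 <- exp(z4[, , , 1] - m); e2 <- exp(z4[, , , 2] - m)
  s <- e1 + e2
  p <- array(0, dim(z4))
  p[, , , 1] <- e1 / s; p[, , , 2] <- e2 / s
  p
}

# ---- full network forward (with cache for backprop) ------------------------

check_input_shape <- function(config, d) {
  L <- config$n_levels
  div <- 2L^(L - 1L)
  if (any(d[1:3] %% div != 0))
    stop(sprintf("input edge lengths (%s) must be multiples of %d for a %d-level network",
                 paste(d[1:3], collapse = "x"), div, L))
  for (l in seq_len(L)) {
    ext <- min(d[1:3]) / 2^(l - 1)
    if (config$large_kernel_edge > ext)
      stop(sprintf("large kernel edge %d exceeds the %g-voxel extent at encoder level %d",
                   config$large_kernel_edge, ext, l))
  }
  invisible(TRUE)
}

net_forward_cached <- function(net, x, training) {
  cfg <- net$config
  L <- cfg$n_levels
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  check_input_shape(cfg, dim(x))
  p <- net$params; b <- net$buffers
  enc <- vector("list", L)
  xin <- x
  for (l in seq_len(L)) {
    e <- list(x_in = xin)
    e$t <- pw_fwd(xin, p[[sprintf("enc%d.pw_in.W", l)]], p[[sprintf("enc%d.pw_in.b", l)]])
    if (net$fused) {
      e$ssum <- dw_fwd(e$t, p[[sprintf("enc%d.dwF.w", l)]], p[[sprintf("enc%d.dwF.b", l)]])
    } else {
      aL <- dw_fwd(e$t, p[[sprintf("enc%d.dwL.w", l)]])
      bnL <- bn_fwd(aL, p[[sprintf("enc%d.bnL.gamma", l)]], p[[sprintf("enc%d.bnL.beta", l)]],
                    b[[sprintf("enc%d.bnL.mean", l)]], b[[sprintf("enc%d.bnL.var", l)]],
                    cfg$bn_eps, training, cfg$bn_momentum)
      aS <- dw_fwd(e$t, p[[sprintf("enc%d.dwS.w", l)]])
      bnS <- bn_fwd(aS, p[[sprintf("enc%d.bnS.gamma", l)]], p[[sprintf("enc%d.bnS.beta", l)]],
                    b[[sprintf("enc%d.bnS.mean", l)]], b[[sprintf("enc%d.bnS.var", l)]],
                    cfg$bn_eps, training, cfg$bn_momentum)
      if (training) {
        b[[sprintf("enc%d.bnL.mean", l)]] <- bnL$rmean
        b[[sprintf("enc%d.bnL.var", l)]] <- bnL$rvar
        b[[sprintf("enc%d.bnS.mean", l)]] <- bnS$rmean
        b[[sprintf("enc%d.bnS.var", l)]] <- bnS$rvar
      }
      e$bnL_cache <- bnL$cache; e$bnS_cache <- bnS$cache
      e$ssum <- bnL$y + bnS$y
    }
    e$g <- gelu(e$ssum)
    e$f <- pw_fwd(e$g, p[[sprintf("enc%d.pw_out.W", l)]], p[[sprintf("enc%d.pw_out.b", l)]])
    enc[[l]] <- e
    if (l < L) xin <- cpp_dwdown2(e$f, p[[sprintf("down%d.w", l)]], p[[sprintf("down%d.b", l)]])
  }

  use_aux <- cfg$mhf_enabled && (training || cfg$mhf_mode == "gating")
  gating <- cfg$mhf_enabled && cfg$mhf_mode == "gating"
  dec <- vector("list", L)
  aux_logits <- vector("list", L - 1)
  aux_prob <- vector("list", L - 1)

  Fmap <- enc[[L]]$f
  dec[[L]] <- list(Fmap = Fmap)
  if (use_aux) {
    s <- L - 1L
    aux_logits[[s]] <- pw_fwd(Fmap, p[[sprintf("aux%d.W", s)]], p[[sprintf("aux%d.b", s)]])
    aux_prob[[s]] <- softmax2(aux_logits[[s]])
  }
  Fg <- Fmap
  if (gating) Fg <- Fmap * (1 + replicate_fg(aux_prob[[L - 1]], dim(Fmap)[4]))
  dec[[L]]$Fg <- Fg

  for (l in seq(L - 1, 1)) {
    dlc <- list()
    dlc$u <- cpp_upsample2(dec[[l + 1]]$Fg)
    dlc$um <- pw_fwd(dlc$u, p[[sprintf("dec%d.up_mix.W", l)]], p[[sprintf("dec%d.up_mix.b", l)]])
    dlc$cat <- concat4(dlc$um, enc[[l]]$f)
    dlc$m_pre <- pw_fwd(dlc$cat, p[[sprintf("dec%d.merge.W", l)]], p[[sprintf("dec%d.merge.b", l)]])
    dlc$m <- gelu(dlc$m_pre)
    dlc$d_pre <- dw_fwd(dlc$m, p[[sprintf("dec%d.dw.w", l)]], p[[sprintf("dec%d.dw.b", l)]])
    dlc$Fmap <- gelu(dlc$d_pre)
    if (l > 1 && use_aux) {
      s <- l - 1L
      aux_logits[[s]] <- pw_fwd(dlc$Fmap, p[[sprintf("aux%d.W", s)]], p[[sprintf("aux%d.b", s)]])
      aux_prob[[s]] <- softmax2(aux_logits[[s]])
    }
    dlc$Fg <- dlc$Fmap
    if (l > 1 && gating)
      dlc$Fg <- dlc$Fmap * (1 + replicate_fg(aux_prob[[l - 1]], dim(dlc$Fmap)[4]))
    dec[[l]] <- dlc
  }
  z_full <- pw_fwd(dec[[1]]$Fmap, p[["head.W"]], p[["head.b"]])
  prob_full <- softmax2(z_full)
  list(prob = prob_full, z_full = z_full,
       aux_prob = if (cfg$mhf_enabled && training) aux_prob else NULL,
       aux_logits = aux_logits,
       cache = list(enc = enc, dec = dec, aux_prob_all = aux_prob,
                    use_aux = use_aux, gating = gating),
       buffers = b)
}

replicate_fg <- function(prob4, n_channels) {
  d <- dim(prob4)
  array(rep(prob4[, , , 2], n_channels), c(d[1:3], n_channels))
}

#' Run the network on a volume
#'
#' @param net an `rlk_net`.
#' @param volume 3D numeric array (or 4D with a channel dimension); edge
#'   lengths must be multiples of `2^(n_levels-1)`.
#' @param training_mode logical; in training mode batch statistics are used
#'   for normalization and, with MHF enabled, auxiliary foreground maps are
#'   returned (one per coarser scale). In inference mode only the
#'   full-resolution map is produced.
#' @return A list of class `multiscale_outputs`: `prob` (4D array, two
#'   softmax channels summing to one at every voxel) and `aux` (list of
#'   coarser two-channel probability maps, or `NULL`).
#' @export
net_forward <- function(net, volume, training_mode = FALSE) {
  out <- net_forward_cached(net, volume, training_mode)
  structure(list(prob = out$prob, aux = out$aux_prob), class = "multiscale_outputs")
}

# ---- backward pass ---------------------------------------------------------

softmax2_bwd_from_fg <- function(prob4, g_fg) {
  # gradient wrt the two logit channels given dL/dp_fg
  pf <- prob4[, , , 2]; pb <- prob4[, , , 1]
  gz <- array(0, dim(prob4))
  gz[, , , 2] <- g_fg * pf * pb
  gz[, , , 1] <- -gz[, , , 2]
  gz
}

net_backward <- function(net, fwd, gz_full, gz_aux) {
  cfg <- net$config
  L <- cfg$n_levels
  p <- net$params
  enc <- fwd$cache$enc; dec <- fwd$cache$dec
  gating <- fwd$cache$gating
  aux_prob <- fwd$cache$aux_prob_all
  g <- list()
  add_g <- function(name, val) {
    if (is.null(g[[name]])) g[[name]] <<- val else g[[name]] <<- g[[name]] + val
  }

  # decoder: walk from the full-resolution head down to the bottleneck.
  # At iteration l, gF holds the gradient wrt dec[[l]]$Fmap.
  hb <- pw_bwd(dec[[1]]$Fmap, p[["head.W"]], gz_full)
  add_g("head.W", hb$gW); add_g("head.b", hb$gb)
  gF <- hb$gx
  gskip <- vector("list", L)
  for (l in seq_len(L - 1)) {
    dlc <- dec[[l]]
    gd_pre <- gelu_bwd(dlc$d_pre, gF)
    dwb <- dw_bwd(dlc$m, p[[sprintf("dec%d.dw.w", l)]], gd_pre)
    add_g(sprintf("dec%d.dw.w", l), dwb$gw); add_g(sprintf("dec%d.dw.b", l), dwb$gb)
    gm_pre <- gelu_bwd(dlc$m_pre, dwb$gx)
    mb <- pw_bwd(dlc$cat, p[[sprintf("dec%d.merge.W", l)]], gm_pre)
    add_g(sprintf("dec%d.merge.W", l), mb$gW); add_g(sprintf("dec%d.merge.b", l), mb$gb)
    cl <- dim(dlc$um)[4]
    g_um <- mb$gx[, , , seq_len(cl), drop = FALSE]
    gskip[[l]] <- mb$gx[, , , cl + seq_len(dim(enc[[l]]$f)[4]), drop = FALSE]
    ub <- pw_bwd(dlc$u, p[[sprintf("dec%d.up_mix.W", l)]], g_um)
    add_g(sprintf("dec%d.up_mix.W", l), ub$gW); add_g(sprintf("dec%d.up_mix.b", l), ub$gb)
    gFg_deep <- cpp_upsample2_grad(ub$gx, dim(dec[[l + 1]]$Fg))

    # deeper feature at scale s = l: undo gating, add the auxiliary head path
    deep <- dec[[l + 1]]
    s <- l
    gF_deep <- gFg_deep
    if (gating) {
      pfg <- replicate_fg(aux_prob[[s]], dim(deep$Fmap)[4])
      gF_deep <- gFg_deep * (1 + pfg)
      g_pfg <- rowSums(matrix(gFg_deep * deep$Fmap,
                              prod(dim(deep$Fmap)[1:3]), dim(deep$Fmap)[4]))
      g_pfg <- array(g_pfg, dim(deep$Fmap)[1:3])
      gz_gate <- softmax2_bwd_from_fg(aux_prob[[s]], g_pfg)
      gz_aux[[s]] <- if (is.null(gz_aux[[s]])) gz_gate else gz_aux[[s]] + gz_gate
    }
    if (s <= length(gz_aux) && !is.null(gz_aux[[s]])) {
      ab <- pw_bwd(deep$Fmap, p[[sprintf("aux%d.W", s)]], gz_aux[[s]])
      add_g(sprintf("aux%d.W", s), ab$gW); add_g(sprintf("aux%d.b", s), ab$gb)
      gF_deep <- gF_deep + ab$gx
    }
    gF <- gF_deep
  }
  # gF is now the gradient wrt dec[[L]]$Fmap = enc[[L]]$f

  # encoder: walk from the bottleneck back to the input; 'carry' is the
  # gradient reaching enc[[l-1]]$f through the downsampling path.
  carry <- NULL
  for (l in seq(L, 1)) {
    e <- enc[[l]]
    gf <- if (l == L) gF else gskip[[l]] + carry
    ob <- pw_bwd(e$g, p[[sprintf("enc%d.pw_out.W", l)]], gf)
    add_g(sprintf("enc%d.pw_out.W", l), ob$gW); add_g(sprintf("enc%d.pw_out.b", l), ob$gb)
    gs <- gelu_bwd(e$ssum, ob$gx)
    bL <- bn_bwd(e$bnL_cache, p[[sprintf("enc%d.bnL.gamma", l)]], gs)
    add_g(sprintf("enc%d.bnL.gamma", l), bL$ggamma); add_g(sprintf("enc%d.bnL.beta", l), bL$gbeta)
    dL <- dw_bwd(e$t, p[[sprintf("enc%d.dwL.w", l)]], bL$gx)
    add_g(sprintf("enc%d.dwL.w", l), dL$gw)
    bS <- bn_bwd(e$bnS_cache, p[[sprintf("enc%d.bnS.gamma", l)]], gs)
    add_g(sprintf("enc%d.bnS.gamma", l), bS$ggamma); add_g(sprintf("enc%d.bnS.beta", l), bS$gbeta)
    dS <- dw_bwd(e$t, p[[sprintf("enc%d.dwS.w", l)]], bS$gx)
    add_g(sprintf("enc%d.dwS.w", l), dS$gw)
    gt <- dL$gx + dS$gx
    ib <- pw_bwd(e$x_in, p[[sprintf("enc%d.pw_in.W", l)]], gt)
    add_g(sprintf("enc%d.pw_in.W", l), ib$gW); add_g(sprintf("enc%d.pw_in.b", l), ib$gb)
    if (l > 1) {
      db <- cpp_dwdown2_grad(enc[[l - 1]]$f, p[[sprintf("down%d.w", l - 1)]], ib$gx)
      add_g(sprintf("down%d.w", l - 1), db$gw); add_g(sprintf("down%d.b", l - 1), db$gb)
      carry <- db$gx
    }
  }
  g
}

# ---- loss ------------------------------------------------------------------

ce_dice_terms <- function(prob4, target3, dice_smooth, with_grad = FALSE) {
  pf <- prob4[, , , 2]; pb <- prob4[, , , 1]
  y <- as.numeric(target3 != 0)
  n <- length(y)
  eps_p <- 1e-12
  ce <- -mean(y * log(pmax(pf, eps_p)) + (1 - y) * log(pmax(pb, eps_p)))
  sp <- sum(pf); sy <- sum(y); ov <- sum(pf * y)
  denom <- sp + sy + dice_smooth
  dice <- (2 * ov + dice_smooth) / denom
  out <- list(ce = ce, dice_loss = 1 - dice)
  if (with_grad) {
    # d(CE)/dz through the two-channel softmax
    gz <- array(0, dim(prob4))
    gz[, , , 2] <- (pf - y) / n
    gz[, , , 1] <- -gz[, , , 2]
    # d(1 - Dice)/dp_fg, then through softmax
    gdice_pf <- -(2 * array(y, dim(pf)) * denom - (2 * ov + dice_smooth)) / denom^2
    gz[, , , 2] <- gz[, , , 2] + gdice_pf * pf * pb
    gz[, , , 1] <- gz[, , , 1] - gdice_pf * pf * pb
    out$gz <- gz
  }
  out
}

#' Foreground-preserving multiscale targets
#'
#' Downsamples a binary ground-truth mask by repeated 2x2x2 max-pooling so
#' that foreground is never lost by averaging: the target at scale `s` is
#' the mask max-pooled `s` times.
#'
#' @param gt_mask binary 3D grid with edges divisible by `2^n_scales`.
#' @param n_scales number of coarser scales.
#' @return List of `n_scales` binary grids, halving in edge length.
#' @export
mhf_targets <- function(gt_mask, n_scales) {
  d <- dim(gt_mask)
  if (any(d %% 2^n_scales != 0))
    stop(sprintf("mask edges (%s) must be divisible by %d",
                 paste(d, collapse = "x"), 2^n_scales))
  out <- vector("list", n_scales)
  cur <- as_int_mask(gt_mask)
  for (s in seq_len(n_scales)) {
    cur <- maxpool2(cur)
    out[[s]] <- cur
  }
  out
}

maxpool2 <- function(m) {
  d <- dim(m)
  ix <- seq(1, d[1], 2); iy <- seq(1, d[2], 2); iz <- seq(1, d[3], 2)
  out <- m[ix, iy, iz, drop = FALSE]
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    if (dx + dy + dz == 0) next
    out <- pmax(out, m[ix + dx, iy + dy, iz + dz, drop = FALSE])
  }
  array(as.integer(out), dim(out))
}

#' Composite segmentation loss
#'
#' Cross-entropy plus soft-Dice at full resolution, plus geometrically
#' down-weighted auxiliary terms (`aux_loss_decay^s`) at each coarser scale
#' when multiscale outputs are present.
#'
#' @param outputs a `multiscale_outputs` from [net_forward()], or any list
#'   with `prob` (4D two-channel map) and optional `aux`.
#' @param gt_mask full-resolution binary ground truth.
#' @param aux_targets targets from [mhf_targets()] matching `outputs$aux`
#'   (ignored when there are no auxiliary maps).
#' @param aux_loss_decay geometric auxiliary weight.
#' @param dice_smooth soft-Dice smoothing.
#' @return Scalar loss with attribute `terms` (a tibble of per-map
#'   cross-entropy and soft-Dice components).
#' @export
composite_loss <- function(outputs, gt_mask, aux_targets = NULL,
                           aux_loss_decay = 0.5, dice_smooth = 1e-5) {
  if (!identical(dim(outputs$prob)[1:3], dim(gt_mask)[1:3]))
    stop("prediction and ground truth shapes do not match")
  t0 <- ce_dice_terms(outputs$prob, gt_mask, dice_smooth)
  total <- t0$ce + t0$dice_loss
  rows <- tibble::tibble(scale = 0L, weight = 1, ce = t0$ce, dice_loss = t0$dice_loss)
  if (!is.null(outputs$aux) && length(outputs$aux) > 0) {
    if (is.null(aux_targets) || length(aux_targets) < length(outputs$aux))
      stop("aux_targets must provide one target per auxiliary map")
    for (s in seq_along(outputs$aux)) {
      if (!identical(dim(outputs$aux[[s]])[1:3], dim(aux_targets[[s]])[1:3]))
        stop(sprintf("auxiliary map %d and its target have different shapes", s))
      ts <- ce_dice_terms(outputs$aux[[s]], aux_targets[[s]], dice_smooth)
      w <- aux_loss_decay^s
      total <- total + w * (ts$ce + ts$dice_loss)
      rows <- rbind(rows, tibble::tibble(scale = s, weight = w, ce = ts$ce,
                                         dice_loss = ts$dice_loss))
    }
  }
  structure(total, terms = rows)
}

# ---- structural re-parameterization ----------------------------------------

#' Construct the parameters of one multi-branch depthwise stage
#'
#' @param large_kernel depthwise weights, dim `(K, K, K, C)`, odd `K`.
#' @param small_kernel depthwise weights, dim `(k, k, k, C)`, odd `k < K`.
#' @param bn_large,bn_small lists with per-channel `gamma`, `beta`, `mean`,
#'   `var` normalization parameters of each branch.
#' @return An object of class `block_params`.
#' @export
block_params <- function(large_kernel, small_kernel, bn_large, bn_small) {
  K <- dim(large_kernel)[1]; k <- dim(small_kernel)[1]
  if (K %% 2 == 0 || k %% 2 == 0) stop("kernel edges must be odd (no centre voxel)")
  if (dim(large_kernel)[4] != dim(small_kernel)[4])
    stop("both depthwise branches must act on the same channel count")
  for (bn in list(bn_large, bn_small))
    if (any(bn$var <= 0)) stop("normalization variances must be positive")
  structure(list(large_kernel = large_kernel, small_kernel = small_kernel,
                 bn_large = bn_large, bn_small = bn_small),
            class = "block_params")
}

fold_bn <- function(w, bn, eps) {
  scale <- bn$gamma / sqrt(bn$var + eps)
  wf <- sweep(w, 4, scale, `*`)
  bf <- bn$beta - bn$mean * scale
  list(w = wf, b = bf)
}

#' Fuse a multi-branch block into a single depthwise kernel
#'
#' Folds each branch's normalization into its kernel
#' (`w' = w * gamma / sqrt(var + eps)`, `b' = beta - mean * gamma /
#' sqrt(var + eps)`), zero-pads the small kernel symmetrically to the large
#' edge, and sums kernels and biases. The fused single-branch forward is
#' algebraically identical to the two-branch (inference-mode) forward.
#'
#' @param block a [block_params()].
#' @param eps normalization variance floor used at training time.
#' @return List with the fused `w` (dim `(K, K, K, C)`) and bias `b`.
#' @export
fuse_reparameterize <- function(block, eps = 1e-5) {
  stopifnot(inherits(block, "block_params"))
  K <- dim(block$large_kernel)[1]; k <- dim(block$small_kernel)[1]
  if (K %% 2 == 0 || k %% 2 == 0) stop("kernel edges must be odd (no centre voxel)")
  fl <- fold_bn(block$large_kernel, block$bn_large, eps)
  fs <- fold_bn(block$small_kernel, block$bn_small, eps)
  pad <- (K - k) / 2
  w <- fl$w
  idx <- pad + seq_len(k)
  w[idx, idx, idx, ] <- w[idx, idx, idx, , drop = FALSE] + fs$w
  list(w = w, b = fl$b + fs$b)
}

# two-branch (inference-mode) forward of a block_params stage; the oracle
# route against which fusion is checked
block_forward <- function(block, x4, eps = 1e-5, fused = FALSE) {
  if (fused) {
    f <- fuse_reparameterize(block, eps)
    return(cpp_dwconv3(x4, f$w, f$b))
  }
  bn_apply <- function(a, bn) {
    d <- dim(a)
    m <- matrix(a, prod(d[1:3]), d[4])
    m <- sweep(sweep(m, 2, bn$mean), 2, 1 / sqrt(bn$var + eps), `*`)
    m <- sweep(sweep(m, 2, bn$gamma, `*`), 2, bn$beta, `+`)
    array(m, d)
  }
  aL <- cpp_dwconv3(x4, block$large_kernel, numeric(dim(block$large_kernel)[4]))
  aS <- cpp_dwconv3(x4, block$small_kernel, numeric(dim(block$small_kernel)[4]))
  bn_apply(aL, block$bn_large) + bn_apply(aS, block$bn_small)
}

#' Fuse every encoder block of a trained network for inference
#'
#' @param net an `rlk_net` in multi-branch form.
#' @return The network with each encoder's two depthwise branches replaced
#'   by one fused kernel; `net$fused` is set. Forward outputs agree with the
#'   multi-branch inference-mode forward to floating-point tolerance.
#' @export
fuse_network <- function(net) {
  stopifnot(inherits(net, "rlk_net"))
  if (net$fused) return(net)
  cfg <- net$config
  for (l in seq_len(cfg$n_levels)) {
    blk <- block_params(
      net$params[[sprintf("enc%d.dwL.w", l)]],
      net$params[[sprintf("enc%d.dwS.w", l)]],
      list(gamma = net$params[[sprintf("enc%d.bnL.gamma", l)]],
           beta = net$params[[sprintf("enc%d.bnL.beta", l)]],
           mean = net$buffers[[sprintf("enc%d.bnL.mean", l)]],
           var = net$buffers[[sprintf("enc%d.bnL.var", l)]]),
      list(gamma = net$params[[sprintf("enc%d.bnS.gamma", l)]],
           beta = net$params[[sprintf("enc%d.bnS.beta", l)]],
           mean = net$buffers[[sprintf("enc%d.bnS.mean", l)]],
           var = net$buffers[[sprintf("enc%d.bnS.var", l)]]))
    f <- fuse_reparameterize(blk, cfg$bn_eps)
    net$params[[sprintf("enc%d.dwF.w", l)]] <- f$w
    net$params[[sprintf("enc%d.dwF.b", l)]] <- f$b
  }
  net$fused <- TRUE
  net
}
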