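# Optimization and inference around the network graph.

adam_init <- function(params) {
  list(m = lapply(params, function(x) array(0, dim(x) %||% length(x))),
       v = lapply(params, function(x) array(0, dim(x) %||% length(x))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# z-score normalization of an intensity volume before it enters the network
normalize_volume <- function(volume) {
  s <- sd(volume)
  if (s == 0) s <- 1
  (volume - mean(volume)) / s
}

loss_and_grads <- function(net, x, gt, aux_targets) {
  cfg <- net$config
  fwd <- net_forward_cached(net, x, training = TRUE)
  t0 <- ce_dice_terms(fwd$prob, gt, cfg$dice_smooth, with_grad = TRUE)
  total <- t0$ce + t0$dice_loss
  gz_aux <- vector("list", cfg$n_levels - 1)
  if (cfg$mhf_enabled) {
    for (s in seq_along(fwd$aux_prob)) {
      ts <- ce_dice_terms(fwd$aux_prob[[s]], aux_targets[[s]], cfg$dice_smooth,
                          with_grad = TRUE)
      w <- cfg$aux_loss_decay^s
      total <- total + w * (ts$ce + ts$dice_loss)
      gz_aux[[s]] <- w * ts$gz
    }
  }
  grads <- net_backward(net, fwd, t0$gz, gz_aux)
  list(loss = total, grads = grads, buffers = fwd$buffers)
}

#' Train a network on a set of volumes
#'
#' Whole-volume optimization (no patching): one Adam step per volume,
#' cycling through the training set in order. Intensities are z-scored per
#' volume; with MHF enabled the auxiliary targets are the max-pooled ground
#' truths from [mhf_targets()]. Training is deterministic: all randomness
#' sits in the seeded initialization of [build_network()].
#'
#' @param net an `rlk_net` (multi-branch form).
#' @param volumes list of 3D intensity arrays.
#' @param gt_masks list of matching binary ground-truth masks.
#' @param steps number of optimizer steps (0 leaves the network at its
#'   initialization).
#' @param lr Adam learning rate.
#' @param validation optional list with `volumes` and `gt_masks` monitored
#'   (forward only) every `val_every` steps.
#' @param val_every validation cadence in steps.
#' @return List with the trained `net` and a `log` tibble (step, volume
#'   index, training loss, optional validation loss).
#' @export
train_network <- function(net, volumes, gt_masks, steps = 100L, lr = 1e-3,
                          validation = NULL, val_every = 25L) {
  stopifnot(inherits(net, "rlk_net"), length(volumes) == length(gt_masks),
            length(volumes) >= 1, steps >= 0)
  if (net$fused) stop("cannot train a fused network; keep the multi-branch form")
  cfg <- net$config
  xs <- lapply(volumes, normalize_volume)
  auxs <- NULL
  if (cfg$mhf_enabled)
    auxs <- lapply(gt_masks, mhf_targets, n_scales = cfg$n_levels - 1)
  state <- adam_init(net$params)
  log <- vector("list", steps)
  n <- length(xs)
  for (step in seq_len(steps)) {
    i <- (step - 1L) %% n + 1L
    lg <- loss_and_grads(net, xs[[i]], gt_masks[[i]],
                         if (is.null(auxs)) NULL else auxs[[i]])
    if (!is.finite(lg$loss))
      stop(sprintf("training diverged (non-finite loss) at step %d", step))
    net$buffers <- lg$buffers
    upd <- adam_step(net$params, lg$grads, state, lr)
    net$params <- upd$params
    state <- upd$state
    val_loss <- NA_real_
    if (!is.null(validation) && (step %% val_every == 0 || step == steps))
      val_loss <- validation_loss(net, validation)
    log[[step]] <- tibble::tibble(step = step, volume = i,
                                  loss = as.numeric(lg$loss), val_loss = val_loss)
  }
  list(net = net,
       log = if (steps > 0) do.call(rbind, log)
             else tibble::tibble(step = integer(), volume = integer(),
                                 loss = numeric(), val_loss = numeric()))
}

validation_loss <- function(net, validation) {
  cfg <- net$config
  losses <- mapply(function(v, g) {
    out <- net_forward(net, normalize_volume(v), training_mode = FALSE)
    as.numeric(composite_loss(out, g, dice_smooth = cfg$dice_smooth))
  }, validation$volumes, validation$gt_masks)
  mean(losses)
}

#' Predict the foreground probability map for a volume
#'
#' @param net a trained `rlk_net` (multi-branch or fused).
#' @param volume 3D intensity array.
#' @param normalize z-score the volume first (as during training).
#' @return 3D array of foreground probabilities in \[0,1\].
#' @export
predict_volume <- function(net, volume, normalize = TRUE) {
  x <- if (normalize) normalize_volume(volume) else volume
  out <- net_forward(net, x, training_mode = FALSE)
  out$prob[, , , 2]
}

#' Save / load a checkpoint
#'
#' A checkpoint is one serialized archive holding the parameters, running
#' statistics and a JSON header with the architecture configuration, so a
#' saved network can be rebuilt without any other context.
#'
#' @param net an `rlk_net`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `rlk_net`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "rlk_net"))
  obj <- list(config_json = jsonlite::toJSON(unclass(net$config), auto_unbox = TRUE,
                                             digits = NA),
              params = net$params, buffers = net$buffers, fused = net$fused,
              seed = net$seed)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg_list <- jsonlite::fromJSON(obj$config_json)
  cfg <- do.call(network_config,
                 cfg_list[intersect(names(cfg_list), names(formals(network_config)))])
  structure(list(config = cfg, params = obj$params, buffers = obj$buffers,
                 fused = obj$fused, seed = obj$seed),
            class = "rlk_net")
}
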