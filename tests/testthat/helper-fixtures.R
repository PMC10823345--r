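# Shared fixture builders. Everything is generated in code at test time.

# compact phantom sized for unit tests: 32^3 grid needs a small off-centre
# choroid, a modest surface margin and 4-6 mm lesions to stay placeable
small_phantom_spec <- function(seed, n_lesions = 2, necrosis_probability = 0.3,
                               n_vessels = 2, noise_sigma = 2,
                               grid = c(32L, 32L, 32L)) {
  phantom_spec(grid_shape = grid, voxel_spacing = c(1, 1, 1),
               n_lesions = n_lesions, lesion_diameter_range = c(4, 6),
               necrosis_probability = necrosis_probability,
               n_vessels = n_vessels,
               choroid_region = list(centre_vox = NULL, semi_axes_mm = c(4, 2, 2)),
               noise_sigma = noise_sigma, seed = seed,
               placement_margin_mm = 2)
}

tiny_net_config <- function(...) {
  args <- utils::modifyList(list(n_levels = 2, base_channels = 4,
                                 large_kernel_edge = 5, parallel_kernel_edge = 3),
                            list(...))
  do.call(network_config, args)
}

# a random multi-branch depthwise stage for fusion checks
random_block <- function(seed, channels = 2, K = 13, k = 5) {
  withr::with_seed(seed, block_params(
    array(rnorm(K^3 * channels), c(K, K, K, channels)),
    array(rnorm(k^3 * channels), c(k, k, k, channels)),
    list(gamma = runif(channels, 0.5, 1.5), beta = rnorm(channels),
         mean = rnorm(channels), var = runif(channels, 0.5, 2)),
    list(gamma = runif(channels, 0.5, 1.5), beta = rnorm(channels),
         mean = rnorm(channels), var = runif(channels, 0.5, 2))))
}

# independent flood-fill component labelling (pure R, breadth-first); the
# oracle route against the C++ labelling
bfs_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  nxt <- 0L
  for (s in which(mask != 0)) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      vc <- arrayInd(v, d)[1, ]
      for (o in seq_len(nrow(offs))) {
        u <- vc + offs[o, ]
        if (any(u < 1) || any(u > d)) next
        ui <- u[1] + d[1] * ((u[2] - 1) + d[2] * (u[3] - 1))
        if (mask[ui] != 0 && lab[ui] == 0L) { lab[ui] <- nxt; queue <- c(queue, ui) }
      }
    }
  }
  lab
}

# a connected blob of exactly n voxels: the first n cells (column-major) of
# a cuboid region anchored at 'origin'
prefix_blob <- function(grid_shape, origin, region_dim, n) {
  m <- array(0L, grid_shape)
  if (n == 0) return(m)
  stopifnot(n <= prod(region_dim))
  idx <- arrayInd(seq_len(n), region_dim)
  idx <- sweep(idx, 2, origin - 1L, `+`)
  m[idx] <- 1L
  m
}
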