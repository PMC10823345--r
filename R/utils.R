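# Internal helpers shared across modules.

# derive a reproducible 32-bit sub-seed from a run seed and a stage index
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 9973) %% 2147483647)
}

assert_binary <- function(mask, what = "mask") {
  if (!all(mask %in% c(0L, 1L, FALSE, TRUE))) {
    stop(sprintf("%s must be binary (0/1)", what), call. = FALSE)
  }
  invisible(TRUE)
}

assert_same_grid <- function(a, b, what_a = "first grid", what_b = "second grid") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s (%s) and %s (%s) are not on the same grid",
                 what_a, paste(dim(a), collapse = "x"),
                 what_b, paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

as_int_mask <- function(mask) {
  m <- array(as.integer(mask != 0), dim = dim(mask))
  m
}

# voxel-centre coordinates (mm) for index i along an axis: (i - 0.5) * spacing
voxel_centres <- function(n, spacing) (seq_len(n) - 0.5) * spacing

# logical ellipsoid on an integer lattice; centre in voxel units, semi-axes in
# voxel units
ellipsoid_mask <- function(grid_shape, centre_vox, semi_axes_vox) {
  dx <- (seq_len(grid_shape[1]) - centre_vox[1]) / semi_axes_vox[1]
  dy <- (seq_len(grid_shape[2]) - centre_vox[2]) / semi_axes_vox[2]
  dz <- (seq_len(grid_shape[3]) - centre_vox[3]) / semi_axes_vox[3]
  q <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  array(as.integer(q <= 1), dim = grid_shape)
}
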