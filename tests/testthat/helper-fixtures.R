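# Fixtures built in code: digital balls, cubes, and small cohorts.

digital_ball <- function(r, voxel_dims = c(1, 1, 1), pad = 3L) {
  half <- as.integer(ceiling(r / voxel_dims)) + pad
  dm <- 2L * half + 1L
  ax <- lapply(1:3, function(d) ((seq_len(dm[d])) - 1 - half[d]) * voxel_dims[d])
  g <- expand.grid(ax[[1]], ax[[2]], ax[[3]])
  array(as.integer(g[, 1]^2 + g[, 2]^2 + g[, 3]^2 <= r^2), dm)
}

solid_cube <- function(side = 20L, pad = 3L) {
  dm <- side + 2L * pad
  cube <- array(0L, c(dm, dm, dm))
  idx <- (pad + 1L):(pad + side)
  cube[idx, idx, idx] <- 1L
  cube
}

# a small cohort spec that keeps test runtime low; generator defaults stay
# at the full study conditions
small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_patients = 16L, n_converters = 11L,
              grid_shape = c(64L, 64L, 48L),
              lesion_count_range = c(1L, 6L), seed = seed, ...)
}

# two disjoint axis-aligned cubes in one mask
two_cubes_mask <- function(dim = c(20L, 20L, 20L), side = 3L,
                           at1 = c(3L, 3L, 3L), at2 = c(12L, 12L, 12L)) {
  m <- array(0L, dim)
  m[at1[1]:(at1[1] + side - 1L), at1[2]:(at1[2] + side - 1L),
    at1[3]:(at1[3] + side - 1L)] <- 1L
  m[at2[1]:(at2[1] + side - 1L), at2[2]:(at2[2] + side - 1L),
    at2[3]:(at2[3] + side - 1L)] <- 1L
  m
}

# Gaussian blobs with class separation `sep` on the first feature
gaussian_blobs <- function(n = 100L, p = 5L, sep = 5, seed = 42L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(0:1, length.out = n)
  X[y == 1, 1] <- X[y == 1, 1] + sep
  list(x = X, y = y)
}
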