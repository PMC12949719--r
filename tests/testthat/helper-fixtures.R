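# Shared fixtures: built in code, no files.

# Twelve well-spread unit directions (axes + face diagonals).
test_directions <- function() {
  d <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
             c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, -1, 1), c(-1, 1, 1))
  d / sqrt(rowSums(d^2))
}

# Single-voxel noiseless dataset from a 3x3 tensor D (mm^2/s).
make_dwi_voxel <- function(D, b = 1000, dirs = test_directions(),
                           s0 = 1000, n_b0 = 2) {
  bvals <- c(rep(0, n_b0), rep(b, nrow(dirs)))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  q <- rowSums((bvecs %*% D) * bvecs)
  s <- s0 * exp(-bvals * q)
  structure(list(
    signals = array(s, dim = c(1, 1, 1, length(s))),
    bvals = bvals, bvecs = bvecs, mask = array(TRUE, c(1, 1, 1)),
    voxel_size_mm = c(2, 2, 2), orientation = "RAS"
  ), class = "dwi_dataset")
}

# Uniform tensor field: every voxel carries the same 3x3 tensor D (mm^2/s).
make_uniform_field <- function(dims, D) {
  comp <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  tens <- array(rep(comp, each = prod(dims)), dim = c(dims, 6))
  structure(list(tensors = tens, valid_mask = array(TRUE, dims)),
            class = "tensor_field")
}

# Small, quick phantom configuration.
small_phantom_cfg <- function(...) {
  phantom_config(grid_shape = c(20L, 20L, 12L), ventricle_level_slice = 6L, ...)
}

# Minimal cohort frame with two identical groups (for null demographics).
mirror_cohort <- function(n = 30, seed = 1) {
  set.seed(seed)
  base <- data.frame(
    age = rnorm(n, 40, 10), sex = sample(c("female", "male"), n, TRUE, c(0.9, 0.1)),
    ed = rnorm(n, 11, 4), bmi = rnorm(n, 25, 4), tbv = rnorm(n, 1.3e6, 1e5),
    alps = rnorm(n, 1.7, 0.2))
  rbind(cbind(group = "CD", base), cbind(group = "HC", base))
}
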