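#' Configuration for the synthetic DWI phantom
#'
#' The phantom emulates the acquisition geometry of a single-shell diffusion
#' protocol (64 directions at b = 1000 s/mm^2 plus four b = 0 volumes, 2 mm
#' isotropic voxels) over a simplified left-hemisphere scene at the level of
#' the lateral ventricle: an isotropic background, a CSF-like ventricle block,
#' a projection-fiber slab whose principal diffusion axis is z (appearing blue
#' on a DEC map), and an association-fiber slab whose principal axis is y
#' (green), both lateral to the ventricle on the left (negative-x) side and
#' spanning at least three consecutive axial slices.
#'
#' Eigenvalue triples are given in 10^-3 mm^2/s, sorted descending. For the
#' fiber slabs the largest eigenvalue is assigned to the fiber axis (z for
#' projection, y for association) and the middle eigenvalue to x, so the
#' analytic ALPS index of the noiseless scene is
#' `mean(l2_proj, l2_assoc) / mean(l3_proj, l3_assoc)`.
#'
#' @param grid_shape integer triple, voxels per axis (x, y, z).
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param b_value diffusion weighting in s/mm^2 for the non-zero shell.
#' @param n_directions number of diffusion-encoding directions (>= 6).
#' @param n_b0 number of b = 0 volumes (>= 1).
#' @param snr signal-to-noise ratio of the b = 0 signal; 0 means noiseless.
#' @param s0 non-diffusion-weighted signal amplitude (arbitrary units).
#' @param tissue_tensors named list of descending eigenvalue triples
#'   (10^-3 mm^2/s) for `background`, `csf`, `projection`, `association`.
#' @param ventricle_level_slice 0-based axial slice index of the
#'   lateral-ventricle plane; the ROI slices are centred here.
#' @param directions optional n x 3 matrix of unit gradient directions
#'   overriding the default deterministic Fibonacci-sphere scheme.
#' @param seed integer master seed for noise generation.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(40L, 40L, 24L),
                           voxel_size_mm = 2,
                           b_value = 1000,
                           n_directions = 64L,
                           n_b0 = 4L,
                           snr = 30,
                           s0 = 1000,
                           tissue_tensors = list(
                             background  = c(0.8, 0.8, 0.8),
                             csf         = c(3.0, 3.0, 3.0),
                             projection  = c(1.4, 0.55, 0.32),
                             association = c(1.4, 0.55, 0.32)
                           ),
                           ventricle_level_slice = NULL,
                           directions = NULL,
                           seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L))
    abort("'grid_shape' must be three positive integers")
  chk_scalar(voxel_size_mm, "voxel_size_mm", 0, strict = TRUE)
  chk_scalar(b_value, "b_value", 0, strict = TRUE)
  if (n_directions < 6L) abort("'n_directions' must be >= 6")
  if (n_b0 < 1L) abort("at least one b = 0 volume is required")
  chk_scalar(snr, "snr", 0)
  needed <- c("background", "csf", "projection", "association")
  if (!all(needed %in% names(tissue_tensors)))
    abort("'tissue_tensors' must name regions: %s", paste(needed, collapse = ", "))
  for (nm in needed) {
    ev <- tissue_tensors[[nm]]
    if (length(ev) != 3L || any(ev < 0) || is.unsorted(rev(ev)))
      abort("eigenvalue triple for region '%s' must be nonnegative and sorted descending", nm)
  }
  if (is.null(ventricle_level_slice)) ventricle_level_slice <- grid_shape[3] %/% 2L
  if (ventricle_level_slice < 2L || ventricle_level_slice > grid_shape[3] - 3L)
    abort("'ventricle_level_slice' leaves no room for three consecutive ROI slices")
  if (!is.null(directions)) {
    directions <- as.matrix(directions)
    if (ncol(directions) != 3L || nrow(directions) != n_directions)
      abort("'directions' must be an n_directions x 3 matrix")
    nrm <- sqrt(rowSums(directions^2))
    if (any(abs(nrm - 1) > 1e-6)) directions <- directions / nrm
  }
  structure(list(
    grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
    b_value = b_value, n_directions = as.integer(n_directions),
    n_b0 = as.integer(n_b0), snr = snr, s0 = s0,
    tissue_tensors = tissue_tensors,
    ventricle_level_slice = as.integer(ventricle_level_slice),
    directions = directions, seed = as.integer(seed)
  ), class = "phantom_config")
}

# Deterministic, roughly uniform unit directions (Fibonacci sphere).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Axis-aligned region boxes (0-based inclusive voxel ranges), scaled to the
# grid. Left hemisphere = low x in RAS. Errors if the slabs would overlap.
phantom_regions <- function(grid_shape, slice) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  hw <- max(1L, nx %/% 16L)              # slab half-width; >= 3 voxels wide
  assoc_cx <- max(hw, as.integer(floor(nx * 0.125)))
  proj_cx  <- as.integer(floor(nx * 0.275))
  vent_x0  <- as.integer(floor(nx * 0.40))
  vent_x1  <- as.integer(floor(nx * 0.475))
  y0 <- as.integer(floor(ny * 0.30)); y1 <- as.integer(floor(ny * 0.65))
  z0 <- max(0L, slice - 6L); z1 <- min(nz - 1L, slice + 6L)
  boxes <- list(
    association = list(x = c(assoc_cx - hw, assoc_cx + hw), y = c(y0, y1), z = c(z0, z1)),
    projection  = list(x = c(proj_cx - hw, proj_cx + hw),  y = c(y0, y1), z = c(z0, z1)),
    ventricle   = list(x = c(vent_x0, vent_x1), y = c(y0, y1), z = c(z0, z1))
  )
  if (boxes$association$x[2] >= boxes$projection$x[1] ||
      boxes$projection$x[2] >= boxes$ventricle$x[1] ||
      boxes$association$x[1] < 0L || boxes$ventricle$x[2] > nx - 1L)
    abort("grid too small: phantom region slabs overlap or leave the volume")
  if (z1 - z0 + 1L < 3L) abort("fiber slabs must span >= 3 consecutive axial slices")
  boxes
}

# Region tensor (3x3, mm^2/s) from a descending eigenvalue triple (1e-3 units).
# Fiber axis gets l1, x gets l2, the remaining axis l3; isotropic regions
# place the triple on the diagonal directly.
region_tensor <- function(ev, role) {
  ev <- ev * 1e-3
  switch(role,
    projection  = diag(c(ev[2], ev[3], ev[1])),  # l1 along z
    association = diag(c(ev[2], ev[1], ev[3])),  # l1 along y
    diag(ev)
  )
}

#' Add Rician noise to a magnitude signal
#'
#' Magnitude MRI noise model: the complex signal is perturbed by two
#' independent zero-mean Gaussian channels and the magnitude taken,
#' `sqrt((S + e1)^2 + e2^2)` with `e1, e2 ~ N(0, sigma)`. `sigma = 0`
#' returns the input unchanged.
#'
#' @param signal nonnegative numeric array of intensities.
#' @param sigma noise scale (>= 0), in the same units as `signal`.
#' @param seed optional integer seed.
#' @return An array of the same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  chk_scalar(sigma, "sigma", 0)
  if (sigma == 0) return(signal)
  set_seed_if(seed)
  n <- length(signal)
  e1 <- stats::rnorm(n, 0, sigma)
  e2 <- stats::rnorm(n, 0, sigma)
  out <- sqrt((signal + e1)^2 + e2^2)
  dim(out) <- dim(signal)
  out
}

#' Generate the synthetic DWI phantom
#'
#' Simulates single-tensor diffusion signals `S(g, b) = S0 exp(-b g' D g)` per
#' voxel from the region-wise tensors of [phantom_config()], applies Rician
#' noise at the configured SNR, and returns the dataset together with the
#' ground truth needed by downstream oracles: the true tensor field, the ALPS
#' ROI specification placed strictly inside the fiber slabs, and the analytic
#' ALPS index of the noiseless scene.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `dwi` (class `dwi_dataset`: `signals`
#'   (x,y,z,volume array), `bvals`, `bvecs` (n x 3), `mask`, `voxel_size_mm`,
#'   `orientation`) and `truth` (class `phantom_truth`: `tensor_field`,
#'   `roi_spec`, `alps_true`, `regions`, `config`).
#' @export
generate_dwi_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$grid_shape
  slice <- config$ventricle_level_slice
  boxes <- phantom_regions(dims, slice)

  # region label array: 1 bg, 2 csf, 3 projection, 4 association
  lab <- array(1L, dim = dims)
  box_idx <- function(b) list(x = (b$x[1]:b$x[2]) + 1L,
                              y = (b$y[1]:b$y[2]) + 1L,
                              z = (b$z[1]:b$z[2]) + 1L)
  bi <- box_idx(boxes$ventricle);   lab[bi$x, bi$y, bi$z] <- 2L
  bi <- box_idx(boxes$projection);  lab[bi$x, bi$y, bi$z] <- 3L
  bi <- box_idx(boxes$association); lab[bi$x, bi$y, bi$z] <- 4L

  tensors <- list(
    region_tensor(config$tissue_tensors$background, "background"),
    region_tensor(config$tissue_tensors$csf, "csf"),
    region_tensor(config$tissue_tensors$projection, "projection"),
    region_tensor(config$tissue_tensors$association, "association")
  )

  dirs <- if (is.null(config$directions)) fibonacci_directions(config$n_directions)
          else config$directions
  bvals <- c(rep(0, config$n_b0), rep(config$b_value, config$n_directions))
  bvecs <- rbind(matrix(0, config$n_b0, 3), dirs)
  nvol <- length(bvals)

  # per-region signal profile over volumes
  profiles <- vapply(tensors, function(D) {
    q <- rowSums((bvecs %*% D) * bvecs)   # g' D g
    config$s0 * exp(-bvals * q)
  }, numeric(nvol))                        # nvol x 4

  nvox <- prod(dims)
  signals <- matrix(0, nvox, nvol)
  for (r in 1:4) {
    vi <- which(lab == r)
    if (length(vi)) signals[vi, ] <- rep(profiles[, r], each = length(vi))
  }
  dim(signals) <- c(dims, nvol)

  if (config$snr > 0) {
    sigma <- config$s0 / config$snr
    signals <- add_rician_noise(signals, sigma,
                                seed = substream_seed(config$seed, "noise"))
  }

  # ground-truth tensor field, stored as (x,y,z,6): Dxx,Dyy,Dzz,Dxy,Dxz,Dyz
  tf <- array(0, dim = c(dims, 6L))
  comp <- function(D) c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  tfm <- matrix(0, nvox, 6L)
  for (r in 1:4) {
    vi <- which(lab == r)
    if (length(vi)) tfm[vi, ] <- rep(comp(tensors[[r]]), each = length(vi))
  }
  tf[] <- tfm
  tensor_field <- structure(list(tensors = tf, valid_mask = array(TRUE, dims)),
                            class = "tensor_field")

  ymid <- as.integer(round(mean(boxes$projection$y)))
  roi_spec <- alps_roi_spec(
    projection_center  = c(as.integer(mean(boxes$projection$x)), ymid, slice),
    association_center = c(as.integer(mean(boxes$association$x)), ymid, slice),
    cube_edge_voxels = 3L,
    slice_indices = (slice - 1L):(slice + 1L),
    volume_dim = dims
  )

  evp <- config$tissue_tensors$projection
  eva <- config$tissue_tensors$association
  alps_true <- mean(c(evp[2], eva[2])) / mean(c(evp[3], eva[3]))

  dwi <- structure(list(
    signals = signals, bvals = bvals, bvecs = bvecs,
    mask = array(TRUE, dims), voxel_size_mm = rep(config$voxel_size_mm, 3),
    orientation = "RAS"
  ), class = "dwi_dataset")

  truth <- structure(list(
    tensor_field = tensor_field, roi_spec = roi_spec, alps_true = alps_true,
    regions = boxes, region_labels = lab, config = config
  ), class = "phantom_truth")

  list(dwi = dwi, truth = truth)
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<dwi_dataset> %d x %d x %d voxels, %d volumes (%d b=0), b = %s s/mm^2\n",
              d[1], d[2], d[3], d[4], sum(x$bvals == 0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = "/")))
  invisible(x)
}
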