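test_that("ROI extraction returns exact means on a uniform field", {
  D <- diag(c(1.2, 0.8, 0.6) * 1e-3)
  f <- make_uniform_field(c(16, 16, 10), D)
  spec <- alps_roi_spec(c(3, 8, 5), c(6, 8, 5), volume_dim = c(16, 16, 10))
  r <- extract_roi_diffusivities(f, spec, 5)
  expect_equal(r$dx_proj, 1.2e-3)
  expect_equal(r$dy_proj, 0.8e-3)
  expect_equal(r$dz_proj, 0.6e-3)
  expect_equal(r$n_voxels, 9L)          # 3 x 3 in-plane patch
  r3 <- extract_roi_diffusivities(f, spec, 5, mode = "cube")
  expect_equal(r3$n_voxels, 27L)
  expect_equal(r3$dx_assoc, 1.2e-3)
})

test_that("ROI extraction rejects out-of-bounds cubes and invalid voxels", {
  f <- make_uniform_field(c(16, 16, 10), diag(rep(1e-3, 3)))
  expect_error(alps_roi_spec(c(0, 0, 5), c(6, 8, 5), volume_dim = c(16, 16, 10)),
               "crosses the volume edge")
  expect_error(alps_roi_spec(c(12, 8, 5), c(3, 8, 5), volume_dim = c(16, 16, 10)),
               "left")
  f$valid_mask[4, 8, 6] <- FALSE
  spec <- alps_roi_spec(c(3, 8, 5), c(6, 8, 5), volume_dim = c(16, 16, 10))
  expect_error(extract_roi_diffusivities(f, spec, 5), "invalid voxels: \\(3,7,5\\)")
})

test_that("ALPS index matches hand-evaluated values", {
  mk <- function(dxp, dyp, dzp, dxa, dya, dza, slice = 5) {
    structure(list(dx_proj = dxp, dy_proj = dyp, dz_proj = dzp,
                   dx_assoc = dxa, dy_assoc = dya, dz_assoc = dza,
                   n_voxels = 9L, slice_index = slice),
              class = "roi_diffusivities")
  }
  # all four used diffusivities equal: isotropy gives exactly 1
  expect_equal(compute_alps_index(mk(1, 1, 1, 1, 1, 1))$mean_index, 1.0)
  # Dx_proj 1.2, Dx_assoc 1.0, Dy_proj 0.8, Dz_assoc 0.6 -> 1.1 / 0.7
  r <- compute_alps_index(mk(1.2e-3, 0.8e-3, 9e-4, 1.0e-3, 9e-4, 0.6e-3))
  expect_equal(r$mean_index, 1.1 / 0.7, tolerance = 1e-12)
  # mean over slices is the arithmetic mean of per-slice indices
  r <- compute_alps_index(list(mk(1.2e-3, 0.8e-3, 9e-4, 1.0e-3, 9e-4, 0.6e-3, 4),
                               mk(1, 1, 1, 1, 1, 1, 5)))
  expect_equal(r$mean_index, mean(r$per_slice_index))
  expect_equal(unname(r$per_slice_index), c(1.1 / 0.7, 1))
  # nonpositive denominator is a hard error naming the slice
  expect_error(compute_alps_index(mk(1, -2, 1, 1, 1, 1, 7)), "slice 7")
})

test_that("noiseless phantom ALPS equals the analytic ground truth", {
  ph <- generate_dwi_phantom(small_phantom_cfg(snr = 0))
  f <- fit_tensor_loglinear(ph$dwi)
  a <- alps_from_tensor(f, ph$truth$roi_spec)
  expect_equal(a$mean_index, ph$truth$alps_true, tolerance = 1e-9)
  expect_equal(unname(a$per_slice_index), rep(ph$truth$alps_true, 3),
               tolerance = 1e-9)
})

test_that("ALPS is scale invariant and detects swapped ROI roles", {
  ph <- generate_dwi_phantom(small_phantom_cfg(snr = 0))
  f <- ph$truth$tensor_field
  spec <- ph$truth$roi_spec
  a1 <- alps_from_tensor(f, spec)$mean_index
  f2 <- f; f2$tensors <- f$tensors * 3.7
  expect_equal(alps_from_tensor(f2, spec)$mean_index, a1, tolerance = 1e-12)
  # swapping the ROI roles exchanges numerator and denominator fibers
  swapped <- alps_roi_spec(spec$association_center, spec$projection_center,
                           spec$cube_edge_voxels, spec$slice_indices)
  expect_gt(a1, 1)
  expect_lt(alps_from_tensor(f, swapped)$mean_index, 1)
})

test_that("rater perturbation is bounded and keeps ALPS finite", {
  ph <- generate_dwi_phantom(small_phantom_cfg(snr = 30, seed = 5L))
  f <- fit_tensor_loglinear(ph$dwi)
  spec <- ph$truth$roi_spec
  dims <- dim(ph$dwi$signals)[1:3]
  expect_identical(simulate_rater_perturbation(spec, 0, dims, seed = 1),
                   spec)
  vals <- vapply(1:100, function(i) {
    sp <- simulate_rater_perturbation(spec, 1, dims, seed = i)
    expect_true(all(abs(sp$projection_center - spec$projection_center) <= 1))
    expect_true(all(abs(sp$association_center - spec$association_center) <= 1))
    alps_from_tensor(f, sp)$mean_index
  }, numeric(1))
  expect_true(all(is.finite(vals) & vals > 0))
})

test_that("ICC(2,1) behaves as an absolute-agreement coefficient", {
  set.seed(21)
  x <- rnorm(40, 1.7, 0.2)
  expect_equal(interrater_icc(cbind(x, x))$icc, 1.0)
  # a constant offset is penalised by absolute agreement
  off <- interrater_icc(cbind(x, x + 0.15))$icc
  expect_lt(off, 1)
  expect_gt(off, 0)
  expect_lte(interrater_icc(cbind(x, rnorm(40)))$icc, 1)
  expect_error(interrater_icc(cbind(x[1:2], x[1:2])), "at least 3")
  expect_error(interrater_icc(matrix(1, 5, 2)), "identical")
})

test_that("a two-rater phantom study yields a valid agreement coefficient", {
  st <- simulate_rater_study(8, small_phantom_cfg(snr = 30), 1, seed = 2)
  expect_equal(dim(st$ratings), c(8L, 2L))
  expect_true(all(is.finite(st$ratings) & st$ratings > 0))
  expect_lte(st$icc$icc, 1)
  expect_identical(st$icc$n_raters, 2L)
})
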