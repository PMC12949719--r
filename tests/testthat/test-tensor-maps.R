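test_that("log-linear fit inverts noiseless signals exactly", {
  D <- diag(rep(0.8e-3, 3))
  f <- fit_tensor_loglinear(make_dwi_voxel(D))
  expect_equal(as.vector(f$tensors[1, 1, 1, 1:3]), rep(0.8e-3, 3),
               tolerance = 1e-12)
  expect_true(all(abs(f$tensors[1, 1, 1, 4:6]) < 1e-15))

  D <- diag(c(1.7, 0.3, 0.3) * 1e-3)
  f <- fit_tensor_loglinear(make_dwi_voxel(D))
  expect_equal(as.vector(f$tensors[1, 1, 1, 1:3]), c(1.7, 0.3, 0.3) * 1e-3,
               tolerance = 1e-12)
  expect_true(all(abs(f$tensors[1, 1, 1, 4:6]) < 1e-15))

  # a rotated anisotropic tensor round-trips too (off-diagonals exercised)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  D <- R %*% diag(c(1.5, 0.5, 0.3) * 1e-3) %*% t(R)
  f <- fit_tensor_loglinear(make_dwi_voxel(D))
  got <- f$tensors[1, 1, 1, ]
  expect_equal(as.vector(got),
               c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
               tolerance = 1e-10)
})

test_that("fit flags degenerate voxels and validates the acquisition", {
  dwi <- make_dwi_voxel(diag(rep(1e-3, 3)))
  dwi$signals[] <- 0
  f <- fit_tensor_loglinear(dwi)
  expect_false(f$valid_mask[1, 1, 1])

  bad <- make_dwi_voxel(diag(rep(1e-3, 3)))
  bad$bvals[] <- 1000                       # no b = 0 volume
  expect_error(fit_tensor_loglinear(bad), "b = 0")
  short <- make_dwi_voxel(diag(rep(1e-3, 3)), dirs = test_directions()[1:3, ])
  expect_error(fit_tensor_loglinear(short), "fewer than 6|at least 7")
})

test_that("noiseless phantom tensors and scalar maps reproduce ground truth", {
  ph <- generate_dwi_phantom(small_phantom_cfg(snr = 0))
  f <- fit_tensor_loglinear(ph$dwi)
  tt <- ph$truth$tensor_field$tensors
  nz <- abs(tt) > 0
  expect_lt(max(abs(f$tensors - tt)[nz] / abs(tt)[nz]), 1e-9)
  expect_lt(max(abs(f$tensors - tt)[!nz]), 1e-12)
  m <- scalar_maps(f)
  mt <- scalar_maps(ph$truth$tensor_field)
  expect_lt(max(abs(m$fa - mt$fa)), 1e-9)
  expect_lt(max(abs(m$md - mt$md)), 1e-9)
})

test_that("eigensystem sorts descending and sign-normalises deterministically", {
  f <- make_uniform_field(c(1, 1, 1), diag(c(1.7, 0.3, 0.3) * 1e-3))
  e <- tensor_eigensystem(f)
  expect_equal(as.vector(e$eigenvalues[1, 1, 1, ]), c(1.7, 0.3, 0.3) * 1e-3)
  # principal axis is x; z and y components are 0, so sign goes to +x
  expect_equal(as.vector(e$principal_direction[1, 1, 1, ]), c(1, 0, 0))

  set.seed(42)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3)
    R <- qr.Q(qr(A))
    lam <- sort(abs(rnorm(3, 1e-3, 5e-4)), decreasing = TRUE)
    D <- R %*% diag(lam) %*% t(R)
    e <- tensor_eigensystem(make_uniform_field(c(1, 1, 1), D))
    ev <- as.vector(e$eigenvalues[1, 1, 1, ])
    expect_equal(ev, lam, tolerance = 1e-9)          # rotation invariance
    expect_equal(sum(ev), sum(diag(D)), tolerance = 1e-12)   # trace
    expect_equal(prod(ev), det(D), tolerance = 1e-12)        # determinant
    expect_gte(e$principal_direction[1, 1, 1, 3], 0)         # sign convention
  }
})

test_that("FA and MD follow the closed forms and stay in range", {
  fm <- compute_fa_md(c(0.7, 0.7, 0.7) * 1e-3)
  expect_equal(fm$fa, 0, ignore_attr = TRUE)
  expect_equal(fm$md, 0.7e-3)

  fm <- compute_fa_md(c(1.7, 0.3, 0.3) * 1e-3)
  expect_equal(as.numeric(fm$fa), 0.7990222, tolerance = 1e-6)
  expect_equal(fm$md, 2.3e-3 / 3, tolerance = 1e-12)

  expect_equal(as.numeric(compute_fa_md(c(1e-3, 0, 0))$fa), 1)
  expect_equal(as.numeric(compute_fa_md(c(0, 0, 0))$fa), 0)

  # random PSD tensors: FA in [0, 1], MD = trace / 3 exactly
  set.seed(9)
  ev <- matrix(abs(rnorm(300, 1e-3, 8e-4)), ncol = 3)
  ev <- t(apply(ev, 1, sort, decreasing = TRUE))
  fm <- compute_fa_md(ev)
  expect_true(all(fm$fa >= 0 & fm$fa <= 1))
  expect_equal(fm$md, rowMeans(ev))

  # negative eigenvalue: clamped inside FA only, MD keeps the raw mean
  fm <- compute_fa_md(c(1.2e-3, 0.2e-3, -0.1e-3))
  expect_equal(fm$md, mean(c(1.2e-3, 0.2e-3, -0.1e-3)))
  expect_true(attr(fm$fa, "clamped"))
  expect_lte(as.numeric(fm$fa), 1)
})

test_that("DEC map follows the RGB convention", {
  expect_equal(dec_fa_map(0.8, c(0, 0, 1)), c(0, 0, 0.8))
  expect_equal(dec_fa_map(0.8, c(0, 1, 0)), c(0, 0.8, 0))
  expect_equal(dec_fa_map(0, c(1, 0, 0) / sqrt(1)), c(0, 0, 0))
  expect_equal(dec_fa_map(0.6, c(-1, 0, 0)), c(0.6, 0, 0))  # absolute value
})
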