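test_that("phantom generation is deterministic under a fixed seed", {
  cfg <- small_phantom_cfg(seed = 7L)
  a <- generate_dwi_phantom(cfg)
  b <- generate_dwi_phantom(cfg)
  expect_identical(a$dwi$signals, b$dwi$signals)
  expect_identical(a$truth$tensor_field$tensors, b$truth$tensor_field$tensors)
})

test_that("projection-fiber signal decays fastest along the fiber axis", {
  # z-aligned gradient sees the large eigenvalue of the projection tensor,
  # so its signal must fall below the x-aligned gradient's
  cfg <- small_phantom_cfg(snr = 0, n_directions = 12L,
                           directions = test_directions())
  ph <- generate_dwi_phantom(cfg)
  ctr <- ph$truth$roi_spec$projection_center + 1L
  vox <- ph$dwi$signals[ctr[1], ctr[2], ctr[3], ]
  ix <- which(apply(ph$dwi$bvecs, 1, function(g) all(abs(g - c(1, 0, 0)) < 1e-9)))
  iz <- which(apply(ph$dwi$bvecs, 1, function(g) all(abs(g - c(0, 0, 1)) < 1e-9)))
  expect_lt(vox[iz], vox[ix])
  # and the association-fiber voxel decays fastest along y
  ctr <- ph$truth$roi_spec$association_center + 1L
  vox <- ph$dwi$signals[ctr[1], ctr[2], ctr[3], ]
  iy <- which(apply(ph$dwi$bvecs, 1, function(g) all(abs(g - c(0, 1, 0)) < 1e-9)))
  expect_lt(vox[iy], vox[ix])
})

test_that("phantom region slabs never overlap and span three ROI slices", {
  ph <- generate_dwi_phantom(small_phantom_cfg(snr = 0))
  lab <- ph$truth$region_labels
  expect_setequal(unique(as.vector(lab)), 1:4)
  for (r in 3:4) {
    sl <- ph$truth$roi_spec$slice_indices + 1L
    expect_true(all(vapply(sl, function(z) any(lab[, , z] == r), TRUE)))
  }
  expect_error(phantom_regions(c(8L, 8L, 8L), 4L), "overlap|too small")
})

test_that("Rician noise has the known closed-form moments", {
  x <- matrix(runif(12), 3, 4)
  expect_identical(add_rician_noise(x, 0), x)
  expect_error(add_rician_noise(x, -1), ">=")
  # zero signal: Rayleigh with mean sigma * sqrt(pi / 2)
  draws <- add_rician_noise(numeric(1e6), sigma = 1, seed = 11)
  expect_equal(mean(draws), sqrt(pi / 2), tolerance = 0.01)
  # large SNR: mean -> S + sigma^2 / (2 S)
  s <- 100
  draws <- add_rician_noise(rep(s, 1e6), sigma = 1, seed = 12)
  expect_equal(mean(draws), s + 1 / (2 * s), tolerance = 5e-5)
})

test_that("default cohort has the study group sizes and missingness pattern", {
  g <- generate_cohort(cohort_config())
  expect_equal(sum(g$cohort$group == "CD"), 69)
  expect_equal(sum(g$cohort$group == "HC"), 64)
  hc <- g$cohort[g$cohort$group == "HC", ]
  expect_true(all(is.na(hc$cortisol_4pm)))
  expect_true(all(is.na(hc$cortisol_0000)))
  cd <- g$cohort[g$cohort$group == "CD", ]
  expect_true(all(cd$cortisol_0000 > 0))
  expect_true(all(g$cohort$cortisol_8am > 0))
  # deterministic under the seed
  g2 <- generate_cohort(cohort_config())
  expect_identical(g$cohort, g2$cohort)
})

test_that("cohort marginals converge to the configured values", {
  cfg <- cohort_config(n_cd = 10000L, n_hc = 10000L, seed = 33L)
  g <- generate_cohort(cfg)
  for (grp in c("CD", "HC")) {
    d <- g$cohort[g$cohort$group == grp, ]
    cm <- cfg$covariate_marginals[[tolower(grp)]]
    am <- cfg$alps_marginals[[tolower(grp)]]
    n <- nrow(d)
    for (v in c("age", "bmi")) {
      se <- cm[[v]][2] / sqrt(n)
      expect_lt(abs(mean(d[[v]]) - cm[[v]][1]), 3 * se)
      expect_lt(abs(sd(d[[v]]) - cm[[v]][2]), 3 * se)
    }
    expect_lt(abs(mean(d$alps) - am[1]), 3 * am[2] / sqrt(n))
    expect_equal(mean(d$sex == "male"), cm$sex_male[1] / cm$sex_male[2],
                 tolerance = 1e-3)
  }
  # 8 a.m. cortisol median matches the configured log-normal median
  cd <- g$cohort[g$cohort$group == "CD", ]
  expect_equal(median(cd$cortisol_8am), 683.36, tolerance = 0.03)
})

test_that("cohort configuration rejects broken tract templates and sizes", {
  tmpl <- default_tract_effects()
  expect_error(cohort_config(tract_effect_template = tmpl[-1, ]), "42 canonical")
  expect_error(cohort_config(n_cd = 0), "positive")
  expect_error(cohort_config(path_a = 1.2), "\\(-1, 1\\)")
})
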