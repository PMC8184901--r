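test_that("dilation by 3 mm at 1 mm spacing grows a voxel to the lattice ball", {
  a <- array(0L, c(15, 15, 15)); a[8, 8, 8] <- 1L
  m <- binary_mask(a, spacing = c(1, 1, 1))
  ext <- expand_mask(m, "dilate", margin_mm = 3)
  # lattice points with x^2 + y^2 + z^2 <= 9: 123 of them
  expect_equal(mask_count(ext$mask), 123L)
  # every retained voxel is within the margin of the seed
  idx <- which(ext$mask$grid$data == 1L, arr.ind = TRUE)
  d2 <- rowSums((idx - matrix(8, nrow(idx), 3, byrow = TRUE))^2)
  expect_true(all(d2 <= 9 + 1e-9))
})

test_that("mask extension is a superset, identity at zero, nested in margin", {
  m <- vd_anat$masks$kidney_left
  e0 <- expand_mask(m, margin_mm = 0)
  expect_identical(e0$mask$grid$data, m$grid$data)
  e3 <- expand_mask(m, "dilate", margin_mm = 3)
  e6 <- expand_mask(m, "dilate", margin_mm = 6)
  expect_true(all(m$grid$data <= e3$mask$grid$data))
  expect_true(all(e3$mask$grid$data <= e6$mask$grid$data))
  expect_gt(mask_count(e6$mask), mask_count(e3$mask))
  g3 <- expand_mask(m, "gaussian", margin_mm = 3)
  expect_true(all(m$grid$data <= g3$mask$grid$data))
  expect_gt(mask_count(g3$mask), mask_count(m))
  expect_error(expand_mask(m, margin_mm = -1), "margin_mm")
})

test_that("activity extraction is exact on a uniform fill and needs one grid", {
  spec <- default_phantom(psf_sigma_mm = 0)
  anat <- make_ct(spec)
  sp <- make_spect(spec, 24)
  m <- anat$masks$kidney_left
  truth <- organ_activity(spec$organs$kidney_left, 24)
  expect_equal(extract_activity(sp, m), truth)
  # the extension adds only zero-activity voxels here, so the sum is unchanged
  expect_equal(extract_activity(sp, expand_mask(m, margin_mm = 3)), truth)
  other <- binary_mask(array(0L, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_error(extract_activity(sp, other), "geometr")
  expect_equal(extract_activity(sp, binary_mask(array(0L, dim(sp$data)),
                                                spacing = spec$spacing_mm)), 0)
})

test_that("the extended mask recovers >= 95% of blurred spill-out activity", {
  sp <- make_spect(vd_spec, 24)
  m <- vd_anat$masks$kidney_left
  truth <- organ_activity(vd_spec$organs$kidney_left, 24)
  base_frac <- extract_activity(sp, m) / truth
  ext_frac <- extract_activity(sp, expand_mask(m, margin_mm = 3)) / truth
  expect_gt(ext_frac, base_frac)  # extension recovers spilled counts
  expect_gte(ext_frac, 0.95)
  expect_lte(ext_frac, 1.02)      # the other kidney is far enough away
})

test_that("noiseless four-point sampling recovers bi-exponential parameters", {
  fit <- fit_biexponential(vd_kin_samples)
  expect_identical(fit$path, "biexp")
  expect_equal(fit$A1_Bq, vd_kin$A1, tolerance = 1e-4)
  expect_equal(fit$lambda1_per_h, vd_kin$l1, tolerance = 1e-4)
  expect_equal(fit$A2_Bq, vd_kin$A2, tolerance = 1e-4)
  expect_equal(fit$lambda2_per_h, vd_kin$l2, tolerance = 1e-4)
  expect_lt(fit$residual_norm, 1e-4 * vd_kin_curve(0.5))
  # components are reported fast-first
  expect_gte(fit$lambda1_per_h, fit$lambda2_per_h)
})

test_that("mono-exponential data fall back to a single component", {
  t <- c(0.5, 6, 24, 72)
  samples <- data.frame(t_h = t, activity_Bq = 5e6 * exp(-0.03 * t))
  fit <- fit_biexponential(samples)
  expect_identical(fit$path, "mono")
  expect_equal(fit$A2_Bq, 0)
  expect_equal(fit$lambda1_per_h, 0.03, tolerance = 1e-6)
  expect_equal(fit$A1_Bq, 5e6, tolerance = 1)
  # explicit mono model works from two samples
  fit2 <- fit_biexponential(samples[c(1, 4), ], model = "mono")
  expect_equal(fit2$lambda1_per_h, 0.03, tolerance = 1e-6)
})

test_that("fitting rejects malformed sample tables", {
  s <- vd_kin_samples
  expect_error(fit_biexponential(s[1:3, ]), ">= 4 samples")
  expect_error(fit_biexponential(data.frame(t = 1:4, a = 1:4)), "columns")
  bad <- s; bad$activity_Bq[2] <- -1
  expect_error(fit_biexponential(bad), "non-negative")
  dup <- s; dup$t_h[2] <- dup$t_h[1]
  expect_error(fit_biexponential(dup), "distinct")
  zero <- s; zero$activity_Bq <- 0
  expect_error(fit_biexponential(zero), "zero")
})

test_that("the physical constraint bounds clearance below 177Lu decay", {
  lam_phys <- log(2) / lu177_half_life_h()
  t <- c(0.5, 6, 24, 72)
  # washout slower than physical decay is unphysical; the bound snaps it up
  slow <- data.frame(t_h = t, activity_Bq = 4e6 * exp(-lam_phys / 3 * t))
  fit <- fit_biexponential(slow, constrain_physical = TRUE)
  expect_gte(fit$lambda2_per_h, lam_phys - 1e-12)
  free <- fit_biexponential(slow)
  expect_lt(free$lambda2_per_h, lam_phys)
})

test_that("cumulated activity matches the closed form and is linear", {
  fit <- fit_biexponential(vd_kin_samples)
  expect_equal(cumulated_activity(fit), vd_kin_cum, tolerance = 1e-6)
  # finite horizon truncates the integral
  a48 <- cumulated_activity(fit, t_max_h = 48)
  expect_lt(a48, cumulated_activity(fit))
  closed <- 3600 * (vd_kin$A1 / vd_kin$l1 * (1 - exp(-vd_kin$l1 * 48)) +
                    vd_kin$A2 / vd_kin$l2 * (1 - exp(-vd_kin$l2 * 48)))
  expect_equal(a48, closed, tolerance = 1e-6)
  # doubling the samples doubles the integral
  s2 <- vd_kin_samples; s2$activity_Bq <- 2 * s2$activity_Bq
  expect_equal(cumulated_activity(fit_biexponential(s2)), 2 * vd_kin_cum,
               tolerance = 1e-6)
})

test_that("fitted integrals agree with adaptive quadrature over random curves", {
  set.seed(31)
  t <- c(0.5, 6, 24, 72)
  for (i in 1:50) {
    A1 <- stats::runif(1, 1e6, 5e8); l1 <- stats::runif(1, 0.1, 1.5)
    A2 <- stats::runif(1, 1e5, A1); l2 <- stats::runif(1, 0.003, 0.05)
    y <- A1 * exp(-l1 * t) + A2 * exp(-l2 * t)
    fit <- fit_biexponential(data.frame(t_h = t, activity_Bq = y))
    quad <- 3600 * stats::integrate(function(u) A1 * exp(-l1 * u) + A2 * exp(-l2 * u),
                                    0, Inf, rel.tol = 1e-10)$value
    expect_lt(abs(cumulated_activity(fit) / quad - 1), 0.001)
  }
})

test_that("2% measurement noise keeps the median cumulated-activity error small", {
  t <- c(0.5, 6, 24, 72)
  y0 <- vd_kin_curve(t)
  set.seed(32)
  errs <- vapply(1:200, function(i) {
    y <- y0 * (1 + stats::rnorm(4, 0, 0.02))
    y[y < 0] <- 0
    fit <- fit_biexponential(data.frame(t_h = t, activity_Bq = y))
    abs(cumulated_activity(fit) / vd_kin_cum - 1)
  }, 0)
  expect_lte(stats::median(errs), 0.05)
})

test_that("predictions reproduce the fitted curve at the samples", {
  fit <- fit_biexponential(vd_kin_samples)
  expect_equal(biexp_predict(fit, vd_kin_samples$t_h),
               vd_kin_samples$activity_Bq, tolerance = 1e-6)
  expect_equal(biexp_predict(fit, 0), fit$A1_Bq + fit$A2_Bq)
})
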