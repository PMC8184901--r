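test_that("organ mass is count x voxel volume x density", {
  a <- array(0L, c(10, 10, 10)); a[1:5, 1:5, 1:4] <- 1L  # 100 voxels
  m <- binary_mask(a, spacing = c(2, 2, 2))              # 8 mm^3 each
  expect_equal(organ_mass(m), 100 * 0.008 * 1.06)
  expect_equal(organ_mass(m, density_g_per_cc = 1), 0.8)
  empty <- binary_mask(array(0L, c(2, 2, 2)), spacing = c(1, 1, 1))
  expect_warning(z <- organ_mass(empty), "empty")
  expect_equal(z, 0)
})

test_that("the local deposition S-value follows E / voxel mass", {
  k <- local_deposition_kernel(c(4.42, 4.42, 4.42))
  mass_kg <- 4.42^3 * 1e-3 * 1.06 * 1e-3
  expect_equal(k$values[1, 1, 1], 0.1479 * 1.602176634e-13 / mass_kg)
  expect_equal(k$values[1, 1, 1], 2.589e-10, tolerance = 1e-3)
  # halving each edge divides the mass by 8 and multiplies s0 by 8
  k2 <- local_deposition_kernel(c(2.21, 2.21, 2.21))
  expect_equal(k2$values[1, 1, 1], 8 * k$values[1, 1, 1])
  # zero energy gives a zero kernel; the option overrides the default energy
  expect_equal(local_deposition_kernel(c(2, 2, 2),
                                       energy_per_decay_MeV = 0)$values[1, 1, 1], 0)
  old <- options(voxdose.lu177_electron_MeV = 0.2958)
  on.exit(options(old))
  expect_equal(local_deposition_kernel(c(4.42, 4.42, 4.42))$values[1, 1, 1],
               2 * k$values[1, 1, 1])
})

test_that("dose_kernel validates shape, sign and centring", {
  expect_error(dose_kernel(array(1, c(2, 3, 3)), c(1, 1, 1)), "odd")
  expect_error(dose_kernel(array(-1, c(1, 1, 1)), c(1, 1, 1)), "non-negative")
  off <- array(0, c(3, 3, 3)); off[1, 1, 1] <- 1
  expect_error(dose_kernel(off, c(1, 1, 1)), "maximum")
  expect_error(dose_kernel(array(1, c(1, 1, 1)), c(1, -1, 1)), "positive")
})

test_that("kernel CSVs round-trip and octant files expand by mirror symmetry", {
  v <- array(0, c(3, 3, 3))
  v[2, 2, 2] <- 1e-9
  v[1, 2, 2] <- v[3, 2, 2] <- 2e-10
  v[2, 1, 2] <- v[2, 3, 2] <- 3e-10
  v[2, 2, 1] <- v[2, 2, 3] <- 1e-10
  k <- dose_kernel(v, c(2, 2, 2))
  f <- tempfile(fileext = ".csv")
  write_kernel(k, f)
  k2 <- load_kernel(f)  # spacing restored from the comment line
  expect_equal(k2$values, k$values)
  expect_equal(k2$spacing_mm, c(2, 2, 2))
  # an octant file listing only non-negative offsets expands to the same kernel
  fo <- tempfile(fileext = ".csv")
  writeLines(c("# spacing_mm: 2 2 2",
               "ix,iy,iz,s_Gy_per_Bq_s",
               "0,0,0,1e-9",
               "1,0,0,2e-10",
               "0,1,0,3e-10",
               "0,0,1,1e-10"), fo)
  ko <- load_kernel(fo, octant = TRUE)
  expect_equal(ko$values, k$values)
  # malformed inputs are rejected
  fb <- tempfile(fileext = ".csv")
  writeLines(c("ix,iy,iz,s_Gy_per_Bq_s", "0,0,0,-1"), fb)
  expect_error(load_kernel(fb, spacing_mm = c(1, 1, 1)), "non-negative")
  fc <- tempfile(fileext = ".csv")
  writeLines(c("ix,iy,iz,s_Gy_per_Bq_s", "1,0,0,1e-10"), fc)
  expect_error(load_kernel(fc, spacing_mm = c(1, 1, 1)), "central")
  writeLines(c("ix,iy,iz,s_Gy_per_Bq_s", "0,0,0,1e-9"), fc)
  expect_error(load_kernel(fc), "spacing")
})

test_that("convolution with a delta kernel is a scaling; spacings must match", {
  set.seed(41)
  amap <- voxel_grid(array(stats::runif(6^3, 0, 1e8), c(6, 6, 6)),
                     spacing = c(2, 2, 2), kind = "cumulated_Bq_s")
  k <- local_deposition_kernel(c(2, 2, 2))
  d <- convolve_dose(amap, k)
  expect_equal(d$data, amap$data * k$values[1, 1, 1])
  expect_identical(d$kind, "dose_Gy")
  kbad <- local_deposition_kernel(c(4, 4, 4))
  expect_error(convolve_dose(amap, kbad), "spacing")
})

test_that("a symmetric kernel spreads dose symmetrically around a point source", {
  v <- array(0, c(3, 3, 3))
  v[2, 2, 2] <- 5e-10
  for (s in list(c(1, 2, 2), c(3, 2, 2), c(2, 1, 2), c(2, 3, 2),
                 c(2, 2, 1), c(2, 2, 3)))
    v[s[1], s[2], s[3]] <- 1e-10
  k <- dose_kernel(v, c(2, 2, 2))
  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 1e6
  amap <- voxel_grid(a, spacing = c(2, 2, 2), kind = "cumulated_Bq_s")
  d <- convolve_dose(amap, k)$data
  expect_equal(d[5, 5, 5], 1e6 * 5e-10, tolerance = 1e-9)
  expect_equal(d[4, 5, 5], 1e6 * 1e-10, tolerance = 1e-6)
  expect_equal(d[4, 5, 5], d[6, 5, 5], tolerance = 1e-9)
  expect_equal(d[5, 4, 5], d[5, 5, 6], tolerance = 1e-9)
  expect_equal(sum(d > 1e-12), 7)
})

test_that("convolution conserves energy for interior sources within 0.5%", {
  v <- array(0, c(5, 5, 5))
  ctr <- c(3, 3, 3)
  idx <- which(array(TRUE, c(5, 5, 5)), arr.ind = TRUE)
  r2 <- rowSums((idx - matrix(ctr, nrow(idx), 3, byrow = TRUE))^2)
  v[idx] <- 1e-10 * exp(-r2 / 2)
  k <- dose_kernel(v, c(2, 2, 2))
  e_per_decay <- sum(k$values)  # Gy kg per Bq s once scaled by voxel mass
  vox_mass_kg <- prod(c(2, 2, 2)) * 1e-3 * 1e-3  # water-density voxel, kg
  set.seed(42)
  for (i in 1:20) {
    a <- array(0, c(20, 20, 20))
    a[5:16, 5:16, 5:16] <- stats::runif(12^3, 0, 1e7)  # interior support
    amap <- voxel_grid(a, spacing = c(2, 2, 2), kind = "cumulated_Bq_s")
    d <- convolve_dose(amap, k)$data
    expect_lt(abs(sum(d) * vox_mass_kg / (sum(a) * e_per_decay * vox_mass_kg) - 1),
              0.005)
  }
})

test_that("organ-scaled cumulated activity conserves the fitted organ total", {
  series <- make_series(vd_small_spec)
  anat <- make_ct(vd_small_spec)
  em <- expand_mask(anat$masks$kidney, margin_mm = 3)
  spects <- lapply(series$acquisitions, `[[`, "spect")
  times <- vapply(series$acquisitions, `[[`, 0, "t_h")
  acts <- vapply(series$acquisitions, function(a)
    extract_activity(a$spect, em), 0)
  fit <- fit_biexponential(data.frame(t_h = times, activity_Bq = acts))
  amap <- cumulated_activity_map(spects, times, em, fit)
  expect_equal(sum(amap$data), cumulated_activity(fit), tolerance = 1e-9)
  # activity lands only inside the retrieval mask
  expect_true(all(amap$data[retrieval_mask(em)$grid$data == 0L] == 0))
  expect_error(cumulated_activity_map(spects, times, em, fit, t_ref_h = 12),
               "not in the series")
})

test_that("per-voxel kinetics agree with organ scaling on clean uniform data", {
  series <- make_series(vd_small_spec)
  anat <- make_ct(vd_small_spec)
  em <- expand_mask(anat$masks$kidney, margin_mm = 3)
  spects <- lapply(series$acquisitions, `[[`, "spect")
  times <- vapply(series$acquisitions, `[[`, 0, "t_h")
  acts <- vapply(series$acquisitions, function(a)
    extract_activity(a$spect, em), 0)
  fit <- fit_biexponential(data.frame(t_h = times, activity_Bq = acts))
  a_org <- cumulated_activity_map(spects, times, em, fit, mode = "organ_scaled")
  a_vox <- cumulated_activity_map(spects, times, em, fit, mode = "per_voxel")
  expect_equal(sum(a_vox$data), sum(a_org$data), tolerance = 0.01)
})

test_that("mean dose averages in-mask voxels only", {
  d <- voxel_grid(array(rep(c(1, 3), each = 4), c(2, 2, 2)),
                  spacing = c(1, 1, 1), kind = "dose_Gy")
  m1 <- binary_mask(array(c(rep(1L, 4), rep(0L, 4)), c(2, 2, 2)),
                    spacing = c(1, 1, 1))
  expect_equal(mean_dose(d, m1), 1)
  mall <- binary_mask(array(1L, c(2, 2, 2)), spacing = c(1, 1, 1))
  expect_equal(mean_dose(d, mall), 2)
  empty <- binary_mask(array(0L, c(2, 2, 2)), spacing = c(1, 1, 1))
  expect_error(mean_dose(d, empty), "empty")
})

test_that("DVH metrics reproduce the order-statistic definition", {
  d <- voxel_grid(array(c(1:10, rep(0, 17)), c(3, 3, 3)),
                  spacing = c(1, 1, 1), kind = "dose_Gy")
  m <- binary_mask(array(c(rep(1L, 10), rep(0L, 17)), c(3, 3, 3)),
                   spacing = c(1, 1, 1))
  cdvh <- dvh(d, m)
  # hottest 30% of 10 voxels = top 3 {10,9,8}; minimum is 8
  expect_equal(dvh_at(cdvh, 30), 8)
  # hottest 70% = top 7 {10..4}; minimum is 4
  expect_equal(dvh_at(cdvh, 70), 4)
  expect_gte(dvh_at(cdvh, 30), dvh_at(cdvh, 70))
  # the curve itself: non-increasing volume fraction, starts at 1
  expect_equal(cdvh$volume_fraction[1], 1)
  expect_true(all(diff(cdvh$volume_fraction) <= 0))
  expect_true(all(diff(dvh_at(cdvh, c(10, 30, 50, 70, 90))) <= 0))
  expect_error(dvh_at(cdvh, 0), "in \\(0, 100\\)")
  # a uniform dose has a flat DVH
  du <- voxel_grid(array(2.5, c(3, 3, 3)), spacing = c(1, 1, 1), kind = "dose_Gy")
  expect_equal(dvh_at(dvh(du, m), c(30, 70)), c(2.5, 2.5))
})
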