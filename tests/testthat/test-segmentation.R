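test_that("slice stacks have 2k+1 frames with repeated-boundary padding", {
  v <- voxel_grid(array(seq_len(4 * 4 * 10), c(4, 4, 10)), spacing = c(1, 1, 1))
  stacks <- build_stacks(v, "axial", k = 1)
  expect_length(stacks, 10)
  expect_true(all(vapply(stacks, function(s) length(s$frames), 0L) == 3L))
  # the first stack's lower context repeats slice 1
  expect_identical(stacks[[1]]$frames[[1]], stacks[[1]]$frames[[2]])
  expect_identical(stacks[[1]]$frames[[2]], v$data[, , 1])
  # pure 2D mode
  stacks0 <- build_stacks(v, "axial", k = 0)
  expect_true(all(vapply(stacks0, function(s) length(s$frames), 0L) == 1L))
  expect_error(build_stacks(v, "axial", k = 10), "slice count")
  # sagittal/coronal stacks slice the other axes
  expect_length(build_stacks(v, "sagittal", k = 1), 4)
})

test_that("dice matches the overlap formula and its edge conventions", {
  a <- array(0L, c(10, 10, 2)); a[1:10, 1:10, 1] <- 1L  # |a| = 100
  b <- array(0L, c(10, 10, 2)); b[1:10, 6:10, 1] <- 1L; b[1:10, 1:5, 2] <- 1L
  expect_equal(dice(a, b), 0.5)  # |b| = 100, overlap 50
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, array(0L, dim(a))), 0)
  expect_equal(dice(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))), 1)
  expect_equal(dice(a, b), dice(b, a))
  m1 <- binary_mask(a, spacing = c(1, 1, 1))
  m2 <- binary_mask(a, spacing = c(2, 2, 2))
  expect_error(dice(m1, m2), "geometr")
})

test_that("consensus is a per-voxel 2-of-3 majority vote", {
  set.seed(21)
  mk <- function() binary_mask(array(rbinom(20^3, 1, 0.5), c(20, 20, 20)),
                               spacing = c(1, 1, 1))
  m1 <- mk(); m2 <- mk(); m3 <- mk()
  got <- consensus(m1, m2, m3)$grid$data
  # brute-force per-voxel oracle
  want <- array(0L, c(20, 20, 20))
  for (i in seq_along(want))
    want[i] <- as.integer(m1$grid$data[i] + m2$grid$data[i] + m3$grid$data[i] >= 2L)
  expect_identical(got, want)
  # identity and permutation invariance
  expect_identical(consensus(m1, m1, m1)$grid$data, m1$grid$data)
  expect_identical(consensus(m2, m3, m1)$grid$data, got)
  expect_identical(consensus(m3, m1, m2)$grid$data, got)
  bad <- binary_mask(array(0L, c(20, 20, 20)), spacing = c(2, 2, 2))
  expect_error(consensus(m1, m2, bad), "geometr")
})

test_that("the reference backend segments the phantom kidneys accurately", {
  r <- segment_plane(vd_anat$ct, "axial", reference_backend())
  expect_gte(dice(r$mask, vd_truth_union), 0.95)
  # plane-agnostic on (near-)symmetric objects: axial vs sagittal runs agree
  sph <- voxel_grid(array(-1000 + 1040 * sphere_array(c(40, 40, 40),
                                                      c(20, 20, 20), 14),
                          c(40, 40, 40)), spacing = c(1, 1, 1), kind = "HU")
  ra <- segment_plane(sph, "axial", reference_backend())
  rs <- segment_plane(sph, "sagittal", reference_backend())
  expect_gte(dice(ra$mask, rs$mask), 0.95)
})

test_that("backend failures leave flagged empty slices; errors carry context", {
  v <- voxel_grid(array(0, c(6, 6, 6)), spacing = c(1, 1, 1))
  fail_all <- segmenter_backend(function(st)
    slice_result(matrix(0L, 6, 6), success = FALSE), "never")
  r <- segment_plane(v, "axial", fail_all)
  expect_true(all(!r$success))
  expect_equal(mask_count(r$mask), 0L)
  boom <- segmenter_backend(function(st) stop("kaput"), "boom")
  expect_error(segment_plane(v, "axial", boom), "slice 1")
})

test_that("a slice with two organs keeps both components under one bbox", {
  f <- matrix(-1000, 64, 64)
  f[10:20, 10:20] <- 40
  f[40:55, 35:50] <- 40
  st <- structure(list(frames = list(f), center_index = 1L,
                       plane = "axial", k = 0L), class = "slice_stack")
  res <- reference_backend()$fun(st)
  expect_true(res$success)
  lab <- EBImage::bwlabel(res$mask)
  expect_equal(max(lab), 2)
  expect_equal(res$bbox, c(10, 10, 55, 50))
  # empty slice fails
  st0 <- structure(list(frames = list(matrix(-1000, 16, 16)), center_index = 1L,
                        plane = "axial", k = 0L), class = "slice_stack")
  expect_false(reference_backend()$fun(st0)$success)
})

test_that("failed-slice repair interpolates shapes, copies ends, needs one success", {
  # identical neighbours reproduce themselves
  a <- array(0L, c(40, 40, 5))
  d10 <- disc_matrix(c(40, 40), c(20, 20), 10)
  for (k in c(1, 3, 5)) a[, , k] <- d10
  m <- binary_mask(a, spacing = c(1, 1, 1))
  rep1 <- interpolate_missing(m, c(TRUE, FALSE, TRUE, FALSE, TRUE), "axial")
  expect_identical(rep1$grid$data[, , 2], d10)
  expect_identical(rep1$grid$data[, , 4], d10)
  # midway between discs of radius 10 and 20 -> a disc of radius ~15
  b <- array(0L, c(64, 64, 3))
  b[, , 1] <- disc_matrix(c(64, 64), c(32, 32), 10)
  b[, , 3] <- disc_matrix(c(64, 64), c(32, 32), 20)
  mb <- binary_mask(b, spacing = c(1, 1, 1))
  rep2 <- interpolate_missing(mb, c(TRUE, FALSE, TRUE), "axial")
  d15 <- disc_matrix(c(64, 64), c(32, 32), 15)
  expect_gte(dice(array(rep2$grid$data[, , 2], c(64, 64, 1)),
                  array(d15, c(64, 64, 1))), 0.97)
  # all successful is the identity
  rep3 <- interpolate_missing(mb, c(TRUE, TRUE, TRUE), "axial")
  expect_identical(rep3$grid$data, mb$grid$data)
  # end failures copy the nearest success
  rep4 <- interpolate_missing(mb, c(FALSE, FALSE, TRUE), "axial")
  expect_identical(rep4$grid$data[, , 1], b[, , 3])
  expect_error(interpolate_missing(mb, c(FALSE, FALSE, FALSE), "axial"),
               "no successful slices")
})

test_that("repair restores most of the Dice lost to sporadic slice failures", {
  fb <- reference_backend()
  clean <- segment_plane(vd_anat$ct, "axial", fb)
  d_clean <- dice(clean$mask, vd_truth_union)
  set.seed(22)
  nz <- dim(vd_anat$ct$data)[3]
  fail_idx <- sample(nz, round(0.1 * nz))
  flaky <- segmenter_backend(function(st) {
    if (st$center_index %in% fail_idx) {
      f <- st$frames[[st$k + 1L]]
      return(slice_result(matrix(0L, nrow(f), ncol(f)), success = FALSE))
    }
    fb$fun(st)
  }, "flaky")
  r <- segment_plane(vd_anat$ct, "axial", flaky)
  # every injected failure is flagged (empty slices are unsuccessful anyway)
  expect_true(all(fail_idx %in% which(!r$success)))
  repaired <- interpolate_missing(r$mask, r$success, "axial")
  expect_gte(dice(repaired, vd_truth_union), d_clean - 0.03)
})

test_that("SPECT threshold segmentation recovers organ support and is monotone", {
  spec0 <- default_phantom(psf_sigma_mm = 0)
  sp0 <- make_spect(spec0, 24)
  seed <- expand_mask(vd_anat$masks$kidney_left, margin_mm = 6)$mask
  s <- spect_threshold_segment(sp0, 0.5, seed_region = seed)
  expect_identical(s$grid$data, vd_anat$masks$kidney_left$grid$data)
  # blurred phantom at the default fraction: frozen regression volume
  sp <- make_spect(vd_spec, 24)
  sb <- spect_threshold_segment(sp, 0.42, seed_region = seed)
  expect_equal(mask_volume_ml(sb), 120.608, tolerance = 1e-3)
  expect_lt(abs(mask_volume_ml(sb) / mask_volume_ml(vd_anat$masks$kidney_left) - 1),
            0.10)
  # monotone in frac: higher fractions give nested subsets
  s99 <- spect_threshold_segment(sp, 0.99, seed_region = seed)
  s50 <- spect_threshold_segment(sp, 0.50, seed_region = seed)
  expect_true(all(s99$grid$data <= s50$grid$data))
  expect_true(all(s50$grid$data <= sb$grid$data))
  expect_error(spect_threshold_segment(
    voxel_grid(array(0, c(4, 4, 4)), c(1, 1, 1)), 0.5), "all zero")
})
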