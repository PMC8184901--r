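# Shared fixtures, built once per test run. The default phantom is the
# study condition every downstream stage is exercised on.

vd_spec <- default_phantom()
vd_anat <- make_ct(vd_spec)

vd_truth_union <- binary_mask(
  voxel_grid(array(pmax(vd_anat$masks$kidney_left$grid$data,
                        vd_anat$masks$kidney_right$grid$data),
                   dim(vd_anat$ct$data)),
             vd_spec$spacing_mm),
  label = "kidneys")

# small single-organ phantom for expensive per-voxel operations
vd_small_spec <- phantom_spec(
  shape = c(28, 28, 28), spacing_mm = c(2, 2, 2),
  organs = list(organ_spec("kidney", center_mm = c(27, 27, 27),
                           semi_axes_mm = c(12, 10, 14), hu_value = 40,
                           A1_Bq = 40e6, lambda1_per_h = 0.40,
                           A2_Bq = 10e6, lambda2_per_h = 0.015)),
  psf_sigma_mm = 3)

# solid sphere mask helper (voxel units)
sphere_array <- function(shape, center, radius) {
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - center[a])^2)
  q <- rep(ax[[1]], times = shape[2] * shape[3]) +
    rep(rep(ax[[2]], each = shape[1]), times = shape[3]) +
    rep(ax[[3]], each = shape[1] * shape[2])
  array(as.integer(q <= radius^2), shape)
}

# filled disc mask helper (pixel units)
disc_matrix <- function(shape, center, radius) {
  r2 <- outer((seq_len(shape[1]) - center[1])^2,
              (seq_len(shape[2]) - center[2])^2, `+`)
  matrix(as.integer(r2 <= radius^2), shape[1], shape[2])
}

# bi-exponential reference parameters used across kinetics tests
vd_kin <- list(A1 = 40e6, l1 = 0.40, A2 = 10e6, l2 = 0.01)
vd_kin_curve <- function(t) vd_kin$A1 * exp(-vd_kin$l1 * t) +
  vd_kin$A2 * exp(-vd_kin$l2 * t)
vd_kin_samples <- data.frame(t_h = c(0.5, 6, 24, 72),
                             activity_Bq = vd_kin_curve(c(0.5, 6, 24, 72)))
vd_kin_cum <- 3600 * (vd_kin$A1 / vd_kin$l1 + vd_kin$A2 / vd_kin$l2)
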