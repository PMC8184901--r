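#' Physical half-life of 177Lu
#'
#' Returned in hours. The default (6.647 days) can be overridden through
#' `options(voxdose.lu177_half_life_days = ...)` so the physical constant is
#' configuration, not hard-coded in the kinetics.
#'
#' @return Half-life in hours.
#' @export
lu177_half_life_h <- function() {
  24 * getOption("voxdose.lu177_half_life_days", 6.647)
}

#' Ellipsoidal organ specification
#'
#' Describes one phantom organ: an axis-aligned ellipsoid with a uniform CT
#' number and bi-exponential total-organ kinetics
#' `A(t) = A1 exp(-lambda1 t) + A2 exp(-lambda2 t)` (t in hours post
#' injection). Ellipsoids are used so volumes and centroids have closed
#' forms against which the voxelised phantom can be checked.
#'
#' @param name organ label.
#' @param center_mm world centre of the ellipsoid (mm).
#' @param semi_axes_mm strictly positive semi-axes (a, b, c) in mm.
#' @param hu_value CT number of the organ (HU).
#' @param A1_Bq,lambda1_per_h,A2_Bq,lambda2_per_h kinetic parameters;
#'   decay constants strictly positive, amplitudes non-negative.
#' @return An object of class `organ_spec`.
#' @export
organ_spec <- function(name, center_mm, semi_axes_mm, hu_value = 40,
                       A1_Bq = 0, lambda1_per_h = 0.3,
                       A2_Bq = 0, lambda2_per_h = 0.01) {
  semi_axes_mm <- as.numeric(semi_axes_mm)
  if (length(semi_axes_mm) != 3L || any(semi_axes_mm <= 0))
    stop("`semi_axes_mm` must be 3 strictly positive values", call. = FALSE)
  if (lambda1_per_h <= 0 || lambda2_per_h <= 0)
    stop("decay constants must be strictly positive", call. = FALSE)
  if (A1_Bq < 0 || A2_Bq < 0)
    stop("activity amplitudes must be non-negative", call. = FALSE)
  structure(list(name = name, center_mm = as.numeric(center_mm),
                 semi_axes_mm = semi_axes_mm, hu_value = hu_value,
                 A1_Bq = A1_Bq, lambda1_per_h = lambda1_per_h,
                 A2_Bq = A2_Bq, lambda2_per_h = lambda2_per_h),
            class = "organ_spec")
}

#' Analytic organ activity at a time point
#'
#' @param organ an [organ_spec].
#' @param t_h hours post injection (vectorised).
#' @return Activity in Bq.
#' @export
organ_activity <- function(organ, t_h) {
  stopifnot(inherits(organ, "organ_spec"), all(t_h >= 0))
  organ$A1_Bq * exp(-organ$lambda1_per_h * t_h) +
    organ$A2_Bq * exp(-organ$lambda2_per_h * t_h)
}

#' Analytic ellipsoid volume in ml
#' @param organ an [organ_spec].
#' @return (4/3) pi a b c / 1000, in ml.
#' @export
organ_analytic_volume_ml <- function(organ) {
  prod(organ$semi_axes_mm) * 4 / 3 * pi / 1000
}

#' Synthetic patient specification
#'
#' Full generative description of a synthetic SPECT/CT patient: grid
#' geometry, organ ellipsoids, acquisition schedule, SPECT point-spread
#' width, optional Poisson noise and per-time-point rigid SPECT/CT
#' misalignment. The default schedule (0.5, 6, 24, 72 h post injection)
#' matches a four-scan quantitative SPECT/CT dosimetry protocol.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing_mm voxel spacing (mm).
#' @param organs list of [organ_spec].
#' @param background_hu CT number outside all organs.
#' @param time_points_h strictly increasing, non-negative acquisition times.
#' @param psf_sigma_mm isotropic Gaussian blur applied to the SPECT (mm).
#' @param noise `"none"`, or `list(type = "poisson", counts_per_Bq = s)`:
#'   Poisson noise on per-voxel expected counts at scale `s`.
#' @param misalignment_mm optional list (one length-3 mm shift per time
#'   point) of rigid SPECT-vs-CT misalignments; default all zero.
#' @param origin_mm world position of the first voxel centre.
#' @param seed integer seed controlling every random element.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing_mm, organs,
                         background_hu = -1000,
                         time_points_h = c(0.5, 6, 24, 72),
                         psf_sigma_mm = 3,
                         noise = "none",
                         misalignment_mm = NULL,
                         origin_mm = c(0, 0, 0),
                         seed = 1234L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0))
  if (any(diff(time_points_h) <= 0) || any(time_points_h < 0))
    stop("time_points_h must be non-negative and strictly increasing", call. = FALSE)
  if (psf_sigma_mm < 0) stop("psf_sigma_mm must be >= 0", call. = FALSE)
  if (is.null(misalignment_mm))
    misalignment_mm <- rep(list(c(0, 0, 0)), length(time_points_h))
  if (length(misalignment_mm) != length(time_points_h))
    stop("one misalignment per time point required", call. = FALSE)
  if (!is.list(organs) || !all(vapply(organs, inherits, TRUE, "organ_spec")))
    stop("`organs` must be a list of organ_spec objects", call. = FALSE)
  names(organs) <- vapply(organs, `[[`, "", "name")
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 organs = organs, background_hu = background_hu,
                 time_points_h = time_points_h, psf_sigma_mm = psf_sigma_mm,
                 noise = noise, misalignment_mm = misalignment_mm,
                 origin_mm = as.numeric(origin_mm), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default two-kidney phantom
#'
#' A 90 x 90 x 60 grid at 2 mm isotropic spacing holding two kidney-sized
#' ellipsoids (semi-axes 20 x 28 x 50 mm, about 117 ml each) at 40 HU on a
#' -1000 HU background, with bi-exponential kinetics whose total injected
#' amplitude (about 0.4 GBq at t = 0) is a realistic kidney share of a
#' 7.5 GBq administration, and a 3 mm SPECT point-spread width. Slow-phase
#' effective decay constants (0.018 and 0.016 per h) are faster than
#' physical 177Lu decay, as any effective clearance must be.
#'
#' @param psf_sigma_mm,noise,misalignment_mm,seed overrides passed through
#'   to [phantom_spec()].
#' @return A [phantom_spec].
#' @export
default_phantom <- function(psf_sigma_mm = 3, noise = "none",
                            misalignment_mm = NULL, seed = 1234L) {
  organs <- list(
    organ_spec("kidney_left", center_mm = c(52, 89, 59),
               semi_axes_mm = c(20, 28, 50), hu_value = 40,
               A1_Bq = 150e6, lambda1_per_h = 0.35,
               A2_Bq = 55e6, lambda2_per_h = 0.018),
    organ_spec("kidney_right", center_mm = c(126, 89, 59),
               semi_axes_mm = c(20, 28, 50), hu_value = 40,
               A1_Bq = 140e6, lambda1_per_h = 0.32,
               A2_Bq = 50e6, lambda2_per_h = 0.016))
  phantom_spec(shape = c(90, 90, 60), spacing_mm = c(2, 2, 2),
               organs = organs, psf_sigma_mm = psf_sigma_mm, noise = noise,
               misalignment_mm = misalignment_mm, seed = seed)
}

# voxelised ellipsoid occupancy on the spec grid, optionally shifted
ellipsoid_array <- function(spec, organ, shift_mm = c(0, 0, 0)) {
  ctr <- organ$center_mm + shift_mm
  ax <- lapply(1:3, function(a) {
    w <- spec$origin_mm[a] + (seq_len(spec$shape[a]) - 1) * spec$spacing_mm[a]
    ((w - ctr[a]) / organ$semi_axes_mm[a])^2
  })
  q <- rep(ax[[1]], times = spec$shape[2] * spec$shape[3]) +
    rep(rep(ax[[2]], each = spec$shape[1]), times = spec$shape[3]) +
    rep(ax[[3]], each = spec$shape[1] * spec$shape[2])
  array(as.integer(q <= 1), spec$shape)
}

#' Rasterise the phantom CT and its ground-truth masks
#'
#' Fills the grid with the background CT number and stamps each organ
#' ellipsoid at its own HU (later organs overwrite earlier ones). Organs
#' whose voxelised volume captures less than half of the analytic ellipsoid
#' volume abort; partial truncation between 50% and 98% warns.
#'
#' @param spec a [phantom_spec].
#' @return `list(ct = voxel_grid[HU], masks = named list of binary_mask)`.
#' @export
make_ct <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  data <- array(spec$background_hu, spec$shape)
  masks <- list()
  vox_ml <- prod(spec$spacing_mm) / 1000
  for (organ in spec$organs) {
    occ <- ellipsoid_array(spec, organ)
    frac <- sum(occ) * vox_ml / organ_analytic_volume_ml(organ)
    if (frac < 0.5)
      stop("organ '", organ$name, "' lies mostly outside the grid (",
           round(100 * frac), "% captured)", call. = FALSE)
    if (frac < 0.98)
      warning("organ '", organ$name, "' truncated by the grid (",
              round(100 * frac), "% captured)", call. = FALSE)
    data[occ == 1L] <- organ$hu_value
    masks[[organ$name]] <- binary_mask(
      voxel_grid(occ, spec$spacing_mm, spec$origin_mm), label = organ$name)
  }
  ct <- voxel_grid(data, spec$spacing_mm, spec$origin_mm, kind = "HU")
  list(ct = ct, masks = masks)
}

#' Simulate a quantitative SPECT volume at one time point
#'
#' Each organ contributes a uniform activity concentration `A(t) / V` over
#' its (possibly misaligned) ellipsoid, where `V` is the voxelised organ
#' volume so the unblurred total activity equals the analytic `A(t)`
#' exactly. The volume is then blurred with the isotropic Gaussian PSF
#' (total activity conserved up to boundary truncation) and, if configured,
#' Poisson noise is applied to per-voxel expected counts.
#'
#' @param spec a [phantom_spec].
#' @param t_h hours post injection.
#' @param misalign_mm rigid SPECT shift (mm); `NULL` looks up the spec's
#'   misalignment for a matching time point, defaulting to no shift.
#' @return A [voxel_grid] of kind `activity_conc_Bq_per_ml`.
#' @export
make_spect <- function(spec, t_h, misalign_mm = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), t_h >= 0)
  if (is.null(misalign_mm)) {
    i <- match(TRUE, abs(spec$time_points_h - t_h) < 1e-9)
    misalign_mm <- if (is.na(i)) c(0, 0, 0) else spec$misalignment_mm[[i]]
  }
  vox_ml <- prod(spec$spacing_mm) / 1000
  conc <- array(0, spec$shape)
  for (organ in spec$organs) {
    occ <- ellipsoid_array(spec, organ, shift_mm = misalign_mm)
    n <- sum(occ)
    if (n == 0L) next
    conc <- conc + occ * (organ_activity(organ, t_h) / (n * vox_ml))
  }
  conc <- gauss_blur3(conc, spec$psf_sigma_mm, spec$spacing_mm)
  if (is.list(spec$noise) && identical(spec$noise$type, "poisson")) {
    scale <- spec$noise$counts_per_Bq
    if (is.null(scale) || scale <= 0)
      stop("poisson noise requires a positive counts_per_Bq", call. = FALSE)
    seed <- (spec$seed + round(1000 * t_h)) %% .Machine$integer.max
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    expected <- conc * vox_ml * scale
    conc <- array(stats::rpois(length(expected), expected), spec$shape) /
      (vox_ml * scale)
  }
  voxel_grid(conc, spec$spacing_mm, spec$origin_mm,
             kind = "activity_conc_Bq_per_ml")
}

# save/restore the RNG state so phantom noise does not disturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate the full acquisition series of a synthetic patient
#'
#' One entry per acquisition time: the simulated SPECT, the low-dose CT
#' (identical geometry to the diagnostic CT; any configured misalignment is
#' applied to the SPECT, emulating SPECT-vs-CT co-registration error), the
#' ground-truth organ masks and the analytic organ activities.
#'
#' @param spec a [phantom_spec].
#' @return `list(spec, ct, masks, acquisitions)` where `acquisitions` is a
#'   list with elements `t_h`, `spect`, `ldct`, `truth_A_Bq` (named per
#'   organ).
#' @export
make_series <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  anat <- make_ct(spec)
  acq <- lapply(seq_along(spec$time_points_h), function(i) {
    t_h <- spec$time_points_h[i]
    list(t_h = t_h,
         spect = make_spect(spec, t_h, misalign_mm = spec$misalignment_mm[[i]]),
         ldct = anat$ct,
         truth_A_Bq = vapply(spec$organs, organ_activity, 0, t_h = t_h))
  })
  list(spec = spec, ct = anat$ct, masks = anat$masks, acquisitions = acq)
}
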