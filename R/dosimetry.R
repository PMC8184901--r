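#' Organ mass from a binary mask
#'
#' Voxel count times voxel volume times soft-tissue density. The default
#' density of 1.06 g/cc is the standard assumption for renal parenchyma.
#'
#' @param m a [binary_mask].
#' @param density_g_per_cc tissue density (g/cc).
#' @return Mass in grams (0 with a warning for an empty mask).
#' @export
organ_mass <- function(m, density_g_per_cc = 1.06) {
  stopifnot(is_binary_mask(m))
  n <- mask_count(m)
  if (n == 0L) {
    warning("empty mask: mass is 0 g", call. = FALSE)
    return(0)
  }
  n * voxel_volume_ml(m) * density_g_per_cc
}

#' Voxel S-value dose kernel
#'
#' A centred 3D table of S-values: absorbed dose (Gy) to a target voxel per
#' unit cumulated activity (Bq s) in the source voxel at the centre. Values
#' are non-negative, the centre element is the maximum, and the kernel
#' spacing must match the cumulated-activity map it is convolved with.
#'
#' @param values numeric 3D array with odd extents.
#' @param spacing_mm voxel spacing of the kernel (mm).
#' @param provenance free-text tag recording where the kernel came from.
#' @return An object of class `dose_kernel`.
#' @export
dose_kernel <- function(values, spacing_mm, provenance = "user") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("kernel values must be a 3D array", call. = FALSE)
  d <- dim(values)
  if (any(d %% 2L == 0L))
    stop("kernel extents must be odd so the source voxel is centred", call. = FALSE)
  if (any(values < 0))
    stop("S-values must be non-negative", call. = FALSE)
  ctr <- values[(d[1] + 1) / 2, (d[2] + 1) / 2, (d[3] + 1) / 2]
  if (ctr < max(values))
    stop("the central S-value must be the kernel maximum", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive values", call. = FALSE)
  structure(list(values = values, spacing_mm = spacing_mm,
                 provenance = provenance), class = "dose_kernel")
}

#' @export
print.dose_kernel <- function(x, ...) {
  cat(sprintf("<dose_kernel> %s  extent %s  spacing %s mm  s0 = %.4g Gy/(Bq s)\n",
              x$provenance, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              max(x$values)))
  invisible(x)
}

# J per MeV
MEV_TO_J <- 1.602176634e-13

#' Local energy-deposition kernel
#'
#' A single-voxel kernel assuming all emitted electron energy is absorbed in
#' the source voxel: `s0 = E (J) / voxel mass (kg)`. For 177Lu the mean beta
#' plus conversion/Auger electron energy per decay is about 0.1479 MeV and
#' the electron range is below typical SPECT voxel sizes, which makes local
#' deposition a physically sensible default when no published voxel S-value
#' table is supplied.
#'
#' @param spacing_mm voxel spacing (mm).
#' @param energy_per_decay_MeV deposited energy per decay (MeV); default the
#'   177Lu mean electron energy, overridable via
#'   `options(voxdose.lu177_electron_MeV = ...)`.
#' @param density_g_per_cc medium density (g/cc).
#' @return A `dose_kernel` of extent 1 x 1 x 1.
#' @export
local_deposition_kernel <- function(spacing_mm,
                                    energy_per_decay_MeV =
                                      getOption("voxdose.lu177_electron_MeV", 0.1479),
                                    density_g_per_cc = 1.06) {
  spacing_mm <- as.numeric(spacing_mm)
  if (any(spacing_mm <= 0) || energy_per_decay_MeV < 0 || density_g_per_cc <= 0)
    stop("spacing and density must be positive, energy non-negative", call. = FALSE)
  vox_mass_kg <- prod(spacing_mm) / 1000 * density_g_per_cc / 1000
  s0 <- energy_per_decay_MeV * MEV_TO_J / vox_mass_kg
  dose_kernel(array(s0, c(1L, 1L, 1L)), spacing_mm,
              provenance = sprintf("local deposition, E = %.4g MeV",
                                   energy_per_decay_MeV))
}

#' Read a voxel S-value kernel from CSV
#'
#' The CSV dialect: a header row `ix,iy,iz,s_Gy_per_Bq_s` with integer voxel
#' offsets relative to the source voxel, optionally preceded by a comment
#' line `# spacing_mm: dx dy dz`. With `octant = TRUE` the file stores only
#' non-negative offsets and the kernel is completed by mirror symmetry.
#'
#' @param path CSV path.
#' @param spacing_mm kernel spacing; required unless recorded in the file
#'   comment.
#' @param octant whether the file stores a single octant.
#' @return A `dose_kernel`.
#' @export
load_kernel <- function(path, spacing_mm = NULL, octant = FALSE) {
  if (!file.exists(path)) stop("kernel file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*spacing_mm:", first)) {
    sp <- as.numeric(strsplit(sub("^#\\s*spacing_mm:\\s*", "", first), "\\s+")[[1]])
    if (is.null(spacing_mm)) spacing_mm <- sp
  }
  if (is.null(spacing_mm))
    stop("kernel spacing not recorded in file; pass `spacing_mm`", call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("ix", "iy", "iz", "s_Gy_per_Bq_s")
  if (!all(need %in% names(df)))
    stop("kernel CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (any(df$s_Gy_per_Bq_s < 0))
    stop("S-values must be non-negative", call. = FALSE)
  if (octant) {
    if (any(df$ix < 0 | df$iy < 0 | df$iz < 0))
      stop("octant kernel files must use non-negative offsets", call. = FALSE)
    full <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      sx <- unique(c(df$ix[i], -df$ix[i]))
      sy <- unique(c(df$iy[i], -df$iy[i]))
      sz <- unique(c(df$iz[i], -df$iz[i]))
      cbind(expand.grid(ix = sx, iy = sy, iz = sz),
            s_Gy_per_Bq_s = df$s_Gy_per_Bq_s[i])
    }))
    df <- full
  }
  r <- c(max(abs(df$ix)), max(abs(df$iy)), max(abs(df$iz)))
  d <- 2L * r + 1L
  vals <- array(0, d)
  vals[cbind(df$ix + r[1] + 1L, df$iy + r[2] + 1L, df$iz + r[3] + 1L)] <-
    df$s_Gy_per_Bq_s
  if (!any(df$ix == 0 & df$iy == 0 & df$iz == 0))
    stop("kernel CSV is missing the central (0,0,0) S-value", call. = FALSE)
  dose_kernel(vals, spacing_mm, provenance = paste("file:", basename(path)))
}

#' Write a voxel S-value kernel to CSV
#'
#' Writes the dialect read by [load_kernel()], including the spacing
#' comment. Zero entries are omitted.
#'
#' @param k a `dose_kernel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(k, path) {
  stopifnot(inherits(k, "dose_kernel"))
  d <- dim(k$values); r <- (d - 1L) / 2L
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  keep <- k$values[idx] != 0 |
    (idx[, 1] == r[1] + 1 & idx[, 2] == r[2] + 1 & idx[, 3] == r[3] + 1)
  idx <- idx[keep, , drop = FALSE]
  df <- data.frame(ix = idx[, 1] - r[1] - 1L, iy = idx[, 2] - r[2] - 1L,
                   iz = idx[, 3] - r[3] - 1L,
                   s_Gy_per_Bq_s = k$values[idx])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# spacing_mm: %s", paste(k$spacing_mm, collapse = " ")), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Distribute cumulated activity over the retrieval mask
#'
#' Builds the per-voxel cumulated-activity map that feeds the dose
#' convolution. `"organ_scaled"` (default) distributes the organ-level
#' cumulated activity proportionally to the voxel activity shares observed
#' at a reference time point — robust, and conserving the organ total by
#' construction. `"per_voxel"` fits an independent bi-exponential to every
#' in-mask voxel time course (falling back to the organ-scaled share where a
#' voxel fit fails); faithful to voxel-wise kinetics but fragile on few,
#' noisy samples.
#'
#' @param spects list of SPECT [voxel_grid]s, one per time point.
#' @param times_h acquisition times (hours), matching `spects`.
#' @param em retrieval mask (`extended_mask` or [binary_mask]).
#' @param fit the organ-level `biexp_fit`.
#' @param mode `"organ_scaled"` or `"per_voxel"`.
#' @param t_ref_h reference time point for `"organ_scaled"` (default 24 h);
#'   must match one of `times_h`.
#' @return A [voxel_grid] of kind `cumulated_Bq_s`.
#' @export
cumulated_activity_map <- function(spects, times_h, em, fit,
                                   mode = c("organ_scaled", "per_voxel"),
                                   t_ref_h = 24) {
  mode <- match.arg(mode)
  mask <- retrieval_mask(em)
  stopifnot(length(spects) == length(times_h))
  for (s in spects)
    if (!same_geometry(s, mask))
      stop("SPECT series and mask must share one grid", call. = FALSE)
  a_total <- cumulated_activity(fit)
  g <- mask$grid
  sel <- which(g$data == 1L)
  out <- array(0, dim(g$data))
  iref <- match(TRUE, abs(times_h - t_ref_h) < 1e-9)
  if (is.na(iref))
    stop("reference time ", t_ref_h, " h is not in the series", call. = FALSE)
  shares <- pmax(spects[[iref]]$data[sel], 0)
  if (sum(shares) <= 0) shares <- rep(1, length(sel))
  shares <- shares / sum(shares)
  if (mode == "organ_scaled") {
    out[sel] <- a_total * shares
  } else {
    vox_ml <- voxel_volume_ml(g)
    conc <- vapply(spects, function(s) s$data[sel], numeric(length(sel)))
    for (j in seq_along(sel)) {
      yv <- conc[j, ] * vox_ml
      av <- tryCatch({
        fv <- fit_biexponential(data.frame(t_h = times_h, activity_Bq = yv))
        cumulated_activity(fv)
      }, error = function(e) a_total * shares[j])
      out[sel[j]] <- av
    }
  }
  voxel_grid(out, g$spacing, g$origin, kind = "cumulated_Bq_s")
}

#' Convolve cumulated activity with a dose kernel
#'
#' Discrete 3D convolution of the cumulated-activity map with the voxel
#' S-value kernel (zero padding at the edges). Kernel and map spacings must
#' match; regenerate or resample the kernel otherwise. Total energy is
#' conserved up to edge truncation: sum(dose x voxel mass) equals
#' sum(cumulated activity) x the kernel's energy-per-decay equivalent.
#'
#' @param amap a [voxel_grid] of kind `cumulated_Bq_s`.
#' @param k a `dose_kernel` on the same spacing.
#' @return A [voxel_grid] of kind `dose_Gy`.
#' @export
convolve_dose <- function(amap, k) {
  stopifnot(is_voxel_grid(amap), inherits(k, "dose_kernel"))
  if (any(abs(amap$spacing - k$spacing_mm) > 1e-6))
    stop("kernel spacing (", paste(k$spacing_mm, collapse = "x"),
         " mm) does not match the activity map (",
         paste(amap$spacing, collapse = "x"),
         " mm); regenerate the kernel at the map spacing", call. = FALSE)
  if (all(dim(k$values) == 1L)) {
    dose <- amap$data * k$values[1, 1, 1]
  } else {
    dose <- conv3_fft(amap$data, k$values)
    dose[dose < 0] <- 0  # FFT round-off
  }
  voxel_grid(dose, amap$spacing, amap$origin, kind = "dose_Gy")
}

#' Mean absorbed dose over a mask
#'
#' @param d a dose [voxel_grid].
#' @param m a [binary_mask] on the same grid.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(d, m) {
  stopifnot(is_voxel_grid(d), is_binary_mask(m))
  if (!same_geometry(d, m)) stop("dose map and mask grids differ", call. = FALSE)
  if (mask_count(m) == 0L) stop("cannot average dose over an empty mask", call. = FALSE)
  mean(d$data[m$grid$data == 1L])
}

#' Cumulative dose-volume histogram
#'
#' The empirical cumulative DVH of the in-mask dose values: for each dose
#' level, the fraction of the organ volume receiving at least that dose
#' (non-increasing, starting at 1).
#'
#' @param d a dose [voxel_grid].
#' @param m a [binary_mask] on the same grid.
#' @param label organ label carried on the curve.
#' @return An object of class `dvh_curve` with fields `dose_Gy` (sorted
#'   increasing) and `volume_fraction`.
#' @export
dvh <- function(d, m, label = m$label) {
  stopifnot(is_voxel_grid(d), is_binary_mask(m))
  if (!same_geometry(d, m)) stop("dose map and mask grids differ", call. = FALSE)
  vals <- d$data[m$grid$data == 1L]
  if (length(vals) == 0L) stop("cannot build a DVH from an empty mask", call. = FALSE)
  s <- sort(vals)
  n <- length(s)
  structure(list(dose_Gy = s, volume_fraction = rev(seq_len(n)) / n,
                 label = label), class = "dvh_curve")
}

#' DVH-x metric
#'
#' `dvh_at(c, x)` is the minimum dose received by the hottest x% of the
#' organ volume: the largest dose D with volume-fraction(dose >= D) at least
#' x/100. Non-increasing in x, so DVH-70 <= DVH-30.
#'
#' @param c a `dvh_curve`.
#' @param x percent of organ volume, in (0, 100).
#' @return Dose in Gy.
#' @export
dvh_at <- function(c, x) {
  stopifnot(inherits(c, "dvh_curve"))
  if (any(x <= 0 | x >= 100)) stop("`x` must be in (0, 100)", call. = FALSE)
  n <- length(c$dose_Gy)
  desc <- rev(c$dose_Gy)
  vapply(x, function(xx) desc[ceiling(xx / 100 * n)], 0)
}
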