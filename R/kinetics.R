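#' Extend a CT mask for activity retrieval
#'
#' Compensates SPECT spill-out / partial-volume losses by growing the CT
#' mask border before activities are summed. Two semantics are provided:
#' `"dilate"` (default) performs morphological dilation by a spherical
#' structuring element of radius `margin_mm` in world units; `"gaussian"`
#' convolves the 0/1 field with an isotropic Gaussian of sigma `margin_mm`
#' and keeps voxels at or above `threshold`. Both produce a superset of the
#' base mask; a zero margin is the identity.
#'
#' @param m a [binary_mask].
#' @param mode `"dilate"` or `"gaussian"`.
#' @param margin_mm extension margin / Gaussian sigma in mm (default 3).
#' @param threshold inclusion threshold for `"gaussian"` mode (default 0.05).
#' @return An object of class `extended_mask`: `list(base, mask, mode,
#'   margin_mm)` where `mask` is the extended [binary_mask].
#' @export
expand_mask <- function(m, mode = c("dilate", "gaussian"), margin_mm = 3,
                        threshold = 0.05) {
  stopifnot(is_binary_mask(m))
  mode <- match.arg(mode)
  if (margin_mm < 0) stop("`margin_mm` must be >= 0", call. = FALSE)
  g <- m$grid
  if (margin_mm == 0) {
    ext <- m
  } else if (mode == "dilate") {
    r <- floor(margin_mm / g$spacing)
    offs <- lapply(1:3, function(ax) (-r[ax]:r[ax]) * g$spacing[ax])
    kd <- 2L * r + 1L
    q <- rep(offs[[1]]^2, times = kd[2] * kd[3]) +
      rep(rep(offs[[2]]^2, each = kd[1]), times = kd[3]) +
      rep(offs[[3]]^2, each = kd[1] * kd[2])
    se <- array(as.numeric(q <= margin_mm^2 + 1e-9), kd)
    hits <- conv3_fft(array(as.numeric(g$data), dim(g$data)), se)
    out <- array(as.integer(hits > 0.5), dim(g$data))
    out[g$data == 1L] <- 1L
    ext <- binary_mask(voxel_grid(out, g$spacing, g$origin), label = m$label)
  } else {
    blur <- gauss_blur3(array(as.numeric(g$data), dim(g$data)),
                        margin_mm, g$spacing)
    out <- array(as.integer(blur >= threshold), dim(g$data))
    out[g$data == 1L] <- 1L
    ext <- binary_mask(voxel_grid(out, g$spacing, g$origin), label = m$label)
  }
  structure(list(base = m, mask = ext, mode = mode, margin_mm = margin_mm),
            class = "extended_mask")
}

is_extended_mask <- function(x) inherits(x, "extended_mask")

# the retrieval mask of an extended_mask / binary_mask argument
retrieval_mask <- function(em) {
  if (is_extended_mask(em)) em$mask
  else if (is_binary_mask(em)) em
  else stop("expected an extended_mask or binary_mask", call. = FALSE)
}

#' Total organ activity within an (extended) mask
#'
#' Sums activity concentration times voxel volume over the retrieval mask.
#' SPECT and mask must live on one grid; resample first otherwise.
#'
#' @param spect a [voxel_grid] of kind `activity_conc_Bq_per_ml`.
#' @param em an `extended_mask` from [expand_mask()] or a plain
#'   [binary_mask].
#' @return Activity in Bq.
#' @export
extract_activity <- function(spect, em) {
  stopifnot(is_voxel_grid(spect))
  mask <- retrieval_mask(em)
  if (!same_geometry(spect, mask))
    stop("SPECT and mask geometries differ; resample first", call. = FALSE)
  sum(spect$data * mask$grid$data) * voxel_volume_ml(spect)
}

#' Fit a bi-exponential time-activity curve
#'
#' Fits `A(t) = A1 exp(-lambda1 t) + A2 exp(-lambda2 t)` to organ-activity
#' samples by nonlinear least squares (Levenberg-Marquardt), initialised by
#' curve stripping: the terminal slope over the last two samples seeds the
#' slow component, and the head residuals seed the fast one. When stripping
#' leaves non-positive head residuals — a mono-exponential washout — the fit
#' falls back to a single exponential, reported with `A2 = 0` and `lambda2`
#' set to the fitted decay constant. Decay constants are kept strictly
#' positive so the time integral is finite, and are returned with the
#' convention `lambda1 >= lambda2`.
#'
#' @param samples data frame with columns `t_h` (hours post injection) and
#'   `activity_Bq`, at least 4 rows at distinct times for the
#'   bi-exponential model.
#' @param model `"auto"` (bi-exponential with mono fallback), `"biexp"`, or
#'   `"mono"` (allowed with as few as 2 samples).
#' @param constrain_physical if `TRUE`, bound both decay constants below by
#'   the physical 177Lu constant `log(2) /` [lu177_half_life_h()] — an
#'   effective clearance can never be slower than physical decay.
#' @param weights `"none"` (default) for unweighted least squares or
#'   `"inverse"` for `1/A` weighting.
#' @return An object of class `biexp_fit` with fields `A1_Bq`,
#'   `lambda1_per_h`, `A2_Bq`, `lambda2_per_h`, `residual_norm`, `path`.
#' @export
fit_biexponential <- function(samples, model = c("auto", "biexp", "mono"),
                              constrain_physical = FALSE,
                              weights = c("none", "inverse")) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  if (!is.data.frame(samples) || !all(c("t_h", "activity_Bq") %in% names(samples)))
    stop("`samples` must have columns t_h and activity_Bq", call. = FALSE)
  ord <- order(samples$t_h)
  t <- samples$t_h[ord]; y <- samples$activity_Bq[ord]
  if (any(t < 0) || any(y < 0))
    stop("times and activities must be non-negative", call. = FALSE)
  if (anyDuplicated(t)) stop("sample times must be distinct", call. = FALSE)
  if (all(y == 0)) stop("all activities are zero; nothing to fit", call. = FALSE)
  if (model != "mono" && length(t) < 4L)
    stop("bi-exponential fitting needs >= 4 samples; use model = \"mono\"",
         call. = FALSE)
  if (model == "mono" && length(t) < 2L)
    stop("mono-exponential fitting needs >= 2 samples", call. = FALSE)
  lam_min <- if (constrain_physical) log(2) / lu177_half_life_h() else 1e-6
  w <- if (weights == "inverse") 1 / pmax(y, max(y) * 1e-6) else rep(1, length(y))

  if (model != "mono") {
    init <- strip_init(t, y)
    if (!is.null(init)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t),
          start = init, weights = w,
          lower = c(A1 = 0, l1 = lam_min, A2 = 0, l2 = lam_min),
          control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                               ptol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        p <- stats::coef(fit)
        return(biexp_fit_obj(p[["A1"]], p[["l1"]], p[["A2"]], p[["l2"]],
                             t, y, path = "biexp"))
      }
      if (model == "biexp")
        stop("bi-exponential fit failed to converge", call. = FALSE)
    } else if (model == "biexp") {
      stop("curve stripping found no bi-exponential structure; ",
           "use model = \"auto\" or \"mono\"", call. = FALSE)
    }
  }

  # mono-exponential path
  pos <- y > 0
  lmfit <- stats::lm(log(y[pos]) ~ t[pos])
  l0 <- max(-unname(stats::coef(lmfit)[2]), lam_min)
  a0 <- exp(unname(stats::coef(lmfit)[1]))
  fit <- minpack.lm::nlsLM(y ~ A1 * exp(-l1 * t),
                           start = list(A1 = a0, l1 = l0), weights = w,
                           lower = c(A1 = 0, l1 = lam_min),
                           control = minpack.lm::nls.lm.control(maxiter = 500,
                                                                ftol = 1e-14,
                                                                ptol = 1e-14))
  p <- stats::coef(fit)
  biexp_fit_obj(p[["A1"]], p[["l1"]], 0, p[["l1"]], t, y, path = "mono")
}

# curve-stripping initial values, or NULL when the tail/head structure is
# not bi-exponential (non-positive residuals or inverted rates)
strip_init <- function(t, y) {
  n <- length(t)
  if (y[n] <= 0 || y[n - 1] <= 0) return(NULL)
  l2 <- log(y[n - 1] / y[n]) / (t[n] - t[n - 1])
  if (l2 <= 0) return(NULL)
  A2 <- y[n] * exp(l2 * t[n])
  r <- y[1:2] - A2 * exp(-l2 * t[1:2])
  # head residuals at or below numerical noise mean a mono-exponential washout
  if (any(r <= 1e-6 * y[1:2])) return(NULL)
  l1 <- log(r[1] / r[2]) / (t[2] - t[1])
  if (l1 <= l2) l1 <- 2 * l2
  A1 <- r[1] * exp(l1 * t[1])
  list(A1 = A1, l1 = l1, A2 = A2, l2 = l2)
}

biexp_fit_obj <- function(A1, l1, A2, l2, t, y, path) {
  if (l2 > l1) { tmp <- c(A1, l1); A1 <- A2; l1 <- l2; A2 <- tmp[1]; l2 <- tmp[2] }
  pred <- A1 * exp(-l1 * t) + A2 * exp(-l2 * t)
  structure(list(A1_Bq = unname(A1), lambda1_per_h = unname(l1),
                 A2_Bq = unname(A2), lambda2_per_h = unname(l2),
                 residual_norm = sqrt(sum((y - pred)^2)), path = path,
                 samples = data.frame(t_h = t, activity_Bq = y)),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit> [%s] A(t) = %.4g exp(-%.4g t) + %.4g exp(-%.4g t) Bq (t in h)\n",
              x$path, x$A1_Bq, x$lambda1_per_h, x$A2_Bq, x$lambda2_per_h))
  cat(sprintf("  cumulated activity %.4g Bq s, residual norm %.3g\n",
              cumulated_activity(x), x$residual_norm))
  invisible(x)
}

#' Evaluate a fitted time-activity curve
#'
#' @param fit a `biexp_fit`.
#' @param t_h hours post injection (vectorised).
#' @return Activity in Bq.
#' @export
biexp_predict <- function(fit, t_h) {
  stopifnot(inherits(fit, "biexp_fit"))
  fit$A1_Bq * exp(-fit$lambda1_per_h * t_h) +
    fit$A2_Bq * exp(-fit$lambda2_per_h * t_h)
}

#' Cumulated activity of a fitted curve
#'
#' The analytic time integral of the bi-exponential,
#' `A1/lambda1 + A2/lambda2` in Bq h, converted to Bq s. `t_max_h` truncates
#' the integral at a finite horizon instead of integrating to infinity.
#'
#' @param fit a `biexp_fit`.
#' @param t_max_h upper integration limit in hours (default `Inf`).
#' @return Cumulated activity in Bq s.
#' @export
cumulated_activity <- function(fit, t_max_h = Inf) {
  stopifnot(inherits(fit, "biexp_fit"))
  if (fit$lambda1_per_h <= 0 || fit$lambda2_per_h <= 0)
    stop("decay constants must be strictly positive for a finite integral",
         call. = FALSE)
  term <- function(A, l) {
    if (is.finite(t_max_h)) A / l * (1 - exp(-l * t_max_h)) else A / l
  }
  3600 * (term(fit$A1_Bq, fit$lambda1_per_h) + term(fit$A2_Bq, fit$lambda2_per_h))
}
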