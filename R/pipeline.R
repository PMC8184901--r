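#' Case configuration for an end-to-end dosimetry run
#'
#' Bundles every choice a run depends on: the synthetic patient, the
#' segmentation route that produces the organ masks, the border-extension
#' settings for activity retrieval, the fit constraints, the dose kernel and
#' the reference time point. All randomness is controlled by the phantom
#' seed, so a configuration determines its outputs exactly.
#'
#' @param phantom a [phantom_spec] describing the patient.
#' @param method mask provenance for activity retrieval:
#'   `"ai"` (automated CT segmentation via the backend), `"expert_ct"`
#'   (ground-truth CT masks plus border extension, the CT-mask expert
#'   route), or `"expert_spect"` (threshold segmentation directly on each
#'   SPECT, seeded by the extended ground-truth mask).
#' @param seg_mode `"axial"`, `"sagittal"`, `"coronal"` or `"consensus"`
#'   (three-plane majority vote); used by the `"ai"` method.
#' @param backend a `segmenter_backend`; default [reference_backend()].
#' @param expand_mode,margin_mm border-extension semantics and margin (mm).
#' @param spect_frac threshold fraction for the `"expert_spect"` method.
#' @param kernel a `dose_kernel`, or `NULL` for the local-deposition default
#'   at the phantom spacing.
#' @param t_ref_h reference time point for the cumulated-activity map.
#' @param amap_mode `"organ_scaled"` or `"per_voxel"`.
#' @param constrain_physical passed to [fit_biexponential()].
#' @return An object of class `case_config`.
#' @export
case_config <- function(phantom,
                        method = c("ai", "expert_ct", "expert_spect"),
                        seg_mode = "axial",
                        backend = reference_backend(),
                        expand_mode = "dilate",
                        margin_mm = 3,
                        spect_frac = 0.42,
                        kernel = NULL,
                        t_ref_h = 24,
                        amap_mode = "organ_scaled",
                        constrain_physical = FALSE) {
  stopifnot(inherits(phantom, "phantom_spec"))
  method <- match.arg(method)
  if (!seg_mode %in% c("axial", "sagittal", "coronal", "consensus"))
    stop("seg_mode must be a plane or 'consensus'", call. = FALSE)
  structure(list(phantom = phantom, method = method, seg_mode = seg_mode,
                 backend = backend, expand_mode = expand_mode,
                 margin_mm = margin_mm, spect_frac = spect_frac,
                 kernel = kernel, t_ref_h = t_ref_h, amap_mode = amap_mode,
                 constrain_physical = constrain_physical),
            class = "case_config")
}

# split a (possibly multi-organ) segmentation mask into per-organ masks by
# matching connected components to the truth masks (largest overlap)
split_by_truth <- function(segmask, truth_masks) {
  lab <- label_components(segmask$grid$data)
  out <- list()
  for (nm in names(truth_masks)) {
    tm <- truth_masks[[nm]]$grid$data
    if (max(lab) == 0L) {
      comp <- array(0L, dim(lab))
    } else {
      ov <- vapply(seq_len(max(lab)), function(l) sum(lab == l & tm == 1L), 0)
      comp <- if (max(ov) == 0) array(0L, dim(lab))
      else array(as.integer(lab == which.max(ov)), dim(lab))
    }
    out[[nm]] <- binary_mask(voxel_grid(comp, segmask$grid$spacing,
                                        segmask$grid$origin), label = nm)
  }
  out
}

#' Run one dosimetry case end to end
#'
#' Generates the synthetic acquisition series, obtains per-organ masks by
#' the configured route, extends them for activity retrieval, extracts the
#' organ activities at each time point, fits the bi-exponential
#' time-activity curve, integrates it to cumulated activity, distributes it
#' over the retrieval mask, convolves with the dose kernel and summarises
#' mass, mean dose (over the retrieval mask, i.e. the SPECT organ mask) and
#' DVH-30/DVH-70 per organ. Deterministic for a fixed configuration.
#'
#' @param cfg a [case_config].
#' @return An object of class `case_summary`: a list with `config` echo and
#'   one entry per organ under `organs` (`mass_g`, `activities`,
#'   `fit`, `cumulated_Bq_s`, `mean_dose_Gy`, `dvh30_Gy`, `dvh70_Gy`,
#'   `retrieval_voxels`, `dice_vs_truth`).
#' @export
run_case <- function(cfg) {
  stopifnot(inherits(cfg, "case_config"))
  series <- make_series(cfg$phantom)
  times <- cfg$phantom$time_points_h
  spects <- lapply(series$acquisitions, `[[`, "spect")
  kernel <- cfg$kernel
  if (is.null(kernel))
    kernel <- local_deposition_kernel(cfg$phantom$spacing_mm)

  # organ masks on the CT grid, by configured provenance
  if (cfg$method == "ai") {
    seg <- if (cfg$seg_mode == "consensus") {
      segment_consensus(series$ct, cfg$backend)
    } else {
      r <- segment_plane(series$ct, cfg$seg_mode, cfg$backend)
      if (any(r$success) && !all(r$success))
        r$mask <- interpolate_missing(r$mask, r$success, cfg$seg_mode)
      r
    }
    organ_masks <- split_by_truth(seg$mask, series$masks)
  } else {
    organ_masks <- series$masks
  }

  organs <- list()
  for (nm in names(organ_masks)) {
    m <- organ_masks[[nm]]
    mass <- organ_mass(m)
    if (cfg$method == "expert_spect") {
      # per-time-point masks directly on the SPECT, seeded near the organ
      seed <- expand_mask(series$masks[[nm]], mode = cfg$expand_mode,
                          margin_mm = max(cfg$margin_mm, 6))$mask
      acts <- vapply(seq_along(times), function(i) {
        sm <- spect_threshold_segment(spects[[i]], frac = cfg$spect_frac,
                                      seed_region = seed, label = nm)
        extract_activity(spects[[i]], sm)
      }, 0)
      retr <- expand_mask(series$masks[[nm]], mode = cfg$expand_mode,
                          margin_mm = cfg$margin_mm)
    } else {
      retr <- expand_mask(m, mode = cfg$expand_mode, margin_mm = cfg$margin_mm)
      acts <- vapply(spects, extract_activity, 0, em = retr)
    }
    fit <- fit_biexponential(data.frame(t_h = times, activity_Bq = acts),
                             constrain_physical = cfg$constrain_physical)
    a_cum <- cumulated_activity(fit)
    amap <- cumulated_activity_map(spects, times, retr, fit,
                                   mode = cfg$amap_mode, t_ref_h = cfg$t_ref_h)
    dmap <- convolve_dose(amap, kernel)
    curve <- dvh(dmap, retr$mask)
    organs[[nm]] <- list(
      mass_g = mass,
      activities = data.frame(t_h = times, activity_Bq = acts),
      fit = fit,
      cumulated_Bq_s = a_cum,
      mean_dose_Gy = mean_dose(dmap, retr$mask),
      dvh30_Gy = dvh_at(curve, 30),
      dvh70_Gy = dvh_at(curve, 70),
      retrieval_voxels = mask_count(retr$mask),
      dice_vs_truth = dice(m, series$masks[[nm]]))
  }
  structure(list(method = cfg$method, seg_mode = cfg$seg_mode,
                 margin_mm = cfg$margin_mm, seed = cfg$phantom$seed,
                 time_points_h = times, organs = organs),
            class = "case_summary")
}

#' Serialise a case summary to JSON
#'
#' Writes the per-organ results plus the configuration echo (method,
#' margins, seed, time points) so a run can be regenerated exactly.
#'
#' @param summary a `case_summary` from [run_case()].
#' @param path output JSON path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_summary <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "case_summary"))
  payload <- list(schema = "voxdose/case_summary/1",
                  method = summary$method, seg_mode = summary$seg_mode,
                  margin_mm = summary$margin_mm, seed = summary$seed,
                  time_points_h = summary$time_points_h,
                  organs = lapply(summary$organs, function(o) {
                    list(mass_g = o$mass_g,
                         activities = o$activities,
                         fit = o$fit[c("A1_Bq", "lambda1_per_h", "A2_Bq",
                                       "lambda2_per_h", "residual_norm", "path")],
                         cumulated_Bq_s = o$cumulated_Bq_s,
                         mean_dose_Gy = o$mean_dose_Gy,
                         dvh30_Gy = o$dvh30_Gy, dvh70_Gy = o$dvh70_Gy,
                         dice_vs_truth = o$dice_vs_truth)
                  }))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Compare two case summaries organ by organ
#'
#' Builds the long-format records for masses and mean doses from an
#' automated and a reference run of the same patient and delegates to the
#' report module's comparison arithmetic.
#'
#' @param ai_summary,ex_summary `case_summary` objects over the same organs.
#' @param patient patient identifier used in the records.
#' @return `list(mass, dose)` of [compare_cohort()] results.
#' @export
run_comparison <- function(ai_summary, ex_summary, patient = 1L) {
  if (!setequal(names(ai_summary$organs), names(ex_summary$organs)))
    stop("the two runs cover different organs", call. = FALSE)
  sides <- c(kidney_left = "left", kidney_right = "right")
  rec <- function(field) {
    do.call(rbind, lapply(names(ai_summary$organs), function(nm) {
      side <- if (nm %in% names(sides)) sides[[nm]] else nm
      data.frame(patient = patient, side = side,
                 provenance = c("ai", "expert"),
                 value = c(ai_summary$organs[[nm]][[field]],
                           ex_summary$organs[[nm]][[field]]))
    }))
  }
  list(mass = compare_cohort(rec("mass_g")),
       dose = compare_cohort(rec("mean_dose_Gy")))
}

#' Closed-form truth for a phantom organ
#'
#' The analytic cumulated activity of the generating kinetics and the
#' corresponding mean dose over a given averaging mask under local energy
#' deposition: cumulated activity x energy per decay / mask mass. This is
#' the oracle the pipeline's estimate is judged against.
#'
#' @param spec the [phantom_spec].
#' @param organ_name organ to evaluate.
#' @param mask the averaging [binary_mask] (e.g. the retrieval mask); may be
#'   omitted when `mass_g` is given directly.
#' @param mass_g mass of the averaging region in grams; overrides `mask`
#'   (use `retrieval_voxels x voxel volume x density` from a run summary so
#'   pipeline and oracle average over the same region).
#' @param energy_per_decay_MeV deposited energy per decay.
#' @param density_g_per_cc tissue density.
#' @return `list(cumulated_Bq_s, mean_dose_Gy)`.
#' @export
phantom_truth <- function(spec, organ_name, mask = NULL, mass_g = NULL,
                          energy_per_decay_MeV =
                            getOption("voxdose.lu177_electron_MeV", 0.1479),
                          density_g_per_cc = 1.06) {
  organ <- spec$organs[[organ_name]]
  if (is.null(organ)) stop("unknown organ: ", organ_name, call. = FALSE)
  a_cum <- 3600 * (organ$A1_Bq / organ$lambda1_per_h +
                     organ$A2_Bq / organ$lambda2_per_h)
  if (is.null(mass_g)) {
    if (is.null(mask)) stop("give either `mask` or `mass_g`", call. = FALSE)
    mass_g <- organ_mass(mask, density_g_per_cc)
  }
  list(cumulated_Bq_s = a_cum,
       mean_dose_Gy = a_cum * energy_per_decay_MeV * MEV_TO_J / (mass_g / 1000))
}

#' Relative mean-dose error of a run against the phantom closed form
#'
#' Compares a run's mean dose for one organ with the analytic
#' `cumulated activity x energy per decay / mass` oracle evaluated over the
#' run's own retrieval mask, so under local energy deposition the error
#' reduces to the activity-capture and fit error.
#'
#' @param summary a `case_summary`.
#' @param spec the generating [phantom_spec].
#' @param organ_name organ to evaluate.
#' @return Signed relative error of the mean dose.
#' @export
mean_dose_error <- function(summary, spec, organ_name) {
  o <- summary$organs[[organ_name]]
  if (is.null(o)) stop("organ not in summary: ", organ_name, call. = FALSE)
  mass_g <- o$retrieval_voxels * prod(spec$spacing_mm) / 1000 * 1.06
  tr <- phantom_truth(spec, organ_name, mass_g = mass_g)
  o$mean_dose_Gy / tr$mean_dose_Gy - 1
}
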