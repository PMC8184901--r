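#' Signed relative difference, integer-rounded
#'
#' `round(100 (ai - ex) / ex)` to the nearest integer, half away from zero.
#' The denominator is always the expert value (treated as ground truth), so
#' a negative result means underestimation by the automated method.
#' Missing values propagate as `NA`.
#'
#' @param ai automated-method value.
#' @param ex expert value (> 0).
#' @return Signed percent difference, integer (vectorised).
#' @export
relative_difference <- function(ai, ex) {
  out <- rep(NA_real_, length(ex))
  have <- !(is.na(ai) | is.na(ex))
  if (any(ex[have] <= 0))
    stop("expert reference values must be > 0", call. = FALSE)
  out[have] <- round_half_away(100 * (ai[have] - ex[have]) / ex[have])
  out
}

#' Per-patient mean absolute difference
#'
#' Mean of the absolute integer-rounded per-side differences; with both
#' kidneys present this is an exact multiple of 0.5, and a patient with a
#' single kidney contributes that side's magnitude unchanged.
#'
#' @param di_left,di_right signed integer per-side differences (`NA` for a
#'   missing organ).
#' @return Mean absolute difference in percent.
#' @export
patient_mean <- function(di_left, di_right) {
  v <- c(di_left, di_right)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("both sides missing for this patient", call. = FALSE)
  mean(abs(v))
}

#' Cohort average of per-patient means
#'
#' Arithmetic mean of the per-patient mean differences, rounded to one
#' decimal (half away from zero).
#'
#' @param patient_means numeric vector of per-patient means (percent).
#' @return Cohort average in percent, one decimal.
#' @export
cohort_average <- function(patient_means) {
  if (length(patient_means) == 0L) stop("empty cohort", call. = FALSE)
  round_half_away(mean(patient_means), 1)
}

#' Spill-out underestimation analysis
#'
#' The magnitude of the dose underestimation `100 (ex - ai) / ex` per
#' kidney, reported at two decimals with truncation toward zero, and their
#' average at one decimal — the arithmetic used when a wider spill-out
#' margin is assessed against the expert doses.
#'
#' @param doses_ai automated-method mean doses (Gy), one per side.
#' @param doses_ex expert mean doses (Gy), same length.
#' @return `list(per_side_pct, average_pct)`.
#' @export
spillout_analysis <- function(doses_ai, doses_ex) {
  if (any(doses_ai <= 0) || any(doses_ex <= 0))
    stop("doses must be positive", call. = FALSE)
  raw <- 100 * (doses_ex - doses_ai) / doses_ex
  per_side <- trunc(abs(raw) * 100) / 100
  list(per_side_pct = per_side,
       average_pct = round_half_away(mean(abs(raw)), 1))
}

# validate a long-format record set: patient, side, provenance, value
check_records <- function(records) {
  need <- c("patient", "side", "provenance", "value")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(records[c("patient", "side", "provenance")]))
    stop("duplicate (patient, side, provenance) records", call. = FALSE)
  if (!all(records$provenance %in% c("expert", "ai")))
    stop("provenance must be 'expert' or 'ai'", call. = FALSE)
  if (!all(records$side %in% c("left", "right")))
    stop("side must be 'left' or 'right'", call. = FALSE)
  records
}

#' Compare automated and expert values across a cohort
#'
#' Regenerates the comparison arithmetic of a mass or dose table from
#' long-format records: per-side signed integer differences, per-patient
#' mean absolute differences (missing organs excluded, never zero-filled)
#' and the cohort average. A rounding trace records the raw unrounded
#' percentage behind every cell so printed-table inconsistencies can be
#' audited rather than chased.
#'
#' @param records data frame with columns `patient`, `side`
#'   (`"left"`/`"right"`), `provenance` (`"expert"`/`"ai"`), `value`
#'   (`NA` = organ missing).
#' @return `list(table, patient_mean, cohort_average_pct, trace)`: `table`
#'   has one row per patient with per-side expert/ai values and differences.
#' @export
compare_cohort <- function(records) {
  records <- check_records(records)
  patients <- sort(unique(records$patient))
  pick <- function(p, s, prov) {
    v <- records$value[records$patient == p & records$side == s &
                         records$provenance == prov]
    if (length(v) == 0L) NA_real_ else v
  }
  rows <- lapply(patients, function(p) {
    exl <- pick(p, "left", "expert"); exr <- pick(p, "right", "expert")
    ail <- pick(p, "left", "ai"); air <- pick(p, "right", "ai")
    dil <- relative_difference(ail, exl); dir_ <- relative_difference(air, exr)
    data.frame(patient = p, ex_left = exl, ex_right = exr,
               ai_left = ail, ai_right = air,
               di_left = dil, di_right = dir_,
               mean_di = patient_mean(dil, dir_))
  })
  tab <- do.call(rbind, rows)
  raw <- function(ai, ex) ifelse(is.na(ai) | is.na(ex), NA, 100 * (ai - ex) / ex)
  trace <- data.frame(patient = rep(tab$patient, 2),
                      side = rep(c("left", "right"), each = nrow(tab)),
                      raw_pct = c(raw(tab$ai_left, tab$ex_left),
                                  raw(tab$ai_right, tab$ex_right)),
                      rounded = c(tab$di_left, tab$di_right))
  list(table = tab,
       patient_mean = stats::setNames(tab$mean_di, tab$patient),
       cohort_average_pct = cohort_average(tab$mean_di),
       trace = trace)
}

#' Render a cohort comparison in the wide table layout
#'
#' Columns are patients plus a final average column; rows are the expert and
#' automated values per side, the per-side differences and the per-patient
#' mean difference. Missing organs print as `"*"` and negative differences
#' carry the `"(-)"` underestimation tag in text output.
#'
#' @param records long-format records as in [compare_cohort()].
#' @param quantity row-label stem, e.g. `"Mass(g)"` or `"Dose(Gy)"`.
#' @return A character data frame in the wide layout.
#' @export
render_tables <- function(records, quantity = "value") {
  cmp <- compare_cohort(records)
  tab <- cmp$table
  fmt_v <- function(v) ifelse(is.na(v), "*", format(v, trim = TRUE))
  fmt_d <- function(d) ifelse(is.na(d), "*",
                              ifelse(d < 0, paste0("(-) ", abs(d)), format(d, trim = TRUE)))
  avg <- function(v) if (all(is.na(v))) "*" else
    format(round_half_away(mean(v, na.rm = TRUE), 1), trim = TRUE)
  body <- rbind(
    c(fmt_v(tab$ex_left), avg(tab$ex_left)),
    c(fmt_v(tab$ex_right), avg(tab$ex_right)),
    c(fmt_v(tab$ai_left), avg(tab$ai_left)),
    c(fmt_v(tab$ai_right), avg(tab$ai_right)),
    c(fmt_d(tab$di_left), avg(abs(tab$di_left))),
    c(fmt_d(tab$di_right), avg(abs(tab$di_right))),
    c(format(tab$mean_di, trim = TRUE), format(cmp$cohort_average_pct)))
  out <- data.frame(row = c(paste0("L Kid Ex ", quantity),
                            paste0("R Kid Ex ", quantity),
                            paste0("L Kid AI ", quantity),
                            paste0("R Kid AI ", quantity),
                            "L Kid Di(%)", "R Kid Di(%)", "Mean Di(%)"),
                    body, check.names = FALSE)
  names(out) <- c("row", tab$patient, "Avg")
  out
}

#' Published eight-patient cohort records
#'
#' Long-format kidney masses (g) and mean absorbed doses (Gy) for an
#' eight-patient 177Lu-DOTATOC cohort, each quantity reported for expert and
#' automated (AI) segmentation; one patient lacks the right kidney. Shipped
#' as package data so the comparison arithmetic can be regenerated from the
#' published input values.
#'
#' @param quantity `"mass_g"` or `"mean_dose_Gy"`.
#' @return Long-format records data frame (see [compare_cohort()]).
#' @export
cohort_records <- function(quantity = c("mass_g", "mean_dose_Gy")) {
  quantity <- match.arg(quantity)
  file <- switch(quantity, mass_g = "cohort_masses.csv",
                 mean_dose_Gy = "cohort_doses.csv")
  path <- system.file("extdata", file, package = "voxdose", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
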