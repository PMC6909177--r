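#' Isodose-volume curve
#'
#' The cumulative volume enclosed by each isodose surface, indexed by isodose
#' level expressed as a percent of the plan's *maximum* dose.  Percents must be
#' strictly increasing and volumes non-increasing (a higher isodose surface
#' encloses no more volume than a lower one).
#'
#' @param percent Isodose levels, percent of maximum dose, strictly
#'   increasing, in (0, 100].
#' @param volume Enclosed volumes in cc, non-increasing, all >= 0.
#' @return An object of class `isodose_curve` (a data.frame with columns
#'   `percent`, `volume`).
#' @export
isodose_curve <- function(percent, volume) {
  percent <- as.numeric(percent); volume <- as.numeric(volume)
  if (length(percent) < 2 || length(percent) != length(volume)) {
    stop("curve needs >= 2 (percent, volume) points of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(percent)) || any(percent <= 0) || any(percent > 100)) {
    stop("curve percents must lie in (0, 100]", call. = FALSE)
  }
  if (any(diff(percent) <= 0)) {
    stop("curve percents must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(volume)) || any(volume < 0)) {
    stop("curve volumes must be >= 0", call. = FALSE)
  }
  if (any(diff(volume) > 0)) {
    stop("curve volumes must be non-increasing in percent", call. = FALSE)
  }
  structure(data.frame(percent = percent, volume = volume),
            class = c("isodose_curve", "data.frame"))
}

#' Express a dose as a percent of the plan maximum
#'
#' With the prescription dose sitting at `pidl` percent of the plan maximum,
#' a dose D corresponds to `100 * D * (pidl/100) / pd` percent of maximum.
#' With the prescription isodose line at 80%, 12 Gy maps to 64, 53.3, 45.7 and
#' 40% of maximum for prescription doses of 15, 18, 21 and 24 Gy.
#'
#' @param dose Dose of interest, Gy (> 0).
#' @param pd Prescription dose, Gy (> 0).
#' @param pidl Prescription isodose line, percent of maximum, in (0, 100].
#' @return Percent of maximum dose (errors if above 100, i.e. the dose
#'   exceeds the plan maximum).
#' @export
isodose_percent_for_dose <- function(dose, pd, pidl) {
  stopifnot(all(dose > 0), all(pd > 0), all(pidl > 0), all(pidl <= 100))
  pct <- 100 * dose * (pidl / 100) / pd
  if (any(pct > 100 + 1e-9)) {
    stop(sprintf("dose %g Gy exceeds the plan maximum (%g Gy)",
                 dose[which(pct > 100)[1]],
                 (pd / (pidl / 100))[which(pct > 100)[1]]), call. = FALSE)
  }
  pmin(pct, 100)
}

#' Express a dose as a percent of the prescription dose
#'
#' `100 * dose / pd`: e.g. 12 Gy is 50% of a 24 Gy prescription and 80% of a
#' 15 Gy prescription.  This is the convention in which the treatment planning
#' system's DVH is binned; [isodose_percent_for_dose()] gives the
#' percent-of-maximum convention used to index [isodose_curve()]s.
#'
#' @inheritParams isodose_percent_for_dose
#' @return Percent of prescription dose.
#' @export
isodose_percent_of_pd <- function(dose, pd) {
  stopifnot(all(dose > 0), all(pd > 0))
  100 * dose / pd
}

#' Enclosed volume at a dose, read off an isodose-volume curve
#'
#' Maps `dose` to a percent of the plan maximum via
#' [isodose_percent_for_dose()] and evaluates the curve there.  The default
#' mode interpolates linearly between curve nodes; `mode = "bin1pct"`
#' emulates a planning system whose DVH reports doses in steps of 1% of the
#' prescription dose, by first rounding the queried dose to the nearest 1%
#' of `pd`.
#'
#' @param curve An [isodose_curve()].
#' @param dose Dose of interest, Gy.
#' @param pd Prescription dose of the (possibly rescaled) plan, Gy.
#' @param pidl Prescription isodose line, percent of maximum.
#' @param mode `"interp"` (default) or `"bin1pct"`.
#' @return Enclosed volume in cc.
#' @export
tv_at_dose <- function(curve, dose, pd, pidl, mode = c("interp", "bin1pct")) {
  stopifnot(inherits(curve, "isodose_curve"))
  mode <- match.arg(mode)
  if (mode == "bin1pct") {
    # snap to the DVH's 1%-of-PD dose grid before converting
    dose <- round(isodose_percent_of_pd(dose, pd)) / 100 * pd
  }
  pct <- isodose_percent_for_dose(dose, pd, pidl)
  rng <- range(curve$percent)
  if (any(pct < rng[1] - 1e-9 | pct > rng[2] + 1e-9)) {
    stop(sprintf(
      "mapped isodose percent %.3f%% outside curve range [%g%%, %g%%]",
      pct[which(pct < rng[1] | pct > rng[2])[1]], rng[1], rng[2]),
      call. = FALSE)
  }
  approx(curve$percent, curve$volume, xout = pct, rule = 1)$y
}

#' Rescale a plan to a new prescription dose
#'
#' Changing only the prescription dose rescales the absolute dose everywhere
#' by the same factor, leaving the *relative* dose distribution - and hence
#' COV, CI, PIDL and all isodose lines - unchanged.  TV12 at the new
#' prescription dose is therefore read directly off the plan's isodose-volume
#' curve at the remapped percent, with no dose recalculation.
#'
#' @param record A [plan_record()] carrying a `curve` and `pidl`.
#' @param new_pd New prescription dose, Gy.
#' @param dose Dose level whose enclosed volume is tracked (default 12 Gy).
#' @param mode Curve evaluation mode, see [tv_at_dose()].
#' @return A `plan_record` identical to `record` except `pd = new_pd`,
#'   `tv12` re-read from the curve, and `ptv_max_dose` rescaled consistently;
#'   the base prescription dose is kept in the `base_pd` field.
#' @export
rescale_plan <- function(record, new_pd, dose = 12,
                         mode = c("interp", "bin1pct")) {
  stopifnot(inherits(record, "plan_record"))
  mode <- match.arg(mode)
  if (is.null(record$curve)) {
    stop(sprintf("plan '%s' has no isodose-volume curve; cannot rescale",
                 record$plan_id), call. = FALSE)
  }
  if (is.na(record$pidl)) {
    stop(sprintf("plan '%s' has no pidl; cannot rescale", record$plan_id),
         call. = FALSE)
  }
  out <- record
  out$pd <- new_pd
  out$tv12 <- tv_at_dose(record$curve, dose, new_pd, record$pidl, mode)
  out$ptv_max_dose <- if (is.na(record$ptv_max_dose)) NA_real_ else
    new_pd / (record$pidl / 100)
  out$base_pd <- record$pd
  out
}

#' Expand a cohort over a set of prescription doses
#'
#' Applies [rescale_plan()] to every plan for every dose in `pd_list`,
#' yielding `length(records) * length(pd_list)` records.  CI, COV and PIDL
#' are copied unchanged (they are invariant under prescription-dose
#' rescaling); TV12 is re-read from each plan's curve at 12 Gy.
#'
#' @param records List of [plan_record()]s, each with a curve and pidl.
#' @param pd_list Prescription doses to expand over, Gy.
#' @param mode Curve evaluation mode, see [tv_at_dose()].
#' @return A list of rescaled `plan_record`s, plans varying fastest.
#' @export
expand_cohort <- function(records, pd_list, mode = c("interp", "bin1pct")) {
  mode <- match.arg(mode)
  stopifnot(length(records) > 0, length(pd_list) > 0, all(pd_list > 0))
  out <- vector("list", length(records) * length(pd_list))
  k <- 0L
  for (pd in pd_list) {
    for (rec in records) {
      k <- k + 1L
      out[[k]] <- rescale_plan(rec, pd, mode = mode)
    }
  }
  out
}
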