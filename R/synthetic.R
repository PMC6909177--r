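#' Specification for a synthetic SRS plan cohort
#'
#' Describes the statistical structure of a simulated cohort of
#' single-isocenter SRS plans: the same `n_plans` lesions planned for every
#' requested plan type (mirroring a clinical CAT cohort re-planned as DCAT),
#' with dosimetry at every requested prescription dose.
#'
#' PTVs are drawn log-uniformly over `ptv_range`; TV12 values scatter
#' log-normally around the `truth` surface.  Because dose rescaling leaves
#' the relative dose distribution of a plan unchanged, the default noise
#' structure (`noise = "per_plan"`) draws one log10 residual per lesion and
#' plan type, shared across all prescription doses of that plan;
#' `noise = "per_record"` draws an independent residual per record instead.
#'
#' The default noise levels are calibrated per plan type so that stage-1
#' coefficients of determination fall in the band observed clinically
#' (roughly 0.92--0.95 for CAT and 0.96--0.98 for DCAT over this PTV range;
#' CAT fits are noisier because cone plans come from many dosimetrists while
#' conformal re-plans are more homogeneous).
#'
#' @param n_plans Number of lesions (default 50).
#' @param pd_levels Prescription doses, Gy (default 15, 18, 21, 24).
#' @param plan_types Plan types to emit (default both CAT and DCAT).
#' @param ptv_range PTV range in cc, drawn log-uniformly (default
#'   0.05--2.43).
#' @param log10_noise_sd Standard deviation of the log10 TV12 residual;
#'   either a scalar or a named vector with elements `CAT`, `DCAT`
#'   (default `c(CAT = 0.105, DCAT = 0.065)`).
#' @param truth Named list of `tv12_model`s used as the generating surface
#'   (default [reference_models()]).
#' @param paired If `TRUE`, couple the DCAT record of each lesion to its CAT
#'   record: coverage within `cov_tolerance` and conformity index lower in a
#'   fraction `dcat_ci_lower_frac` of pairs (conformal re-plans almost always
#'   improve conformity).
#' @param cov_tolerance Maximum paired coverage difference, percentage
#'   points (default 0.5).
#' @param dcat_ci_lower_frac Fraction of pairs with DCAT conformity index
#'   below CAT (default 0.9).
#' @param margin_factor_range GTV is `ptv / (1 + f)` with `f` uniform over
#'   this range; the default 0--1.5 spans the volumetric effect of 0--2 mm
#'   margins on few-mm lesions.
#' @param noise `"per_plan"` (default) or `"per_record"`, see Details.
#' @param with_curves Attach a synthetic isodose-volume curve to each record
#'   (see [generate_curve()]); default `FALSE`.
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_plans = 50, pd_levels = c(15, 18, 21, 24),
                        plan_types = c("CAT", "DCAT"),
                        ptv_range = c(0.05, 2.43),
                        log10_noise_sd = c(CAT = 0.105, DCAT = 0.065),
                        truth = reference_models(), paired = FALSE,
                        cov_tolerance = 0.5, dcat_ci_lower_frac = 0.9,
                        margin_factor_range = c(0, 1.5),
                        noise = c("per_plan", "per_record"),
                        with_curves = FALSE, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_plans >= 1, all(pd_levels > 0),
            all(plan_types %in% c("CAT", "DCAT")),
            length(ptv_range) == 2, ptv_range[1] > 0,
            ptv_range[1] < ptv_range[2],
            all(log10_noise_sd >= 0), cov_tolerance >= 0,
            dcat_ci_lower_frac >= 0, dcat_ci_lower_frac <= 1,
            length(margin_factor_range) == 2, margin_factor_range[1] >= 0,
            margin_factor_range[1] <= margin_factor_range[2])
  if (length(log10_noise_sd) == 1 && is.null(names(log10_noise_sd))) {
    log10_noise_sd <- c(CAT = unname(log10_noise_sd),
                        DCAT = unname(log10_noise_sd))
  }
  if (!all(plan_types %in% names(log10_noise_sd))) {
    stop("log10_noise_sd must name every requested plan type", call. = FALSE)
  }
  for (pt in plan_types) {
    if (!inherits(truth[[pt]], "tv12_model")) {
      stop("truth must contain a tv12_model for plan type ", pt,
           call. = FALSE)
    }
  }
  structure(list(n_plans = as.integer(n_plans), pd_levels = pd_levels,
                 plan_types = plan_types, ptv_range = ptv_range,
                 log10_noise_sd = log10_noise_sd, truth = truth,
                 paired = paired, cov_tolerance = cov_tolerance,
                 dcat_ci_lower_frac = dcat_ci_lower_frac,
                 margin_factor_range = margin_factor_range, noise = noise,
                 with_curves = with_curves, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic plan cohort
#'
#' Draws a cohort per the [cohort_spec()]: lesion geometry (PTV log-uniform,
#' GTV from a volumetric margin factor), TV12 log-normal around the truth
#' surface, and plausible CI/COV/PIDL dosimetry (prescription isodose line
#' fixed at 80% of maximum, the usual starting point for cone and conformal
#' arc plans).  Output is deterministic given the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return List of [plan_record()]s, ordered by lesion, then plan type, then
#'   prescription dose.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_plans
  ptv <- 10^runif(n, log10(spec$ptv_range[1]), log10(spec$ptv_range[2]))
  margin_f <- runif(n, spec$margin_factor_range[1],
                    spec$margin_factor_range[2])
  gtv <- ptv / (1 + margin_f)
  pidl <- 80
  records <- list()
  for (i in seq_len(n)) {
    id <- sprintf("sim%03d", i)
    ci <- cov <- eps <- list()
    for (pt in spec$plan_types) {
      if (pt == "CAT" || !spec$paired || !"CAT" %in% spec$plan_types) {
        ci[[pt]] <- 1 + abs(rnorm(1, 0.30, 0.12))
        cov[[pt]] <- min(100, 99 + runif(1, 0.05, 0.95))
      } else {
        # paired DCAT: CI usually improves, coverage matched within tolerance
        lower <- runif(1) < spec$dcat_ci_lower_frac
        factor <- if (lower) 1 - runif(1, 0.02, 0.20) else
          1 + runif(1, 0, 0.05)
        ci[[pt]] <- ci[["CAT"]] * factor
        cov[[pt]] <- min(100, max(0, cov[["CAT"]] +
                                    runif(1, -spec$cov_tolerance,
                                          spec$cov_tolerance)))
      }
      eps[[pt]] <- rnorm(1, 0, spec$log10_noise_sd[[pt]])
    }
    for (pt in spec$plan_types) {
      tr <- spec$truth[[pt]]
      for (pd in spec$pd_levels) {
        e <- if (spec$noise == "per_plan") eps[[pt]] else
          rnorm(1, 0, spec$log10_noise_sd[[pt]])
        tv12 <- suppressWarnings(predict_tv12(tr, ptv[i], pd)) * 10^e
        rec <- plan_record(id, pt, pd = pd, ptv = ptv[i], gtv = gtv[i],
                           tv12 = tv12, ci = ci[[pt]], cov = cov[[pt]],
                           ptv_max_dose = pd / (pidl / 100), pidl = pidl)
        if (spec$with_curves) rec$curve <- generate_curve(rec)
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  records
}

#' Synthetic isodose-volume curve through a plan's measured nodes
#'
#' Builds a monotone curve passing *exactly* through the record's 12 Gy node
#' (the percent-of-maximum corresponding to 12 Gy at the record's
#' prescription dose, with enclosed volume `tv12`) and, when `ci` is
#' present, through the prescription node (`pidl`, PIV = ci * ptv).  Between
#' and beyond the nodes the curve follows a power decay
#' \eqn{V(p) = A\,p^{-k}}, the shape of the enclosed volume of a steep
#' radiosurgical dose fall-off; with a single node the decay exponent
#' defaults to 2.5.  The percent grid spans 20--100% of maximum.
#'
#' @param record A [plan_record()] with `tv12`, `pd` and `pidl` present.
#' @param pidl Prescription isodose line, percent of maximum (default: the
#'   record's).
#' @return An [isodose_curve()].
#' @export
generate_curve <- function(record, pidl = record$pidl) {
  stopifnot(inherits(record, "plan_record"))
  if (is.na(record$tv12) || is.na(record$pd) || is.na(pidl)) {
    stop(sprintf("plan '%s': tv12, pd and pidl are required to build a curve",
                 record$plan_id), call. = FALSE)
  }
  p12 <- isodose_percent_for_dose(12, record$pd, pidl)
  if (!is.na(record$ci)) {
    piv <- record$ci * record$ptv
    if (abs(log(pidl / p12)) < 1e-12) {
      if (abs(record$tv12 - piv) > 1e-9) {
        stop(sprintf(
          "plan '%s': inconsistent curve nodes at coincident percents",
          record$plan_id), call. = FALSE)
      }
      k <- 2.5
    } else {
      k <- log(record$tv12 / piv) / log(pidl / p12)
      if (k < 0) {
        stop(sprintf(
          paste0("plan '%s': inconsistent curve nodes (volume would ",
                 "increase with isodose percent)"), record$plan_id),
          call. = FALSE)
      }
    }
  } else {
    k <- 2.5
  }
  A <- record$tv12 * p12^k
  pct <- sort(unique(c(seq(20, 100, by = 4), p12, if (!is.na(record$ci)) pidl)))
  isodose_curve(pct, A * pct^(-k))
}
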