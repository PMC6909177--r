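warn_extrapolation <- function(msg) {
  warning(warningCondition(msg, class = "srspreplan_extrapolation"))
}

check_model_domain <- function(model, ptv = NULL, pd = NULL) {
  if (!is.null(pd) && any(pd < model$pd_domain[1] | pd > model$pd_domain[2])) {
    warn_extrapolation(sprintf(
      "pd outside fitted domain [%g, %g] Gy; prediction is an extrapolation",
      model$pd_domain[1], model$pd_domain[2]))
  }
  if (!is.null(ptv) &&
      any(ptv < model$ptv_domain[1] | ptv > model$ptv_domain[2])) {
    warn_extrapolation(sprintf(
      "ptv outside fitted domain [%g, %g] cc; prediction is an extrapolation",
      model$ptv_domain[1], model$ptv_domain[2]))
  }
}

#' Predict TV12 from the fitted surface
#'
#' Evaluates \eqn{TV12 = (n \, PD + d)\, PTV^{\,a\,PD^{\,c}}} (volumes in cc,
#' doses in Gy).  Queries outside the fitted PD or PTV domain are answered,
#' but with a warning of class `srspreplan_extrapolation`.
#'
#' @param model A `tv12_model` (from [build_model()] or [reference_model()]).
#' @param ptv Planning target volume(s), cc (> 0).
#' @param pd Prescription dose(s), Gy.
#' @return Predicted TV12 in cc (vectorized over `ptv` and `pd`).
#' @export
predict_tv12 <- function(model, ptv, pd) {
  stopifnot(inherits(model, "tv12_model"), all(ptv > 0), all(pd > 0))
  check_model_domain(model, ptv = ptv, pd = pd)
  mult <- model$n * pd + model$d
  if (any(mult <= 0)) {
    stop(sprintf(
      "model multiplier n*pd + d = %.4g is not positive at pd = %g Gy",
      mult[which(mult <= 0)[1]], pd[which(mult <= 0)[1]]), call. = FALSE)
  }
  mult * ptv^(model$a * pd^model$c)
}

#' Predict V12 (normal-brain 12 Gy volume)
#'
#' `predict_tv12(model, ptv, pd) - gtv`.  A negative prediction signals an
#' out-of-domain query (or a GTV larger than the predicted 12 Gy volume); it
#' is returned as-is with a warning of class `srspreplan_negative_v12`,
#' never clamped, so that inverse queries stay exactly invertible.
#'
#' @inheritParams predict_tv12
#' @param gtv Gross tumor volume, cc (>= 0).
#' @return Predicted V12 in cc.
#' @export
predict_v12 <- function(model, ptv, pd, gtv) {
  stopifnot(all(gtv >= 0))
  v12 <- predict_tv12(model, ptv, pd) - gtv
  if (any(v12 < 0)) {
    warning(warningCondition(
      "negative V12 prediction: query is outside the model's useful domain",
      class = "srspreplan_negative_v12"))
  }
  v12
}

#' Largest PTV compatible with a V12 goal
#'
#' Closed-form inversion of the surface in PTV:
#' \deqn{PTV = \left(\frac{V12_{goal} + GTV}{n\,PD + d}\right)^{1/(a\,PD^c)}.}
#' Since TV12 increases with PTV, this is the largest PTV whose predicted V12
#' does not exceed the goal.  Values outside the fitted PTV domain are
#' returned with an extrapolation warning.
#'
#' @inheritParams predict_v12
#' @param v12_goal V12 goal, cc (`v12_goal + gtv` must be positive).
#' @return PTV in cc.
#' @export
max_ptv_for_goal <- function(model, pd, gtv, v12_goal) {
  stopifnot(inherits(model, "tv12_model"), all(pd > 0), all(gtv >= 0))
  if (any(v12_goal + gtv <= 0)) {
    stop("v12_goal + gtv must be positive", call. = FALSE)
  }
  check_model_domain(model, pd = pd)
  mult <- model$n * pd + model$d
  if (any(mult <= 0)) stop("n*pd + d must be positive", call. = FALSE)
  expo <- model$a * pd^model$c
  ptv <- ((v12_goal + gtv) / mult)^(1 / expo)
  check_model_domain(model, ptv = ptv)
  ptv
}

#' Largest prescription dose compatible with a V12 goal
#'
#' Solves `predict_v12(model, ptv, pd, gtv) = v12_goal` for `pd` by bracketed
#' root finding over `pd_range` (tolerance 1e-6 Gy).  Predicted V12 is
#' strictly increasing in PD over the validity domain, so the root is unique.
#' If the goal is not bracketed the function returns a no-solution result
#' (not an error) carrying the V12 values at the range boundaries.
#'
#' @inheritParams predict_v12
#' @param v12_goal V12 goal, cc.
#' @param pd_range Dose search interval, Gy (default: the model's PD domain).
#' @return A list with `solution` (logical), `pd` (Gy, `NA` if no solution),
#'   and `v12_at_min` / `v12_at_max`, the predicted V12 at the interval ends.
#' @export
max_pd_for_goal <- function(model, ptv, gtv, v12_goal,
                            pd_range = model$pd_domain) {
  stopifnot(inherits(model, "tv12_model"), length(pd_range) == 2,
            pd_range[1] < pd_range[2])
  f <- function(pd) suppressWarnings(
    predict_v12(model, ptv, pd, gtv)) - v12_goal
  lo <- f(pd_range[1]); hi <- f(pd_range[2])
  out <- list(solution = FALSE, pd = NA_real_,
              v12_at_min = lo + v12_goal, v12_at_max = hi + v12_goal)
  eps <- 1e-9 * max(1, abs(v12_goal))   # roots at the bracket edges count
  if (lo > eps || hi < -eps) return(out)
  out$solution <- TRUE
  out$pd <- if (abs(lo) <= eps) pd_range[1] else if (abs(hi) <= eps)
    pd_range[2] else uniroot(f, interval = pd_range, tol = 1e-9)$root
  out
}

#' RTOG diameter-based prescription dose guidelines
#'
#' Piecewise-constant dose lookup by maximal lesion diameter, as printed in
#' the protocols: RTOG 90-05 gives 24, 18 and 15 Gy for maximal diameters of
#' <=20, 21--30 and 31--40 mm; RTOG 1270 gives 24, 22 and 20 Gy for <10,
#' 10--<20 and 20--<30 mm.  Diameters beyond the last bracket are not
#' eligible (`NA`).  RTOG 90-05 prints integer bracket edges; non-integer
#' diameters in (20, 21) mm are assigned to the 18 Gy bracket.
#' `local_convention = TRUE` additionally marks diameters above 20 mm as not
#' treated (a conservative single-fraction SRS cutoff).
#'
#' @param max_diameter Maximal lesion diameter(s), mm (> 0).
#' @param protocol `"RTOG_9005"` or `"RTOG_1270"`.
#' @param local_convention If `TRUE`, diameters > 20 mm return `NA`.
#' @return Guideline dose(s) in Gy; `NA` where not eligible.
#' @examples
#' rtog_dose_guideline(25, "RTOG_9005")  # 18 Gy
#' rtog_dose_guideline(15, "RTOG_1270")  # 22 Gy
#' @export
rtog_dose_guideline <- function(max_diameter,
                                protocol = c("RTOG_9005", "RTOG_1270"),
                                local_convention = FALSE) {
  protocol <- match.arg(protocol)
  stopifnot(all(max_diameter > 0))
  dose <- if (protocol == "RTOG_9005") {
    ifelse(max_diameter <= 20, 24,
           ifelse(max_diameter <= 30, 18,
                  ifelse(max_diameter <= 40, 15, NA_real_)))
  } else {
    ifelse(max_diameter < 10, 24,
           ifelse(max_diameter < 20, 22,
                  ifelse(max_diameter < 30, 20, NA_real_)))
  }
  if (local_convention) dose[max_diameter > 20] <- NA_real_
  dose
}
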