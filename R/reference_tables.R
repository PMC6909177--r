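#' Reference per-category fit parameters
#'
#' Per-category slope/intercept fits (`m`, `b`, R^2) distributed with the
#' package, obtained from a 50-plan clinical cohort of single-isocenter SRS
#' plans (each CAT plan re-planned as DCAT, dose-rescaled to prescription
#' doses of 15, 18, 21 and 24 Gy; PTV up to 2.43 cc).  These values seed the
#' packaged [reference_model()] and serve as regression fixtures in the test
#' suite.
#'
#' @return A data.frame with columns `plan_type`, `pd_gy`, `m`, `b`, `r2`
#'   (8 rows).
#' @export
reference_stage1_fits <- function() {
  read.csv(system.file("extdata", "reference_stage1_fits.csv",
                       package = "srspreplan"), stringsAsFactors = FALSE)
}

#' Reference surface parameters
#'
#' Stage-2 parameters (`a`, `c`, `n`, `d` with their fit R^2 values) of the
#' packaged reference TV12 surface, one row per plan type.  See
#' [reference_stage1_fits()] for the provenance of the underlying cohort.
#'
#' @return A data.frame with columns `plan_type`, `a`, `c`, `r2_slope`, `n`,
#'   `d`, `r2_intercept` (2 rows).
#' @export
reference_stage2_params <- function() {
  read.csv(system.file("extdata", "reference_stage2_params.csv",
                       package = "srspreplan"), stringsAsFactors = FALSE)
}

#' Packaged reference TV12 model
#'
#' Builds a [tv12 model][build_model] directly from the packaged reference
#' surface parameters.  The recorded domains are those of the underlying
#' cohort: prescription doses 15--24 Gy and PTV 0.05--2.43 cc.
#'
#' @param plan_type `"CAT"` or `"DCAT"`.
#' @return A `tv12_model`.
#' @examples
#' predict_tv12(reference_model("CAT"), ptv = 1, pd = 24)
#' @export
reference_model <- function(plan_type = c("CAT", "DCAT")) {
  plan_type <- match.arg(plan_type)
  p <- reference_stage2_params()
  p <- p[p$plan_type == plan_type, ]
  new_tv12_model(plan_type, a = p$a, c = p$c, n = p$n, d = p$d,
                 r2_slope_fit = p$r2_slope, r2_intercept_fit = p$r2_intercept,
                 pd_domain = c(15, 24), ptv_domain = c(0.05, 2.43))
}

#' Both packaged reference models
#'
#' @return Named list with the `"CAT"` and `"DCAT"` [reference_model()]s.
#' @export
reference_models <- function() {
  list(CAT = reference_model("CAT"), DCAT = reference_model("DCAT"))
}
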