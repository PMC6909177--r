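#' Percent difference in conformity index, DCAT relative to CAT
#'
#' \deqn{\Delta CI = 100\,(CI_{DCAT} - CI_{CAT}) / CI_{CAT}.}
#'
#' @param ci_cat CAT conformity index (> 0).
#' @param ci_dcat DCAT conformity index.
#' @return Percent difference (vectorized).
#' @export
delta_ci <- function(ci_cat, ci_dcat) {
  if (any(ci_cat <= 0)) stop("ci_cat must be > 0", call. = FALSE)
  100 * (ci_dcat - ci_cat) / ci_cat
}

#' Percent difference in TV12, DCAT relative to CAT
#'
#' \deqn{\Delta TV12 = 100\,(TV12_{DCAT} - TV12_{CAT}) / TV12_{CAT}.}
#'
#' @param tv12_cat CAT 12 Gy isodose volume, cc (> 0).
#' @param tv12_dcat DCAT 12 Gy isodose volume, cc.
#' @return Percent difference (vectorized).
#' @export
delta_tv12 <- function(tv12_cat, tv12_dcat) {
  if (any(tv12_cat <= 0)) stop("tv12_cat must be > 0", call. = FALSE)
  100 * (tv12_dcat - tv12_cat) / tv12_cat
}

#' Pair CAT and DCAT plans and compute percent differences
#'
#' Records are paired on (`plan_id`, `pd`): each pair must contain exactly
#' one CAT and one DCAT record with `ci` and `tv12` present.  Unpaired
#' records are reported in the `unpaired` attribute and via a warning, never
#' silently dropped.
#'
#' @param records List of [plan_record()]s containing both plan types.
#' @return A data.frame of class `comparison_records` with columns `plan_id`,
#'   `ptv_cc`, `pd_gy`, `delta_ci`, `delta_tv12`, plus an `unpaired`
#'   attribute (character vector of `plan_id@pd` keys).
#' @export
compare_plans <- function(records) {
  df <- cohort_table(records)
  key <- paste(df$plan_id, df$pd_gy, sep = "@")
  out <- list(); unpaired <- character()
  for (k in unique(key)) {
    sub <- df[key == k, ]
    cat_row <- sub[sub$plan_type == "CAT", ]
    dcat_row <- sub[sub$plan_type == "DCAT", ]
    if (nrow(cat_row) != 1 || nrow(dcat_row) != 1) {
      unpaired <- c(unpaired, k)
      next
    }
    out[[k]] <- data.frame(
      plan_id = cat_row$plan_id, ptv_cc = cat_row$ptv_cc,
      pd_gy = cat_row$pd_gy,
      delta_ci = delta_ci(cat_row$ci, dcat_row$ci),
      delta_tv12 = delta_tv12(cat_row$tv12_cc, dcat_row$tv12_cc),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no complete CAT/DCAT pairs found", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(unpaired)) {
    warning(sprintf("%d unpaired record key(s) excluded: %s",
                    length(unpaired), paste(unpaired, collapse = ", ")))
  }
  attr(res, "unpaired") <- unpaired
  class(res) <- c("comparison_records", "data.frame")
  res
}

#' Summarize TV12 percent changes at one prescription dose
#'
#' The set of per-pair `delta_tv12` values at a given dose is characterized
#' by its maximum, minimum and median (the median of an even-length set is
#' the mean of the middle two), together with counts of increasing
#' (delta > 0), decreasing (delta < 0) and unchanged (delta == 0) pairs.
#'
#' @param pairs A `comparison_records` data.frame from [compare_plans()].
#' @param pd Prescription dose, Gy.
#' @return A one-row data.frame: `pd_gy`, `max`, `min`, `median`,
#'   `n_increasing`, `n_decreasing`, `n_unchanged`.
#' @export
summarize_deltas <- function(pairs, pd) {
  d <- pairs$delta_tv12[pairs$pd_gy == pd]
  if (!length(d)) {
    stop(sprintf("no pairs at pd = %g Gy", pd), call. = FALSE)
  }
  data.frame(pd_gy = pd, max = max(d), min = min(d), median = median(d),
             n_increasing = sum(d > 0), n_decreasing = sum(d < 0),
             n_unchanged = sum(d == 0))
}

#' Per-dose comparison summary table
#'
#' Applies [summarize_deltas()] at every prescription dose present, mirroring
#' a per-dose panel layout (one block per dose).
#'
#' @param pairs A `comparison_records` data.frame from [compare_plans()].
#' @return A data.frame with one row per prescription dose.
#' @export
summarize_comparison <- function(pairs) {
  pds <- sort(unique(pairs$pd_gy))
  do.call(rbind, lapply(pds, function(p) summarize_deltas(pairs, p)))
}

#' PTV at which CAT and DCAT TV12 predictions cross
#'
#' In log space both surfaces are linear in `log10(ptv)` at fixed dose, with
#' slope \eqn{m(PD) = a\,PD^c} and intercept \eqn{b(PD) = \log_{10}(n\,PD+d)},
#' so the crossing is closed-form:
#' \deqn{\log_{10}(PTV^*) = \frac{b_{CAT} - b_{DCAT}}{m_{DCAT} - m_{CAT}}.}
#' Below the crossing the DCAT prediction is the larger (its larger penumbra
#' dominates small targets); above it the CAT prediction is larger.  If the
#' slopes are equal the curves are parallel in log space and `NA` is
#' returned.  A crossing outside the models' common PTV domain is returned
#' with an extrapolation warning.
#'
#' @param model_cat,model_dcat Fitted `tv12_model`s for the two plan types.
#' @param pd Prescription dose, Gy.
#' @return Crossover PTV in cc, or `NA` if the curves are parallel.
#' @export
crossover_ptv <- function(model_cat, model_dcat, pd) {
  stopifnot(inherits(model_cat, "tv12_model"),
            inherits(model_dcat, "tv12_model"), length(pd) == 1, pd > 0)
  m_cat <- model_cat$a * pd^model_cat$c
  m_dcat <- model_dcat$a * pd^model_dcat$c
  mult_cat <- model_cat$n * pd + model_cat$d
  mult_dcat <- model_dcat$n * pd + model_dcat$d
  if (mult_cat <= 0 || mult_dcat <= 0) {
    stop("n*pd + d must be positive for both models", call. = FALSE)
  }
  if (abs(m_dcat - m_cat) < 1e-12) return(NA_real_)
  ptv <- 10^((log10(mult_cat) - log10(mult_dcat)) / (m_dcat - m_cat))
  dom <- c(max(model_cat$ptv_domain[1], model_dcat$ptv_domain[1]),
           min(model_cat$ptv_domain[2], model_dcat$ptv_domain[2]))
  if (ptv < dom[1] || ptv > dom[2]) {
    warn_extrapolation(sprintf(
      "crossover at %.3g cc lies outside the fitted PTV domain [%g, %g] cc",
      ptv, dom[1], dom[2]))
  }
  ptv
}
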