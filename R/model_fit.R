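#' Per-category log-log fit of TV12 against PTV
#'
#' Within one category (one plan type at one prescription dose), TV12 and PTV
#' obey a power law over the small-target range, so ordinary least squares of
#' `log10(tv12 / 1 cc)` on `log10(ptv / 1 cc)` characterizes the category by
#' a slope `m` and intercept `b`:
#' \deqn{\log_{10}(TV12) = m \log_{10}(PTV) + b.}
#' R^2 is the coefficient of determination on the log10 scale.
#'
#' @param ptv Planning target volumes, cc (> 0).
#' @param tv12 12 Gy isodose volumes, cc (> 0), same length.
#' @param plan_type `"CAT"` or `"DCAT"` (metadata carried on the fit).
#' @param pd Prescription dose of the category, Gy.
#' @return An object of class `stage1_fit`: list with `plan_type`, `pd`, `m`,
#'   `b`, `r2`, `n_points`.
#' @export
fit_stage1 <- function(ptv, tv12, plan_type, pd) {
  stopifnot(length(ptv) == length(tv12))
  if (length(ptv) < 3) {
    stop("stage-1 fit needs at least 3 records per category", call. = FALSE)
  }
  if (any(!is.finite(ptv)) || any(ptv <= 0) ||
      any(!is.finite(tv12)) || any(tv12 <= 0)) {
    stop("stage-1 fit requires strictly positive ptv and tv12", call. = FALSE)
  }
  x <- log10(ptv)
  if (diff(range(x)) < 1e-12) {
    stop(sprintf("category (%s, %g Gy) unfittable: all ptv values equal",
                 plan_type, pd), call. = FALSE)
  }
  y <- log10(tv12)
  fit <- lm(y ~ x)
  r2 <- 1 - sum(resid(fit)^2) / sum((y - mean(y))^2)
  structure(list(plan_type = plan_type, pd = pd,
                 m = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
                 r2 = r2, n_points = length(ptv)),
            class = "stage1_fit")
}

stage1_frame <- function(stage1) {
  stopifnot(length(stage1) >= 1, all(vapply(stage1, inherits, TRUE,
                                            "stage1_fit")))
  data.frame(plan_type = vapply(stage1, `[[`, "", "plan_type"),
             pd = vapply(stage1, `[[`, 0, "pd"),
             m = vapply(stage1, `[[`, 0, "m"),
             b = vapply(stage1, `[[`, 0, "b"),
             r2 = vapply(stage1, `[[`, 0, "r2"),
             n_points = vapply(stage1, function(f) as.numeric(f$n_points), 0),
             stringsAsFactors = FALSE)
}

#' Dose dependence of the per-category slope
#'
#' Fits the power law \eqn{m = a \, (PD)^c} to the stage-1 slopes of one plan
#' type.  The default method is nonlinear least squares on the `m` scale
#' (Levenberg-Marquardt), initialized from the exact log-log linear solution;
#' `method = "loglinear"` instead keeps that log-space solution, for users who
#' prefer the linearized convention.  R^2 is always reported on the `m` scale.
#' When all slopes are equal the exponent is 0 and R^2 is degenerate
#' (`NA`, since the total sum of squares vanishes).
#'
#' @param stage1 List of [fit_stage1()] results for one plan type, covering
#'   at least 3 distinct prescription doses.
#' @param method `"nls"` (default) or `"loglinear"`.
#' @return List with `a`, `c`, `r2`, `method`.
#' @export
fit_slope_vs_pd <- function(stage1, method = c("nls", "loglinear")) {
  method <- match.arg(method)
  df <- stage1_frame(stage1)
  if (length(unique(df$pd)) < 3) {
    stop("slope fit needs >= 3 distinct prescription doses", call. = FALSE)
  }
  if (any(df$m <= 0)) stop("slope fit requires positive slopes", call. = FALSE)
  if (diff(range(df$m)) < 1e-12) {
    return(list(a = df$m[1], c = 0, r2 = NA_real_, method = method))
  }
  ll <- lm(log10(m) ~ log10(pd), data = df)
  a0 <- unname(10^coef(ll)[1]); c0 <- unname(coef(ll)[2])
  if (method == "nls") {
    fit <- minpack.lm::nlsLM(m ~ a * pd^c, data = df,
                             start = list(a = a0, c = c0),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-12, ptol = 1e-12))
    a_hat <- unname(coef(fit)["a"]); c_hat <- unname(coef(fit)["c"])
  } else {
    a_hat <- a0; c_hat <- c0
  }
  pred <- a_hat * df$pd^c_hat
  r2 <- 1 - sum((df$m - pred)^2) / sum((df$m - mean(df$m))^2)
  list(a = a_hat, c = c_hat, r2 = r2, method = method)
}

#' Dose dependence of the per-category intercept
#'
#' Fits the linear law \eqn{10^b = n \, (PD) + d} by ordinary least squares
#' of `10^b` on the prescription dose; R^2 is reported on the `10^b` scale.
#'
#' @param stage1 List of [fit_stage1()] results for one plan type, covering
#'   at least 2 distinct prescription doses.
#' @return List with `n`, `d`, `r2`.
#' @export
fit_intercept_vs_pd <- function(stage1) {
  df <- stage1_frame(stage1)
  if (length(unique(df$pd)) < 2) {
    stop("intercept fit needs >= 2 distinct prescription doses",
         call. = FALSE)
  }
  y <- 10^df$b
  fit <- lm(y ~ pd, data = df)
  pred <- unname(coef(fit)[1] + coef(fit)[2] * df$pd)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst < 1e-24) NA_real_ else 1 - sum((y - pred)^2) / sst
  list(n = unname(coef(fit)[2]), d = unname(coef(fit)[1]), r2 = r2)
}

new_tv12_model <- function(plan_type, a, c, n, d, r2_slope_fit,
                           r2_intercept_fit, pd_domain, ptv_domain,
                           stage1 = NULL, stage2_slope = "nls") {
  model <- structure(
    list(plan_type = plan_type, a = a, c = c, n = n, d = d,
         r2_slope_fit = r2_slope_fit, r2_intercept_fit = r2_intercept_fit,
         pd_domain = as.numeric(pd_domain), ptv_domain = as.numeric(ptv_domain),
         stage1 = stage1, stage2_slope = stage2_slope),
    class = "tv12_model")
  if (a <= 0) stop("model coefficient a must be > 0", call. = FALSE)
  mult <- n * pd_domain + d
  if (any(mult <= 0)) {
    stop(sprintf(
      "invalid model: multiplier n*pd + d is not positive over [%g, %g] Gy",
      pd_domain[1], pd_domain[2]), call. = FALSE)
  }
  model
}

#' @export
print.tv12_model <- function(x, ...) {
  cat(sprintf("<tv12_model> %s: TV12 = (%.4g*PD %+.4g) * PTV^(%.4g*PD^%.4g)\n",
              x$plan_type, x$n, x$d, x$a, x$c))
  cat(sprintf("  domains: PD [%g, %g] Gy, PTV [%g, %g] cc\n",
              x$pd_domain[1], x$pd_domain[2],
              x$ptv_domain[1], x$ptv_domain[2]))
  cat(sprintf("  stage-2 R2: slope %.4g, intercept %.4g\n",
              x$r2_slope_fit, x$r2_intercept_fit))
  invisible(x)
}

#' Fit the two-stage TV12 model to a plan cohort
#'
#' Stage 1 fits `log10(TV12)` against `log10(PTV)` within each (plan type,
#' prescription dose) category; stage 2 fits the dose dependence of the
#' resulting slopes (power law) and intercepts (linear in `10^b`).
#' Substituting the stage-2 laws back gives the closed-form surface
#' \deqn{TV12 = (n \, PD + d) \; PTV^{\,a \, PD^{\,c}},}
#' with volumes in cc and doses in Gy, one parameter set per plan type.
#'
#' @param records List of [plan_record()]s (e.g. from [read_cohort()],
#'   [expand_cohort()] or [generate_cohort()]) with `tv12` present, covering
#'   at least 3 prescription doses and at least 3 plans per category for each
#'   requested plan type.
#' @param plan_types Plan types to fit (default: those present).
#' @param stage2_slope Method for the stage-2 slope fit, see
#'   [fit_slope_vs_pd()].
#' @return A named list of `tv12_model` objects, one per plan type.
#' @export
build_model <- function(records, plan_types = NULL,
                        stage2_slope = c("nls", "loglinear")) {
  stage2_slope <- match.arg(stage2_slope)
  df <- cohort_table(records)
  if (any(is.na(df$tv12_cc))) {
    stop("all records must have tv12 to fit the model", call. = FALSE)
  }
  if (is.null(plan_types)) plan_types <- sort(unique(df$plan_type))
  out <- list()
  for (pt in plan_types) {
    sub <- df[df$plan_type == pt, ]
    pds <- sort(unique(sub$pd_gy))
    small <- pds[vapply(pds, function(p) sum(sub$pd_gy == p) < 3, TRUE)]
    if (length(pds) < 3 || length(small)) {
      stop(sprintf(
        paste0("plan type %s: need >= 3 prescription doses with >= 3 plans ",
               "each; have doses {%s}%s"),
        pt, paste(pds, collapse = ", "),
        if (length(small)) sprintf(" (under-filled: %s)",
                                   paste(small, collapse = ", ")) else ""),
        call. = FALSE)
    }
    stage1 <- lapply(pds, function(p) {
      cat_sub <- sub[sub$pd_gy == p, ]
      fit_stage1(cat_sub$ptv_cc, cat_sub$tv12_cc, pt, p)
    })
    out[[pt]] <- build_model_from_stage1(
      stage1, ptv_domain = range(sub$ptv_cc), stage2_slope = stage2_slope)
  }
  out
}

#' Assemble the TV12 surface from per-category fits
#'
#' Runs only the stage-2 fits, taking per-category slopes and intercepts as
#' given; useful when the per-category fits come from an external source
#' (e.g. the packaged reference table) rather than from raw plan data.
#'
#' @param stage1 List of `stage1_fit` objects for a single plan type.
#' @param ptv_domain PTV domain to record on the model, cc.
#' @param stage2_slope Method for the stage-2 slope fit.
#' @return A `tv12_model`.
#' @export
build_model_from_stage1 <- function(stage1, ptv_domain = c(0.05, 2.43),
                                    stage2_slope = c("nls", "loglinear")) {
  stage2_slope <- match.arg(stage2_slope)
  df <- stage1_frame(stage1)
  pt <- unique(df$plan_type)
  if (length(pt) != 1) {
    stop("stage1 fits must all belong to one plan type", call. = FALSE)
  }
  sl <- fit_slope_vs_pd(stage1, method = stage2_slope)
  ic <- fit_intercept_vs_pd(stage1)
  new_tv12_model(pt, a = sl$a, c = sl$c, n = ic$n, d = ic$d,
                 r2_slope_fit = sl$r2, r2_intercept_fit = ic$r2,
                 pd_domain = range(df$pd), ptv_domain = ptv_domain,
                 stage1 = stage1, stage2_slope = stage2_slope)
}

#' Write fitted models to a JSON file
#'
#' @param models Named list of `tv12_model` objects (as from [build_model()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(models, path) {
  if (inherits(models, "tv12_model")) models <- setNames(
    list(models), models$plan_type)
  payload <- list(
    format = "srspreplan-tv12-model",
    version = as.character(packageVersion("srspreplan")),
    models = lapply(models, function(m) {
      list(plan_type = m$plan_type, a = m$a, c = m$c, n = m$n, d = m$d,
           r2_slope_fit = m$r2_slope_fit, r2_intercept_fit = m$r2_intercept_fit,
           pd_domain = m$pd_domain, ptv_domain = m$ptv_domain,
           stage2_slope = m$stage2_slope,
           stage1 = if (!is.null(m$stage1)) stage1_frame(m$stage1))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read fitted models from a JSON file
#'
#' @param path Path written by [write_model()].
#' @return Named list of `tv12_model` objects.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "srspreplan-tv12-model")) {
    stop(path, " is not an srspreplan model file", call. = FALSE)
  }
  models <- lapply(payload$models, function(m) {
    stage1 <- NULL
    if (!is.null(m$stage1) && length(m$stage1)) {
      stage1 <- lapply(seq_len(nrow(m$stage1)), function(i) {
        structure(as.list(m$stage1[i, ]), class = "stage1_fit")
      })
    }
    new_tv12_model(m$plan_type, m$a, m$c, m$n, m$d,
                   m$r2_slope_fit, m$r2_intercept_fit,
                   m$pd_domain, m$ptv_domain, stage1 = stage1,
                   stage2_slope = m$stage2_slope %||% "nls")
  })
  setNames(models, vapply(models, `[[`, "", "plan_type"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
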