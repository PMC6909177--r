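#' Construct a single SRS plan record
#'
#' A plan record is the atomic unit of a cohort: the geometry of one lesion
#' (GTV, PTV, optionally the three principal-axis diameters) together with the
#' dosimetric metrics extracted from the corresponding single-isocenter plan.
#'
#' Volumes are in cc, doses in Gy, lengths in mm.  `pidl` (the prescription
#' isodose line, i.e. the prescription dose expressed as a percent of the plan
#' maximum dose) is derived from `ptv_max_dose` when absent; when both are
#' given they must agree to within 0.1 percentage points.
#'
#' @param plan_id Opaque plan identifier (character scalar).
#' @param plan_type `"CAT"` (circular-cone arc therapy) or `"DCAT"` (dynamic
#'   conformal arc therapy).
#' @param pd Prescription dose in Gy (> 0).
#' @param ptv Planning target volume in cc (> 0).
#' @param gtv Gross tumor volume in cc (0 <= gtv <= ptv).
#' @param tv12 Total volume enclosed by the 12 Gy isodose surface, cc
#'   (optional).
#' @param ci Conformity index, PIV/PTV (optional, > 0).
#' @param cov Coverage: percent of the PTV receiving at least `pd`
#'   (optional, 0--100).
#' @param ptv_max_dose Maximum dose in the PTV, Gy (optional).
#' @param pidl Prescription isodose line, percent of plan maximum dose
#'   (optional, derivable from `ptv_max_dose`).
#' @param diameters Numeric length-3 vector of principal-axis diameters in mm
#'   (optional).
#' @param curve An [isodose_curve()] for the plan (optional).
#' @return An object of class `plan_record` (a named list).
#' @examples
#' plan_record("p1", "CAT", pd = 24, ptv = 1.0, gtv = 0.8, tv12 = 4.4,
#'             ptv_max_dose = 30)
#' @export
plan_record <- function(plan_id, plan_type, pd, ptv, gtv,
                        tv12 = NA_real_, ci = NA_real_, cov = NA_real_,
                        ptv_max_dose = NA_real_, pidl = NA_real_,
                        diameters = NULL, curve = NULL) {
  rec <- structure(
    list(plan_id = as.character(plan_id),
         plan_type = as.character(plan_type),
         pd = as.numeric(pd), ptv = as.numeric(ptv), gtv = as.numeric(gtv),
         tv12 = as.numeric(tv12), ci = as.numeric(ci), cov = as.numeric(cov),
         ptv_max_dose = as.numeric(ptv_max_dose), pidl = as.numeric(pidl),
         diameters = if (!is.null(diameters)) as.numeric(diameters),
         curve = curve),
    class = "plan_record")
  if (is.na(rec$pidl) && !is.na(rec$ptv_max_dose)) {
    rec$pidl <- 100 * rec$pd / rec$ptv_max_dose
  }
  validate_plan_record(rec)
  rec
}

validate_plan_record <- function(rec) {
  id <- rec$plan_id
  fail <- function(msg) {
    stop(sprintf("plan '%s': %s", id, msg), call. = FALSE)
  }
  if (!rec$plan_type %in% c("CAT", "DCAT")) {
    fail(sprintf("plan_type must be 'CAT' or 'DCAT', got '%s'", rec$plan_type))
  }
  if (!is.finite(rec$pd) || rec$pd <= 0) fail("pd must be > 0")
  if (!is.finite(rec$ptv) || rec$ptv <= 0) fail("ptv must be > 0")
  if (!is.finite(rec$gtv) || rec$gtv < 0) fail("gtv must be >= 0")
  if (rec$gtv > rec$ptv) fail("invariant violated: gtv <= ptv")
  if (!is.na(rec$tv12) && rec$tv12 < 0) fail("tv12 must be >= 0")
  if (!is.na(rec$ci) && rec$ci <= 0) fail("ci must be > 0")
  if (!is.na(rec$cov) && (rec$cov < 0 || rec$cov > 100)) {
    fail("cov must be in [0, 100]")
  }
  if (!is.na(rec$pidl) && (rec$pidl <= 0 || rec$pidl > 100)) {
    fail("pidl must be in (0, 100]")
  }
  if (!is.na(rec$pidl) && !is.na(rec$ptv_max_dose)) {
    implied <- 100 * rec$pd / rec$ptv_max_dose
    if (abs(implied - rec$pidl) > 0.1) {
      fail(sprintf(
        "pidl (%.2f%%) inconsistent with 100*pd/ptv_max_dose (%.2f%%)",
        rec$pidl, implied))
    }
  }
  if (!is.null(rec$diameters)) {
    if (length(rec$diameters) != 3 || any(!is.finite(rec$diameters)) ||
        any(rec$diameters <= 0)) {
      fail("diameters must be three positive lengths (mm)")
    }
  }
  if (!is.null(rec$curve) && !inherits(rec$curve, "isodose_curve")) {
    fail("curve must be an isodose_curve")
  }
  invisible(rec)
}

#' @export
print.plan_record <- function(x, ...) {
  cat(sprintf("<plan_record> %s [%s]  PD=%g Gy  PTV=%g cc  GTV=%g cc\n",
              x$plan_id, x$plan_type, x$pd, x$ptv, x$gtv))
  extras <- c(TV12 = x$tv12, CI = x$ci, COV = x$cov, PIDL = x$pidl)
  extras <- extras[!is.na(extras)]
  if (length(extras)) {
    cat(" ", paste(sprintf("%s=%g", names(extras), extras), collapse = "  "),
        "\n")
  }
  if (!is.null(x$curve)) cat("  + isodose-volume curve\n")
  invisible(x)
}

# column order of the cohort CSV interchange schema
cohort_columns <- c("plan_id", "plan_type", "pd_gy", "ptv_cc", "gtv_cc",
                    "tv12_cc", "ci", "cov_pct", "ptv_max_dose_gy", "pidl_pct",
                    "d1_mm", "d2_mm", "d3_mm")

#' Read a cohort of plan records from CSV
#'
#' The file must be comma-separated, UTF-8, `.`-decimal, with a header naming
#' (at least) the columns `plan_id, plan_type, pd_gy, ptv_cc, gtv_cc`;
#' the optional columns are `tv12_cc, ci, cov_pct, ptv_max_dose_gy, pidl_pct,
#' d1_mm, d2_mm, d3_mm`.  Missing optional values are empty cells.  Every row
#' is validated (see [plan_record()]); a violation aborts with a message
#' naming the offending plan.
#'
#' @param path Path to a cohort CSV file.
#' @return A list of [plan_record()] objects, in file row order.
#' @seealso [write_cohort()], [cohort_table()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- cohort_columns[1:5]
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(cohort_columns, names(df))) df[[col]] <- NA
  num_cols <- setdiff(cohort_columns, c("plan_id", "plan_type"))
  for (col in num_cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad)) {
      stop(sprintf("parse error in %s, row %d, column '%s': '%s'",
                   path, bad[1], col, raw[bad[1]]), call. = FALSE)
    }
    df[[col]] <- val
  }
  lapply(seq_len(nrow(df)), function(i) {
    diam <- unlist(df[i, c("d1_mm", "d2_mm", "d3_mm")], use.names = FALSE)
    plan_record(df$plan_id[i], df$plan_type[i], df$pd_gy[i], df$ptv_cc[i],
                df$gtv_cc[i], tv12 = df$tv12_cc[i], ci = df$ci[i],
                cov = df$cov_pct[i], ptv_max_dose = df$ptv_max_dose_gy[i],
                pidl = df$pidl_pct[i],
                diameters = if (!all(is.na(diam))) diam)
  })
}

#' Tabulate a list of plan records
#'
#' @param records List of [plan_record()] objects.
#' @return A `data.frame` in the cohort CSV column schema.
#' @export
cohort_table <- function(records) {
  stopifnot(length(records) > 0)
  rows <- lapply(records, function(r) {
    d <- if (is.null(r$diameters)) rep(NA_real_, 3) else r$diameters
    data.frame(plan_id = r$plan_id, plan_type = r$plan_type, pd_gy = r$pd,
               ptv_cc = r$ptv, gtv_cc = r$gtv, tv12_cc = r$tv12, ci = r$ci,
               cov_pct = r$cov, ptv_max_dose_gy = r$ptv_max_dose,
               pidl_pct = r$pidl, d1_mm = d[1], d2_mm = d[2], d3_mm = d[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a cohort of plan records to CSV
#'
#' Inverse of [read_cohort()]: numeric fields with up to 6 significant digits
#' round-trip bit-identically.  Missing optional fields become empty cells.
#'
#' @param records List of [plan_record()] objects (or a data.frame already in
#'   the cohort schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  df <- if (is.data.frame(records)) records else cohort_table(records)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Normal-brain 12 Gy volume of a measured plan
#'
#' V12 = TV12 - GTV, valid when the 12 Gy isodose surface lies entirely within
#' brain parenchyma.  A record with TV12 < GTV is physically inconsistent and
#' raises an error; the result is never clamped.
#'
#' @param record A [plan_record()] with `tv12` present.
#' @return V12 in cc.
#' @export
derive_v12 <- function(record) {
  stopifnot(inherits(record, "plan_record"))
  if (is.na(record$tv12)) {
    stop(sprintf("plan '%s': tv12 is absent; cannot derive V12",
                 record$plan_id), call. = FALSE)
  }
  v12 <- record$tv12 - record$gtv
  if (v12 < 0) {
    stop(sprintf("plan '%s': inconsistent record, tv12 (%g) < gtv (%g)",
                 record$plan_id, record$tv12, record$gtv), call. = FALSE)
  }
  v12
}

#' Nominal SRS planning goals
#'
#' Defaults are the nominal single-isocenter SRS planning goals: coverage
#' above 99%, conformity index below 1.5, and V12 below 3.3 cc.  All three
#' are strict inequalities.
#'
#' @param min_cov Minimum coverage, percent (goal: COV > `min_cov`).
#' @param max_ci Maximum conformity index (goal: CI < `max_ci`).
#' @param max_v12 Maximum V12 in cc (goal: V12 < `max_v12`).
#' @return An object of class `goal_set`.
#' @export
goal_set <- function(min_cov = 99, max_ci = 1.5, max_v12 = 3.3) {
  stopifnot(min_cov > 0, max_ci > 0, max_v12 > 0)
  structure(list(min_cov = min_cov, max_ci = max_ci, max_v12 = max_v12),
            class = "goal_set")
}

#' Evaluate a plan against planning goals
#'
#' Applies the strict inequalities COV > min_cov, CI < max_ci and
#' V12 < max_v12 (with V12 from [derive_v12()]); boundary values fail.
#'
#' @param record A [plan_record()] with `cov`, `ci`, `tv12` and `gtv` present.
#' @param goals A [goal_set()].
#' @return A list with logical `cov_pass`, `ci_pass`, `v12_pass`, the derived
#'   `v12`, and `pass` (all three goals met).
#' @export
evaluate_goals <- function(record, goals = goal_set()) {
  stopifnot(inherits(record, "plan_record"), inherits(goals, "goal_set"))
  for (metric in c("cov", "ci", "tv12")) {
    if (is.na(record[[metric]])) {
      stop(sprintf("plan '%s': metric '%s' is absent", record$plan_id, metric),
           call. = FALSE)
    }
  }
  v12 <- derive_v12(record)
  out <- list(cov_pass = record$cov > goals$min_cov,
              ci_pass = record$ci < goals$max_ci,
              v12_pass = v12 < goals$max_v12,
              v12 = v12)
  out$pass <- out$cov_pass && out$ci_pass && out$v12_pass
  out
}

#' Surface area of the volume-matched ellipsoid
#'
#' The three principal-axis diameters fix the *shape* of an ellipsoid; the
#' diameters are then rescaled uniformly so that the ellipsoid volume
#' (pi/6 * d1 * d2 * d3, in mm^3) equals `target_volume` (in cc, 1 cc =
#' 1000 mm^3).  The surface area of the rescaled ellipsoid is computed with
#' the Thomsen approximation
#' \deqn{S \approx 4\pi\left(\frac{a^p b^p + a^p c^p + b^p c^p}{3}\right)^{1/p},
#'   \quad p = 1.6075,}
#' whose worst-case relative error is about 1.06%.  The result is invariant
#' under uniform rescaling and permutation of the input diameters.
#'
#' @param diameters Three principal-axis diameters, mm (all > 0).
#' @param target_volume Target volume to match, cc (> 0).
#' @return Surface area in mm^2.
#' @examples
#' # a sphere of volume pi/6 cc has diameter 10 mm and area pi * 10^2 mm^2
#' ellipsoid_surface_area(c(10, 10, 10), pi / 6)
#' @export
ellipsoid_surface_area <- function(diameters, target_volume) {
  if (length(diameters) != 3 || any(!is.finite(diameters)) ||
      any(diameters <= 0)) {
    stop("diameters must be three positive lengths (mm)", call. = FALSE)
  }
  if (!is.finite(target_volume) || target_volume <= 0) {
    stop("target_volume must be > 0 (cc)", call. = FALSE)
  }
  vol_mm3 <- target_volume * MM3_PER_CC
  scale <- (vol_mm3 / (pi / 6 * prod(diameters)))^(1 / 3)
  semi <- scale * diameters / 2
  p <- 1.6075
  a <- semi[1]; b <- semi[2]; c <- semi[3]
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}
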