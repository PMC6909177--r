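test_that("plan_record maps fields, derives pidl, and enforces invariants", {
  r <- plan_record("p1", "CAT", pd = 24, ptv = 1.0, gtv = 0.8, tv12 = 4.4)
  expect_s3_class(r, "plan_record")
  expect_identical(r$plan_id, "p1")
  expect_equal(r$ptv, 1.0)
  expect_equal(r$tv12, 4.4)

  # pidl derived from the maximum dose: 100 * 24 / 30
  r2 <- plan_record("p2", "DCAT", pd = 24, ptv = 1, gtv = 0.5,
                    ptv_max_dose = 30)
  expect_equal(r2$pidl, 80.0)

  expect_error(plan_record("bad", "CAT", pd = 24, ptv = 1.0, gtv = 1.2),
               "gtv <= ptv")
  expect_error(plan_record("bad", "CAT", pd = 0, ptv = 1, gtv = 0.5), "pd")
  expect_error(plan_record("bad", "XAT", pd = 24, ptv = 1, gtv = 0.5),
               "plan_type")
  expect_error(plan_record("bad", "CAT", pd = 24, ptv = 1, gtv = 0.5,
                           ci = -1), "ci")
  # inconsistent pidl vs maximum dose (80 vs 60) is rejected
  expect_error(plan_record("bad", "CAT", pd = 24, ptv = 1, gtv = 0.5,
                           ptv_max_dose = 40, pidl = 80), "inconsistent")
})

test_that("derive_v12 subtracts GTV and refuses inconsistent records", {
  rec <- function(tv12, gtv) plan_record("p", "CAT", 24, ptv = 1, gtv = gtv,
                                         tv12 = tv12)
  expect_equal(derive_v12(rec(4.4, 0.8)), 3.6)
  expect_equal(derive_v12(rec(2.7, 0)), 2.7)
  expect_error(derive_v12(rec(0.5, 0.8)), "inconsistent")
  expect_error(derive_v12(plan_record("p", "CAT", 24, ptv = 1, gtv = 0.8)),
               "tv12 is absent")
})

test_that("evaluate_goals applies strict inequalities and is monotone", {
  rec <- function(cov, ci, tv12, gtv = 0) {
    plan_record("p", "CAT", 24, ptv = 1, gtv = gtv, tv12 = tv12, ci = ci,
                cov = cov)
  }
  g <- goal_set()  # COV > 99, CI < 1.5, V12 < 3.3
  all_pass <- evaluate_goals(rec(99.5, 1.3, 2.0), g)
  expect_true(all_pass$pass)

  expect_false(evaluate_goals(rec(99.0, 1.3, 2.0), g)$cov_pass)  # boundary
  expect_false(evaluate_goals(rec(99.5, 1.5, 2.0), g)$ci_pass)   # boundary
  expect_false(evaluate_goals(rec(99.5, 1.3, 3.3), g)$v12_pass)  # boundary

  expect_error(evaluate_goals(rec(NA, 1.3, 2.0), g), "'cov'")
  expect_error(
    evaluate_goals(plan_record("p", "CAT", 24, ptv = 1, gtv = 0, ci = 1.3,
                               cov = 99.5), g), "'tv12'")

  # improving any single metric never flips a pass to a fail
  set.seed(42)
  for (i in 1:40) {
    cov <- runif(1, 97, 100); ci <- runif(1, 1, 2); tv12 <- runif(1, 0.5, 5)
    base <- evaluate_goals(rec(cov, ci, tv12), g)
    better_cov <- evaluate_goals(rec(min(100, cov + runif(1, 0, 1)), ci,
                                     tv12), g)
    better_ci <- evaluate_goals(rec(cov, ci * runif(1, 0.5, 1), tv12), g)
    better_v12 <- evaluate_goals(rec(cov, ci, tv12 * runif(1, 0.5, 1)), g)
    for (b in list(better_cov, better_ci, better_v12)) {
      expect_true(!base$pass || b$pass)
    }
  }
})

test_that("cohort CSV I/O round-trips and reports malformed input precisely", {
  recs <- list(
    plan_record("a1", "CAT", pd = 24, ptv = 1.25, gtv = 0.8, tv12 = 4.4,
                ci = 1.31, cov = 99.42, ptv_max_dose = 30,
                diameters = c(12.5, 10, 8.2)),
    plan_record("a2", "DCAT", pd = 15, ptv = 0.387, gtv = 0.21),
    plan_record("a3", "CAT", pd = 18, ptv = 2.43, gtv = 2.43, tv12 = 7.01,
                pidl = 82.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(recs, f)
  back <- read_cohort(f)
  expect_length(back, 3)
  for (i in seq_along(recs)) {
    for (field in c("plan_id", "plan_type", "pd", "ptv", "gtv", "tv12", "ci",
                    "cov", "pidl")) {
      expect_identical(back[[i]][[field]], recs[[i]][[field]],
                       label = sprintf("row %d field %s", i, field))
    }
  }
  expect_identical(back[[1]]$diameters, recs[[1]]$diameters)
  expect_null(back[[2]]$diameters)

  # parse error names file position; validation error names the plan
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plan_id,plan_type,pd_gy,ptv_cc,gtv_cc",
               "p1,CAT,24,oops,0.5"), bad)
  expect_error(read_cohort(bad), "row 1, column 'ptv_cc'")
  writeLines(c("plan_id,plan_type,pd_gy,ptv_cc,gtv_cc",
               "p9,CAT,24,1.0,1.2"), bad)
  expect_error(read_cohort(bad), "p9")
  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("ellipsoid surface area matches closed forms and quadrature", {
  sphere_vol <- pi / 6  # cc: a 10 mm diameter sphere
  expect_equal(ellipsoid_surface_area(c(10, 10, 10), sphere_vol), pi * 100,
               tolerance = 1e-10)
  # invariance under uniform scaling and permutation of the diameters
  expect_equal(ellipsoid_surface_area(c(20, 20, 20), sphere_vol), pi * 100,
               tolerance = 1e-10)
  a1 <- ellipsoid_surface_area(c(20, 10, 10), sphere_vol)
  expect_equal(ellipsoid_surface_area(c(10, 20, 10), sphere_vol), a1)
  expect_equal(ellipsoid_surface_area(c(2, 1, 1), sphere_vol), a1)

  # approximation agrees with exact quadrature within its documented 1.1%
  skip_if_not_installed("pracma")
  shapes <- list(c(20, 10, 10), c(18.3, 9, 6), c(15, 12, 4), c(10, 9.5, 9))
  for (d in shapes) {
    vol <- 0.8
    approx_area <- ellipsoid_surface_area(d, vol)
    scale <- (vol * 1000 / (pi / 6 * prod(d)))^(1 / 3)
    exact <- ellipsoid_area_quadrature(scale * d / 2)
    expect_lt(abs(approx_area - exact) / exact, 0.011)
  }

  # the sphere minimizes area at fixed volume
  sphere <- ellipsoid_surface_area(c(1, 1, 1), 0.6)
  set.seed(7)
  for (i in 1:20) {
    d <- runif(3, 0.3, 3)
    expect_gte(ellipsoid_surface_area(d, 0.6), sphere - 1e-9)
  }
  expect_error(ellipsoid_surface_area(c(-1, 1, 1), 0.5), "positive")
  expect_error(ellipsoid_surface_area(c(1, 1, 1), 0), "target_volume")
})
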