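test_that("stage-1 fit recovers exact lines and validates its input", {
  m_true <- 0.795; b_true <- 0.654
  ptv <- c(1, 10^0.5, 10)
  tv12 <- 10^(m_true * log10(ptv) + b_true)
  fit <- fit_stage1(ptv, tv12, "CAT", 24)
  expect_equal(fit$m, m_true, tolerance = 1e-10)
  expect_equal(fit$b, b_true, tolerance = 1e-10)
  expect_equal(fit$r2, 1.0, tolerance = 1e-12)
  expect_equal(fit$n_points, 3L)

  expect_error(fit_stage1(c(1, 2), c(1, 2), "CAT", 24), "at least 3")
  expect_error(fit_stage1(c(1, 2, -1), c(1, 2, 3), "CAT", 24), "positive")
  expect_error(fit_stage1(c(1, 1, 1), c(1, 2, 3), "CAT", 24), "unfittable")
})

test_that("stage-1 least squares and r2 agree with a grid-search oracle", {
  set.seed(19)
  x <- log10(10^runif(8, -1.2, 0.35))
  y <- 0.8 * x + 0.5 + rnorm(8, 0, 0.08)
  fit <- fit_stage1(10^x, 10^y, "CAT", 24)
  oracle <- grid_search_line(x, y, c(0.5, 1.1), c(0.2, 0.8))
  ss_fit <- sum((y - fit$m * x - fit$b)^2)
  expect_lte(ss_fit, oracle$ss + 1e-9)
  expect_equal(fit$m, oracle$m, tolerance = 2e-3)
  expect_equal(fit$b, oracle$b, tolerance = 2e-3)
  expect_equal(fit$r2, 1 - ss_fit / sum((y - mean(y))^2), tolerance = 1e-12)
})

test_that("stage-1 on noisy synthetic data recovers the generating slope", {
  truth <- reference_model("CAT")
  set.seed(101)
  ptv <- 10^runif(50, log10(0.05), log10(2.43))
  m_true <- truth$a * 24^truth$c
  tv12 <- suppressWarnings(predict_tv12(truth, ptv, 24)) * 10^rnorm(50, 0, 0.05)
  fit <- fit_stage1(ptv, tv12, "CAT", 24)
  expect_lt(abs(fit$m - m_true), 0.05)
  expect_gt(fit$r2, 0.90)
  expect_lte(fit$r2, 1.0)
})

test_that("stage-2 fits reproduce the reference surface parameters", {
  for (pt in c("CAT", "DCAT")) {
    ref <- ref_params(pt)
    sl <- fit_slope_vs_pd(ref_stage1(pt))
    ic <- fit_intercept_vs_pd(ref_stage1(pt))
    expect_lt(abs(sl$a - ref["a"]) / abs(ref["a"]), 0.01)
    expect_lt(abs(sl$c - ref["c"]) / abs(ref["c"]), 0.01)
    expect_lt(abs(ic$n - ref["n"]) / abs(ref["n"]), 0.01)
    expect_lt(abs(ic$d - ref["d"]) / abs(ref["d"]), 0.01)
  }
})

test_that("stage-2 slope fit handles degenerate and exact inputs", {
  mk <- function(pd, m, b) structure(
    list(plan_type = "CAT", pd = pd, m = m, b = b, r2 = 1, n_points = 10L),
    class = "stage1_fit")
  # constant slopes: exponent 0, r2 undefined
  const <- lapply(c(15, 18, 21, 24), function(p) mk(p, 0.8, 0.5))
  sl <- fit_slope_vs_pd(const)
  expect_equal(sl$a, 0.8)
  expect_equal(sl$c, 0)
  expect_true(is.na(sl$r2))
  # slopes exactly on a power law: nls equals the log-linear solution
  exact <- lapply(c(15, 18, 21, 24),
                  function(p) mk(p, 1.3 * p^-0.2, log10(0.24 * p - 1.2)))
  for (method in c("nls", "loglinear")) {
    sl <- fit_slope_vs_pd(exact, method = method)
    expect_equal(sl$a, 1.3, tolerance = 1e-8)
    expect_equal(sl$c, -0.2, tolerance = 1e-8)
    expect_equal(sl$r2, 1.0, tolerance = 1e-10)
  }
  # intercepts exactly on a line in 10^b
  two <- lapply(c(10, 20), function(p) mk(p, 0.8, log10(0.2 * p + 1)))
  ic <- fit_intercept_vs_pd(two)
  expect_equal(ic$n, 0.2, tolerance = 1e-10)
  expect_equal(ic$d, 1.0, tolerance = 1e-10)
  expect_equal(ic$r2, 1.0, tolerance = 1e-12)

  expect_error(fit_slope_vs_pd(const[1:2]), ">= 3 distinct")
  expect_error(fit_slope_vs_pd(lapply(c(15, 18, 21), function(p)
    mk(p, -0.1, 0))), "positive")
  expect_error(fit_intercept_vs_pd(list(mk(15, 0.8, 0.4))), ">= 2 distinct")
})

test_that("reference per-category fits show the expected ordering", {
  df <- reference_stage1_fits()
  cat_m <- df$m[df$plan_type == "CAT"][order(df$pd_gy[df$plan_type == "CAT"])]
  dcat_m <- df$m[df$plan_type == "DCAT"][order(df$pd_gy[df$plan_type == "DCAT"])]
  expect_true(all(dcat_m < cat_m))         # conformal slopes are shallower
  expect_true(all(diff(cat_m) < 0))        # slopes fall with dose
  expect_true(all(diff(dcat_m) < 0))
})

test_that("build_model round-trips a noiseless surface and is idempotent", {
  truth <- reference_models()
  ptv <- 10^seq(log10(0.05), log10(2.43), length.out = 12)
  recs <- c(exact_surface_records(truth$CAT, ptv, c(15, 18, 21, 24)),
            exact_surface_records(truth$DCAT, ptv, c(15, 18, 21, 24)))
  fit <- build_model(recs)
  for (pt in c("CAT", "DCAT")) {
    for (p in c("a", "c", "n", "d")) {
      expect_equal(fit[[pt]][[p]], truth[[pt]][[p]], tolerance = 1e-6,
                   label = paste(pt, p))
    }
    expect_equal(fit[[pt]]$pd_domain, c(15, 24))
    expect_equal(fit[[pt]]$ptv_domain, range(ptv))
  }
  # refitting on data generated from the fitted model reproduces it
  recs2 <- exact_surface_records(fit$CAT, ptv, c(15, 18, 21, 24))
  fit2 <- build_model(recs2)
  for (p in c("a", "c", "n", "d")) {
    expect_equal(fit2$CAT[[p]], fit$CAT[[p]], tolerance = 1e-8)
  }
})

test_that("build_model reports exactly which categories are missing or thin", {
  truth <- reference_model("CAT")
  recs <- exact_surface_records(truth, c(0.1, 0.5, 1.5), c(15, 18))
  expect_error(build_model(recs), ">= 3 prescription doses")
  recs2 <- c(exact_surface_records(truth, c(0.1, 0.5, 1.5), c(15, 18, 21)),
             exact_surface_records(truth, c(0.1, 0.5), 24))
  expect_error(build_model(recs2), "under-filled: 24")
  nomeas <- list(plan_record("q", "CAT", 24, ptv = 1, gtv = 0.5))
  expect_error(build_model(nomeas), "tv12")
})

test_that("model JSON serialization round-trips", {
  spec <- cohort_spec(n_plans = 12, seed = 23)
  models <- build_model(generate_cohort(spec))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(models, f)
  back <- read_model(f)
  expect_setequal(names(back), c("CAT", "DCAT"))
  for (pt in names(models)) {
    for (p in c("a", "c", "n", "d", "r2_slope_fit", "r2_intercept_fit")) {
      expect_equal(back[[pt]][[p]], models[[pt]][[p]], tolerance = 1e-12)
    }
    expect_equal(back[[pt]]$pd_domain, models[[pt]]$pd_domain)
  }
  expect_error(read_model(system.file("extdata", "reference_stage1_fits.csv",
                                      package = "srspreplan")))
})
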