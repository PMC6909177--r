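# shared fixtures and independent oracles

# stage1_fit objects rebuilt from the packaged reference table
ref_stage1 <- function(plan_type) {
  df <- reference_stage1_fits()
  df <- df[df$plan_type == plan_type, ]
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(plan_type = plan_type, pd = df$pd_gy[i], m = df$m[i],
                   b = df$b[i], r2 = df$r2[i], n_points = 50L),
              class = "stage1_fit")
  })
}

ref_params <- function(plan_type) {
  p <- reference_stage2_params()
  unlist(p[p$plan_type == plan_type, c("a", "c", "n", "d")])
}

# plan records lying exactly on a model surface (no noise)
exact_surface_records <- function(model, ptv, pds) {
  recs <- list()
  for (pd in pds) {
    tv <- suppressWarnings(predict_tv12(model, ptv, pd))
    for (i in seq_along(ptv)) {
      recs[[length(recs) + 1L]] <- plan_record(
        sprintf("x%02d", i), model$plan_type, pd = pd, ptv = ptv[i],
        gtv = 0.5 * ptv[i], tv12 = tv[i], pidl = 80)
    }
  }
  recs
}

# exact ellipsoid surface area by numerical quadrature of the surface integral
# over the standard spherical parametrization
ellipsoid_area_quadrature <- function(semi) {
  a <- semi[1]; b <- semi[2]; c <- semi[3]
  integrand <- function(theta, phi) {
    sin(phi) * sqrt((b * c * sin(phi) * cos(theta))^2 +
                    (a * c * sin(phi) * sin(theta))^2 +
                    (a * b * cos(phi))^2)
  }
  pracma::integral2(integrand, 0, 2 * pi, 0, pi, reltol = 1e-10)$Q
}

# brute-force (m, b) grid search oracle for the stage-1 least-squares problem
grid_search_line <- function(x, y, m_range, b_range, n_grid = 401) {
  ms <- seq(m_range[1], m_range[2], length.out = n_grid)
  bs <- seq(b_range[1], b_range[2], length.out = n_grid)
  best <- list(ss = Inf)
  for (m in ms) {
    res <- outer(y - m * x, bs, `-`)   # residuals for every b at this m
    ss <- colSums(res^2)
    j <- which.min(ss)
    if (ss[j] < best$ss) best <- list(m = m, b = bs[j], ss = ss[j])
  }
  best
}
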