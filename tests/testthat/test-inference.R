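test_that("modal ratios carry values and propagated uncertainty", {
  r <- modal_ratios(c(1.0, 2.7566, 5.4039) * 1e6)
  expect_equal(r$r21, 2.7566, tolerance = 1e-12)
  expect_equal(r$r32, 5.4039 / 2.7566, tolerance = 1e-12)
  # string-like frequencies
  rs <- modal_ratios(c(1, 2, 3) * 1e6)
  expect_equal(c(rs$r21, rs$r32), c(2, 1.5))
  # uncertainty propagation: relative errors add in quadrature
  rp <- modal_ratios(c(1e6, 2e6), se = c(1e4, 2e4))
  expect_equal(rp$r21_se, 2 * sqrt(0.01^2 + 0.01^2), tolerance = 1e-12)
  # duplicated modes are flagged degenerate
  expect_true(modal_ratios(c(1e6, 1e6, 2e6))$degenerate)
  expect_error(modal_ratios(1e6))
})

test_that("configuration classification separates beam, string and midpoint", {
  expect_equal(classify_configuration(c(2.76, 1.96), se = c(0.01, 0.01))$class,
               "beam")
  expect_equal(classify_configuration(c(2.0, 1.5), se = c(0.01, 0.01))$class,
               "string")
  # normalized midpoint is indeterminate even with tight uncertainty
  mid <- classify_configuration(c(2.378, 1.730), se = c(0.01, 0.01))
  expect_equal(mid$class, "indeterminate")
  expect_equal(mid$d_beam, mid$d_string, tolerance = 0.02)
  # works from f2/f1 alone
  expect_equal(classify_configuration(c(2.7, NA))$class, "beam")
  expect_error(classify_configuration(c(NA, NA)), "f2/f1")
})

test_that("frequencies from the unstressed beam always classify as beam, and
           tension-dominated ones as string", {
  set.seed(31)
  for (i in 1:20) {
    g <- bundle_geometry(runif(1, 10e-6, 15e-6), runif(1, 30e-9, 100e-9))
    m <- material_state(runif(1, 2e9, 13e9), 1700)
    f <- beam_frequencies(g, m, 3)$frequency
    expect_equal(classify_configuration(modal_ratios(f))$class, "beam")
    lam1 <- clamped_clamped_modal_factors(1)
    sig <- 100 * m$young_modulus * g$moment * lam1^2 / (g$area * g$length^2)
    fs <- string_frequencies(g, material_state(m$young_modulus, 1700, sig),
                             3)$frequency
    expect_equal(classify_configuration(modal_ratios(fs))$class, "string")
  }
})

test_that("frequency-geometry regression inverts to the generating modulus", {
  lam1 <- clamped_clamped_modal_factors(1)
  set.seed(8)
  L <- runif(12, 10e-6, 15e-6)
  R <- runif(12, 15e-9, 50e-9)
  E0 <- 5.3e9; rho <- 1700
  f1 <- lam1^2 / (4 * pi) * R / L^2 * sqrt(E0 / rho)
  fit <- suppressWarnings(   # noise-free points: exact fit is intended
    fit_frequency_vs_geometry(data.frame(f1 = f1, R = R, L = L)))
  expect_equal(fit$slope, lam1^2 / (4 * pi) * sqrt(E0 / rho),
               tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  em <- young_modulus_from_slope(fit$slope, rho, fit$slope_se)
  expect_equal(em$E, E0, tolerance = 1e-12)
  # density misspecification scales E linearly
  em15 <- young_modulus_from_slope(fit$slope, rho * 1.5 / 1.7)
  expect_equal(em15$E / em$E, 1.5 / 1.7, tolerance = 1e-12)
  # uncertainty: dE/E = 2 dslope/slope
  em_se <- young_modulus_from_slope(fit$slope, rho, 0.05 * fit$slope)
  expect_equal(em_se$E_se / em_se$E, 0.10, tolerance = 1e-12)
  expect_error(fit_frequency_vs_geometry(
    data.frame(f1 = c(1, 2), R = c(1, 2) * 1e-8, L = c(1, 1) * 1e-5)),
    "3 bundles")
  expect_error(fit_frequency_vs_geometry(
    data.frame(f1 = c(1, 2, 3), R = rep(2e-8, 3), L = rep(1e-5, 3))),
    "degenerate")
})

test_that("noisy populations recover the modulus within 10%", {
  lam1 <- clamped_clamped_modal_factors(1)
  E0 <- 5.3e9; rho <- 1700
  set.seed(99)
  ok <- 0L
  for (rep in 1:20) {
    L <- runif(25, 10e-6, 15e-6)
    R <- runif(25, 15e-9, 50e-9)
    f1 <- lam1^2 / (4 * pi) * R / L^2 * sqrt(E0 / rho) *
      (1 + rnorm(25, 0, 0.02))
    fit <- fit_frequency_vs_geometry(data.frame(f1 = f1, R = R, L = L))
    Eh <- young_modulus_from_slope(fit$slope, rho)$E
    if (abs(Eh - E0) / E0 < 0.10) ok <- ok + 1L
  }
  expect_gte(ok, 19)
})

test_that("asymmetry factor conversions match the worked examples", {
  expect_equal(asymmetry_from_split(1e6, 1e6)$omega_freq, 0)
  a <- asymmetry_from_split(1.0115e6, 1.0e6)
  expect_equal(a$omega_freq, 0.0115 / 1.0115, tolerance = 1e-12)
  expect_equal(a$diameter_ratio, 1.0115, tolerance = 1e-12)
  expect_equal(a$omega_exact, 0.0115, tolerance = 1e-9)
  # reported diameter-difference band: Omega = 1.15% on 30 and 100 nm
  expect_equal(omega_to_diameter_difference(0.0115, 30), 0.345,
               tolerance = 1e-12)
  expect_equal(omega_to_diameter_difference(0.0115, 100), 1.15,
               tolerance = 1e-12)
  expect_error(asymmetry_from_split(1.0e6, 1.1e6), "f_fast")
  # exact and first-order forms agree within 2 Omega^2 for Omega <= 5%
  for (om in c(0.005, 0.0115, 0.03, 0.05)) {
    b <- asymmetry_from_split(1e6 * (1 + om), 1e6)
    expect_lt(abs(b$omega_freq - b$omega_exact) / b$omega_exact, 2 * om)
  }
})

test_that("condition summaries report means, stds and splitting changes", {
  set.seed(4)
  mk <- function(cond, E, om, n = 10)
    data.frame(condition = cond, E = rnorm(n, E, 0.05 * E),
               omega = rnorm(n, om, 0.01 * om), q_air = 5, q_vacuum = 250)
  meas <- rbind(mk("pristine", 5.3e9, 0.0115), mk("YOYO-1", 8.1e9, 0.0115 * 1.32),
                mk("GelRed", 12.6e9, 0.0115 * 1.82), mk("CisPt", 2.6e9, 0.0115 * 1.21))
  s <- summarize_condition(meas)
  expect_equal(s$condition[order(-s$E_mean)],
               c("GelRed", "YOYO-1", "pristine", "CisPt"))
  chg <- s$splitting_change_pct[match(c("YOYO-1", "CisPt", "GelRed"),
                                      s$condition)]
  expect_equal(chg, c(32, 21, 82), tolerance = 0.1)
  expect_true(is.na(s$splitting_change_pct[s$condition == "pristine"]))
  # single-bundle group: mean only, no std
  s1 <- summarize_condition(data.frame(condition = c("pristine", "solo"),
                                       E = c(5e9, 6e9)))
  expect_true(is.na(s1$E_sd[s1$condition == "solo"]))
  expect_equal(s1$E_mean[s1$condition == "solo"], 6e9)
})

test_that("titration summaries flag the plateau and the sub-saturation trend", {
  set.seed(5)
  doses <- c("4x", "2x", "1x", "0.5x", "0.05x", "0.01x")
  truth <- c(2.55e9, 2.65e9, 2.6e9, 3.3e9, 4.4e9, 5.1e9)
  meas <- do.call(rbind, lapply(seq_along(doses), function(i)
    data.frame(dose = doses[i], E = rnorm(8, truth[i], 0.1e9))))
  t1 <- titration_summary(meas)
  expect_true(t1$monotone_below_saturation)
  expect_true(t1$plateau)
  expect_equal(t1$plateau_status, "ok")
  expect_equal(t1$table$dose, c(4, 2, 1, 0.5, 0.05, 0.01))
  # constant series: plateau but no trend
  cst <- data.frame(dose = rep(doses, each = 4), E = 2.6e9)
  t2 <- titration_summary(cst)
  expect_true(t2$plateau)
  expect_false(isTRUE(t2$monotone_below_saturation))
  # two doses only: underpowered plateau check
  t3 <- titration_summary(data.frame(dose = c("1x", "0.5x", "1x", "0.5x"),
                                     E = c(2.6e9, 3.5e9, 2.7e9, 3.4e9)))
  expect_equal(t3$plateau_status, "underpowered")
  expect_true(is.na(t3$plateau))
  expect_error(titration_summary(data.frame(dose = "9x", E = 1e9)),
               "unknown dose")
})
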