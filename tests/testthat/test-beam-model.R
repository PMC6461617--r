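# Eigenvalues frozen from an independent bracketed bisection on
# cos(l)cosh(l) - 1 over ((k - 1/2)pi, (k + 1/2)pi) (scipy.optimize.brentq,
# xtol 1e-14):
LAMBDA_REF <- c(4.7300407449, 7.8532046241, 10.9956078380,
                14.1371654913, 17.2787596574)

test_that("clamped-clamped modal factors match the characteristic equation", {
  l <- clamped_clamped_modal_factors(5)
  expect_equal(l, LAMBDA_REF, tolerance = 1e-9)
  expect_true(all(diff(l) > 0))
  # residual of the characteristic equation itself
  expect_true(all(abs(cos(l) * cosh(l) - 1) < 1e-6 * cosh(l)))
  # unstressed mode ratios at the conventionally quoted 2-decimal precision
  expect_equal(round((l[2] / l[1])^2, 2), 2.76)
  expect_equal(round((l[3] / l[2])^2, 2), 1.96)
  # large-n asymptote lambda_n -> (n + 1/2) pi
  expect_lt(abs(l[5] / (5.5 * pi) - 1), 1e-4)
  expect_error(clamped_clamped_modal_factors(0), "positive integer")
})

test_that("general, circular and unstressed beam forms agree to 1e-12", {
  set.seed(42)
  for (i in 1:100) {
    L <- runif(1, 5e-6, 20e-6)
    d <- runif(1, 20e-9, 200e-9)
    E <- runif(1, 1e9, 20e9)
    rho <- runif(1, 1200, 2000)
    sig <- runif(1, 0, 5e7)
    g <- bundle_geometry(L, d)
    m <- material_state(E, rho, sig)
    f_gen <- beam_frequencies_general(g, m, 3)$frequency
    f_circ <- beam_frequencies(g, m, 3)$frequency
    expect_equal(f_circ, f_gen, tolerance = 1e-12)
    m0 <- material_state(E, rho, 0)
    f0_gen <- beam_frequencies_general(g, m0, 3)$frequency
    f0_circ <- beam_frequencies(g, m0, 3)$frequency
    expect_equal(f0_circ, f0_gen, tolerance = 1e-12)
    # tension factor is exactly 1 at sigma = 0
    lam <- clamped_clamped_modal_factors(3)
    f0_closed <- lam^2 / (4 * pi) * (d / 2) / L^2 * sqrt(E / rho)
    expect_equal(f0_circ, f0_closed, tolerance = 1e-12)
  }
})

test_that("unstressed frequencies scale as R / L^2 and match the worked value", {
  m <- pristine_material()
  f_base <- beam_frequencies(pristine_geometry(), m, 3)$frequency
  f_2R <- beam_frequencies(pristine_geometry(d = 200e-9), m, 3)$frequency
  f_2L <- beam_frequencies(pristine_geometry(L = 24e-6), m, 3)$frequency
  expect_equal(f_2R, 2 * f_base, tolerance = 1e-12)
  expect_equal(f_2L, f_base / 4, tolerance = 1e-12)
  # E = 5.3 GPa, rho = 1700, R = 50 nm, L = 12 um -> f1 ~ 1.0915 MHz
  # (independent one-line evaluation of the unstressed form)
  expect_equal(f_base[1], 1091543, tolerance = 1e-5)
})

test_that("string frequencies have integer mode ratios and sqrt(sigma) scaling", {
  g <- pristine_geometry()
  m1 <- material_state(5.3e9, 1700, 1e6)
  f <- string_frequencies(g, m1, 3)$frequency
  expect_equal(f[2] / f[1], 2, tolerance = 1e-15)
  expect_equal(f[3] / f[2], 1.5, tolerance = 1e-15)
  # prefactor: standard taut string n / (2L) sqrt(sigma / rho)
  expect_equal(f[1], 1 / (2 * g$length) * sqrt(1e6 / 1700), tolerance = 1e-15)
  m4 <- material_state(5.3e9, 1700, 4e6)
  expect_equal(string_frequencies(g, m4, 3)$frequency, 2 * f,
               tolerance = 1e-15)
  expect_error(string_frequencies(g, pristine_material(), 3), "tension")
})

test_that("stressed beam approaches the tension-dominated limit", {
  g <- pristine_geometry()
  # choose sigma so the tension term is ~1e6 for mode 1
  lam1 <- clamped_clamped_modal_factors(1)
  sig <- 1e6 * 5.3e9 * g$moment * lam1^2 / (g$area * g$length^2)
  m <- material_state(5.3e9, 1700, sig)
  chk <- high_tension_limit_check(g, m, 3)
  expect_true(attr(chk, "applicable"))
  expect_gt(chk$tension_term[1], 1e5)
  expect_true(all(abs(chk$ratio - 1) < 1e-3))
  # not applicable without tension
  chk0 <- high_tension_limit_check(g, pristine_material(), 3)
  expect_false(attr(chk0, "applicable"))
  expect_true(all(is.na(chk0$ratio)))
})

test_that("elliptic splitting obeys f_M / f_m = d_max / d_min and the circular limit", {
  m <- pristine_material()
  set.seed(7)
  for (i in 1:50) {
    d <- runif(1, 30e-9, 100e-9)
    ecc <- 1 + runif(1, 0, 0.05)
    g <- bundle_geometry(12e-6, d, d_max = d * ecc, d_min = d)
    sp <- split_frequencies(g, m, 2)
    ff <- sp$frequency[sp$plane == "fast"]
    fs <- sp$frequency[sp$plane == "slow"]
    expect_equal(ff / fs, rep(ecc, 2), tolerance = 1e-12)
    # relative splitting = 1 - d_min/d_max
    expect_equal((ff - fs) / ff, rep(1 - 1 / ecc, 2), tolerance = 1e-12)
  }
  # degenerate ellipse reproduces the circular beam exactly
  g0 <- bundle_geometry(12e-6, 100e-9)
  sp0 <- split_frequencies(g0, m, 3)
  f_circ <- beam_frequencies(g0, m, 3)$frequency
  expect_equal(sp0$frequency[sp0$plane == "fast"], f_circ, tolerance = 1e-12)
  expect_equal(sp0$frequency[sp0$plane == "slow"], f_circ, tolerance = 1e-12)
  expect_error(bundle_geometry(12e-6, 1e-7, d_max = 9e-8, d_min = 1e-7),
               "d_min")
})

test_that("mass, sensitivity and limit of detection reproduce worked values", {
  g <- bundle_geometry(10e-6, 100e-9)
  m <- pristine_material()
  mass <- mass_of_bundle(g, m)
  expect_equal(kg_to_ag(mass), 1.335177e5, tolerance = 1e-6)
  # density scaling is linear
  m15 <- material_state(5.3e9, 1500)
  expect_equal(mass_of_bundle(g, m15) / mass, 1500 / 1700, tolerance = 1e-12)
  f1 <- beam_frequencies(g, m, 1)$frequency
  s <- sensitivity(f1, mass)
  expect_lt(s$S_hz_per_kg, 0)                       # added mass lowers f
  expect_equal(s$abs_S_hz_per_ag, 5.886194, tolerance = 1e-6)
  expect_equal(sensitivity(f1, 2 * mass)$abs_S_hz_per_ag,
               s$abs_S_hz_per_ag / 2, tolerance = 1e-12)
  expect_equal(sensitivity(0, mass)$S_hz_per_kg, 0)
  lod <- limit_of_detection(mass, 1e-4)
  expect_equal(lod$dm_min_ag, 26.70354, tolerance = 1e-6)
  expect_equal(limit_of_detection(mass, 0)$dm_min_ag, 0)
  # round trip: dm_min equals f * (df/f) / |S|
  expect_equal(lod$dm_min_kg, f1 * 1e-4 / abs(s$S_hz_per_kg),
               tolerance = 1e-12)
})

test_that("invalid physical inputs are rejected with descriptive errors", {
  expect_error(bundle_geometry(-1e-6, 1e-7), "length")
  expect_error(bundle_geometry(1e-5, Inf), "diameter")
  expect_error(material_state(0, 1700), "young_modulus")
  expect_error(material_state(5e9, 1700, -1), "axial_stress")
  expect_error(split_frequencies(pristine_geometry(),
                                 material_state(5e9, 1700, 1e5)),
               "unstressed")
  expect_error(beam_frequencies(
    bundle_geometry(1e-5, 1e-7, d_max = 1.1e-7, d_min = 1e-7),
    pristine_material()), "circular")
})
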