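test_that("driven-oscillator lineshape has the stated resonance properties", {
  f0 <- 1e6
  expect_equal(sho_response(f0, f0, 250, 2), 2 * 250)   # a * Q at resonance
  # 3 dB bandwidth approx f0 / Q in the high-Q limit
  sp <- single_mode_spectrum(f0, q = 250, snr = Inf, n = 60000)
  q3 <- q_from_3db(sp, f0)
  expect_equal(q3$f_hi - q3$f_lo, 4000, tolerance = 0.01)
  # bandwidth scales as 1/Q
  sp5 <- single_mode_spectrum(f0, q = 5, snr = Inf, n = 60000)
  q5 <- q_from_3db(sp5, f0)
  expect_equal((q5$f_hi - q5$f_lo) / (q3$f_hi - q3$f_lo), 50,
               tolerance = 0.05)
})

test_that("3 dB estimator matches Q across the damping range on exact curves", {
  for (q in c(5, 8, 50, 250, 500)) {
    sp <- single_mode_spectrum(1e6, q = q, snr = Inf, n = 60000)
    expect_equal(q_from_3db(sp, 1e6)$q, q, tolerance = 0.05)
  }
  # truncated spectrum missing the upper crossing errors by name
  f0 <- 1e6
  grid <- seq(0.5 * f0, f0, length.out = 2000)
  spt <- synthesize_spectrum(data.frame(frequency = f0, q = 5), grid, 0,
                             seed = 1)
  expect_error(q_from_3db(spt, f0), "upper")
})

test_that("spectrum synthesis is seed-deterministic and additive", {
  f0 <- 1e6
  modes <- data.frame(frequency = f0, q = 5)
  grid <- seq(0.5 * f0, 1.5 * f0, length.out = 500)
  a <- synthesize_spectrum(modes, grid, 0.3, seed = 11)
  b <- synthesize_spectrum(modes, grid, 0.3, seed = 11)
  c_ <- synthesize_spectrum(modes, grid, 0.3, seed = 12)
  expect_identical(a$amplitude, b$amplitude)
  expect_false(identical(a$amplitude, c_$amplitude))
  # zero noise reproduces the exact lineshape
  clean <- synthesize_spectrum(modes, grid, 0, seed = 1)
  expect_equal(clean$amplitude, sho_response(grid, f0, 5), tolerance = 1e-12)
  expect_error(synthesize_spectrum(modes, grid, -1, seed = 1), "noise_sd")
})

test_that("peak detection finds modes and nothing on flat traces", {
  g <- pristine_geometry(); m <- pristine_material()
  f <- beam_frequencies(g, m, 3)$frequency
  grid <- seq(0.55 * f[1], 1.25 * f[3], length.out = 2000)
  modes <- data.frame(frequency = f, q = c(5, 8, 8))
  clean <- synthesize_spectrum(modes, grid, 0, seed = 1)
  pk <- detect_peaks(clean, min_prominence = 1)
  expect_equal(nrow(pk), 3)
  # apparent maxima sit slightly below f0 at low Q (the amplitude-response
  # peak is at f0 sqrt(1 - 1/(2 Q^2))) and are nudged by neighbouring-mode
  # tails, so locations are checked to 2%
  expect_true(all(abs(pk$frequency - f) <= 0.02 * f))
  flat <- synthesize_spectrum(
    data.frame(frequency = 1, q = 1, amplitude = 0), grid, 0, seed = 1)
  expect_equal(nrow(detect_peaks(flat, min_prominence = 0.1)), 0)
})

test_that("noisy three-mode spectra yield three candidates in most seeds", {
  g <- pristine_geometry(); m <- pristine_material()
  f <- beam_frequencies(g, m, 3)$frequency
  grid <- seq(0.55 * f[1], 1.25 * f[3], length.out = 2000)
  modes <- data.frame(frequency = f, q = c(5, 8, 8))
  hits <- 0L
  for (s in 1:100) {
    sp <- synthesize_spectrum(modes, grid, noise_sd = 8 / 20, seed = s)
    pk <- detect_peaks(sp)
    near <- vapply(f, function(fm)
      any(abs(pk$frequency - fm) < 0.05 * fm), logical(1))
    if (all(near)) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("resonance fitting recovers truth and rejects peakless windows", {
  sp <- single_mode_spectrum(1e6, q = 5, snr = Inf, n = 2000)
  fit <- fit_resonance(sp, 1e6)
  expect_equal(fit$f0, 1e6, tolerance = 1e-6)
  expect_equal(fit$q, 5, tolerance = 1e-6)
  # flat window -> descriptive error, never a silent non-fit
  grid <- seq(5e5, 1.5e6, length.out = 800)
  flatish <- synthesize_spectrum(
    data.frame(frequency = 1e6, q = 5, amplitude = 1e-9), grid,
    noise_sd = 1, seed = 3)
  expect_error(fit_resonance(flatish, 1e6), "resonance")
})

test_that("fit and 3 dB quality factors agree on isolated peaks", {
  for (q in c(5, 20, 100, 500)) {
    sp <- single_mode_spectrum(1e6, q = q, snr = Inf, n = 40000)
    fit <- fit_resonance(sp, 1e6)
    q3 <- q_from_3db(sp, 1e6)$q
    expect_equal(q3 / fit$q, 1, tolerance = 0.05)
  }
})

test_that("noisy round-trip recovery of f0 and Q is accurate in the median", {
  errs_f <- errs_q <- numeric(50)
  for (s in 1:50) {
    sp <- single_mode_spectrum(1e6, q = 5, snr = 10, seed = s, n = 3000)
    pk <- detect_peaks(sp)
    fit <- fit_resonance(sp, pk$frequency[which.max(pk$prominence)])
    errs_f[s] <- abs(fit$f0 - 1e6) / 1e6
    errs_q[s] <- abs(fit$q - 5) / 5
  }
  expect_lt(stats::median(errs_f), 0.001)
  expect_lt(stats::median(errs_q), 0.10)
})

test_that("doublet resolution follows the Omega x Q criterion", {
  # vacuum: Omega * Q = 2.9 -> resolved, centers within 0.05%
  db <- resolve_doublet(doublet_spectrum(seed = 5), 1e6 * 1.006)
  expect_true(db$resolved)
  expect_equal(db$slow$f0, 1e6, tolerance = 5e-4)
  expect_equal(db$fast$f0, 1.0115e6, tolerance = 5e-4)
  # zero splitting -> unresolved flag, not an error
  sp0 <- doublet_spectrum(omega = 0, seed = 6)
  db0 <- resolve_doublet(sp0, 1e6)
  expect_false(db0$resolved)
  expect_null(db0$slow)
  # air Q = 5 cannot resolve a 1.15% splitting (Omega * Q << 1)
  f0 <- 1e6; ff <- f0 * 1.0115
  grid <- seq(0.4e6, 1.8e6, length.out = 1500)
  spa <- synthesize_spectrum(data.frame(frequency = c(ff, f0), q = 5),
                             grid, noise_sd = 0.5, seed = 7)
  dba <- resolve_doublet(spa, f0)
  expect_false(dba$resolved)
})

test_that("doublet resolvability is monotone in Omega x Q", {
  resolved_at <- vapply(c(0.0005, 0.002, 0.0115, 0.02), function(om) {
    db <- resolve_doublet(doublet_spectrum(omega = om, seed = 9),
                          1e6 * (1 + om / 2))
    db$resolved
  }, logical(1))
  # once resolvable, stays resolvable at larger splitting
  expect_true(all(diff(as.integer(resolved_at)) >= 0))
  expect_false(resolved_at[1])
  expect_true(resolved_at[3])
})
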