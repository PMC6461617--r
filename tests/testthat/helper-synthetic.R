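# shared fixtures built in code

# canonical pristine bundle used across tests
pristine_geometry <- function(L = 12e-6, d = 100e-9)
  bundle_geometry(L, d)

pristine_material <- function(E = 5.3e9, rho = 1700, sigma = 0)
  material_state(E, rho, sigma)

# single-mode spectrum with controllable Q and signal-to-noise ratio;
# noise_sd is peak height / snr (snr = Inf -> noise-free)
single_mode_spectrum <- function(f0 = 1e6, q = 5, snr = Inf, seed = 1,
                                 n = 1500, span = c(0.3, 2.2)) {
  grid <- seq(f0 * span[1], f0 * span[2], length.out = n)
  noise <- if (is.finite(snr)) q / snr else 0
  synthesize_spectrum(data.frame(frequency = f0, q = q, amplitude = 1),
                      grid, noise_sd = noise, seed = seed)
}

# vacuum-style doublet spectrum around a split fundamental
doublet_spectrum <- function(f0 = 1e6, omega = 0.0115, q = 250, snr = 20,
                             seed = 1, n = 900) {
  ff <- f0 * (1 + omega)
  ctr <- (f0 + ff) / 2
  grid <- seq(ctr * 0.975, ctr * 1.025, length.out = n)
  noise <- if (is.finite(snr)) q / snr else 0
  synthesize_spectrum(data.frame(frequency = c(ff, f0), q = q),
                      grid, noise_sd = noise, seed = seed,
                      environment = "vacuum")
}
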