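#' Condition presets for the synthetic experiment
#'
#' Ground-truth parameters of the four experimental conditions used by the
#' generator: effective Young's modulus, density (pristine DNA 1700
#' kg m^-3, intercalated ~1500), asymmetry-factor multiplier relative to
#' pristine (whose base splitting is 1.15%), and air/vacuum quality
#' factors. These are generator INPUTS used for recovery testing, never
#' outputs of the pipeline.
#'
#' @return Data frame with one row per condition (`pristine`, `YOYO-1`,
#'   `GelRed`, `CisPt`): `E` (Pa), `rho` (kg m^-3), `omega_mult`,
#'   `q_air1`, `q_air23`, `q_vacuum`, `cv_E`, `cv_omega`.
#' @export
condition_presets <- function() {
  data.frame(
    condition  = c("pristine", "YOYO-1", "GelRed", "CisPt"),
    E          = c(5.3e9, 8.1e9, 12.6e9, 2.6e9),
    rho        = c(1700, 1500, 1500, 1500),
    omega_mult = c(1.00, 1.32, 1.82, 1.21),
    q_air1     = 5,
    q_air23    = 8,
    q_vacuum   = 250,
    cv_E       = 0.20,
    cv_omega   = 0.05,
    stringsAsFactors = FALSE
  )
}

#' Generator configuration
#'
#' Study-level knobs of the synthetic experiment: geometry ranges of the
#' suspended bundles (lengths 10-15 um, diameters 30-100 nm), the 7%
#' within-bundle diameter variability treated as diameter measurement
#' error, base asymmetry 1.15%, 1% frequency measurement jitter, and
#' spectral signal-to-noise ratios.
#'
#' @param n_bundles Bundles per condition (default 25).
#' @param L_range Length range in m.
#' @param d_range Diameter range in m.
#' @param diameter_variability Relative sd of the reported diameter.
#' @param omega_base Pristine asymmetry factor (default 0.0115).
#' @param freq_jitter Relative sd of per-mode frequency measurement error.
#' @param snr_air,snr_vacuum Peak-amplitude / noise-sd ratios.
#' @param n_points_air,n_points_vacuum Spectrum grid sizes.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_bundles = 25,
                             L_range = c(10e-6, 15e-6),
                             d_range = c(30e-9, 100e-9),
                             diameter_variability = 0.07,
                             omega_base = 0.0115,
                             freq_jitter = 0.01,
                             snr_air = 20, snr_vacuum = 20,
                             n_points_air = 2000,
                             n_points_vacuum = 900) {
  stopifnot(n_bundles >= 1, diff(L_range) >= 0, diff(d_range) >= 0,
            omega_base >= 0, freq_jitter >= 0, snr_air > 0, snr_vacuum > 0)
  structure(list(n_bundles = n_bundles, L_range = L_range, d_range = d_range,
                 diameter_variability = diameter_variability,
                 omega_base = omega_base, freq_jitter = freq_jitter,
                 snr_air = snr_air, snr_vacuum = snr_vacuum,
                 n_points_air = n_points_air,
                 n_points_vacuum = n_points_vacuum),
            class = "generator_config")
}

rnorm_trunc_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Sample a bundle population with ground truth
#'
#' Draws `n_bundles` bundles for one condition: lengths and nominal
#' diameters uniform over the configured ranges, per-bundle modulus normal
#' around the preset truth (truncated positive, CV per preset), per-bundle
#' asymmetry normal around `omega_base * omega_mult`, and a reported
#' ("measured") diameter carrying the 7% variability. Elliptical axes are
#' set as d_min = d, d_max = d (1 + Omega).
#'
#' @param config A [generator_config()].
#' @param preset One row of [condition_presets()] (data frame or list).
#' @param seed Integer seed (mandatory).
#' @return Data frame, one row per bundle, with identifiers, true
#'   geometry/material, elliptical axes and the reported diameter.
#' @export
sample_bundles <- function(config, preset, seed) {
  stopifnot(inherits(config, "generator_config"))
  if (missing(seed)) stop("seed is required")
  n <- config$n_bundles
  withr::with_seed(seed, {
    L <- stats::runif(n, config$L_range[1], config$L_range[2])
    d <- stats::runif(n, config$d_range[1], config$d_range[2])
    E <- rnorm_trunc_pos(n, preset$E, preset$cv_E * preset$E)
    omega <- rnorm_trunc_pos(n, config$omega_base * preset$omega_mult,
                             config$cv_omega_abs %||%
                               (preset$cv_omega * config$omega_base *
                                  preset$omega_mult))
    d_obs <- d * (1 + stats::rnorm(n, 0, config$diameter_variability))
    data.frame(
      bundle_id = sprintf("%s-%02d", preset$condition, seq_len(n)),
      condition = preset$condition,
      L = L, d = d, d_obs = pmax(d_obs, 0.2 * d),
      d_min = d, d_max = d * (1 + omega),
      E_true = E, rho = preset$rho, omega_true = omega,
      stringsAsFactors = FALSE
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a full synthetic vibrometer experiment
#'
#' For every bundle of every condition, synthesizes an air spectrum with
#' the first three flexural modes (Q = 5 for the fundamental, 8 for modes
#' 2-3) and a vacuum spectrum with the fundamental split into a fast/slow
#' doublet at Q = 250. Mode frequencies come from the unstressed-beam
#' model (elliptic split for the doublet); each air mode gets independent
#' multiplicative frequency jitter, while the vacuum doublet is jittered
#' common-mode (drift moves the whole doublet, preserving the splitting
#' within a sweep).
#'
#' @param config A [generator_config()].
#' @param presets Data frame of condition presets (default
#'   [condition_presets()]).
#' @param seed Integer master seed (mandatory); per-bundle seeds are
#'   derived deterministically from it.
#' @return A list with `manifest` (bundle table including ground truth and
#'   true mode frequencies) and `spectra` (named list of `spectrum`
#'   objects, two per bundle: `<id>_air`, `<id>_vacuum`).
#' @export
generate_experiment <- function(config = generator_config(),
                                presets = condition_presets(), seed) {
  if (missing(seed)) stop("seed is required")
  manifest <- do.call(rbind, lapply(seq_len(nrow(presets)), function(i) {
    sample_bundles(config, presets[i, ], seed + i)
  }))
  manifest$q_air1 <- presets$q_air1[match(manifest$condition, presets$condition)]
  manifest$q_air23 <- presets$q_air23[match(manifest$condition, presets$condition)]
  manifest$q_vacuum <- presets$q_vacuum[match(manifest$condition, presets$condition)]
  spectra <- vector("list", 2 * nrow(manifest))
  nms <- character(2 * nrow(manifest))
  f1_true <- f2_true <- f3_true <- ff_true <- fs_true <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    b <- manifest[i, ]
    bseed <- (seed * 7919 + i * 104729) %% 2147483647
    geom_circ <- bundle_geometry(b$L, b$d)
    geom_ell <- bundle_geometry(b$L, b$d, d_max = b$d_max, d_min = b$d_min)
    mat <- material_state(b$E_true, b$rho)
    air_modes <- beam_frequencies(geom_circ, mat, 3)
    f1_true[i] <- air_modes$frequency[1]
    f2_true[i] <- air_modes$frequency[2]
    f3_true[i] <- air_modes$frequency[3]
    doublet <- split_frequencies(geom_ell, mat, 1)
    ff_true[i] <- doublet$frequency[doublet$plane == "fast"]
    fs_true[i] <- doublet$frequency[doublet$plane == "slow"]
    sp <- withr::with_seed(bseed, {
      jit_air <- 1 + stats::rnorm(3, 0, config$freq_jitter)
      jit_vac <- 1 + stats::rnorm(1, 0, config$freq_jitter)
      f_air <- air_modes$frequency * jit_air
      modes_air <- data.frame(frequency = f_air,
                              q = c(b$q_air1, b$q_air23, b$q_air23),
                              amplitude = 1)
      grid_air <- seq(0.55 * f_air[1], 1.25 * f_air[3],
                      length.out = config$n_points_air)
      noise_air <- max(modes_air$q) / config$snr_air
      f_vac <- c(ff_true[i], fs_true[i]) * jit_vac
      modes_vac <- data.frame(frequency = f_vac, q = b$q_vacuum,
                              amplitude = 1)
      ctr <- mean(f_vac)
      grid_vac <- seq(ctr * (1 - 0.025), ctr * (1 + 0.025),
                      length.out = config$n_points_vacuum)
      noise_vac <- b$q_vacuum / config$snr_vacuum
      list(
        air = synthesize_spectrum(modes_air, grid_air, noise_air,
                                  seed = bseed + 1, environment = "air",
                                  bundle_id = b$bundle_id),
        vacuum = synthesize_spectrum(modes_vac, grid_vac, noise_vac,
                                     seed = bseed + 2,
                                     environment = "vacuum",
                                     bundle_id = b$bundle_id)
      )
    })
    spectra[[2 * i - 1]] <- sp$air
    spectra[[2 * i]] <- sp$vacuum
    nms[2 * i - 1] <- paste0(b$bundle_id, "_air")
    nms[2 * i] <- paste0(b$bundle_id, "_vacuum")
  }
  names(spectra) <- nms
  manifest$f1_true <- f1_true
  manifest$f2_true <- f2_true
  manifest$f3_true <- f3_true
  manifest$f_fast_true <- ff_true
  manifest$f_slow_true <- fs_true
  list(manifest = manifest, spectra = spectra)
}

#' Ground-truth presets of the pulling simulations
#'
#' Per-system moduli used by [generate_pulling_tables()]: pristine DNA and
#' DNA with YOYO-1 or cisplatin at saturating (16 YOYO-1 / 7 CisPt) and
#' sub-saturating (8 / 3) intercalant counts.
#'
#' @return Data frame with `system`, `E_smd` (Pa), `n_intercalant`.
#' @export
smd_system_presets <- function() {
  data.frame(
    system = c("DNA", "DNA/YOYO-1", "DNA/CisPt",
               "DNA/YOYO-1-sub", "DNA/CisPt-sub"),
    E_smd = c(1.50e9, 2.61e9, 1.11e9, 1.98e9, 1.23e9),
    n_intercalant = c(0L, 16L, 7L, 8L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Generate constant-force pulling tables
#'
#' Emulates the constant-force protocol: for each system, 8 uniformly
#' spaced forces, 3 replicates each; equilibrium lengths follow linear
#' elasticity (strain = stress / E) with multiplicative Gaussian strain
#' noise per replicate, so a zero-force row always has strain exactly 0.
#'
#' @param presets Data frame as from [smd_system_presets()] (subsettable).
#' @param forces_pn Applied forces in pN (default 8 uniform levels,
#'   50-400 pN).
#' @param replicates Replicates per force (default 3).
#' @param strain_noise Relative sd of the replicate strain (default 0.02).
#' @param L0_nm Zero-force filament length (default 22.4 nm, the nominal
#'   contour of the 66-bp duplex).
#' @param helix_area_nm2 Helix cross-section (default `pi` nm^2).
#' @param seed Integer seed (mandatory).
#' @return Data frame with columns `system`, `replicate`, `force_pN`,
#'   `length_nm`; attributes `L0_nm` and `helix_area_nm2`.
#' @export
generate_pulling_tables <- function(presets = smd_system_presets(),
                                    forces_pn = seq(50, 400, length.out = 8),
                                    replicates = 3, strain_noise = 0.02,
                                    L0_nm = 22.4, helix_area_nm2 = pi,
                                    seed) {
  if (missing(seed)) stop("seed is required")
  if (length(forces_pn) < 3) stop("at least 3 force levels are required")
  out <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(presets)), function(i) {
      p <- presets[i, ]
      grid <- expand.grid(replicate = seq_len(replicates),
                          force_pN = forces_pn)
      strain_true <- stress_from_force(grid$force_pN, helix_area_nm2) /
        p$E_smd * 100
      strain <- strain_true *
        (1 + stats::rnorm(nrow(grid), 0, strain_noise))
      data.frame(system = p$system, replicate = grid$replicate,
                 force_pN = grid$force_pN,
                 length_nm = L0_nm * (1 + strain / 100),
                 stringsAsFactors = FALSE)
    }))
  })
  attr(out, "L0_nm") <- L0_nm
  attr(out, "helix_area_nm2") <- helix_area_nm2
  out
}

#' Generate a hydrogen-bond time series
#'
#' Emulates the hydrogen-bond count during maximum-stress pulling:
#' pristine DNA decays linearly to about 70% of its initial count,
#' DNA/YOYO-1 stays essentially stable, and DNA/CisPt starts lower
#' (adducts already interrupt the network) and decays beyond 40% loss.
#' Counts are rounded to non-negative integers.
#'
#' @param system One of "DNA", "DNA/YOYO-1", "DNA/CisPt".
#' @param t_ns Time grid in ns (default 0-20 ns, 201 samples).
#' @param noise_sd Count noise sd (default 2).
#' @param seed Integer seed (mandatory).
#' @return Data frame with `time_ns`, `hbonds`, `system`.
#' @export
generate_hbond_series <- function(system = c("DNA", "DNA/YOYO-1", "DNA/CisPt"),
                                  t_ns = seq(0, 20, length.out = 201),
                                  noise_sd = 2, seed) {
  system <- match.arg(system)
  if (missing(seed)) stop("seed is required")
  par <- switch(system,
                "DNA" = c(start = 160, end = 112),       # -30%
                "DNA/YOYO-1" = c(start = 160, end = 156),# stable
                "DNA/CisPt" = c(start = 130, end = 72))  # < -44%
  base <- seq(par["start"], par["end"], length.out = length(t_ns))
  counts <- withr::with_seed(seed, {
    pmax(round(base + stats::rnorm(length(t_ns), 0, noise_sd)), 0)
  })
  data.frame(time_ns = t_ns, hbonds = as.integer(counts),
             system = system, stringsAsFactors = FALSE)
}
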