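#' Analyze a synthetic or measured experiment end to end
#'
#' Runs the full spectral inference chain for every bundle in a manifest:
#' peak detection and lineshape fits of the first three air modes, doublet
#' resolution of the vacuum fundamental, modal-ratio classification,
#' per-bundle modulus inversion, pooled frequency-geometry regression per
#' condition, and condition summaries. Per-bundle fit failures are caught,
#' tallied and reported — never silently dropped.
#'
#' @param experiment A list with `manifest` and `spectra` as returned by
#'   [generate_experiment()] (or assembled from files via
#'   [read_spectrum()]/[read_table_tsv()]).
#' @param densities Named vector mapping condition to the density (kg
#'   m^-3) assumed when inverting for E. Default: 1700 for `pristine`,
#'   1500 otherwise.
#' @param pristine Reference condition label for splitting changes.
#' @param air_q_max Upper plausibility bound on air-mode quality factors;
#'   fitted candidates narrower than this are treated as noise spikes and
#'   skipped (air damping keeps Q below ~10).
#' @return A list with `measurements` (per-bundle table: fitted f1-f3,
#'   ratios, classification, per-bundle E, omega, Q), `condition_fits`
#'   (per-condition pooled regression slope and E), `summary` (from
#'   [summarize_condition()], with pooled E columns merged), and
#'   `failures` (data frame of skipped bundles with reasons).
#' @export
analyze_experiment <- function(experiment, densities = NULL,
                               pristine = "pristine", air_q_max = 50) {
  manifest <- experiment$manifest
  spectra <- experiment$spectra
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1)
  conds <- unique(manifest$condition)
  if (is.null(densities)) {
    densities <- stats::setNames(ifelse(conds == pristine, 1700, 1500), conds)
  }
  rows <- list()
  fails <- list()
  for (i in seq_len(nrow(manifest))) {
    b <- manifest[i, ]
    res <- tryCatch({
      air <- spectra[[paste0(b$bundle_id, "_air")]]
      vac <- spectra[[paste0(b$bundle_id, "_vacuum")]]
      if (is.null(air) || is.null(vac)) stop("missing spectra")
      cand <- detect_peaks(air)
      if (nrow(cand) < 3) stop("fewer than 3 air peaks detected")
      cand <- cand[order(-cand$prominence), ]
      # walk candidates by prominence, keeping fits that converge to
      # distinct low-Q modes; spurious noise spikes fail the fit or
      # produce implausibly narrow lines
      fits <- list()
      for (k in seq_len(nrow(cand))) {
        if (length(fits) >= 3) break
        ft <- tryCatch(
          fit_resonance(air, cand$frequency[k],
                        half_width = 0.25 * cand$frequency[k]),
          error = function(e) NULL)
        if (is.null(ft) || ft$q > air_q_max) next
        if (any(vapply(fits, function(x)
          abs(x$f0 - ft$f0) < 0.2 * ft$f0, logical(1)))) next
        fits[[length(fits) + 1L]] <- ft
      }
      if (length(fits) < 3) stop("fewer than 3 air modes could be fitted")
      fits <- fits[order(vapply(fits, `[[`, numeric(1), "f0"))]
      for (k in 1:3) fits[[k]]$mode <- k
      f <- vapply(fits, `[[`, numeric(1), "f0")
      fse <- vapply(fits, `[[`, numeric(1), "f0_se")
      rat <- modal_ratios(f, fse)
      cls <- classify_configuration(rat)
      vcand <- detect_peaks(vac)
      vcenter <- if (nrow(vcand)) vcand$frequency[which.max(vcand$amplitude)]
        else vac$frequency[which.max(vac$amplitude)]
      dbl <- resolve_doublet(vac, vcenter)
      if (dbl$resolved) {
        asy <- asymmetry_from_split(dbl$fast$f0, dbl$slow$f0)
        omega <- asy$omega_exact        # (d_max - d_min)/d_min, unbiased
        omega_freq <- asy$omega_freq    # (f_f - f_s)/f_f, as printed
      } else omega <- omega_freq <- NA_real_
      q_vac <- if (dbl$resolved) mean(c(dbl$fast$q, dbl$slow$q))
        else dbl$single$q
      E_i <- young_modulus_per_bundle(f[1], b$d_obs / 2, b$L,
                                      densities[[b$condition]])
      data.frame(bundle_id = b$bundle_id, condition = b$condition,
                 L = b$L, R_obs = b$d_obs / 2,
                 f1 = f[1], f2 = f[2], f3 = f[3],
                 r21 = rat$r21, r32 = rat$r32,
                 classification = cls$class,
                 E = E_i, omega = omega, omega_freq = omega_freq,
                 q_air = fits[[1]]$q, q_vacuum = q_vac,
                 doublet_resolved = dbl$resolved,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(bundle_id = b$bundle_id, condition = b$condition,
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- res
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else
    stop("no bundle could be analyzed")
  cond_fits <- do.call(rbind, lapply(unique(measurements$condition),
    function(cc) {
      d <- measurements[measurements$condition == cc, ]
      fit <- fit_frequency_vs_geometry(
        data.frame(f1 = d$f1, R = d$R_obs, L = d$L))
      em <- young_modulus_from_slope(fit$slope, densities[[cc]],
                                     fit$slope_se)
      data.frame(condition = cc, slope = fit$slope,
                 slope_se = fit$slope_se, r_squared = fit$r_squared,
                 E_pooled = em$E, E_pooled_se = em$E_se,
                 density = em$density, stringsAsFactors = FALSE)
    }))
  summ <- summarize_condition(measurements, pristine = pristine)
  summ <- merge(summ, cond_fits[, c("condition", "E_pooled", "E_pooled_se")],
                by = "condition", sort = FALSE)
  list(measurements = measurements, condition_fits = cond_fits,
       summary = summ,
       failures = if (length(fails)) do.call(rbind, fails) else
         data.frame(bundle_id = character(0), condition = character(0),
                    reason = character(0)))
}

#' Repeated-condition recovery study
#'
#' Monte-Carlo check of the inference chain at the fitted-peak level: for
#' each seeded repetition and condition it samples a bundle population,
#' forms fundamental frequencies from the unstressed-beam model with the
#' generator's multiplicative measurement jitter, and recovers the pooled
#' effective modulus from the frequency-geometry regression using the
#' reported (noisy) diameters. Lineshape synthesis and refitting are
#' validated separately (their contribution to the frequency error is far
#' below the measurement jitter), which keeps many repetitions cheap.
#'
#' @param n_runs Number of seeded repetitions.
#' @param config A [generator_config()].
#' @param presets Condition presets (default [condition_presets()]).
#' @param seed Integer master seed.
#' @return A list with `E_hat` (matrix, runs x conditions, Pa),
#'   `ordering_ok` (logical vector: recovered condition ordering matches
#'   the true ordering of preset moduli) and `conditions`.
#' @export
condition_recovery_study <- function(n_runs = 100,
                                     config = generator_config(),
                                     presets = condition_presets(),
                                     seed = 1) {
  conds <- presets$condition
  E_hat <- matrix(NA_real_, n_runs, length(conds),
                  dimnames = list(NULL, conds))
  for (r in seq_len(n_runs)) {
    run_seed <- (seed + 1000003 * r) %% 2147483647
    for (j in seq_along(conds)) {
      p <- presets[j, ]
      bundles <- sample_bundles(config, p, seed = run_seed + j)
      f1_true <- vapply(seq_len(nrow(bundles)), function(i) {
        beam_frequencies(bundle_geometry(bundles$L[i], bundles$d[i]),
                         material_state(bundles$E_true[i], p$rho),
                         1)$frequency
      }, numeric(1))
      f1_obs <- withr::with_seed((run_seed * 31 + j) %% 2147483647, {
        f1_true * (1 + stats::rnorm(length(f1_true), 0, config$freq_jitter))
      })
      fit <- fit_frequency_vs_geometry(
        data.frame(f1 = f1_obs, R = bundles$d_obs / 2, L = bundles$L))
      E_hat[r, j] <- young_modulus_from_slope(fit$slope, p$rho)$E
    }
  }
  true_order <- order(presets$E, decreasing = TRUE)
  ordering_ok <- apply(E_hat, 1, function(e)
    identical(order(e, decreasing = TRUE), true_order))
  list(E_hat = E_hat, ordering_ok = ordering_ok, conditions = conds)
}

#' Sensitivity and limit-of-detection survey over the geometry box
#'
#' Evaluates the mass responsivity |S| = f1 / (2 m) of the fundamental
#' mode over a grid of bundle geometries (lengths 10-15 um, diameters
#' 30-100 nm) and material states (density 1500-1700 kg m^-3, modulus
#' 2.6-12.6 GPa), and optionally the mass limit of detection for a given
#' relative frequency stability.
#'
#' @param L_grid,d_grid,rho_grid,E_grid Numeric grids (SI units).
#' @param relative_frequency_stability Optional delta_f/f; when supplied a
#'   `lod_ag` column is added.
#' @return Data frame with one row per combination: geometry, `f1_hz`,
#'   `mass_ag`, `abs_S_hz_per_ag` (and `lod_ag` when requested).
#' @export
sensitivity_survey <- function(L_grid = seq(10e-6, 15e-6, length.out = 6),
                               d_grid = seq(30e-9, 100e-9, length.out = 8),
                               rho_grid = c(1500, 1700),
                               E_grid = c(2.6e9, 5.3e9, 8.1e9, 12.6e9),
                               relative_frequency_stability = NULL) {
  grid <- expand.grid(L = L_grid, d = d_grid, rho = rho_grid, E = E_grid)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- bundle_geometry(grid$L[i], grid$d[i])
    m <- material_state(grid$E[i], grid$rho[i])
    f1 <- beam_frequencies(g, m, 1)$frequency
    mass <- mass_of_bundle(g, m)
    s <- sensitivity(f1, mass)
    row <- data.frame(L = grid$L[i], d = grid$d[i], rho = grid$rho[i],
                      E = grid$E[i], f1_hz = f1, mass_ag = kg_to_ag(mass),
                      abs_S_hz_per_ag = s$abs_S_hz_per_ag)
    if (!is.null(relative_frequency_stability))
      row$lod_ag <- limit_of_detection(
        mass, relative_frequency_stability)$dm_min_ag
    row
  }))
  out
}
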