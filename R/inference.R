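#' Modal frequency ratios with propagated uncertainty
#'
#' Ratios of consecutive fitted mode frequencies, the discriminant between
#' the unstressed-beam configuration (2.76, 1.96) and the
#' tension-dominated string (2, 1.5).
#'
#' @param f Vector of fitted mode frequencies, ascending mode order
#'   (at least 2).
#' @param se Optional vector of standard errors (same length); default 0.
#' @return A list with `r21`, `r21_se` and, when three modes are present,
#'   `r32`, `r32_se`; absent ratios are `NA`. A `degenerate` flag is set
#'   when any consecutive frequencies coincide.
#' @export
modal_ratios <- function(f, se = NULL) {
  stopifnot(is.numeric(f), length(f) >= 2)
  if (is.null(se)) se <- rep(0, length(f))
  stopifnot(length(se) == length(f))
  ratio <- function(i, j) {
    r <- f[j] / f[i]
    list(r = r, se = abs(r) * sqrt((se[i] / f[i])^2 + (se[j] / f[j])^2))
  }
  r21 <- ratio(1, 2)
  out <- list(r21 = r21$r, r21_se = r21$se, r32 = NA_real_, r32_se = NA_real_)
  if (length(f) >= 3) {
    r32 <- ratio(2, 3)
    out$r32 <- r32$r
    out$r32_se <- r32$se
  }
  out$degenerate <- any(diff(f) == 0)
  out
}

#' Classify a bundle as beam or string from its modal ratios
#'
#' Compares the measured ratios (f2/f1, f3/f2) with the theoretical beam
#' point (2.7565, 1.9604) and string point (2, 1.5) in a normalized space
#' where each ratio is scaled by the beam-string gap, so both ratios
#' contribute comparably. The nearer point wins; when the two distances
#' differ by less than the propagated (normalized) uncertainty the result
#' is `"indeterminate"`.
#'
#' @param ratios A list as returned by [modal_ratios()], or a numeric
#'   vector `c(r21, r32)` (r32 may be `NA`).
#' @param se Optional numeric vector of uncertainties when `ratios` is a
#'   plain vector.
#' @return A list with `class` ("beam", "string" or "indeterminate"),
#'   `d_beam`, `d_string` (normalized distances) and `uncertainty`.
#' @export
classify_configuration <- function(ratios, se = NULL) {
  if (is.list(ratios)) {
    r <- c(ratios$r21, ratios$r32)
    u <- c(ratios$r21_se, ratios$r32_se)
  } else {
    r <- c(ratios[1], if (length(ratios) > 1) ratios[2] else NA_real_)
    u <- if (is.null(se)) c(0, 0) else c(se[1], if (length(se) > 1) se[2] else 0)
  }
  if (!is.finite(r[1])) stop("at least f2/f1 must be available")
  beam <- beam_mode_ratios()
  str_ <- string_mode_ratios()
  gap <- abs(beam - str_)
  use <- is.finite(r)
  z <- (r / gap)[use]
  d_beam <- sqrt(sum((z - (beam / gap)[use])^2))
  d_string <- sqrt(sum((z - (str_ / gap)[use])^2))
  u[!is.finite(u)] <- 0
  unc <- sqrt(sum((u / gap)[use]^2))
  cls <- if (abs(d_beam - d_string) < unc) "indeterminate"
  else if (d_beam < d_string) "beam" else "string"
  list(class = cls, d_beam = d_beam, d_string = d_string, uncertainty = unc)
}

#' Fit the fundamental frequency against geometry
#'
#' Ordinary least squares of f1 on x = R / L^2, the linear relation implied
#' by the unstressed-beam model (which has no intercept): the main fit is
#' through the origin, and a free-intercept diagnostic fit is reported
#' alongside to expose systematic offsets.
#'
#' @param points Data frame with columns `f1` (Hz), `R` (m), `L` (m).
#' @return A list with `slope` (Hz m^-1 scale of f1 vs R/L^2), `slope_se`,
#'   `r_squared`, `n`, and `diagnostic` (list with `intercept`, `slope`
#'   from the free-intercept fit).
#' @export
fit_frequency_vs_geometry <- function(points) {
  stopifnot(is.data.frame(points), all(c("f1", "R", "L") %in% names(points)))
  if (nrow(points) < 3) stop("at least 3 bundles are required for the fit")
  if (any(points$R <= 0) || any(points$L <= 0))
    stop("R and L must be positive")
  x <- points$R / points$L^2
  if (stats::sd(x) == 0) stop("degenerate fit: all R/L^2 values identical")
  y <- points$f1
  fit0 <- stats::lm(y ~ 0 + x)
  sm <- summary(fit0)
  fit1 <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit0)[1]),
       slope_se = sm$coefficients[1, "Std. Error"],
       r_squared = sm$r.squared,
       n = nrow(points),
       diagnostic = list(intercept = unname(stats::coef(fit1)[1]),
                         slope = unname(stats::coef(fit1)[2])))
}

#' Effective Young's modulus from the frequency-geometry slope
#'
#' Inverts the unstressed-beam relation f1 = (lambda_1^2 / 4 pi) (R / L^2)
#' sqrt(E / rho): E = rho * (4 pi * slope / lambda_1^2)^2. Uncertainty by
#' first-order propagation from the slope standard error and an optional
#' density uncertainty.
#'
#' @param slope Fitted slope of f1 vs R/L^2 (from
#'   [fit_frequency_vs_geometry()]).
#' @param density Assumed density rho in kg m^-3.
#' @param slope_se,density_se Standard errors (default 0).
#' @return A list with `E` (Pa), `E_se` (Pa) and the `density` used.
#' @export
young_modulus_from_slope <- function(slope, density, slope_se = 0,
                                     density_se = 0) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  l1 <- clamped_clamped_modal_factors(1)
  E <- density * (4 * pi * slope / l1^2)^2
  rel <- sqrt((2 * slope_se / slope)^2 + (density_se / density)^2)
  list(E = E, E_se = E * rel, density = density)
}

# invert the unstressed-beam relation for a single bundle:
# E_i = rho * (4 pi f1 L^2 / (lambda1^2 R))^2
young_modulus_per_bundle <- function(f1, R, L, density) {
  l1 <- clamped_clamped_modal_factors(1)
  density * (4 * pi * f1 * L^2 / (l1^2 * R))^2
}

#' Cross-section asymmetry from a resolved doublet
#'
#' The asymmetry factor estimated from the fast/slow split frequencies,
#' Omega = (f_f - f_s) / f_f, together with the exact diameter ratio
#' d_max / d_min = f_f / f_s implied by the elliptic-beam model. The
#' frequency form equals (d_max - d_min)/d_max exactly and the diameter
#' definition (d_max - d_min)/d_min to first order; both are returned and
#' named.
#'
#' @param f_fast,f_slow Fast and slow mode frequencies (Hz),
#'   f_fast >= f_slow > 0.
#' @param d_min Optional nominal minor diameter (m) for which the implied
#'   diameter difference d_max - d_min is reported.
#' @return A list with `omega_freq` ((f_f - f_s)/f_f), `omega_exact`
#'   (f_f/f_s - 1, the exact (d_max - d_min)/d_min), `diameter_ratio`
#'   (f_f/f_s) and, when `d_min` is given, `diameter_difference` (m,
#'   omega_exact * d_min).
#' @export
asymmetry_from_split <- function(f_fast, f_slow, d_min = NULL) {
  if (!is.finite(f_fast) || !is.finite(f_slow) || f_slow <= 0)
    stop("frequencies must be finite and positive")
  if (f_fast < f_slow)
    stop("f_fast must be >= f_slow (order the doublet before calling)")
  ratio <- f_fast / f_slow
  out <- list(omega_freq = (f_fast - f_slow) / f_fast,
              omega_exact = ratio - 1,
              diameter_ratio = ratio)
  if (!is.null(d_min)) out$diameter_difference <- (ratio - 1) * d_min
  out
}

#' Diameter difference implied by an asymmetry factor
#'
#' With Omega defined as (d_max - d_min)/d_min, the axis difference for a
#' bundle of minor diameter d_min is simply Omega * d_min.
#'
#' @param omega Asymmetry factor (dimensionless, e.g. 0.0115).
#' @param d_min Minor diameter (m or any length unit; output in the same
#'   unit).
#' @return d_max - d_min in the unit of `d_min`.
#' @export
omega_to_diameter_difference <- function(omega, d_min) {
  stopifnot(is.numeric(omega), is.numeric(d_min))
  omega * d_min
}

#' Summarize bundle measurements per condition
#'
#' Per-condition means and standard deviations of the effective Young's
#' modulus, asymmetry factor and quality factors, plus the relative change
#' of the mean splitting with respect to the pristine condition.
#'
#' @param measurements Data frame with columns `condition` and any of `E`
#'   (Pa), `omega`, `q_air`, `q_vacuum`; one row per bundle.
#' @param pristine Label of the reference condition (default
#'   `"pristine"`).
#' @return Data frame with one row per condition: `n`, `E_mean`, `E_sd`,
#'   `omega_mean`, `omega_sd`, `q_air_mean`, `q_vacuum_mean`,
#'   `splitting_change_pct` (NA for the reference). Standard deviations
#'   are `NA` for single-bundle groups.
#' @export
summarize_condition <- function(measurements, pristine = "pristine") {
  stopifnot(is.data.frame(measurements), "condition" %in% names(measurements))
  conds <- unique(measurements$condition)
  col <- function(d, nm) if (nm %in% names(d)) d[[nm]] else rep(NA_real_, nrow(d))
  rows <- lapply(conds, function(cc) {
    d <- measurements[measurements$condition == cc, , drop = FALSE]
    stat <- function(x) {
      x <- x[is.finite(x)]
      c(mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) >= 2) stats::sd(x) else NA_real_)
    }
    e <- stat(col(d, "E")); o <- stat(col(d, "omega"))
    qa <- stat(col(d, "q_air")); qv <- stat(col(d, "q_vacuum"))
    data.frame(condition = cc, n = nrow(d),
               E_mean = e["mean"], E_sd = e["sd"],
               omega_mean = o["mean"], omega_sd = o["sd"],
               q_air_mean = qa["mean"], q_vacuum_mean = qv["mean"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  ref <- out$omega_mean[out$condition == pristine]
  out$splitting_change_pct <- if (length(ref) == 1 && is.finite(ref)) {
    ifelse(out$condition == pristine, NA_real_,
           100 * (out$omega_mean / ref - 1))
  } else NA_real_
  out
}

DOSE_LABELS <- c("4x" = 4, "2x" = 2, "1x" = 1,
                 "0.5x" = 0.5, "0.05x" = 0.05, "0.01x" = 0.01)

#' Dose-response summary of a titration series
#'
#' Per-dose mean and standard deviation of the effective Young's modulus,
#' with two qualitative checks of the expected cisplatin dose-response:
#' below saturation (dose < 1x) the modulus should rise monotonically as
#' the dose drops toward pristine, and at saturating/oversaturating doses
#' (>= 1x) the means should plateau (differ by less than the pooled
#' standard deviation).
#'
#' @param measurements Data frame with columns `dose` (labels among
#'   "4x", "2x", "1x", "0.5x", "0.05x", "0.01x", or numeric multipliers)
#'   and `E` (Pa).
#' @return A list with `table` (per-dose `n`, `E_mean`, `E_sd`, descending
#'   dose), `monotone_below_saturation` (logical or NA), `plateau`
#'   (logical or NA) and `plateau_status` ("ok" or "underpowered" when
#'   fewer than two saturating doses are available).
#' @export
titration_summary <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("dose", "E") %in% names(measurements)))
  dose <- measurements$dose
  if (is.character(dose) || is.factor(dose)) {
    dose <- as.character(dose)
    bad <- setdiff(unique(dose), names(DOSE_LABELS))
    if (length(bad))
      stop("unknown dose labels: ", paste(bad, collapse = ", "))
    dnum <- unname(DOSE_LABELS[dose])
  } else dnum <- as.numeric(dose)
  if (any(!is.finite(dnum)) || any(dnum <= 0))
    stop("doses must be positive multipliers of the saturating amount")
  lv <- sort(unique(dnum), decreasing = TRUE)
  if (length(lv) < 2) stop("at least 2 dose levels are required")
  tab <- do.call(rbind, lapply(lv, function(d) {
    e <- measurements$E[dnum == d]
    data.frame(dose = d, n = length(e), E_mean = mean(e),
               E_sd = if (length(e) >= 2) stats::sd(e) else NA_real_)
  }))
  below <- tab[tab$dose < 1, , drop = FALSE]     # descending dose order
  monotone <- if (nrow(below) >= 2) {
    all(diff(below$E_mean) > 0)                  # E rises as dose falls
  } else NA
  sat <- tab[tab$dose >= 1, , drop = FALSE]
  if (nrow(sat) >= 2) {
    pooled <- sqrt(mean(sat$E_sd[is.finite(sat$E_sd)]^2))
    plateau <- if (is.finite(pooled) && pooled > 0)
      (max(sat$E_mean) - min(sat$E_mean)) < pooled
    else max(sat$E_mean) == min(sat$E_mean)
    status <- "ok"
  } else {
    plateau <- NA
    status <- "underpowered"
  }
  list(table = tab, monotone_below_saturation = monotone,
       plateau = plateau, plateau_status = status)
}
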