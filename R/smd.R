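#' Engineering strain in percent
#'
#' Strain = (L - L0) / L0 * 100. Negative values (compression) are allowed
#' but flagged with a warning, since constant-force pulling should only
#' extend the filament.
#'
#' @param L Length under load (any length unit).
#' @param L0 Reference length (> 0, same unit).
#' @return Strain in percent.
#' @export
strain_percent <- function(L, L0) {
  if (any(!is.finite(L0)) || any(L0 <= 0)) stop("L0 must be positive")
  s <- 100 * (L - L0) / L0
  if (any(s < 0)) warning("negative strain (compression) encountered")
  s
}

#' Stress from applied force
#'
#' Stress = force / cross-sectional area of the helix. The default area,
#' pi * (1 nm)^2 ~ 3.14 nm^2, takes the duplex radius as 1 nm; absolute
#' moduli scale inversely with this choice while between-system
#' comparisons do not.
#'
#' @param force_pn Applied force in pN.
#' @param helix_area_nm2 Cross-section area in nm^2 (default `pi`).
#' @return Stress in Pa (1 pN/nm^2 = 1 MPa).
#' @export
stress_from_force <- function(force_pn, helix_area_nm2 = pi) {
  if (!is.finite(helix_area_nm2) || helix_area_nm2 <= 0)
    stop("helix_area_nm2 must be positive")
  force_pn / helix_area_nm2 * 1e6
}

#' Build a stress-strain curve from constant-force pulling records
#'
#' Aggregates replicate equilibrium lengths per applied force into mean
#' strain with replicate standard errors, and converts forces to stress.
#'
#' @param records Data frame with columns `force_pN`, `length_nm`,
#'   `replicate` (and optionally `system`, which must then be unique).
#' @param L0_nm Reference (zero-force) length in nm.
#' @param helix_area_nm2 Helix cross-section area in nm^2 (default `pi`).
#' @return An object of class `stress_strain_curve`: data frame with one
#'   row per force level (`force_pN`, `stress_pa`, `strain_pct`,
#'   `strain_se`, `n_rep`), with attributes `L0_nm` and `helix_area_nm2`.
#' @export
build_stress_strain <- function(records, L0_nm, helix_area_nm2 = pi) {
  stopifnot(is.data.frame(records),
            all(c("force_pN", "length_nm") %in% names(records)))
  if ("system" %in% names(records) &&
      length(unique(records$system)) > 1)
    stop("records mix systems: ", paste(unique(records$system), collapse = ", "))
  if (any(records$force_pN < 0)) stop("forces must be non-negative")
  if (any(records$length_nm <= 0)) stop("lengths must be positive")
  forces <- sort(unique(records$force_pN))
  rows <- lapply(forces, function(fo) {
    len <- records$length_nm[records$force_pN == fo]
    s <- strain_percent(len, L0_nm)
    data.frame(force_pN = fo,
               stress_pa = stress_from_force(fo, helix_area_nm2),
               strain_pct = mean(s),
               strain_se = if (length(s) >= 2)
                 stats::sd(s) / sqrt(length(s)) else 0,
               n_rep = length(s))
  })
  out <- do.call(rbind, rows)
  attr(out, "L0_nm") <- L0_nm
  attr(out, "helix_area_nm2") <- helix_area_nm2
  class(out) <- c("stress_strain_curve", "data.frame")
  out
}

#' Young's modulus from a stress-strain curve
#'
#' Weighted least-squares fit of stress (Pa) on strain (percent); the
#' modulus is the slope times 100 (percent-strain convention, stated
#' explicitly to avoid a silent factor-100 error). Replicate-averaged
#' strains are weighted by their inverse squared standard errors; rows
#' with zero standard error (e.g. the zero-force anchor) receive the
#' largest finite weight, and the fit is unweighted when no finite
#' weights exist (noise-free input).
#'
#' @param curve A `stress_strain_curve` from [build_stress_strain()], or a
#'   data frame with columns `stress_pa`, `strain_pct` and optionally
#'   `strain_se`.
#' @return A list with `E` (Pa), `E_se` (Pa), `slope_pa_per_pct`,
#'   `intercept_pa`, `n_levels`, and a `monotone` flag (FALSE triggers a
#'   warning but the fit is still returned).
#' @export
fit_e_smd <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("stress_pa", "strain_pct") %in% names(curve)))
  if (nrow(curve) < 3) stop("at least 3 force levels are required")
  o <- order(curve$stress_pa)
  curve <- curve[o, , drop = FALSE]
  monotone <- !is.unsorted(curve$strain_pct)
  if (!monotone)
    warning("strain is not monotone in stress; fit returned anyway")
  se <- if ("strain_se" %in% names(curve)) curve$strain_se else
    rep(0, nrow(curve))
  w <- ifelse(is.finite(se) & se > 0, 1 / se^2, NA_real_)
  if (all(is.na(w))) w <- rep(1, nrow(curve))
  else w[is.na(w)] <- max(w, na.rm = TRUE)
  fit <- stats::lm(stress_pa ~ strain_pct, data = curve, weights = w)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)["strain_pct"])
  slope_se <- sm$coefficients["strain_pct", "Std. Error"]
  list(E = slope * 100, E_se = slope_se * 100,
       slope_pa_per_pct = slope,
       intercept_pa = unname(stats::coef(fit)["(Intercept)"]),
       n_levels = nrow(curve), monotone = monotone)
}

#' Percent change in hydrogen-bond count
#'
#' Compares the mean hydrogen-bond count in a final time window with that
#' in an initial window: 100 * (mean_final - mean_initial) / mean_initial.
#' Negative values are losses; the pristine duplex loses about 30% under
#' full stretching while cisplatin adducts push the loss past 40%.
#'
#' @param series Data frame with columns `time_ns` (strictly increasing)
#'   and `hbonds` (non-negative counts).
#' @param window_initial,window_final Length-2 numeric ranges (ns) within
#'   the series.
#' @return Percent change (negative = loss).
#' @export
hbond_loss <- function(series, window_initial, window_final) {
  stopifnot(is.data.frame(series),
            all(c("time_ns", "hbonds") %in% names(series)))
  if (is.unsorted(series$time_ns, strictly = TRUE))
    stop("time_ns must be strictly increasing")
  if (any(series$hbonds < 0)) stop("hbond counts must be non-negative")
  pick <- function(win, label) {
    stopifnot(length(win) == 2)
    sel <- series$time_ns >= min(win) & series$time_ns <= max(win)
    if (!any(sel)) stop("no samples in the ", label, " window")
    series$hbonds[sel]
  }
  m0 <- mean(pick(window_initial, "initial"))
  m1 <- mean(pick(window_final, "final"))
  if (m0 == 0) stop("initial window has zero mean hydrogen-bond count")
  100 * (m1 - m0) / m0
}
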