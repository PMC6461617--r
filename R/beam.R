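#' Modal factors of a doubly clamped beam
#'
#' Computes the first `n_modes` eigenvalues lambda_n of the clamped-clamped
#' Euler-Bernoulli characteristic equation
#' \deqn{\cos\lambda \cosh\lambda = 1,}
#' excluding the trivial root at zero. Roots are found by bracketed
#' root-finding around the asymptotic locations (n + 1/2) pi, where the
#' characteristic function changes sign, to a tolerance far below 1e-8
#' relative.
#'
#' The squared ratios of consecutive eigenvalues give the unstressed-beam
#' frequency ratios f2/f1 = 2.76 and f3/f2 = 1.96 used to discriminate the
#' beam configuration from the tension-dominated string (ratios 2 and 1.5).
#'
#' @param n_modes Number of eigenvalues to return (>= 1).
#' @return Numeric vector of length `n_modes`, strictly increasing.
#' @examples
#' l <- clamped_clamped_modal_factors(3)
#' (l[2] / l[1])^2  # 2.7565
#' @export
clamped_clamped_modal_factors <- function(n_modes) {
  if (!is.numeric(n_modes) || length(n_modes) != 1L ||
      !is.finite(n_modes) || n_modes < 1 || n_modes != floor(n_modes))
    stop("n_modes must be a positive integer")
  chr <- function(x) cos(x) * cosh(x) - 1
  vapply(seq_len(n_modes), function(n) {
    center <- (n + 0.5) * pi
    # the root lies within ~0.02 of (n+1/2)pi and the sign flips across it
    stats::uniroot(chr, lower = center - 0.1, upper = center + 0.1,
                   tol = 1e-13)$root
  }, numeric(1))
}

# squared eigenvalue ratios of the unstressed clamped-clamped beam,
# the theoretical "beam" point (f2/f1, f3/f2)
beam_mode_ratios <- function() {
  l <- clamped_clamped_modal_factors(3)
  c(r21 = (l[2] / l[1])^2, r32 = (l[3] / l[2])^2)
}

string_mode_ratios <- function() c(r21 = 2, r32 = 1.5)

mode_set <- function(n, lambda, frequency, plane = "single") {
  data.frame(mode = n, lambda = lambda, frequency = frequency,
             plane = plane, stringsAsFactors = FALSE)
}

#' Flexural resonance frequencies of a stressed clamped-clamped beam
#'
#' General form for arbitrary cross section,
#' \deqn{f_n = \frac{\lambda_n^2}{2\pi L^2}\sqrt{\frac{EI}{\rho A}}
#'       \sqrt{1 + \frac{\sigma A L^2}{E I \lambda_n^2}},}
#' i.e. the unstressed eigenfrequency times a tension correction.
#'
#' @param geometry A [bundle_geometry()]; `area` and `moment` are used.
#' @param material A [material_state()].
#' @param n_modes Number of modes.
#' @return A data frame with columns `mode`, `lambda`, `frequency` (Hz),
#'   `plane`.
#' @seealso [beam_frequencies()] for the circular-section specialization.
#' @export
beam_frequencies_general <- function(geometry, material, n_modes = 3) {
  stopifnot(inherits(geometry, "bundle_geometry"),
            inherits(material, "material_state"))
  lam <- clamped_clamped_modal_factors(n_modes)
  L <- geometry$length
  A <- geometry$area
  I <- geometry$moment
  E <- material$young_modulus
  rho <- material$density
  sig <- material$axial_stress
  base <- lam^2 / (2 * pi * L^2) * sqrt(E * I / (rho * A))
  tension <- sqrt(1 + sig * A * L^2 / (E * I * lam^2))
  mode_set(seq_len(n_modes), lam, base * tension)
}

#' Flexural resonance frequencies of a circular clamped-clamped beam
#'
#' Circular-section specialization: substituting A = pi R^2 and
#' I = pi R^4 / 4 gives
#' \deqn{f_n = \frac{\lambda_n^2}{4\pi L^2}\sqrt{\frac{E R^2}{\rho}}
#'       \sqrt{1 + \frac{4\sigma L^2}{E R^2 \lambda_n^2}},}
#' which at sigma = 0 reduces to the unstressed form
#' f_n = lambda_n^2 / (4 pi) * (R / L^2) * sqrt(E / rho), linear in the
#' geometric parameter R / L^2.
#'
#' @inheritParams beam_frequencies_general
#' @return A data frame as in [beam_frequencies_general()].
#' @examples
#' g <- bundle_geometry(12e-6, 100e-9)
#' s <- material_state(5.3e9, 1700)
#' beam_frequencies(g, s, 3)$frequency[1] / 1e6  # ~1.09 MHz
#' @export
beam_frequencies <- function(geometry, material, n_modes = 3) {
  stopifnot(inherits(geometry, "bundle_geometry"),
            inherits(material, "material_state"))
  if (!is_circular(geometry))
    stop("beam_frequencies expects a circular section (d_max == d_min); ",
         "use split_frequencies for elliptical sections")
  lam <- clamped_clamped_modal_factors(n_modes)
  L <- geometry$length
  R <- geometry$radius
  E <- material$young_modulus
  rho <- material$density
  sig <- material$axial_stress
  base <- lam^2 / (4 * pi * L^2) * sqrt(E * R^2 / rho)
  tension <- sqrt(1 + 4 * sig * L^2 / (E * R^2 * lam^2))
  mode_set(seq_len(n_modes), lam, base * tension)
}

#' Resonance frequencies in the taut-string limit
#'
#' When axial tension dominates flexural rigidity the bundle behaves as a
#' taut string with integer modal factors (lambda_n = n) and
#' \deqn{f_n = \frac{n}{2L}\sqrt{\frac{\sigma}{\rho}}.}
#' Consecutive-mode ratios are then exactly 2/1, 3/2, ... regardless of the
#' prefactor.
#'
#' @inheritParams beam_frequencies_general
#' @return A data frame as in [beam_frequencies_general()].
#' @export
string_frequencies <- function(geometry, material, n_modes = 3) {
  stopifnot(inherits(geometry, "bundle_geometry"),
            inherits(material, "material_state"))
  if (material$axial_stress <= 0)
    stop("string model undefined without tension (axial_stress must be > 0)")
  n <- seq_len(n_modes)
  f <- n / (2 * geometry$length) *
    sqrt(material$axial_stress / material$density)
  mode_set(n, as.numeric(n), f)
}

#' High-tension limit check of the stressed-beam model
#'
#' As the dimensionless tension term sigma A L^2 / (E I lambda_n^2) grows,
#' the stressed-beam frequency approaches lambda_n / (2 pi L) *
#' sqrt(sigma / rho). Returns the per-mode ratio of the full beam
#' expression to that limit; the ratio tends to 1 as tension dominates.
#'
#' @inheritParams beam_frequencies_general
#' @return A data frame with columns `mode`, `tension_term` (dimensionless)
#'   and `ratio`; at sigma = 0 the check is not applicable and `ratio` is
#'   `NA` with attribute `applicable = FALSE`.
#' @export
high_tension_limit_check <- function(geometry, material, n_modes = 3) {
  stopifnot(inherits(geometry, "bundle_geometry"),
            inherits(material, "material_state"))
  lam <- clamped_clamped_modal_factors(n_modes)
  sig <- material$axial_stress
  term <- sig * geometry$area * geometry$length^2 /
    (material$young_modulus * geometry$moment * lam^2)
  out <- data.frame(mode = seq_len(n_modes), tension_term = term,
                    ratio = NA_real_)
  if (sig <= 0) {
    attr(out, "applicable") <- FALSE
    return(out)
  }
  full <- beam_frequencies_general(geometry, material, n_modes)$frequency
  limit <- lam / (2 * pi * geometry$length) * sqrt(sig / material$density)
  out$ratio <- full / limit
  attr(out, "applicable") <- TRUE
  out
}

#' Mode splitting of an elliptical-section beam
#'
#' A non-circular cross section breaks the degeneracy of the two orthogonal
#' flexural polarizations. With major and minor diameters d_max >= d_min
#' the two second moments are
#' \deqn{I_M = \pi d_{max}^3 d_{min} / 4, \quad
#'       I_m = \pi d_{max} d_{min}^3 / 4}
#' (in the convention that absorbs the factor 1/16 into the frequency
#' prefactor below) and the fast/slow frequencies of each unstressed mode
#' are
#' \deqn{f_{M,m} = \frac{\lambda_n^2}{2\pi L^2}
#'       \sqrt{\frac{E\, I_{M,m}}{\rho A}}}
#' with ellipse area A = pi d_max d_min / 4. The exact identity
#' f_M / f_m = d_max / d_min follows, so the relative splitting
#' (f_M - f_m)/f_M equals 1 - d_min/d_max, which is the asymmetry factor
#' Omega = (d_max - d_min)/d_min to first order.
#'
#' Splitting is modelled on the unstressed beam; `material$axial_stress`
#' must be 0.
#'
#' @inheritParams beam_frequencies_general
#' @return A data frame with two rows per mode (`plane` = "fast"/"slow").
#' @export
split_frequencies <- function(geometry, material, n_modes = 1) {
  stopifnot(inherits(geometry, "bundle_geometry"),
            inherits(material, "material_state"))
  if (material$axial_stress != 0)
    stop("mode splitting is modelled on the unstressed beam (sigma = 0)")
  lam <- clamped_clamped_modal_factors(n_modes)
  L <- geometry$length
  dM <- geometry$d_max
  dm <- geometry$d_min
  E <- material$young_modulus
  rho <- material$density
  A <- pi * dM * dm / 4
  # I_{M,m}/16: the printed section moments carry d^4/4; the circular limit
  # fixes the prefactor so that d_max = d_min reproduces beam_frequencies
  I_M <- pi * dM^3 * dm / 64
  I_m <- pi * dM * dm^3 / 64
  f_fast <- lam^2 / (2 * pi * L^2) * sqrt(E * I_M / (rho * A))
  f_slow <- lam^2 / (2 * pi * L^2) * sqrt(E * I_m / (rho * A))
  rbind(
    mode_set(seq_len(n_modes), lam, f_fast, "fast"),
    mode_set(seq_len(n_modes), lam, f_slow, "slow")
  )
}

#' Mass sensitivity of a resonator
#'
#' Responsivity of the resonance frequency to added mass,
#' \deqn{S = \frac{\delta f}{\delta m} = -\frac{f}{2m}.}
#' The sign is negative (added mass lowers the frequency); the magnitude in
#' Hz/ag is the figure of merit usually quoted.
#'
#' @param f Resonance frequency in Hz (>= 0).
#' @param m Resonator mass in kg (> 0).
#' @return A list with `S_hz_per_kg` (signed), `S_hz_per_ag` (signed) and
#'   `abs_S_hz_per_ag`.
#' @examples
#' g <- bundle_geometry(10e-6, 100e-9)
#' s <- material_state(5.3e9, 1700)
#' f1 <- beam_frequencies(g, s, 1)$frequency
#' sensitivity(f1, mass_of_bundle(g, s))$abs_S_hz_per_ag  # ~5.9
#' @export
sensitivity <- function(f, m) {
  if (!is.finite(f) || f < 0) stop("f must be finite and non-negative (Hz)")
  if (!is.finite(m) || m <= 0) stop("m must be finite and positive (kg)")
  S <- -f / (2 * m)
  list(S_hz_per_kg = S,
       S_hz_per_ag = hz_per_kg_to_hz_per_ag(S),
       abs_S_hz_per_ag = abs(hz_per_kg_to_hz_per_ag(S)))
}

#' Limit of detection in mass
#'
#' Smallest added mass resolvable given the relative frequency stability
#' delta_f / f of the resonator: inverting the sensitivity relation,
#' delta_m_min = delta_f / |S| = 2 m (delta_f / f).
#'
#' The frequency stability is instrument- and bundle-specific and must be
#' supplied by the caller; there is no meaningful default.
#'
#' @param m Resonator mass in kg.
#' @param relative_frequency_stability Dimensionless delta_f / f (> 0).
#' @return A list with `dm_min_kg` and `dm_min_ag`.
#' @export
limit_of_detection <- function(m, relative_frequency_stability) {
  if (!is.finite(m) || m <= 0) stop("m must be finite and positive (kg)")
  df_f <- relative_frequency_stability
  if (!is.finite(df_f) || df_f < 0)
    stop("relative_frequency_stability must be finite and non-negative")
  dm <- 2 * m * df_f
  list(dm_min_kg = dm, dm_min_ag = kg_to_ag(dm))
}
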