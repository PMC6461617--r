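---
title: "Nanomechanics of suspended DNA-bundle resonators: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanomechanics of suspended DNA-bundle resonators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundleres)
```

## The physical system and the questions asked of it

A droplet of DNA solution evaporating on a super-hydrophobic micropillar
array leaves behind self-suspended bundles of DNA strands spanning
adjacent pillars: doubly clamped beams 10–15 µm long and 30–100 nm in
diameter, made entirely of (possibly ligand-modified) DNA. Driving the
device with a piezo and reading the bundle's vibration with a laser
Doppler vibrometer yields amplitude spectra whose resonance peaks encode
the bundle's mechanics. `bundleres` implements the full inference chain
from such spectra to material parameters:

1. Is the bundle a **beam** (flexural rigidity dominates) or a **string**
   (axial tension dominates)?
2. What is the **effective Young's modulus** of the bundle material, and
   how does it change when the DNA is intercalated with YOYO-1 or GelRed,
   or carries cisplatin (CisPt) adducts?
3. How **circular** is the cross section? An elliptical section splits
   each flexural mode into two orthogonally polarized modes; the relative
   splitting measures the axis asymmetry at sub-nanometre resolution.
4. What mass **sensitivity** and **limit of detection** would the bundle
   offer as a gravimetric sensor?
5. Independently, constant-force steered-MD pulling records of a 66-bp
   duplex are post-processed into stress–strain curves and an elastic
   modulus per ligand state.

No public raw data accompany these experiments, so a first-class
synthetic-data generator stands in for the vibrometer and the MD engine;
every estimator is validated by parameter recovery against the
generator's ground truth.

## Flexural modes of a doubly clamped bundle

The flexural eigenfrequencies of a clamped–clamped Euler–Bernoulli beam
of length $L$, cross-section area $A$, second moment $I$, density $\rho$,
Young's modulus $E$ and axial stress $\sigma$ are

$$f_n = \frac{\lambda_n^2}{2\pi L^2}\sqrt{\frac{EI}{\rho A}}
\sqrt{1 + \frac{\sigma A L^2}{E I \lambda_n^2}},$$

where the modal factors $\lambda_n$ solve $\cos\lambda\cosh\lambda = 1$.
`clamped_clamped_modal_factors()` computes them by bracketed
root-finding (`stats::uniroot`, tolerance $10^{-13}$) around the
asymptotic locations $(n + \tfrac12)\pi$, where the characteristic
function provably changes sign; textbook constants appear only in tests
as cross-checks. For a circular section ($A = \pi R^2$,
$I = \pi R^4/4$) the unstressed case reduces to

$$f_n = \frac{\lambda_n^2}{4\pi}\,\frac{R}{L^2}\sqrt{\frac{E}{\rho}},$$

linear in the geometric parameter $R/L^2$ with zero intercept.

**Beam vs string.** The squared eigenvalue ratios give the unstressed
beam's frequency ratios $f_2/f_1 = 2.76$ and $f_3/f_2 = 1.96$; a
tension-dominated string has integer modal factors and ratios exactly
$2$ and $3/2$. `classify_configuration()` compares measured ratios with
the two theoretical points in a normalized space (each ratio scaled by
the beam–string gap so both contribute comparably) and returns
`indeterminate` when the two distances differ by less than the
propagated ratio uncertainty — a quantitative version of judging
proximity to dashed reference lines by eye.

**The string prefactor.** For the string limit the package uses the
standard taut-string result $f_n = \tfrac{n}{2L}\sqrt{\sigma/\rho}$,
which is exactly the high-tension limit of the stressed-beam formula
(up to the modal-factor change $\lambda_n \to n\pi$); a printed variant
with prefactor $\lambda_n\pi/L$ circulates but disagrees with that limit
by a constant factor. Only mode *ratios* enter the classification, and
they are identical under either convention.
`high_tension_limit_check()` exposes the limit explicitly: at a tension
term of $10^6$ the full expression matches the limiting form to better
than $10^{-3}$.

**Elliptical splitting.** With major/minor diameters
$d_\mathrm{max} \ge d_\mathrm{min}$ the two polarizations have second
moments $\propto d_\mathrm{max}^3 d_\mathrm{min}$ and
$\propto d_\mathrm{max} d_\mathrm{min}^3$; the package normalizes both
by the standard elliptic-section factor ($\pi d^4/64$ in the circular
limit) so that $d_\mathrm{max} = d_\mathrm{min}$ reproduces the circular
beam exactly, and uses the ellipse area
$A = \pi d_\mathrm{max} d_\mathrm{min}/4$. Two exact identities follow
and are tested to $10^{-12}$: $f_M/f_m = d_\mathrm{max}/d_\mathrm{min}$,
and relative splitting $(f_M - f_m)/f_M = 1 - d_\mathrm{min}/d_\mathrm{max}$.
The asymmetry factor is defined as
$\Omega = (d_\mathrm{max} - d_\mathrm{min})/d_\mathrm{min}$ but is
estimated in practice from frequencies as $(f_f - f_s)/f_f$, which
equals $(d_\mathrm{max} - d_\mathrm{min})/d_\mathrm{max}$ — the same
thing to first order in $\Omega$. `asymmetry_from_split()` returns both
(`omega_freq` and the exact `omega_exact` $= f_f/f_s - 1$) and labels
them; multiplier-recovery summaries use the exact form because the
generator's ground truth is defined on the diameter ratio.

**Sensitivity and limit of detection.** A point mass added at the
antinode shifts the resonance by $S = \delta f/\delta m = -f/2m$ with
$m = \rho\pi R^2 L$; the magnitude is reported in Hz/ag. The limit of
detection inverts this against the resonator's relative frequency
stability, $\Delta m_\mathrm{min} = 2m\,(\delta f/f)$. The stability is
instrument- and bundle-specific and is therefore a required input, not a
default. All computation is SI internally; Hz/ag, GPa and attograms
appear only at presentation boundaries.

## Spectra: synthesis and estimation

**Lineshape.** The package models each peak as the amplitude response of
a driven damped harmonic oscillator,
$a(f) = a_0 f_0^2 / \sqrt{(f_0^2 - f^2)^2 + (f_0 f/Q)^2}$ — the standard
model for piezo-driven resonators read out interferometrically. Its
half-power (amplitude factor $1/\sqrt2$) bandwidth is $f_0/Q$ up to
$O(1/Q^2)$, which makes the instrumentalists' "$Q$ from the 3 dB
bandwidth" exact in the high-$Q$ limit. The 3 dB convention here is
**amplitude** $1/\sqrt2$ (3 dB in power); switching to the power
convention would rescale the bandwidth by a known factor and is a
documented substitution, not a silent one.

**Q estimators.** `q_from_3db()` interpolates the outermost half-power
crossings around the apparent maximum — scanning inward from the window
edges, which is robust to noise dips next to the peak — and divides the
peak frequency by the bandwidth. At $Q = 5$ the lineshape is visibly
asymmetric and its maximum sits at $f_0\sqrt{1 - 1/(2Q^2)}$, so the
3 dB estimate differs from the fitted $Q$ by a couple of percent; the
two agree within 5% for isolated peaks across $Q \in [5, 500]$, and the
nonlinear fit (`fit_resonance()`) is the primary estimator.

**Fitting.** `fit_resonance()` fits lineshape plus constant background
by Levenberg–Marquardt (`minpack.lm::nlsLM`) on a window around a
candidate peak. Two numerical choices matter and were set after
observing optimizer behaviour on synthetic data: (i) the initial $Q$
comes from a half-power scan, and the fit is **multi-started** at
$\{Q_0, 10Q_0, 100Q_0\}$ because a too-broad start can collapse into a
constant-like local minimum when the window holds unresolved structure;
(ii) a fit must reduce the residual sum of squares by at least 10%
relative to a constant model, otherwise a descriptive error is raised —
a window without a resonance never returns silently.

**Doublet resolution.** `resolve_doublet()` compares a single-peak with
a two-peak joint fit (shared constant background) on the same window and
accepts the doublet only if it improves the Bayesian information
criterion by more than 10 (strong evidence; ties resolve conservatively
to "unresolved") **and** the fitted centers are at least one mean
bandwidth apart. The second condition is a Rayleigh-type resolvability
floor, $\Omega Q \gtrsim 1$: with enough signal-to-noise a statistical
test can detect two components that completely overlap, but no reader
of the spectrum would call them resolved, and the air/vacuum contrast
the analysis relies on ($Q \approx 5$–8 in air hides the ~1% splitting
that $Q \approx 250$ in vacuum reveals) is exactly this criterion.
Candidate pairs are only sought within a few bandwidths of the anchor
peak; a wider net would pair distinct flexural modes rather than the
fine structure of one.

**Peak detection.** Local maxima filtered by topographic prominence
(default threshold: five times a robust noise estimate from the first
difference). This ~25-line primitive is hand-written because no
installed R routine exposes prominence-based filtering.

## From fitted peaks to material parameters

The effective modulus comes from ordinary least squares of $f_1$ on
$R/L^2$ **through the origin** — the unstressed-beam relation has no
intercept — with a free-intercept diagnostic fit reported alongside to
expose systematic offsets. Inverting the slope gives
$E = \rho\,(4\pi\,\text{slope}/\lambda_1^2)^2$, with first-order error
propagation from the slope (and optionally the density). Tension is
treated as exactly zero in this inversion, consistent with the beam-like
mode ratios; $\sigma$ remains an explicit model parameter so the
approximation itself is testable. Two condition-level variants are
reported: the pooled regression slope, and per-bundle inversions
averaged within the condition (whose standard deviation matches the
"spread over 25 measurements" style of reporting). Each modulus report
names the density used: 1700 kg m⁻³ for pristine DNA, 1500 kg m⁻³ for
intercalated conditions (intercalation lengthens the helix and lowers
the packing density); misspecifying $\rho$ scales $E$ exactly linearly.

The titration summary (`titration_summary()`) reduces dose-labelled
measurements (4×, 2×, 1×, 0.5×, 0.05×, 0.01× of the saturating CisPt
amount, or numeric multipliers) to per-dose means and two qualitative
flags: monotone increase of $E$ as the dose falls below saturation, and
a plateau across saturating/oversaturating doses (means differing by
less than the pooled standard deviation). With fewer than two
saturating dose levels the plateau check is reported as underpowered
rather than guessed.

## Steered-MD stress–strain post-processing

Constant-force pulling records (applied force, equilibrium length,
replicate id) become stress–strain curves via
$\text{strain} = 100\,(L - L_0)/L_0$ (percent) and
$\text{stress} = F/A_\mathrm{helix}$. The helix cross-section is not a
measured quantity; the default $A_\mathrm{helix} = \pi\,(1\ \text{nm})^2$
takes the B/A-DNA radius as 1 nm and is explicitly configurable —
absolute moduli scale inversely with this choice, between-system
comparisons do not. The same caveat applies to the reference length
(default $L_0 = 22.4$ nm, the nominal 66-bp contour at 0.34 nm rise):
absolute reproduction of MD moduli is not claimed, only recovery of
generator truths and preservation of system ordering. Strains are
averaged over replicates per force with inverse-variance weights from
the replicate standard errors (zero-variance anchors such as the
zero-force row get the largest finite weight); the modulus is the
regression slope times 100, the percent-strain conversion stated
explicitly to avoid a silent factor-100 error. Hydrogen-bond series are
summarized as the percent change between the means of an initial and a
final time window; note the asymmetry under swapping windows (the
denominator changes), which is inherent to a percent-change measure.

## What the generator emulates — and what it does not

`generate_experiment()` draws, per condition, bundle lengths uniform on
10–15 µm and diameters uniform on 30–100 nm (the reported ranges; only
ranges are reported, so uniform is the least-informative choice and
alternatives are pluggable), per-bundle moduli normal around the
condition truth with a 20% coefficient of variation (a free parameter
chosen so recovered spreads are of the order of the reported error
bars), and per-bundle asymmetries normal around 1.15% times the
condition multiplier with 5% CV (modest geometric variability; no
spread is reported for it). The observed diameter carries 7%
multiplicative error — the reported within-bundle diameter variability,
treated here as measurement error on the radius entering $R/L^2$.
Air spectra hold modes 1–3 at $Q = 5, 8, 8$; vacuum spectra hold the
fundamental doublet at $Q = 250$; peak-amplitude-to-noise is 20. Mode
frequencies are jittered multiplicatively by 1% per mode (measurement
repeatability; flagged as the calibration knob of the study) —
independently per air mode, but **common-mode across the two doublet
planes**, since slow drift moves the whole doublet within one sweep
while their separation is set by the cross section. Condition presets
(moduli 5.3/8.1/12.6/2.6 GPa; splitting multipliers 1.00/1.32/1.82/1.21;
densities 1700 vs 1500 kg m⁻³) are generator *inputs* for recovery
testing, never claimed as outputs.

Not emulated: 1/f noise and drift within a sweep, temperature/humidity
dependence of the modulus (measurement conditions are fixed), amplitude
calibration (the vibrometer's transduction gain is unknown, so
amplitudes are arbitrary units and all inference uses only $f_0$ and
$Q$), torsional/longitudinal modes, and nonlinear (Duffing) response.
Passing recovery tests therefore demonstrates the estimators' internal
consistency under realistic statistical structure — not immunity to the
systematic effects real spectra may carry.

## Problem sizes and numerical conventions

- Synthetic spectra use dense grids (about 280 points per bandwidth at
  $Q = 5$, 400 at $Q = 250$ in the validation studies; the generator's
  experiment spectra use 2000/900-point grids), consistent with
  zoom-FFT acquisition on a vibrometer; density is chosen so the
  noise-limited $f_0$ precision, which is unbiased, sits below 0.1% at
  peak SNR 10.
- The repeated-recovery study (`condition_recovery_study()`) runs 100
  seeded repetitions at the fitted-peak level: bundle populations and
  measurement jitter are generated, but lineshape synthesis and refit
  are skipped, since the single full spectra→inference run demonstrates
  that fitting contributes far less frequency error than the 1% jitter.
  This keeps the study to seconds while measuring the same estimator.
- Seeds are mandatory wherever randomness enters; every generator is
  byte-reproducible under its seed (`withr::with_seed`, leaving the
  caller's RNG state untouched).
- Degenerate inputs fail loudly and early: non-positive geometry or
  material parameters, unordered elliptic diameters, string models
  without tension, regression on fewer than three bundles or identical
  abscissae, 3 dB crossings outside the window (naming the missing
  side), unknown titration dose labels.

## Known limitations

- Absolute SMD moduli depend on the helix-area and $L_0$ conventions
  (above); only relative comparisons are convention-free.
- The per-bundle modulus inversion inherits the squared diameter
  measurement error ($E_i \propto R_\mathrm{obs}^{-2}$), inflating the
  per-bundle spread relative to the pooled regression; both are
  reported.
- The classification treats modes beyond the third as uninformative,
  matching how the mode-ratio diagnostic is used in practice.
- At $Q \lesssim 5$ the 3 dB estimator's low-$Q$ bias (documented above)
  makes the lineshape fit the estimator of record.
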