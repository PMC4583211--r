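---
title: "Spin-Hamiltonian analysis of VTVH MCD data with mcdspin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin-Hamiltonian analysis of VTVH MCD data with mcdspin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdspin)
```

## The physical problem

Low-temperature magnetic circular dichroism (MCD) of paramagnetic
transition-metal complexes is dominated by *C*-terms: differential
absorption of circularly polarized light arising from the unequal Boltzmann
populations of the ground-state magnetic sublevels. Two families of
information can be extracted from variable-temperature, variable-field
(VTVH) measurements of this signal:

* **ground-state spin-Hamiltonian (SH) parameters** — zero-field splitting
  (D, E/D), g-values and, for coupled clusters, the Heisenberg exchange
  constant J — because they control how the sublevel populations and spin
  expectation values respond to field and temperature; and
* **excited-state polarizations** — the fraction of each band's intensity
  polarized along each molecular axis — because each spin direction couples
  to a different bilinear product of transition dipole moments.

`mcdspin` implements this analysis for the two systems that motivated it: a
mononuclear S = 1 iron(IV)-oxo centre with a large positive axial ZFS
(D = +28 cm⁻¹, E/D = 0) and a ferromagnetically exchange-coupled
diiron(IV) dimer of two local S = 1 spins, plus the band-level machinery
(Gaussian ABS/MCD deconvolution with C₀/D₀ classification, and C-term /
pseudo-A-term sign prediction for one-electron d–d transitions).

## The spin Hamiltonian

For each site i the package builds

$$\hat H_i = \hat{\mathbf S}_i \cdot \mathbf D_i \cdot \hat{\mathbf S}_i
  + \beta \, \mathbf B \cdot \mathbf g_i \cdot \hat{\mathbf S}_i,$$

with the ZFS tensor in principal form
$\mathrm{diag}(-D/3+E,\; -D/3-E,\; 2D/3)$ (so that the familiar
$D[\hat S_z^2 - S(S+1)/3] + E(\hat S_x^2-\hat S_y^2)$ is recovered, and the
zero-field gap of an axial S = 1 system equals D). For a dimer the two site
Hamiltonians act on the Kronecker-product basis $|M_A, M_B\rangle$ and an
isotropic exchange term is added. Two conventions are supported and
interconverted exactly:
$\hat H_\mathrm{ex} = -2J\,\hat{\mathbf s}_A\cdot\hat{\mathbf s}_B$
(J > 0 ferromagnetic; the package default) and
$\hat H_\mathrm{ex} = +J\,\hat{\mathbf s}_A\cdot\hat{\mathbf s}_B$, with
$J_{+J} = -2J_{-2J}$.

Constants are fixed at β = 0.4668645 cm⁻¹ T⁻¹ and k = 0.6950348 cm⁻¹ K⁻¹;
energies are cm⁻¹, fields Tesla, temperatures Kelvin throughout.

**Orientation conventions.** Euler angles are Z-Y-Z, *active*, in degrees;
each site's g-tensor is diagonal in the site's ZFS principal frame and
co-rotates with it. For the diiron preset, the B-site tensor is rotated by
90° about the molecular Y axis (`euler = c(0, 90, 0)`), placing its
principal axis perpendicular to the A-site axis as the magnetometric
analyses of such open-core dimers indicate. The rotation *axis* is a
genuinely open choice (only "rotated by 90°" is documented for the original
system); it is exposed in full through the three Euler angles, and the
perpendicular default is the package's own decision — it is also the
geometry in which the B-site rhombicity is cleanly identifiable from powder
data.

## C-term intensity and VTVH curves

The saturation-magnetization intensity of a band is computed as the exact
powder average

$$\frac{\Delta\varepsilon}{E} =
 \frac{\gamma}{4\pi S}\oint \sum_i N_i \left(
 l_x \langle \hat S_x \rangle_i M^\mathrm{eff}_{yz} +
 l_y \langle \hat S_y \rangle_i M^\mathrm{eff}_{xz} +
 l_z \langle \hat S_z \rangle_i M^\mathrm{eff}_{xy}\right) d\Omega,$$

with the Hamiltonian diagonalized exactly at every orientation node (no
linear-response shortcut), $N_i$ the Boltzmann populations, and
$M^\mathrm{eff}_{vw}$ the signed effective transition dipole moment
products. Only C-terms are modeled: A-terms (derivative shapes from
degenerate excited states) and B-terms (field-induced state mixing) are
deliberately out of scope, which is the standard low-temperature regime of
this analysis.

Within degenerate eigen-subspaces (relevant at zero field) the spin
expectation values are replaced by the subspace average
$\mathrm{tr}(P\hat S_u P)/\dim P$, so that the arbitrary mixing a numerical
eigensolver picks inside a degenerate block cannot leak into the result;
time-reversal partners then cancel exactly and the intensity vanishes at
B = 0 identically.

**Quadrature.** The orientation integral uses Gauss–Legendre nodes in
cos θ × a uniform (trapezoidal) grid in φ; the default density of 32 × 64
changes by less than 10⁻⁶ relative on doubling for these smooth integrands
(the test suite verifies this). Fitting loops use a reduced 12 × 24 –
20 × 40 grid, which is still orders of magnitude below the other error
sources in a fit.

**Normalization.** $S$ is the total spin of the zero-field ground
multiplet, determined numerically from ⟨Ŝ²⟩ in the ground subspace (S = 2
for the ferromagnetic dimer). For dimer bands the spin expectation values
may be taken over the *total* spin or over a *single site's* spin
(`site = "A"`, `"B"`), reflecting that a localized excitation senses the
local moment; which choice the original dimer analyses used is not
documented, so both are provided and the synthetic presets tag each band
with the site of its parent transition.

Diagnostics: for an isotropic S = 1/2 system the powder curve collapses
onto $\tanh(g\beta B/2kT)$ (verified to 10⁻⁴ against the closed form) and
isotherms overlay on a βB/kT axis; zero-field-split S ≥ 1 systems produce
nested isotherms. `nesting_metric()` quantifies nesting as the largest
normalized spread between isotherm pairs over their shared βB/kT range,
anchoring each pair at the common endpoint so that genuinely overlaying
curves score zero regardless of sampling.

## Fitting: moments, SH parameters, error surfaces

At fixed SH parameters the intensity is *linear* in the three products
γM_vw, so per-band moments are estimated by exact weighted linear least
squares (variable projection) rather than iterative search. Two numerical
choices matter:

* **Truncated SVD (rtol = 10⁻⁴).** Powder quasi-symmetries can make design
  columns (near-)collinear — exactly collinear for an axial system, where
  x and y are equivalent. A naive solver then amplifies quadrature-level
  column differences into enormous moment amplitudes that overfit noise.
  Directions with singular values below 10⁻⁴ of the largest are discarded;
  the threshold sits well above numerical noise (~10⁻⁸ relative) and well
  below the smallest physically resolved anisotropy directions (~10⁻³).
  The minimum-norm solution also splits exactly degenerate directions
  symmetrically, which is the physically sensible gauge.
* **Sign gauge.** Predictions depend only on the relative signs of the
  products, so the overall sign is fixed by M_xz ≥ 0, absorbed into γ.

Free SH parameters (any subset of D and E/D per site and J, with finite
box bounds; E/D always within [0, 1/3]) are refined by `nlminb` with the
moments profiled out at every evaluation. Because such fits possess many
local minima, optimization is multi-started from a seeded Latin-hypercube
design plus the user's starting values; the per-restart table is part of
the result. The loss is the weighted sum of squared residuals (1/σ² with
per-point σ when available, unit weights otherwise — no loss function is
canonical here, and this is the maximum-likelihood choice for Gaussian
noise).

Uncertainty in flat directions is assessed by `scan_error_surface()`
(profile-likelihood style): the named parameter is clamped on a grid and
everything else re-optimized, warm-starting each grid point from its
neighbour. For the diiron system the J surface is flat over tens of cm⁻¹,
with the fitted D_B rising to compensate increasing J — reproducing the
documented behaviour of such dimer fits and the reason covariance-matrix
errors would be misleading here.

## Gaussian deconvolution and C₀/D₀

`simultaneous_deconvolve()` fits n bands jointly to an absorption and an
MCD spectrum: shared centers (the MCD center may shift by at most a hard
bound of 3% of the center), one free width per band shared between the two
spectra, non-negative ABS amplitudes, signed MCD amplitudes. Bands are
Gaussian in *energy*, not wavelength. Both spectra are internally rescaled
to unit maximum so neither dominates the Levenberg–Marquardt residual and
the optimization path is exactly invariant under a common rescaling of the
data. Centers are box-constrained within ±1500 cm⁻¹ of their initial
guesses to preserve band identities; `deconvolution_init()` builds starting
amplitudes by reading the spectra at the candidate centers.

The C₀/D₀ ratio implemented is the moment-analysis definition

$$C_0/D_0 = \frac{kT}{\beta B}\,
  \frac{\int (\Delta\varepsilon/E)\, dE}{\int (\varepsilon/E)\, dE},$$

with the integrals over the band's fitted Gaussian profiles. The original
deconvolution software's exact normalization is not documented, so only the
sign and threshold behaviour of the ratio is relied upon: |C₀/D₀| strictly
greater than 0.17 classifies a band as metal-centered (d–d), otherwise as
charge transfer; a ratio exactly at the threshold is CT (the boundary
convention is arbitrary and therefore documented rather than meaningful).

## C-term signs of coupled d–d transitions

For two one-electron transitions sharing a common orbital, the
saturation-limit C-term sign of member J coupled to partner K is

$$\mathrm{sign}\left[\frac{1}{\Delta_{KJ}}\sum_t L^{KJ}_t\,
 (\mathbf D^J \times \mathbf D^K)_t\right],\qquad
 \Delta_{KJ} = E_K - E_J,$$

where $L^{KJ}$ collects the one-electron orbital angular-momentum matrix
elements between the differing orbitals (donor orbitals for a shared
acceptor, acceptor orbitals for a shared donor, with the hole/particle
ordering fixed so that the rule is antisymmetric under J ↔ K). This is
equivalent to the graphical handedness rule — a left-handed triple
(D^J, D^K, L) with Δ > 0 absorbs right-circular light and gives a negative
C-term — and the test suite verifies the equivalence exhaustively over all
orbital pairs with axis-aligned dipoles. Real d orbitals carry
Condon–Shortley-derived phases; all signs are stated relative to this
documented convention, calibrated so the in-plane E pair
(d_xz → d_x²−y², dipole −x, lower) / (d_yz → d_x²−y², dipole −y, upper)
yields a negative lower C-term and a positive pseudo-A term. The two
members of a pair always have opposite signs, and the pseudo-A sign (that
of the higher-energy member) is independent of which member lies lower.

Transition dipole *directions* are user inputs: they come from
transition-density arguments outside the scope of a spin-Hamiltonian
package. `complex1_pairs()` ships the two preset pairs of the mononuclear
complex: (−x, −y) for the pair reaching d_x²−y² (the documented overlap
analysis) and (−x, +y) for the pair reaching d_z², the relative orientation
consistent with that feature's negative pseudo-A assignment (the original
derivation lives in supporting material that is not reproduced here, so
this orientation is a preset convention, not a derived result). The
two-electron intensity-borrowing mechanism of the lowest band is out of
scope, and no sign is asserted for it.

## Synthetic data: what it emulates, what it does not

`synth_mono_vtvh()`, `synth_dimer_vtvh()` and `synth_spectra()` generate
the three study scenarios with seeded Gaussian noise, attaching the full
generating truth to every dataset so parameter recovery can be scored
automatically.

* Mono: D = 28 cm⁻¹, E/D = 0, g = 2.00, B = 10 T, T ∈ {2, 5, 10, 20, 40,
  60} K, four bands with synthetic polarization choices (z-polarized,
  two in-plane components, mixed).
* Dimer: D_A = 28 / (E/D)_A = 0, D_B = 5.3 / (E/D)_B = 0.30 (rotated 90°),
  g = 2.00, J = 35 cm⁻¹ (−2J convention), B = 0–7 T in 0.5 T steps (the
  typical sampling density of published VTVH isotherms; the original
  figure shows quasi-continuous sweeps), T ∈ {2, 5, 10, 20} K, six
  detection wavelengths whose moment products are synthesized from the
  published per-band polarization percentages via
  `moments_from_polarization()` (zero percentages floored at 1% to keep
  the inversion regular). The published band *amplitudes* are not
  available, so these moments are synthetic choices that reproduce the
  polarization classes, nothing more.
* Spectra: ten Gaussians at the published band energies, FWHM 2500 cm⁻¹,
  unit ABS amplitudes, MCD signs following the published C₀/D₀ signs.
* Noise: Gaussian, defaulting to 1% of each curve's (or spectrum's)
  maximum — no noise figures are published, and 1% is a realistic
  signal-to-noise for low-temperature MCD intensities.

The generators deliberately do **not** emulate instrument baselines,
glass-strain depolarization, wavelength-dependent noise, or B-/A-term
contamination. Passing recovery tests therefore demonstrates that the
estimator is consistent and well-conditioned under the stated statistical
model, not that real spectra of arbitrary quality will yield parameters at
this precision. Under the study conditions the (D_B, E/D_B) maximum-
likelihood estimator has a standard error comparable to the recovery
tolerances used in the tests (±1.5 cm⁻¹, ±0.05), so individual noise
realizations near the edge of that band are expected behaviour, not
estimator failure.

## Problem sizes and determinism

The shipped tests run the dimer recovery at a 12 × 24 orientation grid
with 3 restarts, the J error-surface scan on a 5-point grid with
warm-started refits, and the deconvolution round-trip on a
5000–30000 cm⁻¹ grid at 25 cm⁻¹ resolution — sizes chosen so the whole
suite completes in well under a minute per module while staying inside the
regimes where each approximation is demonstrably converged. Every source
of randomness (noise draws, restart designs, initial-center perturbations)
is derived from explicit integer seeds; identical seeds give bit-identical
datasets, fits and files.

## Known limitations

* Absolute Δε units (and hence absolute C₀/D₀ magnitudes for fitted real
  spectra) are out of scope; γ is an arbitrary per-band scale.
* Only bilinear isotropic exchange; no antisymmetric or anisotropic
  exchange, no hyperfine terms.
* The sign rules cover single excitations in the saturation limit;
  out-of-state spin–orbit distortions of band shapes are not modeled.
* Gaussian band shapes only (no skew/Voigt profiles).
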