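---
title: "Membrane biophysics of antimicrobial peptides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane biophysics of antimicrobial peptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampscatter)
```

# Scope

`ampscatter` implements the quantitative analysis chain used to
characterize short cationic antimicrobial peptides (AMPs) interacting with
lipid model membranes: sequence descriptors and MIC statistics, circular
dichroism (CD) secondary-structure decomposition, diffuse low-angle X-ray
scattering (XDS) fits of the bilayer bending modulus, wide-angle (WAXS)
chain order parameters, scattering-density-profile (SDP) form-factor
modeling with peptide localization, lamellar/Scherrer analysis of solution
SAXS as a vesicle-fusion readout, and composition-space modeling of
specular neutron reflectivity (NR). Because raw scattering images and
spectra of such studies are rarely published, every module is paired with
a seeded synthetic-data generator with known ground truth; the test suite
and the acceptance script quantify recovery of that truth.

# Peptide descriptors and MIC statistics

Hydrophobicity `H` is the arithmetic mean of per-residue values on the
Fauchere–Pliska octanol/water scale (the scale used by the HeliQuest
server); `net_charge()` uses integer counting at pH 7 (+1 for Arg/Lys, -1
for Asp/Glu, His neutral, termini ignored), the convention under which the
charges of Arg/Trp-rich designed peptides equal their arginine counts.
MIC panels are summarised as unweighted means over species; the standard
error combines per-species standard deviations in quadrature,
`sqrt(sum(sigma_i^2))/N`, or falls back to the (N-1) sample SD of species
means over `sqrt(N)` when only species-level values are available. A
single species yields SEM 0 by convention. Display rounding is
round-half-even at the printed precision; stored values keep full
precision.

# CD decomposition

Instrument ellipticity converts to mean residue ellipticity as
`MRE = epsilon * 1e4 / N`; the constant folds in the fixed acquisition
conditions (10 uM peptide, 3 mL cell) and the conversion is only valid
there. Decomposition minimises the squared misfit of the MRE trace
against four motif reference spectra (alpha-helix, beta-sheet, beta-turn,
random coil) under non-negativity and a sum-to-one constraint. The
constraint is enforced by a heavily weighted augmented row in a
non-negative least squares problem (solved with an active-set NNLS after
column normalization), which is deterministic and needs no tuning; the
weight scales with the basis so fractions are invariant to a common
rescaling of spectrum and basis.

No measured reference basis is bundled: the shipped basis
(`cd_basis()`, `inst/extdata/cd_basis_synthetic.csv`) is a synthetic
Gaussian-sum approximation of the classic poly-peptide motif band shapes
on 200–240 nm, versioned and clearly labelled synthetic. Decompositions
of real spectra are therefore basis-dependent; only recovery of synthetic
mixtures is asserted by tests. Users supply their own basis for
quantitative work, and the tryptophan side-chain reference and its scale
(`n_W/N` is the conventional default) are explicit inputs to
`subtract_reference()` because the appropriate trace is
instrument-dependent.

Per-motif uncertainties mirror the spread over a handful of repeated
fits: since NNLS is deterministic, the four repeats perturb the spectrum
by residual-RMS-scaled seeded noise rather than jittering start points.

# Smectic elasticity from diffuse XDS

A stack of `N` fluctuating bilayers is described by the discrete smectic
free energy

F = 1/2 sum_n int [ K_C (laplacian u_n)^2 + B (u_{n+1} - u_n)^2 ] d^2r,

with bending modulus `K_C` (reported both in k_BT at 310.15 K and in
1e-21 J) and interlayer compression modulus `B` (k_BT/A^4). Equipartition
gives each discrete mode the amplitude
`kBT / (A (K_C q_r^4 + 2B(1 - cos(2 pi m/N))))`; height-difference
correlations `delta_k(r)` follow by quadrature over the lateral spectrum
with infrared cutoff `2 pi / L_r` and an upper cutoff of 2 /A at
molecular scales, on a log-spaced grid doubled until stable to 0.1%. The
diffuse structure factor sums layer pairs weighted by `(N - |k|)` with a
Hankel-type radial integral of the Gaussian-fluctuation factor
`exp(-q_z^2 delta_k(r)/2)` over the finite domain, normalised so a frozen
stack reproduces the ideal finite-lattice interference (S = N^2 at the
Bragg point). The observation model multiplies by `|F(q_z)|^2 / q_z` (the
flat-sample Lorentz factor) with optional Gaussian lateral resolution;
the beam/specular region below a configurable `q_z` cutoff is masked.

`fit_elasticity()` runs weighted Levenberg–Marquardt least squares over
`(log K_C, log B, log scale)` with `N`, `L_r`, `D` fixed at configured
values. A higher fitted `K_C` means a stiffer membrane. Estimates pinned
at the stiff bound are flagged (`kc_at_upper_bound`), which is also the
correct diagnostic for patterns with no lateral fall-off. Oriented
samples in experiments contain on the order of a thousand bilayers, but
the fitted `N` is an effective coherence number; the package default
(`N_layers = 16`, `L_r = 800` A, pattern grids of a few hundred pixels)
keeps a desk-scale study — 20 seeded noisy patterns fitted jointly for
(K_C, B) — inside a couple of minutes on one core, and the recovery
study shows this size already gives <5% bias and well under 15% spread
at 5% multiplicative noise.

# WAXS chain order

Acyl-chain scattering is modelled as long thin rods tilted by `beta` from
the local director with Maier–Saupe weighting
`f(beta) ~ exp(m cos^2 beta) sin(beta)` on [0, pi/2] (evaluated as
`exp(-m sin^2 beta)` to stay finite at large concentration `m`). The
order parameter is `S_xray = (3 <cos^2 beta> - 1)/2`: 0 for isotropic
chains, 1 for perfect alignment. The default detector-arc model
identifies the arc angle phi with the rod tilt (small-angle mapping, unit
Jacobian), fitting `I(phi) = scale * exp(m cos^2 phi) + background`; the
exact geometric projection — the azimuthal delta-ring integral with its
integrable edge singularity, regularised by a square-root substitution —
is available via `projection = "exact"`. Both give flat profiles at
`m = 0`. A vanishing modulation amplitude leaves `m` unidentified and is
reported as `m_pinned_at_zero`. The flat additive background suffices
because the incidence-pair subtraction (`subtract_incidence_pair()`)
removes structured window scatter. The q band integrated over the arc is
a required input: chain–chain correlations for fluid-phase phospholipids
sit near 1.2–1.6 1/A, but the exact band is instrument-dependent.

# SDP electron-density modeling

The bilayer is decomposed into component groups: Gaussians for the
phosphate-plus-outer-headgroup (Phos) and carbonyl/glycerol (CG) in each
leaflet, a central terminal-methyl (CH3) Gaussian, a methylene (CH2)
region bounded by an error-function slab of half-width
`D_C = V_HC / A_L`, an optional peptide Gaussian (single, or a pair with
a fitted split for the "both" placement), and water. Volume bookkeeping
uses a displacement convention: groups overlapping the hydrocarbon
envelope displace methylenes, while outside it they displace water, so
total occupancy is exactly one everywhere — the headgroup tails of
realistic parameter sets always intrude a few percent into the slab, and
treating water as a clipped complement would silently violate
probability conservation there. A slab overfill (negative methylene
occupancy) is reported, and models whose headgroup-plus-peptide occupancy
exceeds one are rejected.

The form factor `F(q_z) = int (rho(z) - rho_w) cos(q_z z) dz` is analytic
for all Gaussian and slab terms; the slab-intrusion product has no
closed-form transform and is integrated numerically on a 0.01 A grid
(trapezoid, exploiting symmetry), accurate to ~1e-9 in absolute terms.
Data are `|F|` in arbitrary units, so one multiplicative scale per
dataset is free and `F(0)` is never constrained by data; lobe signs are
implicit in the signed model `F`. Peptide electrons and volume come from
the sequence (`peptide_electrons()`, summed residue formulas plus one
water, Zamyatnin-style residue volumes), scaled by the lipid:peptide
molar ratio (75:1 in the fits this package emulates). Default lipid
component volumes and electrons are plausible values for mixed
fluid-phase phosphoethanolamine/phosphoglycerol membranes at 37 C,
chosen so a control bilayer with `A_L = 70.8` A^2 realizes a hydrocarbon
thickness `2 D_C = 29.1` A; all are user-overridable, and component
volumes stay fixed during fitting by default (free volumes are easily
under-determined by a single `|F|` curve).

Structural outputs: `D_HH` is the peak-to-peak distance of the summed
Phos+CG electron density (grid peak with quadratic refinement), `2 D_C`
the FWHM of the hydrocarbon envelope, `A_L` read from the model.
`fit_form_factor(placement = "scan")` fits the three peptide placements
and selects by chi-square with a BIC-style penalty of log(n) per fitted
parameter; because the two-Gaussian "both" model nests the
single-Gaussian placements, raw minimal chi-square (or even the milder
AIC penalty) would select it on a sizeable fraction of noise
realizations, while the BIC penalty identifies the generating placement
consistently.

# SAXS lamellar analysis

Curves are reduced by azimuthal averaging and water-background
subtraction with quadrature error propagation. Bragg candidates are
local maxima at least 3 sigma above a rolling median background over a
15-point window — robust against the broad diffuse lobe of unilamellar
vesicles — with three robustness guards: the base threshold is lifted to
a family-wise 5% level across the curve (isolated noise excursions
otherwise become spurious "orders" in the low-signal region near
form-factor zeros), a 20%-of-background prominence floor rejects broad
diffuse maxima on low-noise data, and each candidate is refined by a
local Gaussian-plus-linear fit whose center drift, width and residuals
filter flank artifacts. Orders are integers against the lowest-q peak
(tolerance 8% per order); inconsistent peaks stay unassigned with a
warning. `D = 2 pi n / q_n` averages assigned orders weighted by
`1/FWHM^2`. Scherrer lamellarity uses `L = 2 pi K / dq` with shape
factor `K = 0.9` by default and quadrature deconvolution of an optional
instrumental resolution; widths at the resolution give only a lower
bound. Phase classification: no assigned orders is ULV; detected orders
dominated an order of magnitude (threshold 10) over the diffuse level —
measured at the peak top against the flank-interpolated background — is
MLV; in between is mixed, covering curves where only small Bragg orders
ride the first diffuse lobe. The published lamellarity numbers (86/107
vs 30/20 bilayers) depend on an unstated shape factor and resolution, so
the package asserts only round-trip recovery (±10%) and the qualitative
ordering.

The paracrystalline generator (`gen_saxs()`) multiplies a finite-N
stacking structure factor with cumulative disorder by a smooth bilayer
form factor, adds an uncorrelated-bilayer (diffuse) component with
configurable weight and a `1/q^2` vesicle Lorentz factor. It gives
analytic control of both peak position and width, which is what the
Scherrer round trip needs.

# Neutron reflectivity

A tethered bilayer on a gold-coated substrate is parameterized by
continuous volume occupancies along the interface normal: substrate
(gold film, 140 A and 4–9 A roughness as generator/prior defaults),
tether/SAM, inner and outer headgroups, hydrocarbon core, a free-form
peptide profile as a monotone-safe cubic Hermite spline with control
points about 15 A apart (spacing under 5 A is rejected as
over-parameterization; the spline count follows the peptide extension),
and solvent filling the remainder. SLDs are bundled constants; only the
solvent SLD switches between H2O and D2O, so a contrast pair shares one
structure by construction. Reflectivity is exact dynamical
(Parratt/Abeles) recursion through a <=2 A slab discretization with
optional Nevot–Croce roughness, vectorized over q; it matches the
Fresnel and single-slab closed forms to 1e-10 and the kinematic (Born)
approximation within 5% well above the critical edge.

`fit_contrast_pair()` samples the joint Gaussian likelihood of both
contrasts with a seeded adaptive Metropolis chain: a global scale
adapted toward ~30% acceptance and a covariance-shaped proposal learned
during burn-in (posterior correlations otherwise throttle mixing). It
reports medians, 68% credible intervals, a split-Rhat mixing diagnostic
(flagged above 1.1) and per-parameter effective sample sizes; the
interval endpoints include the Monte Carlo standard error of the
quantile estimates, so finite chains yield slightly conservative rather
than too-narrow intervals. The calibration study uses 8000 steps with
2000 burn-in (effective sample sizes around 400) on a 4-parameter
profile — hydrocarbon thickness, bilayer completeness, two peptide
control values — at an identifiable operating point (completeness 0.88:
a volume-saturated bilayer would leave the peptide spline amplitudes
partially unidentified and make calibration statements meaningless).
A 20-replicate study runs in roughly a quarter hour on one core.
Coverage is assessed per parameter: the fraction of replicates in which
each parameter's marginal 68% interval contains the truth must be at
least 60%. (Requiring all parameters jointly inside their marginal
intervals would have nominal probability near 0.68^p, not 0.68, and is
not a calibration statement.)

# Synthetic data: what it does and does not emulate

Generators produce CD mixtures with absolute Gaussian noise (a fraction
of the peak |MRE|, on the 0.5 nm pitch a scanning CD instrument
records), diffuse XDS patterns and WAXS arcs (1-degree bins) with
multiplicative noise — the counting-statistics convention for detector
data — SDP form-factor curves with relative noise (I ~ F^2 at constant
relative error makes sigma_F proportional to F, floored near the
form-factor zeros), paracrystalline SAXS curves, two-contrast NR pairs,
and log-normal strain-resolved MIC panels (optionally quantized to the
two-fold dilution series). Defaults reflect the study conditions this
package emulates: 37 C, lamellar spacings of 50–60 A, bending moduli of
order 20 k_BT, 5% detector noise, 3% noise on |F| and NR curves,
lipid:peptide 75:1, MIC strain dispersion ~30%. All generators are
deterministic under a fixed seed and serialize their truth alongside the
data (`generator_truth()`).

Passing recovery tests on these data shows the estimators are correct
and well-conditioned under the stated noise models; it does not certify
behavior under real-data pathologies the generators deliberately omit:
mosaic spread, beam footprint and absorption, detector gaps and
beamstop shadows, absorption flattening in CD, incoherent background in
NR, or model error in the reference basis and component volumes.

# Numerical choices and limitations

- Quadratures: smectic height correlations on log-spaced grids doubled
  to 0.1% stability; tilt-density averages via adaptive quadrature at
  1e-10; SDP intrusion transform by trapezoid at 0.01 A.
- Optimisers: Levenberg–Marquardt (`minpack.lm`) everywhere a nonlinear
  least-squares fit is specified; log-parameterization keeps moduli and
  concentrations positive; bound hits are flagged, never silently
  accepted.
- Ties and degeneracies: rank-deficient CD bases warn and still return a
  constrained fit; flat WAXS profiles pin `m = 0`; resolution-limited
  Scherrer widths return lower bounds; non-mixing MCMC chains are
  flagged by split-Rhat.
- The Caillé-theory fits fix `N_layers` and `L_r`; letting them float
  trades against `B` and is deliberately left to explicit configuration.
- Real-data CD and SDP results are basis- and volume-dependent
  respectively; both inputs are exposed and versioned rather than
  hidden.
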