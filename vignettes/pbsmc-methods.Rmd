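---
title: "Methods: a desk-scale Monte Carlo engine for proton pencil beam scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale Monte Carlo engine for proton pencil beam scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pbsmc is a self-contained dose-calculation platform for proton pencil beam
scanning (PBS): a parameterized beam source commissioned from simple
measurements, a condensed-history Monte Carlo transport engine with a range
shifter and voxelized phantoms, and the QA analyses used to validate such
engines (field-size factors, SOBP metrics, gamma index, DVH). This vignette
is the package's own account of the models, the numerical choices, and what
the synthetic study conditions do and do not demonstrate.

## Coordinates and source model

All geometry uses the IEC61217 gantry system: the origin at isocenter, the
source plane on the positive z axis at the upstream face of the range
shifter, and the beam travelling toward decreasing z. Positions are in mm,
energies in MeV.

Each scanned spot's transverse phase space per axis is a Courant–Snyder
(sigma-matrix) description: spot sigma $\sigma_0$ at isocenter, angular
sigma $\sigma_\theta$, and correlation $\rho_0$. A free drift by $Z$ maps the
sigma matrix through $M = \begin{pmatrix}1 & -Z\\ 0 & 1\end{pmatrix}$, giving
the closed forms

$$\sigma^2(Z) = \sigma_0^2 - 2\rho_0\sigma_0\sigma_\theta Z +
\sigma_\theta^2 Z^2, \qquad
\rho(Z) = \frac{\rho_0\sigma_0 - \sigma_\theta Z}{\sigma(Z)},$$

with $\rho > 0$ on the defocusing side. `fit_optics()` recovers
$(\sigma_0, \sigma_\theta, \rho_0)$ by least squares on $\sigma^2(z)$
measured at several in-air planes; the divergence is treated as constant in
air (the fitted value already absorbs air scattering), so the region between
source plane and phantom is simulated as vacuum. Scanning deflections aim
each spot from effective focal points at distances $f_x$, $f_y$ fitted from
beam positions at two planes (`fit_effective_sad()`). The x and y axes are
commissioned independently (spots are elliptical); no x–y correlation is
modeled. Parameters at non-commissioned energies are interpolated linearly
component by component — matching how machine lookup tables are used
clinically — with no extrapolation outside the commissioned band.

## Single-proton physics

*Stopping power.* The Bethe formula without shell or density-effect
corrections, with the material's mean excitation energy. This is adequate in
the 10–300 MeV transport band: against PSTAR water values the implementation
agrees to better than 1% (asserted in the test suite). Below ~10 MeV the
formula drifts from tabulated data, which is immaterial here because protons
below the 2 MeV transport cutoff deposit locally and carry sub-millimeter
residual range. Range–energy tables are built once per material by
trapezoidal integration of $1/S$ on a grid that is fine (0.02 MeV) below
2 MeV and 0.5 MeV pitch above 10 MeV, cached, and interpolated monotonically
(Hyman splines); the engine uses uniform-grid resamplings for O(1) lookups.

*Water-equivalent thickness.* By range differencing: the exit energy after a
slab is read off the material's range table and mapped onto water's.
Computed at 160 MeV by default (mid-band); the WET of plastics varies by
less than 0.5% over 100–225 MeV, so one reference energy suffices.

*Energy straggling.* Relativistic Bohr formula; Gaussian per step, variance
proportional to path length.

*Multiple Coulomb scattering.* The Highland parameterization of
Rossi–Greisen scattering,
$\theta_0 = \frac{14.1}{pv}\sqrt{t/X_0}\,[1 + \tfrac19\log_{10}(t/X_0)]$,
with radiation lengths from the Tsai per-element approximation combined by
mass fraction. In the stepping loop the logarithmic factor uses the
*cumulative* path rather than the step, so many small steps accumulate the
same angular variance as one large step; this keeps the step-size dependence
of the lateral spread below ~1% and makes the Monte Carlo agree with a
deterministic Fermi–Eyges quadrature within 3% down to late depths.

*Nonelastic nuclear interactions.* A macroscopic nonelastic cross section
for water is embedded on a coarse energy grid: zero below the ~8 MeV
threshold, a maximum near 25 MeV, and a ~290 mb plateau above 150 MeV
(hydrogen contributes no nonelastic channel at these energies); the values
are literature-scale numbers for p+O, and their absolute normalization is
validated through the primary-loss budget of the range shifter (loss of
~9% of 115 MeV primaries over 74 mm water-equivalent path). Other materials
scale the water curve by water-equivalent path length. Elastic nuclear
scattering is not sampled separately; its lateral effect is absorbed by the
calibrated secondary channel below.

## The effective secondary-proton channel

A nonelastic event terminates the proton and emits **one** weighted
effective secondary proton; the event energy not carried by the secondary is
split between local deposition and escaping neutrals (neutrons, gammas —
bookkept, never transported). The emission parameters are not measurable
from first principles at this model's granularity, so they are **calibrated
once** against the field-size-factor (FSF) halo scale of scanned fields and
then frozen:

| parameter | default | meaning |
|---|---|---|
| `multiplicity_weight` | 0.92 | statistical weight of the emitted secondary |
| `e_frac_range` | (0.45, 0.95) | uniform energy fraction of the event energy |
| `angular_sigma_deg_100` | 42° | angular sigma for a 100 MeV secondary |
| `angular_energy_exponent` | 2.0 | sigma scales as $(100/E)^p$, capped at 69° |
| `local_deposit_fraction` | 0.3 | non-secondary event energy deposited locally |

The calibration targets were the two field-size observables that bracket the
halo: the 40 vs 200 mm FSF difference of ~3% for a 115 MeV field at plateau
depths, and a maximum of ~11% for 225 MeV near mid-range. The hard spectrum
(fractions up to 0.95) with moderate angles is what populates radii beyond
the 40 mm field edge: soft, wide-angle secondaries stop within ~10 mm of the
axis and produce no field-size dependence at all. The weighted energy carried
by secondaries (≤ `multiplicity_weight` × 0.95 of the event energy) never
exceeds the event energy, so conservation holds by construction; the test
suite asserts closure of the full energy ledger to 0.1%.

Because the commissioned source is purely Gaussian (a parameterized model
has no nozzle spray), the FSF difference necessarily starts near zero at the
phantom surface and builds up with the in-phantom nuclear halo. "Plateau
depths" for the 115 MeV observable therefore means the central plateau band,
0.35–0.65 of R80 (35–65 mm); at the surface itself a parameterized-source
engine cannot show a halo, and this is a known structural difference from
measured FSF data, not a statistical one.

## Transport numerics

- Step length: min(1 mm, 2% of the residual CSDA range, distance to the next
  region boundary, one voxel pitch inside voxel grids). The 2% cap keeps the
  Highland step bias small; near the end of range steps shrink to ~0.1 mm.
- Per step: CSDA mean energy loss by range differencing (not an Euler step on
  $S(E)$, so the Bragg peak position is exact by construction), plus Bohr
  straggling; Highland deflection; nonelastic removal with probability
  $\Sigma(E)\,\Delta s$.
- Transport cutoff 2 MeV; residual energy is deposited at the endpoint.
- Energy deposits are split across depth bins in proportion to segment
  overlap (IDD, cylindrical and 3D scorers), with the lateral position
  interpolated along the segment.
- Voxel grids store material id and density per voxel; all per-cm physics
  scales linearly with density relative to the material's nominal density.
  Voxel lookup uses the position at the step start; steps are capped at one
  voxel pitch. Coordinates are 0-based half-open intervals with the world
  position of a voxel center at `origin + (index + 0.5) * spacing`.
- The RNG is R's generator, single stream; every simulation entry point
  takes a `seed`, and identical seeds give bit-identical dose arrays (an
  always-on test).
- Gantry and couch angles are carried in the plan model but transport
  assumes incidence along $-z$; oblique incidence on voxel phantoms is out
  of scope.

## Commissioning procedures

*Mean energy* (`tune_mean_energy()`): initial estimate by inverting the
water range–energy table at the measured R80, then a refinement loop that
simulates the depth-dose at the current estimate and updates the energy by
the table slope $dR/dE$ until the simulated R80 matches the measurement
within 0.1 mm. The table-slope update converges in 2–3 simulations; a
plain bisection would need ~15 at the same tolerance. Candidate simulations
share one RNG seed (common random numbers), so the loop sees a smooth
response.

*Energy spread* (`tune_energy_spread()`): grid search on an absolute
0.05 MeV sigma grid. The objective is an equally weighted sum of the
relative peak-to-plateau-ratio discrepancy and the mean point-to-point
relative dose discrepancy between integral-normalized curves. The plateau is
defined as the mean dose over 20–40% of R80 (the flat entrance region); the
peak as the maximum of the 0.5 mm-binned curve. Equal weights are a design
choice exposed as an argument. All candidates share one seed, which makes
the objective smooth in the candidate and the argmin stable at Monte Carlo
sample sizes of $2\times10^5$.

*Protons per MU* (`calibrate_protons_per_mu()`):
$N_{MU} = D_{meas}/(D_{MC}/N_{MC})$ on the standard reference field — 625
spots at 4 mm spacing over 100×100 mm², 1 MU per spot, dose averaged over
the central 16×16 mm² at 42 mm depth — simulated by single-spot kernel
superposition. The "1 MU = 3 nC" chamber definition is carried as metadata
only; the virtual machine generates measured doses from a ground truth with
$N_{MU} \propto 1/S_{air}(E)$, emulating an air-filled monitor chamber.

*IDD scoring* mirrors a Bragg-peak chamber stack: energy per 0.5 mm depth
bin inside an 81.6 mm diameter cylinder, normalized to the integral.

## The virtual machine and its limits

`make_virtual_machine()` is the ground truth for all end-to-end studies:
six commissioned energies (100–225 MeV), spot sigmas falling from ~6 mm to
~3.2 mm with a slight upturn at 225 MeV, divergences from ~6 to ~3 mrad,
energy spreads from 0.67% to 0.28% of the mean, protons per MU anchored at
9×10⁷ at 100 MeV and exactly proportional to $1/S_{air}$, focal distances
$f_x$ = 1859.1 mm and $f_y$ = 2234.8 mm, and a 65 mm Lexan range shifter
(C 75.575%, O 18.876%, H 5.549%; 1.20 g/cm³; I = 73.1 eV) at the source
plane (460 mm). Optics values at energies without published anchors are
smooth interpolants of those trends — fixture inventions, useful for
recovery studies only.

`generate_measurement_set()` adds Gaussian noise (1% on spot sigmas, 0.5% on
absolute doses, 0.05 mm on deflection positions) and produces depth-dose
curves with the package's own engine. Passing recovery tests therefore shows
that the commissioning chain inverts the engine's forward model under
realistic noise — it does not certify the engine against real measured data,
detector response (Lynx/MatriXX), beam spray upstream of the nozzle exit, or
line-specific optics. Those require machine data this package deliberately
does not ship.

Problem sizes used by the shipped studies: $2\times10^5$ protons per
depth-dose curve (statistical noise below 0.5% near the peak), $10^6$ per
FSF kernel, $10^6$ for the range-shifter primary budget, $5\times10^4$ per
SOBP layer. These give Monte Carlo errors comfortably below each
observable's tolerance band.

## SOBP construction

`make_sobp()` selects energy layers so the distal layer's R80 equals the
nominal range, spacing successive layers by ~80% of the pristine-peak FWHM
(straggling plus spectrum width estimated from the range tables), then
solves non-negative least squares on the simulated per-layer depth-dose
curves for a flat central-axis dose across the modulation region (margins of
2 mm at both ends). The R120M40 configuration achieves ~1% flatness and a
distal R80 within 1 mm of nominal.

## QA analyses

- **FSF**: central-axis dose is the mean over a centered 10×10 mm² aperture
  (the chamber-array averaging aperture is not standardized; this choice is
  exposed as an argument). Kernel superposition assumes lateral shift
  invariance of the spot kernel and radial symmetry of the scored kernel;
  the small ellipticity of the optics is averaged out.
- **Gamma index**: global normalization to the reference maximum, 10%
  low-dose threshold, exact search over a 2×DTA neighborhood with subvoxel
  (multilinear) interpolation. A brute-force double-loop implementation is
  kept purely as the test oracle. Gamma is asymmetric under swapping
  reference and evaluated distributions; a test documents this.
- **DVH**: $D_q$ is the order statistic — the largest dose level covering at
  least $q$% of the masked volume — so `dvh_stat()` agrees with a sort-based
  oracle to 1e-9 by construction. $D_{0}$ is the maximum, $D_{100}$ the
  minimum.
- **Radial halo**: fractional integrated planar dose versus radius,
  normalized at 200 mm; the halo metric is $1 - f(40\,\mathrm{mm})$.

## Known limitations

- Neutrons, photons, electrons and heavy fragments are energy sinks, not
  transported particles; their spatial dose is approximated by the local
  deposit fraction at nonelastic vertices.
- Dose is dose-to-medium via energy/mass in the scoring voxel; no
  dose-to-water conversion or detector response modeling.
- The secondary channel is a single effective species with calibrated
  parameters; species-resolved budgets (neutron/electron/photon yields) are
  out of scope.
- Shell and density-effect corrections to the stopping power are omitted
  (validity band 10–300 MeV).
- Normal incidence only; patient DICOM ingestion is behind the HU-array
  interface and not part of the tested surface.
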