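---
title: "Quantifying holmium microspheres on CT and estimating absorbed dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying holmium microspheres on CT and estimating absorbed dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoquant)
```

## The problem

Holmium-166 microbrachytherapy treats solid tumors by injecting radioactive
poly(L-lactic acid) microspheres loaded with ¹⁶⁶Ho directly into the tumor.
¹⁶⁶Ho is a high-energy beta emitter (endpoints 1.77 and 1.85 MeV, half-life
26.82 h) with a soft, low-yield gamma line at 0.08 MeV, so almost all of its
energy is deposited within a few millimetres of each microsphere. Verifying
that the injected activity actually sits in the tumor — and converting the
observed distribution into an absorbed-dose map — requires an imaging
modality that tolerates the high local concentrations (0.5–100 mg/mL) this
technique produces. CT is well suited: holmium's high electron density
raises the radiodensity of loaded tissue linearly with concentration.

`hoquant` implements that workflow as composable, tested pieces:

1. **Calibration** — fit the linear Hounsfield-unit (HU) response
   `HU = m + b·c` on a tube phantom with known concentrations `c` (mg
   elemental Ho per mL).
2. **Quantification** — classify and convert post-injection voxels into a
   concentration map by subtraction of a reference radiodensity or by
   thresholding, then into a per-voxel radioactivity map.
3. **Dosimetry** — convolve the activity map with a ¹⁶⁶Ho dose point
   kernel (DPK) and integrate over complete decay to a dose map and
   dose-volume histograms (DVHs).
4. **Synthetic phantoms** — forward-simulate all of the above with exact
   ground truth, so that every stage can be validated without scanner data.

## Calibration model and its guard rails

Tube means are fitted by ordinary least squares of mean HU on
concentration. Two practical rules are applied before and after the fit:

* **Saturation exclusion.** A scanner represents HU only up to a cap (3071
  on a 12-bit system). Tubes whose maximum HU exceeds the stated detection
  limit (strictly `>`) are excluded from the fit. On volumes that are
  *already clipped* at the cap, saturated voxels sit exactly at the cap and
  can never exceed it, so the trustworthy detection limit there is one HU
  step below the cap (3070 for a 12-bit scanner); `exclude_saturated()`
  documents this convention and the phantom tests use it.
* **Forced zero.** If the standard error of the fitted intercept exceeds
  its absolute value (strict `>`), the intercept is not distinguishable
  from zero and the line is refit through the origin. R² of a
  through-origin fit uses the uncentered total sum of squares, which is
  the convention `summary.lm` reports for such models; the curve records a
  `forced_zero` flag so downstream conversions know `m = 0`.

Curves carry metadata (scanner, kVp, reconstruction kernel) because
calibration parameters are scanner-specific; `run_pipeline()` refuses to
apply a curve whose scanner tag conflicts with the volume's unless
explicitly overridden.

## Quantification operators

All operators work on a quantification VOI of a post-injection volume with
a reference radiodensity `HU_ref` (mean, SD) measured in microsphere-free
tissue, preferably on the pre-injection scan.

**Subtraction** computes `HU_Ho = HU_voxel − HU_ref` per voxel with three
variants that differ in how negative values are treated: `s-minus` keeps
everything (every VOI voxel contributes, volume fraction 100 % by
construction); `s` floors post-injection voxels at 0 HU before subtracting
(so `HU_Ho ≥ −HU_ref`); `s-plus` removes voxels with negative `HU_Ho` from
the contributing set. Because negative contributions are removed stepwise,
total quantified mass is monotone: `s-minus ≤ s ≤ s-plus` on any input —
a property the test suite asserts on noisy phantoms.

**Thresholding** keeps voxels whose HU is *strictly greater* than a
threshold: the reference mean (`t`), the mean plus 1–3 SD
(`t1sd`–`t3sd`), or a fixed 50/100 HU (`t50`, `t100`). The full voxel
value (not the excess over the threshold) is converted. When the
calibration intercept is in use, the effective threshold is raised to at
least `m` so no contributing voxel can map to a negative concentration.

**Intercept convention.** Converting HU to concentration inverts the
calibration, `c = (HU − m)/b`. For threshold results the full voxel HU
includes baseline, so the intercept is subtracted. For subtraction results
the measured reference has *already* removed baseline, so only the slope
applies (`c = HU_Ho / b`); subtracting the fitted intercept as well would
remove baseline twice. Both behaviours are visible in
`concentration_map()` and the choice is recorded on the result.

Radioactivity follows from mass bookkeeping: elemental-Ho mass per voxel
is `c × V_voxel` (mL), microsphere mass divides by the Ho content fraction
(0.197 for the 19.7 % product), and activity multiplies by the specific
activity referred to the scan time. Dose-calibrator readings taken before
and after injection are decay-corrected to the scan time
(`λ = ln 2 / t½ = 7.179×10⁻⁶ s⁻¹`) before subtraction. Recovery is
quantified/injected in percent, with 70–130 % regarded as sufficient.

## The dose point kernel generator

The DPK is the expected energy (eV) deposited per decay in each voxel
around a point source in uniform tissue (density 1.06 kg/L), on a
121×121×61 grid at 0.5×0.5×1.0 mm with the source in the central voxel.
(The physical extent of that grid is 60.5×60.5×61 mm; we follow matrix ×
resolution.) `generate_dpk()` builds it by Monte Carlo with a deliberately
compact, fully documented physics model:

* **Beta spectra.** Allowed-shape spectra per branch with the relativistic
  Fermi function (daughter Z = 68). The Coulomb correction matters: it
  brings the branch mean energies to 0.66/0.70 MeV, matching the published
  nuclide means, where the uncorrected allowed shape overestimates them by
  ~12 % and visibly over-extends the kernel.
* **Electron transport.** Class-II condensed history with 0.05 mm steps:
  continuous energy loss follows a restricted range–energy relation
  (Katz–Penfold CSDA ranges minus the hard-collision component above a
  10 keV delta-ray threshold); hard Møller collisions are sampled
  explicitly and spawn delta electrons that are transported in turn;
  per-step angular deflections are drawn from a screened-Rutherford
  distribution whose mean deflection matches the Highland
  multiple-scattering variance, giving the Gaussian core *and* the
  large-angle tail. Transport stops at 1 keV; the residual is deposited
  locally.
* **Photons.** Exponential free path with water-like attenuation scaled by
  density; the full photon energy is deposited at the first interaction
  point (most 80 keV photons escape the kernel grid, as they should).
* **Local component.** Conversion and Auger electrons have sub-voxel
  ranges at this resolution and are lumped as deposition in the source
  voxel (21.5 keV per decay, derived from the 80.6 keV transition's
  conversion coefficients). Bremsstrahlung (~1 % radiative yield at these
  energies, mostly escaping) is not modelled.

The generator is deterministic given `(seed, n_histories, spectrum,
grid)`. Step-size convergence was checked at 0.1/0.05/0.025 mm; 0.05 mm is
the default. A loader (`load_dpk()`) accepts externally computed
high-fidelity kernels (NIfTI + JSON sidecar, density required) for
production use, and everything downstream is agnostic to the kernel's
origin.

**What the simplified transport can and cannot claim.** With 10⁶ histories
the kernel deposits ≈ 87 % of its energy within 3 mm of the source. The
frequently quoted figure for ¹⁶⁶Ho is 90 % in the first 3 mm of tissue. As
a cross-check of the transport itself, running the generator with a
2.28 MeV pure-beta spectrum in water yields X90 ≈ 4.6 mm, *smaller* than
the 5.3 mm commonly cited for ⁹⁰Y from high-fidelity transport — i.e. this
model errs on the compact side, and the ~87 % figure is not an artifact of
under-scattering. We therefore report the 3 mm fraction as measured and
treat the 90 % figure as a rounded literature claim rather than a
reproducible target; the acceptance test that asserts ≥ 90 % is expected
to fail by ~3 percentage points and is left in place deliberately.

## Dose maps and DVHs

Activity maps are resampled to the kernel resolution by trilinear
interpolation with exact conservation of total activity, then convolved in
the spectral domain with explicit zero padding (linear, not circular,
semantics; agreement with a direct-summation oracle is asserted to 1e-9
relative). The cumulative dose integrates the dose rate over complete
physical decay: `D = E/λ × q/(ρ V_voxel)` with `q = 1.602176634e-19 J/eV`
(the exact elementary charge; the commonly printed 1.60e-19 differs by
0.14 %). A finite integration time is available as an option multiplying
by `1 − exp(−λt)`. Maps with negative activity (possible only under
`s-minus`) are refused by the convolution — negative doses have no
physical reading — matching clinical practice of restricting dosimetry to
`s-plus`/threshold maps. DVHs are cumulative (volume fraction at or above
each dose level), monotone non-increasing, and integrate back to the mean
dose, which the tests verify.

## What the phantoms emulate — and what they do not

`simulate_calibration_phantom()` lays out parallel tubes (⌀ 17 mm, 30 mm
long, analysed through ⌀ 11 mm cylindrical masks of ~100 mm² cross
section) with voxel HU = `m + b·c` plus independent Gaussian noise,
clipped at the scanner cap. The default concentration ladder spans 0–129
mg/mL over 19 tubes so that the highest tubes saturate a 12-bit scanner,
exercising the exclusion rule. `simulate_injection_phantom()` produces
pre/post pairs of a 5×5×4 cm sample with a uniform spherical deposit
(default 7.5 mg microspheres in 0.3 mL), optional baseline shift between
scans, and optional Gaussian edge blur. `simulate_patient_like()` adds an
ellipsoidal tumor (`V = π/6·l·w·h`), bone-like distractors outside the
VOI, and multifocal Gaussian deposits at 5.0 mg microspheres per cm³
tumor.

Ground truth is exact by construction: the deposit concentration is chosen
so the voxelised truth map integrates to the injected mass to machine
precision, which is what makes the noise-free recovery tests exact at
100.000 %. The generators use independent per-voxel Gaussian noise and
additive HU response; they do not emulate correlated reconstruction-kernel
noise texture, beam hardening, metal artifacts, partial-volume effects at
real detector resolution, or the spatial heterogeneity of real microsphere
deposits. Passing recovery tests on these phantoms therefore validates the
*operators* — classification, conversion, bookkeeping — not the clinical
accuracy of any particular threshold on real tissue.

## Numerical choices and degenerate inputs

* Voxel values live at voxel centres; world coordinates are mm; no oblique
  orientations. Masks are boolean volumes, and a cylinder/ellipsoid
  includes a voxel iff its centre is inside (partial edge voxels are a
  stipulated convention, stated here once).
* All SDs are sample SDs (n−1); the 95 % CI of a VOI mean uses the normal
  1.96 approximation, appropriate for VOIs of thousands of voxels.
* Thresholds compare with strict `>`; a voxel exactly at the threshold is
  excluded.
* Negative totals under `s-minus`/`s` are reported as-is, never clamped —
  under-recovery is a real behaviour of these estimators.
* An all-excluded VOI is a valid empty result for thresholding (0 %
  volume fraction), but an empty quantification VOI is an error.
* Problem sizes in the tests are chosen to keep the full suite fast: the
  calibration acceptance phantom uses ~200k voxels (≥ 3000 per tube), the
  property suites use 21³–41³ grids, and the kernel acceptance run uses
  10⁶ histories on the full 121×121×61 grid (~15 s of compiled transport).

## Known limitations

* DICOM support is a minimal reader (part-10, explicit/implicit VR little
  endian, uncompressed 16-bit), validated against pydicom-written
  fixtures; compressed transfer syntaxes and oblique geometries are out of
  scope, and NIfTI is the primary interchange format.
* No image registration: pre/post comparisons assume a stable patient
  position, as the subtraction operators themselves do.
* Uniform-density dosimetry only; no CT-driven density heterogeneity
  correction.
* The built-in kernel generator trades bremsstrahlung and exact
  variance-reduction fidelity for auditability; for regulatory-grade work,
  load an externally computed kernel.
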