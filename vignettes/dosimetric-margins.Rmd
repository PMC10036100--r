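---
title: "Dosimetric margins and the biological conversion factor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosimetric margins and the biological conversion factor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosimargin)
```

## The problem

Stereotactic body radiotherapy (SBRT) delivers a few large fractions with
steep dose gradients, so the margin that protects target coverage against
setup error is a first-order planning quantity. Coverage can be judged in two
currencies. In *physical* dose, the plan is robust as long as the CTV D95
(the minimum dose received by the best-covered 95% of the clinical target
volume) stays at or above 90% of the prescription. In *biological* terms the
same question is asked of the biologically effective dose (BED), because a
voxel that receives 90% of the physical prescription receives *less* than
90% of the prescribed BED: with the linear-quadratic (LQ) model

$$\mathrm{BED} = n\,d\left(1 + \frac{d}{\alpha/\beta}\right),$$

a voxel at relative physical dose $r < 1$ sits at relative BED
$r\,(1 + r d/(\alpha/\beta)) / (1 + d/(\alpha/\beta)) < r$, and the deficit
grows with the dose per fraction $d$. The *physical dosimetric margin* (PDM)
is the largest isocenter displacement for which CTV D95 stays at or above 90%
of the prescribed physical dose; the *biological dosimetric margin* (BDM) is
the same quantity measured on the BED distribution against the prescribed
BED. Their ratio, the *biological conversion factor*

$$\mathrm{BCF} = \frac{\mathrm{BDM}}{\mathrm{PDM}},$$

converts a physical margin into the biological margin appropriate for a given
fractionation scheme. The package models the BCF two ways, depending on how
the plan was prescribed:

$$\mathrm{BCF}_{\text{point}} = A \ln\!\frac{d}{\alpha/\beta} + B,
\qquad
\mathrm{BCF}_{\text{marginal}} = (C\cdot ID + D) \ln\!\frac{d}{\alpha/\beta}
+ (E\cdot ID + F),$$

where $ID$ is the prescription isodose level in percent of the maximum dose
(60–80% for marginal SBRT prescriptions). Both are linear in their
parameters, so `fit_bcf()` solves the least-squares problem exactly by QR
decomposition — no iterative optimizer, no starting values, no convergence
tolerance. Reported per-parameter standard deviations are the classical
linear-model estimate $\hat\sigma^2 (X^\top X)^{-1}$; a bootstrap could be
substituted but the closed form is the default and is what the tests pin
down.

## The margin engine

`dosimetric_margin()` scans isocenter shifts $0, \pm 1, \dots, \pm 20$ mm
along one cardinal axis (LR/AP/CC). A shift of the isocenter by $+s$ is
realized as translating the structure by $-s$ in the fixed dose frame and
re-rasterizing the sphere analytically at the translated centre — no dose
interpolation ever happens, which keeps the scan free of resampling error;
the equivalence of the two viewpoints is itself a tested invariant. At every
shift the CTV D95 is the bin-free voxel-count quantile: the
$\lceil 0.95\,n\rceil$-th largest masked voxel value. There is no DVH
binning, so "within one DVH bin" contracts are met exactly.

The positive acceptance extent is the largest scanned shift such that the
criterion holds at *every* intermediate scanned shift (contiguity guards
against isolated numerical blips); the negative extent likewise; the margin
is the minimum of the two, with both extents retained in the result so a
different summary (e.g. the mean) can be formed downstream.

Two resolutions of the scan are exposed:

* **raw steps** (default): margins are whole scan steps, exactly what a 1-mm
  scan can resolve;
* **sub-step interpolation** (`coverage_criterion(interpolate = TRUE)`):
  the D95-vs-shift curve is linearly interpolated at the threshold crossing.

The *study pipeline* turns interpolation on by default. The reason is
structural, not cosmetic: the BCF is a ratio of two margins of a few
millimetres, and at whole-millimetre quantization that ratio collapses onto
small-integer fractions (frequently exactly 1), so fitted slopes would
measure the quantization pattern rather than the radiobiology. With the
crossing interpolated, the BED-contraction mechanism is resolved at any dose
per fraction. Module-level margin calls keep the raw 1-mm convention.

## The synthetic dose generator

The generator emulates the *outcome* of treatment planning — the shape of
the dose falloff around a spherical lung target — not the planning process.
The phantom is a water-equivalent sphere of radius 10 mm (GTV = CTV, PTV =
CTV + 5 mm) centred in lung, on an isotropic grid (2 mm default, 1 mm for
convergence checks) sized to hold the PTV, the full ±20 mm scan and one
penumbra width. A voxel belongs to a structure iff its centre lies inside
the sphere (closed ball); this rasterization convention is fixed everywhere.

Both prescription styles share a radially symmetric, monotonically
non-increasing profile built from a plateau and an algebraic "shoulder"

$$S(\rho) = \left(1 + \frac{u}{k}\right)^{-k}, \qquad
u = \frac{\rho - R_0}{w} \ge 0,$$

with penumbra scale $w$ (mm) and shape exponent $k$ (default 0.5; as
$k \to \infty$ the shoulder becomes exponential).

**Why a power-law shoulder rather than a logistic/erf step.** The study's
empirical ordering — the 60% isodose prescription has *larger* PDM and BDM
than the 80% one at matched penumbra — constrains the falloff family. For a
marginal prescription the margin is governed by the distance between the
isodose surfaces at relative levels $ID$ and $0.9\,ID$ of the maximum. For
any *symmetric* sigmoid (logistic, erf) that distance grows with $ID$ over
60–80% (the band moves off the steep midpoint of the step), which would give
the 80% plan the larger margin — the opposite of the observed ordering. A
falloff whose local slope scales like a power of the local dose
($|f'| \propto f^{(k+1)/k}$, steep near the top, heavy-tailed below) makes
that distance *shrink* with $ID$, reproducing the observed ordering from the
geometry alone. Physically, the heavy low-dose tail also resembles the
scatter tails of photon fields in low-density lung better than an
exponential cutoff.

**Marginal style.** The plateau radius is solved in closed form so that the
PTV D95 equals the prescription dose exactly while the maximum (plateau)
dose equals prescription × 100/ID; the prescription isodose surface then
sits at exactly ID% of the maximum. If the required plateau radius is
non-positive (penumbra far too wide for the target), generation aborts with
an explicit error.

**Point style.** Isocenter prescriptions from conformal multi-beam plans
keep a near-uniform high-dose core with a gentle rolloff before the field
edge. The profile is a uniform plateau to `plateau_radius` (13 mm), a linear
fractional decline `core_gradient` (0.01/mm) over `core_range` (15 mm), then
the shared shoulder; the centre voxel is normalized to the prescription dose
exactly. A linear decline *from the isocenter itself* was considered and
rejected: at gradients steep enough to matter it either breaks D95 coverage
at zero shift or drives the point-style BDM below the marginal one at high
dose per fraction, contradicting the qualitative behaviour the generator
must reproduce (point margins larger than marginal, in both currencies, for
dose per fraction 3–20 Gy at tumour $\alpha/\beta$). The three defaults were
chosen so that the 90%-of-prescription surface falls a few mm beyond the PTV
(point margins ≈ 10–15 mm, marginal ≈ 5–8 mm, separations of a few mm —
the scale reported for phantom SBRT plans).

**Density knob.** Tumour/lung electron density cannot change transport here
(there is none); its dosimetric signature — a broader penumbra at lower
density — is emulated by `density_to_penumbra()`, log-linear through the
anchors w(1.0 g/cm³) = 4 mm and w(0.4 g/cm³) = 8 mm. Log-linear rather than
linear interpolation keeps the map strictly decreasing and positive on the
whole admissible domain (0, 2] g/cm³. The anchors are package defaults
standing in for planning-system behaviour, not measured constants, and are
exposed in the study configuration.

## Parameters that matter

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `gtv_radius` | mm | 10 | tumour sphere radius |
| `ptv_margin` | mm | 5 | CTV→PTV expansion, all axes |
| `prescription_dose` | Gy | 48 | total physical prescription |
| `isodose_level` | % | 60/70/80 | marginal prescription surface, % of max |
| `penumbra_width` w | mm | 4 (at density 1.0) | shoulder scale of the falloff |
| `shoulder_exponent` k | — | 0.5 | falloff heaviness (tail weight) |
| `plateau_radius` | mm | 13 | point style: uniform core radius |
| `core_gradient` | /mm | 0.01 | point style: fractional decline past the core |
| `core_range` | mm | 15 | point style: length of the linear decline |
| `quantile` | — | 0.95 | DVH coverage quantile (D95) |
| `threshold_fraction` | — | 0.90 | acceptance level, fraction of prescribed |
| `shift_range`, `shift_step` | mm | 20, 1 | scan geometry |
| `alpha_beta` | Gy | 10 (tumour), 3 | LQ repair-capacity ratio |

The eleven fractionation schemes (3 Gy × 15 … 20 Gy × 3) span dose per
fraction 3–20 Gy, i.e. $d/(\alpha/\beta) \in [0.3, 2]$ at the tumour
$\alpha/\beta$ of 10 Gy. The BED conversion rescales each plan so the
prescription metric carries the scheme's total dose $n\,d$, then splits each
voxel's dose into the scheme's $n$ equal fractions — the only reading
consistent with a single fraction number per scheme, and the one that makes
the PDM scheme-invariant so one physical margin serves all schemes.

## The study sweep

`run_study()` crosses prescription styles (point; marginal at 60/70/80%),
eleven schemes, $\alpha/\beta \in \{10, 3\}$ Gy, three axes and the density
sweep {0.4, 0.7, 1.0} g/cm³: dose generated once per style/density, PDM per
axis, then BED and BDM per scheme. All four styles share the penumbra of the
evaluated density so the style contrast isolates the prescription method.
Headline BCF fits pool all three directions as separate samples (not
per-scheme means) at the reference density 1.0 g/cm³ and the tumour
$\alpha/\beta$; the $\alpha/\beta$ = 3 Gy results are computed and tabulated
but excluded from the fits. Everything is deterministic given the
configuration; `rng_seed` exists for stochastic extensions and reruns are
byte-identical.

Problem sizes: the default grid is 45³ voxels at 2 mm; the full three-density
sweep is 792 table rows and runs in a few seconds, so the whole default study
(and the test suite's repeated sweeps) stays interactive.

## What the synthetic data can and cannot show

The generator reproduces the *mechanisms* the margin study rests on — a
normalized prescription, a monotone radial falloff whose steepness differs by
prescription style and isodose level, and the LQ contraction of relative
dose — so the qualitative claims are testable: BDM ≤ PDM with equality in
the $\alpha/\beta \to \infty$ limit; BDM non-increasing in dose per
fraction; larger margins for the 60% isodose level than for 80%; larger
margins for point than for marginal prescriptions; fitted slope signs
(negative $A$, positive $C$ and $E$).

It does not transport particles, so absolute margin values and fitted
parameter magnitudes are emulation-scale, not clinical predictions. The
phantom is perfectly isotropic, hence LR/AP/CC margins agree to within a scan
step and the standard error of the mean across directions is essentially
zero — unlike an anthropomorphic phantom, where anatomy breaks the symmetry.
Two consequences are worth naming: direction-pooled fits here have almost no
between-direction variance, and the density-robustness report's
"within SEM" comparison is degenerate (an SEM of zero cannot absorb any
density effect), so that report should be read as effect sizes, not as a
hypothesis test. Respiratory/random errors, normal-tissue BDM and non-radial
dose shapes are out of scope.

## Numerical conventions, edge cases

* DVH quantile: bin-free, voxel-count, `ceiling(q n)`-th largest value;
  `q = 1` degenerates to the masked minimum.
* Acceptance uses a relative slack of 10⁻¹² on the threshold so that fields
  sitting exactly at 90% are accepted rather than lost to roundoff.
* A criterion that fails at zero shift yields margin 0 with an explicit
  warning and a `status` flag, never silently.
* Contiguity: an accepted shift beyond a rejected one does not extend the
  margin.
* Empty masks, shifted structures leaving the grid, non-physical densities,
  rank-deficient fit designs (e.g. one isodose level for the marginal model)
  and quantity mismatches (BED fed where physical is expected) all raise
  errors naming the violated requirement.
* Grid files: NRRD0004 raw little-endian (float32 dose, uchar masks) with
  the carried quantity in a `key:=value` field, plus a documented JSON-header
  + raw float32 fallback; both round-trip bit-exactly at float32 precision.
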