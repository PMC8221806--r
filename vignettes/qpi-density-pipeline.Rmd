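---
title: "Measuring absolute cytoplasmic density from bright-field z-stacks"
author: "qpicell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring absolute cytoplasmic density from bright-field z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpicell)
```

## The measurement

A cell's dry mass (protein, nucleic acid, lipid — everything but water)
raises its refractive index above that of the surrounding medium in
proportion to concentration. The slope of that relation, the specific
refractive increment $\alpha \approx 0.18$ mL/g, is nearly the same for all
major biomolecules, so the optical phase delay accumulated by light crossing
a cell is a direct, label-free readout of its dry mass:

$$\varphi(x, y) \;=\; \frac{2\pi}{\lambda}\,\alpha \int \rho(x, y, z)\, dz ,$$

with $\rho$ the dry-mass density (g/mL) and $\lambda$ the illumination
wavelength. `qpicell` recovers $\varphi$ from an ordinary bright-field
defocus stack, converts it to absolute density in mg/mL with an in-situ
calibration standard, extracts single-cell geometry for rod-shaped cells,
tracks cells through division in time lapse, and runs the downstream
growth/density analyses. A companion module inverts paired buoyant-mass
measurements from a suspended microchannel resonator (SMR) into total
(buoyant) density and volume.

Everything is testable without a microscope: the `synthcell` side of the
package renders spherocylindrical phantoms with known density fields and
forward-simulates their defocused bright-field images.

## Phase retrieval from defocus

A pure-phase object is invisible exactly in focus; contrast appears with
defocus, governed by the transport-of-intensity equation (TIE)

$$k\,\frac{\partial I}{\partial z} \;=\; -\,\nabla \cdot \big( I\, \nabla
\varphi \big), \qquad k = 2\pi/\lambda .$$

`retrieve_phase()` estimates $\partial I/\partial z$ by a per-pixel
least-squares slope over all planes (default seven planes at
$\pm\{0.5, 1.0, 1.5\}\ \mu m$, obtained from an oversampled stack by
`select_planes()`), inverts the Laplacian spectrally, and refines the
intensity-weighted divergence by fixed-point iteration. The focal plane is
selected by `find_focal_plane()` as the plane of minimum spatial intensity
standard deviation — the in-focus plane of a phase object — with ties broken
toward the stack center.

Numerical choices:

* **Regularization.** The spectral inverse Laplacian divides by
  $q^2 + \varepsilon\,\overline{q^2}$ with $\varepsilon = 10^{-3}$
  (`eps`). This biases low spatial frequencies, but the fixed-point
  refinement (up to 10 iterations, stopping when the relative residual
  change falls below $10^{-3}$) re-injects the residual each pass, so the
  bias contracts geometrically; the weak-phase round trip recovers a
  synthetic phantom with < 1% RMSE of peak phase.
* **Padding and anchoring.** Images are mirror-padded by 32 px around the
  FFTs to suppress wrap-around; the mean phase over a 5 px border frame is
  set to zero, and `background_correct()` then centers the background mode
  exactly: a Gaussian is least-squares fitted to the tallest histogram peak
  (256 bins over the 1st–99th percentile range) $\pm$ 5 bins and its center
  subtracted. If the fit fails the histogram mode is subtracted instead.
* **Degenerate inputs.** Uniform stacks return $\varphi \equiv 0$;
  zero-intensity pixels are floored at $10^{-6}$ of the mean; retrieval is
  exactly invariant to a global intensity (camera gain) rescaling.

## Calibration to absolute density

The phase of a cell measures the *excess* of cell over medium. Dissolving a
known concentration $C$ (typically 100 mg/mL) of a protein standard in the
medium at dedicated timepoints lowers every cell's phase contrast by
$K\,C\,\bar{t}$, where $\bar t$ is the mean optical path through the cell.
`compute_calibration_scale()` therefore takes, per calibration frame,

$$\text{scale} = \frac{\overline{\varphi}_{\text{flanking}} -
\overline{\varphi}_{\text{calibration}}}{C}\quad[\text{rad per mg/mL}],$$

averaging the non-calibration neighbors on either side, and multiple
calibration frames are averaged. Dividing a cell's mean phase by this scale
cancels $\bar t$ exactly, which is what makes the method *absolute*: the
recovered density is independent of cell thickness (verified to 3% between
radii of 1.6 and 2.2 µm) and of any linear bias in retrieval. A standard
that fails to *reduce* contrast indicates mis-flagged frames and is an
error, not a warning.

## Morphometry of rod-shaped cells

Cells are segmented in two passes (`segment_cells()`): an Otsu threshold on
the phase map detects cells and seeds a distance-transform watershed that
splits touching cells; each label is then grown out to a low outline level —
by default 12% of the label's 98th-percentile phase, floored at 4 background
MADs. The low outline matters because the phase profile of a cylinder falls
off as a chord length, $2\sqrt{r^2 - d^2}$: a mid-level threshold such as
Otsu's sits well inside the physical outline and would bias all widths and
volumes low by tens of percent. Contours are traced at the same level by
marching squares with linear (sub-pixel) interpolation
(`cell_contours()`).

`skeletonize_cell()` implements the classic rod-cell centerline: minimum-
area bounding rectangle for the initial axis, perpendicular section lines
every 250 nm clipped to the contour, centerline through the section
midpoints, section directions re-estimated perpendicular to the local
centerline, crossing sections removed, iterated to convergence. End "A" is
the lexicographically smaller tip, so orientation is reproducible; biological
old/new-end identity is assigned downstream from the inherited division-site
position, and is reported as unpolarized before the first observed division.

`compute_geometry()` sums per-section disks $V_i = \pi r_i^2 d$ and lateral
bands $A_i = 2\pi r_i d$ (sections are thin enough, 250 nm, that frustum
corrections would change volumes by well under 0.5%) and closes each pole
with a regular spherical cap. The cap junction is the first section, walking
in from the tip, whose distance to the tip is at least its half-width — for
an ideal spherocylinder this is exactly the cylinder–hemisphere tangent
point, and randomized spherocylinders recover closed-form volume and area
within 2% (in practice ~0.1%).

Whole-cell density is the mean phase over the cell mask divided by the
calibration scale (septa and droplets included), and mass follows as
$m = \rho V \times 10^{-3}$ pg. For *local* quantities — polar densities and
septum analysis — the per-pixel phase is first divided by the modeled chord
through the rotationally symmetric body (`cell_density_map()`), then the map
is re-anchored so that its well-conditioned central pixels average to the
unbiased whole-cell density; thin-edge pixels (chord < 0.5 µm) are excluded
as ill-conditioned. Polar density is the histogram mode (2 mg/mL bins,
quadratic peak interpolation) over the region within 3 µm arclength of the
pole — a mode, not a mean, so bright inclusions such as lipid droplets do
not bias it. Regions smaller than 50 px fall back to the mean, logged.

Septa appear as transverse high-density bands. `measure_septum_bend()`
detects a band when the 0.9-quantile of a section's transverse density
samples exceeds 1.3× the cell median over a run at most ~1 µm wide (a high
quantile rather than a mean, because a bent band crosses each section only
partially), traces the ridge of maximal density across the width, and
reports the sagitta of the ridge against its chord. |sagitta| < 0.15 µm is
reported as flat. These operational thresholds are package defaults —
documented, adjustable, and exercised against constructed ground truth.

## Lineage tracking and cell-cycle alignment

Frame-to-frame linking uses the thresholded rule: same cell iff centers are
within 20 px (≈2 µm; converted to 2.0 µm when the pixel size differs from
0.1075 µm) *and* the new cross-sectional area exceeds 70% of the old.
Matching is greedy in order of increasing center distance — the rule is
per-cell and thresholded, so a global assignment would add nondeterminism
without changing outcomes on well-spaced cells; distance ties resolve toward
the smaller area change. A division is recorded when a terminated track is
succeeded by exactly two new tracks inside its dilated (10 px) bounding box
whose areas sum to 0.8–1.2× the parent's; birth is the first frame with two
separate components. Tracks ending at the field edge are censored, others
lost — there is no gap closing and no claim that automated tracking
reproduces manually curated lineages on crowded real data.

Complete birth-to-division tracks are resampled onto a normalized cycle
time grid (100 points, linear interpolation, endpoints preserved exactly)
and averaged into population mean ± SD curves
(`population_trajectories()`).

## Growth analyses

`fit_mass_growth()` compares $m = a + bt$ against $m = m_0 e^{kt}$, both
two-parameter models, by residual SSE on the original scale (AIC is also
reported); the exponential fit is solved by Levenberg–Marquardt initialized
from the log-linear fit, with a logged log-linear fallback. Ties prefer
linear. Percent stage changes round half away from zero to integers.
Separation events report
$\Delta V\% = 100(\sum V_d - V_m)/V_m$ and the density change using the
mass-weighted daughter mean (an unweighted mean is also emitted; the choice
is a documented default, as the two coincide for symmetric daughters). At
constant mass these obey $\Delta\rho/\rho = -\Delta V/(V + \Delta V)$
exactly. Density homeostasis is Pearson's correlation between birth density
and the density change over the cycle. Tip-growth asymmetry attributes each
end's elongation and cycle-mean polar density to old/new ends using the
inherited division-site coordinate as the fiduciary landmark — a computable
stand-in for physical birth scars, which the imaging pipeline cannot see.

## The SMR companion

With buoyant masses $m_1, m_2$ of the same cell in fluids of densities
$\rho_1 \ne \rho_2$, the relation $m_b = V(\rho_{\text{cell}} -
\rho_{\text{fluid}})$ inverts exactly:

$$V = \frac{m_1 - m_2}{\rho_2 - \rho_1}, \qquad
\rho_{\text{cell}} = \rho_1 + \frac{m_1}{V}.$$

Units are fixed at pg/fL/(g/mL), making the algebra unit-coefficient. The
inversion assumes no mass change between the paired measurements (taken a
few seconds apart). Non-physical volumes are flagged, not dropped. The
population simulator draws volumes uniformly and supports a U-shaped
density–volume profile (lower at intermediate volumes) to emulate
cell-cycle-dependent dilution; `bin_by_volume()` summarizes.

## What the simulator emulates — and what it does not

`simulate_timelapse()` implements the growth model the analyses are designed
to detect: biomass synthesized at a constant *relative* rate (default
$\ln 2 / T$ with cycle $T$ = 150 min, i.e. mass doubles per cycle), volume
growing by tip elongation (defaults 0.035 and 0.018 µm/min for old and new
ends, ≈4 and 2 µm per cycle), volume growth halted in the division phase
(final 25% of the cycle, with a visible septum band at 1.5× body density),
and a separation event in which the two daughters jointly swell by 5% in
volume at constant mass. Density is never prescribed directly — it emerges
as mass/volume, which is exactly why the aligned-cycle density curve (fall
through growth, rise through division, drop at birth) is a meaningful test
of the analysis chain rather than a tautology. Elongating cells push their
neighbors (capsule-contact relaxation), as cells in a crowded chamber do.

The optical forward model propagates the unit-amplitude field
$e^{i\varphi}$ by the angular spectrum to each defocus, so the TIE solver is
tested against a model it does not trivially invert; a linearized
`mode = "linear"` forward (intensity exactly
$1 - (z/k)\nabla^2\varphi$) exists for unit-level identities, and retains
mathematically negative intensities at strong-phase edges so it stays
exactly invertible. Illumination is coherent and monochromatic at 680 nm;
partial coherence, apodization, aberrations, halo/shade-off and shot-noise
statistics are *not* modeled — camera noise is additive Gaussian as a
fraction of background. Passing tests therefore demonstrate the inverse
chain is correct under its stated model, not that every property of a
physical microscope is captured.

Default geometry mirrors the instrument the pipeline is designed around:
pixel 0.1075 µm (60×, 6.5 µm camera pixels), $\lambda$ = 0.68 µm, 7 planes
at 500 nm spacing selected from 250 nm-step stacks.

## Problem sizes

The shipped tests run phantoms on 256×256×7 stacks, a 30-frame six-cell
tracking field of 410×410 px, 20 randomized geometry oracles, 50 growth
series, and 1000-cell SMR round trips; these sizes give each check clear
headroom over its tolerance while keeping the whole suite in the
tens-of-seconds range on a laptop core. The same computations at larger
fields change only runtime, not code paths.

## Known limitations

* Calibrated density assumes the calibration and measurement frames see the
  same cell population statistics; strongly growing fields should use
  flanking frames close to each calibration point.
* The thickness-normalized local density map relies on rotational symmetry;
  it is a model-based quantity near poles and septa, and edge pixels are
  excluded rather than deconvolved.
* Mis-segmentations (merged or fragmented cells) are flagged and dropped,
  never repaired automatically.
* Tracking assumes per-frame displacements below the 20 px rule and no
  crossing trajectories.
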