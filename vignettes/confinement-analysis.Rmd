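---
title: "Quantifying T-cell confinement experiments: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying T-cell confinement experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experimental system

`confinemetry` analyses experiments in which T cells interact with a
supported lipid bilayer (SLB) that mimics an antigen-presenting cell —
carrying adhesion proteins, co-stimulatory ligands and fluorescently
labelled pMHC — while a pressure-actuated device confines the cells to a
preset height between two glass surfaces (spacer microbeads of 4 or 6 um
define the gap). The readouts are:

* **bilayer quality and antigen dose** — single-molecule TIRF movies of the
  labelled pMHC give its surface density and lateral mobility;
* **cell morphology and calcium signalling** — dual-excitation Fura-2
  stacks give per-cell sectional areas and Ca^2+ ratios before and after
  confinement;
* **motility** — tracked cell centroids give diffusion and directed-motion
  parameters;
* **Erk1/2 phosphorylation** — immunostained confocal images give per-cell
  pErk1/2 intensity and nucleus/cell areas;
* **device mechanics** — membrane deflection profiles give the engineering
  strain, the deflection–pressure relation, and the expected confinement
  gap; z-stacks of membrane-stained cells validate the realized height.

Everything is driven by a synthetic-data generator with known ground
truth, so every estimator in the package is validated by recovery tests
rather than by eye.

## Models and estimators

### Antigen density by brightness normalization

The surface density of labelled molecules is
$$\rho = \frac{\langle I - B\rangle / A_\mathrm{px}}{\beta},$$
the background-corrected mean brightness per um^2 of the first movie frame
divided by the mean brightness $\beta$ of an individual molecule. $\beta$
is measured later in the same movie: photobleaching thins the field until
the per-frame localization density falls to the single-molecule threshold
(0.09 um^-2); $\beta$ is the mean integrated brightness over the following
10 frames. Spots are refined by least-squares fits of a pixel-integrated
2D Gaussian and filtered for size (fitted sigma strictly between 0.75 and
1.25 px); the density threshold comparison uses `<=`, i.e. a frame exactly
at the threshold qualifies.

The "signal size" unit is taken to be the fitted Gaussian sigma in
pixels: filter bounds of order 1 px match a diffraction-limited sigma, not
a FWHM (which would be ~2.35 px).

### Molecular mobility

Localizations are linked frame-to-frame (assignment by increasing
displacement within a 6 px search radius, no gap closing). Trajectories
with at least 5 steps enter an ensemble MSD; the diffusion coefficient
comes from a weighted linear fit
$\mathrm{MSD}(t) = 4Dt + c$ over the first 5 lag times, with weights
proportional to the number of displacement pairs and the intercept
constrained non-negative (it absorbs localization error). The mobile
fraction counts retained tracks whose individual D exceeds a cutoff,
0.01 um^2/s by default — the published ">98% mobile" does not state a
criterion, so the cutoff is an explicit parameter.

### Fura-2 sum/ratio pipeline

The sum stack $I_{340}+I_{380}$ carries total dye signal and is what cells
are segmented and tracked on; the calcium readout is the ratio
$(I_{340}-B_{340})/(I_{380}-B_{380})$, masked invalid where the corrected
denominator is not positive. The per-cell Ca^2+ ratio is the mean of
per-pixel ratios over the segmented footprint (not the ratio of means),
and the sectional cell area is the footprint times the pixel area.
Segmentation is Gaussian smoothing (sigma 1 px), global Otsu threshold,
hole filling, watershed on the distance transform, and a 20 um^2 minimum
object size; the published workflow used a CellProfiler pipeline whose
internals are not public, so this recipe is this package's own, with every
parameter in the config. Identity tracking is greedy nearest-centroid
within 15 um per frame; recordings separated by the actuator-application
gap are joined by centroid proximity within 25 um. Cells touching the
image border are flagged (their sectional area is censored by the field
edge). Pre/post comparisons average each cell over two user-chosen frame
windows; the published window extents are not printed, so windows are
mandatory inputs.

### Motility model

Pooled over all trajectories of a condition (overlapping pairs, equal
weight per pair),
$$\mathrm{MSD}(t) = 4Dt + V^2t^2 + 4\,\mathrm{PA}^2,$$
with D the diffusion coefficient, V the global movement speed and PA the
positional accuracy. The model is linear in $(D, V^2, \mathrm{PA}^2)$, so
the fit is a non-negative least-squares solve — exact on noiseless curves.
Uncertainties come from bootstrapping whole trajectories (the bootstrap
unit is the trajectory, 1000 replicates by default, deterministic per
seed). The default fit range is all lags up to a quarter of the median
track length. Per-cell kinematics: average local velocity is the
window-smoothed mean frame-to-frame speed (um/min); directional
persistence is net displacement over path length (defined 0 for a zero
path); the source describing these measures is not restated in the text,
so these definitions are this package's own, stated here.

### Immunostain quantification

Nucleus and cell channels are segmented with the same recipe as the
Fura-2 sum frames; the mean pErk1/2 intensity is measured inside each
pErk-segmented footprint, and each nucleus is paired to the cell whose
footprint contains the nucleus centroid (unpaired objects are retained
and flagged). Pixel size defaults target the 20x confocal acquisition
(0.22 um/px). No illumination-field correction is applied; a flat-field
hook is left in the config.

### Membrane mechanics

Deflection profiles are fitted with even polynomials up to order 12
(an even basis enforces apex symmetry; "12th-order parabola" is read as
polynomial order 12). The engineering strain of the membrane's radial
section is
$$\varepsilon = \frac{L - 2a}{2a}, \qquad
L = \int_{-a}^{a}\sqrt{1 + z'(x)^2}\,dx,$$
computed by adaptive quadrature at 1e-9 relative tolerance; the reference
length is the flat chord $2a$ (the membrane starts flat). The
deflection–pressure relation is an ordinary least-squares line through
(pressure, apex height); the gap resolution is the slope times the
0.1 mbar controller step. Confinement heights are measured from z-stacks
as the distance between the two outermost axial intensity maxima (the two
plasma membranes), each refined by 3-point parabolic interpolation for
sub-z-step precision, falling back to the FWHM of the envelope when the
maxima merge.

### Statistics

Welch's two-tailed t-test with Welch–Satterthwaite degrees of freedom;
one-way ANOVA followed by Games-Howell pairwise comparisons
($q = |m_i-m_j|/\sqrt{(s_i^2/n_i + s_j^2/n_j)/2}$, Welch-type per-pair df,
p from the studentized range distribution via `ptukey`); notched boxplot
summaries with type-7 quartiles, notch half-width $1.57\,\mathrm{IQR}/\sqrt n$
(the McGill convention for the stated 95% confidence on medians) and the
1.5 x IQR outlier rule. Significance level 0.05 throughout.

## What the generator emulates — and what it does not

The generator reproduces the *statistical structure* of the acquisitions:
Poisson molecule counts, Brownian steps of per-axis variance
$2D/\Delta t$ with reflecting boundaries, single-step irreversible
bleaching, log-normal per-molecule brightness (drawn once per molecule —
density estimation assumes a stable per-molecule brightness), integrated-
Gaussian PSFs, Gaussian read noise on a constant background; cells as
disks whose area and ratio follow prescribed curves; two-lamella membrane
phantoms; near-parabolic deflection with apex height linear in pressure.
PSF mass that would fall outside the field is folded back by mirror
reflection at the border, consistent with the reflecting-boundary motion,
so photon accounting is exact.

It does **not** emulate amoeboid cell shapes, camera EM gain, 3D PSFs,
blinking or multi-step photophysics, uneven illumination, or focus drift.
Passing recovery tests therefore demonstrates estimator correctness under
the stated noise model, not robustness to every artefact of real
microscopy data.

Defaults follow the acquisitions the pipeline targets: 200 frames at
40 Hz for single-molecule movies; 0.5 um z-steps; 0.22 um confocal
pixels. The TIRF camera pixel size is not a published quantity; the
default 0.16 um/px (typical of a 100x/EMCCD combination) is configurable.
The per-frame bleaching probability (0.02) is likewise a modelling choice
producing the observed thinning from a crowded first frame into the
single-molecule regime within a 200-frame movie.

## Numerical choices

* Spot refinement uses variable projection: for a candidate position and
  sigma the best mass and offset are a closed-form linear solve, leaving a
  3-parameter Nelder-Mead search. The default fit window is 5 x 5 px: for
  sigma ~ 1 px spots the integrated model compensates the window
  truncation exactly, while a tighter window keeps neighbouring signals
  out — with a 7 x 7 window, crowding near the 0.09 um^-2 threshold
  measurably inflates the single-molecule brightness and hence biases the
  density low.
* Candidates closer than 1 px after refinement are merged keeping the
  brighter; saturated candidates are flagged, not fitted.
* All constrained linear fits (MSD model, D with non-negative intercept)
  use non-negative least squares (`pracma::lsqnonneg`), which inverts
  noiseless curves to machine precision.
* Peak-to-peak heights use 3-point parabolic interpolation; because both
  lamellae sit at the same phase of the z-grid when the height is a
  multiple of the z-step, their interpolation biases cancel and the preset
  heights are recovered exactly.
* Profile fits rescale positions to the half-width before building the
  even-power design matrix (conditioning at order 12); rank deficiency
  reduces the order with a warning.
* Ties in greedy matching (linking, cell tracking, recording joins) are
  broken by ascending distance, then lower id — results are deterministic
  and invariant to input order.
* Degenerate inputs have defined behaviour rather than NaNs: zero-variance
  Welch tests return p = 1 (equal means) or 0; zero path length gives
  persistence 0; a ratio denominator at background is masked invalid; a
  phantom shallower than two z-steps and a single axial peak narrower than
  two z-steps are errors.

## Problem sizes used by the test suite

Recovery tests run at sizes chosen to give the estimators enough
statistics while keeping the suite quick: 222 trajectories for the
bilayer-diffusion recovery (matching the published trajectory count), 500
tracks x 100 steps for drift recovery and 50-repetition bootstrap
coverage (100 bootstrap replicates per repetition), 120-frame movies on
12.8-25.6 um fields for density-estimator bias, and a nine-cell,
two-recording confinement phantom for the end-to-end Fura-2 check.

## Known limitations

* Localization is single-emitter; overlapping molecules below ~2 px are
  merged, which is why single-molecule statistics only start once the
  field has bleached below the density threshold.
* Linking has no gap closing: a missed detection splits a trajectory.
  This matches the published tracking settings but shortens tracks at low
  signal quality.
* The density estimator inherits a small negative bias (~4% at
  0.5 um^-2) from residual crowding at the brightness-interval density;
  it is within the 5% validation band but not zero.
* Segmentation is tuned for convex, well-separated footprints; strongly
  amoeboid or touching cells with shallow distance-map saddles may merge.
* The strain computation assumes an initially flat membrane and symmetry
  about the apex; it reports section strain, not a full strain tensor.
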