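---
title: "Quantifying spheroid invasion and unjamming: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spheroid invasion and unjamming: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unjamr)
```

# The assay and its observables

A multicellular spheroid (~200 um diameter) embedded in a hydrogel is
imaged in bright field at its equator at fixed intervals (typically 1 h)
for 24–72 h. Two hydrogel families bracket the confinement range:
fibrous collagen networks with micrometric pores (partial confinement)
and dense GelMA gels with ~10 nm pores (full confinement, impassable
without proteolytic degradation). The pipeline reduces each movie to:

* a per-frame **effective circular radius** `r_eff = sqrt(area/pi)` of the
  segmented cross-section — robust to shape because only the enclosed area
  enters;
* the **normalized radius** `r_norm(t) = r_eff(t) / r_eff(0)`, removing
  initial-size variation between spheroids;
* the **invasion onset** `t_ons`: the first time `r_norm` reaches 1.1.
  A 10% radius increase is well above segmentation noise (< 0.5% per
  frame in practice) yet early enough to capture the start of invasion;
* the **expansion rate** `alpha`: the OLS slope of `log r_norm` vs
  `log t` over the window from onset to saturation, i.e. the exponent of
  a power law `r_norm ~ A t^alpha`;
* an endpoint **unjamming phase**: solid, liquid (strand-forming) or gas
  (cell-shedding), from protrusion lengths and dissociated-cell counts.

# Segmentation

Bright-field spheroids are dark, low-contrast objects on a bright
background; absolute intensity thresholds are unreliable, so the detector
is gradient-based:

1. derivative-of-Gaussian edge magnitude at scale `gradient_sigma`
   (default 2 px);
2. binary gradient mask at `edge_threshold` — Otsu's threshold on the
   gradient image by default, overridable per dataset because
   illumination and contrast vary between image sets;
3. dilation by `dilation_radius` (default 5 px), hole filling, and
   erosion by the same radius (a morphological closing) to produce solid
   candidate objects;
4. the largest connected component above `min_spheroid_area`
   (default 2000 px²) is the spheroid body — debris and single cells are
   far smaller;
5. boundary refinement: the thresholded gradient band is roughly
   symmetric about the true edge, so the closed mask overshoots by the
   outer half of the band. A half-maximum intensity threshold — midway
   between the object-core and far-background means of the smoothed image,
   applied in a neighbourhood of the candidate — relocates the boundary
   to sub-pixel accuracy (for noiseless rendered disks of radius 30–120 px
   the radius error is below 0.03%). The refinement region is the body
   dilated by `dilation_radius + 2 * gradient_sigma` so that protrusion
   tips thinner than the closing diameter, which the erosion removes, are
   recovered by the intensity threshold.

Dissociated cells are connected components of the same closed gradient
mask with area in `cell_area_range` (default 10–500 px²) that do not touch
the spheroid mask dilated by `dilation_radius`; components touching that
margin cannot be called dissociated with confidence and are discarded, so
counts are deliberately conservative. Spheroids whose mask comes within
`border_margin` (default 10 px) of the image border are returned with a
`BorderContact` flag (and warning) rather than rejected, so batch
pipelines can decide; wall-contacting spheroids violate the radial-growth
geometry and are normally excluded.

An optional unsharp-mask pre-filter (`sharpen_amount`) mirrors the
contrast-enhancement step some acquisition pipelines apply; it is off by
default because its strength is dataset-specific and the synthetic data
does not need it.

# Invasion kinetics

**Onset.** The threshold crossing is linearly interpolated between the
two bracketing frames: reported onsets at half-hour resolution from
hourly sampling imply sub-frame interpolation. "Reaches" is inclusive: a
sample exactly at 1.1 defines the onset. If the trajectory never reaches
the threshold the onset is undefined (`NA`) — dense gels legitimately
show no invasion — and no rate is fitted.

**Replicates.** Assays run 4–10 spheroids per condition.
`aggregate_replicates()` computes the pointwise mean and standard
deviation on a common time grid (linear resampling if needed), and
onset/slope statistics are computed on the mean curve, matching how such
data are presented; per-replicate onsets remain available for dispersion.

**Saturation.** Strand-shedding spheroids stop growing in `r_eff` once
dissociating cells (not counted in the area) dominate; the fit window
must stop there. The rule: the saturation time is the start of the
earliest interval, at or after onset, during which the relative rate
`(dr/dt)/r` stays below `saturation_rel_rate` (default 1%/h) for at least
`saturation_run` (default 3 h); above-threshold excursions shorter than
`saturation_run` are treated as noise. If no such interval exists the
final time point is returned — which reproduces, with no cell-type
switch, both the "fit to saturation" behaviour of fast invaders and the
"fit to the end" behaviour of slow ones. The 1%/h and 3 h defaults are
our construction (no operational definition is published); they
correspond to growth slower than the fitted power laws anywhere inside
their windows (`alpha/t > 1%/h` whenever `t < 100 alpha` hours).

**Fitting.** `alpha` is the OLS slope of `log r_norm` on `log t` over
samples inside the window; `t = 0` samples are excluded (log undefined).
The interval is the symmetric t-based confidence interval at
`interval_confidence` (default 95%); published brackets for such slopes
are sometimes asymmetric with unstated provenance, so the symmetric OLS
interval is reported and documented as such. A constant trajectory
yields exactly `alpha = 0` with a zero-width interval. Noiseless power
laws are recovered to 1e-10; scale changes of `r_eff` and time-unit
changes leave the slope invariant (properties enforced in the tests).

# Protrusions and phase classification

The endpoint boundary is resampled on `theta_bins` (default 360) uniform
angular bins; each bin records the outermost contour crossing so
overhanging protrusions are measured at full extent, and empty bins are
filled by circular interpolation.

**Center choice.** Radii are measured from the center of the largest
inscribed disk (the maximum of the mask's distance transform), not from
the area centroid. Long protrusions drag the area centroid toward
themselves; in synthetic scenes with three 50 um protrusions clustered on
one side the centroid shifts by ~18 px, which depresses the measured
protrusion lengths by that amount and manufactures a phantom peak on the
opposite side. The inscribed-disk center is protrusion-insensitive and
rotation-equivariant.

**Baseline.** A protrusion's length is its peak radius minus the mean
radius of the *full* profile — the literal "peaks relative to the average
radius" definition, protrusions included. This biases lengths slightly
low: a rectangular bump of height `A` covering a fraction `f` of the
circle is measured as `A(1 - f)` (a 40 um, 20-degree bump reads 37.8 um —
the closed form is frozen in the tests). A second, resolution-dependent
bias (a few um) comes from the narrow sub-resolution tip of a tapering
protrusion. Both biases are small compared to the 25 um classification
cutoff.

**Detection.** Maximal circular runs with `r > r_mean` become one
protrusion each; runs with peak height below `min_prominence` (default
5 um) are discarded as pixel noise. The published criterion has no
prominence filter; because the classification cutoff is 25 um, the label
is insensitive to any prominence choice well below it. The mean
protrusion length averages over detected protrusions (averaging over all
bins would re-count the baseline).

**Classification.** With net dissociated cells
`n = max(count_end - count_t0, 0)` (cells present at t = 0 are
subtracted):

| condition | label |
|---|---|
| `n > 10` | gas (precedence) |
| else `mean length > 25 um` | liquid |
| otherwise | solid |

Both inequalities are strict — exactly 25 um or exactly 10 cells stays in
the lower phase, since the criteria are "above 25 um" / "above 10". When
both criteria hold the label is gas and `coexistence = TRUE`: phase
diagrams assign one color per condition, but strand-forming,
cell-shedding spheroids are physically a liquid/gas coexistence and the
flag preserves that. The 25 um cutoff reflects that intact spheroids at
t = 0 occasionally show apparent protrusions up to this length.

# Matrix characterization

**Bubble-method pore sizes** (fibrous gels, confocal reflectance
stacks). Per slice: total-variation denoising (Chambolle's projection
algorithm, `tv_weight` default 0.1 on contrast-normalized slices), local
mean threshold (`local_threshold_block` default 51 px, plus 2% of the
intensity range — the published pipeline names no threshold method),
exact Euclidean distance map of the void phase (distance to the nearest
fiber), Gaussian smoothing with `edm_gauss_sigma = 5` px, local maxima
with plateau merging and a `min_separation` (default = the smoothing
sigma; duplicate-maximum handling is unspecified in the original
method). Twice the distance at a maximum is the local pore diameter. Two
choices deserve note: the *smoothed* map locates maxima but the *raw*
distance value is reported — smoothing a ridge lowers its height, and
reporting the smoothed value would shrink a two-fiber 40 px separation
test by ~20%; and maxima touching the image border are discarded because
their pores are truncated by the field of view. Each slice is processed
in 2D: the axial step (2 um) is an order of magnitude coarser than the
lateral sampling, and the denoising is defined slice-by-slice; a 3D
variant would interpolate anisotropic voxels and is out of scope.
Intensity rescaling of the stack leaves the result unchanged by
construction (slices are range-normalized first).

**Void fraction.** Maximum-intensity projection along z, contrast
stretch, Otsu binarization with white = fibers; reported both as the
black-to-white pixel *ratio* (the published convention) and as the
conventional fraction `black/(black+white)`. A projection with no
separable fiber phase raises `AllVoid` (the condition carries
`fraction_void = 1`) rather than dividing by zero.

**Darcy permeability** (nanoporous gels, too dense for imaging pores).
The transverse mean intensity profile along the flow axis gives a front
position per frame: the first distance at which the background-subtracted
profile drops to epsilon, sub-pixel interpolated. Epsilon is two
background-noise standard deviations (far field of the first frame)
floored at 2% of the front amplitude: the literal "intensity reaches
zero" is unattainable with noise, and a crossing placed in the far
logistic tail is ill-conditioned (profile slope there is of the order of
the noise, so position jitter is ~1 px per frame); the amplitude floor
sits on the steep part of the front and shifts every frame's position by
the same constant, which cancels in the velocity. Uniformly saturated
frames (no dye-free far field) raise `NoFront`; a front regressing more
than one pixel raises a `NonMonotonicFront` warning. The velocity is the
mean frame-to-frame displacement over the interval; `K = v L mu / dP`
inverts Darcy's law, and the pore size is reported literally as
`sqrt(K)` with no geometric (e.g. Kozeny–Carman) prefactor — that is the
modeling convention of the source method, kept as-is. Note the unit
trap: `sqrt(2.36e-16 m^2) = 1.536e-8 m` is 15.4 nm; reports printing
"1.54 nm" for this permeability are using units of 1e-8 m. The function
returns SI meters and attaches `nm` and `per_1e8_m` attributes so both
conventions are explicit.

**Elasticity.** `E = 2 G (1 + nu)`; for incompressible gels
(`nu = 0.5`) the Young's modulus is three times the storage modulus.
`nu` outside [0, 0.5] is rejected.

# Condition-level grids

Conditions (cell line x matrix x treatment) carry GAPDH-normalized
EMT-marker levels (MMP1, MMP2, vimentin, E-cadherin) as *inputs* —
Western-blot densitometry is upstream of this package. Grids rank
conditions by marker level (x) and pore size (y); rank ties are broken by
the full condition key so assembly is deterministic and
permutation-invariant (enforced by test). Conditions with undefined onset
become distinguished "no-invasion" cells that carry no numeric value; a
record with a fitted rate but no onset is rejected as inconsistent
(the fit window starts at the onset). Color scaling in the rendering is
linear between the observed extremes of each metric.

# The synthetic world

`simulate_spheroid_timelapse()` renders what the segmenter assumes: a
dark body (intensity 0.15) with a logistic edge of sub-pixel width and a
faint halo on a bright background (0.85), additive Gaussian noise of 2%
of the dynamic range by default, 1 um pixels, hourly frames. The body
radius follows

    r_norm(t) = 1                 for t <= t0,
    r_norm(t) = (t / t0)^alpha    for t > t0,

with the motion start `t0 = t_ons * 1.1^(-1/alpha)` chosen so that the
*operational* onset — the 1.1 threshold crossing the pipeline measures —
lands exactly on the requested `t_ons`. (Anchoring the power law at
`t_ons` itself would place the measured onset at
`t_ons * 1.1^(1/alpha)`, e.g. 16 h instead of 11.5 h for `alpha = 0.29`;
the generator parameter is defined as the measurable onset so
ground-truth comparisons are meaningful.) Default parameters are the
control melanoma condition in a dense gel: `r0 = 100` um, onset 11.5 h,
`alpha = 0.29`, 24 h duration. Protrusions are Gaussian angular bumps
(15-degree width) growing linearly after `t0`; overlapping bumps sum.
Dissociated cells are emitted by a Poisson process after onset and
rendered as 5 px dark disks placed at least 25 px outside the final
spheroid outline and 25 px apart — the closing step of the detector
merges structures closer than twice the dilation radius, and the
generator's job is to make ground-truth counts unambiguous, not to test
blob splitting. Cells do not migrate after placement.

What the generator does **not** emulate: uneven illumination, halo
artifacts of real bright-field optics, cell-scale texture inside the
spheroid, protrusion branching, cell migration and proliferation, and
focal drift. A green end-to-end test therefore establishes that the
pipeline recovers the stated kinetics from images with realistic
contrast, noise and geometry — not that it is robust to every artifact
of a real microscope.

`simulate_fiber_stack()` renders straight fibers of isotropic random
orientation as bright tubes; real collagen is curved, cross-linked and
polydisperse, but straight segments reproduce the one property the
bubble method measures — the void-size distribution shrinking with fiber
density. `simulate_dye_front()` renders a sigmoidal front of constant
velocity with the assay's default geometry (0.62 um pixels, 30 s
interval, 20 mbar over 1 mm, water-like viscosity).

All generators are seeded and bit-reproducible; identical parameters and
seed give identical arrays.

# Numerical choices and degenerate inputs

* Coordinates are 0-based (row, col) with the origin at the top-left
  pixel center; physical units (um, m, Pa) appear only at reporting
  boundaries.
* Contours are traced at half-pixel resolution (midpoints of exposed
  pixel faces) and ordered by angle about the centroid — sufficient for
  the star-shaped masks this assay produces, and cheaper than a full
  marching-squares chain.
* The distance transform is the exact Felzenszwalb–Huttenlocher
  algorithm (C++); dilation/erosion are distance thresholds, so
  structuring elements are true Euclidean disks.
* Otsu's threshold uses 256 bins; a constant image returns its value
  (and yields `NoObjectFound` downstream).
* Plateau maxima merge to their centroid; the greedy minimum-separation
  filter keeps the larger peak.
* Degenerate trajectories: a single-sample window or one containing
  non-positive radii raises a classed error (`InsufficientData`,
  `NonPositiveValues`) instead of returning nonsense.
* Image I/O is plain-text PGM plus CSV/JSON: the offline R stack has no
  TIFF reader, and the analysis operates on numeric matrices; PGM keeps
  fixtures human-readable and the deliverable text-only.

# Known limitations

* One spheroid per field of view; no multi-object tracking.
* 2D equatorial analysis only; no 3D segmentation.
* Radius growth conflates migration and proliferation; the pipeline does
  not separate them.
* The amoeboid (blebbing) transitional phase is not algorithmically
  defined; only solid/liquid/gas are labelled.
* Dissociated-cell counts are conservative near the spheroid boundary by
  design.
* No statistical testing of condition differences; grids are descriptive.
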