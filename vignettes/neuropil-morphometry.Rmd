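---
title: "Methods: dense-reconstruction morphometry of cortical neuropil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dense-reconstruction morphometry of cortical neuropil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropilr)
```

# The measurement problem

Volume electron microscopy of cortical neuropil yields two kinds of raw
material: *point annotations* of every synapse in a large imaged stack
(a ball at the contact center whose diameter equals the contact's maximum
width on the section where it appears largest), and *dense triangle-mesh
reconstructions* of every axon, dendrite, bouton, spine head, synaptic
contact and mitochondrion inside a small sub-volume (here the canonical
5 × 5 × 5 µm cube, 125 µm³). This package implements the measurement layer
that turns those inputs into comparable group-level quantities for an
adult (4-month) versus aged (24-month) comparison of layer-1 somatosensory
neuropil: synapse densities by type, the inhibitory/excitatory balance,
synapse size distributions, neurite length densities, synaptic surface per
unit length and volume, vesicle distance profiles, mitochondria censuses,
and the statistics used on all of them.

All coordinates are micrometres; annotation diameters are nanometres and
converted at module boundaries (factor 10⁻³), because densities are
naturally expressed per µm³ while synapse sizes are conventionally quoted
in nm.

# Unbiased counting: the brick

Counting objects in a finite box over-counts anything that straddles the
boundary. The classical correction is the counting brick: three mutually
orthogonal *inclusion* faces (markers on them count) and the three
opposite *exclusion* faces (markers on or beyond them do not). With marker
centers as the counted feature this gives an unbiased density estimator
for any face assignment; `counting_brick()` defaults to inclusion on
−x ("left"), +y ("top") and +z ("upper"), configurable because imaging
axes are arbitrary. The brick is inset 1 µm from every stack edge so that
structures near the boundary can still be identified. The rule is applied
to the center point only — the ball's extent is ignored — because that is
how the annotations are counted; `test-stereology.R` verifies
unbiasedness by Monte Carlo (uniform markers, recovered within 3 binomial
standard errors) and the face rule against an exhaustive predicate.

The census categories are the seven published ones: asymmetric
(glutamatergic-type) on spines and on shafts, each split by single versus
multi-synaptic bouton; symmetric (GABAergic-type) on spines and on
shafts; and unclassified. A bouton is multi-synaptic when at least two
asymmetric markers passing the brick filter share its id; symmetric-only
groups are never called boutons, since symmetric varicosities cannot be
delineated reliably. The E/I ratio is (symmetric on spines + shafts) /
(all four asymmetric categories), computed per animal and then averaged.

# Synapse size: proxy, calibration, distribution

`max_section_diameter()` models the annotation procedure: a *section* is a
slab of thickness equal to the milling pitch (default 6 nm — a typical
FIBSEM step; the true voxel size of any given acquisition is unknown, so
the pitch is an explicit parameter). Mesh content inside each slab is
projected into the section plane and the maximum caliper width over slabs
is the diameter. Modelling sections as slabs rather than cutting planes
matters for contacts lying nearly parallel to the section plane, which a
zero-thickness plane at the anchor would merely graze.

The proxy is validated by a quadratic OLS calibration of true contact
area against annotated diameter, `fit_calibration()`; on synthetic tilted
elliptical contacts with realistic noise the R² lands in the published
regime (≈0.8). `apply_calibration()` clamps negative predictions to zero
with a warning, since a quadratic with a negative linear term dips below
zero for very small diameters outside the calibrated range.

Size distributions are summarised by a least-squares fit of the
log-normal peak function

$$f(x) = A \exp\!\left(-\frac{\ln^2(x/c)}{2w^2}\right)$$

to the binned percent-frequency histogram (default 25-nm bins; the
binning of the original histograms is not documented, so it is a
parameter). Curve fitting rather than maximum likelihood is deliberate:
an amplitude parameter only exists for a fitted curve. One numerical
subtlety is documented in `fit_lognormal_histogram()`: if diameters are
log-normally distributed with log-median $m$ and log-sd $s$, the *linear*
-axis histogram peaks at $c = m e^{-s^2}$, not at $m$ (the $1/x$ Jacobian
of the log-normal density). The exact identity median $= c\,e^{w^2}$ is
therefore reported alongside the raw fit, and all recovery tests assert
the median against the generator's programmed log-median (within 2%) and
the width against the programmed log-sd (within 5%). Fits use
Levenberg–Marquardt (minpack.lm) with moment-based starts and up to 8
jittered restarts; non-convergence is an error carrying the start values.

Perforations are counted from mesh topology: for each connected component
of the contact surface, holes = boundary loops − 1, with the loop count
cross-checked in tests against 1 − χ from the Euler characteristic
V − E + F. A deep horse-shoe notch that opens onto the rim adds no loop
and counts zero, matching the definition that only a clear through-hole is
a perforation. This replaces the supervised image-based detector used on
the raw micrographs, which is out of scope here; the mesh-topological
definition is exact on reconstructed surfaces but cannot see perforations
that a segmentation closed over.

# Sub-volume morphometry

Neurite centerlines are supplied (reconstruction tools export them); the
package measures them. Lengths are clipped to the analysis box by
parametric (Liang–Barsky) segment clipping, so partial segments contribute
exactly their inside portion and splitting a polyline at a face conserves
length to machine precision. Length density is clipped length / 125 µm³;
synapses per unit length divides the contact count by that length, and its
reciprocal is the "µm of axon per synapse" formulation.

Surface areas are triangle-area sums; volumes use the divergence theorem
on closed meshes (anchored at the centroid so translation invariance is
exact) and refuse open meshes, reporting the boundary-edge count. Size
summaries over boutons, spine heads, contacts and mitochondria follow the
published convention: objects whose mesh touches or crosses the box are
*incomplete* — counted, but excluded from means, SDs and totals. The SD is
the sample SD (n − 1); the original tables do not state which convention
they used, and at n in the hundreds the difference is far below the 2%
comparison tolerance used in tests. Completeness reduces to a strict
vertex-interiority test with ε = 10⁻⁶ µm, exact because the box is convex.

Compartment occupancy (connecting units = boutons + spines, axons,
dendrites, glia, mitochondria) sums enclosed volumes clipped to the box
over 125 µm³. Meshes fully inside are measured exactly; boundary-crossing
meshes fall back to voxel containment (ray-parity, default 40-nm voxels).
Compartments need not sum to 100% — extracellular space and unassigned
structures remain — and an optional voxel-based overlap check warns above
1% of the box volume. The donut (toroidal) flag on mitochondria is an
annotation input and is never computed: toroidal topology survives
reconstruction only when the hole is resolved, so the original census was
visual, and the generator programs the flag.

# Vesicle profiles

Vesicle positions are sphere centers that approximately fill each vesicle
(which also makes double-annotation geometrically hard; the generator
turns this into a hard non-overlap constraint enforced by dart throwing).
The distance of each center to the nearest point of the presynaptic
membrane mesh is exact point-to-triangle distance — the vesicle radius is
*not* subtracted, matching the published measurement rule. Distances are
binned at 30-nm intervals in half-open bins [k·30, (k+1)·30) — the
boundary convention is not documented in the source, so the conventional
right-open choice is made and tested — and the profile is normalized by
the synaptic contact area for group comparisons, which use the two-sample
KS test on pooled distances.

# The statistical layer

Group descriptives are mean ± SEM (sample SD / √n; the captions do not
say, and SEM reproduces the printed ±0.006 on the adult total density).
The default two-sample test is Student's pooled-variance t (it reproduces
the published significance calls at n = 3 per group); Welch is a flag.
Degenerate zero-variance-equal-means input returns t = 0, p = 1 by
convention. KS tests are standard two-sided two-sample. Slope equality
between two regressions is the interaction term of the pooled model
y ~ x * group, equivalent to the ANOVA comparison used for the
bouton-volume slopes. Percent change defaults to
100·(reference − other)/reference with the adult group as reference; a
"vs larger" convention is provided because published percentages mix both.
No multiple-testing correction is applied anywhere, matching the original
analyses; p-values are two-sided throughout. Type-I error of the t-test
at α = 0.05 is verified by simulation (10⁴ null replicates, 3σ band), and
both t and KS are checked against closed-form statistics to 10⁻⁹.

# The synthetic generator: what it emulates and what it does not

`neuropil_config()` defaults are the adult study conditions: per-category
synapse densities equal to the published adult group means (total
≈1.40 µm⁻³, asymmetric:symmetric ≈ 8:1), log-normal diameters (median
290 nm, log-sd 0.33), axon length density 8.15 µm/µm³ and dendrite
1.37 µm/µm³, ≈1.5 reconstructed contacts per µm³ in the sub-volume,
perforation probability 3.8%, ≈190 mitochondria per cube with donut
probability 0.18%, vesicle clouds at 2000 µm⁻³ (≈250 per 0.125-µm³
bouton), and a linear spine-volume→contact-area coupling
(area = αV + ε, α = 2 µm²/µm³, noise set for r ≈ 0.8–0.9). The `"aged"`
preset switches every target to the aged group values (median 305 nm,
log-sd 0.47, axon 10.07 µm/µm³, perforation 8.1%, donut 1.31%). These
values were fixed once from the published group means and are the
conditions under which all closure tests run.

Stacks are 10 × 10 × 10 µm with the 1-µm brick inset (a compromise:
large enough for ≈1400 markers and stable densities, small enough that
the full suite runs in under a minute of generator time; the real stacks
were 660–1520 µm³). Markers of one bouton are placed within 0.15 µm of a
shared center so the brick treats a bouton's synapses coherently.
Neurites are random smooth polylines accumulated until the programmed
clipped length density is met, with the realised value recorded as ground
truth; contacts are disc meshes (perforated ones are punctured grid
patches whose hole count is known), boutons ellipsoids, spine heads
spheres, mitochondria elongated ellipsoids.

What the generator does *not* emulate: curvature and tortuosity of real
neurites beyond a smoothed random walk, physical contact between pre- and
postsynaptic meshes (objects are placed independently, so compartments can
interpenetrate — the disjoint `generate_phantom()` exists for exact
volume-fraction ground truth), segmentation noise on mesh surfaces, and
any spatial correlation between synapses beyond bouton co-location.
Passing closure tests therefore demonstrates that the estimators recover
programmed parameters from geometrically faithful inputs; they do not
certify robustness to segmentation artefacts in real reconstructions.

# Numerical choices and degenerate inputs

* Mesh construction merges vertices within 10⁻⁶ µm and drops zero-area
  faces, recording counts in an attribute.
* `enclosed_volume()` errors on open meshes naming the boundary-edge
  count; `count_perforations()` errors on non-manifold edges listing
  them.
* The calibration design matrix must have rank 3 (three distinct
  diameters); two points are an explicit error.
* Vesicle dart throwing gives up after a bounded run of consecutive
  rejections and reports placed/requested counts — infeasible densities
  fail loudly rather than silently under-packing.
* Voxelization guards memory (default 2 × 10⁷ voxels) and requires an
  explicit box for an empty scene.
* Ties in section-caliper or completeness comparisons are measure-zero
  under the generator's continuous placements; boundary contacts in the
  brick rule are exercised explicitly in tests instead.

# Reproduction scope

Two published numbers are documented as not following from the printed
per-animal tables and are flagged rather than matched: the synapses-per-
µm-of-axon values (0.173/0.116; the tables give ≈0.185/0.152) and the
aged axon length density (10.27; the tables give ≈10.07). The E/I decrease
prints as 36.6%, which is exact on the rounded ratios 0.123/0.078 and
36.3% on the unrounded ones; the package reports the unrounded value.
Quantities that require the raw image stacks (mean diameters 377.8/427.7
nm, the empirical log-normal fit values, perforated percentages, the
Fig-5-style R² values, vesicle densities 1847/2225 µm⁻³) are covered by
parameter-recovery closures on the generator at the corresponding
programmed values instead of by direct reproduction.

# Problem sizes

The test suite and the acceptance script run the generator at the sizes
above (one 10-µm stack per call, four pooled stacks for histogram fits,
one 5-µm sub-volume with five vesicle clouds), 10⁴ null replicates for
t-test calibration, 2 × 10³ for KS calibration, and 300-point oracle
batches for geometry equivalence. These sizes give sampling errors
comfortably inside every asserted tolerance while keeping a full run in
the low minutes on one core.
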