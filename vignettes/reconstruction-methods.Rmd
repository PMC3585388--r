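---
title: "Reconstructing flattened retinae: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing flattened retinae: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinamorph)
```

## The problem

Retinal flat-mounts render the quasi-spherical retina into a 2D
preparation by dissection and a number of radial relaxing cuts.  The
cuts, and the tears that occur during flattening, vary from preparation
to preparation, which frustrates quantitative comparison across animals:
the same retinal location can land in very different places on two
flat-mounts, and a single focus of labelled cells can be split in two by
a cut.  `retinamorph` infers, for every point of a flat-mount, where it
lay on the intact, approximately spherical retina, and expresses the
result in a standard spherical coordinate system (colatitude measured
from the retinal pole at the back of the eye, longitude with the nasal
pole at 0&deg;, dorsal at 90&deg;).

## The reconstruction model

The pipeline has four stages.

1. **Mark-up and validation.**  The outline is an ordered, simple
   polygon in micrometres.  Each cut or tear is marked by three vertex
   indices: the two rim-side ends of the V and its apex.  The nasal pole
   is a marked perimeter vertex.  `validate_markup()` enforces the
   structural rules (apex inside its interval; cuts disjoint or strictly
   nested; attached data inside the outline) and reports violations
   rather than repairing them.

2. **Meshing and stitching.**  The outline is resampled to roughly
   uniform spacing and triangulated into at least 500 triangles of
   roughly equal size (a Delaunay triangulation of the outline plus a
   hexagonal grid of interior points; outline segments that the Delaunay
   construction misses are enforced by classical flip-based
   constrained-edge insertion, and triangles outside the outline are
   discarded by a flood fill that treats outline segments as walls).
   Triangles with all three corners on the outline are split at their
   centroids: such "ears" would degenerate once their corners are pinned
   to the rim circle on the sphere.  Each cut's two flanks are then
   parameterised by normalised arc length from rim to apex, and vertices
   at equal parameter are recorded as corresponding pairs, inserting a
   partner by boundary-edge splitting where none exists (an existing
   vertex within 10% of the local spacing is reused).  Nested tears are
   processed after the cut containing them and contribute zero effective
   arc length to the outer flank's parameterisation, since their mouths
   are identified when the tear itself is stitched.  After contracting
   all correspondences the mesh is a topological disc whose single
   boundary ring is the retinal rim.

3. **Projection and relaxation.**  The stitched mesh is projected onto a
   sphere curtailed at the rim colatitude $\phi_0$: rim vertices go to
   the rim circle at longitudes proportional to cumulative rim arc
   length, and an interior vertex enclosing a fraction $A$ of the flat
   area (measured by radius about the area centroid) goes to the
   colatitude whose cap area is the same fraction of the cap inside the
   rim.  Every mesh edge is a spring with natural length equal to its
   flat length, scaled by the single global factor that equates total
   flat area with the cap area; the spring energy is
   $E = \sum_i (l_i - L_i)^2 / (2 L_i)$, whose $1/L_i$ stiffness makes
   the energy extensive and gives the deformation measure (below) the
   character of a mean fractional strain.  The energy is minimised by
   L-BFGS-B over rim longitudes and interior positions, the latter
   parameterised as unnormalised 3D vectors projected radially onto the
   sphere, which avoids the longitude singularity at the pole.
   Corresponded vertices are a single unknown, so cuts stay closed;
   rim vertices satisfy the rim constraint exactly by construction.  A
   quadratic hinge on the signed volume of each spherical triangle,
   ramped over three stages (weights 1, 10, 100, with further tenfold
   stages only if flipped triangles remain), discourages folds.
   Finally the mesh is rotated about the pole so the nasal vertex sits
   at longitude 0.

4. **Mapping and statistics.**  Data points are located in their flat
   triangle, carried to the sphere with planar barycentric weights and
   renormalised.  Group means are Karcher (intrinsic) means with an
   angular standard deviation; distributions are summarised by von
   Mises–Fisher kernel density estimates (or Nadaraya–Watson kernel
   regression for counted sampling boxes), with contours that exclude a
   stated fraction of the points, computed as order statistics of the
   point densities.

## The deformation measure

The residual deformation of a reconstruction is
$$
E_L \;=\; \sqrt{\frac{1}{N\,\bar L}\sum_{i}\frac{(l_i-L_i)^2}{L_i}},
$$
the square root of the spring energy normalised by the number of edges
$N$ and the mean flat edge length $\bar L$.  Under a uniform fractional
strain $\varepsilon$ of every edge, $E_L = |\varepsilon|$ exactly, so it
reads as a mean fractional deformation.  Quality flags follow fixed
thresholds: above 0.1 the mark-up deserves checking, above 0.15 the
reconstruction is noticeably bad, and above 0.2 it is rejected
(stitching has failed).  Retinae that have lost tissue can still be
forced onto the sphere but produce high $E_L$; the tests exercise this
with fixtures from which 20–30% of the area has been shaved, which
raises $E_L$ from about 0.026 to 0.10 and 0.18 respectively.

## The rim angle

Because the retina is more than hemispherical, the colatitude of its
rim must be supplied.  It can be given directly, derived from eye
measurements with $\phi_0 = \arccos(1 - 2b/a)$ (modelling the eye as a
sphere of diameter $a$, the axial depth, with the rim at perpendicular
distance $b$ from the back pole), or inferred by re-running the full
reconstruction at 1&deg; steps over a range and picking the angle with
the lowest $E_L$ (`infer_rim_angle()`; ties break towards the centre of
the range).  The packaged table of mouse eye measurements from P0 to
adulthood reproduces its published colatitude column to within 0.1&deg;
(the published values averaged four eyes before rounding); the adult
value is 111.6&deg;, giving a nasotemporal arc of 223&deg;.  Automatic
rim-angle refinement is deliberately not a default: on a noise-free
synthetic cap the search recovers the generating angle to 1&deg;, but on
real preparations the improvement over the measured angle is modest and
the 1&deg;-step search multiplies the run time by the width of the
search window.

## The synthetic validation model

`synth_retina()` builds a flat-mount whose spherical origin is known
exactly.  A cap of the requested rim angle is cut along `n_cuts`
meridians to a depth of `cut_depth` times the rim colatitude, developed
into the plane (radius proportional to colatitude; azimuths scaled
within each sector so circumferential arcs keep their true length
relative to the apex circle, which opens a V-shaped gap at each cut),
and then relaxed as a 2D elastic sheet whose spring natural lengths are
the true spherical geodesic lengths, optionally perturbed by
multiplicative noise of amplitude `noise`.  The relaxation step is
deliberate: a spherical sector is not developable, so *no* flattening is
isometric, and the elastic equilibrium is the natural model of how real
tissue distributes the unavoidable strain.  Because the generator's mesh
carries its exact spherical truth, any point of the flat-mount can be
assigned a ground-truth position through the mesh's barycentric map.

Defaults mimic an adult mouse flat-mount: rim angle 111.56&deg;, four
cuts of depth 0.8, a flattened radius of about 1.6&nbsp;mm, 2%
edge-length noise.  Two numerical guards are worth knowing about.
First, the relaxation's fold penalty covers virtual triangles spanning
each open slit, with a tiny positive area margin, so the two flanks of a
cut may come close but never into exact contact (exact contact would
make the outline numerically non-simple and defeat any constrained
triangulation).  Second, the development used as the relaxation's
starting layout is only the initial guess; the returned outline is the
equilibrium.

What the generator does *not* emulate: irregular, curved cuts (cuts are
meridional, with irregularity supplied only through the noise term),
branching tears, non-spherical eye shapes, and digitisation error in the
outline itself.  Passing the round-trip tests therefore shows that the
algorithm inverts realistic *elastic* flattening distortion, not that it
is robust to every failure mode of a real dissection; the deformation
flags exist for exactly that reason.

### Intrinsic strain of a flattening

The elastic equilibrium of the default 4-cut, depth-0.8 adult cap
carries a mean fractional strain of about 0.027, independent of mesh
resolution — this is the geometric price of flattening that much
curvature with four cuts, and reconstructions of such fixtures settle at
$E_L \approx 0.026$.  More or deeper cuts lower the floor (six cuts of
depth 0.8 give 0.015; twelve of depth 0.9 give 0.005), which is why the
"distortion-free" property test uses a six-cut fixture.  For comparison,
real adult preparations typically reconstruct around $E_L \approx 0.07$.

## Validation results computed by this package

The test suite and `scripts/acceptance.R` recompute, among others:

* the rim-colatitude column of the developmental eye table from its
  measurement columns (to 0.1&deg;);
* the pooled median ground-truth recovery error over twenty seeded
  default synthetic retinae with 500 uniform sample points each, which
  falls around a third of a degree — far inside the 8&deg; (3.6% of the
  nasotemporal arc) validation bound — with no folded triangle in any
  final mesh;
* sub-degree median recovery and monotone error growth across noise
  levels 0, 0.02, 0.05 and 0.1.

## Visuotopic transformation

The optics of the eye are reduced to a proportional model: a ray
through the posterior nodal point is deviated in proportion to its
angle of incidence, with the constant fixed so that rays at 90&deg; to
the optic axis reach the retinal rim whatever the rim angle.  A retinal
point at colatitude $\phi$ therefore appears at visual angle
$90\,\phi/\phi_0$ from the optic axis.  This is deliberately not a
schematic-eye ray trace, which is not designed for wide-field rays.
Head-centred coordinates follow the facing-the-observer convention:
elevation above the horizontal, azimuth between meridian planes,
positive in the left visual field; the poses of the two eyes are mirror
images, and at $|{\rm elevation}| = 90°$ azimuth is reported as 0.  The
image inversion through the nodal point sends nasal retina to the
temporal field and dorsal retina to the inferior field; this sign map is
pinned down by the mirror-symmetry and decussation tests rather than
asserted.

The decussation-line congruence check is constructed geometrically: the
synthetic decussation line is the retinal preimage of the vertical
meridian under the true optic-axis pose (64&deg; azimuth, 22&deg;
elevation).  Projected forward under that pose it lies on the vertical
meridian for both eyes; under the alternative optic-disc pose (60&deg;,
35&deg;) the two eyes' lines visibly separate.  A small circle at a
fixed colatitude cannot play this role: under the proportional optics a
64&deg;-colatitude circle sits at 51.6&deg; from the axis, while the
vertical-meridian plane is 56.4&deg; away from the posed axis, so the
circle misses the meridian by several degrees whatever the data — the
preimage construction is the geometric content of the claim that the
decussation line corresponds to the vertical meridian.

## Numerical choices

* Angles are degrees everywhere in the interfaces; radians only inside
  trigonometric calls.  Central angles use the `atan2` form, stable for
  nearly coincident and nearly antipodal points.
* Triangulation determinism: the Delaunay backend may jitter degenerate
  inputs through R's random stream; meshing pins the RNG state locally
  and restores it, so all pipelines are bit-reproducible for a given
  seed.
* The optimiser runs L-BFGS-B with a gradient tolerance of $10^{-6}$
  and an iteration cap of 2000 per stage; the demo-scale retina
  (roughly 600–900 triangles) converges in seconds.  Problem sizes in
  the tests (600-triangle generator meshes, 500 sample points, 20
  seeds) were chosen so the whole validation runs on a laptop-class
  machine in minutes.
* Kernel concentrations ($\kappa$) are selected by leave-one-out
  cross-validation on a log-spaced grid (likelihood for densities,
  squared prediction error for regression).  Densities are normalised
  over the whole sphere rather than the cap: for realistic
  concentrations the mass beyond the rim is negligible, and the
  whole-sphere constant is closed-form.
* Exclusion contours are order statistics: the level for fraction $f$
  is the $(\lfloor fn\rfloor + 1)$-th smallest point density, so
  exactly $\lfloor fn\rfloor$ points fall strictly below it.

## Known limitations

* Partial retinae are out of scope: the rim must be a single closed
  ring after stitching, and tissue loss shows up as high $E_L$ rather
  than being modelled.
* The stitching rule (equal normalised arc length along the two flanks)
  is an assumption; flanks that healed or stretched asymmetrically will
  be paired slightly wrong, and show up as localised strain.
* The proportional optics model is a first-order account of a real
  eye's wide-field behaviour.
* ImageJ ROI support covers polygon and freehand outline ROIs only;
  composite ROIs are rejected.
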