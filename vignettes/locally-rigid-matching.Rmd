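---
title: "Locally rigid matching of longitudinal body-MR volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally rigid matching: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locorigid)
```

## The model

Two co-registered whole-body scans of one patient — baseline and
follow-up — are linked by a dense deformation field $d(x)$ on the
baseline grid, precomputed by non-rigid registration: the tissue at
baseline world point $x$ (mm) is found at follow-up point $x + d(x)$.
Such a field is anatomically faithful in soft tissue but physically wrong
inside bone, which can only move rigidly. The quantity this package
derives is the *locally rigid transform* of a region $M$: the rotation
$R$ (unit quaternion $q$) and translation $t$ minimizing

$$\sum_{x_i \in M} \lVert (x_i + d(x_i)) - (R\,x_i + t) \rVert^2 .$$

Restricted to one bone this is exactly the posture correction between the
scans; the residual $e(x) = \lVert (x + d(x)) - (R x + t)\rVert$ measures
where the rigid reading stops being trustworthy and feeds the uncertainty
visualizations.

Assumptions inherited from this formulation:

* the deformable registration is correct enough that $x + d(x)$ is the
  true correspondence over the region of interest (the package treats the
  field as input, never re-estimates it);
* grids are axis-aligned with positive spacing (identity direction
  cosines); oblique acquisitions must be resampled upstream, and the
  readers reject them rather than silently reorienting;
* the region grown from the seed is dominated by one rigid structure.
  The segmentation does not need to be anatomically complete — any
  bone-dominated voxel sample determines the rigid fit.

## Pipeline stages and their parameters

### Region growing (`confidenceConnected`)

Confidence-connected growing accepts, starting from the seed, the
6-connected voxels whose intensity lies in
$[\mu - m\sigma,\ \mu + m\sigma]$. Defaults (all overridable through
`growParams()`):

| parameter | default | meaning |
|---|---|---|
| `multiplier` (m) | 1 | acceptance half-width in standard deviations |
| `nIterations` | 1 | statistics-refresh passes over the grown region |
| `initialRadius` | 2 voxels | cubic seed neighborhood for the initial statistics |
| `boxHalfWidth` | 50 mm | clamp box half-width (a 10 cm box) around the seed |
| `replaceValue` | data maximum | foreground value when exporting the mask |

The algorithm follows the reference ITK implementation in every detail
that the generic description leaves open, because those details matter:

* the initial neighborhood is the cube of side $2r+1$ voxels (clipped at
  the box), with the *unbiased* ($n-1$) standard deviation;
* the acceptance interval is widened, at every pass, to contain the
  seed's own intensity, and the flood fill always includes and expands
  from the seed. Without this, a refresh pass over a homogeneous noisy
  region shrinks the interval to roughly $\pm 0.55\sigma$ of the noise
  and then excludes the seed value itself with high probability,
  collapsing the mask to a single voxel;
* each refresh recomputes mean and deviation over the current region and
  regrows from scratch;
* connectivity is 6-neighborhood (face adjacency) — the conservative
  choice, since false positives (bleeding into a neighboring structure)
  harm the rigid fit far more than false negatives;
* a degenerate (zero-variance) neighborhood accepts only exactly-equal
  intensities, with an absolute epsilon of 1e-6 to absorb float volumes.

A consequence worth knowing: with `multiplier = 1` on a *homogeneous*
region with i.i.d. Gaussian noise, at most ~68% of the region's voxels
can pass the first interval, and the refresh pass narrows that further
(the deviation of a $\pm 1\sigma$-truncated Gaussian sample is
$\approx 0.54\sigma$), so masks cover roughly half of such a region.
This is intended, conservative behavior — the fit needs a bone-dominated
sample, not a complete segmentation — but it bounds the Dice overlap
attainable against a full ground-truth mask well below 1 (about
0.5–0.8 on the phantom, as the test suite and acceptance script
measure). On real marrow, spatially structured intensity variation makes
the interval wider relative to noise, which is why the conservative
multiplier works clinically.

### Point matching and the rigid fit (`extractPointPairs`, `estimateRigid`)

Every foreground voxel contributes one pair: baseline center $x$ and
follow-up point $x + d(x)$ using the voxel's own stored field value
(mask voxels are grid points, so no interpolation enters). All pairs are
weighted equally; masks are not subsampled — the closed-form cost is
linear in $N$.

The fit is the unit-quaternion absolute-orientation solution: subtract
centroids, accumulate the $3\times 3$ cross-covariance $S$, assemble the
symmetric $4\times 4$ matrix

$$N = \begin{pmatrix}
\mathrm{tr}\,S & \Delta^T \\
\Delta & S + S^T - \mathrm{tr}\,S \cdot I
\end{pmatrix},\qquad
\Delta = (S_{23}-S_{32},\ S_{31}-S_{13},\ S_{12}-S_{21}),$$

and take the eigenvector of the largest eigenvalue as the rotation
quaternion; $t$ is the follow-up centroid minus the rotated baseline
centroid. The solution is non-iterative, allows no scaling and no
reflection (it is constrained to proper rotations), and agrees with the
independent SVD (Kabsch) route to numerical precision — the test suite
checks both that agreement and, by random perturbation, local optimality
of the returned transform.

Degenerate inputs are refused rather than guessed: fewer than 3 pairs
(`TooFewPoints`), numerically collinear baseline points (rotation about
the line unidentifiable), and a tied largest eigenvalue pair (a
180-degree ambiguity) all raise `DegenerateGeometry`. The returned
quaternion is normalized with $w \ge 0$ ($q$ and $-q$ encode the same
rotation). Because the identity transform is always a feasible candidate,
the fitted RMS residual never exceeds the raw baseline/follow-up RMS
discrepancy; `matchAtPoint()` reports both (`rmsBefore`, `rmsAfter`).

### Resampling (`applyRigidResample`)

Pull-back sampling: the output voxel at baseline point $x$ reads the
follow-up volume at $T(x)$ by trilinear interpolation — one interpolation
pass, no hole filling. Trilinear interpolation is used for all scalar
sampling (the slicing of a prototype viewer is not specified anywhere
authoritative; trilinear is the standard choice and is exact on linear
intensity fields, which the tests exploit). Nearest-neighbor is available
for masks only, where averaging labels is meaningless. Out-of-grid volume
samples return a caller-supplied background (default 0); out-of-grid
*field* samples are an error, because fabricating a displacement would
silently corrupt the fit.

## Visualizations

* **Color fusion**: baseline in orange $(1, 0.5, 0)$, follow-up in light
  blue $(0, 0.5, 1)$. These are the unique orange/blue pair that is
  exactly complementary (sums to white), so equal intensities fuse to
  neutral gray, a local intensity decrease leaves orange and an increase
  leaves blue. Both timepoints are windowed with the *baseline's* 1st-99th
  percentile window so that real intensity change remains visible.
* **Uncertainty contours**: from the seed, 360 rays (1 degree apart) are
  marched in 0.5 mm steps to at most 150 mm, interpolating $e$; per
  threshold (default 3, 6, 9 mm) the *first* crossing radius is recorded.
  First-crossing (rather than last) guarantees the nesting invariant
  even for non-monotone error profiles; rays that never cross stay
  "open". The march defaults keep the contour discretization at or below
  voxel scale. Contours are computed in the current slice plane; 3D
  iso-surfaces are out of scope.
* **Deformation sphere**: `nPoints` (default 200) points on a sphere of
  default radius 20 mm placed by a deterministic Fibonacci lattice
  (uniform coverage without randomness), warped through the field;
  residuals are taken after removing a supplied rigid transform, so they
  show only unexplained, genuinely non-rigid motion.
* **Magic lens**: a circular viewport (pixel-space center and radius)
  that composites the co-located secondary channel (STIR-like) into the
  primary view, with a 1 px white boundary ring; in the triptych the lens
  position is shared by all three views. Outside-ROI grayscale context
  uses the Rec. 601 luma.

## The synthetic phantom

`generatePhantom()` emulates the *geometry* of the clinical problem, not
MR physics. A phantom is: capsule bones (cylinder + hemispherical caps —
a long-bone approximation) of distinct bright intensities inside a
mid-intensity soft-tissue ellipsoid on a dark background; per-bone
ground-truth rigid transforms; spherical lesions as signed intensity
offsets (dark in the primary channel, the same offset inverted in the
secondary channel, mirroring T1W-dark / STIR-bright lesions); i.i.d.
Gaussian noise.

The reference conditions (the no-argument `phantomSpec()`) are a
96 x 96 x 160 grid at 1.5 mm isotropic spacing — the working resolution
of whole-body preprocessing — with two bones articulated by 10 degrees
about z and -6 degrees about y plus a few mm of translation, soft tissue
at 300, bones at 1000/950, noise sigma = 2% of the brightest bone, and
one regressing plus one newly appearing dark lesion. Geometry scales
with the grid extent so smaller grids stay valid phantoms; the test
suite mostly runs 32-48 voxel grids and reserves the full reference size
for the headline recovery check, keeping the default run fast.

The ground-truth field blends the per-bone rigid displacements with
normalized exponential weights $w_k(x) \propto e^{-\mathrm{dist}_k(x)/\tau}$
($\mathrm{dist}_k$ = distance to bone $k$'s surface, 0 inside;
$\tau$ defaults to 3.5% of the lateral extent). Inside any bone the
field is set to that bone's rigid displacement *exactly* — this is the
property the whole pipeline is tested against — and the phantom validator
requires every inter-bone gap to exceed $6\tau$, which bounds the
resulting mismatch at a bone surface by $e^{-6}\approx 0.25\%$ of the
inter-bone displacement difference (hundredths of a millimetre at
phantom scales). The follow-up volume is synthesized by warping the
clean baseline structure through the analytically known inverse (exact
inverse rigid transforms inside bones, blended on the follow-up grid),
painting follow-up lesions at their field-mapped positions, and adding
independent noise. Everything is deterministic given `rngSeed`.

What the phantom does *not* emulate — and hence what passing tests do
not show about real data: MR physics (bias fields, Rician noise, partial
volume, coil profiles), marrow texture, multi-station stitching
artifacts, and above all *registration error*: the phantom field is a
perfect correspondence by construction, so phantom results isolate the
locally-rigid derivation from the quality of the upstream registration.

## File formats and conventions

World coordinates are millimetres; voxel index $(0,0,0)$ is centered at
the volume origin. MetaImage (.mha embedded-raw / .mhd + .raw) is the
primary on-disk dialect, NIfTI-1 (.nii, .nii.gz) is accepted for
interoperability; both readers reject non-identity direction matrices.
The canonical scalar write type is 16-bit unsigned (floats accepted and
auto-selected when data are not integral). Deformation fields are
3-component 32-bit float vector images — 12 bytes per voxel plus header —
distinguished from scalar volumes by component count, never by filename.
Rendered images are 8-bit PNG with `round(255 v)` quantization; all
writers are deterministic (identical inputs give byte-identical files).

## Numerical choices, in one place

* quaternion sign: $w \ge 0$; validity demands unit norm within 1e-9 and
  an orthonormal, determinant $+1$ rotation within 1e-9;
* rotation angles are computed with the atan2 form
  $2\,\mathrm{atan2}(\lVert q_{xyz}\rVert, |q_w|)$, which stays accurate
  near 0 and 180 degrees where $\arccos$ loses half the digits;
* collinearity test: second singular value of the centered baseline set
  below $10^{-9}$ of the first; eigenvalue tie test at the same relative
  tolerance;
* trilinear sampling at the top lattice plane shifts the support cell
  down one voxel (fraction 1), so on-grid points reproduce stored values
  bit-exactly — this is what makes the identity-posture phantom's
  follow-up *identical* to its baseline;
* the ray marcher treats leaving the error volume as the end of the ray
  (remaining thresholds stay open) rather than extrapolating.

## Known limitations

* Single rigid structure per click: no articulated or affine local fits,
  no ICP refinement — by design, the fit has exactly six degrees of
  freedom.
* The segmentation inherits the conservative multiplier; on noisy
  homogeneous data the mask undershoots the full structure (see above).
  This costs nothing for transform recovery but matters if the mask is
  reused as a segmentation proper.
* Fields are trusted as given; there is no consistency or invertibility
  check on the input registration.
* Grids must share an identity orientation; no DICOM, no multi-station
  stitching, no bias-field correction — those belong to upstream
  preprocessing.
* The CLI renders static PNGs; all interactive behaviors (mouse-driven
  lens, live contours) are frozen into explicit parameters.
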