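# locorigid

Locally rigid matching and comparative visualization of longitudinal 3D
body-MR volumes.

## The problem

Whole-body MR follow-up studies compare a baseline and a later scan of the
same patient, for example when reading skeletal lesions in multiple
myeloma. Patient posture differs between sessions, so no single global
alignment makes the two scans comparable everywhere. A precomputed
deformable (B-spline) registration captures the full correspondence as a
dense displacement field d(x), but it bends rigid anatomy: a femur must
not be warped when the question is whether a lesion inside it grew.

`locorigid` resolves this with a *locally rigid transform*: restricted to
one bone, the rigid component of the deformation field is exactly the
posture correction a reader wants, while true anatomical change stays
visible. One click (a seed point in the anatomy of interest) drives the
whole pipeline:

1. **Segmentation** — confidence-connected region growing around the
   seed (ITK semantics: accept intensities in mean ± multiplier·sd of the
   seed neighborhood, refresh statistics over the grown region), clamped
   to a 10 cm box.
2. **Point matching** — every region voxel x is paired with its
   follow-up position x + d(x) by sampling the deformation field.
3. **Rigid estimation** — the closed-form least-squares rotation R and
   translation t minimizing sum_i ||q_i − (R p_i + t)||^2, via the
   unit-quaternion (absolute orientation / landmark) method: the 4x4
   symmetric matrix built from the cross-covariance of the centered point
   sets is eigen-decomposed and the leading eigenvector is the rotation
   quaternion. No scaling, no reflection; non-iterative and exact.
4. **Resampling** — the follow-up volume is pulled back onto the
   baseline grid through T, so the anatomy around the seed appears
   aligned.

Around the core sit the comparison views the pipeline was built for:
orange–blue color fusion (exactly complementary hues, so agreement is
gray, intensity decrease orange, increase blue), radial uncertainty
iso-contours of ||(x + d(x)) − (R x + t)|| at 3/6/9 mm, the deformation
sphere (a Fibonacci-lattice point cloud warped by the field, residuals
after rigid removal), and a magic-lens composite of the co-located
secondary (STIR-like) channel.

A synthetic articulated phantom — capsule bones of distinct intensity in
a soft-tissue ellipsoid, per-bone ground-truth rigid transforms, a
deformation field exactly rigid inside every bone and smoothly blended in
between, optional lesions and Gaussian noise — provides a fully known
test bed; real patient data is never required.

## Worked example

```r
library(locorigid)

truth  <- generatePhantom(phantomSpec(gridShape = c(48, 48, 80)))
bundle <- phantomBundle(truth)
seed   <- c(21.6, 36, 60)          # world mm, inside bone 1
res    <- matchAtPoint(bundle, seed)
res
#> Locally rigid match
#>   1056 point pairs from a 1056-voxel region
#> RigidTransform: rotation 10.000 deg, quaternion (0.99619, 0.00000, -0.00000, 0.08716)
#>   translation (2.579, -6.204, 2.000) mm
#>   RMS discrepancy: 5.4353 mm before -> 0.0000 mm after rigid removal
```

The fitted transform matches the phantom's ground truth for that bone
(`truth@boneTransforms[[1]]`: 10 degrees about z, identical translation)
to machine precision, and the RMS point-pair discrepancy drops from
5.44 mm (posture difference) to ~1e-14 mm (the field is exactly rigid
inside the bone). Where is the rigid approximation trustworthy?

```r
err <- errorField(truth@field, res@transform)
radialContours(err, seed, axisU = c(1, 0, 0), axisV = c(0, 0, 1))
#> UncertaintyContours at (21.6, 36, 60) mm, 360 rays
#>   3 mm: 158/360 rays crossed, radius 13.5-59.5 mm
#>   6 mm: 149/360 rays crossed, radius 15.0-58.5 mm
#>   9 mm: 115/360 rays crossed, radius 17.0-59.0 mm

deformationSphere(truth@field, seed, radius = 10, transform = res@transform)
#> SphereSample: 200 points, radius 10 mm; residuals 0-0.324 mm (mean 0.0294)
```

Inside the bone the error is zero (rays stay open); moving outward into
soft tissue the 3/6/9 mm contours close in. Rendering:

```r
plane <- canonicalPlane(bundle@baseline, "coronal", through = seed)
views <- renderTriptych(bundle, res@transform, plane)
writeRGBImage(views$fusion, "fusion.png")
```

## Command line

A thin wrapper (`exec/locorigid`, or `runLocorigid()` in R) exposes the
workflow as subcommands with deterministic file outputs:

```sh
locorigid phantom --out data                        # synthetic bundle + truth.json
locorigid match   --bundle data/bundle.yaml --seed 21.6,36,60 --out run
locorigid uncertainty --bundle data/bundle.yaml --seed 21.6,36,60 --out run
locorigid sphere  --bundle data/bundle.yaml --center 21.6,36,60 --out run
locorigid render  --bundle data/bundle.yaml --seed 21.6,36,60 \
                  --plane coronal --lens 20,20,8 --out run
```

`match` writes `mask.mha`, `matched.mha` and a JSON report (quaternion,
translation, RMS before/after, point count). Exit codes: 0 success,
1 data error, 2 usage error.

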