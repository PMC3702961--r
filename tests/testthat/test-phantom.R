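test_that("identity posture with zero noise gives identical timepoints and a zero field", {
  truth <- identityTruth()
  expect_identical(truth@followup@data, truth@baseline@data)
  expect_identical(truth@followupSecondary@data, truth@baselineSecondary@data)
  expect_true(all(truth@field@vectors == 0))
})

test_that("the field is exactly the bone's rigid displacement at every bone voxel", {
  truth <- smallTruth()
  for (k in seq_along(truth@boneMasks)) {
    pairs <- extractPointPairs(truth@boneMasks[[k]], truth@field)
    pred <- transformPoints(truth@boneTransforms[[k]], pairs@baselinePoints)
    expect_lt(max(abs(pairs@followupPoints - pred)), 1e-9)
  }
})

test_that("an example posture of 10 deg about z plus (6,-4,0) mm is honoured exactly", {
  bones <- locorigid:::defaultBones(c(72, 72, 120))
  c1 <- (bones[[1]]$a + bones[[1]]$b) / 2
  bones[[1]]$transform <- rigidAboutPoint(c(0, 0, 1), 10, c1,
                                          shift = c(6, -4, 0))
  bones[[2]]$transform <- rigidTransform(translation = c(4, 2, 0))
  truth <- generatePhantom(phantomSpec(gridShape = c(48, 48, 80),
                                       bones = bones, lesions = list()))
  pairs <- extractPointPairs(truth@boneMasks[[1]], truth@field)
  pred <- transformPoints(bones[[1]]$transform, pairs@baselinePoints)
  expect_lt(max(abs(pairs@followupPoints - pred)), 1e-9)
})

test_that("bone voxels land on their baseline intensities after warping (up to noise + interpolation)", {
  truth <- smallTruth()
  spec <- truth@spec
  k <- 1L
  bn <- spec@bones[[k]]
  # interior bone voxels, eroded away from the surface
  pts <- locorigid:::gridPoints(truth@baseline)
  interior <- locorigid:::capsuleSignedDistance(pts, bn$a, bn$b,
                                                bn$radius) <= -2
  x <- pts[interior, , drop = FALSE]
  fuAtWarped <- sampleTrilinear(truth@followup,
                                transformPoints(truth@boneTransforms[[k]], x))
  baseAt <- sampleTrilinear(truth@baseline, x)
  # both samples carry independent sigma-noise; interpolation adds a bound
  expect_lt(mean(abs(fuAtWarped - baseAt)), 2 * spec@noiseSigma + 1)
})

test_that("generation is deterministic in the seed and sensitive to it", {
  spec <- phantomSpec(gridShape = c(24, 24, 24),
                      bones = list(phantomBone(c(18, 18, 6), c(18, 18, 30), 4)),
                      lesions = list(), blendTau = 2, rngSeed = 7L)
  a <- generatePhantom(spec); b <- generatePhantom(spec)
  expect_identical(a@baseline@data, b@baseline@data)
  expect_identical(a@followup@data, b@followup@data)
  expect_identical(a@field@vectors, b@field@vectors)
  spec@rngSeed <- 8L
  expect_false(identical(generatePhantom(spec)@baseline@data,
                         a@baseline@data))
})

test_that("invalid phantom specifications are rejected with the violated constraint named", {
  expect_error(phantomSpec(gridShape = c(8, 32, 32)), "SpecInvalid.*16")
  expect_error(phantomSpec(gridShape = c(32, 32, 32), noiseSigma = -1),
               "SpecInvalid.*noiseSigma")
  expect_error(phantomBone(c(0, 0, 0), c(0, 0, 10), -2), "SpecInvalid.*radius")
  # bones closer than the blend support
  close2 <- list(
    phantomBone(c(30, 36, 20), c(30, 36, 100), 8),
    phantomBone(c(50, 36, 20), c(50, 36, 100), 8,
                transform = rigidTransform(translation = c(3, 0, 0))))
  expect_error(phantomSpec(gridShape = c(48, 48, 80), bones = close2,
                           blendTau = 10), "SpecInvalid.*blend support")
})

test_that("single-bone blends are rigid everywhere; two-bone blends average at equidistance", {
  g <- imageVolume(array(0, c(20, 20, 20)), spacing = 2)
  tr <- rigidAboutPoint(c(0, 0, 1), 8, c(10, 20, 20), shift = c(2, 1, -1))
  bone <- phantomBone(c(10, 20, 8), c(10, 20, 32), 5, transform = tr)
  f <- blendField(list(bone), g, tau = 3)
  pts <- locorigid:::gridPoints(g)
  disp <- transformPoints(tr, pts) - pts
  expect_lt(max(abs(matrix(f@vectors, ncol = 3) - disp)), 1e-12)

  # symmetric translations: midpoint gets the average displacement
  b1 <- phantomBone(c(10, 30, 10), c(10, 30, 50), 4,
                    transform = rigidTransform(translation = c(2, 0, 0)))
  b2 <- phantomBone(c(50, 30, 10), c(50, 30, 50), 4,
                    transform = rigidTransform(translation = c(0, 2, 0)))
  mid <- matrix(c(30, 30, 30), 1)
  d <- locorigid:::blendDisplacement(mid, list(b1, b2),
                                     list(b1$transform, b2$transform), 5)
  expect_equal(as.vector(d), c(1, 1, 0), tolerance = 1e-12)
})

test_that("the blended field is smooth away from bone surfaces", {
  g <- imageVolume(array(0, c(32, 32, 32)), spacing = 2)
  b1 <- phantomBone(c(16, 32, 12), c(16, 32, 52), 5,
                    transform = rigidAboutPoint(c(0, 0, 1), 10, c(16, 32, 32),
                                                shift = c(3, -2, 1)))
  b2 <- phantomBone(c(48, 32, 12), c(48, 32, 52), 5,
                    transform = rigidTransform(translation = c(-2, 4, 0)))
  f <- blendField(list(b1, b2), g, tau = 4)
  v <- f@vectors
  # second central differences along x, in soft tissue between the bones
  d2 <- v[13:24, , , ] - 2 * v[14:25, , , ] + v[15:26, , , ]
  expect_lt(max(abs(d2)), 0.5)  # mm per (2 mm step)^2: visibly smooth
})

test_that("lesions follow the prescribed timepoints with inverted secondary contrast", {
  # soft-tissue positions, radially clear of both bone capsules
  les <- list(phantomLesion(c(36, 36, 36), 6, -150, "baseline"),
              phantomLesion(c(36, 36, 84), 6, -150, "followup"))
  truth <- testPhantom("lesioned", gridShape = c(48, 48, 80), lesions = les,
                       noiseSigma = 0)
  atVox <- function(vol, p) {
    idx <- round(worldToIndex(vol, p)) + 1
    vol@data[idx[1], idx[2], idx[3]]
  }
  # regressing lesion: dark at baseline, recovered at follow-up
  expect_lt(atVox(truth@baseline, les[[1]]$center),
            truth@spec@softTissueIntensity - 100)
  expect_gt(atVox(truth@followup, les[[1]]$center),
            atVox(truth@baseline, les[[1]]$center) + 100)
  # secondary channel inverts the contrast (bright where primary is dark)
  expect_gt(atVox(truth@baselineSecondary, les[[1]]$center),
            0.6 * truth@spec@softTissueIntensity + 100)
  # new lesion: appears at follow-up at its field-mapped position
  c2 <- les[[2]]$center
  mapped <- c2 + as.vector(sampleField(truth@field, c2))
  expect_lt(atVox(truth@followup, mapped),
            truth@spec@softTissueIntensity - 100)
})
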