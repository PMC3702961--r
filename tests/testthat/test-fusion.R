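test_that("axis-aligned slices equal the corresponding array planes", {
  set.seed(61)
  vol <- imageVolume(array(rnorm(10 * 12 * 14), c(10, 12, 14)), spacing = 1.5)
  plane <- slicePlane(origin = c(0, 0, 5 * 1.5), axisU = c(1, 0, 0),
                      axisV = c(0, 1, 0), width = 10, height = 12,
                      pixelSpacing = 1.5)
  expect_equal(extractSlice(vol, plane), vol@data[, , 6], tolerance = 1e-12)

  const <- imageVolume(array(4.2, c(10, 10, 10)))
  oblique <- slicePlane(c(1, 1, 1), c(1, 1, 0) / sqrt(2), c(0, 0, 1), 8, 8,
                        0.7)
  expect_lt(max(abs(extractSlice(const, oblique) - 4.2)), 1e-12)
})

test_that("a 45-degree plane through a linear ramp has slope sqrt(2)/2 of the axis slope", {
  ramp <- imageVolume(array(0, c(20, 20, 20)))
  g <- locorigid:::gridPoints(ramp)
  ramp@data[] <- g[, 1]                      # f(x, y, z) = x, slope 1 per mm
  plane <- slicePlane(c(2, 2, 10), c(1, 1, 0) / sqrt(2), c(0, 0, 1),
                      width = 15, height = 3, pixelSpacing = 1)
  sl <- extractSlice(ramp, plane)
  slopes <- diff(sl[, 2])
  expect_lt(max(abs(slopes - sqrt(2) / 2)), 1e-9)
  expect_error(slicePlane(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), 5, 5),
               "InvalidPlane")
})

test_that("window normalization maps low/high/midpoint and clips", {
  wl <- windowLevel(100, 300)
  expect_equal(normalizeWindow(matrix(c(100, 300, 200, 50, 400), 1), wl),
               matrix(c(0, 1, 0.5, 0, 1), 1))
  expect_error(windowLevel(5, 5), "low < high")
})

test_that("color fusion uses exactly complementary orange and blue", {
  v <- matrix(seq(0, 1, length.out = 11), 11, 5)
  fused <- colorFuse(v, v)
  # equal inputs: zero chroma gray of the shared intensity
  expect_equal(fused[, , 1], v, tolerance = 1e-12)
  expect_equal(fused[, , 2], v, tolerance = 1e-12)
  expect_equal(fused[, , 3], v, tolerance = 1e-12)

  expect_equal(as.vector(colorFuse(matrix(1), matrix(0))), c(1, 0.5, 0))
  expect_equal(as.vector(colorFuse(matrix(0), matrix(1))), c(0, 0.5, 1))

  # sign property + swap symmetry on random images
  set.seed(62)
  a <- matrix(runif(60), 6); b <- matrix(runif(60), 6)
  f1 <- colorFuse(a, b); f2 <- colorFuse(b, a)
  dec <- a > b
  expect_true(all((f1[, , 1] > f1[, , 3]) == dec))
  expect_true(all((f2[, , 3] > f2[, , 1]) == dec))
  expect_equal(f1[, , 1], f2[, , 3]); expect_equal(f1[, , 3], f2[, , 1])
  expect_equal(f1[, , 2], f2[, , 2])
  expect_error(colorFuse(a, matrix(0, 2, 2)), "ShapeMismatch")
})

test_that("the magic lens takes exactly the brute-force pixel disc from the secondary", {
  set.seed(63)
  prim <- matrix(runif(40 * 30), 40)
  sec <- matrix(runif(40 * 30), 40)
  center <- c(17.3, 12.8); r <- 9.4
  out <- magicLensComposite(prim, sec, center, r, ring = FALSE)
  inside <- outer(seq_len(40), seq_len(30), function(i, j)
    sqrt((i - center[1])^2 + (j - center[2])^2) < r)
  expect_identical(out[, , 1] == sec, inside)
  expect_identical(out[, , 1] == prim, !inside)

  # radius 0 leaves the primary; huge radius replaces everything
  expect_equal(magicLensComposite(prim, sec, center, 0,
                                  ring = FALSE)[, , 1], prim)
  expect_equal(magicLensComposite(prim, sec, center, 1000,
                                  ring = FALSE)[, , 2], sec)

  # idempotence with the same secondary
  once <- magicLensComposite(prim, sec, center, r)
  twice <- magicLensComposite(once, locorigid:::grayToRGB(sec), center, r)
  expect_identical(twice, once)
  expect_error(magicLensComposite(prim, matrix(0, 3, 3), center, r),
               "ShapeMismatch")
})

test_that("grayscale ROI context keeps the ROI and luma-grays the rest", {
  orange <- array(0, c(5, 4, 3))
  orange[, , 1] <- 1; orange[, , 2] <- 0.5
  allTrue <- matrix(TRUE, 5, 4)
  expect_identical(roiContextGray(orange, allTrue), orange)
  gray <- roiContextGray(orange, matrix(FALSE, 5, 4))
  expect_equal(gray[, , 1], gray[, , 2])
  expect_equal(gray[, , 2], gray[, , 3])
  expect_equal(gray[1, 1, 1], 0.299 + 0.587 * 0.5)
  # gray pixels are fixed points
  g5 <- array(0.5, c(3, 3, 3))
  expect_equal(roiContextGray(g5, matrix(FALSE, 3, 3)), g5)
})

test_that("identity-posture triptychs are gray with identical side views", {
  truth <- identityTruth()
  bundle <- phantomBundle(truth)
  plane <- canonicalPlane(bundle@baseline, "coronal",
                          through = boneSeed(truth, 1))
  views <- renderTriptych(bundle, rigidTransform(), plane)
  expect_equal(views$baseline, views$followup, tolerance = 1e-12)
  fus <- views$fusion
  expect_lt(max(abs(fus[, , 1] - fus[, , 3])), 1e-9)
})

test_that("matched fusion is near-gray inside the bone; unmatched is not", {
  truth <- smallTruth()
  bundle <- phantomBundle(truth)
  res <- matchAtPoint(bundle, boneSeed(truth, 1))
  plane <- canonicalPlane(bundle@baseline, "coronal",
                          through = boneSeed(truth, 1))
  maskSlice <- extractSlice(maskAsVolume(truth@boneMasks[[1]], 1),
                            plane) > 0.5
  chroma <- function(tr) {
    f <- renderTriptych(bundle, tr, plane)$fusion
    mean(abs(f[, , 1] - f[, , 3])[maskSlice])
  }
  matched <- chroma(res@transform)
  unmatched <- chroma(rigidTransform())
  expect_lt(matched, 0.05)
  expect_gt(unmatched, matched)
})

test_that("a new follow-up lesion fuses blue (B > R) and a regressed one orange", {
  truth <- testPhantom("lesion-fusion", gridShape = c(48, 48, 80),
                       noiseSigma = 0)
  bundle <- phantomBundle(truth)
  les <- truth@spec@lesions
  # lesion 2 is new at follow-up (intensity decrease at follow-up = orange);
  # lesion 1 was present at baseline only (recovery = blue)
  for (i in c(1, 2)) {
    le <- les[[i]]
    plane <- canonicalPlane(bundle@baseline, "axial", through = le$center)
    fus <- renderTriptych(bundle, rigidTransform(), plane)$fusion
    px <- round((le$center[1:2] - plane@origin[1:2]) / plane@pixelSpacing) + 1
    pix <- fus[px[1], px[2], ]
    if (le$timepoint == "followup")
      expect_gt(pix[1], pix[3])   # darker follow-up: orange dominates
    else
      expect_gt(pix[3], pix[1])   # brighter follow-up: blue dominates
  }
})
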