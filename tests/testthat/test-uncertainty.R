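rigidConsistentField <- function(transform, dims = c(20, 20, 20), sp = 2) {
  g <- imageVolume(array(0, dims), sp)
  pts <- locorigid:::gridPoints(g)
  deformationField(array(transformPoints(transform, pts) - pts,
                         c(dims, 3L)), sp)
}

test_that("the error field vanishes iff the transform explains the field", {
  tr <- rigidAboutPoint(c(0, 1, 0), 12, c(20, 20, 20), shift = c(3, -1, 2))
  f <- rigidConsistentField(tr)
  e <- errorField(f, tr)
  expect_lt(max(e@data), 1e-9)

  cf <- deformationField(array(rep(c(3, 0, 0), each = 8000), c(20, 20, 20, 3)),
                         2)
  e3 <- errorField(cf, rigidTransform())
  expect_equal(max(abs(e3@data - 3)), 0, tolerance = 1e-12)
})

test_that("each bone's own transform explains its region better than the other bone's", {
  truth <- smallTruth()
  fits <- lapply(1:2, function(k)
    estimateRigid(extractPointPairs(truth@boneMasks[[k]], truth@field)))
  e11 <- errorField(truth@field, fits[[1]])
  e21 <- errorField(truth@field, fits[[2]])
  m1 <- truth@boneMasks[[1]]@data
  expect_lt(mean(e11@data[m1]), mean(e21@data[m1]))
  m2 <- truth@boneMasks[[2]]@data
  expect_lt(mean(e21@data[m2]), mean(e11@data[m2]))
})

test_that("the fitted transform minimizes the mask-averaged error field", {
  truth <- smallTruth()
  mask <- truth@boneMasks[[1]]@data
  pairs <- extractPointPairs(truth@boneMasks[[1]], truth@field)
  fit <- estimateRigid(pairs)
  base <- mean(errorField(truth@field, fit)@data[mask])
  set.seed(51)
  for (rep in 1:50) {
    wob <- composeRigid(randomRigid(runif(1, 0.01, 1), runif(1, 0.01, 1)), fit)
    expect_gte(mean(errorField(truth@field, wob)@data[mask]), base)
  }
})

linearErrorVolume <- function(center, slope = 0.1, n = 111L, sp = 2) {
  g <- imageVolume(array(0, c(n, n, 3)), sp,
                   origin = c(center[1] - sp * (n - 1) / 2,
                              center[2] - sp * (n - 1) / 2, center[3] - sp))
  pts <- locorigid:::gridPoints(g)
  g@data[] <- slope * sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
  g
}

test_that("contours cross a 0.1 mm/mm radial error at 30/60/90 mm for 3/6/9 mm levels", {
  center <- c(0, 0, 0)
  err <- linearErrorVolume(center)
  ct <- radialContours(err, center, thresholds = c(3, 6, 9), nRays = 90L,
                       step = 0.5, maxRadius = 120)
  for (k in 1:3)
    expect_lt(max(abs(ct@radii[, k] - 30 * k)), 0.5 + 1e-9)
})

test_that("a zero error field leaves every ray open with empty polylines", {
  err <- imageVolume(array(0, c(41, 41, 3)), 2, origin = c(-40, -40, -2))
  ct <- radialContours(err, c(0, 0, 0), maxRadius = 35)
  expect_true(all(is.na(ct@radii)))
  expect_true(all(vapply(ct@polylines, length, 1L) == 0L))
})

test_that("first crossings match a 10x finer march on an anisotropic error field", {
  g <- imageVolume(array(0, c(81, 81, 3)), 2, origin = c(-80, -80, -2))
  pts <- locorigid:::gridPoints(g)
  # stretched along x (low error) and steep along y, cf. error contours
  # extending further along bony structures
  g@data[] <- 0.05 * abs(pts[, 1]) + 0.25 * abs(pts[, 2]) +
    0.02 * pts[, 1] * sin(pts[, 2] / 9)
  coarse <- radialContours(g, c(0, 0, 0), nRays = 36L, step = 1, maxRadius = 70)
  fine <- radialContours(g, c(0, 0, 0), nRays = 36L, step = 0.1,
                         maxRadius = 70)
  agree <- abs(coarse@radii - fine@radii) <= 1 + 1e-9
  expect_true(all(agree | (is.na(coarse@radii) & is.na(fine@radii))))
})

test_that("contours nest for arbitrary random error fields", {
  set.seed(52)
  for (rep in 1:20) {
    g <- imageVolume(array(0, c(31, 31, 3)), 2, origin = c(-30, -30, -2))
    base <- array(runif(8, 0, 12), c(2, 2, 2))
    pts <- locorigid:::gridPoints(g)
    g@data[] <- runif(1, 0, 6) * abs(sin(pts[, 1] / runif(1, 4, 15))) +
      runif(1, 0, 6) * abs(cos(pts[, 2] / runif(1, 4, 15)))
    ct <- radialContours(g, c(0, 0, 0), nRays = 60L, maxRadius = 28)
    for (ray in seq_len(nrow(ct@radii))) {
      r <- ct@radii[ray, ]
      known <- which(!is.na(r))
      if (length(known) > 1)
        expect_true(all(diff(r[known]) >= 0))
      # once open, all larger thresholds are open too
      if (length(known) && length(known) < length(r))
        expect_true(max(known) == length(known))
    }
  }
})

test_that("halving the march step moves crossings by at most one step", {
  err <- linearErrorVolume(c(0, 0, 0), slope = 0.15)
  a <- radialContours(err, c(0, 0, 0), nRays = 45L, step = 1, maxRadius = 80)
  b <- radialContours(err, c(0, 0, 0), nRays = 45L, step = 0.5, maxRadius = 80)
  expect_true(all(abs(a@radii - b@radii) <= 1 + 1e-9))
})

test_that("the deformation sphere separates rigid from non-rigid motion", {
  tr <- rigidAboutPoint(c(1, 1, 0), 9, c(20, 20, 20), shift = c(2, 0, -1))
  f <- rigidConsistentField(tr)
  sph <- deformationSphere(f, c(20, 20, 20), radius = 8, transform = tr)
  expect_lt(max(abs(sph@residuals)), 1e-9)

  zero <- deformationField(array(0, c(20, 20, 20, 3)), 2)
  s0 <- deformationSphere(zero, c(20, 20, 20), radius = 8)
  expect_identical(s0@warpedPoints, s0@baselinePoints)
  expect_true(all(s0@residuals == 0))

  # rigid + constant extra: the residual recovers the constant exactly
  extra <- f
  extra@vectors[, , , 3] <- extra@vectors[, , , 3] + 2
  se <- deformationSphere(extra, c(20, 20, 20), radius = 8, transform = tr)
  expect_lt(max(abs(se@residuals - rep(c(0, 0, 2), each = 200))), 1e-9)
})

test_that("sphere sampling is deterministic, exact-radius and exactly n points", {
  f <- deformationField(array(0, c(20, 20, 20, 3)), 2)
  s1 <- deformationSphere(f, c(20, 20, 20), radius = 7, nPoints = 137L)
  s2 <- deformationSphere(f, c(20, 20, 20), radius = 7, nPoints = 137L)
  expect_identical(s1@baselinePoints, s2@baselinePoints)
  expect_equal(nrow(s1@baselinePoints), 137L)
  rad <- sqrt(rowSums(sweep(s1@baselinePoints, 2, c(20, 20, 20))^2))
  expect_lt(max(abs(rad - 7)), 1e-9)
  expect_error(deformationSphere(f, c(1, 1, 1), radius = 10), "OutOfDomain")
})
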