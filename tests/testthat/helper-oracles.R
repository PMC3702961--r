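# Independent oracles used to cross-check the package's own algorithms.
# They deliberately take different computational routes than the
# implementation (SVD instead of quaternion eigen-decomposition;
# morphological-dilation fixed point instead of frontier BFS).

# Kabsch: least-squares rigid fit via SVD of the cross-covariance,
# reflection-corrected. Returns list(R = 3x3, t = length-3).
oracleKabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = qc - as.vector(R %*% pc))
}

# angle (rad) between a RigidTransform's rotation and a rotation matrix,
# via the relative quaternion (atan2 form, precise near zero)
rotationGapRad <- function(transform, R) {
  q <- matrixToQuaternion(t(rotationMatrix(transform)) %*% R)
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1]))
}

# random proper rotation + translation drawn from the current RNG stream
randomRigid <- function(maxAngleDeg = 180, maxShift = 20) {
  ax <- stats::rnorm(3)
  rigidTransform(axisAngleQuaternion(ax, stats::runif(1, -1, 1) * maxAngleDeg),
                 stats::runif(3, -1, 1) * maxShift)
}

# brute-force confidence-connected oracle: same statistical definition,
# but the fill is a morphological-dilation fixed point over the whole box
# rather than a frontier search
oracleConfidenceConnected <- function(volume, seed, params = growParams()) {
  d <- dim(volumeData(volume))
  sp <- spacing(volume); or <- origin(volume)
  seedIdx <- round((as.numeric(seed) - or) / sp)
  lo <- pmax(0, ceiling((as.numeric(seed) - params@boxHalfWidth - or) / sp -
                          1e-9))
  hi <- pmin(d - 1L, floor((as.numeric(seed) + params@boxHalfWidth - or) / sp +
                             1e-9))
  lo <- pmin(lo, seedIdx); hi <- pmax(hi, seedIdx)
  sub <- volumeData(volume)[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                            (lo[3] + 1):(hi[3] + 1), drop = FALSE]
  s1 <- as.integer(seedIdx - lo + 1L)
  sd3 <- dim(sub)

  dilate6 <- function(m) {
    out <- m
    n <- dim(m)
    if (n[1] > 1) {
      out[-1, , ] <- out[-1, , ] | m[-n[1], , ]
      out[-n[1], , ] <- out[-n[1], , ] | m[-1, , ]
    }
    if (n[2] > 1) {
      out[, -1, ] <- out[, -1, ] | m[, -n[2], ]
      out[, -n[2], ] <- out[, -n[2], ] | m[, -1, ]
    }
    if (n[3] > 1) {
      out[, , -1] <- out[, , -1] | m[, , -n[3]]
      out[, , -n[3]] <- out[, , -n[3]] | m[, , -1]
    }
    out
  }
  fill <- function(acc) {
    m <- array(FALSE, sd3)
    m[s1[1], s1[2], s1[3]] <- TRUE
    repeat {
      grown <- m | (dilate6(m) & acc)
      if (identical(grown, m)) break
      m <- grown
    }
    m
  }

  ri <- floor(params@initialRadius)
  ig <- expand.grid(i = s1[1] + (-ri:ri), j = s1[2] + (-ri:ri),
                    k = s1[3] + (-ri:ri))
  ig <- ig[ig$i >= 1 & ig$i <= sd3[1] & ig$j >= 1 & ig$j <= sd3[2] &
             ig$k >= 1 & ig$k <= sd3[3], ]
  nbVals <- sub[as.matrix(ig)]
  seedVal <- sub[s1[1], s1[2], s1[3]]
  accFor <- function(vals) {
    mu <- mean(vals)
    sig <- if (length(vals) < 2) 0 else stats::sd(vals)
    lo_ <- min(mu - params@multiplier * sig, seedVal) - 1e-6
    hi_ <- max(mu + params@multiplier * sig, seedVal) + 1e-6
    sub >= lo_ & sub <= hi_
  }
  m <- fill(accFor(nbVals))
  for (it in seq_len(params@nIterations)) m <- fill(accFor(sub[m]))

  full <- array(FALSE, d)
  full[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
       (lo[3] + 1):(hi[3] + 1)] <- m
  maskVolume(full, sp, or)
}
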