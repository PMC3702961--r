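# Shared small phantoms, generated once per test file.

.phantomCache <- new.env(parent = emptyenv())

testPhantom <- function(key = "default", ...) {
  if (is.null(.phantomCache[[key]]))
    .phantomCache[[key]] <- generatePhantom(phantomSpec(...))
  .phantomCache[[key]]
}

# 48 x 48 x 80 articulated two-bone phantom at the default study conditions
smallTruth <- function() {
  testPhantom("small", gridShape = c(48, 48, 80))
}

# same geometry, identity posture, no noise, no lesions
identityTruth <- function() {
  testPhantom("identity", gridShape = c(32, 32, 48), noiseSigma = 0,
              lesions = list(),
              bones = lapply(locorigid:::defaultBones(c(48, 48, 72)),
                             function(b) { b$transform <- rigidTransform(); b }))
}

boneSeed <- function(truth, k) {
  b <- truth@spec@bones[[k]]
  (b$a + b$b) / 2
}
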