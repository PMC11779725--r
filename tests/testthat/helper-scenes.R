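# Scenes reused across test files (generated once per run).

.sceneCache <- new.env()

cachedScene <- function(key, params) {
  if (is.null(.sceneCache[[key]]))
    assign(key, generateScene(params), envir = .sceneCache)
  get(key, envir = .sceneCache)
}

# the study-condition scene: 350x geometry, 80 stomata/mm^2, noise sd 8
noisyScene <- function()
  cachedScene("noisy", sceneParams(targetDensity = 80, noiseSd = 8, seed = 7))

# noise-free scene with an even number of stomata (46)
noiseFreeScene <- function()
  cachedScene("nf", sceneParams(targetDensity = 78, noiseSd = 0, seed = 11))

# small fast scene for structural tests
smallScene <- function()
  cachedScene("small", sceneParams(fieldWidthUm = 300, fieldHeightUm = 300,
                                   pixelsPerSide = 400, targetDensity = 50,
                                   noiseSd = 3, seed = 5))

# match non-border instances to truth rows by nearest centroid; returns
# data.frame of measured traits and the matched truth rows
matchedTraits <- function(scene, instances, measured) {
  tr <- truthTraits(scene)
  s <- umPerPx(scene)
  keep <- !vapply(instances, function(i) i@borderTouching, logical(1))
  ctr <- t(vapply(instances[keep], function(i) {
    w <- arrayInd(i@pixels, i@maskDim)
    c(mean(w[, 2]), mean(w[, 1]))
  }, numeric(2)))
  idx <- apply(ctr, 1, function(cc)
    which.min((tr$centerXUm / s - cc[1])^2 + (tr$centerYUm / s - cc[2])^2))
  list(measured = measured, truth = tr[idx, , drop = FALSE])
}
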