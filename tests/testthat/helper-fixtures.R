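# Shared fixture builders. Everything is generated in code at test time.

# Two well-separated blob sources on a small grid.
twoBlobSpecs <- function(radius = 1.5) {
  list(
    sourceSpec(1, c(4, 4, 4), radius = radius, amplitude = 1),
    sourceSpec(2, c(13, 13, 5), radius = radius, amplitude = 1))
}

# Five-source layout with pairwise separation >= 4 radii (sources close to
# spatially independent), for blind-source-recovery checks.
separatedFiveSpecs <- function() {
  ctrs <- rbind(
    c(4, 4, 2), c(13, 4, 6), c(4, 13, 6), c(13, 13, 2), c(8.5, 8.5, 4))
  lapply(seq_len(nrow(ctrs)), function(i) {
    sourceSpec(i, ctrs[i, ], radius = 1.5, amplitude = 1)
  })
}

# Noise-free exact mixture volume from given specs.
mixtureVolume <- function(specs, nTimepoints = 120, seed = 11,
                          noiseSd = 0, grid = c(16, 16, 8)) {
  g <- defaultCausalGraph(length(specs))
  tc <- simulateVarTimecourses(g, nTimepoints, seed = seed)
  synthesizeSubject(specs, grid, tc, noiseSd = noiseSd,
    seed = seed + 1)
}

trueMapsFor <- function(specs, vol, grid = c(16, 16, 8)) {
  mapValues(makeSourceMaps(specs, grid))[as.vector(brainMask(vol)), ,
    drop = FALSE]
}

# quick white-noise map matrix
noiseMaps <- function(nVox, nMaps, seed = 1) {
  withr::with_seed(seed, matrix(stats::rnorm(nVox * nMaps), nVox, nMaps))
}
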