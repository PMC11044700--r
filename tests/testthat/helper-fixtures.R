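# Shared heavy fixtures, built once per test run and memoised. Everything
# is generated in code under fixed seeds; no files are read.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Classifier dataset at the study size: ~600 frames, 300 per class.
fixtureDataset <- function() {
  memo("dataset", function() makeClassifierDataset(300, seed = 101L))
}

# Trained shallow CNN on that dataset.
fixtureClassifier <- function() {
  memo("classifier", function() {
    trainInterfaceClassifier(buildInterfaceClassifier(seed = 7L),
                             fixtureDataset(), epochs = 6L, seed = 7L)
  })
}

# Closed-loop run with the trained CNN (2 completed gradients).
fixtureLoopRun <- function() {
  memo("looprun", function() {
    runGradientLoop(fixtureClassifier()$model, nGradients = 2L, seed = 31L)
  })
}

# Occluded / noisy frame benchmark: frames from both class bands with many
# cells and strong noise, where classical edge detection struggles.
fixtureOccludedSet <- function(n = 200L) {
  memo("occluded", function() {
    seeds <- fanOutSeeds(404L, n)
    f <- withr::with_seed(405L, ifelse(seq_len(n) %% 2 == 0,
                                       runif(n, 0, 0.2),
                                       runif(n, 0.8, 1)))
    frames <- lapply(seq_len(n), function(i) {
      renderFlowFrame(f[i], nCells = 8L, noiseSd = 10,
                      illumGradient = 0.2, seed = seeds[i])
    })
    list(frames = frames, fHigh = f,
         labels = ifelse(f >= 0.8, "HIGH_VF", "LOW_VF"))
  })
}

# Bead fields at the bead-detector study scale (50 fields x 20 beads) and
# a detector trained on them.
fixtureBeadFields <- function() {
  memo("beadfields", function() {
    trace <- withr::with_seed(501L, runif(4000, 0.1, 0.9))
    beads <- sampleBeadPopulation(1000L, fHighTrace = trace, seed = 502L)
    seeds <- fanOutSeeds(503L, 50L)
    lapply(seq_len(50L), function(i) {
      renderBeadField(beads[((i - 1) * 20 + 1):(i * 20), ], seed = seeds[i])
    })
  })
}

fixtureBeadDetector <- function() {
  memo("beaddetector", function() {
    trainGridDetector(fixtureBeadFields(), "bead", seed = 504L)
  })
}
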