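## Naive double-loop reference implementation of one generation, written
## independently of the package's C++ engine and kept deliberately
## unoptimised. It reproduces the engine's exact RNG draw sequence
## (births in row-major site order; per birth: parent index as
## floor(k * runif(1)), mutation gate, gene index, normal deviate) so
## full trajectories including genomes can be compared bit for bit.

.oracleOffsets <- rbind(
  c(-1, -1), c(-1, 0), c(-1, 1),
  c(0, -1), c(0, 1),
  c(1, -1), c(1, 0), c(1, 1))

oracleRound <- function(x) sign(x) * floor(abs(x) + 0.5)

## raw state: list(occupancy, lonely, born, crowded)
oracleStep <- function(raw, rate, magnitude) {
  occ <- raw$occupancy
  n <- nrow(occ)
  newOcc <- matrix(0L, n, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      m <- sum(occ[(i - 1):(i + 1), (j - 1):(j + 1)]) - occ[i, j]
      if (occ[i, j] == 1L) {
        if (m >= oracleRound(raw$lonely[i, j]) &&
            m <= oracleRound(raw$crowded[i, j]))
          newOcc[i, j] <- 1L
      } else {
        if (m == oracleRound(raw$born[i, j])) newOcc[i, j] <- 1L
      }
    }
  }
  newLon <- raw$lonely; newBrn <- raw$born; newCrw <- raw$crowded
  for (i in 1:n) {
    for (j in 1:n) {
      if (occ[i, j] == 1L && newOcc[i, j] == 0L) {
        newLon[i, j] <- 2; newBrn[i, j] <- 3; newCrw[i, j] <- 3
      } else if (occ[i, j] == 0L && newOcc[i, j] == 1L) {
        cand <- matrix(0L, 0, 2)
        for (q in 1:8) {
          pi <- i + .oracleOffsets[q, 1]; pj <- j + .oracleOffsets[q, 2]
          if (occ[pi, pj] == 1L) cand <- rbind(cand, c(pi, pj))
        }
        idx <- min(floor(nrow(cand) * runif(1)), nrow(cand) - 1) + 1
        pi <- cand[idx, 1]; pj <- cand[idx, 2]
        child <- c(raw$lonely[pi, pj], raw$born[pi, pj], raw$crowded[pi, pj])
        if (runif(1) < rate) {
          g <- min(floor(3 * runif(1)), 2) + 1
          child[g] <- child[g] + magnitude * rnorm(1)
        }
        newLon[i, j] <- child[1]; newBrn[i, j] <- child[2]
        newCrw[i, j] <- child[3]
      }
    }
  }
  list(occupancy = newOcc, lonely = newLon, born = newBrn, crowded = newCrw)
}

## fast-engine step on a raw grid list, default modes
.stepRawForTest <- function(raw, rate, magnitude) {
  mutableLife:::.stepRaw(raw, rate, magnitude, "site", "synchronous")
}

rawFromState <- function(state) {
  list(occupancy = occupancy(state), lonely = lonelyGrid(state),
       born = bornGrid(state), crowded = crowdedGrid(state))
}

## shared cache for expensive simulation summaries reused across
## acceptance test blocks (filled lazily, deterministic seeds)
.simCache <- new.env(parent = emptyenv())

cachedClassicRuns <- function(nSeeds = 20) {
  key <- paste0("classic", nSeeds)
  if (is.null(.simCache[[key]])) {
    out <- data.frame(seed = seq_len(nSeeds), end_generation = NA_real_,
                      occupancy_pct = NA_real_)
    for (i in seq_len(nSeeds)) {
      set.seed(i)
      r <- simulateRun(randomSoup(100, 0.5), MutationParams(0, 1),
                       RunConfig())
      out$end_generation[i] <- endGeneration(r)
      out$occupancy_pct[i] <- 100 * endPopulation(r) / 1e4
    }
    .simCache[[key]] <- out
  }
  .simCache[[key]]
}

cachedHighMagnitudeSweep <- function() {
  if (is.null(.simCache$highMag)) {
    .simCache$highMag <- runSweep(
      rates = c(0.05, 0.1, 0.4), magnitudes = c(4, 6, 10),
      replicates = 2, baseSeed = 11, config = RunConfig())
  }
  .simCache$highMag
}

cachedTransitionSweep <- function() {
  if (is.null(.simCache$transition)) {
    .simCache$transition <- runSweep(
      rates = c(0.05, 0.1), magnitudes = c(0.25, 0.5, 0.75, 1.0, 1.5),
      replicates = 3, baseSeed = 23, config = RunConfig())
  }
  .simCache$transition
}

cachedSelectionSweep <- function() {
  if (is.null(.simCache$selection)) {
    .simCache$selection <- runSweep(
      rates = c(0.01, 0.05, 0.1, 0.4), magnitudes = c(0.5, 1, 2, 6),
      replicates = 1, baseSeed = 37, config = RunConfig())
  }
  .simCache$selection
}
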