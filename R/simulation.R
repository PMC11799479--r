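#' Random initial soup
#'
#' Generates the reference initial condition: exactly
#' `round(density * size^2)` live cells placed uniformly without
#' replacement over the full lattice, borders included (border cells can
#' be alive at generation 0 only; they die at the first update). All
#' genome grids start wildtype. At the defaults (size 100, density 0.5)
#' the initial population is exactly 5000 cells.
#'
#' @param size lattice side length.
#' @param density live fraction in \[0, 1\].
#' @return A [LatticeState-class] at generation 0.
#' @examples
#' set.seed(1)
#' population(randomSoup(100, 0.5))   # 5000
#' @export
randomSoup <- function(size = 100, density = 0.5) {
  size <- as.integer(size)
  if (!is.numeric(density) || is.na(density) || density < 0 || density > 1)
    stop("density must be in [0, 1]")
  state <- emptyLattice(size)
  k <- as.integer(roundHalfAway(density * size^2))
  if (k > 0) {
    live <- sample.int(size * size, k)
    occ <- state@occupancy
    occ[live] <- 1L
    state@occupancy <- occ
  }
  state
}

#' Detect steady state of a run
#'
#' The run loop terminates when the population reaches a steady state or
#' hits the generation cap, whichever comes first. Two detectors are
#' available:
#' * `"population"` (default): the live-cell count has been identical
#'   over the last `window + 1` generations. This tolerates the period-2
#'   oscillators of typical Life ash (their counts are constant) and the
#'   window guards against transient plateaus of the slow early decline.
#' * `"state"`: there is a period `p <= maxPeriod` such that the
#'   occupancy grid equals its p-step predecessor at each of the last
#'   `window` generations — strict periodicity up to `maxPeriod`.
#'
#' Histories shorter than `window + maxPeriod + 1` entries never
#' qualify.
#'
#' @param popHistory integer vector of live-cell counts, generation 0
#'   first.
#' @param detector `"population"` or `"state"`.
#' @param window trailing generations over which constancy/periodicity
#'   must hold.
#' @param maxPeriod largest accepted period for the state detector.
#' @param stateHistory list of occupancy matrices (oldest first) covering
#'   at least the last `window + maxPeriod` generations; only used by the
#'   state detector.
#' @return `TRUE` if the steady-state criterion holds.
#' @examples
#' detectSteadyState(c(50:21, rep(20, 26)))          # TRUE
#' detectSteadyState(seq(100, 2))                    # FALSE
#' @export
detectSteadyState <- function(popHistory, detector = c("population", "state"),
                              window = 25, maxPeriod = 2,
                              stateHistory = NULL) {
  detector <- match.arg(detector)
  ng <- length(popHistory)
  if (ng <= window + maxPeriod) return(FALSE)
  if (detector == "population") {
    tail <- popHistory[(ng - window):ng]
    return(all(tail == tail[1]))
  }
  nh <- length(stateHistory)
  if (is.null(stateHistory) || nh < window + maxPeriod) return(FALSE)
  for (p in seq_len(maxPeriod)) {
    ok <- TRUE
    for (t in (nh - window + 1):nh) {
      if (!identical(stateHistory[[t]], stateHistory[[t - p]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Mean thresholds over the whole lattice
#'
#' Arithmetic mean of each threshold grid over all `size^2` sites; dead
#' sites contribute their wildtype values (2/3/3). These are the
#' per-run summary statistics reported by the sweep experiments.
#'
#' @param state a [LatticeState-class].
#' @return Named numeric vector `c(mean_lonely, mean_born, mean_crowded)`.
#' @examples
#' latticeMeans(emptyLattice(10))   # 2 3 3
#' @export
latticeMeans <- function(state) {
  c(mean_lonely = mean(state@lonely),
    mean_born = mean(state@born),
    mean_crowded = mean(state@crowded))
}

#' Live-cell occupancy fraction
#'
#' @param state a [LatticeState-class].
#' @return Live count divided by `size^2`, in \[0, 1\].
#' @examples
#' occupancyFraction(emptyLattice(10))   # 0
#' @export
occupancyFraction <- function(state) {
  population(state) / latticeSize(state)^2
}

#' Run the simulation loop from a given initial state
#'
#' Repeatedly applies [caStep()] until [detectSteadyState()] fires or the
#' generation cap is reached, recording the population at every
#' generation (generation 0 is the initial state). Deterministic given
#' the RNG state on entry.
#'
#' @param initial a [LatticeState-class] at any generation (its counter
#'   is taken as generation 0 of the run).
#' @param params a [MutationParams-class].
#' @param config a [RunConfig-class]; `size`, `initDensity` and `seed`
#'   are ignored here (the initial state and current RNG state are
#'   used) — see [runSimulation()] for the seeded driver.
#' @return A [RunResult-class].
#' @examples
#' set.seed(1)
#' res <- simulateRun(randomSoup(30, 0.4), MutationParams(0, 1),
#'                    RunConfig(size = 30, maxGenerations = 500))
#' terminatedBy(res)
#' @export
simulateRun <- function(initial, params, config = RunConfig()) {
  stopifnot(is(initial, "LatticeState"), is(params, "MutationParams"),
            is(config, "RunConfig"))
  maxGen <- config@maxGenerations
  window <- config@window
  maxPeriod <- config@maxPeriod
  useState <- config@steadyDetector == "state"
  bufLen <- window + maxPeriod + 1L

  raw <- list(occupancy = initial@occupancy, lonely = initial@lonely,
              born = initial@born, crowded = initial@crowded)
  pop <- integer(maxGen + 1L)
  pop[1L] <- sum(raw$occupancy)
  stateBuf <- if (useState) list(raw$occupancy) else NULL
  terminated <- "max_generations"
  g <- 0L
  while (g < maxGen) {
    raw <- .stepRaw(raw, params@rate, params@magnitude,
                    config@birthRule, config@genomeUpdate)
    g <- g + 1L
    pop[g + 1L] <- sum(raw$occupancy)
    if (useState) {
      stateBuf[[length(stateBuf) + 1L]] <- raw$occupancy
      if (length(stateBuf) > bufLen) stateBuf <- stateBuf[-1L]
    }
    if (detectSteadyState(pop[seq_len(g + 1L)], config@steadyDetector,
                          window, maxPeriod, stateBuf)) {
      terminated <- "steady_state"
      break
    }
  }
  final <- new("LatticeState", occupancy = raw$occupancy,
               lonely = raw$lonely, born = raw$born, crowded = raw$crowded,
               generation = initial@generation + g)
  mns <- latticeMeans(final)
  new("RunResult",
      populationTrajectory = pop[seq_len(g + 1L)],
      endGeneration = g,
      endPopulation = pop[g + 1L],
      terminatedBy = terminated,
      meanLonely = unname(mns[1]), meanBorn = unname(mns[2]),
      meanCrowded = unname(mns[3]),
      finalState = final)
}

#' Seeded end-to-end run at the reference conditions
#'
#' Convenience driver: seeds the RNG (if `config@seed` is not `NA`),
#' draws a random soup per `config`, and calls [simulateRun()].
#'
#' @param params a [MutationParams-class].
#' @param config a [RunConfig-class].
#' @return A [RunResult-class].
#' @examples
#' res <- runSimulation(MutationParams(0, 1),
#'                      RunConfig(size = 30, maxGenerations = 300, seed = 7))
#' endGeneration(res)
#' @export
runSimulation <- function(params = MutationParams(), config = RunConfig()) {
  stopifnot(is(config, "RunConfig"))
  if (!is.na(config@seed)) set.seed(config@seed)
  simulateRun(randomSoup(config@size, config@initDensity), params, config)
}
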