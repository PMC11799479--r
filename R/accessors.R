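#' @name accessors
#' @title Accessors for simulator objects
#'
#' @description Slot accessors for [LatticeState-class], [RunResult-class]
#' and [Pattern-class] objects. Use these rather than `@` slot access.
#'
#' @param object a simulator object.
#' @return The corresponding component; see each generic's description.
NULL

#' @describeIn accessors integer occupancy matrix of a lattice (1 = live).
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))
#' @describeIn accessors per-site loneliness-threshold matrix.
#' @export
setGeneric("lonelyGrid", function(object) standardGeneric("lonelyGrid"))
#' @describeIn accessors per-site birth-threshold matrix.
#' @export
setGeneric("bornGrid", function(object) standardGeneric("bornGrid"))
#' @describeIn accessors per-site overcrowding-threshold matrix.
#' @export
setGeneric("crowdedGrid", function(object) standardGeneric("crowdedGrid"))
#' @describeIn accessors generation counter of a lattice state.
#' @export
setGeneric("generation", function(object) standardGeneric("generation"))
#' @describeIn accessors lattice side length.
#' @export
setGeneric("latticeSize", function(object) standardGeneric("latticeSize"))
#' @describeIn accessors number of live cells.
#' @export
setGeneric("population", function(object) standardGeneric("population"))

setMethod("occupancy", "LatticeState", function(object) object@occupancy)
setMethod("lonelyGrid", "LatticeState", function(object) object@lonely)
setMethod("bornGrid", "LatticeState", function(object) object@born)
setMethod("crowdedGrid", "LatticeState", function(object) object@crowded)
setMethod("generation", "LatticeState", function(object) object@generation)
setMethod("latticeSize", "LatticeState", function(object) nrow(object@occupancy))
setMethod("population", "LatticeState", function(object) sum(object@occupancy))

#' @describeIn accessors population trajectory of a run (index 1 is
#'   generation 0).
#' @export
setGeneric("trajectory", function(object) standardGeneric("trajectory"))
#' @describeIn accessors generation at which a run stopped.
#' @export
setGeneric("endGeneration", function(object) standardGeneric("endGeneration"))
#' @describeIn accessors final live-cell count of a run.
#' @export
setGeneric("endPopulation", function(object) standardGeneric("endPopulation"))
#' @describeIn accessors `"steady_state"` or `"max_generations"`.
#' @export
setGeneric("terminatedBy", function(object) standardGeneric("terminatedBy"))
#' @describeIn accessors final [LatticeState-class] of a run.
#' @export
setGeneric("finalState", function(object) standardGeneric("finalState"))

setMethod("trajectory", "RunResult", function(object) object@populationTrajectory)
setMethod("endGeneration", "RunResult", function(object) object@endGeneration)
setMethod("endPopulation", "RunResult", function(object) object@endPopulation)
setMethod("terminatedBy", "RunResult", function(object) object@terminatedBy)
setMethod("finalState", "RunResult", function(object) object@finalState)

#' @describeIn accessors 0-based live-cell coordinate matrix of a pattern.
#' @export
setGeneric("patternCells", function(object) standardGeneric("patternCells"))
#' @describeIn accessors pattern name.
#' @export
setGeneric("patternName", function(object) standardGeneric("patternName"))

setMethod("patternCells", "Pattern", function(object) object@cells)
setMethod("patternName", "Pattern", function(object) object@name)

setMethod("show", "LatticeState", function(object) {
  n <- latticeSize(object)
  mut <- sum(object@lonely != 2 | object@born != 3 | object@crowded != 3)
  cat(sprintf("LatticeState %dx%d, generation %d\n", n, n,
              generation(object)))
  cat(sprintf("  live cells: %d (%.1f%% occupancy)\n", population(object),
              100 * population(object) / n^2))
  cat(sprintf("  sites with non-wildtype genome: %d\n", mut))
})

setMethod("show", "MutationParams", function(object) {
  cat(sprintf("MutationParams: rate = %g, magnitude = %g\n",
              object@rate, object@magnitude))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: %dx%d lattice, density %g, max %d generations\n",
    object@size, object@size, object@initDensity, object@maxGenerations))
  cat(sprintf(
    "  detector = %s (window %d, max period %d), birthRule = %s, genomeUpdate = %s\n",
    object@steadyDetector, object@window, object@maxPeriod,
    object@birthRule, object@genomeUpdate))
})

setMethod("show", "RunResult", function(object) {
  cat(sprintf("RunResult: terminated by %s at generation %d\n",
              object@terminatedBy, object@endGeneration))
  cat(sprintf("  end population: %d (%.1f%% occupancy)\n",
              object@endPopulation,
              100 * occupancyFraction(object@finalState)))
  cat(sprintf("  mean thresholds (lonely/born/crowded): %.3f / %.3f / %.3f\n",
              object@meanLonely, object@meanBorn, object@meanCrowded))
})

setMethod("show", "Pattern", function(object) {
  cat(sprintf("Pattern '%s': %dx%d, %d live cells\n", object@name,
              object@width, object@height, nrow(object@cells)))
})
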