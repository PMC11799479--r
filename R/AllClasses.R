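#' @import methods
#' @importFrom stats runif rnorm sd median
#' @importFrom utils read.table write.table
#' @useDynLib mutableLife, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Wildtype rule genome
#'
#' The classic Conway thresholds: a live cell dies of loneliness below 2
#' live Moore neighbours, dies of overcrowding above 3, and an empty site
#' spawns a cell at exactly 3 (the B3/S23 rule). Every dead lattice site
#' carries this genome, and it is the initial genome of every site.
#'
#' @return Named numeric vector with elements `lonely`, `born`, `crowded`
#'   equal to `c(2, 3, 3)`.
#' @examples
#' wildtypeGenome()
#' @export
wildtypeGenome <- function() c(lonely = 2, born = 3, crowded = 3)

.WT <- c(lonely = 2, born = 3, crowded = 3)

#' LatticeState: full state of the mutable-rule Life simulator
#'
#' Holds the binary occupancy grid, the three real-valued threshold
#' ("gene") grids of the same shape, and a generation counter. Threshold
#' values are unrounded accumulators; they are rounded (half away from
#' zero) only at rule-enforcement time and are not clamped, so they may
#' drift below 0 or above 8.
#'
#' Class invariants, checked by the validity method:
#' * all four grids are square matrices of identical dimension (side
#'   length at least 3);
#' * occupancy entries are 0/1;
#' * every dead site carries exactly the wildtype genome (2/3/3) — the
#'   reset-on-death rule maintains this after every step;
#' * for generation >= 1, every border site is dead (only interior sites
#'   are ever written by the update, which is how the model avoids a
#'   boundary condition).
#'
#' @slot occupancy integer matrix, 1 = live cell.
#' @slot lonely,born,crowded numeric matrices of per-site thresholds.
#' @slot generation single non-negative integer.
#'
#' @seealso [emptyLattice()], [randomSoup()], [caStep()]
#' @export
setClass("LatticeState",
  representation(
    occupancy = "matrix",
    lonely = "matrix",
    born = "matrix",
    crowded = "matrix",
    generation = "integer"
  )
)

setValidity("LatticeState", function(object) {
  d <- dim(object@occupancy)
  if (d[1] != d[2]) return("occupancy grid must be square")
  if (d[1] < 3) return("lattice side length must be at least 3")
  for (s in c("lonely", "born", "crowded")) {
    if (!identical(dim(slot(object, s)), d))
      return(sprintf("'%s' grid shape differs from occupancy grid", s))
  }
  occ <- object@occupancy
  if (!all(occ == 0L | occ == 1L)) return("occupancy entries must be 0 or 1")
  if (length(object@generation) != 1L || is.na(object@generation) ||
      object@generation < 0L)
    return("generation must be a single non-negative integer")
  dead <- occ == 0L
  if (any(object@lonely[dead] != 2) || any(object@born[dead] != 3) ||
      any(object@crowded[dead] != 3))
    return("dead sites must carry the wildtype genome (2/3/3)")
  if (object@generation >= 1L) {
    n <- d[1]
    if (any(occ[c(1L, n), ] == 1L) || any(occ[, c(1L, n)] == 1L))
      return("border sites must be dead for generation >= 1")
  }
  TRUE
})

#' MutationParams: the two swept mutation parameters
#'
#' @slot rate probability in \[0, 1\] that a birth event mutates one gene.
#' @slot magnitude non-negative scale factor multiplying the standard
#'   normal perturbation added to the mutated gene.
#'
#' @export
setClass("MutationParams",
  representation(rate = "numeric", magnitude = "numeric")
)

setValidity("MutationParams", function(object) {
  r <- object@rate; m <- object@magnitude
  if (length(r) != 1L || is.na(r) || r < 0 || r > 1)
    return("rate must be a single value in [0, 1]")
  if (length(m) != 1L || is.na(m) || m < 0 || !is.finite(m))
    return("magnitude must be a single finite value >= 0")
  TRUE
})

#' Construct mutation parameters
#'
#' @param rate probability in \[0, 1\] that a new cell birth carries a
#'   mutation (the average fraction of births that mutate).
#' @param magnitude non-negative scalar multiplying a standard normal
#'   deviate to form the additive perturbation applied to one randomly
#'   chosen threshold.
#' @return A [MutationParams-class] object.
#' @examples
#' MutationParams(rate = 0.05, magnitude = 6)
#' @export
MutationParams <- function(rate = 0, magnitude = 1) {
  new("MutationParams", rate = as.numeric(rate),
      magnitude = as.numeric(magnitude))
}

#' RunConfig: configuration of one simulation run
#'
#' Defaults reproduce the reference setup: a 100x100 lattice, a random
#' soup occupying 50% of all lattice nodes, and at most 10,000
#' generations, terminating earlier once the population reaches a steady
#' state.
#'
#' @slot size lattice side length.
#' @slot maxGenerations maximum number of generations before forced
#'   termination.
#' @slot initDensity initial live-cell density in \[0, 1\] of the random
#'   soup (exact count: `round(density * size^2)` live sites).
#' @slot seed integer seed for [runSimulation()]; `NA` means "use the
#'   current RNG state".
#' @slot steadyDetector `"population"` (live-cell count constant over the
#'   window) or `"state"` (occupancy grid periodic with period at most
#'   `maxPeriod` over the window).
#' @slot window number of trailing generations over which constancy or
#'   periodicity must hold.
#' @slot maxPeriod largest oscillator period the state detector accepts.
#' @slot birthRule `"site"` (the genome stored at the empty site decides
#'   a birth; by reset-on-death that genome is always wildtype) or
#'   `"parental"` (a dead site is born if its live-neighbour count equals
#'   the rounded born threshold of at least one live neighbour, and the
#'   parent is drawn among those eligible neighbours).
#' @slot genomeUpdate `"synchronous"` (inheritance reads pre-step genome
#'   grids; order-independent) or `"raster"` (genome grids updated in
#'   place in row-major order, emulating nested-loop implementations).
#' @slot snapshotEvery write a grid snapshot every this many generations
#'   from the CLI (0 = never).
#'
#' @export
setClass("RunConfig",
  representation(
    size = "integer",
    maxGenerations = "integer",
    initDensity = "numeric",
    seed = "integer",
    steadyDetector = "character",
    window = "integer",
    maxPeriod = "integer",
    birthRule = "character",
    genomeUpdate = "character",
    snapshotEvery = "integer"
  )
)

setValidity("RunConfig", function(object) {
  if (object@size < 3L) return("size must be at least 3")
  if (object@maxGenerations < 1L) return("maxGenerations must be positive")
  if (object@initDensity < 0 || object@initDensity > 1)
    return("initDensity must be in [0, 1]")
  if (!object@steadyDetector %in% c("population", "state"))
    return("steadyDetector must be 'population' or 'state'")
  if (object@window < 1L) return("window must be positive")
  if (object@maxPeriod < 1L) return("maxPeriod must be positive")
  if (!object@birthRule %in% c("site", "parental"))
    return("birthRule must be 'site' or 'parental'")
  if (!object@genomeUpdate %in% c("synchronous", "raster"))
    return("genomeUpdate must be 'synchronous' or 'raster'")
  if (object@snapshotEvery < 0L) return("snapshotEvery must be >= 0")
  TRUE
})

#' Construct a run configuration
#'
#' @param size lattice side length (default 100).
#' @param maxGenerations generation cap (default 10000).
#' @param initDensity initial live fraction of the random soup
#'   (default 0.5).
#' @param seed integer seed used by [runSimulation()]; `NA` leaves the
#'   RNG state untouched.
#' @param steadyDetector,window,maxPeriod steady-state detection; see
#'   [detectSteadyState()].
#' @param birthRule,genomeUpdate engine variants; see [caStep()].
#' @param snapshotEvery CLI snapshot cadence in generations (0 = never).
#' @return A [RunConfig-class] object.
#' @examples
#' RunConfig()                  # the reference defaults
#' RunConfig(size = 30, maxGenerations = 500)
#' @export
RunConfig <- function(size = 100, maxGenerations = 10000, initDensity = 0.5,
                      seed = NA_integer_, steadyDetector = "population",
                      window = 25, maxPeriod = 2, birthRule = "site",
                      genomeUpdate = "synchronous", snapshotEvery = 0) {
  new("RunConfig",
      size = as.integer(size), maxGenerations = as.integer(maxGenerations),
      initDensity = as.numeric(initDensity), seed = as.integer(seed),
      steadyDetector = steadyDetector, window = as.integer(window),
      maxPeriod = as.integer(maxPeriod), birthRule = birthRule,
      genomeUpdate = genomeUpdate, snapshotEvery = as.integer(snapshotEvery))
}

#' RunResult: outcome of one simulation run
#'
#' @slot populationTrajectory integer vector of live-cell counts,
#'   one entry per generation starting at generation 0; its length is
#'   `endGeneration + 1`.
#' @slot endGeneration generation at which the run stopped.
#' @slot endPopulation live-cell count of the final state.
#' @slot terminatedBy `"steady_state"` or `"max_generations"`.
#' @slot meanLonely,meanBorn,meanCrowded final threshold means over all
#'   lattice sites (dead sites contribute their wildtype values).
#' @slot finalState the final [LatticeState-class].
#'
#' @export
setClass("RunResult",
  representation(
    populationTrajectory = "integer",
    endGeneration = "integer",
    endPopulation = "integer",
    terminatedBy = "character",
    meanLonely = "numeric",
    meanBorn = "numeric",
    meanCrowded = "numeric",
    finalState = "LatticeState"
  )
)

setValidity("RunResult", function(object) {
  tr <- object@populationTrajectory
  if (length(tr) != object@endGeneration + 1L)
    return("trajectory length must equal endGeneration + 1")
  if (tr[length(tr)] != object@endPopulation)
    return("endPopulation must equal the last trajectory entry")
  if (object@endPopulation != sum(object@finalState@occupancy))
    return("endPopulation must equal the final state's live count")
  if (!object@terminatedBy %in% c("steady_state", "max_generations"))
    return("terminatedBy must be 'steady_state' or 'max_generations'")
  TRUE
})

#' Pattern: a finite Life pattern as a set of live cells
#'
#' Cell coordinates are 0-based `(row, col)` pairs, row-major, origin at
#' the top-left corner — the convention of the RLE and plaintext pattern
#' file formats.
#'
#' @slot name pattern name.
#' @slot width,height bounding-box extents.
#' @slot cells integer matrix with columns `row`, `col` of live-cell
#'   coordinates (0-based).
#'
#' @export
setClass("Pattern",
  representation(
    name = "character",
    width = "integer",
    height = "integer",
    cells = "matrix"
  )
)

setValidity("Pattern", function(object) {
  w <- object@width; h <- object@height
  if (w < 1L || h < 1L) return("width and height must be positive")
  cells <- object@cells
  if (ncol(cells) != 2L) return("cells must have two columns (row, col)")
  if (nrow(cells) > 0) {
    if (any(cells[, 1] < 0L) || any(cells[, 1] >= h) ||
        any(cells[, 2] < 0L) || any(cells[, 2] >= w))
      return("cell coordinates must lie within [0, height) x [0, width)")
    if (anyDuplicated(paste(cells[, 1], cells[, 2])))
      return("duplicate cell coordinates")
  }
  TRUE
})

#' Construct a Pattern from live-cell coordinates
#'
#' @param cells two-column integer matrix of 0-based `(row, col)` live
#'   cell coordinates (row-major, origin top-left), or a matrix with zero
#'   rows for an empty pattern.
#' @param width,height bounding-box extents; default to the smallest box
#'   containing the cells.
#' @param name pattern name.
#' @return A [Pattern-class] object.
#' @examples
#' Pattern(rbind(c(0, 1), c(1, 2), c(2, 0), c(2, 1), c(2, 2)),
#'         name = "glider")
#' @export
Pattern <- function(cells, width = NULL, height = NULL, name = "pattern") {
  cells <- matrix(as.integer(cells), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
  if (is.null(width))
    width <- if (nrow(cells)) max(cells[, 2]) + 1L else 1L
  if (is.null(height))
    height <- if (nrow(cells)) max(cells[, 1]) + 1L else 1L
  ord <- order(cells[, 1], cells[, 2])
  new("Pattern", name = name, width = as.integer(width),
      height = as.integer(height), cells = cells[ord, , drop = FALSE])
}
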