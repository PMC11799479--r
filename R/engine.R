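#' Round half away from zero
#'
#' Threshold values accumulate fractional mutations but the rules are
#' enforced on integers: each threshold is rounded to the nearest integer
#' immediately before rule enforcement, with exact halves rounded away
#' from zero (2.5 -> 3, -0.5 -> -1). Note this differs from base R's
#' [round()], which rounds halves to even.
#'
#' @param x numeric vector of finite values.
#' @return Integer-valued numeric vector of the same length.
#' @examples
#' roundHalfAway(c(3.49, 2.5, -0.5, 3))   # 3 3 -1 3
#' @export
roundHalfAway <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("roundHalfAway() requires finite numeric input")
  sign(x) * floor(abs(x) + 0.5)
}

#' Create an empty (all-dead, all-wildtype) lattice
#'
#' @param size lattice side length (>= 3).
#' @return A [LatticeState-class] at generation 0 with no live cells and
#'   every site at the wildtype genome.
#' @examples
#' emptyLattice(11)
#' @export
emptyLattice <- function(size = 100) {
  size <- as.integer(size)
  if (is.na(size) || size < 3L) stop("size must be an integer >= 3")
  new("LatticeState",
      occupancy = matrix(0L, size, size),
      lonely = matrix(2, size, size),
      born = matrix(3, size, size),
      crowded = matrix(3, size, size),
      generation = 0L)
}

#' Count live Moore neighbours of an interior site
#'
#' @param state a [LatticeState-class].
#' @param site length-2 integer vector `c(row, col)`, 1-based matrix
#'   indices. Must be an interior site: border sites are never evaluated
#'   by the update rule and are rejected here.
#' @return Integer in 0..8.
#' @examples
#' s <- emptyLattice(9)
#' liveNeighborCount(s, c(5, 5))   # 0
#' @export
liveNeighborCount <- function(state, site) {
  n <- latticeSize(state)
  i <- as.integer(site[1]); j <- as.integer(site[2])
  if (i <= 1L || i >= n || j <= 1L || j >= n)
    stop("site must be an interior site (border sites are never evaluated)")
  sum(state@occupancy[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]) -
    state@occupancy[i, j]
}

#' Decide the fate of one site under its rule genome
#'
#' Thresholds are rounded half away from zero before comparison. A live
#' cell survives iff `round(lonely) <= n <= round(crowded)`; otherwise it
#' dies of loneliness or overcrowding. A dead site gives birth iff
#' `n == round(born)`.
#'
#' @param alive logical; is the site currently occupied?
#' @param n live Moore-neighbour count, 0..8.
#' @param genome numeric vector of the three thresholds in the order
#'   lonely, born, crowded (see [wildtypeGenome()]).
#' @return One of `"survive"`, `"die"`, `"born"`, `"stay_dead"`.
#' @examples
#' cellFate(TRUE, 1, wildtypeGenome())            # "die" (loneliness)
#' cellFate(FALSE, 3, wildtypeGenome())           # "born"
#' cellFate(TRUE, 5, c(2, 3, 5.4))                # "survive" (5.4 -> 5)
#' @export
cellFate <- function(alive, n, genome) {
  stopifnot(length(genome) == 3, n >= 0, n <= 8)
  if (alive) {
    if (n >= roundHalfAway(genome[[1]]) && n <= roundHalfAway(genome[[3]]))
      "survive" else "die"
  } else {
    if (n == roundHalfAway(genome[[2]])) "born" else "stay_dead"
  }
}

#' Choose a parent uniformly among candidate neighbours
#'
#' Used at each birth: one live Moore neighbour is selected uniformly at
#' random and its current genome is passed to the newborn cell. The
#' index is drawn as `floor(k * runif(1))`, the same primitive the C++
#' engine uses, so R-level and engine-level choices are reproducible
#' from the same seed.
#'
#' @param sites matrix of candidate coordinates, one row per candidate
#'   (any number of columns); must be non-empty.
#' @return The selected row, as a vector.
#' @examples
#' set.seed(1)
#' chooseParent(rbind(c(2, 2), c(2, 3), c(3, 2)))
#' @export
chooseParent <- function(sites) {
  sites <- rbind(sites)
  k <- nrow(sites)
  if (k == 0L) stop("chooseParent() requires at least one candidate")
  idx <- min(floor(k * runif(1)), k - 1) + 1
  sites[idx, ]
}

#' Inherit a genome with possible mutation
#'
#' The child starts as an exact copy of the parent genome. With
#' probability `rate` (a uniform deviate compared against the rate),
#' exactly one of the three genes, chosen uniformly, receives an additive
#' perturbation `delta = magnitude * z` with `z` standard normal.
#' Draw order is fixed: mutation gate, then gene index, then the normal
#' deviate; unmutated births consume only the gate draw.
#'
#' @param parent numeric length-3 genome (lonely, born, crowded).
#' @param params a [MutationParams-class].
#' @return List with elements `child` (length-3 named numeric),
#'   `mutated` (logical), `gene` (`"lonely"`, `"born"`, `"crowded"` or
#'   `NA`), `delta` (numeric, 0 when unmutated).
#' @examples
#' set.seed(1)
#' inheritAndMutate(wildtypeGenome(), MutationParams(rate = 1, magnitude = 2))
#' @export
inheritAndMutate <- function(parent, params) {
  stopifnot(is(params, "MutationParams"), length(parent) == 3)
  child <- as.numeric(parent)
  names(child) <- c("lonely", "born", "crowded")
  mutated <- runif(1) < params@rate
  gene <- NA_character_
  delta <- 0
  if (mutated) {
    g <- min(floor(3 * runif(1)), 2) + 1
    delta <- params@magnitude * rnorm(1)
    child[g] <- child[g] + delta
    gene <- names(child)[g]
  }
  list(child = child, mutated = mutated, gene = gene, delta = delta)
}

## internal raw-matrix step; `raw` is list(occupancy, lonely, born, crowded)
.stepRaw <- function(raw, rate, magnitude, birthRule, genomeUpdate,
                     events = FALSE) {
  lifeStepCpp(raw$occupancy, raw$lonely, raw$born, raw$crowded,
              rate, magnitude,
              parentalBirth = identical(birthRule, "parental"),
              rasterGenome = identical(genomeUpdate, "raster"),
              collectEvents = events)
}

#' Advance the lattice by one generation
#'
#' Performs one synchronous update: all fates are computed from the
#' pre-step occupancy and genomes; the next occupancy buffer starts
#' all-dead and only interior sites are written, so border sites are
#' dead from generation 1 on (the model's substitute for a boundary
#' condition). Each birth site inherits the genome of a uniformly chosen
#' live neighbour, possibly mutated (see [inheritAndMutate()]); each
#' death site has its genome reset to wildtype. Births are processed in
#' row-major site order with a fixed per-birth RNG draw sequence
#' (parent index, mutation gate, then gene index and normal deviate if
#' mutated), so trajectories are reproducible from a seed.
#'
#' @param state a [LatticeState-class].
#' @param params a [MutationParams-class].
#' @param birthRule `"site"` (default): the genome stored at the empty
#'   site decides the birth; since dead sites are always wildtype this
#'   makes the born gene inert at decision time. `"parental"`: a dead
#'   site is born if its live-neighbour count equals the rounded born
#'   threshold of at least one live neighbour; the parent is chosen
#'   among those eligible neighbours (with no eligible parent the child
#'   is wildtype and no mutation occurs).
#' @param genomeUpdate `"synchronous"` (default; inheritance reads
#'   pre-step grids) or `"raster"` (genome grids updated in place in
#'   row-major order).
#' @param events if `TRUE`, also return per-event records.
#' @return When `events = FALSE` (default) the next [LatticeState-class].
#'   Otherwise a list with elements `state`, `births` (data frame: site,
#'   parent site, mutated flag, mutated gene 1/2/3 =
#'   lonely/born/crowded, delta) and `deaths` (data frame of sites);
#'   coordinates are 1-based matrix indices.
#' @examples
#' set.seed(1)
#' s <- randomSoup(20, 0.5)
#' s1 <- caStep(s, MutationParams(0.1, 1))
#' generation(s1)
#' @export
caStep <- function(state, params, birthRule = c("site", "parental"),
                   genomeUpdate = c("synchronous", "raster"),
                   events = FALSE) {
  stopifnot(is(state, "LatticeState"), is(params, "MutationParams"))
  birthRule <- match.arg(birthRule)
  genomeUpdate <- match.arg(genomeUpdate)
  res <- .stepRaw(
    list(occupancy = state@occupancy, lonely = state@lonely,
         born = state@born, crowded = state@crowded),
    params@rate, params@magnitude, birthRule, genomeUpdate, events)
  nxt <- new("LatticeState", occupancy = res$occupancy,
             lonely = res$lonely, born = res$born, crowded = res$crowded,
             generation = state@generation + 1L)
  if (!events) return(nxt)
  births <- res$births
  births$mutated <- as.logical(births$mutated)
  list(state = nxt, births = births, deaths = res$deaths)
}
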