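#' Reference parameter grids of the sweep
#'
#' The mutation rates and magnitudes systematically varied in the sweep
#' experiments: rates 0, 0.01, 0.05, 0.1, 0.2, 0.4, 1.0 and magnitudes
#' 0.25, 0.5, 0.75, 1.0, 1.5, 2, 3, 4, 5, 6, 10.
#'
#' @return Numeric vector of grid values.
#' @examples
#' length(defaultRates()) * length(defaultMagnitudes())   # 77 cells
#' @export
defaultRates <- function() c(0, 0.01, 0.05, 0.1, 0.2, 0.4, 1.0)

#' @rdname defaultRates
#' @export
defaultMagnitudes <- function() c(0.25, 0.5, 0.75, 1.0, 1.5, 2, 3, 4, 5, 6, 10)

## deterministic per-cell seed below 2^31, derived from the base seed and
## the (rate, magnitude, replicate) indices
deriveSeed <- function(baseSeed, rateIdx, magIdx, rep) {
  as.integer((as.double(baseSeed) * 1009 + rateIdx * 7919 +
                magIdx * 104729 + rep * 1299709) %% 2147483647)
}

#' Run a mutation-rate x mutation-magnitude parameter sweep
#'
#' Performs one independent simulation per (rate, magnitude, replicate)
#' cell with a deterministic seed derived from `baseSeed` and the cell
#' indices, at the configuration's lattice size, density and termination
#' settings. Rows appear in deterministic order (rate, then magnitude,
#' then replicate).
#'
#' @param rates,magnitudes non-empty numeric grids (defaults:
#'   [defaultRates()], [defaultMagnitudes()]).
#' @param replicates runs per cell (>= 1).
#' @param baseSeed integer base seed.
#' @param config a [RunConfig-class] giving lattice size, density and
#'   termination settings for every run.
#' @return Data frame with columns `rate`, `magnitude`, `replicate`,
#'   `seed`, `end_generation`, `end_population`, `occupancy_pct`
#'   (100 x end_population / size^2), `mean_lonely`, `mean_born`,
#'   `mean_crowded`, `terminated_by` — one row per run.
#' @examples
#' tab <- runSweep(rates = 0, magnitudes = 1, baseSeed = 1,
#'                 config = RunConfig(size = 30, maxGenerations = 200))
#' tab$mean_crowded   # exactly 3: no mutation
#' @export
runSweep <- function(rates = defaultRates(), magnitudes = defaultMagnitudes(),
                     replicates = 1, baseSeed = 1, config = RunConfig()) {
  if (length(rates) == 0 || length(magnitudes) == 0)
    stop("rates and magnitudes must be non-empty")
  if (replicates < 1) stop("replicates must be >= 1")
  rows <- vector("list", length(rates) * length(magnitudes) * replicates)
  n2 <- as.double(config@size)^2
  k <- 0L
  for (ri in seq_along(rates)) {
    for (mi in seq_along(magnitudes)) {
      for (rep in seq_len(replicates)) {
        seed <- deriveSeed(baseSeed, ri, mi, rep)
        set.seed(seed)
        res <- simulateRun(randomSoup(config@size, config@initDensity),
                           MutationParams(rates[ri], magnitudes[mi]), config)
        k <- k + 1L
        rows[[k]] <- data.frame(
          rate = rates[ri], magnitude = magnitudes[mi], replicate = rep,
          seed = seed,
          end_generation = endGeneration(res),
          end_population = endPopulation(res),
          occupancy_pct = 100 * endPopulation(res) / n2,
          mean_lonely = res@meanLonely,
          mean_born = res@meanBorn,
          mean_crowded = res@meanCrowded,
          terminated_by = terminatedBy(res))
      }
    }
  }
  do.call(rbind, rows)
}

#' Ash density of the classic (no-mutation) Game of Life
#'
#' Runs `replicates` independent rate-0 simulations from random soups and
#' summarises the final occupancy: classic Life ash settles to a sparse
#' debris of still lifes and oscillators occupying a few percent of the
#' lattice.
#'
#' @param replicates number of runs (>= 2).
#' @param baseSeed integer base seed.
#' @param config a [RunConfig-class].
#' @return Named numeric vector `c(mean_pct, sd_pct)` of the final
#'   occupancy percentage over the runs.
#' @examples
#' ashDensity(2, baseSeed = 1,
#'            config = RunConfig(size = 30, maxGenerations = 400))
#' @export
ashDensity <- function(replicates = 10, baseSeed = 1, config = RunConfig()) {
  if (replicates < 2) stop("replicates must be >= 2")
  tab <- runSweep(rates = 0, magnitudes = 1, replicates = replicates,
                  baseSeed = baseSeed, config = config)
  c(mean_pct = mean(tab$occupancy_pct), sd_pct = sd(tab$occupancy_pct))
}

#' Maximum occupancy over a sweep table
#'
#' @param table a sweep data frame from [runSweep()].
#' @return Largest `occupancy_pct` over the rows.
#' @examples
#' maxOccupancy(data.frame(occupancy_pct = c(2.5, 59, 30)))
#' @export
maxOccupancy <- function(table) {
  if (is.null(table) || nrow(table) == 0) stop("empty sweep table")
  max(table$occupancy_pct)
}

#' Critical mutation magnitude of the growth transition
#'
#' The transition to dense, tumour-like growth is operationalised as a
#' final occupancy of at least `occupancyThresholdPct` percent of the
#' lattice — an order of magnitude above the ~3% classic ash density and
#' well below the ~59% packing ceiling. The critical magnitude is the
#' smallest magnitude on the swept grid at which at least one run crossed
#' that threshold.
#'
#' @param table a sweep data frame from [runSweep()].
#' @param occupancyThresholdPct occupancy percentage defining
#'   "tumour-like growth" (default 20).
#' @return The smallest qualifying magnitude, or `NA` if no magnitude
#'   qualifies.
#' @examples
#' tab <- data.frame(magnitude = c(0.25, 0.5, 1), occupancy_pct = c(3, 45, 55))
#' criticalMagnitude(tab)   # 0.5
#' @export
criticalMagnitude <- function(table, occupancyThresholdPct = 20) {
  if (is.null(table) || nrow(table) == 0) stop("empty sweep table")
  hit <- table$magnitude[table$occupancy_pct >= occupancyThresholdPct]
  if (length(hit) == 0) return(NA_real_)
  min(hit)
}
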