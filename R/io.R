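## CSV grid dumps. One file per grid, no headers or row names; values are
## written row-by-row exactly as the matrices are laid out (row-major,
## origin top-left, 0-based in the file in the sense that the first CSV
## line is lattice row 0). Thresholds are written at full precision (15
## significant digits).

.gridFiles <- c(occupancy = "occupancy.csv", lonely = "lonely.csv",
                born = "born.csv", crowded = "crowded.csv")

#' Write a lattice state as four CSV grid files
#'
#' Writes `occupancy.csv` (integers) and `lonely.csv`, `born.csv`,
#' `crowded.csv` (reals, 15 significant digits) into `dir`, each a
#' `size x size` comma-separated grid with no header.
#'
#' @param state a [LatticeState-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [readLatticeCSV()]
#' @examples
#' d <- tempfile(); writeLatticeCSV(emptyLattice(5), d); dir(d)
#' @export
writeLatticeCSV <- function(state, dir) {
  stopifnot(is(state, "LatticeState"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(state@occupancy, file.path(dir, .gridFiles["occupancy"]),
              sep = ",", row.names = FALSE, col.names = FALSE)
  for (s in c("lonely", "born", "crowded")) {
    m <- slot(state, s)
    storage.mode(m) <- "character"
    m[] <- formatC(as.numeric(m), digits = 15, format = "g")
    write.table(m, file.path(dir, .gridFiles[s]), sep = ",",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a lattice state from four CSV grid files
#'
#' Inverse of [writeLatticeCSV()]: bit-exact for occupancy, to 15
#' significant digits for the threshold grids.
#'
#' @param dir directory containing `occupancy.csv`, `lonely.csv`,
#'   `born.csv`, `crowded.csv`.
#' @param generation generation counter to stamp on the restored state
#'   (the grid files do not carry it; default 0).
#' @return A [LatticeState-class].
#' @export
readLatticeCSV <- function(dir, generation = 0) {
  readGrid <- function(f, mode) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing grid file: ", path)
    m <- as.matrix(read.table(path, sep = ",", header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- mode
    m
  }
  occ <- readGrid(.gridFiles["occupancy"], "integer")
  if (nrow(occ) != ncol(occ)) stop("occupancy grid is not square")
  grids <- lapply(c("lonely", "born", "crowded"), function(s)
    readGrid(.gridFiles[s], "double"))
  for (g in grids)
    if (!identical(dim(g), dim(occ)))
      stop("grid files have mismatched shapes")
  new("LatticeState", occupancy = occ, lonely = grids[[1]],
      born = grids[[2]], crowded = grids[[3]],
      generation = as.integer(generation))
}

#' Write a population trajectory as CSV
#'
#' Two columns, `generation` (starting at 0) and `population`.
#'
#' @param result a [RunResult-class] or an integer vector of populations
#'   (generation 0 first).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeTrajectoryCSV <- function(result, file) {
  pop <- if (is(result, "RunResult")) trajectory(result) else as.integer(result)
  df <- data.frame(generation = seq_along(pop) - 1L, population = pop)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a sweep table as CSV
#'
#' Fixed header: rate, magnitude, replicate, seed, end_generation,
#' end_population, occupancy_pct, mean_lonely, mean_born, mean_crowded,
#' terminated_by.
#'
#' @param table a data frame from [runSweep()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSweepCSV <- function(table, file) {
  cols <- c("rate", "magnitude", "replicate", "seed", "end_generation",
            "end_population", "occupancy_pct", "mean_lonely", "mean_born",
            "mean_crowded", "terminated_by")
  stopifnot(all(cols %in% names(table)))
  write.csv(table[, cols], file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an initial pattern or grid from a file
#'
#' Dispatches on the file extension: `.rle` ([parseRLE()]), `.cells`
#' ([parsePlaintext()]), or `.csv` (a 0/1 occupancy grid, converted to a
#' pattern containing its live cells).
#'
#' @param path file path.
#' @return A [Pattern-class].
#' @export
readPatternFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  txt <- readLines(path, warn = FALSE)
  if (ext == "rle") return(parseRLE(txt))
  if (ext == "cells") return(parsePlaintext(txt))
  if (ext == "csv") {
    m <- as.matrix(read.table(path, sep = ",", header = FALSE))
    if (!all(m %in% c(0, 1))) stop("CSV grid must contain only 0/1")
    live <- which(m == 1, arr.ind = TRUE)
    return(Pattern(cbind(live[, 1] - 1L, live[, 2] - 1L),
                   width = ncol(m), height = nrow(m),
                   name = sub("\\.[^.]*$", "", basename(path))))
  }
  stop("unsupported pattern format: .", ext,
       " (expected .rle, .cells or .csv)")
}
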