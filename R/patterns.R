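## Pattern file formats. Coordinates are 0-based (row, col), row-major,
## origin top-left — the convention shared by the RLE and plaintext
## community formats.

#' Parse a run-length-encoded (RLE) Life pattern
#'
#' Accepts the common RLE dialect: optional `#` comment lines, a header
#' line `x = <w>, y = <h>` with an optional `, rule = B3/S23`, then a
#' body of run counts over `b` (dead), `o` (alive) and `$` (end of row),
#' terminated by `!`. Row remainders left unfilled are dead.
#'
#' @param text character: either a single string (possibly multi-line) or
#'   a vector of lines.
#' @param name pattern name (defaults to the first `#N` comment, if any).
#' @return A [Pattern-class].
#' @examples
#' parseRLE("x = 3, y = 3\nbob$2bo$3o!")   # the glider, 5 live cells
#' @export
parseRLE <- function(text, name = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  nameFromComment <- NULL
  headerAt <- 0L
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      if (startsWith(ln, "#N") && is.null(nameFromComment))
        nameFromComment <- trimws(sub("^#N", "", ln))
      next
    }
    headerAt <- k
    break
  }
  if (headerAt == 0L) stop("RLE format error: missing header line")
  hdr <- lines[headerAt]
  m <- regmatches(hdr, regexec(
    "^\\s*x\\s*=\\s*(\\d+)\\s*,\\s*y\\s*=\\s*(\\d+)\\s*(,\\s*rule\\s*=\\s*\\S+\\s*)?$",
    hdr, ignore.case = TRUE))[[1]]
  if (length(m) == 0)
    stop(sprintf("RLE format error at line %d: malformed header '%s'",
                 headerAt, hdr))
  w <- as.integer(m[2]); h <- as.integer(m[3])

  rows <- integer(0); cols <- integer(0)
  r <- 0L; cpos <- 0L
  count <- 0L
  done <- FALSE
  for (k in seq(headerAt + 1L, length.out = max(0L, length(lines) - headerAt))) {
    if (done) break
    chars <- strsplit(lines[k], "")[[1]]
    for (ci in seq_along(chars)) {
      ch <- chars[ci]
      if (ch %in% c(" ", "\t", "\r")) next
      if (grepl("^[0-9]$", ch)) {
        count <- count * 10L + as.integer(ch)
      } else if (ch == "b" || ch == "o") {
        n <- if (count == 0L) 1L else count
        if (ch == "o") {
          if (r >= h || cpos + n > w)
            stop(sprintf(
              "RLE format error at line %d, column %d: cells exceed declared extents",
              k, ci))
          rows <- c(rows, rep.int(r, n))
          cols <- c(cols, cpos + seq_len(n) - 1L)
        }
        cpos <- cpos + n
        count <- 0L
      } else if (ch == "$") {
        n <- if (count == 0L) 1L else count
        r <- r + n
        cpos <- 0L
        count <- 0L
      } else if (ch == "!") {
        done <- TRUE
        break
      } else {
        stop(sprintf("RLE format error at line %d, column %d: unknown character '%s'",
                     k, ci, ch))
      }
    }
  }
  if (!done) stop("RLE format error: missing '!' terminator")
  if (is.null(name))
    name <- if (!is.null(nameFromComment)) nameFromComment else "pattern"
  Pattern(cbind(rows, cols), width = w, height = h, name = name)
}

#' Write a pattern as RLE text
#'
#' Emits a header with `rule = B3/S23` and a body that [parseRLE()]
#' inverts exactly.
#'
#' @param pattern a [Pattern-class].
#' @return A single RLE string (with trailing newline).
#' @examples
#' cat(writeRLE(builtinPatterns()$glider))
#' @export
writeRLE <- function(pattern) {
  stopifnot(is(pattern, "Pattern"))
  w <- pattern@width; h <- pattern@height
  cells <- pattern@cells
  enc <- function(n, ch) if (n == 1L) ch else paste0(n, ch)
  encodeRow <- function(r) {
    cc <- sort(cells[cells[, 1] == r, 2])
    if (length(cc) == 0L) return("")
    runs <- character(0)
    pos <- 0L
    i <- 1L
    while (i <= length(cc)) {
      j <- i
      while (j < length(cc) && cc[j + 1L] == cc[j] + 1L) j <- j + 1L
      if (cc[i] > pos) runs <- c(runs, enc(cc[i] - pos, "b"))
      runs <- c(runs, enc(j - i + 1L, "o"))
      pos <- cc[j] + 1L
      i <- j + 1L
    }
    paste(runs, collapse = "")
  }
  rowsEnc <- vapply(seq_len(h) - 1L, encodeRow, "")
  last <- if (nrow(cells)) max(cells[, 1]) + 1L else 0L
  if (last == 0L) {
    body <- "b!"   # fully empty pattern
  } else {
    body <- ""
    gap <- 0L      # pending row terminators
    for (r in seq_len(last)) {
      if (rowsEnc[r] == "") {
        gap <- gap + 1L
        next
      }
      if (gap > 0L) body <- paste0(body, enc(gap, "$"))
      body <- paste0(body, rowsEnc[r])
      gap <- 1L    # terminator owed after this content row
    }
    body <- paste0(body, "!")
  }
  ## wrap body lines at 70 characters, the customary limit
  body <- paste(regmatches(body, gregexpr(".{1,70}", body))[[1]],
                collapse = "\n")
  paste0(sprintf("#N %s\nx = %d, y = %d, rule = B3/S23\n", pattern@name, w, h),
         body, "\n")
}

#' Parse a plaintext (.cells) Life pattern
#'
#' Convention: `!` lines are comments, `.` is dead, `O` is alive. Ragged
#' rows are padded dead on the right.
#'
#' @param text single string or vector of lines.
#' @param name pattern name (defaults to the first `!Name:` comment).
#' @return A [Pattern-class].
#' @examples
#' parsePlaintext(".O.\n..O\nOOO")   # the glider
#' @export
parsePlaintext <- function(text, name = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  nm <- NULL
  body <- character(0)
  for (ln in lines) {
    if (startsWith(trimws(ln), "!")) {
      if (is.null(nm) && grepl("^!\\s*Name\\s*:", ln, ignore.case = TRUE))
        nm <- trimws(sub("^!\\s*Name\\s*:", "", ln, ignore.case = TRUE))
      next
    }
    body <- c(body, sub("\\s+$", "", ln))
  }
  while (length(body) && body[length(body)] == "") body <- body[-length(body)]
  if (length(body) == 0) stop("plaintext format error: no body rows")
  rows <- integer(0); cols <- integer(0)
  for (r in seq_along(body)) {
    chars <- strsplit(body[r], "")[[1]]
    bad <- which(!chars %in% c(".", "O"))
    if (length(bad))
      stop(sprintf("plaintext format error at row %d, column %d: character '%s'",
                   r, bad[1], chars[bad[1]]))
    live <- which(chars == "O")
    rows <- c(rows, rep.int(r - 1L, length(live)))
    cols <- c(cols, live - 1L)
  }
  w <- max(nchar(body), 1L)
  if (is.null(name)) name <- if (!is.null(nm)) nm else "pattern"
  Pattern(cbind(rows, cols), width = w, height = length(body), name = name)
}

#' Write a pattern as plaintext (.cells)
#'
#' @param pattern a [Pattern-class].
#' @return A single string that [parsePlaintext()] inverts.
#' @examples
#' cat(writePlaintext(builtinPatterns()$blinker))
#' @export
writePlaintext <- function(pattern) {
  stopifnot(is(pattern, "Pattern"))
  grid <- matrix(".", pattern@height, pattern@width)
  if (nrow(pattern@cells))
    grid[pattern@cells + 1L] <- "O"
  paste0(sprintf("!Name: %s\n", pattern@name),
         paste(apply(grid, 1, paste, collapse = ""), collapse = "\n"), "\n")
}

#' Place a pattern onto a lattice
#'
#' Sets the pattern's live cells into the lattice with the pattern's
#' top-left corner at 1-based matrix position `(top, left)`. All placed
#' sites keep the genome already stored there (wildtype on a fresh
#' lattice); other sites are unchanged. The pattern must fit strictly
#' inside the interior: border sites are never evaluated by the update
#' rule, so live border cells could never act.
#'
#' @param pattern a [Pattern-class].
#' @param state a [LatticeState-class].
#' @param top,left 1-based matrix indices of the pattern's top-left
#'   bounding-box corner.
#' @return The modified [LatticeState-class].
#' @examples
#' s <- placePattern(builtinPatterns()$glider, emptyLattice(30), 2, 2)
#' population(s)   # 5
#' @export
placePattern <- function(pattern, state, top, left) {
  stopifnot(is(pattern, "Pattern"), is(state, "LatticeState"))
  n <- latticeSize(state)
  top <- as.integer(top); left <- as.integer(left)
  if (top < 2L || left < 2L || top + pattern@height - 1L > n - 1L ||
      left + pattern@width - 1L > n - 1L)
    stop("pattern must fit within the lattice interior (not touch the border)")
  occ <- state@occupancy
  if (nrow(pattern@cells))
    occ[cbind(pattern@cells[, 1] + top, pattern@cells[, 2] + left)] <- 1L
  state@occupancy <- occ
  validObject(state)
  state
}

#' Centre a pattern on a fresh lattice
#'
#' @param pattern a [Pattern-class].
#' @param size lattice side length.
#' @return A generation-0 [LatticeState-class] with the pattern centred.
#' @examples
#' population(latticeFromPattern(builtinPatterns()$blinker, 11))
#' @export
latticeFromPattern <- function(pattern, size = 100) {
  size <- as.integer(size)
  top <- max(2L, (size - pattern@height) %/% 2L + 1L)
  left <- max(2L, (size - pattern@width) %/% 2L + 1L)
  placePattern(pattern, emptyLattice(size), top, left)
}

#' Built-in library of classic Life patterns
#'
#' The classic fixtures used throughout the test suite: the block (4
#' cells, stable), blinker (3 cells, period 2), toad (6 cells, period 2),
#' glider (5 cells, moves (1,1) every 4 generations), Gosper glider gun
#' (36 cells, emits a glider every 30 generations) and the r-pentomino
#' (5 cells, long-lived methuselah).
#'
#' @return Named list of [Pattern-class] objects.
#' @examples
#' vapply(builtinPatterns(), function(p) nrow(patternCells(p)), 1L)
#' @export
builtinPatterns <- function() {
  list(
    block = parseRLE("x = 2, y = 2\n2o$2o!", name = "block"),
    blinker = parseRLE("x = 3, y = 1\n3o!", name = "blinker"),
    toad = parseRLE("x = 4, y = 2\nb3o$3o!", name = "toad"),
    glider = parseRLE("x = 3, y = 3\nbob$2bo$3o!", name = "glider"),
    gosperGliderGun = parseRLE(paste0(
      "x = 36, y = 9\n",
      "24bo$22bobo$12b2o6b2o12b2o$11bo3bo4b2o12b2o$2o8bo5bo3b2o$2o8bo3b\n",
      "ob2o4bobo$10bo5bo7bo$11bo3bo$12b2o!"), name = "gosperGliderGun"),
    rPentomino = parseRLE("x = 3, y = 3\nb2o$2o$bo!", name = "rPentomino")
  )
}
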