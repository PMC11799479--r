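test_that("RLE parsing matches the format's canonical examples", {
  g <- parseRLE("x = 3, y = 3\nbob$2bo$3o!")
  expect_equal(nrow(patternCells(g)), 5)
  expect_equal(patternCells(g),
               matrix(c(0L, 1L, 2L, 2L, 2L, 1L, 2L, 0L, 1L, 2L), ncol = 2,
                      dimnames = list(NULL, c("row", "col"))))
  two <- parseRLE("x = 2, y = 1\n2o!")
  expect_equal(unname(patternCells(two)), rbind(c(0L, 0L), c(0L, 1L)))
  # counts may span wrapped lines, comments and rule headers are accepted
  wrapped <- parseRLE("#N demo\n#C a comment\nx = 5, y = 1, rule = B3/S23\n5\no!")
  expect_equal(nrow(patternCells(wrapped)), 5)
  expect_equal(patternName(wrapped), "demo")
})

test_that("malformed RLE input is rejected with located errors", {
  expect_error(parseRLE("bob$2bo$3o!"), "header")
  expect_error(parseRLE("x = 3, y = 3\nbob$2bo$3o"), "terminator")
  expect_error(parseRLE("x = 3, y = 3\nbob$2bo$4o!"), "extents")
  expect_error(parseRLE("x = 3, y = 3\nbob$2bo$3z!"), "unknown character")
  expect_error(parseRLE("x = 2, y = 1\n3o!"), "extents")
})

test_that("plaintext parsing handles ragged rows and comments", {
  g <- parsePlaintext(".O.\n..O\nOOO")
  expect_equal(nrow(patternCells(g)), 5)
  expect_identical(patternCells(g),
                   patternCells(parseRLE("x = 3, y = 3\nbob$2bo$3o!")))
  blk <- parsePlaintext("!Name: block\nOO\nOO")
  expect_equal(nrow(patternCells(blk)), 4)
  expect_equal(patternName(blk), "block")
  ragged <- parsePlaintext("O\n..O")
  expect_equal(unname(patternCells(ragged)), rbind(c(0L, 0L), c(1L, 2L)))
  expect_error(parsePlaintext("!only a comment"), "no body")
  expect_error(parsePlaintext("OXO"), "character")
})

test_that("every library pattern round-trips through both formats", {
  lib <- builtinPatterns()
  expect_true(all(c("block", "blinker", "toad", "glider", "gosperGliderGun",
                    "rPentomino") %in% names(lib)))
  counts <- vapply(lib, function(p) nrow(patternCells(p)), 1L)
  expect_equal(unname(counts[c("block", "blinker", "toad", "glider",
                               "gosperGliderGun", "rPentomino")]),
               c(4L, 3L, 6L, 5L, 36L, 5L))
  for (p in lib) {
    expect_identical(patternCells(parseRLE(writeRLE(p))), patternCells(p))
    expect_identical(patternCells(parsePlaintext(writePlaintext(p))),
                     patternCells(p))
  }
  # an empty pattern survives the RLE round trip too
  empt <- Pattern(matrix(integer(0), 0, 2), width = 1, height = 1)
  expect_equal(nrow(patternCells(parseRLE(writeRLE(empt)))), 0)
})

test_that("library patterns show their canonical dynamics", {
  p0 <- MutationParams(0, 1)
  lib <- builtinPatterns()
  # block is a still life
  blk <- latticeFromPattern(lib$block, 10)
  expect_identical(occupancy(caStep(blk, p0)), occupancy(blk))
  # toad has period 2
  toad <- latticeFromPattern(lib$toad, 12)
  expect_identical(occupancy(caStep(caStep(toad, p0), p0)), occupancy(toad))
  expect_false(identical(occupancy(caStep(toad, p0)), occupancy(toad)))
  # the gun emits one five-cell glider every 30 generations
  gun <- placePattern(lib$gosperGliderGun, emptyLattice(60), 3, 3)
  s <- gun
  pops <- integer(0)
  for (g in 1:61) {
    s <- caStep(s, p0)
    pops <- c(pops, population(s))
  }
  expect_equal(pops[30], 36 + 5)
  expect_equal(pops[60], 36 + 10)
})

test_that("patterns are placed in the interior only, and placements commute", {
  lib <- builtinPatterns()
  s <- placePattern(lib$glider, emptyLattice(30), 2, 2)
  expect_equal(population(s), 5)
  expect_error(placePattern(lib$glider, emptyLattice(30), 1, 5), "interior")
  expect_error(placePattern(lib$glider, emptyLattice(30), 28, 5), "interior")
  ab <- placePattern(lib$block, placePattern(lib$blinker, emptyLattice(20),
                                             3, 3), 10, 10)
  ba <- placePattern(lib$blinker, placePattern(lib$block, emptyLattice(20),
                                               10, 10), 3, 3)
  expect_identical(occupancy(ab), occupancy(ba))
})

test_that("grid CSV dumps invert bit-exactly", {
  set.seed(6)
  s <- randomSoup(15, 0.4)
  p <- MutationParams(0.5, 1.7)
  for (i in 1:10) s <- caStep(s, p)
  d <- tempfile("grids")
  writeLatticeCSV(s, d)
  r <- readLatticeCSV(d, generation = generation(s))
  expect_identical(occupancy(r), occupancy(s))
  expect_equal(lonelyGrid(r), lonelyGrid(s), tolerance = 1e-14)
  expect_equal(bornGrid(r), bornGrid(s), tolerance = 1e-14)
  expect_equal(crowdedGrid(r), crowdedGrid(s), tolerance = 1e-14)
  expect_equal(generation(r), generation(s))
  # all-dead lattice writes constants
  d2 <- tempfile("grids")
  writeLatticeCSV(emptyLattice(5), d2)
  lon <- as.matrix(read.table(file.path(d2, "lonely.csv"), sep = ","))
  expect_true(all(lon == 2))
  # shape mismatch between the four files is an error
  writeLines("0,0,0", file.path(d2, "occupancy.csv"))
  expect_error(readLatticeCSV(d2), "square|mismatch")
})

test_that("pattern files are dispatched on extension", {
  d <- tempfile(fileext = ".rle")
  writeLines(writeRLE(builtinPatterns()$toad), d)
  expect_equal(nrow(patternCells(readPatternFile(d))), 6)
  d2 <- tempfile(fileext = ".cells")
  writeLines(writePlaintext(builtinPatterns()$glider), d2)
  expect_equal(nrow(patternCells(readPatternFile(d2))), 5)
  d3 <- tempfile(fileext = ".csv")
  writeLines(c("0,1,0", "0,0,1", "1,1,1"), d3)
  expect_identical(patternCells(readPatternFile(d3)),
                   patternCells(builtinPatterns()$glider))
  mat <- tempfile(fileext = ".mat")
  file.create(mat)
  expect_error(readPatternFile(mat), "unsupported")
  expect_error(readPatternFile(tempfile(fileext = ".rle")), "no such file")
})
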