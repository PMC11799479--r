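test_that("threshold rounding is half-away-from-zero", {
  expect_equal(roundHalfAway(3.49), 3)
  expect_equal(roundHalfAway(2.5), 3)
  expect_equal(roundHalfAway(-0.5), -1)
  expect_equal(roundHalfAway(3.0), 3)
  expect_equal(roundHalfAway(c(-2.5, -1.2, 0, 0.5, 7.5)), c(-3, -1, 0, 1, 8))
  expect_error(roundHalfAway(NaN), "finite")
  expect_error(roundHalfAway(Inf), "finite")
})

test_that("live neighbour counting covers the Moore neighbourhood", {
  s <- emptyLattice(9)
  expect_equal(liveNeighborCount(s, c(5, 5)), 0)
  # full 3x3 block around the centre
  occ <- occupancy(s); occ[4:6, 4:6] <- 1L
  s@occupancy <- occ
  expect_equal(liveNeighborCount(s, c(5, 5)), 8)
  # middle of a horizontal blinker sees its two flank cells
  b <- latticeFromPattern(builtinPatterns()$blinker, 9)
  mid <- which(occupancy(b) == 1L, arr.ind = TRUE)[2, ]
  expect_equal(liveNeighborCount(b, mid), 2)
  expect_error(liveNeighborCount(s, c(1, 5)), "interior")
  expect_error(liveNeighborCount(s, c(5, 9)), "interior")
})

test_that("cell fate follows the rounded per-site thresholds", {
  wt <- wildtypeGenome()
  expect_equal(cellFate(TRUE, 1, wt), "die")          # loneliness
  expect_equal(cellFate(TRUE, 2, wt), "survive")
  expect_equal(cellFate(TRUE, 3, wt), "survive")
  expect_equal(cellFate(TRUE, 4, wt), "die")          # overcrowding
  expect_equal(cellFate(FALSE, 3, wt), "born")
  expect_equal(cellFate(FALSE, 2, wt), "stay_dead")
  # mutated genomes are rounded before enforcement
  expect_equal(cellFate(TRUE, 5, c(2, 3, 5.4)), "survive")
  expect_equal(cellFate(TRUE, 6, c(2, 3, 5.4)), "die")
  expect_equal(cellFate(FALSE, 3, c(2, 3.6, 3)), "stay_dead")
  expect_equal(cellFate(FALSE, 4, c(2, 3.6, 3)), "born")
})

test_that("parent choice is uniform and seed-reproducible", {
  cand <- rbind(c(2, 2), c(2, 3), c(3, 2))
  set.seed(99)
  one <- chooseParent(cand[1, , drop = FALSE])
  expect_equal(one, cand[1, ])
  set.seed(123)
  draws <- replicate(30000, {
    x <- chooseParent(cand)
    x[1] * 10 + x[2]
  })
  freq <- as.numeric(table(draws)) / length(draws)
  # binomial 3-standard-error band around 1/3
  se <- sqrt((1 / 3) * (2 / 3) / 30000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
  set.seed(7); a <- chooseParent(cand)
  set.seed(7); b <- chooseParent(cand)
  expect_identical(a, b)
  expect_error(chooseParent(cand[0, , drop = FALSE]), "at least one")
})

test_that("inheritance copies the parent and mutates one gene at the stated rate", {
  parent <- c(1.7, 3.2, 4.1)
  # rate 0: always an exact copy
  set.seed(1)
  for (k in 1:20) {
    r <- inheritAndMutate(parent, MutationParams(0, 5))
    expect_false(r$mutated)
    expect_equal(unname(r$child), parent)
    expect_equal(r$delta, 0)
  }
  # magnitude 0, rate 1: flagged mutated but unchanged
  r <- inheritAndMutate(parent, MutationParams(1, 0))
  expect_true(r$mutated)
  expect_equal(unname(r$child), parent)
  # monte carlo at rate 0.2
  set.seed(42)
  n <- 30000
  res <- replicate(n, {
    r <- inheritAndMutate(parent, MutationParams(0.2, 1.5))
    c(r$mutated, match(r$gene, c("lonely", "born", "crowded")), r$delta)
  })
  frac <- mean(res[1, ])
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  genes <- res[2, res[1, ] == 1]
  freq <- as.numeric(table(genes)) / length(genes)
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / length(genes))))
  deltas <- res[3, res[1, ] == 1]
  expect_gt(stats::ks.test(deltas / 1.5, "pnorm")$p.value, 0.001)
})

test_that("a step reproduces canonical oscillator and spaceship dynamics", {
  p0 <- MutationParams(0, 1)
  # horizontal blinker in an 11x11 lattice has period 2
  b <- latticeFromPattern(builtinPatterns()$blinker, 11)
  b1 <- caStep(b, p0)
  b2 <- caStep(b1, p0)
  expect_false(identical(occupancy(b), occupancy(b1)))
  expect_identical(occupancy(b), occupancy(b2))
  # the one-step image is the vertical phase
  expect_equal(population(b1), 3)
  cells1 <- which(occupancy(b1) == 1L, arr.ind = TRUE)
  expect_equal(length(unique(cells1[, 2])), 1)   # one column
  # glider translates by (1,1) every 4 generations in a 30x30 lattice
  g <- placePattern(builtinPatterns()$glider, emptyLattice(30), 5, 5)
  g4 <- g
  for (i in 1:4) g4 <- caStep(g4, p0)
  a <- which(occupancy(g) == 1L, arr.ind = TRUE)
  d <- which(occupancy(g4) == 1L, arr.ind = TRUE)
  expect_identical(a + 1L, d)
  expect_equal(generation(g4), 4L)
})

test_that("dead sites stay wildtype and borders die after every step", {
  set.seed(31)
  s <- randomSoup(25, 0.5)      # soup covers the borders at generation 0
  p <- MutationParams(0.3, 2)
  for (g in 1:40) {
    s <- caStep(s, p)
    dead <- occupancy(s) == 0L
    expect_true(all(lonelyGrid(s)[dead] == 2))
    expect_true(all(bornGrid(s)[dead] == 3))
    expect_true(all(crowdedGrid(s)[dead] == 3))
    n <- latticeSize(s)
    expect_true(all(occupancy(s)[c(1, n), ] == 0L))
    expect_true(all(occupancy(s)[, c(1, n)] == 0L))
  }
})

test_that("trajectories are deterministic given the seed, events included", {
  runOnce <- function() {
    set.seed(77)
    s <- randomSoup(20, 0.5)
    evs <- list()
    for (g in 1:15) {
      r <- caStep(s, MutationParams(0.4, 1.5), events = TRUE)
      s <- r$state
      evs[[g]] <- r$births
    }
    list(state = s, events = evs)
  }
  a <- runOnce()
  b <- runOnce()
  expect_identical(occupancy(a$state), occupancy(b$state))
  expect_identical(crowdedGrid(a$state), crowdedGrid(b$state))
  expect_identical(a$events, b$events)
})

test_that("birth events record a live parent and a consistent delta", {
  set.seed(8)
  s <- randomSoup(20, 0.5)
  p <- MutationParams(0.5, 2)
  for (g in 1:10) {
    prev <- s
    r <- caStep(s, p, events = TRUE)
    s <- r$state
    b <- r$births
    if (nrow(b) == 0) next
    # birth sites were dead, death sites were alive
    expect_true(all(occupancy(prev)[cbind(b$row, b$col)] == 0L))
    expect_true(all(occupancy(s)[cbind(b$row, b$col)] == 1L))
    d <- r$deaths
    expect_true(all(occupancy(prev)[cbind(d$row, d$col)] == 1L))
    expect_true(all(occupancy(s)[cbind(d$row, d$col)] == 0L))
    # parents were alive pre-step; unmutated children copy them exactly
    expect_true(all(occupancy(prev)[cbind(b$parent_row, b$parent_col)] == 1L))
    for (k in seq_len(nrow(b))) {
      pg <- c(lonelyGrid(prev)[b$parent_row[k], b$parent_col[k]],
              bornGrid(prev)[b$parent_row[k], b$parent_col[k]],
              crowdedGrid(prev)[b$parent_row[k], b$parent_col[k]])
      if (b$mutated[k]) pg[b$gene[k]] <- pg[b$gene[k]] + b$delta[k]
      cg <- c(lonelyGrid(s)[b$row[k], b$col[k]],
              bornGrid(s)[b$row[k], b$col[k]],
              crowdedGrid(s)[b$row[k], b$col[k]])
      expect_equal(cg, pg, tolerance = 0)
    }
  }
})

test_that("the parental birth rule lets mutated born thresholds act", {
  # three cells in a column with born = 2 can spawn with two neighbours,
  # which the site rule (wildtype born = 3 at empty sites) never allows
  s <- emptyLattice(9)
  occ <- occupancy(s); occ[4:6, 4] <- 1L
  s@occupancy <- occ
  s@born[4:6, 4] <- 2
  set.seed(5)
  siteNext <- caStep(s, MutationParams(0, 1), birthRule = "site")
  set.seed(5)
  parNext <- caStep(s, MutationParams(0, 1), birthRule = "parental")
  # site rule: a blinker (flanks die lonely, two births at n = 3)
  expect_equal(population(siteNext), 3)
  # parental rule: extra births where exactly 2 live neighbours agree
  # with the parents' born threshold of 2
  expect_gt(population(parNext), population(siteNext))
})

test_that("raster genome update differs from synchronous only in inheritance", {
  set.seed(12)
  s <- randomSoup(20, 0.5)
  p <- MutationParams(1, 1)
  set.seed(1)
  syn <- caStep(s, p, genomeUpdate = "synchronous")
  set.seed(1)
  ras <- caStep(s, p, genomeUpdate = "raster")
  # occupancy fates are identical: both read pre-step occupancy
  expect_identical(occupancy(syn), occupancy(ras))
  expect_true(validObject(ras))
})
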