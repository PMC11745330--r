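# Rod-cell mechanics: growth, division, overlap relaxation, spatial binning.

test_that("volume/length conversion is a closed-form round trip", {
  L <- c(0, 1, 2.5, 6)
  expect_equal(lengthFromVolume(capsuleVolume(L)), L)
  expect_equal(capsuleVolume(0), pi * cellRadius()^2)  # a disc at L = 0
  expect_error(lengthFromVolume(0.1), "below the minimal")
})

test_that("growth is exponential, multiplicative, and spares the dead", {
  pop <- singleCellPop(length = 2, kGrow = log(2))
  expect_equal(growCells(pop, 0)@cells$length, 2)
  grown <- growCells(pop, 1)
  expect_equal(capsuleVolume(grown@cells$length), 2 * capsuleVolume(2))
  # two shorter steps equal one long step
  expect_equal(growCells(growCells(pop, 0.3), 0.7)@cells$length,
               growCells(pop, 1)@cells$length)
  # a corpse does not grow
  dead <- pop
  dead@cells$dead <- TRUE
  dead@cells$deathTime <- 0
  dead@cells$kGrow <- 0
  expect_equal(growCells(dead, 1)@cells$length, 2)
})

test_that("division conserves volume and splits into equal end-to-end daughters", {
  pop <- singleCellPop(length = 2, eta = 0)
  expect_identical(nCells(divideCells(pop)), 1L)     # below 2 V0: no division
  ready <- growCells(pop, 1)                         # doubles at kGrow = ln 2
  set.seed(1)
  div <- divideCells(ready)
  expect_identical(nCells(div), 2L)
  expect_equal(sum(capsuleVolume(div@cells$length)),
               capsuleVolume(ready@cells$length))
  expect_equal(div@cells$length[1], div@cells$length[2])
  expect_equal(div@cells$angle, c(0, 0))             # parent orientation kept
  # daughters sit symmetrically on the parent axis
  expect_equal(div@cells$x[1], -div@cells$x[2])
  expect_equal(div@cells$y, c(0, 0))
  expect_equal(div@cells$birthVolume,
               rep(capsuleVolume(ready@cells$length) / 2, 2))
  expect_true(all(div@cells$id != 1L))               # fresh ids
})

test_that("a noise-free lineage doubles every hour", {
  pop <- singleCellPop(length = 2, kGrow = log(2), eta = 0)
  set.seed(5)
  # sub-steps overshoot the hour slightly so the doubling threshold is met
  # despite floating-point rounding of the exponential products
  for (hour in 1:3) {
    for (i in 1:4) {
      pop <- growCells(pop, 0.2501)
      pop <- divideCells(pop, etaWidth = 0)
      pop@cells$eta <- 0  # deterministic threshold for the oracle
      pop <- suppressWarnings(relaxOverlaps(pop))
    }
    expect_identical(nCells(pop), as.integer(2^hour))
  }
})

test_that("relaxation separates an overlapping pair symmetrically", {
  pop <- makeFixture("overlap-pair")
  expect_equal(maxOverlap(pop), 0.2)
  rel <- relaxOverlaps(pop, tolerance = 0.01)
  expect_lte(maxOverlap(rel), 0.01)
  # both rods displaced by the same amount, in opposite directions
  dy <- rel@cells$y - pop@cells$y
  expect_equal(dy[1], -dy[2], tolerance = 1e-9)
  # lengths, volumes, life status untouched
  expect_equal(rel@cells$length, pop@cells$length)
  expect_identical(rel@cells$dead, pop@cells$dead)
})

test_that("relaxation is a fixed point on non-overlapping states", {
  pop <- makeFixture("lattice3x3")
  rel <- relaxOverlaps(pop)
  expect_equal(rel@cells$x, pop@cells$x)
  expect_equal(rel@cells$y, pop@cells$y)
  # idempotence within tolerance
  rel2 <- relaxOverlaps(relaxOverlaps(makeFixture("overlap-pair")))
  expect_lte(maxOverlap(rel2), 0.01)
})

test_that("post-relaxation overlap stays below tolerance (independent oracle)", {
  set.seed(21)
  for (i in 1:3) {
    pop <- randomPopulation(60, box = 12)
    rel <- suppressWarnings(relaxOverlaps(pop, tolerance = 0.01,
                                          maxIterations = 500))
    # the compiled max-overlap agrees with the optimisation-based oracle
    expect_equal(maxOverlap(rel), oracleMaxOverlap(rel), tolerance = 5e-3)
    expect_lte(oracleMaxOverlap(rel), 0.015)
  }
})

test_that("the spatial grid registers cells in every overlapped bin", {
  # point-like cell at (5, 5) in a 10 um grid
  pop <- newPopulation(T6SSim:::.cellFrame(id = 1L, strainLabel = "s",
                                           x = 5, y = 5, angle = 0,
                                           length = 0, nToxins = 1),
                       nToxins = 1)
  g <- buildGrid(pop, cellSize = 10)
  expect_true("0,0" %in% names(g@bins))
  expect_identical(gridLookup(g, 4, 6, 4, 6), 1L)

  # rod whose extent spans x in [9, 11] straddles two bin columns
  pop2 <- newPopulation(T6SSim:::.cellFrame(id = 7L, strainLabel = "s",
                                            x = 10, y = 5, angle = 0,
                                            length = 1, nToxins = 1),
                        nToxins = 1)
  g2 <- buildGrid(pop2, cellSize = 10)
  expect_setequal(names(g2@bins), c("0,0", "1,0"))

  # empty population, empty grid
  g3 <- buildGrid(newPopulation(T6SSim:::.cellFrame(
    id = integer(), strainLabel = character(), x = numeric(),
    y = numeric(), angle = numeric(), length = numeric(), nToxins = 1),
    nToxins = 1))
  expect_length(g3@bins, 0)
})

test_that("grid lookups return a superset of true neighbours", {
  set.seed(9)
  for (rep in 1:5) {
    pop <- randomPopulation(40, box = 25)
    g <- buildGrid(pop, cellSize = 10)
    cells <- cellTable(pop)
    box <- sort(runif(2, -25, 25)); boy <- sort(runif(2, -25, 25))
    got <- gridLookup(g, box[1], box[2], boy[1], boy[2])
    # brute force: any cell whose capsule AABB intersects the query box
    hx <- abs(cells$length / 2 * cos(cells$angle)) + cellRadius()
    hy <- abs(cells$length / 2 * sin(cells$angle)) + cellRadius()
    truth <- cells$id[cells$x + hx >= box[1] & cells$x - hx <= box[2] &
                      cells$y + hy >= boy[1] & cells$y - hy <= boy[2]]
    expect_true(all(truth %in% got))
  }
})
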