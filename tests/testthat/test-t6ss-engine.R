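# The stochastic T6SS machinery: firing statistics, needle geometry,
# first-hit resolution, intoxication and corpse lysis.

test_that("firing counts are per-cell Poisson draws and corpses never fire", {
  pop <- makeFixture("lattice3x3")
  expect_identical(sampleFiringCounts(pop, kFire = 0, dt = 0.1),
                   integer(9))
  # mark one corpse
  pop@cells$dead[4] <- TRUE
  pop@cells$deathTime[4] <- 0
  set.seed(1)
  counts <- sampleFiringCounts(pop, kFire = 100, dt = 1)
  expect_identical(counts[4], 0L)
  expect_true(all(counts[-4] > 0))

  # moment check: mean of many draws within 3 standard errors of k dt
  big <- replicatedPop(1e5)
  set.seed(2)
  draws <- sampleFiringCounts(big, kFire = 2, dt = 1)
  expect_lt(abs(mean(draws) - 2), 3 * sqrt(2 / 1e5))
})

test_that("needle bases lie on the membrane and point outward", {
  pop <- newPopulation(T6SSim:::.cellFrame(id = 1L, strainLabel = "s",
                                           x = 3, y = -2, angle = 0.7,
                                           length = 3, nToxins = 2),
                       nToxins = 2)
  expect_identical(nrow(spawnNeedles(pop, 0L)), 0L)
  set.seed(4)
  ndl <- spawnNeedles(pop, 500L)
  d <- mapply(function(bx, by) oracleDistPointSeg(bx, by, 3, -2, 0.7, 3),
              ndl$bx, ndl$by)
  expect_equal(d, rep(cellRadius(), 500), tolerance = 1e-9)
  expect_equal(ndl$ux^2 + ndl$uy^2, rep(1, 500), tolerance = 1e-12)
  # the needle tip is farther from the axis than the base (outwardness)
  tip <- mapply(function(bx, by, ux, uy)
    oracleDistPointSeg(bx + 0.1 * ux, by + 0.1 * uy, 3, -2, 0.7, 3),
    ndl$bx, ndl$by, ndl$ux, ndl$uy)
  expect_true(all(tip > d - 1e-9))
  # determinism under a fixed seed
  set.seed(4)
  expect_identical(spawnNeedles(pop, 500L), ndl)
})

test_that("random outward directions stay within the outward half plane", {
  pop <- singleCellPop(length = 3)
  set.seed(8)
  ndl <- spawnNeedles(pop, 300L, direction = "random")
  tip <- mapply(function(bx, by, ux, uy)
    oracleDistPointSeg(bx + 1e-4 * ux, by + 1e-4 * uy, 0, 0, 0, 3),
    ndl$bx, ndl$by, ndl$ux, ndl$uy)
  expect_true(all(tip >= cellRadius() - 1e-7))
})

test_that("hit resolution finds the first struck cell, never the firer", {
  pop <- makeFixture("aimed-needle")
  # neighbour surface 0.3 um away along +x: struck at 0.3 um
  ndl <- data.frame(firerRow = 1L, firerId = 1L, bx = 1.5, by = 0,
                    ux = 1, uy = 0)
  h <- resolveHits(ndl, pop)
  expect_identical(h$targetId, 2L)
  expect_equal(h$distance, 0.3, tolerance = 1e-6)
  # fired the other way: nothing within reach
  ndl$ux <- -1
  ndl$bx <- -1.5
  expect_identical(nrow(resolveHits(ndl, pop)), 0L)
  # two stacked targets: only the nearer is struck
  cells <- rbind(pop@cells, transform(pop@cells[2, ], id = 3L, x = x + 0.1))
  pop3 <- newPopulation(cells, nToxins = 2)
  h3 <- resolveHits(data.frame(firerRow = 1L, firerId = 1L, bx = 1.5,
                               by = 0, ux = 1, uy = 0), pop3)
  expect_identical(h3$targetId, 2L)
})

test_that("grid-accelerated hit resolution equals the brute-force oracle", {
  set.seed(31)
  for (rep in 1:4) {
    pop <- randomPopulation(40, box = 8)   # crowded: many real hits
    counts <- integer(40)
    counts[sample(40, 12)] <- sample(1:3, 12, replace = TRUE)
    ndl <- spawnNeedles(pop, counts)
    got <- resolveHits(ndl, pop)
    want <- oracleResolveHits(ndl, pop)
    expect_identical(got$targetId, want$targetId)
    expect_identical(got$firerId, want$firerId)
    expect_equal(got$distance, want$distance, tolerance = 1e-6)
    expect_true(all(got$distance <= needleLength() + 1e-9))
  }
})

test_that("intoxication applies strain arsenals with kin immunity", {
  strains <- list(strain("attacker", a = c(0, 0), d = c(1, 0), count = 1),
                  strain("duo", a = c(0, 0), d = c(1, 1), count = 1),
                  strain("target", a = c(1, 1), count = 1))
  cells <- T6SSim:::.cellFrame(id = 1:4,
                               strainLabel = c("attacker", "duo", "target",
                                               "attacker"),
                               x = c(0, 10, 20, 30), y = 0, angle = 0,
                               length = 2, nToxins = 2)
  pop <- newPopulation(cells, time = 1, nToxins = 2)

  # single-toxin hit on a fully sensitive target kills in one hit
  h <- data.frame(firerId = 1L, targetId = 3L, distance = 0.1)
  p1 <- intoxicate(pop, h, strains)
  expect_true(p1@cells$dead[3])
  expect_identical(p1@cells$kGrow[3], 0)
  expect_identical(p1@cells$deathTime[3], 1)
  expect_equal(unname(toxinMatrix(p1)[3, ]), c(1, 0))

  # a two-toxin hit translocates one unit of each
  h2 <- data.frame(firerId = 2L, targetId = 3L, distance = 0.1)
  expect_equal(unname(toxinMatrix(intoxicate(pop, h2, strains))[3, ]),
               c(1, 1))

  # clonemate hits are harmless
  h3 <- data.frame(firerId = 1L, targetId = 4L, distance = 0.1)
  p3 <- intoxicate(pop, h3, strains)
  expect_equal(unname(toxinMatrix(p3)[4, ]), c(0, 0))
  expect_false(p3@cells$dead[4])
})

test_that("corpses persist for the lysis delay and block needles meanwhile", {
  pop <- makeFixture("aimed-needle")
  pop@cells$dead[2] <- TRUE
  pop@cells$deathTime[2] <- 0
  pop@cells$kGrow[2] <- 0
  # corpse still absorbs the needle
  h <- resolveHits(data.frame(firerRow = 1L, firerId = 1L, bx = 1.5,
                              by = 0, ux = 1, uy = 0), pop)
  expect_identical(h$targetId, 2L)
  # not yet lysed before the delay, removed at/after it
  expect_identical(nCells(cullAndLyse(pop, now = 0.4, kLysis = 2)), 2L)
  expect_identical(nCells(cullAndLyse(pop, now = 0.5, kLysis = 2)), 1L)
  # in the fast-lysis limit corpses vanish on the next step
  expect_identical(nCells(cullAndLyse(pop, now = 1e-6, kLysis = 1e6)), 1L)
  # living cells are never removed
  expect_identical(cullAndLyse(pop, now = 10, kLysis = 2)@cells$id, 1L)
})

test_that("cell book-keeping balances births, deaths and lysis", {
  cfg <- tripartiteConfig(attackerD = c(1, 0), mutantA = c(0, 1),
                          counts = c(40, 12, 4), arenaRadius = 15,
                          duration = 1.5, kFire = 20)
  set.seed(3)
  pop <- seedDisc(cfg)
  strains <- cfg@strains
  labels <- vapply(strains, strainLabel, "")
  born <- nCells(pop)
  lysed <- 0L
  for (step in 1:30) {
    pop <- growCells(pop, cfg@dt)
    nBeforeDiv <- nCells(pop)
    pop <- divideCells(pop)
    born <- born + (nCells(pop) - nBeforeDiv)  # each division nets one cell
    pop <- suppressWarnings(relaxOverlaps(pop))
    nf <- sampleFiringCounts(pop, cfg@kFire, cfg@dt,
                             attackers = pop@cells$strain == "attacker")
    hits <- resolveHits(spawnNeedles(pop, nf), pop)
    pop <- intoxicate(pop, hits, strains, now = pop@time)
    nBefore <- nCells(pop)
    pop <- cullAndLyse(pop, pop@time, cfg@kLysis)
    lysed <- lysed + nBefore - nCells(pop)
    expect_identical(born, nCells(pop) + lysed)
    expect_identical(sum(!pop@cells$dead) + sum(pop@cells$dead), nCells(pop))
  }
})
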