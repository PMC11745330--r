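# Competition assembly and summary statistics.

test_that("disc seeding places every strain inside the arena, overlap-free", {
  set.seed(2)
  pop <- makeFixture("fig1-disc")   # 500:90:10 in a 50 um disc
  expect_identical(nCells(pop), 600L)
  expect_equal(unname(strainCounts(pop)[c("attacker", "susceptible",
                                          "mutant")]),
               c(500L, 90L, 10L))
  # placed inside the disc; the overlap-removing relaxation may nudge edge
  # cells outward by at most a couple of cell widths
  expect_true(all(sqrt(pop@cells$x^2 + pop@cells$y^2) <= 52.5))
  expect_lte(maxOverlap(pop), 0.01)
  # identical seed, identical layout
  set.seed(2)
  expect_identical(cellTable(makeFixture("fig1-disc")), cellTable(pop))
})

test_that("infeasible packing is rejected up front", {
  cfg <- tripartiteConfig(counts = c(2000, 0, 0), arenaRadius = 10)
  expect_error(seedDisc(cfg), "infeasible packing")
})

test_that("competitive advantage follows the frequency-ratio definition", {
  expect_equal(competitiveAdvantage(c(mutant = 10, susceptible = 90),
                                    c(mutant = 20, susceptible = 90)), 2)
  expect_equal(competitiveAdvantage(c(mutant = 5, susceptible = 50),
                                    c(mutant = 20, susceptible = 200)), 1)
  expect_identical(competitiveAdvantage(c(mutant = 5, susceptible = 50),
                                        c(mutant = 0, susceptible = 80)), 0)
  expect_identical(competitiveAdvantage(c(mutant = 5, susceptible = 50),
                                        c(mutant = 9, susceptible = 0)), Inf)
  expect_identical(competitiveAdvantage(c(mutant = 5, susceptible = 50),
                                        c(mutant = 0, susceptible = 0)),
                   NA_real_)
  expect_error(competitiveAdvantage(c(mutant = 0, susceptible = 50),
                                    c(mutant = 1, susceptible = 1)),
               "positive")
})

test_that("absolute fitness is the per-hour log2 division rate", {
  expect_equal(absoluteFitness(100, 200, 0, 1), 1)
  expect_equal(absoluteFitness(100, 800, 0, 2), 1.5)
  expect_equal(absoluteFitness(100, 100, 0, 5), 0)
  expect_identical(absoluteFitness(100, 0, 0, 1), -Inf)
  expect_error(absoluteFitness(0, 10, 0, 1), "positive")
  expect_error(absoluteFitness(10, 10, 2, 1), "exceed")
})

test_that("identical config and seed replay bit-for-bit", {
  cfg <- tripartiteConfig(attackerD = c(1, 0), mutantA = c(0, 1),
                          counts = c(30, 6, 2), arenaRadius = 12,
                          duration = 1)
  r1 <- suppressWarnings(runCompetitionOnce(cfg, seed = 99))
  r2 <- suppressWarnings(runCompetitionOnce(cfg, seed = 99))
  expect_identical(countsOverTime(r1), countsOverTime(r2))
  expect_identical(r1@competitiveAdvantage, r2@competitiveAdvantage)
  # and a different seed gives a different trajectory
  r3 <- suppressWarnings(runCompetitionOnce(cfg, seed = 100))
  expect_false(identical(countsOverTime(r1), countsOverTime(r3)))
})

test_that("a neutral label split has mean competitive advantage near 1", {
  strains <- list(strain("mutant", a = c(1, 1), count = 40),
                  strain("susceptible", a = c(1, 1), count = 40))
  cfg <- competitionConfig(strains, arenaRadius = 20, duration = 2,
                           replicates = 20)
  res <- suppressWarnings(runCompetition(cfg, seed = 5))
  ca <- vapply(res, function(r) r@competitiveAdvantage, 1)
  expect_true(all(is.finite(ca)))
  expect_lt(abs(mean(log(ca))), 0.1)
})

test_that("swapping the focal labels inverts competitive advantage", {
  strains <- list(strain("attacker", a = c(0, 0), d = c(1, 0), count = 40),
                  strain("alpha", a = c(0.6, 1), count = 10),
                  strain("beta", a = c(0.6, 1), count = 10))
  mk <- function(mut, sus)
    competitionConfig(strains, arenaRadius = 14, duration = 2,
                      mutantLabel = mut, susceptibleLabel = sus)
  r1 <- suppressWarnings(runCompetitionOnce(mk("alpha", "beta"), seed = 17))
  r2 <- suppressWarnings(runCompetitionOnce(mk("beta", "alpha"), seed = 17))
  expect_identical(countsOverTime(r1), countsOverTime(r2))
  expect_equal(r1@competitiveAdvantage, 1 / r2@competitiveAdvantage)
})

test_that("an extra toxin never improves target survival on average", {
  mk <- function(d) tripartiteConfig(
    attackerD = d, mutantA = c(0.5, 1), counts = c(60, 10, 10),
    arenaRadius = 17, duration = 3)
  finals <- function(d, seed) {
    res <- suppressWarnings(runCompetition(mk(d), seed = seed,
                                           replicates = 4))
    mean(vapply(res, function(r)
      r@counts[nrow(r@counts), "mutant"], 1))
  }
  # against the partially A-resistant target, adding toxin B (to which it is
  # fully sensitive) can only hurt it
  expect_lte(finals(c(1, 1), 7), finals(c(1, 0), 7))
})

test_that("total target extinction terminates the run and flags the result", {
  cfg <- tripartiteConfig(attackerD = c(1, 1), mutantA = c(1, 1),
                          counts = c(80, 3, 2), arenaRadius = 14,
                          duration = 6, kFire = 40)
  res <- suppressWarnings(runCompetitionOnce(cfg, seed = 21))
  expect_true(res@targetExtinct)
  expect_true(all(res@extinct[c("susceptible", "mutant")]))
  # CA is degenerate (0, Inf or NA), never a finite positive ratio
  expect_false(is.finite(res@competitiveAdvantage) &&
                 res@competitiveAdvantage > 0)
  # early termination: fewer recorded steps than the full schedule
  expect_lt(nrow(countsOverTime(res)), 6 / cfg@dt + 1)
})

test_that("cross-protection sweep flags help only when attack is present", {
  grid <- data.frame(nAttacker = c(0, 60), nSusceptible = 14, nMutant = 6)
  sw <- suppressWarnings(protectionSweep(
    grid, attackerD = c(1, 0), arenaRadius = 16, duration = 3,
    replicates = 5, seed = 3))
  expect_identical(nrow(sw$summary), 2L)
  # no attackers: resistance is irrelevant, no cross-protection signal
  noatt <- sw$summary[sw$summary$nAttacker == 0, ]
  expect_false(noatt$crossProtection)
  expect_lt(abs(noatt$meanFitSusResistant - noatt$meanFitSusControl), 0.2)
  # under attack, resistance is beneficial for the mutant itself
  att <- sw$summary[sw$summary$nAttacker == 60, ]
  expect_gt(att$mutantFitnessGain, 0)
})
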