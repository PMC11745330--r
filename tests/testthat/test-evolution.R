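# Mutate-select-replace adaptive walks, both selection backends.

test_that("mutation proposals are Normal, bounded, and redraw out-of-range", {
  a <- c(0.3, 0.8)
  expect_identical(proposeMutation(a, sigma = 0), a)
  set.seed(1)
  draws <- t(replicate(2000, proposeMutation(c(0.05, 0.95), sigma = 0.1)))
  expect_true(all(draws >= 0 & draws <= 1))
  # accepted perturbations from an interior point keep the Normal moments
  set.seed(2)
  delta <- t(replicate(2e4, proposeMutation(c(0.5, 0.5), 0.1))) - 0.5
  expect_lt(abs(mean(delta)), 3 * 0.1 / sqrt(2 * 2e4))
  expect_equal(sd(delta), 0.1, tolerance = 0.01)
  expect_error(proposeMutation(c(0.5, 0.5), sigma = 50, maxRedraws = 5),
               "redraws")
})

test_that("simplified fixation compares phenotypic resistance strictly", {
  expect_identical(simplifiedSelectionStep(c(1, 1), c(0.9, 1), d = c(1, 0)),
                   "FIXED")      # 2 hits beat 1
  expect_identical(simplifiedSelectionStep(c(1, 1), c(0.9, 1), d = c(1, 1)),
                   "REJECTED")   # ceil(1/1.9) = 1: no gain
  expect_identical(simplifiedSelectionStep(c(1, 1), c(0.4, 0.4), d = c(1, 1)),
                   "FIXED")      # ceil(1/0.8) = 2
  expect_identical(simplifiedSelectionStep(c(1, 1), c(1, 1), d = c(1, 0)),
                   "REJECTED")   # ties never fix in the analytic backend
})

test_that("a zero-step trajectory records only its starting state", {
  tr <- runTrajectory("simplified", attackerD = c(1, 0), maxSteps = 0,
                      seed = 1)
  expect_identical(nrow(tr@states), 1L)
  expect_length(tr@outcomes, 0)
  expect_identical(tr@endpoint, c(1, 1))
  expect_identical(tr@terminatedBy, "completed")
})

test_that("single-toxin walks gain resistance; two-toxin walks cannot", {
  one <- runTrajectories(10, seed = 101, backend = "simplified",
                         attackerD = c(1, 0), maxSteps = 30)
  hitsOne <- vapply(one, function(r) r@endpointNHits, 1)
  expect_true(all(hitsOne >= 2))

  two <- runTrajectories(10, seed = 202, backend = "simplified",
                         attackerD = c(1, 1), maxSteps = 30)
  for (r in two) {
    expect_identical(r@endpoint, c(1, 1))        # never moved
    expect_identical(r@endpointNHits, 1)
    expect_true(all(r@outcomes == "REJECTED"))
  }
})

test_that("resident resistance is non-decreasing along simplified walks", {
  recs <- runTrajectories(6, seed = 33, backend = "simplified",
                          attackerD = c(1, 0), maxSteps = 20)
  for (r in recs) {
    hits <- apply(r@states, 1, nHits, d = r@attacker)
    expect_true(all(diff(hits) >= 0))
  }
})

test_that("two-toxin fixation from full susceptibility is effectively impossible", {
  # crossing a_A + a_B < 1 from (1,1) needs a ~7 sigma joint draw
  tr <- runTrajectory("simplified", attackerD = c(1, 1), maxSteps = 10000,
                      seed = 9)
  expect_identical(sum(tr@outcomes == "FIXED"), 0L)
})

test_that("trajectory summaries count thresholds and extinctions", {
  mk <- function(endpoint, outcomes, term) new(
    "TrajectoryRecord",
    states = rbind(c(1, 1), matrix(endpoint, length(outcomes),
                                   2, byrow = TRUE)),
    outcomes = outcomes, attacker = c(1, 0), endpoint = endpoint,
    endpointNHits = nHits(endpoint, c(1, 0)), terminatedBy = term,
    backend = "simplified", seed = 1)
  recs <- list(mk(c(0.7, 1), c("FIXED"), "completed"),
               mk(c(1, 1), c("REJECTED", "EXTINCT"), "extinction"),
               mk(c(0.02, 1), c("FIXED"), "completed"))
  s <- trajectorySummary(recs)
  expect_identical(s$trajectories$endpointNHits, c(2, 1, 50))
  expect_identical(unname(s$counts["atLeastDouble"]), 2L)
  expect_identical(unname(s$counts["above20"]), 1L)
  expect_identical(unname(s$counts["extinct"]), 1L)
  expect_error(trajectorySummary(list()), "non-empty")
})

test_that("neutral mutants fix by drift about half the time in the arena", {
  ctl <- list(counts = c(100, 18, 2), arenaRadius = 50 * sqrt(120 / 600))
  out <- vapply(1:12, function(s) do.call(abmSelectionStep, c(
    list(resident = c(1, 1), mutant = c(1, 1), attackerD = c(1, 0),
         seed = s), ctl)), "")
  expect_true(all(out %in% c("FIXED", "REJECTED", "EXTINCT")))
  expect_gte(sum(out == "FIXED"), 2)
  expect_lte(sum(out == "FIXED"), 10)
})

test_that("arena-based walks mirror the simplified predictions and add
           extinction and cross-resistance", {
  ctl <- list(counts = c(100, 18, 2), arenaRadius = 50 * sqrt(120 / 600))
  one <- runTrajectories(12, seed = 10, backend = "abm",
                         attackerD = c(1, 0), maxSteps = 15,
                         abmControl = ctl)
  two <- runTrajectories(12, seed = 20, backend = "abm",
                         attackerD = c(1, 1), maxSteps = 15,
                         abmControl = ctl)
  s1 <- trajectorySummary(one)
  s2 <- trajectorySummary(two)
  # resistance evolves readily against one toxin, not against two
  expect_gt(median(s1$trajectories$endpointNHits),
            median(s2$trajectories$endpointNHits))
  expect_identical(unname(s2$counts["atLeastDouble"]), 0L)
  expect_gt(unname(s1$counts["atLeastDouble"]), 6)
  # sustained lethality drives more lineages extinct under two toxins
  expect_gt(unname(s2$counts["extinct"]), unname(s1$counts["extinct"]))
  # drift yields resistance to the unused toxin B in some surviving walks
  aB <- s1$trajectories$a2[!s1$trajectories$extinct]
  expect_gt(mean(aB < 1), 0)
})
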