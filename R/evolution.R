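# Mutate-select-replace evolutionary trajectories, with two selection
# backends: full agent-based competitions, or the simplified analytic
# comparison of phenotypic resistance.

#' Propose a mutant sensitivity profile
#'
#' Perturbs every component by an independent Normal(0, sigma^2) draw. If
#' any component leaves [0, 1] the whole vector is rejected and redrawn, so
#' the result is always a valid profile.
#'
#' @param a current sensitivity profile.
#' @param sigma mutation standard deviation (default 0.1).
#' @param maxRedraws redraw cap guarding against pathological \code{sigma}.
#' @return the mutated profile.
#' @export
proposeMutation <- function(a, sigma = 0.1, maxRedraws = 10000L) {
  .checkToxinVectors(a)
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(a)
  for (i in seq_len(maxRedraws)) {
    prop <- a + rnorm(length(a), 0, sigma)
    if (all(prop >= 0 & prop <= 1)) return(prop)
  }
  stop("proposeMutation: exceeded ", maxRedraws,
       " redraws; 'sigma' is too large for the [0, 1] constraint")
}

#' Simplified analytic selection step
#'
#' The mutant replaces the resident iff its phenotypic resistance strictly
#' exceeds the resident's:
#' \deqn{\Delta = N_{hits}^{mutant} - N_{hits}^{resident} > 0.}
#' With a non-zero interaction matrix the ceiling formula no longer holds,
#' so hits-to-death are counted by direct dose application
#' (\code{\link{hitsToDeath}}). With a positive cost coefficient, fixation
#' instead compares an expected-divisions-before-death proxy (growth
#' multiplier times hits-to-death), which reduces to the \eqn{\Delta > 0}
#' rule at zero cost. Extinction is impossible in this backend.
#'
#' @param resident,mutant sensitivity profiles.
#' @param d attacker arsenal.
#' @param B optional toxin interaction matrix.
#' @param costCoefficient growth cost per unit insensitivity.
#' @return \code{"FIXED"} or \code{"REJECTED"}.
#' @examples
#' simplifiedSelectionStep(c(1, 1), c(0.9, 1), d = c(1, 0))  # "FIXED"
#' simplifiedSelectionStep(c(1, 1), c(0.9, 1), d = c(1, 1))  # "REJECTED"
#' @export
simplifiedSelectionStep <- function(resident, mutant, d, B = NULL,
                                    costCoefficient = 0) {
  hits <- function(a)
    if (is.null(B) || all(B == 0)) nHits(a, d) else hitsToDeath(a, d, B)
  hR <- hits(resident); hM <- hits(mutant)
  if (costCoefficient > 0) {
    score <- function(h, a) {
      g <- growthMultiplier(a, costCoefficient)
      if (g <= 0) 0 else g * h
    }
    fixed <- score(hM, mutant) > score(hR, resident)
  } else {
    fixed <- hM > hR
  }
  if (fixed) "FIXED" else "REJECTED"
}

#' Agent-based selection step
#'
#' Runs one tripartite spatial competition (attacker : resident : mutant,
#' 500:90:10 by default, 1.5 h) and classifies the outcome: \code{"FIXED"}
#' if the mutant's competitive advantage over the resident exceeds 1 (it
#' would ultimately supplant the resident), \code{"EXTINCT"} if every
#' target cell died, \code{"REJECTED"} otherwise. Unlike the simplified
#' backend, near-neutral mutations can fix here through demographic
#' stochasticity (drift).
#'
#' @param resident,mutant sensitivity profiles.
#' @param attackerD attacker arsenal.
#' @param seed RNG seed for the competition.
#' @param counts attacker:resident:mutant seeding counts.
#' @param duration competition length, hours.
#' @param arenaRadius seeding disc radius, um.
#' @param B optional toxin interaction matrix.
#' @param costCoefficient growth cost coefficient.
#' @param ... further arguments to \code{\link{competitionConfig}}.
#' @return \code{"FIXED"}, \code{"REJECTED"} or \code{"EXTINCT"}.
#' @export
abmSelectionStep <- function(resident, mutant, attackerD, seed = 1,
                             counts = c(500, 90, 10), duration = 1.5,
                             arenaRadius = 50, B = NULL,
                             costCoefficient = 0, ...) {
  ntox <- length(attackerD)
  strains <- list(
    strain("attacker", a = rep(0, ntox), d = attackerD, count = counts[1]),
    strain("resident", a = resident, count = counts[2]),
    strain("mutant", a = mutant, count = counts[3]))
  cfg <- competitionConfig(strains, arenaRadius = arenaRadius,
                           duration = duration, B = B,
                           costCoefficient = costCoefficient,
                           mutantLabel = "mutant",
                           susceptibleLabel = "resident", ...)
  res <- suppressWarnings(runCompetitionOnce(cfg, seed))
  if (res@targetExtinct) return("EXTINCT")
  ca <- res@competitiveAdvantage
  if (!is.na(ca) && ca > 1) "FIXED" else "REJECTED"
}

#' Run one evolutionary trajectory
#'
#' Iterates the mutate-select-replace loop from a starting resident profile
#' (all-ones by default: total susceptibility): propose a mutant
#' (\code{\link{proposeMutation}}), subject it to selection by the chosen
#' backend, and replace the resident on fixation. An \code{EXTINCT} outcome
#' (agent-based backend only) terminates the walk. Each step consumes an
#' RNG substream derived from \code{(seed, step)}, so trajectories are
#' reproducible and extendable.
#'
#' @param backend \code{"simplified"} or \code{"abm"}.
#' @param attackerD attacker arsenal the walk evolves against.
#' @param start starting resident profile.
#' @param sigma mutation standard deviation.
#' @param maxSteps number of mutate-select steps.
#' @param seed trajectory seed.
#' @param B optional toxin interaction matrix.
#' @param costCoefficient growth cost coefficient.
#' @param abmControl named list of overrides for
#'   \code{\link{abmSelectionStep}} (e.g. \code{counts}, \code{duration},
#'   \code{arenaRadius}, \code{kFire}).
#' @return A \code{\linkS4class{TrajectoryRecord}}.
#' @examples
#' tr <- runTrajectory("simplified", attackerD = c(1, 0), seed = 7,
#'                     maxSteps = 10)
#' tr@endpointNHits  # >= 2 almost surely: single-toxin resistance evolves
#' @export
runTrajectory <- function(backend = c("simplified", "abm"),
                          attackerD, start = rep(1, length(attackerD)),
                          sigma = 0.1, maxSteps = 30, seed = 1,
                          B = NULL, costCoefficient = 0,
                          abmControl = list()) {
  backend <- match.arg(backend)
  stopifnot(maxSteps >= 0)
  .checkToxinVectors(start, d = attackerD)
  states <- matrix(NA_real_, maxSteps + 1, length(start))
  states[1, ] <- start
  outcomes <- character(0)
  resident <- start
  nVisited <- 1L
  terminatedBy <- "completed"

  for (step in seq_len(maxSteps)) {
    set.seed(deriveSeed(seed, "step", step))
    mutant <- proposeMutation(resident, sigma)
    outcome <- if (backend == "simplified") {
      simplifiedSelectionStep(resident, mutant, attackerD, B = B,
                              costCoefficient = costCoefficient)
    } else {
      do.call(abmSelectionStep, c(
        list(resident = resident, mutant = mutant, attackerD = attackerD,
             seed = deriveSeed(seed, "competition", step),
             B = B, costCoefficient = costCoefficient),
        abmControl))
    }
    outcomes <- c(outcomes, outcome)
    if (outcome == "FIXED") resident <- mutant
    nVisited <- nVisited + 1L
    states[nVisited, ] <- resident
    if (outcome == "EXTINCT") {
      terminatedBy <- "extinction"
      break
    }
  }
  states <- states[seq_len(nVisited), , drop = FALSE]
  endHits <- if (is.null(B) || all(B == 0)) nHits(resident, attackerD)
             else hitsToDeath(resident, attackerD, B)
  new("TrajectoryRecord", states = states, outcomes = outcomes,
      attacker = attackerD, endpoint = resident, endpointNHits = endHits,
      terminatedBy = terminatedBy, backend = backend, seed = seed)
}

#' Run a set of independent trajectories
#'
#' @param n number of trajectories.
#' @param seed top-level seed; trajectory \code{i} uses
#'   \code{deriveSeed(seed, "trajectory", i)}.
#' @param ... passed to \code{\link{runTrajectory}}.
#' @return list of \code{\linkS4class{TrajectoryRecord}}.
#' @export
runTrajectories <- function(n, seed = 1, ...) {
  lapply(seq_len(n), function(i)
    runTrajectory(seed = deriveSeed(seed, "trajectory", i), ...))
}

#' Summarize a set of trajectories
#'
#' @param records non-empty list of \code{\linkS4class{TrajectoryRecord}}.
#' @return list with \code{$trajectories} (one row each: endpoint
#'   sensitivities, endpoint resistance, fixation count, extinction flag)
#'   and \code{$counts} (trajectories with endpoint resistance >= 2, > 20,
#'   extinctions, total).
#' @export
trajectorySummary <- function(records) {
  if (!length(records)) stop("'records' must be a non-empty list")
  ntox <- length(records[[1]]@endpoint)
  df <- do.call(rbind, lapply(seq_along(records), function(i) {
    r <- records[[i]]
    row <- data.frame(trajectory = i, backend = r@backend, seed = r@seed,
                      steps = length(r@outcomes),
                      nFixed = sum(r@outcomes == "FIXED"),
                      extinct = r@terminatedBy == "extinction",
                      endpointNHits = r@endpointNHits)
    for (j in seq_len(ntox)) row[[paste0("a", j)]] <- r@endpoint[j]
    row
  }))
  list(trajectories = df,
       counts = c(atLeastDouble = sum(df$endpointNHits >= 2),
                  above20 = sum(df$endpointNHits > 20),
                  extinct = sum(df$extinct),
                  total = nrow(df)))
}
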