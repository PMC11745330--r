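# Head-to-head spatial competitions: seeding, the main time loop, and the
# summary statistics (competitive advantage, absolute fitness, extinction,
# cross-protection sweeps).

#' Build a competition configuration
#'
#' @param strains list of \code{\linkS4class{Strain}} (with their initial
#'   counts).
#' @param arenaRadius seeding disc radius, um.
#' @param duration simulated time, hours.
#' @param dt timestep, hours.
#' @param kFire firing rate per attacker, firings/cell/hour.
#' @param kLysis corpse removal rate, 1/hour.
#' @param B toxin interaction matrix; \code{NULL} = purely additive.
#' @param costCoefficient growth cost per unit total insensitivity.
#' @param replicates default replicate count.
#' @param mutantLabel,susceptibleLabel labels entering the competitive
#'   advantage ratio.
#' @param relaxTol,relaxMaxIter overlap relaxation tolerance / sweep cap.
#' @param gridSize hit-detection hash element size, um.
#' @param needleDirection \code{"normal"} or \code{"random"}.
#' @return A \code{\linkS4class{CompetitionConfig}}.
#' @seealso \code{\link{tripartiteConfig}} for the standard
#'   attacker/susceptible/mutant setup.
#' @export
competitionConfig <- function(strains, arenaRadius = 50, duration = 10,
                              dt = 0.025, kFire = 10, kLysis = 2, B = NULL,
                              costCoefficient = 0, replicates = 20,
                              mutantLabel = "mutant",
                              susceptibleLabel = "susceptible",
                              relaxTol = 0.01, relaxMaxIter = 100,
                              gridSize = 10,
                              needleDirection = c("normal", "random")) {
  ntox <- length(strains[[1]]@a)
  if (is.null(B)) B <- matrix(0, ntox, ntox)
  new("CompetitionConfig", strains = strains, arenaRadius = arenaRadius,
      duration = duration, dt = dt, kFire = kFire, kLysis = kLysis,
      B = B, costCoefficient = costCoefficient, replicates = replicates,
      mutantLabel = mutantLabel, susceptibleLabel = susceptibleLabel,
      relaxTol = relaxTol, relaxMaxIter = relaxMaxIter, gridSize = gridSize,
      needleDirection = match.arg(needleDirection))
}

#' Standard attacker / susceptible / mutant competition
#'
#' The canonical selection experiment: an attacker (immune to its own
#' arsenal, \code{a = 0}), a fully susceptible target, and a rare mutant
#' target, seeded 500:90:10 by default in a 50 um disc for 10 h.
#'
#' @param attackerD attacker arsenal (doses per hit).
#' @param mutantA mutant sensitivity profile.
#' @param susceptibleA susceptible sensitivity profile (all-ones by default).
#' @param counts attacker:susceptible:mutant seeding counts.
#' @param ... further arguments to \code{\link{competitionConfig}}.
#' @return A \code{\linkS4class{CompetitionConfig}}.
#' @examples
#' cfg <- tripartiteConfig(attackerD = c(1, 0), mutantA = c(0, 1))
#' @export
tripartiteConfig <- function(attackerD = c(1, 0), mutantA = c(0, 1),
                             susceptibleA = rep(1, length(attackerD)),
                             counts = c(500, 90, 10), ...) {
  ntox <- length(attackerD)
  strains <- list(
    strain("attacker", a = rep(0, ntox), d = attackerD, count = counts[1]),
    strain("susceptible", a = susceptibleA, count = counts[2]),
    strain("mutant", a = mutantA, count = counts[3]))
  competitionConfig(strains = strains, ...)
}

#' Seed a random mixed disc of cells
#'
#' Places each strain's cells at uniform-random positions and orientations
#' inside the arena disc, at random growth phases (volumes uniform between
#' one and two birth volumes), then relaxes once so the initial state is
#' overlap-free. Consumes RNG; call under \code{set.seed} for
#' reproducibility.
#'
#' @param config a \code{\linkS4class{CompetitionConfig}}.
#' @return A \code{\linkS4class{Population}} at time 0.
#' @export
seedDisc <- function(config) {
  stopifnot(is(config, "CompetitionConfig"))
  strains <- config@strains
  counts <- vapply(strains, function(s) s@count, 1)
  n <- sum(counts)
  if (n == 0) stop("no cells to seed")
  ntox <- length(strains[[1]]@a)
  V0 <- capsuleVolume(birthLength())
  # area demanded beyond the disc cannot be packed overlap-free
  if (n * 2 * V0 > pi * config@arenaRadius^2)
    stop("infeasible packing: requested cell area exceeds the seeding disc")

  labels <- rep(vapply(strains, strainLabel, ""), counts)
  kGrow <- rep(vapply(strains, function(s) s@kGrow, 1), counts)
  gmult <- rep(vapply(strains, function(s)
    growthMultiplier(s@a, config@costCoefficient), 1), counts)

  r <- config@arenaRadius * sqrt(runif(n))
  phi <- runif(n, 0, 2 * pi)
  ang <- runif(n, 0, 2 * pi)
  V <- V0 * runif(n, 1, 2)          # random phase of the cell cycle
  eta <- runif(n, -0.1, 0.1) * V0
  cells <- .cellFrame(id = seq_len(n), strainLabel = labels,
                      x = r * cos(phi), y = r * sin(phi), angle = ang,
                      length = lengthFromVolume(V), nToxins = ntox,
                      kGrow = kGrow, growthMult = gmult,
                      birthVolume = V0, eta = eta)
  pop <- newPopulation(cells, time = 0, nToxins = ntox)
  relaxOverlaps(pop, tolerance = config@relaxTol,
                maxIterations = max(500, config@relaxMaxIter))
}

#' Competitive advantage of a mutant over the susceptible strain
#'
#' \deqn{CA = \frac{(N_{mut}/N_{sus})_{final}}{(N_{mut}/N_{sus})_{initial}}.}
#' Degenerate outcomes are encoded explicitly rather than dropped: a mutant
#' that went extinct gives 0; a surviving mutant whose susceptible
#' competitor went extinct gives \code{Inf}; both extinct gives \code{NA}.
#'
#' @param initialCounts,finalCounts named counts containing the mutant and
#'   susceptible entries.
#' @param mutant,susceptible names of the two strains in the count vectors.
#' @return CA as a single numeric (possibly 0, \code{Inf} or \code{NA}).
#' @examples
#' competitiveAdvantage(c(mutant = 10, susceptible = 90),
#'                      c(mutant = 20, susceptible = 90))  # 2
#' @export
competitiveAdvantage <- function(initialCounts, finalCounts,
                                 mutant = "mutant",
                                 susceptible = "susceptible") {
  m0 <- initialCounts[[mutant]]; s0 <- initialCounts[[susceptible]]
  m1 <- finalCounts[[mutant]]; s1 <- finalCounts[[susceptible]]
  if (is.na(m0) || is.na(s0) || m0 <= 0 || s0 <= 0)
    stop("initial mutant and susceptible counts must both be positive")
  if (m1 == 0 && s1 == 0) return(NA_real_)
  if (m1 == 0) return(0)
  if (s1 == 0) return(Inf)
  (m1 / s1) / (m0 / s0)
}

#' Absolute fitness as a division rate
#'
#' \deqn{Fitness = \frac{1}{t_{final}-t_{initial}}
#'   \log_2\!\frac{N(t_{final})}{N(t_{start})}} in divisions per hour.
#' Extinction (\code{nFinal = 0}) gives \code{-Inf}.
#'
#' @param nStart,nFinal population sizes at the two timepoints
#'   (\code{nStart} > 0).
#' @param tInitial,tFinal times, hours (\code{tFinal} > \code{tInitial}).
#' @return fitness in divisions/hour.
#' @examples
#' absoluteFitness(100, 800, 0, 2)  # 1.5
#' @export
absoluteFitness <- function(nStart, nFinal, tInitial = 0, tFinal) {
  if (any(nStart <= 0)) stop("'nStart' must be positive")
  if (any(tFinal <= tInitial)) stop("'tFinal' must exceed 'tInitial'")
  log2(nFinal / nStart) / (tFinal - tInitial)
}

# One full time loop. Assumes the RNG seed has been set by the caller.
.runLoop <- function(config, seed) {
  strains <- config@strains
  labels <- vapply(strains, strainLabel, "")
  isAtt <- vapply(strains, isAttacker, TRUE)
  targetLabels <- labels[!isAtt]
  B <- if (any(config@B != 0)) config@B else NULL
  nSteps <- ceiling(config@duration / config@dt - 1e-9)

  pop <- seedDisc(config)
  counts <- matrix(0L, nSteps + 1, length(labels),
                   dimnames = list(NULL, labels))
  times <- numeric(nSteps + 1)
  counts[1, ] <- strainCounts(pop, labels)
  recorded <- 1L
  relaxFails <- 0L

  for (step in seq_len(nSteps)) {
    dt <- min(config@dt, config@duration - pop@time)
    pop <- growCells(pop, dt)
    pop <- divideCells(pop)
    pop <- withCallingHandlers(
      relaxOverlaps(pop, config@relaxTol, config@relaxMaxIter),
      warning = function(w) {
        relaxFails <<- relaxFails + 1L
        invokeRestart("muffleWarning")
      })
    if (config@kFire > 0 && any(isAtt)) {
      attackerCell <- pop@cells$strain %in% labels[isAtt]
      nf <- sampleFiringCounts(pop, config@kFire, dt, attackers = attackerCell)
      if (any(nf > 0)) {
        needles <- spawnNeedles(pop, nf, config@needleDirection)
        hits <- resolveHits(needles, pop, config@gridSize)
        pop <- intoxicate(pop, hits, strains, B = B, now = pop@time)
      }
    }
    pop <- cullAndLyse(pop, pop@time, config@kLysis)
    recorded <- recorded + 1L
    counts[recorded, ] <- strainCounts(pop, labels)
    times[recorded] <- pop@time
    if (all(counts[recorded, targetLabels] == 0)) break  # total target loss
  }
  if (relaxFails > 0)
    warning(sprintf("overlap relaxation hit the sweep cap in %d of %d steps",
                    relaxFails, nSteps))

  counts <- counts[seq_len(recorded), , drop = FALSE]
  times <- times[seq_len(recorded)]
  final <- counts[recorded, ]
  initial <- setNames(vapply(strains, function(s) s@count, 1), labels)
  ca <- if (config@mutantLabel %in% labels &&
            config@susceptibleLabel %in% labels &&
            initial[[config@mutantLabel]] > 0 &&
            initial[[config@susceptibleLabel]] > 0)
    competitiveAdvantage(initial, final, config@mutantLabel,
                         config@susceptibleLabel)
  else NA_real_
  tEnd <- max(times[recorded], config@dt)
  fitness <- ifelse(initial > 0,
                    absoluteFitness(pmax(initial, 1), final, 0, tEnd),
                    NA_real_)
  new("CompetitionResult", counts = counts, times = times,
      competitiveAdvantage = ca, fitness = setNames(fitness, labels),
      extinct = setNames(final == 0, labels),
      targetExtinct = all(final[targetLabels] == 0), seed = seed)
}

#' Run a single competition replicate
#'
#' Seeds the arena and iterates the timestep loop (grow, divide, relax,
#' fire, resolve hits, intoxicate, cull/lyse), recording living-cell counts
#' per strain at every step. The run terminates early once every
#' non-attacker strain is extinct.
#'
#' @param config a \code{\linkS4class{CompetitionConfig}}.
#' @param seed RNG seed; identical config + seed reproduces the run
#'   bit-for-bit.
#' @return A \code{\linkS4class{CompetitionResult}}.
#' @export
runCompetitionOnce <- function(config, seed = 1) {
  stopifnot(is(config, "CompetitionConfig"))
  set.seed(seed)
  .runLoop(config, seed)
}

#' Run replicated competitions
#'
#' Runs \code{replicates} independent replicates; each replicate's RNG
#' stream derives deterministically from \code{(seed, replicate index)} via
#' \code{\link{deriveSeed}}, so results do not depend on execution order.
#'
#' @param config a \code{\linkS4class{CompetitionConfig}}.
#' @param seed top-level seed.
#' @param replicates number of replicates (defaults to the config's).
#' @param result a \code{\linkS4class{CompetitionResult}} (accessor).
#' @return list of \code{\linkS4class{CompetitionResult}}.
#' @seealso \code{\link{summarizeCompetitions}},
#'   \code{\link{meanCompetitiveAdvantage}}
#' @export
runCompetition <- function(config, seed = 1, replicates = config@replicates) {
  lapply(seq_len(replicates), function(r)
    runCompetitionOnce(config, deriveSeed(seed, "replicate", r)))
}

#' Tidy per-replicate summary of competition results
#'
#' @param results list of \code{\linkS4class{CompetitionResult}}.
#' @return data.frame with one row per replicate: seed, competitive
#'   advantage, target extinction flag, and final count and fitness columns
#'   per strain.
#' @export
summarizeCompetitions <- function(results) {
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    final <- r@counts[nrow(r@counts), ]
    row <- data.frame(replicate = i, seed = r@seed,
                      competitiveAdvantage = r@competitiveAdvantage,
                      targetExtinct = r@targetExtinct,
                      duration = r@times[length(r@times)])
    for (s in colnames(r@counts)) {
      row[[paste0("final_", s)]] <- final[[s]]
      row[[paste0("fitness_", s)]] <- r@fitness[[s]]
    }
    row
  }))
}

#' Mean competitive advantage over surviving replicates
#'
#' Replicates in which either focal strain went extinct have CA 0,
#' \code{Inf} or \code{NA}; maps of selection average over the surviving
#' (finite, positive) replicates, optionally on the log scale.
#'
#' @param results list of \code{\linkS4class{CompetitionResult}}.
#' @param logScale average log-transformed CA and back-transform?
#' @return mean CA (NA if no replicate had both strains survive).
#' @export
meanCompetitiveAdvantage <- function(results, logScale = FALSE) {
  ca <- vapply(results, function(r) r@competitiveAdvantage, 1)
  ca <- ca[is.finite(ca) & ca > 0]
  if (!length(ca)) return(NA_real_)
  if (logScale) exp(mean(log(ca))) else mean(ca)
}

#' Cross-protection sweep
#'
#' For each row of the sweep grid, runs replicated competitions in two
#' conditions that differ only in the mutant's sensitivity to toxin A:
#' resistant (\code{a = (0, 1, ...)}) versus a fully susceptible control
#' mutant. Cross-protection is flagged where the susceptible strain's mean
#' absolute fitness is significantly higher with the resistant mutant
#' present (Welch two-sample test over replicates, one-sided).
#'
#' @param grid data.frame with columns \code{nAttacker}, \code{nSusceptible},
#'   \code{nMutant} and optionally \code{costCoefficient}.
#' @param attackerD attacker arsenal.
#' @param arenaRadius,duration,dt,kFire,kLysis,... passed to
#'   \code{\link{tripartiteConfig}}.
#' @param replicates replicates per condition and grid point.
#' @param seed top-level seed.
#' @param alpha significance level for the cross-protection flag.
#' @return list with \code{$replicates} (one row per grid point, condition
#'   and replicate: fitness of mutant and susceptible) and \code{$summary}
#'   (one row per grid point: mean fitnesses, mutant fitness gain, p-value
#'   and \code{crossProtection} flag).
#' @export
protectionSweep <- function(grid, attackerD = c(1, 0), arenaRadius = 50,
                            duration = 10, dt = 0.025, kFire = 10,
                            kLysis = 2, replicates = 10, seed = 1,
                            alpha = 0.05, ...) {
  if (is.null(grid$costCoefficient)) grid$costCoefficient <- 0
  ntox <- length(attackerD)
  resistantA <- c(0, rep(1, ntox - 1))
  perRep <- NULL
  summary <- NULL
  for (g in seq_len(nrow(grid))) {
    fits <- list()
    for (cond in c("resistant", "control")) {
      mutA <- if (cond == "resistant") resistantA else rep(1, ntox)
      cfg <- tripartiteConfig(
        attackerD = attackerD, mutantA = mutA,
        counts = c(grid$nAttacker[g], grid$nSusceptible[g], grid$nMutant[g]),
        arenaRadius = arenaRadius, duration = duration, dt = dt,
        kFire = kFire, kLysis = kLysis,
        costCoefficient = grid$costCoefficient[g], ...)
      res <- runCompetition(cfg, seed = deriveSeed(seed, cond, g),
                            replicates = replicates)
      sm <- summarizeCompetitions(res)
      fits[[cond]] <- sm
      perRep <- rbind(perRep, data.frame(
        gridPoint = g, condition = cond, replicate = sm$replicate,
        fitnessMutant = sm$fitness_mutant,
        fitnessSusceptible = sm$fitness_susceptible))
    }
    fsR <- fits$resistant$fitness_susceptible
    fsC <- fits$control$fitness_susceptible
    fsR <- fsR[is.finite(fsR)]; fsC <- fsC[is.finite(fsC)]
    p <- if (length(fsR) > 1 && length(fsC) > 1 &&
             (stats::sd(fsR) > 0 || stats::sd(fsC) > 0))
      t.test(fsR, fsC, alternative = "greater")$p.value else 1
    mfR <- fits$resistant$fitness_mutant
    mfC <- fits$control$fitness_mutant
    summary <- rbind(summary, data.frame(
      gridPoint = g, nAttacker = grid$nAttacker[g],
      nSusceptible = grid$nSusceptible[g], nMutant = grid$nMutant[g],
      costCoefficient = grid$costCoefficient[g],
      meanFitSusResistant = mean(fsR), meanFitSusControl = mean(fsC),
      mutantFitnessGain = mean(mfR[is.finite(mfR)]) -
        mean(mfC[is.finite(mfC)]),
      pValue = p, crossProtection = p < alpha))
  }
  list(replicates = perRep, summary = summary)
}
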