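# Constructors, accessors and show() methods for the S4 classes.

#' Create a strain
#'
#' @param label strain name (unique within a config).
#' @param a per-toxin sensitivities in [0, 1].
#' @param d per-toxin doses translocated per successful hit (an all-zero
#'   vector makes the strain an unarmed target).
#' @param count initial cell count when the strain is seeded.
#' @param kGrow specific growth rate, per hour; the default gives roughly
#'   four doublings in a 10 h competition.
#' @return A \code{\linkS4class{Strain}}.
#' @examples
#' attacker <- strain("attacker", a = c(0, 0), d = c(1, 0), count = 500)
#' target   <- strain("susceptible", a = c(1, 1), count = 90)
#' @export
strain <- function(label, a, d = rep(0, length(a)), count = 0,
                   kGrow = defaultGrowthRate()) {
  new("Strain", label = label, a = as.numeric(a), d = as.numeric(d),
      kGrow = kGrow, count = as.numeric(count))
}

#' Default specific growth rate
#'
#' ln(2)/2.5 per hour, i.e. a 2.5 h doubling time, so that a 10 h
#' competition spans approximately four doubling events.
#' @return Growth rate in 1/hour.
#' @export
defaultGrowthRate <- function() log(2) / 2.5

#' Is a strain an attacker?
#'
#' A strain is an attacker when it translocates a positive dose of at least
#' one toxin.
#' @param x a \code{\linkS4class{Strain}}.
#' @return logical.
#' @export
isAttacker <- function(x) any(x@d > 0)

#' @describeIn strain label accessor.
#' @param x a \code{Strain}.
#' @export
strainLabel <- function(x) x@label

#' Fresh integrity state
#'
#' A newborn cell: zero accumulated toxin, integrity 1, alive.
#' @param nToxins number of toxins tracked.
#' @return An \code{\linkS4class{IntegrityState}}.
#' @export
newIntegrityState <- function(nToxins) {
  new("IntegrityState", x = numeric(nToxins), I = 1, dead = FALSE)
}

#' Number of cells in a population
#' @param pop a \code{\linkS4class{Population}}.
#' @param aliveOnly count only living cells?
#' @return integer.
#' @export
nCells <- function(pop, aliveOnly = FALSE) {
  if (aliveOnly) sum(!pop@cells$dead) else nrow(pop@cells)
}

#' Living-cell counts per strain
#' @param pop a \code{\linkS4class{Population}}.
#' @param labels optional strain labels fixing the output order (strains
#'   with no remaining cells then report 0).
#' @return named integer vector.
#' @export
strainCounts <- function(pop, labels = NULL) {
  alive <- pop@cells[!pop@cells$dead, "strain"]
  if (is.null(labels)) labels <- sort(unique(pop@cells$strain))
  tab <- table(factor(alive, levels = labels))
  setNames(as.integer(tab), labels)
}

#' Per-cell table of a population
#' @param pop a \code{\linkS4class{Population}}.
#' @return the cells data.frame (one row per living or dead-unlysed cell).
#' @export
cellTable <- function(pop) pop@cells

#' Cumulative toxin amounts as a matrix
#' @param pop a \code{\linkS4class{Population}}.
#' @return numeric matrix, cells x toxins.
#' @export
toxinMatrix <- function(pop) {
  cols <- paste0("tox", seq_len(pop@nToxins))
  as.matrix(pop@cells[, cols, drop = FALSE])
}

#' @describeIn runCompetition counts time series accessor.
#' @export
countsOverTime <- function(result) {
  stopifnot(is(result, "CompetitionResult"))
  result@counts
}

setMethod("show", "Strain", function(object) {
  cat(sprintf("Strain '%s': %s, a = (%s), d = (%s), kGrow = %.3g/h, n0 = %d\n",
              object@label,
              if (isAttacker(object)) "attacker" else "target",
              paste(signif(object@a, 3), collapse = ", "),
              paste(signif(object@d, 3), collapse = ", "),
              object@kGrow, as.integer(object@count)))
})

setMethod("show", "IntegrityState", function(object) {
  cat(sprintf("IntegrityState: I = %.4g, %s, x = (%s)\n", object@I,
              if (object@dead) "dead" else "alive",
              paste(signif(object@x, 3), collapse = ", ")))
})

setMethod("show", "Population", function(object) {
  counts <- strainCounts(object)
  cat(sprintf("Population at t = %.3g h: %d cells (%d alive)\n",
              object@time, nrow(object@cells), sum(!object@cells$dead)))
  cat("  alive per strain:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
})

setMethod("show", "SpatialGrid", function(object) {
  cat(sprintf("SpatialGrid: element size %.3g um, %d occupied bins\n",
              object@cellSize, length(object@bins)))
})

setMethod("show", "CompetitionConfig", function(object) {
  cat(sprintf(
    "CompetitionConfig: %d strains, disc r = %g um, %g h @ dt = %g h\n",
    length(object@strains), object@arenaRadius, object@duration, object@dt))
  cat(sprintf("  kFire = %g /cell/h, kLysis = %g /h, cost = %g, replicates = %d\n",
              object@kFire, object@kLysis, object@costCoefficient,
              as.integer(object@replicates)))
  for (s in object@strains) show(s)
})

setMethod("show", "CompetitionResult", function(object) {
  cat(sprintf("CompetitionResult (seed %d): %d strains, %d recorded steps\n",
              as.integer(object@seed), ncol(object@counts),
              nrow(object@counts)))
  cat(sprintf("  competitive advantage = %.4g; target extinction: %s\n",
              object@competitiveAdvantage, object@targetExtinct))
  final <- object@counts[nrow(object@counts), ]
  cat("  final counts:",
      paste(sprintf("%s=%d", colnames(object@counts), final), collapse = ", "),
      "\n")
})

setMethod("show", "TrajectoryRecord", function(object) {
  cat(sprintf(
    "TrajectoryRecord (%s backend, seed %d): %d steps, %d fixed, %s\n",
    object@backend, as.integer(object@seed), length(object@outcomes),
    sum(object@outcomes == "FIXED"), object@terminatedBy))
  cat(sprintf("  endpoint a = (%s), N_hits = %s\n",
              paste(signif(object@endpoint, 3), collapse = ", "),
              format(object@endpointNHits)))
})
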