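#' @import methods
#' @importFrom stats rnorm rpois runif t.test setNames
#' @importFrom utils write.csv packageVersion
#' @useDynLib T6SSim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' IntegrityState: a cell's cumulative toxin load and health
#'
#' Tracks the cumulative intracellular amount of each toxin (\code{x}, units:
#' toxins per cell), the scaled integrity \code{I} (1 at birth, death at the
#' zero threshold), and a sticky death flag. Toxin amounts only ever increase
#' over a cell's life; integrity is recomputed from them via
#' \code{\link{integrityValue}}.
#'
#' @slot x numeric vector of cumulative toxin amounts, one per toxin.
#' @slot I scaled integrity (dimensionless; 1 when \code{x} is all zero).
#' @slot dead logical; once \code{TRUE} it never reverts.
#'
#' @seealso \code{\link{newIntegrityState}}, \code{\link{applyDose}}
#' @export
setClass("IntegrityState",
  representation(x = "numeric", I = "numeric", dead = "logical"),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@x)) || any(object@x < 0))
      msg <- c(msg, "toxin amounts 'x' must be finite and >= 0")
    if (length(object@I) != 1L || length(object@dead) != 1L)
      msg <- c(msg, "'I' and 'dead' must be scalars")
    if (length(msg)) msg else TRUE
  })

#' Strain: label, toxin sensitivities, arsenal and growth parameters
#'
#' A strain couples a per-toxin sensitivity profile \code{a} (how much
#' integrity one unit of each toxin removes; 1 = one unit is lethal, 0 =
#' complete insensitivity) with a per-hit arsenal \code{d} (doses translocated
#' per successful T6SS hit). A strain with any positive dose is an attacker;
#' attackers are perfectly immune to their own arsenal, so attacker strains
#' normally carry \code{a = 0}.
#'
#' @slot label character strain name.
#' @slot a numeric sensitivities in [0, 1], one per toxin.
#' @slot d numeric doses per hit, >= 0, same length as \code{a}.
#' @slot kGrow specific growth rate (per hour).
#' @slot count initial number of cells seeded for this strain.
#'
#' @export
setClass("Strain",
  representation(label = "character", a = "numeric", d = "numeric",
                 kGrow = "numeric", count = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@label) != 1L || !nzchar(object@label))
      msg <- c(msg, "'label' must be a non-empty string")
    if (length(object@a) != length(object@d))
      msg <- c(msg, "'a' and 'd' must have the same length (one entry per toxin)")
    if (any(!is.finite(object@a)) || any(object@a < 0) || any(object@a > 1))
      msg <- c(msg, "sensitivities 'a' must lie in [0, 1]")
    if (any(!is.finite(object@d)) || any(object@d < 0))
      msg <- c(msg, "doses 'd' must be finite and >= 0")
    if (length(object@kGrow) != 1L || object@kGrow < 0)
      msg <- c(msg, "'kGrow' must be a single non-negative rate")
    if (length(object@count) != 1L || object@count < 0 ||
        object@count != round(object@count))
      msg <- c(msg, "'count' must be a single non-negative integer")
    if (length(msg)) msg else TRUE
  })

#' Population: a collection of rod cells at a simulation time
#'
#' Cells are spherocylinders of fixed radius 0.5 um on an unbounded 2-D
#' plane. The \code{cells} data frame has one row per cell (living or
#' dead-but-unlysed) with columns \code{id}, \code{strain}, \code{x},
#' \code{y}, \code{angle}, \code{length}, \code{birthVolume}, \code{eta},
#' \code{kGrow}, \code{growthMult}, \code{integrity}, \code{dead},
#' \code{deathTime}, and one \code{tox<i>} column per toxin.
#'
#' @slot cells data.frame of per-cell state (see Details).
#' @slot time simulation clock, hours.
#' @slot nToxins number of toxins tracked per cell.
#'
#' @seealso \code{\link{seedDisc}}, \code{\link{growCells}},
#'   \code{\link{relaxOverlaps}}
#' @export
setClass("Population",
  representation(cells = "data.frame", time = "numeric", nToxins = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("id", "strain", "x", "y", "angle", "length", "birthVolume",
              "eta", "kGrow", "growthMult", "integrity", "dead", "deathTime")
    missing_cols <- setdiff(need, names(object@cells))
    if (length(missing_cols))
      msg <- c(msg, paste("cells is missing columns:",
                          paste(missing_cols, collapse = ", ")))
    else {
      if (anyDuplicated(object@cells$id))
        msg <- c(msg, "cell ids must be unique")
      if (any(object@cells$length < 0))
        msg <- c(msg, "segment lengths must be >= 0")
      if (any(object@cells$dead & is.na(object@cells$deathTime)) ||
          any(!object@cells$dead & !is.na(object@cells$deathTime)))
        msg <- c(msg, "deathTime must be set iff the cell is dead")
    }
    if (length(msg)) msg else TRUE
  })

#' SpatialGrid: infinite square binning of cells by extent
#'
#' Cells are registered in every 10 um (by default) grid element their
#' capsule extent overlaps, so a bin lookup returns a superset of the true
#' neighbours of any object overlapping that bin.
#'
#' @slot cellSize grid element side, um.
#' @slot bins named list mapping \code{"ix,iy"} keys to integer cell ids.
#'
#' @seealso \code{\link{buildGrid}}, \code{\link{gridLookup}}
#' @export
setClass("SpatialGrid",
  representation(cellSize = "numeric", bins = "list"),
  validity = function(object) {
    if (length(object@cellSize) != 1L || object@cellSize <= 0)
      "cellSize must be a single positive number" else TRUE
  })

#' CompetitionConfig: everything needed to run one spatial battle
#'
#' Bundles the strains (with their initial counts), the seeding geometry, the
#' biophysical and T6SS rates, the toxin interaction matrix and the
#' resistance cost coefficient. Defaults follow the reference competition
#' design: 500:90:10 attacker:susceptible:mutant cells in a 50 um disc,
#' 10 h duration, 20 replicates.
#'
#' @slot strains list of \code{\linkS4class{Strain}}.
#' @slot arenaRadius seeding disc radius, um.
#' @slot duration simulated time, hours.
#' @slot dt timestep, hours.
#' @slot kFire firing rate per attacker cell, firings/cell/hour.
#' @slot kLysis corpse removal rate, 1/hour (persistence = 1/kLysis).
#' @slot B square toxin interaction matrix (all zero = purely additive).
#' @slot costCoefficient linear growth cost per unit total insensitivity.
#' @slot replicates default replicate count for \code{\link{runCompetition}}.
#' @slot mutantLabel,susceptibleLabel strain labels used for the competitive
#'   advantage numerator and denominator.
#' @slot relaxTol,relaxMaxIter overlap relaxation tolerance (um) / iteration cap.
#' @slot gridSize spatial hash element size for hit detection, um.
#' @slot needleDirection \code{"normal"} (outward surface normal) or
#'   \code{"random"} (uniform outward half-plane).
#'
#' @seealso \code{\link{competitionConfig}}, \code{\link{runCompetition}}
#' @export
setClass("CompetitionConfig",
  representation(strains = "list", arenaRadius = "numeric",
                 duration = "numeric", dt = "numeric", kFire = "numeric",
                 kLysis = "numeric", B = "matrix",
                 costCoefficient = "numeric", replicates = "numeric",
                 mutantLabel = "character", susceptibleLabel = "character",
                 relaxTol = "numeric", relaxMaxIter = "numeric",
                 gridSize = "numeric", needleDirection = "character"),
  validity = function(object) {
    msg <- character()
    if (!length(object@strains) ||
        !all(vapply(object@strains, is, TRUE, "Strain")))
      msg <- c(msg, "'strains' must be a non-empty list of Strain objects")
    else {
      ntox <- length(object@strains[[1]]@a)
      if (!all(vapply(object@strains, function(s) length(s@a), 1L) == ntox))
        msg <- c(msg, "all strains must describe the same number of toxins")
      if (anyDuplicated(vapply(object@strains, function(s) s@label, "")))
        msg <- c(msg, "strain labels must be unique")
      if (!all(dim(object@B) == c(ntox, ntox)))
        msg <- c(msg, "'B' must be a square matrix with one row per toxin")
    }
    if (object@duration <= 0) msg <- c(msg, "'duration' must be > 0")
    if (object@dt <= 0) msg <- c(msg, "'dt' must be > 0")
    if (object@kFire < 0) msg <- c(msg, "'kFire' must be >= 0")
    if (object@kLysis <= 0) msg <- c(msg, "'kLysis' must be > 0")
    if (object@arenaRadius <= 0) msg <- c(msg, "'arenaRadius' must be > 0")
    if (object@costCoefficient < 0)
      msg <- c(msg, "'costCoefficient' must be >= 0")
    if (!object@needleDirection %in% c("normal", "random"))
      msg <- c(msg, "'needleDirection' must be 'normal' or 'random'")
    if (length(msg)) msg else TRUE
  })

#' CompetitionResult: time series and summaries of one replicate battle
#'
#' @slot counts integer matrix of living-cell counts, one row per recorded
#'   time, one column per strain.
#' @slot times numeric vector of recording times (hours), parallel to the
#'   rows of \code{counts}.
#' @slot competitiveAdvantage final mutant:susceptible ratio divided by the
#'   initial one; 0 if the mutant went extinct, \code{Inf} if only the
#'   susceptible did, \code{NA} if both did.
#' @slot fitness named per-strain absolute fitness, divisions per hour;
#'   \code{-Inf} marks extinction.
#' @slot extinct named logical per strain.
#' @slot targetExtinct \code{TRUE} when every non-attacker strain reached
#'   zero (the run then terminated early).
#' @slot seed RNG seed used for this replicate.
#'
#' @seealso \code{\link{runCompetition}}, \code{\link{competitiveAdvantage}}
#' @export
setClass("CompetitionResult",
  representation(counts = "matrix", times = "numeric",
                 competitiveAdvantage = "numeric", fitness = "numeric",
                 extinct = "logical", targetExtinct = "logical",
                 seed = "numeric"))

#' TrajectoryRecord: one mutate-select-replace adaptive walk
#'
#' @slot states numeric matrix of resident sensitivity profiles, one row per
#'   visited state (the first row is the starting profile).
#' @slot outcomes character vector of per-step outcomes in
#'   \code{c("FIXED", "REJECTED", "EXTINCT")}.
#' @slot attacker numeric arsenal (doses per hit) the walk evolved against.
#' @slot endpoint final resident sensitivity profile.
#' @slot endpointNHits phenotypic resistance of the endpoint against
#'   \code{attacker} (may be \code{Inf}).
#' @slot terminatedBy \code{"completed"} or \code{"extinction"}.
#' @slot backend \code{"simplified"} or \code{"abm"}.
#' @slot seed RNG seed of the walk.
#'
#' @seealso \code{\link{runTrajectory}}, \code{\link{trajectorySummary}}
#' @export
setClass("TrajectoryRecord",
  representation(states = "matrix", outcomes = "character",
                 attacker = "numeric", endpoint = "numeric",
                 endpointNHits = "numeric", terminatedBy = "character",
                 backend = "character", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(object@outcomes %in% c("FIXED", "REJECTED", "EXTINCT")))
      msg <- c(msg, "outcomes must be FIXED, REJECTED or EXTINCT")
    if (!object@terminatedBy %in% c("completed", "extinction"))
      msg <- c(msg, "terminatedBy must be 'completed' or 'extinction'")
    ext <- which(object@outcomes == "EXTINCT")
    if (length(ext) && ext[1] != length(object@outcomes))
      msg <- c(msg, "no steps may follow an EXTINCT outcome")
    if (length(msg)) msg else TRUE
  })
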