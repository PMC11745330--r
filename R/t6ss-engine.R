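# Stochastic T6SS machinery: Poisson firing, needle spawning on the cell
# boundary, first-hit resolution against the population, dose translocation
# and corpse lysis.

#' Needle length (um)
#'
#' Fired needles reach one cell radius beyond the membrane point they are
#' launched from.
#' @return 0.5
#' @export
needleLength <- function() cellRadius()

#' Draw per-cell firing counts
#'
#' Every timestep each living attacker fires \eqn{N \sim
#' Poisson(k_{fire}\,\Delta t)} needles, independently per cell. Dead cells
#' (corpses) never fire.
#'
#' @param pop a \code{\linkS4class{Population}}.
#' @param kFire firing rate, firings per cell per hour.
#' @param dt timestep, hours.
#' @param attackers logical vector (one per cell) marking cells capable of
#'   firing; defaults to all cells.
#' @return integer vector of firing counts, one per cell (0 for corpses).
#' @export
sampleFiringCounts <- function(pop, kFire, dt, attackers = NULL) {
  stopifnot(is(pop, "Population"), kFire >= 0, dt >= 0)
  n <- nrow(pop@cells)
  if (is.null(attackers)) attackers <- rep(TRUE, n)
  can <- attackers & !pop@cells$dead
  counts <- integer(n)
  if (any(can)) counts[can] <- rpois(sum(can), kFire * dt)
  counts
}

# Sample points uniformly on capsule boundaries, with outward normals.
# rows: one per needle; firerRow gives the cell row index for each needle.
.sampleBoundary <- function(cells, firerRow) {
  L <- cells$length[firerRow]
  R <- cellRadius()
  theta <- cells$angle[firerRow]
  cx <- cells$x[firerRow]; cy <- cells$y[firerRow]
  ux <- cos(theta); uy <- sin(theta)       # axis direction
  nx <- -uy; ny <- ux                      # left normal
  P <- 2 * L + 2 * pi * R                  # boundary perimeter
  u <- runif(length(firerRow)) * P

  bx <- numeric(length(u)); by <- bx; ox <- bx; oy <- bx
  # flat sides
  side1 <- u < L
  side2 <- !side1 & u < 2 * L
  s <- u - ifelse(side1, 0, L) - L / 2     # signed position along the axis
  flat <- side1 | side2
  sgn <- ifelse(side1, 1, -1)
  bx[flat] <- (cx + s * ux + sgn * R * nx)[flat]
  by[flat] <- (cy + s * uy + sgn * R * ny)[flat]
  ox[flat] <- (sgn * nx)[flat]
  oy[flat] <- (sgn * ny)[flat]
  # hemispherical caps: psi measured from the world x-axis
  cap1 <- !flat & u < 2 * L + pi * R       # cap at the +axis end
  cap2 <- !flat & !cap1
  psi <- ifelse(cap1, theta - pi / 2 + (u - 2 * L) / R,
                theta + pi / 2 + (u - 2 * L - pi * R) / R)
  ex <- cx + ifelse(cap1, 1, -1) * (L / 2) * ux
  ey <- cy + ifelse(cap1, 1, -1) * (L / 2) * uy
  caps <- cap1 | cap2
  bx[caps] <- (ex + R * cos(psi))[caps]
  by[caps] <- (ey + R * sin(psi))[caps]
  ox[caps] <- cos(psi)[caps]
  oy[caps] <- sin(psi)[caps]
  list(bx = bx, by = by, nx = ox, ny = oy)
}

#' Spawn T6SS needles from firing cells
#'
#' Base points are uniform over each firer's capsule boundary; every needle
#' has length one cell radius. The firing direction is the outward surface
#' normal at the base point (\code{direction = "normal"}), or uniformly
#' random within the outward half-plane (\code{direction = "random"}).
#'
#' @param pop a \code{\linkS4class{Population}}.
#' @param counts integer firing counts, one per cell (e.g. from
#'   \code{\link{sampleFiringCounts}}).
#' @param direction direction convention, \code{"normal"} or \code{"random"}.
#' @return data.frame with one row per needle: \code{firerRow},
#'   \code{firerId}, base point \code{bx, by}, unit direction \code{ux, uy}.
#' @export
spawnNeedles <- function(pop, counts, direction = c("normal", "random")) {
  stopifnot(is(pop, "Population"), length(counts) == nrow(pop@cells),
            all(counts >= 0))
  direction <- match.arg(direction)
  firerRow <- rep(seq_along(counts), counts)
  if (!length(firerRow))
    return(data.frame(firerRow = integer(), firerId = integer(),
                      bx = numeric(), by = numeric(),
                      ux = numeric(), uy = numeric()))
  b <- .sampleBoundary(pop@cells, firerRow)
  if (direction == "random") {
    xi <- runif(length(firerRow), -pi / 2, pi / 2)
    ux <- cos(xi) * b$nx - sin(xi) * b$ny
    uy <- sin(xi) * b$nx + cos(xi) * b$ny
  } else {
    ux <- b$nx; uy <- b$ny
  }
  data.frame(firerRow = firerRow, firerId = pop@cells$id[firerRow],
             bx = b$bx, by = b$by, ux = ux, uy = uy)
}

#' Resolve which cell each needle strikes first
#'
#' For each needle, finds the first cell (smallest entry distance along the
#' needle segment) whose capsule the needle enters, excluding the firer
#' itself. Dead-but-unlysed cells are valid targets: corpses absorb hits
#' until they lyse. Candidate cells come from a spatial hash (10 um square
#' elements by default); the result is identical to the all-pairs check.
#'
#' @param needles data.frame from \code{\link{spawnNeedles}}.
#' @param pop a \code{\linkS4class{Population}}.
#' @param gridSize spatial hash element size, um.
#' @return data.frame of hit events: \code{firerId}, \code{targetId},
#'   \code{distance} (entry distance along the needle, um). Needles that
#'   reach nothing produce no row.
#' @export
resolveHits <- function(needles, pop, gridSize = 10) {
  stopifnot(is(pop, "Population"))
  cells <- pop@cells
  if (!nrow(needles) || nrow(cells) == 0)
    return(data.frame(firerId = integer(), targetId = integer(),
                      distance = numeric()))
  res <- cpp_resolve_hits(needles$bx, needles$by, needles$ux, needles$uy,
                          needleLength(), as.integer(needles$firerRow),
                          cells$x, cells$y, cells$angle, cells$length,
                          cellRadius(), gridSize)
  hit <- res$target > 0
  data.frame(firerId = needles$firerId[hit],
             targetId = cells$id[res$target[hit]],
             distance = res$distance[hit])
}

#' Translocate toxin doses along resolved hits
#'
#' Each hit delivers the firer strain's arsenal to the struck cell:
#' accumulated toxin increases by the dose vector and integrity is
#' recomputed via the integrity equation. Kin are perfectly immune: hits
#' whose firer and target share a strain deliver nothing. Cells whose
#' integrity reaches zero are killed: growth stops (\code{kGrow = 0}) and
#' the death time is recorded; they persist as corpses until lysis.
#'
#' @param pop a \code{\linkS4class{Population}}.
#' @param hits data.frame from \code{\link{resolveHits}}.
#' @param strains list of \code{\linkS4class{Strain}} covering every strain
#'   label present.
#' @param B optional toxin interaction matrix.
#' @param now current simulation time (hours), stamped on new deaths;
#'   defaults to the population clock.
#' @return the intoxicated \code{Population}.
#' @export
intoxicate <- function(pop, hits, strains, B = NULL, now = pop@time) {
  stopifnot(is(pop, "Population"))
  if (!nrow(hits)) return(pop)
  cells <- pop@cells
  labels <- vapply(strains, strainLabel, "")
  row <- match(hits$targetId, cells$id)
  frow <- match(hits$firerId, cells$id)
  if (anyNA(row) || anyNA(frow))
    stop("hit refers to a cell id not present in the population")
  firerStrain <- match(cells$strain[frow], labels)
  targetStrain <- match(cells$strain[row], labels)
  if (anyNA(firerStrain) || anyNA(targetStrain))
    stop("population contains a strain label with no Strain definition")
  # kin immunity: same-strain hits deliver nothing
  keep <- firerStrain != targetStrain
  if (!any(keep)) return(pop)
  row <- row[keep]; firerStrain <- firerStrain[keep]

  dMat <- do.call(rbind, lapply(strains, function(s) s@d))
  aMat <- do.call(rbind, lapply(strains, function(s) s@a))
  # aggregate doses per target (several hits may land in one step)
  doses <- rowsum(dMat[firerStrain, , drop = FALSE], group = row)
  trow <- as.integer(rownames(doses))

  toxCols <- paste0("tox", seq_len(pop@nToxins))
  tox <- as.matrix(cells[trow, toxCols, drop = FALSE]) + doses
  cells[trow, toxCols] <- tox
  a <- aMat[match(cells$strain[trow], labels), , drop = FALSE]
  I <- 1 - rowSums(a * tox)
  if (!is.null(B) && any(B != 0)) I <- I - rowSums((tox %*% B) * tox)
  cells$integrity[trow] <- I
  newlyDead <- trow[I <= 0 & !cells$dead[trow]]
  if (length(newlyDead)) {
    cells$dead[newlyDead] <- TRUE
    cells$kGrow[newlyDead] <- 0
    cells$deathTime[newlyDead] <- now
  }
  initialize(pop, cells = cells)
}

#' Remove corpses past their lysis delay
#'
#' Dead cells persist as physical corpses (still blocking needles) for
#' \eqn{1/k_{lysis}} hours after death, then are removed from the
#' simulation. Living cells are never removed.
#'
#' @param pop a \code{\linkS4class{Population}}.
#' @param now current simulation time, hours.
#' @param kLysis lysis rate, 1/hour (> 0).
#' @return the \code{Population} with lysed corpses dropped.
#' @export
cullAndLyse <- function(pop, now = pop@time, kLysis) {
  stopifnot(is(pop, "Population"), kLysis > 0)
  cells <- pop@cells
  lyse <- cells$dead & (now - cells$deathTime >= 1 / kLysis - 1e-12)
  if (!any(lyse)) return(pop)
  cells <- cells[!lyse, , drop = FALSE]
  rownames(cells) <- NULL
  initialize(pop, cells = cells)
}
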