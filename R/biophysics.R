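# Rod-cell biophysics: spherocylinder geometry, exponential growth, lengthwise
# division, mechanical overlap relaxation and spatial binning on an unbounded
# 2-D plane.

#' Fixed cell radius (um)
#'
#' All cells are spherocylinders of radius 0.5 um; only the segment length
#' varies.
#' @return 0.5
#' @export
cellRadius <- function() 0.5

#' Default birth segment length (um)
#' @return 2
#' @export
birthLength <- function() 2

#' Spherocylinder volume/length conversions
#'
#' In 2-D the "volume" is the capsule footprint area: a rectangle of size
#' \code{L x 2R} plus two half-disc caps, \eqn{V = 2RL + \pi R^2}. The
#' conversion is closed-form in both directions at fixed radius.
#'
#' @param L segment length, um.
#' @param V capsule volume (area), um^2.
#' @param R cell radius, um.
#' @return \code{capsuleVolume}: volume; \code{lengthFromVolume}: segment
#'   length.
#' @export
capsuleVolume <- function(L, R = cellRadius()) 2 * R * L + pi * R^2

#' @rdname capsuleVolume
#' @export
lengthFromVolume <- function(V, R = cellRadius()) {
  L <- (V - pi * R^2) / (2 * R)
  if (any(L < -1e-9)) stop("volume below the minimal (zero-length) capsule")
  pmax(L, 0)
}

# Build the per-cell data.frame used by Population. All vectors recycled to
# length n; toxin amounts start at zero unless given as a matrix.
.cellFrame <- function(id, strainLabel, x, y, angle, length, nToxins,
                       kGrow = defaultGrowthRate(), growthMult = 1,
                       birthVolume = NULL, eta = 0, tox = NULL,
                       integrity = 1, dead = FALSE, deathTime = NA_real_) {
  n <- base::length(id)
  if (is.null(birthVolume)) birthVolume <- capsuleVolume(length)
  cells <- data.frame(id = as.integer(id),
                      strain = rep_len(strainLabel, n),
                      x = rep_len(x, n), y = rep_len(y, n),
                      angle = rep_len(angle, n),
                      length = rep_len(length, n),
                      birthVolume = rep_len(birthVolume, n),
                      eta = rep_len(eta, n),
                      kGrow = rep_len(kGrow, n),
                      growthMult = rep_len(growthMult, n),
                      integrity = rep_len(integrity, n),
                      dead = rep_len(dead, n),
                      deathTime = rep_len(deathTime, n),
                      stringsAsFactors = FALSE)
  if (is.null(tox)) tox <- matrix(0, n, nToxins)
  colnames(tox) <- paste0("tox", seq_len(nToxins))
  cbind(cells, as.data.frame(tox))
}

#' Assemble a population from a cell table
#'
#' @param cells data.frame in the \code{\linkS4class{Population}} layout
#'   (see that class for the required columns).
#' @param time simulation clock, hours.
#' @param nToxins number of \code{tox<i>} columns.
#' @return A \code{\linkS4class{Population}}.
#' @export
newPopulation <- function(cells, time = 0, nToxins = 2) {
  new("Population", cells = cells, time = time, nToxins = nToxins)
}

#' Grow cells exponentially
#'
#' Each living cell's volume increases as \eqn{dV/dt = k V} with
#' \eqn{k = k_{grow} \times} the strain's cost multiplier, i.e.
#' \eqn{V \to V e^{k\,dt}} over a timestep; the segment length is updated
#' consistently at fixed radius. Dead cells are unchanged.
#'
#' @param pop a \code{\linkS4class{Population}}.
#' @param dt timestep, hours (>= 0).
#' @return the grown \code{Population} (clock advanced by \code{dt}).
#' @export
growCells <- function(pop, dt) {
  stopifnot(is(pop, "Population"), dt >= 0)
  cells <- pop@cells
  alive <- !cells$dead
  if (any(alive)) {
    V <- capsuleVolume(cells$length[alive])
    V <- V * exp(cells$kGrow[alive] * cells$growthMult[alive] * dt)
    cells$length[alive] <- lengthFromVolume(V)
  }
  initialize(pop, cells = cells, time = pop@time + dt)
}

#' Divide cells that have reached their division volume
#'
#' A living cell divides lengthwise once its volume reaches
#' \eqn{2 V_0 + \eta}, where \eqn{V_0} is its birth volume and \eqn{\eta}
#' uniform noise on \eqn{[-0.1 V_0, +0.1 V_0]}. The two daughters have equal
#' volume summing exactly to the parent's, share the parent's orientation,
#' and are placed end-to-end so the pair's outer extent coincides with the
#' parent capsule (their inner caps overlap slightly; relaxation resolves
#' this). Each daughter records its own birth volume, draws a fresh
#' \eqn{\eta}, and inherits the parent's accumulated toxin amounts and
#' integrity unchanged.
#'
#' Consumes RNG for the daughters' division noise.
#'
#' @param pop a \code{\linkS4class{Population}}.
#' @param etaWidth half-width of the division-volume noise as a fraction of
#'   birth volume.
#' @return the \code{Population} after all due divisions.
#' @export
divideCells <- function(pop, etaWidth = 0.1) {
  stopifnot(is(pop, "Population"))
  cells <- pop@cells
  V <- capsuleVolume(cells$length)
  idx <- which(!cells$dead & V >= 2 * cells$birthVolume + cells$eta)
  if (!length(idx)) return(pop)
  k <- length(idx)
  Vd <- V[idx] / 2
  Ld <- lengthFromVolume(Vd)
  ux <- cos(cells$angle[idx]); uy <- sin(cells$angle[idx])
  off <- (cells$length[idx] - Ld) / 2
  nextId <- max(cells$id) + 1L

  daughter <- function(sgn, ids) {
    d <- cells[idx, , drop = FALSE]
    d$id <- ids
    d$x <- d$x + sgn * off * ux
    d$y <- d$y + sgn * off * uy
    d$length <- Ld
    d$birthVolume <- Vd
    d
  }
  d1 <- daughter(+1, seq.int(nextId, length.out = k))
  d2 <- daughter(-1, seq.int(nextId + k, length.out = k))
  # one fresh eta per daughter, in parent order then sign order
  etas <- runif(2 * k, -etaWidth, etaWidth) * Vd
  d1$eta <- etas[seq_len(k)]
  d2$eta <- etas[k + seq_len(k)]

  cells <- rbind(cells[-idx, , drop = FALSE], d1, d2)
  rownames(cells) <- NULL
  initialize(pop, cells = cells)
}

#' Relax mechanical overlaps between cells
#'
#' Growth and division push neighbouring capsules into one another; this
#' applies damped pairwise translations and rotations (position-based
#' iteration over grid-selected neighbour pairs) until the largest
#' surface-surface interpenetration is at most \code{tolerance} or the sweep
#' cap is reached. Lengths, volumes and life status never change.
#'
#' @param pop a \code{\linkS4class{Population}}.
#' @param tolerance largest permitted residual overlap, um.
#' @param maxIterations sweep cap; non-convergence raises a warning, not an
#'   error.
#' @param damping fraction of each pairwise correction applied per sweep.
#' @param binSize neighbour-search bin size, um; defaults to the largest
#'   capsule extent so every interacting pair shares a bin.
#' @return the displaced \code{Population}.
#' @export
relaxOverlaps <- function(pop, tolerance = 0.01, maxIterations = 100,
                          damping = 0.7, binSize = NULL) {
  stopifnot(is(pop, "Population"), tolerance > 0)
  cells <- pop@cells
  if (nrow(cells) < 2) return(pop)
  R <- cellRadius()
  if (is.null(binSize)) binSize <- max(cells$length) + 2 * R + 0.1
  res <- cpp_relax(cells$x, cells$y, cells$angle, cells$length, R,
                   tolerance, as.integer(maxIterations), binSize, damping)
  if (!res$converged)
    warning(sprintf(
      "overlap relaxation did not converge in %d sweeps (residual %.4g um)",
      as.integer(maxIterations), res$max_overlap))
  cells$x <- res$x; cells$y <- res$y; cells$angle <- res$angle
  initialize(pop, cells = cells)
}

#' Largest pairwise overlap in a population
#'
#' Exhaustive all-pairs check of capsule surface interpenetration (um);
#' intended for assertions on modest populations.
#' @param pop a \code{\linkS4class{Population}}.
#' @return largest overlap in um (<= 0 means no contact anywhere).
#' @export
maxOverlap <- function(pop) {
  cells <- pop@cells
  if (nrow(cells) < 2) return(0)
  cpp_max_overlap(cells$x, cells$y, cells$angle, cells$length, cellRadius())
}

# Integer bin range covered by an interval [lo, hi] at bin size h.
.binRange <- function(lo, hi, h) seq.int(floor(lo / h), floor(hi / h))

#' Bin cells on an infinite square grid
#'
#' Registers every cell in each grid element its capsule extent (segment
#' inflated by the radius) overlaps, so bin lookups return a superset of the
#' true neighbours of any query region.
#'
#' @param pop a \code{\linkS4class{Population}}.
#' @param cellSize grid element side, um (default 10).
#' @return A \code{\linkS4class{SpatialGrid}}.
#' @export
buildGrid <- function(pop, cellSize = 10) {
  stopifnot(is(pop, "Population"), cellSize > 0)
  cells <- pop@cells
  bins <- new.env(parent = emptyenv())
  R <- cellRadius()
  for (i in seq_len(nrow(cells))) {
    hx <- abs(cells$length[i] / 2 * cos(cells$angle[i])) + R
    hy <- abs(cells$length[i] / 2 * sin(cells$angle[i])) + R
    for (ix in .binRange(cells$x[i] - hx, cells$x[i] + hx, cellSize))
      for (iy in .binRange(cells$y[i] - hy, cells$y[i] + hy, cellSize)) {
        key <- paste0(ix, ",", iy)
        bins[[key]] <- c(bins[[key]], cells$id[i])
      }
  }
  new("SpatialGrid", cellSize = cellSize, bins = as.list(bins))
}

#' Query a spatial grid
#'
#' Ids registered in any bin overlapped by the axis-aligned query box; a
#' superset of the cells actually intersecting the box.
#'
#' @param grid a \code{\linkS4class{SpatialGrid}}.
#' @param xmin,xmax,ymin,ymax query box, um.
#' @return integer vector of cell ids (possibly empty).
#' @export
gridLookup <- function(grid, xmin, xmax, ymin, ymax) {
  h <- grid@cellSize
  keys <- as.vector(outer(.binRange(xmin, xmax, h),
                          .binRange(ymin, ymax, h),
                          function(ix, iy) paste0(ix, ",", iy)))
  sort(unique(unlist(grid@bins[intersect(keys, names(grid@bins))],
                     use.names = FALSE)))
}
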