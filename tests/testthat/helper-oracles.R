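# Independent geometry oracles, written against the same mathematical
# definitions as the compiled kernels but by a different route (generic 1-D
# optimisation / root finding instead of closed-form branch logic).

# distance from point p to the segment with centre, angle, length
oracleDistPointSeg <- function(px, py, cx, cy, angle, len) {
  ax <- cx - len / 2 * cos(angle); ay <- cy - len / 2 * sin(angle)
  bx <- cx + len / 2 * cos(angle); by <- cy + len / 2 * sin(angle)
  dx <- bx - ax; dy <- by - ay
  L2 <- dx^2 + dy^2
  t <- if (L2 < 1e-14) 0 else max(0, min(1, ((px - ax) * dx + (py - ay) * dy) / L2))
  sqrt((ax + t * dx - px)^2 + (ay + t * dy - py)^2)
}

# distance between two capsule axis segments via 1-D convex minimisation:
# min over t of dist(pointOnSeg2(t), seg1)
oracleSegSegDist <- function(c1, c2) {
  f <- function(t) {
    px <- c2["x"] - c2["len"] / 2 * cos(c2["angle"]) +
      t * c2["len"] * cos(c2["angle"])
    py <- c2["y"] - c2["len"] / 2 * sin(c2["angle"]) +
      t * c2["len"] * sin(c2["angle"])
    oracleDistPointSeg(px, py, c1["x"], c1["y"], c1["angle"], c1["len"])
  }
  if (c2["len"] < 1e-12) return(f(0.5))
  opt <- optimize(f, c(0, 1), tol = 1e-12)
  min(opt$objective, f(0), f(1))
}

# brute-force all-pairs maximum capsule overlap
oracleMaxOverlap <- function(pop, R = cellRadius()) {
  cells <- cellTable(pop)
  best <- 0
  n <- nrow(cells)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    c1 <- c(x = cells$x[i], y = cells$y[i], angle = cells$angle[i],
            len = cells$length[i])
    c2 <- c(x = cells$x[j], y = cells$y[j], angle = cells$angle[j],
            len = cells$length[j])
    best <- max(best, 2 * R - oracleSegSegDist(c1, c2))
  }
  best
}

# first-hit resolution by exhaustive search: for every needle x cell pair,
# find the entry distance (first t with dist(needle(t), axis) <= R) via
# optimize + uniroot, then keep the nearest struck cell.
oracleResolveHits <- function(needles, pop, R = cellRadius(),
                              nlen = needleLength()) {
  cells <- cellTable(pop)
  out <- data.frame(firerId = integer(), targetId = integer(),
                    distance = numeric())
  for (k in seq_len(nrow(needles))) {
    best <- NA_integer_; bestT <- Inf
    for (j in seq_len(nrow(cells))) {
      if (j == needles$firerRow[k]) next
      f <- function(t) oracleDistPointSeg(
        needles$bx[k] + t * needles$ux[k], needles$by[k] + t * needles$uy[k],
        cells$x[j], cells$y[j], cells$angle[j], cells$length[j]) - R
      tEntry <- if (f(0) <= 0) 0 else {
        opt <- optimize(f, c(0, nlen), tol = 1e-12)
        if (min(opt$objective, f(nlen)) > 0) NA_real_
        else uniroot(f, c(0, if (opt$objective <= 0) opt$minimum else nlen),
                     tol = 1e-12)$root
      }
      if (!is.na(tEntry) && tEntry < bestT) { bestT <- tEntry; best <- j }
    }
    if (!is.na(best))
      out <- rbind(out, data.frame(firerId = needles$firerId[k],
                                   targetId = cells$id[best],
                                   distance = bestT))
  }
  out
}

# scatter n cells at random non-degenerate poses in a box
randomPopulation <- function(n, box = 20, lenRange = c(1, 4), nToxins = 2) {
  cells <- T6SSim:::.cellFrame(
    id = seq_len(n), strainLabel = "s",
    x = runif(n, -box, box), y = runif(n, -box, box),
    angle = runif(n, 0, 2 * pi),
    length = runif(n, lenRange[1], lenRange[2]), nToxins = nToxins)
  newPopulation(cells, nToxins = nToxins)
}

# n identical cells at the origin (for firing-statistics checks)
replicatedPop <- function(n, kGrow = log(2)) {
  cells <- T6SSim:::.cellFrame(id = seq_len(n), strainLabel = "s",
                               x = 0, y = 0, angle = 0, length = 2,
                               nToxins = 2, kGrow = kGrow)
  newPopulation(cells, nToxins = 2)
}

# single cell population helper
singleCellPop <- function(length = 2, kGrow = log(2), eta = 0, nToxins = 2,
                          strainLabel = "s") {
  cells <- T6SSim:::.cellFrame(id = 1L, strainLabel = strainLabel,
                               x = 0, y = 0, angle = 0, length = length,
                               nToxins = nToxins, kGrow = kGrow, eta = eta)
  newPopulation(cells, nToxins = nToxins)
}
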