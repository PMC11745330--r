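# Configuration parsing/validation, deterministic fixtures, result
# serialization and the command-line surface.

#' Derive a reproducible sub-seed
#'
#' All randomness in the package flows from one top-level seed; substreams
#' (replicates, trajectories, per-step streams) use
#' \code{(seed * 69069 + 1013 * hash(role) + index) mod (2^31 - 1)}, where
#' \code{hash} is a position-weighted sum of the role string's character
#' codes. Deterministic across platforms and independent of scheduling.
#'
#' @param seed top-level integer seed.
#' @param role short string naming the substream family.
#' @param index substream index within the family.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(seed, role, index = 0) {
  h <- sum(utf8ToInt(role) * seq_along(utf8ToInt(role)))
  # products stay below 2^53, so double arithmetic is exact here
  as.integer(((seed %% 2147483647) * 69069 + 1013 * h + index) %% 2147483647)
}

.runConfigDefaults <- function() {
  list(
    kind = "compete",
    attackerD = c(1, 0),        # single-toxin-A attacker
    mutantA = c(0, 1),          # fully A-resistant mutant
    susceptibleA = c(1, 1),
    counts = c(500, 90, 10),    # attacker : susceptible : mutant
    arenaRadius = 50,           # um
    duration = 10,              # hours
    dt = 0.025,                 # hours
    kFire = 10,                 # firings / cell / hour
    kLysis = 2,                 # per hour (corpse persistence 0.5 h)
    costCoefficient = 0,
    B = NULL,                   # NULL = purely additive toxins
    sigma = 0.1,                # mutation s.d.
    maxSteps = 30,              # mutations per trajectory
    trajectories = 30,
    backend = "simplified",
    trajectoryDuration = 1.5,   # hours per selection competition (abm)
    replicates = 20,
    seed = 1,
    needleDirection = "normal",
    outputDir = "."
  )
}

#' Parse and validate a run configuration
#'
#' Accepts a named list, or a path to a JSON or YAML file of key-value
#' pairs. Unknown keys, out-of-range values and malformed vectors raise an
#' error naming the offending key. Omitted keys take the package defaults
#' (500:90:10 seeding in a 50 um disc, 10 h at dt = 0.025 h, kFire = 10,
#' kLysis = 2, mutation sigma = 0.1).
#'
#' @param input named list or file path.
#' @return validated named list of class \code{"RunConfig"} with all
#'   defaults applied.
#' @examples
#' cfg <- parseRunConfig(list(kind = "evolve", attackerD = c(1, 1)))
#' @export
parseRunConfig <- function(input = list()) {
  if (is.character(input) && length(input) == 1L) {
    if (!file.exists(input)) stop("config file not found: ", input)
    input <- if (grepl("\\.ya?ml$", input, ignore.case = TRUE))
      yaml::read_yaml(input)
    else jsonlite::fromJSON(input, simplifyVector = TRUE)
  }
  if (!is.list(input)) stop("config must be a named list or a file path")
  defaults <- .runConfigDefaults()
  unknown <- setdiff(names(input), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, input, keep.null = TRUE)

  chkProb <- function(key) {
    v <- cfg[[key]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop("config key '", key, "' must lie in [0, 1]")
  }
  chkPos <- function(key, strict = TRUE) {
    v <- cfg[[key]]
    if (any(!is.finite(v)) || (strict && any(v <= 0)) ||
        (!strict && any(v < 0)))
      stop("config key '", key, "' must be ",
           if (strict) "positive" else "non-negative")
  }
  if (!cfg$kind %in% c("compete", "evolve", "sweep", "analytic"))
    stop("config key 'kind' must be compete, evolve, sweep or analytic")
  chkProb("mutantA"); chkProb("susceptibleA")
  chkPos("attackerD", strict = FALSE)
  chkPos("counts", strict = FALSE)
  chkPos("arenaRadius"); chkPos("duration"); chkPos("dt")
  chkPos("kFire", strict = FALSE); chkPos("kLysis")
  chkPos("costCoefficient", strict = FALSE)
  chkPos("sigma", strict = FALSE)
  chkPos("trajectoryDuration")
  if (!is.null(cfg$B)) {
    cfg$B <- as.matrix(cfg$B)
    if (nrow(cfg$B) != ncol(cfg$B) || any(!is.finite(cfg$B)))
      stop("config key 'B' must be a finite square matrix")
  }
  if (length(cfg$mutantA) != length(cfg$attackerD) ||
      length(cfg$susceptibleA) != length(cfg$attackerD))
    stop("config keys 'attackerD', 'mutantA', 'susceptibleA' must agree ",
         "on the number of toxins")
  if (!cfg$backend %in% c("simplified", "abm"))
    stop("config key 'backend' must be 'simplified' or 'abm'")
  if (!cfg$needleDirection %in% c("normal", "random"))
    stop("config key 'needleDirection' must be 'normal' or 'random'")
  for (key in c("maxSteps", "trajectories", "replicates", "seed"))
    if (!is.finite(cfg[[key]]) || cfg[[key]] < 0)
      stop("config key '", key, "' must be a non-negative number")
  structure(cfg, class = "RunConfig")
}

#' Write a run configuration to JSON
#'
#' Inverse of \code{\link{parseRunConfig}}: a written config parses back to
#' an identical object.
#' @param cfg a RunConfig.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Build a CompetitionConfig from a RunConfig
#' @param cfg a RunConfig (see \code{\link{parseRunConfig}}).
#' @return A \code{\linkS4class{CompetitionConfig}}.
#' @export
asCompetitionConfig <- function(cfg) {
  tripartiteConfig(attackerD = cfg$attackerD, mutantA = cfg$mutantA,
                   susceptibleA = cfg$susceptibleA, counts = cfg$counts,
                   arenaRadius = cfg$arenaRadius, duration = cfg$duration,
                   dt = cfg$dt, kFire = cfg$kFire, kLysis = cfg$kLysis,
                   B = cfg$B, costCoefficient = cfg$costCoefficient,
                   replicates = cfg$replicates,
                   needleDirection = cfg$needleDirection)
}

#' Write a population snapshot as CSV
#'
#' One row per living or dead-but-unlysed cell: id, strain, pose, length,
#' integrity, per-toxin amounts and the death flag.
#' @param pop a \code{\linkS4class{Population}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSnapshot <- function(pop, path) {
  cols <- c("id", "strain", "x", "y", "angle", "length", "integrity",
            paste0("tox", seq_len(pop@nToxins)), "dead")
  write.csv(pop@cells[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write run outputs and a provenance manifest
#'
#' Serializes results as RFC-4180 CSV plus a JSON manifest recording the
#' configuration, seed and package version, so any run can be replayed
#' bit-for-bit. Competition results produce \code{timeseries.csv} (one row
#' per replicate, step and strain) and \code{summary.csv}; trajectory
#' results produce \code{trajectories.csv} (one row per step with the
#' resident profile and outcome) and \code{trajectory_summary.csv}; sweep
#' results produce \code{sweep_replicates.csv} and \code{sweep_summary.csv}.
#'
#' @param x list of \code{\linkS4class{CompetitionResult}}, list of
#'   \code{\linkS4class{TrajectoryRecord}}, or a \code{\link{protectionSweep}}
#'   result.
#' @param directory output directory (created if needed).
#' @param config optional RunConfig to embed in the manifest.
#' @param seed the top-level seed used.
#' @return character vector of files written, invisibly.
#' @export
writeOutputs <- function(x, directory, config = NULL, seed = NA) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  out <- function(name) file.path(directory, name)

  if (is.list(x) && length(x) && is(x[[1]], "CompetitionResult")) {
    ts <- do.call(rbind, lapply(seq_along(x), function(i) {
      r <- x[[i]]
      data.frame(replicate = i,
                 step = rep(seq_len(nrow(r@counts)) - 1L, ncol(r@counts)),
                 t = rep(r@times, ncol(r@counts)),
                 strain = rep(colnames(r@counts), each = nrow(r@counts)),
                 count = as.vector(r@counts))
    }))
    write.csv(ts, out("timeseries.csv"), row.names = FALSE)
    write.csv(summarizeCompetitions(x), out("summary.csv"),
              row.names = FALSE)
    files <- c(files, out("timeseries.csv"), out("summary.csv"))
  } else if (is.list(x) && length(x) && is(x[[1]], "TrajectoryRecord")) {
    steps <- do.call(rbind, lapply(seq_along(x), function(i) {
      r <- x[[i]]
      n <- nrow(r@states)
      df <- data.frame(trajectory = i, step = seq_len(n) - 1L,
                       outcome = c(NA, r@outcomes))
      for (j in seq_len(ncol(r@states)))
        df[[paste0("a", j)]] <- r@states[, j]
      hitsFun <- function(k) nHits(r@states[k, ], r@attacker)
      df$nHits <- vapply(seq_len(n), hitsFun, 1)
      df
    }))
    write.csv(steps, out("trajectories.csv"), row.names = FALSE)
    write.csv(trajectorySummary(x)$trajectories,
              out("trajectory_summary.csv"), row.names = FALSE)
    files <- c(files, out("trajectories.csv"), out("trajectory_summary.csv"))
  } else if (is.list(x) && !is.null(x$summary) && !is.null(x$replicates)) {
    write.csv(x$replicates, out("sweep_replicates.csv"), row.names = FALSE)
    write.csv(x$summary, out("sweep_summary.csv"), row.names = FALSE)
    files <- c(files, out("sweep_replicates.csv"), out("sweep_summary.csv"))
  } else stop("writeOutputs: unrecognized result object")

  manifest <- list(package = "T6SSim",
                   version = as.character(packageVersion("T6SSim")),
                   seed = seed,
                   config = if (!is.null(config)) unclass(config),
                   written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(c(files, out("manifest.json")))
}

#' Deterministic toy populations for tests and examples
#'
#' \describe{
#'   \item{overlap-pair}{two parallel rods interpenetrating by 0.2 um
#'     (relaxation oracle).}
#'   \item{lattice3x3}{nine cells on a 4 um square lattice, axes aligned.}
#'   \item{aimed-needle}{two cells 0.3 um apart along the x axis, so a
#'     needle fired from the first along +x strikes the second.}
#'   \item{fig1-disc}{a 500:90:10 attacker:susceptible:mutant disc of 600
#'     cells, radius 50 um, seeded and relaxed at the given seed.}
#' }
#' Identical (name, seed) pairs always return identical fixtures.
#'
#' @param name fixture name.
#' @param seed RNG seed (used where the fixture is random).
#' @return A \code{\linkS4class{Population}}.
#' @export
makeFixture <- function(name, seed = 1) {
  set.seed(seed)
  switch(name,
    "overlap-pair" = {
      gap <- 2 * cellRadius() - 0.2  # centre distance: overlap of 0.2 um
      cells <- .cellFrame(id = 1:2, strainLabel = "s",
                          x = c(0, 0), y = c(0, gap), angle = c(0, 0),
                          length = c(2, 2), nToxins = 2)
      newPopulation(cells, nToxins = 2)
    },
    "lattice3x3" = {
      g <- expand.grid(x = c(0, 4, 8), y = c(0, 4, 8))
      cells <- .cellFrame(id = seq_len(9), strainLabel = "s",
                          x = g$x, y = g$y, angle = 0,
                          length = 2, nToxins = 2)
      newPopulation(cells, nToxins = 2)
    },
    "aimed-needle" = {
      # surfaces 0.3 um apart along x: centre gap = L + 2R + 0.3
      cells <- .cellFrame(id = 1:2, strainLabel = c("attacker", "target"),
                          x = c(0, 2 + 2 * cellRadius() + 0.3), y = c(0, 0),
                          angle = 0, length = 2, nToxins = 2)
      newPopulation(cells, nToxins = 2)
    },
    "fig1-disc" = seedDisc(tripartiteConfig()),
    stop("unknown fixture name: ", name))
}

.cliUsage <- function() {
  cat("usage: t6ss <compete|evolve|sweep|nhits> [options]\n",
      "  compete --config FILE [--seed N] [--replicates N] [--out DIR]\n",
      "  evolve  --backend simplified|abm [--config FILE] [--seed N]\n",
      "          [--trajectories N] [--out DIR]\n",
      "  sweep   [--config FILE] [--seed N] [--replicates N] [--out DIR]\n",
      "  nhits   --a v1,v2,... --d v1,v2,...\n", sep = "")
}

.cliParseOpts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

#' Command-line entry point
#'
#' Thin argv-driven wrapper over the package functions; used by the
#' \code{inst/scripts/t6ss} Rscript. Subcommands: \code{compete} (replicated
#' competitions), \code{evolve} (evolutionary trajectories), \code{sweep}
#' (cross-protection sweep), \code{nhits} (analytic phenotypic resistance).
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @examples
#' cliMain(c("nhits", "--a", "0.7", "--d", "1"))  # prints 2
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) { .cliUsage(); return(invisible(1L)) }
    sub <- args[1]
    opts <- .cliParseOpts(args[-1])
    numvec <- function(s) as.numeric(strsplit(s, ",")[[1]])
    cfg <- parseRunConfig(if (!is.null(opts$config)) opts$config else list())
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts$replicates)) cfg$replicates <- as.integer(opts$replicates)
    if (!is.null(opts$trajectories))
      cfg$trajectories <- as.integer(opts$trajectories)
    if (!is.null(opts$backend)) cfg$backend <- opts$backend
    if (!is.null(opts$out)) cfg$outputDir <- opts$out

    switch(sub,
      nhits = {
        if (is.null(opts$a) || is.null(opts$d))
          stop("nhits requires --a and --d")
        cat(format(nHits(numvec(opts$a), numvec(opts$d))), "\n", sep = "")
      },
      compete = {
        res <- runCompetition(asCompetitionConfig(cfg), seed = cfg$seed,
                              replicates = cfg$replicates)
        writeOutputs(res, cfg$outputDir, config = cfg, seed = cfg$seed)
        cat(sprintf("mean competitive advantage: %.4g over %d replicates\n",
                    meanCompetitiveAdvantage(res), length(res)))
      },
      evolve = {
        recs <- runTrajectories(cfg$trajectories, seed = cfg$seed,
                                backend = cfg$backend,
                                attackerD = cfg$attackerD,
                                sigma = cfg$sigma, maxSteps = cfg$maxSteps,
                                B = cfg$B,
                                costCoefficient = cfg$costCoefficient,
                                abmControl = list(
                                  counts = cfg$counts,
                                  duration = cfg$trajectoryDuration,
                                  arenaRadius = cfg$arenaRadius,
                                  kFire = cfg$kFire, kLysis = cfg$kLysis,
                                  dt = cfg$dt))
        writeOutputs(recs, cfg$outputDir, config = cfg, seed = cfg$seed)
        print(trajectorySummary(recs)$counts)
      },
      sweep = {
        grid <- data.frame(nAttacker = cfg$counts[1],
                           nSusceptible = cfg$counts[2],
                           nMutant = cfg$counts[3])
        sw <- protectionSweep(grid, attackerD = cfg$attackerD,
                              arenaRadius = cfg$arenaRadius,
                              duration = cfg$duration, dt = cfg$dt,
                              kFire = cfg$kFire, kLysis = cfg$kLysis,
                              replicates = cfg$replicates, seed = cfg$seed)
        writeOutputs(sw, cfg$outputDir, config = cfg, seed = cfg$seed)
        print(sw$summary)
      },
      { .cliUsage(); stop("unknown subcommand: ", sub) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
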