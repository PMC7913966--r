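#' Configure the evolutionary search
#'
#' Returns an [EvolutionConfig-class] holding every hyper-parameter of
#' [evolve()]. The defaults are the recommended operating point: population
#' of 100, at most 100 generations with early stopping after 10 stagnant
#' generations, crossover probability 0.4 and mutation probability 0.1 per
#' operator, all initialization, crossover and mutation operators enabled.
#'
#' \code{maxLen} defaults to the shortest series length M of the dataset the
#' configuration is eventually used with. \code{W}, the upper bound on the
#' size of freshly initialized sets, defaults to \code{ceiling(sqrt(M))}:
#' initial sets are deliberately small and grow through the add mutation,
#' which keeps early generations cheap and final sets compact.
#'
#' @param popSize population size (>= 2).
#' @param generations maximum generations.
#' @param patience early-stopping window in generations.
#' @param pMutation per-operator mutation probability.
#' @param pCrossover per-operator crossover probability.
#' @param maxLen maximum shapelet length; NA resolves to M at run time.
#' @param minLen minimum shapelet length.
#' @param W initial set sizes are drawn uniformly from 2..W; NA resolves to
#'   \code{ceiling(sqrt(M))}.
#' @param maxShapelets hard cap on shapelets per individual (Inf = none).
#'   Useful to force a fixed-size transform, e.g. a single shapelet.
#' @param tournamentSize selection tournament size.
#' @param initOps subset of \code{c("kmeans", "random")}.
#' @param crossoverOps subset of \code{c("set", "shapelet", "merge")}.
#' @param mutationOps subset of \code{c("mask", "remove", "add")}.
#' @param ridgePenalty weight decay of the fitness model (see
#'   [evaluateFitness()]).
#' @param seed integer seed applied by [evolve()]; NA leaves the RNG alone.
#' @return an \code{EvolutionConfig}.
#' @export
evolutionConfig <- function(popSize = 100, generations = 100, patience = 10,
                            pMutation = 0.1, pCrossover = 0.4,
                            maxLen = NA, minLen = 4, W = NA,
                            maxShapelets = Inf, tournamentSize = 3,
                            initOps = c("kmeans", "random"),
                            crossoverOps = c("set", "shapelet", "merge"),
                            mutationOps = c("mask", "remove", "add"),
                            ridgePenalty = 0.01, seed = NA) {
  new("EvolutionConfig",
      popSize = as.integer(popSize), generations = as.integer(generations),
      patience = as.integer(patience),
      pMutation = as.numeric(pMutation), pCrossover = as.numeric(pCrossover),
      minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      W = as.integer(W), maxShapelets = as.numeric(maxShapelets),
      tournamentSize = as.integer(tournamentSize),
      initOps = if (length(initOps))
        match.arg(initOps, .INIT_OPS, several.ok = TRUE) else
          stop("initOps must enable at least one initialization operator"),
      crossoverOps = if (length(crossoverOps))
        match.arg(crossoverOps, .CROSSOVER_OPS, several.ok = TRUE) else character(),
      mutationOps = if (length(mutationOps))
        match.arg(mutationOps, .MUTATION_OPS, several.ok = TRUE) else character(),
      ridgePenalty = as.numeric(ridgePenalty), seed = as.integer(seed))
}

# resolve data-dependent defaults against a dataset
.resolveConfig <- function(config, dataset) {
  M <- minSeriesLength(dataset)
  if (is.na(config@maxLen)) config@maxLen <- as.integer(M)
  if (config@maxLen > M)
    stop("maxLen (", config@maxLen, ") exceeds the shortest series length (", M, ")")
  if (is.na(config@W)) config@W <- as.integer(max(2L, ceiling(sqrt(M))))
  validObject(config)
  config
}

#' @export
setMethod("show", "EvolutionConfig", function(object) {
  cat("EvolutionConfig: P =", object@popSize, ", G =", object@generations,
      ", patience =", object@patience, "\n")
  cat("  pCrossover =", object@pCrossover, ", pMutation =", object@pMutation,
      ", tournament =", object@tournamentSize, "\n")
  cat("  lengths in [", object@minLen, ",",
      if (is.na(object@maxLen)) "M" else object@maxLen,
      "], W =", if (is.na(object@W)) "ceiling(sqrt(M))" else object@W,
      ", maxShapelets =", object@maxShapelets, "\n")
  cat("  ops:", paste(object@initOps, collapse = ","), "|",
      paste(object@crossoverOps, collapse = ","), "|",
      paste(object@mutationOps, collapse = ","), "\n")
  cat("  seed:", object@seed, "\n")
})

#' Flat key-value round trip for configurations
#'
#' Writes/reads an [EvolutionConfig-class] as a plain \code{key = value} text
#' file, one parameter per line.
#'
#' @param config an \code{EvolutionConfig}.
#' @param path file path.
#' @return \code{readEvolutionConfig} returns an \code{EvolutionConfig};
#'   \code{writeEvolutionConfig} returns \code{path} invisibly.
#' @export
writeEvolutionConfig <- function(config, path) {
  kv <- c(
    popSize = config@popSize, generations = config@generations,
    patience = config@patience, pMutation = config@pMutation,
    pCrossover = config@pCrossover, minLen = config@minLen,
    maxLen = config@maxLen, W = config@W, maxShapelets = config@maxShapelets,
    tournamentSize = config@tournamentSize, ridgePenalty = config@ridgePenalty,
    seed = config@seed)
  lines <- c(paste(names(kv), unname(kv), sep = " = "),
             paste("initOps =", paste(config@initOps, collapse = ",")),
             paste("crossoverOps =", paste(config@crossoverOps, collapse = ",")),
             paste("mutationOps =", paste(config@mutationOps, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeEvolutionConfig
#' @export
readEvolutionConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(parts, `[`, "", 1))
  vals <- trimws(vapply(parts, function(p) paste(p[-1], collapse = "="), ""))
  names(vals) <- keys
  splitOps <- function(v) if (nzchar(v)) strsplit(v, ",", fixed = TRUE)[[1]] else character()
  num <- function(k) {
    v <- vals[[k]]
    if (identical(v, "NA")) NA else suppressWarnings(as.numeric(v))
  }
  evolutionConfig(
    popSize = num("popSize"), generations = num("generations"),
    patience = num("patience"), pMutation = num("pMutation"),
    pCrossover = num("pCrossover"), maxLen = num("maxLen"),
    minLen = num("minLen"), W = num("W"), maxShapelets = num("maxShapelets"),
    tournamentSize = num("tournamentSize"),
    initOps = splitOps(vals[["initOps"]]),
    crossoverOps = splitOps(vals[["crossoverOps"]]),
    mutationOps = splitOps(vals[["mutationOps"]]),
    ridgePenalty = num("ridgePenalty"), seed = num("seed"))
}
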