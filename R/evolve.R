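#' Evolve a shapelet set
#'
#' Runs the generational loop: evaluate unevaluated individuals, select P
#' parents by rank-weighted tournament, pair consecutive parents and apply
#' each enabled crossover operator independently with probability
#' \code{pCrossover}, apply each enabled mutation operator to each offspring
#' independently with probability \code{pMutation}, re-evaluate modified
#' offspring, and form the next population from the offspring with the
#' incumbent elite injected in place of the worst offspring. The elite is
#' never crossed over or mutated, so the best fitness is non-increasing
#' across generations. The loop stops after \code{generations} generations,
#' or early once the elite's fitness has not strictly improved (in the
#' lexicographic (error, complexity) order) for \code{patience} consecutive
#' generations.
#'
#' Only individuals whose shapelets changed are re-evaluated; fitness values
#' are cached on the individuals themselves.
#'
#' @param dataset a [TimeSeriesDataset-class] with at least two classes.
#' @param config an [EvolutionConfig-class]; \code{config@seed} (unless NA)
#'   seeds the RNG so that identical data, configuration and seed give an
#'   identical elite and log.
#' @return a list with components
#'   \describe{
#'     \item{best}{the elite [ShapeletSet-class], fitness cached,}
#'     \item{log}{data frame with one row per generation (generation 0 is the
#'       initial population): best error, best complexity, best set size,
#'       mean population error, cumulative evaluation count,}
#'     \item{reason}{\code{"patience"}, \code{"max_generations"} or
#'       \code{"converged"},}
#'     \item{evaluations}{total number of fitness evaluations.}
#'   }
#' @examples
#' ds <- makeMotifTwoClass(nPerClass = 5, length = 30, motifLength = 6, seed = 1)
#' res <- evolve(ds, evolutionConfig(popSize = 10, generations = 5, seed = 1))
#' res$log
#' @export
evolve <- function(dataset, config = evolutionConfig()) {
  config <- .resolveConfig(config, dataset)
  if (length(unique(dataset@labels)) < 2L)
    stop("evolution requires at least two classes")
  if (!is.na(config@seed)) set.seed(config@seed)

  minLen <- config@minLen; maxLen <- config@maxLen
  maxShp <- config@maxShapelets
  yInt <- .labelCodes(dataset); lev <- labelLevels(dataset)
  evalErr <- function(shp)
    .fitnessError(distanceMatrix(shp, dataset), yInt, lev, config@ridgePenalty)

  pop <- lapply(initializePopulation(dataset, config), .shapeletList)
  P <- config@popSize
  err <- numeric(P); cplx <- numeric(P)
  for (i in seq_len(P)) {
    err[i] <- evalErr(pop[[i]]); cplx[i] <- sum(lengths(pop[[i]]))
  }
  nEval <- P

  bestOf <- function() {
    b <- 1L
    for (i in seq_len(P))
      if (err[i] < err[b] || (err[i] == err[b] && cplx[i] < cplx[b])) b <- i
    b
  }
  b <- bestOf()
  elite <- pop[[b]]; eliteFit <- c(err[b], cplx[b])

  log <- data.frame(generation = 0L, bestError = eliteFit[1],
                    bestComplexity = eliteFit[2],
                    bestSize = length(elite), meanError = mean(err),
                    evaluations = nEval)
  stale <- 0L
  reason <- "max_generations"

  for (g in seq_len(config@generations)) {
    # selection (indices into current population)
    sel <- vapply(seq_len(P), function(i)
      .tournamentIdx(err, cplx, min(config@tournamentSize, P)), integer(1))
    off <- pop[sel]; offErr <- err[sel]; offCplx <- cplx[sel]
    modified <- logical(P)

    # crossover on consecutive pairs; operators fire independently
    for (i in seq(1L, P - 1L, by = 2L)) {
      a <- off[[i]]; b2 <- off[[i + 1L]]; changed <- FALSE
      for (op in config@crossoverOps) {
        if (stats::runif(1) < config@pCrossover) {
          ch <- switch(op,
            set = .cxSet(a, b2),
            shapelet = .cxShapelet(a, b2, maxLen),
            merge = .cxMerge(a, b2))
          a <- ch[[1]]; b2 <- ch[[2]]; changed <- TRUE
        }
      }
      if (changed) {
        if (length(a) > maxShp) a <- a[seq_len(maxShp)]
        if (length(b2) > maxShp) b2 <- b2[seq_len(maxShp)]
        off[[i]] <- a; off[[i + 1L]] <- b2
        modified[c(i, i + 1L)] <- TRUE
      }
    }

    # mutation, applied per offspring
    for (i in seq_len(P)) {
      s <- off[[i]]; changed <- FALSE
      for (op in config@mutationOps) {
        if (stats::runif(1) < config@pMutation) {
          s <- switch(op,
            mask = .mutMask(s, minLen),
            remove = .mutRemove(s),
            add = .mutAdd(s, dataset, minLen, maxLen, maxShp))
          changed <- TRUE
        }
      }
      if (changed) { off[[i]] <- s; modified[i] <- TRUE }
    }

    for (i in which(modified)) {
      offErr[i] <- evalErr(off[[i]])
      offCplx[i] <- sum(lengths(off[[i]]))
      nEval <- nEval + 1L
    }

    # elitism: the incumbent elite replaces the worst offspring
    worst <- 1L
    for (i in seq_len(P))
      if (offErr[i] > offErr[worst] ||
          (offErr[i] == offErr[worst] && offCplx[i] > offCplx[worst])) worst <- i
    off[[worst]] <- elite; offErr[worst] <- eliteFit[1]; offCplx[worst] <- eliteFit[2]

    pop <- off; err <- offErr; cplx <- offCplx
    b <- bestOf()
    if (err[b] < eliteFit[1] ||
        (err[b] == eliteFit[1] && cplx[b] < eliteFit[2])) {
      elite <- pop[[b]]; eliteFit <- c(err[b], cplx[b]); stale <- 0L
    } else {
      stale <- stale + 1L
    }

    log <- rbind(log, data.frame(generation = g, bestError = eliteFit[1],
                                 bestComplexity = eliteFit[2],
                                 bestSize = length(elite),
                                 meanError = mean(err), evaluations = nEval))
    if (eliteFit[1] <= 0) { reason <- "converged"; break }
    if (stale >= config@patience) { reason <- "patience"; break }
  }

  list(best = .asSet(elite, fitness = c(error = eliteFit[1],
                                        complexity = eliteFit[2])),
       log = log, reason = reason, evaluations = nEval)
}

#' Write an evolution log as line-delimited records
#'
#' One tab-separated record per generation: generation index, best error,
#' best complexity, best set size, mean population error, cumulative
#' evaluations.
#'
#' @param log the \code{log} component of an [evolve()] result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEvolutionLog <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
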