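# --- initialization -------------------------------------------------------

# one random subsequence, series and offset uniform, length uniform
.randomSubsequence <- function(dataset, minLen, maxLen) {
  t <- dataset@series[[sample.int(nSeries(dataset), 1)]]
  hi <- min(maxLen, length(t))
  L <- if (hi > minLen) sample(minLen:hi, 1) else minLen
  o <- sample.int(length(t) - L + 1L, 1)
  t[o:(o + L - 1L)]
}

#' Initialization operators
#'
#' \code{initKmeans} draws one common length L uniformly from
#' \code{[minLen, maxLen]}, samples \code{max(10 * K, 50)} random
#' subsequences of that length, clusters them with K-means and returns the K
#' centroids as a shapelet set; clusters that cannot be formed (fewer
#' distinct subsequences than K) are replaced by fresh random subsequences.
#' \code{initRandom} returns K verbatim subsequences with independently
#' uniform lengths, series and offsets.
#'
#' Both consume the session RNG; seed the stream (or use the \code{seed} slot
#' of the configuration passed to [evolve()]) for reproducibility.
#'
#' @param dataset a [TimeSeriesDataset-class].
#' @param K number of shapelets to generate (>= 1).
#' @param minLen,maxLen admissible shapelet lengths; \code{maxLen = NULL}
#'   means the shortest series length.
#' @return a [ShapeletSet-class] of size K.
#' @export
initKmeans <- function(dataset, K, minLen = 4, maxLen = NULL) {
  M <- minSeriesLength(dataset)
  if (is.null(maxLen)) maxLen <- M
  if (minLen > M) stop("dataset series are shorter than minLen (", minLen, ")")
  L <- if (maxLen > minLen) sample(minLen:maxLen, 1) else minLen
  nDraws <- max(10L * K, 50L)
  X <- t(vapply(seq_len(nDraws), function(i) {
    t <- dataset@series[[sample.int(nSeries(dataset), 1)]]
    o <- sample.int(length(t) - L + 1L, 1)
    t[o:(o + L - 1L)]
  }, numeric(L)))
  Xu <- unique(X)
  if (nrow(Xu) <= K) {
    centers <- Xu
  } else {
    centers <- stats::kmeans(X, centers = K, iter.max = 25L)$centers
  }
  out <- lapply(seq_len(nrow(centers)), function(i) as.numeric(centers[i, ]))
  while (length(out) < K)
    out <- c(out, list(.randomSubsequence(dataset, minLen, maxLen)))
  .asSet(out)
}

#' @rdname initKmeans
#' @export
initRandom <- function(dataset, K, minLen = 4, maxLen = NULL) {
  M <- minSeriesLength(dataset)
  if (is.null(maxLen)) maxLen <- M
  if (minLen > M) stop("dataset series are shorter than minLen (", minLen, ")")
  .asSet(lapply(seq_len(K), function(i)
    .randomSubsequence(dataset, minLen, maxLen)))
}

#' Seed a population of shapelet sets
#'
#' Creates \code{popSize} individuals. Each individual's size K is drawn
#' uniformly from \code{2..W} (clamped to \code{maxShapelets}) and its
#' generating strategy is chosen uniformly among the enabled initialization
#' operators.
#'
#' @param dataset a [TimeSeriesDataset-class].
#' @param config an [EvolutionConfig-class].
#' @return list of [ShapeletSet-class] of length \code{config@popSize}.
#' @export
initializePopulation <- function(dataset, config) {
  config <- .resolveConfig(config, dataset)
  if (!length(config@initOps))
    stop("no initialization operators enabled")
  lapply(seq_len(config@popSize), function(i) {
    Kdraw <- if (config@W > 2L) sample(2:config@W, 1) else 2L
    K <- max(1L, min(Kdraw, config@maxShapelets))
    op <- if (length(config@initOps) == 1L) config@initOps else
      sample(config@initOps, 1)
    switch(op,
      kmeans = initKmeans(dataset, K, config@minLen, config@maxLen),
      random = initRandom(dataset, K, config@minLen, config@maxLen))
  })
}

# --- crossover ------------------------------------------------------------

# internal crossovers operate on plain lists of shapelets

# one- or two-point crossover at cut positions shared by both member lists
# (cuts are drawn within the shorter list, so identical parents reproduce
# themselves and the children's multiset union equals the parents')
.cxSet <- function(a, b) {
  lmin <- min(length(a), length(b))
  if (stats::runif(1) < 0.5) {  # one-point
    if (lmin < 2L) return(list(a, b))
    cut <- sample.int(lmin - 1L, 1)
    list(c(a[seq_len(cut)], b[(cut + 1):length(b)]),
         c(b[seq_len(cut)], a[(cut + 1):length(a)]))
  } else {                      # two-point
    if (lmin < 3L) return(list(a, b))
    cc <- sort(sample.int(lmin - 1L, 2))
    ch1 <- a; ch2 <- b
    ch1[(cc[1] + 1):cc[2]] <- b[(cc[1] + 1):cc[2]]
    ch2[(cc[1] + 1):cc[2]] <- a[(cc[1] + 1):cc[2]]
    list(ch1, ch2)
  }
}

.spliceShapelet <- function(x, y, maxLen) {
  Lm <- min(length(x), length(y))
  if (Lm < 2L) return(x)
  out <- if (stats::runif(1) < 0.5) {  # one-point at a common cut
    cut <- sample.int(Lm - 1L, 1)
    c(x[seq_len(cut)], y[(cut + 1):length(y)])
  } else {                             # two-point within the shorter length
    if (Lm < 3L) return(x)
    cc <- sort(sample.int(Lm - 1L, 2))
    out <- x
    out[(cc[1] + 1):cc[2]] <- y[(cc[1] + 1):cc[2]]
    out
  }
  if (length(out) > maxLen) out <- out[seq_len(maxLen)]
  out
}

.cxShapelet <- function(a, b, maxLen) {
  list(lapply(a, function(s) .spliceShapelet(s, b[[sample.int(length(b), 1)]], maxLen)),
       lapply(b, function(s) .spliceShapelet(s, a[[sample.int(length(a), 1)]], maxLen)))
}

.mergeShapelet <- function(x, y) {
  if (length(x) > length(y)) { tmp <- x; x <- y; y <- tmp }
  o <- sample.int(length(y) - length(x) + 1L, 1)
  (x + y[o:(o + length(x) - 1L)]) / 2
}

.cxMerge <- function(a, b) {
  list(lapply(a, function(s) .mergeShapelet(s, b[[sample.int(length(b), 1)]])),
       lapply(b, function(s) .mergeShapelet(s, a[[sample.int(length(a), 1)]])))
}

#' Crossover operators on shapelet sets
#'
#' Three recombination schemes, each taking two parent sets and returning two
#' children (fitness caches cleared):
#' \describe{
#'   \item{\code{crossoverSetPoint}}{one- or two-point crossover (probability
#'     1/2 each) on the ordered member lists: children are composed of whole
#'     shapelets from both parents and the multiset union of the children's
#'     shapelets equals that of the parents. Cut positions are uniform within
#'     each list; degenerate cuts return clones.}
#'   \item{\code{crossoverShapeletPoint}}{one- or two-point crossover applied
#'     to the value vectors of individual shapelets: each shapelet of one
#'     parent is spliced with a uniformly chosen shapelet of the other at a
#'     common cut within the shorter length.}
#'   \item{\code{crossoverMerge}}{barycenter merge: each shapelet of one
#'     parent is averaged pointwise with a uniformly chosen shapelet of the
#'     other; with unequal lengths the shorter is averaged against a uniform
#'     random window of the longer, the child having the shorter length.
#'     This operator can produce shapelets that occur nowhere in the data.}
#' }
#'
#' @param a,b parent [ShapeletSet-class] objects (or plain lists).
#' @param maxLen length cap applied to spliced children.
#' @return list of two \code{ShapeletSet} children.
#' @export
crossoverSetPoint <- function(a, b) {
  ch <- .cxSet(.shapeletList(a), .shapeletList(b))
  list(.asSet(ch[[1]]), .asSet(ch[[2]]))
}

#' @rdname crossoverSetPoint
#' @export
crossoverShapeletPoint <- function(a, b, maxLen = Inf) {
  ch <- .cxShapelet(.shapeletList(a), .shapeletList(b), maxLen)
  list(.asSet(ch[[1]]), .asSet(ch[[2]]))
}

#' @rdname crossoverSetPoint
#' @export
crossoverMerge <- function(a, b) {
  ch <- .cxMerge(.shapeletList(a), .shapeletList(b))
  list(.asSet(ch[[1]]), .asSet(ch[[2]]))
}

# --- mutation -------------------------------------------------------------

.mutMask <- function(s, minLen) {
  i <- sample.int(length(s), 1)
  x <- s[[i]]
  half <- floor(length(x) / 2)
  if (half < 1L) return(s)
  m <- sample.int(half, 1)
  if (length(x) - m < minLen) return(s)
  s[[i]] <- if (stats::runif(1) < 0.5) x[-seq_len(m)]
            else x[seq_len(length(x) - m)]
  s
}

.mutRemove <- function(s) {
  if (length(s) <= 1L) return(s)
  s[-sample.int(length(s), 1)]
}

.mutAdd <- function(s, dataset, minLen, maxLen, maxShapelets) {
  if (length(s) >= maxShapelets) return(s)
  c(s, list(.randomSubsequence(dataset, minLen, maxLen)))
}

#' Mutation operators on shapelet sets
#'
#' \code{mutateMask} trims m points (m uniform on 1..floor(|s|/2)) off the
#' start or end (probability 1/2 each) of one uniformly chosen shapelet; the
#' trim is skipped if it would push the shapelet below \code{minLen}.
#' \code{mutateRemove} deletes one uniformly chosen shapelet, keeping at
#' least one. \code{mutateAdd} appends one fresh random subsequence, drawn
#' exactly as a single [initRandom()] candidate.
#'
#' @param set a [ShapeletSet-class] (or plain list).
#' @param dataset the dataset to sample new shapelets from.
#' @param minLen,maxLen admissible shapelet lengths (\code{maxLen = NULL}
#'   means the shortest series length).
#' @param maxShapelets cap on set size; \code{mutateAdd} is a no-op at the cap.
#' @return a \code{ShapeletSet} (fitness cache cleared).
#' @export
mutateMask <- function(set, minLen = 4) {
  .asSet(.mutMask(.shapeletList(set), minLen))
}

#' @rdname mutateMask
#' @export
mutateRemove <- function(set) {
  .asSet(.mutRemove(.shapeletList(set)))
}

#' @rdname mutateMask
#' @export
mutateAdd <- function(set, dataset, minLen = 4, maxLen = NULL,
                      maxShapelets = Inf) {
  if (is.null(maxLen)) maxLen <- minSeriesLength(dataset)
  .asSet(.mutAdd(.shapeletList(set), dataset, minLen, maxLen, maxShapelets))
}

# --- selection ------------------------------------------------------------

# pick one index: sample tournamentSize without replacement, then sample one
# with probability proportional to reverse fitness rank (best = largest)
.tournamentIdx <- function(err, cplx, tournamentSize) {
  idx <- sample.int(length(err), tournamentSize)
  ord <- idx[order(err[idx], cplx[idx])]
  w <- rev(seq_along(ord))
  ord[sample.int(length(ord), 1, prob = w)]
}

#' Rank-weighted tournament selection
#'
#' Samples \code{tournamentSize} individuals uniformly without replacement
#' and returns one of them, drawn with probability proportional to its
#' reverse fitness rank within the tournament (the fittest member gets the
#' largest weight). Rank weighting makes selection pressure independent of
#' the scale of the loss. All individuals must carry cached fitness values.
#'
#' @param population list of evaluated [ShapeletSet-class] individuals.
#' @param tournamentSize tournament size (small values preserve diversity).
#' @return one \code{ShapeletSet} from the population.
#' @export
tournamentSelect <- function(population, tournamentSize = 3) {
  fit <- lapply(population, fitnessValue)
  if (any(vapply(fit, is.null, logical(1))))
    stop("all individuals must be evaluated before selection")
  if (tournamentSize > length(population))
    stop("tournamentSize exceeds population size")
  err <- vapply(fit, `[[`, numeric(1), 1)
  cplx <- vapply(fit, `[[`, numeric(1), 2)
  population[[.tournamentIdx(err, cplx, tournamentSize)]]
}
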