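# Independent brute-force oracles. These deliberately use plain double loops
# and direct formulas so they share no code with the package implementations.

naiveSlidingDistance <- function(s, t) {
  best <- Inf
  for (o in 0:(length(t) - length(s))) {
    acc <- 0
    for (i in seq_along(s)) acc <- acc + (s[i] - t[o + i])^2
    acc <- acc / length(s)
    if (acc < best) best <- acc
  }
  best
}

naiveDistanceMatrix <- function(shapelets, series) {
  D <- matrix(0, length(series), length(shapelets))
  for (i in seq_along(series))
    for (k in seq_along(shapelets))
      D[i, k] <- naiveSlidingDistance(shapelets[[k]], series[[i]])
  D
}

# entropy-based gain by direct enumeration of all midpoint thresholds
naiveInformationGain <- function(d, y) {
  y <- as.character(y)
  ent <- function(labels) {
    if (!length(labels)) return(0)
    p <- table(labels) / length(labels)
    -sum(p * log2(p))
  }
  H <- ent(y)
  ds <- sort(unique(d))
  best <- 0
  if (length(ds) > 1) {
    for (i in seq_len(length(ds) - 1)) {
      thr <- (ds[i] + ds[i + 1]) / 2
      left <- y[d <= thr]; right <- y[d > thr]
      g <- H - length(left) / length(y) * ent(left) -
        length(right) / length(y) * ent(right)
      if (g > best) best <- g
    }
  }
  best
}

# motif fixture used across engine tests: separable at zero noise
motifFixture <- function(n = 5, len = 30, mlen = 6, noise = 0, seed = 1) {
  makeMotifTwoClass(nPerClass = n, length = len, motifLength = mlen,
                    noise = noise, seed = seed)
}

# is x a verbatim contiguous subsequence of any series in the dataset?
isVerbatimSubsequence <- function(x, dataset) {
  for (t in shapevolve:::.shapeletList(list())) NULL  # no-op, keep lintr quiet
  for (i in seq_len(nSeries(dataset))) {
    t <- getSeries(dataset, i)
    L <- length(x)
    if (L > length(t)) next
    for (o in 0:(length(t) - L))
      if (isTRUE(all.equal(x, t[(o + 1):(o + L)], tolerance = 0))) return(TRUE)
  }
  FALSE
}
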