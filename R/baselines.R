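# base-2 entropy of a count vector
.entropyBits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# core split search on one distance vector; yInt integer codes 1..C
# returns c(gain, threshold, margin, splitIndex) over sorted distances
.bestSplit <- function(d, yInt, C) {
  n <- length(d)
  ord <- order(d)
  ds <- d[ord]; ys <- yInt[ord]
  tot <- tabulate(yInt, C)
  H <- .entropyBits(tot)
  splits <- which(diff(ds) > 0)
  if (!length(splits))
    return(c(gain = 0, threshold = ds[1], margin = 0, split = 0))
  # cumulative class counts at each prefix
  cum <- matrix(0L, n, C)
  cum[cbind(seq_len(n), ys)] <- 1L
  cum <- apply(cum, 2, cumsum)
  gains <- vapply(splits, function(i) {
    left <- cum[i, ]; right <- tot - left
    H - (i / n) * .entropyBits(left) - ((n - i) / n) * .entropyBits(right)
  }, numeric(1))
  margins <- ds[splits + 1] - ds[splits]
  best <- which(gains == max(gains))
  best <- best[which.max(margins[best])]  # gain ties: widest gap wins
  i <- splits[best]
  c(gain = gains[best], threshold = (ds[i] + ds[i + 1]) / 2,
    margin = margins[best], split = i)
}

#' Information gain of the best threshold split
#'
#' Evaluates every threshold lying at the midpoint between consecutive
#' distinct sorted distances and returns the split maximizing the entropy
#' reduction \eqn{H(y) - w_L H(y_L) - w_R H(y_R)} (base 2). Among
#' equally-good splits the one with the widest gap between the two distances
#' it separates is preferred, as wider gaps generalize better.
#'
#' @param distances numeric vector of distances (one per series).
#' @param labels class labels, any atomic type.
#' @return a [SplitQuality-class].
#' @examples
#' q <- informationGain(c(1, 2, 8, 9), c("a", "a", "b", "b"))
#' q@gain       # 1 bit
#' q@threshold  # 5
#' @export
informationGain <- function(distances, labels) {
  if (length(distances) < 2L)
    stop("need at least two observations")
  if (length(distances) != length(labels))
    stop("distances and labels must have equal length")
  lev <- as.character(unique(labels))
  yInt <- match(as.character(labels), lev)
  r <- .bestSplit(distances, yInt, length(lev))
  left <- distances <= r[["threshold"]]
  lc <- tabulate(yInt[left], length(lev))
  rc <- tabulate(yInt[!left], length(lev))
  names(lc) <- names(rc) <- lev
  new("SplitQuality", gain = r[["gain"]], threshold = r[["threshold"]],
      margin = r[["margin"]], leftCounts = as.integer(lc),
      rightCounts = as.integer(rc))
}

#' @export
setMethod("show", "SplitQuality", function(object) {
  cat("SplitQuality: gain =", signif(object@gain, 6), "bits, threshold =",
      signif(object@threshold, 6), ", margin =", signif(object@margin, 6), "\n")
  cat("  left counts:", paste(object@leftCounts, collapse = "/"),
      " right counts:", paste(object@rightCounts, collapse = "/"), "\n")
})

#' Enumerate candidate subsequences
#'
#' Yields every contiguous subsequence of every series for every length in
#' \code{lengths}, deduplicated by exact value equality. Provenance (series
#' index, 0-based offset, length) is attached as attribute
#' \code{"provenance"}.
#'
#' @param dataset a [TimeSeriesDataset-class].
#' @param lengths integer vector of candidate lengths; default 4 up to the
#'   shortest series length.
#' @return list of numeric vectors.
#' @export
enumerateCandidates <- function(dataset, lengths = NULL) {
  M <- minSeriesLength(dataset)
  if (is.null(lengths)) lengths <- 4:M
  lengths <- as.integer(lengths)
  if (!length(lengths)) stop("empty candidate length range")
  if (any(lengths < 4L) || any(lengths > M))
    stop("candidate lengths must lie within [4, ", M, "]")
  cand <- list(); prov <- list()
  for (L in sort(lengths)) {
    for (si in seq_len(nSeries(dataset))) {
      t <- dataset@series[[si]]
      for (o in seq_len(length(t) - L + 1L)) {
        cand[[length(cand) + 1L]] <- t[o:(o + L - 1L)]
        prov[[length(prov) + 1L]] <- c(series = si, offset = o - 1L, length = L)
      }
    }
  }
  keep <- !duplicated(cand)
  out <- cand[keep]
  attr(out, "provenance") <- do.call(rbind, prov)[keep, , drop = FALSE]
  out
}

# Batched scoring of every candidate subsequence: for each length, all
# candidates of all series are scored against all series at once through a
# cross-product expansion of the squared distance, which keeps the full-range
# enumeration tractable. Returns a data frame sorted in enumeration order
# (length ascending, series, offset); duplicated candidates are dropped.
.candidateGains <- function(dataset, lengths = NULL) {
  M <- minSeriesLength(dataset)
  if (is.null(lengths)) lengths <- 4:M
  lengths <- sort(unique(as.integer(lengths)))
  if (!length(lengths)) stop("empty candidate length range")
  if (any(lengths < 4L) || any(lengths > M))
    stop("candidate lengths must lie within [4, ", M, "]")
  yInt <- .labelCodes(dataset); C <- .nClasses(dataset)
  N <- nSeries(dataset)
  res <- vector("list", length(lengths))
  for (li in seq_along(lengths)) {
    L <- lengths[li]
    wins <- lapply(dataset@series, function(t)
      stats::embed(t, L)[, L:1, drop = FALSE])
    Cand <- do.call(rbind, wins)
    prov <- do.call(rbind, lapply(seq_len(N), function(i)
      cbind(series = i, offset = seq_len(nrow(wins[[i]])) - 1L)))
    dup <- duplicated(Cand)
    rc <- rowSums(Cand^2)
    dmin <- matrix(0, nrow(Cand), N)
    for (j in seq_len(N)) {
      Wj <- wins[[j]]
      D2 <- outer(rc, rowSums(Wj^2), "+") - 2 * tcrossprod(Cand, Wj)
      dmin[, j] <- do.call(pmin, as.data.frame(D2)) / L
    }
    dmin[dmin < 0] <- 0  # guard against negative rounding residue
    g <- t(apply(dmin, 1, function(d) .bestSplit(d, yInt, C)[1:3]))
    res[[li]] <- data.frame(length = L, series = prov[, 1],
                            offset = prov[, 2], gain = g[, 1],
                            threshold = g[, 2], margin = g[, 3])[!dup, ]
  }
  do.call(rbind, res)
}

# ranking shared by bestSingleShapelet and topKIndependent:
# gain desc, then separation margin desc, then shorter, then enumeration order
.rankCandidates <- function(tab) {
  tab[order(-tab$gain, -tab$margin, tab$length, tab$series, tab$offset), ]
}

.extractCandidate <- function(dataset, row) {
  t <- dataset@series[[row$series]]
  t[(row$offset + 1):(row$offset + row$length)]
}

#' Exhaustive single-shapelet search
#'
#' Scores every candidate subsequence (see [enumerateCandidates()]) by the
#' information gain of its distance vector and returns the best one. Ties on
#' gain are broken by the wider separation margin, then the shorter
#' candidate, then enumeration order.
#'
#' @param dataset a [TimeSeriesDataset-class] with at least two classes.
#' @param lengths candidate lengths (default full range 4..M).
#' @return list with components \code{shapelet} (numeric vector),
#'   \code{quality} (a [SplitQuality-class]) and \code{provenance}
#'   (series, 0-based offset, length).
#' @export
bestSingleShapelet <- function(dataset, lengths = NULL) {
  if (length(unique(dataset@labels)) < 2L)
    stop("need at least two classes")
  tab <- .rankCandidates(.candidateGains(dataset, lengths))
  top <- tab[1, ]
  s <- .extractCandidate(dataset, top)
  list(shapelet = s,
       quality = informationGain(
         vapply(dataset@series, function(t) slidingDistance(s, t), numeric(1)),
         seriesLabels(dataset)),
       provenance = c(series = top$series, offset = top$offset,
                      length = top$length))
}

#' Independent top-k shapelet selection
#'
#' The deliberately naive comparator to whole-set evolution: every candidate
#' is ranked by the information gain of its own distance vector, with no
#' interaction between picks and no similarity pruning, and the top k are
#' returned. Because similar subsequences achieve similar gains, the top of
#' the ranking is typically dominated by near-duplicates from the classes
#' that are easiest to isolate.
#'
#' @param dataset a [TimeSeriesDataset-class].
#' @param k number of shapelets to select.
#' @param lengths candidate lengths (default full range 4..M).
#' @return a [ShapeletSet-class] of size k (or fewer, with a warning, if the
#'   dataset yields fewer candidates). Provenance rows are attached as
#'   attribute \code{"provenance"} of the returned set's shapelet list.
#' @export
topKIndependent <- function(dataset, k, lengths = NULL) {
  if (k < 1) stop("k must be >= 1")
  tab <- .rankCandidates(.candidateGains(dataset, lengths))
  if (nrow(tab) < k) {
    warning("only ", nrow(tab), " candidates available; returning all")
    k <- nrow(tab)
  }
  top <- tab[seq_len(k), ]
  shp <- lapply(seq_len(k), function(i) .extractCandidate(dataset, top[i, ]))
  attr(shp, "provenance") <- top[, c("series", "offset", "length", "gain", "margin")]
  .asSet(shp)
}
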