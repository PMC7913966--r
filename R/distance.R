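#' Sliding-window minimum distance between a shapelet and a series
#'
#' Slides the shapelet across the series and returns the smallest
#' length-normalized squared Euclidean distance over all
#' \code{length(t) - length(s) + 1} windows:
#' \deqn{d(s, t) = \min_w \frac{1}{|s|}\sum_i (s_i - w_i)^2.}
#' Normalizing by the shapelet length makes distances comparable across
#' shapelets of different lengths, which matters when variable-length sets
#' compete within one fitness value. A distance of zero occurs exactly when
#' the shapelet occurs pointwise in the series.
#'
#' @param s numeric vector, the shapelet.
#' @param t numeric vector, the series; must be at least as long as \code{s}.
#' @param earlyAbandon if TRUE, window sums are abandoned as soon as they
#'   exceed the best distance found so far. Purely an optimization: results
#'   are identical.
#' @return non-negative scalar.
#' @examples
#' slidingDistance(c(1, 2), c(0, 1, 2, 3))   # exact subsequence: 0
#' slidingDistance(c(0, 0), c(1, 2, 3))      # min(2.5, 6.5) = 2.5
#' @export
slidingDistance <- function(s, t, earlyAbandon = FALSE) {
  s <- as.numeric(s); t <- as.numeric(t)
  L <- length(s); n <- length(t)
  if (L > n)
    stop("shapelet length (", L, ") exceeds series length (", n, ")")
  if (earlyAbandon) {
    best <- Inf
    for (o in 0:(n - L)) {
      acc <- 0
      for (i in seq_len(L)) {
        acc <- acc + (s[i] - t[o + i])^2
        if (acc >= best) break
      }
      if (acc < best) best <- acc
    }
    return(best / L)
  }
  if (L == n) return(mean((s - t)^2))
  # rows of embed() hold windows in reverse time order
  W <- stats::embed(t, L)[, L:1, drop = FALSE]
  min(rowSums((W - rep(s, each = nrow(W)))^2)) / L
}

#' @describeIn distanceMatrix distance transform of a whole dataset: entry
#'   (i, k) is \code{slidingDistance(shapelet k, series i)}. With
#'   \code{countOps = TRUE} the returned matrix carries an \code{"ops"}
#'   attribute holding the number of pointwise comparisons performed,
#'   \code{sum((n_i - L_k + 1) * L_k)}.
#' @param countOps attach the operation count as an attribute.
#' @export
setMethod("distanceMatrix", signature("ANY", "TimeSeriesDataset"),
  function(shapelets, dataset, countOps = FALSE) {
    shp <- .shapeletList(shapelets)
    if (!length(shp)) stop("empty shapelet set")
    M <- minSeriesLength(dataset)
    tooLong <- which(lengths(shp) > M)
    if (length(tooLong))
      stop("shapelet ", tooLong[1], " (length ", length(shp[[tooLong[1]]]),
           ") is longer than the shortest series (", M, ")")
    D <- vapply(shp, function(s)
      vapply(dataset@series, function(t) slidingDistance(s, t), numeric(1)),
      numeric(nSeries(dataset)))
    D <- matrix(D, nrow = nSeries(dataset), ncol = length(shp))
    if (countOps) {
      lens <- seriesLengths(dataset)
      attr(D, "ops") <- sum(vapply(lengths(shp), function(L)
        sum((lens - L + 1) * L), numeric(1)))
    }
    D
  })
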