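#' Dynamic time warping distance between two sequences
#'
#' Classic dynamic-programming DTW with absolute-difference local cost, full
#' alignment and no warping window: returns the accumulated cost of the
#' optimal warping path. No path-length normalization is applied; set
#' \code{normalize = TRUE} to divide by the optimal path length instead.
#'
#' Used to compare shapelets discovered by independent runs, where plain
#' Euclidean distance is too rigid: two shapelets carrying the same shape at
#' slightly different time scales should score as similar.
#'
#' @param a,b non-empty numeric vectors.
#' @param normalize divide the accumulated cost by the path length.
#' @return non-negative scalar; 0 iff the sequences are identical up to
#'   duplicated points along the warping path.
#' @examples
#' dtwDistance(c(1, 2, 3), c(1, 2, 2, 3))  # 0: duplicate point warps freely
#' dtwDistance(0, 1)                       # 1
#' @export
dtwDistance <- function(a, b, normalize = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  if (!n || !m) stop("DTW inputs must be non-empty")
  cost <- outer(a, b, function(x, y) abs(x - y))
  acc <- matrix(Inf, n + 1L, m + 1L)
  steps <- matrix(0L, n + 1L, m + 1L)
  acc[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      prev <- c(acc[i, j], acc[i, j + 1L], acc[i + 1L, j])
      k <- which.min(prev)
      acc[i + 1L, j + 1L] <- cost[i, j] + prev[k]
      steps[i + 1L, j + 1L] <- 1L + switch(k, steps[i, j], steps[i, j + 1L],
                                           steps[i + 1L, j])
    }
  }
  if (normalize) acc[n + 1L, m + 1L] / steps[n + 1L, m + 1L]
  else acc[n + 1L, m + 1L]
}

#' Pairwise DTW distances between two shapelet sets
#'
#' Entry (i, j) is the DTW distance between shapelet i of the first set and
#' shapelet j of the second. Comparing the discovered sets of two seeded runs
#' shows whether the runs recovered semantically matching shapelets: matching
#' pairs appear as entries well below the bulk of the matrix.
#'
#' @param set1,set2 [ShapeletSet-class] objects (or plain lists).
#' @param normalize passed to [dtwDistance()].
#' @return numeric matrix of dimension \code{setSize(set1) x setSize(set2)}.
#' @export
stabilityMatrix <- function(set1, set2, normalize = FALSE) {
  s1 <- .shapeletList(set1); s2 <- .shapeletList(set2)
  if (!length(s1) || !length(s2)) stop("both sets must be non-empty")
  out <- matrix(0, length(s1), length(s2),
                dimnames = list(paste0("run1.", seq_along(s1)),
                                paste0("run2.", seq_along(s2))))
  for (i in seq_along(s1))
    for (j in seq_along(s2))
      out[i, j] <- dtwDistance(s1[[i]], s2[[j]], normalize = normalize)
  out
}

#' Export a stability matrix as delimited text
#'
#' @param mat matrix from [stabilityMatrix()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStabilityMatrix <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
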