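# evaluate expr under a fixed seed without disturbing the caller's RNG stream
.withFixedSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) saved <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Gaussian-smoothed white noise: a fixed, aperiodic, smooth base waveform.
# Aperiodicity matters: it pins the distance-minimizing alignment of long
# subsequences, because no time shift of an aperiodic wave resembles itself.
.smoothWave <- function(len, seed, width = 7) {
  .withFixedSeed(seed, {
    z <- stats::rnorm(len + 6 * width)
    k <- stats::dnorm(seq(-3, 3, length.out = 2 * width + 1))
    s <- stats::filter(z, k / sum(k), sides = 2)
    as.numeric(s[(3 * width + 1):(3 * width + len)])
  })
}

#' Imbalanced three-class benchmark collection
#'
#' Generates a train/test pair reproducing a skewed classification problem:
#' a large homogeneous majority class (n0 very similar low-noise series) and
#' two small heterogeneous minority classes (n1, n2 noisier series) that
#' share their entire base shape and differ from each other only in a short
#' class-specific motif placed at a random position.
#'
#' Construction, for series length \code{length} (default 100): the first
#' ~68\% of every series carries a base waveform and the remainder is a flat
#' segment. The majority class uses a fixed smooth aperiodic wave; the
#' minority classes share that same wave plus a fixed high-frequency
#' alternating texture of uniform local energy, so that every majority-class
#' subsequence is roughly equally far from every minority series regardless
#' of position or length. The minority motif - a short plateau bump, positive
#' for class 1 and negative for class 2 - sits strictly inside the shared
#' flat segment at a per-series random offset. Because the flat segment is
#' common to all classes and the wave-aligned window is always the cheaper
#' match for wave-born subsequences, distances from majority-class
#' subsequences carry (by construction) no information about the minority
#' motif: candidates ranked individually can isolate the majority class but
#' cannot tell the minority classes apart, while a shapelet matching one of
#' the motifs separates them easily.
#'
#' @param n0,n1,n2 series counts per class (same in train and test).
#' @param length series length (>= 50 recommended).
#' @param noiseMajority,noiseMinority Gaussian noise standard deviations.
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return list with \code{train} and \code{test}
#'   [TimeSeriesDataset-class] objects, labels \code{"0"}, \code{"1"},
#'   \code{"2"}.
#' @export
makeImbalancedThreeClass <- function(n0 = 25, n1 = 5, n2 = 5, length = 100,
                                     noiseMajority = 0.05,
                                     noiseMinority = 0.3, seed = NULL) {
  stopifnot(n0 >= 2, n1 >= 2, n2 >= 2, length >= 50)
  if (!is.null(seed)) set.seed(seed)
  len <- as.integer(length)
  waveEnd <- as.integer(round(0.68 * len))
  taper <- rep(0, len); taper[seq_len(waveEnd)] <- 1
  taper[(waveEnd - 3):(waveEnd + 3)] <- seq(1, 0, length.out = 7)
  w0 <- .smoothWave(len, seed = 20240501L)
  w0 <- w0 / sqrt(mean(w0[seq_len(waveEnd)]^2)) * 2.5
  # alternating +/-2: every window of every length has local energy 4, so no
  # subsequence is systematically closer to or farther from the texture than
  # any other - the majority/minority contrast is uniform across positions
  texture <- 2 * (-1)^seq_len(len)
  baseMajority <- w0 * taper
  baseMinority <- (w0 + texture) * taper
  mLen <- as.integer(round(0.15 * len))
  motif <- 1.5 * 0.5 * (1 - cos(2 * pi * seq_len(mLen) / (mLen + 1)))
  posLo <- waveEnd + 4L
  posHi <- len - mLen - 3L
  oneSeries <- function(base, motifSign, noise) {
    s <- base
    if (motifSign != 0) {
      p <- if (posHi > posLo) sample(posLo:posHi, 1) else posLo
      s[p:(p + mLen - 1L)] <- s[p:(p + mLen - 1L)] + motifSign * motif
    }
    s + stats::rnorm(len, 0, noise)
  }
  onePart <- function() {
    series <- c(
      lapply(seq_len(n0), function(i) oneSeries(baseMajority, 0, noiseMajority)),
      lapply(seq_len(n1), function(i) oneSeries(baseMinority, 1, noiseMinority)),
      lapply(seq_len(n2), function(i) oneSeries(baseMinority, -1, noiseMinority)))
    timeSeriesDataset(series, c(rep("0", n0), rep("1", n1), rep("2", n2)))
  }
  list(train = onePart(), test = onePart())
}

#' Four-series nested-amplitude collection
#'
#' A minimal two-class problem on which no subsequence of the data separates
#' the classes but an out-of-data shapelet does. Four series on a zero
#' baseline each carry one rectangular plateau bump of width
#' \code{bumpWidth} at a fixed position; the bump amplitudes are 0 and 4 for
#' class A and 1 and 3 for class B, so the class-B amplitudes nest strictly
#' inside the class-A ones.
#'
#' For any candidate subsequence taken from these series, the induced
#' distance ordering interleaves the classes (this is checked exhaustively in
#' the test suite at zero noise), so no distance threshold recovers the
#' labels on all four series. The amplitude-2 plateau - the pointwise mean of
#' the two class-B bumps, a shapelet occurring nowhere in the data - has
#' distance E to both class-B series and 4E to both class-A series (E the
#' mean squared plateau height), a perfect split with wide margin. The merge
#' crossover reaches it in one step from the two class-B bumps.
#'
#' @param length series length.
#' @param bumpWidth plateau width (< length).
#' @param noise Gaussian noise sd (default 0: the construction is exact).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return a [TimeSeriesDataset-class] with 4 series and labels
#'   \code{c("A", "A", "B", "B")} (amplitudes 0, 4, 1, 3).
#' @export
makeNestedAmplitudeTwoClass <- function(length = 50, bumpWidth = 20,
                                        noise = 0, seed = NULL) {
  stopifnot(bumpWidth < length, bumpWidth >= 4)
  if (!is.null(seed)) set.seed(seed)
  len <- as.integer(length)
  pos <- as.integer(floor((len - bumpWidth) / 2) + 1L)
  mk <- function(a) {
    s <- rep(0, len)
    s[pos:(pos + bumpWidth - 1L)] <- a
    s + stats::rnorm(len, 0, noise)
  }
  ds <- timeSeriesDataset(list(mk(0), mk(4), mk(1), mk(3)),
                          c("A", "A", "B", "B"))
  attr(ds@series, "bumpPosition") <- pos
  ds
}

#' Generic separable two-class motif collection
#'
#' Noise series with a class-specific motif implanted at a uniformly random
#' position: class 1 carries a positive plateau of height \code{amplitude},
#' class 2 a negative one. At zero noise a single in-data shapelet per class
#' separates the collection perfectly, which makes this the standard fixture
#' for end-to-end checks of the evolutionary search.
#'
#' @param nPerClass series per class.
#' @param length series length.
#' @param motifLength motif length (>= 4, <= length).
#' @param noise Gaussian noise sd.
#' @param amplitude plateau height.
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return a [TimeSeriesDataset-class] with labels \code{"1"}, \code{"2"}.
#' @export
makeMotifTwoClass <- function(nPerClass = 10, length = 60, motifLength = 8,
                              noise = 0.1, amplitude = 2, seed = NULL) {
  stopifnot(motifLength <= length, motifLength >= 4, nPerClass >= 1)
  if (!is.null(seed)) set.seed(seed)
  len <- as.integer(length); mLen <- as.integer(motifLength)
  mk <- function(sign) {
    s <- stats::rnorm(len, 0, noise)
    p <- sample.int(len - mLen + 1L, 1)
    s[p:(p + mLen - 1L)] <- s[p:(p + mLen - 1L)] + sign * amplitude
    s
  }
  series <- c(lapply(seq_len(nPerClass), function(i) mk(1)),
              lapply(seq_len(nPerClass), function(i) mk(-1)))
  timeSeriesDataset(series, rep(c("1", "2"), each = nPerClass))
}
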