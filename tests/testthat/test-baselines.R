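test_that("information gain matches hand-enumerated splits", {
  q <- informationGain(c(1, 2, 8, 9), c("a", "a", "b", "b"))
  expect_equal(q@gain, 1)
  expect_equal(q@threshold, 5)
  expect_equal(q@leftCounts, c(2L, 0L))
  expect_equal(q@rightCounts, c(0L, 2L))
  # interleaved labels: best split isolates one endpoint
  q2 <- informationGain(c(1, 3, 5, 7), c("a", "b", "a", "b"))
  expect_equal(q2@gain, naiveInformationGain(c(1, 3, 5, 7), c("a", "b", "a", "b")),
               tolerance = 1e-12)
  expect_equal(q2@gain, 0.311278, tolerance = 1e-5)
  # zero-entropy base
  expect_equal(informationGain(c(1, 2, 3), c("a", "a", "a"))@gain, 0)
  # all-equal distances: no split available
  expect_equal(informationGain(c(2, 2, 2, 2), c("a", "b", "a", "b"))@gain, 0)
})

test_that("information gain agrees with brute force over all labelings", {
  set.seed(41)
  d <- sort(runif(8)) + c(0, cumsum(rep(0.05, 7)))  # distinct distances
  for (code in 0:(2^8 - 1)) {
    y <- ifelse(bitwAnd(code, 2^(0:7)) > 0, "a", "b")
    expect_equal(informationGain(d, y)@gain, naiveInformationGain(d, y),
                 tolerance = 1e-12, info = paste("labeling", code))
  }
})

test_that("gain ties are broken towards the wider margin", {
  # two splits with gain 1 bit; the right one has the wider gap
  q <- informationGain(c(1, 1.4, 8, 9, 20, 21), rep(c("a", "b", "c"), each = 2))
  expect_equal(q@gain, naiveInformationGain(c(1, 1.4, 8, 9, 20, 21),
                                            rep(c("a", "b", "c"), each = 2)),
               tolerance = 1e-12)
  expect_gte(q@margin, 6.6)
})

test_that("candidate enumeration counts and deduplicates", {
  ds <- timeSeriesDataset(list(c(1, 2, 3, 4, 5, 6)), "a")
  cand <- enumerateCandidates(ds, lengths = 4)
  expect_length(cand, 3)  # |t| - L + 1
  # two identical series yield the same deduplicated candidates
  ds2 <- timeSeriesDataset(list(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6)),
                           c("a", "b"))
  expect_length(enumerateCandidates(ds2, lengths = 4), 3)
  # pre-deduplication count matches the direct formula
  set.seed(42)
  series <- lapply(1:3, function(i) rnorm(sample(8:12, 1)))
  ds3 <- timeSeriesDataset(series, c("a", "b", "a"))
  lens <- c(4, 5)
  expected <- sum(vapply(lens, function(L)
    sum(lengths(series) - L + 1), numeric(1)))
  expect_length(enumerateCandidates(ds3, lengths = lens), expected)
  expect_error(enumerateCandidates(ds3, lengths = integer()), "empty")
  expect_error(enumerateCandidates(ds3, lengths = 50), "within")
})

test_that("best single shapelet finds an implanted motif", {
  ds <- makeMotifTwoClass(nPerClass = 5, length = 24, motifLength = 6,
                          noise = 0, seed = 43)
  bf <- bestSingleShapelet(ds, lengths = 4:8)
  # a pure split attains the full label entropy (1 bit, balanced classes)
  expect_equal(bf$quality@gain, 1)
  # the winning candidate overlaps a motif: it must contain saturated values
  expect_gte(max(abs(bf$shapelet)), 2)
  # degenerate single-candidate range returns that candidate
  one <- timeSeriesDataset(list(c(5, 1, 4, 2), c(0, 0, 0, 0)), c("a", "b"))
  bf1 <- bestSingleShapelet(one, lengths = 4)
  expect_true(identical(bf1$shapelet, c(5, 1, 4, 2)) ||
              identical(bf1$shapelet, c(0, 0, 0, 0)))
})

test_that("best single shapelet is invariant to series order", {
  set.seed(44)
  ds <- makeMotifTwoClass(nPerClass = 4, length = 20, motifLength = 5,
                          noise = 0.05, seed = 44)
  perm <- sample(nSeries(ds))
  dsP <- timeSeriesDataset(lapply(perm, function(i) getSeries(ds, i)),
                           as.character(seriesLabels(ds))[perm])
  a <- bestSingleShapelet(ds, lengths = 4:6)
  b <- bestSingleShapelet(dsP, lengths = 4:6)
  expect_equal(a$shapelet, b$shapelet)
  expect_equal(a$quality@gain, b$quality@gain)
})

test_that("top-k selection clamps, warns, and nests the top-1", {
  ds <- makeMotifTwoClass(nPerClass = 3, length = 16, motifLength = 4,
                          noise = 0, seed = 45)
  expect_warning(all6 <- topKIndependent(ds, 10000, lengths = 4),
                 "candidates")
  expect_equal(setSize(all6), length(enumerateCandidates(ds, lengths = 4)))
  top1 <- topKIndependent(ds, 1, lengths = 4:6)
  bf <- bestSingleShapelet(ds, lengths = 4:6)
  expect_equal(top1[[1]], bf$shapelet)
})

test_that("batched candidate scoring matches per-candidate recomputation", {
  set.seed(46)
  ds <- makeMotifTwoClass(nPerClass = 3, length = 18, motifLength = 5,
                          noise = 0.2, seed = 46)
  tab <- shapevolve:::.candidateGains(ds, lengths = c(4, 6))
  y <- seriesLabels(ds)
  for (r in sample(nrow(tab), 25)) {
    row <- tab[r, ]
    s <- getSeries(ds, row$series)[(row$offset + 1):(row$offset + row$length)]
    d <- vapply(ds@series, function(t) slidingDistance(s, t), numeric(1))
    q <- informationGain(d, y)
    expect_equal(row$gain, q@gain, tolerance = 1e-9)
    expect_equal(row$margin, q@margin, tolerance = 1e-9)
  }
})
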