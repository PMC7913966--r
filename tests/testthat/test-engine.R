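test_that("k-means initialization honors its contract", {
  set.seed(21)
  ds <- motifFixture(n = 4, len = 24, noise = 0.2)
  s3 <- initKmeans(ds, 3)
  expect_equal(setSize(s3), 3)
  lens <- lengths(shapelets(s3))
  expect_true(all(lens >= 4), info = "minimum length")
  expect_equal(length(unique(lens)), 1)  # one common drawn length
  expect_lte(lens[1], minSeriesLength(ds))
  # constant dataset: every centroid is the constant value
  const <- timeSeriesDataset(list(rep(2, 10), rep(2, 12)), c("a", "b"))
  s2 <- initKmeans(const, 2)
  expect_true(all(vapply(shapelets(s2), function(x) all(x == 2), logical(1))))
  # K = 1: the single centroid is a mean of subsequences, hence within range
  s1 <- initKmeans(ds, 1)
  expect_equal(setSize(s1), 1)
  rng <- range(unlist(ds@series))
  expect_true(all(s1[[1]] >= rng[1] & s1[[1]] <= rng[2]))
})

test_that("random initialization yields verbatim subsequences", {
  set.seed(22)
  ds <- motifFixture(n = 4, len = 20, noise = 0.3)
  s <- initRandom(ds, 5)
  expect_equal(setSize(s), 5)
  for (x in shapelets(s))
    expect_true(isVerbatimSubsequence(x, ds))
  # degenerate range: every shapelet has length exactly 4
  s4 <- initRandom(ds, 6, maxLen = 4)
  expect_true(all(lengths(shapelets(s4)) == 4))
  # determinism under a fixed seed
  set.seed(99); a <- initRandom(ds, 3)
  set.seed(99); b <- initRandom(ds, 3)
  expect_identical(shapelets(a), shapelets(b))
})

test_that("population initialization respects sizes and operator toggles", {
  ds <- motifFixture(n = 5, len = 25, noise = 0.2)
  set.seed(23)
  cfg <- evolutionConfig(popSize = 25, W = 4)
  pop <- initializePopulation(ds, cfg)
  expect_length(pop, 25)
  sizes <- vapply(pop, setSize, integer(1))
  expect_true(all(sizes >= 2 & sizes <= 4))
  # W = 2 forces every individual to two shapelets
  pop2 <- initializePopulation(ds, evolutionConfig(popSize = 10, W = 2))
  expect_true(all(vapply(pop2, setSize, integer(1)) == 2))
  # random-only initialization produces only verbatim subsequences
  popR <- initializePopulation(ds, evolutionConfig(popSize = 6, W = 3,
                                                   initOps = "random"))
  for (ind in popR)
    for (x in shapelets(ind))
      expect_true(isVerbatimSubsequence(x, ds))
  expect_error(evolutionConfig(initOps = character()), "initOps")
})

test_that("fitness is low on separable data and penalizes complexity", {
  ds <- motifFixture(n = 6, len = 30, mlen = 6, noise = 0)
  # a shapelet equal to the class-1 motif separates perfectly
  motif <- rep(2, 6)
  ev <- evaluateFitness(shapeletSet(list(motif)), ds)
  fv <- fitnessValue(ev)
  expect_lt(fv[["error"]], 0.1)
  expect_equal(fv[["complexity"]], 6)
  # duplicating a shapelet leaves the error essentially unchanged (the ridge
  # penalty splits the weight across the duplicate columns) but raises the
  # complexity, so with errors tied the smaller set is the fitter one
  ev2 <- evaluateFitness(shapeletSet(list(motif, motif)), ds)
  fv2 <- fitnessValue(ev2)
  expect_lt(abs(fv2[["error"]] - fv[["error"]]), 2e-3)
  expect_gt(fv2[["complexity"]], fv[["complexity"]])
  expect_true(shapevolve:::.fitterThan(c(fv[["error"]], fv[["complexity"]]),
                                       c(fv[["error"]], fv2[["complexity"]])))
  # lexicographic order: equal error, lower complexity wins
  expect_true(shapevolve:::.fitterThan(c(0.5, 10), c(0.5, 12)))
  expect_false(shapevolve:::.fitterThan(c(0.5, 12), c(0.5, 10)))
  expect_true(shapevolve:::.fitterThan(c(0.4, 12), c(0.5, 10)))
  # degenerate labels are rejected
  one <- timeSeriesDataset(list(rnorm(8), rnorm(8)), c("a", "a"))
  expect_error(evaluateFitness(shapeletSet(list(rnorm(4))), one),
               "single-class")
})

test_that("cached fitness equals a fresh recomputation", {
  set.seed(24)
  ds <- motifFixture(n = 5, len = 25, noise = 0.1)
  s <- initRandom(ds, 3)
  ev <- evaluateFitness(s, ds)
  again <- evaluateFitness(shapeletSet(shapelets(ev)), ds)
  expect_equal(fitnessValue(ev), fitnessValue(again))
})

test_that("set-level point crossover conserves shapelets", {
  a <- shapeletSet(list(rep(1, 4), rep(2, 4), rep(3, 4)))
  b <- shapeletSet(list(rep(4, 4), rep(5, 4)))
  set.seed(25)
  for (i in 1:20) {
    ch <- crossoverSetPoint(a, b)
    pool <- c(shapelets(ch[[1]]), shapelets(ch[[2]]))
    expect_equal(length(pool), 5)
    # multiset union is conserved
    key <- sort(vapply(pool, function(x) x[1], numeric(1)))
    expect_equal(key, 1:5)
    expect_gte(setSize(ch[[1]]), 1)
    expect_gte(setSize(ch[[2]]), 1)
  }
  # identical parents reproduce themselves
  for (i in 1:10) {
    ch <- crossoverSetPoint(a, a)
    expect_identical(shapelets(ch[[1]]), shapelets(a))
    expect_identical(shapelets(ch[[2]]), shapelets(a))
  }
})

test_that("one-point set crossover at cut 1 swaps the tails", {
  a <- shapeletSet(list(rep(1, 4), rep(2, 4), rep(3, 4)))
  b <- shapeletSet(list(rep(4, 4), rep(5, 4)))
  # find the one-point branch with cut 1 by scanning seeds
  found <- FALSE
  for (seed in 1:50) {
    set.seed(seed)
    ch <- crossoverSetPoint(a, b)
    k1 <- vapply(shapelets(ch[[1]]), function(x) x[1], numeric(1))
    k2 <- vapply(shapelets(ch[[2]]), function(x) x[1], numeric(1))
    if (identical(k1, c(1, 5)) && identical(k2, c(4, 2, 3))) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("shapelet-level point crossover splices values", {
  a <- shapeletSet(list(c(1, 1, 1, 1)))
  b <- shapeletSet(list(c(9, 9, 9, 9)))
  seen <- character()
  set.seed(26)
  for (i in 1:60) {
    ch <- crossoverShapeletPoint(a, b)
    x <- ch[[1]][[1]]
    expect_equal(length(x), 4)
    seen <- c(seen, paste(x, collapse = ","))
  }
  expect_true("1,1,9,9" %in% seen)  # one-point at cut 2
  # identical parents are fixed points
  ch <- crossoverShapeletPoint(a, a)
  expect_identical(ch[[1]][[1]], c(1, 1, 1, 1))
  # children lengths stay within bounds
  set.seed(27)
  p1 <- shapeletSet(lapply(1:3, function(i) rnorm(sample(4:10, 1))))
  p2 <- shapeletSet(lapply(1:2, function(i) rnorm(sample(4:10, 1))))
  for (i in 1:20) {
    ch <- crossoverShapeletPoint(p1, p2, maxLen = 10)
    lens <- lengths(c(shapelets(ch[[1]]), shapelets(ch[[2]])))
    expect_true(all(lens >= 4 & lens <= 10))
  }
})

test_that("merge crossover averages values", {
  a <- shapeletSet(list(c(0, 2, 4)))
  b <- shapeletSet(list(c(2, 4, 6)))
  ch <- crossoverMerge(a, b)
  expect_equal(ch[[1]][[1]], c(1, 3, 5))
  # idempotence
  ch2 <- crossoverMerge(a, a)
  expect_equal(ch2[[1]][[1]], c(0, 2, 4))
  # unequal lengths: child is the mean of the shorter with a window of the
  # longer, so with constant parents the value is forced
  s <- shapeletSet(list(c(0, 0)))
  l <- shapeletSet(list(c(4, 4, 4, 4)))
  ch3 <- crossoverMerge(s, l)
  expect_equal(ch3[[1]][[1]], c(2, 2))
  expect_equal(length(ch3[[2]][[1]]), 2)
})

test_that("mask mutation trims without violating the length floor", {
  s4 <- shapeletSet(list(as.numeric(1:4)))
  set.seed(28)
  for (i in 1:10)
    expect_identical(mutateMask(s4)[[1]], as.numeric(1:4))  # trim would go below 4
  base10 <- as.numeric(1:10)
  s10 <- shapeletSet(list(base10))
  for (i in 1:50) {
    m <- mutateMask(s10)[[1]]
    expect_gte(length(m), 4)
    # retained values are a verbatim prefix or suffix
    expect_true(identical(m, utils::head(base10, length(m))) ||
                identical(m, utils::tail(base10, length(m))))
  }
  # set size is unchanged by masking
  multi <- shapeletSet(lapply(1:3, function(i) rnorm(8)))
  expect_equal(setSize(mutateMask(multi)), 3)
})

test_that("remove mutation keeps at least one shapelet", {
  one <- shapeletSet(list(rnorm(5)))
  expect_identical(shapelets(mutateRemove(one)), shapelets(one))
  five <- shapeletSet(lapply(1:5, function(i) rnorm(4) + i))
  set.seed(29)
  r <- mutateRemove(five)
  expect_equal(setSize(r), 4)
  expect_true(all(shapelets(r) %in% shapelets(five)))
  expect_lt(complexity(r), complexity(five))
})

test_that("add mutation appends a verbatim subsequence", {
  set.seed(30)
  ds <- motifFixture(n = 4, len = 20, noise = 0.2)
  s <- shapeletSet(lapply(1:2, function(i) rnorm(5)))
  a <- mutateAdd(s, ds)
  expect_equal(setSize(a), 3)
  expect_identical(shapelets(a)[1:2], shapelets(s))
  expect_true(isVerbatimSubsequence(a[[3]], ds))
  # no-op at the cap
  expect_equal(setSize(mutateAdd(s, ds, maxShapelets = 2)), 2)
})

test_that("tournament selection prefers fitter individuals at rank odds", {
  mk <- function(err) shapevolve:::.asSet(list(rnorm(4)),
                                          fitness = c(error = err, complexity = 4))
  pop <- list(mk(0.1), mk(0.9))
  set.seed(31)
  picks <- replicate(10000, {
    s <- tournamentSelect(pop, tournamentSize = 2)
    fitnessValue(s)[["error"]] == 0.1
  })
  # rank weights 2:1 within the tournament
  expect_equal(mean(picks), 2 / 3, tolerance = 0.02)
  # tournament of one returns a uniformly sampled individual
  set.seed(32)
  p1 <- replicate(2000, fitnessValue(tournamentSelect(pop, 1))[["error"]] == 0.1)
  expect_equal(mean(p1), 0.5, tolerance = 0.04)
  expect_error(tournamentSelect(pop, 5), "exceeds")
})

test_that("evolution is reproducible and monotone, and solves motif data", {
  ds <- motifFixture(n = 5, len = 30, mlen = 6, noise = 0)
  cfg <- evolutionConfig(popSize = 30, generations = 25, patience = 10, seed = 42)
  res1 <- evolve(ds, cfg)
  res2 <- evolve(ds, cfg)
  expect_identical(shapelets(res1$best), shapelets(res2$best))
  expect_identical(res1$log, res2$log)
  # lexicographic monotonicity of the logged best fitness
  lg <- res1$log
  for (i in 2:nrow(lg)) {
    expect_true(lg$bestError[i] < lg$bestError[i - 1] ||
                (lg$bestError[i] == lg$bestError[i - 1] &&
                 lg$bestComplexity[i] <= lg$bestComplexity[i - 1]))
  }
  # the elite improved on the initial population and solves the task
  expect_lt(lg$bestError[nrow(lg)], lg$bestError[1])
  test <- makeMotifTwoClass(nPerClass = 8, length = 30, motifLength = 6,
                            noise = 0, seed = 77)
  set.seed(5)
  lr <- fitTunedLR(distanceMatrix(res1$best, ds), seriesLabels(ds))
  expect_equal(evaluateAccuracy(lr, res1$best, test), 1)
  # all shapelets respect the configured bounds
  expect_true(all(lengths(shapelets(res1$best)) >= 4))
  expect_true(all(lengths(shapelets(res1$best)) <= minSeriesLength(ds)))
})

test_that("early stopping fires after exactly patience stagnant generations", {
  # identical constant series: every candidate is the same shapelet, so no
  # strict improvement is ever possible after generation 0
  ds <- timeSeriesDataset(list(rep(1, 8), rep(1, 8), rep(1, 8), rep(1, 8)),
                          c("a", "a", "b", "b"))
  cfg <- evolutionConfig(popSize = 6, generations = 50, patience = 4,
                         maxLen = 4, W = 2, maxShapelets = 1, seed = 9)
  res <- evolve(ds, cfg)
  expect_equal(res$reason, "patience")
  expect_equal(max(res$log$generation), 4)  # exactly patience generations
})

test_that("disabling the add mutation stalls search on undersized sets", {
  data <- makeImbalancedThreeClass(n0 = 12, n1 = 4, n2 = 4, length = 60,
                                   seed = 303)
  base <- evolutionConfig(popSize = 16, generations = 12, patience = 12,
                          W = 2, initOps = "random", seed = 404)
  noAdd <- base
  noAdd@mutationOps <- c("mask", "remove")
  full <- evolve(data$train, base)
  crippled <- evolve(data$train, noAdd)
  nf <- nrow(full$log); nc <- nrow(crippled$log)
  expect_lt(full$log$meanError[nf], crippled$log$meanError[nc])
  expect_lte(full$log$bestError[nf], crippled$log$bestError[nc])
})
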