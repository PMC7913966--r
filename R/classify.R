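# stratified fold assignment (consumes the session RNG)
.stratifiedFolds <- function(yInt, nfolds) {
  folds <- integer(length(yInt))
  for (cls in unique(yInt)) {
    idx <- sample(which(yInt == cls))
    folds[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  folds
}

# glmnet multinomial at one fixed penalty; fitted along a short descending
# path for numerical stability, predictions extracted at the target lambda
.glmnetAt <- function(X, y, alpha, lambda) {
  # small-class fits trigger benign sample-size warnings
  suppressWarnings(
    glmnet::glmnet(X, y, family = "multinomial", alpha = alpha,
                   lambda = lambda * c(64, 16, 4, 1)))
}

.padColumns <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) cbind(X, .pad = 0) else X
}

#' Tune and fit a logistic regression on a distance transform
#'
#' Grid search over penalty type (ridge, lasso) and inverse penalty strength
#' \code{C} in \{0.001, 0.01, 0.1, 1, 10, 100, 1000\} - 14 configurations -
#' by stratified cross-validated mean log loss, then refit of the winning
#' configuration on all rows. Exact ties are resolved towards the stronger
#' regularization (smaller C). The glmnet penalty is \code{lambda = 1 / (C n)}
#' so that C scales an unnormalized loss, the usual convention for inverse
#' regularization strengths.
#'
#' @param D numeric matrix, series in rows, shapelet distances in columns.
#' @param y class labels (one per row).
#' @param nfolds requested folds (default 3). If the smallest class has fewer
#'   members than \code{nfolds} the fold count is reduced to that class count,
#'   with a warning.
#' @return a [TunedClassifier-class].
#' @examples
#' ds <- makeMotifTwoClass(nPerClass = 6, length = 30, motifLength = 6, seed = 1)
#' D <- distanceMatrix(initRandom(ds, 2), ds)
#' fit <- fitTunedLR(D, seriesLabels(ds))
#' fit@alpha; fit@C
#' @export
fitTunedLR <- function(D, y, nfolds = 3) {
  D <- .padColumns(D)
  lev <- as.character(unique(y))
  if (length(lev) < 2L) stop("need at least two classes")
  yf <- factor(as.character(y), levels = lev)
  yInt <- as.integer(yf)
  n <- length(yInt)
  if (nrow(D) != n) stop("D and y disagree on the number of series")
  minClass <- min(table(yInt))
  if (minClass < nfolds) {
    nfolds <- max(2L, as.integer(minClass))
    warning("smallest class has ", minClass,
            " members; reducing to ", nfolds, "-fold CV")
  }
  folds <- .stratifiedFolds(yInt, nfolds)
  grid <- expand.grid(alpha = c(0, 1),
                      C = c(0.001, 0.01, 0.1, 1, 10, 100, 1000))
  cvloss <- vapply(seq_len(nrow(grid)), function(g) {
    lam <- 1 / (grid$C[g] * n)
    fold <- vapply(seq_len(nfolds), function(f) {
      tr <- folds != f
      tryCatch({
        fit <- .glmnetAt(D[tr, , drop = FALSE], yf[tr], grid$alpha[g], lam)
        p <- stats::predict(fit, D[!tr, , drop = FALSE], type = "response",
                            s = lam)[, , 1]
        if (is.null(dim(p))) p <- matrix(p, nrow = 1)
        .logLoss(p[, lev, drop = FALSE], yInt[!tr])
      }, error = function(e) NA_real_)  # degenerate training fold
    }, numeric(1))
    if (all(is.na(fold))) Inf else mean(fold, na.rm = TRUE)
  }, numeric(1))
  pick <- order(cvloss, grid$C, grid$alpha)[1]
  alpha <- grid$alpha[pick]; C <- grid$C[pick]
  lambda <- 1 / (C * n)
  fit <- .glmnetAt(D, yf, alpha, lambda)
  # (slots set individually: a named `C` argument to new() would be swallowed
  # by partial matching against its `Class` formal)
  obj <- new("TunedClassifier")
  obj@fit <- fit; obj@alpha <- alpha; obj@C <- C; obj@lambda <- lambda
  obj@levels <- lev
  obj@cvLoss <- data.frame(alpha = grid$alpha, C = grid$C, logLoss = cvloss)
  obj@nfolds <- as.integer(nfolds)
  obj
}

#' @describeIn fitTunedLR predicted class labels (\code{type = "class"}) or
#'   class-probability matrix (\code{type = "prob"}) for a new distance
#'   matrix.
#' @param object a \code{TunedClassifier}.
#' @param newdata distance matrix with the same number of columns as used in
#'   training.
#' @param type \code{"class"} or \code{"prob"}.
#' @export
setMethod("predict", "TunedClassifier", function(object, newdata,
                                                 type = c("class", "prob")) {
  type <- match.arg(type)
  X <- .padColumns(newdata)
  p <- stats::predict(object@fit, X, type = "response", s = object@lambda)[, , 1]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  p <- p[, object@levels, drop = FALSE]
  if (type == "prob") return(p)
  factor(object@levels[apply(p, 1, which.max)], levels = object@levels)
})

#' @export
setMethod("show", "TunedClassifier", function(object) {
  cat(sprintf("TunedClassifier: %s multinomial logistic regression, C = %g\n",
              if (object@alpha == 0) "ridge" else "lasso", object@C))
  cat(sprintf("  classes: %s (%d-fold CV)\n",
              paste(object@levels, collapse = ", "), object@nfolds))
})

#' Accuracy of a tuned classifier on a test collection
#'
#' Transforms the test series by their distances to the shapelet set and
#' returns the fraction of correctly predicted labels.
#'
#' @param model a [TunedClassifier-class].
#' @param set the [ShapeletSet-class] defining the transform.
#' @param dataset test [TimeSeriesDataset-class].
#' @return scalar in \[0, 1\].
#' @export
evaluateAccuracy <- function(model, set, dataset) {
  D <- distanceMatrix(set, dataset)
  pred <- predict(model, D)
  mean(as.character(pred) == as.character(seriesLabels(dataset)))
}

# cross-validated log loss of the fitness-style ridge multinomial model on a
# fixed distance transform
.cvTransformLoss <- function(D, yInt, lev, nfolds = 3, decay = 0.01) {
  folds <- .stratifiedFolds(yInt, nfolds)
  mean(vapply(seq_len(nfolds), function(f) {
    tr <- folds != f
    df <- as.data.frame(D); names(df) <- paste0("d", seq_len(ncol(df)))
    df$.y <- factor(lev[yInt], levels = lev)
    fit <- nnet::multinom(.y ~ ., data = df[tr, , drop = FALSE], trace = FALSE,
                          decay = decay, maxit = 200)
    p <- stats::predict(fit, df[!tr, , drop = FALSE], type = "probs")
    if (is.null(dim(p))) p <- cbind(1 - p, p)
    .logLoss(p, yInt[!tr])
  }, numeric(1)))
}

#' Cross-validated choice of the maximum shapelet length
#'
#' The single hyper-parameter worth tuning per dataset is \code{maxLen},
#' which combats overfitting to long, overly specific subsequences. For each
#' candidate length in \{ceil(M/4), ceil(M/2), ceil(3M/4), M\} a
#' reduced-budget evolution is run with that cap, the training collection is
#' transformed by the resulting elite, and the transform is scored by
#' stratified 3-fold cross-validated log loss of the logistic-regression
#' model. The length with the smallest CV loss wins (ties: the shorter
#' length).
#'
#' The evolution budget inside the loop is deliberately small
#' (\code{budgetPop}, \code{budgetGenerations}) so that the protocol stays
#' cheap; it estimates the relative merit of the length caps, not the final
#' model.
#'
#' @param dataset training [TimeSeriesDataset-class] (shortest series length
#'   must be at least 16).
#' @param config base [EvolutionConfig-class]; population size, generation
#'   count and maxLen are overridden per candidate.
#' @param budgetPop,budgetGenerations evolution budget used inside the loop.
#' @param nfolds folds for the transform CV.
#' @return the selected maximum length (integer).
#' @export
tuneMaxLen <- function(dataset, config = evolutionConfig(),
                       budgetPop = 25, budgetGenerations = 30, nfolds = 3) {
  M <- minSeriesLength(dataset)
  if (M < 16) stop("maxLen tuning needs series of length >= 16")
  grid <- unique(as.integer(ceiling(M * (1:4) / 4)))
  grid <- grid[grid >= config@minLen]
  yInt <- .labelCodes(dataset); lev <- labelLevels(dataset)
  losses <- vapply(seq_along(grid), function(i) {
    cfg <- config
    cfg@popSize <- as.integer(budgetPop)
    cfg@generations <- as.integer(budgetGenerations)
    cfg@maxLen <- grid[i]
    cfg@W <- NA_integer_
    if (!is.na(cfg@seed)) cfg@seed <- cfg@seed + i - 1L
    res <- evolve(dataset, cfg)
    D <- distanceMatrix(res$best, dataset)
    .cvTransformLoss(D, yInt, lev, nfolds, config@ridgePenalty)
  }, numeric(1))
  grid[which.min(losses)]
}
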