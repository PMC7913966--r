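# mean multiclass log loss; probabilities clipped away from 0
.logLoss <- function(prob, yInt) {
  prob <- pmax(prob, 1e-15)
  mean(-log(prob[cbind(seq_along(yInt), yInt)]))
}

# in-sample mean log loss of a ridge-penalized multinomial logistic
# regression fitted on the distance transform D (deterministic BFGS fit)
.fitnessError <- function(D, yInt, levels, decay = 0.01) {
  df <- as.data.frame(D)
  names(df) <- paste0("d", seq_len(ncol(df)))
  df$.y <- factor(levels[yInt], levels = levels)
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, decay = decay,
                        maxit = 200)
  p <- stats::predict(fit, df, type = "probs")
  if (is.null(dim(p))) p <- cbind(1 - p, p)  # two-class: vector of P(level 2)
  .logLoss(p, yInt)
}

#' Fitness of a shapelet set on a dataset
#'
#' Computes the distance transform of the dataset under the set, fits a
#' ridge-penalized multinomial logistic regression on it, and scores the set
#' by the in-sample mean log loss of that model. The second fitness
#' component is the set complexity, the sum of shapelet lengths; fitness
#' values are ordered lexicographically, so of two sets with equal error the
#' less complex one is fitter. The result is cached on the returned set.
#'
#' The internal model is deliberately simple and deterministic: it ranks
#' candidate sets cheaply inside the evolutionary loop and is distinct from
#' the cross-validation tuned classifier ([fitTunedLR()]) used for final
#' prediction.
#'
#' @param set a [ShapeletSet-class] (or list of numeric shapelets).
#' @param dataset a [TimeSeriesDataset-class] with at least two classes.
#' @param decay ridge penalty of the fitness model.
#' @return the set, as a \code{ShapeletSet} with the \code{fitness} slot set
#'   to \code{c(error =, complexity =)}.
#' @examples
#' ds <- makeMotifTwoClass(nPerClass = 5, length = 30, motifLength = 6, seed = 1)
#' s <- initRandom(ds, 2)
#' fitnessValue(evaluateFitness(s, ds))
#' @export
evaluateFitness <- function(set, dataset, decay = 0.01) {
  shp <- .shapeletList(set)
  if (.nClasses(dataset) < 2L || length(unique(dataset@labels)) < 2L)
    stop("fitness is undefined for single-class data")
  D <- distanceMatrix(shp, dataset)
  err <- .fitnessError(D, .labelCodes(dataset), labelLevels(dataset), decay)
  .asSet(shp, fitness = c(error = err, complexity = sum(lengths(shp))))
}
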