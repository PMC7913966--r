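#' @import methods
NULL

#' Labeled collection of univariate time series
#'
#' Container for a collection of \code{N} real-valued series of possibly
#' unequal lengths together with a class label per series. Labels are stored
#' internally as integer codes \code{1..C} in first-appearance order; the
#' original label values are kept in \code{labelLevels}.
#'
#' @slot series list of numeric vectors, one per series; every series has at
#'   least 4 finite values.
#' @slot labels integer vector of label codes, one per series.
#' @slot labelLevels character vector mapping codes to the original labels.
#'
#' @seealso [timeSeriesDataset()], [readUcrTsv()]
#' @export
setClass("TimeSeriesDataset",
  representation(series = "list", labels = "integer", labelLevels = "character"),
  prototype(series = list(), labels = integer(), labelLevels = character())
)

setValidity("TimeSeriesDataset", function(object) {
  msgs <- character()
  n <- length(object@series)
  if (n < 1L) msgs <- c(msgs, "dataset must contain at least one series")
  if (!all(vapply(object@series, is.numeric, logical(1))))
    msgs <- c(msgs, "all series must be numeric vectors")
  lens <- lengths(object@series)
  if (n >= 1L && any(lens < 4L))
    msgs <- c(msgs, sprintf("every series needs >= 4 observations (offending: %s)",
                            paste(which(lens < 4L), collapse = ", ")))
  if (any(!vapply(object@series, function(s) all(is.finite(s)), logical(1))))
    msgs <- c(msgs, "series values must all be finite")
  if (length(object@labels) != n)
    msgs <- c(msgs, "labels must have exactly one entry per series")
  if (length(object@labels) && (any(object@labels < 1L) ||
      any(object@labels > length(object@labelLevels))))
    msgs <- c(msgs, "label codes must index labelLevels")
  if (length(msgs)) msgs else TRUE
})

#' A candidate shapelet set
#'
#' An individual of the evolutionary search: an ordered collection of
#' real-valued shapelets, optionally carrying a cached fitness value
#' \code{c(error, complexity)} computed on some training dataset. The cache
#' is written by [evaluateFitness()] and invalidated by any operator that
#' modifies the member shapelets.
#'
#' @slot shapelets list of numeric vectors.
#' @slot fitness numeric; either \code{numeric(0)} (not evaluated) or a named
#'   vector \code{c(error =, complexity =)}.
#'
#' @seealso [shapeletSet()], [evaluateFitness()], [evolve()]
#' @export
setClass("ShapeletSet",
  representation(shapelets = "list", fitness = "numeric"),
  prototype(shapelets = list(), fitness = numeric())
)

setValidity("ShapeletSet", function(object) {
  msgs <- character()
  if (length(object@shapelets) < 1L)
    msgs <- c(msgs, "a shapelet set must contain at least one shapelet")
  if (!all(vapply(object@shapelets, is.numeric, logical(1))))
    msgs <- c(msgs, "shapelets must be numeric vectors")
  if (any(lengths(object@shapelets) < 1L))
    msgs <- c(msgs, "shapelets must be non-empty")
  if (!all(vapply(object@shapelets, function(s) all(is.finite(s)), logical(1))))
    msgs <- c(msgs, "shapelet values must be finite")
  if (length(object@fitness) && length(object@fitness) != 2L)
    msgs <- c(msgs, "fitness must be numeric(0) or c(error, complexity)")
  if (length(msgs)) msgs else TRUE
})

#' Hyper-parameters of the evolutionary search
#'
#' All knobs of [evolve()]. \code{maxLen} and \code{W} may be left \code{NA}
#' to be resolved against the dataset at run time (\code{maxLen = M}, the
#' shortest series length, and \code{W = ceiling(sqrt(M))}).
#'
#' @slot popSize population size P.
#' @slot generations maximum number of generations G.
#' @slot patience early-stopping window: stop after this many consecutive
#'   generations without strict improvement of the elite.
#' @slot pMutation per-operator mutation probability.
#' @slot pCrossover per-operator crossover probability.
#' @slot minLen minimum shapelet length (4).
#' @slot maxLen maximum shapelet length, or NA for the shortest series length.
#' @slot W upper bound of the initial set-size draw (sizes are uniform on
#'   2..W), or NA for \code{ceiling(sqrt(M))}.
#' @slot maxShapelets hard cap on the number of shapelets per individual
#'   (Inf = unbounded).
#' @slot tournamentSize number of individuals per selection tournament.
#' @slot initOps,crossoverOps,mutationOps enabled operators.
#' @slot ridgePenalty weight-decay strength of the fitness model.
#' @slot seed RNG seed used by [evolve()] (NA = leave the RNG state alone).
#'
#' @seealso [evolutionConfig()], [evolve()]
#' @export
setClass("EvolutionConfig",
  representation(
    popSize = "integer", generations = "integer", patience = "integer",
    pMutation = "numeric", pCrossover = "numeric",
    minLen = "integer", maxLen = "integer", W = "integer",
    maxShapelets = "numeric", tournamentSize = "integer",
    initOps = "character", crossoverOps = "character", mutationOps = "character",
    ridgePenalty = "numeric", seed = "integer"
  )
)

.INIT_OPS <- c("kmeans", "random")
.CROSSOVER_OPS <- c("set", "shapelet", "merge")
.MUTATION_OPS <- c("mask", "remove", "add")

setValidity("EvolutionConfig", function(object) {
  msgs <- character()
  if (object@popSize < 2L) msgs <- c(msgs, "popSize must be >= 2")
  if (object@generations < 1L) msgs <- c(msgs, "generations must be >= 1")
  if (object@patience < 1L) msgs <- c(msgs, "patience must be >= 1")
  for (p in c(object@pMutation, object@pCrossover))
    if (is.na(p) || p < 0 || p > 1) msgs <- c(msgs, "probabilities must lie in [0, 1]")
  if (object@minLen < 2L) msgs <- c(msgs, "minLen must be >= 2")
  if (!is.na(object@maxLen) && object@maxLen < object@minLen)
    msgs <- c(msgs, "maxLen must be >= minLen")
  if (!is.na(object@W) && object@W < 2L) msgs <- c(msgs, "W must be >= 2")
  if (object@maxShapelets < 1) msgs <- c(msgs, "maxShapelets must be >= 1")
  if (object@tournamentSize < 1L) msgs <- c(msgs, "tournamentSize must be >= 1")
  if (!length(object@initOps) || !all(object@initOps %in% .INIT_OPS))
    msgs <- c(msgs, "initOps must be a non-empty subset of kmeans, random")
  if (!all(object@crossoverOps %in% .CROSSOVER_OPS))
    msgs <- c(msgs, "crossoverOps must be a subset of set, shapelet, merge")
  if (!all(object@mutationOps %in% .MUTATION_OPS))
    msgs <- c(msgs, "mutationOps must be a subset of mask, remove, add")
  if (object@ridgePenalty < 0) msgs <- c(msgs, "ridgePenalty must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Quality of the best threshold split of a distance vector
#'
#' Result of [informationGain()]: the maximal entropy reduction achievable by
#' thresholding one shapelet's distances, the threshold itself, and the gap
#' between the two distances the threshold separates.
#'
#' @slot gain information gain in bits.
#' @slot threshold split point on the distance axis.
#' @slot margin distance gap around the threshold.
#' @slot leftCounts,rightCounts per-class counts on either side.
#' @export
setClass("SplitQuality",
  representation(gain = "numeric", threshold = "numeric", margin = "numeric",
                 leftCounts = "integer", rightCounts = "integer")
)

#' Cross-validation tuned logistic regression on a distance transform
#'
#' Multinomial logistic regression whose penalty type (ridge or lasso) and
#' inverse penalty strength C were selected by stratified cross-validated log
#' loss over a fixed grid, then refit on all rows.
#'
#' @slot fit the fitted glmnet model.
#' @slot alpha elastic-net mixing parameter of the winner (0 ridge, 1 lasso).
#' @slot C inverse regularization strength of the winner.
#' @slot lambda the glmnet penalty corresponding to C.
#' @slot levels class labels in training order.
#' @slot cvLoss data frame of mean CV log loss per grid point.
#' @slot nfolds number of folds actually used.
#' @export
setClass("TunedClassifier",
  representation(fit = "ANY", alpha = "numeric", C = "numeric",
                 lambda = "numeric", levels = "character",
                 cvLoss = "data.frame", nfolds = "integer")
)
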