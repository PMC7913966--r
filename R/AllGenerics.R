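#' @rdname TimeSeriesDataset-class
#' @param x a \code{TimeSeriesDataset}.
#' @export
setGeneric("nSeries", function(x) standardGeneric("nSeries"))

#' @rdname TimeSeriesDataset-class
#' @export
setGeneric("seriesLengths", function(x) standardGeneric("seriesLengths"))

#' @rdname TimeSeriesDataset-class
#' @export
setGeneric("minSeriesLength", function(x) standardGeneric("minSeriesLength"))

#' @rdname TimeSeriesDataset-class
#' @export
setGeneric("seriesLabels", function(x) standardGeneric("seriesLabels"))

#' @rdname TimeSeriesDataset-class
#' @export
setGeneric("labelLevels", function(x) standardGeneric("labelLevels"))

#' @rdname TimeSeriesDataset-class
#' @param i series index.
#' @export
setGeneric("getSeries", function(x, i) standardGeneric("getSeries"))

#' @rdname ShapeletSet-class
#' @param x a \code{ShapeletSet}.
#' @export
setGeneric("shapelets", function(x) standardGeneric("shapelets"))

#' @rdname ShapeletSet-class
#' @export
setGeneric("setSize", function(x) standardGeneric("setSize"))

#' @rdname ShapeletSet-class
#' @export
setGeneric("complexity", function(x) standardGeneric("complexity"))

#' @rdname ShapeletSet-class
#' @export
setGeneric("fitnessValue", function(x) standardGeneric("fitnessValue"))

#' Distance transform of a dataset under a shapelet set
#'
#' @param shapelets a [ShapeletSet-class] or plain list of numeric vectors.
#' @param dataset a [TimeSeriesDataset-class].
#' @param ... further arguments (\code{countOps}).
#' @return numeric matrix, one row per series, one column per shapelet.
#' @export
setGeneric("distanceMatrix",
           function(shapelets, dataset, ...) standardGeneric("distanceMatrix"))
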