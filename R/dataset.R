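#' Build a labeled time-series dataset
#'
#' Assembles a [TimeSeriesDataset-class] from a list of numeric series and a
#' parallel label vector. Labels of any atomic type are mapped to integer
#' codes \code{1..C} in order of first appearance; the original values are
#' preserved and restored by [seriesLabels()].
#'
#' @param series list of numeric vectors (each of length >= 4); a numeric
#'   matrix is also accepted, rows becoming series.
#' @param labels vector with one class label per series.
#' @param standardize if TRUE, each series is centred and scaled to unit
#'   variance before storage. Off by default: the sliding distance operates
#'   on the raw measurement scale.
#' @return a \code{TimeSeriesDataset}.
#' @examples
#' ds <- timeSeriesDataset(list(sin(1:20), cos(1:20)), c("a", "b"))
#' nSeries(ds)
#' @export
timeSeriesDataset <- function(series, labels, standardize = FALSE) {
  if (is.matrix(series))
    series <- lapply(seq_len(nrow(series)), function(i) as.numeric(series[i, ]))
  series <- lapply(series, as.numeric)
  if (length(labels) != length(series))
    stop("need exactly one label per series (", length(series), " series, ",
         length(labels), " labels)")
  if (standardize)
    series <- lapply(series, function(s) {
      sdv <- stats::sd(s)
      if (sdv == 0) s - mean(s) else (s - mean(s)) / sdv
    })
  lev <- as.character(unique(labels))
  codes <- match(as.character(labels), lev)
  new("TimeSeriesDataset", series = series, labels = as.integer(codes),
      labelLevels = lev)
}

#' @rdname TimeSeriesDataset-class
#' @export
setMethod("nSeries", "TimeSeriesDataset", function(x) length(x@series))

#' @rdname TimeSeriesDataset-class
#' @export
setMethod("seriesLengths", "TimeSeriesDataset", function(x) lengths(x@series))

#' @rdname TimeSeriesDataset-class
#' @export
setMethod("minSeriesLength", "TimeSeriesDataset", function(x) min(lengths(x@series)))

#' @rdname TimeSeriesDataset-class
#' @export
setMethod("seriesLabels", "TimeSeriesDataset", function(x)
  factor(x@labelLevels[x@labels], levels = x@labelLevels))

#' @rdname TimeSeriesDataset-class
#' @export
setMethod("labelLevels", "TimeSeriesDataset", function(x) x@labelLevels)

#' @rdname TimeSeriesDataset-class
#' @export
setMethod("getSeries", "TimeSeriesDataset", function(x, i) x@series[[i]])

#' @export
setMethod("show", "TimeSeriesDataset", function(object) {
  lens <- lengths(object@series)
  cat("TimeSeriesDataset:", length(object@series), "series,",
      length(object@labelLevels), "classes\n")
  cat("  lengths:", if (length(unique(lens)) == 1L) lens[1]
      else paste0("[", min(lens), ", ", max(lens), "]"), "\n")
  cat("  classes:", paste0(object@labelLevels, " (",
      tabulate(object@labels, length(object@labelLevels)), ")",
      collapse = ", "), "\n")
})

# integer label codes 1..C (internal)
.labelCodes <- function(x) x@labels

.nClasses <- function(x) length(x@labelLevels)
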