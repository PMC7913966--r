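#' Read a delimited time-series collection (UCR convention)
#'
#' Each row holds one series: the class label in the first field followed by
#' the observations. Rows may have different lengths; fields are separated by
#' \code{delimiter}. Labels (integer or string) are mapped to internal codes
#' in first-appearance order and restored by [seriesLabels()].
#'
#' @param path input file.
#' @param delimiter field separator (default tab).
#' @param standardize per-series standardization flag, passed to
#'   [timeSeriesDataset()].
#' @return a [TimeSeriesDataset-class].
#' @export
readUcrTsv <- function(path, delimiter = "\t", standardize = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty dataset file: ", path)
  labels <- character(length(lines))
  series <- vector("list", length(lines))
  for (r in seq_along(lines)) {
    fields <- strsplit(trimws(lines[r]), delimiter, fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 5L)
      stop("row ", r, " has ", length(fields) - 1L,
           " values; every series needs at least 4")
    labels[r] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals))
      stop("row ", r, ", column ", which(is.na(vals))[1] + 1L,
           ": non-numeric value '", fields[-1][which(is.na(vals))[1]], "'")
    series[[r]] <- vals
  }
  timeSeriesDataset(series, labels, standardize = standardize)
}

#' @rdname readUcrTsv
#' @param dataset a [TimeSeriesDataset-class] to write.
#' @export
writeUcrTsv <- function(dataset, path, delimiter = "\t") {
  lab <- as.character(seriesLabels(dataset))
  lines <- vapply(seq_len(nSeries(dataset)), function(i)
    paste(c(lab[i], format(dataset@series[[i]], digits = 17, trim = TRUE,
                           scientific = FALSE)),
          collapse = delimiter), character(1))
  writeLines(lines, path)
  invisible(path)
}

.SHAPELET_DOC_VERSION <- "1.0"

#' Serialize and restore shapelet sets
#'
#' \code{writeShapeletSet} stores a shapelet set as a versioned JSON document
#' with full-precision values, an optional configuration snapshot and the
#' cached fitness; \code{readShapeletSet} restores it, checking the format
#' version. The round trip is lossless.
#'
#' @param set a [ShapeletSet-class].
#' @param path file path.
#' @param config optional [EvolutionConfig-class] to snapshot.
#' @param provenance optional data frame (series/offset/length) or character
#'   note, e.g. \code{"evolved"}.
#' @return \code{readShapeletSet} returns a \code{ShapeletSet};
#'   \code{writeShapeletSet} returns \code{path} invisibly.
#' @export
writeShapeletSet <- function(set, path, config = NULL, provenance = NULL) {
  doc <- list(
    version = .SHAPELET_DOC_VERSION,
    shapelets = lapply(.shapeletList(set), function(s) list(values = s))
  )
  fv <- if (is(set, "ShapeletSet")) fitnessValue(set) else NULL
  if (!is.null(fv))
    doc$fitness <- list(error = unname(fv[[1]]), complexity = unname(fv[[2]]))
  if (!is.null(provenance)) doc$provenance <- provenance
  if (!is.null(config)) {
    doc$config <- list(
      popSize = config@popSize, generations = config@generations,
      patience = config@patience, pMutation = config@pMutation,
      pCrossover = config@pCrossover, minLen = config@minLen,
      maxLen = config@maxLen, W = config@W,
      maxShapelets = config@maxShapelets,
      tournamentSize = config@tournamentSize,
      initOps = config@initOps, crossoverOps = config@crossoverOps,
      mutationOps = config@mutationOps, seed = config@seed)
  }
  # I(17) = 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname writeShapeletSet
#' @export
readShapeletSet <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$version))
    stop("not a shapelet-set document: missing version field")
  if (!identical(as.character(doc$version), .SHAPELET_DOC_VERSION))
    stop("unsupported shapelet-set document version: ", doc$version)
  if (is.null(doc$shapelets) || !length(doc$shapelets))
    stop("malformed shapelet-set document: no shapelets")
  shp <- lapply(doc$shapelets, function(el) {
    v <- unlist(el$values, use.names = FALSE)
    if (is.null(v) || !is.numeric(v))
      stop("malformed shapelet-set document: bad values entry")
    as.numeric(v)
  })
  fitness <- numeric()
  if (!is.null(doc$fitness))
    fitness <- c(error = as.numeric(doc$fitness$error),
                 complexity = as.numeric(doc$fitness$complexity))
  .asSet(shp, fitness = fitness)
}

#' Write a distance matrix as delimited text
#'
#' @param D matrix from [distanceMatrix()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMatrix <- function(D, path) {
  colnames(D) <- paste0("shapelet", seq_len(ncol(D)))
  utils::write.table(D, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
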