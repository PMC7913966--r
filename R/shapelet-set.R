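#' Build a shapelet set
#'
#' @param shapelets list of numeric vectors, or a single numeric vector for a
#'   singleton set.
#' @return a [ShapeletSet-class] with empty fitness cache.
#' @examples
#' s <- shapeletSet(list(c(1, 2, 3, 4), c(0, 0, 1, 1, 0)))
#' setSize(s); complexity(s)
#' @export
shapeletSet <- function(shapelets) {
  if (is.numeric(shapelets)) shapelets <- list(shapelets)
  new("ShapeletSet", shapelets = lapply(shapelets, as.numeric),
      fitness = numeric())
}

#' @rdname ShapeletSet-class
#' @export
setMethod("shapelets", "ShapeletSet", function(x) x@shapelets)

#' @rdname ShapeletSet-class
#' @export
setMethod("setSize", "ShapeletSet", function(x) length(x@shapelets))

#' @rdname ShapeletSet-class
#' @export
setMethod("complexity", "ShapeletSet", function(x) sum(lengths(x@shapelets)))

#' @rdname ShapeletSet-class
#' @export
setMethod("fitnessValue", "ShapeletSet", function(x)
  if (length(x@fitness)) x@fitness else NULL)

#' @export
setMethod("show", "ShapeletSet", function(object) {
  cat(sprintf("ShapeletSet: %d shapelets, lengths %s (complexity %d)\n",
              length(object@shapelets),
              paste(lengths(object@shapelets), collapse = "/"),
              sum(lengths(object@shapelets))))
  if (length(object@fitness))
    cat(sprintf("  fitness: error = %.6g, complexity = %d\n",
                object@fitness[[1]], as.integer(object@fitness[[2]])))
})

#' @export
setMethod("[[", "ShapeletSet", function(x, i) x@shapelets[[i]])

# internal: raw list view, and rebuild (fitness cache dropped on rebuild)
.shapeletList <- function(x) if (is(x, "ShapeletSet")) x@shapelets else x
.asSet <- function(lst, fitness = numeric()) {
  new("ShapeletSet", shapelets = lst, fitness = fitness)
}

# lexicographic fitness order: lower error wins, then lower complexity
.fitterThan <- function(a, b) {
  (a[[1]] < b[[1]]) || (a[[1]] == b[[1]] && a[[2]] < b[[2]])
}
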