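#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared across the package's S4 classes. Slot
#' access from user code should go through these rather than `@`.
#'
#' @param x An object of one of the package's S4 classes.
#' @param ... Passed on to methods.
#' @return The slot contents (a matrix, numeric vector, or scalar as
#'   documented on each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meanGrid", function(x, ...) standardGeneric("meanGrid"))

#' @rdname accessors
#' @export
setGeneric("sdGrid", function(x, ...) standardGeneric("sdGrid"))

#' @rdname accessors
#' @export
setGeneric("cellSize", function(x, ...) standardGeneric("cellSize"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x, ...) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x, ...) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("distances", function(x, ...) standardGeneric("distances"))

#' @rdname accessors
#' @export
setGeneric("values", function(x, ...) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("valueSds", function(x, ...) standardGeneric("valueSds"))

#' @rdname accessors
#' @export
setGeneric("isotope", function(x, ...) standardGeneric("isotope"))

#' @rdname accessors
#' @export
setGeneric("toothId", function(x, ...) standardGeneric("toothId"))

#' @rdname accessors
#' @export
setGeneric("posteriorGrid", function(x, ...) standardGeneric("posteriorGrid"))

#' @rdname accessors
#' @export
setGeneric("topMask", function(x, ...) standardGeneric("topMask"))

#' @rdname accessors
#' @export
setGeneric("layerNames", function(x, ...) standardGeneric("layerNames"))

#' @rdname accessors
#' @export
setGeneric("getLayer", function(x, name, ...) standardGeneric("getLayer"))

#' @rdname accessors
#' @export
setGeneric("nYears", function(x, ...) standardGeneric("nYears"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x, ...) standardGeneric("isDegenerate"))

#' @rdname accessors
#' @export
setGeneric("phaseSummary", function(x, ...) standardGeneric("phaseSummary"))

#' @rdname accessors
#' @export
setGeneric("hpdIntervals", function(x, ...) standardGeneric("hpdIntervals"))
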