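#' @rdname exprValues
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname geneRoles
#' @export
setGeneric("geneRoles", function(x) standardGeneric("geneRoles"))

#' @rdname isTransformed
#' @export
setGeneric("isTransformed", function(x) standardGeneric("isTransformed"))

#' @rdname filterExpressed
#' @export
setGeneric("filterExpressed",
           function(x, minFraction = 0.7) standardGeneric("filterExpressed"))

#' @rdname log2Transform
#' @export
setGeneric("log2Transform",
           function(x, offset = 1) standardGeneric("log2Transform"))

#' @rdname targetSet
#' @export
setGeneric("targetSet",
           function(x, lncrnaId) standardGeneric("targetSet"))
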