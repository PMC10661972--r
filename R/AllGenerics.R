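#' @rdname ExpressionMatrix-class
#' @param x,object an object.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname PriorNetwork-class
#' @param x,object an object.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname PriorNetwork-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname PriorNetwork-class
#' @export
setGeneric("tfSet", function(x) standardGeneric("tfSet"))

#' @rdname PriorNetwork-class
#' @export
setGeneric("networkDensity", function(x) standardGeneric("networkDensity"))
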