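#' @rdname InteractionGraph-class
#' @param x an `InteractionGraph`.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname InteractionGraph-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname InteractionGraph-class
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname InteractionGraph-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname InteractionGraph-class
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))
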