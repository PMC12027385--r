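#' Accessors for SeedSet and CeNET objects
#'
#' Slot access goes through these generics; `members()` returns the sorted
#' miRNA ids of a seed set, `stage()`/`cenetPolarity()` the stage label and
#' network polarity, `netNodes()`/`netEdges()` the node and edge tables of
#' a network, and `missingSeeds()`/`droppedSeeds()` the seed miRNAs without
#' interactions and those removed by the expression filter.
#'
#' @param x a [SeedSet-class] or [CeNET-class] object.
#' @return `members`, `missingSeeds`, `droppedSeeds`: character vectors;
#'   `stage`, `mirnaDirection`, `cenetPolarity`: character(1);
#'   `netNodes`, `netEdges`: data.frames; `isFiltered`: logical(1).
#' @name cenet-accessors
NULL

#' @rdname cenet-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname cenet-accessors
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))
#' @rdname cenet-accessors
#' @export
setGeneric("mirnaDirection", function(x) standardGeneric("mirnaDirection"))
#' @rdname cenet-accessors
#' @export
setGeneric("cenetPolarity", function(x) standardGeneric("cenetPolarity"))
#' @rdname cenet-accessors
#' @export
setGeneric("netNodes", function(x) standardGeneric("netNodes"))
#' @rdname cenet-accessors
#' @export
setGeneric("netEdges", function(x) standardGeneric("netEdges"))
#' @rdname cenet-accessors
#' @export
setGeneric("missingSeeds", function(x) standardGeneric("missingSeeds"))
#' @rdname cenet-accessors
#' @export
setGeneric("droppedSeeds", function(x) standardGeneric("droppedSeeds"))
#' @rdname cenet-accessors
#' @export
setGeneric("isFiltered", function(x) standardGeneric("isFiltered"))

#' @rdname cenet-accessors
setMethod("members", "SeedSet", function(x) x@members)
#' @rdname cenet-accessors
setMethod("stage", "SeedSet", function(x) x@stage)
#' @rdname cenet-accessors
setMethod("mirnaDirection", "SeedSet", function(x) x@mirnaDirection)
#' @rdname cenet-accessors
setMethod("cenetPolarity", "SeedSet", function(x) x@cenetPolarity)

#' @rdname cenet-accessors
setMethod("stage", "CeNET", function(x) x@stage)
#' @rdname cenet-accessors
setMethod("cenetPolarity", "CeNET", function(x) x@polarity)
#' @rdname cenet-accessors
setMethod("netNodes", "CeNET", function(x) x@nodes)
#' @rdname cenet-accessors
setMethod("netEdges", "CeNET", function(x) x@edges)
#' @rdname cenet-accessors
setMethod("missingSeeds", "CeNET", function(x) x@missingSeeds)
#' @rdname cenet-accessors
setMethod("droppedSeeds", "CeNET", function(x) x@droppedSeeds)
#' @rdname cenet-accessors
setMethod("isFiltered", "CeNET", function(x) x@filtered)
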