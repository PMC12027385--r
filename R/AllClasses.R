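#' @import methods
NULL

.DIRECTIONS <- c("up", "down", "ns")
.RNA_CLASSES <- c("miRNA", "mRNA", "lncRNA", "circRNA")
.CERNA_CLASSES <- c("mRNA", "lncRNA", "circRNA")
.COMPARTMENTS <- c("EV", "tissue")
.POLARITIES <- c("UP", "DOWN")

## ceNET polarity is always the opposite of the seed miRNA direction:
## up-regulated miRNAs imply their sponges are off, so the network of
## their down-regulated targets is the DOWN ceNET, and dually.
.oppositePolarity <- function(direction) {
    switch(direction, up = "DOWN", down = "UP",
           stop("direction must be 'up' or 'down'", call. = FALSE))
}

.polarityToDirection <- function(polarity) {
    switch(polarity, UP = "up", DOWN = "down",
           stop("polarity must be 'UP' or 'DOWN'", call. = FALSE))
}

#' SeedSet: direction-concordant miRNAs for one stage
#'
#' A `SeedSet` holds the miRNAs found dysregulated in the same direction in
#' both the extracellular-vesicle cargo and the tissue at one pathology
#' stage. The derived `cenetPolarity` is the polarity of the ceNET these
#' seeds give rise to: up-regulated miRNAs seed the DOWN ceNET (their
#' targets are expected down-regulated) and down-regulated miRNAs seed the
#' UP ceNET.
#'
#' @slot stage character(1), stage label (e.g. `"6m"`).
#' @slot mirnaDirection `"up"` or `"down"`, the shared miRNA direction.
#' @slot members sorted character vector of miRNA identifiers.
#' @slot cenetPolarity `"UP"` or `"DOWN"`, always opposite to
#'   `mirnaDirection`.
#'
#' @exportClass SeedSet
setClass("SeedSet",
    representation(
        stage = "character",
        mirnaDirection = "character",
        members = "character",
        cenetPolarity = "character"
    )
)

setValidity("SeedSet", function(object) {
    msg <- character()
    if (length(object@stage) != 1L || !nzchar(object@stage))
        msg <- c(msg, "'stage' must be a single non-empty string")
    if (length(object@mirnaDirection) != 1L ||
        !object@mirnaDirection %in% c("up", "down"))
        msg <- c(msg, "'mirnaDirection' must be 'up' or 'down'")
    if (anyDuplicated(object@members))
        msg <- c(msg, "'members' must be unique")
    if (is.unsorted(object@members))
        msg <- c(msg, "'members' must be sorted")
    if (length(object@mirnaDirection) == 1L &&
        object@mirnaDirection %in% c("up", "down") &&
        !identical(object@cenetPolarity,
                   .oppositePolarity(object@mirnaDirection)))
        msg <- c(msg, "'cenetPolarity' must be opposite to 'mirnaDirection'")
    if (length(msg)) msg else TRUE
})

#' Construct a SeedSet
#'
#' @param stage stage label.
#' @param direction shared miRNA direction, `"up"` or `"down"`.
#' @param members character vector of miRNA ids; deduplicated and sorted
#'   lexicographically (C locale) for deterministic downstream output.
#'
#' @return A [SeedSet-class] object. An empty member set is allowed but
#'   flagged with a warning, since it yields an empty network.
#' @export
#' @examples
#' SeedSet("6m", "up", c("mmu-miR-369-5p", "mmu-miR-339-3p"))
SeedSet <- function(stage, direction, members = character()) {
    direction <- match.arg(direction, c("up", "down"))
    members <- sort(unique(as.character(members)), method = "radix")
    if (length(members) == 0L)
        warning("empty seed set for stage ", stage, ", direction ", direction)
    new("SeedSet", stage = as.character(stage), mirnaDirection = direction,
        members = members, cenetPolarity = .oppositePolarity(direction))
}

setMethod("show", "SeedSet", function(object) {
    cat("SeedSet: stage ", object@stage, ", miRNA ", object@mirnaDirection,
        " -> ceNET ", object@cenetPolarity, "\n", sep = "")
    cat("  ", length(object@members), " member miRNA(s)\n", sep = "")
    if (length(object@members))
        cat("  ", paste(utils::head(object@members, 5L), collapse = ", "),
            if (length(object@members) > 5L) ", ..." else "", "\n", sep = "")
})

.emptyNodes <- function() {
    data.frame(id = character(), rna_class = character(),
               direction = character(), stringsAsFactors = FALSE)
}

.emptyEdges <- function() {
    data.frame(mirna_id = character(), target_id = character(),
               target_class = character(), clip_support = integer(),
               stringsAsFactors = FALSE)
}

#' CeNET: a polarity-consistent bipartite miRNA-ceRNA network
#'
#' Bipartite network for one stage and polarity: every edge runs from a
#' seed miRNA to a competing endogenous RNA (mRNA, lncRNA or circRNA).
#' Before expression filtering (`filtered = FALSE`) the targets carry no
#' direction; after [applyCernaFilter()] every retained target's tissue
#' direction equals the network polarity and every seed miRNA's direction
#' is the opposite.
#'
#' @slot stage character(1) stage label.
#' @slot polarity `"UP"` or `"DOWN"`.
#' @slot nodes data.frame with columns `id`, `rna_class`, `direction`.
#' @slot edges data.frame with columns `mirna_id`, `target_id`,
#'   `target_class`, `clip_support`.
#' @slot missingSeeds seed miRNAs with no interaction in the source table.
#' @slot droppedSeeds seed miRNAs whose edges were all removed by the
#'   expression filter (degree 0 after filtering).
#' @slot filtered logical(1), whether the ceRNA expression filter ran.
#'
#' @exportClass CeNET
setClass("CeNET",
    representation(
        stage = "character",
        polarity = "character",
        nodes = "data.frame",
        edges = "data.frame",
        missingSeeds = "character",
        droppedSeeds = "character",
        filtered = "logical"
    ),
    prototype(
        nodes = .emptyNodes(),
        edges = .emptyEdges(),
        missingSeeds = character(),
        droppedSeeds = character(),
        filtered = FALSE
    )
)

setValidity("CeNET", function(object) {
    msg <- character()
    if (length(object@polarity) != 1L || !object@polarity %in% .POLARITIES)
        msg <- c(msg, "'polarity' must be 'UP' or 'DOWN'")
    ncol_ok <- all(c("id", "rna_class", "direction") %in%
                   names(object@nodes))
    if (!ncol_ok)
        msg <- c(msg, "'nodes' needs columns id, rna_class, direction")
    if (!all(c("mirna_id", "target_id", "target_class", "clip_support") %in%
             names(object@edges)))
        msg <- c(msg,
            "'edges' needs columns mirna_id, target_id, target_class, clip_support")
    if (ncol_ok && nrow(object@nodes)) {
        if (!all(object@nodes$rna_class %in% .RNA_CLASSES))
            msg <- c(msg, "unknown rna_class in nodes")
        mirna <- object@nodes$id[object@nodes$rna_class == "miRNA"]
        targ <- object@nodes$id[object@nodes$rna_class != "miRNA"]
        if (nrow(object@edges)) {
            if (!all(object@edges$mirna_id %in% mirna))
                msg <- c(msg, "edge source not a miRNA node")
            if (!all(object@edges$target_id %in% targ))
                msg <- c(msg, "edge target not a ceRNA node")
        }
        # bipartite: every non-miRNA node must be the target of >= 1 edge
        if (length(targ) && !all(targ %in% object@edges$target_id))
            msg <- c(msg, "ceRNA node with degree 0")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CeNET", function(object) {
    cat("CeNET (", if (object@filtered) "filtered" else "unfiltered",
        "): stage ", object@stage, ", polarity ", object@polarity,
        "\n", sep = "")
    n_mirna <- sum(object@nodes$rna_class == "miRNA")
    cat("  ", n_mirna, " miRNA node(s), ",
        nrow(object@nodes) - n_mirna, " ceRNA node(s), ",
        nrow(object@edges), " edge(s)\n", sep = "")
    if (length(object@missingSeeds))
        cat("  missing seeds: ",
            paste(object@missingSeeds, collapse = ", "), "\n", sep = "")
    if (length(object@droppedSeeds))
        cat("  seeds dropped by filter: ",
            paste(object@droppedSeeds, collapse = ", "), "\n", sep = "")
})
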