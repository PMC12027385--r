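## ceNET construction: expand seed miRNAs over the CLIP interaction table
## (whole-genome network), then keep only targets whose tissue direction
## matches the network polarity (ceRNA-hypothesis filter).

.sortEdges <- function(edges) {
    if (nrow(edges) == 0L) return(edges)
    o <- order(edges$mirna_id, edges$target_id, method = "radix")
    out <- edges[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

.sortNodes <- function(nodes) {
    if (nrow(nodes) == 0L) return(nodes)
    # miRNAs first, then targets, each lexicographic
    o <- order(nodes$rna_class != "miRNA", nodes$id, method = "radix")
    out <- nodes[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build the whole-genome network for a seed set
#'
#' Collects every interaction whose miRNA is a seed member. Targets carry
#' no direction yet (`NA`): this is the unfiltered network of everything
#' the seeds can touch. Seeds without a single interaction are recorded in
#' `missingSeeds` rather than silently dropped.
#'
#' @param seeds a [SeedSet-class].
#' @param interactions deduplicated interaction data.frame
#'   ([readInteractionTable()]).
#' @param clipSupportMin optional minimum number of supporting CLIP
#'   experiments per edge (default 0: keep all, matching the source
#'   table as published).
#' @return An unfiltered [CeNET-class] whose polarity is the seed set's
#'   `cenetPolarity`.
#' @export
buildWholeGenomeNet <- function(seeds, interactions, clipSupportMin = 0) {
    stopifnot(is(seeds, "SeedSet"))
    if (length(members(seeds)) == 0L)
        warning("empty seed set: returning an empty network")
    keep <- interactions$clip_support >= clipSupportMin &
        interactions$mirna_id %in% members(seeds)
    edges <- .sortEdges(interactions[keep, , drop = FALSE])
    mirnaDir <- .polarityToDirection(
        switch(cenetPolarity(seeds), UP = "DOWN", DOWN = "UP"))
    connected <- sort(unique(edges$mirna_id), method = "radix")
    targets <- unique(edges[, c("target_id", "target_class")])
    targets <- targets[!duplicated(targets$target_id), , drop = FALSE]
    nodes <- rbind(
        data.frame(id = connected, rna_class = rep("miRNA", length(connected)),
                   direction = rep(mirnaDir, length(connected)),
                   stringsAsFactors = FALSE),
        data.frame(id = targets$target_id, rna_class = targets$target_class,
                   direction = rep(NA_character_, nrow(targets)),
                   stringsAsFactors = FALSE)
    )
    new("CeNET", stage = stage(seeds), polarity = cenetPolarity(seeds),
        nodes = .sortNodes(nodes), edges = edges,
        missingSeeds = setdiff(members(seeds), connected),
        droppedSeeds = character(), filtered = FALSE)
}

#' Apply the ceRNA-hypothesis polarity filter
#'
#' Keeps an edge only when its target is present in the tissue ceRNA
#' differential-expression records with direction equal to the network
#' polarity: an UP ceNET (seeded by down-regulated miRNAs) retains only
#' up-regulated ceRNAs, a DOWN ceNET only down-regulated ones. Targets are
#' matched by the (identifier, RNA class) pair; when a target identifier
#' is found only under a different RNA class the mismatch is reported and
#' the interaction table's class wins (the DE record still supplies the
#' direction). Seed miRNAs left with no edge are moved to
#' `droppedSeeds`. Filtering never adds nodes or edges.
#'
#' @param net an unfiltered [CeNET-class].
#' @param cernaRecords tissue DE data.frame covering the ceRNA classes
#'   (`mRNA`, `lncRNA`, `circRNA`) for the network's stage.
#' @return The filtered [CeNET-class].
#' @export
applyCernaFilter <- function(net, cernaRecords) {
    stopifnot(is(net, "CeNET"))
    rec <- cernaRecords
    if (nrow(rec)) {
        if (!all(rec$rna_class %in% .CERNA_CLASSES))
            stop("cernaRecords must contain only ceRNA classes",
                 call. = FALSE)
        if (!all(rec$compartment == "tissue"))
            stop("cernaRecords must come from the tissue compartment",
                 call. = FALSE)
        if (!all(rec$stage == stage(net)))
            stop("cernaRecords stage does not match network stage '",
                 stage(net), "'", call. = FALSE)
    }
    wanted <- .polarityToDirection(cenetPolarity(net))
    edges <- netEdges(net)
    pairKey <- function(id, cls) paste(id, cls, sep = "\r")
    recPair <- pairKey(rec$feature_id, rec$rna_class)
    # a target is retained iff some matching DE record carries the wanted
    # direction; (id, class) match preferred, id-only match reported
    okPair <- unique(recPair[rec$direction == wanted])
    okId <- unique(rec$feature_id[rec$direction == wanted])
    edgePair <- pairKey(edges$target_id, edges$target_class)
    hitPair <- edgePair %in% okPair
    hitIdOnly <- !hitPair & !(edgePair %in% recPair) &
        edges$target_id %in% okId
    if (any(hitIdOnly))
        message(sum(hitIdOnly), " edge target(s) matched the DE table ",
                "under a different RNA class; keeping the interaction ",
                "table's class")
    keep <- hitPair | hitIdOnly
    edges <- .sortEdges(edges[keep, , drop = FALSE])
    connected <- sort(unique(edges$mirna_id), method = "radix")
    targets <- unique(edges[, c("target_id", "target_class")])
    targets <- targets[!duplicated(targets$target_id), , drop = FALSE]
    mirnaDir <- .polarityToDirection(
        switch(cenetPolarity(net), UP = "DOWN", DOWN = "UP"))
    nodes <- rbind(
        data.frame(id = connected, rna_class = rep("miRNA", length(connected)),
                   direction = rep(mirnaDir, length(connected)),
                   stringsAsFactors = FALSE),
        data.frame(id = targets$target_id, rna_class = targets$target_class,
                   direction = rep(wanted, nrow(targets)),
                   stringsAsFactors = FALSE)
    )
    before <- netNodes(net)
    hadEdges <- before$id[before$rna_class == "miRNA"]
    new("CeNET", stage = stage(net), polarity = cenetPolarity(net),
        nodes = .sortNodes(nodes), edges = edges,
        missingSeeds = missingSeeds(net),
        droppedSeeds = sort(setdiff(hadEdges, connected), method = "radix"),
        filtered = TRUE)
}

#' Export a ceNET to Cytoscape-compatible formats
#'
#' `SIF` writes one `mirna_id<TAB>cerna_of<TAB>target_id` line per edge;
#' `GraphML` carries node attributes `rna_class` and `direction`, the edge
#' attribute `clip_support`, and the graph attributes `stage`, `polarity`
#' and `filtered` (so [importNetworkGraphML()] can reconstruct the
#' object); `TSV` writes an edge list mirroring the GraphML attributes.
#' Output is deterministically sorted, so identical networks produce
#' byte-identical files.
#'
#' @param net a [CeNET-class].
#' @param path output file path.
#' @param format `"SIF"`, `"GraphML"` or `"TSV"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("SIF", "GraphML", "TSV")) {
    stopifnot(is(net, "CeNET"))
    format <- match.arg(format)
    validObject(net)
    edges <- .sortEdges(netEdges(net))
    nodes <- .sortNodes(netNodes(net))
    if (format == "SIF") {
        lines <- if (nrow(edges))
            paste(edges$mirna_id, "cerna_of", edges$target_id, sep = "\t")
        else character()
        writeLines(lines, path, useBytes = TRUE)
    } else if (format == "TSV") {
        dirOf <- structure(nodes$direction, names = nodes$id)
        out <- data.frame(
            mirna_id = edges$mirna_id,
            target_id = edges$target_id,
            target_class = edges$target_class,
            clip_support = edges$clip_support,
            mirna_direction = unname(dirOf[edges$mirna_id]),
            target_direction = unname(dirOf[edges$target_id]),
            stringsAsFactors = FALSE
        )
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA",
                           fileEncoding = "UTF-8")
    } else {
        g <- .asIgraph(net, nodes, edges)
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}

.asIgraph <- function(net, nodes = .sortNodes(netNodes(net)),
                      edges = .sortEdges(netEdges(net))) {
    # GraphML string attributes cannot carry NA; "" stands for "no call"
    nodes$direction[is.na(nodes$direction)] <- ""
    g <- igraph::graph_from_data_frame(
        d = edges[, c("mirna_id", "target_id", "target_class",
                      "clip_support")],
        directed = TRUE,
        vertices = nodes[, c("id", "rna_class", "direction")]
    )
    g <- igraph::set_graph_attr(g, "stage", stage(net))
    g <- igraph::set_graph_attr(g, "polarity", cenetPolarity(net))
    g <- igraph::set_graph_attr(g, "filtered", isFiltered(net))
    g
}

#' Re-import a GraphML export
#'
#' Reads a GraphML file written by [exportNetwork()] back into a
#' [CeNET-class]; node and edge sets round-trip exactly. Bookkeeping not
#' stored in GraphML (`missingSeeds`, `droppedSeeds`) comes back empty.
#'
#' @param path GraphML file path.
#' @return A [CeNET-class].
#' @export
importNetworkGraphML <- function(path) {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(
        id = igraph::vertex_attr(g, "name"),
        rna_class = igraph::vertex_attr(g, "rna_class"),
        direction = igraph::vertex_attr(g, "direction"),
        stringsAsFactors = FALSE
    )
    nodes$direction[is.na(nodes$direction) | nodes$direction == ""] <-
        NA_character_
    el <- igraph::as_edgelist(g, names = TRUE)
    edges <- data.frame(
        mirna_id = el[, 1L],
        target_id = el[, 2L],
        target_class = if (igraph::ecount(g))
            igraph::edge_attr(g, "target_class") else character(),
        clip_support = if (igraph::ecount(g))
            as.integer(igraph::edge_attr(g, "clip_support")) else integer(),
        stringsAsFactors = FALSE
    )
    new("CeNET",
        stage = as.character(igraph::graph_attr(g, "stage")),
        polarity = as.character(igraph::graph_attr(g, "polarity")),
        nodes = .sortNodes(nodes), edges = .sortEdges(edges),
        missingSeeds = character(), droppedSeeds = character(),
        filtered = as.logical(igraph::graph_attr(g, "filtered")))
}
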