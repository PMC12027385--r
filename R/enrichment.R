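## Local over-representation analysis mirroring the settings used for the
## network gene sets: hypergeometric upper-tail p, Benjamini-Hochberg FDR
## within each annotation category, a log10(observed/expected) "strength"
## effect-size filter, a minimum-hit filter, and single-linkage grouping
## of significant terms by Jaccard similarity of their hit sets.

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated genes when `n` genes are sampled without
#' replacement from a universe of `N` genes of which `K` carry the
#' annotation. Delegates to `stats::phyper(lower.tail = FALSE)`, which
#' evaluates the tail directly (no 1-minus cancellation).
#'
#' @param k observed hits, `0 <= k <= min(K, n)`.
#' @param K annotated genes in the universe, `K <= N`.
#' @param n query size, `n <= N`.
#' @param N universe size.
#' @return the tail probability in (0, 1].
#' @export
#' @examples
#' hypergeomUpperTail(4, 5, 5, 20)  # 76/15504
hypergeomUpperTail <- function(k, K, n, N) {
    if (any(k < 0) || any(K < 0) || any(n < 0) || any(N < 0) ||
        any(K > N) || any(n > N) || any(k > pmin(K, n)))
        stop("domain error: need 0 <= k <= min(K, n), K <= N, n <= N",
             call. = FALSE)
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (via `stats::p.adjust`), order-aligned
#' with the input and capped at 1. Input outside (0, 1] is a domain
#' error rather than silently clamped.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
    if (length(pvalues) == 0L) return(numeric())
    if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
        stop("domain error: p-values must lie in (0, 1]", call. = FALSE)
    stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a gene set
#'
#' Tests every annotation term with at least one query hit against the
#' background universe with the hypergeometric upper tail, adjusts
#' p-values per annotation category with Benjamini-Hochberg, computes the
#' strength effect size `log10((k/n)/(K/N))`, and returns the terms
#' passing `fdr_bh <= fdrMax`, `strength >= strengthMin` and
#' `k >= minHits` — the same three gates used when analysing the network
#' gene sets. Query genes absent from the background are dropped with a
#' warning, as are annotation genes outside the background.
#'
#' @param query character vector of gene identifiers.
#' @param annotations annotation data.frame ([readGMT()]); multiple GMT
#'   reads can be `rbind`-ed, categories are adjusted independently.
#' @param background character vector: the gene universe.
#' @param fdrMax BH-FDR cutoff (default 0.05).
#' @param strengthMin minimum strength (default 0.01).
#' @param minHits minimum query genes in a term (default 2).
#' @param keepAll if `TRUE`, return every tested term (hits >= 1) without
#'   applying the three gates; useful for calibration and reporting.
#' @return data.frame sorted by (category, fdr_bh, -strength) with
#'   columns `term_id`, `term_name`, `category`, `k`, `K`, `n`, `N`,
#'   `p_hyper`, `fdr_bh`, `strength`, a list-column `members` (the query
#'   hits), and `group_id` (`NA` until [groupTerms()]).
#' @export
enrich <- function(query, annotations, background, fdrMax = 0.05,
                   strengthMin = 0.01, minHits = 2, keepAll = FALSE) {
    background <- unique(as.character(background))
    if (length(background) == 0L)
        stop("empty background universe", call. = FALSE)
    query <- unique(as.character(query))
    outside <- setdiff(query, background)
    if (length(outside)) {
        warning("dropping ", length(outside),
                " query gene(s) not in the background universe")
        query <- intersect(query, background)
    }
    N <- length(background)
    n <- length(query)
    termGenes <- lapply(annotations$genes, function(g) {
        g <- unique(g)
        inBg <- g %in% background
        g[inBg]
    })
    nDropped <- sum(lengths(annotations$genes) - lengths(termGenes))
    if (nDropped > 0)
        warning("dropped ", nDropped,
                " annotation gene(s) outside the background universe")
    hits <- lapply(termGenes, function(g)
        sort(intersect(g, query), method = "radix"))
    k <- lengths(hits)
    K <- lengths(termGenes)
    tested <- which(k >= 1L & K >= 1L)
    out <- data.frame(
        term_id = annotations$term_id[tested],
        term_name = annotations$term_name[tested],
        category = annotations$category[tested],
        k = k[tested], K = K[tested],
        n = rep(n, length(tested)), N = rep(N, length(tested)),
        stringsAsFactors = FALSE
    )
    out$p_hyper <- if (nrow(out))
        hypergeomUpperTail(out$k, out$K, out$n, out$N) else numeric()
    out$fdr_bh <- rep(NA_real_, nrow(out))
    for (cat in unique(out$category)) {
        i <- out$category == cat
        out$fdr_bh[i] <- bhAdjust(out$p_hyper[i])
    }
    out$strength <- log10((out$k / out$n) / (out$K / out$N))
    out$members <- hits[tested]
    out$group_id <- rep(NA_integer_, nrow(out))
    if (!keepAll)
        out <- out[out$fdr_bh <= fdrMax & out$strength >= strengthMin &
                   out$k >= minHits, , drop = FALSE]
    o <- order(out$category, out$fdr_bh, -out$strength, out$term_id,
               method = "radix")
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    out
}

.jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
}

#' Group enriched terms by hit-set similarity
#'
#' Single-linkage clustering of enrichment results on the Jaccard
#' similarity of their query-hit sets: two terms are linked when their
#' Jaccard similarity is at least `similarityMin`, and a group is a
#' connected component of that link graph. Each group's representative is
#' its lowest-FDR term (ties broken by raw p, then term id); group ids
#' are assigned 1, 2, ... in representative order, so the numbering is
#' deterministic.
#'
#' @param results data.frame from [enrich()].
#' @param similarityMin Jaccard threshold in \[0, 1\] (default 0.2).
#' @return `results` with `group_id` filled in.
#' @export
groupTerms <- function(results, similarityMin = 0.2) {
    m <- nrow(results)
    if (m == 0L) return(results)
    sim <- matrix(0, m, m)
    for (i in seq_len(m)) {
        for (j in seq_len(m)) {
            if (j > i) sim[i, j] <- sim[j, i] <-
                .jaccard(results$members[[i]], results$members[[j]])
        }
    }
    g <- igraph::graph_from_adjacency_matrix(sim >= similarityMin,
                                             mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    # representative = best (fdr, p, term_id) inside each component;
    # groups are numbered in representative order
    rank <- order(results$fdr_bh, results$p_hyper, results$term_id,
                  method = "radix")
    groupOf <- integer(max(comp))
    nextId <- 0L
    for (r in rank) {
        if (groupOf[comp[r]] == 0L) {
            nextId <- nextId + 1L
            groupOf[comp[r]] <- nextId
        }
    }
    results$group_id <- groupOf[comp]
    results
}

#' Write enrichment results as TSV
#'
#' @param results data.frame from [enrich()]/[groupTerms()]; the
#'   `members` list-column is pipe-joined.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTable <- function(results, path) {
    out <- results
    out$members <- vapply(out$members, paste, character(1), collapse = "|")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
    invisible(path)
}
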