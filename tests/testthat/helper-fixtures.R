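# Shared fixture builders and independent oracles. Oracles are written
# from first principles (enumeration, direct formulas, linear scans) and
# never call the code paths they check.

deFrame <- function(ids, direction, compartment = "tissue", stage = "6m",
                    rna_class = "miRNA", mean_ctrl = NULL,
                    mean_case = NULL) {
    n <- length(ids)
    data.frame(
        feature_id = ids,
        rna_class = rep(rna_class, length.out = n),
        compartment = rep(compartment, n),
        stage = rep(stage, n),
        mean_ctrl = if (is.null(mean_ctrl)) rep(NA_real_, n) else mean_ctrl,
        mean_case = if (is.null(mean_case)) rep(NA_real_, n) else mean_case,
        log2fc = rep(NA_real_, n),
        padj = rep(NA_real_, n),
        direction = rep(direction, length.out = n),
        stringsAsFactors = FALSE
    )
}

writeTSV <- function(df, path = tempfile(fileext = ".tsv")) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    path
}

# exact hypergeometric upper tail by term-wise enumeration of
# C(K,j) C(N-K,n-j) / C(N,n), summed in log space for stability
enumUpperTail <- function(k, K, n, N) {
    j <- k:min(K, n)
    if (length(j) == 0L) return(0)
    lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
    sum(exp(lt))
}

# direct Benjamini-Hochberg step-up: sort, scale by m/rank, cumulative
# minimum from the largest p downwards, cap at 1, restore input order
bhStepUp <- function(p) {
    m <- length(p)
    o <- order(p)
    scaled <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(scaled)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    out
}

# brute-force polarity filter: for every edge, scan every DE record
bruteFilter <- function(edges, cerna, polarity) {
    wanted <- if (polarity == "UP") "up" else "down"
    keep <- logical(nrow(edges))
    for (i in seq_len(nrow(edges))) {
        for (j in seq_len(nrow(cerna))) {
            if (cerna$feature_id[j] == edges$target_id[i] &&
                cerna$direction[j] == wanted) {
                keep[i] <- TRUE
                break
            }
        }
    }
    edges[keep, , drop = FALSE]
}

jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) return(1)
    length(intersect(a, b)) / u
}

fixtureTables <- function() {
    p <- function(f) system.file("extdata", "table1", f, package = "cenet",
                                 mustWork = TRUE)
    list(
        ev = readDETable(p("ev_mirna_reconstructed.tsv"), "EV", "any"),
        t6 = readDETable(p("cortex_mirna_6m.tsv"), "tissue", "6m"),
        t9 = readDETable(p("cortex_mirna_9m.tsv"), "tissue", "9m")
    )
}
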