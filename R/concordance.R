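#' Infer a differential-expression direction call
#'
#' Classifies features as `up`, `down` or `ns` from effect size and
#' adjusted p-value: `up` when `log2fc > lfcThreshold` and
#' `padj <= padjThreshold`, `down` when `log2fc < -lfcThreshold` and
#' `padj <= padjThreshold`, otherwise `ns`. With `padjThreshold >= 1`
#' the p-value is ignored (pre-filtered input). Missing values never
#' error: a record lacking the needed fields is classified `ns` with a
#' warning.
#'
#' @param log2fc numeric vector of log2 fold changes (case vs control).
#' @param padj numeric vector of adjusted p-values in \[0, 1\], or `NULL`.
#' @param lfcThreshold nonnegative log2-fold-change threshold; 0 means any
#'   nonzero change qualifies.
#' @param padjThreshold adjusted-p significance cutoff.
#' @return character vector of `"up"`, `"down"`, `"ns"`.
#' @export
#' @examples
#' inferDirection(c(1.5, -2, 0), c(0.01, 0.2, 0.001))
inferDirection <- function(log2fc, padj = NULL, lfcThreshold = 0,
                           padjThreshold = 0.05) {
    stopifnot(lfcThreshold >= 0)
    n <- length(log2fc)
    if (is.null(padj)) padj <- rep(NA_real_, n)
    stopifnot(length(padj) == n)
    usePadj <- padjThreshold < 1
    if (any(is.na(log2fc)) || (usePadj && any(is.na(padj))))
        warning("records with missing log2fc/padj classified as 'ns'")
    sig <- if (usePadj) !is.na(padj) & padj <= padjThreshold else TRUE
    out <- rep("ns", n)
    ok <- !is.na(log2fc) & sig
    out[ok & log2fc > lfcThreshold] <- "up"
    out[ok & log2fc < -lfcThreshold] <- "down"
    out
}

## One direction per miRNA per compartment: duplicates that agree collapse,
## duplicates that conflict (both up and down observed) are excluded.
.directionSet <- function(records, direction, label) {
    rec <- records[records$direction %in% c("up", "down"), , drop = FALSE]
    dirs <- split(rec$direction, rec$feature_id)
    confl <- names(dirs)[vapply(dirs, function(d)
        length(unique(d)) > 1L, logical(1))]
    if (length(confl))
        message("excluding ", length(confl), " miRNA(s) with conflicting ",
                "directions in ", label, " compartment: ",
                paste(sort(confl), collapse = ", "))
    keep <- names(dirs)[vapply(dirs, function(d)
        length(unique(d)) == 1L && d[[1L]] == direction, logical(1))]
    setdiff(keep, confl)
}

#' Select direction-concordant miRNAs between EV cargo and tissue
#'
#' The seed-selection step: a miRNA enters the seed set for a given stage
#' and direction when it is called in that same direction in both the
#' extracellular-vesicle cargo and the tissue. The EV table is treated as
#' stage-independent (stressed neurons are assumed to release a stable set
#' of dysregulated miRNAs), so only the tissue records are required to
#' match `stage`. Records called `ns` never enter a seed set.
#'
#' @param evRecords DE data.frame ([readDETable()]) with
#'   `compartment == "EV"`, `rna_class == "miRNA"`.
#' @param tissueRecords DE data.frame with `compartment == "tissue"`,
#'   `rna_class == "miRNA"`, `stage` matching the `stage` argument.
#' @param direction `"up"` or `"down"` — the shared direction required.
#' @param stage stage label of the tissue table.
#' @return A [SeedSet-class]; members sorted lexicographically.
#' @export
selectConcordant <- function(evRecords, tissueRecords,
                             direction = c("up", "down"), stage) {
    direction <- match.arg(direction)
    stopifnot(length(stage) == 1L)
    if (!all(evRecords$rna_class == "miRNA") ||
        !all(tissueRecords$rna_class == "miRNA"))
        stop("seed selection requires rna_class == 'miRNA' records",
             call. = FALSE)
    # each argument must be one homogeneous compartment; the selection
    # itself is symmetric, so the two tables may be passed in either order
    comp1 <- unique(evRecords$compartment)
    comp2 <- unique(tissueRecords$compartment)
    if (length(comp1) > 1L || length(comp2) > 1L ||
        (nrow(evRecords) > 0L && nrow(tissueRecords) > 0L &&
         identical(comp1, comp2)))
        stop("records must come from the two compartments EV and tissue",
             call. = FALSE)
    tstage <- c(tissueRecords$stage[tissueRecords$compartment == "tissue"],
                evRecords$stage[evRecords$compartment == "tissue"])
    if (!all(tstage == stage))
        stop("tissue records stage does not match '", stage, "'",
             call. = FALSE)
    evSet <- .directionSet(evRecords, direction, comp1[1L])
    tiSet <- .directionSet(tissueRecords, direction, comp2[1L])
    SeedSet(stage, direction, intersect(evSet, tiSet))
}

#' Intersect seed sets across stages
#'
#' Returns the miRNAs present in every given seed set, e.g. the miRNAs
#' up-regulated in both compartments at every pathology stage.
#'
#' @param seedSets list of at least two [SeedSet-class] objects.
#' @return sorted character vector of shared miRNA ids.
#' @export
crossStageOverlap <- function(seedSets) {
    if (!is.list(seedSets) || length(seedSets) < 2L)
        stop("need at least two seed sets", call. = FALSE)
    if (!all(vapply(seedSets, is, logical(1), "SeedSet")))
        stop("all elements must be SeedSet objects", call. = FALSE)
    sort(Reduce(intersect, lapply(seedSets, members)), method = "radix")
}
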