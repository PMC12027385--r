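## Tabular input/output: DE tables and interaction tables are
## header-mandatory TSV, annotations are standard GMT. '#'-prefixed lines
## are comments. Parse errors always carry the 1-based line number of the
## offending line in the physical file.

.readTSVLines <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
    list(lines = raw[keep], lineno = which(keep))
}

.parseTSV <- function(path) {
    tsv <- .readTSVLines(path)
    if (length(tsv$lines) == 0L)
        stop("no header row in ", path, call. = FALSE)
    header <- trimws(strsplit(tsv$lines[[1L]], "\t", fixed = TRUE)[[1L]])
    rows <- lapply(tsv$lines[-1L], function(l)
        trimws(strsplit(l, "\t", fixed = TRUE)[[1L]]))
    lineno <- tsv$lineno[-1L]
    cells <- lapply(seq_along(header), function(j)
        vapply(rows, function(r) if (j <= length(r)) r[[j]] else "",
               character(1)))
    names(cells) <- header
    df <- as.data.frame(cells, stringsAsFactors = FALSE, optional = TRUE)
    names(df) <- header
    attr(df, "lineno") <- lineno
    df
}

.requireColumns <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop("format error in ", path, ": missing mandatory column(s) ",
             paste(miss, collapse = ", "), call. = FALSE)
}

.parseNumericColumn <- function(df, col, path, required = FALSE) {
    if (!col %in% names(df)) {
        if (required)
            stop("format error in ", path, ": missing mandatory column ",
                 col, call. = FALSE)
        return(rep(NA_real_, nrow(df)))
    }
    x <- df[[col]]
    x[x == "" | toupper(x) == "NA"] <- NA
    # Table-style thousands separators ("104,812") are accepted
    out <- suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
        ln <- attr(df, "lineno")[bad[1L]]
        stop("format error in ", path, " line ", ln,
             ": unparseable numeric value '", x[bad[1L]],
             "' in column ", col, call. = FALSE)
    }
    out
}

#' Read a differential-expression table
#'
#' Reads a TSV of per-feature differential-expression evidence for one
#' compartment (EV cargo or tissue) and stage. Mandatory columns are
#' `feature_id` and `rna_class`, plus either a `direction` column
#' (`up`/`down`/`ns`) or the pair `log2fc`, `padj` from which the
#' direction is inferred via [inferDirection()]. Optional columns
#' `mean_ctrl` and `mean_case` carry normalized expression (e.g.
#' median-of-ratios scale); when both are present together with a call of
#' `up` or `down` their ordering is validated against the call. When
#' `direction` and `log2fc` are both present a sign disagreement is a
#' validation error. A missing `padj` together with an explicit
#' `direction` is accepted as pre-filtered input.
#'
#' @param path TSV file path (`#` comment lines ignored).
#' @param compartment `"EV"` or `"tissue"`.
#' @param stage stage label attached to every record (e.g. `"6m"`).
#' @param lfcThreshold,padjThreshold thresholds handed to
#'   [inferDirection()] when no `direction` column is present.
#'
#' @return data.frame with columns `feature_id`, `rna_class`,
#'   `compartment`, `stage`, `mean_ctrl`, `mean_case`, `log2fc`, `padj`,
#'   `direction`; input row order preserved.
#' @export
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeLines(c("feature_id\trna_class\tmean_ctrl\tmean_case\tdirection",
#'              "mmu-miR-369-5p\tmiRNA\t2999\t3361\tup"), p)
#' readDETable(p, "EV", "6m")
readDETable <- function(path, compartment = c("EV", "tissue"), stage,
                        lfcThreshold = 0, padjThreshold = 0.05) {
    compartment <- match.arg(compartment)
    stopifnot(length(stage) == 1L, nzchar(stage))
    df <- .parseTSV(path)
    .requireColumns(df, c("feature_id", "rna_class"), path)
    hasDir <- "direction" %in% names(df)
    if (!hasDir && !all(c("log2fc", "padj") %in% names(df)))
        stop("format error in ", path,
             ": need a 'direction' column or both 'log2fc' and 'padj'",
             call. = FALSE)
    lineno <- attr(df, "lineno")
    n <- nrow(df)
    out <- data.frame(
        feature_id = trimws(df$feature_id),
        rna_class = trimws(df$rna_class),
        compartment = rep(compartment, n),
        stage = rep(as.character(stage), n),
        mean_ctrl = .parseNumericColumn(df, "mean_ctrl", path),
        mean_case = .parseNumericColumn(df, "mean_case", path),
        log2fc = .parseNumericColumn(df, "log2fc", path),
        padj = .parseNumericColumn(df, "padj", path),
        stringsAsFactors = FALSE
    )
    if (n == 0L) {
        out$direction <- character()
        return(out)
    }
    bad <- which(!out$rna_class %in% .RNA_CLASSES)
    if (length(bad))
        stop("format error in ", path, " line ", lineno[bad[1L]],
             ": unknown rna_class '", out$rna_class[bad[1L]], "'",
             call. = FALSE)
    if (any(!is.na(out$mean_ctrl) & out$mean_ctrl < 0) ||
        any(!is.na(out$mean_case) & out$mean_case < 0))
        stop("format error in ", path, ": negative mean expression",
             call. = FALSE)
    if (any(!is.na(out$padj) & (out$padj < 0 | out$padj > 1)))
        stop("format error in ", path, ": padj outside [0, 1]",
             call. = FALSE)
    if (hasDir) {
        dir <- tolower(trimws(df$direction))
        bad <- which(!dir %in% .DIRECTIONS)
        if (length(bad))
            stop("format error in ", path, " line ", lineno[bad[1L]],
                 ": unknown direction '", df$direction[bad[1L]], "'",
                 call. = FALSE)
        # explicit call must not contradict the sign of log2fc
        confl <- which((dir == "up" & !is.na(out$log2fc) & out$log2fc <= 0) |
                       (dir == "down" & !is.na(out$log2fc) & out$log2fc >= 0))
        if (length(confl))
            stop("validation error in ", path, " line ", lineno[confl[1L]],
                 ": direction '", dir[confl[1L]],
                 "' disagrees with sign of log2fc", call. = FALSE)
    } else {
        dir <- inferDirection(out$log2fc, out$padj,
                              lfcThreshold = lfcThreshold,
                              padjThreshold = padjThreshold)
    }
    both <- !is.na(out$mean_ctrl) & !is.na(out$mean_case)
    confl <- which(both &
                   ((dir == "up" & out$mean_case <= out$mean_ctrl) |
                    (dir == "down" & out$mean_case >= out$mean_ctrl)))
    if (length(confl))
        stop("validation error in ", path, " line ", lineno[confl[1L]],
             ": direction '", dir[confl[1L]],
             "' disagrees with mean_ctrl/mean_case ordering",
             call. = FALSE)
    out$direction <- dir
    out
}

#' Write a differential-expression table
#'
#' Inverse of [readDETable()]: writes the canonical DE columns as TSV so
#' that reading the file back reproduces the records field by field
#' (`compartment` and `stage` are call-time arguments of the reader and
#' are not stored in the file).
#'
#' @param records data.frame as returned by [readDETable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDETable <- function(records, path) {
    cols <- c("feature_id", "rna_class", "mean_ctrl", "mean_case",
              "log2fc", "padj", "direction")
    keep <- intersect(cols, names(records))
    utils::write.table(records[, keep, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA",
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a CLIP-supported miRNA-target interaction table
#'
#' Reads an ENCORI-style flat table of miRNA-ceRNA interactions. Mandatory
#' columns: `mirna_id`, `target_id`, `target_class` (one of `mRNA`,
#' `lncRNA`, `circRNA`) and `clip_support` (number of supporting CLIP-seq
#' experiments, nonnegative integer). Duplicate (`mirna_id`, `target_id`)
#' pairs are collapsed keeping the maximum `clip_support`; the number of
#' rows read and collapsed is reported via `message()`.
#'
#' @param path TSV file path.
#' @return data.frame with one row per unique (miRNA, target) pair, first
#'   occurrence order preserved.
#' @export
readInteractionTable <- function(path) {
    df <- .parseTSV(path)
    .requireColumns(df, c("mirna_id", "target_id", "target_class",
                          "clip_support"), path)
    lineno <- attr(df, "lineno")
    n <- nrow(df)
    out <- data.frame(
        mirna_id = trimws(df$mirna_id),
        target_id = trimws(df$target_id),
        target_class = trimws(df$target_class),
        clip_support = .parseNumericColumn(df, "clip_support", path),
        stringsAsFactors = FALSE
    )
    if (n == 0L) {
        out$clip_support <- integer()
        message("read 0 interaction rows, collapsed 0 duplicates")
        return(out)
    }
    bad <- which(!out$target_class %in% .CERNA_CLASSES)
    if (length(bad))
        stop("format error in ", path, " line ", lineno[bad[1L]],
             ": unknown target_class '", out$target_class[bad[1L]], "'",
             call. = FALSE)
    if (any(!nzchar(out$mirna_id)) || any(!nzchar(out$target_id)))
        stop("format error in ", path, ": empty mirna_id or target_id",
             call. = FALSE)
    if (any(is.na(out$clip_support) | out$clip_support < 0 |
            out$clip_support != floor(out$clip_support)))
        stop("format error in ", path,
             ": clip_support must be a nonnegative integer", call. = FALSE)
    out$clip_support <- as.integer(out$clip_support)
    key <- paste(out$mirna_id, out$target_id, sep = "\r")
    if (anyDuplicated(key)) {
        maxsup <- tapply(out$clip_support, key, max)
        first <- !duplicated(key)
        collapsed <- out[first, , drop = FALSE]
        collapsed$clip_support <- as.integer(maxsup[key[first]])
        message("read ", n, " interaction rows, collapsed ",
                n - nrow(collapsed), " duplicates")
        rownames(collapsed) <- NULL
        return(collapsed)
    }
    message("read ", n, " interaction rows, collapsed 0 duplicates")
    out
}

#' Write an interaction table
#'
#' @param records data.frame as returned by [readInteractionTable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeInteractionTable <- function(records, path) {
    cols <- c("mirna_id", "target_id", "target_class", "clip_support")
    utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a GMT annotation file
#'
#' Standard GMT dialect: one term per line, tab-separated fields
#' `term_id`, `description`, then one or more gene symbols. Genes are
#' stored with set semantics (duplicates within a line collapse to one).
#'
#' @param path GMT file path.
#' @param category category label attached to every term (defaults to the
#'   file name without extension, e.g. `"GO-CC"` for `GO-CC.gmt`).
#' @return data.frame with columns `term_id`, `term_name`, `category` and
#'   a list-column `genes` of character vectors.
#' @export
readGMT <- function(path, category = NULL) {
    tsv <- .readTSVLines(path)
    if (is.null(category))
        category <- tools::file_path_sans_ext(basename(path))
    fields <- lapply(tsv$lines, strsplit, split = "\t", fixed = TRUE)
    fields <- lapply(fields, `[[`, 1L)
    bad <- which(vapply(fields, length, integer(1)) < 3L)
    if (length(bad))
        stop("format error in ", path, " line ", tsv$lineno[bad[1L]],
             ": GMT line needs at least 3 tab-separated fields",
             call. = FALSE)
    genes <- lapply(fields, function(f) unique(trimws(f[-c(1L, 2L)])))
    genes <- lapply(genes, function(g) g[nzchar(g)])
    empty <- which(lengths(genes) == 0L)
    if (length(empty))
        stop("format error in ", path, " line ", tsv$lineno[empty[1L]],
             ": term has an empty gene list", call. = FALSE)
    out <- data.frame(
        term_id = vapply(fields, function(f) trimws(f[[1L]]), character(1)),
        term_name = vapply(fields, function(f) trimws(f[[2L]]), character(1)),
        category = rep(category, length(fields)),
        stringsAsFactors = FALSE
    )
    out$genes <- genes
    out
}

#' Write annotations to a GMT file
#'
#' @param annotations data.frame as returned by [readGMT()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(annotations, path) {
    lines <- vapply(seq_len(nrow(annotations)), function(i) {
        paste(c(annotations$term_id[i], annotations$term_name[i],
                annotations$genes[[i]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}
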