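## End-to-end orchestration: seed selection -> whole-genome network ->
## polarity filter -> export + enrichment, per stage and polarity, from a
## validated run configuration. The pipeline is a pure function of the
## configuration and input files; identical inputs yield byte-identical
## artifacts.

.defaultThresholds <- function() {
    list(lfc = 0, padj = 0.05, fdr_max = 0.05, strength_min = 0.01,
         min_hits = 2, similarity_min = 0.2, clip_support_min = 0)
}

.configError <- function(...) {
    stop(errorCondition(paste0(...), class = c("cenetConfigError", "error")))
}

.validateRunConfig <- function(cfg, base = ".") {
    resolve <- function(p) {
        if (is.null(p)) return(p)
        ifelse(file.exists(p), p, file.path(base, p))
    }
    if (is.null(cfg$stages) || length(cfg$stages) == 0L)
        .configError("config: 'stages' must be a nonempty list")
    cfg$stages <- as.character(cfg$stages)
    ins <- cfg$inputs
    if (is.null(ins))
        .configError("config: missing 'inputs' section")
    ins$ev_mirna <- resolve(ins$ev_mirna)
    ins$interactions <- resolve(ins$interactions)
    ins$annotations <- lapply(ins$annotations, resolve)
    for (s in cfg$stages) {
        if (is.null(ins$tissue_mirna[[s]]))
            .configError("config: missing tissue_mirna table for stage ", s)
        ins$tissue_mirna[[s]] <- resolve(ins$tissue_mirna[[s]])
        if (is.null(ins$tissue_cerna[[s]]))
            .configError("config: missing tissue_cerna table(s) for stage ",
                         s)
        ins$tissue_cerna[[s]] <- lapply(ins$tissue_cerna[[s]], resolve)
    }
    paths <- c(ins$ev_mirna, ins$interactions, unlist(ins$annotations),
               unlist(ins$tissue_mirna[cfg$stages]),
               unlist(ins$tissue_cerna[cfg$stages]))
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing))
        .configError("config: input file(s) not found: ",
                     paste(missing, collapse = ", "))
    cfg$inputs <- ins
    cfg$thresholds <- utils::modifyList(.defaultThresholds(),
                                        as.list(cfg$thresholds))
    if (is.null(cfg$output_dir))
        .configError("config: missing 'output_dir'")
    cfg
}

#' Read and validate a pipeline run configuration
#'
#' YAML with a versioned schema: `schema_version`, `stages`, an `inputs`
#' section (`ev_mirna`, per-stage `tissue_mirna` and `tissue_cerna`
#' lists, `interactions`, `annotations`), an optional `thresholds`
#' section (`lfc`, `padj`, `fdr_max`, `strength_min`, `min_hits`,
#' `similarity_min`, `clip_support_min`) and `output_dir`. Relative paths
#' are resolved against the config file's directory. Referenced files
#' must exist at validation time.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        .configError("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    .validateRunConfig(cfg, base = dirname(path))
}

.writeSeedArtifacts <- function(seeds, prefix, counts) {
    df <- data.frame(mirna_id = members(seeds),
                     direction = rep(mirnaDirection(seeds),
                                     length(members(seeds))),
                     stringsAsFactors = FALSE)
    utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    side <- c(list(stage = stage(seeds),
                   mirna_direction = mirnaDirection(seeds),
                   cenet_polarity = cenetPolarity(seeds),
                   n_members = length(members(seeds))), counts)
    jsonlite::write_json(side, paste0(prefix, ".json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.writeTrace <- function(filtered, evMirna, tissueMirna, cerna, path) {
    edges <- netEdges(filtered)
    lookupDir <- function(rec, ids, cls = NULL) {
        key <- if (is.null(cls)) rec$feature_id
               else paste(rec$feature_id, rec$rna_class, sep = "\r")
        want <- if (is.null(cls)) ids else paste(ids, cls, sep = "\r")
        rec$direction[match(want, key)]
    }
    out <- data.frame(
        mirna_id = edges$mirna_id,
        target_id = edges$target_id,
        target_class = edges$target_class,
        clip_support = edges$clip_support,
        mirna_ev_direction = lookupDir(evMirna, edges$mirna_id),
        mirna_tissue_direction = lookupDir(tissueMirna, edges$mirna_id),
        target_direction = lookupDir(cerna, edges$target_id,
                                     edges$target_class),
        stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
}

#' Run the full ceNET pipeline
#'
#' For every stage and both miRNA directions: selects the
#' direction-concordant seed set, expands it over the interaction table,
#' applies the ceRNA polarity filter, exports the unfiltered and filtered
#' networks (SIF, GraphML, TSV), writes a per-edge trace linking each
#' retained interaction to its supporting DE calls, runs
#' over-representation analysis of the filtered network's gene set, and
#' aggregates everything into `report.json`.
#'
#' @param config a YAML path or a config list (see [readRunConfig()]).
#' @return invisibly, a list with the per-(stage, polarity) `seedSets`,
#'   `networks` (unfiltered and filtered [CeNET-class]), `enrichment`
#'   tables, and the `outputDir`.
#' @export
runPipeline <- function(config) {
    cfg <- if (is.character(config)) readRunConfig(config)
           else .validateRunConfig(config)
    th <- cfg$thresholds
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    evMirna <- readDETable(cfg$inputs$ev_mirna, "EV", "any",
                           th$lfc, th$padj)
    interactions <- readInteractionTable(cfg$inputs$interactions)
    annotations <- do.call(rbind, lapply(cfg$inputs$annotations, readGMT))
    background <- sort(unique(unlist(annotations$genes)), method = "radix")
    results <- list()
    report <- list(schema_version = cfg$schema_version, runs = list())
    for (s in cfg$stages) {
        tissueMirna <- readDETable(cfg$inputs$tissue_mirna[[s]], "tissue",
                                   s, th$lfc, th$padj)
        cerna <- do.call(rbind, lapply(cfg$inputs$tissue_cerna[[s]],
                                       readDETable, compartment = "tissue",
                                       stage = s, lfcThreshold = th$lfc,
                                       padjThreshold = th$padj))
        for (dir in c("up", "down")) {
            seeds <- suppressWarnings(
                selectConcordant(evMirna, tissueMirna, dir, s))
            pol <- cenetPolarity(seeds)
            tag <- paste0(s, "_", pol)
            prefix <- file.path(cfg$output_dir, tag)
            .writeSeedArtifacts(seeds, paste0(prefix, "_seeds"),
                list(n_ev_records = nrow(evMirna),
                     n_tissue_records = nrow(tissueMirna)))
            net <- suppressWarnings(
                buildWholeGenomeNet(seeds, interactions,
                                    clipSupportMin = th$clip_support_min))
            filtered <- applyCernaFilter(net, cerna)
            for (obj in list(list(net, "unfiltered"),
                             list(filtered, "filtered"))) {
                base <- paste0(prefix, "_net_", obj[[2L]])
                exportNetwork(obj[[1L]], paste0(base, ".sif"), "SIF")
                exportNetwork(obj[[1L]], paste0(base, ".graphml"),
                              "GraphML")
                exportNetwork(obj[[1L]], paste0(base, "_edges.tsv"), "TSV")
            }
            .writeTrace(filtered, evMirna, tissueMirna, cerna,
                        paste0(prefix, "_trace.tsv"))
            query <- netNodes(filtered)$id[
                netNodes(filtered)$rna_class != "miRNA"]
            enr <- suppressWarnings(
                enrich(query, annotations, background,
                       fdrMax = th$fdr_max, strengthMin = th$strength_min,
                       minHits = th$min_hits))
            enr <- groupTerms(enr, similarityMin = th$similarity_min)
            writeEnrichmentTable(enr, paste0(prefix, "_enrichment.tsv"))
            classCounts <- table(factor(
                netNodes(filtered)$rna_class,
                levels = c("miRNA", .CERNA_CLASSES)))
            report$runs[[tag]] <- list(
                stage = s, polarity = pol, mirna_direction = dir,
                n_seeds = length(members(seeds)),
                seeds = members(seeds),
                missing_seeds = missingSeeds(net),
                dropped_seeds = droppedSeeds(filtered),
                n_edges_unfiltered = nrow(netEdges(net)),
                n_edges_filtered = nrow(netEdges(filtered)),
                nodes_per_class = as.list(classCounts),
                n_enriched_terms = nrow(enr)
            )
            results[[tag]] <- list(seeds = seeds, unfiltered = net,
                                   filtered = filtered, enrichment = enr)
        }
    }
    jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(c(results, list(outputDir = cfg$output_dir)))
}

#' Write a simulated, ready-to-run input directory
#'
#' Generates the synthetic DE tables, interaction table and annotations
#' for `cfg`, writes them in the pipeline's TSV/GMT dialects together
#' with the planted truth (`truth.json`) and a runnable `config.yaml`.
#'
#' @param cfg a [simConfig()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the validated run config for the written directory.
#' @export
simulateInputs <- function(cfg, outdir) {
    stopifnot(inherits(cfg, "SimConfig"))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    sim <- genDETables(cfg)
    interactions <- genInteractionTable(cfg, sim$truth)
    ann <- genAnnotation(cfg, sim$truth)
    writeDETable(sim$evMirna, file.path(outdir, "ev_mirna.tsv"))
    writeDETable(sim$tissueMirna, file.path(outdir, "tissue_mirna.tsv"))
    writeDETable(sim$tissueCerna, file.path(outdir, "tissue_cerna.tsv"))
    writeInteractionTable(interactions,
                          file.path(outdir, "interactions.tsv"))
    writeGMT(ann$annotations, file.path(outdir, "annotations.gmt"))
    jsonlite::write_json(
        list(concordant_up = sim$truth$concordantUp,
             concordant_down = sim$truth$concordantDown,
             planted_edges = sim$truth$plantedEdges,
             flipped = sim$truth$flipped),
        file.path(outdir, "truth.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    runCfg <- list(
        schema_version = 1,
        stages = list(.simStage),
        inputs = list(
            ev_mirna = "ev_mirna.tsv",
            tissue_mirna = stats::setNames(list("tissue_mirna.tsv"),
                                           .simStage),
            tissue_cerna = stats::setNames(list(list("tissue_cerna.tsv")),
                                           .simStage),
            interactions = "interactions.tsv",
            annotations = list("annotations.gmt")
        ),
        thresholds = .defaultThresholds(),
        output_dir = file.path(outdir, "out")
    )
    yaml::write_yaml(runCfg, file.path(outdir, "config.yaml"))
    invisible(readRunConfig(file.path(outdir, "config.yaml")))
}

#' Run configuration for the packaged worked-example fixture
#'
#' Points at the tables shipped under `inst/extdata/table1`: the
#' published per-stage cortex miRNA direction calls, the reconstructed
#' EV-side calls, and synthetic ceRNA/interaction/annotation stand-ins
#' (see the files' comment headers).
#'
#' @param outputDir where pipeline artifacts should be written.
#' @return validated config list for [runPipeline()].
#' @export
#' @examples
#' cfg <- table1FixtureConfig(file.path(tempdir(), "table1-run"))
#' res <- runPipeline(cfg)
#' members(res[["6m_DOWN"]]$seeds)
table1FixtureConfig <- function(outputDir = file.path(tempdir(),
                                                      "cenet-table1")) {
    p <- function(f) system.file("extdata", "table1", f, package = "cenet",
                                 mustWork = TRUE)
    cfg <- list(
        schema_version = 1,
        stages = c("6m", "9m"),
        inputs = list(
            ev_mirna = p("ev_mirna_reconstructed.tsv"),
            tissue_mirna = list("6m" = p("cortex_mirna_6m.tsv"),
                                "9m" = p("cortex_mirna_9m.tsv")),
            tissue_cerna = list(
                "6m" = list(p("cortex_cerna_6m_synthetic.tsv")),
                "9m" = list(p("cortex_cerna_9m_synthetic.tsv"))),
            interactions = p("interactions_synthetic.tsv"),
            annotations = list(p("annotations_synthetic.gmt"))
        ),
        thresholds = .defaultThresholds(),
        output_dir = outputDir
    )
    .validateRunConfig(cfg)
}
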