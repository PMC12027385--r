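## Synthetic-data generator with planted structure: two-compartment miRNA
## DE tables with a controllable concordant fraction, an interaction table
## with planted polarity-consistent miRNA->ceRNA edges across the three
## ceRNA classes, and annotations with one planted enriched term. Three
## derived RNG streams (rngSeed, rngSeed + 1, rngSeed + 2) keep each
## generator reproducible standalone, with every draw made in a fixed,
## documented order.

#' Simulation configuration
#'
#' Validated parameter set for the synthetic-data generators. Defaults
#' describe a desk-scale study: 60 candidate miRNAs of which 10% are
#' concordantly up- and 10% concordantly down-regulated across EV cargo
#' and tissue (the in-paper tables list 23 concordant miRNAs out of a
#' larger candidate pool), 120 ceRNAs per class, a sparse CLIP
#' interaction background, 3 planted polarity-consistent edges per seed,
#' and one planted annotation term covering 80% of the planted network's
#' gene set.
#'
#' @param nMirna number of candidate miRNAs.
#' @param nCernaPerClass ceRNAs per class (mRNA, lncRNA, circRNA).
#' @param fracConcordantUp,fracConcordantDown fractions of miRNAs planted
#'   as direction-concordant (sum must be <= 1).
#' @param edgeDensity probability of a background interaction per
#'   (miRNA, ceRNA) pair, in (0, 1].
#' @param plantedEdgesPerSeed polarity-consistent edges planted per seed.
#' @param nTerms number of annotation terms (one of them planted).
#' @param plantedTermSize gene count of the planted term.
#' @param plantedTermCoverage fraction of the planted network gene set
#'   covered by the planted term, in \[0, 1\].
#' @param noiseFlipProb probability that a tissue direction label is
#'   flipped (up <-> down) relative to the EV label, in \[0, 0.5).
#' @param rngSeed integer seed for the generator streams.
#' @return a validated `list` of class `SimConfig`.
#' @export
simConfig <- function(nMirna = 60, nCernaPerClass = 120,
                      fracConcordantUp = 0.1, fracConcordantDown = 0.1,
                      edgeDensity = 0.02, plantedEdgesPerSeed = 3,
                      nTerms = 20, plantedTermSize = 25,
                      plantedTermCoverage = 0.8, noiseFlipProb = 0,
                      rngSeed = 1) {
    stopifnot(
        nMirna >= 1, nCernaPerClass >= 2,
        fracConcordantUp >= 0, fracConcordantDown >= 0,
        fracConcordantUp + fracConcordantDown <= 1,
        edgeDensity > 0, edgeDensity <= 1,
        plantedEdgesPerSeed >= 1,
        nTerms >= 1, plantedTermSize >= 1,
        plantedTermCoverage >= 0, plantedTermCoverage <= 1,
        noiseFlipProb >= 0, noiseFlipProb < 0.5
    )
    cfg <- list(nMirna = as.integer(nMirna),
                nCernaPerClass = as.integer(nCernaPerClass),
                fracConcordantUp = fracConcordantUp,
                fracConcordantDown = fracConcordantDown,
                edgeDensity = edgeDensity,
                plantedEdgesPerSeed = as.integer(plantedEdgesPerSeed),
                nTerms = as.integer(nTerms),
                plantedTermSize = as.integer(plantedTermSize),
                plantedTermCoverage = plantedTermCoverage,
                noiseFlipProb = noiseFlipProb,
                rngSeed = as.integer(rngSeed))
    class(cfg) <- "SimConfig"
    cfg
}

.simStage <- "sim"

.cernaIds <- function(cfg) {
    list(mRNA = sprintf("sim-gene-%04d", seq_len(cfg$nCernaPerClass)),
         lncRNA = sprintf("sim-lnc-%04d", seq_len(cfg$nCernaPerClass)),
         circRNA = sprintf("sim-circ-%04d", seq_len(cfg$nCernaPerClass)))
}

## expression means consistent with a direction call: log-normal baseline,
## fold change drawn away from 1 for up/down so mean ordering always holds
.simMeans <- function(direction, baselineLog) {
    n <- length(direction)
    base <- stats::rlnorm(n, meanlog = baselineLog, sdlog = 1)
    fc <- stats::runif(n, 1.5, 3)
    case <- ifelse(direction == "up", base * fc,
                   ifelse(direction == "down", base / fc,
                          base * stats::runif(n, 0.95, 1.05)))
    padj <- ifelse(direction == "ns", stats::runif(n, 0.2, 0.9),
                   stats::runif(n, 1e-4, 0.04))
    data.frame(mean_ctrl = base, mean_case = case,
               log2fc = log2(case / base), padj = padj,
               stringsAsFactors = FALSE)
}

.deFrame <- function(ids, rnaClass, compartment, direction, baselineLog) {
    m <- .simMeans(direction, baselineLog)
    data.frame(feature_id = ids, rna_class = rnaClass,
               compartment = compartment, stage = .simStage,
               mean_ctrl = m$mean_ctrl, mean_case = m$mean_case,
               log2fc = m$log2fc, padj = m$padj, direction = direction,
               stringsAsFactors = FALSE)
}

#' Generate synthetic two-compartment DE tables
#'
#' Plants `fracConcordantUp`/`fracConcordantDown` of the miRNAs as
#' direction-concordant between EV and tissue; the remaining miRNAs get
#' deliberately non-concordant label pairs (discordant or involving `ns`)
#' so that, at `noiseFlipProb = 0`, seed recovery is exact. Tissue ceRNA
#' directions are drawn so that the edges planted later by
#' [genInteractionTable()] are polarity-consistent. Tissue miRNA labels
#' are then flipped (up <-> down) with probability `noiseFlipProb`.
#'
#' @param cfg a [simConfig()].
#' @return list with elements `evMirna`, `tissueMirna`, `tissueCerna`
#'   (DE data.frames) and `truth`: the planted concordant sets
#'   (`concordantUp`, `concordantDown`), planted polarity-consistent
#'   edges (`plantedEdges`), all ceRNA direction labels
#'   (`cernaDirections`) and the tissue miRNAs whose label was flipped
#'   by noise (`flipped`).
#' @export
genDETables <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$rngSeed)
    ids <- sprintf("sim-miR-%04d", seq_len(cfg$nMirna))
    nUp <- round(cfg$fracConcordantUp * cfg$nMirna)
    nDown <- round(cfg$fracConcordantDown * cfg$nMirna)
    concordantUp <- ids[seq_len(nUp)]
    concordantDown <- ids[nUp + seq_len(nDown)]
    decoys <- ids[-(seq_len(nUp + nDown))]
    # non-concordant (EV, tissue) label pairs for the decoys
    combos <- rbind(c("up", "down"), c("down", "up"), c("up", "ns"),
                    c("down", "ns"), c("ns", "up"), c("ns", "down"),
                    c("ns", "ns"))
    pick <- sample.int(nrow(combos), length(decoys), replace = TRUE)
    evDir <- c(rep("up", nUp), rep("down", nDown), combos[pick, 1L])
    tiDir <- c(rep("up", nUp), rep("down", nDown), combos[pick, 2L])
    flip <- stats::runif(cfg$nMirna) < cfg$noiseFlipProb & tiDir != "ns"
    tiDirNoisy <- tiDir
    tiDirNoisy[flip & tiDir == "up"] <- "down"
    tiDirNoisy[flip & tiDir == "down"] <- "up"
    evMirna <- .deFrame(ids, "miRNA", "EV", evDir, log(500))
    tissueMirna <- .deFrame(ids, "miRNA", "tissue", tiDirNoisy, log(500))

    # plant polarity-consistent targets: up-seeds feed the DOWN ceNET so
    # their planted targets are down-regulated (drawn from the first half
    # of each class pool), and dually for down-seeds (second half)
    pools <- .cernaIds(cfg)
    half <- floor(cfg$nCernaPerClass / 2)
    classes <- .CERNA_CLASSES
    plantOne <- function(seedId, polarity) {
        cls <- classes[(seq_len(cfg$plantedEdgesPerSeed) - 1L) %% 3L + 1L]
        idx <- vapply(cls, function(cl) {
            rng <- if (polarity == "DOWN") seq_len(half)
                   else half + seq_len(cfg$nCernaPerClass - half)
            as.integer(sample(rng, 1L))
        }, integer(1))
        data.frame(mirna_id = seedId,
                   target_id = unname(mapply(function(cl, i) pools[[cl]][i],
                                             cls, idx)),
                   target_class = cls, polarity = polarity,
                   stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, c(
        lapply(concordantUp, plantOne, polarity = "DOWN"),
        lapply(concordantDown, plantOne, polarity = "UP")
    ))
    if (is.null(planted)) {
        planted <- data.frame(mirna_id = character(),
                              target_id = character(),
                              target_class = character(),
                              polarity = character(),
                              stringsAsFactors = FALSE)
    } else {
        planted <- unique(planted)
        rownames(planted) <- NULL
    }
    cernaDir <- data.frame(
        feature_id = unlist(pools, use.names = FALSE),
        rna_class = rep(classes, each = cfg$nCernaPerClass),
        stringsAsFactors = FALSE
    )
    cernaDir$direction <- sample(c("up", "down", "ns"), nrow(cernaDir),
                                 replace = TRUE, prob = c(0.3, 0.3, 0.4))
    plantedKey <- paste(planted$target_id, planted$target_class)
    dirKey <- paste(cernaDir$feature_id, cernaDir$rna_class)
    isPlanted <- dirKey %in% plantedKey
    plantedDir <- ifelse(
        dirKey %in% plantedKey[planted$polarity == "DOWN"], "down", "up")
    cernaDir$direction[isPlanted] <- plantedDir[isPlanted]
    tissueCerna <- .deFrame(cernaDir$feature_id, cernaDir$rna_class,
                            "tissue", cernaDir$direction, log(200))
    truth <- list(
        concordantUp = sort(concordantUp, method = "radix"),
        concordantDown = sort(concordantDown, method = "radix"),
        plantedEdges = planted,
        cernaDirections = cernaDir,
        flipped = ids[flip]
    )
    list(evMirna = evMirna, tissueMirna = tissueMirna,
         tissueCerna = tissueCerna, truth = truth)
}

#' Generate a synthetic interaction table
#'
#' Emits the planted polarity-consistent edges plus background edges
#' sampled per (miRNA, ceRNA) pair at `edgeDensity`. Background pairs
#' that would survive the polarity filter by accident (a seed miRNA
#' paired with a ceRNA whose planted tissue direction equals the seed's
#' network polarity) are excluded from sampling, so the filtered networks
#' of a noiseless run contain exactly the planted edges. `clip_support`
#' is drawn uniformly from 1..10.
#'
#' @param cfg a [simConfig()].
#' @param truth the `truth` element of [genDETables()] run on the same
#'   config.
#' @return interaction data.frame (`mirna_id`, `target_id`,
#'   `target_class`, `clip_support`), deduplicated and sorted.
#' @export
genInteractionTable <- function(cfg, truth) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$rngSeed + 1L)
    mirnas <- sprintf("sim-miR-%04d", seq_len(cfg$nMirna))
    cerna <- truth$cernaDirections
    pairs <- expand.grid(mi = seq_len(cfg$nMirna),
                         tg = seq_len(nrow(cerna)))
    key <- function(m, t, cl) paste(m, t, cl, sep = "\r")
    plantedKey <- key(truth$plantedEdges$mirna_id,
                      truth$plantedEdges$target_id,
                      truth$plantedEdges$target_class)
    allKey <- key(mirnas[pairs$mi], cerna$feature_id[pairs$tg],
                  cerna$rna_class[pairs$tg])
    seedPol <- c(stats::setNames(rep("DOWN", length(truth$concordantUp)),
                                 truth$concordantUp),
                 stats::setNames(rep("UP", length(truth$concordantDown)),
                                 truth$concordantDown))
    pol <- seedPol[mirnas[pairs$mi]]
    # would this pair pass the polarity filter if it existed?
    consistent <- !is.na(pol) &
        ((pol == "DOWN" & cerna$direction[pairs$tg] == "down") |
         (pol == "UP" & cerna$direction[pairs$tg] == "up"))
    eligible <- !(allKey %in% plantedKey) & !consistent
    drawn <- eligible & stats::runif(nrow(pairs)) < cfg$edgeDensity
    bg <- data.frame(
        mirna_id = mirnas[pairs$mi][drawn],
        target_id = cerna$feature_id[pairs$tg][drawn],
        target_class = cerna$rna_class[pairs$tg][drawn],
        stringsAsFactors = FALSE
    )
    out <- rbind(truth$plantedEdges[, c("mirna_id", "target_id",
                                        "target_class")], bg)
    out$clip_support <- sample.int(10L, nrow(out), replace = TRUE)
    out <- out[!duplicated(paste(out$mirna_id, out$target_id, sep = "\r")),
               , drop = FALSE]
    out <- out[order(out$mirna_id, out$target_id, method = "radix"),
               , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Generate synthetic annotations with one planted term
#'
#' The background universe is the full ceRNA id space. One planted term
#' covers `plantedTermCoverage` of the planted network's gene set (padded
#' with random background genes up to `plantedTermSize`); the remaining
#' `nTerms - 1` terms are random draws from the background.
#'
#' @param cfg a [simConfig()].
#' @param truth the `truth` element of [genDETables()].
#' @return list with `annotations` (data.frame as from [readGMT()],
#'   planted term first with id `"sim-term-planted"`) and `background`
#'   (character vector).
#' @export
genAnnotation <- function(cfg, truth) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$rngSeed + 2L)
    background <- truth$cernaDirections$feature_id
    netGenes <- sort(unique(truth$plantedEdges$target_id), method = "radix")
    nCov <- min(round(cfg$plantedTermCoverage * length(netGenes)),
                cfg$plantedTermSize)
    covered <- if (nCov > 0) sample(netGenes, nCov) else character()
    pad <- cfg$plantedTermSize - length(covered)
    filler <- setdiff(background, netGenes)
    plantedGenes <- c(covered,
                      if (pad > 0) sample(filler, min(pad, length(filler)))
                      else character())
    randTerm <- function(i) {
        size <- sample(10:40, 1L)
        sample(background, min(size, length(background)))
    }
    others <- lapply(seq_len(cfg$nTerms - 1L), randTerm)
    ann <- data.frame(
        term_id = c("sim-term-planted",
                    sprintf("sim-term-%03d", seq_len(cfg$nTerms - 1L))),
        term_name = c("planted enriched term",
                      sprintf("random term %d", seq_len(cfg$nTerms - 1L))),
        category = "synthetic",
        stringsAsFactors = FALSE
    )
    ann$genes <- c(list(unique(plantedGenes)), others)
    list(annotations = ann, background = background)
}
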