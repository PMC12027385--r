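interFrame <- function(mirna, target, class = "mRNA", support = 1L) {
    data.frame(mirna_id = mirna, target_id = target,
               target_class = rep(class, length.out = length(mirna)),
               clip_support = rep(as.integer(support),
                                  length.out = length(mirna)),
               stringsAsFactors = FALSE)
}

test_that("seeds absent from the interaction table are reported, not dropped silently", {
    seeds <- SeedSet("6m", "up", c("m1", "m2"))
    inter <- interFrame("m1", c("g1"))
    net <- buildWholeGenomeNet(seeds, inter)
    expect_identical(missingSeeds(net), "m2")
    expect_equal(nrow(netEdges(net)), 1L)
    expect_equal(cenetPolarity(net), "DOWN")
    # empty interaction table: everything missing, zero edges
    net0 <- buildWholeGenomeNet(seeds, interFrame(character(), character()))
    expect_identical(missingSeeds(net0), c("m1", "m2"))
    expect_equal(nrow(netEdges(net0)), 0L)
})

test_that("whole-genome edge count equals a linear-scan count on random tables", {
    set.seed(41)
    inter <- interFrame(
        sample(sprintf("m%02d", 1:30), 2000, replace = TRUE),
        sample(sprintf("g%03d", 1:200), 2000, replace = TRUE),
        class = sample(c("mRNA", "lncRNA", "circRNA"), 2000, replace = TRUE),
        support = sample(1:10, 2000, replace = TRUE))
    inter <- inter[!duplicated(paste(inter$mirna_id, inter$target_id)), ]
    seeds <- SeedSet("6m", "down", sprintf("m%02d", 1:8))
    net <- buildWholeGenomeNet(seeds, inter)
    ref <- 0L
    for (i in seq_len(nrow(inter)))
        if (inter$mirna_id[i] %in% members(seeds)) ref <- ref + 1L
    expect_equal(nrow(netEdges(net)), ref)
    # clip-support threshold is a plain cutoff
    net5 <- buildWholeGenomeNet(seeds, inter, clipSupportMin = 5)
    expect_equal(nrow(netEdges(net5)),
                 sum(inter$mirna_id %in% members(seeds) &
                     inter$clip_support >= 5))
})

test_that("polarity filter keeps exactly the targets matching network polarity", {
    seeds <- SeedSet("6m", "down", "miR-X")   # down miRNA -> UP ceNET
    inter <- interFrame(rep("miR-X", 3), c("A", "B", "C"))
    net <- buildWholeGenomeNet(seeds, inter)
    cerna <- deFrame(c("A", "B"), c("up", "down"), rna_class = "mRNA")
    filt <- applyCernaFilter(net, cerna)
    expect_equal(netEdges(filt)$target_id, "A")
    expect_equal(netNodes(filt)$direction[netNodes(filt)$id == "A"], "up")
    # no DE record matches: zero edges, seed flagged as dropped
    none <- applyCernaFilter(net, deFrame("Z", "up", rna_class = "mRNA"))
    expect_equal(nrow(netEdges(none)), 0L)
    expect_identical(droppedSeeds(none), "miR-X")
})

test_that("filter equals a brute-force scan over edges x DE records", {
    set.seed(42)
    for (rep in 1:20) {
        targets <- sprintf("g%03d", 1:100)
        inter <- interFrame(
            sample(sprintf("m%02d", 1:10), 300, replace = TRUE),
            sample(targets, 300, replace = TRUE),
            class = sample(c("mRNA", "lncRNA", "circRNA"), 300,
                           replace = TRUE))
        inter <- inter[!duplicated(paste(inter$mirna_id, inter$target_id)), ]
        dir <- sample(c("up", "down"), 1)
        seeds <- SeedSet("6m", dir, sprintf("m%02d", 1:5))
        net <- suppressWarnings(buildWholeGenomeNet(seeds, inter))
        present <- sample(targets, 60)
        classOf <- vapply(present, function(t)
            inter$target_class[match(t, inter$target_id)], character(1))
        classOf[is.na(classOf)] <- "mRNA"
        cerna <- deFrame(present,
                         sample(c("up", "down", "ns"), 60, replace = TRUE),
                         rna_class = classOf)
        filt <- suppressMessages(applyCernaFilter(net, cerna))
        ref <- bruteFilter(netEdges(net), cerna, cenetPolarity(net))
        ref <- ref[order(ref$mirna_id, ref$target_id, method = "radix"), ]
        rownames(ref) <- NULL
        expect_identical(netEdges(filt), ref)
        # anti-monotone: never adds anything
        expect_lte(nrow(netEdges(filt)), nrow(netEdges(net)))
        expect_true(all(netNodes(filt)$id %in% netNodes(net)$id))
        # seed partition: missing, dropped and retained cover the seed set
        retained <- netNodes(filt)$id[netNodes(filt)$rna_class == "miRNA"]
        parts <- c(missingSeeds(filt), droppedSeeds(filt), retained)
        expect_identical(sort(parts, method = "radix"), members(seeds))
        expect_equal(anyDuplicated(parts), 0L)
    }
})

test_that("class mismatches between DE and interaction table are reported and resolved", {
    seeds <- SeedSet("6m", "down", "m1")
    inter <- interFrame("m1", "G", class = "lncRNA")
    net <- buildWholeGenomeNet(seeds, inter)
    # G appears only as mRNA in the DE table
    cerna <- deFrame("G", "up", rna_class = "mRNA")
    expect_message(filt <- applyCernaFilter(net, cerna), "different RNA class")
    expect_equal(netEdges(filt)$target_class, "lncRNA")
    expect_equal(nrow(netEdges(filt)), 1L)
})

test_that("SIF export writes sorted relation lines and handles empty networks", {
    seeds <- SeedSet("6m", "up", c("miR-2", "miR-1"))
    inter <- interFrame(c("miR-2", "miR-1", "miR-1"),
                        c("GeneB", "GeneA", "GeneC"))
    net <- buildWholeGenomeNet(seeds, inter)
    p <- tempfile(fileext = ".sif")
    exportNetwork(net, p, "SIF")
    expect_identical(readLines(p),
                     c("miR-1\tcerna_of\tGeneA", "miR-1\tcerna_of\tGeneC",
                       "miR-2\tcerna_of\tGeneB"))
    empty <- suppressWarnings(
        buildWholeGenomeNet(SeedSet("6m", "up", "zz"),
                            interFrame(character(), character())))
    p0 <- tempfile(fileext = ".sif")
    exportNetwork(empty, p0, "SIF")
    expect_identical(readLines(p0), character())
    expect_error(exportNetwork(net, tempfile(), "XGMML"))
})

test_that("GraphML export round-trips node and edge sets exactly", {
    seeds <- SeedSet("9m", "down", c("m1", "m2"))
    inter <- interFrame(c("m1", "m1", "m2"), c("A", "B", "C"),
                        class = c("mRNA", "lncRNA", "circRNA"),
                        support = c(3L, 1L, 7L))
    net <- buildWholeGenomeNet(seeds, inter)
    cerna <- deFrame(c("A", "B", "C"), c("up", "up", "down"),
                     stage = "9m", rna_class = c("mRNA", "lncRNA", "circRNA"))
    filt <- applyCernaFilter(net, cerna)
    for (obj in list(net, filt)) {
        p <- tempfile(fileext = ".graphml")
        exportNetwork(obj, p, "GraphML")
        back <- importNetworkGraphML(p)
        expect_identical(netNodes(back), netNodes(obj))
        expect_identical(netEdges(back), netEdges(obj))
        expect_identical(stage(back), stage(obj))
        expect_identical(cenetPolarity(back), cenetPolarity(obj))
        expect_identical(isFiltered(back), isFiltered(obj))
    }
})

test_that("filtering then exporting equals exporting the filtered network", {
    seeds <- SeedSet("6m", "up", c("m1", "m2"))
    inter <- interFrame(c("m1", "m2"), c("A", "B"))
    net <- buildWholeGenomeNet(seeds, inter)
    cerna <- deFrame(c("A", "B"), c("down", "up"), rna_class = "mRNA")
    filt <- applyCernaFilter(net, cerna)
    p1 <- tempfile(); p2 <- tempfile()
    exportNetwork(applyCernaFilter(net, cerna), p1, "TSV")
    exportNetwork(filt, p2, "TSV")
    expect_identical(readLines(p1), readLines(p2))
})
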