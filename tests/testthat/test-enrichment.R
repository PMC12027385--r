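test_that("hypergeometric tail handles boundary cases and the worked example", {
    expect_equal(hypergeomUpperTail(0, 5, 5, 20), 1.0)
    expect_equal(hypergeomUpperTail(0, 1, 1, 2), 1.0)
    # degenerate universe: every draw is a success
    expect_equal(hypergeomUpperTail(3, 10, 3, 10), 1.0)
    expect_equal(hypergeomUpperTail(4, 5, 5, 20), 76 / 15504,
                 tolerance = 1e-14)
    expect_error(hypergeomUpperTail(6, 5, 5, 20), "domain")
    expect_error(hypergeomUpperTail(1, 25, 5, 20), "domain")
})

test_that("hypergeometric tail matches exact enumeration on a parameter sweep", {
    for (N in c(5, 12, 20, 33, 47)) {
        for (K in unique(c(1, N %/% 3, N))) {
            for (n in unique(c(1, N %/% 2, N))) {
                for (k in 0:min(K, n)) {
                    expect_equal(hypergeomUpperTail(k, K, n, N),
                                 enumUpperTail(k, K, n, N),
                                 tolerance = 1e-12)
                }
            }
        }
    }
})

test_that("BH adjustment matches the step-up definition and is order-equivariant", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_error(bhAdjust(c(0.5, 0)), "domain")
    expect_error(bhAdjust(c(0.5, 1.2)), "domain")
    set.seed(51)
    for (rep in 1:50) {
        p <- stats::runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), bhStepUp(p), tolerance = 1e-12)
        perm <- sample(seq_along(p))
        expect_equal(bhAdjust(p[perm])[order(perm)], bhAdjust(p),
                     tolerance = 1e-12)
    }
})

makeAnnotations <- function(sets, category = "cat") {
    ann <- data.frame(term_id = names(sets),
                      term_name = names(sets),
                      category = category, stringsAsFactors = FALSE)
    ann$genes <- unname(sets)
    ann
}

test_that("a term fully covering the query ranks first; disjoint queries return nothing", {
    bg <- sprintf("g%03d", 1:100)
    ann <- makeAnnotations(list(hit = bg[1:10], other = bg[50:80]))
    res <- enrich(bg[1:10], ann, bg)
    expect_equal(res$term_id[1], "hit")
    expect_equal(res$k[1], res$n[1])
    res2 <- enrich(bg[90:95], makeAnnotations(list(t = bg[1:10])), bg)
    expect_equal(nrow(res2), 0L)
})

test_that("enrichment p-values equal the enumeration oracle term by term", {
    set.seed(52)
    bg <- sprintf("g%03d", 1:200)
    sets <- lapply(1:12, function(i) sample(bg, sample(5:40, 1)))
    names(sets) <- sprintf("T%02d", 1:12)
    ann <- makeAnnotations(sets)
    query <- sample(bg, 30)
    res <- enrich(query, ann, bg, keepAll = TRUE)
    for (i in seq_len(nrow(res))) {
        k <- length(intersect(query, sets[[res$term_id[i]]]))
        expect_equal(res$k[i], k)
        expect_equal(res$p_hyper[i],
                     enumUpperTail(k, length(sets[[res$term_id[i]]]),
                                   30, 200),
                     tolerance = 1e-12)
        # strength: log10 observed/expected
        expect_equal(res$strength[i],
                     log10((k / 30) / (length(sets[[res$term_id[i]]]) / 200)),
                     tolerance = 1e-12)
    }
    # adjusted values are nondecreasing when sorted by raw p (per category)
    o <- order(res$p_hyper)
    expect_true(all(diff(res$fdr_bh[o]) >= -1e-12))
})

test_that("strength is zero exactly at proportional representation", {
    # k/n = K/N  ->  strength 0; over-representation -> positive
    bg <- sprintf("g%02d", 1:40)
    # prop: k/n = 5/10 equals K/N = 20/40; over: 5/10 > 5/40
    ann <- makeAnnotations(list(prop = c(bg[1:5], bg[11:25]),
                                over = bg[1:5]))
    res <- enrich(bg[1:10], ann, bg, keepAll = TRUE)
    expect_equal(res$strength[res$term_id == "prop"], 0)
    expect_gt(res$strength[res$term_id == "over"], 0)
})

test_that("BH families are per category and thresholds gate the output", {
    bg <- sprintf("g%03d", 1:100)
    a1 <- makeAnnotations(list(A = bg[1:10]), category = "c1")
    a2 <- makeAnnotations(list(B = bg[1:10], B2 = c(bg[10], bg[60:98])),
                          category = "c2")
    ann <- rbind(a1, a2)
    res <- enrich(bg[1:10], ann, bg, keepAll = TRUE)
    # identical raw p for A and B, but B shares its BH family with B2
    pA <- res$p_hyper[res$term_id == "A"]
    expect_equal(res$fdr_bh[res$term_id == "A"], pA)
    expect_equal(res$fdr_bh[res$term_id == "B"], 2 * pA)  # m = 2 in c2
    gated <- enrich(bg[1:10], ann, bg, minHits = 2)
    expect_true(all(gated$k >= 2 & gated$fdr_bh <= 0.05 &
                    gated$strength >= 0.01))
})

test_that("query and annotation genes outside the background are dropped with warnings", {
    bg <- sprintf("g%02d", 1:50)
    ann <- makeAnnotations(list(t = c(bg[1:5], "alien")))
    expect_warning(
        expect_warning(res <- enrich(c(bg[1:5], "ghost"), ann, bg),
                       "query gene"),
        "annotation gene")
    expect_equal(res$K[1], 5L)
    expect_equal(res$n[1], 5L)
    expect_error(enrich(bg[1:5], ann, character()), "background")
})

test_that("term grouping follows single-linkage Jaccard components", {
    mk <- function(id, genes, fdr, p = fdr) {
        data.frame(term_id = id, term_name = id, category = "c",
                   k = length(genes), K = 10L, n = 10L, N = 100L,
                   p_hyper = p, fdr_bh = fdr, strength = 1,
                   stringsAsFactors = FALSE)
    }
    res <- rbind(mk("a", c("A", "B", "C"), 0.01),
                 mk("b", c("B", "C", "D"), 0.02),
                 mk("c", c("X", "Y"), 0.03),
                 mk("d", c("X", "Y"), 0.04))
    res$members <- list(c("A", "B", "C"), c("B", "C", "D"),
                        c("X", "Y"), c("X", "Y"))
    res$group_id <- NA_integer_
    out <- groupTerms(res, similarityMin = 0.2)
    # Jaccard(a, b) = 2/4 = 0.5 >= 0.2 -> same group, led by lowest fdr
    expect_equal(out$group_id[1], out$group_id[2])
    # identical member sets always share a group
    expect_equal(out$group_id[3], out$group_id[4])
    # disjoint sets never share one
    expect_true(out$group_id[1] != out$group_id[3])
    # ids numbered in representative (fdr) order
    expect_equal(out$group_id, c(1L, 1L, 2L, 2L))
    # threshold 1 still groups identical sets but splits overlapping ones
    strict <- groupTerms(res, similarityMin = 1)
    expect_true(strict$group_id[1] != strict$group_id[2])
    expect_equal(strict$group_id[3], strict$group_id[4])
})
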