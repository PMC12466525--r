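mkDE <- function(lfc, p, genes = sprintf("g%03d", seq_along(lfc))) {
    new("DEResult", S4Vectors::DataFrame(
        baseMean = rep(10, length(lfc)), log2FC = lfc,
        dispersion = rep(0.05, length(lfc)), stat = lfc,
        pvalue = p, padj = p, degFlag = rep("none", length(lfc)),
        converged = rep(TRUE, length(lfc)), row.names = genes))
}

test_that("the ranking statistic is sign(lfc) * -log10(p)", {
    de <- mkDE(c(-0.5, 1, 2, -3), c(0.01, 0.001, 1, 1),
               genes = c("a", "b", "c", "d"))
    r <- rankGenes(de)
    expect_equal(unname(r["a"]), -2)
    expect_equal(unname(r["b"]), 3)
    expect_equal(unname(r["c"]), 0)   # p = 1 kills the sign
    expect_equal(unname(r["d"]), 0)
    ## sorted descending, ties broken lexicographically
    expect_identical(names(r), c("b", "c", "d", "a"))
    ## p floor keeps ranks finite
    de0 <- mkDE(c(1, -1), c(0, 0.5), genes = c("a", "b"))
    expect_message(r0 <- rankGenes(de0), "clamped")
    expect_equal(unname(r0["a"]), 300)
})

test_that("enrichment score equals the brute-force running sum", {
    set.seed(107)
    for (i in 1:5) {
        stat <- sort(rnorm(50, sd = 2), decreasing = TRUE)
        names(stat) <- sprintf("g%02d", sample(50))
        set <- sample(names(stat), 10)
        es <- enrichmentScore(stat, set)
        expect_equal(es$es, naiveES(stat, set), tolerance = 1e-12)
        expect_true(abs(es$es) <= 1)
        ## the internal hit-only path agrees with the full profile
        hit <- which(names(stat) %in% set)
        expect_equal(CoexRewire:::esFromHits(hit, abs(stat[hit]), 50),
                     es$es, tolerance = 1e-12)
    }
})

test_that("enrichment score edge cases follow the declared contract", {
    stat <- setNames(seq(5, 0.5, length.out = 10), paste0("g", 1:10))
    ## the single top-ranked gene: running sum hits 1 immediately
    expect_equal(enrichmentScore(stat, "g1")$es, 1)
    ## all member statistics zero: undefined hit normalizer
    stat0 <- c(setNames(seq(5, 1, length.out = 8), paste0("g", 1:8)),
               h1 = 0, h2 = 0)
    expect_error(enrichmentScore(stat0, c("h1", "h2")), "zero")
    expect_error(enrichmentScore(stat, "absent"), "intersect")
    expect_error(enrichmentScore(stat, names(stat)), "whole universe")
})

test_that("weight 0 reduces to the classical KS statistic", {
    set.seed(109)
    stat <- sort(rnorm(40), decreasing = TRUE)
    names(stat) <- sprintf("g%02d", sample(40))
    set <- sample(names(stat), 8)
    es0 <- enrichmentScore(stat, set, weight = 0)$es
    ## direct KS-style computation: ecdf difference at every position
    hit <- names(stat) %in% set
    dev <- cumsum(hit) / 8 - cumsum(!hit) / 32
    expect_equal(es0, dev[which.max(abs(dev))], tolerance = 1e-12)
})

test_that("preranked GSEA is deterministic and scale-invariant", {
    set.seed(113)
    stat <- sort(rnorm(200, sd = 1.5), decreasing = TRUE)
    names(stat) <- sprintf("g%03d", sample(200))
    sets <- list(s1 = sample(names(stat), 15),
                 s2 = sample(names(stat), 25),
                 s3 = names(stat)[1:10])
    g1 <- gseaPrerank(stat, sets, n_perm = 200, seed = 9)
    g2 <- gseaPrerank(stat, sets, n_perm = 200, seed = 9)
    expect_identical(g1, g2)
    ## multiplying all rank statistics by a positive constant changes
    ## neither ES nor the nominal p
    g3 <- gseaPrerank(stat * 7, sets, n_perm = 200, seed = 9)
    expect_equal(g1$es, g3$es, tolerance = 1e-12)
    expect_equal(g1$pvalue, g3$pvalue)
    ## sign(NES) matches sign(ES); a top-loaded set scores positive
    expect_true(all(sign(g1$nes[g1$nesDefined]) ==
                    sign(g1$es[g1$nesDefined])))
    expect_gt(g1$es[g1$set == "s3"], 0.8)
})

test_that("ORA matches the exact hypergeometric tail", {
    universe <- sprintf("u%03d", 1:100)
    set10 <- universe[1:10]
    lst <- c(universe[1:5], universe[90:94])   # overlap 5
    res <- ora(lst, universe, list(s = set10))
    oracle <- sum(sapply(5:10, function(k) {
        choose(10, k) * choose(90, 10 - k) / choose(100, 10)
    }))
    expect_equal(res$pvalue, oracle, tolerance = 1e-12)
    ## zero overlap: upper tail includes 0, p = 1
    res0 <- ora(universe[50:59], universe, list(s = universe[1:10]))
    expect_equal(res0$pvalue, 1)
    ## disjoint sets are excluded with a message
    expect_message(resd <- ora(lst, universe,
                               list(s = set10, ghost = c("x", "y"))),
                   "disjoint")
    expect_identical(resd$set, "s")
    expect_error(ora(c("zzz"), universe, list(s = set10)), "subset")
    expect_error(ora(lst, character(0), list(s = set10)), "universe")
})
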