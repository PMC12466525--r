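test_that("identical parameters give bit-identical simulations", {
    p <- simParams(n_genes = 200, n_tfs = 20, n_modules = 2,
                   module_size = 5, seed = 7)
    a <- simulateCounts(p)
    b <- simulateCounts(p)
    expect_identical(SummarizedExperiment::assay(a$se),
                     SummarizedExperiment::assay(b$se))
    expect_identical(degLfc(a$truth), degLfc(b$truth))
    d <- simulateCounts(simParams(n_genes = 200, n_tfs = 20, n_modules = 2,
                                  module_size = 5, seed = 8))
    expect_false(identical(SummarizedExperiment::assay(a$se),
                           SummarizedExperiment::assay(d$se)))
})

test_that("no planted effects means empty truth", {
    p <- simParams(n_genes = 150, n_tfs = 10, n_modules = 2,
                   module_size = 5, frac_deg = 0,
                   coupling_A = 0.5, coupling_B = 0.5, seed = 3)
    sim <- simulateCounts(p)
    expect_length(degIds(sim$truth), 0)
    expect_length(rewiredTfIds(sim$truth), 0)
})

test_that("module sizing beyond the gene count is rejected", {
    expect_error(simParams(n_genes = 100, n_tfs = 20, n_modules = 10,
                           module_size = 10), "exceeds")
    expect_error(simParams(n_genes = 100, frac_deg = 1.5), "fracDeg")
    expect_error(simParams(n_genes = 100, n_tfs = 10, n_modules = 2,
                           module_size = 5, coupling_A = 1), "coupling")
})

test_that("planted log2 fold changes are recovered from normalized means", {
    ## Monte-Carlo check against the generative model: with |lfc| pinned at
    ## 1 the mean log2 ratio of normalized condition means over up-DEGs
    ## should sit near 1 at n = 6/group
    sim <- simulateCounts(simParams(n_genes = 2000, frac_deg = 0.05,
                                    lfc_range = c(1, 1), coupling_A = 0,
                                    coupling_B = 0, seed = 11))
    counts <- SummarizedExperiment::assay(sim$se)
    cond <- SummarizedExperiment::colData(sim$se)$condition
    sf <- colSums(counts) / mean(colSums(counts))
    q <- sweep(counts, 2, sf, `/`)
    up <- names(which(degLfc(sim$truth) > 0))
    ratio <- log2(rowMeans(q[up, cond == "VTM"]) /
                  rowMeans(q[up, cond == "CON"]))
    expect_lt(abs(mean(ratio) - 1), 0.15)
})

test_that("with no signal the counts match NB moments", {
    ## var = mu + alpha mu^2 within Monte-Carlo tolerance at 1e4 samples
    p <- simParams(n_genes = 25, n_tfs = 2, n_modules = 1, module_size = 3,
                   n_samples_per_condition = 5000, frac_deg = 0,
                   coupling_A = 0, coupling_B = 0,
                   lib_size_range = c(1, 1), mean_log_mu = 4,
                   sd_log_mu = 0.5, seed = 13)
    sim <- simulateCounts(p)
    counts <- SummarizedExperiment::assay(sim$se)
    alpha <- sim$truth@dispersion
    mu <- rowMeans(counts)
    v <- apply(counts, 1, var)
    expected <- mu + alpha * mu^2
    expect_lt(max(abs(v / expected - 1)), 0.15)
})

test_that("TF-target correlation rises monotonically with coupling", {
    cors <- vapply(c(0, 0.3, 0.6, 0.9), function(cpl) {
        p <- simParams(n_genes = 60, n_tfs = 5, n_modules = 1,
                       module_size = 10, n_samples_per_condition = 200,
                       frac_deg = 0, coupling_A = cpl, coupling_B = cpl,
                       lib_size_range = c(1, 1), seed = 17)
        sim <- simulateCounts(p)
        expr <- log2(SummarizedExperiment::assay(sim$se) + 1)
        cond <- SummarizedExperiment::colData(sim$se)$condition
        tf <- names(moduleMap(sim$truth))[1]
        tg <- moduleMap(sim$truth)[[1]]
        mean(cor(expr[tf, cond == "CON"],
                 t(expr[tg, cond == "CON"])))
    }, numeric(1))
    expect_true(all(diff(cors) > 0))
    expect_lt(abs(cors[1]), 0.1)
    expect_gt(cors[4], 0.6)
})

test_that("planted gene sets follow the module map and are reproducible", {
    sim <- smallSim()
    sets0 <- plantGeneSets(sim$truth, n_random_sets = 0)
    expect_length(sets0, length(moduleMap(sim$truth)))
    expect_identical(unname(sets0[[1]]), moduleMap(sim$truth)[[1]])
    a <- plantGeneSets(sim$truth, n_random_sets = 10, seed = 4)
    b <- plantGeneSets(sim$truth, n_random_sets = 10, seed = 4)
    expect_identical(a, b)
    expect_error(plantGeneSets(sim$truth, set_size_range = c(10, 1e6)),
                 "size")
})

test_that("random set overlap with DEGs follows the hypergeometric law", {
    sim <- simulateCounts(simParams(n_genes = 1000, n_tfs = 50,
                                    n_modules = 5, module_size = 10,
                                    frac_deg = 0.1, coupling_A = 0,
                                    coupling_B = 0, seed = 23))
    nDeg <- length(degIds(sim$truth))
    k <- 40
    sets <- plantGeneSets(sim$truth, n_random_sets = 300,
                          set_size_range = c(k, k), seed = 29)
    ov <- vapply(sets[grep("random", names(sets))],
                 function(s) sum(s %in% degIds(sim$truth)), integer(1))
    expHyper <- k * nDeg / 1000
    sdHyper <- sqrt(k * (nDeg / 1000) * (1 - nDeg / 1000) *
                    (1000 - k) / 999)
    ## mean of 300 draws within 4 standard errors of the closed form
    expect_lt(abs(mean(ov) - expHyper), 4 * sdHyper / sqrt(300))
})
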