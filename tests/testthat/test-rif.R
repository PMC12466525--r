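test_that("condition correlations match a per-pair Pearson loop", {
    set.seed(59)
    mat <- matrix(rnorm(10 * 8), 10, 8,
                  dimnames = list(paste0("g", 1:10), NULL))
    vse <- exprSE(mat, rep(c("CON", "VTM"), each = 4))
    tf <- paste0("g", 1:3)
    dg <- paste0("g", 4:10)
    cc <- conditionCorrelations(vse, tf, dg)
    expect_equal(cc$rA, naivePearson(mat[tf, 1:4], mat[dg, 1:4]),
                 tolerance = 1e-12)
    expect_equal(cc$rB, naivePearson(mat[tf, 5:8], mat[dg, 5:8]),
                 tolerance = 1e-12)
})

test_that("degenerate pairs get the declared conventions", {
    mat <- rbind(tf1 = c(1, 1, 1, 1, 2, 3),    # constant in CON
                 tf2 = c(1, 2, 3, 4, 5, 6),
                 d1 = c(2, 4, 6, 1, 3, 5),
                 tf2twin = c(1, 2, 3, 4, 5, 6))
    vse <- exprSE(mat, rep(c("CON", "VTM"), each = 3))
    expect_warning(cc <- conditionCorrelations(vse, c("tf1", "tf2"),
                                               c("d1", "tf2twin")),
                   "zero-variance")
    expect_equal(unname(cc$rA["tf1", ]), c(0, 0))     # constant TF
    expect_equal(cc$rA["tf2", "tf2twin"], 1)          # identical columns
    ## self-pair convention: a TF that is also a DEG scores 0 with itself
    cc2 <- conditionCorrelations(vse, c("tf2", "d1"), c("d1", "tf2twin"))
    expect_equal(cc2$rA["d1", "d1"], 0)
    expect_equal(cc2$rB["d1", "d1"], 0)
    ## too few samples
    expect_error(conditionCorrelations(exprSE(mat[, c(1, 2, 4, 5)],
                                              c("CON", "CON", "VTM",
                                                "VTM")), "tf2", "d1"),
                 ">= 3")
})

test_that("the single TF/DEG worked example evaluates exactly", {
    vse <- rifWorkedExample()
    ## both metrics warn once each about the degenerate single-TF spread
    expect_warning(
        expect_warning(
            rif <- suppressMessages(computeRIF(vse, "TF1", "DEG1")),
            "zero spread"),
        "zero spread")
    ## PIF = 9 * 2 = 18, dw = 1.8, RIF1 = 18 * 3.24 = 58.32
    expect_equal(rif$rif1Raw, 58.32, tolerance = 1e-9)
    ## RIF2 = (10 * 0.9)^2 - (8 * -0.9)^2 = 81 - 51.84 = 29.16
    expect_equal(rif$rif2Raw, 29.16, tolerance = 1e-9)
    expect_equal(rif$rif1Z, 0)   # single TF: zero spread, z = 0
})

test_that("identical conditions give identically zero raw scores", {
    set.seed(61)
    half <- matrix(rnorm(6 * 3), 6, 3)
    mat <- cbind(half, half)
    rownames(mat) <- paste0("g", 1:6)
    vse <- exprSE(mat, rep(c("CON", "VTM"), each = 3))
    rif <- suppressWarnings(suppressMessages(
        computeRIF(vse, paste0("g", 1:2), paste0("g", 3:6))))
    expect_equal(unname(rif$rif1Raw), c(0, 0), tolerance = 1e-12)
    expect_equal(unname(rif$rif2Raw), c(0, 0), tolerance = 1e-12)
})

test_that("swapping condition labels negates every raw score", {
    sim <- smallSim(seed = 67)
    fse <- filterLowExpressed(sim$se)
    vse <- vstExpr(fse)
    de <- suppressWarnings(nbWaldTest(fse))
    dg <- callDEGs(de)$gene
    tfs <- grep("^TF", rownames(fse), value = TRUE)
    r1 <- suppressMessages(computeRIF(vse, tfs, dg, ref = "CON"))
    r2 <- suppressMessages(computeRIF(vse, tfs, dg, ref = "VTM"))
    expect_equal(r1$rif1Raw, -r2$rif1Raw, tolerance = 1e-10)
    expect_equal(r1$rif2Raw, -r2$rif2Raw, tolerance = 1e-10)
})

test_that("z-columns are standardized and flags are consistent", {
    sim <- smallSim(seed = 71)
    fse <- filterLowExpressed(sim$se)
    vse <- vstExpr(fse)
    de <- suppressWarnings(nbWaldTest(fse))
    tfs <- grep("^TF", rownames(fse), value = TRUE)
    rif <- suppressMessages(computeRIF(vse, tfs, callDEGs(de)$gene))
    expect_lt(abs(mean(rif$rif1Z)), 1e-9)
    expect_lt(abs(sd(rif$rif1Z) - 1), 1e-9)
    expect_lt(abs(mean(rif$rif2Z)), 1e-9)
    expect_lt(abs(sd(rif$rif2Z) - 1), 1e-9)
    expect_identical(rif$significantRif1, abs(rif$rif1Z) >= 1.96)
    expect_identical(rif$significantRif2, abs(rif$rif2Z) >= 1.96)
    expect_setequal(significantRifIds(rif),
                    rownames(rif)[rif$significantRif1 |
                                  rif$significantRif2])
})

test_that("TF bookkeeping reports list, tested and removed counts", {
    sim <- smallSim(seed = 73)
    fse <- filterLowExpressed(sim$se)
    vse <- vstExpr(fse)
    de <- suppressWarnings(nbWaldTest(fse))
    tfs <- c(grep("^TF", rownames(fse), value = TRUE),
             "GHOST1", "GHOST2", "GHOST3")
    expect_message(
        rif <- computeRIF(vse, tfs, callDEGs(de)$gene),
        "TF list n = \\d+; tested n = \\d+; removed as unexpressed n = 3")
    md <- S4Vectors::metadata(rif)
    expect_identical(md$nTfList, length(tfs))
    expect_identical(md$nTested, length(tfs) - 3L)
    expect_identical(md$nRemoved, 3L)
})
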