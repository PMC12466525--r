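test_that("partial correlation follows the textbook formula", {
    expect_equal(partialCorrelation(0.4, 0, 0), 0.4)
    expect_equal(partialCorrelation(0.3, 0.6, 0.5), 0,
                 tolerance = 1e-12)   # r_xy = r_xz * r_yz
    expect_equal(partialCorrelation(0.8, 0.5, 0.5), 0.55 / 0.75,
                 tolerance = 1e-12)
    expect_error(partialCorrelation(0.5, 1, 0.2), "strictly inside")
})

test_that("trio tolerance matches hand arithmetic and its closed form", {
    Req <- function(rho) {
        R <- matrix(rho, 3, 3); diag(R) <- 1; R
    }
    ## equicorrelated 0.9: each partial 0.09/0.19, ratio 0.5263...
    expect_equal(trioTolerance(Req(0.9), 1, 2, 3), (0.09 / 0.19) / 0.9,
                 tolerance = 1e-12)
    ## closed form eps = 1/(1+rho) over a grid
    for (rho in c(0.1, 0.25, 0.5, 0.75, 0.95)) {
        expect_equal(trioTolerance(Req(rho), 1, 2, 3), 1 / (1 + rho),
                     tolerance = 1e-12)
    }
    ## asymmetric trio vs a naive direct evaluation
    R3 <- matrix(c(1, 0.1, 0.6, 0.1, 1, 0.6, 0.6, 0.6, 1), 3)
    expect_equal(trioTolerance(R3, 1, 2, 3), -0.60038835, tolerance = 1e-6)
    ## near-zero direct correlation: non-informative
    R0 <- R3; R0[1, 2] <- R0[2, 1] <- 0
    expect_true(is.na(trioTolerance(R0, 1, 2, 3)))
})

test_that("elimination examples behave as derived", {
    ## trio (0.1, 0.6, 0.6): |eps * 0.6| = 0.36 >= 0.1 on both arms
    R3 <- matrix(c(1, 0.1, 0.6, 0.1, 1, 0.6, 0.6, 0.6, 1), 3)
    sig <- pcitSignificantEdges(R3)
    expect_false(sig[1, 2])
    expect_true(sig[1, 3] && sig[2, 3])
    ## equicorrelated: eps * rho = rho / (1 + rho) < rho, nothing eliminated
    for (rho in c(0.2, 0.5, 0.9)) {
        R <- matrix(rho, 4, 4); diag(R) <- 1
        s <- pcitSignificantEdges(R)
        expect_true(all(s[upper.tri(s)]))
    }
})

test_that("compiled PCIT equals the literal triple-loop oracle", {
    for (seed in 1:10) {
        n <- sample(c(8, 15, 25), 1)
        R <- randomCorrMatrix(n, seed = seed)
        expect_identical(unname(pcitSignificantEdges(R)), naivePcit(R))
    }
})

test_that("perturbing one correlation leaves implementation and oracle in
           lockstep", {
    ## Elimination is NOT monotone in |r_xy| for the signed-tolerance
    ## rule: as |r_xy| -> 1 the (1 - r_xy^2) denominators inflate the
    ## trio tolerance until even a strong edge is eliminated. What must
    ## hold is that the compiled scan tracks the literal rule at every
    ## perturbation, including across that regime change.
    R <- randomCorrMatrix(12, seed = 79)
    sig <- pcitSignificantEdges(R)
    idx <- which(sig & upper.tri(sig), arr.ind = TRUE)[1, ]
    s <- sign(R[idx[1], idx[2]])
    r0 <- abs(R[idx[1], idx[2]])
    states <- logical(0)
    for (rNew in seq(r0, 0.99, length.out = 6)) {
        R2 <- R
        R2[idx[1], idx[2]] <- R2[idx[2], idx[1]] <- s * rNew
        cpp <- pcitSignificantEdges(R2)[idx[1], idx[2]]
        expect_identical(cpp, naivePcit(R2)[idx[1], idx[2]])
        states <- c(states, cpp)
    }
    expect_true(states[1])   # the starting edge really did survive
})

test_that("degenerate matrices are handled", {
    expect_warning(s <- pcitSignificantEdges(matrix(c(1, .5, .5, 1), 2)),
                   "trivially")
    expect_true(s[1, 2])
    expect_error(pcitSignificantEdges(matrix(c(1, .5, .2, 1), 2)),
                 "symmetric")
})

test_that("condition networks retain exactly the filtered PCIT edges", {
    sim <- smallSim(seed = 83)
    fse <- filterLowExpressed(sim$se)
    vse <- vstExpr(fse)
    keep <- degIds(sim$truth)
    net <- buildConditionNetwork(vse, "CON", keep, r_threshold = 0.8)
    ## recompute with the naive oracle then filter
    R <- conditionCorrelationMatrix(vse, "CON")
    sig <- naivePcit(R)
    inKeep <- rownames(R) %in% keep
    ok <- sig & abs(R) >= 0.8 &
        (matrix(inKeep, nrow(R), nrow(R)) |
         matrix(inKeep, nrow(R), nrow(R), byrow = TRUE))
    expect_identical(nrow(edges(net)), sum(ok[upper.tri(ok)]))
    expect_setequal(nodes(net),
                    rownames(R)[rowSums(ok) > 0])
    ## every retained edge respects the contract
    ed <- edges(net)
    expect_true(all(ed$geneX < ed$geneY))
    expect_true(all(abs(ed$r) >= 0.8))
    expect_true(all(ed$geneX %in% keep | ed$geneY %in% keep))
    expect_error(buildConditionNetwork(vse, "CON", character(0)), "empty")
})

test_that("a perfectly co-varying anchored pair is always retained", {
    set.seed(89)
    base <- matrix(rnorm(8 * 6), 8, 6,
                   dimnames = list(paste0("g", 1:8), NULL))
    base["g2", ] <- 2 * base["g1", ] + 5      # r = 1, clipped internally
    vse <- exprSE(base, rep(c("CON", "VTM"), each = 3))
    net <- buildConditionNetwork(vse, "CON", "g1", r_threshold = 0.9)
    ed <- edges(net)
    expect_true(any(ed$geneX == "g1" & ed$geneY == "g2"))
})

test_that("partial-threshold mode bounds edges by their weakest partial", {
    R <- randomCorrMatrix(10, seed = 97)
    res <- pcitSignificantEdges(R, track_partial = TRUE)
    expect_identical(unname(res$significant), naivePcit(R))
    ## oracle: min over z of |partial(x, y | z)|
    i <- 2; j <- 7
    ps <- sapply(setdiff(1:10, c(i, j)), function(z) {
        abs(partialCorrelation(R[i, j], R[i, z], R[j, z]))
    })
    expect_equal(res$minAbsPartial[i, j], min(ps), tolerance = 1e-12)
})
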