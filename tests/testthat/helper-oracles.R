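## Independent reference implementations used as oracles. These are kept
## deliberately literal (per-element loops, textbook formulas) and must not
## share code with the package internals they check.

# correlation matrix of n variables observed on p samples (PSD by
# construction); few samples give strong off-diagonal structure
randomCorrMatrix <- function(n, seed, p = max(4, n %/% 2)) {
    set.seed(seed)
    x <- matrix(rnorm(n * p), n, p)
    stats::cor(t(x))
}

# literal triple-loop PCIT: for each pair, scan every third gene and apply
# the elimination rule exactly as written
naivePcit <- function(R) {
    n <- nrow(R)
    lim <- 0.999999
    R[R > lim] <- lim; R[R < -lim] <- -lim; diag(R) <- 1
    sig <- !diag(TRUE, n)
    for (x in seq_len(n - 1)) for (y in seq(x + 1, n)) {
        for (z in seq_len(n)[-c(x, y)]) {
            rxy <- R[x, y]; rxz <- R[x, z]; ryz <- R[y, z]
            if (min(abs(c(rxy, rxz, ryz))) <= 1e-12) next
            pxy <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
            pxz <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
            pyz <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
            eps <- (pxy / rxy + pxz / rxz + pyz / ryz) / 3
            if (abs(rxy) <= abs(eps * rxz) && abs(rxy) <= abs(eps * ryz)) {
                sig[x, y] <- sig[y, x] <- FALSE
                break
            }
        }
    }
    sig
}

# textbook per-pair Pearson correlation loop
naivePearson <- function(A, B) {
    out <- matrix(NA_real_, nrow(A), nrow(B),
                  dimnames = list(rownames(A), rownames(B)))
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
        a <- A[i, ]; b <- B[j, ]
        out[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
            sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    }
    out
}

# literal GSEA running sum, one step per ranked gene
naiveES <- function(ranked, set, weight = 1) {
    N <- length(ranked)
    hit <- names(ranked) %in% set
    w <- abs(ranked)^weight
    sw <- sum(w[hit])
    run <- numeric(N)
    cur <- 0
    for (i in seq_len(N)) {
        cur <- if (hit[i]) cur + w[i] / sw else cur - 1 / (N - sum(hit))
        run[i] <- cur
    }
    run[which.max(abs(run))]
}

# expression SummarizedExperiment for direct construction of fixtures
exprSE <- function(mat, condition, ref = "CON") {
    lev <- unique(as.character(condition))
    cond <- factor(as.character(condition),
                   levels = c(ref, setdiff(lev, ref)))
    if (is.null(colnames(mat))) {
        colnames(mat) <- paste0(as.character(condition), "_",
                                seq_len(ncol(mat)))
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(vst = mat),
        colData = S4Vectors::DataFrame(condition = cond,
                                       row.names = colnames(mat)))
}

# rank-based AUROC of a score against a logical positive label
auroc <- function(score, positive) {
    r <- rank(score)
    nP <- sum(positive)
    (mean(r[positive]) - (nP + 1) / 2) / (length(score) - nP)
}

# two-gene expression fixture realizing exact condition means and exact
# within-condition correlations between a "TF" and a "DEG" (3 samples per
# condition): regressor x and an orthogonal mean-zero contrast e
rifWorkedExample <- function(meanA = 10, meanB = 8, rA = 0.9, rB = -0.9) {
    x <- c(-1, 0, 1)
    e <- c(1, -2, 1)
    degA <- meanA + rA * x / sqrt(2) + sqrt(1 - rA^2) * e / sqrt(6)
    degB <- meanB + rB * x / sqrt(2) + sqrt(1 - rB^2) * e / sqrt(6)
    mat <- rbind(TF1 = c(x, x), DEG1 = c(degA, degB))
    exprSE(mat, rep(c("CON", "VTM"), each = 3))
}

# CoexpressionNetwork straight from an edge data.frame (canonicalized)
makeNet <- function(condition, gx, gy, r = rep(0.95, length(gx))) {
    if (length(gx)) {
        swap <- gx > gy
        tmp <- gx[swap]; gx[swap] <- gy[swap]; gy[swap] <- tmp
        ord <- order(gx, gy)
        ed <- data.frame(geneX = gx[ord], geneY = gy[ord], r = r[ord],
                         stringsAsFactors = FALSE)
    } else {
        ed <- data.frame(geneX = character(0), geneY = character(0),
                         r = numeric(0), stringsAsFactors = FALSE)
    }
    new("CoexpressionNetwork", condition = condition, edges = ed,
        nodes = sort(union(ed$geneX, ed$geneY)))
}

# small ready-made simulated experiment reused across tests
smallSim <- function(seed = 5, ...) {
    simulateCounts(simParams(n_genes = 300, n_tfs = 30, n_modules = 3,
                             module_size = 8, seed = seed, ...))
}
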