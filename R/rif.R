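#' Within-condition TF-to-DEG Pearson correlations
#'
#' For every (TF, DEG) pair, the Pearson correlation of their
#' variance-stabilized expression across the samples of each condition.
#' Pairs where either gene has zero variance within a condition get r = 0
#' (with a counted warning); a TF that is itself a DEG gets r = 0 against
#' itself in both conditions, so it never contributes to its own target
#' sum.
#'
#' @param vse expression \code{SummarizedExperiment} with assay
#'   \code{"vst"} (see \code{\link{vstExpr}}).
#' @param tf_ids,deg_ids gene ids; must be rows of \code{vse}.
#' @param ref reference condition (condition A, conventionally \code{CON}).
#' @return list with elements \code{rA} and \code{rB} (TF x DEG matrices)
#'   and \code{nZeroVar} (count of zero-variance genes encountered).
#' @export
conditionCorrelations <- function(vse, tf_ids, deg_ids, ref = NULL) {
    expr <- assayMatrix(vse, "vst")
    cond <- conditionFactor(vse, ref)
    if (min(table(cond)) < 3) {
        stop("need >= 3 samples per condition for correlations")
    }
    missing <- setdiff(union(tf_ids, deg_ids), rownames(expr))
    if (length(missing)) {
        stop("ids absent from the expression matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
    }
    out <- list()
    nZero <- 0L
    for (i in 1:2) {
        sub <- expr[, cond == levels(cond)[i], drop = FALSE]
        sdTf <- apply(sub[tf_ids, , drop = FALSE], 1, stats::sd)
        sdDeg <- apply(sub[deg_ids, , drop = FALSE], 1, stats::sd)
        r <- suppressWarnings(
            stats::cor(t(sub[tf_ids, , drop = FALSE]),
                       t(sub[deg_ids, , drop = FALSE])))
        zero <- outer(sdTf == 0, sdDeg == 0, `|`)
        r[zero] <- 0
        nZero <- nZero + sum(sdTf == 0) + sum(sdDeg == 0)
        self <- outer(tf_ids, deg_ids, `==`)
        r[self] <- 0
        dimnames(r) <- list(tf_ids, deg_ids)
        out[[i]] <- r
    }
    if (nZero > 0) {
        warning(nZero, " zero-variance gene(s) in a condition; their ",
                "correlations were set to 0")
    }
    list(rA = out[[1]], rB = out[[2]], nZeroVar = nZero)
}

#' Regulatory impact factors RIF1 and RIF2
#'
#' Scores every tested transcription factor i against the DEG set j by
#' \deqn{RIF1_i = \frac{1}{n_{de}} \sum_j PIF_j \, (dw_{ij})^2, \qquad
#'       RIF2_i = \frac{1}{n_{de}} \sum_j \left[(e^A_j r^A_{ij})^2 -
#'                (e^B_j r^B_{ij})^2\right]}
#' where \eqn{e^A_j, e^B_j} are the DEG's mean variance-stabilized
#' expression per condition, \eqn{a_j = (e^A_j + e^B_j)/2},
#' \eqn{d_j = e^A_j - e^B_j}, the phenotypic impact factor
#' \eqn{PIF_j = a_j d_j}, and the differential wiring
#' \eqn{dw_{ij} = r^A_{ij} - r^B_{ij}} is the change in within-condition
#' TF-DEG correlation. RIF1 rewards regulators that change co-expression
#' with abundant, strongly shifted DEGs; RIF2 rewards regulators whose
#' expression predicts DEG abundance differently in the two conditions.
#' Condition A is the reference (\code{CON}), condition B the other level
#' (\code{VTM}); swapping the labels negates every raw score exactly.
#'
#' Each metric is z-standardized across tested TFs and a TF is flagged
#' significant for a metric when |z| >= \code{z_thr}. TFs in
#' \code{tf_list} that are not rows of \code{vse} are dropped as
#' unexpressed; the list/tested/removed counts are reported in a message
#' and kept in \code{metadata()}.
#'
#' @param vse expression \code{SummarizedExperiment} with assay
#'   \code{"vst"}.
#' @param tf_list character vector of candidate regulator ids (an
#'   AnimalTFDB-style TF list).
#' @param deg_ids character vector of DEG ids (rows of \code{vse}).
#' @param ref reference condition level.
#' @param z_thr significance threshold on |z| (default 1.96).
#' @return a \linkS4class{RIFTable} with one row per tested TF.
#' @examples
#' sim <- simulateCounts(simParams(n_genes = 300, n_tfs = 30, n_modules = 3,
#'     module_size = 8, seed = 2))
#' v <- vstExpr(sim$se)
#' rif <- computeRIF(v, rownames(sim$se)[1:30], degIds(sim$truth))
#' @export
computeRIF <- function(vse, tf_list, deg_ids, ref = NULL, z_thr = 1.96) {
    expr <- assayMatrix(vse, "vst")
    tfTested <- intersect(tf_list, rownames(expr))
    nRemoved <- length(tf_list) - length(tfTested)
    message("RIF: TF list n = ", length(tf_list), "; tested n = ",
            length(tfTested), "; removed as unexpressed n = ", nRemoved)
    if (!length(tfTested)) stop("no TF from the list is expressed")
    deg_ids <- intersect(deg_ids, rownames(expr))
    if (!length(deg_ids)) stop("no DEG is present in the expression matrix")

    cond <- conditionFactor(vse, ref)
    eA <- rowMeans(expr[deg_ids, cond == levels(cond)[1], drop = FALSE])
    eB <- rowMeans(expr[deg_ids, cond == levels(cond)[2], drop = FALSE])
    a <- (eA + eB) / 2
    d <- eA - eB
    pif <- a * d

    cc <- conditionCorrelations(vse, tfTested, deg_ids, ref)
    dw <- cc$rA - cc$rB
    ## self-pairs carry r = 0 already; they are also excluded from n_de
    isSelf <- outer(tfTested, deg_ids, `==`)
    nDe <- length(deg_ids) - rowSums(isSelf)
    if (any(nDe == 0)) stop("a TF has no non-self DEG to score against")

    rif1 <- as.numeric((dw^2 %*% pif) / nDe)
    rif2 <- as.numeric((sweep(cc$rA^2, 2, eA^2, `*`) -
                        sweep(cc$rB^2, 2, eB^2, `*`)) %*%
                       rep(1, length(deg_ids))) / nDe

    zstd <- function(v) {
        s <- stats::sd(v)
        if (!is.finite(s) || s == 0) {
            warning("zero spread in raw RIF scores; all z set to 0")
            return(rep(0, length(v)))
        }
        (v - mean(v)) / s
    }
    z1 <- zstd(rif1)
    z2 <- zstd(rif2)
    res <- S4Vectors::DataFrame(
        rif1Raw = rif1, rif1Z = z1, rif2Raw = rif2, rif2Z = z2,
        significantRif1 = abs(z1) >= z_thr,
        significantRif2 = abs(z2) >= z_thr,
        row.names = tfTested)
    out <- new("RIFTable", res)
    S4Vectors::metadata(out) <- list(
        nTfList = length(tf_list), nTested = length(tfTested),
        nRemoved = nRemoved, nDeg = length(deg_ids), z_thr = z_thr,
        conditionA = levels(cond)[1], conditionB = levels(cond)[2],
        signConvention = paste("d_j = e^A - e^B with A =", levels(cond)[1],
                               "; positive RIF2 means stronger squared",
                               "expression-weighted correlation in A"))
    out
}

#' Ids of TFs significant for either RIF metric
#'
#' @param rif a \linkS4class{RIFTable}.
#' @return character vector of TF ids with |z| >= threshold for RIF1 or
#'   RIF2.
#' @export
significantRifIds <- function(rif) {
    stopifnot(is(rif, "RIFTable"))
    rownames(rif)[rif$significantRif1 | rif$significantRif2]
}
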