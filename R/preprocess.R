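#' Counts per million
#'
#' \code{cpm[g,s] = counts[g,s] / libsize[s] * 1e6} with
#' \code{libsize[s] = sum_g counts[g,s]}.
#'
#' @param se counts \code{SummarizedExperiment} (see
#'   \code{\link{makeCountsSE}}).
#' @return numeric matrix of the same shape as the counts.
#' @export
computeCPM <- function(se) {
    counts <- assayMatrix(se, "counts")
    libsize <- colSums(counts)
    if (any(libsize == 0)) {
        stop("zero library size for sample(s): ",
             paste(colnames(counts)[libsize == 0], collapse = ", "))
    }
    sweep(counts, 2, libsize, `/`) * 1e6
}

#' Remove unexpressed and lowly expressed genes
#'
#' A gene is kept iff it has CPM >= \code{min_cpm} in at least
#' \code{min_samples} samples \emph{and} a total raw count >=
#' \code{min_total}. This is a deterministic, documented stand-in for
#' design-aware expression filters; gene order is preserved. Filtering is
#' idempotent: dropping genes can only shrink library sizes, which raises
#' the CPM of the survivors, so a second pass removes nothing.
#'
#' @param se counts \code{SummarizedExperiment}.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples number of samples that must pass \code{min_cpm};
#'   default: size of the smallest condition group.
#' @param min_total minimum total raw count across all samples (default 15).
#' @return the filtered counts \code{SummarizedExperiment}.
#' @export
filterLowExpressed <- function(se, min_cpm = 1.0, min_samples = NULL,
                               min_total = 15) {
    cond <- conditionFactor(se)
    if (is.null(min_samples)) min_samples <- min(table(cond))
    cpm <- computeCPM(se)
    counts <- assayMatrix(se, "counts")
    keep <- rowSums(cpm >= min_cpm) >= min_samples &
        rowSums(counts) >= min_total
    if (!any(keep)) {
        stop("no gene passes the expression filter; lower min_cpm/min_total")
    }
    se[keep, ]
}

#' Median-of-ratios size factors
#'
#' For each sample s, \code{sf[s]} is the median over genes (restricted to
#' genes with a positive geometric mean across samples) of
#' \code{counts[g,s] / geomean[g]}. This is the classical count-depth
#' normalization for comparing samples with different sequencing depths.
#'
#' @param se counts \code{SummarizedExperiment}.
#' @return named positive numeric vector, one entry per sample.
#' @export
sizeFactorsMoR <- function(se) {
    counts <- assayMatrix(se, "counts")
    logGeo <- rowMeans(log(counts))          # -Inf when any count is zero
    use <- is.finite(logGeo)
    if (!any(use)) {
        stop("no gene has positive counts in every sample; cannot compute ",
             "median-of-ratios size factors")
    }
    sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
        stats::median(exp(log(col) - logGeo[use]))
    })
    stats::setNames(sf, colnames(counts))
}

#' Variance-stabilized expression (shifted log)
#'
#' \code{expr[g,s] = log2(counts[g,s] / sf[s] + 1)}: a closed-form,
#' monotone stand-in for a fitted-dispersion variance-stabilizing
#' transform, adequate for the correlation-based stages downstream. The
#' transform and size factors used are recorded in
#' \code{metadata()$provenance}.
#'
#' @param se counts \code{SummarizedExperiment}.
#' @param sf per-sample positive size factors (default:
#'   \code{\link{sizeFactorsMoR}}).
#' @return a \code{SummarizedExperiment} with assay \code{"vst"}.
#' @export
vstExpr <- function(se, sf = sizeFactorsMoR(se)) {
    counts <- assayMatrix(se, "counts")
    if (length(sf) != ncol(counts)) {
        stop("sf must have one entry per sample")
    }
    if (any(sf <= 0)) stop("size factors must be positive")
    expr <- log2(sweep(counts, 2, sf, `/`) + 1)
    out <- SummarizedExperiment::SummarizedExperiment(
        assays = list(vst = expr),
        colData = SummarizedExperiment::colData(se)
    )
    S4Vectors::metadata(out)$provenance <- list(
        transform = "log2(counts/sf + 1)", sizeFactors = sf)
    out
}
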