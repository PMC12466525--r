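#' @useDynLib CoexRewire, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' First-order partial correlation
#'
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' the correlation between x and y after removing the linear effect of z.
#' Vectorized over its arguments.
#'
#' @param r_xy,r_xz,r_yz direct Pearson correlations in (-1, 1).
#' @return numeric vector of partial correlations.
#' @examples
#' partialCorrelation(0.8, 0.5, 0.5)   # 0.7333...
#' @export
partialCorrelation <- function(r_xy, r_xz, r_yz) {
    if (any(abs(c(r_xz, r_yz)) >= 1)) {
        stop("conditioning correlations must lie strictly inside (-1, 1)")
    }
    den <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
    if (any(den <= 1e-12)) {
        stop("degenerate denominator in partial correlation")
    }
    (r_xy - r_xz * r_yz) / den
}

#' PCIT trio tolerance
#'
#' The local information-theoretic tolerance of the trio \{x, y, z\}:
#' the mean of the three signed ratios of first-order partial to direct
#' correlation,
#' \deqn{\varepsilon = \frac{1}{3}\left(\frac{r_{xy.z}}{r_{xy}} +
#'   \frac{r_{xz.y}}{r_{xz}} + \frac{r_{yz.x}}{r_{yz}}\right).}
#' For an equicorrelated trio with correlation \eqn{\rho} this reduces to
#' \eqn{1/(1+\rho)}. A trio where any direct |r| is at or below 1e-12 is
#' non-informative and returns \code{NA} (it can never eliminate an edge).
#'
#' @param R symmetric correlation matrix.
#' @param x,y,z row/column indices (or rownames) of the trio.
#' @return the tolerance, or \code{NA} for a non-informative trio.
#' @export
trioTolerance <- function(R, x, y, z) {
    rxy <- R[x, y]; rxz <- R[x, z]; ryz <- R[y, z]
    if (any(abs(c(rxy, rxz, ryz)) <= 1e-12)) return(NA_real_)
    pxy <- partialCorrelation(rxy, rxz, ryz)
    pxz <- partialCorrelation(rxz, rxy, ryz)
    pyz <- partialCorrelation(ryz, rxy, rxz)
    (pxy / rxy + pxz / rxz + pyz / ryz) / 3
}

#' PCIT edge significance
#'
#' Applies the PCIT elimination rule to a full correlation matrix: an edge
#' (x, y) is eliminated iff some third gene z exists with
#' \eqn{|r_{xy}| \le |\varepsilon\, r_{xz}|} and
#' \eqn{|r_{xy}| \le |\varepsilon\, r_{yz}|}, with \eqn{\varepsilon} the
#' tolerance of that trio (\code{\link{trioTolerance}}). Surviving edges
#' are flagged significant. The scan is an O(n^3) compiled loop over
#' unordered trios.
#'
#' @param R symmetric correlation matrix with unit diagonal; off-diagonal
#'   entries are clipped to |r| <= 0.999999.
#' @param track_partial also return, per pair, the minimum absolute
#'   first-order partial correlation over all third genes (needed by the
#'   \code{"partial"} magnitude filter; roughly doubles the cost).
#' @return logical adjacency matrix of significant edges (diagonal
#'   \code{FALSE}); if \code{track_partial}, a list with elements
#'   \code{significant} and \code{minAbsPartial}.
#' @export
pcitSignificantEdges <- function(R, track_partial = FALSE) {
    R <- as.matrix(R)
    n <- nrow(R)
    if (n != ncol(R)) stop("R must be square")
    if (max(abs(R - t(R))) > 1e-12) stop("R must be symmetric")
    R <- clipCorrelations(R)
    if (n < 3) {
        warning("fewer than 3 genes: all edges trivially significant")
        sig <- !diag(TRUE, n)
        dimnames(sig) <- dimnames(R)
        if (track_partial) {
            return(list(significant = sig,
                        minAbsPartial = matrix(NA_real_, n, n,
                                               dimnames = dimnames(R))))
        }
        return(sig)
    }
    res <- pcit_core_cpp(R, track_partial)
    dimnames(res$significant) <- dimnames(R)
    if (track_partial) {
        mp <- res$minAbsPartial
        mp[!is.finite(mp)] <- NA_real_
        dimnames(mp) <- dimnames(R)
        return(list(significant = res$significant, minAbsPartial = mp))
    }
    res$significant
}

# Unit diagonal, off-diagonal entries clipped into [-0.999999, 0.999999].
clipCorrelations <- function(R, limit = 0.999999) {
    R[R > limit] <- limit
    R[R < -limit] <- -limit
    diag(R) <- 1
    R
}

#' Per-condition correlation matrix
#'
#' Pearson correlations of variance-stabilized expression across the
#' samples of one condition. Genes with zero variance get r = 0 against
#' everything (counted warning); off-diagonal values are clipped to
#' |r| <= 0.999999 so downstream partial correlations stay defined.
#'
#' @param vse expression \code{SummarizedExperiment} with assay
#'   \code{"vst"}.
#' @param condition the condition label to use.
#' @return symmetric correlation matrix over all genes of \code{vse}.
#' @export
conditionCorrelationMatrix <- function(vse, condition) {
    expr <- assayMatrix(vse, "vst")
    cond <- as.character(SummarizedExperiment::colData(vse)$condition)
    use <- cond == condition
    if (!any(use)) stop("condition '", condition, "' not present")
    if (sum(use) < 3) {
        stop("need >= 3 samples in condition '", condition, "'")
    }
    sub <- expr[, use, drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    R <- suppressWarnings(stats::cor(t(sub)))
    if (any(sds == 0)) {
        warning(sum(sds == 0), " zero-variance gene(s) in condition '",
                condition, "'; correlations set to 0")
        R[sds == 0, ] <- 0
        R[, sds == 0] <- 0
    }
    clipCorrelations(R)
}

#' Build one condition's co-expression network
#'
#' Runs the full per-condition network inference: Pearson correlation
#' matrix on that condition's samples, PCIT edge significance, then edge
#' retention. An edge is retained iff it is PCIT-significant, its
#' correlation magnitude passes \code{r_threshold}, and at least one of
#' its endpoints is in \code{keep_ids} (typically DEGs plus significant
#' RIF TFs). With \code{threshold_on = "direct"} (default) the magnitude
#' filter applies to the direct Pearson r; with \code{"partial"} it
#' applies to the edge's minimum absolute first-order partial correlation
#' across all third genes.
#'
#' @param vse expression \code{SummarizedExperiment} with assay
#'   \code{"vst"}.
#' @param condition condition label to build the network from.
#' @param keep_ids non-empty character vector of anchor genes.
#' @param r_threshold magnitude threshold (default 0.9).
#' @param threshold_on \code{"direct"} or \code{"partial"}; see above.
#' @param gene_cap soft cap on the gene count: above it the cubic PCIT
#'   scan is still run but a hard warning is emitted.
#' @return a \linkS4class{CoexpressionNetwork}.
#' @export
buildConditionNetwork <- function(vse, condition, keep_ids,
                                  r_threshold = 0.9,
                                  threshold_on = c("direct", "partial"),
                                  gene_cap = 5000) {
    threshold_on <- match.arg(threshold_on)
    if (length(keep_ids) == 0) {
        stop("keep_ids is empty: supply DEG and/or significant RIF ids")
    }
    R <- conditionCorrelationMatrix(vse, condition)
    n <- nrow(R)
    if (n > gene_cap) {
        warning("PCIT on ", n, " genes exceeds the configured cap (",
                gene_cap, "); expect a long cubic scan", immediate. = TRUE)
    }
    track <- threshold_on == "partial"
    pc <- pcitSignificantEdges(R, track_partial = track)
    sig <- if (track) pc$significant else pc
    mag <- if (track) {
        mp <- pc$minAbsPartial
        mp[is.na(mp)] <- 0
        mp
    } else {
        abs(R)
    }
    inKeep <- rownames(R) %in% keep_ids
    keepEdge <- sig & mag >= r_threshold &
        (matrix(inKeep, n, n) | matrix(inKeep, n, n, byrow = TRUE))
    keepEdge[lower.tri(keepEdge, diag = TRUE)] <- FALSE
    idx <- which(keepEdge, arr.ind = TRUE)
    g1 <- rownames(R)[idx[, 1]]
    g2 <- rownames(R)[idx[, 2]]
    swap <- g1 > g2
    edges <- data.frame(
        geneX = ifelse(swap, g2, g1),
        geneY = ifelse(swap, g1, g2),
        r = R[idx],
        stringsAsFactors = FALSE)
    edges <- edges[order(edges$geneX, edges$geneY), , drop = FALSE]
    rownames(edges) <- NULL
    new("CoexpressionNetwork", condition = condition, edges = edges,
        nodes = sort(union(edges$geneX, edges$geneY)))
}

#' Write a network edge list as TSV
#'
#' Columns \code{gene_x}, \code{gene_y}, \code{r}, \code{condition}.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param path output file.
#' @param header optional comment lines to prepend (each prefixed
#'   \code{#}).
#' @export
writeEdgeList <- function(net, path, header = character(0)) {
    stopifnot(is(net, "CoexpressionNetwork"))
    ed <- edges(net)
    out <- data.frame(gene_x = ed$geneX, gene_y = ed$geneY, r = ed$r,
                      condition = rep(networkCondition(net),
                                      length.out = nrow(ed)))
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(paste0("# ", header), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export a network to GraphML
#'
#' Thin convenience wrapper around \pkg{igraph} for use with external
#' visualization tools; requires \pkg{igraph} to be installed.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param path output .graphml file.
#' @export
writeGraphML <- function(net, path) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
        stop("GraphML export requires the 'igraph' package")
    }
    ed <- edges(net)
    g <- igraph::graph_from_data_frame(
        ed[, c("geneX", "geneY", "r")], directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}
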