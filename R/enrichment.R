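#' Rank genes for preranked GSEA
#'
#' Per gene, \code{rank = sign(log2FC) * (-log10 p)} with the p-value
#' clamped to at least \code{p_floor} (clamping is reported in a message).
#' Genes are sorted by the statistic, descending; ties are broken
#' lexicographically by gene id so the order is deterministic.
#'
#' @param de a \linkS4class{DEResult}.
#' @param p_floor lower clamp for p-values (default 1e-300).
#' @return named numeric vector (the ranked list), sorted descending.
#' @examples
#' # log2FC = -0.5, p = 0.01  ->  rank = -2
#' @export
rankGenes <- function(de, p_floor = 1e-300) {
    stopifnot(is(de, "DEResult"))
    p <- de$pvalue
    nClamp <- sum(p < p_floor, na.rm = TRUE)
    if (nClamp > 0) {
        message(nClamp, " p-value(s) clamped to the floor ", p_floor)
    }
    p <- pmax(p, p_floor)
    stat <- sign(de$log2FC) * (-log10(p))
    names(stat) <- rownames(de)
    ord <- order(-stat, names(stat), method = "radix")
    stat[ord]
}

## Weighted Kolmogorov-Smirnov enrichment score from hit positions only.
## positions: sorted indices of set members in the ranked list; w: their
## |stat|^weight. Between hits the running sum decays linearly, so its
## extremes occur immediately after a hit or just before the next one;
## scanning those 2m+1 candidates reproduces the full running sum's
## signed maximum deviation in O(m).
esFromHits <- function(positions, w, N) {
    m <- length(positions)
    sw <- sum(w)
    if (sw == 0) stop("all member statistics are zero: undefined hit ",
                      "normalizer in the enrichment score")
    miss <- 1 / (N - m)
    cw <- cumsum(w) / sw
    high <- cw - (positions - seq_len(m)) * miss
    lowBefore <- c(0, cw) - (c(positions, N + 1) - 1 -
                             c(0, seq_len(m))) * miss
    cand <- unname(c(high, lowBefore))
    cand[which.max(abs(cand))]
}

#' GSEA enrichment score and running sum
#'
#' The weighted Kolmogorov-Smirnov statistic of a gene set against a
#' ranked list: walking down the list, hitting a set member increments the
#' running sum by \eqn{|r_g|^{weight} / \sum_{hits} |r_g|^{weight}} and a
#' miss decrements it by \eqn{1/(N - n_{set})}; the enrichment score is the
#' signed maximum deviation from zero.
#'
#' @param ranked named numeric vector sorted descending (see
#'   \code{\link{rankGenes}}).
#' @param set character vector of gene ids; its intersection with the
#'   ranked universe must be non-empty and proper.
#' @param weight exponent on |rank| for hit increments (default 1; 0 gives
#'   the classical KS statistic).
#' @return list with \code{es} (the score) and \code{running} (the full
#'   running-sum profile, one value per ranked gene).
#' @export
enrichmentScore <- function(ranked, set, weight = 1) {
    N <- length(ranked)
    hit <- names(ranked) %in% set
    m <- sum(hit)
    if (m == 0) stop("the set does not intersect the ranked universe")
    if (m == N) stop("the set covers the whole universe")
    w <- abs(ranked[hit])^weight
    if (sum(w) == 0) stop("all member statistics are zero: undefined hit ",
                          "normalizer in the enrichment score")
    steps <- numeric(N)
    steps[hit] <- w / sum(w)
    steps[!hit] <- -1 / (N - m)
    running <- cumsum(steps)
    es <- running[which.max(abs(running))]
    list(es = es, running = running)
}

#' Preranked GSEA with permutation NES
#'
#' For each gene set, computes the enrichment score of its members against
#' the ranked list, then builds a null distribution by gene-label
#' permutation: \code{n_perm} random sets of the same size drawn from the
#' ranked universe. The normalized enrichment score is
#' \deqn{NES = ES / \mathrm{mean}(|ES^*|)}
#' over permutation scores of the same sign as ES, and the nominal p-value
#' is the add-one-smoothed fraction of same-sign permutations with
#' \eqn{|ES^*| \ge |ES|}. A set is flagged significant when
#' \eqn{p \le p_{thr}} and \eqn{|NES| \ge nes_{thr}}. Sets with no
#' same-sign permutation get \code{NA} NES and are flagged undefined.
#' Benjamini-Hochberg FDR is computed across sets with defined p.
#'
#' @param ranked named numeric vector sorted descending.
#' @param sets named list of character vectors (e.g. from
#'   \code{\link{readGMT}} or \code{\link{plantGeneSets}}).
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @param weight hit-increment exponent (default 1).
#' @param p_thr,nes_thr significance rule (defaults 0.1 and 1.5).
#' @param min_size sets with a smaller intersection with the universe are
#'   dropped (with a message); default 2.
#' @return data.frame, one row per usable set: \code{set}, \code{size},
#'   \code{es}, \code{nes}, \code{pvalue}, \code{fdr}, \code{nesDefined},
#'   \code{significant}, \code{leadingEdge} (comma-separated ids).
#' @export
gseaPrerank <- function(ranked, sets, n_perm = 1000, seed = 1, weight = 1,
                        p_thr = 0.1, nes_thr = 1.5, min_size = 2) {
    N <- length(ranked)
    universe <- names(ranked)
    absw <- abs(ranked)^weight
    keep <- vapply(sets, function(s) {
        k <- sum(universe %in% s)
        k >= min_size && k < N
    }, logical(1))
    if (any(!keep)) {
        message(sum(!keep), " set(s) dropped: empty, too small, or ",
                "covering the whole universe")
    }
    sets <- sets[keep]
    if (!length(sets)) stop("no usable gene set")

    set.seed(fanSeed(seed, 21L))
    rows <- lapply(names(sets), function(nm) {
        hit <- which(universe %in% sets[[nm]])
        m <- length(hit)
        prof <- enrichmentScore(ranked, sets[[nm]], weight)
        es <- prof$es
        ## gene-label permutations: same-size random sets
        esPerm <- vapply(seq_len(n_perm), function(i) {
            pos <- sort(sample.int(N, m))
            w <- absw[pos]
            if (sum(w) == 0) return(NA_real_)
            esFromHits(pos, w, N)
        }, numeric(1))
        esPerm <- esPerm[!is.na(esPerm)]
        same <- esPerm[sign(esPerm) == sign(es)]
        if (length(same) == 0 || es == 0) {
            nes <- NA_real_
            p <- NA_real_
        } else {
            nes <- es / mean(abs(same))
            p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
        }
        peak <- which.max(abs(prof$running))
        le <- if (es >= 0) {
            universe[intersect(seq_len(peak), hit)]
        } else {
            universe[intersect(seq(peak, N), hit)]
        }
        data.frame(set = nm, size = m, es = es, nes = nes, pvalue = p,
                   nesDefined = !is.na(nes),
                   leadingEdge = paste(le, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$fdr <- NA_real_
    ok <- !is.na(res$pvalue)
    res$fdr[ok] <- stats::p.adjust(res$pvalue[ok], method = "BH")
    res$significant <- ok & res$pvalue <= p_thr & abs(res$nes) >= nes_thr
    res <- res[, c("set", "size", "es", "nes", "pvalue", "fdr",
                   "nesDefined", "significant", "leadingEdge")]
    rownames(res) <- NULL
    res
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the one-sided upper-tail hypergeometric p-value of
#' the overlap between \code{test_ids} and the set, both restricted to
#' \code{universe_ids}; Benjamini-Hochberg FDR across sets. Sets disjoint
#' from the universe are excluded with a message.
#'
#' @param test_ids gene list of interest (e.g. DEGs); must be a subset of
#'   the universe.
#' @param universe_ids background universe (e.g. all expressed genes).
#' @param sets named list of character vectors.
#' @param fdr_thr significance threshold on FDR (default 0.05).
#' @return data.frame per tested set: \code{set}, \code{setSize} (in
#'   universe), \code{listSize}, \code{overlap}, \code{expected},
#'   \code{pvalue}, \code{fdr}, \code{significant}.
#' @export
ora <- function(test_ids, universe_ids, sets, fdr_thr = 0.05) {
    universe_ids <- unique(universe_ids)
    if (!length(universe_ids)) stop("empty universe")
    test_ids <- unique(test_ids)
    if (!all(test_ids %in% universe_ids)) {
        stop("test_ids must be a subset of universe_ids")
    }
    Nu <- length(universe_ids)
    nL <- length(test_ids)
    sizes <- vapply(sets, function(s) sum(universe_ids %in% s), integer(1))
    if (any(sizes == 0)) {
        message(sum(sizes == 0), " set(s) disjoint from the universe ",
                "excluded")
    }
    sets <- sets[sizes > 0]
    sizes <- sizes[sizes > 0]
    if (!length(sets)) stop("no set overlaps the universe")
    ov <- vapply(sets, function(s) sum(test_ids %in% s), integer(1))
    p <- stats::phyper(ov - 1, sizes, Nu - sizes, nL, lower.tail = FALSE)
    fdr <- stats::p.adjust(p, method = "BH")
    data.frame(set = names(sets), setSize = sizes, listSize = nL,
               overlap = ov, expected = nL * sizes / Nu,
               pvalue = p, fdr = fdr, significant = fdr <= fdr_thr,
               row.names = NULL, stringsAsFactors = FALSE)
}
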