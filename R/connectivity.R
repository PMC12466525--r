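#' Node degrees of a co-expression network
#'
#' Number of retained edges incident to each gene. Genes listed in
#' \code{genes} but absent from the network get degree 0, which is how the
#' two condition networks are brought onto a common gene universe before
#' differential connectivity.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param genes optional character vector defining the output universe
#'   (default: the network's own node set).
#' @return named integer vector of degrees.
#' @export
nodeDegrees <- function(net, genes = NULL) {
    stopifnot(is(net, "CoexpressionNetwork"))
    if (is.null(genes)) genes <- nodes(net)
    ed <- edges(net)
    k <- table(factor(c(ed$geneX, ed$geneY), levels = genes))
    stats::setNames(as.integer(k), genes)
}

#' Differential connectivity between two condition networks
#'
#' Per gene over the union of both node sets, the degree K in each network
#' is max-normalized to \eqn{k = K / \max(K)} (k = 0 throughout for an
#' empty network), the differential connectivity is
#' \deqn{DK = k_{VTM} - k_{CON},}
#' and DK is z-scored across genes. A gene is classified \code{"gained"}
#' when \eqn{z \ge z_{thr}}, \code{"lost"} when \eqn{z \le -z_{thr}}, else
#' \code{"unchanged"}. Swapping the two networks negates DK and z exactly
#' and exchanges the gained/lost classes.
#'
#' @param kCon,kVtm named integer degree vectors (from
#'   \code{\link{nodeDegrees}}) for the reference (CON) and contrast (VTM)
#'   networks; names may differ, the union is used.
#' @param z_thr significance threshold on |z| (default 1.96).
#' @return a \linkS4class{ConnectivityTable} with columns \code{kConRaw},
#'   \code{kVtmRaw}, \code{kCon}, \code{kVtm}, \code{dk}, \code{dkZ},
#'   \code{class}, \code{inCon}, \code{inVtm}.
#' @examples
#' differentialConnectivity(c(g1 = 4L, g2 = 2L), c(g1 = 1L, g2 = 4L))
#' @export
differentialConnectivity <- function(kCon, kVtm, z_thr = 1.96) {
    genes <- sort(union(names(kCon), names(kVtm)))
    if (!length(genes)) stop("both degree vectors are empty and unnamed")
    full <- function(k) {
        v <- stats::setNames(integer(length(genes)), genes)
        v[names(k)] <- as.integer(k)
        v
    }
    KC <- full(kCon)
    KV <- full(kVtm)
    norm <- function(K) if (max(K) > 0) K / max(K) else K * 0
    kc <- norm(KC)
    kv <- norm(KV)
    dk <- kv - kc
    s <- stats::sd(dk)
    if (!is.finite(s) || s == 0) {
        warning("zero spread in DK; all z set to 0, all genes unchanged")
        z <- rep(0, length(dk))
    } else {
        z <- (dk - mean(dk)) / s
    }
    cls <- ifelse(z >= z_thr, "gained", ifelse(z <= -z_thr, "lost",
                                               "unchanged"))
    res <- S4Vectors::DataFrame(
        kConRaw = KC, kVtmRaw = KV, kCon = kc, kVtm = kv,
        dk = dk, dkZ = z, class = cls,
        inCon = KC > 0, inVtm = KV > 0, row.names = genes)
    out <- new("ConnectivityTable", res)
    S4Vectors::metadata(out) <- list(z_thr = z_thr,
                                     nGained = sum(cls == "gained"),
                                     nLost = sum(cls == "lost"))
    out
}
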