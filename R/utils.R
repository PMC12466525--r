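## Internal helpers: seed fan-out, hashing, condition handling.

# Counter-based child seeds: independent of call order, stable across R
# versions, always < 2^31 so they are valid set.seed() inputs.
fanSeed <- function(seed, counter) {
    stopifnot(length(seed) == 1, is.finite(seed))
    x <- (as.double(seed) %% 2147483647) + 1
    for (c in counter) {
        x <- (x * 48271 + as.double(c) * 7919 + 1) %% 2147483647
    }
    as.integer(x)
}

# FNV-1a 32-bit hash of a string, returned as 8 hex digits. Used to stamp
# pipeline outputs with a configuration fingerprint without extra deps.
fnv1a <- function(x) {
    bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
    h <- 2166136261
    for (b in bytes) {
        h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30
        h <- (h * 16777619) %% 2^32
    }
    sprintf("%08x", as.integer(h %% 2^31))
}

# Extract and check the two-level condition factor from a counts/expression
# SummarizedExperiment. Returns a factor whose first level is the reference.
conditionFactor <- function(se, ref = NULL) {
    cd <- SummarizedExperiment::colData(se)
    if (!"condition" %in% names(cd)) {
        stop("colData(se) must contain a 'condition' column")
    }
    cond <- as.character(cd$condition)
    lev <- unique(cond)
    if (length(lev) != 2) {
        stop("exactly two condition levels are required, found: ",
             paste(lev, collapse = ", "))
    }
    if (is.null(ref)) {
        f <- SummarizedExperiment::colData(se)$condition
        ref <- if (is.factor(f)) levels(f)[1] else sort(lev)[1]
    }
    if (!ref %in% lev) stop("reference level '", ref, "' not present")
    factor(cond, levels = c(ref, setdiff(lev, ref)))
}

assayMatrix <- function(se, name) {
    if (!name %in% SummarizedExperiment::assayNames(se)) {
        stop("assay '", name, "' not found in the SummarizedExperiment")
    }
    as.matrix(SummarizedExperiment::assay(se, name))
}

#' Assemble a counts SummarizedExperiment
#'
#' Wraps an integer count matrix and its two-level condition labels into the
#' \code{SummarizedExperiment} all pipeline stages consume. The first factor
#' level of \code{condition} is treated as the reference (by convention
#' \code{CON}); set it explicitly with \code{ref}.
#'
#' @param counts integer matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param condition character/factor of length \code{ncol(counts)} with
#'   exactly two levels.
#' @param ref reference condition level (default: first factor level, or the
#'   alphabetically first label).
#' @return a \code{SummarizedExperiment} with assay \code{"counts"}.
#' @examples
#' m <- matrix(rpois(24, 50), 4, 6,
#'     dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
#' se <- makeCountsSE(m, rep(c("CON", "VTM"), each = 3))
#' @export
makeCountsSE <- function(counts, condition, ref = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
        stop("counts must have unique rownames (gene ids)")
    }
    if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
        stop("counts must have unique colnames (sample ids)")
    }
    if (any(counts < 0) || any(counts != round(counts))) {
        stop("counts must be non-negative integers")
    }
    if (length(condition) != ncol(counts)) {
        stop("condition must have one entry per sample")
    }
    lev <- unique(as.character(condition))
    if (length(lev) != 2) stop("exactly two condition levels are required")
    if (is.null(ref)) {
        ref <- if (is.factor(condition)) levels(condition)[1] else sort(lev)[1]
    }
    cond <- factor(as.character(condition), levels = c(ref, setdiff(lev, ref)))
    if (min(table(cond)) < 2) stop("need >= 2 samples per condition")
    storage.mode(counts) <- "integer"
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(condition = cond,
                                       row.names = colnames(counts))
    )
}
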