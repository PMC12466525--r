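#' Read a counts table
#'
#' Two formats are supported. \code{"tsv"}: a tab-separated table, first
#' column gene ids, header row of sample ids, integer counts. \code{"mtx"}:
#' a MatrixMarket sparse matrix plus two side files with one gene id
#' (\code{rows_path}) and one sample id (\code{cols_path}) per line.
#' \code{"auto"} picks by file extension. Lines starting with \code{#} in
#' the TSV are ignored.
#'
#' @param path counts file.
#' @param format \code{"auto"}, \code{"tsv"} or \code{"mtx"}.
#' @param rows_path,cols_path id side files (MTX only; default
#'   \code{<path>.rows} / \code{<path>.cols}).
#' @return integer matrix with gene rownames and sample colnames. Combine
#'   with metadata via \code{\link{makeCountsSE}}.
#' @export
readCounts <- function(path, format = c("auto", "tsv", "mtx"),
                       rows_path = paste0(path, ".rows"),
                       cols_path = paste0(path, ".cols")) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
                  else "tsv"
    }
    if (format == "mtx") {
        m <- as.matrix(Matrix::readMM(path))
        rn <- readLines(rows_path)
        cn <- readLines(cols_path)
        if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
            stop("id side files do not match the matrix dimensions")
        }
        dimnames(m) <- list(rn, cn)
    } else {
        tab <- utils::read.table(path, header = TRUE, sep = "\t",
                                 comment.char = "#", check.names = FALSE,
                                 stringsAsFactors = FALSE)
        ids <- as.character(tab[[1]])
        m <- as.matrix(tab[, -1, drop = FALSE])
        rownames(m) <- ids
    }
    dup <- which(duplicated(rownames(m)))
    if (length(dup)) {
        stop("duplicate gene id '", rownames(m)[dup[1]], "' at data line ",
             dup[1])
    }
    if (anyDuplicated(colnames(m))) stop("duplicate sample ids in header")
    if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
        stop("counts must be finite non-negative integers")
    }
    storage.mode(m) <- "integer"
    m
}

#' Write a counts matrix (or any gene-by-sample table) as TSV
#'
#' First column \code{gene}, then one column per sample. Optional
#' \code{#}-prefixed comment lines carry provenance.
#'
#' @param m matrix with rownames and colnames.
#' @param path output file.
#' @param header optional comment lines.
#' @export
writeCountsTSV <- function(m, path, header = character(0)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(paste0("# ", header), con)
    tab <- data.frame(gene = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated with columns \code{sample} and \code{condition}; exactly
#' two condition levels are required.
#'
#' @param path metadata file.
#' @return data.frame with columns \code{sample}, \code{condition}.
#' @export
readMetadata <- function(path) {
    md <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#",
                            stringsAsFactors = FALSE)
    if (!all(c("sample", "condition") %in% names(md))) {
        stop("metadata must have columns 'sample' and 'condition'")
    }
    if (anyDuplicated(md$sample)) stop("duplicate sample ids in metadata")
    if (length(unique(md$condition)) != 2) {
        stop("metadata must contain exactly two condition levels")
    }
    md[, c("sample", "condition")]
}

#' Read a transcription-factor list
#'
#' One gene id per line; blank lines and \code{#} comments are skipped.
#'
#' @param path list file.
#' @return character vector of TF ids.
#' @export
readTFList <- function(path) {
    ln <- trimws(readLines(path))
    keep <- nzchar(ln) & !startsWith(ln, "#")
    ids <- ln[keep]
    dup <- which(duplicated(ids))
    if (length(dup)) {
        stop("duplicate TF id '", ids[dup[1]], "' at line ",
             which(keep)[dup[1]])
    }
    ids
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: per line a set name, a description, then
#' the member gene ids. Lines with fewer than three fields or duplicate
#' set names raise an error naming the line.
#'
#' @param path GMT file.
#' @return named list of character vectors with a \code{"descriptions"}
#'   attribute.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3)) {
        stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
    }
    nm <- vapply(parts, `[[`, character(1), 1)
    dup <- which(duplicated(nm))
    if (length(dup)) {
        stop("duplicate set name '", nm[dup[1]], "' at GMT line ", dup[1])
    }
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- nm
    if (any(lengths(sets) == 0)) {
        stop("GMT line ", which(lengths(sets) == 0)[1], " has no members")
    }
    attr(sets, "descriptions") <-
        stats::setNames(vapply(parts, `[[`, character(1), 2), nm)
    sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors; an optional
#'   \code{"descriptions"} attribute (named character) fills the second
#'   GMT column, which otherwise repeats the set name.
#' @param path output file.
#' @export
writeGMT <- function(sets, path) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
        stop("sets must have unique names")
    }
    desc <- attr(sets, "descriptions")
    lines <- vapply(names(sets), function(nm) {
        d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else nm
        paste(c(nm, d, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
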