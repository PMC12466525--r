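#' Pipeline configuration
#'
#' Validated flat configuration for \code{\link{runPipeline}}. Unknown
#' names are rejected so typos fail fast. The reference condition (which
#' label plays the role of \code{CON}) is always taken from the config,
#' never inferred from the data.
#'
#' @param counts,metadata,tf_list,gmt,outdir input paths and the output
#'   directory.
#' @param ref_condition reference condition label (default \code{"CON"}).
#' @param p_thr,lfc_thr DEG thresholds (raw p and |log2FC|).
#' @param rif_z,dk_z z-score thresholds for RIF and DK significance.
#' @param r_threshold network edge magnitude threshold.
#' @param threshold_on \code{"direct"} or \code{"partial"}: which
#'   correlation the magnitude filter applies to (see
#'   \code{\link{buildConditionNetwork}}).
#' @param dk_population \code{"union"} (z-score DK over the union of both
#'   node sets) or \code{"keep"} (restrict to DEG/RIF anchor genes).
#' @param nes_thr,gsea_p,ora_fdr enrichment significance rules.
#' @param n_perm GSEA permutation count.
#' @param min_cpm,min_samples,min_total expression filter controls
#'   (\code{min_samples = NA} means the smallest group size).
#' @param pcit_gene_cap warn when PCIT is asked to scan more genes.
#' @param seed master seed for every stochastic stage.
#' @return a \code{PipelineConfig} (a validated named list).
#' @export
pipelineConfig <- function(counts, metadata, tf_list, gmt, outdir,
                           ref_condition = "CON",
                           p_thr = 0.05, lfc_thr = 0.5,
                           rif_z = 1.96, dk_z = 1.96,
                           r_threshold = 0.9,
                           threshold_on = c("direct", "partial"),
                           dk_population = c("union", "keep"),
                           nes_thr = 1.5, gsea_p = 0.1, ora_fdr = 0.05,
                           n_perm = 1000,
                           min_cpm = 1.0, min_samples = NA,
                           min_total = 15,
                           pcit_gene_cap = 5000, seed = 1) {
    cfg <- list(counts = counts, metadata = metadata, tf_list = tf_list,
                gmt = gmt, outdir = outdir, ref_condition = ref_condition,
                p_thr = p_thr, lfc_thr = lfc_thr, rif_z = rif_z,
                dk_z = dk_z, r_threshold = r_threshold,
                threshold_on = match.arg(threshold_on),
                dk_population = match.arg(dk_population),
                nes_thr = nes_thr, gsea_p = gsea_p, ora_fdr = ora_fdr,
                n_perm = n_perm, min_cpm = min_cpm,
                min_samples = min_samples, min_total = min_total,
                pcit_gene_cap = pcit_gene_cap, seed = seed)
    thr <- c("p_thr", "lfc_thr", "rif_z", "dk_z", "r_threshold",
             "nes_thr", "gsea_p", "ora_fdr", "n_perm", "min_cpm",
             "min_total", "pcit_gene_cap")
    for (nm in thr) {
        if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 ||
            cfg[[nm]] <= 0) {
            stop("config field '", nm, "' must be a positive number")
        }
    }
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a flat key=value config file into a PipelineConfig
#'
#' One \code{key = value} pair per line; \code{#} comments allowed.
#' Unknown keys are rejected. Values are parsed as numbers when possible.
#'
#' @param path config file.
#' @param ... overrides applied after the file (e.g. \code{seed}).
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path, ...) {
    ln <- trimws(readLines(path))
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    kv <- strsplit(ln, "=", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) stop("malformed config line: ", ln[which(bad)[1]])
    keys <- trimws(vapply(kv, `[[`, character(1), 1))
    vals <- trimws(vapply(kv, `[[`, character(1), 2))
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(keys, known)
    if (length(unknown)) {
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    args <- stats::setNames(as.list(vals), keys)
    num <- suppressWarnings(lapply(args, as.numeric))
    args <- mapply(function(v, n) if (!is.na(n)) n else v, args, num,
                   SIMPLIFY = FALSE)
    args <- utils::modifyList(args, list(...))
    do.call(pipelineConfig, args)
}

stageWrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
        stop("pipeline aborted at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
    })
}

#' Run the full differential co-expression pipeline
#'
#' Executes, in order: expression filtering and normalization, the NB Wald
#' differential expression test, RIF1/RIF2 regulator scoring, PCIT network
#' inference for each condition, differential connectivity, and ORA plus
#' preranked GSEA against the supplied gene sets. Every stage writes its
#' table under \code{outdir} with a \code{#}-comment header carrying the
#' config hash and seed, and a JSON run manifest records versions, the
#' seed, the config hash, warning counts and every per-stage count
#' (genes kept, DEGs by direction, TFs tested/significant by metric,
#' edges and nodes per network, shared and unique nodes, DK genes gained
#' and lost). If a stage fails, the run aborts with the stage name and the
#' manifest collected so far is written with a \code{.partial} suffix.
#'
#' @param config a \code{PipelineConfig} from \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the stage results (\code{se},
#'   \code{de}, \code{degs}, \code{rif}, \code{netCon}, \code{netVtm},
#'   \code{dk}, \code{oraRes}, \code{gseaRes}, \code{manifest}).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    ## fingerprint the analysis parameters; the output location is not part
    ## of the analysis identity
    hashed <- config[setdiff(names(config), "outdir")]
    cfgHash <- fnv1a(paste(names(hashed), vapply(hashed, paste,
                                                 character(1)),
                           sep = "=", collapse = ";"))
    hdr <- c(paste0("config_hash: ", cfgHash),
             paste0("seed: ", config$seed))
    manifest <- list(
        package = "CoexRewire",
        version = as.character(utils::packageVersion("CoexRewire")),
        r_version = as.character(getRversion()),
        seed = config$seed, config_hash = cfgHash,
        counts = list(), warnings = list())
    warnCount <- new.env()
    countWarn <- function(expr, key) {
        withCallingHandlers(expr, warning = function(w) {
            n <- mget(key, warnCount, ifnotfound = 0L)[[1]]
            assign(key, n + 1L, warnCount)
            invokeRestart("muffleWarning")
        })
    }
    outPath <- function(f) file.path(config$outdir, f)
    finish <- function(partial = FALSE) {
        manifest$warnings <- as.list(warnCount)
        nm <- if (partial) "manifest.json.partial" else "manifest.json"
        jsonlite::write_json(manifest, outPath(nm), auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        manifest
    }
    on.exit(finish(partial = TRUE))

    ## ---- load + preprocess -------------------------------------------
    se <- stageWrap("preprocess", {
        m <- readCounts(config$counts)
        md <- readMetadata(config$metadata)
        if (!setequal(md$sample, colnames(m))) {
            stop("metadata samples do not match counts columns")
        }
        md <- md[match(colnames(m), md$sample), ]
        if (!config$ref_condition %in% md$condition) {
            stop("ref_condition '", config$ref_condition,
                 "' absent from metadata")
        }
        makeCountsSE(m, md$condition, ref = config$ref_condition)
    })
    manifest$counts$genes_input <- nrow(se)
    manifest$counts$samples <- ncol(se)
    fse <- stageWrap("preprocess", {
        ms <- if (is.na(config$min_samples)) NULL else config$min_samples
        filterLowExpressed(se, min_cpm = config$min_cpm,
                           min_samples = ms,
                           min_total = config$min_total)
    })
    manifest$counts$genes_kept <- nrow(fse)
    sf <- stageWrap("preprocess", sizeFactorsMoR(fse))
    vse <- stageWrap("preprocess", vstExpr(fse, sf))
    writeCountsTSV(assayMatrix(fse, "counts"), outPath("filtered_counts.tsv"),
                   hdr)
    sfCon <- file(outPath("size_factors.tsv"), "w")
    writeLines(paste0("# ", hdr), sfCon)
    utils::write.table(data.frame(sample = names(sf), size_factor = sf),
                       sfCon, sep = "\t", quote = FALSE, row.names = FALSE)
    close(sfCon)
    writeCountsTSV(assayMatrix(vse, "vst"), outPath("expression_vst.tsv"),
                   hdr)

    ## ---- differential expression -------------------------------------
    de <- stageWrap("diffexpr", countWarn(
        nbWaldTest(fse, sf, ref = config$ref_condition,
                   p_thr = config$p_thr, lfc_thr = config$lfc_thr),
        "nonconverged_glm"))
    degs <- callDEGs(de, config$p_thr, config$lfc_thr)
    manifest$counts$degs <- nrow(degs)
    manifest$counts$degs_up <- sum(degs$direction == "up")
    manifest$counts$degs_down <- sum(degs$direction == "down")
    deTab <- data.frame(gene = rownames(de), as.data.frame(de))
    con <- file(outPath("de_table.tsv"), "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.table(deTab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)

    ## ---- RIF ----------------------------------------------------------
    rif <- stageWrap("rif", {
        if (!file.exists(config$tf_list)) {
            stop("TF list file not found: ", config$tf_list)
        }
        tfs <- readTFList(config$tf_list)
        if (nrow(degs) == 0) stop("no DEG to score regulators against")
        countWarn(computeRIF(vse, tfs, degs$gene,
                             ref = config$ref_condition,
                             z_thr = config$rif_z), "rif_zero_variance")
    })
    rifSig <- significantRifIds(rif)
    manifest$counts$tfs_list <- S4Vectors::metadata(rif)$nTfList
    manifest$counts$tfs_tested <- S4Vectors::metadata(rif)$nTested
    manifest$counts$tfs_removed_unexpressed <-
        S4Vectors::metadata(rif)$nRemoved
    manifest$counts$tfs_significant_rif1 <- sum(rif$significantRif1)
    manifest$counts$tfs_significant_rif2 <- sum(rif$significantRif2)
    manifest$counts$tfs_significant_any <- length(rifSig)
    rifTab <- data.frame(gene = rownames(rif), as.data.frame(rif))
    con <- file(outPath("rif_table.tsv"), "w")
    writeLines(paste0("# ", c(hdr, S4Vectors::metadata(rif)$signConvention)),
               con)
    utils::write.table(rifTab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)

    ## ---- PCIT networks ------------------------------------------------
    keepIds <- union(degs$gene, rifSig)
    cond <- conditionFactor(vse, config$ref_condition)
    condA <- levels(cond)[1]
    condB <- levels(cond)[2]
    nets <- list()
    for (cc in c(condA, condB)) {
        nets[[cc]] <- stageWrap("pcit", countWarn(
            buildConditionNetwork(vse, cc, keepIds,
                                  r_threshold = config$r_threshold,
                                  threshold_on = config$threshold_on,
                                  gene_cap = config$pcit_gene_cap),
            "pcit_warnings"))
        writeEdgeList(nets[[cc]],
                      outPath(sprintf("network_%s_edges.tsv", cc)), hdr)
    }
    netCon <- nets[[condA]]
    netVtm <- nets[[condB]]
    manifest$counts$edges_con <- nrow(edges(netCon))
    manifest$counts$edges_vtm <- nrow(edges(netVtm))
    manifest$counts$nodes_con <- length(nodes(netCon))
    manifest$counts$nodes_vtm <- length(nodes(netVtm))
    manifest$counts$nodes_shared <-
        length(intersect(nodes(netCon), nodes(netVtm)))
    manifest$counts$nodes_unique_con <-
        length(setdiff(nodes(netCon), nodes(netVtm)))
    manifest$counts$nodes_unique_vtm <-
        length(setdiff(nodes(netVtm), nodes(netCon)))

    ## ---- differential connectivity ------------------------------------
    dk <- stageWrap("dk", {
        uni <- union(nodes(netCon), nodes(netVtm))
        if (config$dk_population == "keep") {
            uni <- intersect(uni, keepIds)
        }
        if (!length(uni)) stop("both networks are empty")
        countWarn(differentialConnectivity(
            nodeDegrees(netCon, uni), nodeDegrees(netVtm, uni),
            z_thr = config$dk_z), "dk_warnings")
    })
    manifest$counts$dk_genes <- sum(dk$class != "unchanged")
    manifest$counts$dk_gained <- sum(dk$class == "gained")
    manifest$counts$dk_lost <- sum(dk$class == "lost")
    dkTab <- data.frame(gene = rownames(dk), as.data.frame(dk))
    names(dkTab) <- c("gene", "K_con", "K_vtm", "k_con", "k_vtm", "dk",
                      "dk_z", "class", "in_con", "in_vtm")
    con <- file(outPath("connectivity.tsv"), "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.table(dkTab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)

    ## ---- enrichment ----------------------------------------------------
    sets <- stageWrap("enrichment", readGMT(config$gmt))
    oraRes <- stageWrap("ora", {
        if (nrow(degs) == 0) stop("no DEG for over-representation")
        ora(degs$gene, rownames(fse), sets, fdr_thr = config$ora_fdr)
    })
    gseaRes <- stageWrap("gsea", {
        ranked <- rankGenes(de)
        gseaPrerank(ranked, sets, n_perm = config$n_perm,
                    seed = config$seed, p_thr = config$gsea_p,
                    nes_thr = config$nes_thr)
    })
    manifest$counts$ora_sets_tested <- nrow(oraRes)
    manifest$counts$ora_significant <- sum(oraRes$significant)
    manifest$counts$gsea_sets_tested <- nrow(gseaRes)
    manifest$counts$gsea_significant <- sum(gseaRes$significant)
    for (nm in c("ora", "gsea")) {
        tab <- if (nm == "ora") oraRes else gseaRes
        con <- file(outPath(paste0(nm, "_results.tsv")), "w")
        writeLines(paste0("# ", hdr), con)
        utils::write.table(tab, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
    }

    on.exit()
    manifest <- finish(partial = FALSE)
    invisible(list(se = fse, de = de, degs = degs, rif = rif,
                   netCon = netCon, netVtm = netVtm, dk = dk,
                   oraRes = oraRes, gseaRes = gseaRes,
                   manifest = manifest))
}

#' Write a simulated experiment to disk
#'
#' Materializes a \code{\link{simulateCounts}} result as the plain-text
#' files \code{\link{runPipeline}} consumes: counts TSV, metadata TSV, a
#' TF list (all simulated TF ids), truth tables, and a GMT of planted plus
#' random gene sets.
#'
#' @param sim list from \code{\link{simulateCounts}}.
#' @param dir output directory (created if needed).
#' @param n_random_sets decoy sets for the GMT (see
#'   \code{\link{plantGeneSets}}).
#' @return named list of the written paths.
#' @export
writeSimulatedExperiment <- function(sim, dir, n_random_sets = 50) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    counts <- assayMatrix(sim$se, "counts")
    writeCountsTSV(counts, p("counts.tsv"))
    md <- data.frame(
        sample = colnames(counts),
        condition = as.character(
            SummarizedExperiment::colData(sim$se)$condition))
    utils::write.table(md, p("metadata.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tfs <- grep("^TF", rownames(counts), value = TRUE)
    writeLines(tfs, p("tf_list.txt"))
    truth <- sim$truth
    utils::write.table(
        data.frame(gene = degIds(truth), log2FC = degLfc(truth)),
        p("truth_degs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(tf = names(moduleMap(truth)),
                   rewired = names(moduleMap(truth)) %in%
                       rewiredTfIds(truth),
                   coupling_A = truth@couplingA,
                   coupling_B = truth@couplingB,
                   targets = vapply(moduleMap(truth), paste,
                                    character(1), collapse = ",")),
        p("truth_modules.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    sets <- plantGeneSets(truth, n_random_sets = n_random_sets,
                          seed = truth@params@seed)
    writeGMT(sets, p("gene_sets.gmt"))
    list(counts = p("counts.tsv"), metadata = p("metadata.tsv"),
         tf_list = p("tf_list.txt"), gmt = p("gene_sets.gmt"),
         truth_degs = p("truth_degs.tsv"),
         truth_modules = p("truth_modules.tsv"))
}
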