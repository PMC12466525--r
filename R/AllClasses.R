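#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Parameters of the two-condition count simulator
#'
#' Describes a synthetic bulk RNA-seq experiment with two conditions
#' (labelled \code{CON} and \code{VTM}), negative-binomial counts, a planted
#' fraction of differentially expressed genes, and transcription-factor (TF)
#' modules whose TF--target coupling may differ between the conditions
#' (regulatory rewiring). Build instances with \code{\link{simParams}}.
#'
#' @slot nGenes total number of genes.
#' @slot nTfs number of transcription factors among the genes.
#' @slot nSamplesPerCondition samples per condition (the design is balanced).
#' @slot nModules number of TF-anchored co-expression modules.
#' @slot moduleSize number of target genes per module (targets are disjoint
#'   from their TF and across modules).
#' @slot couplingA,couplingB per-module TF--target coupling in [0,1) for the
#'   CON (A) and VTM (B) condition; scalars are recycled over modules.
#' @slot fracDeg fraction of genes (outside rewired-module targets) that
#'   receive a planted log2 fold change.
#' @slot lfcRange length-2 numeric, min and max |log2FC| of planted DEGs.
#' @slot dispersionShape,dispersionRate gamma shape/rate for per-gene NB
#'   dispersion alpha.
#' @slot meanLogMu,sdLogMu normal parameters of the per-gene baseline
#'   natural-log mean count.
#' @slot libSizeRange length-2 numeric, uniform range of relative per-sample
#'   library-size multipliers.
#' @slot signalSd natural-log standard deviation of the latent module signal.
#' @slot seed integer master seed; all stage seeds are derived from it.
#'
#' @seealso \code{\link{simParams}}, \code{\link{simulateCounts}}
#' @exportClass SimulationParams
setClass("SimulationParams",
    representation(
        nGenes = "numeric", nTfs = "numeric",
        nSamplesPerCondition = "numeric",
        nModules = "numeric", moduleSize = "numeric",
        couplingA = "numeric", couplingB = "numeric",
        fracDeg = "numeric", lfcRange = "numeric",
        dispersionShape = "numeric", dispersionRate = "numeric",
        meanLogMu = "numeric", sdLogMu = "numeric",
        libSizeRange = "numeric", signalSd = "numeric",
        seed = "numeric"
    )
)

setValidity("SimulationParams", function(object) {
    msg <- character(0)
    cnt <- c(
        nGenes = object@nGenes, nTfs = object@nTfs,
        nSamplesPerCondition = object@nSamplesPerCondition,
        nModules = object@nModules, moduleSize = object@moduleSize
    )
    if (any(cnt < 1) || any(cnt != round(cnt))) {
        msg <- c(msg, "count fields must be integers >= 1")
    }
    if (object@fracDeg < 0 || object@fracDeg > 1) {
        msg <- c(msg, "fracDeg must be in [0, 1]")
    }
    for (nm in c("couplingA", "couplingB")) {
        v <- slot(object, nm)
        if (any(v < 0) || any(v >= 1)) {
            msg <- c(msg, sprintf("%s values must be in [0, 1)", nm))
        }
        if (!(length(v) %in% c(1L, object@nModules))) {
            msg <- c(msg, sprintf("%s must have length 1 or nModules", nm))
        }
    }
    if (length(object@lfcRange) != 2 || object@lfcRange[1] < 0 ||
        diff(object@lfcRange) < 0) {
        msg <- c(msg, "lfcRange must be (min, max) with 0 <= min <= max")
    }
    if (object@dispersionShape <= 0 || object@dispersionRate <= 0) {
        msg <- c(msg, "dispersion gamma parameters must be positive")
    }
    if (length(object@libSizeRange) != 2 || object@libSizeRange[1] <= 0 ||
        diff(object@libSizeRange) < 0) {
        msg <- c(msg, "libSizeRange must be positive and ordered")
    }
    if (object@signalSd <= 0) msg <- c(msg, "signalSd must be positive")
    # total module footprint: each module owns its TF plus moduleSize targets
    if (object@nModules * object@moduleSize + object@nTfs > object@nGenes) {
        msg <- c(msg, "nModules * moduleSize + nTfs exceeds nGenes")
    }
    if (object@nTfs < object@nModules) {
        msg <- c(msg, "need at least one TF per module")
    }
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated experiment
#'
#' Records everything the simulator planted: DEG identities and their true
#' log2 fold changes, which TFs were rewired (coupling differs between
#' conditions), the TF-to-target module map, per-module couplings, per-gene
#' NB dispersions and per-sample library factors. Downstream recovery tests
#' score pipeline output against this object.
#'
#' @slot degIds character, planted DEG ids.
#' @slot degLfc named numeric, true log2FC (VTM vs CON) per planted DEG.
#' @slot rewiredTfIds character, TFs whose module coupling differs between
#'   conditions.
#' @slot moduleMap named list, TF id -> character vector of target gene ids.
#' @slot couplingA,couplingB numeric per module (named by TF id).
#' @slot dispersion named numeric, per-gene NB dispersion alpha.
#' @slot libFactors named numeric, per-sample library-size multiplier.
#' @slot params the \linkS4class{SimulationParams} that generated the data.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(
        degIds = "character", degLfc = "numeric",
        rewiredTfIds = "character", moduleMap = "list",
        couplingA = "numeric", couplingB = "numeric",
        dispersion = "numeric", libFactors = "numeric",
        params = "SimulationParams"
    )
)

setValidity("SyntheticTruth", function(object) {
    msg <- character(0)
    if (!setequal(names(object@degLfc), object@degIds)) {
        msg <- c(msg, "degLfc must be named by degIds")
    }
    if (!all(object@degIds %in% names(object@dispersion))) {
        msg <- c(msg, "degIds must be a subset of simulated gene ids")
    }
    tf <- names(object@moduleMap)
    if (any(vapply(seq_along(object@moduleMap), function(i) {
        tf[i] %in% object@moduleMap[[i]]
    }, logical(1)))) {
        msg <- c(msg, "a module's targets must not contain its own TF")
    }
    if (length(object@rewiredTfIds)) {
        same <- object@couplingA[object@rewiredTfIds] ==
            object@couplingB[object@rewiredTfIds]
        if (any(same)) {
            msg <- c(msg, "rewired TFs must have couplingA != couplingB")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Per-gene differential expression results
#'
#' A \code{DataFrame} subclass with one row per tested gene and columns
#' \code{baseMean}, \code{log2FC} (VTM vs CON), \code{dispersion},
#' \code{stat} (Wald), \code{pvalue}, \code{padj} (Benjamini-Hochberg),
#' \code{degFlag} (\code{"up"}, \code{"down"}, \code{"none"}) and
#' \code{converged}. Thresholds and the reference level are stored in
#' \code{metadata()}.
#'
#' @exportClass DEResult
setClass("DEResult", contains = "DFrame")

#' Regulatory impact factor table
#'
#' A \code{DataFrame} subclass with one row per tested TF and columns
#' \code{rif1Raw}, \code{rif1Z}, \code{rif2Raw}, \code{rif2Z},
#' \code{significantRif1}, \code{significantRif2}. TF bookkeeping counts
#' (list size, tested, removed as unexpressed) live in \code{metadata()}.
#'
#' @exportClass RIFTable
setClass("RIFTable", contains = "DFrame")

#' Differential connectivity table
#'
#' A \code{DataFrame} subclass over the union of both networks' node sets
#' with degrees \code{kConRaw}/\code{kVtmRaw}, max-normalized connectivities
#' \code{kCon}/\code{kVtm}, \code{dk} = kVtm - kCon, \code{dkZ}, class
#' (\code{"gained"}, \code{"lost"}, \code{"unchanged"}) and per-network
#' membership flags.
#'
#' @exportClass ConnectivityTable
setClass("ConnectivityTable", contains = "DFrame")

#' A per-condition co-expression network
#'
#' Edge list retained after PCIT significance testing, the |r| magnitude
#' threshold, and restriction to edges touching the keep set (DEGs and
#' significant RIF TFs). Edges are stored canonically with
#' \code{geneX < geneY}; the node set is the set of edge endpoints.
#'
#' @slot condition condition label the network was built from.
#' @slot edges data.frame with columns \code{geneX}, \code{geneY}, \code{r}.
#' @slot nodes character vector of edge endpoints.
#'
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
    representation(
        condition = "character",
        edges = "data.frame",
        nodes = "character"
    )
)

setValidity("CoexpressionNetwork", function(object) {
    msg <- character(0)
    ed <- object@edges
    need <- c("geneX", "geneY", "r")
    if (!all(need %in% names(ed))) {
        msg <- c(msg, "edges must have columns geneX, geneY, r")
    } else if (nrow(ed)) {
        if (any(ed$geneX == ed$geneY)) msg <- c(msg, "self-edges not allowed")
        if (any(as.character(ed$geneX) >= as.character(ed$geneY))) {
            msg <- c(msg, "edges must be canonical (geneX < geneY)")
        }
        if (!setequal(object@nodes, union(ed$geneX, ed$geneY))) {
            msg <- c(msg, "nodes must equal the set of edge endpoints")
        }
    } else if (length(object@nodes)) {
        msg <- c(msg, "empty network must have an empty node set")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams:", object@nGenes, "genes (", object@nTfs, "TFs),",
        object@nModules, "modules x", object@moduleSize, "targets,",
        2 * object@nSamplesPerCondition, "samples\n")
    cat("  couplingA:", paste(unique(object@couplingA), collapse = "/"),
        " couplingB:", paste(unique(object@couplingB), collapse = "/"),
        " fracDeg:", object@fracDeg, " seed:", object@seed, "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@degIds), "planted DEGs,",
        length(object@rewiredTfIds), "rewired TFs,",
        length(object@moduleMap), "modules\n")
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork [", object@condition, "]: ",
        nrow(object@edges), " edges over ", length(object@nodes),
        " nodes\n", sep = "")
})

#' @rdname CoexpressionNetwork-class
#' @param x,object a \code{CoexpressionNetwork}.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname CoexpressionNetwork-class
#' @export
setGeneric("networkCondition", function(x) standardGeneric("networkCondition"))

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("edges", "CoexpressionNetwork", function(x) x@edges)

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("nodes", "CoexpressionNetwork", function(x) x@nodes)

#' @rdname CoexpressionNetwork-class
#' @export
setMethod("networkCondition", "CoexpressionNetwork", function(x) x@condition)

#' Accessors for SyntheticTruth
#'
#' @param x a \linkS4class{SyntheticTruth}.
#' @return \code{degIds}: character vector of planted DEG ids;
#'   \code{degLfc}: named numeric of true log2 fold changes;
#'   \code{rewiredTfIds}: character vector of rewired TFs;
#'   \code{moduleMap}: named list of TF -> targets.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
setGeneric("degIds", function(x) standardGeneric("degIds"))
#' @rdname truth-accessors
#' @export
setMethod("degIds", "SyntheticTruth", function(x) x@degIds)

#' @rdname truth-accessors
#' @export
setGeneric("degLfc", function(x) standardGeneric("degLfc"))
#' @rdname truth-accessors
#' @export
setMethod("degLfc", "SyntheticTruth", function(x) x@degLfc)

#' @rdname truth-accessors
#' @export
setGeneric("rewiredTfIds", function(x) standardGeneric("rewiredTfIds"))
#' @rdname truth-accessors
#' @export
setMethod("rewiredTfIds", "SyntheticTruth", function(x) x@rewiredTfIds)

#' @rdname truth-accessors
#' @export
setGeneric("moduleMap", function(x) standardGeneric("moduleMap"))
#' @rdname truth-accessors
#' @export
setMethod("moduleMap", "SyntheticTruth", function(x) x@moduleMap)
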