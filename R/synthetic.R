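#' Construct simulation parameters
#'
#' Builds a validated \linkS4class{SimulationParams}. The defaults are a
#' desk-scale version of a 6-vs-6 bulk RNA-seq liver study: 2,000 expressed
#' genes of which 100 are transcription factors, ten TF-anchored modules of
#' 15 targets each, a mean sequencing depth near one million counts per
#' sample, 5\% planted DEGs with |log2FC| between 0.5 and 2, and all ten
#' modules rewired from strong coupling (0.9) in CON to none (0.0) in VTM.
#'
#' @param n_genes,n_tfs,n_samples_per_condition,n_modules,module_size design
#'   sizes; see \linkS4class{SimulationParams}.
#' @param coupling_A,coupling_B per-module TF--target coupling in [0,1),
#'   recycled over modules.
#' @param frac_deg fraction of genes given a planted log2FC (rewired-module
#'   targets are planted in addition, see \code{\link{simulateCounts}}).
#' @param lfc_range min/max |log2FC| of planted effects.
#' @param dispersion_shape,dispersion_rate gamma law of per-gene NB
#'   dispersion (defaults give mean alpha 0.05).
#' @param mean_log_mu,sd_log_mu baseline natural-log mean count distribution.
#' @param lib_size_range relative library-size multiplier range.
#' @param signal_sd natural-log SD of the latent module signal.
#' @param seed master seed.
#' @return a \linkS4class{SimulationParams}.
#' @examples
#' simParams(seed = 1)
#' @export
simParams <- function(n_genes = 2000, n_tfs = 100,
                      n_samples_per_condition = 6,
                      n_modules = 10, module_size = 15,
                      coupling_A = 0.9, coupling_B = 0.0,
                      frac_deg = 0.05, lfc_range = c(0.5, 2.0),
                      dispersion_shape = 2, dispersion_rate = 40,
                      mean_log_mu = 5.0, sd_log_mu = 1.5,
                      lib_size_range = c(0.7, 1.3),
                      signal_sd = 1.0, seed = 1) {
    new("SimulationParams",
        nGenes = n_genes, nTfs = n_tfs,
        nSamplesPerCondition = n_samples_per_condition,
        nModules = n_modules, moduleSize = module_size,
        couplingA = coupling_A, couplingB = coupling_B,
        fracDeg = frac_deg, lfcRange = lfc_range,
        dispersionShape = dispersion_shape, dispersionRate = dispersion_rate,
        meanLogMu = mean_log_mu, sdLogMu = sd_log_mu,
        libSizeRange = lib_size_range, signalSd = signal_sd,
        seed = seed)
}

#' Simulate a two-condition count matrix with known truth
#'
#' Generative model, per gene g and sample s of condition c:
#' \deqn{\log \mu_{gs} = b_g + \ln(2)\,\beta_g\,[c = VTM] + \sigma x_{gs} -
#'   \sigma^2/2, \qquad y_{gs} \sim NB(\ell_s \mu_{gs},\ \alpha_g)}
#' where \eqn{b_g} is the baseline log-mean, \eqn{\beta_g} the planted log2
#' fold change (zero off the DEG set), and \eqn{x_{gs}} a latent module
#' signal. Within a module with coupling \eqn{\rho} in condition c, the TF
#' carries \eqn{x = f_s} (the module factor, standard normal per sample) and
#' each target \eqn{x = \rho f_s + \sqrt{1-\rho^2}\,\epsilon_{gs}}, so the
#' log-scale TF--target correlation equals \eqn{\rho} and target--target
#' correlation \eqn{\rho^2}. At \eqn{\rho = 0} the module carries no latent
#' term and counts are exactly negative binomial. The \eqn{-\sigma^2/2}
#' term keeps expected counts invariant to coupling, so rewiring alone does
#' not shift means between conditions.
#'
#' Planted DEGs are a uniform draw of \code{frac_deg * n_genes} genes
#' outside rewired-module targets (random sign, |log2FC| uniform in
#' \code{lfc_range}) \emph{plus} every target of a rewired module
#' (\code{coupling_A != coupling_B}), which share one sign per module --
#' a regulator whose wiring changed is assumed to shift its targets
#' coherently.
#'
#' Identical \code{params} (including \code{seed}) give bit-identical
#' output; stage seeds fan out from the master seed by counter so the four
#' draw blocks (gene-level parameters, DEG selection, latent signals, NB
#' sampling) are independent.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return list with elements \code{se} (a counts
#'   \code{SummarizedExperiment}, conditions \code{CON}/\code{VTM}) and
#'   \code{truth} (a \linkS4class{SyntheticTruth}).
#' @examples
#' sim <- simulateCounts(simParams(n_genes = 200, n_tfs = 20,
#'     n_modules = 2, module_size = 5, seed = 7))
#' sim$se
#' sim$truth
#' @export
simulateCounts <- function(params) {
    validObject(params)
    p <- params
    G <- as.integer(p@nGenes)
    S <- as.integer(p@nSamplesPerCondition)
    nTf <- as.integer(p@nTfs)
    M <- as.integer(p@nModules)
    msz <- as.integer(p@moduleSize)
    if (M * msz + nTf > G) stop("module sizing exceeds n_genes")

    tfIds <- sprintf("TF%04d", seq_len(nTf))
    bgIds <- sprintf("G%06d", seq_len(G - nTf))
    geneIds <- c(tfIds, bgIds)
    sampleIds <- c(sprintf("CON_%d", seq_len(S)), sprintf("VTM_%d", seq_len(S)))
    condition <- factor(rep(c("CON", "VTM"), each = S),
                        levels = c("CON", "VTM"))

    cA <- rep(p@couplingA, length.out = M)
    cB <- rep(p@couplingB, length.out = M)
    moduleTfs <- tfIds[seq_len(M)]
    names(cA) <- names(cB) <- moduleTfs
    targetPool <- bgIds[seq_len(M * msz)]
    moduleMap <- split(targetPool, rep(seq_len(M), each = msz))
    names(moduleMap) <- moduleTfs
    rewiredTfs <- moduleTfs[cA != cB]

    ## block 1: gene- and sample-level parameters
    set.seed(fanSeed(p@seed, 1L))
    baseline <- stats::rnorm(G, p@meanLogMu, p@sdLogMu)
    alpha <- stats::rgamma(G, shape = p@dispersionShape,
                           rate = p@dispersionRate)
    libf <- stats::runif(2L * S, p@libSizeRange[1], p@libSizeRange[2])
    names(alpha) <- geneIds
    names(libf) <- sampleIds

    ## block 2: planted DEGs and their effect sizes
    set.seed(fanSeed(p@seed, 2L))
    rewTargets <- unlist(moduleMap[rewiredTfs], use.names = FALSE)
    pool <- setdiff(geneIds, rewTargets)
    nDeg <- min(round(p@fracDeg * G), length(pool))
    degFree <- if (nDeg > 0) sample(pool, nDeg) else character(0)
    lfcFree <- sample(c(-1, 1), length(degFree), replace = TRUE) *
        stats::runif(length(degFree), p@lfcRange[1], p@lfcRange[2])
    moduleSign <- sample(c(-1, 1), M, replace = TRUE)
    lfcRew <- numeric(0)
    for (m in which(cA != cB)) {
        tg <- moduleMap[[m]]
        lfcRew <- c(lfcRew, stats::setNames(
            moduleSign[m] * stats::runif(length(tg), p@lfcRange[1],
                                         p@lfcRange[2]), tg))
    }
    degLfc <- c(stats::setNames(lfcFree, degFree), lfcRew)
    if (is.null(names(degLfc))) names(degLfc) <- character(0)
    degIds <- names(degLfc)

    ## block 3: latent module signals
    set.seed(fanSeed(p@seed, 3L))
    logMu <- matrix(baseline, nrow = G, ncol = 2L * S,
                    dimnames = list(geneIds, sampleIds))
    isB <- condition == "VTM"
    if (length(degIds)) {
        logMu[degIds, isB] <- logMu[degIds, isB] + degLfc * log(2)
    }
    sg <- p@signalSd
    for (cond in 1:2) {
        cols <- if (cond == 1) which(!isB) else which(isB)
        cpl <- if (cond == 1) cA else cB
        for (m in seq_len(M)) {
            rho <- cpl[m]
            if (rho <= 0) next
            f <- stats::rnorm(S)
            tf <- moduleTfs[m]
            tg <- moduleMap[[m]]
            logMu[tf, cols] <- logMu[tf, cols] + sg * f - sg^2 / 2
            eps <- matrix(stats::rnorm(length(tg) * S), length(tg), S)
            x <- rho * matrix(f, length(tg), S, byrow = TRUE) +
                sqrt(1 - rho^2) * eps
            logMu[tg, cols] <- logMu[tg, cols] + sg * x - sg^2 / 2
        }
    }

    ## block 4: NB sampling
    set.seed(fanSeed(p@seed, 4L))
    mu <- sweep(exp(logMu), 2, libf, `*`)
    counts <- matrix(stats::rnbinom(G * 2L * S, mu = mu,
                                    size = rep(1 / alpha, 2L * S)),
                     nrow = G, ncol = 2L * S,
                     dimnames = dimnames(logMu))

    truth <- new("SyntheticTruth",
        degIds = degIds, degLfc = degLfc,
        rewiredTfIds = rewiredTfs, moduleMap = moduleMap,
        couplingA = cA, couplingB = cB,
        dispersion = alpha, libFactors = libf, params = p)
    list(se = makeCountsSE(counts, condition, ref = "CON"), truth = truth)
}

#' Plant gene sets that match a simulated experiment
#'
#' Produces one "true" gene set per module (the module's planted targets,
#' named after its TF) plus \code{n_random_sets} sets drawn uniformly from
#' all simulated genes. The collection is GMT-writable via
#' \code{\link{writeGMT}} and is the natural input for testing
#' \code{\link{ora}} and \code{\link{gseaPrerank}} against known truth.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param n_random_sets number of uniformly drawn decoy sets.
#' @param set_size_range integer min/max size of the random sets.
#' @param seed RNG seed for the random sets.
#' @return named list of character vectors with a \code{"descriptions"}
#'   attribute (named character), as returned by \code{\link{readGMT}}.
#' @export
plantGeneSets <- function(truth, n_random_sets = 50,
                          set_size_range = c(10, 50), seed = 1) {
    stopifnot(is(truth, "SyntheticTruth"))
    geneIds <- names(truth@dispersion)
    if (max(set_size_range) > length(geneIds)) {
        stop("set size exceeds the number of simulated genes")
    }
    sets <- truth@moduleMap
    names(sets) <- paste0("module_", names(truth@moduleMap))
    desc <- stats::setNames(
        paste0("planted targets of ", names(truth@moduleMap)), names(sets))
    if (n_random_sets > 0) {
        set.seed(fanSeed(seed, 11L))
        sizeChoices <- seq(set_size_range[1], set_size_range[2])
        sizes <- sizeChoices[sample.int(length(sizeChoices),
                                        n_random_sets, replace = TRUE)]
        rnd <- lapply(sizes, function(k) sample(geneIds, k))
        names(rnd) <- sprintf("random_%03d", seq_len(n_random_sets))
        sets <- c(sets, rnd)
        desc <- c(desc, stats::setNames(
            paste0("uniform decoy set of size ", sizes), names(rnd)))
    }
    attr(sets, "descriptions") <- desc
    sets
}
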