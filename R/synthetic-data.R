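## Seeded planted-module TPM simulator with ground-truth labels, so every
## pipeline stage is testable without any external expression data.

#' Configure the planted-module expression simulator
#'
#' Defaults describe the package's reference scenario: 200 genes over 40
#' samples, four co-expression modules of 30 genes, 20 planted
#' low-expression genes and 60 uncorrelated background genes. A fifth of the
#' genes in each module load negatively (anti-correlated regulators), module
#' signal strength is 1 on the latent scale against multiplicative log-normal
#' noise with sd 0.25, and baselines span log-TPM 1 to 4 (TPM roughly 3 to
#' 55). Low-expression genes are zero-inflated (60% dropout) below a 0.3 TPM
#' ceiling so that the pooled 3-sigma threshold separates them cleanly.
#'
#' @param nGenes total genes.
#' @param nSamples samples (tissues/conditions).
#' @param moduleSizes integer vector of planted module sizes (each >= 2).
#' @param antiCorrFraction fraction of each module loading negatively.
#' @param noiseSd sd of the per-gene-per-sample log-scale noise.
#' @param signalStrength latent signal scale (lambda); co-expression is
#'   detectable when `signalStrength / noiseSd` is large.
#' @param nLowExprGenes planted genes below the intended 3-sigma threshold.
#' @param baselineLogTpmRange range the per-gene log-TPM baseline is drawn
#'   from.
#' @param lowExprCeiling upper bound of low-expression TPM draws.
#' @param lowExprDropout probability a low-expression value is exactly 0.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the config.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nGenes = 200L, nSamples = 40L,
                            moduleSizes = rep(30L, 4L),
                            antiCorrFraction = 0.2, noiseSd = 0.25,
                            signalStrength = 1, nLowExprGenes = 20L,
                            baselineLogTpmRange = c(1, 4),
                            lowExprCeiling = 0.3, lowExprDropout = 0.6,
                            seed = 1L) {
    methods::new("SyntheticConfig", nGenes = as.integer(nGenes),
        nSamples = as.integer(nSamples),
        moduleSizes = as.integer(moduleSizes),
        antiCorrFraction = antiCorrFraction, noiseSd = noiseSd,
        signalStrength = signalStrength,
        nLowExprGenes = as.integer(nLowExprGenes),
        baselineLogTpmRange = as.numeric(baselineLogTpmRange),
        lowExprCeiling = lowExprCeiling, lowExprDropout = lowExprDropout,
        seed = as.integer(seed))
}

#' Generate a planted-module TPM dataset
#'
#' Each module m gets a latent sample profile: a standardised Gaussian random
#' walk across samples (mimicking tissue/developmental gradients), squashed
#' to `w_m = 0.9 * tanh(signalStrength * z_m)` so expression stays positive.
#' A gene g of module m with baseline `b_g ~ U(baselineLogTpmRange)` and
#' loading sign `s_g` is
#' \deqn{TPM_{gs} = e^{b_g + \epsilon_{gs}} (1 + s_g w_{ms}),
#'       \quad \epsilon_{gs} \sim N(0, noiseSd^2),}
#' so with `noiseSd = 0` two same-sign module genes are correlated exactly
#' +1 and opposite signs exactly -1 on the TPM scale the pipeline consumes.
#' Background genes carry baseline and noise only; low-expression genes are
#' zero-inflated uniform draws below `lowExprCeiling`. Everything is a
#' deterministic function of `cfg@seed`.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return a [SyntheticDataset-class].
#' @export
simulateExpression <- function(cfg) {
    stopifnot(methods::is(cfg, "SyntheticConfig"))
    methods::validObject(cfg)
    nMod <- length(cfg@moduleSizes)
    nModGenes <- sum(cfg@moduleSizes)
    nBg <- cfg@nGenes - nModGenes - cfg@nLowExprGenes
    ids <- sprintf("g%04d", seq_len(cfg@nGenes))
    moduleOf <- integer(cfg@nGenes)
    moduleOf[seq_len(nModGenes)] <- rep(seq_len(nMod), cfg@moduleSizes)
    names(moduleOf) <- ids
    lowIds <- ids[seq.int(nModGenes + nBg + 1L, length.out = cfg@nLowExprGenes)]
    sign <- rep(1, cfg@nGenes)
    off <- 0L
    for (m in seq_len(nMod)) {
        sz <- cfg@moduleSizes[m]
        nNeg <- floor(cfg@antiCorrFraction * sz)
        if (nNeg > 0L)
            sign[off + sz - seq_len(nNeg) + 1L] <- -1  # last genes load negatively
        off <- off + sz
    }
    names(sign) <- ids
    v <- .withSeed(cfg@seed, {
        z <- vapply(seq_len(nMod), function(m) {
            w <- cumsum(stats::rnorm(cfg@nSamples))
            w <- w - mean(w)
            s <- stats::sd(w)
            if (s > 0) w <- w / s
            w
        }, numeric(cfg@nSamples))
        w <- 0.9 * tanh(cfg@signalStrength * z)  # samples x modules
        base <- stats::runif(cfg@nGenes, cfg@baselineLogTpmRange[1L],
                             cfg@baselineLogTpmRange[2L])
        eps <- matrix(stats::rnorm(cfg@nGenes * cfg@nSamples,
                                   sd = cfg@noiseSd),
                      cfg@nGenes, cfg@nSamples)
        out <- exp(base + eps)
        for (i in seq_len(nModGenes))
            out[i, ] <- out[i, ] * (1 + sign[i] * w[, moduleOf[i]])
        if (cfg@nLowExprGenes > 0L) {
            li <- seq.int(nModGenes + nBg + 1L,
                          length.out = cfg@nLowExprGenes)
            nv <- cfg@nLowExprGenes * cfg@nSamples
            drop <- stats::runif(nv) < cfg@lowExprDropout
            vals <- stats::runif(nv, 0, cfg@lowExprCeiling)
            vals[drop] <- 0
            out[li, ] <- matrix(vals, cfg@nLowExprGenes, cfg@nSamples)
        }
        out
    })
    dimnames(v) <- list(ids, sprintf("s%03d", seq_len(cfg@nSamples)))
    methods::new("SyntheticDataset",
        experiment = TpmExperiment(v, metadata = list(seed = cfg@seed)),
        moduleOf = moduleOf, loadingSign = sign, lowExpression = lowIds,
        config = cfg)
}

#' Module membership of a synthetic dataset
#' @param d a [SyntheticDataset-class].
#' @return named integer vector, 0 for background/low-expression genes.
#' @export
moduleOf <- function(d) d@moduleOf

#' TpmExperiment of a synthetic dataset
#' @param d a [SyntheticDataset-class].
#' @export
syntheticExperiment <- function(d) d@experiment

#' Planted low-expression gene ids
#' @param d a [SyntheticDataset-class].
#' @export
lowExpressionGenes <- function(d) d@lowExpression

#' Gold standard from planted module truth
#'
#' Positives are all within-module gene pairs; negatives are a seeded
#' uniform sample of pairs spanning different modules or involving
#' background genes (planted low-expression genes are excluded from both
#' sides, since the pipeline is expected to remove them before correlation).
#'
#' @param d a [SyntheticDataset-class] with at least one module of size
#'   >= 2.
#' @param negRatio negatives per positive (default 1).
#' @param seed seed for the negative sample.
#' @return a [GoldStandard-class].
#' @export
goldStandardFromTruth <- function(d, negRatio = 1, seed = 1L) {
    stopifnot(methods::is(d, "SyntheticDataset"))
    keep <- setdiff(geneIds(d), d@lowExpression)
    mod <- d@moduleOf[keep]
    if (!any(table(mod[mod > 0]) >= 2L))
        stop("no module of size >= 2")
    pairs <- .allPairs(keep)
    ma <- mod[pairs$gene_a]
    mb <- mod[pairs$gene_b]
    posIdx <- which(ma > 0 & ma == mb)
    negPool <- which(!(ma > 0 & ma == mb))
    want <- min(round(negRatio * length(posIdx)), length(negPool))
    negIdx <- .withSeed(seed, sort(sample(negPool, want)))
    p <- rbind(cbind(pairs[posIdx, , drop = FALSE], label = "positive"),
               cbind(pairs[negIdx, , drop = FALSE], label = "negative"))
    rownames(p) <- NULL
    methods::new("GoldStandard", pairs = p, source = "planted module truth",
                 seed = as.integer(seed))
}

#' Write the ground truth of a synthetic dataset to TSV
#' @param d a [SyntheticDataset-class].
#' @param path output path; columns gene_id, module, loading_sign,
#'   low_expression.
#' @export
writeSyntheticTruth <- function(d, path) {
    ids <- geneIds(d)
    out <- data.frame(gene_id = ids, module = unname(d@moduleOf[ids]),
                      loading_sign = ifelse(d@loadingSign[ids] < 0, "-", "+"),
                      low_expression = as.integer(ids %in% d@lowExpression),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
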