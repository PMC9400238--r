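## End-to-end pipeline: 3-sigma filter -> (PCC thresholds + MR edges) and
## (soft power -> TOM edges) -> integration -> statistics [-> evaluation].

#' Assemble and validate a pipeline configuration
#'
#' Defaults are the method's printed operating point: 5% expression tail,
#' top/bottom 5% correlation quantiles, mutual-rank cut 30 with
#' unidirectional cut 3 combined as a union, scale-free fit target R-squared
#' 0.90 with automatic power selection, TOM cut 0.1, offset grid step 0.1,
#' and union integration.
#'
#' @param input path to a TPM TSV (see [readExpressionTsv()]) or a
#'   [TpmExperiment-class].
#' @param gold optional path to a gold-standard TSV or a
#'   [GoldStandard-class]; required when `optimize = TRUE`.
#' @param tailFraction low-expression tail fraction.
#' @param topQ,bottomQ correlation quantile fractions.
#' @param offset fixed correlation-threshold offset (ignored when
#'   `optimize = TRUE`).
#' @param optimize sweep the offset grid and use the AUC-maximizing offset.
#' @param step,maxOffset offset grid (used when `optimize = TRUE`).
#' @param mrCut,uniCut,combine mutual-rank filter parameters.
#' @param pccMrMode how the correlation-threshold and mutual-rank edge sets
#'   combine into the hard-threshold network: `"union"`, `"intersection"`,
#'   or `"mr_only"`.
#' @param r2Target scale-free fit target.
#' @param beta `"auto"` or a fixed integer soft power.
#' @param tomCut TOM edge cutoff.
#' @param mode integration of hard-threshold and TOM edge sets: `"union"`
#'   or `"intersection"`.
#' @param seed integer seed recorded in the manifest and used wherever the
#'   pipeline samples (gold-standard negatives are sampled upstream).
#' @return a validated list of class `cenRunConfig`.
#' @export
runConfig <- function(input, gold = NULL, tailFraction = 0.05, topQ = 0.05,
                      bottomQ = 0.05, offset = 0, optimize = FALSE,
                      step = 0.1, maxOffset = 0.4, mrCut = 30, uniCut = 3,
                      combine = c("any", "all"),
                      pccMrMode = c("union", "intersection", "mr_only"),
                      r2Target = 0.90, beta = "auto", tomCut = 0.1,
                      mode = c("union", "intersection"), seed = 1L) {
    combine <- match.arg(combine)
    pccMrMode <- match.arg(pccMrMode)
    mode <- match.arg(mode)
    if (optimize && is.null(gold))
        stop("optimize = TRUE requires a gold standard")
    if (!identical(beta, "auto")) {
        beta <- as.integer(beta)
        if (is.na(beta) || beta < 1L) stop("beta must be 'auto' or >= 1")
    }
    cfg <- list(input = input, gold = gold, tailFraction = tailFraction,
                topQ = topQ, bottomQ = bottomQ, offset = offset,
                optimize = optimize, step = step, maxOffset = maxOffset,
                mrCut = mrCut, uniCut = uniCut, combine = combine,
                pccMrMode = pccMrMode, r2Target = r2Target, beta = beta,
                tomCut = tomCut, mode = mode, seed = as.integer(seed),
                ## accepted for provenance; module detection is out of scope
                minModuleSize = 30L, mergeCutHeight = 0.25,
                reassignThreshold = 0)
    class(cfg) <- "cenRunConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match the [runConfig()] arguments.
#' @return a `cenRunConfig` list.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(runConfig, y)
}

.statsToList <- function(s) list(
    n_genes_in_network = s@nGenes, n_edges = s@nEdges,
    gene_coverage_pct = s@geneCoveragePct,
    mean_connectivity = s@meanConnectivity,
    pct_negative_edges = s@pctNegativeEdges)

#' Run the integrated network-construction pipeline
#'
#' Stages: read + 3-sigma low-expression filter; Pearson correlations;
#' hard-threshold edges (quantile cuts, optionally AUC-optimized offset) and
#' mutual-rank edges, combined per `pccMrMode`; scale-free soft power,
#' adjacency, TOM and TOM edges; integration of the two strategies; network
#' statistics; optional ROC evaluation. Every stage output is materialized
#' under `outDir` so any threshold decision can be audited and re-run:
#' `filtered.tsv`, `removed.tsv`, `softpower.tsv`, `network.tsv`,
#' `stats.json`, `auc_table.tsv` (when a gold standard is given) and
#' `manifest.json` (parameters, seed, package version, input checksums).
#'
#' @param cfg a `cenRunConfig` from [runConfig()] or [readRunConfig()].
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with the main in-memory results
#'   (`network`, `stats`, `softpower`, `threshold`, and when evaluated
#'   `rocs`/`aucTable`).
#' @export
runPipeline <- function(cfg, outDir) {
    stopifnot(inherits(cfg, "cenRunConfig"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    inputPath <- NULL
    x <- cfg$input
    if (is.character(x)) {
        inputPath <- x
        x <- readExpressionTsv(x)
    }
    stopifnot(methods::is(x, "TpmExperiment"))
    gs <- cfg$gold
    if (is.character(gs)) gs <- readGoldStandard(gs)

    ## stage 1: 3-sigma low-expression filter
    thr <- computeTpmThreshold(x, cfg$tailFraction)
    filtered <- filterLowExpression(x, thr)
    writeExpressionTsv(filtered, file.path(outDir, "filtered.tsv"))
    writeRemovalReport(filtered, file.path(outDir, "removed.tsv"))

    ## stage 2: correlations
    pcc <- computePcc(filtered)

    ## stage 3a: hard correlation thresholds (fixed or AUC-optimized offset)
    aucTable <- NULL
    offset <- cfg$offset
    if (cfg$optimize) {
        opt <- optimizePccOffset(pcc, gs, step = cfg$step,
                                 maxOffset = cfg$maxOffset, topQ = cfg$topQ,
                                 bottomQ = cfg$bottomQ)
        offset <- opt$bestOffset
        aucTable <- opt$table
        writeAucTable(opt, file.path(outDir, "auc_table.tsv"))
    }
    cuts <- pccQuantileThresholds(pcc, cfg$topQ, cfg$bottomQ, offset = offset)
    pccEdges <- pccEdgeFilter(pcc, cuts)

    ## stage 3b: mutual ranks
    ranks <- computeRanks(pcc)
    mr <- computeMr(ranks)
    mrEdges <- mrEdgeFilter(mr, ranks, pcc, mrCut = cfg$mrCut,
                            uniCut = cfg$uniCut, combine = cfg$combine)
    hard <- switch(cfg$pccMrMode,
        union = integrateEdges(pccEdges, mrEdges, "union"),
        intersection = integrateEdges(pccEdges, mrEdges, "intersection"),
        mr_only = mrEdges)

    ## stage 4: soft power -> TOM
    sp <- fitScaleFree(pcc, r2Target = cfg$r2Target)
    beta <- cfg$beta
    if (identical(beta, "auto")) {
        beta <- selectedBeta(sp)
        if (is.na(beta)) {
            beta <- defaultSoftPower(ncol(filtered))
            warning("no power reached the scale-free target; ",
                    "falling back to the sample-count default beta = ", beta)
        }
    }
    utils::write.table(softPowerTable(sp), file.path(outDir, "softpower.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    adj <- computeAdjacency(pcc, beta)
    tomEdges <- tomEdgeFilter(computeTom(adj), tomCut = cfg$tomCut, c = pcc)

    ## stage 5: integrate the two strategies + statistics
    network <- integrateEdges(hard, tomEdges, cfg$mode)
    writeEdgeTable(network, file.path(outDir, "network.tsv"))
    stats <- networkStats(network, geneIds(x))

    ## stage 6: optional evaluation
    rocs <- NULL
    if (!is.null(gs)) {
        rocs <- list(
            pcc = rocAuc(gs, scoreEdges(pccEdges, "pcc_abs")),
            mr = rocAuc(gs, scoreEdges(mrEdges, "neg_mr")),
            integrated = rocAuc(gs, scoreEdges(network, "integrated")))
        if (is.null(aucTable)) {
            aucTable <- data.frame(offset = offset, pos_cut = cuts@posCut,
                                   neg_cut = cuts@negCut,
                                   n_edges = nEdges(pccEdges),
                                   auc = auc(rocs$pcc))
            utils::write.table(aucTable, file.path(outDir, "auc_table.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }
    statsOut <- .statsToList(stats)
    statsOut$tpm_threshold <- thresholdValue(thr)
    statsOut$n_genes_removed <- nrow(removalReport(filtered))
    statsOut$selected_beta <- beta
    statsOut$pcc_pos_cut <- cuts@posCut
    statsOut$pcc_neg_cut <- cuts@negCut
    statsOut$offset <- offset
    if (!is.null(rocs))
        statsOut$auc <- lapply(rocs, auc)
    jsonlite::write_json(statsOut, file.path(outDir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    manifest <- list(
        package = "cenweaver",
        version = as.character(utils::packageVersion("cenweaver")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        created = NA,  # timestamps omitted: outputs must be byte-identical
        parameters = cfg[setdiff(names(cfg), c("input", "gold"))],
        seed = cfg$seed,
        input = if (!is.null(inputPath)) list(
            path = inputPath,
            md5 = unname(tools::md5sum(inputPath))) else "in-memory",
        outputs = c("filtered.tsv", "removed.tsv", "softpower.tsv",
                    "network.tsv", "stats.json",
                    if (!is.null(gs)) "auc_table.tsv", "manifest.json"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(list(network = network, stats = stats, softpower = sp,
                   threshold = thr, cuts = cuts, pccEdges = pccEdges,
                   mrEdges = mrEdges, tomEdges = tomEdges, rocs = rocs,
                   aucTable = aucTable))
}
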