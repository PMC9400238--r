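#' Gene identifiers of an object
#' @param x an object holding genes.
#' @return character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Sample identifiers of an object
#' @param x an object holding samples.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' TPM assay matrix
#' @param x a [TpmExperiment-class].
#' @return numeric genes-by-samples matrix.
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' Edge rows of an edge table
#' @param x an [EdgeTable-class].
#' @return data.frame, one row per undirected pair.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Number of edges
#' @param x an [EdgeTable-class].
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "TpmExperiment", function(x) rownames(x))
#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneScoreMatrix", function(x) rownames(x@values))
#' @rdname geneIds
#' @export
setMethod("geneIds", "EdgeTable",
          function(x) sort(unique(c(x@edges$gene_a, x@edges$gene_b)),
                           method = "radix"))
#' @rdname geneIds
#' @export
setMethod("geneIds", "SyntheticDataset", function(x) rownames(x@experiment))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "TpmExperiment", function(x) colnames(x))

#' @rdname tpm
#' @export
setMethod("tpm", "TpmExperiment",
          function(x) SummarizedExperiment::assay(x, "tpm"))

#' @rdname edges
#' @export
setMethod("edges", "EdgeTable", function(x) x@edges)

#' @rdname nEdges
#' @export
setMethod("nEdges", "EdgeTable", function(x) nrow(x@edges))

#' Matrix view of a gene score matrix
#' @param x a [GeneScoreMatrix-class] derivative.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "GeneScoreMatrix", function(x, ...) x@values)

#' @export
#' @describeIn EdgeTable data.frame view of the edge rows.
#' @param x an EdgeTable.
#' @param ... ignored.
setMethod("as.data.frame", "EdgeTable", function(x, ...) x@edges)

## ---- show methods ---------------------------------------------------------

setMethod("show", "TpmExperiment", function(object) {
    cat(sprintf("TpmExperiment: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    v <- tpm(object)
    cat(sprintf("  tpm range [%.4g, %.4g]\n", min(v), max(v)))
    rem <- metadata(object)$removed
    if (!is.null(rem))
        cat(sprintf("  %d genes removed by the low-expression filter\n",
                    nrow(rem)))
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat(sprintf("CorrelationMatrix: %d genes (%d undefined)\n",
                nrow(object@values), sum(object@undefined)))
})

setMethod("show", "RankMatrix", function(object) {
    cat(sprintf("RankMatrix: directional ranks over %d genes\n",
                nrow(object@values)))
})

setMethod("show", "MutualRankMatrix", function(object) {
    cat(sprintf("MutualRankMatrix: %d genes\n", nrow(object@values)))
})

setMethod("show", "AdjacencyMatrix", function(object) {
    cat(sprintf("AdjacencyMatrix: %d genes, beta = %d\n",
                nrow(object@values), object@beta))
})

setMethod("show", "TomMatrix", function(object) {
    cat(sprintf("TomMatrix: %d genes\n", nrow(object@values)))
})

setMethod("show", "EdgeTable", function(object) {
    e <- object@edges
    cat(sprintf("EdgeTable: %d edges over %d genes\n",
                nrow(e), length(geneIds(object))))
    if (nrow(e)) {
        meth <- sort(unique(unlist(strsplit(e$methods, ","))))
        cat(sprintf("  methods: %s; %d negative edges\n",
                    paste(meth, collapse = ","), sum(e$sign == "-", na.rm = TRUE)))
    }
})

setMethod("show", "TpmThreshold", function(object) {
    cat(sprintf(
        "TpmThreshold: %.4g (low-tail mean %.4g + 3 x %.4g, tail %.3g)\n",
        object@threshold, object@meanLow, object@d, object@tailFraction))
})

setMethod("show", "SampleClusteringReport", function(object) {
    cat(sprintf("SampleClusteringReport: %d samples, %d flagged (cutoff %.4g)\n",
                length(object@tree$order), length(object@flagged),
                object@cutoff))
    if (length(object@flagged))
        cat("  flagged:", paste(object@flagged, collapse = ", "), "\n")
})

setMethod("show", "PccThresholds", function(object) {
    cat(sprintf(
        "PccThresholds: keep pcc >= %.4g or pcc <= %.4g (offset %.3g)\n",
        object@posCut, object@negCut, object@offset))
})

setMethod("show", "SoftPowerReport", function(object) {
    sel <- if (is.na(object@selectedBeta)) "none"
           else as.character(object@selectedBeta)
    cat(sprintf("SoftPowerReport: %d candidate powers, selected beta = %s (target R2 %.2f)\n",
                nrow(object@table), sel, object@r2Target))
})

setMethod("show", "GoldStandard", function(object) {
    cat(sprintf("GoldStandard: %d positives, %d negatives (%s)\n",
                sum(object@pairs$label == "positive"),
                sum(object@pairs$label == "negative"), object@source))
})

setMethod("show", "RocResult", function(object) {
    cat(sprintf("RocResult: AUC = %.4f (%d positives, %d negatives)\n",
                object@auc, object@nPos, object@nNeg))
})

setMethod("show", "NetworkStats", function(object) {
    cat(sprintf(paste0("NetworkStats: %d genes, %d edges, coverage %.2f%%, ",
                       "mean connectivity %.3f, %.2f%% negative\n"),
                object@nGenes, object@nEdges, object@geneCoveragePct,
                object@meanConnectivity, object@pctNegativeEdges))
})

setMethod("show", "SyntheticConfig", function(object) {
    cat(sprintf(paste0("SyntheticConfig: %d genes (%d module genes in %d ",
                       "modules, %d low-expression), %d samples, seed %d\n"),
                object@nGenes, sum(object@moduleSizes),
                length(object@moduleSizes), object@nLowExprGenes,
                object@nSamples, object@seed))
})

setMethod("show", "SyntheticDataset", function(object) {
    cat("SyntheticDataset\n")
    show(object@config)
})

## ---- small accessors ------------------------------------------------------

#' Numeric value of a TpmThreshold
#' @param t a [TpmThreshold-class].
#' @export
thresholdValue <- function(t) t@threshold

#' Flagged outlier samples of a clustering report
#' @param r a [SampleClusteringReport-class].
#' @export
flaggedOutliers <- function(r) r@flagged

#' Removal report of the low-expression filter
#' @param x a filtered [TpmExperiment-class].
#' @return data.frame (gene_id, max_tpm, threshold) or NULL.
#' @export
removalReport <- function(x) metadata(x)$removed

#' Selected soft power of a scale-free fit
#' @param r a [SoftPowerReport-class].
#' @export
selectedBeta <- function(r) r@selectedBeta

#' Candidate table of a scale-free fit
#' @param r a [SoftPowerReport-class].
#' @export
softPowerTable <- function(r) r@table

#' Labelled pairs of a gold standard
#' @param gs a [GoldStandard-class].
#' @export
goldPairs <- function(gs) gs@pairs

#' AUC of an ROC result
#' @param r a [RocResult-class].
#' @export
auc <- function(r) r@auc

#' ROC curve points
#' @param r a [RocResult-class].
#' @export
rocCurve <- function(r) r@curve
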