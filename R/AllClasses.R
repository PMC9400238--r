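#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors metadata metadata<-
NULL

#' TpmExperiment: a validated genes-by-samples TPM matrix
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single `tpm` assay. Validity enforces the contract every downstream
#' correlation step relies on: unique gene and sample identifiers and
#' non-negative, finite TPM values.
#'
#' @slot ... inherited from `SummarizedExperiment`; the `tpm` assay is the
#'   expression matrix.
#' @export
setClass("TpmExperiment", contains = "SummarizedExperiment")

.validTpmExperiment <- function(object) {
    msg <- NULL
    if (!("tpm" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'tpm' is required")
    else {
        v <- SummarizedExperiment::assay(object, "tpm")
        if (is.null(rownames(v)) || is.null(colnames(v)))
            msg <- c(msg, "gene (row) and sample (column) names are required")
        else {
            if (anyDuplicated(rownames(v)))
                msg <- c(msg, sprintf("duplicate gene ids: %s",
                    paste(unique(rownames(v)[duplicated(rownames(v))]),
                          collapse = ", ")))
            if (anyDuplicated(colnames(v)))
                msg <- c(msg, sprintf("duplicate sample ids: %s",
                    paste(unique(colnames(v)[duplicated(colnames(v))]),
                          collapse = ", ")))
        }
        if (!is.numeric(v))
            msg <- c(msg, "tpm values must be numeric")
        else {
            if (any(!is.finite(v)))
                msg <- c(msg, "tpm values must be finite")
            else if (any(v < 0))
                msg <- c(msg, "tpm values must be non-negative")
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("TpmExperiment", .validTpmExperiment)

#' Construct a TpmExperiment from a TPM matrix
#'
#' @param values numeric matrix of TPM, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param metadata optional list stored in the object metadata.
#' @return a [TpmExperiment-class] object.
#' @examples
#' m <- matrix(1:12, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' TpmExperiment(m)
#' @export
TpmExperiment <- function(values, metadata = list()) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(tpm = values), metadata = metadata)
    methods::new("TpmExperiment", se)
}

## ---- symmetric / directional gene-by-gene score matrices -------------------

#' Virtual parent for gene-by-gene score matrices
#'
#' Square matrices indexed by the same gene ids on both margins
#' (correlations, ranks, mutual ranks, adjacencies, topological overlap).
#' @slot values square numeric matrix with identical row/col gene ids.
#' @export
setClass("GeneScoreMatrix", representation("VIRTUAL", values = "matrix"))

.validGeneScoreMatrix <- function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
        return("row and column gene ids must be identical")
    if (anyDuplicated(rownames(v))) return("duplicate gene ids")
    TRUE
}
setValidity("GeneScoreMatrix", .validGeneScoreMatrix)

.validSymmetric <- function(object, tol = 1e-8) {
    v <- object@values
    d <- abs(v - t(v))
    if (any(d > tol, na.rm = TRUE)) return("matrix must be symmetric")
    TRUE
}

#' Pairwise Pearson correlation matrix
#'
#' @slot values symmetric matrix of Pearson correlations in `[-1, 1]`;
#'   entries involving an undefined (zero-variance) gene are `NA`.
#' @slot undefined logical vector flagging zero-variance genes, for which no
#'   correlation is defined.
#' @export
setClass("CorrelationMatrix", contains = "GeneScoreMatrix",
         representation(undefined = "logical"))

setValidity("CorrelationMatrix", function(object) {
    ok <- .validSymmetric(object)
    if (!isTRUE(ok)) return(ok)
    if (length(object@undefined) != nrow(object@values) ||
        !identical(names(object@undefined), rownames(object@values)))
        return("'undefined' must be named per gene")
    v <- object@values
    def <- !object@undefined
    if (any(abs(v[def, def, drop = FALSE]) > 1 + 1e-8, na.rm = TRUE))
        return("correlations must lie in [-1, 1]")
    dg <- diag(v)[def]
    if (any(abs(dg - 1) > 1e-8, na.rm = TRUE))
        return("diagonal must be 1 for defined genes")
    TRUE
})

#' Directional correlation rank matrix
#'
#' `values[A, B]` is the rank of gene B when A's partners are sorted by
#' correlation, best first (self excluded); ties broken by gene id. Rows for
#' undefined genes are `NA`.
#' @export
setClass("RankMatrix", contains = "GeneScoreMatrix")

setValidity("RankMatrix", function(object) {
    v <- object@values
    for (i in seq_len(nrow(v))) {
        r <- v[i, -i]
        r <- r[!is.na(r)]
        if (any(r < 1)) return("ranks must be >= 1")
        if (anyDuplicated(r))
            return(sprintf("row %s has duplicated ranks", rownames(v)[i]))
    }
    TRUE
})

#' Mutual rank matrix
#'
#' Symmetric geometric means of the two directional correlation ranks:
#' `MR(A,B) = sqrt(Rank(A->B) * Rank(B->A))`.
#' @export
setClass("MutualRankMatrix", contains = "GeneScoreMatrix")

setValidity("MutualRankMatrix", function(object) {
    ok <- .validSymmetric(object)
    if (!isTRUE(ok)) return(ok)
    off <- object@values[upper.tri(object@values)]
    if (any(off < 1 - 1e-8, na.rm = TRUE)) return("mutual ranks must be >= 1")
    TRUE
})

#' Soft-threshold adjacency matrix
#'
#' Unsigned adjacency `a_ij = |pcc_ij|^beta` with unit diagonal.
#' @slot beta integer soft power applied to `|pcc|`.
#' @export
setClass("AdjacencyMatrix", contains = "GeneScoreMatrix",
         representation(beta = "integer"))

setValidity("AdjacencyMatrix", function(object) {
    ok <- .validSymmetric(object)
    if (!isTRUE(ok)) return(ok)
    v <- object@values
    if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
        return("adjacency values must lie in [0, 1]")
    if (length(object@beta) != 1L || object@beta < 1L)
        return("beta must be a single integer >= 1")
    TRUE
})

#' Topological overlap matrix
#'
#' Unsigned TOM in `[0, 1]`, diagonal 1 by convention.
#' @export
setClass("TomMatrix", contains = "GeneScoreMatrix")

setValidity("TomMatrix", function(object) {
    ok <- .validSymmetric(object)
    if (!isTRUE(ok)) return(ok)
    v <- object@values
    if (any(v < -1e-10 | v > 1 + 1e-10, na.rm = TRUE))
        return("TOM values must lie in [0, 1]")
    TRUE
})

## ---- edge tables ----------------------------------------------------------

.edgeCols <- c("gene_a", "gene_b", "pcc", "rank_ab", "rank_ba", "mr", "tom",
               "sign", "methods")

#' Undirected co-expression edge table with method provenance
#'
#' One row per undirected gene pair with `gene_a < gene_b`. Score columns
#' (`pcc`, `rank_ab`, `rank_ba`, `mr`, `tom`) are `NA` where the producing
#' method did not compute them; `methods` is a comma-set drawn from
#' `{pcc, mr, tom}` recording which filters retained the pair; `sign` is
#' `"+"`/`"-"` following the sign of the correlation.
#'
#' @slot edges data.frame with the columns above (extra method-qualified
#'   columns may appear after integration of conflicting score columns).
#' @export
setClass("EdgeTable", representation(edges = "data.frame"))

setValidity("EdgeTable", function(object) {
    e <- object@edges
    if (!all(.edgeCols %in% colnames(e)))
        return(sprintf("missing columns: %s",
                       paste(setdiff(.edgeCols, colnames(e)), collapse = ", ")))
    if (!nrow(e)) return(TRUE)
    if (any(e$gene_a >= e$gene_b))
        return("gene_a must sort before gene_b in every row")
    if (anyDuplicated(paste(e$gene_a, e$gene_b, sep = "\r")))
        return("duplicate gene pairs")
    if (any(!nzchar(e$methods)))
        return("methods must be non-empty")
    has <- !is.na(e$pcc)
    if (any(has & e$sign != ifelse(e$pcc < 0, "-", "+")))
        return("sign must agree with the sign of pcc where pcc is present")
    TRUE
})

#' Construct an EdgeTable
#'
#' Pairs are normalised so `gene_a < gene_b` (directional ranks are swapped
#' accordingly) and rows are sorted by pair for deterministic output.
#'
#' @param gene_a,gene_b character endpoints of each undirected pair.
#' @param pcc,rank_ab,rank_ba,mr,tom numeric score columns (`NA` when absent).
#' @param methods character comma-set of producing methods per row.
#' @return an [EdgeTable-class].
#' @export
edgeTable <- function(gene_a = character(), gene_b = character(), pcc = NA_real_,
                      rank_ab = NA_real_, rank_ba = NA_real_, mr = NA_real_,
                      tom = NA_real_, methods = character()) {
    n <- length(gene_a)
    stopifnot(length(gene_b) == n)
    e <- data.frame(gene_a = as.character(gene_a),
                    gene_b = as.character(gene_b),
                    pcc = rep_len(pcc, n), rank_ab = rep_len(rank_ab, n),
                    rank_ba = rep_len(rank_ba, n), mr = rep_len(mr, n),
                    tom = rep_len(tom, n),
                    sign = rep_len(NA_character_, n),
                    methods = rep_len(as.character(methods), n),
                    stringsAsFactors = FALSE)
    if (n) {
        swap <- e$gene_a > e$gene_b
        if (any(swap)) {
            tmp <- e$gene_a[swap]
            e$gene_a[swap] <- e$gene_b[swap]
            e$gene_b[swap] <- tmp
            tmp <- e$rank_ab[swap]
            e$rank_ab[swap] <- e$rank_ba[swap]
            e$rank_ba[swap] <- tmp
        }
        e$sign <- ifelse(is.na(e$pcc), NA_character_,
                         ifelse(e$pcc < 0, "-", "+"))
        e <- e[order(e$gene_a, e$gene_b, method = "radix"), , drop = FALSE]
        rownames(e) <- NULL
    }
    methods::new("EdgeTable", edges = e)
}

## ---- small report objects -------------------------------------------------

#' 3-sigma low-expression TPM threshold
#'
#' `threshold = mean(low tail) + 3 * sd(low tail)` where the low tail is the
#' lowest `tailFraction` of all strictly positive TPM values in the matrix.
#' @slot threshold,meanLow,d,tailFraction numeric scalars.
#' @export
setClass("TpmThreshold", representation(threshold = "numeric",
    meanLow = "numeric", d = "numeric", tailFraction = "numeric"))

setValidity("TpmThreshold", function(object) {
    if (object@d < 0) return("dispersion d must be >= 0")
    if (abs(object@threshold - (object@meanLow + 3 * object@d)) > 1e-8)
        return("threshold must equal meanLow + 3 * d")
    TRUE
})

#' Sample hierarchical-clustering report with flagged outliers
#' @slot tree the `hclust` object (ward.D2 on Euclidean distances).
#' @slot flagged sample ids whose first merge height exceeds the height
#'   quantile cutoff.
#' @slot heightQuantile the quantile used; @slot cutoff its value.
#' @export
setClass("SampleClusteringReport", representation(tree = "ANY",
    flagged = "character", heightQuantile = "numeric", cutoff = "numeric"))

#' Hard correlation thresholds from quantiles plus an offset
#' @slot posCut retain `pcc >= posCut`; @slot negCut retain `pcc <= negCut`.
#' @slot topQ,bottomQ defining quantile fractions; @slot offset additive
#'   tightening applied to both cuts.
#' @export
setClass("PccThresholds", representation(posCut = "numeric",
    negCut = "numeric", topQ = "numeric", bottomQ = "numeric",
    offset = "numeric"))

setValidity("PccThresholds", function(object) {
    if (object@negCut >= object@posCut)
        return("negCut must be strictly below posCut")
    if (object@posCut > 1 || object@negCut < -1)
        return("cuts must lie within [-1, 1]")
    TRUE
})

#' Scale-free soft-power fit report
#' @slot table data.frame with columns beta, r2 (signed), slope, mean_k,
#'   selected.
#' @slot selectedBeta smallest beta reaching the fit target (`NA` if none).
#' @slot r2Target the signed R-squared target.
#' @export
setClass("SoftPowerReport", representation(table = "data.frame",
    selectedBeta = "integer", r2Target = "numeric"))

#' Labelled gold-standard gene pairs for ROC evaluation
#' @slot pairs data.frame with gene_a, gene_b (gene_a < gene_b), label in
#'   {"positive","negative"}.
#' @slot source free-text description; @slot seed seed used for negative
#'   sampling.
#' @export
setClass("GoldStandard", representation(pairs = "data.frame",
    source = "character", seed = "integer"))

setValidity("GoldStandard", function(object) {
    p <- object@pairs
    if (!all(c("gene_a", "gene_b", "label") %in% colnames(p)))
        return("pairs needs columns gene_a, gene_b, label")
    if (!nrow(p)) return("at least one labelled pair required")
    if (any(p$gene_a >= p$gene_b)) return("gene_a must sort before gene_b")
    if (!all(p$label %in% c("positive", "negative")))
        return("labels must be 'positive' or 'negative'")
    key <- paste(p$gene_a, p$gene_b, sep = "\r")
    if (anyDuplicated(key)) return("a pair appears more than once")
    if (!any(p$label == "positive") || !any(p$label == "negative"))
        return("need at least one positive and one negative")
    TRUE
})

#' ROC curve and area under the curve
#' @slot auc tie-corrected AUC in `[0, 1]` (equals the normalised
#'   Mann-Whitney U statistic).
#' @slot nPos,nNeg label counts; @slot curve data.frame of (fpr, tpr) points.
#' @export
setClass("RocResult", representation(auc = "numeric", nPos = "integer",
    nNeg = "integer", curve = "data.frame"))

setValidity("RocResult", function(object) {
    if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
        return("auc must lie in [0, 1]")
    cv <- object@curve
    if (nrow(cv)) {
        if (any(diff(cv$fpr) < -1e-12) || any(diff(cv$tpr) < -1e-12))
            return("curve coordinates must be non-decreasing")
    }
    TRUE
})

#' Whole-network summary statistics
#' @slot nGenes,nEdges counts; @slot geneCoveragePct percent of the stated
#'   gene universe touched by an edge; @slot meanConnectivity `2E / V`;
#'   @slot pctNegativeEdges percent of signed edges with negative sign.
#' @export
setClass("NetworkStats", representation(nGenes = "integer", nEdges = "integer",
    geneCoveragePct = "numeric", meanConnectivity = "numeric",
    pctNegativeEdges = "numeric"))

## ---- synthetic data -------------------------------------------------------

#' Configuration of the planted-module expression simulator
#'
#' See [simulateExpression()] for the generative model. Gene budget:
#' `sum(moduleSizes) + nLowExprGenes + background = nGenes`.
#' @export
setClass("SyntheticConfig", representation(nGenes = "integer",
    nSamples = "integer", moduleSizes = "integer",
    antiCorrFraction = "numeric", noiseSd = "numeric",
    signalStrength = "numeric", nLowExprGenes = "integer",
    baselineLogTpmRange = "numeric", lowExprCeiling = "numeric",
    lowExprDropout = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    bg <- object@nGenes - sum(object@moduleSizes) - object@nLowExprGenes
    if (bg < 0)
        return("module sizes plus low-expression genes exceed nGenes")
    if (any(object@moduleSizes < 2L))
        return("each module needs at least 2 genes")
    if (object@nSamples < 3L) return("need at least 3 samples")
    if (object@antiCorrFraction < 0 || object@antiCorrFraction > 1)
        return("antiCorrFraction must lie in [0, 1]")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (length(object@baselineLogTpmRange) != 2L ||
        diff(object@baselineLogTpmRange) < 0)
        return("baselineLogTpmRange must be an increasing pair")
    if (object@lowExprDropout < 0 || object@lowExprDropout >= 1)
        return("lowExprDropout must lie in [0, 1)")
    TRUE
})

#' Simulated expression dataset with planted ground truth
#' @slot experiment the generated [TpmExperiment-class].
#' @slot moduleOf named integer, module id per gene (0 = background or
#'   low-expression).
#' @slot loadingSign named numeric in {+1, -1}, loading direction per module
#'   gene.
#' @slot lowExpression ids of the planted low-expression genes.
#' @slot config the generating [SyntheticConfig-class].
#' @export
setClass("SyntheticDataset", representation(experiment = "TpmExperiment",
    moduleOf = "integer", loadingSign = "numeric", lowExpression = "character",
    config = "SyntheticConfig"))
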