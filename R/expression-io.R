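## Reading, writing and filtering of genes x samples TPM matrices.

#' Read a TPM expression matrix from TSV
#'
#' Expects a tab-delimited UTF-8 file whose first row holds sample ids (first
#' header cell is the gene-id column name, conventionally `gene_id`) and whose
#' first column holds gene ids. Duplicated gene or sample ids and negative or
#' non-numeric cells are errors, never silently merged or coerced.
#'
#' @param path path to the TSV file.
#' @return a [TpmExperiment-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(0:11, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' writeExpressionTsv(TpmExperiment(m), f)
#' readExpressionTsv(f)
#' @export
readExpressionTsv <- function(path) {
    if (!file.exists(path)) stop("expression file not found: ", path)
    raw <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             quote = "", comment.char = "",
                             fileEncoding = "UTF-8")
    if (ncol(raw) < 2L) stop("expected a gene-id column plus >= 1 sample")
    gene_ids <- raw[[1L]]
    dup <- unique(gene_ids[duplicated(gene_ids)])
    if (length(dup))
        stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     vals[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
                     colnames(vals)[bad[1L, 2L]]))
    if (anyNA(num)) stop("missing values are not allowed")
    if (any(num < 0)) {
        bad <- which(num < 0, arr.ind = TRUE)
        stop(sprintf("negative TPM at gene '%s', sample '%s'",
                     gene_ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
    }
    dimnames(num) <- list(gene_ids, colnames(vals))
    TpmExperiment(num)
}

#' Write a TPM expression matrix to TSV
#'
#' Values are written with `format(..., digits = 15)` so a read/write
#' round-trip reproduces them to full double precision.
#'
#' @param x a [TpmExperiment-class].
#' @param path output path.
#' @param idColumn header of the gene-id column.
#' @return `path`, invisibly.
#' @export
writeExpressionTsv <- function(x, path, idColumn = "gene_id") {
    stopifnot(methods::is(x, "TpmExperiment"))
    v <- tpm(x)
    df <- data.frame(id = rownames(v),
                     format(v, digits = 15, trim = TRUE, scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df)[1L] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Merge samples belonging to the same experimental group by mean
#'
#' @param x a [TpmExperiment-class].
#' @param groups named character vector or two-column data.frame mapping
#'   sample id to group label; samples absent from the map are kept as
#'   singleton groups.
#' @return a [TpmExperiment-class] with one column per group, values averaged.
#' @export
mergeSampleGroups <- function(x, groups) {
    if (is.data.frame(groups)) {
        g <- as.character(groups[[2L]])
        names(g) <- as.character(groups[[1L]])
        groups <- g
    }
    sm <- sampleIds(x)
    lab <- ifelse(sm %in% names(groups), groups[sm], sm)
    v <- tpm(x)
    out <- vapply(unique(lab), function(l)
        rowMeans(v[, lab == l, drop = FALSE]), numeric(nrow(v)))
    rownames(out) <- rownames(v)
    TpmExperiment(out, metadata = metadata(x))
}

#' Compute the 3-sigma low-expression TPM threshold
#'
#' The low tail is the lowest `ceiling(tailFraction * N)` of the strictly
#' positive TPM values pooled across the whole matrix (N = number of positive
#' values); the threshold is `mean(tail) + 3 * sd(tail)` with the sample
#' standard deviation (`sd` of a single value is taken as 0). Zeros are
#' excluded so that sparsely expressed matrices do not collapse the tail.
#'
#' @param x a [TpmExperiment-class].
#' @param tailFraction fraction of positive values defining the low tail,
#'   in (0, 0.5); default 0.05.
#' @return a [TpmThreshold-class].
#' @examples
#' m <- matrix(c(0.1, 0.1, 0.2, 0.2, rep(10, 8)), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' computeTpmThreshold(TpmExperiment(m), tailFraction = 1 / 3)
#' @export
computeTpmThreshold <- function(x, tailFraction = 0.05) {
    stopifnot(methods::is(x, "TpmExperiment"))
    if (tailFraction <= 0 || tailFraction >= 0.5)
        stop("tailFraction must lie in (0, 0.5)")
    v <- tpm(x)
    pos <- v[v > 0]
    if (!length(pos)) stop("no strictly positive TPM values in the matrix")
    n <- ceiling(tailFraction * length(pos))
    tail <- sort(pos, method = "radix")[seq_len(n)]
    meanLow <- mean(tail)
    d <- if (length(tail) > 1L) stats::sd(tail) else 0
    methods::new("TpmThreshold", threshold = meanLow + 3 * d,
                 meanLow = meanLow, d = d, tailFraction = tailFraction)
}

#' Remove genes below a TPM threshold in every sample
#'
#' A gene is removed only when its TPM is below the threshold in all samples
#' (`max(tpm) < threshold`); genes expressed above threshold in even one
#' sample — e.g. tissue-specific genes — are retained. The removal report
#' (gene_id, max_tpm, threshold) is stored in the result's metadata and
#' available via [removalReport()].
#'
#' @param x a [TpmExperiment-class].
#' @param t a [TpmThreshold-class] or a numeric threshold.
#' @return the filtered [TpmExperiment-class]; samples unchanged.
#' @export
filterLowExpression <- function(x, t) {
    stopifnot(methods::is(x, "TpmExperiment"))
    thr <- if (methods::is(t, "TpmThreshold")) t@threshold else as.numeric(t)
    v <- tpm(x)
    mx <- apply(v, 1L, max)
    drop <- mx < thr
    report <- data.frame(gene_id = rownames(v)[drop],
                         max_tpm = unname(mx[drop]),
                         threshold = rep_len(thr, sum(drop)),
                         row.names = NULL, stringsAsFactors = FALSE)
    md <- metadata(x)
    md$removed <- report
    TpmExperiment(v[!drop, , drop = FALSE], metadata = md)
}

#' Write a low-expression removal report to TSV
#' @param x a filtered [TpmExperiment-class] (see [filterLowExpression()]).
#' @param path output path.
#' @export
writeRemovalReport <- function(x, path) {
    rep <- removalReport(x)
    if (is.null(rep)) stop("no removal report attached; run filterLowExpression first")
    utils::write.table(rep, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Flag outlier samples by hierarchical clustering
#'
#' Samples are clustered on the Euclidean distance between expression
#' profiles with Ward linkage in its squared-distance form
#' (`hclust(..., method = "ward.D2")`). A sample is flagged when the height
#' at which it first merges into the tree strictly exceeds the
#' `heightQuantile` quantile (linear-interpolation convention) of all merge
#' heights. Flagging is report-only: no sample is ever dropped automatically.
#'
#' @param x a [TpmExperiment-class] with at least 3 samples.
#' @param heightQuantile quantile of merge heights used as the cutoff.
#' @return a [SampleClusteringReport-class].
#' @export
detectOutlierSamples <- function(x, heightQuantile = 0.99) {
    stopifnot(methods::is(x, "TpmExperiment"))
    if (ncol(x) < 3L) stop("need at least 3 samples")
    v <- t(tpm(x))
    hc <- stats::hclust(stats::dist(v), method = "ward.D2")
    cutoff <- unname(stats::quantile(hc$height, heightQuantile, type = 7))
    ## height at which each leaf first joins a cluster (merges are in
    ## non-decreasing height order, so the first occurrence is the join)
    firstH <- vapply(seq_len(ncol(x)), function(i) {
        hit <- which(hc$merge[, 1L] == -i | hc$merge[, 2L] == -i)[1L]
        hc$height[hit]
    }, numeric(1L))
    flagged <- sort(colnames(x)[firstH > cutoff], method = "radix")
    methods::new("SampleClusteringReport", tree = hc, flagged = flagged,
                 heightQuantile = heightQuantile, cutoff = cutoff)
}
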