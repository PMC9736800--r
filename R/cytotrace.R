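#' Detected genes per cell
#'
#' Number of genes with a nonzero value in each cell, the raw signal behind
#' the differentiation-potential score: cells of higher developmental
#' potential tend to express more genes.
#'
#' @param x SummarizedExperiment (its `counts` assay if present, otherwise
#'   `logcounts`) or a genes x cells matrix.
#' @return named integer vector, one count per cell.
#' @export
geneCounts <- function(x) {
    if (methods::is(x, "SummarizedExperiment")) {
        nm <- SummarizedExperiment::assayNames(x)
        m <- SummarizedExperiment::assay(x, if ("counts" %in% nm) "counts"
                                            else nm[1L])
    } else m <- as.matrix(x)
    colSums(m > 0)
}

#' Gene-counts signature score
#'
#' Correlates each gene's log-normalized expression with the per-cell
#' detected-gene count, then averages the `topN` most positively correlated
#' genes per cell. This is the core of CytoTRACE-style potency estimation:
#' genes tracking cellular gene-count diversity report developmental
#' potential more robustly than the raw count itself.
#'
#' @param x SummarizedExperiment with `logcounts`, or a log-normalized
#'   matrix.
#' @param topN number of top-correlated genes to average (200 is the cited
#'   method's convention).
#' @return named numeric vector, one score per cell.
#' @export
gcsScore <- function(x, topN = 200L) {
    if (methods::is(x, "SummarizedExperiment")) {
        .requireLayer(x, "logcounts")
        m <- SummarizedExperiment::assay(x, "logcounts")
    } else m <- as.matrix(x)
    if (ncol(m) < 3L) stop("at least 3 cells required", call. = FALSE)
    if (topN > nrow(m)) stop("topN exceeds the number of genes", call. = FALSE)
    gc <- geneCounts(m)
    if (stats::var(gc) == 0)
        stop("no potency signal: detected-gene counts are constant",
             call. = FALSE)
    cors <- suppressWarnings(as.vector(stats::cor(t(m), gc)))
    cors[is.na(cors)] <- -Inf           # zero-variance genes rank last
    ord <- order(-cors, rownames(m))
    top <- ord[seq_len(topN)]
    colMeans(m[top, , drop = FALSE])
}

#' k-nearest-neighbor smoothing of per-cell scores
#'
#' Replaces each cell's score by the mean over its `k` nearest neighbors
#' (Euclidean distance in PCA space of the log-normalized matrix), the cell
#' itself included. `k = 1` is the identity.
#'
#' @param scores numeric vector, one value per cell.
#' @param x SummarizedExperiment with `logcounts`, or a log-normalized
#'   matrix whose columns match `scores`.
#' @param k neighborhood size (including self); must be < number of cells.
#' @param nPCs number of principal components for the neighbor metric.
#' @return smoothed numeric vector.
#' @export
smoothScores <- function(scores, x, k = 30L, nPCs = 30L) {
    if (k <= 0) stop("k must be positive", call. = FALSE)
    if (methods::is(x, "SummarizedExperiment")) {
        .requireLayer(x, "logcounts")
        m <- SummarizedExperiment::assay(x, "logcounts")
    } else m <- as.matrix(x)
    n <- ncol(m)
    if (k >= n) stop("k must be smaller than the number of cells",
                     call. = FALSE)
    if (length(scores) != n)
        stop("scores length does not match the number of cells", call. = FALSE)
    if (k == 1L) return(scores)
    keep <- apply(m, 1L, stats::var) > 0
    pc <- stats::prcomp(t(m[keep, , drop = FALSE]), center = TRUE,
                        rank. = min(nPCs, sum(keep), n - 1L))$x
    d <- as.matrix(stats::dist(pc))
    vapply(seq_len(n), function(i) {
        nb <- order(d[i, ])[seq_len(k)]
        mean(scores[nb])
    }, numeric(1))
}

#' Differentiation-potential score per cell
#'
#' Full CytoTRACE-style pipeline: detected-gene counts, gene-counts
#' signature ([gcsScore()]), kNN smoothing ([smoothScores()]), and a final
#' rank transform to \[0,1\] (ties averaged). Higher values indicate higher
#' developmental potential, i.e. less differentiated cells. The final score
#' depends on the smoothed signature only through ranks, so it is invariant
#' under monotone rescaling of the signature.
#'
#' @param x SummarizedExperiment with `logcounts`, or a log-normalized
#'   matrix.
#' @param topN genes averaged in the signature (see [gcsScore()]).
#' @param k smoothing neighborhood (see [smoothScores()]); `smooth = FALSE`
#'   disables smoothing.
#' @param nPCs principal components for the neighbor metric.
#' @param smooth logical; apply kNN smoothing.
#' @return [S4Vectors::DataFrame] with columns `cell_id`, `detected_genes`,
#'   `gcs`, `smoothed`, `scaled_score`.
#' @export
cytotraceScore <- function(x, topN = 200L, k = 30L, nPCs = 30L,
                           smooth = TRUE) {
    if (methods::is(x, "SummarizedExperiment")) {
        .requireLayer(x, "logcounts")
        m <- SummarizedExperiment::assay(x, "logcounts")
    } else m <- as.matrix(x)
    gc <- geneCounts(m)
    if (stats::var(gc) == 0 && all(m == m[, 1L])) {
        # fully degenerate input: identical cells carry no potency ordering
        gcs <- colMeans(m)
        sm <- gcs
    } else {
        gcs <- gcsScore(m, topN = topN)
        sm <- if (smooth) smoothScores(gcs, m, k = k, nPCs = nPCs) else gcs
    }
    n <- length(sm)
    r <- rank(sm, ties.method = "average")
    scaled <- if (n > 1L) (r - 1) / (n - 1) else 0.5
    S4Vectors::DataFrame(
        cell_id = colnames(m), detected_genes = as.integer(gc),
        gcs = gcs, smoothed = sm, scaled_score = scaled,
        row.names = colnames(m))
}
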