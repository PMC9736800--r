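#' Min-max scaling to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1. A constant
#' vector is mapped to all 0.5 with a warning (the degenerate case carries
#' no ordering information).
#'
#' @param x numeric vector of length >= 2.
#' @return numeric vector in \[0,1\].
#' @export
minmaxScale <- function(x) {
    if (length(x) < 2L)
        stop("minmaxScale requires at least 2 values", call. = FALSE)
    rng <- range(x)
    if (rng[1L] == rng[2L]) {
        warning("constant input: all scaled scores set to 0.5", call. = FALSE)
        return(rep(0.5, length(x)))
    }
    (x - rng[1L]) / (rng[2L] - rng[1L])
}

# signed sum-statistic ssGSEA for one expression vector.
# ord: gene order (descending expression, ties by gene id); inSet: logical in
# ranked order; weights w_i = (N - i + 1)^alpha, i.e. rank counted from the
# bottom so the top gene carries N^alpha.
.ssgseaOne <- function(inRanked, alpha) {
    N <- length(inRanked)
    s <- sum(inRanked)
    w <- (N - seq_len(N) + 1)^alpha
    inc <- ifelse(inRanked, w / sum(w[inRanked]), -1 / (N - s))
    sum(cumsum(inc))
}

#' Single-sample GSEA scores
#'
#' For every sample (cell or bulk sample), genes are ranked by expression in
#' decreasing order (ties broken deterministically by gene identifier) and a
#' weighted running sum walks the ranking: in-set genes add their rank weight
#' `(N - position + 1)^alpha` normalized by the in-set total, out-of-set
#' genes subtract `1/(N - |G|)`. The raw score is the sum of the running sum
#' over all positions (the sum statistic, not the maximum deviation), and is
#' therefore invariant under any strictly monotone transform of a sample's
#' expression. Raw scores are min-max scaled to \[0,1\] across the scored
#' population.
#'
#' Genes of the set absent from the matrix are dropped with a message; at
#' least 2 set genes must remain. All-constant samples are scored but
#' flagged in the `constant` column.
#'
#' @param x SingleCellExperiment/SummarizedExperiment with a `logcounts`
#'   assay, or a genes x samples numeric matrix of log-normalized values.
#' @param geneSet character vector of gene identifiers.
#' @param alpha rank-weight exponent; 0.25 is the cited single-sample GSEA
#'   convention (`alpha = 0` gives the unweighted Kolmogorov-Smirnov walk).
#' @return [S4Vectors::DataFrame] with columns `sample_id`, `raw_score`,
#'   `scaled_score`, `constant`; scaling metadata in `metadata()`.
#' @export
ssgseaScore <- function(x, geneSet, alpha = 0.25) {
    if (methods::is(x, "SummarizedExperiment")) {
        .requireLayer(x, "logcounts")
        m <- SummarizedExperiment::assay(x, "logcounts")
    } else m <- as.matrix(x)
    genes <- rownames(m)
    geneSet <- unique(geneSet)
    present <- geneSet[geneSet %in% genes]
    dropped <- length(geneSet) - length(present)
    if (dropped > 0L)
        message(dropped, " gene(s) of the set absent from the matrix; dropped")
    if (length(present) < 2L)
        stop("gene set overlaps the matrix in fewer than 2 genes; missing: ",
             paste(utils::head(setdiff(geneSet, genes), 10L), collapse = ", "),
             call. = FALSE)
    inSet <- genes %in% present
    nS <- ncol(m)
    raw <- numeric(nS)
    constant <- logical(nS)
    tieBreak <- order(genes)          # lexicographic gene-id tie-break
    for (j in seq_len(nS)) {
        e <- m[, j]
        constant[j] <- length(unique(e)) == 1L
        ord <- tieBreak[order(-e[tieBreak])]   # stable: ties by gene id
        raw[j] <- .ssgseaOne(inSet[ord], alpha)
    }
    if (any(constant))
        warning(sum(constant), " all-constant sample(s) flagged", call. = FALSE)
    scaled <- if (nS >= 2L) minmaxScale(raw) else rep(0.5, nS)
    out <- S4Vectors::DataFrame(
        sample_id = colnames(m), raw_score = raw, scaled_score = scaled,
        constant = constant, row.names = colnames(m))
    S4Vectors::metadata(out) <- list(alpha = alpha, set_size = length(present),
                                     dropped = dropped)
    out
}
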