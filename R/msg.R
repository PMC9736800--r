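#' Wilcoxon differential expression between two cell groups
#'
#' Per-gene two-sample Wilcoxon rank-sum test on log-normalized expression,
#' with the log fold change computed on de-logged means with a pseudocount:
#' `log_fc = ln(mean(expm1(a)) + 1) - ln(mean(expm1(b)) + 1)` (natural log).
#' Only genes detected in at least `minPct` of either group are tested;
#' p-values are Benjamini-Hochberg adjusted across all tested genes.
#' The `direction` column applies the signature-gene rule: `up` when
#' `adj_p < pThresh` and `log_fc > lfcThresh`, `down` for the mirrored
#' condition, `ns` otherwise.
#'
#' @param x SummarizedExperiment with `logcounts`, or a log-normalized
#'   genes x cells matrix.
#' @param groupA,groupB disjoint character vectors of cell identifiers
#'   (each >= 3 cells); `groupA` is the numerator of the fold change.
#' @param minPct minimum detection fraction in either group for a gene to be
#'   tested.
#' @param pThresh,lfcThresh thresholds feeding the `direction` call
#'   (adjusted p < `pThresh`, |log fold change| > `lfcThresh`, both strict).
#' @return data.frame with `gene_id`, `log_fc`, `p_value`, `adj_p`,
#'   `direction`, ordered by `p_value`.
#' @export
wilcoxonDE <- function(x, groupA, groupB, minPct = 0.1,
                       pThresh = 0.05, lfcThresh = 0.25) {
    if (methods::is(x, "SummarizedExperiment")) {
        .requireLayer(x, "logcounts")
        m <- SummarizedExperiment::assay(x, "logcounts")
    } else m <- as.matrix(x)
    if (length(intersect(groupA, groupB)))
        stop("groups must be disjoint", call. = FALSE)
    if (length(groupA) < 3L || length(groupB) < 3L)
        stop("each group needs at least 3 cells", call. = FALSE)
    bad <- setdiff(c(groupA, groupB), colnames(m))
    if (length(bad))
        stop("cell id(s) absent from the matrix: ",
             paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    A <- m[, groupA, drop = FALSE]
    B <- m[, groupB, drop = FALSE]
    pct <- pmax(rowMeans(A > 0), rowMeans(B > 0))
    tested <- which(pct >= minPct)
    if (!length(tested)) stop("no genes pass the detection filter",
                              call. = FALSE)
    p <- vapply(tested, function(i) {
        a <- A[i, ]; b <- B[i, ]
        if (length(unique(c(a, b))) == 1L) return(1)   # fully tied gene
        pv <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
        if (is.na(pv)) 1 else pv
    }, numeric(1))
    lfc <- log(rowMeans(expm1(A[tested, , drop = FALSE])) + 1) -
           log(rowMeans(expm1(B[tested, , drop = FALSE])) + 1)
    adj <- bhAdjust(p)
    dir <- ifelse(adj < pThresh & lfc > lfcThresh, "up",
                  ifelse(adj < pThresh & lfc < -lfcThresh, "down", "ns"))
    out <- data.frame(gene_id = rownames(m)[tested], log_fc = unname(lfc),
                      p_value = p, adj_p = adj, direction = dir)
    out[order(out$p_value, out$gene_id), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validated wrapper around
#' `p.adjust(method = "BH")`.
#'
#' @param pValues numeric vector of p-values in \[0,1\].
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(pValues) {
    if (any(!is.finite(pValues)) || any(pValues < 0 | pValues > 1))
        stop("p-values must lie in [0,1]", call. = FALSE)
    stats::p.adjust(pValues, method = "BH")
}

#' Select metastatic signature genes from a differential-expression table
#'
#' Partitions genes by the signature rule: up-regulated when
#' `adj_p < pThresh` and `log_fc > lfcThresh`, down-regulated for the
#' mirrored condition (both inequalities strict).
#'
#' @param results data.frame from [wilcoxonDE()].
#' @param pThresh adjusted-p threshold.
#' @param lfcThresh absolute log-fold-change threshold.
#' @return list with character vectors `up` and `down`.
#' @export
selectMSGs <- function(results, pThresh = 0.05, lfcThresh = 0.25) {
    if (!nrow(results)) stop("empty results", call. = FALSE)
    up <- results$gene_id[results$adj_p < pThresh &
                          results$log_fc > lfcThresh]
    down <- results$gene_id[results$adj_p < pThresh &
                            results$log_fc < -lfcThresh]
    message(length(up), " up- and ", length(down),
            " down-regulated signature genes selected")
    list(up = up, down = down)
}

#' Over-representation analysis against a gene-set collection
#'
#' Hypergeometric upper-tail test of the overlap between a query gene list
#' and each set (both restricted to the universe), Benjamini-Hochberg
#' adjusted across sets. Rows with overlap >= 1 and adjusted p < 0.05 are
#' returned.
#'
#' @param query character vector; must be a subset of `universe`.
#' @param universe character vector of all testable genes.
#' @param sets a [GeneSetCollection-class] or named list.
#' @param pThresh adjusted-p cutoff for reporting.
#' @param minCount minimum overlap for reporting.
#' @return data.frame with `set_name`, `overlap_count`, `set_size`,
#'   `p_value`, `adj_p`, ordered by p-value.
#' @export
oraEnrichment <- function(query, universe, sets, pThresh = 0.05,
                          minCount = 1L) {
    offenders <- setdiff(query, universe)
    if (length(offenders))
        stop("query gene(s) not in universe: ",
             paste(utils::head(offenders, 10L), collapse = ", "),
             call. = FALSE)
    sets <- geneSets(sets)
    if (!length(sets)) stop("empty gene-set collection", call. = FALSE)
    if (!length(query))
        return(data.frame(set_name = character(), overlap_count = integer(),
                          set_size = integer(), p_value = numeric(),
                          adj_p = numeric()))
    N <- length(unique(universe))
    n <- length(unique(query))
    rows <- lapply(names(sets), function(nm) {
        K <- length(intersect(sets[[nm]], universe))
        k <- length(intersect(sets[[nm]], query))
        p <- if (K == 0L) 1 else
            stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(set_name = nm, overlap_count = k, set_size = K,
                   p_value = p)
    })
    out <- do.call(rbind, rows)
    out$adj_p <- bhAdjust(out$p_value)
    out <- out[out$overlap_count >= minCount & out$adj_p < pThresh, ,
               drop = FALSE]
    out <- out[order(out$p_value, out$set_name), , drop = FALSE]
    rownames(out) <- NULL
    out
}
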