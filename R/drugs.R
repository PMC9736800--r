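#' Construct a ranked gene list
#'
#' @param genes character vector of unique genes, most up-regulated first.
#' @param label identifier for the list.
#' @return a [RankedList-class].
#' @export
rankedList <- function(genes, label = "ranking") {
    methods::new("RankedList", label = label, genes = as.character(genes))
}

#' Build per-drug rankings from a fold-change table
#'
#' Splits a long-format table (`drug`, `condition`, `gene`, `log_fc`) into
#' one [RankedList-class] per drug/condition, ordering genes by decreasing
#' fold change (ties broken by gene identifier).
#'
#' @param fc data.frame with columns `drug`, `condition`, `gene`, `log_fc`.
#' @return named list: per drug, a list of `RankedList`s.
#' @export
rankingsFromFC <- function(fc) {
    need <- c("drug", "condition", "gene", "log_fc")
    if (!all(need %in% names(fc)))
        stop("fold-change table must have columns ",
             paste(need, collapse = ", "), call. = FALSE)
    out <- list()
    for (d in unique(fc$drug)) {
        sub <- fc[fc$drug == d, , drop = FALSE]
        out[[d]] <- lapply(unique(sub$condition), function(cond) {
            cs <- sub[sub$condition == cond, , drop = FALSE]
            ord <- order(-cs$log_fc, cs$gene)
            rankedList(cs$gene[ord], label = paste(d, cond, sep = ":"))
        })
    }
    out
}

.checkUniverse <- function(a, b) {
    if (length(a@genes) != length(b@genes) ||
        !setequal(a@genes, b@genes))
        stop("rankings do not share the same gene universe", call. = FALSE)
    invisible(TRUE)
}

#' Spearman footrule distance between two rankings
#'
#' Sum over genes of the absolute rank difference.
#'
#' @param a,b [RankedList-class] objects over the same gene universe.
#' @return non-negative number.
#' @export
footruleDistance <- function(a, b) {
    .checkUniverse(a, b)
    rb <- match(a@genes, b@genes)
    sum(abs(seq_along(a@genes) - rb))
}

#' Borda merge of two rankings
#'
#' Re-ranks the shared universe by the mean of the two ranks; ties broken
#' lexicographically by gene identifier.
#'
#' @param a,b [RankedList-class] objects over the same gene universe.
#' @return merged [RankedList-class].
#' @export
bordaMerge <- function(a, b) {
    .checkUniverse(a, b)
    meanRank <- (seq_along(a@genes) + match(a@genes, b@genes)) / 2
    ord <- order(meanRank, a@genes)
    rankedList(a@genes[ord], label = paste(a@label, b@label, sep = "+"))
}

#' Prototype Ranked List merge
#'
#' Hierarchical majority-voting aggregation of several per-condition
#' rankings of one drug: repeatedly find the pair of lists with the smallest
#' Spearman footrule distance (ties resolved toward the first pair in stable
#' input order), replace the pair by their Borda merge, and iterate until a
#' single prototype list remains. Genes consistently up- or down-regulated
#' across conditions end up at the top or bottom of the prototype.
#'
#' @param lists list of [RankedList-class] objects sharing one universe.
#' @param drug drug identifier for the result.
#' @return a [PRLResult-class].
#' @export
prlMerge <- function(lists, drug = "drug") {
    if (!length(lists)) stop("empty list of rankings", call. = FALSE)
    nIn <- length(lists)
    for (l in lists[-1L]) .checkUniverse(lists[[1L]], l)
    while (length(lists) > 1L) {
        best <- NULL; bestD <- Inf
        for (i in seq_len(length(lists) - 1L)) {
            for (j in seq(i + 1L, length(lists))) {
                dij <- footruleDistance(lists[[i]], lists[[j]])
                if (dij < bestD) { bestD <- dij; best <- c(i, j) }
            }
        }
        merged <- bordaMerge(lists[[best[1L]]], lists[[best[2L]]])
        lists[[best[1L]]] <- merged
        lists[[best[2L]]] <- NULL
    }
    methods::new("PRLResult", drug = drug, merged = lists[[1L]],
                 nConditions = as.integer(nIn))
}

# Enrichment score from sorted hit positions. The running sum increases by
# w[pos]/sum(w[pos]) at hits and decreases by 1/(N - s) per miss; extrema can
# only occur immediately after a hit or immediately before the next hit, so
# the walk is evaluated only there.
.esFromPositions <- function(pos, w, N) {
    s <- length(pos)
    wHit <- w[pos]
    if (sum(wHit) == 0) wHit <- rep(1, s)
    cumIn <- cumsum(wHit) / sum(wHit)
    miss <- 1 / (N - s)
    idx <- seq_len(s)
    afterHit <- cumIn - (pos - idx) * miss
    beforeNext <- cumIn - (c(pos[-1L], N + 1L) - 1L - idx) * miss
    candidates <- c(-(pos[1L] - 1L) * miss, afterHit, beforeNext)
    hi <- max(candidates); lo <- min(candidates)
    if (abs(hi) >= abs(lo)) hi else lo
}

#' Preranked GSEA on a ranked gene list
#'
#' Weighted Kolmogorov-Smirnov enrichment of a gene set along a ranking
#' that carries no magnitudes (e.g. a Prototype Ranked List): each gene at
#' position `i` is assigned the centered rank score `(N+1)/2 - i` (positive
#' at the top), in-set genes advance the running sum by
#' `|score|^weight / sum(in-set |score|^weight)`, out-of-set genes retreat
#' it by `1/(N - |S|)`, and the enrichment score (ES) is the signed maximum
#' deviation. The p-value is a one-sided gene-label permutation test toward
#' the observed sign, floored at `1/(nPerm+1)`.
#'
#' @param ranking a [RankedList-class] or character vector (top first).
#' @param geneSet character vector; at least 2 members must be present in
#'   the ranking, and the set must not cover the whole universe.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @param weight exponent on the centered-rank magnitudes (1 = the common
#'   weighted default; 0 = classic unweighted KS).
#' @param alternative `"observed"` (default) tests the tail of the observed
#'   ES sign — the convention of fast preranked GSEA implementations, but
#'   anti-conservative as an unconditional p-value since the tested tail is
#'   chosen from the data; `"less"`/`"greater"` fix the tested direction in
#'   advance and are calibrated (uniform under the null).
#' @return list with `es` in \[-1, 1\] and `p`.
#' @export
gseaPreranked <- function(ranking, geneSet, nPerm = 1000L, seed = 0L,
                          weight = 1,
                          alternative = c("observed", "less", "greater")) {
    alternative <- match.arg(alternative)
    genes <- if (methods::is(ranking, "RankedList")) ranking@genes
             else as.character(ranking)
    N <- length(genes)
    pos <- sort(which(genes %in% geneSet))
    s <- length(pos)
    if (s < 2L)
        stop("gene set overlaps the ranking in fewer than 2 genes",
             call. = FALSE)
    if (s >= N)
        stop("gene set covers the whole ranking; enrichment undefined",
             call. = FALSE)
    if (nPerm < 100L) stop("nPerm must be at least 100", call. = FALSE)
    score <- (N + 1) / 2 - seq_len(N)
    w <- abs(score)^weight
    es <- .esFromPositions(pos, w, N)
    lower <- switch(alternative, observed = es < 0, less = TRUE,
                    greater = FALSE)
    set.seed(seed)
    extreme <- 0L
    for (b in seq_len(nPerm)) {
        esPerm <- .esFromPositions(sort(sample.int(N, s)), w, N)
        if (if (lower) esPerm <= es else esPerm >= es)
            extreme <- extreme + 1L
    }
    list(es = es, p = (1 + extreme) / (nPerm + 1))
}

#' Call candidate signature-reversing drugs
#'
#' For every drug's prototype ranking, tests the up- and down-regulated
#' signature genes by [gseaPreranked()]. A drug is a reversal candidate when
#' the up-signature is enriched among its down-regulated genes (negative ES,
#' `p < alpha`) or the down-signature among its up-regulated genes (positive
#' ES, `p < alpha`).
#'
#' @param prls list of [PRLResult-class] objects (one per drug).
#' @param upMsgs,downMsgs character vectors: the signature to reverse.
#' @param alpha significance threshold for candidate calling.
#' @param nPerm,weight passed to [gseaPreranked()].
#' @param seed integer; each drug/signature test draws a distinct,
#'   reproducible sub-seed.
#' @return data.frame with `drug`, `es_up`, `p_up`, `es_down`, `p_down`,
#'   `candidate`.
#' @export
predictInhibitors <- function(prls, upMsgs, downMsgs, alpha = 0.05,
                              nPerm = 1000L, seed = 0L, weight = 1) {
    if (!length(upMsgs) && !length(downMsgs))
        stop("both signatures are empty", call. = FALSE)
    rows <- lapply(seq_along(prls), function(i) {
        prl <- prls[[i]]
        ranking <- prl@merged
        up <- if (length(upMsgs) >= 2L)
            gseaPreranked(ranking, upMsgs, nPerm = nPerm,
                          seed = .subSeed(seed, 2L * i), weight = weight)
            else list(es = NA_real_, p = NA_real_)
        dn <- if (length(downMsgs) >= 2L)
            gseaPreranked(ranking, downMsgs, nPerm = nPerm,
                          seed = .subSeed(seed, 2L * i + 1L), weight = weight)
            else list(es = NA_real_, p = NA_real_)
        cand <- (isTRUE(up$p < alpha) && isTRUE(up$es < 0)) ||
                (isTRUE(dn$p < alpha) && isTRUE(dn$es > 0))
        data.frame(drug = prl@drug, es_up = up$es, p_up = up$p,
                   es_down = dn$es, p_down = dn$p, candidate = cand)
    })
    do.call(rbind, rows)
}
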