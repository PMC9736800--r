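#' The scMetR metastatic-risk score
#'
#' Combines the scaled EMT enrichment score and the scaled
#' differentiation-potential score of each cell into a standardized risk
#' score. With `S_EMT` and `S_CyTo` both scaled to \[0,1\]:
#'
#' \deqn{X_m = S_{EMT} + S_{CyTo}}
#' \deqn{MX_m = mean(S_{EMT}) + mean(S_{CyTo})}
#' \deqn{SDX_m = \sqrt{SD(S_{EMT})^2 + SD(S_{CyTo})^2 +
#'       2 r \, SD(S_{EMT}) SD(S_{CyTo})}}
#' \deqn{Score_m = (X_m - MX_m) / SDX_m}
#'
#' where `r` is the Pearson correlation between the two inputs. `SDX_m` is
#' exactly the (sample) standard deviation of the sum, so `Score_m` has mean
#' 0 and standard deviation 1 over the scored population by construction.
#'
#' @param sEmt,sCyto numeric vectors in \[0,1\] of equal length >= 3 (the
#'   scaled per-cell scores).
#' @param cellIds optional cell identifiers.
#' @return [S4Vectors::DataFrame] with columns `cell_id`, `s_emt`, `s_cyto`,
#'   `x_m`, `scmetr`; `metadata()` carries `mxm`, `sdxm` and `r`.
#' @export
scMetRScore <- function(sEmt, sCyto, cellIds = NULL) {
    if (length(sEmt) != length(sCyto))
        stop("sEmt and sCyto must have equal length", call. = FALSE)
    n <- length(sEmt)
    if (n < 3L) stop("at least 3 cells required", call. = FALSE)
    if (any(sEmt < -1e-9 | sEmt > 1 + 1e-9) ||
        any(sCyto < -1e-9 | sCyto > 1 + 1e-9))
        stop("inputs must be scaled to [0,1]", call. = FALSE)
    if (is.null(cellIds)) {
        cellIds <- names(sEmt)
        if (is.null(cellIds)) cellIds <- sprintf("cell%05d", seq_len(n))
    }
    xm <- sEmt + sCyto
    mxm <- mean(sEmt) + mean(sCyto)
    sdE <- stats::sd(sEmt)
    sdC <- stats::sd(sCyto)
    # 2 r sdE sdC == 2 cov(sEmt, sCyto); the covariance form is also defined
    # when one input is constant (r undefined but the cross term is 0)
    sdxm <- sqrt(sdE^2 + sdC^2 + 2 * stats::cov(sEmt, sCyto))
    r <- if (sdE > 0 && sdC > 0) stats::cor(sEmt, sCyto) else NA_real_
    if (!is.finite(sdxm) || sdxm < 1e-12)
        stop("degenerate score distribution: SDX_m is zero", call. = FALSE)
    out <- S4Vectors::DataFrame(
        cell_id = cellIds, s_emt = sEmt, s_cyto = sCyto, x_m = xm,
        scmetr = (xm - mxm) / sdxm, row.names = cellIds)
    S4Vectors::metadata(out) <- list(mxm = mxm, sdxm = sdxm, r = r)
    out
}

#' Classify tumor sub-clusters into metastatic-risk tiers
#'
#' Each sub-cluster's scMetR scores are compared against all remaining tumor
#' cells by a two-sample Wilcoxon rank-sum test. Sub-clusters significantly
#' HIGHER than the rest (one-sided `p < alpha`) become metastasis-featuring
#' tumor cells (MFTC); significantly LOWER ones become conventional tumor
#' cells (ConvTC); everything else is transitional (TransMTC). The
#' higher/lower-than-rest operationalization is this package's reading of
#' per-cluster significance testing; the threshold default is `alpha = 0.01`.
#'
#' Because single-cell cluster sizes make the rank-sum test sensitive to
#' negligible shifts, significance alone cannot separate extreme from
#' transitional clusters (an intermediate cluster drifting a few percent off
#' the rest-average would be "significant" yet is biologically
#' transitional). An extreme tier therefore additionally requires at least a
#' medium-sized effect: the rank-biserial correlation of the cluster-vs-rest
#' comparison (`2*AUC - 1`) must reach `minEffect` in the corresponding
#' direction.
#'
#' @param scores a ScoreTable from [scMetRScore()] or a numeric vector of
#'   scMetR scores.
#' @param subClusters integer/character sub-cluster label per cell.
#' @param alpha per-cluster significance threshold.
#' @param minEffect minimum absolute rank-biserial effect size for the MFTC
#'   and ConvTC calls (0.3 is the conventional medium-effect boundary; set
#'   to 0 to classify on significance alone).
#' @return data.frame with one row per sub-cluster: `sub_cluster`,
#'   `n_cells`, `median_scmetr`, `effect_size` (rank-biserial vs rest),
#'   `p_high`, `p_low`, `p_vs_rest` (the smaller one-sided p), `tier`.
#'   Per-cell tiers are recoverable with [cellTiers()].
#' @export
classifySubpopulations <- function(scores, subClusters, alpha = 0.01,
                                   minEffect = 0.3) {
    x <- if (methods::is(scores, "DataFrame")) scores$scmetr else
        as.numeric(scores)
    if (length(x) != length(subClusters))
        stop("scores and subClusters length mismatch", call. = FALSE)
    cl <- as.character(subClusters)
    tab <- table(cl)
    if (length(tab) < 2L)
        stop("at least 2 sub-clusters required", call. = FALSE)
    if (any(tab < 3L))
        stop("every sub-cluster needs at least 3 cells", call. = FALSE)
    ids <- names(tab)
    res <- lapply(ids, function(id) {
        a <- x[cl == id]; b <- x[cl != id]
        pHigh <- suppressWarnings(
            stats::wilcox.test(a, b, alternative = "greater")$p.value)
        pLow <- suppressWarnings(
            stats::wilcox.test(a, b, alternative = "less")$p.value)
        r <- rank(c(a, b))
        auc <- (sum(r[seq_along(a)]) -
                length(a) * (length(a) + 1) / 2) /
               (length(a) * length(b))
        eff <- 2 * auc - 1
        tier <- if (pHigh < alpha && eff >= minEffect) "MFTC"
                else if (pLow < alpha && eff <= -minEffect) "ConvTC"
                else "TransMTC"
        data.frame(sub_cluster = id, n_cells = as.integer(sum(cl == id)),
                   median_scmetr = stats::median(a), effect_size = eff,
                   p_high = pHigh, p_low = pLow,
                   p_vs_rest = min(pHigh, pLow), tier = tier)
    })
    out <- do.call(rbind, res)
    if (!any(out$tier == "MFTC") && !any(out$tier == "ConvTC"))
        warning("no sub-cluster differs significantly from the rest; ",
                "all assigned TransMTC", call. = FALSE)
    else if (!any(out$tier == "MFTC") || !any(out$tier == "ConvTC"))
        warning("an extreme tier (MFTC or ConvTC) is empty", call. = FALSE)
    out
}

#' Per-cell tier labels from a sub-cluster classification
#'
#' @param assignments data.frame from [classifySubpopulations()].
#' @param subClusters per-cell sub-cluster labels.
#' @return character vector of tiers, one per cell.
#' @export
cellTiers <- function(assignments, subClusters) {
    m <- match(as.character(subClusters), assignments$sub_cluster)
    if (anyNA(m))
        stop("sub-cluster label(s) absent from the classification",
             call. = FALSE)
    assignments$tier[m]
}

#' Tier composition by condition
#'
#' Counts tumor cells per (tier, condition) and the within-condition
#' proportions, the summary used to contrast primary and metastatic samples.
#'
#' @param annotation data.frame with columns `condition` and `tier`
#'   (non-tumor cells may carry `NA` tier and are ignored).
#' @return data.frame with `condition`, `tier`, `n`, `proportion`;
#'   proportions sum to 1 within each condition.
#' @export
compositionTable <- function(annotation) {
    if (!all(c("condition", "tier") %in% names(annotation)))
        stop("annotation must contain 'condition' and 'tier'", call. = FALSE)
    ann <- annotation[!is.na(annotation$tier), , drop = FALSE]
    if (anyNA(ann$condition))
        stop("missing condition labels", call. = FALSE)
    conds <- unique(as.character(annotation$condition))
    empty <- setdiff(conds, unique(as.character(ann$condition)))
    if (length(empty))
        warning("condition(s) with no tumor cells omitted: ",
                paste(empty, collapse = ", "), call. = FALSE)
    tab <- as.data.frame(table(condition = as.character(ann$condition),
                               tier = as.character(ann$tier)))
    names(tab)[3L] <- "n"
    tab <- tab[tab$n > 0 | TRUE, ]           # keep zero tiers within condition
    tot <- stats::ave(tab$n, tab$condition, FUN = sum)
    tab$proportion <- ifelse(tot > 0, tab$n / tot, NA_real_)
    tab <- tab[tot > 0, , drop = FALSE]
    tab$condition <- as.character(tab$condition)
    tab$tier <- as.character(tab$tier)
    rownames(tab) <- NULL
    tab
}
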