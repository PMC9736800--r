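#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Quality-control report
#'
#' Tallies of cells and genes removed by each quality-control rule applied by
#' [qcFilter()]. Per-rule cell counts may overlap (a cell can fail several
#' rules); `cellsRemoved` counts the union.
#'
#' @slot cellsIn,cellsOut,genesIn,genesOut integer dimensions before/after.
#' @slot cellsFailMito,cellsFailGenes,cellsFailUMI integer cells failing the
#'   mitochondrial-fraction, detected-gene, and total-count rule respectively.
#' @slot cellsRemoved,genesRemoved integer unique removals.
#' @exportClass QCReport
setClass("QCReport", representation(
    cellsIn = "integer", cellsOut = "integer",
    genesIn = "integer", genesOut = "integer",
    cellsFailMito = "integer", cellsFailGenes = "integer",
    cellsFailUMI = "integer",
    cellsRemoved = "integer", genesRemoved = "integer"
))

setValidity("QCReport", function(object) {
    msg <- NULL
    if (object@cellsOut > object@cellsIn)
        msg <- c(msg, "cellsOut exceeds cellsIn")
    if (object@genesOut > object@genesIn)
        msg <- c(msg, "genesOut exceeds genesIn")
    if (object@cellsRemoved != object@cellsIn - object@cellsOut)
        msg <- c(msg, "cellsRemoved does not reconcile with in/out difference")
    if (object@genesRemoved != object@genesIn - object@genesOut)
        msg <- c(msg, "genesRemoved does not reconcile with in/out difference")
    perRule <- c(object@cellsFailMito, object@cellsFailGenes,
                 object@cellsFailUMI)
    if (object@cellsRemoved > sum(perRule) || object@cellsRemoved < max(perRule, 0L))
        msg <- c(msg, "per-rule cell counts inconsistent with total removed")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn QCReport compact display
#' @param object a `QCReport`
#' @export
setMethod("show", "QCReport", function(object) {
    cat("QCReport\n")
    cat(sprintf("  cells: %d -> %d (removed %d; mito %d, genes %d, UMI %d)\n",
                object@cellsIn, object@cellsOut, object@cellsRemoved,
                object@cellsFailMito, object@cellsFailGenes,
                object@cellsFailUMI))
    cat(sprintf("  genes: %d -> %d (removed %d low-detection)\n",
                object@genesIn, object@genesOut, object@genesRemoved))
})

#' Collection of named gene sets
#'
#' A validated named list of character vectors, as parsed from a GMT file by
#' [readGeneSets()]. Set names are unique and every set is non-empty after
#' deduplication.
#'
#' @slot sets named list of character vectors.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
    s <- object@sets
    if (length(s) == 0L) return("collection is empty")
    nm <- names(s)
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
        return("all sets must be named")
    if (anyDuplicated(nm))
        return(paste("duplicate set names:",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (!all(vapply(s, is.character, logical(1))))
        return("sets must be character vectors")
    if (any(vapply(s, length, integer(1)) == 0L))
        return("empty gene set after deduplication")
    if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
        return("duplicate genes within a set")
    TRUE
})

#' @describeIn GeneSetCollection compact display
#' @param object a `GeneSetCollection`
#' @export
setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection with %d set(s)\n", length(object@sets)))
    n <- vapply(object@sets, length, integer(1))
    for (i in seq_len(min(5L, length(n))))
        cat(sprintf("  %s (%d genes)\n", names(n)[i], n[i]))
    if (length(n) > 5L) cat(sprintf("  ... and %d more\n", length(n) - 5L))
})

#' Resolution sweep result
#'
#' Output of [selectResolution()]: per-resolution cluster counts and mean
#' silhouette widths, plus the selected resolution (the silhouette argmax,
#' ties broken toward the smallest resolution). Grid points that collapse to
#' a single cluster carry `NA` silhouette and are excluded from the argmax.
#'
#' @slot sweep data.frame with columns `resolution`, `n_clusters`,
#'   `mean_silwidth`.
#' @slot selected numeric(1) selected resolution.
#' @slot labels integer vector of cluster labels at the selected resolution.
#' @exportClass ResolutionSweep
setClass("ResolutionSweep", representation(
    sweep = "data.frame", selected = "numeric", labels = "integer"
))

setValidity("ResolutionSweep", function(object) {
    sw <- object@sweep
    need <- c("resolution", "n_clusters", "mean_silwidth")
    if (!all(need %in% names(sw))) return("sweep lacks required columns")
    if (is.unsorted(sw$resolution, strictly = TRUE))
        return("resolutions must be strictly increasing")
    ok <- !is.na(sw$mean_silwidth)
    if (!any(ok)) return("no resolution with a defined silhouette")
    best <- max(sw$mean_silwidth[ok])
    cand <- sw$resolution[ok & sw$mean_silwidth == best]
    if (!isTRUE(all.equal(object@selected, min(cand))))
        return("selected resolution is not the silhouette argmax")
    TRUE
})

#' @describeIn ResolutionSweep compact display
#' @param object a `ResolutionSweep`
#' @export
setMethod("show", "ResolutionSweep", function(object) {
    cat("ResolutionSweep\n")
    print(object@sweep, row.names = FALSE)
    cat(sprintf("selected resolution: %g (%d clusters)\n", object@selected,
                length(unique(object@labels))))
})

#' Optimal survival cutpoint
#'
#' Output of [optimalCutpoint()]: the score threshold maximizing the
#' standardized two-group log-rank statistic over all candidates leaving at
#' least `minprop` of the cohort on each side.
#'
#' @slot cutpoint numeric(1) selected threshold (group "high" is
#'   `score > cutpoint`).
#' @slot statistic numeric(1) standardized log-rank statistic at the cutpoint.
#' @slot candidates integer(1) number of admissible thresholds evaluated.
#' @exportClass CutpointResult
setClass("CutpointResult", representation(
    cutpoint = "numeric", statistic = "numeric", candidates = "integer"
))

#' @describeIn CutpointResult compact display
#' @param object a `CutpointResult`
#' @export
setMethod("show", "CutpointResult", function(object) {
    cat(sprintf(
        "CutpointResult: cutpoint %.4g, |standardized log-rank| %.3f (%d candidates)\n",
        object@cutpoint, object@statistic, object@candidates))
})

#' Ranked gene list
#'
#' An ordered gene list for one drug/condition; position 1 is the gene most
#' up-regulated by the perturbation.
#'
#' @slot label character(1) identifier (e.g. "drugA:cellline1").
#' @slot genes character vector of unique gene identifiers, most up-regulated
#'   first.
#' @exportClass RankedList
setClass("RankedList", representation(label = "character", genes = "character"))

setValidity("RankedList", function(object) {
    if (length(object@label) != 1L) return("label must be a single string")
    if (length(object@genes) == 0L) return("empty ranking")
    if (anyDuplicated(object@genes)) return("duplicate genes in ranking")
    TRUE
})

#' @describeIn RankedList compact display
#' @param object a `RankedList`
#' @export
setMethod("show", "RankedList", function(object) {
    n <- length(object@genes)
    cat(sprintf("RankedList '%s' (%d genes): %s ... %s\n", object@label, n,
                paste(utils::head(object@genes, 3L), collapse = ", "),
                object@genes[n]))
})

#' Prototype Ranked List for one drug
#'
#' The hierarchical majority-voting merge of all per-condition rankings of a
#' drug, as produced by [prlMerge()].
#'
#' @slot drug character(1) drug identifier.
#' @slot merged [RankedList-class] merged ranking.
#' @slot nConditions integer(1) number of condition rankings merged.
#' @exportClass PRLResult
setClass("PRLResult", representation(
    drug = "character", merged = "RankedList", nConditions = "integer"
))

setValidity("PRLResult", function(object) {
    if (object@nConditions < 1L) return("nConditions must be >= 1")
    TRUE
})

#' @describeIn PRLResult compact display
#' @param object a `PRLResult`
#' @export
setMethod("show", "PRLResult", function(object) {
    cat(sprintf("PRLResult for '%s' (%d conditions merged)\n",
                object@drug, object@nConditions))
    show(object@merged)
})
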