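# internal validation helpers shared across modules

.assertCounts <- function(x, what = "matrix") {
    if (any(x < 0)) stop(what, " contains negative values", call. = FALSE)
    if (any(x != round(x)))
        stop(what, " counts layer must contain integers only", call. = FALSE)
    invisible(TRUE)
}

.assertUniqueIds <- function(ids, what) {
    if (anyDuplicated(ids)) {
        dup <- unique(ids[duplicated(ids)])
        stop("duplicate ", what, " identifiers: ",
             paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
    }
    invisible(TRUE)
}

# layer bookkeeping on a SingleCellExperiment / SummarizedExperiment
.layerOf <- function(se) {
    tag <- S4Vectors::metadata(se)$layer_tag
    if (is.null(tag)) {
        tag <- if ("logcounts" %in% SummarizedExperiment::assayNames(se))
            "lognorm" else "counts"
    }
    tag
}

.requireLayer <- function(se, layer) {
    if (!(layer %in% SummarizedExperiment::assayNames(se)))
        stop("matrix lacks the '", layer, "' layer; ",
             if (layer == "logcounts") "run normalizeLog1p() first"
             else "raw counts are required", call. = FALSE)
    invisible(TRUE)
}

.asDense <- function(x) as.matrix(x)

# seed sub-streams: derive independent, reproducible seeds per component
.subSeed <- function(seed, offset) {
    (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}
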