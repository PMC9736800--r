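#' Read an expression matrix
#'
#' Reads a genes x cells (or genes x bulk samples) expression matrix either
#' from a matrix-market triplet directory (`matrix.mtx` plus `genes.tsv` and
#' `barcodes.tsv` companions, 10x-style) or from a dense delimited text file
#' with gene identifiers as row names and cell identifiers as the header.
#'
#' @param path for `format = "mtx_triplet"`, the directory holding
#'   `matrix.mtx`, `genes.tsv` and `barcodes.tsv`; for
#'   `format = "dense_delimited"`, a TSV/CSV file.
#' @param format input dialect.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay and `layer_tag = "counts"` recorded in its metadata.
#' @examples
#' d <- tempfile(); dir.create(d)
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' writeExpressionMatrix(m, d, format = "mtx_triplet")
#' sce <- readExpressionMatrix(d, format = "mtx_triplet")
#' @export
readExpressionMatrix <- function(path,
                                 format = c("mtx_triplet", "dense_delimited")) {
    format <- match.arg(format)
    if (format == "mtx_triplet") {
        files <- file.path(path, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
        missing <- files[!file.exists(files)]
        if (length(missing))
            stop("missing input file(s): ", paste(missing, collapse = ", "),
                 call. = FALSE)
        m <- as.matrix(Matrix::readMM(files[1L]))
        genes <- utils::read.delim(files[2L], header = FALSE,
                                   stringsAsFactors = FALSE)[[1L]]
        cells <- utils::read.delim(files[3L], header = FALSE,
                                   stringsAsFactors = FALSE)[[1L]]
        if (nrow(m) != length(genes) || ncol(m) != length(cells))
            stop("matrix dimensions do not match companion id files",
                 call. = FALSE)
        dimnames(m) <- list(genes, cells)
    } else {
        if (!file.exists(path))
            stop("missing input file: ", path, call. = FALSE)
        sep <- if (grepl("\\.csv$", path)) "," else "\t"
        first <- utils::read.table(path, sep = sep, header = TRUE,
                                   check.names = FALSE,
                                   stringsAsFactors = FALSE)
        genes <- as.character(first[[1L]])
        .assertUniqueIds(genes, "gene")
        m <- as.matrix(first[, -1L, drop = FALSE])
        rownames(m) <- genes
    }
    .assertUniqueIds(rownames(m), "gene")
    .assertUniqueIds(colnames(m), "cell")
    .assertCounts(m)
    storage.mode(m) <- "integer"
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m))
    S4Vectors::metadata(sce)$layer_tag <- "counts"
    sce
}

#' Write an expression matrix
#'
#' Counterpart of [readExpressionMatrix()]; writes either a matrix-market
#' triplet directory or a dense TSV.
#'
#' @param m matrix or SummarizedExperiment (its `counts` assay is written).
#' @param path output directory (`mtx_triplet`) or file (`dense_delimited`).
#' @param format output dialect.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(m, path,
                                  format = c("mtx_triplet", "dense_delimited")) {
    format <- match.arg(format)
    if (methods::is(m, "SummarizedExperiment"))
        m <- SummarizedExperiment::assay(m, "counts")
    m <- as.matrix(m)
    if (format == "mtx_triplet") {
        if (!dir.exists(path)) dir.create(path, recursive = TRUE)
        Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                    "generalMatrix"),
                        file.path(path, "matrix.mtx"))
        writeLines(rownames(m), file.path(path, "genes.tsv"))
        writeLines(colnames(m), file.path(path, "barcodes.tsv"))
    } else {
        df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Descriptions are discarded;
#' duplicate genes within a set are deduplicated with a warning.
#'
#' @param path path to a GMT file.
#' @return a [GeneSetCollection-class].
#' @export
readGeneSets <- function(path) {
    if (!file.exists(path))
        stop("missing input file: ", path, call. = FALSE)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list()
    for (i in seq_along(lines)) {
        fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(fields) < 3L)
            stop("GMT parse error at line ", i,
                 ": fewer than 3 tab-separated fields", call. = FALSE)
        name <- fields[1L]
        genes <- fields[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (anyDuplicated(genes)) {
            warning("set '", name, "': ", sum(duplicated(genes)),
                    " duplicate gene(s) removed", call. = FALSE)
            genes <- unique(genes)
        }
        if (name %in% names(sets))
            stop("duplicate set name in GMT: '", name, "'", call. = FALSE)
        sets[[name]] <- genes
    }
    methods::new("GeneSetCollection", sets = sets)
}

#' Write gene sets to a GMT file
#'
#' @param gsc a [GeneSetCollection-class] or named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(gsc, path) {
    sets <- geneSets(gsc)
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Extract the list of gene sets
#'
#' @param gsc a [GeneSetCollection-class] or a named list.
#' @return named list of character vectors.
#' @export
geneSets <- function(gsc) {
    if (methods::is(gsc, "GeneSetCollection")) gsc@sets
    else if (is.list(gsc)) gsc
    else stop("not a gene set collection", call. = FALSE)
}

#' Quality-control filtering of a counts matrix
#'
#' Removes low-quality cells, then low-detection genes, on raw counts.
#' A cell is removed when its mitochondrial count fraction exceeds
#' `maxMitoFrac`, when it has more than `maxGenesPerCell` detected genes, or
#' more than `maxUMIPerCell` total counts; all thresholds are strict
#' inequalities ("more than"). A gene is then removed when it is detected
#' (count > 0) in fewer than `minCellsPerGene` of the *retained* cells.
#' Mitochondrial genes are recognised by the symbol prefix `mitoPrefix`.
#'
#' The defaults (40% mitochondrial, 7500 genes, 100,000 UMIs, 3 cells) are
#' the conventional droplet scRNA-seq thresholds this pipeline assumes.
#'
#' @param sce a SingleCellExperiment with a raw `counts` assay.
#' @param minCellsPerGene minimum number of QC-passing cells a gene must be
#'   detected in.
#' @param maxMitoFrac maximum mitochondrial count fraction.
#' @param maxGenesPerCell maximum detected genes per cell.
#' @param maxUMIPerCell maximum total counts per cell.
#' @param mitoPrefix gene-symbol prefix marking mitochondrial genes.
#' @return the filtered SingleCellExperiment; the [QCReport-class] is stored
#'   in `metadata(.)$qcReport` and retrievable with [qcReport()].
#' @export
qcFilter <- function(sce, minCellsPerGene = 3L, maxMitoFrac = 0.4,
                     maxGenesPerCell = 7500L, maxUMIPerCell = 100000L,
                     mitoPrefix = "MT-") {
    .requireLayer(sce, "counts")
    if (.layerOf(sce) != "counts")
        stop("qcFilter expects the raw counts layer", call. = FALSE)
    m <- SummarizedExperiment::assay(sce, "counts")
    totals <- colSums(m)
    detected <- colSums(m > 0)
    mito <- startsWith(rownames(m), mitoPrefix)
    mitoFrac <- if (any(mito)) colSums(m[mito, , drop = FALSE]) / pmax(totals, 1)
                else rep(0, ncol(m))
    failMito <- mitoFrac > maxMitoFrac
    failGenes <- detected > maxGenesPerCell
    failUMI <- totals > maxUMIPerCell
    keepCell <- !(failMito | failGenes | failUMI)
    if (!any(keepCell))
        stop("all cells removed by QC filtering", call. = FALSE)
    kept <- sce[, keepCell]
    mk <- SummarizedExperiment::assay(kept, "counts")
    geneDetect <- rowSums(mk > 0)
    keepGene <- geneDetect >= minCellsPerGene
    out <- kept[keepGene, ]
    report <- methods::new(
        "QCReport",
        cellsIn = ncol(sce), cellsOut = ncol(out),
        genesIn = nrow(sce), genesOut = nrow(out),
        cellsFailMito = sum(failMito), cellsFailGenes = sum(failGenes),
        cellsFailUMI = sum(failUMI),
        cellsRemoved = sum(!keepCell), genesRemoved = sum(!keepGene))
    S4Vectors::metadata(out)$qcReport <- report
    S4Vectors::metadata(out)$layer_tag <- "counts"
    out
}

#' Retrieve the QC report attached by [qcFilter()]
#'
#' @param sce a filtered SingleCellExperiment.
#' @return a [QCReport-class], or `NULL` if QC has not been run.
#' @export
qcReport <- function(sce) S4Vectors::metadata(sce)$qcReport

#' Library-size normalization with log1p transform
#'
#' Scales each cell to `scaleFactor` total counts and applies the natural
#' log1p transform: `log(1 + count * scaleFactor / total)`. This reproduces
#' the conventional global-scaling normalization of droplet scRNA-seq
#' toolkits (default scale factor 10,000).
#'
#' @param sce a SingleCellExperiment with a raw `counts` assay.
#' @param scaleFactor per-cell target total.
#' @return the input with a `logcounts` assay added and
#'   `layer_tag = "lognorm"`.
#' @export
normalizeLog1p <- function(sce, scaleFactor = 1e4) {
    .requireLayer(sce, "counts")
    m <- SummarizedExperiment::assay(sce, "counts")
    totals <- colSums(m)
    if (any(totals == 0)) {
        bad <- colnames(m)[totals == 0]
        stop("zero-count cell(s): ", paste(utils::head(bad, 5), collapse = ", "),
             call. = FALSE)
    }
    ln <- log1p(sweep(m, 2L, totals, "/") * scaleFactor)
    SummarizedExperiment::assay(sce, "logcounts") <- ln
    S4Vectors::metadata(sce)$layer_tag <- "lognorm"
    sce
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their clipped standardized counts
#' (vst-style): per-gene count mean and variance are computed, the variance
#' trend against the mean is fitted by loess on log10 scale, counts are
#' standardized by the trend-expected standard deviation, clipped at
#' `sqrt(n_cells)`, and the variance of the clipped values is the ranking
#' statistic. Ties are broken lexicographically by gene identifier.
#'
#' @param sce a SingleCellExperiment carrying both `counts` and `logcounts`.
#' @param n number of genes to return.
#' @return character vector of `n` gene identifiers, highest statistic first.
#' @export
selectHVG <- function(sce, n = 2000L) {
    if (n <= 0) stop("n must be positive", call. = FALSE)
    .requireLayer(sce, "logcounts")
    m <- SummarizedExperiment::assay(sce, "counts")
    if (n > nrow(m)) stop("n exceeds the number of genes", call. = FALSE)
    mu <- rowMeans(m)
    v <- apply(m, 1L, stats::var)
    usable <- mu > 0 & v > 0
    stat <- numeric(nrow(m))
    if (sum(usable) >= 4L) {
        fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]), span = 0.5,
                            degree = 2)
        sdExp <- sqrt(10^stats::predict(fit))
        clipMax <- sqrt(ncol(m))
        z <- sweep(m[usable, , drop = FALSE], 1L, mu[usable], "-")
        z <- sweep(z, 1L, sdExp, "/")
        z <- pmin(pmax(z, -clipMax), clipMax)
        stat[usable] <- apply(z, 1L, stats::var)
    } else {
        stat <- v
    }
    ord <- order(-stat, rownames(m))
    rownames(m)[ord][seq_len(n)]
}
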