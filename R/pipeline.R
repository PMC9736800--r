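#' Assemble and validate a pipeline configuration
#'
#' A plain named list collecting every stage threshold and seed, suitable
#' for YAML round-tripping. Thresholds are validated against their domains
#' up front so a misconfigured run fails before any compute.
#'
#' @param simulate logical; generate inputs with the synthetic-data module
#'   (`TRUE`) or read them from `matrixPath`/`gmtPath` (`FALSE`).
#' @param matrixPath,matrixFormat,gmtPath,emtSetName input locations when
#'   `simulate = FALSE`.
#' @param sim named list of overrides for [simConfig()].
#' @param seed master seed.
#' @param minCellsPerGene,maxMitoFrac,maxGenesPerCell,maxUMIPerCell QC
#'   thresholds (see [qcFilter()]).
#' @param scaleFactor normalization scale factor.
#' @param nHVG highly variable genes used for the clustering embedding.
#' @param nPCs principal components of the embedding.
#' @param ssgseaAlpha rank-weight exponent for [ssgseaScore()].
#' @param cytoTopN,cytoK differentiation-score parameters.
#' @param alphaTier per-cluster Wilcoxon threshold for tier calling.
#' @param pMsg,lfcMsg signature-gene thresholds.
#' @param minprop minimum group proportion for the survival cutpoint.
#' @param alphaDrug candidate-drug threshold.
#' @param nPerm GSEA permutations.
#' @param stages character subset of
#'   `c("qc","semt","scyto","cluster","score","msg","survival","drugs")`.
#' @return validated configuration list of class `scmetrConfig`.
#' @export
pipelineConfig <- function(simulate = TRUE, matrixPath = NULL,
                           matrixFormat = "mtx_triplet", gmtPath = NULL,
                           emtSetName = NULL, sim = list(), seed = 1L,
                           minCellsPerGene = 3L, maxMitoFrac = 0.4,
                           maxGenesPerCell = 7500L, maxUMIPerCell = 100000L,
                           scaleFactor = 1e4, nHVG = 500L, nPCs = 20L,
                           ssgseaAlpha = 0.25, cytoTopN = 200L, cytoK = 30L,
                           alphaTier = 0.01, pMsg = 0.05, lfcMsg = 0.25,
                           minprop = 0.1, alphaDrug = 0.05, nPerm = 1000L,
                           stages = c("qc", "semt", "scyto", "cluster",
                                      "score", "msg", "survival", "drugs")) {
    cfg <- list(simulate = simulate, matrixPath = matrixPath,
                matrixFormat = matrixFormat, gmtPath = gmtPath,
                emtSetName = emtSetName, sim = sim, seed = as.integer(seed),
                minCellsPerGene = as.integer(minCellsPerGene),
                maxMitoFrac = maxMitoFrac,
                maxGenesPerCell = as.integer(maxGenesPerCell),
                maxUMIPerCell = as.integer(maxUMIPerCell),
                scaleFactor = scaleFactor, nHVG = as.integer(nHVG),
                nPCs = as.integer(nPCs), ssgseaAlpha = ssgseaAlpha,
                cytoTopN = as.integer(cytoTopN), cytoK = as.integer(cytoK),
                alphaTier = alphaTier, pMsg = pMsg, lfcMsg = lfcMsg,
                minprop = minprop, alphaDrug = alphaDrug,
                nPerm = as.integer(nPerm), stages = stages)
    class(cfg) <- c("scmetrConfig", "list")
    validatePipelineConfig(cfg)
    cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg list as produced by [pipelineConfig()] or parsed from YAML.
#' @return the config, invisibly; stops with a precondition error otherwise.
#' @export
validatePipelineConfig <- function(cfg) {
    inUnit <- function(x) is.numeric(x) && x > 0 && x < 1
    if (!inUnit(cfg$maxMitoFrac))
        stop("maxMitoFrac must lie in (0,1)", call. = FALSE)
    for (nm in c("alphaTier", "pMsg", "alphaDrug"))
        if (!inUnit(cfg[[nm]]))
            stop(nm, " must lie in (0,1)", call. = FALSE)
    if (cfg$minprop <= 0 || cfg$minprop >= 0.5)
        stop("minprop must lie in (0, 0.5)", call. = FALSE)
    if (cfg$lfcMsg < 0) stop("lfcMsg must be non-negative", call. = FALSE)
    known <- c("qc", "semt", "scyto", "cluster", "score", "msg",
               "survival", "drugs")
    if (!all(cfg$stages %in% known))
        stop("unknown stage(s): ",
             paste(setdiff(cfg$stages, known), collapse = ", "),
             call. = FALSE)
    if (!isTRUE(cfg$simulate)) {
        if ("semt" %in% cfg$stages && is.null(cfg$gmtPath))
            stop("precondition: gmtPath is required when the S_EMT stage ",
                 "is enabled on real data", call. = FALSE)
        if (is.null(cfg$matrixPath))
            stop("precondition: matrixPath is required when simulate = FALSE",
                 call. = FALSE)
    }
    invisible(cfg)
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return [readPipelineConfig()]: the validated config;
#'   [writePipelineConfig()]: `path`, invisibly.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    cfg <- utils::modifyList(pipelineConfig(), cfg)
    class(cfg) <- c("scmetrConfig", "list")
    validatePipelineConfig(cfg)
    cfg
}

#' @rdname readPipelineConfig
#' @param cfg a config list.
#' @export
writePipelineConfig <- function(cfg, path) {
    yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))], path)
    invisible(path)
}

.writeStamped <- function(df, path, stamp) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# config_md5: ", stamp), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the end-to-end metastatic-risk pipeline
#'
#' Executes the enabled stages in dependency order on either simulated or
#' user-supplied inputs: QC and normalization, EMT enrichment scoring,
#' differentiation-potential scoring, tumor re-clustering with
#' silhouette-selected resolution, scMetR scoring and tier classification,
#' signature-gene derivation, bulk survival stratification, and drug
#' reversal screening. Every output table is stamped with the MD5 of the
#' config snapshot; identical config and seed reproduce identical outputs.
#' A stage failure aborts with the stage name; outputs of completed stages
#' are left in place.
#'
#' @param cfg a config from [pipelineConfig()] (or a YAML path).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
runPipeline <- function(cfg, outDir) {
    if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
    validatePipelineConfig(cfg)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    cfgPath <- file.path(outDir, "config.yaml")
    writePipelineConfig(cfg, cfgPath)
    stamp <- unname(tools::md5sum(cfgPath))
    res <- list(config = cfg)
    stage <- function(name, expr) {
        if (!(name %in% c("input", cfg$stages))) return(invisible(NULL))
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    stage("input", {
        if (isTRUE(cfg$simulate)) {
            simCfg <- do.call(simConfig, utils::modifyList(
                list(seed = cfg$seed), cfg$sim))
            sim <- simulateScRNAseq(simCfg)
            res$sce <- sim$sce
            res$truth <- sim$truth
            res$simCfg <- simCfg
            res$emtSet <- sim$truth$emtGenes
        } else {
            res$sce <- readExpressionMatrix(cfg$matrixPath,
                                             format = cfg$matrixFormat)
            gsc <- readGeneSets(cfg$gmtPath)
            nm <- if (is.null(cfg$emtSetName)) names(geneSets(gsc))[1L]
                  else cfg$emtSetName
            res$emtSet <- geneSets(gsc)[[nm]]
        }
        message("input: ", nrow(res$sce), " genes x ", ncol(res$sce), " cells")
    })

    stage("qc", {
        res$sce <- qcFilter(res$sce, minCellsPerGene = cfg$minCellsPerGene,
                             maxMitoFrac = cfg$maxMitoFrac,
                             maxGenesPerCell = cfg$maxGenesPerCell,
                             maxUMIPerCell = cfg$maxUMIPerCell)
        rep <- qcReport(res$sce)
        .writeStamped(data.frame(
            metric = c("cells_in", "cells_out", "genes_in", "genes_out"),
            value = c(rep@cellsIn, rep@cellsOut, rep@genesIn, rep@genesOut)),
            file.path(outDir, "qc_report.tsv"), stamp)
        res$sce <- normalizeLog1p(res$sce, scaleFactor = cfg$scaleFactor)
    })
    if (!("qc" %in% cfg$stages) &&
        !("logcounts" %in% SummarizedExperiment::assayNames(res$sce)))
        res$sce <- normalizeLog1p(res$sce, scaleFactor = cfg$scaleFactor)

    tumor <- if ("cell_type" %in%
                 names(SummarizedExperiment::colData(res$sce)))
        res$sce[, res$sce$cell_type == "tumor"] else res$sce

    stage("semt", {
        res$semt <- ssgseaScore(tumor, res$emtSet, alpha = cfg$ssgseaAlpha)
        .writeStamped(as.data.frame(res$semt),
                      file.path(outDir, "semt.tsv"), stamp)
    })

    stage("scyto", {
        res$scyto <- cytotraceScore(tumor, topN = min(cfg$cytoTopN,
                                                       nrow(tumor)),
                                     k = min(cfg$cytoK, ncol(tumor) - 1L))
        .writeStamped(as.data.frame(res$scyto),
                      file.path(outDir, "scyto.tsv"), stamp)
    })

    stage("cluster", {
        hvg <- selectHVG(tumor, n = min(cfg$nHVG, nrow(tumor)))
        lm <- SummarizedExperiment::assay(tumor, "logcounts")[hvg, ,
                                                              drop = FALSE]
        keep <- apply(lm, 1L, stats::var) > 0
        pc <- stats::prcomp(t(lm[keep, , drop = FALSE]), center = TRUE,
                            rank. = min(cfg$nPCs, sum(keep),
                                        ncol(lm) - 1L))$x
        res$embedding <- pc
        res$sweep <- selectResolution(pc, seed = cfg$seed)
        .writeStamped(res$sweep@sweep, file.path(outDir, "sweep.tsv"), stamp)
    })

    stage("score", {
        st <- scMetRScore(res$semt$scaled_score, res$scyto$scaled_score,
                          cellIds = colnames(tumor))
        clusters <- res$sweep@labels
        res$scores <- st
        res$tiers <- classifySubpopulations(st, clusters,
                                             alpha = cfg$alphaTier)
        res$cellTier <- cellTiers(res$tiers, clusters)
        ann <- data.frame(cell_id = colnames(tumor),
                          sub_cluster = clusters, tier = res$cellTier,
                          condition = tumor$condition)
        res$composition <- compositionTable(ann)
        .writeStamped(cbind(as.data.frame(st), sub_cluster = clusters,
                            tier = res$cellTier),
                      file.path(outDir, "scores.tsv"), stamp)
        .writeStamped(res$tiers, file.path(outDir, "tiers.tsv"), stamp)
        .writeStamped(res$composition,
                      file.path(outDir, "composition.tsv"), stamp)
    })

    stage("msg", {
        mf <- colnames(tumor)[res$cellTier == "MFTC"]
        cv <- colnames(tumor)[res$cellTier == "ConvTC"]
        res$de <- wilcoxonDE(tumor, mf, cv, pThresh = cfg$pMsg,
                              lfcThresh = cfg$lfcMsg)
        res$msgs <- selectMSGs(res$de, pThresh = cfg$pMsg,
                                lfcThresh = cfg$lfcMsg)
        .writeStamped(res$de, file.path(outDir, "msgs.tsv"), stamp)
    })

    stage("survival", {
        bulk <- simulateBulkCohort(res$simCfg,
                                   plantedGenes = if (length(res$msgs$up) >= 2L)
                                       res$msgs$up else NULL)
        lbulk <- log1p(sweep(bulk$expr, 2L, colSums(bulk$expr), "/") * 1e4)
        sc <- ssgseaScore(lbulk, if (length(res$msgs$up) >= 2L) res$msgs$up
                                 else bulk$truth$genes,
                          alpha = cfg$ssgseaAlpha)
        ct <- optimalCutpoint(sc$scaled_score, bulk$cohort$time,
                              bulk$cohort$event, minprop = cfg$minprop)
        split <- survivalSplit(sc$scaled_score, bulk$cohort$time,
                               bulk$cohort$event, ct)
        res$survival <- list(cohort = bulk$cohort, scores = sc,
                              cutpoint = ct, chi_square = split$chi_square,
                              p = split$p, group = split$group,
                              truth = bulk$truth)
        .writeStamped(data.frame(cutpoint = ct@cutpoint,
                                 statistic = ct@statistic,
                                 chi_square = split$chi_square, p = split$p),
                      file.path(outDir, "survival.tsv"), stamp)
    })

    stage("drugs", {
        up <- res$msgs$up; down <- res$msgs$down
        if (length(up) < 2L)
            stop("too few signature genes for the drug screen")
        if (length(down) < 2L) down <- character(0)
        prof <- simulateDrugProfiles(res$simCfg, up, down)
        rk <- rankingsFromFC(prof$fc)
        prls <- lapply(names(rk), function(d) prlMerge(rk[[d]], drug = d))
        res$drugs <- predictInhibitors(prls, up, down,
                                        alpha = cfg$alphaDrug,
                                        nPerm = cfg$nPerm, seed = cfg$seed)
        res$drugTruth <- prof$truth
        .writeStamped(res$drugs, file.path(outDir, "drug_candidates.tsv"),
                      stamp)
    })

    invisible(res)
}
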