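#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' describe the study conditions the pipeline targets: a droplet scRNA-seq
#' tumor sample with a majority tumor-cell fraction, three tumor
#' sub-populations spanning a gradient of EMT activity and differentiation
#' potential, an EMT programme planted in a subset of genes, negative
#' binomial counts with moderate overdispersion and dropout, a bulk cohort
#' whose hazard increases with signature burden, and a drug panel in which
#' half the drugs truly reverse the planted signature.
#'
#' @slot nGenes,nCells integer problem size.
#' @slot cellTypeProps named numeric proportions per cell type (must contain
#'   `"tumor"`); sums to 1.
#' @slot nTumorSubpops integer number of tumor sub-populations.
#' @slot emtActivity,diffPotential numeric in \[0,1\], one value per tumor
#'   sub-population.
#' @slot nEmtGenes integer number of genes carrying the planted EMT
#'   programme.
#' @slot nbDispersion numeric > 0 negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @slot dropoutRate numeric in \[0,1) independent Bernoulli zeroing rate.
#' @slot seed integer master seed; each generator draws from its own
#'   sub-stream so modules are independently reproducible.
#' @slot bulk list with `n_samples`, `hazard_coef`, `censor_rate`.
#' @slot drugs list with `n_drugs`, `n_true_inhibitors`, `reversal_strength`,
#'   `n_conditions`, `n_background` (universe genes beyond the signature).
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nGenes = "integer", nCells = "integer",
    cellTypeProps = "numeric", nTumorSubpops = "integer",
    emtActivity = "numeric", diffPotential = "numeric",
    nEmtGenes = "integer", nbDispersion = "numeric",
    dropoutRate = "numeric", seed = "integer",
    bulk = "list", drugs = "list"
))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (abs(sum(object@cellTypeProps) - 1) > 1e-9)
        msg <- c(msg, "cell type proportions must sum to 1")
    if (!("tumor" %in% names(object@cellTypeProps)))
        msg <- c(msg, "cellTypeProps must include 'tumor'")
    if (length(object@emtActivity) != object@nTumorSubpops ||
        length(object@diffPotential) != object@nTumorSubpops)
        msg <- c(msg, "per-subpopulation vectors must have length nTumorSubpops")
    if (any(object@emtActivity < 0 | object@emtActivity > 1) ||
        any(object@diffPotential < 0 | object@diffPotential > 1))
        msg <- c(msg, "emtActivity and diffPotential must lie in [0,1]")
    if (object@nEmtGenes > object@nGenes)
        msg <- c(msg, "nEmtGenes exceeds nGenes")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be positive")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
        msg <- c(msg, "dropoutRate must lie in [0,1)")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SimConfig constructor with study-condition defaults
#' @param nGenes,nCells,cellTypeProps,nTumorSubpops,emtActivity,diffPotential
#'   see slots.
#' @param nEmtGenes,nbDispersion,dropoutRate,seed,bulk,drugs see slots.
#' @return a validated `SimConfig`.
#' @export
simConfig <- function(nGenes = 2000L, nCells = 1000L,
                      cellTypeProps = c(tumor = 0.6, immune = 0.25,
                                        stromal = 0.15),
                      nTumorSubpops = 3L,
                      emtActivity = c(0.9, 0.5, 0.1),
                      diffPotential = c(0.9, 0.5, 0.1),
                      nEmtGenes = 100L, nbDispersion = 0.5,
                      dropoutRate = 0.2, seed = 1L,
                      bulk = list(n_samples = 200L, hazard_coef = 2,
                                  censor_rate = 0.3),
                      drugs = list(n_drugs = 20L, n_true_inhibitors = 10L,
                                   reversal_strength = 2,
                                   n_conditions = 3L, n_background = 400L)) {
    methods::new("SimConfig",
                 nGenes = as.integer(nGenes), nCells = as.integer(nCells),
                 cellTypeProps = cellTypeProps,
                 nTumorSubpops = as.integer(nTumorSubpops),
                 emtActivity = emtActivity, diffPotential = diffPotential,
                 nEmtGenes = as.integer(nEmtGenes),
                 nbDispersion = nbDispersion, dropoutRate = dropoutRate,
                 seed = as.integer(seed), bulk = bulk, drugs = drugs)
}

# map tumor sub-populations to risk tiers by the ordering of
# emtActivity + diffPotential: highest-sum subpops are MFTC, lowest ConvTC,
# everything in between TransMTC; a flat profile yields a single TransMTC tier
.trueTiers <- function(emt, diff) {
    s <- emt + diff
    u <- sort(unique(round(s, 12L)))
    tier <- rep("TransMTC", length(s))
    if (length(u) >= 2L) {
        tier[round(s, 12L) == u[length(u)]] <- "MFTC"
        tier[round(s, 12L) == u[1L]] <- "ConvTC"
    }
    tier
}

#' Simulate a tumor scRNA-seq dataset with planted metastatic-risk structure
#'
#' Counts are negative binomial around lognormal per-gene baselines. Tumor
#' cells belong to sub-populations; each sub-population multiplies the means
#' of the planted EMT genes by `1 + 3 * emtActivity` and realizes its
#' differentiation potential through the fraction of genes a cell expresses:
#' each gene is retained in a cell with probability `0.4 + 0.6 * d` where `d`
#' is the sub-population's potential (non-tumor cells use `d = 0.5`), so
#' higher-potential cells detect more genes — the signal a
#' CytoTRACE-style score keys on. Independent Bernoulli dropout is applied
#' on top. All randomness derives from the config seed.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `sce` (SingleCellExperiment; `counts` assay, colData
#'   columns `sample_id`, `condition`, `cell_type`) and `truth` (list with
#'   per-cell `subpop` and `tier`, the planted `emtGenes`, per-gene
#'   `baseline` means, and the per-cell retention probability `keepProb`).
#' @export
simulateScRNAseq <- function(cfg) {
    methods::validObject(cfg)
    set.seed(.subSeed(cfg@seed, 1L))
    G <- cfg@nGenes; N <- cfg@nCells
    geneIds <- sprintf("G%05d", seq_len(G))
    cellIds <- sprintf("cell%05d", seq_len(N))
    baseline <- stats::rlnorm(G, meanlog = log(0.5), sdlog = 1)
    emtGenes <- sort(sample(geneIds, cfg@nEmtGenes))
    cellType <- sample(names(cfg@cellTypeProps), N, replace = TRUE,
                       prob = cfg@cellTypeProps)
    isTumor <- cellType == "tumor"
    subpop <- rep(NA_integer_, N)
    subpop[isTumor] <- sample(seq_len(cfg@nTumorSubpops), sum(isTumor),
                              replace = TRUE)
    sampleId <- paste0("S", sample(1:4, N, replace = TRUE))
    condition <- ifelse(sampleId %in% c("S1", "S2"), "primary", "metastatic")

    mu <- matrix(baseline, nrow = G, ncol = N)
    emtIdx <- match(emtGenes, geneIds)
    for (j in seq_len(cfg@nTumorSubpops)) {
        cols <- which(!is.na(subpop) & subpop == j)
        if (length(cols))
            mu[emtIdx, cols] <- mu[emtIdx, cols] * (1 + 3 * cfg@emtActivity[j])
    }
    counts <- matrix(stats::rnbinom(G * N, mu = mu, size = 1 / cfg@nbDispersion),
                     nrow = G, ncol = N, dimnames = list(geneIds, cellIds))
    d <- ifelse(isTumor, cfg@diffPotential[subpop], 0.5)
    keepProb <- pmin(1, 0.4 + 0.6 * d)
    keep <- matrix(stats::runif(G * N), G, N) < rep(keepProb, each = G)
    counts <- counts * keep
    if (cfg@dropoutRate > 0)
        counts <- counts * (matrix(stats::runif(G * N), G, N) >= cfg@dropoutRate)
    storage.mode(counts) <- "integer"

    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            cell_id = cellIds, sample_id = sampleId, condition = condition,
            cell_type = cellType, row.names = cellIds))
    S4Vectors::metadata(sce)$layer_tag <- "counts"
    tierOfSubpop <- .trueTiers(cfg@emtActivity, cfg@diffPotential)
    truth <- list(
        subpop = stats::setNames(subpop, cellIds),
        tier = stats::setNames(
            ifelse(is.na(subpop), NA_character_, tierOfSubpop[subpop]),
            cellIds),
        diffPotential = stats::setNames(d, cellIds),
        emtGenes = emtGenes, baseline = stats::setNames(baseline, geneIds),
        keepProb = stats::setNames(keepProb, cellIds))
    list(sce = sce, truth = truth)
}

#' Simulate a bulk expression cohort with survival driven by signature burden
#'
#' Each sample carries a latent signature burden `b ~ Uniform(0,1)` that
#' multiplies the planted genes' means by `1 + 2b`. Survival times are
#' exponential with rate `0.01 * exp(hazard_coef * b)`; a sample is censored
#' independently with probability `censor_rate`, in which case the observed
#' time is uniform on (0, T).
#'
#' @param cfg a [SimConfig-class] with the `bulk` block set.
#' @param plantedGenes optional character vector of gene identifiers (within
#'   the simulated universe) to carry the burden signal; defaults to a
#'   random draw of `nEmtGenes` genes. Passing the up-regulated signature
#'   derived from the single-cell arm links the two simulations.
#' @return list with `expr` (genes x samples integer matrix), `cohort`
#'   (data.frame `sample_id`, `time`, `event`), and `truth` (per-sample
#'   `burden` and the planted `genes`).
#' @export
simulateBulkCohort <- function(cfg, plantedGenes = NULL) {
    methods::validObject(cfg)
    set.seed(.subSeed(cfg@seed, 2L))
    n <- as.integer(cfg@bulk$n_samples)
    G <- cfg@nGenes
    geneIds <- sprintf("G%05d", seq_len(G))
    sampleIds <- sprintf("pt%04d", seq_len(n))
    baseline <- stats::rlnorm(G, meanlog = log(20), sdlog = 1)
    planted <- if (is.null(plantedGenes)) sort(sample(geneIds, cfg@nEmtGenes))
               else {
        missing <- setdiff(plantedGenes, geneIds)
        if (length(missing))
            stop("planted gene(s) outside the simulated universe: ",
                 paste(utils::head(missing, 5L), collapse = ", "),
                 call. = FALSE)
        sort(unique(plantedGenes))
    }
    burden <- stats::runif(n)
    mu <- matrix(baseline, G, n)
    pidx <- match(planted, geneIds)
    mu[pidx, ] <- mu[pidx, ] * rep(1 + 2 * burden, each = length(pidx))
    expr <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / cfg@nbDispersion),
                   G, n, dimnames = list(geneIds, sampleIds))
    storage.mode(expr) <- "integer"
    rate <- 0.01 * exp(cfg@bulk$hazard_coef * burden)
    time <- stats::rexp(n, rate = rate)
    censored <- stats::runif(n) < cfg@bulk$censor_rate
    obsTime <- ifelse(censored, time * stats::runif(n), time)
    cohort <- data.frame(sample_id = sampleIds, time = obsTime,
                         event = as.integer(!censored))
    list(expr = expr, cohort = cohort,
         truth = list(burden = stats::setNames(burden, sampleIds),
                      genes = planted))
}

#' Simulate per-drug, per-condition fold-change profiles
#'
#' Emulates drug-perturbation exports: for every drug and condition, a table
#' of per-gene log fold changes between treated and untreated states. True
#' inhibitors push the `upGenes` down and the `downGenes` up by
#' `reversal_strength` (plus unit-normal noise) in every condition;
#' non-inhibitors are pure noise.
#'
#' @param cfg a [SimConfig-class] with the `drugs` block set.
#' @param upGenes,downGenes disjoint character vectors: the signature to be
#'   reversed.
#' @return list with `fc` (data.frame `drug`, `condition`, `gene`, `log_fc`)
#'   and `truth` (data.frame `drug`, `inhibitor`).
#' @export
simulateDrugProfiles <- function(cfg, upGenes, downGenes) {
    methods::validObject(cfg)
    if (length(intersect(upGenes, downGenes)))
        stop("upGenes and downGenes must be disjoint", call. = FALSE)
    set.seed(.subSeed(cfg@seed, 3L))
    dcfg <- cfg@drugs
    nBg <- as.integer(dcfg$n_background)
    universe <- c(upGenes, downGenes, sprintf("BG%05d", seq_len(nBg)))
    .assertUniqueIds(universe, "gene")
    drugs <- sprintf("drug%02d", seq_len(dcfg$n_drugs))
    inhibitor <- seq_along(drugs) <= dcfg$n_true_inhibitors
    rows <- vector("list", dcfg$n_drugs * dcfg$n_conditions)
    k <- 0L
    for (i in seq_along(drugs)) {
        for (cond in seq_len(dcfg$n_conditions)) {
            fc <- stats::rnorm(length(universe))
            names(fc) <- universe
            if (inhibitor[i]) {
                fc[upGenes] <- fc[upGenes] - dcfg$reversal_strength
                fc[downGenes] <- fc[downGenes] + dcfg$reversal_strength
            }
            k <- k + 1L
            rows[[k]] <- data.frame(
                drug = drugs[i], condition = paste0("cond", cond),
                gene = universe, log_fc = unname(fc))
        }
    }
    list(fc = do.call(rbind, rows),
         truth = data.frame(drug = drugs, inhibitor = inhibitor))
}
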