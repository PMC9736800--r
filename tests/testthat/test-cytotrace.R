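test_that("geneCounts matches a per-column nonzero oracle", {
    m <- toyCounts(40, 15, seed = 2, lambda = 0.5)
    got <- geneCounts(m)
    want <- apply(m, 2, function(col) sum(col != 0))
    expect_equal(unname(got), unname(want))
    expect_equal(unname(geneCounts(cbind(z = rep(0, 5)))), 0)
    expect_equal(unname(geneCounts(cbind(d = rep(2, 7)))), 7)
})

test_that("a gene tracking the gene-counts vector tops the correlation", {
    set.seed(3)
    m <- matrix(stats::rexp(30 * 20), 30, 20,
                dimnames = list(sprintf("g%02d", 1:30),
                                sprintf("c%02d", 1:20)))
    m[stats::runif(length(m)) < 0.4] <- 0          # vary detected counts
    m[1, ] <- 0.01 * geneCounts(m[-1, , drop = FALSE]) + 0.01  # potency proxy
    gcs1 <- gcsScore(m, topN = 1L)
    expect_equal(unname(gcs1), unname(m[1, ]), tolerance = 1e-9)
    # topN = all genes reduces to the per-cell mean
    expect_equal(unname(gcsScore(m, topN = 30L)), unname(colMeans(m)),
                 tolerance = 1e-12)
})

test_that("constant detected-gene counts carry no potency signal", {
    m <- matrix(stats::runif(50, 1, 2), 10, 5,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:5)))
    expect_error(gcsScore(m, topN = 3L), "no potency signal")
})

test_that("kNN smoothing: identity at k = 1, constants unchanged, denoising", {
    set.seed(6)
    m <- matrix(stats::rnorm(100 * 60, 5), 100, 60,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("c%03d", 1:60)))
    m[, 31:60] <- m[, 31:60] + 4            # two clusters in expression space
    scores <- rep(c(0, 1), each = 30) + stats::rnorm(60, sd = 0.5)
    expect_identical(smoothScores(scores, m, k = 1L), scores)
    expect_equal(smoothScores(rep(2, 60), m, k = 10L), rep(2, 60))
    sm <- smoothScores(scores, m, k = 10L)
    grp <- rep(1:2, each = 30)
    varWithin <- function(x) mean(tapply(x, grp, stats::var))
    expect_lt(varWithin(sm), varWithin(scores))
    expect_error(smoothScores(scores, m, k = 0L), "positive")
    expect_error(smoothScores(scores, m, k = 60L), "smaller")
})

test_that("the potency score recovers a planted differentiation gradient", {
    cfg <- simConfig(nGenes = 800L, nCells = 500L,
                     cellTypeProps = c(tumor = 1), nTumorSubpops = 2L,
                     emtActivity = c(0.5, 0.5), diffPotential = c(0.9, 0.1),
                     nEmtGenes = 50L, seed = 31L)
    sim <- simulateScRNAseq(cfg)
    sce <- normalizeLog1p(sim$sce)
    cy <- cytotraceScore(sce, topN = 200L, k = 20L)
    sub <- sim$truth$subpop
    expect_gt(stats::median(cy$scaled_score[sub == 1]),
              stats::median(cy$scaled_score[sub == 2]))
    expect_equal(range(cy$scaled_score), c(0, 1))
})

test_that("subpopulation medians are strictly ordered across 3 potency levels", {
    cfg <- simConfig(nGenes = 600L, nCells = 900L,
                     cellTypeProps = c(tumor = 1), nTumorSubpops = 3L,
                     emtActivity = c(0.5, 0.5, 0.5),
                     diffPotential = c(0.9, 0.5, 0.1),
                     nEmtGenes = 50L, seed = 12L)
    sim <- simulateScRNAseq(cfg)
    cy <- cytotraceScore(normalizeLog1p(sim$sce), topN = 200L, k = 30L)
    med <- tapply(cy$scaled_score, sim$truth$subpop, stats::median)
    truthLevel <- c(0.9, 0.5, 0.1)
    expect_equal(stats::cor(med, truthLevel, method = "kendall"), 1)
})

test_that("identical cells score 0.5 and cell order only permutes scores", {
    m <- matrix(rep(c(3, 1, 0, 2), 5), 4, 5,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
    cy <- cytotraceScore(m, topN = 2L, k = 2L)
    expect_equal(unname(cy$scaled_score), rep(0.5, 5))

    set.seed(9)
    m2 <- matrix(stats::rexp(50 * 30), 50, 30,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("c%02d", 1:30)))
    m2[stats::runif(length(m2)) < 0.4] <- 0
    perm <- sample(30)
    a <- cytotraceScore(m2, topN = 10L, k = 5L)
    b <- cytotraceScore(m2[, perm], topN = 10L, k = 5L)
    expect_equal(b$scaled_score, a$scaled_score[perm], tolerance = 1e-9)
})

test_that("the final score is invariant under monotone rescaling of the GCS", {
    set.seed(14)
    m <- matrix(stats::rexp(60 * 40), 60, 40,
                dimnames = list(sprintf("g%02d", 1:60),
                                sprintf("c%02d", 1:40)))
    m[stats::runif(length(m)) < 0.4] <- 0
    gcs <- gcsScore(m, topN = 15L)
    sm <- smoothScores(gcs, m, k = 5L)
    scaled <- cytotraceScore(m, topN = 15L, k = 5L)$scaled_score
    # the [0,1] transform is rank-based, so any strictly monotone transform
    # of the smoothed signature leaves the final score untouched
    n <- length(sm)
    expect_equal(unname(scaled), unname((rank(sm) - 1) / (n - 1)))
    expect_equal(unname((rank(exp(3 * sm)) - 1) / (n - 1)),
                 unname(scaled))
})
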