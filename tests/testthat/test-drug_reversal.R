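test_that("footrule distance: hand examples, symmetry, universe check", {
    a <- rankedList(c("g1", "g2", "g3"), "a")
    b <- rankedList(c("g3", "g2", "g1"), "b")
    expect_equal(footruleDistance(a, a), 0)
    expect_equal(footruleDistance(a, b), 4)
    expect_equal(footruleDistance(a, b), footruleDistance(b, a))
    expect_error(footruleDistance(a, rankedList(c("g1", "g2", "g9"), "c")),
                 "universe")
})

test_that("Borda merge: identity, tie-breaking, symmetry up to ties", {
    a <- rankedList(c("g1", "g2", "g3"), "a")
    b <- rankedList(c("g3", "g2", "g1"), "b")
    expect_identical(bordaMerge(a, a)@genes, a@genes)
    expect_identical(bordaMerge(a, b)@genes, c("g1", "g2", "g3"))
    expect_identical(bordaMerge(b, a)@genes, bordaMerge(a, b)@genes)
    c1 <- rankedList(c("g2", "g1", "g4", "g3"), "c1")
    c2 <- rankedList(c("g1", "g2", "g3", "g4"), "c2")
    expect_identical(bordaMerge(c1, c2)@genes, bordaMerge(c2, c1)@genes)
})

test_that("PRL merge pairs the closest lists first", {
    a <- rankedList(c("g1", "g2", "g3", "g4"), "a1")
    a2 <- rankedList(c("g1", "g2", "g3", "g4"), "a2")
    rev <- rankedList(c("g4", "g3", "g2", "g1"), "r")
    prl <- prlMerge(list(a, rev, a2), drug = "d")
    # identical pair merges first (distance 0), then meets the reversal:
    # mean ranks tie everywhere and the lexicographic rule decides
    expect_identical(prl@merged@genes, c("g1", "g2", "g3", "g4"))
    expect_equal(prl@nConditions, 3L)
    expect_identical(prlMerge(list(a), "d")@merged@genes, a@genes)
    expect_identical(prlMerge(list(a, a2, a2), "d")@merged@genes, a@genes)
    expect_error(prlMerge(list(), "d"), "empty")
})

test_that("PRL is order-invariant when pairwise distances are distinct", {
    set.seed(2)
    universe <- sprintf("g%02d", 1:15)
    lists <- lapply(1:4, function(i)
        rankedList(sample(universe), paste0("l", i)))
    dists <- c()
    for (i in 1:3) for (j in (i + 1):4)
        dists <- c(dists, footruleDistance(lists[[i]], lists[[j]]))
    expect_false(anyDuplicated(dists) > 0)
    p1 <- prlMerge(lists, "d")@merged@genes
    p2 <- prlMerge(lists[c(3, 1, 4, 2)], "d")@merged@genes
    expect_identical(p1, p2)
})

test_that("enrichment score hits the ±1 extremes and the brute-force oracle", {
    genes <- sprintf("g%02d", 1:20)
    top <- gseaPreranked(genes, genes[1:4], nPerm = 100, seed = 1)
    expect_equal(top$es, 1)
    bottom <- gseaPreranked(genes, genes[17:20], nPerm = 100, seed = 1)
    expect_equal(bottom$es, -1)
    set.seed(12)
    for (rep in 1:20) {
        set <- sample(genes, sample(2:8, 1))
        for (w in c(0, 1)) {
            got <- gseaPreranked(genes, set, nPerm = 100, seed = 2,
                                 weight = w)$es
            expect_equal(got, bruteES(genes, set, weight = w),
                         tolerance = 1e-12)
        }
    }
    expect_error(gseaPreranked(genes, c("g01", "zz")), "fewer than 2")
    expect_error(gseaPreranked(genes, genes), "whole ranking")
})

test_that("ES agrees with the independent fgsea implementation", {
    set.seed(30)
    genes <- sprintf("g%03d", 1:100)
    stats <- sort(stats::rnorm(100), decreasing = TRUE)
    names(stats) <- genes
    for (rep in 1:5) {
        set <- sample(genes, 10)
        ours <- gseaPreranked(genes, set, nPerm = 100, seed = 3,
                              weight = 1)$es
        # fgsea on the centered-rank statistic this ranking implies
        centered <- (100 + 1) / 2 - seq_len(100)
        names(centered) <- genes
        ref <- fgsea::calcGseaStat(centered, which(genes %in% set),
                                   gseaParam = 1)
        expect_equal(ours, ref, tolerance = 1e-9)
    }
})

test_that("ES flips sign when the ranking is reversed", {
    set.seed(13)
    genes <- sprintf("g%02d", 1:20)
    set <- sample(genes, 5)
    a <- gseaPreranked(genes, set, nPerm = 100, seed = 1)$es
    b <- gseaPreranked(rev(genes), set, nPerm = 100, seed = 1)$es
    expect_equal(a, -b, tolerance = 1e-12)
})

test_that("permutation p-values are reproducible and floored", {
    genes <- sprintf("g%02d", 1:30)
    set <- genes[1:5]
    a <- gseaPreranked(genes, set, nPerm = 200, seed = 99)
    b <- gseaPreranked(genes, set, nPerm = 200, seed = 99)
    expect_identical(a, b)
    expect_gte(a$p, 1 / 201)
})

test_that("an up-signature at the ranking bottom is a perfect candidate", {
    genes <- sprintf("g%02d", 1:30)
    up <- genes[26:30]; down <- genes[1:5]
    prl <- methods::new("PRLResult", drug = "d",
                        merged = rankedList(genes, "d"), nConditions = 1L)
    res <- predictInhibitors(list(prl), up, down, nPerm = 200, seed = 5)
    expect_equal(res$es_up, -1)
    expect_equal(res$es_down, 1)
    expect_true(res$candidate)
})

test_that("true inhibitors are recovered end to end", {
    up <- sprintf("UP%02d", 1:20); down <- sprintf("DN%02d", 1:20)
    cfg <- simConfig(seed = 27L,
                     drugs = list(n_drugs = 8L, n_true_inhibitors = 4L,
                                  reversal_strength = 2, n_conditions = 3L,
                                  n_background = 150L))
    prof <- simulateDrugProfiles(cfg, up, down)
    rk <- rankingsFromFC(prof$fc)
    prls <- lapply(names(rk), function(d) prlMerge(rk[[d]], drug = d))
    res <- predictInhibitors(prls, up, down, nPerm = 500, seed = 6)
    hit <- res$candidate[match(prof$truth$drug, res$drug)]
    expect_true(all(hit[prof$truth$inhibitor]))
})
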