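test_that("scMetR standardizes exactly and reduces to a z-score when r = 1", {
    set.seed(1)
    for (rep in 1:5) {
        e <- stats::runif(60); c <- stats::runif(60)
        st <- scMetRScore(e, c)
        expect_equal(mean(st$scmetr), 0, tolerance = 1e-12)
        expect_equal(stats::sd(st$scmetr), 1, tolerance = 1e-12)
        expect_equal(st$x_m, e + c)
    }
    # s_cyto == s_emt: SDX_m = 2*sd and Score_m is the z-score of s_emt
    e <- stats::runif(40)
    st <- scMetRScore(e, e)
    expect_equal(S4Vectors::metadata(st)$sdxm, 2 * stats::sd(e),
                 tolerance = 1e-12)
    expect_equal(st$scmetr, as.numeric(scale(e)), tolerance = 1e-12)
    expect_equal(S4Vectors::metadata(st)$r, 1)
})

test_that("perfect anticorrelation collapses SDX_m and errors", {
    expect_error(scMetRScore(c(0, 0.5, 1), c(1, 0.5, 0)), "degenerate")
    expect_error(scMetRScore(c(0, 0.5), c(1, 0.5)), "at least 3")
    expect_error(scMetRScore(c(0, 0.5, 1), c(1, 0.5)), "equal length")
    expect_error(scMetRScore(c(0, 0.5, 2), c(1, 0.5, 0.2)), "\\[0,1\\]")
})

test_that("raising one cell's EMT score raises its risk score", {
    set.seed(4)
    e <- stats::runif(50, 0.1, 0.8); c <- stats::runif(50)
    base <- scMetRScore(e, c)$scmetr[7]
    e2 <- e; e2[7] <- e2[7] + 0.1
    expect_gt(scMetRScore(e2, c)$scmetr[7], base)
})

test_that("planted score shifts recover the expected 2/3/1 tier structure", {
    set.seed(11)
    shifts <- c("0" = 2, "1" = -2, "2" = 2, "3" = 0, "4" = 0, "5" = 0)
    cl <- rep(names(shifts), each = 100)
    x <- stats::rnorm(600) + shifts[cl]
    tiers <- classifySubpopulations(x, cl, alpha = 0.01)
    expect_identical(tiers$tier[tiers$sub_cluster %in% c("0", "2")],
                     c("MFTC", "MFTC"))
    expect_identical(tiers$tier[tiers$sub_cluster == "1"], "ConvTC")
    expect_identical(tiers$tier[tiers$sub_cluster %in% c("3", "4", "5")],
                     rep("TransMTC", 3))
    expect_gt(min(tiers$median_scmetr[tiers$tier == "MFTC"]),
              max(tiers$median_scmetr[tiers$tier == "ConvTC"]))
})

test_that("a null score distribution yields only TransMTC, with a warning", {
    set.seed(2)
    x <- stats::rnorm(300)
    cl <- rep(1:3, each = 100)
    expect_warning(tiers <- classifySubpopulations(x, cl), "TransMTC")
    expect_true(all(tiers$tier == "TransMTC"))
})

test_that("two separated clusters split into MFTC and ConvTC", {
    set.seed(3)
    x <- c(stats::rnorm(100), stats::rnorm(100) + 3)
    cl <- rep(c("b", "a"), each = 100)
    tiers <- classifySubpopulations(x, cl, alpha = 0.01)
    expect_identical(tiers$tier[tiers$sub_cluster == "a"], "MFTC")
    expect_identical(tiers$tier[tiers$sub_cluster == "b"], "ConvTC")
})

test_that("classification is invariant to sub-cluster relabeling", {
    set.seed(8)
    x <- stats::rnorm(300) + rep(c(2, 0, -2), each = 100)
    cl <- rep(c("x", "y", "z"), each = 100)
    relab <- c(x = "cluster7", y = "cluster1", z = "cluster4")
    a <- classifySubpopulations(x, cl)
    b <- classifySubpopulations(x, relab[cl])
    aMap <- stats::setNames(a$tier, relab[a$sub_cluster])
    bMap <- stats::setNames(b$tier, b$sub_cluster)
    expect_identical(aMap[sort(names(aMap))], bMap[sort(names(bMap))])
    expect_identical(cellTiers(a, cl), cellTiers(b, relab[cl]))
})

test_that("small or single clusters are rejected", {
    expect_error(classifySubpopulations(stats::rnorm(10), rep(1, 10)),
                 "at least 2")
    expect_error(classifySubpopulations(stats::rnorm(5),
                                        c(1, 1, 1, 2, 2)), "3 cells")
})

test_that("composition table counts match brute-force tabulation", {
    set.seed(5)
    ann <- data.frame(
        condition = sample(c("primary", "metastatic"), 400, replace = TRUE),
        tier = sample(c("MFTC", "TransMTC", "ConvTC", NA), 400,
                      replace = TRUE))
    tab <- compositionTable(ann)
    for (i in seq_len(nrow(tab))) {
        want <- sum(ann$condition == tab$condition[i] &
                    !is.na(ann$tier) & ann$tier == tab$tier[i])
        expect_equal(tab$n[i], want)
    }
    sums <- as.numeric(tapply(tab$proportion, tab$condition, sum))
    expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
})

test_that("composition handles simple proportions and empty conditions", {
    ann <- data.frame(condition = rep("primary", 20),
                      tier = c(rep("MFTC", 10), rep("ConvTC", 10)))
    tab <- compositionTable(ann)
    expect_equal(tab$proportion[tab$tier == "MFTC"], 0.5)

    ann2 <- rbind(ann, data.frame(condition = "metastatic", tier = NA))
    expect_warning(tab2 <- compositionTable(ann2), "metastatic")
    expect_false("metastatic" %in% tab2$condition)

    expect_error(compositionTable(data.frame(tier = "MFTC")), "condition")
})
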