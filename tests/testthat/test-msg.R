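lnMat <- function(m) log1p(sweep(m, 2, colSums(m), "/") * 1e4)

test_that("identical groups give zero fold change and p = 1", {
    set.seed(1)
    ln <- matrix(stats::rexp(20 * 12), 20, 12,
                 dimnames = list(sprintf("g%03d", 1:20),
                                 sprintf("c%03d", 1:12)))
    ln[5, ] <- 0.7                        # gene constant across all cells
    res <- wilcoxonDE(ln, colnames(ln)[1:6], colnames(ln)[7:12], minPct = 0)
    row <- res[res$gene_id == "g005", ]
    expect_equal(row$log_fc, 0, tolerance = 1e-9)
    expect_equal(row$p_value, 1)
    expect_identical(row$direction, "ns")
})

test_that("4-vs-4 p-values match exact enumeration over 70 rank splits", {
    m <- matrix(0, 3, 8, dimnames = list(paste0("g", 1:3), paste0("c", 1:8)))
    m[1, ] <- c(11, 12, 13, 14, 1, 2, 3, 4)   # extreme separation
    m[2, ] <- c(5, 1, 7, 3, 2, 8, 4, 6)       # interleaved
    m[3, ] <- c(9, 2, 7, 4, 5, 6, 3, 8)
    res <- wilcoxonDE(m, paste0("c", 1:4), paste0("c", 5:8), minPct = 0)
    for (g in rownames(m)) {
        want <- bruteWilcoxP(m[g, 1:4], m[g, 5:8])
        expect_equal(res$p_value[res$gene_id == g], want, tolerance = 1e-12)
    }
})

test_that("a planted 2-fold gene is called up at n = 100 per group", {
    set.seed(20)
    m <- matrix(rpois(200 * 200, 3), 200, 200,
                dimnames = list(sprintf("g%03d", 1:200),
                                sprintf("c%03d", 1:200)))
    m[7, 1:100] <- rpois(100, 6)
    ln <- lnMat(m)
    res <- wilcoxonDE(ln, colnames(m)[1:100], colnames(m)[101:200])
    expect_identical(res$direction[res$gene_id == "g007"], "up")
    expect_gt(res$log_fc[res$gene_id == "g007"], 0.25)
})

test_that("Wilcoxon p is invariant under monotone transforms of expression", {
    set.seed(21)
    m <- matrix(stats::rexp(50 * 20), 50, 20,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("c%02d", 1:20)))
    a <- wilcoxonDE(m, colnames(m)[1:10], colnames(m)[11:20], minPct = 0)
    b <- wilcoxonDE(sqrt(m), colnames(m)[1:10], colnames(m)[11:20],
                    minPct = 0)
    expect_equal(a$p_value, b$p_value[match(a$gene_id, b$gene_id)],
                 tolerance = 1e-12)
})

test_that("group preconditions are enforced", {
    m <- lnMat(toyCounts(10, 10, seed = 2) + 1L)
    expect_error(wilcoxonDE(m, colnames(m)[1:5], colnames(m)[5:10]),
                 "disjoint")
    expect_error(wilcoxonDE(m, colnames(m)[1:2], colnames(m)[3:10]),
                 "3 cells")
    expect_error(wilcoxonDE(m, c("c001", "nope", "x"), colnames(m)[4:10]),
                 "absent")
})

test_that("BH adjustment matches hand computation and its invariants", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0,1\\]")
    set.seed(3)
    p <- stats::runif(100)
    adj <- bhAdjust(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    # re-adjusting a flat step-up fixed point changes nothing
    expect_equal(bhAdjust(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
})

test_that("signature selection applies strict thresholds", {
    res <- data.frame(gene_id = c("a", "b", "c", "d"),
                      log_fc = c(0.3, 0.25, 2, -0.6),
                      p_value = c(0.001, 0.001, 0.02, 0.001),
                      adj_p = c(0.01, 0.01, 0.06, 0.01))
    expect_message(msgs <- selectMSGs(res), "1 up")
    expect_identical(msgs$up, "a")          # lfc 0.25 and adj 0.06 excluded
    expect_identical(msgs$down, "d")
    expect_error(selectMSGs(res[0, ]), "empty")
})

test_that("over-representation matches the hypergeometric oracle", {
    universe <- sprintf("u%03d", 1:100)
    query <- universe[1:50]
    sets <- list(hit = universe[1:50], none = universe[51:60],
                 part = universe[c(1:5, 96:100)])
    out <- oraEnrichment(query, universe, sets)
    expect_true("hit" %in% out$set_name)
    expect_false("none" %in% out$set_name)  # zero overlap dropped
    hitRow <- out[out$set_name == "hit", ]
    want <- stats::phyper(50 - 1, 50, 50, 50, lower.tail = FALSE)
    expect_equal(hitRow$p_value, want, tolerance = 1e-12)
    # independent oracle: sum of point hypergeometric masses
    wantPart <- sum(stats::dhyper(5:10, 10, 90, 50))
    rawPart <- stats::phyper(4, 10, 90, 50, lower.tail = FALSE)
    expect_equal(rawPart, wantPart, tolerance = 1e-12)

    expect_error(oraEnrichment(c("u001", "zzz"), universe, sets), "zzz")
    expect_equal(nrow(oraEnrichment(character(), universe, sets)), 0L)
})

test_that("null differential expression keeps the false-positive rate at bay", {
    frac <- vapply(1:10, function(rep) {
        set.seed(100 + rep)
        m <- matrix(rpois(300 * 16, 4), 300, 16,
                    dimnames = list(sprintf("g%03d", 1:300),
                                    sprintf("c%02d", 1:16)))
        res <- wilcoxonDE(lnMat(m + 1L), colnames(m)[1:8], colnames(m)[9:16],
                          minPct = 0)
        mean(res$adj_p < 0.05)
    }, numeric(1))
    expect_lte(mean(frac), 0.05 + 0.02)
})
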