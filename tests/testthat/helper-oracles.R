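# Independent brute-force oracles, deliberately written as plain loops that
# mirror the definitions, not the package's vectorized implementations.

# ssGSEA sum statistic for one expression vector
bruteSsgsea <- function(expr, geneSet, alpha) {
    genes <- names(expr)
    ord <- genes[order(-expr, genes)]        # descending, ties by gene id
    N <- length(ord)
    inSet <- ord %in% geneSet
    nIn <- sum(inSet)
    wts <- (N:1)^alpha                       # position-from-bottom weights
    sumIn <- sum(wts[inSet])
    pin <- 0; pout <- 0; total <- 0
    for (i in seq_len(N)) {
        if (inSet[i]) pin <- pin + wts[i] / sumIn
        else pout <- pout + 1 / (N - nIn)
        total <- total + (pin - pout)
    }
    total
}

# weighted KS enrichment score by walking the full ranking
bruteES <- function(rankedGenes, geneSet, weight = 1) {
    N <- length(rankedGenes)
    score <- (N + 1) / 2 - seq_len(N)
    hit <- rankedGenes %in% geneSet
    w <- abs(score)^weight
    if (sum(w[hit]) == 0) w[hit] <- 1
    denomIn <- sum(w[hit])
    miss <- 1 / (N - sum(hit))
    run <- 0; best <- 0
    for (i in seq_len(N)) {
        run <- if (hit[i]) run + w[i] / denomIn else run - miss
        if (abs(run) > abs(best)) best <- run
        # prefer the positive extremum on exact magnitude ties
        if (abs(run) == abs(best) && run > best) best <- run
    }
    best
}

# two-group log-rank chi-square by looping over distinct event times
bruteLogrank <- function(g, times, events) {
    g <- as.integer(as.factor(g))
    O1 <- 0; E1 <- 0; V <- 0
    for (t in sort(unique(times[events == 1]))) {
        atRisk <- times >= t
        n <- sum(atRisk); n1 <- sum(atRisk & g == 1L)
        d <- sum(times == t & events == 1)
        d1 <- sum(times == t & events == 1 & g == 1L)
        O1 <- O1 + d1
        E1 <- E1 + d * n1 / n
        if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O1 - E1)^2 / V
}

# mean silhouette width from explicit pairwise distances
bruteSilhouette <- function(embedding, labels) {
    d <- as.matrix(stats::dist(embedding))
    n <- nrow(d)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- which(labels == labels[i])
        if (length(own) == 1L) { s[i] <- 0; next }
        a <- mean(d[i, setdiff(own, i)])
        b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
            mean(d[i, labels == l]), numeric(1)))
        s[i] <- (b - a) / max(a, b)
    }
    mean(s)
}

# exact two-sample rank-sum p by enumerating every group-A rank split
bruteWilcoxP <- function(a, b) {
    pooled <- c(a, b)
    r <- rank(pooled)
    obs <- sum(r[seq_along(a)])
    splits <- utils::combn(length(pooled), length(a))
    stats <- apply(splits, 2L, function(idx) sum(r[idx]))
    mu <- mean(stats)
    mean(abs(stats - mu) >= abs(obs - mu))
}

# small dense counts fixture with named dimensions
toyCounts <- function(nGenes, nCells, seed = 1, lambda = 3) {
    set.seed(seed)
    matrix(stats::rpois(nGenes * nCells, lambda), nGenes, nCells,
           dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                           sprintf("c%03d", seq_len(nCells))))
}

toySCE <- function(counts) {
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts))
    S4Vectors::metadata(sce)$layer_tag <- "counts"
    sce
}
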