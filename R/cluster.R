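#' Community-detection clustering at a given resolution
#'
#' Builds a shared-nearest-neighbor (SNN) graph on the embedding (k nearest
#' neighbors including self, Jaccard edge weights between neighbor sets,
#' edges below the prune threshold dropped) and partitions it by
#' modularity-based Louvain community detection at the requested resolution.
#' Deterministic for a fixed seed.
#'
#' @param embedding cells x d numeric matrix (d >= 2), e.g. PCA coordinates.
#' @param resolution modularity resolution parameter (> 0).
#' @param seed integer seed for the community detection.
#' @param kNeighbors SNN neighborhood size.
#' @param prune Jaccard weight below which SNN edges are dropped.
#' @return integer vector of cluster labels `0..K-1`, in order of first
#'   appearance.
#' @export
clusterAtResolution <- function(embedding, resolution, seed = 0L,
                                kNeighbors = 20L, prune = 1 / 15) {
    embedding <- as.matrix(embedding)
    n <- nrow(embedding)
    if (ncol(embedding) < 2L)
        stop("embedding must have at least 2 dimensions", call. = FALSE)
    if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
    if (kNeighbors >= n)
        stop("fewer cells than the neighbors parameter", call. = FALSE)
    d <- as.matrix(stats::dist(embedding))
    # k nearest neighbors including self (self-distance 0 sorts first)
    nb <- t(apply(d, 1L, function(row) order(row)[seq_len(kNeighbors)]))
    A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = kNeighbors),
                              j = as.vector(t(nb)), x = 1, dims = c(n, n))
    shared <- Matrix::tcrossprod(A)
    jac <- as.matrix(shared) / (2 * kNeighbors - as.matrix(shared))
    jac[jac < prune] <- 0
    diag(jac) <- 0
    g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                             weighted = TRUE)
    set.seed(seed)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    mem <- igraph::membership(comm)
    labels <- match(mem, unique(mem)) - 1L   # relabel by first appearance
    as.integer(labels)
}

#' Mean silhouette width of a clustering
#'
#' Standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with
#' Euclidean distances on the embedding; cells in singleton clusters
#' contribute 0. Larger values indicate that cells of the same cluster are
#' more similar to each other than to the nearest other cluster.
#'
#' @param embedding cells x d numeric matrix.
#' @param labels per-cell cluster labels (>= 2 distinct values).
#' @return mean silhouette width in \[-1, 1\].
#' @export
meanSilhouette <- function(embedding, labels) {
    labels <- as.integer(factor(labels))
    if (length(unique(labels)) < 2L)
        stop("silhouette undefined for a single cluster", call. = FALSE)
    if (length(labels) != nrow(as.matrix(embedding)))
        stop("labels length does not match embedding rows", call. = FALSE)
    sil <- cluster::silhouette(labels, stats::dist(embedding))
    if (is.matrix(sil)) mean(sil[, "sil_width"]) else 0
}

#' Sweep clustering resolutions and select by mean silhouette width
#'
#' Clusters the embedding at every resolution of the grid, scores each
#' clustering by [meanSilhouette()], and selects the resolution with the
#' largest mean silhouette width (ties resolved toward the smallest
#' resolution). Grid points collapsing to a single cluster are recorded with
#' `NA` silhouette and excluded from the argmax.
#'
#' @param embedding cells x d numeric matrix.
#' @param resolutions numeric grid; the default spans 0.1 to 1.0 in steps of
#'   0.1.
#' @param seed integer seed passed to [clusterAtResolution()].
#' @param kNeighbors SNN neighborhood size.
#' @return a [ResolutionSweep-class].
#' @export
selectResolution <- function(embedding, resolutions = seq(0.1, 1, by = 0.1),
                             seed = 0L, kNeighbors = 20L) {
    if (length(resolutions) < 1L) stop("empty resolution grid", call. = FALSE)
    resolutions <- sort(unique(resolutions))
    nClusters <- integer(length(resolutions))
    sil <- rep(NA_real_, length(resolutions))
    labelList <- vector("list", length(resolutions))
    for (i in seq_along(resolutions)) {
        lab <- clusterAtResolution(embedding, resolutions[i], seed = seed,
                                   kNeighbors = kNeighbors)
        labelList[[i]] <- lab
        nClusters[i] <- length(unique(lab))
        if (nClusters[i] >= 2L) sil[i] <- meanSilhouette(embedding, lab)
    }
    if (all(is.na(sil)))
        stop("every resolution yields a single cluster; silhouette undefined",
             call. = FALSE)
    best <- which(!is.na(sil) & sil == max(sil, na.rm = TRUE))[1L]
    methods::new("ResolutionSweep",
                 sweep = data.frame(resolution = resolutions,
                                    n_clusters = nClusters,
                                    mean_silwidth = sil),
                 selected = resolutions[best],
                 labels = labelList[[best]])
}
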