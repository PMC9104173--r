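#' Depth-normalize and log-transform counts
#'
#' Computes `log(1 + scale * count / depth)` per cell (depth = the cell's
#' total counts), the standard library-size normalization with scale factor
#' 1e4. Cells with zero depth are left all-zero with a warning.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param scale scale factor, default `1e4`.
#' @return The same object with a `logcounts` assay added.
#' @export
normalizeCounts <- function(sce, scale = 1e4) {
  if (scale <= 0) stop("scale must be > 0")
  counts <- SummarizedExperiment::assay(sce, "counts")
  depth <- Matrix::colSums(counts)
  zero <- depth == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero depth left all-zero")
    depth[zero] <- 1
  }
  norm <- counts %*% Matrix::Diagonal(x = scale / depth)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  sce
}

#' PCA embedding of normalized expression
#'
#' Standardizes genes (zero mean, unit variance; zero-variance genes
#' dropped), runs PCA over cells and returns the top components, ordered by
#' explained variance with a deterministic sign convention: each component is
#' flipped so that its largest-magnitude gene loading is positive.
#'
#' @param sce a normalized `SingleCellExperiment` (see [normalizeCounts]).
#' @param nPCs number of components (10 for all-cell clustering, 7 for the
#'   fibroblast subclustering, by convention).
#' @param genes optional subset of genes to use.
#' @return cells-by-nPCs numeric matrix with an attribute
#'   `varExplained` (proportion of variance per component).
#' @export
pcaEmbed <- function(sce, nPCs = 10, genes = NULL) {
  x <- SummarizedExperiment::assay(sce, "logcounts")
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  x <- as.matrix(Matrix::t(x))                       # cells x genes
  v <- matrixStats::colVars(x)
  x <- x[, v > 0, drop = FALSE]
  if (nPCs > min(dim(x))) stop("nPCs exceeds data dimensions")
  pc <- prcomp(x, center = TRUE, scale. = TRUE, rank. = nPCs)
  flip <- apply(pc$rotation, 2L, function(w) sign(w[which.max(abs(w))]))
  emb <- sweep(pc$x, 2L, flip, "*")
  rownames(emb) <- colnames(sce)
  attr(emb, "varExplained") <- pc$sdev^2 / sum(pc$sdev^2)
  attr(emb, "eigenvalues") <- pc$sdev^2
  attr(emb, "nGenes") <- ncol(x)
  emb
}

#' Choose the number of informative principal components
#'
#' Elbow-style selection: keeps the components whose eigenvalue (on
#' standardized genes) exceeds the Marchenko-Pastur upper noise edge
#' `(1 + sqrt(nGenes / nCells))^2`, the spectrum bound for a pure-noise
#' matrix. An automated stand-in for picking the elbow of a PC scree plot.
#'
#' @param embedding a matrix from [pcaEmbed] (computed with enough
#'   components to cover the signal, e.g. 20).
#' @param minPCs,maxPCs bounds on the returned count.
#' @return integer number of components to retain.
#' @export
choosePCs <- function(embedding, minPCs = 2, maxPCs = ncol(embedding)) {
  eig <- attr(embedding, "eigenvalues")
  p <- attr(embedding, "nGenes")
  n <- nrow(embedding)
  edge <- (1 + sqrt(p / n))^2
  min(max(minPCs, sum(eig > edge)), maxPCs)
}

#' Merge clusters with no distinguishing markers
#'
#' Modularity optimization at a fixed resolution occasionally splits one
#' transcriptomic population into two communities. This post-pass merges any
#' pair of clusters that cannot be told apart by differential expression:
#' clusters are merged when fewer than `minMarkers` genes separate them
#' strongly (two-fold, `|log2FC| > minLog2FC`, at Benjamini-Hochberg
#' `q < alpha`; pairwise Wilcoxon rank-sum), repeating until all remaining
#' pairs are distinct. The two-fold bar guards against the double-dipping
#' inflation of weak differences between halves of one population.
#' Labels are re-densified from 0 by decreasing size.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param clusters integer cluster ids per cell.
#' @param minMarkers minimum number of separating genes (default 5).
#' @param minLog2FC,alpha pairwise DE thresholds.
#' @return integer cluster ids after merging.
#' @export
mergeIndistinct <- function(sce, clusters, minMarkers = 5, minLog2FC = 1,
                            alpha = 0.05) {
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  cl <- as.integer(factor(clusters)) - 1L
  nSeparating <- function(a, b) {
    cells <- cl %in% c(a, b)
    sub <- x[, cells, drop = FALSE]
    inA <- cl[cells] == a
    fc <- log2((rowMeans(expm1(sub[, inA, drop = FALSE])) + 1) /
               (rowMeans(expm1(sub[, !inA, drop = FALSE])) + 1))
    cand <- abs(fc) > minLog2FC
    if (sum(cand) < minMarkers) return(sum(cand))
    # rank tests only where the fold gate passes; others cannot qualify
    p <- rep(1, nrow(sub))
    p[cand] <- rankSumTest(sub[cand, , drop = FALSE], inA)
    q <- p.adjust(p, "BH")
    sum(q < alpha & cand)
  }
  repeat {
    ids <- sort(unique(cl))
    merged <- FALSE
    for (i in seq_along(ids)) {
      for (k in seq_along(ids)) {
        if (k <= i) next
        if (nSeparating(ids[i], ids[k]) < minMarkers) {
          cl[cl == ids[k]] <- ids[i]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- unname(relabel[as.character(cl)])
  names(out) <- names(clusters)
  out
}

# Shared-nearest-neighbor graph with Jaccard weights, Seurat-style.
snnGraph <- function(embedding, kNeighbors = 20, prune = 1 / 15) {
  n <- nrow(embedding)
  nn <- RANN::nn2(embedding, k = kNeighbors)$nn.idx
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = kNeighbors),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * kNeighbors - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Louvain clustering on a shared-nearest-neighbor graph
#'
#' Builds a k-nearest-neighbor graph in the PCA embedding, reweights edges by
#' the Jaccard overlap of neighborhoods (pruned below 1/15), and partitions
#' by Louvain modularity optimization at the given resolution. Cluster ids
#' are dense from 0, ordered by decreasing size.
#'
#' @param embedding cells-by-PCs matrix from [pcaEmbed].
#' @param kNeighbors neighbors per cell (default 20); must be < n cells.
#' @param resolution Louvain resolution (default 1).
#' @param seed integer seed (Louvain is stochastic).
#' @return integer vector of cluster ids (0-based), one per cell, with
#'   attribute `parameters`.
#' @export
clusterCells <- function(embedding, kNeighbors = 20, resolution = 1,
                         seed = 0L) {
  if (kNeighbors >= nrow(embedding)) stop("kNeighbors must be < number of cells")
  g <- snnGraph(embedding, kNeighbors)
  set.seed(seed)
  com <- igraph::cluster_louvain(g, resolution = resolution)
  mem <- igraph::membership(com)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- unname(relabel[as.character(mem)])
  names(out) <- rownames(embedding)
  attr(out, "parameters") <- list(kNeighbors = kNeighbors,
                                  resolution = resolution, seed = seed)
  out
}

#' Assign cell-type identities to clusters by marker score
#'
#' Scores each cluster for each candidate type as the mean (over the type's
#' marker genes) of the cluster-average z-scored log-normalized expression.
#' A cluster gets the best-scoring type if its score exceeds the threshold;
#' a cluster exceeding the threshold for both ductal marker sets gets the
#' combined label `"Ductal cell 1 + Ductal cell 2"`; a cluster below
#' threshold for every type is labeled `"others"`.
#'
#' @param clusters integer cluster ids per cell (from [clusterCells]).
#' @param sce normalized `SingleCellExperiment`.
#' @param markerMap named list mapping type to marker gene symbols.
#' @param tau marker-score threshold (default 0.25).
#' @param ductalTypes the two type names eligible for the combined label.
#' @return named character vector: cluster id -> assigned type.
#' @export
assignCellTypes <- function(clusters, sce, markerMap, tau = 0.25,
                            ductalTypes = c("Ductal cell 1", "Ductal cell 2")) {
  if (length(markerMap) == 0L) stop("markerMap must be non-empty")
  x <- SummarizedExperiment::assay(sce, "logcounts")
  ids <- sort(unique(clusters))
  scores <- matrix(NA_real_, length(ids), length(markerMap),
                   dimnames = list(as.character(ids), names(markerMap)))
  for (ty in names(markerMap)) {
    genes <- intersect(toupper(markerMap[[ty]]), rownames(x))
    if (!length(genes)) next
    sub <- as.matrix(x[genes, , drop = FALSE])
    mu <- rowMeans(sub)
    sdv <- matrixStats::rowSds(sub)
    sdv[sdv == 0] <- 1
    z <- (sub - mu) / sdv
    for (cl in ids)
      scores[as.character(cl), ty] <- mean(z[, clusters == cl, drop = FALSE])
  }
  assign <- vapply(as.character(ids), function(cl) {
    s <- scores[cl, ]
    s[is.na(s)] <- -Inf
    if (all(ductalTypes %in% names(s)) && all(s[ductalTypes] > tau))
      return(paste(ductalTypes, collapse = " + "))
    if (max(s) > tau) names(s)[which.max(s)] else "others"
  }, character(1L))
  names(assign) <- as.character(ids)
  attr(assign, "scores") <- scores
  assign
}

# Vectorized two-sided Mann-Whitney (normal approximation with tie
# correction and continuity correction) of each gene, group vs rest.
rankSumTest <- function(x, inGroup) {
  n1 <- sum(inGroup); n2 <- sum(!inGroup); n <- n1 + n2
  ranks <- matrixStats::rowRanks(x, ties.method = "average")
  w <- rowSums(ranks[, inGroup, drop = FALSE]) - n1 * (n1 + 1) / 2
  # tie correction per gene
  tieTerm <- apply(x, 1L, function(r) {
    l <- rle(sort(r))$lengths
    sum(l^3 - l)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
  z <- w - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  z[sigma2 == 0] <- 0
  2 * stats::pnorm(-abs(z))
}

#' Differential markers of a cluster (Wilcoxon rank-sum)
#'
#' Tests every gene, cluster vs all other cells, by the two-sided Wilcoxon
#' rank-sum test on log-normalized expression. The log2 fold change is
#' computed Seurat-style from the de-logged means with pseudocount 1:
#' `log2((mean(expm1 x_in) + 1) / (mean(expm1 x_out) + 1))`. The default
#' marker filter follows the raw p-value cutoff (p < 0.05,
#' |log2FC| > 0.5); Benjamini-Hochberg adjusted p-values are also reported.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param clusters integer cluster ids per cell.
#' @param clusterId the cluster to test (needs >= 3 cells).
#' @param minLog2FC,alpha marker filter thresholds.
#' @param genes optional gene subset.
#' @return data.frame with columns `gene`, `cluster`, `log2fc`, `p_value`,
#'   `p_adjusted`, `frac_in`, `frac_out`, `is_marker`, ordered by p then
#'   |log2fc| descending.
#' @export
findClusterMarkers <- function(sce, clusters, clusterId, minLog2FC = 0.5,
                               alpha = 0.05, genes = NULL) {
  x <- SummarizedExperiment::assay(sce, "logcounts")
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  inGroup <- clusters == clusterId
  if (sum(inGroup) < 3L) stop("cluster must have >= 3 cells")
  xm <- as.matrix(x)
  p <- rankSumTest(xm, inGroup)
  meanIn <- rowMeans(expm1(xm[, inGroup, drop = FALSE]))
  meanOut <- rowMeans(expm1(xm[, !inGroup, drop = FALSE]))
  log2fc <- log2((meanIn + 1) / (meanOut + 1))
  out <- data.frame(
    gene = rownames(xm), cluster = clusterId, log2fc = log2fc,
    p_value = p, p_adjusted = p.adjust(p, "BH"),
    frac_in = rowMeans(xm[, inGroup, drop = FALSE] > 0),
    frac_out = rowMeans(xm[, !inGroup, drop = FALSE] > 0),
    row.names = NULL)
  out$is_marker <- out$p_value < alpha & abs(out$log2fc) > minLog2FC
  out[order(out$p_value, -abs(out$log2fc)), ]
}

#' Cluster composition per stage
#'
#' Tabulates, for each stage, the fraction of its cells in each cluster
#' (fractions sum to 1 within a stage). Stages with no cells are omitted
#' with a warning.
#'
#' @param clusters cluster ids per cell.
#' @param stage stage label per cell.
#' @return data.frame `cluster` x `stage` -> `fraction`.
#' @export
stageProportions <- function(clusters, stage) {
  stage <- as.character(stage)
  present <- intersect(stageLevels(), unique(stage))
  missing <- setdiff(stageLevels(), present)
  if (length(missing))
    warning("no cells at stage(s): ", paste(missing, collapse = ", "))
  tab <- table(cluster = clusters, stage = factor(stage, levels = present))
  frac <- prop.table(tab, margin = 2L)
  out <- as.data.frame(frac, responseName = "fraction")
  out$cluster <- as.character(out$cluster)
  out$stage <- as.character(out$stage)
  out
}

#' Two-dimensional t-SNE display embedding
#'
#' Deterministic under a fixed seed; used for visualization only (cluster
#' identification itself is graph-based).
#'
#' @param embedding cells-by-PCs matrix from [pcaEmbed].
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity; requires `3 * perplexity < n - 1`.
#' @return cells-by-2 coordinate matrix.
#' @export
embedTSNE <- function(embedding, seed = 0L, perplexity = 30) {
  if (nrow(embedding) - 1 < 3 * perplexity)
    stop("too few cells for perplexity ", perplexity)
  set.seed(seed)
  fit <- Rtsne::Rtsne(embedding, perplexity = perplexity, pca = FALSE,
                      check_duplicates = FALSE)
  out <- fit$Y
  rownames(out) <- rownames(embedding)
  colnames(out) <- c("tsne1", "tsne2")
  out
}
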