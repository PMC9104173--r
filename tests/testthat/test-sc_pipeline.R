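test_that("normalization matches hand arithmetic and is depth-invariant", {
  m <- matrix(c(1L, 3L), nrow = 2, dimnames = list(c("A", "B"), "c1"))
  sce <- normalizeCounts(toyCounts(m), scale = 1e4)
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  expect_equal(unname(x[, 1]), c(log1p(2500), log1p(7500)))

  # doubling a cell's counts leaves its normalized column unchanged
  m2 <- cbind(c1 = c(1L, 3L), c2 = c(2L, 6L))
  rownames(m2) <- c("A", "B")
  x2 <- as.matrix(SummarizedExperiment::assay(normalizeCounts(toyCounts(m2)),
                                              "logcounts"))
  expect_equal(x2[, 1], x2[, 2])

  m3 <- cbind(c1 = c(1L, 3L), c2 = c(0L, 0L))
  rownames(m3) <- c("A", "B")
  expect_warning(sce3 <- normalizeCounts(toyCounts(m3)), "zero depth")
  expect_equal(as.numeric(SummarizedExperiment::assay(sce3, "logcounts")[, 2]),
               c(0, 0))
})

test_that("PCA matches the closed-form eigenvector and is equivariant", {
  # rank-1 structure on the log scale: one direction explains ~all variance
  set.seed(2)
  m <- matrix(rpois(5 * 60, 8), 5,
              dimnames = list(paste0("G", 1:5), sprintf("c%02d", 1:60)))
  storage.mode(m) <- "integer"
  sce <- normalizeCounts(toyCounts(m))
  score <- rnorm(60)
  x1 <- outer(c(2, -1, 0.5, 1, -2), score) + rnorm(300, sd = 0.01)
  dimnames(x1) <- dimnames(m)
  SummarizedExperiment::assay(sce, "logcounts") <- x1
  emb <- pcaEmbed(sce, 2)
  expect_gt(attr(emb, "varExplained")[1], 0.9)

  # 2-gene correlated Gaussian: loading direction from 2x2 eigendecomposition
  set.seed(3)
  n <- 4000
  z <- rnorm(n); e <- rnorm(n, sd = 0.6)
  g1 <- z; g2 <- 0.8 * z + e
  x <- cbind(scale(g1), scale(g2))
  cv <- cov(x)
  ev <- eigen(cv)$vectors[, 1]
  ev <- ev * sign(ev[which.max(abs(ev))])
  pc <- prcomp(x, rank. = 1)
  w <- pc$rotation[, 1]; w <- w * sign(w[which.max(abs(w))])
  expect_equal(unname(w), unname(ev), tolerance = 1e-6)

  # permuting cells permutes embedding rows identically
  perm <- sample(ncol(sce))
  embP <- pcaEmbed(sce[, perm], 2)
  expect_equal(unname(embP), unname(emb[perm, ]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("clustering separates planted blobs and respects limits", {
  # neighborhood size comparable to blob size: blobs stay whole
  two <- blobEmbedding(rbind(c(0, 0), c(100, 0)), nPer = 20, seed = 4)
  cl <- clusterCells(two$embedding, kNeighbors = 10, seed = 1)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(ari(cl, two$labels), 1)

  three <- blobEmbedding(rbind(c(0, 0), c(30, 0), c(0, 30)), nPer = 100,
                         seed = 5)
  cl3 <- clusterCells(three$embedding, kNeighbors = 30, seed = 1)
  expect_gte(ari(cl3, three$labels), 0.95)

  # resolution -> 0 collapses a connected graph to a single cluster
  one <- blobEmbedding(rbind(c(0, 0)), nPer = 100, seed = 6)
  cl0 <- clusterCells(one$embedding, kNeighbors = 15, resolution = 1e-4,
                      seed = 1)
  expect_equal(length(unique(cl0)), 1L)

  expect_error(clusterCells(two$embedding[1:5, ], kNeighbors = 10),
               "kNeighbors")
})

test_that("cluster typing follows the marker-score rule", {
  set.seed(6)
  genes <- c("LUM", "DCN", "COL1A1", "AMBP", "CFTR", "KRT19", "MUC1",
             paste0("BG", 1:13))
  nPer <- 40
  cl <- rep(0:3, each = nPer)
  m <- matrix(rpois(length(genes) * length(cl), 2), length(genes),
              dimnames = list(genes, sprintf("c%03d", seq_along(cl))))
  fibM <- c("LUM", "DCN", "COL1A1"); d1M <- c("AMBP", "CFTR")
  d2M <- c("KRT19", "MUC1")
  m[fibM, cl == 0] <- m[fibM, cl == 0] + 20L
  m[c(d1M, d2M), cl == 1] <- m[c(d1M, d2M), cl == 1] + 20L   # both ductal sets
  m[d1M, cl == 2] <- m[d1M, cl == 2] + 20L
  storage.mode(m) <- "integer"
  sce <- normalizeCounts(toyCounts(m))
  markerMap <- list("Fibroblast" = fibM, "Ductal cell 1" = d1M,
                    "Ductal cell 2" = d2M)
  types <- assignCellTypes(cl, sce, markerMap)
  expect_equal(unname(types["0"]), "Fibroblast")
  expect_equal(unname(types["1"]), "Ductal cell 1 + Ductal cell 2")
  expect_equal(unname(types["2"]), "Ductal cell 1")
  expect_equal(unname(types["3"]), "others")
})

test_that("marker calling agrees with wilcox.test and flags planted markers", {
  set.seed(7)
  nIn <- 100; nOut <- 100
  cl <- rep(c(1L, 0L), c(nIn, nOut))
  m <- matrix(rnbinom(30 * 200, mu = 4, size = 2), nrow = 30,
              dimnames = list(sprintf("G%02d", 1:30), sprintf("c%03d", 1:200)))
  m["G01", cl == 1] <- rnbinom(nIn, mu = 16, size = 2)   # planted 4-fold
  storage.mode(m) <- "integer"
  sce <- normalizeCounts(toyCounts(m))
  res <- findClusterMarkers(sce, cl, 1L)
  expect_true(res$is_marker[res$gene == "G01"])

  # gene identical in/out (equal depths): exactly zero fold change, no marker
  mEq <- matrix(c(3L, 7L), nrow = 2, ncol = 200,
                dimnames = list(c("G02", "FILL"), sprintf("e%03d", 1:200)))
  resEq <- findClusterMarkers(normalizeCounts(toyCounts(mEq)), cl, 1L)
  g2 <- resEq[resEq$gene == "G02", ]
  expect_equal(g2$log2fc, 0)
  expect_equal(g2$p_value, 1)
  expect_false(g2$is_marker)

  # p-values match a per-gene wilcox.test oracle (normal approx, ties)
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  pOracle <- vapply(rownames(x), function(g) {
    suppressWarnings(wilcox.test(x[g, cl == 1], x[g, cl == 0],
                                 exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  pPkg <- setNames(res$p_value, res$gene)[names(pOracle)]
  expect_equal(unname(pPkg), unname(pOracle), tolerance = 1e-10)

  expect_error(findClusterMarkers(sce, cl, 2L), ">= 3 cells")
})

test_that("false-marker rate under label permutation is near alpha", {
  set.seed(8)
  nG <- 40; n <- 120
  m <- matrix(rnbinom(nG * n, mu = 5, size = 2), nrow = nG,
              dimnames = list(sprintf("G%02d", 1:nG), sprintf("c%03d", 1:n)))
  storage.mode(m) <- "integer"
  sce <- normalizeCounts(toyCounts(m))
  nSim <- 60
  hits <- 0L
  for (b in seq_len(nSim)) {
    cl <- sample(rep(0:1, each = n / 2))
    res <- findClusterMarkers(sce, cl, 1L)
    hits <- hits + sum(res$p_value < 0.05)
  }
  rate <- hits / (nSim * nG)
  se <- sqrt(0.05 * 0.95 / (nSim * nG))
  expect_lt(abs(rate - 0.05), 3 * se + 0.01)
})

test_that("stage proportions sum to one and recover planted composition", {
  cl <- rep(0L, 10); st <- rep("IB", 10)
  p1 <- suppressWarnings(stageProportions(cl, st))
  expect_equal(p1$fraction, 1)

  set.seed(9)
  truth <- c(`0` = 0.7, `1` = 0.2, `2` = 0.1)
  n <- 2000
  cl2 <- sample(0:2, n, TRUE, prob = truth)
  p2 <- suppressWarnings(stageProportions(cl2, rep("IIB", n)))
  for (k in names(truth)) {
    se <- sqrt(truth[[k]] * (1 - truth[[k]]) / n)
    expect_lt(abs(p2$fraction[p2$cluster == k] - truth[[k]]), 3 * se)
  }
  expect_equal(sum(p2$fraction), 1)
  expect_warning(stageProportions(cl, st), "no cells at stage")
})

test_that("t-SNE display embedding is seeded and keeps blobs apart", {
  blobs <- blobEmbedding(rbind(c(0, 0, 0), c(60, 0, 0)), nPer = 80, seed = 10)
  y1 <- embedTSNE(blobs$embedding, seed = 3, perplexity = 15)
  y2 <- embedTSNE(blobs$embedding, seed = 3, perplexity = 15)
  expect_identical(y1, y2)
  d <- as.matrix(dist(y1))
  within <- mean(d[1:80, 1:80]); across <- mean(d[1:80, 81:160])
  expect_gt(across, within)
  expect_error(embedTSNE(blobs$embedding[1:20, ], perplexity = 15),
               "too few cells")
})

test_that("indistinct clusters merge, distinct ones survive", {
  set.seed(11)
  nG <- 60; nPer <- 60
  m <- matrix(rnbinom(nG * 3 * nPer, mu = 4, size = 2), nrow = nG,
              dimnames = list(sprintf("G%02d", 1:nG),
                              sprintf("c%03d", 1:(3 * nPer))))
  truth <- rep(c(0L, 0L, 1L), each = nPer)    # labels 0/1 split one population
  m[1:10, truth == 1] <- m[1:10, truth == 1] * 4L
  storage.mode(m) <- "integer"
  sce <- normalizeCounts(toyCounts(m))
  fake <- rep(c(0L, 1L, 2L), each = nPer)
  merged <- mergeIndistinct(sce, fake)
  expect_equal(length(unique(merged)), 2L)
  expect_equal(ari(merged, truth), 1)
})
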