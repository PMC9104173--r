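test_that("extreme singleton sets give ES of exactly +1 / -1", {
  scores <- setNames(seq(5, -5, length.out = 11), paste0("G", 1:11))
  ranked <- rankedList(scores)
  top <- gsea(ranked, GeneSet("top", ranked$gene[1]), weightP = 0,
              nPerm = 100, seed = 1)
  expect_equal(top$ES, 1)
  bottom <- gsea(ranked, GeneSet("bot", ranked$gene[11]), weightP = 0,
                 nPerm = 100, seed = 1)
  expect_equal(bottom$ES, -1)
  expect_error(gsea(ranked, GeneSet("none", "ZZZ"), nPerm = 100),
               "does not intersect")
})

test_that("running-sum ES matches the brute-force oracle to 1e-12", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    names(scores) <- paste0("G", seq_len(n))
    ranked <- rankedList(scores)
    hitIdx <- sample(n, sample(2:min(8, n - 1), 1))
    set <- GeneSet("s", ranked$gene[hitIdx])
    res <- gsea(ranked, set, weightP = 1, nPerm = 100, seed = i)
    oracle <- bruteES(ranked$score, ranked$gene %in% members(set), 1)
    expect_equal(res$ES, oracle, tolerance = 1e-12)
  }
})

test_that("leading edge contains exactly the set members driving the peak", {
  scores <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5), paste0("G", 1:10))
  ranked <- rankedList(scores)
  res <- gsea(ranked, GeneSet("s", c("G1", "G3", "G9")), nPerm = 100, seed = 1)
  expect_true(all(res$leading_edge %in% c("G1", "G3", "G9")))
  expect_true(all(match(res$leading_edge, ranked$gene) <= res$peak_rank))
  expect_equal(sign(res$NES), sign(res$ES))

  resNeg <- gsea(ranked, GeneSet("s", c("G8", "G10")), nPerm = 100, seed = 1)
  expect_lt(resNeg$ES, 0)
  expect_true(all(match(resNeg$leading_edge, ranked$gene) >= resNeg$peak_rank))
})

test_that("ES agrees with fgsea on a reference case", {
  skip_if_not_installed("fgsea")
  set.seed(32)
  scores <- setNames(rnorm(80), paste0("G", 1:80))
  ranked <- rankedList(scores)
  set <- GeneSet("s", paste0("G", c(3, 11, 17, 40, 55, 71)))
  mine <- gsea(ranked, set, weightP = 1, nPerm = 200, seed = 1)
  stats <- setNames(ranked$score, ranked$gene)
  ref <- suppressWarnings(
    fgsea::fgsea(list(s = members(set)), stats, nperm = 200,
                 gseaParam = 1))
  expect_equal(mine$ES, ref$ES, tolerance = 1e-9)
})

test_that("permutation p-values are honestly sized on a modest null sample", {
  set.seed(33)
  scores <- setNames(rnorm(60), paste0("G", 1:60))
  ranked <- rankedList(scores)
  ps <- vapply(1:60, function(i) {
    set <- GeneSet("s", sample(ranked$gene, 6))
    gsea(ranked, set, nPerm = 200, seed = i)$p_perm
  }, numeric(1))
  expect_gt(mean(ps < 0.2), 0.05)   # not degenerate at 1
  expect_lt(mean(ps < 0.05), 0.20)  # not wildly anti-conservative
})

test_that("within-set correlation test finds planted and ignores null", {
  makeData <- function(nCells, nSet, nBg, r, seed) {
    set.seed(seed)
    z <- rnorm(nCells)
    a <- sqrt(r / (1 - r))
    xs <- t(vapply(seq_len(nSet), function(i) a * z + rnorm(nCells),
                   numeric(nCells)))
    xb <- matrix(rnorm(nBg * nCells), nBg)
    x <- abs(rbind(xs, xb))
    rownames(x) <- c(sprintf("S%02d", seq_len(nSet)),
                     sprintf("B%03d", seq_len(nBg)))
    colnames(x) <- sprintf("c%03d", seq_len(nCells))
    m <- matrix(1L, nrow(x), ncol(x), dimnames = dimnames(x))
    sce <- normalizeCounts(toyCounts(m))
    SummarizedExperiment::assay(sce, "logcounts") <- x
    sce
  }
  set <- GeneSet("s", sprintf("S%02d", 1:50))

  # two identical set genes -> within-pair strength 1
  sceDup <- makeData(50, 2, 10, 0, 1)
  x <- SummarizedExperiment::assay(sceDup, "logcounts")
  x["S02", ] <- x["S01", ]
  SummarizedExperiment::assay(sceDup, "logcounts") <- x
  dup <- suppressWarnings(
    genesetCorrelationTest(sceDup, GeneSet("s", c("S01", "S02"))))
  expect_equal(dup$mean_strength_in, 1)

  # planted r = 0.5: overwhelmingly significant
  plant <- genesetCorrelationTest(makeData(100, 50, 100, 0.5, 2), set)
  expect_lt(plant$p, 1e-6)
  expect_gt(plant$mean_strength_in, plant$mean_strength_out)

  # independent null: moderate rejection rate at alpha = 0.05
  rej <- vapply(1:40, function(i) {
    genesetCorrelationTest(makeData(80, 20, 60, 0, 100 + i),
                           GeneSet("s", sprintf("S%02d", 1:20)))$p < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.25)

  expect_error(genesetCorrelationTest(makeData(50, 2, 10, 0, 3),
                                      GeneSet("s", "S01")), "2 set genes")
})

test_that("over-representation p equals the closed-form hypergeometric tail", {
  universe <- sprintf("U%02d", 1:20)
  term <- universe[1:5]
  query <- universe[c(1:4, 10)]
  res <- ora(query, list(T1 = term), universe)
  oracle <- sum(dhyper(4:5, 5, 15, 5))
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_equal(res$fold_enrichment, (4 / 5) / (5 / 20))

  # exhaustive small-universe check against phyper-free summation
  set.seed(34)
  for (i in 1:25) {
    nU <- sample(8:30, 1)
    uni <- sprintf("U%02d", seq_len(nU))
    term <- sample(uni, sample(2:nU, 1))
    query <- sample(uni, sample(2:nU, 1))
    k <- length(intersect(term, query))
    res <- ora(query, list(t = term), uni)
    oracle <- sum(dhyper(k:min(length(term), length(query)), length(term),
                         nU - length(term), length(query)))
    expect_equal(res$p, oracle, tolerance = 1e-12)
  }

  # term equal to the query has the smallest p; disjoint term has FE 0
  res2 <- ora(universe[1:5],
              list(exact = universe[1:5], disjoint = universe[6:10],
                   broad = universe[1:15]),
              universe)
  expect_equal(res2$term[1], "exact")
  expect_equal(res2$fold_enrichment[res2$term == "disjoint"], 0)
  expect_error(ora(c("NOTU"), list(t = term), universe), "universe")
})

test_that("bulk two-group ranking orders planted genes by direction", {
  set.seed(35)
  counts <- matrix(rnbinom(200 * 20, mu = 50, size = 5), 200,
                   dimnames = list(sprintf("G%03d", 1:200),
                                   sprintf("s%02d", 1:20)))
  group <- rep(c(TRUE, FALSE), each = 10)
  counts["G001", group] <- counts["G001", group] * 6L
  counts["G002", !group] <- counts["G002", !group] * 6L
  ranked <- rankGenesBulk(counts, group)
  expect_equal(ranked$gene[1], "G001")
  expect_equal(ranked$gene[200], "G002")
})
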