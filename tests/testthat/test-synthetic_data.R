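smallSpec <- function(...) {
  simulationSpec(nPatientsPerStage = c(Normal = 2, IB = 1, IIA = 1, IIB = 2,
                                       III = 1),
                 cellsPerPatient = 50, ...)
}

test_that("identical seeds give byte-identical cohorts", {
  a <- simulateCounts(smallSpec(), seed = 11)
  b <- simulateCounts(smallSpec(), seed = 11)
  expect_identical(as.matrix(SummarizedExperiment::assay(a, "counts")),
                   as.matrix(SummarizedExperiment::assay(b, "counts")))
  expect_identical(SummarizedExperiment::colData(a),
                   SummarizedExperiment::colData(b))
  c2 <- simulateCounts(smallSpec(), seed = 12)
  expect_false(identical(as.matrix(SummarizedExperiment::assay(a, "counts")),
                         as.matrix(SummarizedExperiment::assay(c2, "counts"))))
})

test_that("negative binomial moments match the design (mean within 3 s.e.)", {
  # background genes carry mean = baseMean exactly when library sizes are fixed
  spec <- simulationSpec(nPatientsPerStage = c(Normal = 7, IB = 7, IIA = 7,
                                               IIB = 7, III = 7),
                         cellsPerPatient = 300, baseMean = 5, nbDispersion = 2,
                         libSizeSdLog = 0)
  sce <- simulateCounts(spec, seed = 4)
  counts <- SummarizedExperiment::assay(sce, "counts")
  n <- ncol(counts)
  expect_gte(n, 10000)
  x <- as.numeric(counts["BG0001", ])
  se <- sqrt((5 + 2 * 25) / n)
  expect_lt(abs(mean(x) - 5), 3 * se)
  # variance should reflect overdispersion, not Poisson
  expect_gt(var(x), 5 * 3)
})

test_that("planted subcluster markers are 4-fold within their subcluster", {
  spec <- smallSpec(libSizeSdLog = 0)
  sce <- simulateCounts(spec, seed = 5)
  cd <- SummarizedExperiment::colData(sce)
  counts <- SummarizedExperiment::assay(sce, "counts")
  fib <- cd$true_type == "Fibroblast"
  # pool all subcluster-marker genes of F2 (the abundant Normal subcluster)
  genes <- spec$subMarkers[["F2"]]
  inC <- fib & !is.na(cd$true_subcluster) & cd$true_subcluster == "F2"
  outC <- fib & !is.na(cd$true_subcluster) & cd$true_subcluster != "F2"
  xin <- as.numeric(counts[genes, inC])
  xout <- as.numeric(counts[genes, outC])
  ratio <- mean(xin) / mean(xout)
  se <- ratio * sqrt(var(xin) / (length(xin) * mean(xin)^2) +
                     var(xout) / (length(xout) * mean(xout)^2))
  expect_lt(abs(ratio - 2^spec$markerLog2Effect), 3 * se)
})

test_that("signature genes reach the requested pairwise correlation (+-0.1)", {
  spec <- simulationSpec(nPatientsPerStage = c(Normal = 4, IB = 4, IIA = 4,
                                               IIB = 4, III = 5),
                         cellsPerPatient = 145, eliCorrelation = 0.3)
  sce <- normalizeCounts(simulateCounts(spec, seed = 6))
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  up <- members(S4Vectors::metadata(sce)$spec$eliUp)
  # non-fibroblasts: no trajectory confound, latent factor only
  cells <- SummarizedExperiment::colData(sce)$true_type != "Fibroblast"
  r <- cor(t(x[up[1:40], cells]))
  meanR <- mean(r[upper.tri(r)])
  expect_lt(abs(meanR - 0.3), 0.1)
  # background genes stay uncorrelated
  bg <- grep("^BG", rownames(x), value = TRUE)[1:40]
  rb <- cor(t(x[bg, cells]))
  expect_lt(abs(mean(rb[upper.tri(rb)])), 0.05)
})

test_that("degenerate simulation specs are rejected", {
  expect_error(simulationSpec(nPatientsPerStage = c(Normal = 0, IB = 1,
                                                    IIA = 1, IIB = 1, III = 1)),
               "degenerate")
  expect_error(simulationSpec(eliCorrelation = 1), "eliCorrelation")
  expect_error(simulationSpec(nbDispersion = 0), "nbDispersion")
})

test_that("planted PPI graphs have target density, clique limit, determinism", {
  eli <- GeneSet("set", sprintf("E%02d", 1:5))
  g <- simulatePPI(50, eli, targetDensity = 1, backgroundP = 0.02, seed = 1)
  sub <- igraph::induced_subgraph(g, members(eli))
  expect_equal(igraph::ecount(sub), 10L)        # clique on 5 nodes

  eli2 <- GeneSet("set", sprintf("E%02d", 1:20))
  n <- 500
  g2 <- simulatePPI(n, eli2, targetDensity = 0.5, backgroundP = 0.01, seed = 2)
  bg <- setdiff(igraph::V(g2)$name, members(eli2))
  gb <- igraph::induced_subgraph(g2, bg)
  nPairs <- length(bg) * (length(bg) - 1) / 2
  phat <- igraph::ecount(gb) / nPairs
  expect_lt(abs(phat - 0.01), 3 * sqrt(0.01 * 0.99 / nPairs))
  expect_gte(graphDensity(igraph::induced_subgraph(g2, members(eli2))), 0.5)

  g3 <- simulatePPI(n, eli2, targetDensity = 0.5, backgroundP = 0.01, seed = 2)
  expect_identical(igraph::as_edgelist(g2), igraph::as_edgelist(g3))
  expect_error(simulatePPI(50, eli, targetDensity = 0.005, backgroundP = 0.01),
               "targetDensity")
})

test_that("planted invasion fronts behave as designed", {
  # no forks, no noise: flat front, constant area
  flat <- simulateInvasion(nForks = 0, noiseSdPx = 0, nTimepoints = 3, seed = 1)
  q <- normalizedInvasion(flat$series)
  expect_equal(q$delta_area, c(0, 0, 0), tolerance = 1e-9)

  # one fork, depth 50, no noise: maximal advance 50 at the last frame
  one <- simulateInvasion(nForks = 1, forkDepthPx = 50, noiseSdPx = 0,
                          interfaceLenPx = 400, nTimepoints = 4, seed = 2)
  poly <- seriesPolygons(one$series)[[4]]
  prof <- roiToProfile(poly, interfaceY = 200, interfaceLength = 400)
  expect_lt(abs(max(prof) - 50), 0.1)   # sub-pixel discretization
  expect_lt(abs(which.max(prof) - 1 - one$forks$position), 1.0)

  # total area change equals the trapezoid integral of the planted profile
  multi <- simulateInvasion(nForks = 3, forkDepthPx = c(30, 50, 40),
                            noiseSdPx = 0, interfaceLenPx = 600,
                            nTimepoints = 3, seed = 3)
  x <- seq(0, 599)
  planted <- rowSums(vapply(seq_len(3), function(k) {
    multi$forks$depth[k] * exp(-(x - multi$forks$position[k])^2 / (2 * 35^2))
  }, numeric(600)))
  dArea <- normalizedInvasion(multi$series)$delta_area[3]
  trapz <- sum((planted[-1] + planted[-600]) / 2)
  expect_lt(abs(dArea - trapz) / 600, 1)       # within 1 px^2 per px

  expect_error(simulateInvasion(nForks = 10, interfaceLenPx = 500),
               "100 px")
})
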