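# Independent oracles used across the suite. These deliberately use naive
# implementations (explicit loops, closed forms, exhaustive enumeration) so
# they cannot share a defect with the package code paths they check.

# Brute-force weighted running-sum enrichment score.
bruteES <- function(scores, isHit, weightP = 1) {
  n <- length(scores)
  nh <- sum(isHit)
  tot <- sum(abs(scores[isHit])^weightP)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (isHit[i]) {
      run <- run + (if (tot > 0) abs(scores[i])^weightP / tot else 1 / nh)
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Shoelace area from first principles (loop form).
bruteShoelace <- function(poly) {
  n <- nrow(poly)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
  }
  abs(unname(s)) / 2
}

# Exhaustive minimum Steiner node count: smallest set of non-seed nodes whose
# addition makes all seeds mutually connected in the induced subgraph.
bruteSteinerNodes <- function(graph, seeds) {
  nodes <- igraph::V(graph)$name
  others <- setdiff(nodes, seeds)
  connectsSeeds <- function(extra) {
    sub <- igraph::induced_subgraph(graph, c(seeds, extra))
    comp <- igraph::components(sub)$membership
    length(unique(comp[seeds])) == 1L
  }
  for (k in 0:length(others)) {
    if (k == 0) {
      if (connectsSeeds(character())) return(0L)
      next
    }
    for (idx in asplit(combn(others, k), 2L)) {
      if (connectsSeeds(idx)) return(k)
    }
  }
  NA_integer_
}

# Adjusted Rand index (delegated to an established implementation).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small dense counts object with uniform metadata.
toyCounts <- function(counts, stage = "IIA") {
  n <- ncol(counts)
  meta <- data.frame(patient_id = rep("p1", n), tissue = rep("tumor", n),
                     stage = rep(stage, length.out = n),
                     row.names = colnames(counts))
  makeCounts(counts, meta)
}

# Gaussian blob embedding with planted labels.
blobEmbedding <- function(centers, nPer, sd = 1, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(nPer * ncol(centers), sd = sd), nPer) +
      rep(centers[i, ], each = nPer)
  }))
  rownames(pts) <- sprintf("c%03d", seq_len(nrow(pts)))
  list(embedding = pts, labels = rep(seq_len(nrow(centers)), each = nPer))
}
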