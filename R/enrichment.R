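#' Build a ranked gene list
#'
#' @param scores named numeric vector of finite signed scores (e.g. log2 fold
#'   changes); names are unique gene symbols.
#' @return data.frame `gene`, `score` in descending score order.
#' @export
rankedList <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be uniquely named by gene")
  if (!all(is.finite(scores))) stop("scores must be finite")
  ord <- order(-scores, names(scores))
  data.frame(gene = names(scores)[ord], score = unname(scores)[ord])
}

# Core weighted Kolmogorov-Smirnov running sum. Hits increment
# |score|^p / sum(|score in set|^p); misses decrement 1/(N - Nh); ES is the
# running-sum extremum (largest absolute deviation).
gseaRunningSum <- function(scores, isHit, weightP = 1) {
  n <- length(scores)
  nh <- sum(isHit)
  w <- abs(scores)^weightP
  inc <- numeric(n)
  tot <- sum(w[isHit])
  inc[isHit] <- if (tot > 0) w[isHit] / tot else 1 / nh
  inc[!isHit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  i <- which.max(abs(rs))
  list(es = rs[i], peak = i, runningSum = rs)
}

#' Preranked gene set enrichment analysis
#'
#' Computes the weighted running-sum enrichment score of a gene set in a
#' ranked list, a permutation p-value from random sets of the same size
#' (gene-label permutation, as in preranked GSEA), a normalized enrichment
#' score (ES divided by the mean |ES| of same-sign permutations), and the
#' leading edge: the set members at or before the running-sum extremum for a
#' positive ES, and at or after it for a negative ES.
#'
#' @param ranked data.frame from [rankedList].
#' @param set a [GeneSet-class]; must intersect the ranked genes.
#' @param weightP score weighting exponent (default 1).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `ES`, `NES`, `p_perm`, `n_perm`, `leading_edge`,
#'   `set_size`, `peak_rank`.
#' @export
gsea <- function(ranked, set, weightP = 1, nPerm = 1000, seed = 0L) {
  if (nPerm < 100) stop("nPerm must be >= 100")
  hits <- ranked$gene %in% members(set)
  nh <- sum(hits)
  if (nh == 0) stop("gene set does not intersect the ranked list")
  obs <- gseaRunningSum(ranked$score, hits, weightP)
  n <- nrow(ranked)
  set.seed(seed)
  permES <- vapply(seq_len(nPerm), function(i) {
    ph <- logical(n)
    ph[sample.int(n, nh)] <- TRUE
    gseaRunningSum(ranked$score, ph, weightP)$es
  }, numeric(1L))
  same <- permES[sign(permES) == sign(obs$es)]
  pPerm <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
  lead <- if (obs$es >= 0) {
    ranked$gene[seq_len(obs$peak)][hits[seq_len(obs$peak)]]
  } else {
    idx <- obs$peak:n
    ranked$gene[idx][hits[idx]]
  }
  list(ES = obs$es, NES = nes, p_perm = pPerm, n_perm = nPerm,
       leading_edge = lead, set_size = nh, peak_rank = obs$peak)
}

#' Within-gene-set co-expression test
#'
#' Measures whether genes of a set are more strongly co-expressed than the
#' background: correlation strength is the absolute Pearson correlation of a
#' gene pair's log-normalized expression across the chosen cells; all
#' within-set pairs are compared with all pairs among genes outside the set
#' (mixed pairs excluded) by a two-sided Welch t-test. When the background
#' has more than `maxPairs` pairs it is uniformly subsampled.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param set a [GeneSet-class].
#' @param cells optional cell subset (logical, integer, or barcodes), e.g. a
#'   fibroblast cluster.
#' @param backgroundGenes optional explicit background gene pool (defaults
#'   to all non-set genes in the matrix).
#' @param maxPairs background pair cap (default 1e6).
#' @param seed seed used only for background subsampling.
#' @return list with `mean_strength_in`, `mean_strength_out`,
#'   `mean_signed_in`, `mean_signed_out`, `t`, `p`, `n_pairs_in`,
#'   `n_pairs_out`.
#' @export
genesetCorrelationTest <- function(sce, set, cells = NULL,
                                   backgroundGenes = NULL, maxPairs = 1e6,
                                   seed = 0L) {
  x <- SummarizedExperiment::assay(sce, "logcounts")
  if (!is.null(cells)) x <- x[, cells, drop = FALSE]
  inGenes <- intersect(members(set), rownames(x))
  outGenes <- if (is.null(backgroundGenes)) {
    setdiff(rownames(x), members(set))
  } else setdiff(intersect(backgroundGenes, rownames(x)), members(set))
  xin <- as.matrix(Matrix::t(x[inGenes, , drop = FALSE]))
  xin <- xin[, matrixStats::colVars(xin) > 0, drop = FALSE]
  if (ncol(xin) < 2) stop("need >= 2 set genes with variance > 0")
  xout <- as.matrix(Matrix::t(x[outGenes, , drop = FALSE]))
  xout <- xout[, matrixStats::colVars(xout) > 0, drop = FALSE]
  if (ncol(xout) < 2) stop("need >= 2 background genes with variance > 0")

  rin <- cor(xin)
  strengthIn <- abs(rin[upper.tri(rin)])
  signedIn <- rin[upper.tri(rin)]
  nOut <- ncol(xout)
  totalOut <- nOut * (nOut - 1) / 2
  if (totalOut > maxPairs) {
    set.seed(seed)
    i <- sample.int(nOut, 2 * maxPairs, replace = TRUE)
    j <- sample.int(nOut, 2 * maxPairs, replace = TRUE)
    ok <- i < j
    ij <- unique(cbind(i[ok], j[ok]))[seq_len(maxPairs), , drop = FALSE]
    signedOut <- vapply(seq_len(nrow(ij)), function(k) {
      cor(xout[, ij[k, 1]], xout[, ij[k, 2]])
    }, numeric(1L))
  } else {
    rout <- cor(xout)
    signedOut <- rout[upper.tri(rout)]
  }
  strengthOut <- abs(signedOut)
  if (length(strengthIn) >= 2 && length(strengthOut) >= 2) {
    tt <- t.test(strengthIn, strengthOut, var.equal = FALSE)
    tStat <- unname(tt$statistic); pVal <- tt$p.value
  } else {
    warning("too few gene pairs for the t test; returning NA")
    tStat <- NA_real_; pVal <- NA_real_
  }
  list(mean_strength_in = mean(strengthIn),
       mean_strength_out = mean(strengthOut),
       mean_signed_in = mean(signedIn), mean_signed_out = mean(signedOut),
       t = tStat, p = pVal,
       n_pairs_in = length(strengthIn), n_pairs_out = length(strengthOut))
}

#' Over-representation analysis (hypergeometric)
#'
#' One-sided hypergeometric tail test of each annotation term's overlap with
#' a query gene list, with fold enrichment and Benjamini-Hochberg q-values.
#'
#' @param genes query gene list; must be a subset of `universe`.
#' @param annotation named list: term -> gene vector.
#' @param universe background gene list.
#' @return data.frame `term`, `n_term`, `n_overlap`, `fold_enrichment`,
#'   `p`, `q`, ordered by p.
#' @export
ora <- function(genes, annotation, universe) {
  genes <- unique(genes); universe <- unique(universe)
  if (!all(genes %in% universe)) stop("query genes must be within the universe")
  nU <- length(universe); nQ <- length(genes)
  rows <- lapply(names(annotation), function(term) {
    termGenes <- intersect(annotation[[term]], universe)
    k <- length(intersect(genes, termGenes))
    m <- length(termGenes)
    fe <- if (m > 0) (k / nQ) / (m / nU) else 0
    p <- phyper(k - 1, m, nU - m, nQ, lower.tail = FALSE)
    data.frame(term = term, n_term = m, n_overlap = k,
               fold_enrichment = fe, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  out[order(out$p), ]
}

#' Rank genes from a two-group bulk cohort
#'
#' Per-gene Welch t statistic on log2 counts-per-million between two groups
#' (e.g. lymph-node-positive N1 vs N0 bulk samples); the signed t statistics
#' are the preranked GSEA input.
#'
#' @param counts gene-by-sample count matrix.
#' @param group logical or two-level factor per sample; the first level (or
#'   `TRUE`) is the reference "positive" group whose higher expression ranks
#'   genes up.
#' @return data.frame from [rankedList] over the Welch t statistics.
#' @export
rankGenesBulk <- function(counts, group) {
  group <- if (is.logical(group)) group else group == levels(factor(group))[1L]
  cpm <- log2(sweep(counts, 2L, colSums(counts) / 1e6, "/") + 1)
  a <- cpm[, group, drop = FALSE]; b <- cpm[, !group, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  va <- matrixStats::rowVars(a); vb <- matrixStats::rowVars(b)
  tstat <- (rowMeans(a) - rowMeans(b)) / sqrt(va / na + vb / nb)
  tstat[!is.finite(tstat)] <- 0
  rankedList(setNames(tstat, rownames(counts)))
}
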