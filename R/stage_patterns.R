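#' Candidate stage-trajectory model profiles
#'
#' Enumerates short-series model profiles on a unit-change grid: between
#' consecutive stages the profile moves by an integer step in
#' `-c ... c` units, anchored at 0 at the first stage (the classic
#' short time-series mining construction). The candidates are then collapsed
#' to `nProfiles` maximally distinct profiles by greedy max-min selection
#' under correlation distance (1 - Pearson r), seeded with the steepest
#' monotone rise and breaking ties lexicographically. The flat profile is
#' always retained (index 0) as the null trajectory.
#'
#' @param nStages number of ordered stages (>= 3).
#' @param c maximum per-stage unit change (default 2).
#' @param nProfiles number of model profiles kept (default 50).
#' @return numeric matrix, profiles in rows (`P0` flat, then `P1` ...),
#'   stages in columns.
#' @export
stageModelProfiles <- function(nStages, c = 2, nProfiles = 50) {
  if (nStages < 3) stop("need >= 3 ordered stages")
  steps <- -c:c
  grid <- as.matrix(expand.grid(rep(list(steps), nStages - 1L)))
  profiles <- cbind(0, t(apply(grid, 1L, cumsum)))
  flat <- which(rowSums(abs(profiles)) == 0)
  cand <- profiles[-flat, , drop = FALSE]
  # deterministic order before greedy selection
  ord <- do.call(order, as.data.frame(cand))
  cand <- cand[ord, , drop = FALSE]
  keepN <- min(nProfiles - 1L, nrow(cand))
  # seed: steepest sustained rise
  sel <- which.max(cand %*% rep(1, nStages))
  dmat <- 1 - cor(t(cand))
  chosen <- sel
  while (length(chosen) < keepN) {
    dmin <- apply(dmat[, chosen, drop = FALSE], 1L, min)
    dmin[chosen] <- -Inf
    chosen <- c(chosen, which.max(dmin))
  }
  out <- rbind(0, cand[chosen, , drop = FALSE])
  dimnames(out) <- list(paste0("P", seq_len(nrow(out)) - 1L),
                        paste0("S", seq_len(nStages)))
  out
}

# Assign each gene's stage profile to the best-correlated model profile;
# zero-variance genes go to the flat profile (row 1).
assignProfiles <- function(stageMeans, profiles) {
  v <- matrixStats::rowVars(stageMeans)
  r <- suppressWarnings(cor(t(stageMeans), t(profiles[-1L, , drop = FALSE])))
  r[!is.finite(r)] <- -Inf
  best <- max.col(r, ties.method = "first") + 1L
  best[v == 0 | !is.finite(v)] <- 1L
  best
}

#' Mine significant stage-expression patterns
#'
#' Assigns each gene (by Pearson correlation of its first-stage-anchored
#' stage-mean profile) to the nearest model profile from
#' [stageModelProfiles], then tests each profile's gene count against a
#' permutation null in which the stage order is shuffled independently
#' within each gene. Profile p-values are Bonferroni-corrected across the
#' non-flat profiles.
#'
#' @param stageMeans gene-by-stage matrix of mean expression over ordered
#'   stages (columns in stage order).
#' @param c per-stage unit-change bound (default 2).
#' @param nProfiles number of model profiles (default 50).
#' @param nPerm stage-order permutations (default 200).
#' @param seed integer seed.
#' @return list with `profiles` (model matrix), `assignment` (profile id per
#'   gene), and `summary` data.frame: `profile`, `n_genes`, `expected`,
#'   `sd_expected`, `p`, `p_bonferroni`.
#' @export
stagePatternMining <- function(stageMeans, c = 2, nProfiles = 50,
                               nPerm = 200, seed = 0L) {
  stageMeans <- as.matrix(stageMeans)
  nS <- ncol(stageMeans)
  profiles <- stageModelProfiles(nS, c, nProfiles)
  anchored <- stageMeans - stageMeans[, 1L]
  obs <- assignProfiles(anchored, profiles)
  nP <- nrow(profiles)
  obsCount <- tabulate(obs, nbins = nP)

  set.seed(seed)
  permCounts <- matrix(0L, nPerm, nP)
  nG <- nrow(stageMeans)
  for (b in seq_len(nPerm)) {
    perm <- t(apply(stageMeans, 1L, sample))
    perm <- perm - perm[, 1L]
    permCounts[b, ] <- tabulate(assignProfiles(perm, profiles), nbins = nP)
  }
  expected <- colMeans(permCounts)
  sdExp <- matrixStats::colSds(permCounts)
  p <- vapply(seq_len(nP), function(j) {
    (1 + sum(permCounts[, j] >= obsCount[j])) / (nPerm + 1)
  }, numeric(1L))
  summary <- data.frame(profile = rownames(profiles), n_genes = obsCount,
                        expected = expected, sd_expected = sdExp, p = p,
                        p_bonferroni = pmin(1, p * (nP - 1L)))
  names(obs) <- rownames(stageMeans)
  list(profiles = profiles,
       assignment = setNames(rownames(profiles)[obs], rownames(stageMeans)),
       summary = summary)
}

#' Mean expression per stage
#'
#' Convenience: gene-by-stage matrix of mean log-normalized expression over
#' the cells of each stage, in stage order.
#'
#' @param sce normalized `SingleCellExperiment` with a `stage` colData column.
#' @param cells optional cell subset.
#' @param genes optional gene subset.
#' @return gene-by-stage numeric matrix.
#' @export
stageMeanMatrix <- function(sce, cells = NULL, genes = NULL) {
  x <- SummarizedExperiment::assay(sce, "logcounts")
  stage <- SummarizedExperiment::colData(sce)$stage
  if (!is.null(cells)) { x <- x[, cells, drop = FALSE]; stage <- stage[cells] }
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  stages <- intersect(stageLevels(), unique(stage))
  out <- vapply(stages, function(s) {
    Matrix::rowMeans(x[, stage == s, drop = FALSE])
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), stages))
  out
}
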