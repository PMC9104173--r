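#' Ligand-receptor interaction strength between two cell types
#'
#' For every (ligand, receptor) pair, the interaction strength between a
#' sender and a receiver cell type is the product
#' `S = E_L * E_R * f_L * f_R`: mean log-normalized ligand expression over
#' all sender cells, mean receptor expression over all receiver cells, and
#' the fractions of senders (receivers) with nonzero ligand (receptor)
#' expression. Pair genes absent from the matrix score 0 and are flagged.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param cellTypes character vector of cell-type labels per cell.
#' @param pairs data.frame from [readLRPairs].
#' @param senderType,receiverType cell-type labels; both must exist.
#' @return data.frame with one row per pair: `sender_type`, `receiver_type`,
#'   `ligand`, `receptor`, `E_L`, `E_R`, `f_L`, `f_R`, `S`, `category`,
#'   `missing_gene`.
#' @export
lrStrength <- function(sce, cellTypes, pairs, senderType, receiverType) {
  x <- SummarizedExperiment::assay(sce, "logcounts")
  for (ty in c(senderType, receiverType))
    if (!ty %in% cellTypes) stop("unknown cell type '", ty, "'")
  send <- cellTypes == senderType
  recv <- cellTypes == receiverType
  statsFor <- function(genes, cells) {
    known <- genes %in% rownames(x)
    e <- f <- numeric(length(genes))
    if (any(known)) {
      sub <- x[genes[known], cells, drop = FALSE]
      e[known] <- Matrix::rowMeans(sub)
      f[known] <- Matrix::rowMeans(sub > 0)
    }
    list(e = e, f = f, known = known)
  }
  lig <- statsFor(pairs$ligand, send)
  rec <- statsFor(pairs$receptor, recv)
  data.frame(sender_type = senderType, receiver_type = receiverType,
             ligand = pairs$ligand, receptor = pairs$receptor,
             E_L = lig$e, E_R = rec$e, f_L = lig$f, f_R = rec$f,
             S = lig$e * rec$e * lig$f * rec$f,
             category = pairs$category,
             missing_gene = !(lig$known & rec$known))
}

#' Select top reported interactions
#'
#' Reproduces the bubble-plot selection rule: on the fibroblast side of the
#' interaction (the ligand side when fibroblasts send, the receptor side when
#' they receive), keep genes passing the expression and expressing-fraction
#' cutoffs, rank the distinct fibroblast genes by their expression and keep
#' the top `nFibro`; then, per partner cell type, keep the `nPartner`
#' top-expressed cognate genes. Ties break by gene symbol.
#'
#' @param table an [lrStrength] table (possibly several receiver/sender types
#'   bound together) in which the fibroblast side is consistent.
#' @param fibroRole `"ligand"` if fibroblasts are the senders, `"receptor"`
#'   if they are the receivers.
#' @param nFibro top fibroblast-side genes kept (default 4).
#' @param nPartner top partner genes kept per partner type (default 3).
#' @param minExpr fibroblast-side expression cutoff (default 0.5).
#' @param minFracLigand expressing-fraction cutoff when fibroblasts send
#'   (default 0.05).
#' @param minFracReceptor expressing-fraction cutoff when fibroblasts
#'   receive (default 0.10).
#' @return filtered and ranked subset of `table`.
#' @export
selectTopInteractions <- function(table, fibroRole = c("ligand", "receptor"),
                                  nFibro = 4, nPartner = 3, minExpr = 0.5,
                                  minFracLigand = 0.05,
                                  minFracReceptor = 0.10) {
  if (!nrow(table)) stop("empty interaction table")
  fibroRole <- match.arg(fibroRole)
  if (fibroRole == "ligand") {
    fibGene <- table$ligand; fibE <- table$E_L; fibF <- table$f_L
    partGene <- table$receptor; partE <- table$E_R
    partType <- table$receiver_type
    keep <- fibE >= minExpr & fibF >= minFracLigand
  } else {
    fibGene <- table$receptor; fibE <- table$E_R; fibF <- table$f_R
    partGene <- table$ligand; partE <- table$E_L
    partType <- table$sender_type
    keep <- fibE >= minExpr & fibF >= minFracReceptor
  }
  tab <- table[keep, , drop = FALSE]
  fibGene <- fibGene[keep]; fibE <- fibE[keep]
  partGene <- partGene[keep]; partE <- partE[keep]; partType <- partType[keep]
  if (!nrow(tab)) return(tab)
  # rank distinct fibroblast genes by expression, tie-break lexicographic
  geneExpr <- tapply(fibE, fibGene, max)
  ord <- order(-geneExpr, names(geneExpr))
  topGenes <- names(geneExpr)[ord][seq_len(min(nFibro, length(geneExpr)))]
  tab2 <- tab[fibGene %in% topGenes, , drop = FALSE]
  partGene <- partGene[fibGene %in% topGenes]
  partE2 <- partE[fibGene %in% topGenes]
  partType2 <- partType[fibGene %in% topGenes]
  keepRows <- unlist(lapply(unique(partType2), function(ty) {
    i <- which(partType2 == ty)
    pe <- tapply(partE2[i], partGene[i], max)
    po <- order(-pe, names(pe))
    top <- names(pe)[po][seq_len(min(nPartner, length(pe)))]
    i[partGene[i] %in% top]
  }))
  out <- tab2[sort(keepRows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-annotation-category interaction summary
#'
#' Aggregates a selected interaction table by functional annotation category:
#' summed strength per (sender, receiver, category), keeping categories whose
#' share of distinct fibroblast-side genes meets the ratio cutoff (9% when
#' fibroblasts send, 7% when they receive, by convention). A tabular stand-in
#' for the chord-diagram aggregation.
#'
#' @param table an [lrStrength]-style table with a `category` column.
#' @param fibroRole as in [selectTopInteractions].
#' @param minRatio minimum fraction of fibroblast-side genes in a category.
#' @return data.frame `sender_type`, `receiver_type`, `category`,
#'   `total_strength`, `n_pairs`, `gene_ratio`.
#' @export
lrCategorySummary <- function(table, fibroRole = c("ligand", "receptor"),
                              minRatio = NULL) {
  fibroRole <- match.arg(fibroRole)
  if (is.null(minRatio)) minRatio <- if (fibroRole == "ligand") 0.09 else 0.07
  fibGene <- if (fibroRole == "ligand") table$ligand else table$receptor
  tot <- length(unique(fibGene))
  key <- interaction(table$sender_type, table$receiver_type, table$category,
                     drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    i <- which(key == k)
    data.frame(sender_type = table$sender_type[i[1]],
               receiver_type = table$receiver_type[i[1]],
               category = table$category[i[1]],
               total_strength = sum(table$S[i]), n_pairs = length(i),
               gene_ratio = length(unique(fibGene[i])) / tot)
  })
  out <- do.call(rbind, rows)
  out[out$gene_ratio >= minRatio & !is.na(out$category), , drop = FALSE]
}
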