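#' Ordered tumor stages used throughout the package
#'
#' AJCC-derived stage labels in progression order: normal pancreas, then
#' stages IB, IIA (pre-metastatic), IIB (first lymph-node metastasis), III.
#' @export
stageLevels <- function() c("Normal", "IB", "IIA", "IIB", "III")

# Uppercase gene symbols and fail on duplicates produced by case folding.
normalizeGeneSymbols <- function(genes) {
  up <- toupper(genes)
  if (anyDuplicated(up)) {
    stop("duplicate gene symbol after uppercasing: '",
         up[duplicated(up)][1L], "'")
  }
  up
}

checkCellMeta <- function(meta, barcodes) {
  required <- c("patient_id", "tissue", "stage")
  miss <- setdiff(required, colnames(meta))
  if (length(miss))
    stop("cell metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(rownames(meta)) || anyDuplicated(rownames(meta)))
    stop("cell metadata must have unique barcode rownames")
  absent <- setdiff(barcodes, rownames(meta))
  if (length(absent))
    stop("metadata missing barcode '", absent[1L], "'")
  bad <- setdiff(unique(meta$stage), stageLevels())
  if (length(bad))
    stop("unknown stage label '", bad[1L], "'")
  meta[barcodes, , drop = FALSE]
}

#' Assemble a single-cell counts container
#'
#' Builds the package's central object: a
#' [SingleCellExperiment::SingleCellExperiment] with a `counts` assay and
#' per-cell metadata (`patient_id`, `tissue`, `stage`, and optionally
#' `cell_type` / `cluster`). Gene symbols are uppercased on ingest; counts
#' must be non-negative integers; every cell must carry a stage label.
#'
#' @param counts gene-by-cell matrix (dense or `Matrix` sparse) of
#'   non-negative integer counts, with gene rownames and barcode colnames.
#' @param cellMeta data.frame keyed by barcode rownames with at least
#'   `patient_id`, `tissue` (`normal`/`tumor`) and `stage` columns.
#' @return A `SingleCellExperiment` with assay `counts`.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(c("a", "b", "c"), c("c1", "c2")))
#' meta <- data.frame(patient_id = c("p1", "p1"), tissue = "tumor",
#'                    stage = "IIA", row.names = c("c1", "c2"))
#' sce <- makeCounts(m, meta)
#' @export
makeCounts <- function(counts, cellMeta) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and barcode colnames")
  vals <- if (inherits(counts, "sparseMatrix")) counts@x else counts
  if (any(vals < 0)) stop("negative count entry")
  if (any(vals != floor(vals))) stop("non-integer count entry")
  rownames(counts) <- normalizeGeneSymbols(rownames(counts))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell barcode '",
         colnames(counts)[duplicated(colnames(counts))][1L], "'")
  cellMeta <- checkCellMeta(as.data.frame(cellMeta), colnames(counts))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(cellMeta))
}

#' Read a gene-by-cell count matrix
#'
#' Reads either a dense CSV (genes in rows, first column the gene symbol) or a
#' MatrixMarket triplet directory (`matrix.mtx` with 1-based coordinates,
#' `features.tsv`, `barcodes.tsv`). Cell metadata is a TSV/CSV keyed by
#' barcode with columns `patient_id`, `tissue`, `stage` and optionally
#' `cell_type`, `cluster`; it must cover every barcode in the matrix.
#'
#' @param path CSV file (`format = "csv"`) or directory holding
#'   `matrix.mtx` + `features.tsv` + `barcodes.tsv` (`format = "mtx"`).
#' @param format `"csv"` or `"mtx"`.
#' @param metaPath metadata table; defaults to `<path dir>/meta.tsv` for MTX.
#' @return A `SingleCellExperiment` (see [makeCounts]).
#' @export
readCounts <- function(path, format = c("csv", "mtx"), metaPath = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (is.null(metaPath)) stop("metaPath is required for CSV input")
    tab <- read.csv(path, check.names = FALSE)
    counts <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(counts) <- tab[[1L]]
  } else {
    counts <- as(Matrix::readMM(file.path(path, "matrix.mtx")), "CsparseMatrix")
    genes <- read.delim(file.path(path, "features.tsv"), header = FALSE)[[1L]]
    cells <- read.delim(file.path(path, "barcodes.tsv"), header = FALSE)[[1L]]
    if (nrow(counts) != length(genes) || ncol(counts) != length(cells))
      stop("MTX dimensions do not match features/barcodes files")
    dimnames(counts) <- list(genes, cells)
    if (is.null(metaPath)) metaPath <- file.path(path, "meta.tsv")
  }
  meta <- read.delim(metaPath, row.names = 1L, sep = "\t")
  if (ncol(meta) == 0L) meta <- read.csv(metaPath, row.names = 1L)
  makeCounts(counts, meta)
}

#' Write a count matrix with metadata
#'
#' Inverse of [readCounts]; `readCounts(writeCounts(x))` round-trips.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param path output CSV file (csv) or directory (mtx).
#' @param format `"csv"` or `"mtx"`.
#' @param metaPath metadata TSV path; defaults to `<path>.meta.tsv` (csv) or
#'   `<path>/meta.tsv` (mtx).
#' @return Invisibly, `path`.
#' @export
writeCounts <- function(sce, path, format = c("csv", "mtx"), metaPath = NULL) {
  format <- match.arg(format)
  counts <- SummarizedExperiment::assay(sce, "counts")
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  if (format == "csv") {
    if (is.null(metaPath)) metaPath <- paste0(path, ".meta.tsv")
    out <- data.frame(gene = rownames(counts), as.matrix(counts),
                      check.names = FALSE)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    if (is.null(metaPath)) metaPath <- file.path(path, "meta.tsv")
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(counts), file.path(path, "features.tsv"))
    writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  }
  write.table(data.frame(barcode = rownames(meta), meta, check.names = FALSE),
              metaPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Member order is preserved
#' exactly as written (signature sets are rank-ordered).
#'
#' @param path GMT file.
#' @return Named list of [GeneSet-class] objects.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    if (anyDuplicated(f[-(1:2)]))
      stop("GMT line ", i, " has a duplicate member '",
           f[-(1:2)][duplicated(f[-(1:2)])][1L], "'")
    GeneSet(f[1L], f[-(1:2)])
  })
  names(sets) <- vapply(sets, setName, character(1L))
  sets
}

#' Write gene sets to a GMT file
#' @param sets list of [GeneSet-class] objects.
#' @param path output file.
#' @param descriptions optional character vector of second-column values.
#' @return Invisibly, `path`.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(setName(sets[[i]]), descriptions[[i]], members(sets[[i]])),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' Tab-separated with header columns `ligand`, `receptor` and optionally
#' `category` (a functional annotation used for per-category interaction
#' summaries). Duplicate (ligand, receptor) rows are rejected.
#'
#' @param path TSV file.
#' @return data.frame with columns `ligand`, `receptor`, `category`.
#' @export
readLRPairs <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% colnames(tab)))
    stop("LR pair table needs 'ligand' and 'receptor' columns")
  tab$ligand <- toupper(tab$ligand)
  tab$receptor <- toupper(tab$receptor)
  if (anyDuplicated(tab[, c("ligand", "receptor")]))
    stop("duplicate (ligand, receptor) pair in table")
  if (is.null(tab$category)) tab$category <- NA_character_
  tab[, c("ligand", "receptor", "category")]
}

#' Read a protein-protein interaction edge list
#'
#' Tab-separated with header columns `gene_a`, `gene_b`. Self loops and
#' duplicate (undirected) edges are dropped.
#'
#' @param path TSV file.
#' @return An undirected simple [igraph::igraph] graph.
#' @export
readPPIEdges <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% colnames(tab)))
    stop("PPI edge list needs 'gene_a' and 'gene_b' columns")
  g <- igraph::graph_from_data_frame(
    data.frame(from = toupper(tab$gene_a), to = toupper(tab$gene_b)),
    directed = FALSE)
  igraph::simplify(g)
}

#' Write a PPI graph as an edge list
#' @param graph an igraph graph.
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
writePPIEdges <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write.table(data.frame(gene_a = el[, 1L], gene_b = el[, 2L]), path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a traced invasion-front ROI series
#'
#' CSV with header `time_h,vertex_index,x_px,y_px`: one closed polygon of
#' traced boundary vertices per imaging time point, pixel coordinates with y
#' increasing downward (image convention). Polygons are re-oriented
#' counter-clockwise on ingest so shoelace areas are positive; duplicated
#' time points and self-intersecting polygons are rejected.
#'
#' @param path CSV file.
#' @param interfaceLength initial cancer-stroma interface length in pixels;
#'   defaults to the x-extent of the first polygon.
#' @return An [InvasionSeries-class] object.
#' @export
readROISeries <- function(path, interfaceLength = NULL) {
  tab <- read.csv(path)
  need <- c("time_h", "vertex_index", "x_px", "y_px")
  if (!all(need %in% colnames(tab)))
    stop("ROI CSV needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab[, c("time_h", "vertex_index")]))
    stop("duplicated time point in ROI series")
  times <- unique(tab$time_h)
  if (is.unsorted(times, strictly = TRUE))
    stop("ROI time points must be strictly increasing")
  polys <- lapply(times, function(tt) {
    sub <- tab[tab$time_h == tt, ]
    sub <- sub[order(sub$vertex_index), ]
    p <- cbind(x = sub$x_px, y = sub$y_px)
    n <- nrow(p)
    if (n > 3L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
    if (polygonSelfIntersects(p))
      stop("self-intersecting ROI polygon at time ", tt)
    p
  })
  if (is.null(interfaceLength))
    interfaceLength <- diff(range(polys[[1L]][, 1L]))
  InvasionSeries(times, polys, interfaceLength)
}

#' Write an ROI series as CSV
#'
#' Inverse of [readROISeries].
#' @param series an [InvasionSeries-class].
#' @param path output CSV.
#' @return Invisibly, `path`.
#' @export
writeROISeries <- function(series, path) {
  rows <- do.call(rbind, lapply(seq_along(series@times), function(i) {
    p <- series@polygons[[i]]
    data.frame(time_h = series@times[i], vertex_index = seq_len(nrow(p)),
               x_px = p[, 1L], y_px = p[, 2L])
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
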