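#' Simulation design for a stage-annotated pancreatic single-cell cohort
#'
#' Builds the parameter object consumed by [simulateCounts]. The defaults
#' describe a cohort patterned on a multi-patient pancreatic ductal
#' adenocarcinoma study: 35 patients (11 normal pancreas, 24 tumors spread
#' over stages IB/IIA/IIB/III), twelve cell types, and eight fibroblast
#' subclusters whose stage proportions shift from homogeneous (Normal and
#' IIA are each dominated by a single subcluster) to diverse (IB, IIB, III).
#' Counts are negative binomial with log-normal library sizes. Two ordered
#' 100-gene invasibility signatures (`ELI_up`, `ELI_dn`) carry a shared
#' per-cell latent factor inducing a target within-set pairwise correlation,
#' and stage-trajectory multipliers: the pro-resistive `ELI_dn` cohort rises
#' to stage IIA then falls, most of `ELI_up` rises with tumorigenesis and
#' stays high, and a smaller `ELI_up` subset peaks at IIB. Subcluster "F4"
#' additionally over-expresses the `ELI_up` genes (a pro-invasive subcluster).
#'
#' @param nPatientsPerStage named integer vector over
#'   `Normal, IB, IIA, IIB, III`.
#' @param cellsPerPatient cells drawn per patient.
#' @param nGenes total genes (type markers, subcluster markers, the two
#'   signature sets, and background filler).
#' @param markerLog2Effect log2 fold elevation of a subcluster marker inside
#'   its subcluster (default 2, i.e. 4-fold).
#' @param typeMarkerFold fold elevation of a cell-type marker in its type.
#' @param eliCorrelation target within-signature pairwise Pearson correlation
#'   on the log-normalized scale.
#' @param nbDispersion negative binomial dispersion `phi`
#'   (variance `mu + phi mu^2`).
#' @param libSizeMean mean library size (expected counts per cell).
#' @param libSizeSdLog log-scale sd of library sizes.
#' @param eliBaseMean baseline mean count (at the mean library size) of
#'   signature genes; other genes default to `baseMean`.
#' @param baseMean baseline mean count of background genes.
#' @param nSubMarkers marker genes per fibroblast subcluster.
#' @param subMarkerBaseMean baseline mean count of subcluster marker genes
#'   (well-expressed identity genes).
#' @param typeMarkerBaseMean baseline mean count of cell-type marker genes.
#' @return A list of class `SimulationSpec`.
#' @export
simulationSpec <- function(nPatientsPerStage = c(Normal = 11, IB = 5, IIA = 6,
                                                 IIB = 9, III = 4),
                           cellsPerPatient = 145,
                           nGenes = 1000,
                           markerLog2Effect = 2,
                           typeMarkerFold = 8,
                           eliCorrelation = 0.05,
                           nbDispersion = 0.4,
                           libSizeMean = 2000,
                           libSizeSdLog = 0.3,
                           eliBaseMean = 2,
                           baseMean = 0.3,
                           nSubMarkers = 25,
                           subMarkerBaseMean = 1,
                           typeMarkerBaseMean = 0.75) {
  stages <- stageLevels()
  if (!all(stages %in% names(nPatientsPerStage)))
    stop("nPatientsPerStage must name every stage")
  if (any(nPatientsPerStage[stages] < 1))
    stop("degenerate spec: every stage needs at least one patient")
  if (eliCorrelation < 0 || eliCorrelation >= 1)
    stop("eliCorrelation must be in [0, 1)")
  if (nbDispersion <= 0) stop("nbDispersion must be > 0")

  cellTypes <- c("Fibroblast", "Stellate cell", "Ductal cell 1",
                 "Ductal cell 2", "Acinar", "Endothelial cell", "Macrophage",
                 "Endocrine cell", "B cell", "T cell", "Ductal cell 1 + Ductal cell 2",
                 "others")
  # tissue-level cell type composition; fibroblast-rich stroma in tumors
  typeProps <- list(
    normal = c(0.22, 0.06, 0.14, 0.08, 0.16, 0.08, 0.06, 0.06, 0.04, 0.06, 0.02, 0.02),
    tumor  = c(0.34, 0.08, 0.14, 0.08, 0.04, 0.06, 0.08, 0.03, 0.03, 0.08, 0.02, 0.02))
  names(typeProps$normal) <- names(typeProps$tumor) <- cellTypes

  # canonical markers for the three identities the typing rule is exercised
  # on; synthetic symbols elsewhere
  markerMap <- list(
    "Fibroblast" = c("LUM", "DCN", "COL1A1", "FIBM4", "FIBM5", "FIBM6"),
    "Stellate cell" = c("RGS5", "ACTA2S", paste0("STEM", 3:6)),
    "Ductal cell 1" = c("AMBP", "CFTR", paste0("DC1M", 3:6)),
    "Ductal cell 2" = c("KRT19", "MUC1", paste0("DC2M", 3:6)),
    "Acinar" = c("PRSS1", "CTRB1", paste0("ACIM", 3:6)),
    "Endothelial cell" = c("CDH5", "PLVAP", paste0("ENDM", 3:6)),
    "Macrophage" = c("AIF1", "CD64", paste0("MACM", 3:6)),
    "Endocrine cell" = c("INS", "CHGB", paste0("ENCM", 3:6)),
    "B cell" = c("MS4A1", "CD79A", paste0("BCM", 3:6)),
    "T cell" = c("CD3D", "CD3E", paste0("TCM", 3:6)))

  subclusters <- paste0("F", 0:7)
  subMarkers <- setNames(lapply(0:7, function(k) {
    sprintf("FSC%dM%02d", k, seq_len(nSubMarkers))
  }), subclusters)
  # stage composition of fibroblast subclusters: homogeneous at Normal (F2)
  # and IIA (F5), diverse at IB / IIB / III
  subProps <- rbind(
    Normal = c(0.02, 0.03, 0.75, 0.04, 0.02, 0.05, 0.06, 0.03),
    IB     = c(0.05, 0.20, 0.10, 0.20, 0.05, 0.20, 0.15, 0.05),
    IIA    = c(0.03, 0.05, 0.05, 0.05, 0.03, 0.70, 0.05, 0.04),
    IIB    = c(0.20, 0.15, 0.05, 0.15, 0.20, 0.05, 0.08, 0.12),
    III    = c(0.15, 0.15, 0.05, 0.15, 0.15, 0.05, 0.10, 0.20))
  colnames(subProps) <- subclusters

  eliUp <- c("KLF5", "NFKB1", "HSPB8", "MAP7D1", "GMFB", "PSMD11",
             sprintf("ELIU%03d", 7:100))
  eliDn <- c("RGS7", "MDFI", "DUSP8", "NPRL2", "ELMO3", "NTPCR", "WDR17",
             "WDR83", "COX10", "MSTO1", "CPT2", "MDH1B",
             sprintf("ELID%03d", 13:100))

  trajectories <- list(
    rise_to_IIA_fall  = list(genes = eliDn,
                             multipliers = c(Normal = 1, IB = 1.3, IIA = 1.55,
                                             IIB = 1.1, III = 0.9)),
    sustained_rise    = list(genes = eliUp[1:70],
                             multipliers = c(Normal = 1, IB = 1.3, IIA = 1.4,
                                             IIB = 1.45, III = 1.45)),
    rise_peak_IIB_fall = list(genes = eliUp[71:100],
                             multipliers = c(Normal = 1, IB = 1.2, IIA = 1.3,
                                             IIB = 1.55, III = 1.0)))

  named <- unique(c(unlist(markerMap), unlist(subMarkers), eliUp, eliDn))
  nBg <- max(nGenes - length(named), 0L)
  genes <- c(named, sprintf("BG%04d", seq_len(nBg)))

  spec <- list(nPatientsPerStage = nPatientsPerStage[stages],
               cellsPerPatient = cellsPerPatient,
               genes = genes, cellTypes = cellTypes, typeProps = typeProps,
               markerMap = markerMap, typeMarkerFold = typeMarkerFold,
               subclusters = subclusters, subMarkers = subMarkers,
               subProps = subProps, markerLog2Effect = markerLog2Effect,
               eliUp = GeneSet("ELI_up", eliUp),
               eliDn = GeneSet("ELI_dn", eliDn),
               eliCorrelation = eliCorrelation,
               eliUpClusterBoostLog2 = 1, eliUpBoostCluster = "F4",
               trajectories = trajectories,
               nbDispersion = nbDispersion, libSizeMean = libSizeMean,
               libSizeSdLog = libSizeSdLog, eliBaseMean = eliBaseMean,
               baseMean = baseMean, subMarkerBaseMean = subMarkerBaseMean,
               typeMarkerBaseMean = typeMarkerBaseMean)
  class(spec) <- "SimulationSpec"
  spec
}

# Numeric moments of y = log1p(scale * X / depth) for X ~ NB(mu, size),
# and the sensitivity dE[y]/dlog(mu); used to size the latent-factor loading.
logNormalMoments <- function(mu, size, scale = 1e4, depth = 2000) {
  kmax <- max(20, ceiling(mu + 12 * sqrt(mu + mu^2 / size)))
  k <- 0:kmax
  p <- stats::dnbinom(k, mu = mu, size = size)
  y <- log1p(scale * k / depth)
  m <- sum(p * y)
  v <- sum(p * y^2) - m^2
  eps <- 0.05
  p2 <- stats::dnbinom(k, mu = mu * exp(eps), size = size)
  g <- (sum(p2 * y) - m) / eps
  list(mean = m, var = v, sens = g)
}

# Loading a such that two genes sharing a N(0,1) factor (multiplying the NB
# mean by exp(a z - a^2/2)) have Pearson correlation ~ r on the
# log1p-normalized scale. The realized correlation is
# B(a) / (B(a) + W(a)) with B the between-cell variance of E[y | z] and W
# the mean conditional variance, computed by Gauss-Hermite quadrature over
# the latent factor and exact NB sums; solved for a by bisection.
latentLoading <- function(r, mu, size, scale = 1e4, depth = 2000,
                          sharedDepthShare = 0) {
  if (r <= 0) return(0)
  gh <- 21L
  # Gauss-Hermite nodes/weights for N(0,1) via eigen of the Jacobi matrix
  i <- seq_len(gh - 1L)
  J <- matrix(0, gh, gh)
  J[cbind(i, i + 1L)] <- J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  z <- e$values * sqrt(2)
  w <- e$vectors[1L, ]^2
  keep <- w > 1e-10          # extreme nodes carry no usable mass
  z <- z[keep]; w <- w[keep]; w <- w / sum(w)
  realized <- function(a) {
    g <- exp(a * z - a^2 / 2)
    mus <- mu * g
    # library normalization divides by the realized depth, which itself
    # carries the factor in proportion to the signature genes' library share
    depths <- depth * ((1 - sharedDepthShare) + sharedDepthShare * g)
    mo <- lapply(seq_along(mus), function(i) {
      logNormalMoments(mus[i], size = size, scale = scale, depth = depths[i])
    })
    m <- vapply(mo, `[[`, numeric(1L), "mean")
    v <- vapply(mo, `[[`, numeric(1L), "var")
    B <- sum(w * m^2) - sum(w * m)^2
    W <- sum(w * v)
    B / (B + W)
  }
  hi <- 0.5
  while (realized(hi) < r && hi < 2.5) hi <- hi * 1.5
  uniroot(function(a) realized(a) - r, c(1e-4, hi), tol = 1e-4)$root
}

#' Simulate a stage-annotated single-cell count cohort
#'
#' Draws negative binomial counts for the design in a [simulationSpec]:
#' per-cell means are the library-size-scaled type profile, multiplied by
#' 4-fold (by default) subcluster marker effects, stage-trajectory
#' multipliers in fibroblasts, and a shared log-scale latent factor over the
#' invasibility signature genes. Truth labels (cell type, fibroblast
#' subcluster) are emitted in `colData`, marker/trajectory assignments in
#' `rowData`, and the signature [GeneSet-class]s in `metadata`.
#'
#' @param spec a `SimulationSpec` from [simulationSpec].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A `SingleCellExperiment` with assay `counts`, colData columns
#'   `patient_id`, `tissue`, `stage`, `true_type`, `true_subcluster`, rowData
#'   columns `marker_of`, `subcluster_marker_of`, `trajectory`, and metadata
#'   entries `eli_up`, `eli_dn`, `spec`.
#' @export
simulateCounts <- function(spec = simulationSpec(), seed = 0L) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(seed)
  stages <- stageLevels()

  patients <- unlist(lapply(stages, function(s) {
    sprintf("%s_P%02d", s, seq_len(spec$nPatientsPerStage[[s]]))
  }))
  patientStage <- rep(stages, times = spec$nPatientsPerStage[stages])
  names(patientStage) <- patients

  cellPatient <- rep(patients, each = spec$cellsPerPatient)
  nCells <- length(cellPatient)
  cellStage <- patientStage[cellPatient]
  cellTissue <- ifelse(cellStage == "Normal", "normal", "tumor")
  barcodes <- sprintf("cell%05d", seq_len(nCells))

  cellType <- character(nCells)
  for (tis in c("normal", "tumor")) {
    idx <- which(cellTissue == tis)
    cellType[idx] <- sample(spec$cellTypes, length(idx), replace = TRUE,
                            prob = spec$typeProps[[tis]])
  }
  isFib <- cellType == "Fibroblast"
  subcl <- rep(NA_character_, nCells)
  for (s in stages) {
    idx <- which(isFib & cellStage == s)
    subcl[idx] <- sample(spec$subclusters, length(idx), replace = TRUE,
                         prob = spec$subProps[s, ])
  }

  genes <- spec$genes
  nGenes <- length(genes)
  base <- rep(spec$baseMean, nGenes)
  names(base) <- genes
  eliGenes <- c(members(spec$eliUp), members(spec$eliDn))
  base[eliGenes] <- spec$eliBaseMean
  base[unlist(spec$markerMap)] <- spec$typeMarkerBaseMean
  base[unlist(spec$subMarkers)] <- spec$subMarkerBaseMean

  # gene x cell mean matrix built blockwise
  mu <- matrix(base, nrow = nGenes, ncol = nCells, dimnames = list(genes, barcodes))
  for (ty in names(spec$markerMap)) {
    idx <- which(cellType == ty)
    if (length(idx))
      mu[spec$markerMap[[ty]], idx] <- mu[spec$markerMap[[ty]], idx] * spec$typeMarkerFold
  }
  # "Ductal cell 1 + Ductal cell 2" expresses both ductal marker sets;
  # "others" expresses none
  idx <- which(cellType == "Ductal cell 1 + Ductal cell 2")
  if (length(idx)) {
    both <- c(spec$markerMap[["Ductal cell 1"]], spec$markerMap[["Ductal cell 2"]])
    mu[both, idx] <- mu[both, idx] * spec$typeMarkerFold
  }
  for (k in spec$subclusters) {
    idx <- which(!is.na(subcl) & subcl == k)
    if (length(idx))
      mu[spec$subMarkers[[k]], idx] <-
        mu[spec$subMarkers[[k]], idx] * 2^spec$markerLog2Effect
  }
  # pro-invasive subcluster over-expresses the ELI_up signature
  idx <- which(!is.na(subcl) & subcl == spec$eliUpBoostCluster)
  if (length(idx))
    mu[members(spec$eliUp), idx] <-
      mu[members(spec$eliUp), idx] * 2^spec$eliUpClusterBoostLog2
  # stage trajectories act on fibroblasts
  for (tr in spec$trajectories) {
    for (s in stages) {
      idx <- which(isFib & cellStage == s)
      if (length(idx))
        mu[tr$genes, idx] <- mu[tr$genes, idx] * tr$multipliers[[s]]
    }
  }

  # shared latent factor over signature genes (log-mean scale, mean-preserving)
  size <- 1 / spec$nbDispersion
  z <- rnorm(nCells)
  eliShare <- sum(base[eliGenes]) / sum(base)
  aUp <- latentLoading(spec$eliCorrelation, spec$eliBaseMean, size,
                       depth = spec$libSizeMean, sharedDepthShare = eliShare)
  for (set in list(members(spec$eliUp), members(spec$eliDn))) {
    mu[set, ] <- mu[set, ] * rep(exp(aUp * z - aUp^2 / 2), each = length(set))
  }

  libFactor <- if (spec$libSizeSdLog > 0) {
    exp(rnorm(nCells, -spec$libSizeSdLog^2 / 2, spec$libSizeSdLog))
  } else rep(1, nCells)
  mu <- sweep(mu, 2L, libFactor, "*")

  counts <- matrix(rnbinom(length(mu), mu = mu, size = size),
                   nrow = nGenes, dimnames = dimnames(mu))

  meta <- data.frame(patient_id = cellPatient, tissue = cellTissue,
                     stage = cellStage, true_type = cellType,
                     true_subcluster = subcl, row.names = barcodes)
  sce <- makeCounts(counts, meta)

  markerOf <- rep(NA_character_, nGenes); names(markerOf) <- genes
  for (ty in names(spec$markerMap)) markerOf[spec$markerMap[[ty]]] <- ty
  subOf <- rep(NA_character_, nGenes); names(subOf) <- genes
  for (k in spec$subclusters) subOf[spec$subMarkers[[k]]] <- k
  trajOf <- rep(NA_character_, nGenes); names(trajOf) <- genes
  for (nm in names(spec$trajectories)) trajOf[spec$trajectories[[nm]]$genes] <- nm
  SummarizedExperiment::rowData(sce)$marker_of <- unname(markerOf[rownames(sce)])
  SummarizedExperiment::rowData(sce)$subcluster_marker_of <- unname(subOf[rownames(sce)])
  SummarizedExperiment::rowData(sce)$trajectory <- unname(trajOf[rownames(sce)])
  S4Vectors::metadata(sce) <- list(eli_up = spec$eliUp, eli_dn = spec$eliDn,
                                   spec = spec)
  sce
}

#' Simulate a PPI graph with a dense planted signature subnetwork
#'
#' Background interactions follow an Erdos-Renyi model; edges among the
#' signature (seed) genes are added until their induced subgraph reaches the
#' target density, emulating the dense hub-spoke architecture of invasibility
#' signature subnetworks in curated interaction databases.
#'
#' @param nBackground number of background genes.
#' @param eliSet a [GeneSet-class] of seed genes (added as nodes).
#' @param targetDensity density required of the induced seed subgraph; must
#'   exceed the background density.
#' @param backgroundP background edge probability.
#' @param seed integer seed.
#' @return An [igraph::igraph] with vertex attribute `role`
#'   (`seed`/`background`).
#' @export
simulatePPI <- function(nBackground = 500, eliSet, targetDensity = 0.25,
                        backgroundP = 0.01, seed = 0L) {
  if (targetDensity <= backgroundP || targetDensity > 1)
    stop("targetDensity must lie in (backgroundP, 1]")
  set.seed(seed)
  bg <- sprintf("BGP%04d", seq_len(nBackground))
  eli <- members(eliSet)
  nodes <- c(bg, eli)
  n <- length(nodes)
  g <- igraph::sample_gnp(n, backgroundP, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  # top up seed-seed edges to the requested density
  m <- length(eli)
  needed <- ceiling(targetDensity * m * (m - 1) / 2)
  allPairs <- t(combn(eli, 2L))
  sub <- igraph::induced_subgraph(g, eli)
  haveEdges <- igraph::as_edgelist(sub)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  existing <- if (nrow(haveEdges)) key(haveEdges[, 1], haveEdges[, 2]) else character()
  candidates <- which(!(key(allPairs[, 1], allPairs[, 2]) %in% existing))
  addN <- max(0L, needed - length(existing))
  if (addN > 0) {
    pick <- sample(candidates, addN)
    g <- igraph::add_edges(g, t(allPairs[pick, , drop = FALSE]))
  }
  g <- igraph::set_vertex_attr(g, "role",
                               value = ifelse(nodes %in% eli, "seed", "background"))
  igraph::simplify(g)
}

#' Simulate a nanopatterned invasion-front ROI series
#'
#' Emulates a live-imaged stromal invasion assay: an initially straight
#' cancer-stroma interface from which invasive forks (Gaussian protrusions
#' aligned with the nanopattern) advance linearly in time, with additive
#' Gaussian pixel noise on the traced boundary. Forks are placed evenly with
#' jitter, at least 100 px apart.
#'
#' @param nForks number of planted forks.
#' @param forkDepthPx final apex depth of each fork (recycled).
#' @param interfaceLenPx interface length in pixels.
#' @param noiseSdPx boundary tracing noise sd in pixels.
#' @param nTimepoints number of hourly frames (t = 0 .. nTimepoints-1 h).
#' @param forkWidthPx Gaussian sd of a fork's lateral extent.
#' @param bandHeightPx height of the cancer band above the interface (sets
#'   the ROI's constant baseline area).
#' @param seed integer seed.
#' @return list with `series` (an [InvasionSeries-class]) and `forks`
#'   (data.frame of planted `position`, `depth`).
#' @export
simulateInvasion <- function(nForks = 5, forkDepthPx = 60,
                             interfaceLenPx = 800, noiseSdPx = 2,
                             nTimepoints = 5, forkWidthPx = 35,
                             bandHeightPx = 200, seed = 0L) {
  set.seed(seed)
  L <- interfaceLenPx
  depths <- rep_len(forkDepthPx, max(nForks, 1L))[seq_len(nForks)]
  if (nForks > 0) {
    slot <- L / nForks
    if (slot < 100) stop("forks do not fit with >= 100 px spacing")
    centers <- (seq_len(nForks) - 0.5) * slot
    jitter <- runif(nForks, -1, 1) * pmax(0, (slot - 100) / 2) * 0.8
    centers <- centers + jitter
  } else centers <- numeric()

  x <- seq(0, L - 1)
  times <- seq(0, length.out = nTimepoints)
  tmax <- max(times[length(times)], 1)
  y0 <- bandHeightPx  # interface sits at y = bandHeightPx, invasion is +y
  polys <- lapply(times, function(tt) {
    adv <- rep(0, length(x))
    for (k in seq_len(nForks)) {
      adv <- adv + depths[k] * (tt / tmax) * exp(-(x - centers[k])^2 / (2 * forkWidthPx^2))
    }
    if (noiseSdPx > 0 && tt > 0) adv <- adv + rnorm(length(x), 0, noiseSdPx)
    cbind(x = c(0, L, rev(x)), y = c(0, 0, y0 + rev(adv)))
  })
  series <- InvasionSeries(times, polys, L)
  list(series = series,
       forks = data.frame(position = centers, depth = depths))
}
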