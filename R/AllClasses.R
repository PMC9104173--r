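#' @import methods
#' @importFrom stats cor dist median p.adjust phyper prcomp pt qnorm quantile
#'   rbinom rlnorm rnbinom rnorm runif sd setNames t.test var wilcox.test
#' @importFrom utils head read.csv read.delim write.csv write.table combn
NULL

#' An ordered gene set
#'
#' A named, ordered collection of gene symbols. Order is meaningful: signature
#' sets ranked by association strength are truncated to their top members
#' (e.g. the top-100 invasibility signatures), so members are stored in the
#' order they were written.
#'
#' @slot name single character, set identifier.
#' @slot members character vector of unique gene symbols, rank order preserved.
#'
#' @examples
#' gs <- GeneSet("ELI_up", c("KLF5", "NFKB1", "HSPB8"))
#' members(gs)
#' @export
setClass("GeneSet", representation(name = "character", members = "character"))

setValidity("GeneSet", function(object) {
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (length(object@members) == 0L)
    return("gene set must be non-empty")
  if (anyDuplicated(object@members))
    return(sprintf("duplicate member '%s'",
                   object@members[duplicated(object@members)][1L]))
  TRUE
})

#' Construct a GeneSet
#'
#' @param name set identifier.
#' @param members character vector of unique gene symbols (order preserved).
#' @return A [GeneSet-class] object.
#' @export
GeneSet <- function(name, members) {
  new("GeneSet", name = as.character(name), members = as.character(members))
}

#' @describeIn GeneSet-class gene symbols in rank order.
#' @param x,object a `GeneSet`.
#' @export
members <- function(x) x@members

#' @describeIn GeneSet-class set identifier.
#' @export
setName <- function(x) x@name

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet '", object@name, "' with ", length(object@members),
      " genes: ", sep = "")
  cat(paste(head(object@members, 5L), collapse = ", "))
  if (length(object@members) > 5L) cat(", ...")
  cat("\n")
})

#' @describeIn GeneSet-class number of member genes.
#' @export
setMethod("length", "GeneSet", function(x) length(x@members))

#' Time series of invasion-front regions of interest
#'
#' Holds one traced ROI polygon per imaging time point for a nanopatterned
#' stromal invasion assay, together with the length of the initial
#' cancer-stroma interface. Coordinates are in pixels with the image
#' convention (y grows downward, in the direction of invasion); polygons are
#' stored counter-clockwise so the shoelace area is positive.
#'
#' @slot times numeric, imaging times in hours, strictly increasing.
#' @slot polygons list of two-column (x, y) vertex matrices, one per time,
#'   not repeating the closing vertex.
#' @slot interfaceLength length of the initial cancer-stroma interface in
#'   pixels.
#'
#' @export
setClass("InvasionSeries",
         representation(times = "numeric", polygons = "list",
                        interfaceLength = "numeric"))

setValidity("InvasionSeries", function(object) {
  if (length(object@times) != length(object@polygons))
    return("one polygon required per time point")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("time points must be strictly increasing")
  if (length(object@interfaceLength) != 1L || object@interfaceLength <= 0)
    return("interfaceLength must be a single positive number")
  for (i in seq_along(object@polygons)) {
    p <- object@polygons[[i]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      return(sprintf("polygon %d is not a vertex matrix with >= 3 rows", i))
    if (!all(is.finite(p)))
      return(sprintf("polygon %d has non-finite vertices", i))
  }
  TRUE
})

#' Construct an InvasionSeries
#'
#' @param times numeric vector of imaging times (hours), strictly increasing.
#' @param polygons list of two-column vertex matrices (pixels), one per time.
#'   Closed polygons (first vertex repeated) are accepted and unclosed;
#'   vertices are re-oriented counter-clockwise.
#' @param interfaceLength initial cancer-stroma interface length in pixels.
#' @return An [InvasionSeries-class] object.
#' @export
InvasionSeries <- function(times, polygons, interfaceLength) {
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("x", "y")
    n <- nrow(p)
    if (n > 3L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
    if (shoelaceArea(p, signed = TRUE) < 0) p <- p[rev(seq_len(nrow(p))), ]
    p
  })
  new("InvasionSeries", times = as.numeric(times), polygons = polygons,
      interfaceLength = as.numeric(interfaceLength))
}

#' @describeIn InvasionSeries-class imaging times in hours.
#' @param x,object an `InvasionSeries`.
#' @export
seriesTimes <- function(x) x@times

#' @describeIn InvasionSeries-class list of ROI vertex matrices.
#' @export
seriesPolygons <- function(x) x@polygons

#' @describeIn InvasionSeries-class initial interface length (pixels).
#' @export
interfaceLength <- function(x) x@interfaceLength

setMethod("show", "InvasionSeries", function(object) {
  cat("InvasionSeries:", length(object@times), "time points over",
      sprintf("%g-%g h;", min(object@times), max(object@times)),
      "interface", object@interfaceLength, "px\n")
})

#' @describeIn InvasionSeries-class number of time points.
#' @export
setMethod("length", "InvasionSeries", function(x) length(x@times))
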