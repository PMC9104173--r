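#' Polygon area by the shoelace formula
#'
#' @param poly two-column (x, y) vertex matrix, closing vertex not repeated.
#' @param signed return the signed area (positive for counter-clockwise in a
#'   y-down image frame after the package's ingest orientation)? Default
#'   returns the absolute area.
#' @return Area in squared coordinate units.
#' @export
shoelaceArea <- function(poly, signed = FALSE) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  a <- sum(x * y[j] - x[j] * y) / 2
  if (signed) a else abs(a)
}

# Proper / improper intersection of segments p1-p2 and p3-p4, excluding shared
# endpoints (adjacent polygon edges always share one).
segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  on <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && on(p3, p4, p1)) || (d2 == 0 && on(p3, p4, p2)) ||
    (d3 == 0 && on(p1, p2, p3)) || (d4 == 0 && on(p1, p2, p4))
}

# TRUE if the closed polygon has self-intersecting (non-adjacent) edges.
polygonSelfIntersects <- function(poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  for (i in 1:(n - 1L)) {
    for (k in (i + 1L):n) {
      # skip adjacent edges (share a vertex), incl. the wrap-around pair
      if (k == i + 1L || (i == 1L && k == n)) next
      if (segmentsIntersect(poly[i, ], poly[nxt[i], ], poly[k, ], poly[nxt[k], ]))
        return(TRUE)
    }
  }
  FALSE
}
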