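#' Normalized invasion extent per time point
#'
#' For each frame, `deltaArea` is the ROI area minus the initial-frame area
#' (shoelace on the traced polygon), and the normalized extent
#' `deltaAreaNorm` divides by the initial cancer-stroma interface length.
#'
#' @param series an [InvasionSeries-class].
#' @return data.frame `time_h`, `area`, `delta_area`, `delta_area_norm`.
#' @export
normalizedInvasion <- function(series) {
  areas <- vapply(seriesPolygons(series), shoelaceArea, numeric(1L))
  d <- areas - areas[1L]
  data.frame(time_h = seriesTimes(series), area = areas, delta_area = d,
             delta_area_norm = d / interfaceLength(series))
}

#' Convert an ROI polygon to a one-dimensional front profile
#'
#' The invasion front advance at each integer interface position `x` is the
#' maximal perpendicular extent of the ROI beyond the initial interface line
#' (image convention: the interface runs along x, invasion advances toward
#' larger y). Positions not covered by the polygon, or where the polygon
#' stays behind the interface, give 0.
#'
#' @param poly two-column (x, y) vertex matrix in pixels.
#' @param interfaceY y-coordinate (pixels) of the initial interface line.
#' @param interfaceLength profile length in pixels; positions are
#'   `0 ... round(interfaceLength) - 1`.
#' @return numeric advance profile (pixels), length `round(interfaceLength)`.
#' @export
roiToProfile <- function(poly, interfaceY, interfaceLength) {
  L <- round(interfaceLength)
  xs <- seq(0, L - 1)
  n <- nrow(poly)
  j <- c(2:n, 1L)
  adv <- numeric(L)
  # for each polygon edge, register its y-extent on the integer x it spans
  for (e in seq_len(n)) {
    x1 <- poly[e, 1L]; y1 <- poly[e, 2L]
    x2 <- poly[j[e], 1L]; y2 <- poly[j[e], 2L]
    lo <- ceiling(min(x1, x2)); hi <- floor(max(x1, x2))
    if (hi < 0 || lo > L - 1) next
    lo <- max(lo, 0); hi <- min(hi, L - 1)
    if (lo > hi) next
    xr <- lo:hi
    yr <- if (x1 == x2) rep(max(y1, y2), length(xr)) else {
      y1 + (xr - x1) * (y2 - y1) / (x2 - x1)
    }
    idx <- xr + 1L
    adv[idx] <- pmax(adv[idx], yr - interfaceY)
  }
  pmax(adv, 0)
}

#' Smooth a front profile by a centered moving average
#'
#' 20-pixel centered moving mean by default; edge windows are truncated to
#' the available positions (no padding), so a constant profile is unchanged
#' everywhere and length is preserved.
#'
#' @param profile numeric front profile.
#' @param window window width in pixels (default 20).
#' @return smoothed profile of the same length.
#' @export
smoothProfile <- function(profile, window = 20) {
  if (window < 1) stop("window must be >= 1")
  n <- length(profile)
  lo <- floor((window - 1) / 2)
  hi <- floor(window / 2)
  cs <- cumsum(c(0, profile))
  i <- seq_len(n)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, n)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

#' Detect invasive forks on a smoothed front profile
#'
#' A position qualifies as a peak when the smoothed profile there strictly
#' exceeds the mean of the smoothed profile over the `side` pixels to its
#' left and, separately, the `side` pixels to its right (truncated at the
#' profile edges). Maximal runs of consecutive qualifying positions collapse
#' to a single fork at the run midpoint (floored to an integer pixel); the
#' fork depth is the smoothed profile value at that midpoint.
#'
#' @param smoothed smoothed profile from [smoothProfile]; its length must
#'   exceed `2 * side`.
#' @param side side-window width in pixels (default 40).
#' @return data.frame `position` (0-based pixel), `depth` (pixels).
#' @export
detectPeaks <- function(smoothed, side = 40) {
  n <- length(smoothed)
  if (n <= 2 * side) stop("profile length must exceed 2 * side")
  cs <- cumsum(c(0, smoothed))
  i <- seq_len(n)
  la <- pmax(i - side, 1L); lb <- i - 1L
  ra <- i + 1L; rb <- pmin(i + side, n)
  leftMean <- ifelse(lb >= la, (cs[lb + 1L] - cs[la]) / (lb - la + 1L), -Inf)
  rightMean <- ifelse(rb >= ra, (cs[rb + 1L] - cs[ra]) / (rb - ra + 1L), -Inf)
  qual <- smoothed > leftMean & smoothed > rightMean
  if (!any(qual)) return(data.frame(position = numeric(), depth = numeric()))
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  mids <- floor((starts[runs] + ends[runs]) / 2)
  data.frame(position = mids - 1L, depth = smoothed[mids])
}

#' Compare fork depth distributions between two conditions
#'
#' Two-sided Mann-Whitney rank-sum test of invasion depths (e.g. control vs
#' gene-silenced stroma): exact when both groups have at most 20
#' observations and no ties are present, otherwise the normal approximation
#' with tie and continuity correction.
#'
#' @param depthsA,depthsB numeric depth samples; both non-empty.
#' @return list `p`, `statistic` (Mann-Whitney U of group A), `median_a`,
#'   `median_b`, `shift` (median_a - median_b), `method`.
#' @export
compareDepths <- function(depthsA, depthsB) {
  if (!length(depthsA) || !length(depthsB)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(depthsA, depthsB)) > 0
  useExact <- length(depthsA) <= 20 && length(depthsB) <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(depthsA, depthsB, exact = useExact,
                                     correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       median_a = median(depthsA), median_b = median(depthsB),
       shift = median(depthsA) - median(depthsB),
       method = if (useExact) "exact" else "normal-approximation")
}

#' Match called forks to planted forks and score recovery
#'
#' Greedy one-to-one matching of called peak positions to true fork
#' positions within a tolerance; returns precision, recall and F1.
#'
#' @param called data.frame from [detectPeaks].
#' @param truth data.frame with a `position` column of planted forks.
#' @param tolerance maximum position error in pixels (default 30).
#' @return list `precision`, `recall`, `f1`, `n_called`, `n_true`,
#'   `n_matched`.
#' @export
peakRecoveryF1 <- function(called, truth, tolerance = 30) {
  nc <- nrow(called); nt <- nrow(truth)
  matched <- 0L
  free <- rep(TRUE, nt)
  for (pos in called$position) {
    d <- abs(truth$position - pos)
    d[!free] <- Inf
    if (length(d) && min(d) <= tolerance) {
      free[which.min(d)] <- FALSE
      matched <- matched + 1L
    }
  }
  precision <- if (nc) matched / nc else NA_real_
  recall <- if (nt) matched / nt else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_called = nc, n_true = nt, n_matched = matched)
}
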