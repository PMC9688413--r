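## One-dimensional pseudotime by PCA + principal curve, NE-score
## orientation, cross-species concordance, and pseudotime summaries.

# Project points onto the polyline through `curve` rows (ordered), return
# arc-length position of each point's projection.
.projectPolyline <- function(P, curve) {
  segStart <- curve[-nrow(curve), , drop = FALSE]
  segVec <- curve[-1, , drop = FALSE] - segStart
  segLen2 <- pmax(rowSums(segVec^2), 1e-12)
  segLen <- sqrt(segLen2)
  cumLen <- c(0, cumsum(segLen))
  arc <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    D <- sweep(segStart, 2, P[i, ], "-")
    tt <- pmin(pmax(-rowSums(D * segVec) / segLen2, 0), 1)
    proj <- segStart + segVec * tt
    d2 <- rowSums(sweep(proj, 2, P[i, ], "-")^2)
    s <- which.min(d2)
    arc[i] <- cumLen[s] + tt[s] * segLen[s]
  }
  arc
}

#' Infer one-dimensional pseudotime with NE-score orientation
#'
#' PCA on standardized top-variable genes, then a principal-curve fit by
#' projection-index iteration: points are ordered, each PCA coordinate is
#' lowess-smoothed along the ordering to form a polyline, points are
#' projected back onto the polyline, and the ordering is updated until it
#' stabilizes. Pseudotime is the normalized arc-length rank on a uniform
#' grid in \[0,1\], flipped if it correlates positively with the NE score
#' (so pseudotime always runs NE -> non-NE).
#'
#' @param x an [ExpressionMatrix-class] or genes x units matrix (log
#'   scale); >= 10 units.
#' @param neScores numeric NE score per unit (orientation anchor).
#' @param nPcs number of principal components for the curve (default 3).
#' @param nTopGenes number of most-variable genes used (default 500,
#'   capped at the gene count).
#' @param smoothSpan lowess span for the curve coordinates.
#' @param maxIter projection-index iterations.
#' @param labels optional subtype labels carried into the result.
#' @return A [TrajectoryResult-class].
#' @export
inferPseudotime <- function(x, neScores, nPcs = 3L, nTopGenes = 500L,
                            smoothSpan = 0.3, maxIter = 10L,
                            labels = character(0)) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  n <- ncol(v)
  if (n < 10) stop("need at least 10 units")
  if (n < nPcs + 1) stop("fewer units than nPcs + 1")
  mads <- apply(v, 1, stats::mad)
  keep <- order(-mads, rownames(v), method = "radix")
  keep <- keep[seq_len(min(nTopGenes, nrow(v)))]
  vv <- v[keep, , drop = FALSE]
  sds <- apply(vv, 1, stats::sd)
  vv <- vv[sds > 0, , drop = FALSE]
  Z <- t(scale(t(vv)))
  pc <- stats::prcomp(t(Z), center = TRUE, scale. = FALSE)
  P <- pc$x[, seq_len(min(nPcs, ncol(pc$x))), drop = FALSE]

  ord <- order(P[, 1])
  iter <- 0L; converged <- FALSE; arcTotal <- NA_real_
  for (iter in seq_len(maxIter)) {
    lambda <- seq_len(n)[order(ord)]   # current rank of each point
    # lowess sorts by lambda, so each smoothed coordinate comes back in
    # curve order (position 1..n along the current ordering)
    curveOrd <- sapply(seq_len(ncol(P)), function(d)
      stats::lowess(lambda, P[, d], f = smoothSpan)$y)
    arc <- .projectPolyline(P, curveOrd)
    arcTotal <- max(arc) - min(arc)
    newOrd <- order(arc, P[, 1])
    if (identical(newOrd, ord)) { converged <- TRUE; break }
    ord <- newOrd
  }
  pt <- stats::setNames(numeric(n), colnames(v))
  pt[ord] <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  if (stats::sd(neScores) > 0 && stats::cor(pt, neScores) > 0)
    pt <- 1 - pt
  new("TrajectoryResult", pseudotime = pt,
      neScores = stats::setNames(as.numeric(neScores), colnames(v)),
      labels = as.character(labels),
      diagnostics = list(nPcs = ncol(P), iterations = iter,
                         converged = converged, arcLength = arcTotal))
}

#' Cross-species expression concordance matrix
#'
#' Restricts both matrices to ortholog-shared genes, standardizes each
#' unit's shared-gene vector, computes all pairwise Pearson correlations,
#' and sorts rows and columns by pseudotime. >= 50 shared genes required.
#'
#' @param humanEpi genes x samples human epithelial matrix (log scale).
#' @param mouseExpr genes x cells mouse matrix (depth-normalized log
#'   scale; see [normalizeUMI()]).
#' @param orthologMap data.frame with columns `human`, `mouse`.
#' @param humanPt,mousePt pseudotime per human sample / mouse cell.
#' @return human x mouse correlation matrix, axes pseudotime-sorted, with
#'   attributes `humanPt`, `mousePt` (sorted).
#' @export
crossSpeciesConcordance <- function(humanEpi, mouseExpr, orthologMap,
                                    humanPt, mousePt) {
  humanEpi <- as.matrix(humanEpi); mouseExpr <- as.matrix(mouseExpr)
  map <- orthologMap[orthologMap$human %in% rownames(humanEpi) &
                     orthologMap$mouse %in% rownames(mouseExpr), ]
  if (nrow(map) == 0) stop("empty ortholog intersection")
  if (nrow(map) < 50) stop("need at least 50 shared genes after mapping")
  H <- humanEpi[map$human, , drop = FALSE]
  M <- mouseExpr[map$mouse, , drop = FALSE]
  Hs <- scale(H); Ms <- scale(M)        # per-unit standardization
  C <- stats::cor(Hs, Ms)
  oh <- order(humanPt); om <- order(mousePt)
  C <- C[oh, om, drop = FALSE]
  attr(C, "humanPt") <- humanPt[oh]
  attr(C, "mousePt") <- mousePt[om]
  C
}

#' Depth-normalize a UMI matrix (counts per 10k, log1p)
#' @param umi genes x cells matrix (sparse or dense).
#' @return dense genes x cells matrix of log1p(CP10K).
#' @export
normalizeUMI <- function(umi) {
  m <- as.matrix(umi)
  depth <- colSums(m)
  depth[depth == 0] <- 1
  log1p(sweep(m, 2, depth, "/") * 1e4)
}

#' Subtype occurrence along pseudotime
#'
#' Per-bin subtype frequencies (each bin's frequencies sum to 1) and the
#' per-subtype median pseudotime.
#'
#' @param labels subtype label per unit.
#' @param pt pseudotime per unit.
#' @param nBins number of equal-width bins (>= 2).
#' @return list: `freq` (subtype x bin), `medianPt` (named numeric).
#' @export
subtypeOccurrence <- function(labels, pt, nBins = 5L) {
  if (nBins < 2) stop("need at least 2 bins")
  labels <- factor(labels)
  bins <- cut(pt, breaks = seq(0, 1, length.out = nBins + 1),
              include.lowest = TRUE)
  tab <- table(labels, bins)
  freq <- sweep(unclass(tab), 2, pmax(colSums(tab), 1), "/")
  med <- tapply(pt, labels, stats::median)
  list(freq = freq, medianPt = med)
}

#' Smoothed marker-set trends along pseudotime
#'
#' Running-median smoothing of the marker-set mean expression along
#' pseudotime; monotonicity is summarized by the Spearman correlation of
#' the set mean with pseudotime.
#'
#' @param x expression matrix (genes x units) or
#'   [ExpressionMatrix-class].
#' @param pt pseudotime per unit.
#' @param markerSets named list of marker gene sets.
#' @param windowFrac running-median window as a fraction of the units
#'   (default 0.15; 1 gives a constant curve at the global median).
#' @return data.frame per set: `set`, `rho` plus attribute `curves`
#'   (named list of smoothed trend vectors along the pseudotime order).
#' @export
markerTrends <- function(x, pt, markerSets, windowFrac = 0.15) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  ord <- order(pt)
  n <- length(ord)
  k <- max(3L, round(windowFrac * n))
  if (k %% 2 == 0 && k < n) k <- k + 1L
  curves <- list(); rho <- numeric(0)
  for (nm in names(markerSets)) {
    g <- intersect(markerSets[[nm]], rownames(v))
    if (length(g) == 0) stop("no markers present for set ", nm)
    sm <- colMeans(v[g, , drop = FALSE])
    curves[[nm]] <- if (k >= n) rep(mean(sm), n)  # full-range window
                    else stats::runmed(sm[ord], k)
    rho[nm] <- suppressWarnings(
      stats::cor(pt, sm, method = "spearman"))
    if (is.na(rho[nm])) rho[nm] <- 0
  }
  out <- data.frame(set = names(markerSets), rho = rho, row.names = NULL)
  attr(out, "curves") <- curves
  out
}
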