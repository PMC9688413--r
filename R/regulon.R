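#' Mutual information between two expression vectors
#'
#' Plugin (maximum-likelihood) estimator on equal-frequency bins, in nats.
#' The default bin count is `floor(sqrt(n/5))` clamped to \[2, 10\].
#' Constant vectors return 0 by convention.
#'
#' @param x,y numeric vectors of equal length >= 8.
#' @param nBins number of equal-frequency bins; NULL for the default rule.
#' @return non-negative mutual information in nats.
#' @export
mutualInformation <- function(x, y, nBins = NULL) {
  n <- length(x)
  if (length(y) != n || n < 8) stop("x and y must have equal length >= 8")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  if (is.null(nBins)) nBins <- max(2L, min(10L, floor(sqrt(n / 5))))
  bin <- function(v) {
    r <- rank(v, ties.method = "first")
    ceiling(r * nBins / n)
  }
  tab <- table(bin(x), bin(y)) / n
  px <- rowSums(tab); py <- colSums(tab)
  e <- outer(px, py)
  pos <- tab > 0
  sum(tab[pos] * log(tab[pos] / e[pos]))
}

#' Build a regulator-target co-expression network by mutual information
#'
#' Computes MI between each regulator and every other gene, keeps edges
#' exceeding the (1 - fdrQ) quantile of a permutation null (regulator values
#' shuffled across samples against randomly drawn genes, destroying the
#' pairing while preserving marginals).
#'
#' @param x an [ExpressionMatrix-class] or genes x samples matrix.
#' @param regulators character vector of regulator gene ids present in `x`.
#' @param nPerm number of null permutations (null MI values).
#' @param fdrQ null quantile level for edge retention (default 0.05).
#' @param nBins passed to [mutualInformation()].
#' @param seed integer seed.
#' @return data.frame of edges: `regulator`, `target`, `mi`; attribute
#'   `threshold` carries the null cutoff.
#' @export
buildNetwork <- function(x, regulators, nPerm = 200L, fdrQ = 0.05,
                         nBins = NULL, seed = 1L) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  if (length(regulators) == 0) stop("regulator list is empty")
  miss <- setdiff(regulators, rownames(v))
  if (length(miss))
    stop("regulator(s) absent from expression: ",
         paste(miss, collapse = ", "))
  set.seed(seed)
  null <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    r <- regulators[((b - 1) %% length(regulators)) + 1]
    g <- sample(setdiff(rownames(v), r), 1)
    null[b] <- mutualInformation(sample(v[r, ]), v[g, ], nBins)
  }
  thr <- stats::quantile(null, 1 - fdrQ, names = FALSE)
  edges <- do.call(rbind, lapply(regulators, function(r) {
    targets <- setdiff(rownames(v), r)
    mi <- vapply(targets, function(g)
      mutualInformation(v[r, ], v[g, ], nBins), 0)
    keep <- mi > thr
    if (!any(keep)) return(NULL)
    data.frame(regulator = r, target = targets[keep], mi = mi[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(regulator = character(0), target = character(0),
                        mi = numeric(0))
  rownames(edges) <- NULL
  attr(edges, "threshold") <- thr
  edges
}

#' Data-processing-inequality pruning of an MI edge list
#'
#' For every triangle of edges, the weakest edge is marked for removal if
#' its MI is below `(1 - tolerance)` times the smaller of the other two
#' (the classic indirect-interaction filter). All marked edges are removed
#' simultaneously, so the operation is idempotent and never increases the
#' edge count. `tolerance = 1` disables pruning.
#'
#' @param edges data.frame with columns `regulator`, `target`, `mi`
#'   (treated as an undirected weighted graph).
#' @param tolerance DPI tolerance in \[0, 1\] (default 0).
#' @return the pruned edge data.frame.
#' @export
dpiPrune <- function(edges, tolerance = 0) {
  if (nrow(edges) < 3) return(edges)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  w <- stats::setNames(edges$mi, key(edges$regulator, edges$target))
  nodes <- unique(c(edges$regulator, edges$target))
  adj <- split(c(edges$target, edges$regulator),
               c(edges$regulator, edges$target))
  drop <- character(0)
  for (a in names(adj)) {
    nb <- adj[[a]]
    if (length(nb) < 2) next
    for (i in seq_len(length(nb) - 1)) for (j in (i + 1):length(nb)) {
      b <- nb[i]; c <- nb[j]
      kbc <- key(b, c)
      if (is.na(w[kbc])) next
      tri <- c(key(a, b), key(a, c), kbc)
      mis <- w[tri]
      weak <- which.min(mis)
      if (mis[weak] < (1 - tolerance) * min(mis[-weak]))
        drop <- c(drop, tri[weak])
    }
  }
  keep <- !(key(edges$regulator, edges$target) %in% drop)
  edges[keep, , drop = FALSE]
}

#' Collect pruned edges into Regulon objects
#' @param edges edge data.frame (`regulator`, `target`, `mi`).
#' @return named list of [Regulon-class] objects.
#' @export
edgesToRegulons <- function(edges) {
  sp <- split(edges, edges$regulator)
  lapply(sp, function(e)
    new("Regulon", regulator = e$regulator[1], targets = e$target,
        weights = stats::setNames(e$mi, e$target)))
}

#' Enrichment of subtype-specific genes in a regulon's targets
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) on the 2x2
#' overlap table between the subtype gene set and the regulon targets over
#' a fixed gene universe.
#'
#' @param subtypeGenes character subtype-specific genes (subset of
#'   `universe`).
#' @param regulon a [Regulon-class] (or character target vector).
#' @param universe character gene universe.
#' @param subtype optional subtype label for the output row.
#' @return one-row data.frame: `subtype`, `regulator`, `overlap`,
#'   `p_value`, `neg_log10_p`.
#' @export
regulonEnrichment <- function(subtypeGenes, regulon, universe,
                              subtype = NA_character_) {
  if (length(universe) == 0) stop("empty universe")
  targets <- if (is(regulon, "Regulon")) regulon@targets else regulon
  reg <- if (is(regulon, "Regulon")) regulon@regulator else NA_character_
  sg <- intersect(subtypeGenes, universe)
  tg <- intersect(targets, universe)
  ov <- length(intersect(sg, tg))
  N <- length(universe)
  # P(X >= ov) for X ~ Hypergeom(N, |tg|, |sg|)
  p <- stats::phyper(ov - 1, length(tg), N - length(tg), length(sg),
                     lower.tail = FALSE)
  data.frame(subtype = subtype, regulator = reg, overlap = ov,
             p_value = p, neg_log10_p = -log10(p),
             stringsAsFactors = FALSE)
}

#' Subtype x regulon enrichment table
#'
#' Applies [regulonEnrichment()] to every (subtype gene set, regulon) pair.
#' @param subtypeGeneSets named list of subtype-specific gene sets (e.g.
#'   top metagene genes per subtype).
#' @param regulons named list of [Regulon-class] objects.
#' @param universe gene universe.
#' @return data.frame, one row per pair.
#' @export
enrichmentTable <- function(subtypeGeneSets, regulons, universe) {
  do.call(rbind, lapply(names(subtypeGeneSets), function(s) {
    do.call(rbind, lapply(regulons, function(r)
      regulonEnrichment(subtypeGeneSets[[s]], r, universe, subtype = s)))
  }))
}
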