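#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Barbie-style running-sum statistic for one expression profile: genes are
#' ranked by expression (descending; ties receive average ranks), and the
#' score is the sum over the ranked list of the difference between the
#' rank^alpha-weighted in-set empirical CDF and the unweighted out-of-set
#' CDF. Rank-based, hence invariant under strictly increasing transforms of
#' the profile.
#'
#' @param exprColumn named numeric expression profile of one sample.
#' @param geneSet character vector of member gene ids; must intersect the
#'   profile and must not cover it entirely.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return numeric enrichment score.
#' @export
ssgseaScore <- function(exprColumn, geneSet, alpha = 0.25) {
  if (length(geneSet) == 0) stop("gene set is empty")
  genes <- names(exprColumn)
  inSet <- genes %in% geneSet
  if (!any(inSet)) stop("gene set has empty intersection with the profile")
  if (all(inSet)) stop("gene set covers the entire profile")
  r <- rank(exprColumn, ties.method = "average")
  ord <- order(-exprColumn, genes, method = "radix")  # descending walk
  inOrd <- inSet[ord]
  w <- r[ord]^alpha
  stepIn <- ifelse(inOrd, w, 0)
  pIn <- cumsum(stepIn) / sum(stepIn)
  pOut <- cumsum(!inOrd) / sum(!inOrd)
  sum(pIn - pOut)
}

#' ssGSEA scores for a matrix and a gene-set collection
#'
#' @param x an [ExpressionMatrix-class] or matrix (genes x samples).
#' @param gsc a [GeneSetCollection-class] or named list of gene sets.
#' @param alpha rank-weighting exponent.
#' @return samples x signatures matrix with attribute `method = "ssgsea"`.
#' @export
scoreSignatures <- function(x, gsc, alpha = 0.25) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  sets <- if (is(gsc, "GeneSetCollection")) geneSets(gsc) else gsc
  out <- sapply(sets, function(s)
    apply(v, 2, ssgseaScore, geneSet = s, alpha = alpha))
  out <- matrix(out, ncol(v), length(sets),
                dimnames = list(colnames(v), names(sets)))
  attr(out, "method") <- "ssgsea"
  out
}

#' Marker-set mean score
#'
#' Arithmetic mean of expression over the markers present in the profile
#' (MCPcounter-style cell-abundance summary). Missing markers are reported
#' via a message.
#'
#' @param exprColumn named numeric profile (log2TPM).
#' @param markerSet character marker gene ids; at least one must be present.
#' @return numeric mean.
#' @export
markerMeanScore <- function(exprColumn, markerSet) {
  present <- intersect(markerSet, names(exprColumn))
  if (length(present) == 0) stop("no markers present in the profile")
  missing <- setdiff(markerSet, present)
  if (length(missing))
    message("markerMeanScore: ", length(missing), " marker(s) absent: ",
            paste(utils::head(missing, 5), collapse = ", "))
  mean(exprColumn[present])
}

#' ESTIMATE-like immune and stromal scores
#'
#' Both scores are ssGSEA enrichments of the supplied immune and stromal
#' signature sets, per sample.
#'
#' @param x an [ExpressionMatrix-class] or matrix.
#' @param immuneSet,stromalSet character gene sets.
#' @param alpha rank-weighting exponent.
#' @return data.frame with columns `sample`, `immune`, `stromal`.
#' @export
estimateLikeScores <- function(x, immuneSet, stromalSet, alpha = 0.25) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  data.frame(sample = colnames(v),
             immune = apply(v, 2, ssgseaScore, geneSet = immuneSet,
                            alpha = alpha),
             stromal = apply(v, 2, ssgseaScore, geneSet = stromalSet,
                             alpha = alpha),
             row.names = NULL)
}

#' Neuroendocrine (NE) score
#'
#' Correlation-contrast statistic for the position of a sample on the
#' NE -> non-NE axis: `(r_NE - r_nonNE) / 2`, where the r are Pearson
#' correlations between the sample's signature-gene vector and the NE and
#' non-NE prototype vectors. Bounded in \[-1, 1\].
#'
#' @param exprColumn named numeric profile.
#' @param nePrototype,nonNePrototype named numeric prototype vectors
#'   defined on `signatureGenes`.
#' @param signatureGenes gene ids over which the correlations are taken.
#' @return numeric in \[-1, 1\].
#' @export
neScore <- function(exprColumn, nePrototype, nonNePrototype,
                    signatureGenes) {
  g <- intersect(signatureGenes, names(exprColumn))
  g <- intersect(g, intersect(names(nePrototype), names(nonNePrototype)))
  if (length(g) < 3) stop("too few signature genes shared with prototypes")
  x <- exprColumn[g]
  if (stats::sd(x) == 0)
    stop("zero-variance sample vector over signature genes")
  (stats::cor(x, nePrototype[g]) - stats::cor(x, nonNePrototype[g])) / 2
}

#' NE/non-NE prototype vectors from labeled training samples
#'
#' Mean expression per gene within NE-labeled and non-NE-labeled groups,
#' restricted to the signature genes; the standard hook when a published
#' prototype list is not supplied.
#'
#' @param x an [ExpressionMatrix-class] or matrix.
#' @param isNE logical per sample.
#' @param signatureGenes gene ids for the prototypes.
#' @return list with `ne` and `nonNe` named prototype vectors.
#' @export
nePrototypes <- function(x, isNE, signatureGenes) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  g <- intersect(signatureGenes, rownames(v))
  if (!any(isNE) || all(isNE)) stop("need both NE and non-NE samples")
  list(ne = rowMeans(v[g, isNE, drop = FALSE]),
       nonNe = rowMeans(v[g, !isNE, drop = FALSE]))
}
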