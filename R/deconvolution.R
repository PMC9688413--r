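## Constrained least-squares deconvolution of bulk expression into four
## cell types (epithelial, fibroblast, endothelial, immune) plus the
## tumor-intrinsic mesenchymal/inflamed (M/I) scoring machinery.
## All mixture fits run on the linear TPM scale, where additivity holds.

.CELLTYPES <- c("epithelial", "fibroblast", "endothelial", "immune")

#' Estimate cell-type fractions for one bulk profile
#'
#' Non-negative least squares of the bulk vector on the signature-matrix
#' columns over the signature genes, with coefficients renormalized to the
#' unit simplex.
#'
#' @param bulkColumn named numeric bulk profile on the linear TPM scale.
#' @param sig genes x 4 signature matrix (epithelial, fibroblast,
#'   endothelial, immune); at least 4 signature genes per cell type must
#'   be present in the bulk profile.
#' @return numeric 4-vector on the simplex.
#' @export
estimateFractions <- function(bulkColumn, sig) {
  g <- intersect(rownames(sig), names(bulkColumn))
  if (length(g) < 4 * ncol(sig))
    stop("too few signature genes present in the bulk profile")
  b <- bulkColumn[g]
  if (all(b == 0)) stop("bulk profile is all zero over signature genes")
  fit <- pracma::lsqnonneg(as.matrix(sig[g, ]), b)
  x <- fit$x
  if (sum(x) == 0) stop("degenerate NNLS fit: all coefficients zero")
  stats::setNames(x / sum(x), colnames(sig))
}

#' Cell-type fractions for a cohort
#' @param x an [ExpressionMatrix-class] with unit `"TPM"` (or a matrix on
#'   the linear scale).
#' @param sig signature matrix as in [estimateFractions()].
#' @return samples x 4 fraction matrix.
#' @export
estimateFractionsMatrix <- function(x, sig) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  t(apply(v, 2, estimateFractions, sig = sig))
}

#' Group-mode purified expression profiles
#'
#' For a group of samples (>= 8), fits per gene a non-negative least
#' squares of the across-sample bulk values on the 4-column fraction
#' matrix, yielding one non-negative profile per cell type for the group.
#' A cell type whose fraction is constant across the group makes the
#' design rank-deficient; it is dropped from the fit with a warning and
#' reported as zero.
#'
#' @param bulkGroup genes x samples bulk matrix (linear scale) for the
#'   group.
#' @param fractionsGroup samples x 4 fraction matrix for the same samples.
#' @return genes x 4 non-negative profile matrix.
#' @export
groupwiseExpression <- function(bulkGroup, fractionsGroup) {
  bulkGroup <- as.matrix(bulkGroup)
  if (ncol(bulkGroup) < 8) stop("group must have at least 8 samples")
  F <- as.matrix(fractionsGroup)
  sds <- apply(F, 2, stats::sd)
  mns <- colMeans(F)
  keep <- mns > 1e-10
  # several constant columns are exactly collinear; keep the largest-mean
  # one as the intercept-like term and drop the rest
  constant <- which(keep & sds <= 1e-10)
  if (length(constant) > 1)
    keep[constant[-which.max(mns[constant])]] <- FALSE
  if (!all(keep))
    warning("dropping absent/constant cell type(s) from groupwise fit: ",
            paste(colnames(F)[!keep], collapse = ", "))
  Fk <- F[, keep, drop = FALSE]
  P <- matrix(0, nrow(bulkGroup), ncol(F),
              dimnames = list(rownames(bulkGroup), colnames(F)))
  for (g in seq_len(nrow(bulkGroup))) {
    P[g, keep] <- pracma::lsqnonneg(Fk, bulkGroup[g, ])$x
  }
  P
}

#' Per-sample epithelial expression approximation
#'
#' Residual-attribution estimate: with group epithelial profile P, bulk
#' residual \eqn{r_{gs}} after subtracting all predicted components, and
#' weight \eqn{w_s = f_{s,epi} / \sum_c f_{s,c}^2}, the estimate is
#' \eqn{\hat e_{gs} = \max(0, P_{g,epi} + w_s r_{gs})}. Samples with
#' epithelial fraction below 0.05 are flagged low-confidence.
#'
#' @param bulk genes x samples matrix (linear scale).
#' @param fractions samples x 4 fraction matrix.
#' @param groupProfiles named list (by group) of genes x 4 profile
#'   matrices from [groupwiseExpression()].
#' @param groups character group label per sample (names of
#'   `groupProfiles`).
#' @return list: `epithelial` (genes x samples), `lowConfidence` (logical
#'   per sample).
#' @export
epithelialPerSample <- function(bulk, fractions, groupProfiles, groups) {
  bulk <- as.matrix(bulk)
  F <- as.matrix(fractions)
  est <- matrix(NA_real_, nrow(bulk), ncol(bulk), dimnames = dimnames(bulk))
  low <- stats::setNames(F[, "epithelial"] < 0.05, colnames(bulk))
  for (s in seq_len(ncol(bulk))) {
    P <- groupProfiles[[groups[s]]]
    if (is.null(P)) stop("no group profile for sample ", colnames(bulk)[s])
    pred <- as.vector(P %*% F[s, ])
    r <- bulk[, s] - pred
    w <- F[s, "epithelial"] / sum(F[s, ]^2)
    est[, s] <- pmax(0, P[, "epithelial"] + w * r)
  }
  list(epithelial = est, lowConfidence = low)
}

#' Full deconvolution of a cohort
#'
#' Convenience wrapper: fractions per sample, group-mode profiles per
#' subtype group, and the per-sample epithelial approximation.
#'
#' @param x an [ExpressionMatrix-class] on the linear TPM scale.
#' @param sig signature matrix.
#' @param groups character group (subtype) label per sample.
#' @return A [DeconvolutionResult-class].
#' @export
deconvolveCohort <- function(x, sig, groups) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  fr <- estimateFractionsMatrix(v, sig)
  groups <- as.character(groups)
  profs <- lapply(split(seq_len(ncol(v)), groups), function(idx) {
    if (length(idx) >= 8)
      groupwiseExpression(v[, idx, drop = FALSE], fr[idx, , drop = FALSE])
    else NULL
  })
  ok <- !vapply(profs, is.null, TRUE)
  profs <- profs[ok]
  haveProfile <- groups %in% names(profs)
  epi <- NULL; low <- logical(0)
  if (any(haveProfile)) {
    eps <- epithelialPerSample(v[, haveProfile, drop = FALSE],
                               fr[haveProfile, , drop = FALSE],
                               profs, groups[haveProfile])
    epi <- eps$epithelial
    low <- eps$lowConfidence
  }
  new("DeconvolutionResult", fractions = fr, groupProfiles = profs,
      epithelial = epi, lowConfidence = low)
}

#' Differential expression between two purified groups (Welch t)
#'
#' Welch t-statistic per gene with Benjamini-Hochberg FDR; genes with zero
#' variance on both sides are skipped (reported via message). Classifier
#' lists are the top `nClassifier/2` genes up in A and in B.
#'
#' @param epiA,epiB genes x samples matrices (log2 scale) for the two
#'   groups; >= 3 samples per side.
#' @param nClassifier total classifier genes (split evenly; default 100).
#' @return list: `table` (gene, t, p, fdr ranked by t), `upA`, `upB`.
#' @export
epithelialDE <- function(epiA, epiB, nClassifier = 100L) {
  epiA <- as.matrix(epiA); epiB <- as.matrix(epiB)
  if (ncol(epiA) < 3 || ncol(epiB) < 3)
    stop("need at least 3 samples per side")
  mA <- rowMeans(epiA); mB <- rowMeans(epiB)
  vA <- apply(epiA, 1, stats::var); vB <- apply(epiB, 1, stats::var)
  nA <- ncol(epiA); nB <- ncol(epiB)
  se2 <- vA / nA + vB / nB
  defined <- se2 > 0
  if (any(!defined))
    message("epithelialDE: skipping ", sum(!defined),
            " zero-variance gene(s)")
  t <- (mA - mB)[defined] / sqrt(se2[defined])
  df <- (se2[defined]^2) /
    ((vA[defined] / nA)^2 / (nA - 1) + (vB[defined] / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  fdr <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(gene = rownames(epiA)[defined], t = t, df = df,
                    p = p, fdr = fdr, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$t), ]
  half <- nClassifier %/% 2
  upA <- utils::head(tab$gene, half)
  upB <- utils::tail(tab$gene, half)
  list(table = tab, upA = upA, upB = rev(upB))
}

#' Tumor-intrinsic M and I scores
#'
#' M score = mean log2 expression over the M-up classifier genes, I score
#' likewise; `diff = M - I` exactly. Swapping the two lists negates the
#' differential score.
#'
#' @param x an [ExpressionMatrix-class] (log2TPM) or matrix.
#' @param classifiers list with character elements `mUp` and `iUp`
#'   (disjoint).
#' @return data.frame per sample: `sample`, `m_score`, `i_score`, `diff`.
#' @export
miIntrinsicScores <- function(x, classifiers) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  if (length(intersect(classifiers$mUp, classifiers$iUp)))
    stop("classifier lists must be disjoint")
  mP <- intersect(classifiers$mUp, rownames(v))
  iP <- intersect(classifiers$iUp, rownames(v))
  if (length(mP) == 0 && length(iP) == 0)
    stop("neither classifier list is represented in the expression matrix")
  m <- colMeans(v[mP, , drop = FALSE])
  i <- colMeans(v[iP, , drop = FALSE])
  data.frame(sample = colnames(v), m_score = m, i_score = i,
             diff = m - i, row.names = NULL)
}

#' Correlation of each gene with the M - I differential score
#'
#' Pearson r per gene against the differential score with the two-sided
#' t-based p-value; zero-variance genes are skipped.
#'
#' @param x expression matrix (genes x samples, log2 scale) or
#'   [ExpressionMatrix-class]; >= 4 samples.
#' @param diffScores numeric differential score per sample.
#' @return data.frame: `gene`, `r`, `p`.
#' @export
geneDiffCorrelation <- function(x, diffScores) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  n <- ncol(v)
  if (n < 4) stop("need at least 4 samples")
  sds <- apply(v, 1, stats::sd)
  keep <- sds > 0 & stats::sd(diffScores) > 0
  r <- as.vector(stats::cor(t(v[keep, , drop = FALSE]), diffScores))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  data.frame(gene = rownames(v)[keep], r = r, p = p,
             stringsAsFactors = FALSE)
}

#' Classic GSEA enrichment of a gene set in a ranked statistic
#'
#' Weighted Kolmogorov-Smirnov running sum (weight = |stat|, Broad classic
#' with exponent 1); ES is the maximum deviation from zero. The p-value is
#' from gene-set permutation: random sets of the same size, two-sided on
#' |ES|.
#'
#' @param rankedStats named numeric gene-level statistics (any order; they
#'   are sorted decreasingly internally).
#' @param geneSet character member gene ids.
#' @param nPerm number of random-set permutations.
#' @param seed integer seed.
#' @return list: `es`, `p`, `runningSum` (named numeric along the
#'   ranking).
#' @export
celltypeGSEA <- function(rankedStats, geneSet, nPerm = 1000L, seed = 1L) {
  stats_sorted <- sort(rankedStats, decreasing = TRUE)
  genes <- names(stats_sorted)
  inSet <- genes %in% geneSet
  if (!any(inSet)) stop("gene set has empty intersection with the ranking")
  if (all(inSet)) stop("gene set covers the entire ranking")
  esOf <- function(inSet) {
    w <- abs(stats_sorted)
    wIn <- ifelse(inSet, w, 0)
    sIn <- sum(wIn)
    if (sIn == 0) wIn <- as.numeric(inSet); sIn <- sum(wIn)
    run <- cumsum(wIn) / sIn - cumsum(!inSet) / sum(!inSet)
    run[which.max(abs(run))]
  }
  w <- abs(stats_sorted)
  wIn <- ifelse(inSet, w, 0)
  run <- cumsum(wIn) / sum(wIn) - cumsum(!inSet) / sum(!inSet)
  es <- run[which.max(abs(run))]
  set.seed(seed)
  m <- sum(inSet)
  null <- replicate(nPerm, {
    idx <- logical(length(genes))
    idx[sample.int(length(genes), m)] <- TRUE
    esOf(idx)
  })
  p <- (1 + sum(abs(null) >= abs(es))) / (nPerm + 1)
  list(es = unname(es), p = p,
       runningSum = stats::setNames(run, genes))
}
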