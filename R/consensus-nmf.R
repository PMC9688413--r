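#' @useDynLib sclcTaxonomy, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Non-negative matrix factorization (generalized KL divergence)
#'
#' Multiplicative updates for the generalized Kullback-Leibler divergence
#' (Brunet-style), stopping when the relative objective change falls below
#' `tol` or after `maxIter` iterations. Basis columns are scaled to unit L1
#' with compensation in H, so H loadings are comparable across metagenes.
#'
#' @param X an [ExpressionMatrix-class] (non-negative; typically log2TPM)
#'   or a plain non-negative matrix.
#' @param K factorization rank, `2 <= K < min(dim)` (K = 1 allowed for the
#'   degenerate rank-1 case).
#' @param seed integer seed for the random uniform initialization.
#' @param maxIter iteration cap.
#' @param tol relative objective-change stopping tolerance (between
#'   successive recorded objective values).
#' @param nRestarts random restarts; the factorization with the lowest
#'   final divergence is kept.
#' @param traceEvery record the objective (and apply the stopping rule)
#'   every this many iterations; 1 gives the full per-iteration trace.
#' @return An [NMFFactors-class].
#' @export
nmfFactorize <- function(X, K, seed = 1L, maxIter = 200L, tol = 1e-5,
                         nRestarts = 1L, traceEvery = 1L) {
  V <- if (is(X, "ExpressionMatrix")) exprValues(X) else as.matrix(X)
  if (any(V < 0)) stop("NMF requires a non-negative matrix")
  if (K < 1 || K >= min(dim(V)) + (K == 1))
    stop("K must satisfy 1 <= K < min(dim(X))")
  best <- NULL
  set.seed(seed)
  for (r in seq_len(nRestarts)) {
    W0 <- matrix(stats::runif(nrow(V) * K, 0.1, 1), nrow(V), K)
    H0 <- matrix(stats::runif(K * ncol(V), 0.1, 1), K, ncol(V))
    fit <- .nmf_kl_cpp(V, W0, H0, as.integer(maxIter), tol,
                       as.integer(traceEvery))
    if (is.null(best) ||
        utils::tail(fit$trace, 1) < utils::tail(best$trace, 1))
      best <- fit
  }
  W <- best$W; H <- best$H
  dimnames(W) <- list(rownames(V), paste0("MG", seq_len(K)))
  dimnames(H) <- list(paste0("MG", seq_len(K)), colnames(V))
  new("NMFFactors", W = W, H = H, trace = best$trace)
}

#' Assign samples to metagene clusters
#'
#' Label = argmax over metagene loadings per sample; ties go to the lower
#' metagene index.
#' @param H K x samples coefficient matrix or an [NMFFactors-class].
#' @return integer labels, named by sample.
#' @export
assignClusters <- function(H) {
  if (is(H, "NMFFactors")) H <- coefMatrix(H)
  stats::setNames(apply(H, 2, which.max), colnames(H))
}

#' Top genes of one metagene
#'
#' Ranks genes by the column-z-scored basis weight of metagene `k` and
#' returns the top `nTop` gene ids.
#' @param W genes x K basis matrix or an [NMFFactors-class].
#' @param k metagene index.
#' @param nTop number of genes.
#' @return character vector of gene ids.
#' @export
extractMetageneGenes <- function(W, k, nTop = 100L) {
  if (is(W, "NMFFactors")) W <- basisMatrix(W)
  Z <- scale(W)
  ord <- order(-Z[, k], rownames(W), method = "radix")
  rownames(W)[ord[seq_len(min(nTop, nrow(W)))]]
}

#' Consensus matrix over gene subsamples
#'
#' For each subsample a random fraction of genes is drawn (all samples
#' retained, so the consensus is over a fixed sample set), an NMF at rank K
#' is fit, and co-clustering connectivity (argmax of the H column) is
#' recorded. The consensus is the mean connectivity across subsamples.
#'
#' @inheritParams nmfFactorize
#' @param nSubsamples number of gene subsamples (>= 2).
#' @param subsampleFrac fraction of genes per subsample, in (0, 1].
#' @param nRestarts NMF restarts per subsample (default 1; consensus
#'   averaging across subsamples already integrates over initializations).
#' @param maxIter,tol,traceEvery NMF control for the per-subsample fits;
#'   the defaults run each fit to deep convergence, which is what makes
#'   over-fitted ranks visibly unstable.
#' @return samples x samples symmetric matrix with unit diagonal.
#' @export
consensusMatrix <- function(X, K, nSubsamples = 50L, subsampleFrac = 0.8,
                            seed = 1L, nRestarts = 1L, maxIter = 500L,
                            tol = 1e-5, traceEvery = 10L) {
  V <- if (is(X, "ExpressionMatrix")) exprValues(X) else as.matrix(X)
  if (nSubsamples < 2) stop("nSubsamples must be at least 2")
  if (subsampleFrac <= 0 || subsampleFrac > 1)
    stop("subsampleFrac must lie in (0, 1]")
  n <- ncol(V)
  acc <- matrix(0, n, n)
  set.seed(seed)
  for (b in seq_len(nSubsamples)) {
    rows <- sample.int(nrow(V), max(2L, round(subsampleFrac * nrow(V))))
    fit <- nmfFactorize(V[rows, , drop = FALSE], K,
                        seed = sample.int(.Machine$integer.max, 1),
                        maxIter = maxIter, tol = tol, nRestarts = nRestarts,
                        traceEvery = traceEvery)
    lab <- assignClusters(fit)
    acc <- acc + outer(lab, lab, "==")
  }
  C <- acc / nSubsamples
  dimnames(C) <- list(colnames(V), colnames(V))
  C
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Average-linkage hierarchical clustering of `D = 1 - C`; returns the
#' Pearson correlation between the dendrogram's cophenetic distances and
#' the entries of D over all pairs — the standard stability score for
#' consensus clustering.
#'
#' @param C consensus matrix (symmetric, entries in \[0,1\], unit diagonal).
#' @return numeric in \[-1, 1\].
#' @export
copheneticCoefficient <- function(C) {
  D <- stats::as.dist(1 - C)
  if (stats::sd(D) == 0)
    stop("cophenetic coefficient undefined: consensus distances constant")
  hc <- stats::hclust(D, method = "average")
  stats::cor(D, stats::cophenetic(hc))
}

# permute every gene's values across samples, destroying sample structure
# while preserving gene marginals
.permuteGenes <- function(V) {
  t(apply(V, 1, sample))
}

#' Permutation null band for cophenetic coefficients
#'
#' Each permutation independently shuffles every gene's values across
#' samples and recomputes the cophenetic coefficient for each K; the
#' empirical 5th/95th percentiles per K form the null band against which
#' observed stability is judged.
#'
#' @inheritParams consensusMatrix
#' @param kRange contiguous integer range of ranks.
#' @param nPerm number of permutations (>= 20).
#' @return matrix with rownames = K, columns `p5`, `p95`.
#' @export
permutationBand <- function(X, kRange, nPerm = 20L, nSubsamples = 50L,
                            subsampleFrac = 0.8, seed = 1L,
                            maxIter = 200L, tol = 1e-4) {
  V <- if (is(X, "ExpressionMatrix")) exprValues(X) else as.matrix(X)
  if (nPerm < 20) stop("nPerm must be at least 20")
  rho <- matrix(NA_real_, nPerm, length(kRange),
                dimnames = list(NULL, kRange))
  set.seed(seed)
  permSeeds <- sample.int(.Machine$integer.max, nPerm)
  for (p in seq_len(nPerm)) {
    set.seed(permSeeds[p])
    Vp <- .permuteGenes(V)
    colnames(Vp) <- colnames(V)
    innerSeeds <- sample.int(.Machine$integer.max, length(kRange))
    for (j in seq_along(kRange)) {
      C <- consensusMatrix(Vp, kRange[j], nSubsamples = nSubsamples,
                           subsampleFrac = subsampleFrac,
                           seed = innerSeeds[j], maxIter = maxIter,
                           tol = tol, traceEvery = 10L)
      rho[p, j] <- tryCatch(copheneticCoefficient(C), error = function(e) 1)
    }
  }
  band <- t(apply(rho, 2, stats::quantile, probs = c(0.05, 0.95),
                  names = FALSE))
  dimnames(band) <- list(kRange, c("p5", "p95"))
  band
}

#' Select the number of subtypes from cophenetic stability
#'
#' K* is the largest K whose cophenetic coefficient sits at or above the
#' null band's 95th percentile and whose stability drops by at least
#' `dropThreshold` at K+1 (a "substantial drop"). When no K qualifies,
#' the fallback is argmax of the coefficients (smallest index on ties).
#'
#' @param rho named numeric of cophenetic coefficients over a contiguous
#'   K range (>= 3 values).
#' @param band matrix as returned by [permutationBand()], or NULL to skip
#'   the band condition.
#' @param dropThreshold minimum stability drop at K+1 (default 0.02).
#' @return list: `K` (selected rank), `rule` (how it was chosen),
#'   `dropThreshold`.
#' @export
selectRank <- function(rho, band = NULL, dropThreshold = 0.02) {
  ks <- as.integer(names(rho))
  if (length(ks) < 3) stop("need at least 3 K values")
  if (any(diff(ks) != 1)) stop("K range must be contiguous")
  qual <- logical(length(ks))
  for (j in seq_len(length(ks) - 1)) {
    aboveBand <- is.null(band) || rho[j] >= band[as.character(ks[j]), "p95"]
    qual[j] <- aboveBand && (rho[j] - rho[j + 1]) >= dropThreshold
  }
  if (any(qual)) {
    K <- ks[max(which(qual))]
    rule <- "largest K above band with substantial drop"
  } else {
    K <- ks[which.max(rho)]
    rule <- "fallback: argmax cophenetic"
  }
  list(K = as.integer(K), rule = rule, dropThreshold = dropThreshold)
}

#' Consensus NMF subtype discovery across a range of ranks
#'
#' Runs [consensusMatrix()] and [copheneticCoefficient()] for each K,
#' optionally computes the permutation null band, selects the rank with
#' [selectRank()], and refits the full data at K* (with restarts) to
#' produce final metagenes and cluster labels.
#'
#' @inheritParams consensusMatrix
#' @param kRange contiguous rank range (default 2:10).
#' @param nPerm permutations for the null band; 0 skips the band.
#' @param bandSubsamples inner consensus subsamples for each permutation
#'   replicate (default 10; the band needs the null distribution's
#'   location, not a high-resolution consensus).
#' @param bandMaxIter,bandTol NMF control for the permutation replicates
#'   (lighter than the observed consensus for the same reason).
#' @param dropThreshold passed to [selectRank()].
#' @param finalRestarts restarts for the final full-data fit.
#' @return A [ConsensusResult-class].
#' @export
consensusNMF <- function(X, kRange = 2:10, nSubsamples = 50L,
                         subsampleFrac = 0.8, nPerm = 20L,
                         bandSubsamples = 10L, seed = 1L,
                         dropThreshold = 0.02, maxIter = 500L, tol = 1e-5,
                         bandMaxIter = 200L, bandTol = 1e-4,
                         finalRestarts = 3L) {
  V <- if (is(X, "ExpressionMatrix")) exprValues(X) else as.matrix(X)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(kRange) + 2)
  cons <- list(); rho <- numeric(length(kRange))
  for (j in seq_along(kRange)) {
    C <- consensusMatrix(V, kRange[j], nSubsamples = nSubsamples,
                         subsampleFrac = subsampleFrac, seed = seeds[j],
                         maxIter = maxIter, tol = tol)
    cons[[as.character(kRange[j])]] <- C
    rho[j] <- tryCatch(copheneticCoefficient(C), error = function(e) 1)
  }
  names(rho) <- kRange
  band <- NULL
  if (nPerm > 0)
    band <- permutationBand(V, kRange, nPerm = nPerm,
                            nSubsamples = bandSubsamples,
                            subsampleFrac = subsampleFrac,
                            seed = seeds[length(kRange) + 1],
                            maxIter = bandMaxIter, tol = bandTol)
  sel <- selectRank(rho, band, dropThreshold)
  fit <- nmfFactorize(V, sel$K, seed = seeds[length(kRange) + 2],
                      maxIter = max(maxIter, 200L), tol = tol,
                      nRestarts = finalRestarts)
  labels <- assignClusters(fit)
  new("ConsensusResult", consensus = cons, cophenetic = rho, band = band,
      selectedRank = sel$K, labels = as.integer(labels), factors = fit,
      rule = sel[c("rule", "dropThreshold")])
}
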