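#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors metadata SimpleList
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ExpressionMatrix: a genes x samples expression container with a unit tag
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] carrying a
#' single `"exprs"` assay and a unit tag, one of `"counts"`, `"TPM"` or
#' `"log2TPM"`. Row names are gene identifiers (opaque strings), column names
#' are sample identifiers; both must be unique. Counts must be non-negative
#' integers; log2(TPM+1) values must be non-negative.
#'
#' @slot unit character(1), one of `"counts"`, `"TPM"`, `"log2TPM"`.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  slots = c(unit = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@unit) != 1L ||
      !object@unit %in% c("counts", "TPM", "log2TPM"))
    msg <- c(msg, "unit must be one of 'counts', 'TPM', 'log2TPM'")
  v <- SummarizedExperiment::assay(object, "exprs")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "sample ids must be present and unique")
  if (any(!is.finite(v)))
    msg <- c(msg, "expression values must be finite")
  if (length(object@unit) == 1L && object@unit == "counts") {
    if (any(v < 0) || any(abs(v - round(v)) > 1e-8))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (length(object@unit) == 1L && object@unit == "log2TPM" && any(v < 0))
    msg <- c(msg, "log2TPM values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric genes x samples matrix with row and column names.
#' @param unit one of `"counts"`, `"TPM"`, `"log2TPM"`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(0:3, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ExpressionMatrix(m, "counts")
#' @export
ExpressionMatrix <- function(values, unit = c("counts", "TPM", "log2TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(exprs = values))
  new("ExpressionMatrix", se, unit = unit)
}

#' @describeIn ExpressionMatrix numeric matrix of expression values
#' @param x an `ExpressionMatrix`
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn ExpressionMatrix the unit tag
#' @export
exprUnit <- function(x) x@unit

setMethod("show", "ExpressionMatrix", function(object) {
  v <- exprValues(object)
  cat("ExpressionMatrix [", object@unit, "]: ",
      nrow(v), " genes x ", ncol(v), " samples\n", sep = "")
})

#' NMFFactors: result of a single non-negative matrix factorization
#'
#' @slot W genes x K non-negative basis matrix (metagenes), columns scaled
#'   to unit L1.
#' @slot H K x samples non-negative coefficient matrix.
#' @slot trace generalized KL divergence per iteration (non-increasing).
#' @export
setClass("NMFFactors",
  slots = c(W = "matrix", H = "matrix", trace = "numeric"))

setValidity("NMFFactors", function(object) {
  msg <- character()
  if (any(object@W < 0) || any(object@H < 0))
    msg <- c(msg, "factors must be non-negative")
  if (ncol(object@W) != nrow(object@H))
    msg <- c(msg, "inner dimensions of W and H must agree")
  if (any(diff(object@trace) > 1e-8 * (abs(object@trace[-length(object@trace)]) + 1)))
    msg <- c(msg, "objective trace must be non-increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NMFFactors", function(object) {
  cat("NMFFactors: ", nrow(object@W), " genes, K = ", ncol(object@W),
      ", ", ncol(object@H), " samples; final KL divergence ",
      format(utils::tail(object@trace, 1), digits = 6), "\n", sep = "")
})

#' @describeIn NMFFactors basis (metagene) matrix
#' @param x an `NMFFactors`
#' @export
basisMatrix <- function(x) x@W

#' @describeIn NMFFactors coefficient matrix
#' @export
coefMatrix <- function(x) x@H

#' @describeIn NMFFactors objective (KL divergence) per iteration
#' @export
objectiveTrace <- function(x) x@trace

#' ConsensusResult: consensus clustering across a range of NMF ranks
#'
#' @slot consensus named list (by K) of samples x samples consensus matrices
#'   with entries in \[0,1\], symmetric, unit diagonal.
#' @slot cophenetic named numeric of cophenetic coefficients per K.
#' @slot band two-column matrix (p5, p95) per K from permutation tests, or
#'   NULL if no null band was computed.
#' @slot selectedRank the selected number of subtypes K*.
#' @slot labels integer cluster labels per sample at K*.
#' @slot factors final full-data NMFFactors at K*.
#' @slot rule list recording the rank-selection rule and threshold used.
#' @export
setClass("ConsensusResult",
  slots = c(consensus = "list", cophenetic = "numeric",
            band = "matrixOrNULL", selectedRank = "integer",
            labels = "integer", factors = "NMFFactors", rule = "list"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  for (C in object@consensus) {
    if (max(abs(C - t(C))) > 1e-12) msg <- c(msg, "consensus must be symmetric")
    if (any(C < -1e-12) || any(C > 1 + 1e-12))
      msg <- c(msg, "consensus entries must lie in [0,1]")
    if (max(abs(diag(C) - 1)) > 1e-12)
      msg <- c(msg, "consensus diagonal must be 1")
  }
  if (any(object@cophenetic < -1 - 1e-12 | object@cophenetic > 1 + 1e-12))
    msg <- c(msg, "cophenetic coefficients must lie in [-1,1]")
  if (!is.null(object@band) && any(object@band[, 1] > object@band[, 2] + 1e-12))
    msg <- c(msg, "band lower percentile must not exceed upper")
  if (length(unique(msg))) unique(msg) else TRUE
})

setMethod("show", "ConsensusResult", function(object) {
  ks <- as.integer(names(object@cophenetic))
  cat("ConsensusResult: K scanned ", min(ks), "..", max(ks),
      "; selected K* = ", object@selectedRank, "\n", sep = "")
  cat("  cophenetic:", paste(sprintf("%d:%.3f", ks, object@cophenetic),
                             collapse = " "), "\n")
})

#' @describeIn ConsensusResult cophenetic coefficient per K
#' @param x a `ConsensusResult`
#' @export
copheneticScores <- function(x) x@cophenetic

#' @describeIn ConsensusResult selected rank K*
#' @export
selectedRank <- function(x) x@selectedRank

#' @describeIn ConsensusResult cluster labels at the selected rank
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn ConsensusResult list of per-K consensus matrices
#' @export
consensusMatrices <- function(x) x@consensus

#' GeneSetCollection: named gene sets with optional descriptions
#'
#' @slot sets named list of character vectors of gene ids; names unique,
#'   sets non-empty.
#' @slot description named character of free-text descriptions.
#' @export
setClass("GeneSetCollection",
  slots = c(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "set names must be present and unique")
  if (any(vapply(object@sets, length, 1L) == 0L))
    msg <- c(msg, "gene sets must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#' @param sets named list of character vectors.
#' @param description optional named character vector of descriptions.
#' @export
GeneSetCollection <- function(sets, description = NULL) {
  if (is.null(description))
    description <- stats::setNames(rep("", length(sets)), names(sets))
  new("GeneSetCollection", sets = sets, description = description)
}

#' @describeIn GeneSetCollection the named list of gene sets
#' @param x a `GeneSetCollection`
#' @export
geneSets <- function(x) x@sets

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets; sizes",
      paste(range(vapply(object@sets, length, 1L)), collapse = "-"), "\n")
})

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' NSCModel: nearest-shrunken-centroid (PAM-style) classifier
#'
#' @slot overallCentroid per-gene overall mean on the training scale.
#' @slot centroids genes x classes raw class centroids.
#' @slot shrunkenCentroids genes x classes centroids after soft-thresholding.
#' @slot si pooled within-class standard deviation per gene.
#' @slot s0 offset added to si (median of si).
#' @slot mk per-class standardization factor sqrt(1/n_k - 1/n).
#' @slot delta the shrinkage threshold in use.
#' @slot priors class priors (sum to 1).
#' @slot genes training gene list.
#' @slot classes class labels.
#' @slot cvTable data.frame of the cross-validated error per candidate delta.
#' @slot trainMedians per-gene training medians (for median-shift
#'   harmonization of new cohorts).
#' @export
setClass("NSCModel",
  slots = c(overallCentroid = "numeric", centroids = "matrix",
            shrunkenCentroids = "matrix", si = "numeric", s0 = "numeric",
            mk = "numeric", delta = "numeric", priors = "numeric",
            genes = "character", classes = "character",
            cvTable = "data.frame", trainMedians = "numeric"))

setValidity("NSCModel", function(object) {
  msg <- character()
  if (abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "priors must sum to 1")
  raw <- abs(object@centroids - object@overallCentroid)
  shr <- abs(object@shrunkenCentroids - object@overallCentroid)
  if (any(shr > raw + 1e-8))
    msg <- c(msg, "shrunken deviations must not exceed raw deviations")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NSCModel", function(object) {
  active <- sum(rowSums(abs(object@shrunkenCentroids -
                              object@overallCentroid)) > 1e-12)
  cat("NSCModel:", length(object@classes), "classes,",
      length(object@genes), "genes (", active, "active ), delta =",
      format(object@delta, digits = 4), "\n")
})

#' DeconvolutionResult: cell-type fractions and purified profiles
#'
#' @slot fractions samples x 4 matrix of cell-type fractions; rows on the
#'   unit simplex.
#' @slot groupProfiles named list (by group) of genes x cell-type profile
#'   matrices from groupwise constrained least squares.
#' @slot epithelial genes x samples per-sample epithelial approximation
#'   (linear TPM scale), or NULL if not computed.
#' @slot lowConfidence logical per sample; TRUE where the epithelial
#'   fraction was below the confidence floor.
#' @export
setClass("DeconvolutionResult",
  slots = c(fractions = "matrix", groupProfiles = "list",
            epithelial = "matrixOrNULL", lowConfidence = "logical"))

setValidity("DeconvolutionResult", function(object) {
  msg <- character()
  f <- object@fractions
  if (any(f < -1e-9)) msg <- c(msg, "fractions must be non-negative")
  if (any(abs(rowSums(f) - 1) > 1e-6))
    msg <- c(msg, "fraction rows must sum to 1")
  for (P in object@groupProfiles)
    if (any(P < -1e-9)) msg <- c(msg, "purified profiles must be non-negative")
  if (length(unique(msg))) unique(msg) else TRUE
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat("DeconvolutionResult:", nrow(object@fractions), "samples,",
      ncol(object@fractions), "cell types;",
      length(object@groupProfiles), "group profile sets",
      if (!is.null(object@epithelial)) "; per-sample epithelial computed",
      "\n")
})

#' @describeIn DeconvolutionResult samples x cell-type fraction matrix
#' @param x a `DeconvolutionResult`
#' @export
cellFractions <- function(x) x@fractions

#' @describeIn DeconvolutionResult per-sample epithelial expression estimate
#' @export
epithelialProfiles <- function(x) x@epithelial

#' TrajectoryResult: one-dimensional pseudotime ordering
#'
#' @slot pseudotime per-unit pseudotime rank on a uniform grid in \[0,1\],
#'   oriented so that correlation with the NE score is non-positive.
#' @slot neScores the NE scores used for orientation.
#' @slot labels optional subtype labels (character(0) when absent).
#' @slot diagnostics list: number of PCs, iterations, converged flag,
#'   total arc length of the fitted curve.
#' @export
setClass("TrajectoryResult",
  slots = c(pseudotime = "numeric", neScores = "numeric",
            labels = "character", diagnostics = "list"))

setValidity("TrajectoryResult", function(object) {
  msg <- character()
  pt <- sort(object@pseudotime)
  n <- length(pt)
  grid <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  if (max(abs(pt - grid)) > 1e-9)
    msg <- c(msg, "pseudotime must be a permutation of the uniform grid")
  if (length(object@neScores) == length(object@pseudotime) &&
      stats::sd(object@neScores) > 0 && stats::sd(object@pseudotime) > 0 &&
      stats::cor(object@pseudotime, object@neScores) > 1e-8)
    msg <- c(msg, "orientation must give corr(pseudotime, NE score) <= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrajectoryResult", function(object) {
  cat("TrajectoryResult:", length(object@pseudotime), "units;",
      "corr(pt, NE) =",
      format(stats::cor(object@pseudotime, object@neScores), digits = 3),
      "\n")
})

#' @describeIn TrajectoryResult pseudotime per unit
#' @param x a `TrajectoryResult`
#' @export
pseudotime <- function(x) x@pseudotime

#' Regulon: a transcriptional regulator with inferred targets
#'
#' @slot regulator gene id of the regulator.
#' @slot targets character vector of target gene ids (never containing the
#'   regulator itself).
#' @slot weights named non-negative mutual-information edge weights.
#' @export
setClass("Regulon",
  slots = c(regulator = "character", targets = "character",
            weights = "numeric"))

setValidity("Regulon", function(object) {
  msg <- character()
  if (object@regulator %in% object@targets)
    msg <- c(msg, "regulator must not be among its own targets")
  if (any(object@weights < 0))
    msg <- c(msg, "MI weights must be non-negative")
  if (length(object@targets) != length(object@weights))
    msg <- c(msg, "one weight per target required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Regulon", function(object) {
  cat("Regulon:", object@regulator, "->", length(object@targets),
      "targets\n")
})
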