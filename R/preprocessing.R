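#' Convert raw counts to log2(TPM + 1)
#'
#' Length-normalizes counts to transcripts per million and log2-transforms
#' with a pseudocount of 1 (keeping the matrix non-negative, as required by
#' downstream non-negative factorization):
#' \deqn{TPM_g = 10^6 \frac{c_g / \ell_g}{\sum_{g'} c_{g'} / \ell_{g'}}}
#' followed by \eqn{\log_2(TPM + 1)}. Column TPM totals equal 1e6 before the
#' transform. The result is invariant to rescaling all lengths by a
#' constant.
#'
#' @param counts an [ExpressionMatrix-class] with unit `"counts"`.
#' @param lengths named numeric of per-gene lengths in kilobases (any
#'   common length unit works; only ratios matter). Must cover all genes
#'   and be strictly positive.
#' @return An [ExpressionMatrix-class] with unit `"log2TPM"`.
#' @examples
#' m <- matrix(c(10, 30), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' x <- ExpressionMatrix(m, "counts")
#' exprValues(countsToLogTPM(x, c(a = 1, b = 1)))
#' @export
countsToLogTPM <- function(counts, lengths) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (exprUnit(counts) != "counts")
    stop("countsToLogTPM expects an ExpressionMatrix with unit 'counts'")
  v <- exprValues(counts)
  lengths <- lengths[rownames(v)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive and cover all genes")
  rate <- v / lengths
  tot <- colSums(rate)
  bad <- tot <= 0
  if (any(bad))
    stop("zero total count in sample(s): ",
         paste(colnames(v)[bad], collapse = ", "))
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  ExpressionMatrix(log2(tpm + 1), "log2TPM")
}

#' Linear TPM from counts (no log transform)
#'
#' Same normalization as [countsToLogTPM()] but returning linear TPM, the
#' scale on which mixture additivity holds for deconvolution.
#' @inheritParams countsToLogTPM
#' @return An [ExpressionMatrix-class] with unit `"TPM"`.
#' @export
countsToTPM <- function(counts, lengths) {
  lg <- countsToLogTPM(counts, lengths)
  ExpressionMatrix(2^exprValues(lg) - 1, "TPM")
}

#' Keep the most variable genes by median absolute deviation
#'
#' Retains the `nTop` genes with the largest MAD across samples, a robust
#' feature-selection step ahead of factorization. Ties are broken by gene id
#' lexical order so the selection is deterministic.
#'
#' @param x an [ExpressionMatrix-class] (any unit).
#' @param nTop number of genes to retain; must not exceed the gene count.
#' @return The filtered [ExpressionMatrix-class], genes in original order.
#' @export
filterVariableGenes <- function(x, nTop) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  if (nTop > nrow(v)) stop("nTop exceeds the number of genes")
  mads <- apply(v, 1, stats::mad)
  ord <- order(-mads, rownames(v), method = "radix")
  keep <- sort(ord[seq_len(nTop)])
  ExpressionMatrix(v[keep, , drop = FALSE], exprUnit(x))
}
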