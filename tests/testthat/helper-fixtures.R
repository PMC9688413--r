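# Shared fixtures, built once per test run.

# small default cohort reused across module tests (full defaults are only
# exercised in the acceptance suite)
.fx <- new.env()

smallCohort <- function() {
  if (is.null(.fx$cohort))
    .fx$cohort <- generateCohort(
      cohortConfig(nSamples = 72L, nGenes = 600L, seed = 7L))
  .fx$cohort
}

smallLogTPM <- function() {
  if (is.null(.fx$logtpm)) {
    co <- smallCohort()
    .fx$logtpm <- countsToLogTPM(co$counts, co$geneLengths)
  }
  .fx$logtpm
}

smallTPM <- function() {
  if (is.null(.fx$tpm)) {
    co <- smallCohort()
    .fx$tpm <- countsToTPM(co$counts, co$geneLengths)
  }
  .fx$tpm
}

randomExprMatrix <- function(nGenes = 30, nSamples = 12, seed = 1,
                             unit = "log2TPM") {
  set.seed(seed)
  m <- matrix(abs(stats::rnorm(nGenes * nSamples, 4, 2)), nGenes, nSamples,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  ExpressionMatrix(m, unit)
}

# independent brute-force cophenetic distances: walk the hclust merge
# matrix tracking cluster membership; the cophenetic distance of a pair is
# the height at which they first share a cluster
bruteCophenetic <- function(hc) {
  n <- length(hc$order)
  members <- lapply(seq_len(n), identity)
  D <- matrix(NA_real_, n, n)
  clusters <- list()
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(idx) if (idx < 0) -idx else clusters[[idx]]
    a <- pick(hc$merge[s, 1]); b <- pick(hc$merge[s, 2])
    for (i in a) for (j in b) D[i, j] <- D[j, i] <- hc$height[s]
    clusters[[s]] <- c(a, b)
  }
  stats::as.dist(D)
}

# direct-summation ssGSEA oracle: explicit loop over ranked positions
ssgseaOracle <- function(expr, geneSet, alpha = 0.25) {
  r <- rank(expr, ties.method = "average")
  ord <- order(-expr, names(expr), method = "radix")
  genes <- names(expr)[ord]
  inSet <- genes %in% geneSet
  wsum <- sum(r[ord][inSet]^alpha)
  nOut <- sum(!inSet)
  pin <- 0; pout <- 0; total <- 0
  for (i in seq_along(genes)) {
    if (inSet[i]) pin <- pin + r[ord][i]^alpha / wsum
    else pout <- pout + 1 / nOut
    total <- total + (pin - pout)
  }
  unname(total)
}

# brute-force Benjamini-Hochberg step-up
bruteBH <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[ord[i]] * n / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# hand product-limit estimator for small datasets
bruteKM <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), survival = numeric(0))
  for (t in ts) {
    nRisk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / nRisk)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

adjustedRand <- function(a, b) {
  t <- table(a, b); n <- sum(t)
  sc <- function(x) sum(choose(x, 2))
  e <- sc(rowSums(t)) * sc(colSums(t)) / choose(n, 2)
  (sc(as.vector(t)) - e) / ((sc(rowSums(t)) + sc(colSums(t))) / 2 - e)
}
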