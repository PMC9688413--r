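test_that("a pure reference column deconvolves to a unit fraction", {
  co <- smallCohort()
  sig <- co$truth$signatureMatrix
  f <- estimateFractions(sig[, "epithelial"], sig)
  expect_equal(unname(f), c(1, 0, 0, 0), tolerance = 1e-9)
})

test_that("a constructed two-component mixture is recovered exactly", {
  co <- smallCohort()
  sig <- co$truth$signatureMatrix
  bulk <- 0.6 * sig[, "epithelial"] + 0.4 * sig[, "immune"]
  f <- estimateFractions(bulk, sig)
  expect_equal(unname(f), c(0.6, 0, 0, 0.4), tolerance = 1e-6)
  expect_error(estimateFractions(bulk * 0, sig), "zero")
})

test_that("cohort fractions are recovered within tolerance at default noise", {
  co <- smallCohort()
  tpm <- smallTPM()
  fr <- estimateFractionsMatrix(tpm, co$truth$signatureMatrix)
  expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)), tolerance = 1e-9)
  expect_true(all(fr >= 0))
  mae <- mean(abs(fr - co$truth$fractions))
  expect_lt(mae, 0.08)
})

test_that("groupwise purification recovers planted epithelial profiles", {
  co <- smallCohort()
  truth <- co$truth
  # noise-free: expected bulk with true fractions
  idx <- which(truth$labels == "A")
  P <- groupwiseExpression(truth$expectedBulk[, idx],
                           truth$fractions[idx, ])
  expect_true(all(P >= 0))
  planted <- rowMeans(truth$epithelialExpected[, idx])
  r <- cor(P[, "epithelial"], planted)
  expect_gt(r, 0.95)
})

test_that("a single-cell-type group returns the mean bulk and a warning", {
  set.seed(4)
  bulk <- matrix(runif(80, 1, 5), 10, 8,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  fr <- cbind(epithelial = rep(1, 8), fibroblast = 0, endothelial = 0,
              immune = 0)
  expect_warning(P <- groupwiseExpression(bulk, fr), "constant")
  expect_equal(unname(P[, "epithelial"]), unname(rowMeans(bulk)),
               tolerance = 1e-8)
  expect_error(groupwiseExpression(bulk[, 1:5], fr[1:5, ]), "8 samples")
})

test_that("per-sample epithelial estimates honor the residual attribution", {
  set.seed(6)
  G <- 12
  P <- matrix(runif(G * 4, 1, 4), G, 4,
              dimnames = list(paste0("g", 1:G),
                              c("epithelial", "fibroblast", "endothelial",
                                "immune")))
  fr <- matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4,
               dimnames = list("s1", colnames(P)))
  bulkExact <- P %*% t(fr)
  est <- epithelialPerSample(bulkExact, fr, list(grp = P), "grp")
  # zero residual -> group profile
  expect_equal(unname(est$epithelial[, 1]), unname(P[, "epithelial"]),
               tolerance = 1e-9)
  # pure epithelial sample -> bulk itself
  frPure <- matrix(c(1, 0, 0, 0), 1, 4,
                   dimnames = list("s1", colnames(P)))
  bulkPure <- P %*% t(frPure)
  est2 <- epithelialPerSample(bulkPure + 0.5, frPure, list(grp = P), "grp")
  expect_equal(unname(est2$epithelial[, 1]), unname(bulkPure[, 1] + 0.5),
               tolerance = 1e-9)
  # low epithelial fraction flags low confidence
  frLow <- matrix(c(0.03, 0.4, 0.17, 0.4), 1, 4,
                  dimnames = list("s1", colnames(P)))
  est3 <- epithelialPerSample(bulkExact, frLow, list(grp = P), "grp")
  expect_true(est3$lowConfidence[1])
})

test_that("planted epithelial NE gradient survives per-sample purification", {
  co <- smallCohort()
  tpm <- smallTPM()
  labs <- as.character(co$truth$labels)
  dec <- deconvolveCohort(tpm, co$truth$signatureMatrix, labs)
  epi <- epithelialProfiles(dec)
  sets <- geneSets(co$truth$geneSets)
  grad <- colMeans(log2(epi[sets$nonNE, ] + 1)) -
    colMeans(log2(epi[sets$NE, ] + 1))
  rho <- cor(grad, co$truth$nePosition[match(colnames(epi),
                                             rownames(co$truth$fractions))],
             method = "spearman")
  expect_gte(rho, 0.7)
})

test_that("Welch DE ranks a single planted gene first", {
  set.seed(8)
  G <- 50; n <- 10
  A <- matrix(rnorm(G * n, 5), G, n,
              dimnames = list(paste0("g", 1:G), paste0("a", 1:n)))
  B <- matrix(rnorm(G * n, 5), G, n,
              dimnames = list(paste0("g", 1:G), paste0("b", 1:n)))
  A["g7", ] <- A["g7", ] + 5
  de <- epithelialDE(A, B, nClassifier = 10)
  expect_equal(de$table$gene[1], "g7")
  expect_true("g7" %in% de$upA)
  expect_error(epithelialDE(A[, 1:2], B), "3 samples")
})

test_that("identical groups yield null t statistics", {
  set.seed(9)
  A <- matrix(rnorm(60, 5), 20, 3,
              dimnames = list(paste0("g", 1:20), paste0("a", 1:3)))
  de <- epithelialDE(A, A)
  expect_true(all(abs(de$table$t) < 1e-12))
})

test_that("BH adjustment equals the brute-force step-up on 20 genes", {
  set.seed(10)
  p <- runif(20)^2
  expect_equal(stats::p.adjust(p, "BH"), bruteBH(p), tolerance = 1e-12)
  # and the DE table uses the same correction
  A <- matrix(rnorm(20 * 5, 5), 20, 5,
              dimnames = list(paste0("g", 1:20), paste0("a", 1:5)))
  B <- matrix(rnorm(20 * 5, 5.5), 20, 5,
              dimnames = list(paste0("g", 1:20), paste0("b", 1:5)))
  de <- epithelialDE(A, B)
  ord <- match(de$table$gene, rownames(A))
  expect_equal(de$table$fdr, bruteBH(de$table$p), tolerance = 1e-12)
})

test_that("M/I scores are antisymmetric under list swap", {
  x <- randomExprMatrix(20, 6, seed = 11)
  cls <- list(mUp = paste0("g", sprintf("%02d", 1:5)),
              iUp = paste0("g", sprintf("%02d", 6:10)))
  s1 <- miIntrinsicScores(x, cls)
  s2 <- miIntrinsicScores(x, list(mUp = cls$iUp, iUp = cls$mUp))
  expect_equal(s1$diff, -s2$diff, tolerance = 1e-12)
  # all-1 M genes, all-0 I genes -> diff exactly 1
  m <- matrix(0, 10, 2, dimnames = list(paste0("g", sprintf("%02d", 1:10)),
                                        c("s1", "s2")))
  m[1:5, ] <- 1
  s3 <- miIntrinsicScores(ExpressionMatrix(m, "log2TPM"), cls)
  expect_equal(s3$diff, c(1, 1))
  expect_error(miIntrinsicScores(x, list(mUp = "zz", iUp = "yy")),
               "neither")
  expect_error(miIntrinsicScores(x, list(mUp = "g01", iUp = "g01")),
               "disjoint")
})

test_that("gene-diff correlations hit closed-form values", {
  d <- c(1, 3, 2, 5, 4)
  x <- rbind(same = d, opp = -d, flat = rep(1, 5),
             other = c(2, 1, 4, 3, 5))
  colnames(x) <- paste0("s", 1:5)
  out <- geneDiffCorrelation(x, d)
  expect_equal(out$r[out$gene == "same"], 1, tolerance = 1e-12)
  expect_equal(out$r[out$gene == "opp"], -1, tolerance = 1e-12)
  expect_false("flat" %in% out$gene)    # zero variance skipped
  r <- cor(x["other", ], d)
  expect_equal(out$r[out$gene == "other"], r, tolerance = 1e-12)
  expect_error(geneDiffCorrelation(x[, 1:3], d[1:3]), "4 samples")
})

test_that("GSEA running sum is internally consistent and matches fgsea", {
  set.seed(12)
  stats_ <- stats::setNames(sort(rnorm(60), decreasing = TRUE),
                            paste0("g", 1:60))
  gs <- paste0("g", c(2, 5, 8, 11, 14))
  out <- celltypeGSEA(stats_, gs, nPerm = 200, seed = 1)
  # direct running-sum recomputation
  inSet <- names(stats_) %in% gs
  w <- abs(stats_)
  run <- cumsum(ifelse(inSet, w, 0)) / sum(w[inSet]) -
    cumsum(!inSet) / sum(!inSet)
  expect_equal(unname(out$runningSum), unname(run), tolerance = 1e-12)
  expect_equal(out$es, run[which.max(abs(run))], tolerance = 1e-12)
  expect_lt(out$p, 0.05)   # top-loaded set is significant
  skip_if_not_installed("fgsea")
  esF <- fgsea::calcGseaStat(stats_, which(inSet), gseaParam = 1)
  expect_equal(out$es, esF, tolerance = 1e-9)
})

test_that("random gene sets give near-uniform GSEA p-values", {
  set.seed(13)
  stats_ <- stats::setNames(rnorm(80), paste0("g", 1:80))
  ps <- replicate(60, {
    gs <- sample(names(stats_), 8)
    celltypeGSEA(stats_, gs, nPerm = 99,
                 seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("opposed M/I programs give anti-correlated scores", {
  set.seed(14)
  n <- 40
  axis <- rnorm(n)                       # latent mesenchymal-ness
  mGenes <- paste0("m", 1:10); iGenes <- paste0("i", 1:10)
  X <- rbind(
    t(sapply(mGenes, function(g) 5 + axis + rnorm(n, 0, 0.5))),
    t(sapply(iGenes, function(g) 5 - axis + rnorm(n, 0, 0.5))))
  colnames(X) <- paste0("s", 1:n)
  sc <- miIntrinsicScores(X, list(mUp = mGenes, iUp = iGenes))
  expect_lt(cor(sc$m_score, sc$i_score), 0)
})
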