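test_that("MI of a variable with itself equals the binned entropy", {
  x <- 1:16                      # distinct values, 4 equal-frequency bins
  expect_equal(mutualInformation(x, x, nBins = 4), log(4))
  expect_equal(mutualInformation(rep(1, 10), rnorm(10)), 0)
})

test_that("MI matches a hand-built 3x3 contingency computation", {
  # 9 observations landing on a known 3x3 joint with 3 bins each
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  y <- c(1, 2, 3, 5, 4, 6, 8, 9, 7)   # permuted within bins of 3
  # equal-frequency bins of size 3: joint is diagonal -> MI = log(3)
  expect_equal(mutualInformation(x, y, nBins = 3), log(3))
  # hand case with off-diagonal mass
  y2 <- c(1, 2, 4, 3, 5, 7, 6, 8, 9)  # one swap across the 1-2 bin border
  tab <- table(ceiling(rank(x, ties.method = "first") * 3 / 9),
               ceiling(rank(y2, ties.method = "first") * 3 / 9)) / 9
  byHand <- sum(tab[tab > 0] *
                  log(tab[tab > 0] /
                        (outer(rowSums(tab), colSums(tab))[tab > 0])))
  expect_equal(mutualInformation(x, y2, nBins = 3), byHand)
})

test_that("MI is non-negative and small for independent data", {
  set.seed(21)
  x <- rnorm(1000); y <- sample(x)
  miObs <- mutualInformation(x, y)
  null <- replicate(50, mutualInformation(x, sample(y)))
  expect_gte(miObs, 0)
  expect_lt(miObs, quantile(null, 0.95) + 0.05)
})

test_that("network recovery finds a planted regulator's targets", {
  set.seed(31)
  n <- 120
  reg <- rnorm(n)
  targets <- sapply(1:30, function(i) reg * runif(1, 0.7, 1.2) +
                      rnorm(n, 0, 0.6))
  noise <- matrix(rnorm(n * 100), 100, n)
  V <- rbind(t(cbind(reg, targets)), noise)
  rownames(V) <- c("REG", paste0("T", 1:30), paste0("N", 1:100))
  colnames(V) <- paste0("s", 1:n)
  V <- V - min(V)
  edges <- buildNetwork(V, "REG", nPerm = 200, seed = 5)
  hit <- mean(paste0("T", 1:30) %in% edges$target)
  expect_gte(hit, 0.8)
  # determinism
  edges2 <- buildNetwork(V, "REG", nPerm = 200, seed = 5)
  expect_identical(edges$target, edges2$target)
  expect_error(buildNetwork(V, character(0)), "empty")
})

test_that("an uncorrelated regulator keeps spurious edges near the q level", {
  set.seed(41)
  V <- matrix(rnorm(200 * 120), 200, 120,
              dimnames = list(c("REG", paste0("g", 1:199)), NULL))
  colnames(V) <- paste0("s", 1:120)
  edges <- buildNetwork(V, "REG", nPerm = 400, fdrQ = 0.05, seed = 2)
  expect_lte(nrow(edges), 0.12 * 199)   # ~5% expected, allow sampling slack
})

test_that("DPI removes the weakest triangle edge and is idempotent", {
  tri <- data.frame(regulator = c("a", "b", "a"),
                    target = c("b", "c", "c"),
                    mi = c(3, 2, 1))
  pruned <- dpiPrune(tri, tolerance = 0)
  expect_equal(nrow(pruned), 2)
  expect_false(any(pruned$mi == 1))
  expect_identical(dpiPrune(pruned, 0), pruned)    # idempotent
  expect_identical(dpiPrune(tri, tolerance = 1), tri)  # disabled
  expect_lte(nrow(dpiPrune(tri, 0.5)), nrow(tri))
})

test_that("DPI removes the indirect edge of a planted chain", {
  set.seed(51)
  n <- 300
  a <- rnorm(n); b <- a + rnorm(n, 0, 0.4); c <- b + rnorm(n, 0, 0.4)
  edges <- data.frame(
    regulator = c("a", "b", "a"),
    target = c("b", "c", "c"),
    mi = c(mutualInformation(a, b), mutualInformation(b, c),
           mutualInformation(a, c)))
  pruned <- dpiPrune(edges, tolerance = 0)
  expect_false(any(pruned$regulator == "a" & pruned$target == "c"))
  expect_equal(nrow(pruned), 2)
})

test_that("Fisher enrichment equals the closed-form hypergeometric tail", {
  # all 5 subtype genes inside the 5 targets: p = 1 / C(20,5)
  u <- paste0("g", 1:20)
  row <- regulonEnrichment(u[1:5], u[1:5], u)
  expect_equal(row$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(row$overlap, 5)
  # zero overlap in a big universe: upper tail includes >= 0 -> p = 1
  u2 <- paste0("g", 1:1000)
  row2 <- regulonEnrichment(u2[1:3], u2[4:6], u2)
  expect_gt(row2$p_value, 0.98)
  expect_error(regulonEnrichment("a", "b", character(0)), "universe")
})

test_that("Fisher p agrees with exhaustive enumeration for small universes", {
  for (s in 1:20) {
    set.seed(s)
    N <- sample(10:30, 1)
    u <- paste0("g", seq_len(N))
    A <- sample(u, sample(2:6, 1))
    B <- sample(u, sample(2:8, 1))
    row <- regulonEnrichment(A, B, u)
    ov <- length(intersect(A, B))
    # enumerate the hypergeometric upper tail from binomial coefficients
    kMax <- min(length(A), length(B))
    pEnum <- sum(vapply(ov:kMax, function(k)
      choose(length(B), k) * choose(N - length(B), length(A) - k), 0)) /
      choose(N, length(A))
    expect_equal(row$p_value, pEnum, tolerance = 1e-12)
  }
})

test_that("the planted EMT regulator tops mesenchymal enrichment", {
  co <- smallCohort()
  lg <- smallLogTPM()
  sets <- geneSets(co$truth$geneSets)
  universe <- rownames(exprValues(lg))
  regulons <- list(
    YAP1L = new("Regulon", regulator = "YAP1L",
                targets = sets$YAP1L_targets,
                weights = stats::setNames(rep(1, length(sets$YAP1L_targets)),
                                          sets$YAP1L_targets)),
    ASCL1L = new("Regulon", regulator = "ASCL1L",
                 targets = sets$ASCL1L_targets,
                 weights = stats::setNames(rep(1, length(sets$ASCL1L_targets)),
                                           sets$ASCL1L_targets)))
  # mesenchymal subtype genes from a supervised contrast (top mean diff)
  v <- exprValues(lg)
  labs <- co$truth$labels
  d <- rowMeans(v[, labs == "M"]) - rowMeans(v[, labs != "M"])
  mGenes <- names(sort(d, decreasing = TRUE))[1:100]
  tab <- enrichmentTable(list(M = mGenes), regulons, universe)
  expect_equal(tab$regulator[which.min(tab$p_value)], "YAP1L")
})
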