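test_that("KM estimator matches hand product-limit computations", {
  # all events at times 1, 2, 3 -> S = 2/3, 1/3, 0
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # no events -> survival constant at 1
  km2 <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$survival == 1))
  # moving a post-last-event censoring time further out changes nothing
  kmA <- kmEstimate(c(1, 2, 3, 3.5), c(1, 1, 1, 0))
  kmB <- kmEstimate(c(1, 2, 3, 9), c(1, 1, 1, 0))
  expect_equal(kmA$survival[kmA$n_event > 0],
               kmB$survival[kmB$n_event > 0])
  expect_error(kmEstimate(c(0, 1), c(1, 1)), "positive")
})

test_that("KM matches brute-force product-limit on random small datasets", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:8, 1)
    time <- round(rexp(n, 0.2) + 0.5, 1)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    km <- kmEstimate(time, event)
    manual <- bruteKM(time, event)
    got <- km[km$n_event > 0, c("time", "survival")]
    expect_equal(got$time, manual$time)
    expect_equal(got$survival, manual$survival, tolerance = 1e-12)
  }
})

test_that("log-rank is null for identical groups and matches hand values", {
  t2 <- c(1, 2, 3, 1, 2, 3)
  e2 <- c(1, 0, 1, 1, 0, 1)
  g2 <- rep(c("a", "b"), each = 3)
  lr <- logrankTest(t2, e2, g2)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  expect_equal(lr$df, 1)

  # hand-computed 2-group example (6 records, distinct event times)
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 1, 1)
  grp <- c("a", "b", "a", "b", "a", "b")
  # observed a events = 3; expected from risk sets:
  # t=1: 3/6, t=2: 2/5, t=3: 2/4, t=4: 1/3, t=5: 1/2, t=6: 0/1
  expA <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 1 / 2 + 0
  varA <- sum(c(3 * 3 / 36, 2 * 3 / 25, 2 * 2 / 16, 1 * 2 / 9,
                1 * 1 / 4, 0))
  chi2hand <- (3 - expA)^2 / varA
  lr2 <- logrankTest(time, event, grp)
  expect_equal(lr2$chi2, chi2hand, tolerance = 1e-8)

  # invariance under group relabeling
  lr3 <- logrankTest(time, event, rev(grp))
  expect_equal(lr2$chi2,
               logrankTest(time, event, c("x", "y")[match(grp, c("a", "b"))])$chi2)
  expect_error(logrankTest(time, event, rep("a", 6)), "2 non-empty")
})

test_that("planted subtype hazards are detected with high power at n = 200", {
  hits <- 0L
  for (s in 1:15) {
    co <- generateCohort(cohortConfig(nSamples = 200L, nGenes = 600L,
                                      seed = 1000L + s))
    cl <- co$clinical
    lr <- logrankTest(cl$os_time, cl$os_event, cl$subtype)
    hits <- hits + (lr$p < 0.05)
  }
  expect_gte(hits / 15, 0.9)
})

test_that("H-score is the proportion-intensity product with range checks", {
  expect_equal(hScore(100, 3), 300)
  expect_equal(hScore(0, 2), 0)
  expect_equal(hScore(50, 2), 100)
  expect_error(hScore(120, 2), "proportion")
  expect_error(hScore(50, 5), "intensity")
})

test_that("CD8 score is the mean of exactly five fields", {
  expect_equal(cd8Score(c(10, 10, 10, 10, 10)), 10)
  expect_equal(cd8Score(c(0, 0, 0, 0, 5)), 1)
  expect_equal(cd8Score(c(3, 1, 4, 1, 5)), cd8Score(c(5, 4, 3, 1, 1)))
  expect_error(cd8Score(c(1, 2, 3)), "five")
  m <- matrix(1:10, 2, 5)
  expect_equal(cd8Score(m), rowMeans(m))
})

test_that("Mann-Whitney exact p matches full enumeration", {
  out <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(out$U, 0)
  expect_equal(out$p, 2 / choose(4, 2))   # 1/3: the two extreme splits
  same <- mannWhitneyU(c(5, 1, 3), c(5, 1, 3))
  expect_equal(same$p, 1)
  # independent oracle: wilcox.test exact on tie-free data
  for (s in 1:10) {
    set.seed(s)
    a <- rnorm(5); b <- rnorm(6)
    out <- mannWhitneyU(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(out$U, unname(ref$statistic))
    expect_equal(out$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p at n = 12 + 12", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12, 0.5)
    # exact reference from the Wilcoxon distribution (tie-free data)
    exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    approx <- mannWhitneyU(a, b)$p     # n = 24 -> normal approximation
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("IHC classification follows the vimentin/CD8 rule and partitions", {
  rec <- data.frame(
    sample_id = paste0("s", 1:4),
    vimentin_proportion = c(0, 50, 60, 0),
    vimentin_intensity = c(0L, 2L, 1L, 3L),
    cd8_f1 = c(9, 1, 30, 2), cd8_f2 = c(9, 2, 30, 2),
    cd8_f3 = c(9, 1, 30, 2), cd8_f4 = c(9, 2, 30, 2),
    cd8_f5 = c(9, 1, 30, 2))
  out <- ihcClassify(rec)
  expect_equal(out$call[1], "other")    # vimentin-negative, any CD8
  expect_equal(out$call[4], "other")    # proportion 0 -> h = 0
  expect_equal(out$call[2], "SCLC-M")   # vim+, CD8 below cutoff
  expect_equal(out$call[3], "SCLC-I")
  expect_setequal(unique(out$call), c("other", "SCLC-I", "SCLC-M"))
  expect_equal(out$h_score, rec$vimentin_proportion * rec$vimentin_intensity)
  # absolute cutoff override
  out2 <- ihcClassify(rec, cd8Cutoff = 100)
  expect_true(all(out2$call[c(2, 3)] == "SCLC-M"))
  # degenerate cutoff
  recSame <- rec[c(2, 2), ]
  expect_error(ihcClassify(recSame), "identical")
})

test_that("generated IHC cohorts recover the mesenchymal call", {
  labs <- sample(c("M", "I", "A", "P", "N", "H"), 150, replace = TRUE,
                 prob = c(0.15, 0.2, 0.2, 0.15, 0.2, 0.1))
  rec <- generateIHCCohort(150, labs, seed = 5)
  out <- ihcClassify(rec)
  recall <- mean(out$call[rec$subtype == "M"] == "SCLC-M")
  expect_gte(recall, 0.8)
  # inflamed CD8 exceeds mesenchymal CD8 at n = 50 each
  recI <- generateIHCCohort(50, rep("I", 50), seed = 6)
  recM <- generateIHCCohort(50, rep("M", 50), seed = 7)
  expect_gt(mean(cd8Score(recI[, paste0("cd8_f", 1:5)])),
            mean(cd8Score(recM[, paste0("cd8_f", 1:5)])))
  # determinism and the empty case
  expect_identical(generateIHCCohort(20, labs[1:20], seed = 9),
                   generateIHCCohort(20, labs[1:20], seed = 9))
  expect_equal(nrow(generateIHCCohort(0, character(0))), 0)
  expect_error(generateIHCCohort(3, c("M", "I")), "length")
})
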