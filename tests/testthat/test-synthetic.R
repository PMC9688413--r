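test_that("config validation rejects malformed parameters", {
  expect_error(cohortConfig(subtypeProportions = c(0.5, 0.5, 0, 0, 0, 0.1)),
               "sum to 1")
  expect_error(cohortConfig(fractionDirichlet = matrix(-1, 6, 4)),
               "strictly positive")
  expect_error(cohortConfig(nSamples = 0), "positive")
  expect_error(timeCourseConfig(timepoints = c(4, 4, 7)), "increasing")
  expect_error(timeCourseConfig(nCells = 10, cellsPerTimepoint = rep(1, 6)),
               "sum")
})

test_that("generation is deterministic under a fixed seed", {
  c1 <- generateCohort(cohortConfig(nSamples = 24L, nGenes = 600L, seed = 7L))
  c2 <- generateCohort(cohortConfig(nSamples = 24L, nGenes = 600L, seed = 7L))
  expect_identical(exprValues(c1$counts), exprValues(c2$counts))
  expect_identical(c1$clinical, c2$clinical)
  c3 <- generateCohort(cohortConfig(nSamples = 24L, nGenes = 600L, seed = 8L))
  expect_false(identical(exprValues(c1$counts), exprValues(c3$counts)))
})

test_that("fraction vectors sit exactly on the simplex", {
  co <- smallCohort()
  f <- co$truth$fractions
  expect_true(all(f >= 0))
  expect_equal(unname(rowSums(f)), rep(1, nrow(f)), tolerance = 1e-12)
})

test_that("counts are non-negative integers with NB overdispersion", {
  co <- smallCohort()
  v <- exprValues(co$counts)
  expect_true(all(v >= 0))
  expect_equal(v, round(v))
})

test_that("the Poisson limit brings variance to the mean", {
  # noiseDispersion = Inf and no nuisance factors: var ~= mean per gene
  cfgs <- lapply(1:4, function(s)
    cohortConfig(nSamples = 40L, nGenes = 600L, noiseDispersion = Inf,
                 nNuisanceModules = 0L, seed = 100L + s))
  # identical expectations across replicates of the same sample set are not
  # available, so compare pooled dispersion statistics against an NB cohort
  pois <- generateCohort(cfgs[[1]])
  nb <- generateCohort(cohortConfig(nSamples = 40L, nGenes = 600L,
                                    noiseDispersion = 2,
                                    nNuisanceModules = 0L, seed = 101L))
  disp <- function(co) {
    v <- exprValues(co$counts)
    keep <- rowMeans(v) > 5
    median(apply(v[keep, ], 1, var) / rowMeans(v[keep, ]))
  }
  # Poisson limit: residual var/mean stays near the planted-signal floor;
  # strong NB dispersion inflates it far beyond that floor
  expect_lt(disp(pois), disp(nb) / 2)
})

test_that("NNLS on noise-free expectations recovers planted fractions", {
  co <- smallCohort()
  sig <- co$truth$signatureMatrix
  fr <- t(apply(co$truth$expectedBulk, 2, estimateFractions, sig = sig))
  expect_lt(mean(abs(fr - co$truth$fractions)), 0.05)
})

test_that("program gene sets are disjoint from the housekeeping panel", {
  co <- smallCohort()
  panel <- co$truth$panel
  progGenes <- unlist(geneSets(co$truth$geneSets))
  expect_length(intersect(progGenes, panel$HKG), 0)
})

test_that("raising program effect widens the planted score gap", {
  lo <- generateCohort(cohortConfig(nSamples = 48L, nGenes = 600L,
                                    programEffect = 1, seed = 11L))
  hi <- generateCohort(cohortConfig(nSamples = 48L, nGenes = 600L,
                                    programEffect = 4, seed = 11L))
  gap <- function(co) {
    sets <- geneSets(co$truth$geneSets)
    expr <- log2(co$truth$epithelialExpected + 1)   # noise-free
    sc <- apply(expr, 2, ssgseaScore, geneSet = sets$EMT)
    mean(sc[co$truth$labels == "M"]) - mean(sc[co$truth$labels != "M"])
  }
  expect_gt(gap(hi), gap(lo))
})

test_that("mouse time course carries the NE -> non-NE gradient", {
  co <- smallCohort()
  sets <- geneSets(co$truth$geneSets)
  shared <- unique(c(sets$NE, sets$nonNE, sets$EMT))
  tc <- generateMouseTimecourse(timeCourseConfig(nCells = 240L, seed = 3L),
                                shared)
  expect_equal(dim(tc$umi), c(length(shared), 240L))
  expr <- normalizeUMI(tc$umi)
  neMean <- colMeans(expr[grepl("^neg", rownames(expr)), ])
  emtMean <- colMeans(expr[grepl("^emt|^yap1l|^tazl", rownames(expr)), ])
  expect_lt(cor(neMean, tc$latentTime), -0.5)
  expect_gt(cor(emtMean, tc$latentTime), 0.5)
  expect_gt(cor(tc$latentTime,
                as.numeric(as.character(tc$days)),
                method = "spearman"), 0.8)
  # determinism
  tc2 <- generateMouseTimecourse(timeCourseConfig(nCells = 240L, seed = 3L),
                                 shared)
  expect_identical(as.matrix(tc$umi), as.matrix(tc2$umi))
  expect_error(generateMouseTimecourse(timeCourseConfig(), character(0)),
               "non-empty")
})

test_that("a flat gradient leaves program means level across timepoints", {
  co <- smallCohort()
  sets <- geneSets(co$truth$geneSets)
  shared <- unique(c(sets$NE, sets$nonNE))
  tc <- generateMouseTimecourse(
    timeCourseConfig(nCells = 360L, gradientSharpness = 0, seed = 4L),
    shared)
  expr <- normalizeUMI(tc$umi)
  neMean <- colMeans(expr[grepl("^neg", rownames(expr)), ])
  byDay <- tapply(neMean, tc$days, mean)
  expect_lt(max(byDay) - min(byDay), 0.1)
})

test_that("matched latent times align across species in expectation", {
  co <- generateCohort(cohortConfig(nSamples = 48L, nGenes = 600L,
                                    seed = 13L))
  sets <- geneSets(co$truth$geneSets)
  shared <- unique(c(sets$NE, sets$nonNE, sets$EMT))
  u <- co$truth$nePosition
  hum <- log2(co$truth$epithelialExpected[shared, ] + 1)
  tc <- generateMouseTimecourse(timeCourseConfig(nCells = 120L, seed = 5L),
                                shared)
  mouse <- normalizeUMI(tc$umi)
  # pick human samples at the NE extremes and a mouse cell near each
  hEarly <- which.min(u); hLate <- which.max(u)
  mEarly <- which.min(tc$latentTime); mLate <- which.max(tc$latentTime)
  zl <- function(x) (x - mean(x)) / sd(x)
  cc <- function(i, j) cor(zl(hum[, i]), zl(mouse[, j]))
  expect_gt(cc(hEarly, mEarly), cc(hEarly, mLate))
  expect_gt(cc(hLate, mLate), cc(hLate, mEarly))
})
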