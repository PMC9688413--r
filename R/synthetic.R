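## Synthetic SCLC-like cohort generator.
##
## Emulates the latent structure the analysis assumes: six epithelial
## expression programs (mesenchymal/YAP-TAZ-EMT, inflamed, ASCL1-, POU2F3-
## and NEUROD1-driven, hypoxic), four-cell-type mixing per bulk sample, a
## shared NE -> non-NE continuum between the human-like bulk cohort and a
## mouse-like single-cell time course, subtype-dependent survival and
## subtype-coupled IHC records. All effect sizes are free parameters of the
## config; the defaults are documented in the methods vignette.

.SUBTYPES <- c("M", "I", "A", "P", "N", "H")

# hierarchical seed stream: one global seed, independent per-component seeds
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1000003) %% 2147483647)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Configuration for a synthetic bulk cohort
#'
#' @param nSamples number of tumors.
#' @param nGenes number of genes (>= 600 so every program panel is
#'   represented).
#' @param nSubtypes number of subtypes (fixed at 6 in this generator:
#'   mesenchymal M, inflamed I, ASCL1-like A, POU2F3-like P, NEUROD1-like N,
#'   hypoxic H).
#' @param subtypeProportions simplex vector of subtype prevalences in the
#'   order M, I, A, P, N, H.
#' @param programEffect log2 fold-change magnitude of each subtype's
#'   epithelial program.
#' @param fractionDirichlet 6 x 4 matrix of Dirichlet parameters over
#'   (epithelial, fibroblast, endothelial, immune) per subtype; all
#'   strictly positive. Mesenchymal and inflamed rows share the fibroblast
#'   parameter (their stromal signal is comparable by construction).
#' @param noiseDispersion negative-binomial size parameter for counts;
#'   `Inf` gives the Poisson limit.
#' @param nNuisanceModules number of sparse nuisance co-expression modules
#'   (stress/proliferation/metabolism-like programs that vary continuously
#'   across tumors, cross-cutting the subtypes); 0 disables them.
#' @param nuisanceModuleSize genes per nuisance module (drawn from the
#'   housekeeping panel).
#' @param nuisanceModuleSd log2 standard deviation of a module's activity
#'   contribution per member gene.
#' @param subtypeCoupling strength (0-1) at which transcriptionally
#'   adjacent subtypes express each other's programs: the NE pair (A, N)
#'   and the non-NE pair (P, M).
#' @param survivalHazards per-subtype exponential event rates per month
#'   (M and H worse by default).
#' @param seed integer; drives a hierarchical stream of per-component seeds.
#' @return A list of class `cohortConfig`.
#' @export
cohortConfig <- function(nSamples = 120L, nGenes = 1000L, nSubtypes = 6L,
                         subtypeProportions = c(0.10, 0.20, 0.23, 0.15,
                                                0.22, 0.10),
                         programEffect = 4,
                         fractionDirichlet = rbind(
                           M = c(80, 24, 8, 12),
                           I = c(120, 36, 12, 72),
                           A = c(120, 16, 8, 16),
                           P = c(120, 16, 8, 16),
                           N = c(120, 16, 8, 16),
                           H = c(104, 20, 8, 16)),
                         noiseDispersion = 10,
                         nNuisanceModules = 8L, nuisanceModuleSize = 25L,
                         nuisanceModuleSd = 1, subtypeCoupling = 0,
                         survivalHazards = c(M = 0.09, I = 0.030, A = 0.035,
                                             P = 0.040, N = 0.035, H = 0.08),
                         seed = 7L) {
  if (nSubtypes != 6L)
    stop("this generator models exactly six subtypes")
  if (nSamples <= 0 || nGenes <= 0) stop("counts must be positive")
  if (nGenes < 600) stop("nGenes must be at least 600")
  if (abs(sum(subtypeProportions) - 1) > 1e-9)
    stop("subtypeProportions must sum to 1")
  if (any(subtypeProportions < 0))
    stop("subtypeProportions must be non-negative")
  if (any(fractionDirichlet <= 0))
    stop("Dirichlet parameters must be strictly positive")
  if (noiseDispersion <= 0) stop("noiseDispersion must be positive")
  if (nNuisanceModules < 0 || nuisanceModuleSize < 1 || nuisanceModuleSd < 0)
    stop("nuisance-module parameters out of range")
  structure(list(nSamples = as.integer(nSamples),
                 nGenes = as.integer(nGenes), nSubtypes = 6L,
                 subtypeProportions = subtypeProportions,
                 programEffect = programEffect,
                 fractionDirichlet = fractionDirichlet,
                 noiseDispersion = noiseDispersion,
                 nNuisanceModules = as.integer(nNuisanceModules),
                 nuisanceModuleSize = as.integer(nuisanceModuleSize),
                 nuisanceModuleSd = nuisanceModuleSd,
                 subtypeCoupling = subtypeCoupling,
                 survivalHazards = survivalHazards,
                 seed = as.integer(seed)),
            class = "cohortConfig")
}

# Partition gene ids into program / marker / housekeeping panels.
.genePanel <- function(nGenes) {
  sz <- function(p, min) max(min, round(p * nGenes))
  n_emt <- sz(0.06, 30); n_imm <- sz(0.06, 30)
  n_a <- sz(0.05, 25); n_p <- sz(0.05, 25); n_n <- sz(0.05, 25)
  n_h <- sz(0.05, 25)
  n_ne <- sz(0.05, 25); n_nng <- sz(0.04, 20)
  n_fib <- sz(0.04, 20); n_end <- sz(0.03, 15); n_epm <- sz(0.025, 12)
  ids <- function(pre, n) sprintf("%s%03d", pre, seq_len(n))
  panel <- list(
    EMT = c("YAP1L", "TAZL", ids("EMT", n_emt - 2)),
    IMM = ids("IMM", n_imm),
    APR = c("ASCL1L", ids("ASC", n_a - 1)),
    PPR = c("POU2F3L", ids("POU", n_p - 1)),
    NPR = c("NEUROD1L", ids("NDT", n_n - 1)),
    HYP = ids("HYP", n_h),
    NEG = ids("NEG", n_ne),
    NNG = ids("NNG", n_nng),
    FIB = ids("FIB", n_fib),
    END = ids("END", n_end),
    EPM = ids("EPM", n_epm))
  used <- length(unlist(panel))
  panel$HKG <- ids("HKG", nGenes - used)
  panel
}

#' Generate a synthetic bulk SCLC-like cohort
#'
#' Draws subtype labels, a latent NE position per tumor on \[0,1\]
#' (NE-like subtypes early, non-NE-like late), per-sample epithelial
#' profiles carrying the subtype programs and the NE gradient, fixed
#' fibroblast/endothelial/immune reference profiles, Dirichlet cell-type
#' fractions, negative-binomial counts around the length-weighted mixture
#' expectation, exponential survival with subtype hazards and independent
#' right-censoring, and IHC records coupled to subtype.
#'
#' @param config a [cohortConfig()].
#' @return A list with elements `counts` ([ExpressionMatrix-class],
#'   unit counts), `geneLengths` (named, kb), `truth` (ground-truth list:
#'   labels, fractions, nePosition, geneSets, regulators, signatureMatrix,
#'   cellProfiles, epithelialExpected, expectedBulk) and `clinical`
#'   (data.frame with survival and IHC columns).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  n <- config$nSamples; G <- config$nGenes
  eff <- config$programEffect
  panel <- .genePanel(G)
  genes <- unlist(panel, use.names = FALSE)
  samples <- sprintf("S%03d", seq_len(n))

  set.seed(.childSeed(config$seed, 1L))
  base <- stats::setNames(exp(stats::rnorm(G, 1.0, 1.0)), genes)
  wgt <- stats::setNames(stats::runif(G, 0.6, 1.0), genes)
  wgt[c("YAP1L", "TAZL", "ASCL1L", "POU2F3L", "NEUROD1L")] <- 1.0
  lengths <- stats::setNames(exp(stats::rnorm(G, log(1.5), 0.4)), genes)

  # non-epithelial reference profiles (sample-independent)
  lift <- function(prof, set, lfc) {
    prof[set] <- prof[set] * 2^(lfc * wgt[set]); prof
  }
  epiBaseline <- lift(base, panel$EPM, 4)
  fib <- lift(base, panel$FIB, 4.5)
  endo <- lift(base, panel$END, 4.5)
  immc <- lift(base, panel$IMM, 5)
  normTot <- function(p) p / sum(p) * length(p)
  fib <- normTot(fib); endo <- normTot(endo); immc <- normTot(immc)

  set.seed(.childSeed(config$seed, 2L))
  labels <- factor(sample(.SUBTYPES, n, replace = TRUE,
                          prob = config$subtypeProportions),
                   levels = .SUBTYPES)
  # evenly spaced positions on the NE -> non-NE axis (A/N early, I/H
  # intermediate, P/M late)
  neMean <- c(M = 0.90, I = 0.42, A = 0.10, P = 0.74, N = 0.26, H = 0.58)
  u <- .clamp(stats::rnorm(n, neMean[as.character(labels)], 0.04),
              0.01, 0.99)
  # program activities: ~1 within the subtype, ~0 outside, with jitter so
  # regulator-target co-variation is continuous
  progOf <- c(M = "EMT", I = "IMM", A = "APR", P = "PPR", N = "NPR",
              H = "HYP")
  act <- sapply(names(progOf), function(s)
    .clamp((labels == s) + stats::rnorm(n, 0, 0.05), -0.3, 1.3))
  # transcriptional adjacency: NE siblings (A, N) and non-NE siblings
  # (P, M) each express the sibling's program at reduced strength
  sib <- c(A = "N", N = "A", P = "M", M = "P")
  cpl <- config$subtypeCoupling
  if (cpl > 0) {
    actRaw <- act
    for (s in names(sib))
      act[, s] <- .clamp(actRaw[, s] + cpl * actRaw[, sib[s]], -0.3, 1.3)
  }

  set.seed(.childSeed(config$seed, 3L))
  fracs <- matrix(NA_real_, n, 4,
                  dimnames = list(samples, c("epithelial", "fibroblast",
                                             "endothelial", "immune")))
  for (s in .SUBTYPES) {
    idx <- which(labels == s)
    if (length(idx))
      fracs[idx, ] <- .rdirichlet(length(idx),
                                  config$fractionDirichlet[s, ])
  }

  neAmp <- 2.25
  epiExp <- matrix(NA_real_, G, n, dimnames = list(genes, samples))
  for (i in seq_len(n)) {
    p <- epiBaseline
    for (s in names(progOf)) {
      g <- panel[[progOf[s]]]
      e <- if (s == "I") 1.0 else eff   # inflamed epithelial program is weak
      p[g] <- p[g] * 2^(e * act[i, s] * wgt[g])
    }
    p[panel$NEG] <- p[panel$NEG] * 2^(neAmp * (0.5 - u[i]) * 2 * wgt[panel$NEG])
    p[panel$NNG] <- p[panel$NNG] * 2^(neAmp * (u[i] - 0.5) * 2 * wgt[panel$NNG])
    p[panel$EMT] <- p[panel$EMT] * 2^(1.0 * (u[i] - 0.5) * 2 * wgt[panel$EMT])
    epiExp[, i] <- normTot(p)
  }

  others <- cbind(fibroblast = fib, endothelial = endo, immune = immc)
  bulkExp <- epiExp %*% diag(fracs[, 1]) + others %*% t(fracs[, -1])
  dimnames(bulkExp) <- list(genes, samples)

  # sparse nuisance co-expression modules on housekeeping genes: per-sample
  # continuous activities cross-cutting the subtypes, as stress /
  # proliferation / metabolic programs are in real cohorts
  if (config$nNuisanceModules > 0 && config$nuisanceModuleSd > 0) {
    set.seed(.childSeed(config$seed, 7L))
    for (m in seq_len(config$nNuisanceModules)) {
      gm <- sample(panel$HKG, min(config$nuisanceModuleSize,
                                  length(panel$HKG)))
      loadM <- stats::runif(length(gm), 0.5, 1)
      actM <- stats::rnorm(n)
      bulkExp[gm, ] <- bulkExp[gm, ] *
        2^(config$nuisanceModuleSd * outer(loadM, actM))
    }
  }

  set.seed(.childSeed(config$seed, 4L))
  lib <- round(stats::runif(n, 2e6, 4e6))
  rate <- bulkExp * lengths           # reads proportional to level x length
  mu <- sweep(rate, 2, colSums(rate), "/") %*% diag(lib)
  counts <- matrix(
    if (is.infinite(config$noiseDispersion))
      stats::rpois(G * n, lambda = as.vector(mu))
    else
      stats::rnbinom(G * n, mu = as.vector(mu),
                     size = config$noiseDispersion),
    G, n, dimnames = list(genes, samples))

  set.seed(.childSeed(config$seed, 5L))
  haz <- config$survivalHazards[as.character(labels)]
  tEvent <- stats::rexp(n, rate = haz)
  tCens <- stats::runif(n, 6, 48)
  osTime <- pmin(tEvent, tCens)
  osEvent <- as.integer(tEvent <= tCens)

  ihc <- generateIHCCohort(n, as.character(labels),
                           seed = .childSeed(config$seed, 6L))
  clinical <- data.frame(sample_id = samples,
                         os_time = round(osTime, 3), os_event = osEvent,
                         subtype = as.character(labels),
                         ihc[, setdiff(names(ihc),
                                       c("sample_id", "subtype"))])

  sigGenes <- c(panel$EPM, panel$FIB, panel$END, panel$IMM)
  sigMat <- cbind(epithelial = epiBaseline, fibroblast = fib,
                  endothelial = endo, immune = immc)[sigGenes, ]
  sigMat[, "epithelial"] <- normTot(epiBaseline)[sigGenes]

  geneSets <- GeneSetCollection(list(
    EMT = panel$EMT, immune = panel$IMM, hypoxia = panel$HYP,
    NE = panel$NEG, nonNE = panel$NNG,
    YAP1L_targets = setdiff(panel$EMT, c("YAP1L", "TAZL")),
    ASCL1L_targets = setdiff(panel$APR, "ASCL1L"),
    POU2F3L_targets = setdiff(panel$PPR, "POU2F3L"),
    NEUROD1L_targets = setdiff(panel$NPR, "NEUROD1L")))

  truth <- list(labels = labels, fractions = fracs, nePosition = u,
                geneSets = geneSets,
                regulators = c("YAP1L", "TAZL", "ASCL1L", "POU2F3L",
                               "NEUROD1L"),
                panel = panel, geneWeights = wgt,
                signatureMatrix = sigMat,
                cellProfiles = others,
                epithelialExpected = epiExp,
                expectedBulk = bulkExp)

  list(counts = ExpressionMatrix(counts, "counts"),
       geneLengths = lengths, truth = truth, clinical = clinical)
}

#' Configuration for the mouse-like single-cell time course
#'
#' @param nCells total cell count; must equal `sum(cellsPerTimepoint)`.
#' @param timepoints strictly increasing day labels.
#' @param cellsPerTimepoint cells captured per day.
#' @param depth mean UMI per cell.
#' @param gradientSharpness positive scale of the NE -> non-NE gradient;
#'   0 gives a flat (degenerate) time course.
#' @param seed integer.
#' @export
timeCourseConfig <- function(nCells = 600L,
                             timepoints = c(4, 7, 11, 14, 17, 21),
                             cellsPerTimepoint = NULL,
                             depth = 2000, gradientSharpness = 1,
                             seed = 11L) {
  if (is.null(cellsPerTimepoint)) {
    k <- length(timepoints)
    cellsPerTimepoint <- rep(nCells %/% k, k)
    cellsPerTimepoint[k] <- nCells - sum(cellsPerTimepoint[-k])
  }
  if (any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing")
  if (sum(cellsPerTimepoint) != nCells)
    stop("cellsPerTimepoint must sum to nCells")
  if (gradientSharpness < 0) stop("gradientSharpness must be non-negative")
  structure(list(nCells = as.integer(nCells), timepoints = timepoints,
                 cellsPerTimepoint = as.integer(cellsPerTimepoint),
                 depth = depth, gradientSharpness = gradientSharpness,
                 seed = as.integer(seed)),
            class = "timeCourseConfig")
}

# Expected (linear-scale) expression of one cell at latent time t, over the
# shared gene panel. Membership is read off the generator's id prefixes.
.mouseMean <- function(sharedGenes, base, t, sharp) {
  neAmp <- 2.25
  m <- base
  isNE <- grepl("^NEG", sharedGenes)
  isNN <- grepl("^NNG", sharedGenes)
  isEMT <- sharedGenes %in% c("YAP1L", "TAZL") | grepl("^EMT", sharedGenes)
  m[isNE] <- m[isNE] * 2^(sharp * neAmp * (0.5 - t) * 2)
  m[isNN] <- m[isNN] * 2^(sharp * neAmp * (t - 0.5) * 2)
  m[isEMT] <- m[isEMT] * 2^(sharp * 1.0 * (t - 0.5) * 2)
  m
}

#' Generate a mouse-like single-cell UMI time course
#'
#' Cells are drawn at the configured day labels; each carries a latent time
#' on \[0,1\] that increases stochastically with day. Expected expression of
#' the NE program decreases (and EMT/non-NE programs increase) along latent
#' time; UMI counts are Poisson around the depth-scaled expectation.
#' Mouse gene ids are the lowercase of the shared human ids; the ortholog
#' map is returned alongside.
#'
#' @param config a [timeCourseConfig()].
#' @param sharedGenes human gene ids shared with the paired cohort; must
#'   include the cohort's NE and non-NE program genes.
#' @return list with `umi` (sparse genes x cells), `days` (factor),
#'   `latentTime`, `orthologMap` (data.frame human/mouse).
#' @export
generateMouseTimecourse <- function(config, sharedGenes) {
  stopifnot(inherits(config, "timeCourseConfig"))
  if (length(sharedGenes) == 0) stop("sharedGenes must be non-empty")
  if (!any(grepl("^NEG", sharedGenes)) || !any(grepl("^NNG", sharedGenes)))
    stop("sharedGenes must include the NE and non-NE program genes")
  set.seed(.childSeed(config$seed, 1L))
  G <- length(sharedGenes)
  base <- stats::setNames(exp(stats::rnorm(G, 1.0, 0.8)), sharedGenes)

  k <- length(config$timepoints)
  days <- rep(config$timepoints, config$cellsPerTimepoint)
  dayFrac <- (match(days, config$timepoints) - 0.5) / k
  set.seed(.childSeed(config$seed, 2L))
  lat <- .clamp(stats::rnorm(length(days), dayFrac, 0.10), 0, 1)

  set.seed(.childSeed(config$seed, 3L))
  umi <- matrix(0L, G, length(days))
  for (i in seq_along(days)) {
    m <- .mouseMean(sharedGenes, base, lat[i], config$gradientSharpness)
    umi[, i] <- stats::rpois(G, config$depth * m / sum(m))
  }
  mouseIds <- tolower(sharedGenes)
  dimnames(umi) <- list(mouseIds,
                        sprintf("C%05d", seq_along(days)))
  list(umi = Matrix::Matrix(umi, sparse = TRUE),
       days = factor(days, levels = config$timepoints),
       latentTime = lat,
       orthologMap = data.frame(human = sharedGenes, mouse = mouseIds,
                                stringsAsFactors = FALSE))
}

#' Generate subtype-coupled IHC records
#'
#' Mesenchymal tumors get high vimentin proportion/intensity with low CD8+
#' TIL field counts; inflamed tumors are vimentin-positive with high CD8
#' counts; the remaining subtypes are mostly vimentin-negative with
#' intermediate CD8 counts.
#'
#' @param n number of records; must equal `length(subtypeLabels)`.
#' @param subtypeLabels character labels from `M, I, A, P, N, H`.
#' @param seed integer.
#' @return data.frame: sample_id, subtype, vimentin_proportion,
#'   vimentin_intensity, cd8_f1..cd8_f5.
#' @export
generateIHCCohort <- function(n, subtypeLabels, seed = 13L) {
  if (n != length(subtypeLabels))
    stop("n must equal length(subtypeLabels)")
  out <- data.frame(sample_id = character(0), subtype = character(0),
                    vimentin_proportion = numeric(0),
                    vimentin_intensity = integer(0),
                    cd8_f1 = numeric(0), cd8_f2 = numeric(0),
                    cd8_f3 = numeric(0), cd8_f4 = numeric(0),
                    cd8_f5 = numeric(0))
  if (n == 0) return(out)
  if (!all(subtypeLabels %in% .SUBTYPES))
    stop("labels must be drawn from ", paste(.SUBTYPES, collapse = ", "))
  set.seed(seed)
  prop <- inten <- numeric(n)
  cd8 <- matrix(0, n, 5)
  for (i in seq_len(n)) {
    s <- subtypeLabels[i]
    if (s == "M") {
      prop[i] <- round(stats::runif(1, 40, 95))
      inten[i] <- sample(2:3, 1)
      cd8[i, ] <- stats::rpois(5, 4)
    } else if (s == "I") {
      pos <- stats::runif(1) < 0.85
      prop[i] <- if (pos) round(stats::runif(1, 15, 60)) else 0
      inten[i] <- if (pos) sample(1:2, 1) else 0L
      cd8[i, ] <- stats::rpois(5, 28)
    } else {
      pos <- stats::runif(1) < 0.06
      prop[i] <- if (pos) round(stats::runif(1, 5, 20)) else 0
      inten[i] <- if (pos) 1L else 0L
      cd8[i, ] <- stats::rpois(5, 12)
    }
  }
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             subtype = subtypeLabels,
             vimentin_proportion = prop, vimentin_intensity = as.integer(inten),
             cd8_f1 = cd8[, 1], cd8_f2 = cd8[, 2], cd8_f3 = cd8[, 3],
             cd8_f4 = cd8[, 4], cd8_f5 = cd8[, 5],
             stringsAsFactors = FALSE)
}
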