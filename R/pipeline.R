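## End-to-end orchestration: simulate -> preprocess -> discover -> score ->
## regulons -> classify -> deconvolve -> trajectory -> clinical, from one
## config (list or YAML path), with a run manifest capturing seeds,
## artifact checksums and per-stage wall-clock.

#' Default pipeline configuration
#'
#' Every numerical default of the analysis is named here so a full run is
#' reproducible from the config alone. `stages` toggles individual stages;
#' a stage whose inputs were produced by a toggled-off stage in a previous
#' run is read back from `outDir`, and a missing upstream artifact is a
#' dependency error.
#'
#' @param outDir output directory.
#' @param seed global integer seed.
#' @param ... overrides for any top-level entry.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(outDir = tempfile("sclc_run_"), seed = 7L, ...) {
  cfg <- list(
    outDir = outDir, seed = as.integer(seed),
    stages = list(simulate = TRUE, preprocess = TRUE, discover = TRUE,
                  score = TRUE, regulons = TRUE, classify = TRUE,
                  deconvolve = TRUE, trajectory = TRUE, clinical = TRUE),
    cohort = list(nSamples = 120L, nGenes = 1000L),
    timecourse = list(nCells = 600L, depth = 2000),
    nTopGenes = 1000L,
    kRange = c(2L, 10L), nSubsamples = 50L, subsampleFrac = 0.8,
    nPerm = 20L, dropThreshold = 0.02,
    ssgseaAlpha = 0.25,
    regulonPerm = 200L, regulonFdrQ = 0.05, dpiTolerance = 0,
    metageneTop = 100L,
    cvFolds = 10L, deltaGridSize = 30L,
    nClassifier = 100L,
    cd8Cutoff = "median")
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "pipelineConfig"
  cfg
}

.readPipelineConfig <- function(config) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    cfg <- do.call(pipelineConfig, y[setdiff(names(y), "stages")])
    if (!is.null(y$stages)) cfg$stages[names(y$stages)] <- y$stages
    cfg
  } else if (inherits(config, "pipelineConfig")) config
  else do.call(pipelineConfig, config)
}

.need <- function(state, what, stage) {
  if (is.null(state[[what]]))
    stop("dependency error: stage '", stage, "' requires '", what,
         "' from an earlier stage that did not run and left no artifact")
  state[[what]]
}

#' Write a generated cohort to disk
#'
#' Expression TSV (genes in rows), gene-length TSV, ground-truth JSON
#' (labels, fractions, NE positions), clinical CSV, and the gene-set GMT.
#' @param cohort result of [generateCohort()].
#' @param dir output directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionTSV(cohort$counts, file.path(dir, "counts.tsv"))
  utils::write.table(
    data.frame(gene_id = names(cohort$geneLengths),
               length_kb = cohort$geneLengths),
    file.path(dir, "gene_lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(labels = as.character(cohort$truth$labels),
         fractions = cohort$truth$fractions,
         nePosition = cohort$truth$nePosition),
    file.path(dir, "truth.json"), digits = NA)
  writeClinicalCSV(cohort$clinical, file.path(dir, "clinical.csv"))
  writeGMT(cohort$truth$geneSets, file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Executes the toggled stages in dependency order, writes all artifacts
#' under `config$outDir`, and returns (and writes) a run manifest with the
#' config hash, per-stage seeds, artifact MD5 checksums and wall-clock.
#' Identical config + seed reproduce identical checksums for the
#' deterministic stages.
#'
#' @param config a `pipelineConfig` list, plain list of overrides, or a
#'   YAML file path.
#' @return the manifest list, invisibly; also written to
#'   `outDir/manifest.json`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  cfg <- .readPipelineConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(configHash = .hashConfig(cfg), seed = cfg$seed,
                   stages = list())
  state <- list()
  artifacts <- function(...) {
    fs <- c(...)
    stats::setNames(as.list(unname(tools::md5sum(fs))), basename(fs))
  }
  stageSeed <- function(k) .childSeed(cfg$seed, 100L + k)
  record <- function(name, t0, files, seedUsed = NA) {
    manifest$stages[[name]] <<- list(
      seed = seedUsed, seconds = round(as.numeric(Sys.time()) - t0, 2),
      artifacts = artifacts(files))
  }
  run <- function(name) isTRUE(cfg$stages[[name]])

  if (run("simulate")) {
    t0 <- as.numeric(Sys.time())
    cc <- cohortConfig(nSamples = cfg$cohort$nSamples,
                       nGenes = cfg$cohort$nGenes, seed = stageSeed(1))
    state$cohort <- generateCohort(cc)
    d <- file.path(cfg$outDir, "simulated")
    writeCohort(state$cohort, d)
    tc <- timeCourseConfig(nCells = cfg$timecourse$nCells,
                           depth = cfg$timecourse$depth,
                           seed = stageSeed(2))
    sets <- geneSets(state$cohort$truth$geneSets)
    sharedGenes <- unique(c(sets$NE, sets$nonNE, sets$EMT))
    state$mouse <- generateMouseTimecourse(tc, sharedGenes)
    writeMTX(state$mouse$umi, file.path(d, "mouse"))
    utils::write.table(state$mouse$orthologMap,
                       file.path(d, "orthologs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    record("simulate", t0,
           file.path(d, c("counts.tsv", "gene_lengths.tsv", "truth.json",
                          "clinical.csv", "gene_sets.gmt")),
           stageSeed(1))
  }

  if (run("preprocess")) {
    t0 <- as.numeric(Sys.time())
    cohort <- .need(state, "cohort", "preprocess")
    state$logtpm <- countsToLogTPM(cohort$counts, cohort$geneLengths)
    state$tpm <- countsToTPM(cohort$counts, cohort$geneLengths)
    state$filtered <- filterVariableGenes(
      state$logtpm, min(cfg$nTopGenes, nrow(state$logtpm)))
    f <- file.path(cfg$outDir, "log2tpm.tsv")
    writeExpressionTSV(state$logtpm, f)
    record("preprocess", t0, f)
  }

  if (run("discover")) {
    t0 <- as.numeric(Sys.time())
    X <- .need(state, "filtered", "discover")
    state$consensus <- consensusNMF(
      X, kRange = seq(cfg$kRange[1], cfg$kRange[2]),
      nSubsamples = cfg$nSubsamples, subsampleFrac = cfg$subsampleFrac,
      nPerm = cfg$nPerm, seed = stageSeed(3),
      dropThreshold = cfg$dropThreshold)
    K <- selectedRank(state$consensus)
    labs <- clusterLabels(state$consensus)
    state$labels <- paste0("NMF", labs)
    rhoF <- file.path(cfg$outDir, "cophenetic.tsv")
    utils::write.table(
      data.frame(K = names(copheneticScores(state$consensus)),
                 rho = copheneticScores(state$consensus)),
      rhoF, sep = "\t", quote = FALSE, row.names = FALSE)
    labF <- file.path(cfg$outDir, "labels.csv")
    utils::write.csv(
      data.frame(sample_id = colnames(exprValues(X)),
                 cluster = state$labels),
      labF, row.names = FALSE, quote = FALSE)
    mg <- lapply(seq_len(K), function(k)
      extractMetageneGenes(state$consensus@factors, k, cfg$metageneTop))
    names(mg) <- paste0("NMF", seq_len(K))
    state$metagenes <- mg
    mgF <- file.path(cfg$outDir, "metagenes.gmt")
    writeGMT(GeneSetCollection(mg), mgF)
    record("discover", t0, c(rhoF, labF, mgF), stageSeed(3))
  }

  if (run("score")) {
    t0 <- as.numeric(Sys.time())
    X <- .need(state, "logtpm", "score")
    sets <- geneSets(.need(state, "cohort", "score")$truth$geneSets)
    sc <- scoreSignatures(X, sets[c("EMT", "immune", "hypoxia")],
                          alpha = cfg$ssgseaAlpha)
    state$scores <- sc
    f <- file.path(cfg$outDir, "signature_scores.tsv")
    utils::write.table(data.frame(sample_id = rownames(sc), sc),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    record("score", t0, f)
  }

  if (run("regulons")) {
    t0 <- as.numeric(Sys.time())
    X <- .need(state, "filtered", "regulons")
    regs <- intersect(.need(state, "cohort", "regulons")$truth$regulators,
                      rownames(exprValues(X)))
    edges <- buildNetwork(X, regs, nPerm = cfg$regulonPerm,
                          fdrQ = cfg$regulonFdrQ, seed = stageSeed(4))
    edges <- dpiPrune(edges, cfg$dpiTolerance)
    regulons <- edgesToRegulons(edges)
    mg <- .need(state, "metagenes", "regulons")
    state$enrichment <- enrichmentTable(mg, regulons,
                                        rownames(exprValues(X)))
    f <- file.path(cfg$outDir, "regulon_enrichment.tsv")
    utils::write.table(state$enrichment, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("regulons", t0, f, stageSeed(4))
  }

  if (run("classify")) {
    t0 <- as.numeric(Sys.time())
    X <- .need(state, "filtered", "classify")
    labs <- .need(state, "labels", "classify")
    model <- nscTrain(X, labs, cvFolds = cfg$cvFolds,
                      seed = stageSeed(5))
    pred <- nscPredict(model, X)
    state$calls <- pred$labels
    mF <- file.path(cfg$outDir, "nsc_model.json")
    writeNSCModel(model, mF)
    cF <- file.path(cfg$outDir, "calls.csv")
    utils::write.csv(data.frame(sample_id = names(pred$labels),
                                call = pred$labels),
                     cF, row.names = FALSE, quote = FALSE)
    record("classify", t0, c(mF, cF), stageSeed(5))
  }

  if (run("deconvolve")) {
    t0 <- as.numeric(Sys.time())
    tpm <- .need(state, "tpm", "deconvolve")
    cohort <- .need(state, "cohort", "deconvolve")
    labs <- .need(state, "labels", "deconvolve")
    dec <- deconvolveCohort(tpm, cohort$truth$signatureMatrix, labs)
    state$deconv <- dec
    # M-like / I-like clusters by EMT and immune signature score means
    sc <- .need(state, "scores", "deconvolve")
    byClust <- function(col) tapply(sc[, col], labs, mean)
    mClust <- names(which.max(byClust("EMT")))
    iClust <- names(which.max(byClust("immune")))
    state$miClusters <- c(M = mClust, I = iClust)
    fF <- file.path(cfg$outDir, "fractions.csv")
    utils::write.csv(data.frame(sample_id = rownames(cellFractions(dec)),
                                cellFractions(dec)),
                     fF, row.names = FALSE, quote = FALSE)
    files <- fF
    epi <- epithelialProfiles(dec)
    if (mClust != iClust && !is.null(epi)) {
      idxM <- which(labs == mClust); idxI <- which(labs == iClust)
      if (length(idxM) >= 3 && length(idxI) >= 3) {
        de <- epithelialDE(log2(epi[, idxM, drop = FALSE] + 1),
                           log2(epi[, idxI, drop = FALSE] + 1),
                           nClassifier = cfg$nClassifier)
        state$mi <- miIntrinsicScores(
          .need(state, "logtpm", "deconvolve"),
          list(mUp = de$upA, iUp = de$upB))
        sF <- file.path(cfg$outDir, "mi_scores.csv")
        utils::write.csv(state$mi, sF, row.names = FALSE, quote = FALSE)
        files <- c(files, sF)
      }
    }
    record("deconvolve", t0, files)
  }

  if (run("trajectory")) {
    t0 <- as.numeric(Sys.time())
    cohort <- .need(state, "cohort", "trajectory")
    dec <- .need(state, "deconv", "trajectory")
    sets <- geneSets(cohort$truth$geneSets)
    epi <- log2(epithelialProfiles(dec) + 1)
    # NE proxy from marker means anchors prototypes and orientation
    proxy <- colMeans(epi[intersect(sets$NE, rownames(epi)), ]) -
      colMeans(epi[intersect(sets$nonNE, rownames(epi)), ])
    isNE <- proxy >= stats::quantile(proxy, 2 / 3)
    isNonNE <- proxy <= stats::quantile(proxy, 1 / 3)
    prot <- nePrototypes(epi, isNE[colnames(epi)] & !isNonNE[colnames(epi)],
                         c(sets$NE, sets$nonNE))
    neH <- apply(epi, 2, neScore, nePrototype = prot$ne,
                 nonNePrototype = prot$nonNe,
                 signatureGenes = c(sets$NE, sets$nonNE))
    labsH <- .need(state, "labels", "trajectory")
    trH <- inferPseudotime(epi, neH,
                           labels = labsH[match(colnames(epi),
                                                names(labsH))])
    mouse <- .need(state, "mouse", "trajectory")
    mExpr <- normalizeUMI(mouse$umi)
    rownames(mExpr) <- mouse$orthologMap$human[
      match(rownames(mExpr), mouse$orthologMap$mouse)]
    neM <- apply(mExpr, 2, neScore, nePrototype = prot$ne,
                 nonNePrototype = prot$nonNe,
                 signatureGenes = c(sets$NE, sets$nonNE))
    trM <- inferPseudotime(mExpr, neM)
    rownames(mExpr) <- mouse$orthologMap$mouse[
      match(rownames(mExpr), mouse$orthologMap$human)]
    conc <- crossSpeciesConcordance(epi, mExpr, mouse$orthologMap,
                                    pseudotime(trH), pseudotime(trM))
    state$trajectory <- list(human = trH, mouse = trM,
                             concordance = conc)
    occ <- subtypeOccurrence(labsH[colnames(epi)], pseudotime(trH))
    state$occurrence <- occ
    hF <- file.path(cfg$outDir, "pseudotime_human.csv")
    utils::write.csv(data.frame(sample_id = names(pseudotime(trH)),
                                pseudotime = pseudotime(trH),
                                ne_score = neH),
                     hF, row.names = FALSE, quote = FALSE)
    cF <- file.path(cfg$outDir, "concordance.tsv")
    utils::write.table(round(conc, 5), cF, sep = "\t", quote = FALSE)
    record("trajectory", t0, c(hF, cF))
  }

  if (run("clinical")) {
    t0 <- as.numeric(Sys.time())
    cohort <- .need(state, "cohort", "clinical")
    cl <- cohort$clinical
    labs <- .need(state, "labels", "clinical")
    lr <- logrankTest(cl$os_time, cl$os_event, labs)
    calls <- ihcClassify(cl, cfg$cd8Cutoff)
    state$logrank <- lr
    state$ihcCalls <- calls
    f <- file.path(cfg$outDir, "ihc_calls.csv")
    utils::write.csv(calls, f, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(lr, file.path(cfg$outDir, "logrank.json"),
                         auto_unbox = TRUE, digits = NA)
    record("clinical", t0, c(f, file.path(cfg$outDir, "logrank.json")))
  }

  mF <- file.path(cfg$outDir, "manifest.json")
  jsonlite::write_json(manifest, mF, auto_unbox = TRUE, digits = NA)
  state$manifest <- manifest
  invisible(state)
}

.hashConfig <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[setdiff(names(cfg), "outDir")]), tmp)
  unname(tools::md5sum(tmp))
}
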