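## Nearest-shrunken-centroid (PAM-style) subtype classifier.
##
## Standardized class-centroid deviations d_ik = (xbar_ik - xbar_i) /
## (m_k (s_i + s0)) with m_k = sqrt(1/n_k - 1/n) are soft-thresholded by
## delta; the shrinkage level is chosen by cross-validation (ties -> the
## largest delta, i.e. the sparsest model).

.nscCentroids <- function(X, labels) {
  classes <- levels(labels)
  n <- ncol(X)
  nk <- table(labels)
  cent <- sapply(classes, function(k)
    rowMeans(X[, labels == k, drop = FALSE]))
  overall <- rowMeans(X)
  ss <- matrix(0, nrow(X), 1)
  for (k in classes) {
    Xi <- X[, labels == k, drop = FALSE]
    ss <- ss + rowSums((Xi - cent[, k])^2)
  }
  si <- sqrt(as.vector(ss) / (n - length(classes)))
  s0 <- stats::median(si)
  mk <- sqrt(1 / as.vector(nk) - 1 / n)
  names(mk) <- classes
  list(classes = classes, centroids = cent, overall = overall, si = si,
       s0 = s0, mk = mk, nk = nk, n = n)
}

.nscShrink <- function(cc, delta) {
  d <- sweep(cc$centroids - cc$overall, 1, cc$si + cc$s0, "/")
  d <- sweep(d, 2, cc$mk, "/")
  dshr <- sign(d) * pmax(abs(d) - delta, 0)
  shr <- cc$overall + sweep(sweep(dshr, 2, cc$mk, "*"), 1,
                            cc$si + cc$s0, "*")
  list(shrunken = shr, active = rowSums(abs(dshr)) > 0)
}

.nscDiscriminant <- function(X, shrunken, si, s0, priors) {
  denom <- (si + s0)^2
  delta <- sapply(colnames(shrunken), function(k) {
    colSums((X - shrunken[, k])^2 / denom) - 2 * log(priors[k])
  })
  matrix(delta, ncol(X), ncol(shrunken),
         dimnames = list(colnames(X), colnames(shrunken)))
}

#' Train a nearest-shrunken-centroid subtype classifier
#'
#' @param X training [ExpressionMatrix-class] or genes x samples matrix
#'   (log2TPM scale).
#' @param labels factor or character of class labels, one per sample;
#'   every class needs at least 2 samples.
#' @param deltaGrid candidate shrinkage thresholds; default a 30-point grid
#'   from 0 to the maximum absolute standardized deviation.
#' @param cvFolds stratified cross-validation folds (default 10, capped at
#'   the smallest class size).
#' @param priors `"uniform"` (default; cohort prevalences differ between
#'   cohorts) or `"empirical"`.
#' @param seed integer seed for fold assignment.
#' @return An [NSCModel-class].
#' @export
nscTrain <- function(X, labels, deltaGrid = NULL, cvFolds = 10L,
                     priors = c("uniform", "empirical"), seed = 1L) {
  priors <- match.arg(priors)
  Xm <- if (is(X, "ExpressionMatrix")) exprValues(X) else as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2))
    stop("every class needs at least 2 training samples")
  cc <- .nscCentroids(Xm, labels)
  if (is.null(deltaGrid)) {
    d <- sweep(cc$centroids - cc$overall, 1, cc$si + cc$s0, "/")
    d <- sweep(d, 2, cc$mk, "/")
    deltaGrid <- seq(0, max(abs(d)), length.out = 30)
  }
  pr <- if (priors == "uniform")
    stats::setNames(rep(1 / nlevels(labels), nlevels(labels)),
                    levels(labels))
  else table(labels) / length(labels)
  pr <- stats::setNames(as.numeric(pr), levels(labels))

  # stratified CV folds
  set.seed(seed)
  folds <- integer(length(labels))
  nf <- min(cvFolds, min(table(labels)))
  for (k in levels(labels)) {
    idx <- which(labels == k)
    folds[idx] <- sample(rep_len(seq_len(nf), length(idx)))
  }
  cvErr <- vapply(deltaGrid, function(delta) {
    err <- 0L
    for (f in seq_len(nf)) {
      tr <- folds != f
      ccf <- .nscCentroids(Xm[, tr, drop = FALSE],
                           droplevels(labels[tr]))
      if (length(ccf$classes) < nlevels(labels)) next
      sh <- .nscShrink(ccf, delta)
      dd <- .nscDiscriminant(Xm[, !tr, drop = FALSE], sh$shrunken,
                             ccf$si, ccf$s0, pr[ccf$classes])
      pred <- ccf$classes[apply(dd, 1, which.min)]
      err <- err + sum(pred != as.character(labels[!tr]))
    }
    err
  }, 0L)
  # ties -> largest delta (fewest genes)
  best <- max(which(cvErr == min(cvErr)))
  delta <- deltaGrid[best]
  sh <- .nscShrink(cc, delta)
  new("NSCModel", overallCentroid = cc$overall, centroids = cc$centroids,
      shrunkenCentroids = sh$shrunken, si = cc$si, s0 = cc$s0, mk = cc$mk,
      delta = delta, priors = pr, genes = rownames(Xm),
      classes = cc$classes,
      cvTable = data.frame(delta = deltaGrid, cv_error = cvErr),
      trainMedians = apply(Xm, 1, stats::median))
}

#' Predict subtypes with a nearest-shrunken-centroid model
#'
#' Discriminant score per class:
#' \eqn{\delta_k(x) = \sum_i (x_i - \bar c_{ik})^2/(s_i+s_0)^2 - 2\log\pi_k};
#' the label is the argmin and soft probabilities are the softmax of
#' \eqn{-\delta/2}. Genes missing from the new cohort are imputed at the
#' overall centroid (reported via a message); more than 50% missing is an
#' error. With `medianShift = TRUE` each gene in the new cohort is shifted
#' so its median matches the training median (simple cross-cohort
#' harmonization).
#'
#' @param model an [NSCModel-class].
#' @param Xnew new cohort [ExpressionMatrix-class] or matrix.
#' @param medianShift apply per-gene median-shift correction.
#' @return list: `labels` (character per sample), `scores` (samples x
#'   classes discriminant matrix), `probabilities` (softmax, rows sum to 1).
#' @export
nscPredict <- function(model, Xnew, medianShift = FALSE) {
  Xm <- if (is(Xnew, "ExpressionMatrix")) exprValues(Xnew)
        else as.matrix(Xnew)
  missing <- setdiff(model@genes, rownames(Xm))
  if (length(missing) > 0.5 * length(model@genes))
    stop(">50% of model genes missing from the new cohort")
  if (length(missing))
    message("nscPredict: imputing ", length(missing),
            " missing gene(s) at the overall centroid")
  X <- matrix(model@overallCentroid, length(model@genes), ncol(Xm),
              dimnames = list(model@genes, colnames(Xm)))
  present <- intersect(model@genes, rownames(Xm))
  X[present, ] <- Xm[present, , drop = FALSE]
  if (medianShift && ncol(X) > 1) {
    shift <- apply(X[present, , drop = FALSE], 1, stats::median) -
      model@trainMedians[present]
    X[present, ] <- X[present, ] - shift
  }
  dd <- .nscDiscriminant(X, model@shrunkenCentroids, model@si, model@s0,
                         model@priors)
  lab <- model@classes[apply(dd, 1, which.min)]
  lo <- -dd / 2
  lo <- lo - apply(lo, 1, max)
  prob <- exp(lo) / rowSums(exp(lo))
  list(labels = stats::setNames(lab, colnames(X)), scores = dd,
       probabilities = prob)
}

#' Serialize an NSC model to JSON
#' @param model an [NSCModel-class].
#' @param path output path.
#' @export
writeNSCModel <- function(model, path) {
  obj <- list(overallCentroid = model@overallCentroid,
              centroids = model@centroids,
              shrunkenCentroids = model@shrunkenCentroids,
              si = model@si, s0 = model@s0, mk = model@mk,
              delta = model@delta, priors = model@priors,
              genes = model@genes, classes = model@classes,
              trainMedians = model@trainMedians)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an NSC model from JSON
#' @param path JSON path written by [writeNSCModel()].
#' @return An [NSCModel-class].
#' @export
readNSCModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixmat <- function(m, genes, classes) {
    m <- as.matrix(m); dimnames(m) <- list(genes, classes); m
  }
  new("NSCModel",
      overallCentroid = stats::setNames(o$overallCentroid, o$genes),
      centroids = fixmat(o$centroids, o$genes, o$classes),
      shrunkenCentroids = fixmat(o$shrunkenCentroids, o$genes, o$classes),
      si = stats::setNames(o$si, o$genes), s0 = o$s0,
      mk = stats::setNames(o$mk, o$classes), delta = o$delta,
      priors = stats::setNames(o$priors, o$classes), genes = o$genes,
      classes = o$classes, cvTable = data.frame(),
      trainMedians = stats::setNames(o$trainMedians, o$genes))
}
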