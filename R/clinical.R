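## Survival comparison across subtypes and the IHC arm: H-score, CD8+ TIL
## score, dichotomization and the IHC-based SCLC-M / SCLC-I call.

#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator with right-censoring (via
#' [survival::survfit()]). Survival starts at 1 and is non-increasing.
#'
#' @param time positive survival times (months).
#' @param event 0/1 event indicators.
#' @return data.frame: `time`, `n_risk`, `n_event`, `survival` at each
#'   observed time.
#' @export
kmEstimate <- function(time, event) {
  if (length(time) < 1) stop("need at least one record")
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' k-group log-rank test
#'
#' Log-rank chi-square with `k - 1` degrees of freedom (via
#' [survival::survdiff()]); p from the chi-square upper tail.
#'
#' @param time,event as in [kmEstimate()].
#' @param group group (subtype) label per record; >= 2 non-empty groups.
#' @return list: `chi2`, `df`, `p`.
#' @export
logrankTest <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need at least 2 non-empty groups")
  if (any(time <= 0)) stop("survival times must be positive")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  list(chi2 = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Immunohistochemistry H-score
#'
#' Product of the percentage of positive tumor cells (0-100) and the
#' staining intensity (0-3); range 0-300.
#'
#' @param proportion percent positive tumor cells, 0-100.
#' @param intensity staining intensity, integer 0-3.
#' @return numeric H-score(s).
#' @export
hScore <- function(proportion, intensity) {
  if (any(proportion < 0 | proportion > 100))
    stop("proportion must lie in [0, 100]")
  if (any(!intensity %in% 0:3)) stop("intensity must be one of 0, 1, 2, 3")
  proportion * intensity
}

#' CD8+ TIL score
#'
#' Arithmetic mean of the five high-power-field CD8+ TIL counts.
#' @param counts numeric vector (or 5-column matrix) of exactly five
#'   non-negative field counts per record.
#' @return numeric mean per record.
#' @export
cd8Score <- function(counts) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    counts <- as.matrix(counts)
    if (ncol(counts) != 5) stop("exactly five field counts required")
    if (any(counts < 0)) stop("counts must be non-negative")
    return(rowMeans(counts))
  }
  if (length(counts) != 5) stop("exactly five field counts required")
  if (any(counts < 0)) stop("counts must be non-negative")
  mean(counts)
}

#' Mann-Whitney U test
#'
#' U statistic with midrank ties. Exact two-sided p by full enumeration of
#' the group assignments when `n_a + n_b <= 12` and there are no ties;
#' otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param a,b numeric samples (both non-empty).
#' @return list: `U` (for group a), `p`, `method`.
#' @export
mannWhitneyU <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (n <= 12 && !ties) {
    # enumerate all assignments of na observations to group a
    combs <- utils::combn(n, na)
    Us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    mu <- na * nb / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    list(U = U, p = p, method = "exact enumeration")
  } else {
    mu <- na * nb / 2
    tieTab <- table(pooled)
    tieCorr <- sum(tieTab^3 - tieTab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tieCorr)
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "degenerate"))
    z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)  # continuity corr.
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation with tie correction")
  }
}

#' IHC-based SCLC-M / SCLC-I call
#'
#' Vimentin-positive means any positivity (H-score > 0). Among
#' vimentin-positive tumors the CD8+ TIL score is dichotomized at
#' `cd8Cutoff` (default: the median of the vimentin-positive CD8 scores):
#' CD8-low -> SCLC-M, CD8-high -> SCLC-I. Vimentin-negative tumors are
#' called `other`. Every record receives exactly one call.
#'
#' @param records data.frame with columns `vimentin_proportion`,
#'   `vimentin_intensity`, `cd8_f1`..`cd8_f5`.
#' @param cd8Cutoff `"median"` (default) or an absolute CD8 score.
#' @return data.frame: input columns plus `h_score`, `cd8_score`, `call`;
#'   attribute `cutoff` carries the cutoff used.
#' @export
ihcClassify <- function(records, cd8Cutoff = "median") {
  h <- hScore(records$vimentin_proportion, records$vimentin_intensity)
  cd8 <- cd8Score(records[, paste0("cd8_f", 1:5)])
  vimPos <- h > 0
  if (identical(cd8Cutoff, "median")) {
    if (!any(vimPos)) stop("no vimentin-positive records; cutoff undefined")
    pool <- cd8[vimPos]
    if (stats::sd(pool) == 0 && length(pool) > 1)
      stop("all vimentin-positive CD8 scores identical; cutoff undefined")
    cutoff <- stats::median(pool)
  } else {
    cutoff <- as.numeric(cd8Cutoff)
  }
  call <- ifelse(!vimPos, "other",
                 ifelse(cd8 < cutoff, "SCLC-M", "SCLC-I"))
  out <- cbind(records,
               data.frame(h_score = h, cd8_score = cd8, call = call,
                          stringsAsFactors = FALSE))
  attr(out, "cutoff") <- cutoff
  out
}
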