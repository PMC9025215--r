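check_two_classes <- function(obs) {
  u <- unique(obs)
  if (!all(u %in% c(0, 1))) stop("obs must be binary 0/1")
  if (length(u) < 2) {
    stop("degenerate observations: only class ", u,
         " present; both classes are required")
  }
}

#' Confusion-table metrics
#'
#' Closed-form metrics from the 2x2 table of binary observations vs binary
#' predictions: sensitivity, specificity, TSS (sensitivity + specificity
#' - 1), Sorensen's index (2TP / (2TP + FP + FN)) and Cohen's kappa.
#'
#' @param obs_binary,pred_binary equal-length 0/1 vectors; both classes
#'   must be present in \code{obs_binary}
#' @return named list of the five metrics
#' @export
confusion_metrics <- function(obs_binary, pred_binary) {
  stopifnot(length(obs_binary) == length(pred_binary))
  check_two_classes(obs_binary)
  tp <- sum(obs_binary == 1 & pred_binary == 1)
  tn <- sum(obs_binary == 0 & pred_binary == 0)
  fp <- sum(obs_binary == 0 & pred_binary == 1)
  fn <- sum(obs_binary == 1 & pred_binary == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  n <- length(obs_binary)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  list(sensitivity = sens, specificity = spec,
       tss = sens + spec - 1,
       sorensen = 2 * tp / (2 * tp + fp + fn),
       kappa = kappa)
}

#' Ranking and calibration metrics for continuous scores
#'
#' AUC via the Mann-Whitney statistic with tie correction (ties count
#' half), AUC-PR by step integration of the precision-recall curve, and the
#' Brier score (mean squared error of scores against 0/1 observations).
#'
#' @param obs_binary 0/1 vector, both classes present
#' @param scores numeric scores (higher = more presence-like)
#' @return named list auc, auc_pr, brier
#' @export
rank_metrics <- function(obs_binary, scores) {
  stopifnot(length(obs_binary) == length(scores))
  check_two_classes(obs_binary)
  n1 <- sum(obs_binary == 1); n0 <- sum(obs_binary == 0)
  r <- rank(scores)
  auc <- (sum(r[obs_binary == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  y <- obs_binary[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # collapse tied score groups to the last index of each group
  last <- rev(!duplicated(rev(s)))
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  auc_pr <- sum(diff(c(0, rec)) * prec) # step integration, right precision

  list(auc = auc, auc_pr = auc_pr,
       brier = mean((scores - obs_binary)^2))
}

#' Continuous Boyce Index
#'
#' Moving windows of width \code{window_frac} x the pooled score range are
#' slid over \code{n_windows} centers spanning the range. Each window's
#' predicted-to-expected ratio P/E contrasts the fraction of presence
#' scores with the fraction of background scores falling in the window;
#' windows with zero expected (background) fraction are skipped. CBI is
#' the Spearman correlation between window center and P/E.
#'
#' @param scores_at_presences,scores_at_background numeric score sets
#' @param n_windows number of window centers (default 101)
#' @param window_frac window width as a fraction of the score range
#'   (default 0.1)
#' @return CBI in [-1, 1]
#' @export
continuous_boyce <- function(scores_at_presences, scores_at_background,
                             n_windows = 101, window_frac = 0.1) {
  p <- scores_at_presences[!is.na(scores_at_presences)]
  b <- scores_at_background[!is.na(scores_at_background)]
  if (!length(p) || !length(b)) stop("empty score set")
  rng <- range(c(p, b))
  if (diff(rng) == 0) stop("all scores identical: windows are empty")
  w <- window_frac * diff(rng)
  centers <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_windows)
  pe <- vapply(centers, function(ct) {
    lo <- ct - w / 2; hi <- ct + w / 2
    e <- mean(b >= lo & b <= hi)
    if (e == 0) return(NA_real_)
    mean(p >= lo & p <= hi) / e
  }, numeric(1))
  ok <- !is.na(pe)
  if (sum(ok) < 2) stop("all windows empty")
  stats::cor(centers[ok], pe[ok], method = "spearman")
}

# vectorized 2x2 counts at every candidate threshold (the observed score
# values plus one above the maximum); thresholds returned in decreasing
# order, prediction rule is score >= threshold
threshold_scan_table <- function(obs_binary, scores) {
  check_two_classes(obs_binary)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- obs_binary[o]
  n1 <- sum(obs_binary == 1); n0 <- length(obs_binary) - n1
  grp <- !duplicated(s)
  last <- c(which(grp)[-1] - 1L, length(s))
  data.frame(threshold = c(s[1] + 1, s[grp]),
             tp = c(0, cumsum(y)[last]),
             fp = c(0, cumsum(1 - y)[last]),
             n1 = n1, n0 = n0)
}

scan_thresholds <- function(obs_binary, scores, objective) {
  tab <- threshold_scan_table(obs_binary, scores)
  vals <- objective(tab)
  best <- which(vals >= max(vals) - 1e-12)
  tab$threshold[max(best)] # thresholds decreasing: last = lowest maximizer
}

#' Threshold maximizing sensitivity + specificity (maxSSS)
#'
#' Candidates are the observed score values plus one value above the
#' maximum; the lowest maximizing threshold is returned. Cells at or above
#' the threshold are predicted present.
#' @param obs_binary 0/1 vector, both classes present
#' @param scores numeric scores
#' @return numeric threshold
#' @export
threshold_maxSSS <- function(obs_binary, scores) {
  scan_thresholds(obs_binary, scores, function(tab)
    tab$tp / tab$n1 + (tab$n0 - tab$fp) / tab$n0)
}

#' Threshold maximizing Sorensen's index
#' @inheritParams threshold_maxSSS
#' @return numeric threshold
#' @export
threshold_maxSorensen <- function(obs_binary, scores) {
  scan_thresholds(obs_binary, scores, function(tab)
    2 * tab$tp / (tab$tp + tab$fp + tab$n1))
}

#' Omission rate at a threshold
#'
#' Fraction of presence scores strictly below the threshold.
#' @param obs_presences_scores scores at presences (nonempty)
#' @param threshold numeric threshold
#' @return fraction in [0, 1]
#' @export
omission_rate <- function(obs_presences_scores, threshold) {
  if (!length(obs_presences_scores)) stop("no presence scores")
  mean(obs_presences_scores < threshold)
}

#' Full evaluation report for continuous scores
#'
#' The seven-metric report used throughout: AUC, AUC-PR, TSS, Sorensen,
#' kappa, Brier and CBI, plus the maxSSS and maxSorensen thresholds.
#' Threshold-dependent metrics (TSS, Sorensen, kappa) are evaluated at the
#' maxSSS threshold.
#'
#' @param obs_binary 0/1 vector (1 = presence, 0 = background)
#' @param scores continuous suitability scores
#' @param n_windows,window_frac CBI settings
#' @return object of class \code{evaluation_report} (a named list)
#' @export
evaluate_scores <- function(obs_binary, scores, n_windows = 101,
                            window_frac = 0.1) {
  rm_ <- rank_metrics(obs_binary, scores)
  th_sss <- threshold_maxSSS(obs_binary, scores)
  th_sor <- threshold_maxSorensen(obs_binary, scores)
  cm <- confusion_metrics(obs_binary, as.numeric(scores >= th_sss))
  cbi <- tryCatch(
    continuous_boyce(scores[obs_binary == 1], scores[obs_binary == 0],
                     n_windows, window_frac),
    error = function(e) NA_real_)
  structure(list(
    auc = rm_$auc, auc_pr = rm_$auc_pr, tss = cm$tss,
    sorensen = cm$sorensen, kappa = cm$kappa, brier = rm_$brier, cbi = cbi,
    thresholds = list(maxSSS = th_sss, maxSorensen = th_sor)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation: AUC %.3f | AUC-PR %.3f | TSS %.3f | Sorensen %.3f | kappa %.3f | Brier %.3f | CBI %s\n",
    x$auc, x$auc_pr, x$tss, x$sorensen, x$kappa, x$brier,
    ifelse(is.na(x$cbi), "NA", sprintf("%.3f", x$cbi))))
  cat(sprintf("  thresholds: maxSSS %.4f, maxSorensen %.4f\n",
              x$thresholds$maxSSS, x$thresholds$maxSorensen))
  invisible(x)
}

#' Spatial-block cross-validated evaluation of a fitted learner
#'
#' Refits the supplied fitting function on each train split and evaluates
#' on the held-out block; returns per-fold reports plus the pooled
#' (concatenated held-out predictions) report.
#'
#' @param fit_fun function(x, y) -> model with a \code{predict_suitability}
#'   method
#' @param x predictor matrix (presences then background)
#' @param y 0/1 response
#' @param folds integer fold ids per row (1..k)
#' @param ... passed to \code{evaluate_scores}
#' @return list with \code{pooled} report, \code{per_fold} list, and the
#'   out-of-fold \code{scores}
#' @export
cv_evaluate <- function(fit_fun, x, y, folds, ...) {
  k <- sort(unique(folds))
  oof <- rep(NA_real_, length(y))
  per_fold <- list()
  for (f in k) {
    test <- folds == f
    m <- fit_fun(x[!test, , drop = FALSE], y[!test])
    oof[test] <- predict_suitability(m, x[test, , drop = FALSE])
    per_fold[[as.character(f)]] <- tryCatch(
      evaluate_scores(y[test], oof[test], ...),
      error = function(e) NULL)
  }
  list(pooled = evaluate_scores(y, oof, ...), per_fold = per_fold,
       scores = oof)
}
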