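as_binary_labels <- function(labels) {
  if (is.factor(labels)) return(labels == "positive")
  if (is.character(labels)) return(labels == "positive")
  as.logical(labels)
}

#' Confusion metrics at a score threshold
#'
#' A window is predicted positive iff its score is strictly greater than the
#' threshold. Reports the seven standard confusion measures: true/false
#' positive and negative rates, accuracy, misclassification rate and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`
#' (defined as 0 when a marginal total is zero).
#'
#' @param scores numeric prediction scores.
#' @param labels window labels (factor/character `positive`/`negative`, or
#'   logical/0-1).
#' @param threshold decision threshold.
#' @return named list with `threshold`, counts `tp/fp/tn/fn`, and `TPR`,
#'   `TNR`, `FPR`, `FNR`, `ACC`, `MCR`, `MCC`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  y <- as_binary_labels(labels)
  if (!any(y) || all(y)) stop("both classes must be present")
  pred <- scores > threshold
  tp <- sum(pred & y); fn <- sum(!pred & y)
  fp <- sum(pred & !y); tn <- sum(!pred & !y)
  mcc_den <- sqrt(prod(c(tp + fn, tn + fp, tp + fp, tn + fn)))
  list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
       TPR = tp / (tp + fn), TNR = tn / (tn + fp),
       FPR = fp / (tn + fp), FNR = fn / (tp + fn),
       ACC = (tp + tn) / (tp + fp + tn + fn),
       MCR = (fp + fn) / (tp + fp + tn + fn),
       MCC = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}

#' Decision threshold at a fixed false positive rate
#'
#' Returns the smallest threshold whose empirical FPR (fraction of negatives
#' scoring strictly above it) does not exceed `fpr_cap` — i.e. the operating
#' point maximizing TPR subject to the cap. Tied scores are grouped
#' all-or-none, so the cap is never exceeded.
#'
#' @param scores numeric prediction scores.
#' @param labels window labels.
#' @param fpr_cap FPR cap in (0, 1] (default 0.20).
#' @return the threshold value.
#' @export
threshold_at_fpr <- function(scores, labels, fpr_cap = 0.20) {
  if (!is.numeric(fpr_cap) || fpr_cap <= 0 || fpr_cap > 1) {
    stop("fpr_cap must be in (0, 1]")
  }
  y <- as_binary_labels(labels)
  neg <- scores[!y]
  if (!length(neg)) stop("no negative windows present")
  cand <- c(min(scores) - 1, sort(unique(scores)))
  for (u in cand) {  # FPR is nonincreasing in the threshold
    if (mean(neg > u) <= fpr_cap) return(u)
  }
  cand[length(cand)]
}

#' ROC curve, AUC and partial AUC
#'
#' Sweeps all distinct score thresholds with tie-grouping to form the
#' empirical ROC; AUC by the trapezoid rule; pAUC as the unnormalized
#' trapezoid area over FPR in `[0, fpr_cap]` with linear interpolation at
#' the cap (so a perfect classifier attains `pAUC = fpr_cap` and
#' `pAUC(cap = 1) == AUC`).
#'
#' @param scores numeric prediction scores.
#' @param labels window labels.
#' @param fpr_cap FPR cap for the partial area (default 0.20).
#' @return list with `roc` (data.frame `fpr`, `tpr`), `auc`, `pauc`, and
#'   `fpr_cap`.
#' @export
roc_auc_pauc <- function(scores, labels, fpr_cap = 0.20) {
  if (!is.numeric(fpr_cap) || fpr_cap <= 0 || fpr_cap > 1) {
    stop("fpr_cap must be in (0, 1]")
  }
  y <- as_binary_labels(labels)
  n1 <- sum(y); n2 <- sum(!y)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  yy <- y[o]
  grp_end <- cumsum(rle(s)$lengths)   # tie groups enter the curve together
  fpr <- c(0, cumsum(!yy)[grp_end] / n2)
  tpr <- c(0, cumsum(yy)[grp_end] / n1)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  pauc <- pauc_trapezoid(fpr, tpr, fpr_cap)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc, pauc = pauc,
       fpr_cap = fpr_cap)
}

# area under the piecewise-linear ROC restricted to fpr <= cap
pauc_trapezoid <- function(fpr, tpr, cap) {
  area <- 0
  for (i in seq_len(length(fpr) - 1L)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1L]
    if (x0 >= cap) break
    y0 <- tpr[i]; y1 <- tpr[i + 1L]
    if (x1 > cap) {        # interpolate the segment at the cap
      y1 <- y0 + (y1 - y0) * (cap - x0) / (x1 - x0)
      x1 <- cap
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

# AUC convenience used internally for fusion-weight derivation
auc_score <- function(scores, labels) {
  roc_auc_pauc(scores, labels, fpr_cap = 1)$auc
}

#' Full evaluation report at a fixed-FPR operating point
#'
#' Picks the threshold at the FPR cap via [threshold_at_fpr()], computes
#' confusion metrics there, and attaches ROC, AUC and pAUC.
#'
#' @param scores numeric prediction scores.
#' @param labels window labels.
#' @param fpr_cap FPR cap (default 0.20).
#' @return an `evaluation_report` list: threshold, counts, the seven
#'   confusion metrics, `auc`, `pauc`, `fpr_cap` and `roc` points.
#' @export
evaluate_scores <- function(scores, labels, fpr_cap = 0.20) {
  thr <- threshold_at_fpr(scores, labels, fpr_cap)
  rep <- confusion_metrics(scores, labels, thr)
  r <- roc_auc_pauc(scores, labels, fpr_cap)
  rep$auc <- r$auc
  rep$pauc <- r$pauc
  rep$fpr_cap <- fpr_cap
  rep$roc <- r$roc
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report @ FPR cap %.2f (threshold %.4f)\n", x$fpr_cap,
    x$threshold))
  cat(sprintf(
    "  TPR %.3f  TNR %.3f  FNR %.3f  ACC %.3f  MCC %.3f  MCR %.3f\n",
    x$TPR, x$TNR, x$FNR, x$ACC, x$MCC, x$MCR))
  cat(sprintf("  AUC %.3f  pAUC %.3f\n", x$auc, x$pauc))
  invisible(x)
}

cv_metric_names <- c("TPR", "TNR", "FPR", "FNR", "ACC", "MCR", "MCC",
                     "auc", "pauc")

#' Ratio-stratified k-fold cross-validation of the full fusion pipeline
#'
#' Partitions the window set into k label-stratified disjoint folds (each
#' fold preserves the positive:negative ratio). For every fold the complete
#' pipeline — encoding, Kruskal-Wallis feature selection, backend training
#' and weight derivation — is refit on the k-1 training folds only, so no
#' information from the held-out fold leaks into feature selection or model
#' fitting. Held-out windows are scored by the fused model and evaluated at
#' the fixed-FPR threshold.
#'
#' @param ws a `window_set` (each class count must be >= k).
#' @param k number of folds (default 5).
#' @param fpr_cap FPR cap for per-fold evaluation (default 0.20).
#' @param seed integer seed for fold assignment and backend training.
#' @param ... pipeline parameters passed to [train_fusion()] (`family`,
#'   `top_n`, `ntree`, `weights`, ...).
#' @return a `cv_result`: per-fold `evaluation_report`s (with per-scheme
#'   single-encoder AUCs attached), and a `summary` data.frame of mean and
#'   standard error per metric across folds.
#' @export
kfold_cv <- function(ws, k = 5L, fpr_cap = 0.20, seed = 1L, ...) {
  stopifnot(inherits(ws, "window_set"))
  k <- as.integer(k)
  n <- n_windows(ws)
  if (min(n) < k) {
    stop(sprintf("each class needs >= %d windows for %d-fold CV", k, k))
  }
  folds <- stratified_folds(ws$label, k, seed)
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    tr_ws <- subset_windows(ws, folds != i)
    te_ws <- subset_windows(ws, folds == i)
    model <- train_fusion(tr_ws, seed = seed + i, ...)
    pred <- stats::predict(model, te_ws)
    rep <- evaluate_scores(pred$fused, te_ws$label, fpr_cap)
    rep$scheme_auc <- c(
      CKSAAP = auc_score(pred$cksaap, te_ws$label),
      BINARY = auc_score(pred$binary, te_ws$label),
      AAC = auc_score(pred$aac, te_ws$label))
    rep$weights <- model$weights
    reports[[i]] <- rep
  }
  vals <- sapply(reports, function(r) unlist(r[cv_metric_names]))
  summ <- data.frame(metric = cv_metric_names,
                     mean = rowMeans(vals),
                     se = apply(vals, 1L, stats::sd) / sqrt(k),
                     row.names = NULL)
  structure(list(folds = reports, summary = summ, k = k,
                 fpr_cap = fpr_cap, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold CV @ FPR cap %.2f\n", x$k, x$fpr_cap))
  print(within(x$summary, {mean <- round(mean, 4); se <- round(se, 4)}))
  invisible(x)
}

#' Mean cross-validated value of one metric
#'
#' @param cv a `cv_result`.
#' @param metric one of `TPR`, `TNR`, `FPR`, `FNR`, `ACC`, `MCR`, `MCC`,
#'   `auc`, `pauc`.
#' @return named numeric `c(mean = , se = )`.
#' @export
cv_metric <- function(cv, metric) {
  stopifnot(inherits(cv, "cv_result"))
  row <- cv$summary[cv$summary$metric == metric, ]
  if (!nrow(row)) stop("unknown metric: ", metric)
  c(mean = row$mean, se = row$se)
}
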