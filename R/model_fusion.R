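#' Train a single classifier backend on an encoded feature matrix
#'
#' Backends share a common score contract: `score_backend()` maps feature
#' rows to a probability-like score for the positive class in `[0, 1]`, so
#' the convex fusion of scores across encoders is well-defined regardless of
#' classifier family.
#'
#' * `RF` — probability random forest ([ranger::ranger()]); the score is the
#'   predicted positive-class probability, and out-of-bag predictions are
#'   retained as an internal resampling performance estimate.
#' * `ADA` — discrete AdaBoost over depth-1 [rpart::rpart()] decision
#'   stumps; the additive margin F(x) is mapped to a score via the logistic
#'   link `1 / (1 + exp(-2 F))`.
#' * `SVM` — RBF-kernel [e1071::svm()] with Platt-calibrated probability
#'   outputs.
#'
#' @param fm a `feature_matrix` (labels included).
#' @param family `"RF"`, `"ADA"` or `"SVM"`.
#' @param seed integer seed governing bootstraps / calibration folds.
#' @param ntree number of random-forest trees (RF only; default 500).
#' @param ada_iter number of boosting rounds (ADA only; default 100).
#' @param svm_cost soft-margin cost (SVM only; default 1).
#' @return a `phosfuse_backend` object.
#' @export
train_backend <- function(fm, family = c("RF", "ADA", "SVM"), seed = 1L,
                          ntree = 500L, ada_iter = 100L, svm_cost = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  family <- match.arg(family)
  y <- fm$labels
  if (nlevels(droplevels(y)) < 2L) {
    stop("training labels contain a single class")
  }
  if (min(table(y)) < 2L) stop("need at least 2 windows per class")
  x <- fm$x
  fit <- switch(family,
    RF = {
      rf <- ranger::ranger(x = x, y = y, probability = TRUE,
                           num.trees = ntree, seed = seed,
                           num.threads = 1L)
      list(model = rf, oob = rf$predictions[, "positive"])
    },
    ADA = with_seed(seed, ada_stumps_fit(x, y, iter = ada_iter)),
    SVM = with_seed(seed, {
      list(model = e1071::svm(x = x, y = y, kernel = "radial",
                              cost = svm_cost, probability = TRUE,
                              scale = FALSE))
    })
  )
  structure(list(family = family, fit = fit, scheme = fm$scheme,
                 feature_names = colnames(x),
                 params = list(seed = seed, ntree = ntree,
                               ada_iter = ada_iter, svm_cost = svm_cost)),
            class = "phosfuse_backend")
}

#' Score windows with a fitted backend
#'
#' @param backend a `phosfuse_backend`.
#' @param x numeric matrix whose columns match the backend's training
#'   features by name.
#' @return numeric vector of positive-class scores in `[0, 1]`.
#' @export
score_backend <- function(backend, x) {
  stopifnot(inherits(backend, "phosfuse_backend"))
  if (is.null(colnames(x)) || !all(backend$feature_names %in% colnames(x))) {
    stop("feature-name mismatch between backend and input matrix")
  }
  x <- x[, backend$feature_names, drop = FALSE]
  switch(backend$family,
    RF = stats::predict(backend$fit$model, data = x,
                        num.threads = 1L)$predictions[, "positive"],
    ADA = ada_stumps_score(backend$fit, x),
    SVM = {
      pr <- attr(stats::predict(backend$fit$model, newdata = x,
                                probability = TRUE), "probabilities")
      pr[, "positive"]
    })
}

# Discrete AdaBoost with depth-1 rpart stumps. Labels in {-1,+1}; per round
# the stump minimizing weighted error is fit, weighted by alpha_t =
# 0.5 log((1-e)/e); early exit on a perfect or uninformative stump.
ada_stumps_fit <- function(x, y, iter) {
  yy <- ifelse(y == "positive", 1, -1)
  n <- nrow(x)
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  wts <- rep(1 / n, n)
  stumps <- vector("list", iter)
  alphas <- numeric(iter)
  t_used <- 0L
  ctrl <- rpart::rpart.control(maxdepth = 1L, cp = -1, minsplit = 2L,
                               minbucket = 1L, xval = 0L)
  dat <- cbind(.y = factor(yy, levels = c(-1, 1)), df)
  for (t in seq_len(iter)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = wts, method = "class",
                        control = ctrl)
    pred <- as.numeric(as.character(stats::predict(fit, type = "class")))
    err <- sum(wts[pred != yy]) / sum(wts)
    if (err >= 0.5) break           # weak learner no better than chance
    err <- max(err, 1e-12)
    alpha <- 0.5 * log((1 - err) / err)
    t_used <- t
    stumps[[t]] <- fit
    alphas[t] <- alpha
    if (err <= 1e-12) break         # perfect stump; margin already decided
    wts <- wts * exp(-alpha * yy * pred)
    wts <- wts / sum(wts)
  }
  if (t_used == 0L) stop("AdaBoost found no informative stump")
  list(stumps = stumps[seq_len(t_used)], alphas = alphas[seq_len(t_used)],
       colmap = names(df))
}

ada_stumps_score <- function(fit, x) {
  df <- as.data.frame(x)
  names(df) <- fit$colmap
  f <- numeric(nrow(x))
  for (t in seq_along(fit$stumps)) {
    pred <- as.numeric(as.character(
      stats::predict(fit$stumps[[t]], newdata = df, type = "class")))
    f <- f + fit$alphas[t] * pred
  }
  1 / (1 + exp(-2 * f))
}

#' Performance-proportional fusion weights
#'
#' Normalizes per-scheme performance values to convex weights
#' `w_i = perf_i / sum(perf)`, so the encoder that predicts best on its own
#' carries the most weight in the fused score.
#'
#' @param perf numeric vector of per-scheme performances (all > 0), e.g.
#'   internal-CV AUCs for CKSAAP, binary and AAC.
#' @return numeric weights of the same length, summing to 1.
#' @export
derive_weights <- function(perf) {
  nm <- names(perf)
  perf <- as.numeric(perf)
  if (any(!is.finite(perf)) || any(perf <= 0)) {
    stop("all performance values must be finite and > 0")
  }
  stats::setNames(perf / sum(perf), nm)
}

#' Train the three-encoder fusion model
#'
#' Encodes the training windows under the CKSAAP, binary and AAC schemes,
#' ranks CKSAAP and binary features by the Kruskal-Wallis statistic and
#' keeps the top N of each (AAC's 20 features pass through unselected),
#' trains one classifier backend per scheme, and derives convex fusion
#' weights proportional to each scheme's standalone performance.
#'
#' Weight modes: `"cv"` (default) uses an internal resampling AUC — the
#' out-of-bag estimate for RF, a 3-fold internal CV for ADA/SVM; `"train"`
#' uses training-set AUC; `"manual"` uses `manual_weights` as given
#' (normalized to sum 1).
#'
#' @param ws training `window_set`.
#' @param family classifier family for all three backends
#'   (`"RF"`, `"ADA"`, `"SVM"`).
#' @param kmax maximum CKSAAP gap (default 5).
#' @param top_n named vector of features to keep per scheme; default
#'   `c(CKSAAP = 1500, BINARY = 400)` (capped at the scheme dimension);
#'   schemes absent from the vector are not selected.
#' @param weights one of `"cv"`, `"train"`, `"manual"`.
#' @param manual_weights length-3 numeric (CKSAAP, BINARY, AAC) when
#'   `weights = "manual"`.
#' @param seed integer seed for backends and internal CV.
#' @param ntree,ada_iter,svm_cost backend hyperparameters, see
#'   [train_backend()].
#' @param internal_k folds for the internal CV used by non-RF weight
#'   derivation (default 3).
#' @return a `fusion_model`: backends, weights, selected feature names per
#'   scheme, and training metadata.
#' @export
train_fusion <- function(ws, family = c("RF", "ADA", "SVM"), kmax = 5L,
                         top_n = c(CKSAAP = 1500L, BINARY = 400L),
                         weights = c("cv", "train", "manual"),
                         manual_weights = NULL, seed = 1L, ntree = 500L,
                         ada_iter = 100L, svm_cost = 1, internal_k = 3L) {
  stopifnot(inherits(ws, "window_set"))
  family <- match.arg(family)
  weights <- match.arg(weights)
  schemes <- c("CKSAAP", "BINARY", "AAC")
  backends <- list()
  selected <- list()
  perf <- numeric(3)
  names(perf) <- schemes
  for (s in schemes) {
    fm <- encode_matrix(ws, scheme = s, kmax = kmax)
    if (s %in% names(top_n) && !is.na(top_n[[s]])) {
      n_keep <- min(as.integer(top_n[[s]]), ncol(fm$x))
      fm <- select_top_n(fm, n_keep)$fm
    }
    selected[[s]] <- colnames(fm$x)
    b <- train_backend(fm, family = family, seed = seed, ntree = ntree,
                       ada_iter = ada_iter, svm_cost = svm_cost)
    backends[[s]] <- b
    perf[s] <- switch(weights,
      manual = 1,
      train = auc_score(score_backend(b, fm$x), fm$labels),
      cv = if (family == "RF") {
        auc_score(b$fit$oob, fm$labels)
      } else {
        internal_cv_auc(fm, family, k = internal_k, seed = seed,
                        ntree = ntree, ada_iter = ada_iter,
                        svm_cost = svm_cost)
      })
  }
  wt <- if (weights == "manual") {
    if (is.null(manual_weights) || length(manual_weights) != 3L) {
      stop("manual_weights must be a length-3 numeric vector")
    }
    mw <- as.numeric(manual_weights)
    if (any(mw < 0) || sum(mw) <= 0) stop("manual weights must be >= 0")
    stats::setNames(mw / sum(mw), schemes)
  } else {
    derive_weights(perf)
  }
  structure(list(backends = backends, weights = wt,
                 selected_features = selected,
                 scheme_performance = if (weights != "manual") perf else NULL,
                 meta = list(family = family, w = attr(ws, "w"),
                             kmax = kmax, weights_mode = weights,
                             seed = seed, n_train = n_windows(ws))),
            class = "fusion_model")
}

internal_cv_auc <- function(fm, family, k, seed, ...) {
  y <- fm$labels
  folds <- stratified_folds(y, k, seed)
  scores <- numeric(length(y))
  for (i in seq_len(k)) {
    tr <- folds != i
    sub <- new_feature_matrix(fm$x[tr, , drop = FALSE], y[tr], fm$scheme,
                              fm$params)
    b <- train_backend(sub, family = family, seed = seed + i, ...)
    scores[!tr] <- score_backend(b, fm$x[!tr, , drop = FALSE])
  }
  auc_score(scores, y)
}

# label-stratified fold assignment, deterministic per seed
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(factor(labels))) {
      idx <- which(labels == lv)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("fusion_model (%s): weights CKSAAP=%.3f BINARY=%.3f AAC=%.3f\n",
              x$meta$family, x$weights[["CKSAAP"]], x$weights[["BINARY"]],
              x$weights[["AAC"]]))
  cat(sprintf("  selected features: %d / %d / %d; trained on %d+%d windows\n",
              length(x$selected_features$CKSAAP),
              length(x$selected_features$BINARY),
              length(x$selected_features$AAC),
              x$meta$n_train[["n1"]], x$meta$n_train[["n2"]]))
  invisible(x)
}

#' Score windows with a fusion model
#'
#' Encodes each window under the three schemes, restricts to the model's
#' selected features, scores the three backends, and returns the convex
#' combination `w1*CKSAAP + w2*BINARY + w3*AAC`.
#'
#' @param object a `fusion_model`.
#' @param ws a `window_set` of windows to score (same half-width as
#'   training).
#' @param ... unused.
#' @return data.frame with per-scheme scores and the `fused` score, row per
#'   window.
#' @export
predict.fusion_model <- function(object, ws, ...) {
  stopifnot(inherits(ws, "window_set"))
  if (attr(ws, "w") != object$meta$w) {
    stop(sprintf("model expects w = %d windows, got w = %d",
                 object$meta$w, attr(ws, "w")))
  }
  out <- data.frame(protein_id = ws$protein_id, center_pos = ws$center_pos)
  fused <- numeric(nrow(ws))
  for (s in names(object$backends)) {
    fm <- encode_matrix(ws, scheme = s, kmax = object$meta$kmax)
    miss <- setdiff(object$selected_features[[s]], colnames(fm$x))
    if (length(miss)) {
      stop(sprintf("encoder output lacks %d feature(s) expected by the %s backend (e.g. %s)",
                   length(miss), s, miss[1L]))
    }
    sc <- score_backend(object$backends[[s]],
                        fm$x[, object$selected_features[[s]], drop = FALSE])
    out[[tolower(s)]] <- sc
    fused <- fused + object$weights[[s]] * sc
  }
  out$fused <- fused
  out
}

#' Fused score for a single peptide window
#'
#' @param model a `fusion_model`.
#' @param peptide a single window peptide string (length 2w+1, center `S`).
#' @return the fused score, a number in `[0, 1]`.
#' @export
fuse_scores <- function(model, peptide) {
  w <- model$meta$w
  df <- data.frame(protein_id = "query", center_pos = w + 1L,
                   peptide = peptide, label = "negative",
                   stringsAsFactors = FALSE)
  stats::predict(model, new_window_set(df, w))$fused
}

#' Save / load a fusion model
#'
#' @param model a `fusion_model`.
#' @param path file path (RDS).
#' @return `load_model()` returns the `fusion_model`; `save_model()` its
#'   input, invisibly. The round trip preserves scores exactly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fusion_model"))
  saveRDS(model, path)
  invisible(model)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fusion_model")) stop("not a saved fusion_model")
  model
}
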