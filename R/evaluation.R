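#' Stratified cross-validation folds with train/validation/test partitions
#'
#' Splits subjects into `n_folds` stratified test folds (each subject is
#' tested exactly once); within each fold the remaining 80% is split 80/20,
#' stratified, into training and validation — i.e. 64/16/20 of the cohort.
#'
#' @param labels two-level factor (or coercible), one per subject.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return list of folds, each a list (fold_id, train, val, test) of subject
#'   indices.
#' @export
make_folds <- function(labels, n_folds = 5, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < n_folds))
    stop("each class needs at least n_folds subjects")
  set.seed(seed)
  test_assign <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    test_assign[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  lapply(seq_len(n_folds), function(f) {
    test <- which(test_assign == f)
    rest <- which(test_assign != f)
    val <- integer(0)
    for (cl in levels(labels)) {
      cl_rest <- sample(rest[labels[rest] == cl])
      n_val <- round(0.2 * length(cl_rest))
      val <- c(val, cl_rest[seq_len(n_val)])
    }
    list(fold_id = f, train = sort(setdiff(rest, val)), val = sort(val),
         test = sort(test))
  })
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, sensitivity (recall on the positive class), specificity,
#' precision, and F1 (harmonic mean of precision and sensitivity). The case
#' group is the positive class. Metrics whose denominator is empty (e.g.
#' sensitivity with no positive labels) are reported as `NA`, not 0.
#'
#' @param predictions,labels aligned factors/vectors.
#' @param positive positive-class label (default "case").
#' @return one-row data.frame (accuracy, sensitivity, specificity,
#'   precision, f1).
#' @export
compute_metrics <- function(predictions, labels, positive = "case") {
  stopifnot(length(predictions) == length(labels))
  p <- predictions == positive
  y <- labels == positive
  tp <- sum(p & y); fn <- sum(!p & y); tn <- sum(!p & !y); fp <- sum(p & !y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  data.frame(accuracy = (tp + tn) / length(labels), sensitivity = sens,
             specificity = spec, precision = prec, f1 = f1)
}

## Standardise with statistics of the fitting rows only.
fold_scaler <- function(X, fit_rows) {
  mu <- colMeans(X[fit_rows, , drop = FALSE])
  sd <- apply(X[fit_rows, , drop = FALSE], 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd,
       apply = function(M) sweep(sweep(M, 2, mu), 2, sd, "/"))
}

#' Cross-validated connectivity classification pipeline
#'
#' For each stratified fold: standardise with training-partition statistics,
#' optionally run SVM-RFE on the training partition (or reuse one global
#' RFE), pre-train and fine-tune the SSAE on the training data with model
#' selection on validation accuracy, and score the held-out test partition.
#' A leakage audit records, per fold, every subject index that entered any
#' fitting call.
#'
#' @param features n x p Fisher-Z feature matrix.
#' @param labels two-level factor (levels control, case).
#' @param ssae an [ssae_config()]; its `input_dim` is overridden to the
#'   post-selection width.
#' @param rfe_k features to keep by SVM-RFE, or `NULL` to skip selection.
#' @param rfe_step RFE step fraction.
#' @param global_rfe if `TRUE`, run RFE once on the full cohort (the leaky
#'   alternative) instead of per training fold.
#' @param n_folds,seed CV settings.
#' @return list of class `cv_result`: `metrics` (per-fold data.frame),
#'   `mean`, `sd` (named metric vectors), `folds` (per-fold details:
#'   split, selected feature indices, trained model, scaler, fit_ids).
#' @export
run_cv <- function(features, labels, ssae = ssae_config(),
                   rfe_k = NULL, rfe_step = 0.1, global_rfe = FALSE,
                   n_folds = 5, seed = 1L) {
  labels <- as.factor(labels)
  folds <- make_folds(labels, n_folds, seed)
  global_sel <- NULL
  if (!is.null(rfe_k) && global_rfe) {
    sc <- fold_scaler(features, seq_len(nrow(features)))
    global_sel <- svm_rfe(sc$apply(features), labels, rfe_k, rfe_step)
  }
  per_fold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    fit_ids <- fold$train
    sc <- fold_scaler(features, fold$train)
    Xtr <- sc$apply(features[fold$train, , drop = FALSE])
    Xva <- sc$apply(features[fold$val, , drop = FALSE])
    Xte <- sc$apply(features[fold$test, , drop = FALSE])
    if (!is.null(rfe_k)) {
      sel <- if (global_rfe) global_sel else
        svm_rfe(Xtr, labels[fold$train], rfe_k, rfe_step)
      keep <- sort(sel$selected_indices)
      Xtr <- Xtr[, keep, drop = FALSE]
      Xva <- Xva[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
    } else {
      sel <- NULL
      keep <- seq_len(ncol(features))
    }
    cfg <- ssae
    cfg$input_dim <- ncol(Xtr)
    cfg$seed <- ssae$seed + 1000L * f
    pre <- ssae_pretrain(Xtr, cfg)
    model <- ssae_finetune(pre, Xtr, labels[fold$train], cfg,
                           Xva, labels[fold$val])
    fit_ids <- union(fit_ids, fold$val)  # val steers model selection
    pred <- predict(model, Xte)
    per_fold[[f]] <- list(
      fold = fold, selected = keep, rfe = sel, model = model, scaler = sc,
      fit_ids = sort(fit_ids),
      metrics = cbind(fold_id = f,
                      compute_metrics(pred, labels[fold$test])))
  }
  metrics <- do.call(rbind, lapply(per_fold, `[[`, "metrics"))
  mcols <- setdiff(names(metrics), "fold_id")
  structure(list(metrics = metrics,
                 mean = colMeans(metrics[mcols], na.rm = TRUE),
                 sd = apply(metrics[mcols], 2, stats::sd, na.rm = TRUE),
                 folds = per_fold, labels = labels),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated SSAE pipeline:", nrow(x$metrics), "folds\n")
  m <- x$mean; s <- x$sd
  for (n in names(m))
    cat(sprintf("  %-11s %.3f +/- %.3f\n", n, m[n], s[n]))
  invisible(x)
}
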