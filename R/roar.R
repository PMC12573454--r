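#' The published Remove-And-Retrain removal thresholds
#' @return numeric vector of 13 proportions.
#' @export
roar_thresholds <- function() {
  c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99)
}

#' Zero-impute the top-ranked features
#'
#' Sets the top `ceiling(threshold * n_features)` features of `ranking` to
#' zero in every sample — train, validation and test alike — leaving all
#' other values untouched. Zero is the uninformative value for connectivity
#' features (no positive or negative relationship). Ties at the cut are
#' resolved by the ranking's own deterministic order (ascending feature
#' index among equals).
#'
#' @param features sample x feature matrix.
#' @param ranking ordered integer vector of feature indices, most important
#'   first, covering all columns.
#' @param threshold proportion in (0, 1) of top features to remove.
#' @return modified copy of `features`.
#' @export
ablate_features <- function(features, ranking, threshold) {
  p <- ncol(features)
  if (length(ranking) != p || !setequal(ranking, seq_len(p)))
    stop("ranking must be a permutation of all feature indices")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  drop <- ranking[seq_len(ceiling(threshold * p))]
  features[, drop] <- 0
  features
}

#' Remove-And-Retrain benchmark over attribution rankings
#'
#' For every (ranking, threshold) pair: zero-impute the top-ranked features
#' in all partitions of the supplied fold split, retrain the SSAE from
#' scratch (pre-training + fine-tuning, fresh seed per repeat, original
#' hyperparameters), and record test accuracy. A ranking whose removal
#' causes the steeper accuracy drop identified the more critical features.
#' A uniformly random ranking (redrawn per repeat) should always be
#' included as the reference; pass it as one element of `rankings` via
#' `random = TRUE` semantics below.
#'
#' @param features sample x feature matrix already reduced to the model's
#'   input width (standardised per the split's training rows internally).
#' @param labels two-level factor.
#' @param split one fold split (list with train/val/test index vectors),
#'   e.g. from [make_folds()].
#' @param rankings named list; each element is an ordered feature-index
#'   vector (most important first) or the string "random" for the
#'   per-repeat random baseline.
#' @param thresholds removal proportions (default [roar_thresholds()]).
#' @param ssae an [ssae_config()] reused unchanged for every retrain.
#' @param n_seeds retrain repeats per (method, threshold) (default 3).
#' @param seed base seed; retrain seed r of method m uses offsets derived
#'   from it.
#' @return list of class `roar_result`: `results` (data.frame method,
#'   threshold, seed, accuracy), `summary` (mean/sd per method x
#'   threshold), `auc` (per-method area under the accuracy-vs-threshold
#'   curve), `baseline_accuracy` (unablated retrain accuracy, mean over
#'   seeds).
#' @export
run_roar <- function(features, labels, split, rankings,
                     thresholds = roar_thresholds(),
                     ssae = ssae_config(), n_seeds = 3, seed = 1L) {
  stopifnot(!is.null(names(rankings)), all(nzchar(names(rankings))))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  labels <- as.factor(labels)
  p <- ncol(features)
  retrain_acc <- function(X, rseed) {
    sc <- fold_scaler(X, split$train)
    cfg <- ssae
    cfg$input_dim <- p
    cfg$seed <- rseed
    Xtr <- sc$apply(X[split$train, , drop = FALSE])
    pre <- ssae_pretrain(Xtr, cfg)
    model <- ssae_finetune(pre, Xtr, labels[split$train], cfg,
                           sc$apply(X[split$val, , drop = FALSE]),
                           labels[split$val])
    pred <- predict(model, sc$apply(X[split$test, , drop = FALSE]))
    compute_metrics(pred, labels[split$test])$accuracy
  }
  base_acc <- vapply(seq_len(n_seeds), function(r)
    retrain_acc(features, seed + 7000L + r), 0)
  rows <- list()
  for (m in names(rankings)) {
    for (r in seq_len(n_seeds)) {
      rk <- rankings[[m]]
      if (identical(rk, "random")) {
        set.seed(seed + 9000L + r)
        rk <- sample.int(p)
      }
      for (t in thresholds) {
        acc <- retrain_acc(ablate_features(features, rk, t),
                           seed + 100L * match(m, names(rankings)) + r)
        rows[[length(rows) + 1L]] <-
          data.frame(method = m, threshold = t, seed = r, accuracy = acc)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results,
                                         results[c("method", "threshold")],
                                         drop = TRUE), function(d)
    data.frame(method = d$method[1], threshold = d$threshold[1],
               mean_accuracy = mean(d$accuracy),
               sd_accuracy = stats::sd(d$accuracy))))
  rownames(summary) <- NULL
  auc <- vapply(unique(summary$method), function(m) {
    d <- summary[summary$method == m, ]
    d <- d[order(d$threshold), ]
    sum(diff(d$threshold) *
          (head(d$mean_accuracy, -1) + tail(d$mean_accuracy, -1)) / 2)
  }, 0)
  structure(list(results = results, summary = summary, auc = auc,
                 baseline_accuracy = mean(base_acc),
                 thresholds = thresholds),
            class = "roar_result")
}
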