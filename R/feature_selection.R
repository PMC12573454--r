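#' SVM recursive feature elimination
#'
#' Iteratively fits a linear soft-margin SVM (C = 1) on the surviving
#' features, ranks them by squared weight magnitude, and removes the
#' lowest-ranked `step_fraction` of survivors (at least one, never
#' overshooting below `k`) until exactly `k` features remain. Features are
#' standardised to zero mean / unit variance on the fitting data before every
#' fit, so the weight magnitudes are comparable across features.
#'
#' @param features n_subjects x n_features numeric matrix.
#' @param labels two-level factor (or coercible), one entry per row.
#' @param k number of features to retain.
#' @param step_fraction fraction of surviving features eliminated per
#'   iteration (default 0.1); `0` forces one-at-a-time elimination.
#' @param cost SVM cost parameter (default 1).
#' @return list of class `rfe_result`: `selected_indices` (ordered by
#'   decreasing final importance), `elimination_order` (list of
#'   (iteration, eliminated_indices)), `ranking` (integer per feature,
#'   1 = eliminated first; survivors continue the sequence in increasing
#'   final importance, so rank n_features = most important survivor).
#' @export
svm_rfe <- function(features, labels, k, step_fraction = 0.1, cost = 1) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("svm_rfe needs two classes in `labels`")
  if (min(table(labels)) < 2) stop("need at least 2 subjects per class")
  n_features <- ncol(features)
  if (k >= n_features) stop("k must be smaller than the number of features")
  surviving <- seq_len(n_features)
  ranking <- integer(n_features)
  elimination_order <- list()
  next_rank <- 1L
  iter <- 0L
  w2 <- NULL
  while (length(surviving) > k) {
    iter <- iter + 1L
    w2 <- rfe_weights2(features[, surviving, drop = FALSE], labels, cost)
    n_drop <- max(1L, floor(step_fraction * length(surviving)))
    n_drop <- min(n_drop, length(surviving) - k)
    ## ties in |w| broken by ascending feature index (order() is stable)
    drop_local <- order(w2)[seq_len(n_drop)]
    dropped <- surviving[sort(drop_local)]
    ## within one sweep, rank in ascending-importance order (stable ties)
    for (f in surviving[drop_local]) {
      ranking[f] <- next_rank
      next_rank <- next_rank + 1L
    }
    elimination_order[[iter]] <- list(iteration = iter,
                                      eliminated_indices = dropped)
    surviving <- setdiff(surviving, dropped)
  }
  w2 <- rfe_weights2(features[, surviving, drop = FALSE], labels, cost)
  ord <- order(w2, surviving)  # ascending importance among survivors
  ranking[surviving[ord]] <- seq(next_rank, length.out = length(surviving))
  structure(
    list(selected_indices = surviving[order(w2, decreasing = TRUE)],
         elimination_order = elimination_order,
         ranking = ranking,
         k = k),
    class = "rfe_result")
}

## Squared linear-SVM weights for the surviving feature block.
rfe_weights2 <- function(X, labels, cost) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  Xs <- scale(X, center = mu, scale = sd)
  fit <- e1071::svm(Xs, labels, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)
  as.numeric(w)^2
}
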