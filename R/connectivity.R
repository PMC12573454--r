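#' Filter a cohort by mean framewise displacement
#'
#' Head motion above 0.2 mm mean FD is widely treated as corrupting
#' resting-state data; subjects with `mean_fd` strictly greater than the
#' threshold are excluded, so the boundary value itself is retained.
#'
#' @param cohort list of subject records carrying `mean_fd`.
#' @param threshold_mm exclusion threshold in millimetres (default 0.2).
#' @return the retained subjects, original order preserved, with attributes
#'   `n_retained` and `n_excluded`.
#' @export
filter_by_fd <- function(cohort, threshold_mm = 0.2) {
  fd <- vapply(cohort, `[[`, 0, "mean_fd")
  if (any(is.na(fd))) stop("every subject must have a mean_fd value")
  keep <- fd <= threshold_mm
  if (!any(keep)) warning("FD filter removed every subject")
  out <- cohort[keep]
  class(out) <- class(cohort)
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Functional connectivity matrix of one ROI time series
#'
#' Pairwise Pearson correlation between ROI columns.
#'
#' @param timeseries numeric matrix, rows = timepoints, columns = ROIs.
#' @return symmetric n_rois x n_rois correlation matrix with unit diagonal.
#' @export
compute_fcm <- function(timeseries) {
  if (nrow(timeseries) < 2) stop("need at least 2 timepoints")
  v <- apply(timeseries, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance ROI column(s): ",
         paste(which(v == 0), collapse = ", "))
  R <- stats::cor(timeseries)
  dimnames(R) <- NULL
  R
}

#' Fisher Z (arctanh) transformation of a correlation matrix
#'
#' Correlations are clipped to +/-(1 - eps) before arctanh so degenerate
#' r = +/-1 entries stay finite.
#'
#' @param r correlation matrix or vector, entries in `[-1, 1]`.
#' @param eps clipping margin (default 1e-7).
#' @return transformed values, same shape as `r`.
#' @export
fisher_z <- function(r, eps = 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Feature index map for lower-triangle vectorization
#'
#' Fixes the flattening convention for symmetric connectivity matrices:
#' row-major over the strict lower triangle, i.e. feature f runs over ROI
#' pairs (i, j) with i > j, i ascending and j ascending within i. For 116
#' ROIs this yields 6670 features.
#'
#' @param n_rois number of regions.
#' @return data.frame (feature_index, roi_i, roi_j) with roi_i > roi_j and
#'   feature_index dense 1..n_rois(n_rois-1)/2.
#' @export
feature_index_map <- function(n_rois) {
  i <- rep(2:n_rois, times = 1:(n_rois - 1))
  j <- unlist(lapply(2:n_rois, function(k) seq_len(k - 1)))
  data.frame(feature_index = seq_along(i), roi_i = i, roi_j = j)
}

#' Vectorize the lower triangle of a connectivity matrix
#'
#' @param fcm symmetric matrix.
#' @param index_map a [feature_index_map()] of matching dimension.
#' @return numeric vector ordered per the index map (diagonal excluded).
#' @export
vectorize_fcm <- function(fcm, index_map = feature_index_map(nrow(fcm))) {
  n <- nrow(fcm)
  if (ncol(fcm) != n) stop("fcm must be square")
  if (max(index_map$roi_i) != n)
    stop("index map dimension does not match matrix")
  if (max(abs(fcm - t(fcm))) > 1e-8) stop("fcm must be symmetric")
  fcm[cbind(index_map$roi_i, index_map$roi_j)]
}

#' Rebuild a symmetric matrix from its lower-triangle vector
#'
#' Inverse of [vectorize_fcm()] on the off-diagonal; the diagonal is set to
#' `diag_value`.
#' @param values feature vector.
#' @param index_map matching [feature_index_map()].
#' @param diag_value diagonal fill (default 1).
#' @return symmetric matrix.
#' @export
devectorize_fcm <- function(values, index_map, diag_value = 1) {
  n <- max(index_map$roi_i)
  m <- matrix(0, n, n)
  m[cbind(index_map$roi_i, index_map$roi_j)] <- values
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Extract Fisher-Z connectivity features for a whole cohort
#'
#' Runs [compute_fcm()], [fisher_z()] and [vectorize_fcm()] per subject and
#' stacks the results.
#'
#' @param cohort list of subject records with `timeseries`.
#' @return list with `features` (n_subjects x n_features matrix, rownames =
#'   subject ids), `labels` (factor, levels control/case), `index_map`,
#'   `subject_ids`.
#' @export
extract_features <- function(cohort) {
  if (!length(cohort)) stop("empty cohort")
  n_rois <- ncol(cohort[[1]]$timeseries)
  imap <- feature_index_map(n_rois)
  feats <- t(vapply(cohort, function(s) {
    fisher_z(vectorize_fcm(compute_fcm(s$timeseries), imap))
  }, numeric(nrow(imap))))
  rownames(feats) <- vapply(cohort, `[[`, "", "subject_id")
  labels <- factor(vapply(cohort, `[[`, "", "label"),
                   levels = c("control", "case"))
  list(features = feats, labels = labels, index_map = imap,
       subject_ids = rownames(feats))
}
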