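#' Cohort specification for synthetic two-group connectivity data
#'
#' Describes a simulated resting-state cohort: two diagnostic groups sharing a
#' block-structured baseline correlation matrix across `n_rois` regions, with a
#' configurable set of ROI-pair correlation shifts planted in the case group,
#' and a motion-corrupted subpopulation whose time series carry extra additive
#' noise and whose mean framewise displacement (FD) falls above the usual
#' 0.2 mm exclusion threshold.
#'
#' Baseline structure: ROIs are partitioned into `n_blocks` contiguous
#' "networks"; within-block correlations equal `base_correlation`,
#' between-block correlations are zero, and `planted_pairs` shifts are applied
#' on top. This gives downstream feature selection and attribution a
#' realistically correlated nuisance background rather than white noise.
#'
#' @param n_per_group subjects per diagnostic group.
#' @param n_rois number of regions (AAL-style parcellation; default 116).
#' @param n_timepoints scan length in volumes (default 150, typical of
#'   resting-state runs).
#' @param planted_pairs data.frame with columns `roi_i`, `roi_j`, `delta_r`
#'   (1-based ROI indices, correlation shift applied to the case group).
#' @param base_correlation within-block baseline correlation, in (-1, 1).
#' @param n_blocks number of network blocks the ROIs are partitioned into.
#' @param noise_sd measurement noise sd added to every subject's series.
#' @param motion_fraction proportion of each group flagged as motion-corrupted.
#' @param motion_fd_range,clean_fd_range mm intervals the per-subject mean FD
#'   is drawn from for corrupted / clean subjects.
#' @param motion_noise_sd extra i.i.d. noise sd added to corrupted subjects.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 100,
                        n_rois = 116,
                        n_timepoints = 150,
                        planted_pairs = default_planted_pairs(),
                        base_correlation = 0.3,
                        n_blocks = 8,
                        noise_sd = 0.1,
                        motion_fraction = 0.2,
                        motion_fd_range = c(0.25, 0.6),
                        clean_fd_range = c(0.02, 0.18),
                        motion_noise_sd = 2.0,
                        seed = 1L) {
  spec <- structure(
    list(n_per_group = as.integer(n_per_group),
         n_rois = as.integer(n_rois),
         n_timepoints = as.integer(n_timepoints),
         planted_pairs = as.data.frame(planted_pairs),
         base_correlation = base_correlation,
         n_blocks = as.integer(n_blocks),
         noise_sd = noise_sd,
         motion_fraction = motion_fraction,
         motion_fd_range = motion_fd_range,
         clean_fd_range = clean_fd_range,
         motion_noise_sd = motion_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Default planted connectivity effect: one hub plus diffuse background
#'
#' Two components, mirroring how group differences present in real
#' case-control connectivity data. (1) A dominant hub: every connection
#' between ROI 43 (Calcarine_L in AAL order) and 17 partner regions spread
#' across the atlas is shifted by +/-0.15 — one strongly implicated region.
#' (2) A diffuse background: 70 further ROI pairs, none touching the hub,
#' each shifted by +/-0.15 — individually weak, collectively informative,
#' the regime in which feature selection and sparse coding earn their keep.
#' The pair list is built from a fixed internal random stream (the global
#' RNG state is saved and restored), so it is a constant of the package.
#'
#' @return data.frame of (roi_i, roi_j, delta_r), hub rows first.
#' @export
default_planted_pairs <- function() {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  partners <- setdiff(seq(2, 116, 7), 43)
  set.seed(2)
  hub <- data.frame(roi_i = 43L, roi_j = partners,
                    delta_r = sample(c(-1, 1), length(partners),
                                     replace = TRUE) * 0.15)
  set.seed(3)
  all_pairs <- t(utils::combn(setdiff(1:116, 43L), 2))
  bg_idx <- sample(nrow(all_pairs), 70)
  bg <- data.frame(roi_i = as.integer(all_pairs[bg_idx, 2]),
                   roi_j = as.integer(all_pairs[bg_idx, 1]),
                   delta_r = sample(c(-0.15, 0.15), 70, replace = TRUE))
  rbind(hub, bg)
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_per_group >= 1, spec$n_rois >= 2, spec$n_timepoints >= 2)
  if (abs(spec$base_correlation) >= 1)
    stop("base_correlation must lie in (-1, 1)")
  if (spec$motion_fraction < 0 || spec$motion_fraction > 1)
    stop("motion_fraction must lie in [0, 1]")
  pp <- spec$planted_pairs
  if (nrow(pp)) {
    stopifnot(all(c("roi_i", "roi_j", "delta_r") %in% names(pp)))
    if (any(pp$roi_i == pp$roi_j))
      stop("planted pair ROI indices must be distinct")
    if (any(pp$roi_i > spec$n_rois | pp$roi_j > spec$n_rois |
            pp$roi_i < 1 | pp$roi_j < 1))
      stop("planted pair ROI indices must lie in 1..n_rois")
    if (anyDuplicated(t(apply(pp[, c("roi_i", "roi_j")], 1, sort))))
      stop("planted pairs must name each unordered ROI pair at most once")
  }
  invisible(spec)
}

## ROI -> network-block assignment: contiguous, near-equal blocks.
block_assignment <- function(n_rois, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n_rois))
}

## Target correlation matrix for one group. Planted shifts (case group only)
## are laid over the block baseline. Fails, naming the offending pair, if the
## result is not positive definite: repair is never applied silently.
group_correlation <- function(spec, planted = FALSE) {
  blk <- block_assignment(spec$n_rois, spec$n_blocks)
  R <- outer(blk, blk, "==") * spec$base_correlation
  diag(R) <- 1
  if (planted && nrow(spec$planted_pairs)) {
    for (r in seq_len(nrow(spec$planted_pairs))) {
      i <- spec$planted_pairs$roi_i[r]
      j <- spec$planted_pairs$roi_j[r]
      v <- R[i, j] + spec$planted_pairs$delta_r[r]
      if (abs(v) >= 1)
        stop(sprintf("planted shift at ROI pair (%d, %d) drives |r| to %.3f >= 1",
                     i, j, abs(v)))
      R[i, j] <- R[j, i] <- v
    }
  }
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    bad <- if (planted && nrow(spec$planted_pairs)) {
      sprintf("; check planted pair(s) %s",
              paste(sprintf("(%d,%d)", spec$planted_pairs$roi_i,
                            spec$planted_pairs$roi_j), collapse = ", "))
    } else ""
    stop("target correlation matrix is not positive definite", bad)
  }
  list(R = R, chol = ch)
}

#' Generate a synthetic two-group cohort of ROI time series
#'
#' Controls are drawn from a zero-mean multivariate normal with the block
#' baseline correlation matrix; cases are identical except that the planted
#' pair correlations are shifted by `delta_r`. A `motion_fraction` of each
#' group receives extra i.i.d. noise of sd `motion_noise_sd` per timepoint and
#' a mean-FD value drawn from `motion_fd_range`; the rest draw FD from
#' `clean_fd_range`. Each subject consumes its own seeded random stream, so
#' enlarging the cohort leaves earlier subjects bit-identical.
#'
#' @param spec a [cohort_spec()].
#' @return list of subject records, each with `subject_id`, `timeseries`
#'   (n_timepoints x n_rois matrix), `label` ("case"/"control"), `site`,
#'   `mean_fd`, `motion` (logical).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  ctrl <- group_correlation(spec, planted = FALSE)
  case <- group_correlation(spec, planted = TRUE)
  n <- spec$n_per_group
  n_motion <- as.integer(round(spec$motion_fraction * n))
  subjects <- vector("list", 2L * n)
  idx <- 0L
  for (grp in c("control", "case")) {
    ch <- if (grp == "case") case$chol else ctrl$chol
    for (s in seq_len(n)) {
      idx <- idx + 1L
      ## independent per-subject stream derived from the cohort seed
      set.seed((spec$seed %% 100000L) * 10000L + idx)
      Z <- matrix(stats::rnorm(spec$n_timepoints * spec$n_rois),
                  spec$n_timepoints, spec$n_rois)
      X <- Z %*% ch
      if (spec$noise_sd > 0)
        X <- X + matrix(stats::rnorm(length(X), sd = spec$noise_sd),
                        nrow(X), ncol(X))
      motion <- s <= n_motion
      if (motion && spec$motion_noise_sd > 0)
        X <- X + matrix(stats::rnorm(length(X), sd = spec$motion_noise_sd),
                        nrow(X), ncol(X))
      fd_range <- if (motion) spec$motion_fd_range else spec$clean_fd_range
      mean_fd <- stats::runif(1, fd_range[1], fd_range[2])
      subjects[[idx]] <- list(
        subject_id = sprintf("sub-%s-%03d", substr(grp, 1, 4), s),
        timeseries = X,
        label = grp,
        site = sprintf("site%02d", ((s - 1L) %% 4L) + 1L),
        mean_fd = mean_fd,
        motion = motion)
    }
  }
  structure(subjects, class = "fc_cohort", spec = spec)
}

#' Write a cohort to disk as plain-text matrices plus a phenotype CSV
#'
#' One whitespace-delimited matrix per subject (rows = timepoints, columns =
#' ROIs), in the style of Preprocessed Connectomes Project ROI time-series
#' exports, plus `phenotype.csv` with columns
#' `subject_id,label,site,mean_fd`.
#'
#' @param cohort output of [generate_cohort()].
#' @param directory output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  files <- character(0)
  for (s in cohort) {
    f <- file.path(directory, paste0(s$subject_id, "_rois.txt"))
    utils::write.table(format(s$timeseries, digits = 10, trim = TRUE,
                              scientific = FALSE),
                       f, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    files <- c(files, f)
  }
  pheno <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    label = vapply(cohort, `[[`, "", "label"),
    site = vapply(cohort, `[[`, "", "site"),
    mean_fd = vapply(cohort, `[[`, 0, "mean_fd"))
  pf <- file.path(directory, "phenotype.csv")
  utils::write.csv(pheno, pf, row.names = FALSE, quote = FALSE)
  invisible(c(files, pf))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory holding `*_rois.txt` files and `phenotype.csv`.
#' @return a cohort list in phenotype-file order.
#' @export
read_cohort <- function(directory) {
  pf <- file.path(directory, "phenotype.csv")
  if (!file.exists(pf)) stop("phenotype.csv not found in ", directory)
  pheno <- utils::read.csv(pf, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(pheno)), function(i) {
    f <- file.path(directory, paste0(pheno$subject_id[i], "_rois.txt"))
    if (!file.exists(f)) stop("missing time-series file: ", f)
    ts <- as.matrix(utils::read.table(f))
    dimnames(ts) <- NULL
    list(subject_id = pheno$subject_id[i],
         timeseries = ts,
         label = pheno$label[i],
         site = pheno$site[i],
         mean_fd = pheno$mean_fd[i])
  })
  structure(subjects, class = "fc_cohort")
}
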