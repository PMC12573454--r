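#' Bundled AAL-116 region table with Brodmann annotations
#'
#' The 116 Automated Anatomical Labelling regions in atlas file order, each
#' with its Brodmann area annotation. Cerebellar, vermis and deep-grey
#' regions carry "-" (no Brodmann assignment). Compiled from published
#' region/area pairings and standard AAL documentation; see the file header
#' in `inst/extdata/aal116_brodmann.tsv` for provenance notes.
#'
#' @return data.frame (aal_index, aal_name, brodmann).
#' @export
aal_brodmann_lookup <- function() {
  f <- system.file("extdata", "aal116_brodmann.tsv", package = "fcxai",
                   mustWork = TRUE)
  utils::read.delim(f, comment.char = "#", stringsAsFactors = FALSE)
}

#' Aggregate a feature ranking to ROI-level importance
#'
#' Counts, for each ROI, how often it appears as an endpoint of the top
#' `top_k` ranked connectivity features (each feature credits both its
#' ROIs), and sums the features' attribution scores per ROI as a secondary
#' weighted importance. ROIs are sorted by descending count, ties broken by
#' descending summed score, then ascending AAL index.
#'
#' @param ranking output of [rank_features()] (data.frame with
#'   feature_index and score in rank order), or an ordered integer vector
#'   of feature indices.
#' @param index_map a [feature_index_map()] resolving feature index to
#'   (roi_i, roi_j).
#' @param top_k number of top features aggregated (default 100).
#' @return data.frame of class `roi_importance` (aal_index, importance,
#'   weight, rank) covering every ROI that appears (importance >= 1).
#' @export
aggregate_to_rois <- function(ranking, index_map, top_k = 100) {
  if (is.data.frame(ranking)) {
    feats <- ranking$feature_index
    scores <- if ("score" %in% names(ranking)) ranking$score
              else rep(1, length(feats))
  } else {
    feats <- as.integer(ranking)
    scores <- rep(1, length(feats))
  }
  top_k <- min(top_k, length(feats))
  feats <- feats[seq_len(top_k)]
  scores <- scores[seq_len(top_k)]
  pos <- match(feats, index_map$feature_index)
  if (anyNA(pos))
    stop("feature index not resolvable in index map: ",
         paste(feats[is.na(pos)], collapse = ", "))
  rois <- c(index_map$roi_i[pos], index_map$roi_j[pos])
  w <- c(abs(scores), abs(scores))
  counts <- tapply(rep(1, length(rois)), rois, sum)
  weights <- tapply(w, rois, sum)
  tab <- data.frame(aal_index = as.integer(names(counts)),
                    importance = as.integer(counts),
                    weight = as.numeric(weights))
  tab <- tab[order(-tab$importance, -tab$weight, tab$aal_index), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("roi_importance", class(tab))
  tab
}

#' Attach AAL names and Brodmann areas to a ROI importance table
#'
#' @param table output of [aggregate_to_rois()].
#' @param lookup region lookup (default the bundled
#'   [aal_brodmann_lookup()]).
#' @return the table with `aal_name` and `brodmann` columns; unknown
#'   indices/names fail.
#' @export
annotate_brodmann <- function(table, lookup = aal_brodmann_lookup()) {
  pos <- match(table$aal_index, lookup$aal_index)
  if (anyNA(pos))
    stop("unknown AAL index: ",
         paste(table$aal_index[is.na(pos)], collapse = ", "))
  table$aal_name <- lookup$aal_name[pos]
  table$brodmann <- lookup$brodmann[pos]
  cols <- c("aal_index", "aal_name", "brodmann", "importance", "weight",
            "rank")
  table[, intersect(cols, names(table))]
}

#' Brodmann area(s) of one named AAL region
#'
#' @param aal_name region name, e.g. "Calcarine_L".
#' @param lookup region lookup table.
#' @return the Brodmann annotation string ("-" for cerebellar/vermis and
#'   deep-grey regions).
#' @export
brodmann_of <- function(aal_name, lookup = aal_brodmann_lookup()) {
  pos <- match(aal_name, lookup$aal_name)
  if (anyNA(pos))
    stop("unknown AAL name: ", paste(aal_name[is.na(pos)], collapse = ", "))
  lookup$brodmann[pos]
}

#' Consensus ROI ranking across several runs or pipelines
#'
#' Ranks ROIs by the number of runs in which they appear within the top `m`
#' rows of each table, ties broken by mean within-run rank (missing
#' appearances counted as m + 1), then AAL index.
#'
#' @param tables list (>= 2) of [aggregate_to_rois()] outputs.
#' @param m depth of each table considered (default 10).
#' @return data.frame (aal_index, n_runs, mean_rank, rank).
#' @export
cross_run_consensus <- function(tables, m = 10) {
  if (length(tables) < 2) stop("need at least two tables for a consensus")
  all_rois <- sort(unique(unlist(lapply(tables, `[[`, "aal_index"))))
  hits <- sapply(tables, function(t) {
    top <- t$aal_index[t$rank <= m]
    r <- t$rank[match(all_rois, t$aal_index)]
    r[!(all_rois %in% top)] <- NA
    r
  })
  hits <- matrix(hits, nrow = length(all_rois))
  n_runs <- rowSums(!is.na(hits))
  mean_rank <- rowMeans(ifelse(is.na(hits), m + 1, hits))
  out <- data.frame(aal_index = all_rois, n_runs = n_runs,
                    mean_rank = mean_rank)
  out <- out[out$n_runs > 0, ]
  out <- out[order(-out$n_runs, out$mean_rank, out$aal_index), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
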