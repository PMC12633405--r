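# Cluster-indel proximity: pairing within a genomic window and the
# per-category distance statistics (means, medians, ratio of medians,
# one-sided Welch test).

#' Proximity pairing parameters
#'
#' @param window Window in bp; a (cluster, indel) pair is kept when the
#'   distance between the cluster center and the indel anchor is strictly
#'   less than `window`. Default 100,000 bp (0.1 Mb).
#' @param indel_anchor `"left_breakpoint"` (0-based start of the event;
#'   default — deterministic and strand-free) or `"midpoint"`.
#' @param dedupe If `TRUE`, keep only the nearest cluster per indel; by
#'   default an indel within the window of several clusters contributes one
#'   pair per cluster.
#' @export
proximity_params <- function(window = 1e5, indel_anchor = c("left_breakpoint",
                                                            "midpoint"),
                             dedupe = FALSE) {
  if (window <= 0) stop("window must be > 0")
  structure(list(window = window,
                 indel_anchor = match.arg(indel_anchor),
                 dedupe = dedupe),
            class = "proximity_params")
}

#' Pair indels with substitution clusters within a window
#'
#' For every (cluster, indel) on the same contig of the same sample the
#' distance `|center - anchor|` is computed and the pair emitted iff it is
#' strictly below the window.
#'
#' @param clusters Cluster table from [detect_clusters()] (needs
#'   cluster_id, sample_id, contig, center, category).
#' @param indels Indel annotation table from [classify_indels()] (needs
#'   contig, start, sample_id, length, channel, is_mmd). An `indel_id`
#'   column is added if absent.
#' @param params A [proximity_params()] list.
#' @return Data.frame of pairs: cluster_id, indel_id, sample_id, contig,
#'   distance, category, indel_channel, indel_is_mmd.
#' @export
pair_within_window <- function(clusters, indels, params = proximity_params()) {
  empty <- data.frame(cluster_id = character(), indel_id = character(),
                      sample_id = character(), contig = character(),
                      distance = numeric(), category = character(),
                      indel_channel = character(), indel_is_mmd = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(clusters) == 0L || nrow(indels) == 0L) return(empty)
  if (!"indel_id" %in% names(indels)) {
    indels$indel_id <- sprintf("%s_%s_%d_%s", indels$sample_id, indels$contig,
                               indels$start, indels$kind)
  }
  anchor <- if (params$indel_anchor == "midpoint") {
    indels$start + floor(ifelse(indels$kind == "deletion", indels$length, 0L) / 2)
  } else {
    indels$start
  }
  out <- list()
  key_c <- paste(clusters$sample_id, clusters$contig)
  key_i <- paste(indels$sample_id, indels$contig)
  for (k in intersect(unique(key_c), unique(key_i))) {
    ci <- which(key_c == k); ii <- which(key_i == k)
    d <- abs(outer(clusters$center[ci], anchor[ii], "-"))
    hit <- which(d < params$window, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    out[[k]] <- data.frame(
      cluster_id = clusters$cluster_id[ci[hit[, 1L]]],
      indel_id = indels$indel_id[ii[hit[, 2L]]],
      sample_id = clusters$sample_id[ci[hit[, 1L]]],
      contig = clusters$contig[ci[hit[, 1L]]],
      distance = d[hit],
      category = clusters$category[ci[hit[, 1L]]],
      indel_channel = indels$channel[ii[hit[, 2L]]],
      indel_is_mmd = indels$is_mmd[ii[hit[, 2L]]],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(out)) do.call(rbind, out) else empty
  rownames(pairs) <- NULL
  if (params$dedupe && nrow(pairs) > 0L) {
    pairs <- pairs[order(pairs$indel_id, pairs$distance), , drop = FALSE]
    pairs <- pairs[!duplicated(pairs$indel_id), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  pairs
}

#' Summarize cluster-indel distances per cluster category
#'
#' Computes per-category pair counts, mean and median distances, the ratio
#' of medians (APOBEC3 / other) and a one-sided Welch t-test of the
#' alternative that distances to APOBEC3-induced clusters are smaller than
#' distances to clusters induced by other mutagenic factors.  When either
#' category has no pairs the contrast fields are `NA` rather than an error.
#'
#' @param pairs Pair table from [pair_within_window()].
#' @param restrict_to `"mmd"` (default: MMD indels only, the TMEJ
#'   footprint) or `"all"`.
#' @return List with `per_category` (data.frame: category, n_pairs,
#'   mean_distance, median_distance), `ratio_of_medians`, `t_statistic`,
#'   `p_one_sided`, and `test` (`"welch_one_sided"`).
#' @export
summarize_proximity <- function(pairs, restrict_to = c("mmd", "all")) {
  restrict_to <- match.arg(restrict_to)
  if (restrict_to == "mmd" && nrow(pairs) > 0L) {
    pairs <- pairs[pairs$indel_is_mmd, , drop = FALSE]
  }
  cats <- c("APOBEC3", "other")
  per_cat <- data.frame(
    category = cats,
    n_pairs = vapply(cats, function(cc) sum(pairs$category == cc), integer(1)),
    mean_distance = vapply(cats, function(cc) {
      d <- pairs$distance[pairs$category == cc]
      if (length(d)) mean(d) else NA_real_
    }, numeric(1)),
    median_distance = vapply(cats, function(cc) {
      d <- pairs$distance[pairs$category == cc]
      if (length(d)) stats::median(d) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  d_a <- pairs$distance[pairs$category == "APOBEC3"]
  d_o <- pairs$distance[pairs$category == "other"]
  ratio <- if (all(per_cat$n_pairs > 0L) && per_cat$median_distance[2L] > 0) {
    per_cat$median_distance[1L] / per_cat$median_distance[2L]
  } else NA_real_
  t_stat <- NA_real_; p <- NA_real_
  if (length(d_a) >= 2L && length(d_o) >= 2L &&
      (stats::sd(d_a) > 0 || stats::sd(d_o) > 0)) {
    tt <- stats::t.test(d_a, d_o, alternative = "less", var.equal = FALSE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(per_category = per_cat, ratio_of_medians = ratio,
       t_statistic = t_stat, p_one_sided = p, test = "welch_one_sided")
}
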