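# Kataegis-like substitution cluster detection and categorization.
#
# Clusters are maximal runs of substitutions on one contig of one sample in
# which every consecutive intermutation distance (IMD) is at or below a
# threshold.  The threshold may be fixed (e.g. the classic 1-kb kataegis
# rule) or derived per sample from a uniform-placement null.  A cluster is
# categorized APOBEC3-induced when coordinated TCW C>T/G substitutions make
# up at least two-thirds of its members.

#' Default cluster detection parameters
#'
#' @param imd_threshold Fixed IMD threshold in bp, or `NULL` to derive one
#'   per sample via [derive_imd_threshold()].
#' @param null_q Tail probability for threshold derivation (default 0.01).
#' @param min_size Minimum cluster size (default 2; doublets count).
#' @param apobec_fraction_threshold Fraction of qualifying members needed to
#'   call a cluster APOBEC3-induced. Fixed at 2/3 by the categorization
#'   rule; values other than 2/3 raise a warning.
#' @param require_strand_coordination Should APOBEC members only qualify
#'   when they share the plurality strand orientation of the cluster's
#'   APOBEC members (processive deamination of one ssDNA strand)? Default
#'   `TRUE`.
#' @return A validated parameter list of class `cluster_params`.
#' @export
cluster_params <- function(imd_threshold = NULL, null_q = 0.01, min_size = 2L,
                           apobec_fraction_threshold = 2 / 3,
                           require_strand_coordination = TRUE) {
  if (!is.null(imd_threshold) && imd_threshold <= 0) {
    stop("imd_threshold must be positive")
  }
  if (null_q <= 0 || null_q >= 1) stop("null_q must lie in (0, 1)")
  if (min_size < 2L) stop("min_size must be >= 2")
  if (abs(apobec_fraction_threshold - 2 / 3) > 1e-12) {
    warning("apobec_fraction_threshold differs from the defining 2/3 rule")
  }
  structure(list(imd_threshold = imd_threshold, null_q = null_q,
                 min_size = as.integer(min_size),
                 apobec_fraction_threshold = apobec_fraction_threshold,
                 require_strand_coordination = require_strand_coordination),
            class = "cluster_params")
}

#' Derive an intermutation-distance threshold from a uniform null
#'
#' Under uniform placement of `n` mutations on `callable_length_bp`,
#' consecutive spacings are approximately exponential with rate
#' `n / L`; the threshold is the distance below which a spacing occurs with
#' probability `q` under that null:
#' `d = floor(-(L / n) * log(1 - q))`.
#'
#' @param n_mutations Number of substitutions in the sample (>= 2).
#' @param callable_length_bp Callable genome length in bp (> 0).
#' @param q Null tail probability (default 0.01).
#' @return Threshold in bp (integer).
#' @export
derive_imd_threshold <- function(n_mutations, callable_length_bp, q = 0.01) {
  if (n_mutations < 2) stop("n_mutations must be >= 2")
  if (callable_length_bp <= 0) stop("callable_length_bp must be > 0")
  if (q < 0 || q >= 1) stop("q must lie in [0, 1)")
  as.integer(floor(-(callable_length_bp / n_mutations) * log(1 - q)))
}

#' Detect substitution clusters by intermutation distance
#'
#' @param subs Data.frame of substitutions with columns `sample_id`,
#'   `contig`, `pos` (bp, any consistent convention), and (for
#'   categorization) `is_apobec3` (logical) and `orientation` (`"+"/"-"`,
#'   the strand carrying the mutated pyrimidine). Within each
#'   (sample, contig) the rows must be position-sorted; unsorted input is an
#'   error.
#' @param params A [cluster_params()] list.
#' @param callable_length_bp Callable length used when the threshold is
#'   derived per sample (required if `params$imd_threshold` is `NULL`).
#' @return List with `clusters` (data.frame: cluster_id, sample_id, contig,
#'   span_start, span_end, center, n_total, n_apobec, category, threshold)
#'   and `members` (the input rows plus a `cluster_id` column, NA for
#'   unclustered substitutions).
#' @export
detect_clusters <- function(subs, params = cluster_params(),
                            callable_length_bp = NULL) {
  need <- c("sample_id", "contig", "pos")
  miss <- setdiff(need, names(subs))
  if (length(miss)) stop("subs is missing column(s): ", paste(miss, collapse = ", "))
  if (!"is_apobec3" %in% names(subs)) subs$is_apobec3 <- NA
  if (!"orientation" %in% names(subs)) subs$orientation <- NA_character_
  subs$cluster_id <- NA_character_

  cluster_rows <- list()
  for (sid in unique(subs$sample_id)) {
    s_idx <- which(subs$sample_id == sid)
    thr <- params$imd_threshold
    if (is.null(thr)) {
      if (is.null(callable_length_bp)) {
        stop("callable_length_bp is required to derive the IMD threshold")
      }
      if (length(s_idx) < 2L) next
      thr <- derive_imd_threshold(length(s_idx), callable_length_bp,
                                  params$null_q)
    }
    for (ctg in unique(subs$contig[s_idx])) {
      idx <- s_idx[subs$contig[s_idx] == ctg]
      pos <- subs$pos[idx]
      if (is.unsorted(pos)) {
        stop(sprintf("substitutions for sample %s contig %s are not position-sorted",
                     sid, ctg))
      }
      if (length(idx) < params$min_size) next
      gap_ok <- diff(pos) <= thr
      run_id <- cumsum(c(0L, !gap_ok))
      for (r in split(seq_along(idx), run_id)) {
        if (length(r) < params$min_size) next
        cid <- sprintf("%s_%s_%d", sid, ctg, subs$pos[idx[r[1L]]])
        subs$cluster_id[idx[r]] <- cid
        cat_res <- categorize_cluster(
          subs$is_apobec3[idx[r]], subs$orientation[idx[r]],
          require_strand_coordination = params$require_strand_coordination)
        cluster_rows[[cid]] <- data.frame(
          cluster_id = cid, sample_id = sid, contig = ctg,
          span_start = pos[r[1L]], span_end = pos[r[length(r)]],
          center = cluster_center(pos[r]),
          n_total = length(r), n_apobec = cat_res$n_qualifying,
          category = cat_res$category, threshold = thr,
          stringsAsFactors = FALSE)
      }
    }
  }
  clusters <- do.call(rbind, cluster_rows)
  if (is.null(clusters)) {
    clusters <- data.frame(cluster_id = character(), sample_id = character(),
                           contig = character(), span_start = numeric(),
                           span_end = numeric(), center = numeric(),
                           n_total = integer(), n_apobec = integer(),
                           category = character(), threshold = numeric(),
                           stringsAsFactors = FALSE)
  }
  rownames(clusters) <- NULL
  list(clusters = clusters, members = subs)
}

#' Categorize a cluster by the two-thirds TCW rule
#'
#' A member qualifies when it is an APOBEC3 TCW substitution and — if strand
#' coordination is required — it shares the plurality strand orientation of
#' the cluster's APOBEC members. The cluster is APOBEC3-induced when
#' qualifying members make up at least two-thirds (inclusive) of the total;
#' the comparison uses integer arithmetic (`3 * n_qualifying >= 2 *
#' n_total`) so the exact-2/3 boundary is handled without floating-point
#' slop.
#'
#' @param is_apobec3 Logical vector over cluster members.
#' @param orientation Strand of the mutated pyrimidine per member
#'   (`"+"/"-"`); only consulted when coordination is required.
#' @param require_strand_coordination See [cluster_params()].
#' @return List with `category` (`"APOBEC3"` or `"other"`) and
#'   `n_qualifying`.
#' @export
categorize_cluster <- function(is_apobec3, orientation = NULL,
                               require_strand_coordination = TRUE) {
  n <- length(is_apobec3)
  if (n == 0L) stop("cannot categorize an empty cluster")
  apo <- !is.na(is_apobec3) & is_apobec3
  if (require_strand_coordination && any(apo)) {
    ori <- orientation[apo]
    n_q <- max(sum(ori == "+", na.rm = TRUE), sum(ori == "-", na.rm = TRUE))
  } else {
    n_q <- sum(apo)
  }
  list(category = if (3L * n_q >= 2L * n) "APOBEC3" else "other",
       n_qualifying = as.integer(n_q))
}

#' Cluster center position
#'
#' Floor midpoint of the outermost member positions — the anchor used for
#' cluster-indel distance measurements.
#'
#' @param pos Member positions (bp).
#' @return `floor((min + max) / 2)`.
#' @export
cluster_center <- function(pos) {
  if (length(pos) == 0L) stop("empty cluster has no center")
  floor((min(pos) + max(pos)) / 2)
}
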