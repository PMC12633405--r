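# Multi-caller somatic variant consensus filter.
#
# Calls from several variant callers are merged on normalized genomic
# position and alleles, then filtered by the retention rules: depth > 10
# (strict), alt allele count > 2 (strict), called by >= 2 distinct callers,
# absent from a dbSNP-style common-site list, and absent from the control
# (untreated) variant set.

#' Consensus filter parameters
#'
#' @param min_depth_exclusive Variants are retained when depth is strictly
#'   greater than this (default 10).
#' @param min_alt_exclusive Strict lower bound on the alt allele count
#'   (default 2).
#' @param min_callers Minimum number of distinct callers (default 2).
#' @export
filter_params <- function(min_depth_exclusive = 10L, min_alt_exclusive = 2L,
                          min_callers = 2L) {
  if (min_callers < 1L) stop("min_callers must be >= 1")
  if (min_depth_exclusive < 0 || min_alt_exclusive < 0) {
    stop("thresholds must be non-negative")
  }
  structure(list(min_depth_exclusive = as.integer(min_depth_exclusive),
                 min_alt_exclusive = as.integer(min_alt_exclusive),
                 min_callers = as.integer(min_callers)),
            class = "filter_params")
}

# Canonical key of a normalized variant: sample, contig, 0-based start,
# kind, and payload.  Left-alignment upstream makes representations from
# different callers comparable.
variant_key <- function(nv) {
  payload <- ifelse(nv$kind == "SNV", paste0(nv$ref_base, ">", nv$alt_base),
                    ifelse(nv$kind == "deletion", nv$deleted_seq,
                           nv$inserted_seq))
  paste(nv$sample_id, nv$contig, nv$start, nv$kind, payload, sep = ":")
}

# Key of a (contig, pos, ref, alt) site list in the same normalized space.
# `sample_id` is omitted so one exclusion list applies to every sample.
site_key <- function(sites, genome) {
  if (nrow(sites) == 0L) return(character())
  sites$sample_id <- "."
  nv <- normalize_variants(sites, genome)
  sub("^[^:]*:", "", variant_key(nv))
}

#' Merge per-caller variant calls on matching position and alleles
#'
#' Each caller's records are normalized (left-aligned, trimmed) so that
#' equivalent indel representations collapse to one key. Depth and alt
#' count of a merged record are the maxima over the reporting callers.
#'
#' @param caller_variants Either a single VariantRecord data.frame with a
#'   `caller` column, or a named list of VariantRecord data.frames (names
#'   are caller names).
#' @param genome A [ref_genome()].
#' @return Data.frame of consensus records: key, sample_id, contig, start,
#'   kind, payload, callers (comma-joined), n_callers, depth, alt_count.
#' @export
merge_callers <- function(caller_variants, genome) {
  if (is.data.frame(caller_variants)) {
    records <- caller_variants
  } else {
    records <- do.call(rbind, lapply(names(caller_variants), function(cl) {
      df <- caller_variants[[cl]]
      df$caller <- cl
      df
    }))
  }
  if (is.null(records$caller) || any(is.na(records$caller))) {
    stop("every record needs a caller name")
  }
  nv_rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    nv_rows[[i]] <- tryCatch({
      nv <- normalize_variant(records$contig[i], records$pos[i],
                              records$ref[i], records$alt[i], genome,
                              sample_id = records$sample_id[i])
      nv$caller <- records$caller[i]
      nv$depth <- records$depth[i]
      nv$alt_count <- records$alt_count[i]
      nv
    }, error = function(e) NULL)
  }
  nv <- do.call(rbind, nv_rows[!vapply(nv_rows, is.null, logical(1))])
  if (is.null(nv) || nrow(nv) == 0L) {
    return(data.frame(key = character(), sample_id = character(),
                      contig = character(), start = integer(),
                      kind = character(), payload = character(),
                      callers = character(), n_callers = integer(),
                      depth = integer(), alt_count = integer(),
                      stringsAsFactors = FALSE))
  }
  nv$key <- variant_key(nv)
  max_or_na <- function(x) if (all(is.na(x))) NA_integer_ else
    as.integer(max(x, na.rm = TRUE))
  merged <- do.call(rbind, lapply(split(nv, nv$key), function(g) {
    data.frame(
      key = g$key[1L], sample_id = g$sample_id[1L], contig = g$contig[1L],
      start = g$start[1L], kind = g$kind[1L],
      payload = if (g$kind[1L] == "SNV") paste0(g$ref_base[1L], ">", g$alt_base[1L])
                else if (g$kind[1L] == "deletion") g$deleted_seq[1L]
                else g$inserted_seq[1L],
      callers = paste(sort(unique(g$caller)), collapse = ","),
      n_callers = length(unique(g$caller)),
      depth = max_or_na(g$depth), alt_count = max_or_na(g$alt_count),
      stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$sample_id, merged$contig, merged$start,
                         merged$kind, merged$payload), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Apply the consensus retention rules
#'
#' Rules are applied in order and the first failing rule is recorded as the
#' record's fate: (1) depth strictly > 10 and alt count strictly > 2
#' (records with missing evidence get the distinct fate
#' `dropped:missing_evidence`); (2) called by at least `min_callers`
#' distinct callers; (3) key not present in the dbSNP-style common-site
#' set; (4) key not shared with the control (untreated) set. The retained
#' set is order-independent; only the recorded first failing rule depends
#' on rule order.
#'
#' @param merged Output of [merge_callers()].
#' @param params A [filter_params()] list.
#' @param dbsnp_sites,control_sites Site lists as data.frames with columns
#'   contig, pos (1-based), ref, alt; matched by normalized key against
#'   every sample.
#' @param genome A [ref_genome()] (used to normalize the site lists).
#' @return List with `retained` (data.frame), `records` (all records plus a
#'   `fate` column) and `drop_counts` (named integer vector: low_depth,
#'   low_alt_count, missing_evidence, insufficient_callers, in_dbsnp,
#'   in_control).
#' @export
apply_filters <- function(merged, params = filter_params(),
                          dbsnp_sites = NULL, control_sites = NULL,
                          genome = NULL) {
  dbsnp_keys <- control_keys <- character()
  if (!is.null(dbsnp_sites) && nrow(dbsnp_sites) > 0L) {
    if (is.null(genome)) stop("genome is required to normalize site lists")
    dbsnp_keys <- site_key(dbsnp_sites, genome)
  }
  if (!is.null(control_sites) && nrow(control_sites) > 0L) {
    if (is.null(genome)) stop("genome is required to normalize site lists")
    control_keys <- site_key(control_sites, genome)
  }
  key_nosample <- sub("^[^:]*:", "", merged$key)
  fate <- rep("retained", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    if (is.na(merged$depth[i]) || is.na(merged$alt_count[i])) {
      fate[i] <- "dropped:missing_evidence"
    } else if (merged$depth[i] <= params$min_depth_exclusive) {
      fate[i] <- "dropped:low_depth"
    } else if (merged$alt_count[i] <= params$min_alt_exclusive) {
      fate[i] <- "dropped:low_alt_count"
    } else if (merged$n_callers[i] < params$min_callers) {
      fate[i] <- "dropped:insufficient_callers"
    } else if (key_nosample[i] %in% dbsnp_keys) {
      fate[i] <- "dropped:in_dbsnp"
    } else if (key_nosample[i] %in% control_keys) {
      fate[i] <- "dropped:in_control"
    }
  }
  merged$fate <- fate
  rules <- c("low_depth", "low_alt_count", "missing_evidence",
             "insufficient_callers", "in_dbsnp", "in_control")
  drop_counts <- vapply(rules, function(r) {
    sum(fate == paste0("dropped:", r))
  }, integer(1))
  list(retained = merged[fate == "retained", , drop = FALSE],
       records = merged, drop_counts = drop_counts)
}
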