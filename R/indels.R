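# ID83-style indel annotation: repeat-unit counts, microhomology lengths,
# channel assignment, and the microhomology-mediated deletion (MMD) flag.
#
# The MMD is the genomic footprint of theta-mediated end joining (TMEJ): a
# deletion of >= 2 bp, not part of a tandem repeat, whose junction shows
# flanking sequence identity (microhomology).  Channel hierarchy follows the
# COSMIC ID83 scheme: repeat context takes precedence over microhomology,
# and 1-bp events are homopolymer channels keyed by the pyrimidine-
# normalized deleted/inserted base.

#' Canonical ID83 channel labels (COSMIC order)
#'
#' `1:Del:C:0-5, 1:Del:T:0-5, 1:Ins:C:0-5, 1:Ins:T:0-5`, then deletion and
#' insertion repeat channels for lengths 2-5+ (`<len>:Del:R:0-5`,
#' `<len>:Ins:R:0-5`), then the 11 microhomology deletion channels
#' (`2:Del:M:1`, `3:Del:M:1-2`, `4:Del:M:1-3`, `5:Del:M:1-5`).
#'
#' @return Character vector of length 83.
#' @export
id83_channels <- function() {
  one_bp <- c(paste0("1:Del:C:", 0:5), paste0("1:Del:T:", 0:5),
              paste0("1:Ins:C:", 0:5), paste0("1:Ins:T:", 0:5))
  del_rep <- unlist(lapply(2:5, function(l) paste0(l, ":Del:R:", 0:5)))
  ins_rep <- unlist(lapply(2:5, function(l) paste0(l, ":Ins:R:", 0:5)))
  mh <- c("2:Del:M:1",
          paste0("3:Del:M:", 1:2),
          paste0("4:Del:M:", 1:3),
          paste0("5:Del:M:", 1:5))
  c(one_bp, del_rep, ins_rep, mh)
}

#' Number of additional adjacent copies of an indel payload
#'
#' Counts the exact, contiguous copies of the payload immediately 3' of the
#' event locus in the reference (3' of the deleted segment for deletions;
#' starting at the insertion point for insertions). The variant must be
#' normalized (left-aligned), so all equivalent copies lie 3'.
#'
#' @param genome A [ref_genome()].
#' @param contig Contig name.
#' @param start0 0-based start of the normalized event.
#' @param payload Deleted or inserted sequence (non-empty).
#' @param kind `"deletion"` or `"insertion"`.
#' @return Integer count >= 0.
#' @export
repeat_unit_count <- function(genome, contig, start0, payload, kind) {
  if (!nzchar(payload)) stop("empty indel payload")
  L <- nchar(payload)
  from <- if (kind == "deletion") start0 + L else start0
  len_contig <- genome$lengths[[contig]]
  n <- 0L
  while (from + (n + 1L) * L <= len_contig) {
    if (ref_fetch(genome, contig, from + n * L, from + (n + 1L) * L) != payload) break
    n <- n + 1L
  }
  n
}

#' Microhomology length of a deletion
#'
#' Returns the maximum of (a) the longest proper prefix of the deleted
#' sequence equal to the reference immediately 3' of the deletion and
#' (b) the longest proper suffix equal to the reference immediately 5' of
#' it; both junction sides are scored and the larger taken. Bounded by
#' `length - 1`. Only meaningful for non-repeat-mediated deletions of
#' >= 2 bp; calling it on an insertion or a repeat-mediated deletion is an
#' error.
#'
#' @inheritParams repeat_unit_count
#' @param deleted_seq The deleted sequence (length >= 2).
#' @export
microhomology_length <- function(genome, contig, start0, deleted_seq) {
  L <- nchar(deleted_seq)
  if (L < 2L) stop("microhomology is defined for deletions of >= 2 bp")
  if (repeat_unit_count(genome, contig, start0, deleted_seq, "deletion") > 0L) {
    stop("microhomology_length called on a repeat-mediated deletion")
  }
  len_contig <- genome$lengths[[contig]]
  # prefix of deleted vs 3' flank
  mh3 <- 0L
  flank_start <- start0 + L
  while (mh3 < L - 1L && flank_start + mh3 < len_contig &&
         ref_fetch(genome, contig, flank_start + mh3, flank_start + mh3 + 1L) ==
           substr(deleted_seq, mh3 + 1L, mh3 + 1L)) {
    mh3 <- mh3 + 1L
  }
  # suffix of deleted vs 5' flank
  mh5 <- 0L
  while (mh5 < L - 1L && start0 - mh5 - 1L >= 0L &&
         ref_fetch(genome, contig, start0 - mh5 - 1L, start0 - mh5) ==
           substr(deleted_seq, L - mh5, L - mh5)) {
    mh5 <- mh5 + 1L
  }
  max(mh3, mh5)
}

#' Annotate indels with ID83 channels and the MMD flag
#'
#' Assignment is total and exclusive over the 83 channels:
#' 1-bp events go to homopolymer channels keyed by the pyrimidine-normalized
#' base and the adjacent-copy class; events of >= 2 bp with at least one
#' full adjacent copy go to repeat channels (repeat context takes precedence
#' over microhomology, so a deletion inside a tandem repeat is never an
#' MMD); deletions of >= 2 bp with no adjacent copy and microhomology
#' length >= 1 go to microhomology channels; everything else falls in the
#' `R:0` channel of its length class.
#'
#' @param nv NormalizedVariant data.frame; non-indel rows are ignored.
#' @param genome A [ref_genome()].
#' @param min_mh Minimum microhomology length for the MMD flag (default 1,
#'   matching the definition of an MMD as a deletion containing any
#'   microhomology sequence).
#' @return Data.frame with one row per indel: contig, start, sample_id,
#'   kind, length, length_class, repeat_count, mh_length, mechanism
#'   (`repeat`/`microhomology`/`none`), channel, is_mmd.
#' @export
classify_indels <- function(nv, genome, min_mh = 1L) {
  idx <- which(nv$kind %in% c("deletion", "insertion"))
  n <- length(idx)
  out <- data.frame(
    contig = nv$contig[idx], start = nv$start[idx],
    sample_id = nv$sample_id[idx], kind = nv$kind[idx],
    length = integer(n), length_class = character(n),
    repeat_count = integer(n), mh_length = integer(n),
    mechanism = character(n), channel = character(n),
    is_mmd = logical(n), stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    i <- idx[j]
    kind <- nv$kind[i]
    payload <- if (kind == "deletion") nv$deleted_seq[i] else nv$inserted_seq[i]
    L <- nchar(payload)
    rep_n <- repeat_unit_count(genome, nv$contig[i], nv$start[i], payload, kind)
    lc <- min(L, 5L)
    lc_lab <- as.character(lc)
    kind_lab <- if (kind == "deletion") "Del" else "Ins"
    mh <- 0L
    if (L == 1L) {
      base <- chartr("AG", "TC", payload)  # pyrimidine-normalize
      mech <- if (rep_n >= 1L) "repeat" else "none"
      chan <- paste0("1:", kind_lab, ":", base, ":", min(rep_n, 5L))
    } else if (rep_n >= 1L) {
      mech <- "repeat"
      chan <- paste0(lc_lab, ":", kind_lab, ":R:", min(rep_n, 5L))
    } else if (kind == "deletion") {
      mh <- microhomology_length(genome, nv$contig[i], nv$start[i], payload)
      if (mh >= 1L) {
        mech <- "microhomology"
        chan <- paste0(lc_lab, ":Del:M:", min(mh, 5L))
      } else {
        mech <- "none"
        chan <- paste0(lc_lab, ":Del:R:0")
      }
    } else {
      mech <- "none"
      chan <- paste0(lc_lab, ":Ins:R:0")
    }
    out$length[j] <- L
    out$length_class[j] <- if (L >= 5L) "5+" else as.character(L)
    out$repeat_count[j] <- rep_n
    out$mh_length[j] <- mh
    out$mechanism[j] <- mech
    out$channel[j] <- chan
    out$is_mmd[j] <- kind == "deletion" && L >= 2L && rep_n == 0L && mh >= min_mh
  }
  out
}

#' Per-sample ID83 burdens
#'
#' @param nv NormalizedVariant data.frame.
#' @param genome A [ref_genome()].
#' @param samples Optional sample set/order.
#' @param min_mh Passed to [classify_indels()].
#' @return List with `matrix` (83 x samples), `summary` (sample_id, total,
#'   mmd_count) and `annotations` (the per-indel table).
#' @export
build_indel_burden <- function(nv, genome, samples = NULL, min_mh = 1L) {
  ann <- classify_indels(nv, genome, min_mh = min_mh)
  channels <- id83_channels()
  if (is.null(samples)) samples <- sort(unique(nv$sample_id))
  tab <- table(factor(ann$channel, levels = channels),
               factor(ann$sample_id, levels = samples))
  mat <- matrix(as.integer(tab), nrow = 83L,
                dimnames = list(channels, samples))
  mmd <- tapply(ann$is_mmd, factor(ann$sample_id, levels = samples), sum)
  summary <- data.frame(
    sample_id = samples,
    total = as.integer(colSums(mat)),
    mmd_count = as.integer(ifelse(is.na(mmd), 0L, mmd)),
    stringsAsFactors = FALSE)
  list(matrix = mat, summary = summary, annotations = ann)
}

#' MMD counts from an ID83 channel matrix
#'
#' Sums the microhomology deletion channels of an ID83 matrix, e.g. one
#' written by [run_pipeline()] or supplied externally.
#'
#' @param mat Numeric matrix with ID83 channel labels as rownames.
#' @return Named numeric vector of per-column MMD counts.
#' @export
mmd_count_from_id83 <- function(mat) {
  mh_channels <- grep(":Del:M:", rownames(mat), value = TRUE, fixed = TRUE)
  colSums(mat[mh_channels, , drop = FALSE])
}
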