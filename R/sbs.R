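# SBS-96 trinucleotide channel classification and APOBEC3 TCW calls.
#
# Channels follow the COSMIC convention: substitutions are expressed on the
# pyrimidine strand (ref C or T); a purine reference base means the
# substitution and its trinucleotide context are reverse-complemented before
# channel assignment.  Labels are "X[R>A]Y" strings, e.g. "T[C>T]A".

PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

#' Canonical SBS-96 channel labels (COSMIC order)
#'
#' Substitution blocks ordered C>A, C>G, C>T, T>A, T>C, T>G; within each
#' block the 16 contexts are ordered by 5' base then 3' base (A, C, G, T).
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f, t3) {
      paste0(f, "[", s, "]", t3)
    })))
  }))
}

#' Classify SNVs into SBS-96 channels
#'
#' @param nv NormalizedVariant data.frame; non-SNV rows are an error.
#' @param genome A [ref_genome()].
#' @return A data.frame with one row per input SNV: `channel` (NA when the
#'   trinucleotide context contains N or runs off the contig end),
#'   `orientation` (`"+"` when the mutated pyrimidine lies on the as-given
#'   strand, `"-"` when the channel was derived by reverse complement), and
#'   `is_apobec3`.
#' @export
classify_sbs96 <- function(nv, genome) {
  if (nrow(nv) > 0L && any(nv$kind != "SNV")) {
    stop("classify_sbs96 expects SNV rows only")
  }
  n <- nrow(nv)
  channel <- character(n); orientation <- character(n)
  for (i in seq_len(n)) {
    ctx <- tryCatch(get_context(genome, nv$contig[i], nv$start[i], 1L),
                    error = function(e) NA_character_)
    if (is.na(ctx) || grepl("N", ctx, fixed = TRUE)) {
      channel[i] <- NA_character_; orientation[i] <- NA_character_
      next
    }
    ref <- nv$ref_base[i]; alt <- nv$alt_base[i]
    if (substr(ctx, 2L, 2L) != ref) {
      stop(sprintf("context/ref disagreement at %s:%d", nv$contig[i],
                   nv$start[i]))
    }
    if (ref %in% PURINES) {
      ctx <- revcomp(ctx); ref <- revcomp(ref); alt <- revcomp(alt)
      orientation[i] <- "-"
    } else {
      orientation[i] <- "+"
    }
    channel[i] <- paste0(substr(ctx, 1L, 1L), "[", ref, ">", alt, "]",
                         substr(ctx, 3L, 3L))
  }
  data.frame(channel = channel, orientation = orientation,
             is_apobec3 = is_apobec3_channel(channel),
             stringsAsFactors = FALSE)
}

#' Is an SBS-96 channel an APOBEC3 TCW substitution?
#'
#' APOBEC3-induced mutations are C>T or C>G substitutions in the TCW motif
#' (W = A or T), evaluated on the pyrimidine-normalized channel, so G>A/G>C
#' events at 5'-WGA-3' on the given strand also qualify via their reverse
#' complement.
#'
#' @param channel Character vector of "X[R>A]Y" channel labels.
#' @return Logical vector (NA for NA channels).
#' @export
is_apobec3_channel <- function(channel) {
  ifelse(is.na(channel), NA,
         substr(channel, 1L, 1L) == "T" &
           substr(channel, 3L, 3L) == "C" &
           substr(channel, 5L, 5L) %in% c("T", "G") &
           substr(channel, 7L, 7L) %in% c("A", "T"))
}

#' The four APOBEC3 TCW channels
#' @return Character vector: T\[C>T\]A, T\[C>T\]T, T\[C>G\]A, T\[C>G\]T.
#' @export
apobec3_channels <- function() {
  ch <- sbs96_channels()
  ch[is_apobec3_channel(ch)]
}

#' Per-sample SBS-96 burdens
#'
#' @param nv NormalizedVariant data.frame (SNV rows are used; other kinds
#'   are ignored).
#' @param genome A [ref_genome()].
#' @param samples Optional character vector fixing the sample set/order
#'   (samples with no SNVs get zero columns).
#' @return A list with `matrix` (96 x samples integer matrix, rows in
#'   canonical channel order), `summary` (data.frame: sample_id, total,
#'   apobec_count, apobec_fraction) and `n_unclassifiable` (SNVs excluded
#'   for N-context or off-contig context).
#' @export
build_sbs_burden <- function(nv, genome, samples = NULL) {
  snv <- nv[nv$kind == "SNV", , drop = FALSE]
  cls <- classify_sbs96(snv, genome)
  channels <- sbs96_channels()
  if (is.null(samples)) samples <- sort(unique(nv$sample_id))
  mat <- matrix(0L, nrow = 96L, ncol = length(samples),
                dimnames = list(channels, samples))
  ok <- !is.na(cls$channel)
  if (any(ok)) {
    tab <- table(factor(cls$channel[ok], levels = channels),
                 factor(snv$sample_id[ok], levels = samples))
    mat[] <- as.integer(tab)
  }
  apo <- apobec3_channels()
  summary <- data.frame(
    sample_id = samples,
    total = as.integer(colSums(mat)),
    apobec_count = as.integer(colSums(mat[apo, , drop = FALSE])),
    stringsAsFactors = FALSE)
  summary$apobec_fraction <- ifelse(summary$total > 0,
                                    summary$apobec_count / summary$total, NA_real_)
  list(matrix = mat, summary = summary, n_unclassifiable = sum(!ok))
}
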