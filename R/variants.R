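# Variant I/O and normalization.
#
# VariantRecord: data.frame with columns
#   contig, pos (1-based, as in VCF), ref, alt, sample_id, caller, depth,
#   alt_count.
# NormalizedVariant: data.frame with columns
#   contig, start (0-based), kind ("SNV"/"insertion"/"deletion"),
#   deleted_seq, inserted_seq, ref_base, alt_base, sample_id.
# For deletions, `start` is the 0-based position of the first deleted base
# and genome[start, start + nchar(deleted_seq)) == deleted_seq.  For
# insertions, `start` is the 0-based position of the reference base the
# payload is inserted *before*.

#' Read somatic variant calls from a VCF file
#'
#' One row is produced per (site, alt allele); multi-allelic records are
#' split.  Depth is taken from the FORMAT `DP` field when present, else from
#' the sum of `AD`; the alt allele count comes from `AD`.  Symbolic alleles
#' (`<DEL>`, breakends, `*`) and alleles containing non-ACGTN letters are
#' skipped with a warning; the number skipped is attached as attribute
#' `n_skipped`.
#'
#' @param path Path to a VCF (optionally bgzipped) file.
#' @param sample_id Sample label to attach to every record.
#' @param caller Optional caller name to attach (default `NA`).
#' @return A VariantRecord data.frame (see above) with attribute `n_skipped`.
#' @export
read_variants <- function(path, sample_id, caller = NA_character_) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  n <- nrow(vcf)
  if (n == 0L) {
    out <- empty_variant_records()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  refs <- as.character(rr$REF)
  alt_list <- lapply(as.list(VariantAnnotation::alt(vcf)), as.character)

  gn <- VariantAnnotation::geno(vcf)
  dp <- if ("DP" %in% names(gn)) gn$DP[, 1L] else rep(NA_integer_, n)
  ad <- if ("AD" %in% names(gn)) gn$AD[, 1L] else vector("list", n)

  rows <- vector("list", n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    alts <- alt_list[[i]]
    keep <- nzchar(alts) & grepl("^[ACGTNacgtn]+$", alts)
    n_skipped <- n_skipped + sum(!keep)
    alts <- alts[keep]
    if (length(alts) == 0L) next
    adi <- if (is.list(ad)) ad[[i]] else ad[i]
    depth_i <- dp[i]
    if (is.na(depth_i) && !is.null(adi) && !all(is.na(adi))) {
      depth_i <- sum(adi, na.rm = TRUE)
    }
    alt_counts <- rep(NA_integer_, length(alts))
    if (!is.null(adi) && length(adi) >= 2L) {
      idx_kept <- which(keep) + 1L  # AD is (ref, alt1, alt2, ...)
      idx_kept <- idx_kept[idx_kept <= length(adi)]
      alt_counts[seq_along(idx_kept)] <- adi[idx_kept]
    }
    rows[[i]] <- data.frame(
      contig = contig[i], pos = pos[i], ref = toupper(refs[i]),
      alt = toupper(alts), sample_id = sample_id, caller = caller,
      depth = as.integer(depth_i), alt_count = as.integer(alt_counts),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty_variant_records()
  rownames(out) <- NULL
  if (n_skipped > 0L) {
    warning(n_skipped, " unsupported allele(s) skipped in ", basename(path))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_variant_records <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), sample_id = character(), caller = character(),
             depth = integer(), alt_count = integer(), stringsAsFactors = FALSE)
}

#' Read variant calls from a flat TSV
#'
#' Expected header: `contig, pos, ref, alt, sample_id[, caller, depth,
#' alt_count]`, with `pos` 1-based.
#'
#' @param path TSV path.
#' @return A VariantRecord data.frame.
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt", "sample_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("TSV is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("caller", "depth", "alt_count")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df$contig <- as.character(df$contig)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$caller <- as.character(df$caller)
  df$depth <- as.integer(df$depth)
  df$alt_count <- as.integer(df$alt_count)
  df[, c(need, "caller", "depth", "alt_count")]
}

#' Write variant records as a minimal VCF 4.2 file
#'
#' Writes one single-sample VCF with `DP` and `AD` FORMAT fields and contig
#' header lines taken from `genome`. Records are sorted by contig (genome
#' order) and position. The written file is readable by standard VCF parsers
#' and by [read_variants()].
#'
#' @param records VariantRecord data.frame for one sample (columns
#'   contig, pos, ref, alt, depth, alt_count; `pos` 1-based).
#' @param path Output path (plain text `.vcf`).
#' @param genome A [ref_genome()] used for the contig header lines.
#' @param sample_id Sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(records, path, genome, sample_id = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tmejscan",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$seq),
            genome$lengths),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  records <- records[order(match(records$contig, names(genome$seq)),
                           records$pos, records$ref, records$alt), ,
                     drop = FALSE]
  body <- character(nrow(records))
  if (nrow(records) > 0L) {
    dp <- ifelse(is.na(records$depth), ".", as.character(records$depth))
    ref_n <- ifelse(is.na(records$depth) | is.na(records$alt_count), NA_integer_,
                    records$depth - records$alt_count)
    ad <- ifelse(is.na(ref_n), ".",
                 paste0(ref_n, ",", records$alt_count))
    body <- paste(records$contig, records$pos, ".", records$ref, records$alt,
                  ".", "PASS", ".", "DP:AD", paste0(dp, ":", ad), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Normalize a single variant (trim + left-align)
#'
#' Shared suffix then shared prefix are trimmed; pure insertions and
#' deletions are then shifted left while the reference base 5' of the event
#' equals the last base of the payload, yielding the smallest equivalent
#' start (parsimonious, left-aligned representation). The operation is
#' idempotent.
#'
#' @param contig,pos1,ref,alt The variant in VCF convention (`pos1` 1-based;
#'   `ref` must match the genome at `pos1`).
#' @param genome A [ref_genome()].
#' @param sample_id Sample label carried through.
#' @return One-row NormalizedVariant data.frame. Errors with a condition of
#'   class `tmej_ref_mismatch` if `ref` disagrees with the genome, class
#'   `tmej_degenerate_variant` if `ref == alt` after trimming, and class
#'   `tmej_complex_variant` for multi-nucleotide/complex substitutions,
#'   which have no single-event normalized form.
#' @export
normalize_variant <- function(contig, pos1, ref, alt, genome,
                              sample_id = NA_character_) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt)) stop("ref and alt must be non-empty")
  if (ref == alt) {
    stop(structure(class = c("tmej_degenerate_variant", "error", "condition"),
                   list(message = sprintf("ref == alt at %s:%d", contig, pos1),
                        call = sys.call())))
  }
  start0 <- pos1 - 1L
  obs <- ref_fetch(genome, contig, start0, start0 + nchar(ref))
  if (obs != ref) {
    stop(structure(class = c("tmej_ref_mismatch", "error", "condition"),
                   list(message = sprintf(
                     "REF mismatch at %s:%d (VCF says %s, genome has %s)",
                     contig, pos1, ref, obs), call = sys.call())))
  }
  r <- ref; a <- alt
  # shared suffix
  while (nchar(r) > 0L && nchar(a) > 0L && str_last(r) == str_last(a)) {
    r <- substr(r, 1L, nchar(r) - 1L)
    a <- substr(a, 1L, nchar(a) - 1L)
  }
  # shared prefix
  while (nchar(r) > 0L && nchar(a) > 0L && str_first(r) == str_first(a)) {
    r <- substr(r, 2L, nchar(r))
    a <- substr(a, 2L, nchar(a))
    start0 <- start0 + 1L
  }
  seq <- genome$seq[[contig]]
  if (nchar(r) == 1L && nchar(a) == 1L) {
    return(data.frame(contig = contig, start = start0, kind = "SNV",
                      deleted_seq = "", inserted_seq = "",
                      ref_base = r, alt_base = a, sample_id = sample_id,
                      stringsAsFactors = FALSE))
  }
  if (nchar(r) > 0L && nchar(a) > 0L) {
    stop(structure(class = c("tmej_complex_variant", "error", "condition"),
                   list(message = sprintf(
                     "complex substitution at %s:%d (%s>%s)", contig, pos1,
                     ref, alt), call = sys.call())))
  }
  payload <- if (nchar(r) > 0L) r else a
  kind <- if (nchar(r) > 0L) "deletion" else "insertion"
  # left-align: shift while the base 5' of the event equals the payload tail
  L <- nchar(payload)
  while (start0 > 0L) {
    prev <- substr(seq, start0, start0)  # 0-based position start0 - 1
    if (prev != str_last(payload)) break
    payload <- paste0(prev, substr(payload, 1L, L - 1L))
    start0 <- start0 - 1L
  }
  data.frame(contig = contig, start = start0, kind = kind,
             deleted_seq = if (kind == "deletion") payload else "",
             inserted_seq = if (kind == "insertion") payload else "",
             ref_base = NA_character_, alt_base = NA_character_,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Normalize a batch of variant records
#'
#' Applies [normalize_variant()] to every row. Records whose REF disagrees
#' with the genome, complex (MNV-style) substitutions, and records whose
#' payload contains N are dropped with a logged count rather than aborting
#' the run; the counts are attached as attribute `dropped` (named integer
#' vector: `ref_mismatch`, `complex`, `with_n`, `degenerate`).
#'
#' @param records VariantRecord data.frame (1-based `pos`).
#' @param genome A [ref_genome()].
#' @return NormalizedVariant data.frame with attribute `dropped`.
#' @export
normalize_variants <- function(records, genome) {
  dropped <- c(ref_mismatch = 0L, complex = 0L, with_n = 0L, degenerate = 0L)
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    ref <- records$ref[i]; alt <- records$alt[i]
    if (grepl("N", ref, fixed = TRUE) || grepl("N", alt, fixed = TRUE)) {
      dropped[["with_n"]] <- dropped[["with_n"]] + 1L
      next
    }
    nv <- tryCatch(
      normalize_variant(records$contig[i], records$pos[i], ref, alt, genome,
                        sample_id = records$sample_id[i]),
      tmej_ref_mismatch = function(e) "ref_mismatch",
      tmej_complex_variant = function(e) "complex",
      tmej_degenerate_variant = function(e) "degenerate")
    if (is.character(nv)) {
      dropped[[nv]] <- dropped[[nv]] + 1L
      next
    }
    out[[i]] <- nv
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(contig = character(), start = integer(),
                      kind = character(), deleted_seq = character(),
                      inserted_seq = character(), ref_base = character(),
                      alt_base = character(), sample_id = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  if (sum(dropped) > 0L) {
    message("normalize_variants: dropped ", sum(dropped), " record(s) [",
            paste(names(dropped), dropped, sep = "=", collapse = ", "), "]")
  }
  attr(res, "dropped") <- dropped
  res
}

# Convert a NormalizedVariant row back to VCF convention (anchored, 1-based).
# Used by the simulator when emitting VCFs and by round-trip tests.
denormalize_variant <- function(nv, genome) {
  if (nv$kind == "SNV") {
    return(list(pos = nv$start + 1L, ref = nv$ref_base, alt = nv$alt_base))
  }
  if (nv$start < 1L) stop("indel at contig start cannot be VCF-anchored")
  anchor <- ref_fetch(genome, nv$contig, nv$start - 1L, nv$start)
  if (nv$kind == "deletion") {
    list(pos = nv$start, ref = paste0(anchor, nv$deleted_seq), alt = anchor)
  } else {
    list(pos = nv$start, ref = anchor, alt = paste0(anchor, nv$inserted_seq))
  }
}

# payload length of a normalized indel (0 for SNV)
indel_length <- function(nv) {
  ifelse(nv$kind == "deletion", nchar(nv$deleted_seq),
         ifelse(nv$kind == "insertion", nchar(nv$inserted_seq), 0L))
}
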