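# Reference genome container and sequence access.
#
# Internally a reference genome is a named character vector of uppercase
# contig sequences plus a length table.  All coordinates in this package are
# 0-based half-open unless a function name or argument says otherwise;
# interchange formats (VCF, TSV with a `pos` column) are 1-based.

#' Construct a reference genome object
#'
#' @param seqs Named character vector, one uppercase A/C/G/T/N string per
#'   contig. Names must be unique and non-empty.
#' @return An object of class `ref_genome` with elements `seq` (named
#'   character vector) and `lengths` (named integer vector, bp).
#' @export
ref_genome <- function(seqs) {
  if (!is.character(seqs) || length(seqs) == 0L) {
    stop("`seqs` must be a non-empty named character vector")
  }
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) stop("all contigs must be named")
  if (anyDuplicated(nm)) stop("duplicate contig names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(seqs)
  bad <- !is_dna(seqs)
  if (any(bad)) stop("contig(s) contain non-ACGTN letters: ",
                     paste(nm[bad], collapse = ", "))
  structure(list(seq = seqs,
                 lengths = stats::setNames(nchar(seqs), nm)),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome:", length(x$seq), "contig(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Load a reference genome from a FASTA file
#'
#' Sequences are upcased on load. Duplicate contig names are an error.
#'
#' @param path Path to a FASTA file.
#' @return A [ref_genome()] object.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in FASTA: ", path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  ref_genome(stats::setNames(as.character(ss), names(ss)))
}

#' Write a reference genome to FASTA
#'
#' @param genome A [ref_genome()] object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(genome, path) {
  stopifnot(inherits(genome, "ref_genome"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  invisible(path)
}

check_contig <- function(genome, contig) {
  if (!contig %in% names(genome$seq)) {
    stop("unknown contig: ", contig)
  }
}

#' Fetch a reference slice
#'
#' @param genome A [ref_genome()] object.
#' @param contig Contig name.
#' @param start0,end0 0-based half-open interval; must satisfy
#'   `0 <= start0 <= end0 <= length(contig)`.
#' @return The sequence `[start0, end0)` as an uppercase string.
#' @export
ref_fetch <- function(genome, contig, start0, end0) {
  stopifnot(inherits(genome, "ref_genome"))
  check_contig(genome, contig)
  len <- genome$lengths[[contig]]
  if (start0 < 0 || end0 < start0 || end0 > len) {
    stop(sprintf("range [%d,%d) out of bounds for contig %s (length %d)",
                 start0, end0, contig, len))
  }
  substr(genome$seq[[contig]], start0 + 1L, end0)
}

#' Centered sequence context
#'
#' Returns the `(2*flank + 1)`-mer centered at `pos0`. The window must lie
#' entirely inside the contig; no clipping is performed.
#'
#' @inheritParams ref_fetch
#' @param pos0 0-based position of the center base.
#' @param flank Flank size in bp (>= 0).
#' @export
get_context <- function(genome, contig, pos0, flank = 1L) {
  if (flank < 0) stop("flank must be >= 0")
  ref_fetch(genome, contig, pos0 - flank, pos0 + flank + 1L)
}

# In-place style replacement used by the simulator: overwrite the bases at
# [start0, start0 + nchar(replacement)) with `replacement`.
ref_replace <- function(genome, contig, start0, replacement) {
  check_contig(genome, contig)
  len <- genome$lengths[[contig]]
  end0 <- start0 + nchar(replacement)
  if (start0 < 0 || end0 > len) stop("replacement out of contig bounds")
  substr(genome$seq[[contig]], start0 + 1L, end0) <- replacement
  genome
}

#' Total genome length in bp
#' @param genome A [ref_genome()] object.
#' @export
genome_length <- function(genome) sum(as.numeric(genome$lengths))
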