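# Independent brute-force oracles and small fixture builders used across
# the suite.  The oracles work on plain character vectors and exhaustive
# enumeration, deliberately sharing no code with the implementation.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

toy_genome <- function(seq, name = "t") ref_genome(stats::setNames(seq, name))

# Enumerate every start at which deleting `del_len` bases from `seq` yields
# `mutant`; the left-aligned representation is the minimum.
oracle_min_del_start <- function(seq, mutant, del_len) {
  n <- nchar(seq)
  starts <- integer(0)
  for (s in 0:(n - del_len)) {
    if (paste0(substr(seq, 1, s), substr(seq, s + del_len + 1, n)) == mutant) {
      starts <- c(starts, s)
    }
  }
  min(starts)
}

# Same for insertions: every insertion point producing `mutant` from `seq`.
oracle_min_ins_start <- function(seq, mutant, ins_len) {
  n <- nchar(seq)
  starts <- integer(0)
  for (s in 0:n) {
    payload <- substr(mutant, s + 1, s + ins_len)
    if (paste0(substr(seq, 1, s), payload, substr(seq, s + 1, n)) == mutant) {
      starts <- c(starts, s)
    }
  }
  min(starts)
}

# Brute-force adjacent-copy count by character-vector comparison.
oracle_repeat_count <- function(seq, from0, payload) {
  sv <- strsplit(seq, "")[[1]]
  pv <- strsplit(payload, "")[[1]]
  L <- length(pv)
  n <- 0L
  repeat {
    idx <- from0 + n * L + seq_len(L)
    if (max(idx) > length(sv) || !identical(sv[idx], pv)) break
    n <- n + 1L
  }
  n
}

# Brute-force microhomology: longest proper prefix of the deleted segment
# matching the 3' flank, longest proper suffix matching the 5' flank.
oracle_mh_length <- function(seq, start0, del_len) {
  sv <- strsplit(seq, "")[[1]]
  dv <- sv[start0 + seq_len(del_len)]
  best3 <- 0L
  for (k in seq_len(del_len - 1L)) {
    idx <- start0 + del_len + seq_len(k)
    if (max(idx) > length(sv)) break
    if (identical(sv[idx], dv[seq_len(k)])) best3 <- k else break
  }
  best5 <- 0L
  for (k in seq_len(del_len - 1L)) {
    idx <- start0 - k + seq_len(k)
    if (min(idx) < 1L) break
    if (identical(sv[idx], dv[del_len - k + seq_len(k)])) best5 <- k else break
  }
  max(best3, best5)
}

# Closed-form Welch one-sided p-value (H1 depends on `alternative`).
oracle_welch_p <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  if (alternative == "greater") stats::pt(t, df, lower.tail = FALSE)
  else stats::pt(t, df)
}

# One-row NormalizedVariant constructors for terse tests.
nv_snv <- function(contig, start, ref, alt, sample = "s") {
  data.frame(contig = contig, start = start, kind = "SNV", deleted_seq = "",
             inserted_seq = "", ref_base = ref, alt_base = alt,
             sample_id = sample, stringsAsFactors = FALSE)
}

nv_del <- function(contig, start, seq, sample = "s") {
  data.frame(contig = contig, start = start, kind = "deletion",
             deleted_seq = seq, inserted_seq = "", ref_base = NA_character_,
             alt_base = NA_character_, sample_id = sample,
             stringsAsFactors = FALSE)
}

nv_ins <- function(contig, start, seq, sample = "s") {
  data.frame(contig = contig, start = start, kind = "insertion",
             deleted_seq = "", inserted_seq = seq, ref_base = NA_character_,
             alt_base = NA_character_, sample_id = sample,
             stringsAsFactors = FALSE)
}

fixture_path <- function(...) {
  system.file("extdata", "consensus_fixture", ..., package = "tmejscan")
}
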