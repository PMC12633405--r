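# Reference loading, bounds contracts, VCF I/O, and variant normalization.

test_that("FASTA loading upcases, records lengths, and enforces bounds", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t", "acgtACGT"), fa)
  g <- load_reference(fa)
  expect_equal(unname(g$lengths), 8L, ignore_attr = TRUE)
  expect_equal(ref_fetch(g, "t", 0, 4), "ACGT")
  expect_equal(ref_fetch(g, "t", 0, 8), "ACGTACGT")
  expect_error(ref_fetch(g, "t", 6, 10), "out of bounds")
  expect_error(ref_fetch(g, "nope", 0, 1), "unknown contig")
  # duplicate contig names are fatal
  writeLines(c(">a", "ACGT", ">a", "GGCC"), fa)
  expect_error(load_reference(fa), "duplicate")
})

test_that("get_context returns centered k-mers and refuses clipping", {
  g <- toy_genome("ACGTA")
  expect_equal(get_context(g, "t", 2, 1), "CGT")
  expect_equal(get_context(g, "t", 2, 0), "G")
  expect_equal(get_context(g, "t", 2, 2), "ACGTA")
  expect_error(get_context(g, "t", 0, 1), "out of bounds")
  expect_error(get_context(g, "t", 4, 1), "out of bounds")
})

test_that("VCF reading splits multi-allelic sites and maps depth fields", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=t,length=50>",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "t\t5\t.\tC\tT,G\t.\tPASS\t.\tDP:AD\t20:10,6,4",
    "t\t9\t.\tC\tT\t.\tPASS\t.\tAD\t8,3",
    "t\t12\t.\tA\t<DEL>\t.\tPASS\t.\tDP\t30"), vcf)
  recs <- suppressWarnings(read_variants(vcf, "S1"))
  # multi-allelic split: one row per alt allele
  multi <- recs[recs$pos == 5, ]
  expect_equal(nrow(multi), 2L)
  expect_setequal(multi$alt, c("T", "G"))
  expect_equal(multi$alt_count[multi$alt == "T"], 6L)
  expect_equal(multi$alt_count[multi$alt == "G"], 4L)
  # depth falls back to sum(AD) when DP is absent
  ad_only <- recs[recs$pos == 9, ]
  expect_equal(ad_only$depth, 11L)
  expect_equal(ad_only$alt_count, 3L)
  # symbolic alleles are skipped and counted
  expect_false(any(recs$pos == 12))
  expect_equal(attr(recs, "n_skipped"), 1L)
})

test_that("VCF writing round-trips through an established parser", {
  g <- toy_genome(random_seq(400))
  set.seed(42)
  recs <- data.frame(
    contig = "t", pos = c(10L, 50L, 120L, 300L),
    ref = c(substr(g$seq[["t"]], 10, 10), substr(g$seq[["t"]], 50, 52),
            substr(g$seq[["t"]], 120, 120), substr(g$seq[["t"]], 300, 300)),
    alt = NA_character_, sample_id = "S1", caller = NA_character_,
    depth = c(30L, 44L, 25L, 61L), alt_count = c(9L, 12L, 6L, 20L),
    stringsAsFactors = FALSE)
  recs$alt <- c(setdiff(c("A", "C", "G", "T"), substr(recs$ref[1], 1, 1))[1],
                substr(recs$ref[2], 1, 1),               # 2-bp deletion
                paste0(recs$ref[3], "TT"),               # insertion
                setdiff(c("A", "C", "G", "T"), recs$ref[4])[1])
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(recs, vcf, g, sample_id = "S1")
  back <- read_variants(vcf, "S1")
  expect_equal(back[, c("contig", "pos", "ref", "alt", "depth", "alt_count")],
               recs[, c("contig", "pos", "ref", "alt", "depth", "alt_count")])
})

test_that("normalization trims anchors and left-aligns indels", {
  #            123456789012345
  g <- toy_genome("GGGGGGGGGCAAATG")
  # anchored deletion: CA>C at pos 10 deletes the first A of the run
  nv <- normalize_variant("t", 10, "CA", "C", g)
  expect_equal(nv$kind, "deletion")
  expect_equal(nv$deleted_seq, "A")
  expect_equal(nv$start, 10L)
  # the same event given at the rightmost run position shifts left
  nv2 <- normalize_variant("t", 12, "AA", "A", g)
  expect_equal(nv2$start, 10L)
  # SNV is the identity case
  nv3 <- normalize_variant("t", 10, "C", "T", g)
  expect_equal(nv3$kind, "SNV")
  expect_equal(nv3$start, 9L)
  expect_equal(c(nv3$ref_base, nv3$alt_base), c("C", "T"))
  # contract errors
  expect_error(normalize_variant("t", 10, "T", "A", g), "REF mismatch")
  expect_error(normalize_variant("t", 10, "C", "C", g), "ref == alt")
})

test_that("normalized starts match exhaustive enumeration on fuzzed indels", {
  set.seed(101)
  for (i in 1:300) {
    seq <- random_seq(200)
    g <- toy_genome(seq)
    if (i %% 2 == 0) {  # deletion
      L <- sample(1:8, 1)
      s <- sample(20:(200 - L - 20), 1)           # 0-based start
      mutant <- paste0(substr(seq, 1, s), substr(seq, s + L + 1, 200))
      # present the event VCF-style, anchored at an arbitrary equivalent pos
      nv <- normalize_variant("t", s, substr(seq, s, s + L),
                              substr(seq, s, s), g)
      expect_equal(nv$start, oracle_min_del_start(seq, mutant, L))
      # idempotence: re-anchoring the normalized event changes nothing
      dn <- tmejscan:::denormalize_variant(nv, g)
      nv_again <- normalize_variant("t", dn$pos, dn$ref, dn$alt, g)
      expect_equal(nv_again$start, nv$start)
      expect_equal(nv_again$deleted_seq, nv$deleted_seq)
    } else {            # insertion
      L <- sample(1:8, 1)
      s <- sample(20:180, 1)
      payload <- random_seq(L)
      mutant <- paste0(substr(seq, 1, s), payload, substr(seq, s + 1, 200))
      nv <- normalize_variant("t", s, substr(seq, s, s),
                              paste0(substr(seq, s, s), payload), g)
      expect_equal(nv$start, oracle_min_ins_start(seq, mutant, L))
      dn <- tmejscan:::denormalize_variant(nv, g)
      nv_again <- normalize_variant("t", dn$pos, dn$ref, dn$alt, g)
      expect_equal(nv_again$start, nv$start)
      expect_equal(nv_again$inserted_seq, nv$inserted_seq)
    }
  }
})

test_that("batch normalization drops bad records with counts, not errors", {
  g <- toy_genome("ACGTACGTACGT")
  recs <- data.frame(
    contig = "t", pos = c(2L, 3L, 5L, 5L),
    ref = c("C", "T", "AN", "ACG"), alt = c("G", "T", "A", "GTA"),
    sample_id = "s", caller = NA, depth = NA_integer_,
    alt_count = NA_integer_, stringsAsFactors = FALSE)
  recs$ref[2] <- "G"  # mismatch: genome has T at pos 3? actually G -> set wrong
  recs$pos[2] <- 4L   # genome has T at 4; ref G mismatches
  nv <- suppressMessages(normalize_variants(recs, g))
  expect_equal(nrow(nv), 1L)
  d <- attr(nv, "dropped")
  expect_equal(unname(d["ref_mismatch"]), 1L)
  expect_equal(unname(d["with_n"]), 1L)
  expect_equal(unname(d["complex"]), 1L)
})
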