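# ID83 annotation: repeat counts, microhomology, channel coverage, MMD flag.

test_that("repeat_unit_count counts adjacent full copies 3' of the event", {
  #               0123456789
  g <- toy_genome("CAAAATGGGC")
  # deletion of A at the start of the AAAA run leaves 3 more copies
  expect_equal(repeat_unit_count(g, "t", 1, "A", "deletion"), 3L)
  g2 <- toy_genome(paste0("GG", "ACGT", "ACGT", "TTTT"))
  expect_equal(repeat_unit_count(g2, "t", 2, "ACGT", "deletion"), 1L)
  g3 <- toy_genome(paste0("GG", "ACGT", "TTTT"))
  expect_equal(repeat_unit_count(g3, "t", 2, "ACGT", "deletion"), 0L)
  # insertions count copies from the insertion point
  expect_equal(repeat_unit_count(g, "t", 1, "A", "insertion"), 4L)
  expect_error(repeat_unit_count(g, "t", 1, "", "deletion"), "empty")
})

test_that("microhomology_length scores both junction sides, takes the max", {
  # deleted TAGC with 3' flank TAGT... -> prefix MH 3
  g <- toy_genome(paste0("GGG", "TAGC", "TAGTCCACC"))
  expect_equal(microhomology_length(g, "t", 3, "TAGC"), 3L)
  # deleted CTAG with 5' flank ...TAG -> suffix MH 3
  g2 <- toy_genome(paste0("GTAG", "CTAG", "CCCCC"))
  expect_equal(microhomology_length(g2, "t", 4, "CTAG"), 3L)
  # no homology on either side
  g3 <- toy_genome(paste0("GGG", "AC", "GGGG"))
  expect_equal(microhomology_length(g3, "t", 3, "AC"), 0L)
  expect_error(microhomology_length(g3, "t", 3, "A"), ">= 2 bp")
  # calling it on a repeat-mediated deletion is a contract violation
  g4 <- toy_genome(paste0("GG", "ACAC", "GGGG"))
  expect_error(microhomology_length(g4, "t", 2, "AC"), "repeat-mediated")
})

test_that("ID83 channels are assigned per the scheme's hierarchy", {
  expect_length(id83_channels(), 83L)
  expect_false(anyDuplicated(id83_channels()) > 0)
  # 1-bp deletion inside AAAA: homopolymer channel, pyrimidine-normalized
  # base (A -> T), 3 additional copies; never an MMD
  g <- toy_genome("CAAAATGGGC")
  a <- classify_indels(nv_del("t", 1, "A"), g)
  expect_equal(a$channel, "1:Del:T:3")
  expect_false(a$is_mmd)
  # 4-bp deletion, no repeat, MH 2 -> microhomology channel, MMD
  g2 <- toy_genome(paste0("GGA", "TACG", "TATTTTTT"))
  a2 <- classify_indels(nv_del("t", 3, "TACG"), g2)
  expect_equal(a2$channel, "4:Del:M:2")
  expect_equal(a2$mechanism, "microhomology")
  expect_true(a2$is_mmd)
  # repeat precedence: a full adjacent copy wins over microhomology
  g3 <- toy_genome(paste0("GGA", "TACG", "TACGCCCC"))
  a3 <- classify_indels(nv_del("t", 3, "TACG"), g3)
  expect_equal(a3$channel, "4:Del:R:1")
  expect_false(a3$is_mmd)
  # insertions are never MMDs
  g4 <- toy_genome("GGGTTTCCCC")
  a4 <- classify_indels(nv_ins("t", 5, "ACGT"), g4)
  expect_false(a4$is_mmd)
  expect_equal(a4$channel, "4:Ins:R:0")
  # plain >= 2 bp deletion with no context lands in its R:0 channel
  g5 <- toy_genome(paste0("GGG", "AC", "GGGG"))
  a5 <- classify_indels(nv_del("t", 3, "AC"), g5)
  expect_equal(a5$channel, "2:Del:R:0")
})

test_that("annotation agrees with brute-force oracles on fuzzed deletions", {
  set.seed(303)
  channels <- id83_channels()
  n_checked <- 0L
  for (i in 1:1500) {
    seq <- random_seq(sample(60:300, 1))
    L <- sample(2:30, 1)
    n <- nchar(seq)
    if (n < L + 40) next
    s <- sample(15:(n - L - 15), 1)
    g <- toy_genome(seq)
    D <- substr(seq, s + 1, s + L)
    rep_impl <- repeat_unit_count(g, "t", s, D, "deletion")
    expect_identical(rep_impl, oracle_repeat_count(seq, s + L, D))
    if (rep_impl == 0L) {
      expect_identical(microhomology_length(g, "t", s, D),
                       oracle_mh_length(seq, s, L))
    }
    # every classifiable deletion lands in exactly one known channel,
    # mh_length < length always, and repeat precedence holds
    a <- classify_indels(nv_del("t", s, D), g)
    expect_true(a$channel %in% channels)
    expect_lt(a$mh_length, a$length)
    if (a$repeat_count > 0) expect_false(a$mechanism == "microhomology")
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 1000L)
})

test_that("indel burdens conserve totals and recount MMDs", {
  set.seed(11)
  seq <- random_seq(800)
  g <- toy_genome(seq)
  rows <- lapply(1:30, function(i) {
    s <- sample(20:760, 1)
    if (i %% 3 == 0) {
      nv_ins("t", s, random_seq(sample(1:4, 1)), sample = sample(c("a", "b"), 1))
    } else {
      L <- sample(1:6, 1)
      nv_del("t", s, substr(seq, s + 1, s + L), sample = sample(c("a", "b"), 1))
    }
  })
  nv <- do.call(rbind, rows)
  b <- build_indel_burden(nv, g)
  expect_equal(sum(b$summary$total), nrow(nv))
  expect_equal(colSums(b$matrix), stats::setNames(b$summary$total,
                                                  b$summary$sample_id))
  for (s in b$summary$sample_id) {
    expect_equal(b$summary$mmd_count[b$summary$sample_id == s],
                 sum(b$annotations$is_mmd[b$annotations$sample_id == s]))
  }
  # mmd counts recoverable from the channel matrix alone
  expect_equal(unname(mmd_count_from_id83(b$matrix)),
               b$summary$mmd_count)
  b0 <- build_indel_burden(nv[0, ], g, samples = "a")
  expect_equal(sum(b0$matrix), 0L)
})
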