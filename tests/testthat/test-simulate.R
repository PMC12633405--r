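# Synthetic-cohort generator: determinism, planted-event truth, and the
# closing of the loop with the classifiers.

small_cfg <- function(seed = 1) {
  sim_config(seed = seed, n_contigs = 2, contig_length = 5e5,
             n_samples_treated = 2, n_samples_control = 2,
             n_dsb_sites = 5, mmd_per_dsb = 1, p_cluster_at_dsb = 1,
             min_dsb_separation = 5e4,
             mmd_offset_sigma_apobec = 1e4, mmd_offset_sigma_other = 2e4)
}

test_that("simulated references are seeded and TCW density is as expected", {
  cfg <- sim_config(seed = 5, n_contigs = 1, contig_length = 1e6)
  g1 <- simulate_reference(cfg)
  g2 <- simulate_reference(cfg)
  expect_identical(g1$seq, g2$seq)
  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_reference(g1, fa1); write_reference(g2, fa2)
  expect_identical(tools::md5sum(fa1)[[1]], tools::md5sum(fa2)[[1]])
  # TCW site frequency: each interior position is a TCW center (either
  # strand) with p = 2 * (1/4)^3 * 2 = 1/16; check within 3 sigma of the
  # binomial expectation
  n_sites <- length(tmejscan:::scan_tcw_sites(g1, "chr1", 0, 1e6, "+")) +
    length(tmejscan:::scan_tcw_sites(g1, "chr1", 0, 1e6, "-"))
  n <- 1e6 - 2
  p <- 1 / 16
  expect_lt(abs(n_sites - n * p), 3 * sqrt(n * p * (1 - p)))
  expect_error(sim_config(n_contigs = 0), "n_contigs")
})

test_that("plant_mmd constructs deletions with the exact requested MH", {
  set.seed(20)
  g <- toy_genome(random_seq(5000))
  for (i in 1:50) {
    del_len <- sample(2:20, 1)
    mh <- sample(0:(del_len - 1), 1)
    s <- 100 + i * 60
    res <- plant_mmd(g, "t", s, del_len, mh)
    ann <- classify_indels(nv_del("t", s, res$deleted_seq), res$genome)
    expect_equal(ann$repeat_count, 0L)
    expect_equal(ann$mh_length, mh)
    expect_equal(ann$is_mmd, mh >= 1)
    # the emitted deletion is already left-aligned
    dn <- tmejscan:::denormalize_variant(
      nv_del("t", s, res$deleted_seq), res$genome)
    nv <- normalize_variant("t", dn$pos, dn$ref, dn$alt, res$genome)
    expect_equal(nv$start, s)
  }
  expect_error(plant_mmd(g, "t", 500, 4, 4), "proper prefix")
})

test_that("cohorts are deterministic per seed and distinct across seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  s1 <- simulate_cohort(small_cfg(3), dir = d1)
  s2 <- simulate_cohort(small_cfg(3), dir = d2)
  s3 <- simulate_cohort(small_cfg(4), dir = d3)
  for (f in basename(unlist(s1$paths))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  expect_false(identical(s1$variants, s3$variants))
  # every emitted variant has exactly one truth row
  expect_equal(nrow(s1$variants), nrow(s1$truth))
  expect_equal(anyDuplicated(s1$truth$event_id), 0L)
  # all truth positions lie within contig bounds
  expect_true(all(s1$truth$position >= 0 &
                    s1$truth$position <
                      s1$genome$lengths[s1$truth$contig]))
})

test_that("planted events are recovered by the classifiers (round trip)", {
  sim <- simulate_cohort(small_cfg(8))
  nv <- suppressMessages(normalize_variants(sim$variants, sim$genome))
  expect_equal(sum(attr(nv, "dropped")), 0L)  # all emitted VCF records valid
  ann <- classify_indels(nv, sim$genome)
  key <- paste(ann$sample_id, ann$contig, ann$start)
  tm <- sim$truth[sim$truth$event_type == "mmd", ]
  m <- match(paste(tm$sample_id, tm$contig, tm$position), key)
  expect_false(any(is.na(m)))
  expect_true(all(ann$is_mmd[m]))
  expect_equal(ann$mh_length[m], tm$planted_mh_length)
  # planted APOBEC cluster members classify as APOBEC3 TCW substitutions
  cls <- classify_sbs96(nv[nv$kind == "SNV", ], sim$genome)
  skey <- paste(nv$sample_id[nv$kind == "SNV"], nv$contig[nv$kind == "SNV"],
                nv$start[nv$kind == "SNV"])
  tc <- sim$truth[sim$truth$event_type == "cluster_member" &
                    !is.na(sim$truth$planted_is_apobec) &
                    sim$truth$planted_is_apobec, ]
  ms <- match(paste(tc$sample_id, tc$contig, tc$position), skey)
  expect_false(any(is.na(ms)))
  expect_true(all(cls$is_apobec3[ms]))
  # planted composition drives the 2/3 categorization
  for (i in seq_len(nrow(sim$truth_clusters))) {
    tcl <- sim$truth_clusters[i, ]
    members <- sim$truth[!is.na(sim$truth$parent_dsb_id) &
                           sim$truth$parent_dsb_id == tcl$dsb_id &
                           sim$truth$event_type == "cluster_member", ]
    cat <- categorize_cluster(members$planted_is_apobec,
                              rep(tcl$strand, nrow(members)))
    want <- if (3 * tcl$n_apobec >= 2 * tcl$n_members) "APOBEC3" else "other"
    expect_equal(cat$category, want)
  }
})
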