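# Intermutation-distance clustering and the two-thirds categorization rule.

test_that("the null-derived IMD threshold follows the closed form", {
  expect_equal(derive_imd_threshold(1000, 1e8, 0.01), 1005L)
  expect_equal(derive_imd_threshold(2, 100, 0.5), 34L)
  # q -> 0 drives the threshold to 0
  expect_equal(derive_imd_threshold(1000, 1e8, 0), 0L)
  expect_error(derive_imd_threshold(1, 1e8, 0.01), ">= 2")
})

test_that("maximal runs under the threshold become clusters", {
  p <- cluster_params(imd_threshold = 1000)
  sub6 <- data.frame(sample_id = "s", contig = "c",
                     pos = seq(0, by = 200, length.out = 6),
                     is_apobec3 = TRUE, orientation = "+",
                     stringsAsFactors = FALSE)
  res <- detect_clusters(sub6, p)
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$clusters$n_total, 6L)
  # two triplets separated by 1 Mb
  sub2 <- data.frame(sample_id = "s", contig = "c",
                     pos = c(0, 100, 200, 1e6, 1e6 + 100, 1e6 + 200),
                     is_apobec3 = TRUE, orientation = "+",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(detect_clusters(sub2, p)$clusters), 2L)
  # all gaps over threshold: nothing clusters
  sub3 <- data.frame(sample_id = "s", contig = "c",
                     pos = c(0, 5000, 10000), is_apobec3 = TRUE,
                     orientation = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(detect_clusters(sub3, p)$clusters), 0L)
  expect_error(detect_clusters(sub3[c(2, 1, 3), ], p), "sorted")
})

test_that("clusters partition their members and never overlap", {
  set.seed(404)
  pos <- sort(sample(1:1e6, 400))
  subs <- data.frame(sample_id = "s", contig = "c", pos = pos,
                     is_apobec3 = FALSE, orientation = "+",
                     stringsAsFactors = FALSE)
  res <- detect_clusters(subs, cluster_params(imd_threshold = 2000))
  m <- res$members
  expect_equal(nrow(m), length(pos))
  # every clustered member belongs to exactly one cluster, counts agree
  tab <- table(m$cluster_id[!is.na(m$cluster_id)])
  expect_equal(sort(as.integer(tab)),
               sort(res$clusters$n_total))
  # spans of distinct clusters are disjoint
  cl <- res$clusters[order(res$clusters$span_start), ]
  if (nrow(cl) > 1) {
    expect_true(all(cl$span_start[-1] > cl$span_end[-nrow(cl)]))
  }
  # threshold monotonicity: a larger threshold never unclusters mutations
  n_clustered <- function(thr) {
    r <- detect_clusters(subs, cluster_params(imd_threshold = thr))
    sum(!is.na(r$members$cluster_id))
  }
  counts <- vapply(c(500, 1000, 2000, 5000), n_clustered, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the 2/3 rule is inclusive and strand coordination gates members", {
  # 4 of 6 qualifying: 4/6 >= 2/3
  expect_equal(categorize_cluster(c(rep(TRUE, 4), FALSE, FALSE),
                                  rep("+", 6))$category, "APOBEC3")
  # exactly 2/3 counts (integer arithmetic, no float slop)
  expect_equal(categorize_cluster(c(TRUE, TRUE, FALSE),
                                  rep("+", 3))$category, "APOBEC3")
  # 3 of 6 does not
  expect_equal(categorize_cluster(c(rep(TRUE, 3), rep(FALSE, 3)),
                                  rep("+", 6))$category, "other")
  # strand-discordant APOBEC members do not qualify under coordination
  split_strand <- categorize_cluster(c(rep(TRUE, 4), FALSE, FALSE),
                                     c("+", "+", "-", "-", "+", "+"))
  expect_equal(split_strand$n_qualifying, 2L)
  expect_equal(split_strand$category, "other")
  # ... but do without it
  no_coord <- categorize_cluster(c(rep(TRUE, 4), FALSE, FALSE),
                                 c("+", "+", "-", "-", "+", "+"),
                                 require_strand_coordination = FALSE)
  expect_equal(no_coord$category, "APOBEC3")
  expect_error(categorize_cluster(logical(0)), "empty")
})

test_that("cluster centers use the floor midpoint of extreme members", {
  expect_equal(cluster_center(c(100, 300)), 200)
  expect_equal(cluster_center(c(500, 500)), 500)
  expect_equal(cluster_center(c(0, 7)), 3)
})

test_that("planted clusters are recovered with matching categories", {
  set.seed(505)
  L <- 5e8
  sim <- simulate_cluster_positions(n_clusters = 60, callable_length_bp = L,
                                    background_rate = 1e-6, span_max = 2000)
  thr <- derive_imd_threshold(nrow(sim$subs), L, 0.01)
  expect_gt(thr, 2000)  # spans are well under the derived threshold
  res <- detect_clusters(sim$subs, cluster_params(imd_threshold = thr))
  m <- res$members
  recovered <- vapply(sim$truth_clusters$cluster_id, function(cid) {
    ids <- m$cluster_id[m$planted_cluster == cid & !is.na(m$planted_cluster)]
    length(unique(ids)) == 1L && !any(is.na(ids))
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
  # category matches the planted composition wherever membership is exact
  for (i in seq_len(nrow(sim$truth_clusters))) {
    cid <- sim$truth_clusters$cluster_id[i]
    det_ids <- unique(m$cluster_id[!is.na(m$planted_cluster) &
                                     m$planted_cluster == cid])
    if (length(det_ids) != 1L || is.na(det_ids)) next
    det_n <- res$clusters$n_total[res$clusters$cluster_id == det_ids]
    if (det_n != sim$truth_clusters$n[i]) next  # background joined: skip
    want <- if (3 * sim$truth_clusters$n_apobec[i] >=
                2 * sim$truth_clusters$n[i]) "APOBEC3" else "other"
    expect_equal(res$clusters$category[res$clusters$cluster_id == det_ids],
                 want)
  }
})
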