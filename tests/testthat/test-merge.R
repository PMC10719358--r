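test_that("sv_match applies the distance, overlap and insertion rules", {
  p <- merge_params()
  del <- function(s, e) sv_tbl("chr1", s, e, "DEL")
  ins <- function(s, l) sv_tbl("chr1", s, s, "INS", length = l)

  expect_true(sv_match(del(1000, 2000), del(1100, 2100), p))
  expect_false(sv_match(del(1000, 2000), del(1000, 1200), p))  # 20% overlap
  expect_true(sv_match(ins(1000, 300), ins(1500, 320), p))
  expect_false(sv_match(del(1000, 2000),
                        sv_tbl("chr1", 1000, 2000, "DUP"), p))
  expect_false(sv_match(del(1000, 2000),
                        sv_tbl("chr2", 1000, 2000, "DEL"), p))
  # breakpoint distance is checked at both ends for spanned types
  expect_false(sv_match(del(1000, 2000), del(1100, 3200), p))
  # insertion length rule: |L1-L2| < 2*min
  expect_false(sv_match(ins(1000, 100), ins(1010, 301), p))
  expect_true(sv_match(ins(1000, 100), ins(1010, 299), p))
})

test_that("sv_match is symmetric and reflexive on random records", {
  svs <- random_jittered_svs(60, n_dup = 2, seed = 11)
  p <- merge_params()
  i <- sample(nrow(svs), 200, replace = TRUE)
  j <- sample(nrow(svs), 200, replace = TRUE)
  expect_equal(sv_match_pairs(svs[i, ], svs[j, ], p),
               sv_match_pairs(svs[j, ], svs[i, ], p))
  expect_true(all(sv_match_pairs(svs, svs, p)))
})

test_that("raw-call filter applies the AF, depth and length rules", {
  calls <- sv_tbl("chr1", c(100, 100, 100, 100), 1100, "DEL",
                  id = paste0("c", 1:4),
                  af_read = c(0.25, 0.5, 0.5, 0.5),
                  depth = c(20, 45, 20, 20))
  calls$length[4] <- 30L
  calls$end[4] <- 130L
  out <- filter_raw_calls(calls, mean_depth = 20)
  expect_equal(out$id, "c3")
  expect_equal(attr(out, "removed"), c(af = 1L, depth = 1L, length = 1L))
  expect_error(filter_raw_calls(calls, mean_depth = 0), "positive")
})

test_that("consensus keeps >=2-caller or cuteSV-HQ clusters, exhaustively", {
  # all 2^3 caller-presence combinations x HQ on/off for cuteSV
  callers <- c("cuteSV", "sniffles", "nanovar")
  for (mask in 0:7) {
    present <- callers[bitwAnd(mask, c(4L, 2L, 1L)) > 0]
    if (length(present) == 0) next
    for (hq in c(FALSE, TRUE)) {
      calls <- sv_tbl("chr1", 1000 + seq_along(present), 2000,
                      "DEL", length = 1000 - seq_along(present),
                      id = paste0("c", seq_along(present)),
                      caller = present, sample = "s1",
                      genotype = "0/1",
                      hq_flag = hq & present == "cuteSV")
      calls$end <- calls$start + calls$length
      out <- within_sample_consensus(calls)
      should_keep <- length(present) >= 2 || (hq && "cuteSV" %in% present)
      expect_equal(nrow(out), as.integer(should_keep),
                   info = sprintf("mask=%d hq=%s", mask, hq))
      if (should_keep) {
        top <- present[which.min(match(present, c("cuteSV", "sniffles",
                                                  "nanovar")))]
        expect_equal(out$caller, top)
        expect_equal(out$n_callers, length(present))
      }
    }
  }
})

test_that("consensus genotype and coordinates come from the priority caller", {
  calls <- dplyr::bind_rows(
    sv_tbl("chr1", 1000, 2000, "DEL", id = "a", caller = "cuteSV",
           sample = "s1", genotype = "0/1"),
    sv_tbl("chr1", 1020, 2020, "DEL", id = "b", caller = "sniffles",
           sample = "s1", genotype = "1/1"))
  out <- within_sample_consensus(calls)
  expect_equal(out$genotype, "0/1")
  expect_equal(out$start, 1000L)
  expect_error(
    within_sample_consensus(dplyr::mutate(calls, sample = c("s1", "s2"))),
    "single sample")
})

test_that("merge partition equals the brute-force transitive closure", {
  for (seed in 1:12) {
    svs <- random_jittered_svs(n_true = 40, n_dup = 4, jitter = 200,
                               seed = seed)
    svs$sample <- sample(c("s1", "s2", "s3", "s4"), nrow(svs),
                         replace = TRUE)
    svs$genotype <- "0/1"
    cohort <- cohort_tbl(paste0("s", 1:4), rep(c("POP_A", "POP_B"), 2))
    m <- merge_cohort(svs, cohort)
    oracle <- brute_force_partition(svs, merge_params())
    got <- partition_sets(m$members$id, m$members$cluster)
    want <- partition_sets(svs$id, oracle)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("merge is idempotent and order-invariant", {
  svs <- random_jittered_svs(n_true = 150, n_dup = 3, jitter = 100,
                             seed = 5)
  svs$sample <- sample(c("s1", "s2", "s3"), nrow(svs), replace = TRUE)
  svs$genotype <- "0/1"
  cohort <- cohort_tbl(paste0("s", 1:3), c("POP_A", "POP_A", "POP_B"))
  m1 <- merge_cohort(svs, cohort)
  # idempotence: re-merging the representatives changes nothing
  reps <- m1$representatives
  reps$sample <- "s1"
  m2 <- merge_cohort(reps, cohort)
  expect_equal(nrow(m2$representatives), nrow(m1$representatives))
  expect_equal(m2$representatives[, c("chrom", "start", "end", "svtype")],
               m1$representatives[, c("chrom", "start", "end", "svtype")])
  # order invariance
  for (k in 1:5) {
    perm <- sample(nrow(svs))
    mp <- merge_cohort(svs[perm, ], cohort)
    expect_equal(mp$representatives$start, m1$representatives$start)
    expect_equal(partition_sets(mp$members$id, mp$members$cluster),
                 partition_sets(m1$members$id, m1$members$cluster))
  }
})

test_that("tighter matching parameters never reduce the cluster count", {
  svs <- random_jittered_svs(n_true = 60, n_dup = 3, jitter = 300, seed = 9)
  svs$sample <- "s1"; svs$genotype <- "0/1"
  cohort <- cohort_tbl("s1", "POP_A")
  n_base <- nrow(merge_cohort(svs, cohort, merge_params())$representatives)
  n_tight_d <- nrow(merge_cohort(svs, cohort,
                                 merge_params(max_dist = 200))$representatives)
  n_tight_o <- nrow(merge_cohort(svs, cohort,
                                 merge_params(min_overlap = 0.8))$representatives)
  expect_gte(n_tight_d, n_base)
  expect_gte(n_tight_o, n_base)
})

test_that("cluster genotypes resolve by caller priority then alternate count", {
  cohort <- cohort_tbl(c("s1", "s2"), c("POP_A", "POP_B"))
  svs <- dplyr::bind_rows(
    sv_tbl("chr1", 1000, 2000, "DEL", id = "a", caller = "sniffles",
           sample = "s1", genotype = "1/1"),
    sv_tbl("chr1", 1010, 2010, "DEL", id = "b", caller = "cuteSV",
           sample = "s1", genotype = "0/1"),
    sv_tbl("chr1", 1020, 2020, "DEL", id = "c", caller = "nanovar",
           sample = "s2", genotype = "0/1"),
    sv_tbl("chr1", 1020, 2020, "DEL", id = "d", caller = "nanovar",
           sample = "s2", genotype = "1/1"))
  m <- merge_cohort(svs, cohort)
  expect_equal(nrow(m$representatives), 1L)
  expect_equal(as.integer(m$gm$dosage[, 1]), c(1L, 2L))  # cuteSV GT; 1/1 tie
  expect_equal(m$representatives$n_carriers, 2L)
})

test_that("callset comparison filters lengths and picks best matches", {
  p <- merge_params()
  q <- dplyr::bind_rows(
    sv_tbl("chr1", 1000, 2000, "DEL", id = "q1"),
    sv_tbl("chr1", 100000, 160000, "DEL", id = "q2"),  # 60 kb: excluded
    sv_tbl("chr2", 5000, 6000, "DEL", id = "q3"))
  r <- dplyr::bind_rows(
    sv_tbl("chr1", 1100, 2100, "DEL", id = "r1"),
    sv_tbl("chr1", 1050, 2050, "DEL", id = "r2"))
  out <- compare_callsets(q, r, p)
  expect_equal(out$shared, 1L)
  expect_equal(out$novel, 1L)  # q3 (q2 filtered out before comparison)
  expect_equal(out$pairs$ref_id, "r2")  # smaller breakpoint distance
  empty <- compare_callsets(q, r[0, ], p)
  expect_equal(empty$novel, 2L)
})
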