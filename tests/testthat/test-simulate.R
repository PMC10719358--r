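small_params <- function(...) {
  args <- utils::modifyList(
    list(n_pop_a = 25L, n_pop_b = 30L, m_svs = 150L, n_selected = 5L,
         n_tag_snps = 9L, n_background_snps = 20L,
         genome = c(chr1 = 8e6, chr2 = 6e6), seed = 21L),
    list(...))
  do.call(sim_params, args)
}

test_that("cohort truth is deterministic given the seed", {
  s1 <- simulate_cohort_truth(small_params())
  s2 <- simulate_cohort_truth(small_params())
  expect_equal(s1$truth, s2$truth)
  expect_equal(s1$gm$dosage, s2$gm$dosage)
  s3 <- simulate_cohort_truth(small_params(seed = 22L))
  expect_false(identical(s1$gm$dosage, s3$gm$dosage))
})

test_that("realized population frequencies track the truth targets", {
  p <- sim_params(n_pop_a = 150L, n_pop_b = 150L, m_svs = 400L,
                  n_selected = 10L, seed = 23L)
  sim <- simulate_cohort_truth(p)
  d <- sim$gm$dosage
  in_a <- sim$cohort$population == "POP_A"
  realized <- colMeans(d[in_a, ]) / 2
  target <- sim$truth$p_a
  # binomial z-scores: |realized - target| within 4 sd (common loci);
  # near-fixed loci get a count-scale slack instead
  common <- target > 0.005 & target < 0.995
  se <- sqrt(target * (1 - target) / (2 * sum(in_a)))
  expect_true(all(abs(realized - target)[common] < (4 * se)[common]))
  expect_true(all(abs(realized - target)[!common] * 2 * sum(in_a) < 8))
  # selected loci implant the differentiated carrier frequencies
  sel <- sim$truth$selected
  f_a <- colMeans((d[in_a, sel, drop = FALSE] >= 1) * 1)
  f_b <- colMeans((d[!in_a, sel, drop = FALSE] >= 1) * 1)
  expect_gt(mean(f_a), 0.5)
  expect_lt(mean(f_b), 0.15)
  expect_error(sim_params(fst_param = 1), "< 1")
})

test_that("fst_param = 0 gives shared frequencies and near-zero theta", {
  p <- sim_params(n_pop_a = 100L, n_pop_b = 100L, m_svs = 1000L,
                  n_selected = 0L, fst_param = 0, seed = 24L)
  sim <- simulate_cohort_truth(p)
  expect_equal(sim$truth$p_a, sim$truth$p_b)
  fst <- weir_cockerham_fst(sim$gm)
  expect_lt(abs(fst$weighted), 0.01)
})

test_that("noise-free caller output reconstructs the truth exactly", {
  p <- small_params(caller_models = tibble::tibble(
    caller = c("cuteSV", "sniffles", "nanovar"),
    sensitivity = 1, fp_per_mb = 0, bp_jitter_sd = 0,
    len_jitter_sd = 0, hq_prob = 0))
  sim <- simulate_cohort_truth(p)
  calls <- simulate_caller_calls(sim, p)
  kept <- filter_raw_calls(calls, p$mean_depth)
  expect_equal(nrow(kept), nrow(calls))  # all true calls pass the filter
  cons <- dplyr::bind_rows(lapply(split(kept, kept$sample),
                                  within_sample_consensus))
  m <- merge_cohort(cons, sim$cohort)
  carried <- colSums(presence_matrix(sim$gm)) > 0
  expect_equal(nrow(m$representatives), sum(carried))
  truth_carried <- sim$truth[carried, ]
  o1 <- order(truth_carried$chrom, truth_carried$start)
  expect_equal(m$representatives$start, truth_carried$start[o1])
  expect_equal(m$representatives$svtype, truth_carried$svtype[o1])
  # carriers match: merged presence equals truth presence
  got <- presence_matrix(m$gm)
  want <- presence_matrix(sim$gm)[, carried][, o1]
  expect_equal(unname(got), unname(want))
})

test_that("single-caller independent false calls are consensus-filtered", {
  p <- small_params(caller_models = tibble::tibble(
    caller = c("cuteSV", "sniffles", "nanovar"),
    sensitivity = 1, fp_per_mb = c(1, 1, 1), bp_jitter_sd = 0,
    len_jitter_sd = 0, hq_prob = 0), fp_fail_frac = 0)
  sim <- simulate_cohort_truth(p)
  calls <- simulate_caller_calls(sim, p)
  expect_gt(sum(is.na(calls$truth_id)), 0)
  kept <- filter_raw_calls(calls, p$mean_depth)
  cons <- dplyr::bind_rows(lapply(split(kept, kept$sample),
                                  within_sample_consensus))
  # every surviving consensus call descends from a true SV cluster:
  # re-match against the truth table
  m <- merge_cohort(cons, sim$cohort)
  carried <- sum(colSums(presence_matrix(sim$gm)) > 0)
  expect_equal(nrow(m$representatives), carried)
})

test_that("correlated false calls survive via agreement across callers", {
  p <- small_params(correlated_fp = TRUE, fp_fail_frac = 0,
                    caller_models = tibble::tibble(
                      caller = c("cuteSV", "sniffles", "nanovar"),
                      sensitivity = 1, fp_per_mb = c(0.5, 0.5, 0.5),
                      bp_jitter_sd = 0, len_jitter_sd = 0, hq_prob = 0))
  sim <- simulate_cohort_truth(p)
  calls <- simulate_caller_calls(sim, p)
  fp <- calls[is.na(calls$truth_id), ]
  expect_equal(length(unique(fp$caller)), 3L)
  kept <- filter_raw_calls(calls, p$mean_depth)
  cons <- dplyr::bind_rows(lapply(split(kept, kept$sample),
                                  within_sample_consensus))
  # correlated artifacts pass the >= 2-caller rule
  m <- merge_cohort(cons, sim$cohort)
  carried <- sum(colSums(presence_matrix(sim$gm)) > 0)
  expect_gt(nrow(m$representatives), carried)
})

test_that("tag SNPs realize their target r2 and background SNPs do not tag", {
  p <- sim_params(n_pop_a = 150L, n_pop_b = 150L, m_svs = 300L,
                  n_selected = 0L, n_tag_snps = 30L,
                  n_background_snps = 50L, seed = 25L)
  sim <- simulate_cohort_truth(p)
  snps <- simulate_linked_snps(sim, p)
  r2 <- purrr::pmap_dbl(snps$tags, function(snp_id, sv_id, target_r2, pos) {
    as.numeric(r2_dosage(sim$gm$dosage[, sv_id],
                         snps$snp_gm$dosage[, snp_id]))
  })
  by_level <- split(r2 - snps$tags$target_r2, snps$tags$target_r2)
  for (lvl in names(by_level)) {
    expect_lt(abs(mean(by_level[[lvl]])), 0.06)
  }
  expect_equal(r2[snps$tags$target_r2 == 1],
               rep(1, sum(snps$tags$target_r2 == 1)), tolerance = 1e-12)
  bg <- grep("^bgsnp", colnames(snps$snp_gm$dosage), value = TRUE)
  set.seed(1)
  some_svs <- sample(colnames(sim$gm$dosage), 20)
  bg_r2 <- outer(some_svs, bg[1:20], Vectorize(function(v, s) {
    as.numeric(r2_dosage(sim$gm$dosage[, v], snps$snp_gm$dosage[, s]))
  }))
  expect_lt(mean(bg_r2, na.rm = TRUE), 0.05)
})

test_that("annotation tracks hit coverage targets and tag selected SVs", {
  p <- small_params()
  sim <- simulate_cohort_truth(p)
  anno <- simulate_annotations(sim$truth, p, repeat_coverage = 0.5)
  cov <- sum(anno$repeats$end - anno$repeats$start) / sum(p$genome)
  expect_gt(cov, 0.49); expect_lt(cov, 0.51)
  expect_false(any(is.na(anno$genes$label)))
  # every selected SV picks up its implanted enhancer within the pad
  sel <- sim$truth[sim$truth$selected, ]
  sel_svs <- sv_tbl(chrom = sel$chrom, start = sel$start, end = sel$end,
                    svtype = sel$svtype, length = sel$length, id = sel$id)
  res <- intersect_elements(sel_svs,
                            regulatory_params(100,
                                              anno["enhancers"]))
  hits <- res$table$n_elements[res$table$track == "enhancers"]
  expect_true(all(hits >= 1))
  expect_error(simulate_annotations(sim$truth, p, repeat_coverage = 1.5),
               "<= 1")
})
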