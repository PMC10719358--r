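test_that("r2 matches the worked pair and the brute-force oracle", {
  expect_equal(as.numeric(r2_dosage(c(0, 1, 2, 2, 0), c(0, 1, 2, 1, 0))),
               9 / 11.2, tolerance = 1e-12)
  expect_equal(as.numeric(r2_dosage(c(0, 1, 2), c(0, 1, 2))), 1)
  set.seed(14)
  for (i in 1:200) {
    g1 <- sample(c(0:2, NA), 30, replace = TRUE, prob = c(.3, .3, .3, .1))
    g2 <- sample(c(0:2, NA), 30, replace = TRUE, prob = c(.3, .3, .3, .1))
    ok <- !is.na(g1) & !is.na(g2)
    if (sum(ok) < 3 || sd(g1[ok]) == 0 || sd(g2[ok]) == 0) next
    brute <- (sum((g1[ok] - mean(g1[ok])) * (g2[ok] - mean(g2[ok]))))^2 /
      (sum((g1[ok] - mean(g1[ok]))^2) * sum((g2[ok] - mean(g2[ok]))^2))
    expect_equal(as.numeric(r2_dosage(g1, g2)), brute, tolerance = 1e-12)
  }
})

test_that("r2 flags constant and under-sampled input rather than 0", {
  out <- r2_dosage(c(1, 1, 1, 1), c(0, 1, 2, 1))
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "constant")
  out2 <- r2_dosage(c(0, 1, NA, NA), c(0, 1, 1, NA))
  expect_true(is.na(out2))
  expect_equal(attr(out2, "n"), 2L)
  expect_error(r2_dosage(1:3, 1:4), "equal length")
})

test_that("r2 is symmetric and invariant under allele relabeling", {
  set.seed(15)
  g1 <- rbinom(50, 2, 0.4); g2 <- rbinom(50, 2, 0.6)
  expect_equal(as.numeric(r2_dosage(g1, g2)),
               as.numeric(r2_dosage(g2, g1)))
  expect_equal(as.numeric(r2_dosage(2 - g1, g2)),
               as.numeric(r2_dosage(g1, g2)), tolerance = 1e-12)
})

make_ld_fixture <- function() {
  set.seed(16)
  n <- 60
  cohort <- cohort_tbl(sprintf("s%02d", 1:n),
                       rep(c("POP_A", "POP_B"), each = n / 2))
  sv_d <- matrix(rbinom(n, 2, 0.5), ncol = 1,
                 dimnames = list(cohort$sample, "sv1"))
  sv_meta <- tibble::tibble(id = "sv1", chrom = "chr1", start = 5e6L,
                            end = 5001000L, svtype = "DEL",
                            length = 1000L)
  snp_d <- cbind(
    near_perfect = sv_d[, 1],
    near_indep = rbinom(n, 2, 0.5),
    far = sv_d[, 1])
  rownames(snp_d) <- cohort$sample
  snp_meta <- tibble::tibble(
    id = colnames(snp_d), chrom = "chr1",
    start = c(5100000L, 5200000L, 6200000L))  # far: 1.2 Mb away
  snp_meta$end <- snp_meta$start + 1L
  list(sv = genotype_matrix(sv_d, variants = sv_meta, cohort = cohort),
       snp = genotype_matrix(snp_d, variants = snp_meta, cohort = cohort))
}

test_that("ld_scan honours the window, the cutoff and sample identity", {
  fx <- make_ld_fixture()
  out <- ld_scan(fx$sv, fx$snp, ld_params())
  expect_true("near_perfect" %in% out$snp_id)
  expect_false("far" %in% out$snp_id)       # outside the 1 Mb window
  expect_false("near_indep" %in% out$snp_id)  # r2 below 0.2
  expect_equal(out$r2[out$snp_id == "near_perfect"], 1)
  # mismatched samples error
  snp2 <- fx$snp
  rownames(snp2$dosage) <- rev(rownames(snp2$dosage))
  expect_error(ld_scan(fx$sv, snp2), "same samples")
})

test_that("window anchors at the breakpoint nearest the SNP", {
  fx <- make_ld_fixture()
  # SNP at 6.0005 Mb: 1.0005 Mb from start but 0.9995 Mb from end
  fx$snp$variants$start[3] <- 6000500L
  out <- ld_scan(fx$sv, fx$snp, ld_params())
  expect_true("far" %in% out$snp_id)
})

test_that("phenotype bridge keeps strong pairs in the catalog, inclusively", {
  pairs <- tibble::tibble(sv_id = c("sv1", "sv1", "sv2", "sv3"),
                          snp_id = c("rs1", "rs2", "rs3", "rs4"),
                          r2 = c(0.85, 0.80, 0.79, 0.9),
                          n = 100L, distance = 1000L)
  catalog <- tibble::tibble(snp_id = c("rs1", "rs2", "rs3"),
                            chrom = "chr1", pos = 1:3,
                            phenotype = c("red blood cell count",
                                          "height", "height"))
  out <- phenotype_bridge(pairs, catalog)
  expect_setequal(out$snp_id, c("rs1", "rs2"))  # 0.80 included, rs4 absent
  expect_equal(out$phenotype[out$snp_id == "rs1"], "red blood cell count")
  per_sv <- attr(out, "per_sv")
  expect_equal(per_sv$phenotypes[per_sv$sv_id == "sv1"],
               "height; red blood cell count")
})

test_that("duplicate catalog rows produce one association per triple", {
  pairs <- tibble::tibble(sv_id = "sv1", snp_id = "rs1", r2 = 0.95,
                          n = 50L, distance = 10L)
  catalog <- tibble::tibble(snp_id = c("rs1", "rs1"), chrom = "chr1",
                            pos = 1L, phenotype = c("height", "height"))
  expect_equal(nrow(phenotype_bridge(pairs, catalog)), 1L)
})

test_that("every realized-strong implanted tag is bridged from truth genotypes", {
  p <- sim_params(n_pop_a = 60L, n_pop_b = 80L, m_svs = 400L,
                  n_selected = 0L, n_tag_snps = 30L,
                  n_background_snps = 40L, seed = 55L)
  sim <- simulate_cohort_truth(p)
  snps <- simulate_linked_snps(sim, p)
  pairs <- ld_scan(sim$gm, snps$snp_gm, ld_params())
  bridge <- phenotype_bridge(pairs, snps$catalog, ld_params())
  realized <- vapply(seq_len(nrow(snps$tags)), function(i) {
    as.numeric(r2_dosage(sim$gm$dosage[, snps$tags$sv_id[i]],
                         snps$snp_gm$dosage[, snps$tags$snp_id[i]]))
  }, numeric(1))
  strong <- snps$tags$snp_id[!is.na(realized) & realized >= 0.8]
  expect_gte(mean(strong %in% bridge$snp_id), 0.95)
})
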