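test_that("carrier frequency is the carrier proportion with missing = 0", {
  d <- matrix(0L, nrow = 119, ncol = 2)
  d[1:24, 1] <- 1L
  d[1:3, 2] <- NA_integer_
  gm <- gm_from_dosage(d, n_a = 119)
  f <- carrier_frequency(gm)
  expect_equal(f$freq[1], 24 / 119)
  expect_equal(f$freq[2], 0)
  expect_error(carrier_frequency(gm, character(0)), "empty")
})

test_that("frequency spectrum bins and singletons follow the level edges", {
  freqs <- tibble::tibble(id = paste0("v", 1:5),
                          freq = c(0.05, 0.1, 0.2, 0.5, 1.0))
  sp <- af_spectrum(freqs)
  expect_equal(unname(sp$bins), c(2L, 1L, 1L, 1L))
  expect_equal(sum(sp$bins), 5L)
  expect_error(af_spectrum(tibble::tibble(id = "x", freq = 1.2)), "0, 1")
  # singleton: exactly one carrier
  d <- matrix(0L, 100, 2); d[1, 1] <- 1L; d[1:2, 2] <- 1L
  gm <- gm_from_dosage(d)
  expect_equal(af_spectrum(carrier_frequency(gm), gm)$singletons, 1L)
  empty <- af_spectrum(tibble::tibble(id = character(), freq = numeric()))
  expect_equal(sum(empty$bins), 0L)
})

test_that("HWE chi-square matches the closed form on worked counts", {
  counts_to_gm <- function(n0, n1, n2) {
    gm_from_dosage(matrix(rep(c(0L, 1L, 2L), c(n0, n1, n2)), ncol = 1))
  }
  r1 <- tidy(hwe_test(counts_to_gm(25, 50, 25)))
  expect_equal(r1$chi2, 0, tolerance = 1e-12)
  expect_equal(r1$p, 1)
  expect_true(r1$in_hwe)
  r2 <- tidy(hwe_test(counts_to_gm(30, 40, 30)))
  expect_equal(r2$chi2, 4.0, tolerance = 1e-12)
  expect_equal(r2$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  r3 <- tidy(hwe_test(counts_to_gm(50, 0, 50)))
  expect_equal(r3$chi2, 100, tolerance = 1e-12)
  # monomorphic column is flagged untested and excluded from m
  d <- cbind(rep(0:2, c(30, 40, 30)), 0L)
  res <- hwe_test(gm_from_dosage(d))
  expect_equal(res$m, 1L)
  expect_true(is.na(tidy(res)$chi2[2]))
})

test_that("Weir-Cockerham components are exact on a fixed-difference site", {
  d <- matrix(c(rep(2L, 10), rep(0L, 10)), ncol = 1)
  gm <- gm_from_dosage(d, n_a = 10)
  fst <- weir_cockerham_fst(gm)
  site <- tidy(fst)
  expect_equal(site$a, 0.5, tolerance = 1e-12)
  expect_equal(site$b, 0, tolerance = 1e-12)
  expect_equal(site$c, 0, tolerance = 1e-12)
  expect_equal(site$theta, 1.0, tolerance = 1e-12)
  expect_equal(fst$weighted, 1.0, tolerance = 1e-12)
})

test_that("theta is non-positive without among-population variance", {
  set.seed(1)
  d <- matrix(rbinom(200, 2, 0.4), ncol = 2)
  gm <- gm_from_dosage(d, n_a = 50)
  # same allele frequencies by construction of the permutation test below
  fst <- weir_cockerham_fst(gm)
  d2 <- rbind(d[1:50, ], d[1:50, ])  # identical populations
  gm2 <- gm_from_dosage(d2, n_a = 50)
  fst2 <- weir_cockerham_fst(gm2)
  expect_true(all(tidy(fst2)$theta <= 0, na.rm = TRUE))
})

test_that("theta is invariant under allele-label swap", {
  set.seed(2)
  d <- matrix(rbinom(500, 2, runif(10, 0.1, 0.9)), nrow = 50, byrow = TRUE)
  gm <- gm_from_dosage(d, n_a = 25)
  gm_sw <- gm_from_dosage(2L - d, n_a = 25)
  expect_equal(tidy(weir_cockerham_fst(gm))$theta,
               tidy(weir_cockerham_fst(gm_sw))$theta, tolerance = 1e-12)
})

test_that("fst errors on more than two populations; hudson option works", {
  d <- matrix(rbinom(30, 2, 0.5), ncol = 1)
  cohort <- cohort_tbl(sprintf("s%02d", 1:30),
                       rep(c("P1", "P2", "P3"), each = 10))
  rownames(d) <- cohort$sample
  gm <- genotype_matrix(d, cohort = cohort)
  expect_error(weir_cockerham_fst(gm), "two populations")
  d2 <- matrix(c(rep(2L, 10), rep(0L, 10)), ncol = 1)
  gm2 <- gm_from_dosage(d2, n_a = 10)
  expect_equal(glance(weir_cockerham_fst(gm2, method = "hudson"))$weighted, 1)
})

test_that("saturation curves are nondecreasing and end at the union size", {
  pres <- rbind(c(1, 1, 0), c(0, 1, 1), c(0, 0, 1))
  gm <- gm_from_dosage(pres)
  sc <- saturation_curve(gm, n_orders = 8, seed = 3)
  final <- sc$curves |> dplyr::group_by(order) |>
    dplyr::summarise(f = max(cumulative), nd = all(diff(cumulative) >= 0))
  expect_true(all(final$f == 3))
  expect_true(all(final$nd))
  one <- saturation_curve(gm_from_dosage(matrix(c(1L, 1L, 0L), 1), n_a = 1),
                          n_orders = 1, seed = 1)
  expect_equal(one$curves$cumulative, 2L)
})

test_that("GC content counts G+C over unambiguous bases", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "GGCCATATGATCNNNN"))
  svs <- dplyr::bind_rows(
    sv_tbl("chr1", 0, 4, "DEL", id = "a"),    # GGCC
    sv_tbl("chr1", 4, 8, "DEL", id = "b"),    # ATAT
    sv_tbl("chr1", 8, 12, "DEL", id = "c"),   # GATC
    sv_tbl("chr1", 8, 16, "DEL", id = "d"))   # GATCNNNN -> 0.5 over ACGT
  out <- gc_content_profile(svs, ref)
  expect_equal(out$gc, c(1, 0, 0.5, 0.5))
  expect_equal(out$high_gc, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(attr(out, "share_high_gc"), 0.25)
  expect_error(gc_content_profile(sv_tbl("chr1", 10, 30, "DEL"), ref),
               "outside")
})

test_that("presence PCA separates disjoint blocks deterministically", {
  set.seed(4)
  block <- function(n, cols, m = 40) {
    x <- matrix(0L, n, m)
    x[, cols] <- rbinom(n * length(cols), 1, 0.9)
    x
  }
  pres <- rbind(block(10, 1:20), block(10, 21:40))
  gm <- gm_from_dosage(pres, n_a = 10)
  pca <- presence_pca(gm, k = 3)
  s <- tidy(pca)
  expect_true(all(sign(s$PC1[1:10]) == sign(s$PC1[1])))
  expect_true(all(sign(s$PC1[11:20]) == -sign(s$PC1[1])))
  # orthogonal scores, deterministic sign
  g <- crossprod(pca$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  pca2 <- presence_pca(gm, k = 3)
  expect_equal(pca$scores, pca2$scores)
  expect_error(presence_pca(gm, k = 20), "smaller")
  # constant column contributes zero variance without failure
  gm2 <- gm_from_dosage(cbind(pres, 1L), n_a = 10)
  expect_silent(presence_pca(gm2, k = 2))
})

test_that("cluster tree splits blocks, emits valid Newick, breaks ties", {
  pres <- rbind(matrix(1L, 3, 10), matrix(0L, 3, 10))
  pres <- cbind(pres, 1L - pres)
  gm <- gm_from_dosage(pres, n_a = 3)
  tr <- cluster_tree(gm, linkage = "average")
  phy <- ape::read.tree(text = tr$newick)
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, rownames(gm$dosage))
  # top split separates the blocks
  top <- stats::cutree(tr$hclust, k = 2)
  expect_equal(length(unique(top[1:3])), 1L)
  expect_equal(length(unique(top[4:6])), 1L)
  expect_true(top[1] != top[4])
  # identical samples merge at height zero first
  expect_equal(tr$hclust$height[1], 0)
  expect_error(cluster_tree(gm_from_dosage(matrix(1L, 1, 3), n_a = 1)),
               "two samples")
})

test_that("power-law fit recovers alpha and rejects degenerate input", {
  set.seed(5)
  x <- 1 * (1 - runif(3000))^(-1 / 1.5)  # alpha = 2.5, xmin = 1
  fit <- powerlaw_fit(x, n_bootstrap = 0, seed = 1)
  expect_gt(fit$alpha, 2.3)
  expect_lt(fit$alpha, 2.7)
  expect_error(powerlaw_fit(rep(2, 100)), "identical")
  expect_error(powerlaw_fit(c(-1, runif(60))), "positive")
  g <- glance(powerlaw_fit(x, n_bootstrap = 20, seed = 2))
  expect_true(g$gof_p >= 0 && g$gof_p <= 1)
})
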