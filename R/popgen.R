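#' Carrier frequency per variant
#'
#' The cohort "SV frequency": the proportion of samples carrying at least
#' one copy of the variant.  Missing genotypes count as non-carriers.
#'
#' @param gm A [genotype_matrix()].
#' @param pop Optional population label (requires a cohort in `gm`) or a
#'   character vector of sample ids; default = all samples.
#' @return Tibble with `id` and `freq`.
#' @export
carrier_frequency <- function(gm, pop = NULL) {
  pres <- presence_matrix(gm)
  rows <- select_samples(gm, pop)
  if (base::length(rows) == 0) abort("empty population selection")
  tibble(id = colnames(pres),
         freq = unname(colMeans(pres[rows, , drop = FALSE])))
}

select_samples <- function(gm, pop) {
  if (is.null(pop)) return(seq_len(nrow(gm$dosage)))
  if (base::length(pop) == 1 && !is.null(gm$cohort) &&
      pop %in% gm$cohort$population) {
    return(which(gm$cohort$population == pop))
  }
  idx <- match(pop, rownames(gm$dosage))
  if (anyNA(idx)) abort("unknown sample or population label in `pop`")
  idx
}

#' Carrier-frequency spectrum
#'
#' Bins carrier frequencies into the four levels (0, 0.1], (0.1, 0.4],
#' (0.4, 1) and the fixed class {1}, and counts singletons (variants with
#' exactly one carrier sample).
#'
#' @param freqs Tibble from [carrier_frequency()] (columns `id`, `freq`).
#' @param gm Optional [genotype_matrix()] for the singleton count.
#' @return A list of class `af_spectrum` with `bins` (named counts) and
#'   `singletons`.
#' @export
af_spectrum <- function(freqs, gm = NULL) {
  f <- freqs$freq
  if (any(f < 0 | f > 1)) abort("frequencies must lie in [0, 1]")
  f <- f[f > 0]
  bins <- c(
    "(0,0.1]" = sum(f <= 0.1),
    "(0.1,0.4]" = sum(f > 0.1 & f <= 0.4),
    "(0.4,1)" = sum(f > 0.4 & f < 1),
    "1" = sum(f == 1)
  )
  singletons <- NA_integer_
  if (!is.null(gm)) {
    singletons <- sum(colSums(presence_matrix(gm)) == 1L)
  }
  structure(list(bins = bins, singletons = singletons),
            class = "af_spectrum")
}

#' @export
print.af_spectrum <- function(x, ...) {
  cat("<af_spectrum>\n")
  print(x$bins)
  if (!is.na(x$singletons)) cat("singletons:", x$singletons, "\n")
  invisible(x)
}

#' @export
tidy.af_spectrum <- function(x, ...) {
  tibble(level = names(x$bins), count = as.integer(x$bins))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Per variant, the allele frequency is estimated from non-missing
#' dosages, expected genotype counts are `(p^2, 2pq, q^2) * n`, and a
#' 1-df chi-square statistic (no continuity correction) is compared with
#' its null distribution.  P values are Bonferroni-corrected over the `m`
#' tested variants; a variant is "in HWE" when the corrected p is not
#' below `alpha`.
#'
#' @param gm A [genotype_matrix()].
#' @param alpha Significance level for the Bonferroni call.
#' @return Object of class `hwe_result`; `tidy()` gives per-variant rows
#'   (`id`, `n`, `p_hat`, `chi2`, `p`, `bonferroni_p`, `in_hwe`),
#'   `glance()` the tested count and fraction in HWE.
#' @export
hwe_test <- function(gm, alpha = 0.05) {
  d <- gm$dosage
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  res <- hwe_chisq(n0, n1, n2)
  tested <- !is.na(res$chi2)
  m <- sum(tested)
  bp <- pmin(1, res$p * m)
  out <- tibble(id = colnames(d), n = unname(n0 + n1 + n2),
                p_hat = res$p_hat, chi2 = res$chi2, p = res$p,
                bonferroni_p = bp, in_hwe = bp >= alpha)
  structure(list(table = out, m = m, alpha = alpha,
                 frac_in_hwe = mean(out$in_hwe[tested])),
            class = "hwe_result")
}

# closed-form 1-df chi-square for genotype counts (vectorised)
hwe_chisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  q <- 1 - p
  e0 <- q^2 * n; e1 <- 2 * p * q * n; e2 <- p^2 * n
  chi2 <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  chi2[n == 0 | p == 0 | p == 1] <- NA_real_  # monomorphic or untyped
  lapply(list(p_hat = p, chi2 = chi2,
              p = pchisq(chi2, df = 1, lower.tail = FALSE)), unname)
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("<hwe_result> %d variants tested; %.1f%% in HWE (alpha = %g, Bonferroni)\n",
              x$m, 100 * x$frac_in_hwe, x$alpha))
  invisible(x)
}

#' @export
tidy.hwe_result <- function(x, ...) x$table

#' @export
glance.hwe_result <- function(x, ...) {
  tibble(n_tested = x$m, frac_in_hwe = x$frac_in_hwe, alpha = x$alpha)
}

#' Weir-Cockerham F_ST for a two-population cohort
#'
#' Method-of-moments variance components for `r = 2` populations at each
#' biallelic site: with `n_i` non-missing individuals, allele frequency
#' `p_i` and observed heterozygote frequency `h_i` per population,
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right],\quad c = \bar h/2}
#' and per-site \eqn{\hat\theta = a/(a+b+c)}.  The cohort-wide weighted
#' estimate is \eqn{\sum a / \sum(a+b+c)} over defined (polymorphic,
#' sufficiently genotyped) sites.  A Hudson-style
#' \eqn{1 - H_S/H_T} alternative is available via `method`.
#'
#' @param gm A [genotype_matrix()] with a two-population cohort.
#' @param cohort Optional cohort override.
#' @param method `"wc"` (default, Weir-Cockerham) or `"hudson"`.
#' @return Object of class `fst_result`; `tidy()` gives per-site
#'   components, `glance()` the weighted and mean estimates.
#' @export
weir_cockerham_fst <- function(gm, cohort = NULL, method = c("wc", "hudson")) {
  method <- match.arg(method)
  cohort <- validate_cohort(as_tibble(cohort %||% gm$cohort))
  pops <- sort(unique(cohort$population))
  if (base::length(pops) != 2) {
    abort("weir_cockerham_fst requires exactly two populations")
  }
  d <- gm$dosage[match(cohort$sample, rownames(gm$dosage)), , drop = FALSE]
  i1 <- cohort$population == pops[1]
  i2 <- cohort$population == pops[2]
  comp <- wc_components(d[i1, , drop = FALSE], d[i2, , drop = FALSE])
  per_site <- tibble(id = colnames(d), n1 = comp$n1, n2 = comp$n2,
                     p1 = comp$p1, p2 = comp$p2,
                     nbar = comp$nbar, nc = comp$nc, pbar = comp$pbar,
                     s2 = comp$s2, hbar = comp$hbar,
                     a = comp$a, b = comp$b, c = comp$c, theta = comp$theta)
  if (method == "hudson") {
    hs <- (comp$p1 * (1 - comp$p1) + comp$p2 * (1 - comp$p2)) / 2
    ht <- comp$pbar * (1 - comp$pbar)
    per_site$theta <- ifelse(ht > 0, 1 - hs / ht, NA_real_)
  }
  defined <- !is.na(per_site$theta)
  weighted <- if (method == "wc") {
    sum(per_site$a[defined]) /
      sum(per_site$a[defined] + per_site$b[defined] + per_site$c[defined])
  } else {
    mean(per_site$theta[defined])
  }
  structure(list(per_site = per_site, weighted = weighted,
                 mean = mean(per_site$theta[defined]),
                 n_defined = sum(defined),
                 n_undefined = sum(!defined),
                 populations = pops, method = method),
            class = "fst_result")
}

# vectorised two-population W&C components over the columns of two
# dosage matrices (rows = individuals)
wc_components <- function(d1, d2) {
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  h1 <- colMeans(d1 == 1L, na.rm = TRUE)
  h2 <- colMeans(d2 == 1L, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  theta <- ifelse(is.finite(tot) & tot != 0, a / tot, NA_real_)
  # monomorphic or under-genotyped sites are undefined
  bad <- pbar %in% c(0, 1) | n1 < 2 | n2 < 2 | !is.finite(theta)
  theta[bad] <- NA_real_
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  lapply(list(n1 = n1, n2 = n2, p1 = p1, p2 = p2, nbar = nbar, nc = nc,
              pbar = pbar, s2 = s2, hbar = hbar, a = a, b = b, c = cc,
              theta = theta), unname)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> %s vs %s (%s): weighted = %.4f, mean = %.4f (%d sites, %d undefined)\n",
              x$populations[1], x$populations[2], x$method, x$weighted,
              x$mean, x$n_defined, x$n_undefined))
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$per_site

#' @export
glance.fst_result <- function(x, ...) {
  tibble(weighted = x$weighted, mean = x$mean, n_defined = x$n_defined,
         n_undefined = x$n_undefined, method = x$method)
}

#' SV discovery saturation curves
#'
#' For each of `n_orders` random sample orderings, the cumulative count of
#' distinct variants present in the first k samples.
#'
#' @param gm A [genotype_matrix()].
#' @param n_orders Number of random orderings.
#' @param seed Integer seed.
#' @return List of class `saturation_curve`: `curves` (tibble `order`,
#'   `k`, `cumulative`), `mean_curve` (tibble `k`, `mean_cumulative`).
#' @export
saturation_curve <- function(gm, n_orders = 10L, seed = 1L) {
  stopifnot(n_orders >= 1)
  pres <- presence_matrix(gm)
  n <- nrow(pres)
  set.seed(seed)
  curves <- purrr::map_dfr(seq_len(n_orders), function(o) {
    ord <- sample.int(n)
    # first carrier position per variant in this ordering
    first <- apply(pres[ord, , drop = FALSE] == 1L, 2, which.max)
    first[colSums(pres[ord, , drop = FALSE]) == 0L] <- NA_integer_
    cum <- cumsum(tabulate(first, nbins = n))
    tibble(order = o, k = seq_len(n), cumulative = cum)
  })
  mean_curve <- curves |>
    group_by(.data$k) |>
    summarise(mean_cumulative = mean(.data$cumulative), .groups = "drop")
  structure(list(curves = curves, mean_curve = mean_curve),
            class = "saturation_curve")
}

#' @export
print.saturation_curve <- function(x, ...) {
  k <- max(x$mean_curve$k)
  cat(sprintf("<saturation_curve> %d orderings, %d samples, final mean count %.1f\n",
              max(x$curves$order), k,
              x$mean_curve$mean_cumulative[x$mean_curve$k == k]))
  invisible(x)
}

#' GC content of SV loci
#'
#' GC fraction of the reference sequence under each SV span (for
#' insertions: a flanking window around the insertion point), with
#' ambiguous bases excluded from the denominator, plus the share of SVs in
#' high-GC regions at the `high_gc_cut` threshold.
#'
#' @param svs SV tibble.
#' @param reference A [Biostrings::DNAStringSet] (names = chromosomes) or
#'   FASTA path.
#' @param high_gc_cut High-GC threshold (default 0.55).
#' @param ins_flank Half-width of the window used for insertions (bp).
#' @return Tibble `id`, `gc`, `high_gc`; the overall high-GC share is
#'   attached as attribute `share_high_gc`.
#' @export
gc_content_profile <- function(svs, reference, high_gc_cut = 0.55,
                               ins_flank = 150L) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  svs <- as_tibble(svs)
  is_ins <- svs$svtype == "INS"
  start <- ifelse(is_ins, pmax(0L, svs$start - ins_flank), svs$start)
  end <- ifelse(is_ins, svs$start + ins_flank, svs$end)
  chrlen <- setNames(Biostrings::width(reference), names(reference))
  if (any(!svs$chrom %in% names(reference)) ||
      any(end > chrlen[svs$chrom])) {
    abort("SV span outside the reference sequence")
  }
  seqs <- Biostrings::subseq(reference[svs$chrom], start = start + 1L,
                             end = pmax(end, start + 1L))
  fr <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  gc <- (fr[, "G"] + fr[, "C"]) / pmax(rowSums(fr), 1)
  out <- tibble(id = svs$id, gc = as.numeric(gc),
                high_gc = as.numeric(gc) >= high_gc_cut)
  attr(out, "share_high_gc") <- mean(out$high_gc)
  out
}

#' PCA of the presence/absence matrix
#'
#' Column-centred 0/1 presence matrix decomposed by SVD.  Score signs are
#' fixed by making the largest-magnitude loading of each component
#' positive, so results are deterministic.
#'
#' @param gm A [genotype_matrix()].
#' @param k Number of components (< number of samples).
#' @return Object of class `sv_pca`; `tidy()` gives per-sample scores
#'   (joined with population labels when available), `glance()` the
#'   explained-variance fractions.
#' @export
presence_pca <- function(gm, k = 2L) {
  pres <- presence_matrix(gm)
  if (k >= nrow(pres)) abort("k must be smaller than the number of samples")
  x <- scale(pres, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(pres)
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores, explained = ev[seq_len(k)],
                 cohort = gm$cohort), class = "sv_pca")
}

#' @export
print.sv_pca <- function(x, ...) {
  cat(sprintf("<sv_pca> %d samples, %d components (%s%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              paste(round(100 * x$explained, 1), collapse = "%, ")))
  invisible(x)
}

#' @export
tidy.sv_pca <- function(x, ...) {
  out <- as_tibble(x$scores)
  out$sample <- rownames(x$scores)
  out <- out[, c("sample", setdiff(names(out), "sample"))]
  if (!is.null(x$cohort)) out <- left_join(out, x$cohort, by = "sample")
  out
}

#' @export
glance.sv_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$explained)),
         explained_variance = x$explained)
}

#' Hierarchical clustering tree of samples
#'
#' Manhattan distance on presence rows, agglomerated with average or
#' complete linkage; the tree is also serialised as a Newick string.
#'
#' @param gm A [genotype_matrix()] with at least 2 samples.
#' @param linkage `"average"` or `"complete"`.
#' @return List of class `sv_tree`: `hclust`, `phylo` ([ape::as.phylo])
#'   and `newick` (text).
#' @export
cluster_tree <- function(gm, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  pres <- presence_matrix(gm)
  if (nrow(pres) < 2) abort("need at least two samples to build a tree")
  d <- stats::dist(pres, method = "manhattan")
  hc <- hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy)), class = "sv_tree")
}

#' @export
print.sv_tree <- function(x, ...) {
  cat(sprintf("<sv_tree> %d tips, %s linkage\n",
              base::length(x$phylo$tip.label), x$hclust$method))
  invisible(x)
}
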