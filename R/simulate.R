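#' Simulation parameters for the synthetic two-population cohort
#'
#' Defaults mirror the cohort structure the pipeline targets: 119 samples
#' in population A and 201 in population B (the Tibetan/Han roles) with
#' Balding-Nichols differentiation at `fst_param = 0.1`.  The 2,000-SV,
#' two-chromosome 100 Mb toy genome keeps full end-to-end runs fast while
#' leaving every statistic well populated.
#'
#' @param n_pop_a,n_pop_b Samples per population.
#' @param m_svs Number of true SV loci.
#' @param fst_param Balding-Nichols differentiation parameter `F` in
#'   `[0, 1)`; per-population allele frequencies are drawn from
#'   `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral `p`.
#' @param n_selected Loci overridden to the differentiated target carrier
#'   frequencies `sel_freq_a`/`sel_freq_b`.
#' @param sel_freq_a,sel_freq_b Target carrier frequencies of selected
#'   loci in each population (defaults 0.6 vs 0.05).
#' @param beta_a,beta_b Ancestral-frequency Beta parameters (default
#'   Beta(0.5, 1.5): a rare-skewed spectrum).
#' @param genome Named numeric vector of chromosome lengths in bp.
#' @param type_probs Named probabilities over DEL/INS/DUP/INV.
#' @param len_range SV length range in bp (log-uniform within).
#' @param mean_depth Simulated mean sequencing depth.
#' @param caller_models Tibble (`caller`, `sensitivity`, `fp_per_mb`,
#'   `bp_jitter_sd`, `len_jitter_sd`, `hq_prob`) for the three long-read
#'   callers; see [default_caller_models()].
#' @param fp_fail_frac Fraction of false calls drawn to fail the raw
#'   AF/depth filter.
#' @param correlated_fp Share identical false calls across callers
#'   (exercises the high-quality-flag pathway instead of the >= 2-caller
#'   rule).
#' @param n_tag_snps Tag SNPs generated per target r-squared level.
#' @param tag_r2 Target r-squared levels of the tag SNPs.
#' @param n_background_snps Unlinked background SNPs.
#' @param seed Integer seed; every generator is deterministic given it.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_pop_a = 119L, n_pop_b = 201L, m_svs = 2000L,
                       fst_param = 0.1, n_selected = 20L,
                       sel_freq_a = 0.6, sel_freq_b = 0.05,
                       beta_a = 0.5, beta_b = 1.5,
                       genome = c(chr1 = 60e6, chr2 = 40e6),
                       type_probs = c(DEL = 0.45, INS = 0.45, DUP = 0.05,
                                      INV = 0.05),
                       len_range = c(50L, 50000L),
                       mean_depth = 20,
                       caller_models = default_caller_models(),
                       fp_fail_frac = 0.5,
                       correlated_fp = FALSE,
                       n_tag_snps = 30L,
                       tag_r2 = c(0.5, 0.8, 1.0),
                       n_background_snps = 200L,
                       seed = 1L) {
  stopifnot(n_pop_a > 0, n_pop_b > 0, m_svs > 0,
            fst_param >= 0, n_selected >= 0,
            all(type_probs >= 0), len_range[1] >= 1,
            len_range[1] < len_range[2], mean_depth > 0)
  if (fst_param >= 1) abort("fst_param must be < 1")
  structure(list(n_pop_a = as.integer(n_pop_a), n_pop_b = as.integer(n_pop_b),
                 m_svs = as.integer(m_svs), fst_param = fst_param,
                 n_selected = as.integer(n_selected),
                 sel_freq_a = sel_freq_a, sel_freq_b = sel_freq_b,
                 beta_a = beta_a, beta_b = beta_b, genome = genome,
                 type_probs = type_probs / sum(type_probs),
                 len_range = as.integer(len_range),
                 mean_depth = mean_depth,
                 caller_models = as_tibble(caller_models),
                 fp_fail_frac = fp_fail_frac,
                 correlated_fp = isTRUE(correlated_fp),
                 n_tag_snps = as.integer(n_tag_snps), tag_r2 = tag_r2,
                 n_background_snps = as.integer(n_background_snps),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Default per-caller noise models
#'
#' Sensitivities, false-positive rates, breakpoint/length jitter and
#' high-quality flag probability for the three long-read SV callers the
#' consensus rule knows about.
#'
#' @return Tibble with one row per caller.
#' @export
default_caller_models <- function() {
  tibble(
    caller = c("cuteSV", "sniffles", "nanovar"),
    sensitivity = c(0.95, 0.92, 0.85),
    fp_per_mb = c(0.5, 0.5, 0.5),
    bp_jitter_sd = c(30, 30, 30),
    len_jitter_sd = c(15, 15, 15),
    hq_prob = c(0.3, 0, 0)
  )
}

#' Simulate the true cohort: SV loci, frequencies and genotypes
#'
#' Ancestral carrier-allele frequencies are Beta-distributed; each
#' population's frequency is drawn from the Balding-Nichols Beta around
#' the ancestral value; genotypes are two independent haploid draws per
#' sample (HWE within population).  `n_selected` loci are overridden to
#' the differentiated target frequencies and flagged in the truth table.
#' Haplotypes are retained (attribute `haplotypes`) for LD-tag SNP
#' generation.
#'
#' @param params [sim_params()].
#' @return List: `truth` (tibble of per-SV truth rows), `gm` (the true
#'   [genotype_matrix()]), `cohort`.
#' @export
simulate_cohort_truth <- function(params = sim_params()) {
  set.seed(derive_seed(params$seed, 1))
  m <- params$m_svs
  genome <- params$genome
  chrom <- sample(names(genome), m, replace = TRUE,
                  prob = genome / sum(genome))
  len <- as.integer(round(exp(runif(m, log(params$len_range[1]),
                                    log(params$len_range[2])))))
  svtype <- sample(names(params$type_probs), m, replace = TRUE,
                   prob = params$type_probs)
  start <- as.integer(floor(runif(m, 0, genome[chrom] - len - 1)))
  end <- as.integer(ifelse(svtype == "INS", start, start + len))

  p_anc <- rbeta(m, params$beta_a, params$beta_b)
  p_anc <- pmin(pmax(p_anc, 0.01), 0.99)
  F <- params$fst_param
  if (F > 0) {
    p_a <- rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    p_b <- rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  } else {
    p_a <- p_anc
    p_b <- p_anc
  }
  selected <- rep(FALSE, m)
  if (params$n_selected > 0) {
    sel <- sample.int(m, min(params$n_selected, m))
    selected[sel] <- TRUE
    # target carrier frequencies -> allele frequencies via 1-(1-p)^2 = f
    p_a[sel] <- 1 - sqrt(1 - params$sel_freq_a)
    p_b[sel] <- 1 - sqrt(1 - params$sel_freq_b)
  }
  n_a <- params$n_pop_a; n_b <- params$n_pop_b
  cohort <- cohort_tbl(
    c(sprintf("A%03d", seq_len(n_a)), sprintf("B%03d", seq_len(n_b))),
    c(rep("POP_A", n_a), rep("POP_B", n_b)))
  p_by_sample <- rbind(matrix(p_a, n_a, m, byrow = TRUE),
                       matrix(p_b, n_b, m, byrow = TRUE))
  h1 <- (matrix(runif((n_a + n_b) * m), n_a + n_b, m) < p_by_sample) * 1L
  h2 <- (matrix(runif((n_a + n_b) * m), n_a + n_b, m) < p_by_sample) * 1L
  dosage <- h1 + h2
  ids <- sprintf("truth%05d", seq_len(m))
  dimnames(dosage) <- list(cohort$sample, ids)
  dimnames(h1) <- dimnames(h2) <- dimnames(dosage)
  truth <- tibble(id = ids, chrom = chrom, start = start, end = end,
                  svtype = svtype, length = len, p_ancestral = p_anc,
                  p_a = p_a, p_b = p_b, selected = selected,
                  direction = ifelse(selected, "A_specific", "none"))
  o <- order(truth$chrom, truth$start, truth$id)
  truth <- truth[o, ]
  dosage <- dosage[, o, drop = FALSE]
  h1 <- h1[, o, drop = FALSE]; h2 <- h2[, o, drop = FALSE]
  meta <- truth[, c("id", "chrom", "start", "end", "svtype", "length")]
  gm <- genotype_matrix(dosage, variants = meta, cohort = cohort)
  attr(gm, "haplotypes") <- list(h1 = h1, h2 = h2)
  list(truth = truth, gm = gm, cohort = cohort)
}

#' Simulate noisy per-sample, per-caller SV calls
#'
#' Every carried true SV is emitted per caller with the caller's
#' sensitivity, with rounded-Gaussian breakpoint and length jitter; false
#' calls are added as a Poisson process over the genome (independent per
#' caller unless `correlated_fp`).  Read-support fractions and depths are
#' drawn so true calls pass the raw filter while `fp_fail_frac` of the
#' false calls fail it.  cuteSV calls carry the high-quality flag with
#' probability `hq_prob`.
#'
#' @param sim Output of [simulate_cohort_truth()].
#' @param params [sim_params()].
#' @return Tibble of calls (all samples and callers pooled; standard SV
#'   columns plus `truth_id`, NA for false calls).
#' @export
simulate_caller_calls <- function(sim, params = sim_params()) {
  set.seed(derive_seed(params$seed, 2))
  truth <- sim$truth
  dosage <- sim$gm$dosage
  genome <- params$genome
  genome_mb <- sum(genome) / 1e6
  cm <- params$caller_models
  calls <- list()
  carried <- which(dosage >= 1L, arr.ind = TRUE)
  carrier_sample <- rownames(dosage)[carried[, 1]]
  carrier_var <- colnames(dosage)[carried[, 2]]
  ti <- match(carrier_var, truth$id)
  gt <- dosage_to_genotype(dosage[carried])
  shared_fp <- NULL
  for (ci in seq_len(nrow(cm))) {
    cc <- cm[ci, ]
    det <- runif(nrow(carried)) < cc$sensitivity
    n_det <- sum(det)
    if (n_det > 0) {
      jit_s <- as.integer(round(rnorm(n_det, 0, cc$bp_jitter_sd)))
      jit_l <- as.integer(round(rnorm(n_det, 0, cc$len_jitter_sd)))
      t <- truth[ti[det], ]
      new_len <- pmax(params$len_range[1], t$length + jit_l)
      new_start <- pmax(0L, t$start + jit_s)
      is_ins <- t$svtype == "INS"
      new_end <- as.integer(ifelse(is_ins, new_start, new_start + new_len))
      calls[[base::length(calls) + 1]] <- tibble(
        id = sprintf("%s_%s_%s", cc$caller, carrier_sample[det], t$id),
        chrom = t$chrom, start = as.integer(new_start), end = new_end,
        svtype = t$svtype, length = as.integer(new_len),
        caller = cc$caller,
        hq_flag = cc$caller == "cuteSV" & runif(n_det) < cc$hq_prob,
        sample = carrier_sample[det], genotype = gt[det],
        depth = pmin(rnorm(n_det, params$mean_depth, 2),
                     2 * params$mean_depth - 1),
        af_read = runif(n_det, 0.35, 1),
        truth_id = t$id)
    }
    # false calls: Poisson per sample over the genome
    n_samples <- nrow(sim$cohort)
    if (params$correlated_fp && ci > 1 && !is.null(shared_fp)) {
      # reuse caller 1's false calls so they agree across callers
      fp <- shared_fp
      fp$caller <- cc$caller
      fp$hq_flag <- FALSE
      fp$id <- sub("^[^_]+", cc$caller, fp$id)
      calls[[base::length(calls) + 1]] <- fp
      next
    }
    n_fp_tot <- rpois(1, cc$fp_per_mb * genome_mb * n_samples)
    if (n_fp_tot > 0) {
      fchrom <- sample(names(genome), n_fp_tot, replace = TRUE,
                       prob = genome / sum(genome))
      flen <- as.integer(round(exp(runif(n_fp_tot, log(params$len_range[1]),
                                         log(params$len_range[2])))))
      fstart <- as.integer(floor(runif(n_fp_tot, 0,
                                       genome[fchrom] - flen - 1)))
      ftype <- sample(names(params$type_probs), n_fp_tot, replace = TRUE,
                      prob = params$type_probs)
      fail <- runif(n_fp_tot) < params$fp_fail_frac
      fsample <- sample(sim$cohort$sample, n_fp_tot, replace = TRUE)
      fp_tbl <- tibble(
        id = sprintf("%s_fp%05d", cc$caller, seq_len(n_fp_tot)),
        chrom = fchrom, start = fstart,
        end = as.integer(ifelse(ftype == "INS", fstart, fstart + flen)),
        svtype = ftype, length = flen, caller = cc$caller,
        hq_flag = FALSE, sample = fsample,
        genotype = "0/1",
        depth = ifelse(fail & runif(n_fp_tot) < 0.5,
                       params$mean_depth * runif(n_fp_tot, 2.1, 3),
                       rnorm(n_fp_tot, params$mean_depth, 2)),
        af_read = ifelse(fail, runif(n_fp_tot, 0.05, 0.3),
                         runif(n_fp_tot, 0.35, 1)),
        truth_id = NA_character_)
      calls[[base::length(calls) + 1]] <- fp_tbl
      if (params$correlated_fp && ci == 1) shared_fp <- fp_tbl
    }
  }
  out <- bind_rows(calls)
  if (!params$correlated_fp) out <- drop_colliding_fp(out)
  out[sv_order(out), ]
}

#' Write simulated calls as per-sample, per-caller VCF files
#'
#' @param calls Tibble from [simulate_caller_calls()].
#' @param dir Output directory (created if needed).
#' @return Tibble `sample`, `caller`, `path` of written files.
#' @export
simulate_caller_vcfs <- function(calls, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- split(calls, list(calls$sample, calls$caller), drop = TRUE)
  purrr::map_dfr(groups, function(g) {
    path <- file.path(dir, sprintf("%s.%s.vcf", g$sample[1], g$caller[1]))
    g <- g[order(g$chrom, g$start), ]
    write_sv_vcf(select(g, -"truth_id"), path)
    tibble(sample = g$sample[1], caller = g$caller[1], path = path)
  })
}

#' Simulate SNPs in tunable LD with SVs
#'
#' Tag SNPs copy the SV allele per haplotype with swap probability
#' `q = (1 - sqrt(r2)) / 2`, the solution of `r2 = (1 - 2q)^2` for two
#' binary loci with preserved allele frequencies, and are placed
#' uniformly within the LD window of their SV.  Background SNPs are drawn
#' independently of all SVs.  Tagged SVs are chosen among
#' intermediate-frequency loci (pooled carrier frequency in [0.2, 0.8])
#' where the attenuation of realized r-squared from frequency skew is
#' negligible.
#'
#' @param sim Output of [simulate_cohort_truth()].
#' @param params [sim_params()].
#' @param window Placement window around the SV (bp).
#' @return List: `snp_gm` (SNP [genotype_matrix()]), `tags` (tibble
#'   `snp_id`, `sv_id`, `target_r2`, `pos`), `catalog` (GWAS-catalog
#'   tibble linking each tag SNP to a synthetic phenotype).
#' @export
simulate_linked_snps <- function(sim, params = sim_params(),
                                 window = 1000000L) {
  set.seed(derive_seed(params$seed, 3))
  if (any(params$tag_r2 > 1 | params$tag_r2 < 0)) {
    abort("target r2 must lie in [0, 1]")
  }
  haps <- attr(sim$gm, "haplotypes")
  if (is.null(haps)) abort("sim$gm lacks haplotypes; rerun simulate_cohort_truth")
  truth <- sim$truth
  pooled <- colMeans(presence_matrix(sim$gm))
  eligible <- which(pooled >= 0.2 & pooled <= 0.8)
  if (base::length(eligible) == 0) abort("no intermediate-frequency SVs to tag")
  n_levels <- base::length(params$tag_r2)
  per_level <- max(1L, params$n_tag_snps %/% n_levels)
  picks <- sample(eligible, min(base::length(eligible),
                                per_level * n_levels), replace = FALSE)
  levels <- rep(params$tag_r2, length.out = base::length(picks))
  n <- nrow(sim$cohort)
  snp_list <- list(); tag_rows <- list()
  for (k in seq_along(picks)) {
    j <- picks[k]
    q <- solve_swap_prob(levels[k], mean(c(haps$h1[, j], haps$h2[, j])))
    flip1 <- runif(n) < q
    flip2 <- runif(n) < q
    s1 <- ifelse(flip1, 1L - haps$h1[, j], haps$h1[, j])
    s2 <- ifelse(flip2, 1L - haps$h2[, j], haps$h2[, j])
    pos <- truth$start[j] +
      as.integer(round(runif(1, -window / 2, window / 2)))
    pos <- max(0L, min(pos, as.integer(params$genome[truth$chrom[j]]) - 1L))
    snp_id <- sprintf("tagsnp%04d", k)
    snp_list[[snp_id]] <- list(dosage = s1 + s2, chrom = truth$chrom[j],
                               pos = pos)
    tag_rows[[k]] <- tibble(snp_id = snp_id, sv_id = truth$id[j],
                            target_r2 = levels[k], pos = pos)
  }
  # unlinked background SNPs
  if (params$n_background_snps > 0) {
    for (k in seq_len(params$n_background_snps)) {
      p <- rbeta(1, 2, 2)
      chrom <- sample(names(params$genome), 1)
      snp_id <- sprintf("bgsnp%05d", k)
      snp_list[[snp_id]] <- list(
        dosage = rbinom(n, 2, p), chrom = chrom,
        pos = as.integer(floor(runif(1, 0, params$genome[chrom]))))
    }
  }
  dosage <- vapply(snp_list, function(x) as.integer(x$dosage),
                   integer(n))
  rownames(dosage) <- sim$cohort$sample
  meta <- tibble(id = names(snp_list),
                 chrom = vapply(snp_list, function(x) x$chrom, character(1)),
                 start = vapply(snp_list, function(x) as.integer(x$pos),
                                integer(1)))
  meta$end <- meta$start + 1L
  snp_gm <- genotype_matrix(dosage, variants = meta, cohort = sim$cohort)
  tags <- bind_rows(tag_rows)
  catalog <- tibble(snp_id = tags$snp_id,
                    chrom = meta$chrom[match(tags$snp_id, meta$id)],
                    pos = tags$pos,
                    phenotype = sprintf("synthetic trait %02d",
                                        seq_len(nrow(tags)) %% 17 + 1))
  list(snp_gm = snp_gm, tags = tags, catalog = catalog)
}

# independent false calls must not agree across callers (that agreement
# is what the correlated_fp mode is for), so chance collisions between
# different callers' false calls in the same sample are resolved by
# keeping only the first caller's call in each colliding run
drop_colliding_fp <- function(out) {
  fp <- which(is.na(out$truth_id))
  if (base::length(fp) < 2) return(out)
  f <- out[fp, ]
  o <- order(f$sample, f$chrom, f$svtype, f$start)
  f <- f[o, ]
  same_grp <- c(FALSE, f$sample[-1] == f$sample[-nrow(f)] &
                  f$chrom[-1] == f$chrom[-nrow(f)] &
                  f$svtype[-1] == f$svtype[-nrow(f)] &
                  diff(f$start) < 1100)
  run <- cumsum(!same_grp)
  keep <- unlist(lapply(split(seq_len(nrow(f)), run), function(ix) {
    ix[f$caller[ix] == f$caller[ix[1]]]
  }))
  drop <- fp[o][setdiff(seq_len(nrow(f)), keep)]
  if (base::length(drop) > 0) out <- out[-drop, ]
  out
}

# haplotype-copy swap probability hitting a target r2 at SV allele
# frequency p.  With flip probability q the tag allele frequency becomes
# pY = p(1-q) + (1-p)q and the per-haplotype correlation
# r(q) = (1-2q) * sqrt(p(1-p) / (pY(1-pY))); the naive q from
# r2 = (1-2q)^2 is attenuation-biased away from 0.5-frequency loci, so q
# is solved numerically.
solve_swap_prob <- function(r2_target, p) {
  if (r2_target >= 1) return(0)
  if (r2_target <= 0) return(0.5)
  r_of_q <- function(q) {
    py <- p * (1 - q) + (1 - p) * q
    (1 - 2 * q) * sqrt(p * (1 - p) / (py * (1 - py)))
  }
  stats::uniroot(function(q) r_of_q(q) - sqrt(r2_target),
                 c(0, 0.5), tol = 1e-10)$root
}

#' Simulate annotation tracks and a GWAS catalog
#'
#' Repeats: non-overlapping intervals randomly placed to a target genome
#' coverage.  Genes: non-overlapping labelled intervals.  Enhancers: one
#' element within `pad` bp of each selected SV plus random elements.
#' TAD boundaries: evenly spaced points widened to 10 kb.
#'
#' @param truth Truth tibble from [simulate_cohort_truth()].
#' @param params [sim_params()].
#' @param repeat_coverage Target repeat genome fraction.
#' @param n_genes Number of genes.
#' @param pad Enhancer placement offset bound (bp).
#' @return Named list of interval tibbles: `repeats`, `genes`,
#'   `enhancers`, `tad_boundaries`.
#' @export
simulate_annotations <- function(truth, params = sim_params(),
                                 repeat_coverage = 0.5, n_genes = 500L,
                                 pad = 100L) {
  if (repeat_coverage > 1) abort("repeat coverage fraction must be <= 1")
  set.seed(derive_seed(params$seed, 4))
  genome <- params$genome
  reps <- purrr::map_dfr(names(genome), function(ch) {
    L <- genome[[ch]]
    n_units <- ceiling(L * repeat_coverage / 5000)
    # deterministic alternating tiling hit by random phase: place 5 kb
    # repeats on a 5 kb / (1/coverage) spacing grid
    spacing <- 5000 / repeat_coverage
    starts <- as.integer(floor(seq(runif(1, 0, spacing), L - 5000,
                                   by = spacing)))
    tibble(track = "repeats", chrom = ch, start = starts,
           end = starts + 5000L,
           label = sample(c("SINE", "LINE", "LTR", "Simple_repeat"),
                          base::length(starts), replace = TRUE))
  })
  genes <- purrr::map_dfr(names(genome), function(ch) {
    L <- genome[[ch]]
    k <- max(1L, as.integer(round(n_genes * L / sum(genome))))
    anchors <- as.integer(floor(seq(0, L - 30000, length.out = k)))
    w <- as.integer(round(runif(k, 5000, 25000)))
    tibble(track = "genes", chrom = ch, start = anchors,
           end = anchors + w,
           label = sprintf("%s_G%04d", toupper(ch), seq_len(k)))
  })
  sel <- truth[truth$selected, ]
  enh_sel <- NULL
  if (nrow(sel) > 0) {
    off <- as.integer(round(runif(nrow(sel), 10, pad - 10)))
    enh_sel <- tibble(track = "enhancers", chrom = sel$chrom,
                      start = pmax(0L, sel$start - off - 500L),
                      end = pmax(0L, sel$start - off),
                      label = sprintf("enh_sel_%s", sel$id))
  }
  n_rand <- 200L
  rchrom <- sample(names(genome), n_rand, replace = TRUE,
                   prob = genome / sum(genome))
  rstart <- as.integer(floor(runif(n_rand, 0, genome[rchrom] - 500)))
  enh <- bind_rows(enh_sel,
                   tibble(track = "enhancers", chrom = rchrom,
                          start = rstart, end = rstart + 500L,
                          label = sprintf("enh%04d", seq_len(n_rand))))
  tad <- purrr::map_dfr(names(genome), function(ch) {
    centers <- seq(1e6, genome[[ch]] - 1e6, by = 2e6)
    tibble(track = "tad_boundaries", chrom = ch,
           start = as.integer(centers - 5000),
           end = as.integer(centers + 5000),
           label = NA_character_)
  })
  list(repeats = reps[order(reps$chrom, reps$start), ],
       genes = genes[order(genes$chrom, genes$start), ],
       enhancers = enh[order(enh$chrom, enh$start), ],
       tad_boundaries = tad)
}
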