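# shared fixture builders -----------------------------------------------

# a deterministic random SV set with controlled jitter groups: n_true loci,
# each duplicated n_dup times with breakpoint jitter; used by the merge
# oracle tests
random_jittered_svs <- function(n_true, n_dup = 3, jitter = 50,
                                chroms = c("chr1", "chr2"),
                                chrom_len = 5e6, seed = 1) {
  set.seed(seed)
  type <- sample(c("DEL", "INS", "DUP", "INV"), n_true, replace = TRUE)
  len <- sample(100:5000, n_true, replace = TRUE)
  chrom <- sample(chroms, n_true, replace = TRUE)
  start <- sample.int(chrom_len, n_true)
  rows <- lapply(seq_len(n_true), function(i) {
    k <- sample.int(n_dup, 1)
    s <- pmax(0L, start[i] + as.integer(round(rnorm(k, 0, jitter))))
    l <- pmax(50L, len[i] + as.integer(round(rnorm(k, 0, jitter / 2))))
    sv_tbl(chrom = chrom[i], start = s,
           end = if (type[i] == "INS") s else s + l,
           svtype = type[i], length = l,
           id = sprintf("t%04d_%d", i, seq_len(k)))
  })
  dplyr::bind_rows(rows)
}

# brute-force single-linkage oracle: all-pairs sv_match + connected
# components (igraph); returns cluster label per row
brute_force_partition <- function(svs, params = merge_params()) {
  n <- nrow(svs)
  if (n == 1) return(1L)
  idx <- t(utils::combn(n, 2))
  hit <- sv_match_pairs(svs[idx[, 1], ], svs[idx[, 2], ], params)
  g <- igraph::graph_from_edgelist(idx[hit, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::gorder(g))
  igraph::components(g)$membership
}

# canonical form of a partition: sets of sorted member ids
partition_sets <- function(ids, labels) {
  unname(sort(vapply(split(ids, labels),
                     function(x) paste(sort(x), collapse = "|"),
                     character(1))))
}

# tiny two-population genotype matrix from explicit dosage rows
gm_from_dosage <- function(dosage, n_a = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  n_a <- n_a %||% (n %/% 2)
  cohort <- cohort_tbl(sprintf("s%03d", seq_len(n)),
                       rep(c("POP_A", "POP_B"), c(n_a, n - n_a)))
  rownames(dosage) <- cohort$sample
  genotype_matrix(dosage, cohort = cohort)
}

`%||%` <- rlang::`%||%`
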