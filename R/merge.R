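#' Merge parameters for SV matching and clustering
#'
#' Encodes the nonredundant-merging rules: two SVs match when their
#' breakpoints lie within `max_dist`, spanned types (DEL/DUP/INV)
#' additionally reciprocally overlap by at least `min_overlap` of each
#' span, and insertions differ in length by less than `ins_len_factor`
#' times the shorter insertion.  `min_len`/`max_len` bound the size range
#' retained for filtering and cross-dataset comparison.
#'
#' @param max_dist Maximum breakpoint distance in bp (exclusive bound).
#' @param min_overlap Minimum reciprocal-overlap fraction for spanned SVs.
#' @param ins_len_factor Insertion length-difference factor.
#' @param min_len,max_len Retained SV length range in bp (inclusive).
#' @param require_same_type Only match SVs of the same type.
#' @param dist_mode `"both"` (default): for spanned types the start AND
#'   end distances must each be below `max_dist`; `"start"`: start only.
#' @param overlap_mode `"reciprocal"` (default) or `"either"` (overlap
#'   fraction of either span suffices).
#' @param ins_rule `"literal"` (default): `|L1 - L2| < f * min(L1, L2)`;
#'   `"ratio"`: `min(L1, L2) / max(L1, L2) >= 1 / f`.
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(max_dist = 1000L, min_overlap = 0.40,
                         ins_len_factor = 2.0, min_len = 50L,
                         max_len = 50000L, require_same_type = TRUE,
                         dist_mode = c("both", "start"),
                         overlap_mode = c("reciprocal", "either"),
                         ins_rule = c("literal", "ratio")) {
  stopifnot(max_dist > 0, min_overlap > 0, min_overlap <= 1,
            ins_len_factor > 0, min_len < max_len)
  structure(list(max_dist = as.integer(max_dist), min_overlap = min_overlap,
                 ins_len_factor = ins_len_factor,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 require_same_type = isTRUE(require_same_type),
                 dist_mode = match.arg(dist_mode),
                 overlap_mode = match.arg(overlap_mode),
                 ins_rule = match.arg(ins_rule)),
            class = "merge_params")
}

#' Filter raw per-caller SV calls
#'
#' Applies the raw-call quality rules: read-support fraction above 0.3,
#' local depth below twice the sample's mean depth, and length within
#' `[min_len, max_len]`.  Calls missing `af_read` or `depth` pass the
#' corresponding criterion (no evidence against them).
#'
#' @param calls SV tibble with `af_read`, `depth`, `length`.
#' @param mean_depth Sample mean sequencing depth (> 0).
#' @param params [merge_params()] supplying the length range.
#' @return The retained calls, input order preserved; counts of calls
#'   removed per criterion attached as attribute `removed` (a named
#'   integer vector `af`, `depth`, `length`).
#' @export
filter_raw_calls <- function(calls, mean_depth, params = merge_params()) {
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    abort("mean_depth must be positive")
  }
  calls <- as_tibble(calls)
  ok_af <- is.na(calls$af_read) | calls$af_read > 0.3
  ok_dp <- is.na(calls$depth) | calls$depth < 2 * mean_depth
  ok_len <- calls$length >= params$min_len & calls$length <= params$max_len
  out <- calls[ok_af & ok_dp & ok_len, ]
  attr(out, "removed") <- c(af = sum(!ok_af), depth = sum(!ok_dp),
                            length = sum(!ok_len))
  out
}

#' Pairwise SV match predicate
#'
#' `sv_match()` decides whether two single records represent the same
#' variant under [merge_params()]; `sv_match_pairs()` is the vectorised
#' form over two equal-length SV tibbles, matched row by row.
#' The relation is symmetric and reflexive, never matches across
#' chromosomes, and (by default) never across SV types.
#'
#' @param a,b Single-row SV tibbles (or two equal-height tibbles for
#'   `sv_match_pairs()`).
#' @param params [merge_params()].
#' @return Logical (vector for the pairwise form).
#' @examples
#' a <- sv_tbl("chr1", 1000, 2000, "DEL")
#' b <- sv_tbl("chr1", 1100, 2100, "DEL")
#' sv_match(a, b)  # distance 100, reciprocal overlap 0.9 -> TRUE
#' @export
sv_match <- function(a, b, params = merge_params()) {
  sv_match_pairs(a, b, params)[1]
}

#' @rdname sv_match
#' @export
sv_match_pairs <- function(a, b, params = merge_params()) {
  ok <- a$chrom == b$chrom
  if (params$require_same_type) ok <- ok & a$svtype == b$svtype
  d_start <- abs(a$start - b$start)
  d_end <- abs(a$end - b$end)
  span <- a$svtype != "INS" & b$svtype != "INS"
  dist <- ifelse(span & params$dist_mode == "both",
                 pmax(d_start, d_end), d_start)
  ok <- ok & dist < params$max_dist
  # reciprocal overlap for spanned types
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  frac_a <- ov / pmax(a$end - a$start, 1L)
  frac_b <- ov / pmax(b$end - b$start, 1L)
  ov_ok <- if (params$overlap_mode == "reciprocal") {
    frac_a >= params$min_overlap & frac_b >= params$min_overlap
  } else {
    frac_a >= params$min_overlap | frac_b >= params$min_overlap
  }
  ok <- ok & (!span | ov_ok)
  ins <- a$svtype == "INS" & b$svtype == "INS"
  len_ok <- if (params$ins_rule == "literal") {
    abs(a$length - b$length) < params$ins_len_factor * pmin(a$length, b$length)
  } else {
    pmin(a$length, b$length) / pmax(a$length, b$length) >=
      1 / params$ins_len_factor
  }
  ok & (!ins | len_ok)
}

# single-linkage clustering of one (chrom, svtype) group, sorted by start.
# returns integer cluster labels; sweep window on start is sound because
# every match implies |start_a - start_b| < max_dist.  works on plain
# vectors for speed on cohort-scale inputs.
cluster_group <- function(svs, params) {
  n <- nrow(svs)
  if (n == 1) return(1L)
  s <- svs$start; e <- svs$end; len <- svs$length
  is_ins <- svs$svtype[1] == "INS"
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in 2:n) {
    j0 <- i - 1
    while (j0 >= 1 && s[i] - s[j0] < params$max_dist) j0 <- j0 - 1
    js <- seq.int(j0 + 1, i - 1)
    if (base::length(js) == 0) next
    if (is_ins) {
      ok <- abs(s[i] - s[js]) < params$max_dist
      ok <- ok & if (params$ins_rule == "literal") {
        abs(len[i] - len[js]) < params$ins_len_factor * pmin(len[i], len[js])
      } else {
        pmin(len[i], len[js]) / pmax(len[i], len[js]) >=
          1 / params$ins_len_factor
      }
    } else {
      d <- if (params$dist_mode == "both") {
        pmax(abs(s[i] - s[js]), abs(e[i] - e[js]))
      } else {
        abs(s[i] - s[js])
      }
      ov <- pmax(0, pmin(e[i], e[js]) - pmax(s[i], s[js]))
      fa <- ov / pmax(e[i] - s[i], 1L)
      fb <- ov / pmax(e[js] - s[js], 1L)
      ok <- d < params$max_dist &
        if (params$overlap_mode == "reciprocal") {
          fa >= params$min_overlap & fb >= params$min_overlap
        } else {
          fa >= params$min_overlap | fb >= params$min_overlap
        }
    }
    for (j in js[ok]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Within-sample multi-caller consensus
#'
#' Clusters one sample's calls across callers with [sv_match()] and keeps
#' clusters supported by at least two distinct callers, or containing a
#' cuteSV call flagged high-quality.  The emitted record (coordinates and
#' genotype) comes from the highest-priority caller present
#' (cuteSV > sniffles > nanovar), and carries the cluster's caller-support
#' count in `n_callers`.
#'
#' @param calls SV tibble from a single sample with `caller` set.
#' @param params [merge_params()].
#' @return Consensus SV tibble (one row per kept cluster) with an added
#'   `n_callers` column.
#' @export
within_sample_consensus <- function(calls, params = merge_params()) {
  calls <- as_tibble(calls)
  smp <- unique(stats::na.omit(calls$sample))
  if (base::length(smp) > 1) {
    abort("within_sample_consensus expects calls from a single sample")
  }
  if (nrow(calls) == 0) {
    calls$n_callers <- integer()
    return(calls)
  }
  calls <- calls[sv_order(calls), ]
  grp <- paste(calls$chrom, calls$svtype)
  labels <- integer(nrow(calls))
  nxt <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    cl <- cluster_group(calls[idx, ], params)
    labels[idx] <- nxt + cl
    nxt <- nxt + max(cl)
  }
  prio <- match(calls$caller, CALLER_PRIORITY)
  prio[is.na(prio)] <- base::length(CALLER_PRIORITY) + 1L
  # per-cluster caller support and cuteSV-HQ presence, vectorised
  n_callers <- vapply(split(calls$caller, labels),
                      function(x) dplyr::n_distinct(stats::na.omit(x)),
                      integer(1))
  has_hq <- vapply(split(calls$caller %in% "cuteSV" &
                           isTRUE_vec(calls$hq_flag), labels),
                   any, logical(1))
  keep_lab <- as.integer(names(n_callers))[n_callers >= 2 | has_hq]
  ord <- order(labels, prio, calls$start, calls$id)
  best <- ord[!duplicated(labels[ord])]  # best row per cluster
  best <- best[labels[best] %in% keep_lab]
  out <- calls[best, ]
  out$n_callers <- unname(n_callers[as.character(labels[best])])
  if (nrow(out) == 0) {
    empty <- calls[0, ]
    empty$n_callers <- integer()
    return(empty)
  }
  out[sv_order(out), ]
}

#' Cross-sample nonredundant merge
#'
#' Single-linkage (transitive) clustering of all samples' consensus calls
#' under [sv_match()], computed per (chromosome, SV type).  Each cluster is
#' collapsed to one representative record — the member with the most
#' caller support, ties broken by caller priority, then smallest start,
#' then record id — and the cohort genotype matrix is filled from member
#' genotypes (samples without a member are homozygous reference).  The
#' partition and output order are independent of input order.
#'
#' @param calls SV tibble pooling all samples' consensus calls (`sample`
#'   and `genotype` set; `n_callers` column used for representative choice
#'   when present).
#' @param cohort [cohort_tbl()] covering every `sample` in `calls`.
#' @param params [merge_params()].
#' @return List with `representatives` (SV tibble, one row per cluster,
#'   with `cluster`, `n_members`, `n_carriers` columns), `members` (input
#'   rows plus `cluster`), and `gm` (the merged [genotype_matrix()]).
#' @export
merge_cohort <- function(calls, cohort, params = merge_params()) {
  cohort <- validate_cohort(as_tibble(cohort))
  calls <- as_tibble(calls)
  if (!"n_callers" %in% names(calls)) calls$n_callers <- 1L
  if (nrow(calls) == 0) {
    reps <- calls
    reps$cluster <- integer(); reps$n_members <- integer()
    reps$n_carriers <- integer()
    gm <- genotype_matrix(matrix(0L, nrow(cohort), 0,
                                 dimnames = list(cohort$sample, NULL)),
                          cohort = cohort)
    return(list(representatives = reps, members = calls, gm = gm))
  }
  calls <- calls[sv_order(calls), ]
  grp <- paste(calls$chrom, calls$svtype)
  labels <- integer(nrow(calls))
  nxt <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    cl <- cluster_group(calls[idx, ], params)
    labels[idx] <- nxt + cl
    nxt <- nxt + max(cl)
  }
  prio <- match(calls$caller, CALLER_PRIORITY)
  prio[is.na(prio)] <- base::length(CALLER_PRIORITY) + 1L
  gt_rank <- match(calls$genotype, c("1/1", "0/1", "0/0"))
  gt_rank[is.na(gt_rank)] <- 4L

  ord <- order(labels, -calls$n_callers, prio, calls$start, calls$id)
  reps_idx <- ord[!duplicated(labels[ord])]
  reps <- calls[reps_idx, ]
  reps$cluster <- labels[reps_idx]
  reps$n_members <- as.integer(tabulate(labels)[reps$cluster])
  # order clusters genomically for stable output
  o <- sv_order(reps)
  reps <- reps[o, ]
  relabel <- integer(max(labels))
  relabel[reps$cluster] <- seq_len(nrow(reps))
  reps$cluster <- seq_len(nrow(reps))
  members <- calls
  members$cluster <- relabel[labels]
  reps$id <- sprintf("merged%06d", seq_len(nrow(reps)))

  # genotype per (cluster, sample): highest-priority caller wins, then the
  # more-alternate genotype
  gt_tbl <- members |>
    mutate(prio = prio, gt_rank = gt_rank,
           row = dplyr::row_number()) |>
    filter(!is.na(.data$sample)) |>
    arrange(.data$cluster, .data$sample, .data$prio, .data$gt_rank) |>
    distinct(.data$cluster, .data$sample, .keep_all = TRUE)
  dosage <- matrix(0L, nrow = nrow(cohort), ncol = nrow(reps),
                   dimnames = list(cohort$sample, reps$id))
  if (nrow(gt_tbl) > 0) {
    unknown <- setdiff(unique(gt_tbl$sample), cohort$sample)
    if (base::length(unknown) > 0) {
      abort(paste0("calls from sample(s) not in cohort: ",
                   paste(unknown, collapse = ", ")))
    }
    # members with an uninterpretable genotype (e.g. "./.") stay missing
    dosage[cbind(match(gt_tbl$sample, cohort$sample), gt_tbl$cluster)] <-
      genotype_to_dosage(gt_tbl$genotype)
  }
  reps$n_carriers <- as.integer(colSums(dosage >= 1L, na.rm = TRUE))
  meta <- reps[, c("id", "chrom", "start", "end", "svtype", "length")]
  gm <- genotype_matrix(dosage, variants = meta, cohort = cohort)
  list(representatives = reps, members = members, gm = gm)
}

#' Compare a query SV callset against a reference set
#'
#' Both sets are first restricted to lengths in `[min_len, max_len]`; a
#' query SV is shared when it matches at least one reference SV under
#' [sv_match()], and matched to the single best reference (smallest
#' breakpoint distance, then smallest length difference, then id).
#'
#' @param query,reference Deduplicated SV tibbles.
#' @param params [merge_params()].
#' @return List with `shared`, `novel` (counts over the filtered query)
#'   and `pairs` (tibble `query_id`, `ref_id`, `distance`, `len_diff`).
#' @export
compare_callsets <- function(query, reference, params = merge_params()) {
  qf <- filter(as_tibble(query), .data$length >= params$min_len,
               .data$length <= params$max_len)
  rf <- filter(as_tibble(reference), .data$length >= params$min_len,
               .data$length <= params$max_len)
  if (nrow(qf) == 0 || nrow(rf) == 0) {
    return(list(shared = 0L, novel = nrow(qf),
                pairs = tibble(query_id = character(), ref_id = character(),
                               distance = integer(), len_diff = integer())))
  }
  pairs <- lapply(seq_len(nrow(qf)), function(i) {
    cand <- rf[rf$chrom == qf$chrom[i] &
                 abs(rf$start - qf$start[i]) < params$max_dist, ]
    if (nrow(cand) == 0) return(NULL)
    hit <- sv_match_pairs(qf[rep(i, nrow(cand)), ], cand, params)
    cand <- cand[hit, ]
    if (nrow(cand) == 0) return(NULL)
    d <- pmax(abs(cand$start - qf$start[i]), abs(cand$end - qf$end[i]))
    ld <- abs(cand$length - qf$length[i])
    best <- order(d, ld, cand$id)[1]
    tibble(query_id = qf$id[i], ref_id = cand$id[best],
           distance = as.integer(d[best]), len_diff = as.integer(ld[best]))
  })
  pairs <- bind_rows(pairs)
  shared <- if (nrow(pairs) > 0) dplyr::n_distinct(pairs$query_id) else 0L
  list(shared = shared, novel = nrow(qf) - shared, pairs = pairs)
}
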