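#' Selection-scan parameters
#'
#' Thresholds for population-specific SV calling: a variant is specific to
#' a population when its carrier frequency there is at least `min_freq`,
#' at least `ratio` times the other population's frequency, and its F_ST
#' exceeds `min_fst`.  `top_fst` is the stricter cutoff used for reporting
#' the top differentiated set.
#'
#' @param min_freq Minimum carrier frequency in the focal population.
#' @param ratio Required frequency ratio between populations.
#' @param min_fst F_ST threshold (strict inequality).
#' @param top_fst Reporting threshold for the highly differentiated set.
#' @return List of class `selection_params`.
#' @export
selection_params <- function(min_freq = 0.2, ratio = 2.0, min_fst = 0.1,
                             top_fst = 0.2) {
  stopifnot(min_freq > 0, min_freq <= 1, ratio >= 1,
            min_fst >= 0, min_fst <= top_fst, top_fst <= 1)
  structure(list(min_freq = min_freq, ratio = ratio, min_fst = min_fst,
                 top_fst = top_fst), class = "selection_params")
}

#' Call population-specific SVs
#'
#' Applies the three-criteria rule in both directions.  A zero frequency
#' in the comparison population satisfies the ratio criterion.  Variants
#' are labelled at most one direction (`A_specific`, `B_specific`, or
#' `none`) and ranked by descending F_ST among called variants.
#'
#' @param freqs_a,freqs_b Tibbles (`id`, `freq`) from
#'   [carrier_frequency()] for populations A and B.
#' @param fst An [weir_cockerham_fst()] result (or tibble `id`, `theta`).
#' @param params [selection_params()].
#' @return Tibble `id`, `freq_a`, `freq_b`, `fst`, `direction`, `rank`
#'   (rank is NA for uncalled variants).
#' @export
population_specific_svs <- function(freqs_a, freqs_b, fst,
                                    params = selection_params()) {
  theta <- fst_table(fst)
  tab <- dplyr::full_join(
    rename(freqs_a, freq_a = "freq"),
    rename(freqs_b, freq_b = "freq"), by = "id") |>
    dplyr::full_join(theta, by = "id")
  miss <- is.na(tab$freq_a) | is.na(tab$freq_b) | !tab$id %in% theta$id
  if (any(miss)) {
    abort(paste0("variant(s) missing from an input: ",
                 paste(head(tab$id[miss], 5), collapse = ", ")))
  }
  fst_ok <- !is.na(tab$fst) & tab$fst > params$min_fst
  a_spec <- tab$freq_a >= params$min_freq &
    (tab$freq_b == 0 | tab$freq_a >= params$ratio * tab$freq_b) & fst_ok
  b_spec <- tab$freq_b >= params$min_freq &
    (tab$freq_a == 0 | tab$freq_b >= params$ratio * tab$freq_a) & fst_ok
  # both directions can only co-fire at equal frequencies with ratio = 1;
  # resolve deterministically in favour of the higher frequency
  both <- a_spec & b_spec
  a_spec[both] <- tab$freq_a[both] >= tab$freq_b[both]
  b_spec[both] <- !a_spec[both]
  tab$direction <- ifelse(a_spec, "A_specific",
                          ifelse(b_spec, "B_specific", "none"))
  called <- tab$direction != "none"
  tab$rank <- NA_integer_
  tab$rank[called] <- rank(-tab$fst[called], ties.method = "first")
  arrange(tab, is.na(.data$rank), .data$rank)
}

fst_table <- function(fst) {
  if (inherits(fst, "fst_result")) {
    return(tibble(id = fst$per_site$id, fst = fst$per_site$theta))
  }
  tab <- as_tibble(fst)
  if ("theta" %in% names(tab)) tab <- rename(tab, fst = "theta")
  tab[, c("id", "fst")]
}

#' Rank variants by F_ST
#'
#' @param fst An [weir_cockerham_fst()] result (or tibble `id`, `theta`).
#' @param threshold Keep variants with defined F_ST strictly above this.
#' @param coords Optional SV tibble used to break ties by (chrom, start).
#' @return Tibble `id`, `fst` sorted descending; the count above threshold
#'   is `nrow()` of the result.
#' @export
rank_by_fst <- function(fst, threshold = 0.1, coords = NULL) {
  tab <- fst_table(fst)
  tab <- filter(tab, !is.na(.data$fst), .data$fst > threshold)
  if (!is.null(coords)) {
    tab <- left_join(tab, as_tibble(coords)[, c("id", "chrom", "start")],
                     by = "id")
    tab <- tab[order(-tab$fst, tab$chrom, tab$start), ]
  } else {
    tab <- tab[order(-tab$fst, tab$id), ]
  }
  tab
}

#' Nearest genes around SVs
#'
#' For each SV: overlapping genes (signed distance 0), plus up to `k`
#' genes upstream (genomically left, negative distances) and `k`
#' downstream (right, positive), ordered by distance with ties broken by
#' name.  Strand is not used.
#'
#' @param svs SV tibble.
#' @param genes Interval tibble from [read_intervals()] with gene names in
#'   `label`.
#' @param k Genes kept per side.
#' @return Tibble `id`, `gene`, `side` (upstream/overlap/downstream),
#'   `distance` (signed bp).
#' @export
annotate_nearest_genes <- function(svs, genes, k = 10L) {
  stopifnot(k >= 1)
  svs <- as_tibble(svs)
  genes <- as_tibble(genes)
  if (nrow(genes) > 0 && all(is.na(genes$label))) {
    abort("gene track must carry names in the label column")
  }
  purrr::map_dfr(seq_len(nrow(svs)), function(i) {
    g <- genes[genes$chrom == svs$chrom[i], ]
    if (nrow(g) == 0) return(NULL)
    s <- svs$start[i]
    e <- max(svs$end[i], s + 1L)  # treat INS points as width-1 for overlap
    ov <- g$start < e & g$end > s
    up <- g$end <= s
    dn <- g$start >= e
    rows <- list()
    if (any(ov)) {
      rows$ov <- tibble(id = svs$id[i], gene = g$label[ov],
                        side = "overlap", distance = 0L)
    }
    if (any(up)) {
      du <- s - g$end[up]
      o <- order(du, g$label[up])[seq_len(min(k, sum(up)))]
      rows$up <- tibble(id = svs$id[i], gene = g$label[up][o],
                        side = "upstream", distance = -as.integer(du[o]))
    }
    if (any(dn)) {
      dd <- g$start[dn] - e
      o <- order(dd, g$label[dn])[seq_len(min(k, sum(dn)))]
      rows$dn <- tibble(id = svs$id[i], gene = g$label[dn][o],
                        side = "downstream", distance = as.integer(dd[o]))
    }
    bind_rows(rows)
  })
}

#' Three-way gene-set overlap (Venn counts)
#'
#' @param genes_sv,genes_snp,genes_indel Character vectors of gene names.
#' @return List with `regions` (named counts for the seven exclusive Venn
#'   regions), `total` distinct genes, and `shared` (genes in >= 2 sets).
#' @export
gene_set_overlap <- function(genes_sv, genes_snp, genes_indel) {
  a <- unique(as.character(genes_sv))
  b <- unique(as.character(genes_snp))
  c_ <- unique(as.character(genes_indel))
  all_genes <- union(union(a, b), c_)
  ina <- all_genes %in% a; inb <- all_genes %in% b; inc <- all_genes %in% c_
  regions <- c(
    sv_only = sum(ina & !inb & !inc),
    snp_only = sum(!ina & inb & !inc),
    indel_only = sum(!ina & !inb & inc),
    sv_snp = sum(ina & inb & !inc),
    sv_indel = sum(ina & !inb & inc),
    snp_indel = sum(!ina & inb & inc),
    all_three = sum(ina & inb & inc)
  )
  list(regions = regions, total = base::length(all_genes),
       shared = sort(all_genes[(ina + inb + inc) >= 2]))
}
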