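#' LD-scan parameters
#'
#' @param window SV-to-SNP search window in bp (anchored at the SV
#'   breakpoint nearest each SNP).
#' @param report_cutoff Minimum r-squared reported by [ld_scan()].
#' @param strong_cutoff "Strong LD" threshold used by
#'   [phenotype_bridge()] (inclusive).
#' @return List of class `ld_params`.
#' @export
ld_params <- function(window = 1000000L, report_cutoff = 0.2,
                      strong_cutoff = 0.8) {
  stopifnot(window > 0, report_cutoff >= 0,
            report_cutoff <= strong_cutoff, strong_cutoff <= 1)
  structure(list(window = as.integer(window),
                 report_cutoff = report_cutoff,
                 strong_cutoff = strong_cutoff), class = "ld_params")
}

#' Squared dosage correlation between two loci
#'
#' r-squared as the squared Pearson correlation of unphased genotype
#' dosages over pairwise-complete samples (the composite allele-count
#' measure computed by standard LD tools on unphased input).
#'
#' @param g1,g2 Equal-length dosage vectors (0/1/2, NA = missing).
#' @return r-squared, with the pairwise-complete sample count as
#'   attribute `n`; `NA` (flagged via attribute `reason`) when fewer than
#'   3 complete pairs remain or either vector is constant.
#' @examples
#' r2_dosage(c(0, 1, 2, 2, 0), c(0, 1, 2, 1, 0))  # 9/11.2
#' @export
r2_dosage <- function(g1, g2) {
  if (base::length(g1) != base::length(g2)) {
    abort("dosage vectors must have equal length")
  }
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  if (n < 3) {
    return(structure(NA_real_, n = n, reason = "fewer than 3 complete pairs"))
  }
  x <- g1[ok]; y <- g2[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(NA_real_, n = n, reason = "constant dosage vector"))
  }
  structure(cor(x, y)^2, n = n, reason = NA_character_)
}

#' Window-limited LD scan between SVs and SNPs
#'
#' For every SV, all SNPs on the same chromosome within `window` bp of the
#' nearer SV breakpoint are tested with [r2_dosage()]; pairs at or above
#' `report_cutoff` are returned.
#'
#' @param sv_gm,snp_gm [genotype_matrix()] objects over the same samples
#'   (same order), with coordinates in their `variants` metadata (`chrom`,
#'   `start`, `end` for SVs; `chrom`, `start` for SNPs).
#' @param params [ld_params()].
#' @return Tibble `sv_id`, `snp_id`, `r2`, `n`, `distance` (bp to the
#'   nearer breakpoint), filtered to `r2 >= report_cutoff`.
#' @export
ld_scan <- function(sv_gm, snp_gm, params = ld_params()) {
  if (!identical(rownames(sv_gm$dosage), rownames(snp_gm$dosage))) {
    abort("SV and SNP matrices must share the same samples in the same order")
  }
  sv_meta <- sv_gm$variants
  snp_meta <- snp_gm$variants
  out <- list()
  for (i in seq_len(nrow(sv_meta))) {
    on_chr <- which(snp_meta$chrom == sv_meta$chrom[i])
    if (base::length(on_chr) == 0) next
    pos <- snp_meta$start[on_chr]
    dist <- pmin(abs(pos - sv_meta$start[i]), abs(pos - sv_meta$end[i]))
    on_chr <- on_chr[dist <= params$window]
    dist <- dist[dist <= params$window]
    if (base::length(on_chr) == 0) next
    g_sv <- sv_gm$dosage[, i]
    r2 <- vapply(on_chr, function(j) {
      as.numeric(r2_dosage(g_sv, snp_gm$dosage[, j]))
    }, numeric(1))
    nn <- vapply(on_chr, function(j) {
      sum(!is.na(g_sv) & !is.na(snp_gm$dosage[, j]))
    }, numeric(1))
    keep <- !is.na(r2) & r2 >= params$report_cutoff
    if (!any(keep)) next
    out[[base::length(out) + 1]] <- tibble(
      sv_id = sv_meta$id[i], snp_id = snp_meta$id[on_chr][keep],
      r2 = r2[keep], n = as.integer(nn[keep]),
      distance = as.integer(dist[keep]))
  }
  if (base::length(out) == 0) {
    return(tibble(sv_id = character(), snp_id = character(), r2 = numeric(),
                  n = integer(), distance = integer()))
  }
  bind_rows(out)
}

#' Bridge SVs to phenotypes through strongly linked catalog SNPs
#'
#' Keeps LD pairs at or above the strong-LD cutoff whose SNP appears in
#' the catalog, and emits one association per (SV, SNP, phenotype) triple.
#'
#' @param ld_pairs Output of [ld_scan()].
#' @param catalog [read_gwas_catalog()] tibble.
#' @param params [ld_params()].
#' @return Tibble `sv_id`, `snp_id`, `r2`, `n`, `phenotype`,
#'   deduplicated; the per-SV phenotype summary is attached as attribute
#'   `per_sv` (tibble `sv_id`, `phenotypes`).
#' @export
phenotype_bridge <- function(ld_pairs, catalog, params = ld_params()) {
  strong <- filter(as_tibble(ld_pairs), .data$r2 >= params$strong_cutoff)
  out <- inner_join(strong, as_tibble(catalog)[, c("snp_id", "phenotype")],
                    by = "snp_id",
                    relationship = "many-to-many") |>
    distinct(.data$sv_id, .data$snp_id, .data$phenotype, .keep_all = TRUE) |>
    select("sv_id", "snp_id", "r2", dplyr::any_of("n"), "phenotype")
  per_sv <- out |>
    group_by(.data$sv_id) |>
    summarise(phenotypes = paste(sort(unique(.data$phenotype)),
                                 collapse = "; "), .groups = "drop")
  attr(out, "per_sv") <- per_sv
  out
}
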