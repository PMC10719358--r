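#' Samples-by-variants genotype container
#'
#' Stores diploid dosages (0, 1, 2, `NA` for missing) as a samples x
#' variants integer matrix together with per-variant metadata and the
#' cohort table.  The derived presence view (1 iff dosage >= 1, with
#' missing treated as absent) backs all carrier-frequency statistics,
#' mirroring the 0/1 N x M matrix used for PCA, trees and hotspots.
#'
#' @param dosage Integer matrix, samples in rows, variants in columns,
#'   values in `{0, 1, 2, NA}`; dimnames give sample and variant ids.
#' @param variants Optional tibble of variant metadata (must contain `id`
#'   matching the column names; typically also `chrom`, `start`, `end`,
#'   `svtype`, `length`).
#' @param cohort Optional cohort tibble ([cohort_tbl()]) matching the rows.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants = NULL, cohort = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("sample%03d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("var%06d", seq_len(ncol(dosage)))
  }
  ok <- dosage %in% c(0L, 1L, 2L, NA)
  if (!all(ok)) abort("dosage values must be 0, 1, 2 or NA")
  if (!is.null(variants)) {
    variants <- as_tibble(variants)
    if (!"id" %in% names(variants)) abort("variants metadata needs an `id` column")
    if (!setequal(variants$id, colnames(dosage)) ||
        nrow(variants) != ncol(dosage)) {
      abort("variants metadata does not match dosage columns")
    }
    variants <- variants[match(colnames(dosage), variants$id), ]
  }
  if (!is.null(cohort)) {
    cohort <- validate_cohort(as_tibble(cohort))
    if (!setequal(cohort$sample, rownames(dosage))) {
      abort("cohort samples do not match dosage rows")
    }
    dosage <- dosage[match(cohort$sample, rownames(dosage)), , drop = FALSE]
  }
  structure(list(dosage = dosage, variants = variants, cohort = cohort),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  if (!is.null(x$cohort)) {
    tb <- table(x$cohort$population)
    cat("populations:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Presence (0/1) view of a genotype matrix
#'
#' Missing dosages count as absence: presence-based statistics (carrier
#' frequency, saturation, PCA, trees) treat an ungenotyped sample as a
#' non-carrier, while dosage-based statistics (HWE, F_ST, LD) drop missing
#' entries pairwise.
#'
#' @param gm A [genotype_matrix()].
#' @return Integer 0/1 matrix of the same shape.
#' @export
presence_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  p <- (gm$dosage >= 1L) * 1L
  p[is.na(p)] <- 0L
  p
}

#' Long tidy view of a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return Tibble with columns `sample`, `variant`, `dosage`, `presence`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  out <- tibble(
    sample = rep(rownames(d), times = ncol(d)),
    variant = rep(colnames(d), each = nrow(d)),
    dosage = as.integer(d)
  )
  out$presence <- ifelse(!is.na(out$dosage) & out$dosage >= 1L, 1L, 0L)
  out
}

#' Assemble a genotype matrix from per-variant SV records
#'
#' Converts genotype strings to dosages (`0/0` -> 0, `0/1` -> 1, `1/1` ->
#' 2, `./.` or absent -> missing) and lays samples out in cohort order.
#' A variant here is one row group sharing an `id`; at most one genotype
#' per (variant, sample) is allowed.
#'
#' @param records SV tibble with `id`, `sample` and `genotype` filled in,
#'   plus coordinate columns used as variant metadata.
#' @param cohort A [cohort_tbl()].
#' @return A [genotype_matrix()].
#' @export
build_genotype_matrix <- function(records, cohort) {
  cohort <- validate_cohort(as_tibble(cohort))
  records <- as_tibble(records)
  unknown <- setdiff(stats::na.omit(unique(records$sample)), cohort$sample)
  if (base::length(unknown) > 0) {
    abort(paste0("genotype for sample(s) not in cohort: ",
                 paste(unknown, collapse = ", ")))
  }
  meta <- records |>
    distinct(.data$id, .keep_all = TRUE) |>
    select(dplyr::any_of(c("id", "chrom", "start", "end", "svtype", "length")))
  meta <- meta[order(meta$chrom, meta$start, meta$end, meta$id), ]
  dup <- records |>
    dplyr::count(.data$id, .data$sample) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("more than one genotype for the same (variant, sample) pair")
  }
  dosage <- matrix(0L, nrow = nrow(cohort), ncol = nrow(meta),
                   dimnames = list(cohort$sample, meta$id))
  if (nrow(records) > 0) {
    ri <- match(records$sample, cohort$sample)
    ci <- match(records$id, meta$id)
    keep <- !is.na(ri)
    dosage[cbind(ri[keep], ci[keep])] <-
      genotype_to_dosage(records$genotype[keep])
  }
  genotype_matrix(dosage, variants = meta, cohort = cohort)
}

genotype_to_dosage <- function(gt) {
  out <- rep(NA_integer_, base::length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  # partially genotyped calls (./1 etc.) are treated as missing
  out
}

dosage_to_genotype <- function(d) {
  out <- rep("./.", base::length(d))
  out[!is.na(d) & d == 0L] <- "0/0"
  out[!is.na(d) & d == 1L] <- "0/1"
  out[!is.na(d) & d == 2L] <- "1/1"
  out
}
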