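#' Read structural variants from a VCF file
#'
#' Parses a VCF 4.x file whose records carry `SVTYPE` (and `END`/`SVLEN`)
#' in INFO into the package's 0-based half-open SV tibble.  `start` is
#' `POS - 1`; for spanned types `end` is the INFO `END` (1-based inclusive,
#' hence equal to the half-open end) or `POS - 1 + |SVLEN|`; insertions are
#' points with `length` from `|SVLEN|` or the ALT allele.
#'
#' @param path VCF file (plain or gzip; any dialect of the long-read SV
#'   callers that writes `SVTYPE`).
#' @param sample Optional sample name whose `FORMAT/GT` is parsed into
#'   `genotype` and recorded in `sample`; default = first sample column if
#'   one exists.
#' @param caller Optional caller label stored in the `caller` column.
#' @param hq_key INFO key treated as the caller's high-quality mark
#'   (flag or truthy value); default `"HQ"`.
#' @return SV tibble (see [sv_tbl()]); the number of records skipped for
#'   unknown `SVTYPE` values is attached as attribute `n_skipped`.
#' @export
read_sv_vcf <- function(path, sample = NULL, caller = NA_character_,
                        hq_key = "HQ") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) {
    out <- sv_tbl(character(), integer(), integer(), character(),
                  length = integer(), id = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  info <- fix[, "INFO"]
  rec <- seq_len(nrow(fix))
  svtype <- info_field(info, "SVTYPE")
  if (anyNA(svtype)) {
    abort(paste0("missing SVTYPE in record(s): ",
                 paste(head(rec[is.na(svtype)], 5), collapse = ", ")))
  }
  known <- svtype %in% SV_TYPES
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warn(sprintf("skipped %d record(s) with unknown SVTYPE (%s)", n_skipped,
                 paste(unique(svtype[!known]), collapse = ", ")))
  }
  pos <- as.integer(fix[, "POS"])
  svlen <- suppressWarnings(as.numeric(info_field(info, "SVLEN")))
  endf <- suppressWarnings(as.integer(info_field(info, "END")))
  alt <- fix[, "ALT"]
  start <- pos - 1L
  is_ins <- svtype == "INS"
  need <- known & !is_ins & is.na(endf) & is.na(svlen)
  if (any(need)) {
    abort(paste0("END and SVLEN both absent for non-INS record(s): ",
                 paste(head(rec[need], 5), collapse = ", ")))
  }
  len <- ifelse(!is.na(svlen), abs(svlen), NA_real_)
  len[!is_ins & is.na(len)] <- endf[!is_ins & is.na(len)] - start[!is_ins & is.na(len)]
  # INS length from a sequence-resolved ALT when SVLEN is absent
  seq_alt <- is_ins & is.na(len) & grepl("^[ACGTNacgtn]+$", alt)
  len[seq_alt] <- nchar(alt[seq_alt]) - 1L
  if (any(is_ins & known & (is.na(len) | len < 1))) {
    abort("INS record without SVLEN or sequence-resolved ALT")
  }
  end <- ifelse(is_ins, start, ifelse(!is.na(endf), endf, start + len))

  gt <- rep(NA_character_, nrow(fix))
  sample_used <- NA_character_
  if (ncol(v@gt %||% matrix(nrow = 0, ncol = 0)) >= 2) {
    samples <- colnames(v@gt)[-1]
    sample_used <- if (is.null(sample)) samples[1] else sample
    if (!sample_used %in% samples) {
      abort(paste0("sample not present in VCF: ", sample_used))
    }
    raw <- v@gt[, sample_used]
    fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
    gt <- vapply(seq_along(raw), function(i) {
      gi <- match("GT", fmt[[i]])
      if (is.na(gi)) return(NA_character_)
      strsplit(raw[i], ":", fixed = TRUE)[[1]][gi]
    }, character(1))
    gt[!gt %in% c(GENOTYPES, "0|0", "0|1", "1|0", "1|1")] <- NA_character_
  }
  hq_raw <- info_field(info, hq_key, flag = TRUE)
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- sprintf("rec%06d", rec[is.na(id) | id == "."])

  out <- tibble(
    id = id[known], chrom = fix[known, "CHROM"],
    start = start[known], end = as.integer(end[known]),
    svtype = svtype[known], length = as.integer(round(len[known])),
    caller = rep(as.character(caller), sum(known)),
    hq_flag = hq_raw[known],
    sample = rep(as.character(sample_used), sum(known)),
    genotype = gsub("|", "/", gt[known], fixed = TRUE),
    depth = suppressWarnings(as.numeric(info_field(info[known], "DEPTH"))),
    af_read = suppressWarnings(as.numeric(info_field(info[known], "AF")))
  )
  out <- validate_sv_tbl(out)
  attr(out, "n_skipped") <- n_skipped
  out
}

info_field <- function(info, key, flag = FALSE) {
  patt <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(patt, info))
  val <- vapply(m, function(x) if (base::length(x) == 2) x[2] else NA_character_,
                character(1))
  if (flag) {
    has_flag <- grepl(paste0("(?:^|;)", key, "(?:;|$)"), info)
    return(has_flag | (!is.na(val) & !val %in% c("0", "false", "FALSE")))
  }
  val
}

#' Write structural variants to a VCF file
#'
#' Emits a minimal VCF 4.2 with `SVTYPE`, `SVLEN`, `END`, `AF`, `DEPTH` and
#' optional `HQ` in INFO plus per-sample `GT` columns for the cohort.
#' Reading the file back with [read_sv_vcf()] reproduces coordinates,
#' types, lengths and genotypes exactly.
#'
#' @param records SV tibble sorted by (chrom, start); one row per variant
#'   (use a genotype matrix for multi-sample output).
#' @param path Output path.
#' @param cohort Optional [cohort_tbl()]; with `gm` supplied, one GT column
#'   per cohort sample is written.
#' @param gm Optional [genotype_matrix()] whose columns match `records$id`.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, path, cohort = NULL, gm = NULL) {
  records <- validate_sv_tbl(as_tibble(records))
  if (nrow(records) > 1) {
    o <- order(records$chrom, records$start)
    if (!identical(o, seq_len(nrow(records)))) {
      abort("records must be sorted by (chrom, start) before writing")
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svpopscan",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based inclusive)">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Read-support fraction">',
    '##INFO=<ID=DEPTH,Number=1,Type=Float,Description="Local read depth">',
    '##INFO=<ID=HQ,Number=0,Type=Flag,Description="Caller high-quality mark">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT")
  sample_names <- character()
  gt_block <- NULL
  if (!is.null(gm)) {
    cohort <- cohort %||% gm$cohort
    sample_names <- rownames(gm$dosage)
    d <- gm$dosage[, records$id, drop = FALSE]
    gt_block <- apply(d, 2, dosage_to_genotype)
    if (is.null(dim(gt_block))) gt_block <- matrix(gt_block, nrow = 1)
    gt_block <- t(gt_block)  # variants x samples
  } else if (!is.na(records$genotype[1]) || any(!is.na(records$genotype))) {
    sample_names <- unique(stats::na.omit(records$sample))
    if (base::length(sample_names) > 1) {
      abort("per-record genotypes from more than one sample; supply `gm`")
    }
    if (base::length(sample_names) == 0) sample_names <- "SAMPLE"
    gt_block <- matrix(ifelse(is.na(records$genotype), "./.",
                              records$genotype), ncol = 1)
  }
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", records$svtype,
                  ifelse(records$svtype == "DEL", -records$length,
                         records$length),
                  ifelse(records$svtype == "INS", records$start,
                         records$end))
  extra <- ifelse(!is.na(records$af_read),
                  sprintf(";AF=%g", records$af_read), "")
  extra <- paste0(extra, ifelse(!is.na(records$depth),
                                sprintf(";DEPTH=%g", records$depth), ""))
  extra <- paste0(extra, ifelse(isTRUE_vec(records$hq_flag), ";HQ", ""))
  body <- if (nrow(records) == 0) character(0) else
    paste(records$chrom, records$start + 1L, records$id, "N",
          paste0("<", records$svtype, ">"), ".", "PASS",
          paste0(info, extra), sep = "\t")
  if (base::length(sample_names) > 0) {
    body <- paste(body, "GT", sep = "\t")
    if (nrow(records) > 0) {
      body <- paste(body, apply(gt_block, 1, paste, collapse = "\t"),
                    sep = "\t")
    }
    cols <- c(cols, sample_names)
  } else {
    cols <- cols[cols != "FORMAT"]
  }
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read a BED interval track
#'
#' @param path BED3+ file (plain or gzip), 0-based half-open.
#' @param name Track name stored in the `track` column.
#' @return Tibble with `track`, `chrom`, `start`, `end`, `label` (4th BED
#'   column when present), sorted by (chrom, start).
#' @export
read_intervals <- function(path, name = "track") {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (base::length(lines) == 0) {
    return(tibble(track = character(), chrom = character(),
                  start = integer(), end = integer(), label = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(paste0("BED line with fewer than 3 fields: line ",
                 which(nf < 3)[1]))
  }
  chrom <- vapply(parts, `[`, character(1), 1)
  s_raw <- vapply(parts, `[`, character(1), 2)
  e_raw <- vapply(parts, `[`, character(1), 3)
  start <- suppressWarnings(as.integer(s_raw))
  end <- suppressWarnings(as.integer(e_raw))
  bad <- is.na(start) | is.na(end) | s_raw != as.character(start) |
    e_raw != as.character(end)
  if (any(bad)) {
    abort(paste0("non-integer coordinates on line ", which(bad)[1]))
  }
  if (any(start >= end)) {
    abort(paste0("start >= end on line ", which(start >= end)[1]))
  }
  label <- vapply(parts, function(x)
    if (base::length(x) >= 4) x[4] else NA_character_, character(1))
  out <- tibble(track = name, chrom = chrom, start = start, end = end,
                label = label)
  out[order(out$chrom, out$start), ]
}

#' Write intervals as BED
#' @param intervals Tibble with `chrom`, `start`, `end` and optional `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  lab <- intervals$label %||% NULL
  df <- intervals[, c("chrom", "start", "end")]
  if (!is.null(lab) && any(!is.na(lab))) df$label <- ifelse(is.na(lab), ".", lab)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a GWAS-catalog-style SNP-to-phenotype table
#'
#' @param path TSV with header columns `snp_id`, `chrom`, `pos`,
#'   `phenotype` (plain or gzip).
#' @return Tibble with those columns, duplicate (snp_id, phenotype) pairs
#'   removed.
#' @export
read_gwas_catalog <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  needed <- c("snp_id", "chrom", "pos", "phenotype")
  miss <- setdiff(needed, names(tab))
  if (base::length(miss) > 0) {
    abort(paste0("GWAS catalog is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  tab$pos <- as.integer(tab$pos)
  if (nrow(tab) > 0 && (anyNA(tab$pos) || any(tab$pos < 0) ||
                        any(!nzchar(tab$snp_id)))) {
    abort("GWAS catalog: snp_id must be nonempty and pos a nonnegative integer")
  }
  distinct(tab[needed], .data$snp_id, .data$phenotype, .keep_all = TRUE)
}
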