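#' Build a tibble of structural-variant records
#'
#' The package represents SV calls as plain tibbles with one row per call.
#' Coordinates are 0-based half-open throughout: `start` is the first base of
#' the affected span and `end` is one past the last.  Insertions are points
#' (`end == start`) whose size lives in `length`.
#'
#' @param chrom Chromosome names.
#' @param start,end Integer 0-based half-open coordinates.  For `svtype ==
#'   "INS"` the `end` is forced equal to `start`.
#' @param svtype One of `"DEL"`, `"INS"`, `"DUP"`, `"INV"`.
#' @param length Variant length in bp (`>= 1`).  Defaults to `end - start`
#'   for spanned types; required for insertions.
#' @param id Record identifiers; autogenerated when `NULL`.
#' @param caller,sample,genotype,hq_flag,depth,af_read Optional provenance
#'   columns; see Details.
#'
#' @details `genotype` uses the strings `"0/0"`, `"0/1"`, `"1/1"` or `NA`
#'   (missing).  `af_read` is the per-call read-support fraction and `depth`
#'   the local read depth, both used by [filter_raw_calls()].  `hq_flag`
#'   marks calls the caller itself labels high-quality.
#'
#' @return A tibble with columns `id`, `chrom`, `start`, `end`, `svtype`,
#'   `length`, `caller`, `hq_flag`, `sample`, `genotype`, `depth`,
#'   `af_read`.
#' @examples
#' sv_tbl(chrom = "chr1", start = 1000, end = 2000, svtype = "DEL")
#' @export
sv_tbl <- function(chrom, start, end, svtype, length = NULL, id = NULL,
                   caller = NA_character_, sample = NA_character_,
                   genotype = NA_character_, hq_flag = FALSE,
                   depth = NA_real_, af_read = NA_real_) {
  n <- max(base::length(chrom), base::length(start))
  svtype <- rep_len(as.character(svtype), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  end[svtype == "INS"] <- start[svtype == "INS"]
  if (is.null(length)) length <- end - start
  if (is.null(id)) id <- sprintf("sv%06d", seq_len(n))
  out <- tibble(
    id = rep_len(as.character(id), n),
    chrom = rep_len(as.character(chrom), n),
    start = start,
    end = end,
    svtype = svtype,
    length = rep_len(as.integer(length), n),
    caller = rep_len(as.character(caller), n),
    hq_flag = rep_len(as.logical(hq_flag), n),
    sample = rep_len(as.character(sample), n),
    genotype = rep_len(as.character(genotype), n),
    depth = rep_len(as.double(depth), n),
    af_read = rep_len(as.double(af_read), n)
  )
  validate_sv_tbl(out)
}

#' Validate a tibble of SV records
#'
#' Checks the coordinate and length invariants: `start >= 0`,
#' `end >= start`, `length >= 1`, `length == end - start` for spanned types
#' and `end == start` for insertions.
#'
#' @param svs A tibble as returned by [sv_tbl()].
#' @return The input, invisibly validated (returned unchanged).
#' @export
validate_sv_tbl <- function(svs) {
  needed <- c("id", "chrom", "start", "end", "svtype", "length")
  missing_cols <- setdiff(needed, names(svs))
  if (base::length(missing_cols) > 0) {
    abort(paste0("SV table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(svs) == 0) return(svs)
  bad_type <- !svs$svtype %in% SV_TYPES
  if (any(bad_type)) {
    abort(paste0("unknown svtype value(s): ",
                 paste(unique(svs$svtype[bad_type]), collapse = ", ")))
  }
  if (any(svs$start < 0)) abort("negative start coordinate")
  if (any(svs$end < svs$start)) abort("end < start")
  if (any(svs$length < 1)) abort("SV length must be >= 1")
  span <- svs$svtype != "INS"
  if (any(svs$length[span] != svs$end[span] - svs$start[span])) {
    abort("for DEL/DUP/INV, length must equal end - start")
  }
  if (any(svs$end[!span] != svs$start[!span])) {
    abort("INS records must have end == start")
  }
  svs
}

#' Construct a two-population cohort table
#'
#' @param sample Character vector of unique sample identifiers.
#' @param population Population label per sample (exactly the assignment
#'   used by the F_ST machinery; any two labels, e.g. `"POP_A"`/`"POP_B"`
#'   for the Tibetan/Han roles).
#' @return A tibble with columns `sample` and `population`.
#' @examples
#' cohort_tbl(c("s1", "s2"), c("POP_A", "POP_B"))
#' @export
cohort_tbl <- function(sample, population) {
  out <- tibble(sample = as.character(sample),
                population = as.character(population))
  validate_cohort(out)
}

validate_cohort <- function(cohort) {
  if (!all(c("sample", "population") %in% names(cohort))) {
    abort("cohort must have columns `sample` and `population`")
  }
  if (anyDuplicated(cohort$sample)) abort("duplicate sample ids in cohort")
  if (anyNA(cohort$population)) abort("every sample needs a population label")
  cohort
}

# total deterministic order on SV records (used for tie-breaking everywhere)
sv_order <- function(svs) {
  order(svs$chrom, svs$start, svs$end, svs$svtype, svs$length, svs$id)
}
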