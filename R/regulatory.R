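#' Regulatory-overlap parameters
#'
#' @param pad Breakpoint padding in bp (default 100; applied to the SV's
#'   outer hull, clipped at 0).
#' @param tracks Named list of interval tibbles ([read_intervals()]);
#'   names must be unique.
#' @param mode `"hull"` (default): one padded interval spanning the SV;
#'   `"breakpoints"`: two windows of `2 * pad` around each breakpoint
#'   (useful for very large SVs).
#' @return List of class `regulatory_params`.
#' @export
regulatory_params <- function(pad = 100L, tracks = list(),
                              mode = c("hull", "breakpoints")) {
  stopifnot(pad >= 0)
  if (anyDuplicated(names(tracks))) abort("track names must be unique")
  structure(list(pad = as.integer(pad), tracks = tracks,
                 mode = match.arg(mode)), class = "regulatory_params")
}

#' Pad SV breakpoints
#'
#' Spanned SVs become `[max(0, start - pad), end + pad)`; insertions
#' become `[max(0, start - pad), start + pad)`.
#'
#' @param svs SV tibble.
#' @param pad Padding in bp (>= 0).
#' @return Tibble `id`, `chrom`, `start`, `end` of padded intervals.
#' @export
extend_breakpoints <- function(svs, pad = 100L) {
  stopifnot(pad >= 0)
  svs <- as_tibble(svs)
  tibble(id = svs$id, chrom = svs$chrom,
         start = as.integer(pmax(0L, svs$start - pad)),
         end = as.integer(ifelse(svs$svtype == "INS",
                                 svs$start + pad, svs$end + pad)))
}

#' Intersect padded SVs with regulatory tracks
#'
#' Half-open interval intersection between each padded SV and every
#' track; reports per-(SV, track) element counts and labels, and summary
#' counts of SVs overlapping at least one element per track and over all
#' tracks ("any element", set semantics).
#'
#' @param svs SV tibble.
#' @param params [regulatory_params()] carrying the tracks and padding.
#' @return List: `table` (tibble `id`, `track`, `n_elements`, `labels`),
#'   `summary` (tibble `track`, `n_svs_overlapping`; includes row
#'   `"any"`).
#' @export
intersect_elements <- function(svs, params = regulatory_params()) {
  svs <- as_tibble(svs)
  padded <- extend_breakpoints(svs, params$pad)
  if (params$mode == "breakpoints") {
    left <- mutate(padded, end = pmin(.data$end,
                                      pmax(svs$start + params$pad,
                                           .data$start + 1L)))
    right <- tibble(id = svs$id, chrom = svs$chrom,
                    start = pmax(0L, svs$end - params$pad),
                    end = svs$end + params$pad)
    padded <- bind_rows(left, right)
  }
  rows <- list()
  hit_any <- setNames(rep(FALSE, nrow(svs)), svs$id)
  for (nm in names(params$tracks)) {
    tr <- as_tibble(params$tracks[[nm]])
    hits <- interval_overlaps(padded, tr)
    per_sv <- hits |>
      group_by(.data$id) |>
      summarise(n_elements = dplyr::n_distinct(.data$element),
                labels = paste(sort(unique(stats::na.omit(.data$label))),
                               collapse = ","), .groups = "drop")
    all_svs <- tibble(id = unique(svs$id))
    per_sv <- left_join(all_svs, per_sv, by = "id") |>
      mutate(track = nm,
             n_elements = dplyr::coalesce(.data$n_elements, 0L),
             labels = dplyr::coalesce(.data$labels, ""))
    rows[[nm]] <- per_sv[, c("id", "track", "n_elements", "labels")]
    hit_any[per_sv$id[per_sv$n_elements > 0]] <- TRUE
  }
  table <- bind_rows(rows)
  summary <- table |>
    group_by(.data$track) |>
    summarise(n_svs_overlapping = sum(.data$n_elements > 0),
              .groups = "drop")
  summary <- bind_rows(summary,
                       tibble(track = "any",
                              n_svs_overlapping = sum(hit_any)))
  list(table = table, summary = summary)
}

# half-open overlap join: returns (id, element index, label)
interval_overlaps <- function(query, track) {
  if (nrow(query) == 0 || nrow(track) == 0) {
    return(tibble(id = character(), element = integer(),
                  label = character()))
  }
  q <- GenomicRanges::GRanges(query$chrom,
                              IRanges::IRanges(query$start + 1L,
                                               pmax(query$end, query$start + 1L) ))
  s <- GenomicRanges::GRanges(track$chrom,
                              IRanges::IRanges(track$start + 1L, track$end))
  # zero-width padded queries (pad = 0 on INS) cannot overlap anything
  zero <- query$end <= query$start
  ov <- GenomicRanges::findOverlaps(q, s)
  keep <- !zero[S4Vectors::queryHits(ov)]
  tibble(id = query$id[S4Vectors::queryHits(ov)][keep],
         element = S4Vectors::subjectHits(ov)[keep],
         label = (track$label %||% rep(NA_character_, nrow(track)))[
           S4Vectors::subjectHits(ov)][keep])
}
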