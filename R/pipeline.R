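#' Assemble and validate a pipeline configuration
#'
#' Bundles the per-stage parameter blocks, the global seed and the output
#' directory.  Validation is total: every invalid block fails here with a
#' named error, before any stage runs.  `config` may also be a YAML or
#' JSON file path holding plain lists that are passed to the corresponding
#' parameter constructors.
#'
#' @param sim [sim_params()].
#' @param merge [merge_params()].
#' @param selection [selection_params()].
#' @param hotspot [hotspot_params()].
#' @param ld [ld_params()].
#' @param regulatory_pad Breakpoint padding (bp) for the regulatory stage.
#' @param seed Global seed; per-stage seeds are derived from it so each
#'   stage is reproducible independently of stage order.
#' @param output_dir Optional directory for TSV/JSON outputs (`NULL` =
#'   in-memory only).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_params(), merge = merge_params(),
                            selection = selection_params(),
                            hotspot = hotspot_params(num_trial = 200L),
                            ld = ld_params(), regulatory_pad = 100L,
                            seed = 1L, output_dir = NULL) {
  stopifnot(inherits(sim, "sim_params"), inherits(merge, "merge_params"),
            inherits(selection, "selection_params"),
            inherits(hotspot, "hotspot_params"), inherits(ld, "ld_params"),
            regulatory_pad >= 0)
  structure(list(sim = sim, merge = merge, selection = selection,
                 hotspot = hotspot, ld = ld,
                 regulatory_pad = as.integer(regulatory_pad),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file whose top-level blocks
#'   (`sim`, `merge`, `selection`, `hotspot`, `ld`, `seed`,
#'   `regulatory_pad`, `output_dir`) map onto [pipeline_config()].
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$genome)) sim_args$genome <- unlist(sim_args$genome)
  pipeline_config(
    sim = do.call(sim_params, sim_args),
    merge = do.call(merge_params, raw$merge %||% list()),
    selection = do.call(selection_params, raw$selection %||% list()),
    hotspot = do.call(hotspot_params, raw$hotspot %||% list(num_trial = 200L)),
    ld = do.call(ld_params, raw$ld %||% list()),
    regulatory_pad = raw$regulatory_pad %||% 100L,
    seed = raw$seed %||% 1L,
    output_dir = raw$output_dir)
}

#' Run the full synthetic-cohort SV population pipeline
#'
#' Executes, in dependency order: cohort simulation, per-caller call
#' simulation, raw-call filtering, within-sample consensus, cross-sample
#' nonredundant merging, landscape statistics (carrier frequencies,
#' spectrum, HWE, F_ST), the population-specificity selection scan,
#' hotspot detection, the LD scan and phenotype bridge, and
#' regulatory-element overlap of the top differentiated SVs.  Every
#' threshold actually applied is recorded in the report's `parameters`
#' block; reruns with an identical config are identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return List of class `pipeline_report` with per-stage results and a
#'   `summary` block; written to `output_dir` (TSV tables +
#'   `report.json`) when configured.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(paste0("[svpopscan] ", ...))
  p <- config$sim

  say("simulating cohort truth")
  sim <- simulate_cohort_truth(p)
  say("simulating per-caller calls")
  calls <- simulate_caller_calls(sim, p)

  say("raw filter + within-sample consensus")
  kept <- filter_raw_calls(calls, p$mean_depth, config$merge)
  consensus <- kept |>
    dplyr::group_split(.data$sample) |>
    purrr::map(within_sample_consensus, params = config$merge) |>
    bind_rows()

  say("cross-sample merge")
  merged <- merge_cohort(select(consensus, -dplyr::any_of("truth_id")),
                         sim$cohort, config$merge)
  reps <- merged$representatives
  gm <- merged$gm

  say("landscape statistics")
  freqs_all <- carrier_frequency(gm)
  freqs_a <- carrier_frequency(gm, "POP_A")
  freqs_b <- carrier_frequency(gm, "POP_B")
  spectrum <- af_spectrum(freqs_all, gm)
  hwe <- hwe_test(gm)
  fst <- weir_cockerham_fst(gm)
  carriers <- colSums(presence_matrix(gm))
  pl <- tryCatch(
    powerlaw_fit(carriers[carriers > 0], n_bootstrap = 50L,
                 seed = derive_seed(config$seed, 11)),
    error = function(e) NULL)
  sat <- saturation_curve(gm, n_orders = 5L,
                          seed = derive_seed(config$seed, 12))

  say("selection scan")
  sel_calls <- population_specific_svs(freqs_a, freqs_b, fst,
                                       config$selection)
  top <- rank_by_fst(fst, config$selection$min_fst, coords = reps)

  say("hotspot detection")
  hot <- kde_hotspots(reps, p$genome, config$hotspot,
                      seed = derive_seed(config$seed, 13))
  bins <- binned_density(reps, p$genome)

  say("LD scan + phenotype bridge")
  snps <- simulate_linked_snps(sim, p, window = config$ld$window)
  ld_pairs <- ld_scan(gm, snps$snp_gm, config$ld)
  bridge <- phenotype_bridge(ld_pairs, snps$catalog, config$ld)

  say("regulatory overlap")
  anno <- simulate_annotations(sim$truth, p)
  cand_ids <- sel_calls$id[sel_calls$direction != "none"]
  cand <- reps[reps$id %in% cand_ids, ]
  reg <- intersect_elements(
    cand, regulatory_params(pad = config$regulatory_pad,
                            tracks = anno[c("enhancers", "tad_boundaries")]))

  report <- structure(list(
    parameters = list(
      raw_filter = list(min_af_read = 0.3, max_depth_factor = 2),
      merge = unclass(config$merge), selection = unclass(config$selection),
      hotspot = unclass(config$hotspot)[c("bw", "num_trial", "alpha")],
      ld = unclass(config$ld), regulatory_pad = config$regulatory_pad,
      seed = config$seed),
    truth = sim$truth, cohort = sim$cohort,
    n_raw_calls = nrow(calls), n_filtered_calls = nrow(kept),
    n_consensus_calls = nrow(consensus),
    representatives = reps, gm = gm,
    sv_counts_by_type = table(reps$svtype),
    freqs = list(all = freqs_all, pop_a = freqs_a, pop_b = freqs_b),
    spectrum = spectrum, hwe = hwe, fst = fst, powerlaw = pl,
    saturation = sat, selection = sel_calls, top_fst = top,
    hotspots = hot, binned = bins,
    ld_pairs = ld_pairs, bridge = bridge, snp_tags = snps$tags,
    regulatory = reg,
    summary = list(
      n_merged_svs = nrow(reps),
      sv_counts_by_type = as.list(table(reps$svtype)),
      weighted_fst = fst$weighted,
      frac_in_hwe = hwe$frac_in_hwe,
      n_selection_calls = sum(sel_calls$direction != "none"),
      n_fst_above_min = nrow(top),
      n_hotspots = nrow(hot),
      n_strong_ld_svs = dplyr::n_distinct(
        ld_pairs$sv_id[ld_pairs$r2 >= config$ld$strong_cutoff]),
      n_bridged_associations = nrow(bridge),
      spectrum = as.list(spectrum$bins))
  ), class = "pipeline_report")

  if (!is.null(config$output_dir)) {
    write_pipeline_report(report, config$output_dir)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_report>\n")
  cat(sprintf("  merged SVs: %d (%s)\n", s$n_merged_svs,
              paste(sprintf("%s=%d", names(s$sv_counts_by_type),
                            unlist(s$sv_counts_by_type)), collapse = ", ")))
  cat(sprintf("  weighted F_ST: %.4f; in HWE: %.1f%%\n", s$weighted_fst,
              100 * s$frac_in_hwe))
  cat(sprintf("  selection calls: %d; hotspots: %d; bridged associations: %d\n",
              s$n_selection_calls, s$n_hotspots, s$n_bridged_associations))
  invisible(x)
}

write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tab, name) {
    readr::write_tsv(tab, file.path(dir, paste0(name, ".tsv")))
  }
  wr(report$representatives, "merged_svs")
  wr(tidy(report$fst), "fst")
  wr(tidy(report$hwe), "hwe")
  wr(report$selection, "selection_calls")
  wr(report$hotspots, "hotspots")
  wr(report$ld_pairs, "ld_pairs")
  wr(report$bridge, "associations")
  wr(report$regulatory$table, "regulatory_overlap")
  jsonlite::write_json(
    c(report$parameters["seed"],
      list(parameters = report$parameters), report$summary),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
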