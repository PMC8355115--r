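# Pipeline configuration, the end-to-end run over a directory of standard
# files, structured drop logs, and the reproducibility manifest.  The
# command-line entry point (inst/cli/dustgeo.R) is a thin wrapper over
# these functions.

#' Pipeline configuration
#'
#' Bundles the filter, grid, threshold and mixture settings.  The defaults
#' reproduce the published pipeline parameters: cull OTUs with < 3 total
#' reads, absent from any of 3 replicates, or at relative abundance <= 1e-4;
#' assign species at 100% identity; call a grid cell positive at >= 2
#' occurrences; 250-km equal-area cells; positivity at TP >= 90% with
#' AT5PE < 600 km; and a 20-mapped-OTU reporting stratum.
#'
#' @param config_file optional YAML file; keys override the defaults below,
#'   and explicit arguments override the file.
#' @param filter a [filter_config()].
#' @param grid a [grid_spec()].
#' @param th a [thresholds()].
#' @param min_occurrences per-cell positivity threshold (default 2).
#' @param k_max,n_rep mixture settings (see [fit_gmm()]).
#' @param seed integer seed for every stochastic step.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(config_file = NULL, filter = NULL, grid = NULL,
                            th = NULL, min_occurrences = NULL, k_max = NULL,
                            n_rep = NULL, seed = NULL) {
  y <- if (!is.null(config_file)) yaml::read_yaml(config_file) else list()
  pick <- function(arg, key, default) {
    if (!is.null(arg)) arg else if (!is.null(y[[key]])) y[[key]] else default
  }
  fy <- y$filter %||% list()
  gy <- y$grid %||% list()
  ty <- y$thresholds %||% list()
  structure(list(
    filter = filter %||% filter_config(
      min_total_reads = fy$min_total_reads %||% 3L,
      min_replicates_present = fy$min_replicates_present %||% 3L,
      min_rel_abundance = fy$min_rel_abundance %||% 1e-4),
    grid = grid %||% grid_spec(
      cell_km = gy$cell_km %||% 250,
      lon0 = gy$lon0 %||% -98, lat0 = gy$lat0 %||% 39.5,
      width_km = gy$width_km %||% 6000,
      height_km = gy$height_km %||% 4000),
    th = th %||% thresholds(
      tp_cutoff = ty$tp_cutoff %||% 90,
      at5pe_cutoff = ty$at5pe_cutoff %||% 600,
      min_mapped_otus = ty$min_mapped_otus %||% 20L),
    min_occurrences = pick(min_occurrences, "min_occurrences", 2L),
    k_max = pick(k_max, "k_max", 10L),
    n_rep = pick(n_rep, "n_rep", 100L),
    seed = as.integer(pick(seed, "seed", 1L))),
    class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the attribution pipeline over a scenario directory
#'
#' Consumes the standard file layout (as written by [write_scenario()] or
#' assembled from real data): `samples.csv` metadata with truth
#' coordinates, `occurrences.csv`, `reference.fasta`, and per-sample
#' `<id>.tsv`/`<id>.fasta` with optional `<id>_negative_control.*` tables.
#' Each sample is stringency-filtered, control-subtracted, assigned,
#' mapped, and attributed; samples failing upstream (e.g. zero mapped
#' OTUs) appear in the outputs with explicit reasons rather than being
#' dropped, because cohort rates count them in denominators.
#'
#' Writes `results.csv` (one row per sample), `cohort_summary.csv`,
#' per-sample surface GeoJSON, a structured `drop_log.csv` (every OTU
#' culled, with reason), and `manifest.yaml` (config, seed, input
#' checksums).
#'
#' @param dir input directory.
#' @param out_dir output directory (default `file.path(dir, "results")`).
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with `results` (data.frame), `summary`
#'   (cohort data.frame) and `out_dir`.
#' @export
run_pipeline <- function(dir, out_dir = file.path(dir, "results"),
                         cfg = pipeline_config()) {
  meta <- utils::read.csv(file.path(dir, "samples.csv"),
                          stringsAsFactors = FALSE)
  store <- read_occurrences(file.path(dir, "occurrences.csv"))
  reference <- read_reference_fasta(file.path(dir, "reference.fasta"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(); drop_logs <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    tab <- read_otu_table(file.path(dir, paste0(sid, ".tsv")),
                          file.path(dir, paste0(sid, ".fasta")),
                          sample_id = sid)
    ctrl_base <- file.path(dir, paste0(sid, "_negative_control"))
    controls <- if (file.exists(paste0(ctrl_base, ".tsv")))
      list(read_otu_table(paste0(ctrl_base, ".tsv"),
                          paste0(ctrl_base, ".fasta"),
                          sample_id = "negative_control"))
    else list()
    filt <- filter_otus(tab, cfg$filter)
    drop_logs[[sid]] <- cbind(sample_id = sid, stage = "filter",
                              attr(filt, "drop_log"))
    clean <- subtract_controls(filt, controls)
    dl <- attr(clean, "drop_log")
    if (nrow(dl))
      drop_logs[[paste0(sid, "_ctrl")]] <- cbind(sample_id = sid,
                                                 stage = "control", dl)
    res <- attribute_sample(clean, reference, store,
                            truth = c(meta$truth_lon[i], meta$truth_lat[i]),
                            spec = cfg$grid, th = cfg$th, seed = cfg$seed,
                            k_max = cfg$k_max, n_rep = cfg$n_rep)
    if (!is.null(res$surface))
      write_surface(res$surface,
                    geojson_path = file.path(out_dir,
                                             paste0(sid, "_surface.geojson")))
    row <- results_to_df(list(res))
    row$site <- meta$site[i]
    results[[sid]] <- row
  }
  results <- do.call(rbind, results)
  num <- vapply(results, is.numeric, TRUE)
  results[num] <- lapply(results[num], function(v) round(v, 6))
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE, na = "")
  summary <- summarize_cohort(results, cfg$th)
  utils::write.csv(summary, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE, na = "")
  dl <- do.call(rbind, drop_logs)
  utils::write.csv(dl, file.path(out_dir, "drop_log.csv"),
                   row.names = FALSE)
  write_manifest(dir, out_dir, cfg)
  invisible(list(results = results, summary = summary, out_dir = out_dir))
}

write_manifest <- function(dir, out_dir, cfg) {
  inputs <- list.files(dir, pattern = "\\.(tsv|csv|fasta)$",
                       full.names = TRUE)
  sums <- tools::md5sum(inputs)
  cfg_flat <- utils::capture.output(utils::str(cfg, give.attr = FALSE))
  manifest <- list(
    seed = cfg$seed,
    config = list(
      filter = unclass(cfg$filter), grid = unclass(cfg$grid),
      thresholds = unclass(cfg$th),
      min_occurrences = cfg$min_occurrences,
      k_max = cfg$k_max, n_rep = cfg$n_rep),
    config_hash = substr(tools::md5sum(
      write_temp(paste(cfg_flat, collapse = "\n"))), 1, 32)[[1]],
    inputs = as.list(stats::setNames(unname(sums), basename(inputs))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

write_temp <- function(text) {
  f <- tempfile(fileext = ".txt")
  writeLines(text, f)
  f
}
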