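# Deterministic synthetic-data generator: species pools with localized
# (Gaussian-range) and cosmopolitan species, occurrence stores, barcode
# reference FASTAs, and per-sample OTU tables with known truth coordinates.
# Emits exactly the file formats the pipeline consumes, so synthetic runs
# exercise the real I/O path.

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe a spring-like collection at a Massachusetts-like site:
#' a regional flora of 80 species (a quarter cosmopolitan), log-normal
#' occurrence-record counts, ~40 OTUs per sample with negative-binomial
#' replicate read counts, and a small contamination rate.  The `season`
#' presets scale OTU yield and the share of cosmopolitan signal the way
#' winter dust differs from spring dust (far fewer airborne plant
#' particles, and what remains is less locally informative).
#'
#' @param seed integer seed (mandatory; every generator is deterministic in
#'   it).
#' @param season `"spring"` or `"winter"`; sets `season_factor` and
#'   `local_preference` defaults.
#' @param n_species number of species in the pool.
#' @param frac_cosmopolitan fraction of pool species with extent-wide
#'   uniform ranges.
#' @param range_sigma_km isotropic Gaussian range spread of localized
#'   species (km).
#' @param center_scatter_km spread of localized species' range centers
#'   around the truth site (km).
#' @param records_meanlog,records_sdlog log-normal parameters of per-species
#'   occurrence-record counts.
#' @param flag_rate fraction of occurrence records carrying a provider QC
#'   flag.
#' @param truth_site `c(lon, lat)` of the collection site.
#' @param site name of the collection site.
#' @param n_otus_per_sample nominal spring OTU yield per sample.
#' @param season_factor multiplier on OTU yield (spring 1.0, winter 0.2).
#' @param local_preference probability that a sampled OTU is drawn from the
#'   range-density-at-truth weights rather than uniformly from the pool
#'   (spring 0.9, winter 0.5).
#' @param read_mu,read_size negative-binomial mean and dispersion of
#'   per-replicate read counts.
#' @param n_junk_otus below-threshold OTUs injected per sample so filters
#'   have work to do.
#' @param contamination_rate per-OTU probability of injecting a
#'   control-contaminant OTU alongside the sample.
#' @param n_replicates sequencing replicates per sample.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            season = c("spring", "winter"),
                            n_species = 80L,
                            frac_cosmopolitan = NULL,
                            range_sigma_km = 500,
                            center_scatter_km = 500,
                            records_meanlog = log(300),
                            records_sdlog = 0.5,
                            flag_rate = 0.05,
                            truth_site = c(-71.1, 42.4),
                            site = "SITE1",
                            n_otus_per_sample = 40L,
                            season_factor = NULL,
                            local_preference = NULL,
                            read_mu = 50, read_size = 5,
                            n_junk_otus = 3L,
                            contamination_rate = 0.05,
                            n_replicates = 3L) {
  if (missing(seed)) stop("seed is mandatory")
  season <- match.arg(season)
  if (is.null(season_factor))
    season_factor <- if (season == "winter") 0.2 else 1.0
  if (is.null(local_preference))
    local_preference <- if (season == "winter") 0.5 else 0.9
  if (is.null(frac_cosmopolitan))
    frac_cosmopolitan <- if (season == "winter") 0.5 else 0.25
  stopifnot(n_species > 0, n_otus_per_sample > 0, season_factor > 0,
            frac_cosmopolitan >= 0, frac_cosmopolitan <= 1)
  structure(list(seed = as.integer(seed), season = season,
                 n_species = as.integer(n_species),
                 frac_cosmopolitan = frac_cosmopolitan,
                 range_sigma_km = range_sigma_km,
                 center_scatter_km = center_scatter_km,
                 records_meanlog = records_meanlog,
                 records_sdlog = records_sdlog,
                 flag_rate = flag_rate,
                 truth_site = truth_site, site = site,
                 n_otus_per_sample = as.integer(n_otus_per_sample),
                 season_factor = season_factor,
                 local_preference = local_preference,
                 read_mu = read_mu, read_size = read_size,
                 n_junk_otus = as.integer(n_junk_otus),
                 contamination_rate = contamination_rate,
                 n_replicates = as.integer(n_replicates)),
            class = "scenario_config")
}

SEQ_LEN <- c(ITS2 = 350L, RBCL3A = 250L)

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_binomial_name <- function() {
  syl <- c("ba", "ca", "da", "fe", "go", "hi", "lo", "mi", "nu", "pe",
           "ra", "si", "ta", "ve", "xo", "zu")
  genus <- paste(sample(syl, 3, replace = TRUE), collapse = "")
  epithet <- paste(sample(syl, 3, replace = TRUE), collapse = "")
  paste(paste0(toupper(substr(genus, 1, 1)), substr(genus, 2, 99)), epithet)
}

#' Generate a synthetic species pool
#'
#' Localized species get range centers scattered (Gaussian,
#' `center_scatter_km`) around the truth site; the configured fraction are
#' cosmopolitan (uniform over the grid extent).  Each species carries one
#' unique DNA sequence per marker, so 100%-identity assignment is
#' unambiguous.  Deterministic in the seed.
#'
#' @param cfg a [scenario_config()].
#' @param spec a [grid_spec()] fixing the extent cosmopolitan species span.
#' @return data.frame, one row per species: `name`, `tsn`, `cosmopolitan`,
#'   `center_x`, `center_y` (km, LAEA plane), `sigma_km`, `n_records`,
#'   `seq_ITS2`, `seq_RBCL3A`.
#' @export
gen_species_pool <- function(cfg, spec = grid_spec()) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_species
  n_cosmo <- round(n * cfg$frac_cosmopolitan)
  cosmo <- c(rep(TRUE, n_cosmo), rep(FALSE, n - n_cosmo))
  names_u <- character(0)
  while (length(names_u) < n)
    names_u <- unique(c(names_u, random_binomial_name()))
  names_u <- names_u[seq_len(n)]
  txy <- project_laea(cfg$truth_site[1], cfg$truth_site[2], spec)
  pool <- data.frame(
    name = names_u, tsn = seq_len(n) + 1000L, cosmopolitan = cosmo,
    center_x = txy$x_km + stats::rnorm(n, 0, cfg$center_scatter_km),
    center_y = txy$y_km + stats::rnorm(n, 0, cfg$center_scatter_km),
    sigma_km = cfg$range_sigma_km,
    n_records = pmax(2L, as.integer(round(stats::rlnorm(
      n, cfg$records_meanlog, cfg$records_sdlog)))),
    stringsAsFactors = FALSE)
  for (mk in names(SEQ_LEN)) {
    seqs <- character(0)
    while (length(seqs) < n)
      seqs <- unique(c(seqs, random_dna(SEQ_LEN[[mk]])))
    pool[[paste0("seq_", mk)]] <- seqs[seq_len(n)]
  }
  pool
}

#' Generate a synthetic occurrence store
#'
#' Samples each species' occurrence records from its range model (isotropic
#' Gaussian in the equal-area plane for localized species, uniform over the
#' extent for cosmopolitan ones), flags a configured fraction to exercise
#' QC, and returns an [occurrence_store()].  Deterministic in the seed.
#'
#' @param pool species pool from [gen_species_pool()].
#' @param cfg a [scenario_config()].
#' @param spec a [grid_spec()].
#' @param path optional CSV path; when given, records are written in
#'   Darwin-Core-style columns and re-read through [read_occurrences()], so
#'   the standard I/O path is exercised.
#' @return an `occurrence_store`.
#' @export
gen_occurrence_store <- function(pool, cfg, spec = grid_spec(),
                                 path = NULL) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  recs <- lapply(seq_len(nrow(pool)), function(i) {
    m <- pool$n_records[i]
    if (pool$cosmopolitan[i]) {
      x <- stats::runif(m, spec$x0, spec$x0 + spec$ncol * spec$cell_km)
      y <- stats::runif(m, spec$y0, spec$y0 + spec$nrow * spec$cell_km)
    } else {
      x <- stats::rnorm(m, pool$center_x[i], pool$sigma_km[i])
      y <- stats::rnorm(m, pool$center_y[i], pool$sigma_km[i])
    }
    ll <- inverse_laea(x, y, spec)
    data.frame(species = pool$name[i], tsn = pool$tsn[i],
               lat = ll$lat, lon = ll$lon,
               flagged = stats::runif(m) < cfg$flag_rate,
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    recs <- data.frame(species = character(0), tsn = integer(0),
                       lat = numeric(0), lon = numeric(0),
                       flagged = logical(0))
  if (!is.null(path)) {
    utils::write.csv(
      data.frame(scientificName = recs$species, TSN = recs$tsn,
                 decimalLatitude = recs$lat, decimalLongitude = recs$lon,
                 flags = recs$flagged),
      path, row.names = FALSE)
    return(read_occurrences(path))
  }
  occurrence_store(recs)
}

#' Write the species pool as a barcode reference FASTA
#'
#' @param pool species pool from [gen_species_pool()].
#' @param path FASTA output path.
#' @return invisibly, the path.
#' @export
write_reference_fasta <- function(pool, path) {
  headers <- c(paste0("ACC", sprintf("%04d", seq_len(nrow(pool))),
                      "|ITS2|", pool$name),
               paste0("ACC", sprintf("%04d", seq_len(nrow(pool)) +
                                       nrow(pool)),
                      "|RBCL3A|", pool$name))
  seqs <- Biostrings::DNAStringSet(c(pool$seq_ITS2, pool$seq_RBCL3A))
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

gaussian_density_at <- function(pool, x, y, spec) {
  area <- (spec$ncol * spec$cell_km) * (spec$nrow * spec$cell_km)
  d2 <- (pool$center_x - x)^2 + (pool$center_y - y)^2
  dens <- exp(-d2 / (2 * pool$sigma_km^2)) / (2 * pi * pool$sigma_km^2)
  dens[pool$cosmopolitan] <- 1 / area
  dens
}

#' Generate one synthetic dust sample
#'
#' Draws OTUs preferentially from species whose range density at the truth
#' site is high (with probability `local_preference`; otherwise uniformly
#' from the pool), assigns each a marker and the species' unique sequence,
#' and simulates negative-binomial replicate read counts.  Below-threshold
#' junk OTUs and control-contaminant OTUs are injected so the stringency
#' filter and control subtraction have work to do.  Deterministic in
#' `cfg$seed + sample_index`.
#'
#' @param pool species pool from [gen_species_pool()].
#' @param cfg a [scenario_config()].
#' @param spec a [grid_spec()].
#' @param sample_index integer >= 1 distinguishing samples of one scenario.
#' @return list with `table` (the raw [sample_table()]), `controls` (list
#'   of control `sample_table`s sharing the contaminant sequences), `truth`
#'   (`c(lon, lat)`), `site`, and `species_drawn`.
#' @export
gen_sample <- function(pool, cfg, spec = grid_spec(), sample_index = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(cfg$seed + 1000L + as.integer(sample_index))
  txy <- project_laea(cfg$truth_site[1], cfg$truth_site[2], spec)
  dens <- gaussian_density_at(pool, txy$x_km, txy$y_km, spec)
  w_local <- dens / sum(dens)
  n_otus <- max(1L, as.integer(round(cfg$n_otus_per_sample *
                                       cfg$season_factor)))
  n_otus <- min(n_otus, nrow(pool))
  use_local <- stats::runif(n_otus) < cfg$local_preference
  chosen <- integer(0)
  for (i in seq_len(n_otus)) {
    avail <- setdiff(seq_len(nrow(pool)), chosen)
    # informative draws follow range density at the truth site; the rest
    # model uninformative (long-distance / resuspended) material and come
    # from the cosmopolitan part of the pool
    cosmo_avail <- avail[pool$cosmopolitan[avail]]
    if (use_local[i] || !length(cosmo_avail)) {
      w <- w_local[avail]
      if (sum(w) <= 0) w <- rep(1, length(avail))
      chosen <- c(chosen, avail[sample.int(length(avail), 1L, prob = w)])
    } else {
      chosen <- c(chosen,
                  cosmo_avail[sample.int(length(cosmo_avail), 1L)])
    }
  }
  markers <- sample(MARKERS, n_otus, replace = TRUE)
  reads <- matrix(stats::rnbinom(n_otus * cfg$n_replicates,
                                 mu = cfg$read_mu, size = cfg$read_size),
                  n_otus, cfg$n_replicates)
  otus <- data.frame(
    otu_id = sprintf("OTU%03d", seq_len(n_otus)),
    marker = markers,
    stringsAsFactors = FALSE)
  for (j in seq_len(cfg$n_replicates)) otus[[paste0("rep", j)]] <- reads[, j]
  otus$sequence <- ifelse(markers == "ITS2",
                          pool$seq_ITS2[chosen], pool$seq_RBCL3A[chosen])

  # junk OTUs that the stringency filter must cull
  if (cfg$n_junk_otus > 0) {
    junk_reads <- list(c(1L, 0L, 0L), c(1L, 1L, 0L), c(2L, 0L, 0L))
    for (i in seq_len(cfg$n_junk_otus)) {
      jr <- junk_reads[[(i - 1L) %% length(junk_reads) + 1L]]
      row <- data.frame(otu_id = sprintf("JUNK%02d", i),
                        marker = sample(MARKERS, 1),
                        stringsAsFactors = FALSE)
      for (j in seq_len(cfg$n_replicates))
        row[[paste0("rep", j)]] <- jr[(j - 1L) %% 3L + 1L]
      row$sequence <- random_dna(60L)
      otus <- rbind(otus, row)
    }
  }

  # contaminants shared verbatim with the negative control / PCR blank
  n_contam <- stats::rbinom(1, n_otus, cfg$contamination_rate)
  ctrl_rows <- NULL
  if (n_contam > 0) {
    for (i in seq_len(n_contam)) {
      seq_c <- random_dna(80L)
      row <- data.frame(otu_id = sprintf("CONT%02d", i),
                        marker = sample(MARKERS, 1),
                        stringsAsFactors = FALSE)
      for (j in seq_len(cfg$n_replicates))
        row[[paste0("rep", j)]] <- stats::rnbinom(1, mu = cfg$read_mu,
                                                  size = cfg$read_size) + 3L
      row$sequence <- seq_c
      otus <- rbind(otus, row)
      crow <- row
      crow$otu_id <- sprintf("CTRLOTU%02d", i)
      for (j in seq_len(cfg$n_replicates))
        crow[[paste0("rep", j)]] <- sample(1:5, 1)
      ctrl_rows <- rbind(ctrl_rows, crow)
    }
  }
  controls <- if (is.null(ctrl_rows)) list() else
    list(sample_table("negative_control", ctrl_rows, cfg$n_replicates))
  sample_id <- sprintf("%s_%s_S%02d", cfg$site, cfg$season, sample_index)
  list(table = sample_table(sample_id, otus, cfg$n_replicates),
       controls = controls,
       truth = cfg$truth_site, site = cfg$site,
       species_drawn = pool$name[chosen])
}

#' Write a full synthetic scenario to disk
#'
#' Emits the standard files the pipeline consumes: per-sample OTU TSV +
#' representative-sequence FASTA (plus control tables), the reference
#' FASTA, the occurrence CSV, and a sample-metadata CSV with truth
#' coordinates.
#'
#' @param cfg a [scenario_config()].
#' @param dir output directory (created if needed).
#' @param n_samples number of samples to generate.
#' @param spec a [grid_spec()].
#' @return invisibly, a list with the metadata data.frame and file paths.
#' @export
write_scenario <- function(cfg, dir, n_samples = 1L, spec = grid_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pool <- gen_species_pool(cfg, spec)
  occ_path <- file.path(dir, "occurrences.csv")
  gen_occurrence_store(pool, cfg, spec, path = occ_path)
  ref_path <- file.path(dir, "reference.fasta")
  write_reference_fasta(pool, ref_path)
  meta <- NULL
  for (s in seq_len(n_samples)) {
    gs <- gen_sample(pool, cfg, spec, sample_index = s)
    tab <- gs$table
    write_sample_files(tab, dir)
    for (ct in gs$controls)
      write_sample_files(ct, dir, prefix = paste0(tab$sample_id, "_"))
    meta <- rbind(meta, data.frame(sample_id = tab$sample_id,
                                   site = gs$site,
                                   truth_lon = gs$truth[1],
                                   truth_lat = gs$truth[2],
                                   n_controls = length(gs$controls)))
  }
  meta_path <- file.path(dir, "samples.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(list(metadata = meta, occurrences = occ_path,
                 reference = ref_path, metadata_path = meta_path))
}

write_sample_files <- function(tab, dir, prefix = "") {
  base <- file.path(dir, paste0(prefix, tab$sample_id))
  df <- tab$otus[, c("otu_id", "marker", rep_cols(tab))]
  utils::write.table(df, paste0(base, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  seqs <- Biostrings::DNAStringSet(tab$otus$sequence)
  names(seqs) <- tab$otus$otu_id
  Biostrings::writeXStringSet(seqs, paste0(base, ".fasta"), width = 80L)
  invisible(base)
}
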