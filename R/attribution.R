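# Attribution metrics: Dirichlet-process GMM over the point-to-grid
# surface, top-5 density peaks, truth percentage (accuracy), average top-5
# peaks error (resolution), the positivity decision, and cohort summaries.

EARTH_R_KM <- 6371.0

#' Attribution decision thresholds
#'
#' @param tp_cutoff truth-percentage cutoff (default 90); a sample passes
#'   accuracy when TP >= this value.
#' @param at5pe_cutoff resolution cutoff in km (default 600); a sample
#'   passes resolution when AT5PE is strictly below it.
#' @param min_mapped_otus reporting stratum floor (default 20): cohort
#'   summaries also report the subset of samples with at least this many
#'   mapped OTUs.
#' @return an object of class `thresholds`.
#' @export
thresholds <- function(tp_cutoff = 90, at5pe_cutoff = 600,
                       min_mapped_otus = 20L) {
  stopifnot(tp_cutoff > 0, at5pe_cutoff > 0, min_mapped_otus > 0)
  structure(list(tp_cutoff = tp_cutoff, at5pe_cutoff = at5pe_cutoff,
                 min_mapped_otus = as.integer(min_mapped_otus)),
            class = "thresholds")
}

#' Fit the attribution mixture to a point-to-grid surface
#'
#' Each nonzero cell contributes its planar centroid, replicated
#' `round(fraction * n_rep)` times (at least once), so cells holding larger
#' fractions of the sample's mapped OTUs carry proportionally more weight.
#' A variational Gaussian mixture with Dirichlet-process prior and at most
#' `k_max` components is then fitted with a fixed seed; components whose
#' weight falls below `1e-3` are flagged pruned.
#'
#' @param surface a `grid_surface` with at least one nonzero cell.
#' @param seed integer seed.
#' @param k_max component cap (default 10).
#' @param n_rep replication factor for cell weights (default 100).
#' @return object of class `gmm_fit`: the [vb_dpgmm()] result plus `pruned`
#'   (logical per component), `k_max`, `seed`.
#' @export
fit_gmm <- function(surface, seed = 1L, k_max = 10L, n_rep = 100L) {
  stopifnot(inherits(surface, "grid_surface"))
  df <- surface_to_df(surface, drop_zero = TRUE)
  if (!nrow(df)) stop("empty surface")
  spec <- surface$spec
  reps <- pmax(1L, as.integer(round(df$fraction * n_rep)))
  x <- spec$x0 + (df$col + 0.5) * spec$cell_km
  y <- spec$y0 + (df$row + 0.5) * spec$cell_km
  X <- cbind(x_km = rep(x, reps), y_km = rep(y, reps))
  fit <- vb_dpgmm(X, k_max = k_max, seed = seed)
  fit$pruned <- fit$weights < 1e-3
  fit$k_max <- as.integer(k_max)
  fit$seed <- as.integer(seed)
  class(fit) <- "gmm_fit"
  fit
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> %d/%d effective components, converged: %s\n",
              sum(!x$pruned), length(x$weights), x$converged))
  invisible(x)
}

#' Top-5 peaks of the attribution surface
#'
#' The fitted mixture density is evaluated at every grid-cell centroid and
#' the five cells with the highest density are returned (ties broken by
#' (row, col) order) — the map grids with highest likelihood.  Two
#' alternative selection modes are available: `"local_max"` restricts
#' candidates to cells that are local maxima over their 8-neighborhood
#' (filling remaining slots with the highest-density non-candidate cells
#' when fewer than five local maxima exist), and `"raw"` ranks the raw
#' overlay fractions instead of the mixture density.
#'
#' @param fit a `gmm_fit`.
#' @param surface the `grid_surface` the fit came from.
#' @param mode `"density"` (default), `"local_max"`, or `"raw"`.
#' @return data.frame of 5 rows: `row`, `col`, `lon`, `lat`, `density`.
#' @export
top5_peaks <- function(fit, surface,
                       mode = c("density", "local_max", "raw")) {
  mode <- match.arg(mode)
  spec <- surface$spec
  if (mode == "raw") {
    rank_mat <- dens_mat <- surface$values
  } else {
    grid <- expand.grid(row = 0:(spec$nrow - 1), col = 0:(spec$ncol - 1))
    X <- cbind(spec$x0 + (grid$col + 0.5) * spec$cell_km,
               spec$y0 + (grid$row + 0.5) * spec$cell_km)
    # rank in log space: far from every component the density underflows
    # to zero, which would turn genuine ordering into spurious ties
    rank_mat <- matrix(dpgmm_density(fit, X, log = TRUE),
                       spec$nrow, spec$ncol)
    dens_mat <- exp(rank_mat)
  }
  peaks_from_density(rank_mat, spec, n_peaks = 5L,
                     candidates_first = (mode == "local_max"),
                     report = dens_mat)
}

peaks_from_density <- function(dens, spec, n_peaks = 5L,
                               candidates_first = FALSE, report = dens) {
  nr <- nrow(dens); nc <- ncol(dens)
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs, cs] <- dens[rs - dr, cs - dc]
    is_max <- is_max & (dens >= shifted)
  }
  ord_df <- data.frame(row = as.vector(row(dens)) - 1L,
                       col = as.vector(col(dens)) - 1L,
                       rank_val = as.vector(dens),
                       density = as.vector(report),
                       candidate = as.vector(is_max))
  ord_df <- ord_df[order(-ord_df$rank_val, ord_df$row, ord_df$col), ]
  if (candidates_first) {
    sel <- ord_df[ord_df$candidate, , drop = FALSE]
    if (nrow(sel) < n_peaks)
      sel <- rbind(sel, ord_df[!ord_df$candidate, , drop = FALSE])
  } else {
    sel <- ord_df
  }
  sel <- sel[seq_len(n_peaks), , drop = FALSE]
  cen <- cell_centroid(sel$row, sel$col, spec)
  out <- data.frame(row = sel$row, col = sel$col,
                    lon = cen$lon, lat = cen$lat, density = sel$density)
  rownames(out) <- NULL
  out
}

#' Truth percentage (attribution accuracy)
#'
#' The percentage of grid cells in the extent whose surface value is
#' strictly less than the value of the cell containing the true collection
#' site.  Cells never touched by any OTU count as zero; the denominator is
#' every cell of the configured extent.  Ranges over [0, 100]; a uniform
#' surface scores 0.
#'
#' @param surface a `grid_surface`.
#' @param truth `c(lon, lat)` of the true collection site; must fall inside
#'   the grid extent.
#' @return percentage in [0, 100].
#' @export
truth_percentage <- function(surface, truth) {
  spec <- surface$spec
  xy <- project_laea(truth[1], truth[2], spec)
  cell <- cell_of(xy$x_km, xy$y_km, spec)
  if (is.na(cell$row)) stop("truth location is off-grid")
  tv <- surface$values[cell$row + 1L, cell$col + 1L]
  100 * sum(surface$values < tv) / (spec$nrow * spec$ncol)
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param a,b `c(lon, lat)` in degrees, or two-column matrices.
#' @return distance(s) in km.
#' @export
haversine_km <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2); b <- matrix(as.numeric(b), ncol = 2)
  lam1 <- a[, 1] * pi / 180; phi1 <- a[, 2] * pi / 180
  lam2 <- b[, 1] * pi / 180; phi2 <- b[, 2] * pi / 180
  h <- sin((phi2 - phi1) / 2)^2 +
    cos(phi1) * cos(phi2) * sin((lam2 - lam1) / 2)^2
  2 * EARTH_R_KM * asin(pmin(1, sqrt(h)))
}

#' Average top-5 peaks error (attribution resolution)
#'
#' Arithmetic mean of the great-circle distances from the true collection
#' site to each of the five density peaks.
#'
#' @param peaks data.frame of exactly 5 peaks with `lon`, `lat` columns
#'   (as returned by [top5_peaks()]).
#' @param truth `c(lon, lat)` of the true site.
#' @return mean distance in km.
#' @export
at5pe <- function(peaks, truth) {
  if (nrow(peaks) != 5) stop("exactly 5 peaks required")
  mean(haversine_km(as.matrix(peaks[, c("lon", "lat")]),
                    matrix(truth, 5, 2, byrow = TRUE)))
}

#' Positivity decision for one sample
#'
#' A true positive regional attribution requires both accuracy and
#' resolution: TP at or above the cutoff and AT5PE strictly below it.
#'
#' @param tp truth percentage.
#' @param at5pe average top-5 peaks error in km.
#' @param th a [thresholds()] object.
#' @return logical.
#' @export
classify_attribution <- function(tp, at5pe, th = thresholds()) {
  tp >= th$tp_cutoff & at5pe < th$at5pe_cutoff
}

#' Attribute one sample end to end
#'
#' Runs species assignment, dedup, per-OTU occurrence gridding, overlay,
#' mixture fitting, and the TP/AT5PE metrics for one filtered sample table.
#' A sample with zero mapped OTUs is returned unattributable (`positive =
#' FALSE`, `reason = "no mapped OTUs"`) rather than erroring, because cohort
#' rates count such samples in their denominators.
#'
#' @param table filtered, control-subtracted [sample_table()].
#' @param reference barcode reference data.frame
#'   ([read_reference_fasta()]).
#' @param store an `occurrence_store`.
#' @param truth `c(lon, lat)` of the true collection site.
#' @param spec a [grid_spec()].
#' @param th a [thresholds()].
#' @param seed integer seed (mixture init and over-cap subsampling).
#' @param synonyms optional synonym map.
#' @param k_max,n_rep mixture settings (see [fit_gmm()]).
#' @return list of class `attribution_result`: `sample_id`,
#'   `n_mapped_otus`, `tp`, `at5pe`, `peaks`, `positive`, `reason`,
#'   `surface` (or `NULL`).
#' @export
attribute_sample <- function(table, reference, store, truth,
                             spec = grid_spec(), th = thresholds(),
                             seed = 1L, synonyms = NULL,
                             k_max = 10L, n_rep = 100L) {
  assignments <- dedupe_species(assign_sample(table, reference, synonyms),
                                table)
  dists <- lapply(assignments, function(a)
    otu_distribution(a$species, store, spec, seed = seed,
                     otu_id = a$otu_id))
  dists <- Filter(function(d) nrow(d$positive_cells) > 0, dists)
  if (!length(dists)) {
    return(structure(list(sample_id = table$sample_id, n_mapped_otus = 0L,
                          tp = NA_real_, at5pe = NA_real_, peaks = NULL,
                          positive = FALSE, reason = "no mapped OTUs",
                          surface = NULL),
                     class = "attribution_result"))
  }
  surface <- overlay(dists, spec)
  fit <- fit_gmm(surface, seed = seed, k_max = k_max, n_rep = n_rep)
  peaks <- top5_peaks(fit, surface)
  tp <- truth_percentage(surface, truth)
  err <- at5pe(peaks, truth)
  structure(list(sample_id = table$sample_id,
                 n_mapped_otus = surface$n_otus,
                 tp = tp, at5pe = err, peaks = peaks,
                 positive = classify_attribution(tp, err, th),
                 reason = NA_character_, surface = surface),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  if (x$n_mapped_otus == 0) {
    cat(sprintf("<attribution_result> %s: unattributable (%s)\n",
                x$sample_id, x$reason))
  } else {
    cat(sprintf(
      "<attribution_result> %s: %d mapped OTUs, TP %.1f%%, AT5PE %.0f km, %s\n",
      x$sample_id, x$n_mapped_otus, x$tp, x$at5pe,
      if (x$positive) "POSITIVE" else "negative"))
  }
  invisible(x)
}

#' Flatten attribution results to a data.frame
#'
#' @param results list of `attribution_result` objects (or a data.frame
#'   already in flat form, returned unchanged).
#' @return data.frame with one row per sample: `sample_id`, `site` (if
#'   present), `n_mapped_otus`, `tp`, `at5pe`, peak coordinates, `positive`.
#' @export
results_to_df <- function(results) {
  if (is.data.frame(results)) return(results)
  do.call(rbind, lapply(results, function(r) {
    pk <- r$peaks
    row <- data.frame(sample_id = r$sample_id,
                      n_mapped_otus = r$n_mapped_otus,
                      tp = r$tp, at5pe = r$at5pe, positive = r$positive,
                      reason = r$reason, stringsAsFactors = FALSE)
    for (i in 1:5) {
      row[[paste0("peak", i, "_lon")]] <-
        if (!is.null(pk)) pk$lon[i] else NA_real_
      row[[paste0("peak", i, "_lat")]] <-
        if (!is.null(pk)) pk$lat[i] else NA_real_
    }
    row
  }))
}

#' Cohort summary of attribution results
#'
#' Per-site and overall counts of samples, TP-passing samples, AT5PE-passing
#' samples and true positives, together with the same counts restricted to
#' samples with at least `min_mapped_otus` mapped OTUs, and positive rates
#' as percentages reported to one decimal.
#'
#' @param results data.frame with columns `sample_id`, `site`,
#'   `n_mapped_otus`, `tp`, `at5pe` (a list of `attribution_result`s is
#'   flattened first; missing `site` becomes `"all"`).
#' @param th a [thresholds()].
#' @return data.frame, one row per site plus an `all sites` row, columns
#'   `site`, `n`, `tp_pass`, `at5pe_pass`, `positive`, `pct_positive`,
#'   `n_ge`, `tp_pass_ge`, `at5pe_pass_ge`, `positive_ge`,
#'   `pct_positive_ge` (the `_ge` block is the >= min_mapped_otus stratum).
#' @export
summarize_cohort <- function(results, th = thresholds()) {
  df <- results_to_df(results)
  if (!nrow(df)) {
    return(data.frame(site = "all sites", n = 0L, tp_pass = 0L,
                      at5pe_pass = 0L, positive = 0L, pct_positive = NA_real_,
                      n_ge = 0L, tp_pass_ge = 0L, at5pe_pass_ge = 0L,
                      positive_ge = 0L, pct_positive_ge = NA_real_))
  }
  if (!"site" %in% names(df)) df$site <- "all"
  df$tp_pass <- !is.na(df$tp) & df$tp >= th$tp_cutoff
  df$at5pe_pass <- !is.na(df$at5pe) & df$at5pe < th$at5pe_cutoff
  df$pos <- df$tp_pass & df$at5pe_pass
  df$ge <- df$n_mapped_otus >= th$min_mapped_otus
  one <- function(sub, label) {
    g <- sub[sub$ge, , drop = FALSE]
    data.frame(site = label, n = nrow(sub),
               tp_pass = sum(sub$tp_pass), at5pe_pass = sum(sub$at5pe_pass),
               positive = sum(sub$pos),
               pct_positive = if (nrow(sub)) round(100 * sum(sub$pos) /
                                                     nrow(sub), 1)
                              else NA_real_,
               n_ge = nrow(g), tp_pass_ge = sum(g$tp_pass),
               at5pe_pass_ge = sum(g$at5pe_pass), positive_ge = sum(g$pos),
               pct_positive_ge = if (nrow(g)) round(100 * sum(g$pos) /
                                                      nrow(g), 1)
                                 else NA_real_,
               stringsAsFactors = FALSE)
  }
  sites <- sort(unique(df$site))
  out <- do.call(rbind, lapply(sites, function(s)
    one(df[df$site == s, , drop = FALSE], s)))
  rbind(out, one(df, "all sites"))
}
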