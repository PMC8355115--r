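MARKERS <- c("ITS2", "RBCL3A")

norm_marker <- function(x) {
  m <- toupper(gsub("[^A-Za-z0-9]", "", x))
  m[m %in% c("RBCL3A", "RBCL")] <- "RBCL3A"
  m[!(m %in% MARKERS)] <- NA_character_
  m
}

#' Stringency-filter configuration
#'
#' Thresholds for culling low-confidence OTUs from a sample table: a minimum
#' total read count summed over sequencing replicates, a minimum number of
#' replicates in which the OTU must be detected, and a minimum relative
#' abundance against the pre-filter sample total.
#'
#' @param min_total_reads minimum total reads over all replicates (default 3;
#'   an OTU with fewer is culled).
#' @param min_replicates_present minimum number of replicates with at least
#'   one read (default 3, i.e. present in 3 of 3 replicates).
#' @param min_rel_abundance relative-abundance floor (default `1e-4`); OTUs
#'   at or below this fraction of the pre-filter sample total are culled.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_total_reads = 3L,
                          min_replicates_present = 3L,
                          min_rel_abundance = 1e-4) {
  stopifnot(min_total_reads > 0, min_replicates_present > 0,
            min_rel_abundance > 0)
  structure(list(min_total_reads = as.integer(min_total_reads),
                 min_replicates_present = as.integer(min_replicates_present),
                 min_rel_abundance = min_rel_abundance),
            class = "filter_config")
}

#' Construct a per-sample OTU table
#'
#' @param sample_id sample identifier.
#' @param otus data.frame with columns `otu_id`, `marker`, replicate read
#'   columns `rep1..repN`, and `sequence` (may be `NA` before sequences are
#'   attached).
#' @param n_replicates number of sequencing replicates (default 3).
#' @return an object of class `sample_table` with the pre-filter read total
#'   recorded in `total_reads` (used as the relative-abundance denominator
#'   even after filtering, which makes the filter idempotent).
#' @export
sample_table <- function(sample_id, otus, n_replicates = 3L) {
  rep_cols <- paste0("rep", seq_len(n_replicates))
  stopifnot(is.data.frame(otus),
            all(c("otu_id", "marker", rep_cols) %in% names(otus)))
  if (!"sequence" %in% names(otus)) otus$sequence <- NA_character_
  otus <- otus[, c("otu_id", "marker", rep_cols, "sequence")]
  otus$otu_id <- as.character(otus$otu_id)
  for (rc in rep_cols) {
    v <- otus[[rc]]
    if (any(v < 0 | v != floor(v), na.rm = TRUE))
      stop("read counts must be non-negative integers")
    otus[[rc]] <- as.integer(v)
  }
  key <- paste(otus$marker, otus$otu_id)
  if (anyDuplicated(key))
    stop("duplicate otu_id within a marker: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  rownames(otus) <- NULL
  structure(list(sample_id = sample_id,
                 otus = otus,
                 n_replicates = as.integer(n_replicates),
                 total_reads = sum(as.matrix(otus[, rep_cols, drop = FALSE]))),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %s: %d OTUs, %d replicates, %d total reads\n",
              x$sample_id, nrow(x$otus), x$n_replicates, x$total_reads))
  invisible(x)
}

rep_cols <- function(tab) paste0("rep", seq_len(tab$n_replicates))

read_matrix <- function(tab) {
  as.matrix(tab$otus[, rep_cols(tab), drop = FALSE])
}

#' Read a per-sample OTU table with representative sequences
#'
#' Reads a TSV/CSV OTU table (`otu_id`, `marker`, `rep1..repN`) as produced
#' by upstream read processing, and attaches the representative sequence of
#' each OTU from a FASTA file keyed by `otu_id`.  Rows whose marker is not a
#' recognized plant minibarcode (ITS2 or rbcL-3A) are rejected and reported
#' via the `rejected` attribute.
#'
#' @param path path to the OTU table (tab- or comma-separated, with header).
#' @param fasta_path path to a FASTA of representative sequences whose ids
#'   match `otu_id`.
#' @param sample_id sample identifier; defaults to the table's base filename.
#' @param n_replicates number of replicate read columns expected.
#' @return a [sample_table()]; attribute `rejected` holds rejected rows.
#' @export
read_otu_table <- function(path, fasta_path, sample_id = NULL,
                           n_replicates = 3L) {
  if (!file.exists(path)) stop("OTU table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  rc <- paste0("rep", seq_len(n_replicates))
  missing_cols <- setdiff(c("otu_id", "marker", rc), names(df))
  if (length(missing_cols))
    stop("OTU table missing columns: ", paste(missing_cols, collapse = ", "))
  df$marker <- norm_marker(df$marker)
  rejected <- df[is.na(df$marker), , drop = FALSE]
  df <- df[!is.na(df$marker), , drop = FALSE]
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  absent <- setdiff(df$otu_id, ids)
  if (length(absent))
    stop("FASTA id absent for OTUs: ", paste(absent, collapse = ", "))
  df$sequence <- toupper(as.character(seqs[match(df$otu_id, ids)]))
  if (is.null(sample_id))
    sample_id <- sub("\\.(tsv|csv|txt)$", "", basename(path),
                     ignore.case = TRUE)
  out <- sample_table(sample_id, df, n_replicates)
  attr(out, "rejected") <- rejected
  out
}

#' Cull low-confidence OTUs from a sample table
#'
#' Retains exactly the OTUs that satisfy all three stringency rules: total
#' reads over replicates at least `min_total_reads`, detected in at least
#' `min_replicates_present` replicates, and relative abundance (total reads
#' divided by the sample's pre-filter read total) strictly greater than
#' `min_rel_abundance`.  The denominator is always the pre-filter total
#' recorded in the table, so the filter is a single pass and idempotent.
#'
#' @param table a [sample_table()].
#' @param cfg a [filter_config()].
#' @return the filtered `sample_table`; attribute `drop_log` is a data.frame
#'   of culled OTUs with the rule(s) each one failed.
#' @export
filter_otus <- function(table, cfg = filter_config()) {
  stopifnot(inherits(table, "sample_table"), inherits(cfg, "filter_config"))
  if (table$total_reads == 0 || nrow(table$otus) == 0) {
    if (table$total_reads == 0 && nrow(table$otus) > 0)
      warning("sample has zero total reads; all OTUs culled")
    out <- table
    out$otus <- table$otus[integer(0), , drop = FALSE]
    attr(out, "drop_log") <- drop_log_frame(table$otus,
                                            rep("zero_total_reads",
                                                nrow(table$otus)))
    return(out)
  }
  m <- read_matrix(table)
  totals <- rowSums(m)
  n_present <- rowSums(m > 0)
  rel <- totals / table$total_reads
  keep <- totals >= cfg$min_total_reads &
    n_present >= cfg$min_replicates_present &
    rel > cfg$min_rel_abundance
  reasons <- character(nrow(m))
  reasons[totals < cfg$min_total_reads] <- "below_min_total_reads"
  f2 <- n_present < cfg$min_replicates_present
  reasons[f2] <- paste0(reasons[f2], ifelse(nzchar(reasons[f2]), ";", ""),
                        "missing_in_replicate")
  f3 <- rel <= cfg$min_rel_abundance
  reasons[f3] <- paste0(reasons[f3], ifelse(nzchar(reasons[f3]), ";", ""),
                        "low_relative_abundance")
  out <- table
  out$otus <- table$otus[keep, , drop = FALSE]
  rownames(out$otus) <- NULL
  # total_reads deliberately unchanged: it is the rel.-abundance denominator
  attr(out, "drop_log") <- drop_log_frame(table$otus[!keep, , drop = FALSE],
                                          reasons[!keep])
  out
}

drop_log_frame <- function(otus, reason) {
  data.frame(otu_id = otus$otu_id, marker = otus$marker,
             reason = reason, stringsAsFactors = FALSE)
}

#' Eliminate OTUs found in negative controls
#'
#' Removes every OTU whose representative sequence is identical to the
#' sequence of any OTU in any control table (negative control or PCR blank).
#' Matching is by exact sequence, not by OTU id, because controls are
#' clustered independently of samples.
#'
#' @param table a [sample_table()].
#' @param controls list of control `sample_table`s (unfiltered).
#' @return the cleaned `sample_table`; attribute `drop_log` lists removals.
#' @export
subtract_controls <- function(table, controls = list()) {
  stopifnot(inherits(table, "sample_table"))
  if (inherits(controls, "sample_table")) controls <- list(controls)
  if (!length(controls)) {
    attr(table, "drop_log") <- drop_log_frame(table$otus[integer(0), ],
                                              character(0))
    return(table)
  }
  ctrl_seqs <- unique(unlist(lapply(controls, function(ct) ct$otus$sequence)))
  hit <- table$otus$sequence %in% ctrl_seqs
  out <- table
  out$otus <- table$otus[!hit, , drop = FALSE]
  rownames(out$otus) <- NULL
  attr(out, "drop_log") <- drop_log_frame(table$otus[hit, , drop = FALSE],
                                          rep("in_control", sum(hit)))
  out
}

#' Combine marker-specific tables of one sample
#'
#' OTUs obtained with each primer set (ITS2, rbcL-3A) are combined and
#' analyzed as a single group; `(marker, otu_id)` keys must stay unique.
#'
#' @param tables list of [sample_table()]s sharing one `sample_id`.
#' @return a single combined `sample_table`.
#' @export
combine_markers <- function(tables) {
  if (inherits(tables, "sample_table")) return(tables)
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "sample_table")))
  ids <- unique(vapply(tables, function(t) t$sample_id, ""))
  if (length(ids) != 1)
    stop("sample_id mismatch across tables: ", paste(ids, collapse = ", "))
  nrep <- unique(vapply(tables, function(t) t$n_replicates, 1L))
  if (length(nrep) != 1) stop("replicate counts differ across tables")
  otus <- do.call(rbind, lapply(tables, function(t) t$otus))
  sample_table(ids, otus, nrep)
}
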