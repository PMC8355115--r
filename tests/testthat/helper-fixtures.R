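# Shared in-code fixtures: toy OTU tables, tiny occurrence stores, and a
# reference data.frame derived from a synthetic species pool.

toy_table <- function(reads, sample_id = "toy", marker = "ITS2",
                      seqs = NULL) {
  n <- nrow(reads)
  df <- data.frame(otu_id = sprintf("O%02d", seq_len(n)),
                   marker = rep_len(marker, n),
                   rep1 = reads[, 1], rep2 = reads[, 2], rep3 = reads[, 3],
                   stringsAsFactors = FALSE)
  df$sequence <- if (is.null(seqs))
    vapply(seq_len(n), function(i)
      paste(rep(c("A", "C", "G", "T")[(i %% 4) + 1], 30), collapse = ""), "")
  else seqs
  sample_table(sample_id, df)
}

# the hand-enumerated 5-OTU table: sample total 10,000 reads
# O01 (1,1,1)    total 3,    rel 3e-4  -> retained
# O02 (1,1,0)    total 2,    rel 2e-4  -> culled (reads < 3, 2/3 replicates)
# O03 (5,4,0)    total 9               -> culled (2/3 replicates)
# O04 (3000,3000,3482) total 9482      -> retained
# O05 (168,168,168) total 504          -> retained
toy5 <- function() {
  toy_table(rbind(c(1, 1, 1), c(1, 1, 0), c(5, 4, 0),
                  c(3000, 3000, 3482), c(168, 168, 168)))
}

pool_reference <- function(pool) {
  data.frame(accession = paste0("A", seq_len(2 * nrow(pool))),
             marker = rep(c("ITS2", "RBCL3A"), each = nrow(pool)),
             species_raw = rep(pool$name, 2),
             sequence = c(pool$seq_ITS2, pool$seq_RBCL3A),
             stringsAsFactors = FALSE)
}

tiny_store <- function(df) occurrence_store(df)

# a small grid for metric tests: 5 x 2 cells of 100 km
small_spec <- function() grid_spec(cell_km = 100, width_km = 500,
                                   height_km = 200)

surface_from_values <- function(values, spec, n_otus = 10L) {
  structure(list(spec = spec, values = values, n_otus = n_otus),
            class = "grid_surface")
}

# independent containment oracle for species assignment (base R only)
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
brute_assign <- function(q, ref_seqs) {
  grepl(q, ref_seqs, fixed = TRUE) |
    grepl(revcomp_chr(q), ref_seqs, fixed = TRUE)
}

# independent strict-less count for the truth percentage
brute_tp <- function(values, truth_row, truth_col) {
  tv <- values[truth_row + 1, truth_col + 1]
  n_less <- 0L
  for (r in seq_len(nrow(values))) for (c in seq_len(ncol(values)))
    if (values[r, c] < tv) n_less <- n_less + 1L
  100 * n_less / length(values)
}
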