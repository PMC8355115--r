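# Species assignment by exact-identity containment against a local
# minibarcode reference, name normalization, and per-sample species dedup.

#' Read a local barcode reference FASTA
#'
#' Header format: `>accession|marker|Genus epithet[ infraspecific...]`.
#' The species name is kept raw; normalization happens at assignment time.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession`, `marker`, `species_raw`,
#'   `sequence`.
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad))
    stop("malformed reference header(s): ",
         paste(names(seqs)[bad][seq_len(min(3, sum(bad)))], collapse = "; "))
  data.frame(accession = vapply(parts, `[`, "", 1),
             marker = norm_marker(vapply(parts, `[`, "", 2)),
             species_raw = vapply(parts, function(p)
               paste(p[-(1:2)], collapse = "|"), ""),
             sequence = toupper(as.character(seqs)),
             stringsAsFactors = FALSE)
}

PLACEHOLDER_TOKENS <- c("uncultured", "unidentified", "environmental",
                        "sample", "sp", "sp.", "cf", "cf.", "aff", "aff.")
RANK_TOKENS <- c("subsp.", "subsp", "ssp.", "ssp", "var.", "var",
                 "f.", "forma", "x")

#' Normalize a raw taxon name to a species binomial
#'
#' Trims to species level: the genus is capitalized, the epithet lowercased,
#' and infraspecific ranks (subsp., var., f.) and any trailing tokens after
#' the epithet are removed.  Placeholder taxa (uncultured, environmental
#' sample, hybrids marked with "x", "Genus sp.") return `NA`, signalling
#' that the name is dropped.  Idempotent.
#'
#' @param raw character vector of raw names.
#' @return character vector of "Genus epithet" binomials or `NA`.
#' @export
normalize_name <- function(raw) {
  vapply(as.character(raw), function(nm) {
    if (is.na(nm)) return(NA_character_)
    toks <- strsplit(trimws(nm), "\\s+")[[1]]
    if (length(toks) < 2) return(NA_character_)
    genus <- toks[1]; epithet <- toks[2]
    if (tolower(genus) %in% PLACEHOLDER_TOKENS ||
        tolower(epithet) %in% c(PLACEHOLDER_TOKENS, RANK_TOKENS))
      return(NA_character_)
    if (!grepl("^[A-Za-z-]+$", genus) || !grepl("^[A-Za-z-]+$", epithet))
      return(NA_character_)
    paste(paste0(toupper(substr(genus, 1, 1)),
                 tolower(substr(genus, 2, nchar(genus)))),
          tolower(epithet))
  }, "", USE.NAMES = FALSE)
}

#' Apply a user-supplied synonym map to a binomial
#'
#' Single-hop lookup: a name present in the map is replaced by its target;
#' chains are deliberately not followed.  Names absent from the map pass
#' through unchanged.
#'
#' @param name character vector of binomials.
#' @param synonyms named character vector or 2-column data.frame
#'   (`from`, `to`).
#' @return character vector of aligned names.
#' @export
apply_synonym_map <- function(name, synonyms = NULL) {
  if (is.null(synonyms) || !length(synonyms)) return(name)
  if (is.data.frame(synonyms)) {
    map <- stats::setNames(as.character(synonyms[[2]]),
                           as.character(synonyms[[1]]))
  } else map <- synonyms
  hit <- name %in% names(map)
  name[hit] <- unname(map[name[hit]])
  name
}

#' Assign species to an OTU by 100%-identity containment
#'
#' A reference record matches when its sequence contains the full OTU
#' sequence with zero mismatches (100% identity over the whole query), on
#' either strand.  All matching species are retained; names are normalized
#' and passed through the synonym map.  An OTU matching no reference is
#' flagged unassigned and excluded from mapping.
#'
#' @param otu_seq the OTU's representative sequence (character).
#' @param reference reference data.frame from [read_reference_fasta()],
#'   already restricted to the OTU's marker.
#' @param otu_id identifier carried into the result.
#' @param synonyms optional synonym map (see [apply_synonym_map()]).
#' @return list with `otu_id`, `species` (character vector of normalized
#'   binomials, possibly empty) and `assigned` (logical).
#' @export
assign_species <- function(otu_seq, reference, otu_id = NA_character_,
                           synonyms = NULL) {
  if (!nrow(reference)) {
    warning("empty reference; OTU unassigned")
    return(list(otu_id = otu_id, species = character(0), assigned = FALSE))
  }
  q <- Biostrings::DNAString(toupper(otu_seq))
  subj <- Biostrings::DNAStringSet(reference$sequence)
  hit_f <- Biostrings::vcountPattern(q, subj, fixed = TRUE) > 0
  hit_r <- Biostrings::vcountPattern(Biostrings::reverseComplement(q),
                                     subj, fixed = TRUE) > 0
  raw <- reference$species_raw[hit_f | hit_r]
  sp <- unique(stats::na.omit(apply_synonym_map(normalize_name(raw),
                                                synonyms)))
  list(otu_id = otu_id, species = sort(sp), assigned = length(sp) > 0)
}

#' Assign species to every OTU of a sample table
#'
#' @param table a [sample_table()] (filtered and control-subtracted).
#' @param reference reference data.frame covering all markers.
#' @param synonyms optional synonym map.
#' @return list of per-OTU assignments (see [assign_species()]).
#' @export
assign_sample <- function(table, reference, synonyms = NULL) {
  lapply(seq_len(nrow(table$otus)), function(i) {
    row <- table$otus[i, ]
    ref_m <- reference[reference$marker == row$marker, , drop = FALSE]
    assign_species(row$sequence, ref_m, otu_id = row$otu_id,
                   synonyms = synonyms)
  })
}

#' Deduplicate species across the OTUs of one sample
#'
#' A plant species is represented at most once per sample even when it
#' matches several OTUs.  OTUs are processed in descending total-read order
#' (ties broken by `otu_id`); a species already claimed by an earlier OTU is
#' removed from later OTUs' sets, and OTUs whose set becomes empty are
#' dropped from mapping.
#'
#' @param assignments list of assignments from [assign_sample()].
#' @param table the [sample_table()] the assignments belong to (supplies
#'   read totals for the ordering).
#' @return list of assignments with disjoint species sets; emptied OTUs
#'   removed.
#' @export
dedupe_species <- function(assignments, table) {
  if (!length(assignments)) return(assignments)
  ids <- vapply(assignments, function(a) a$otu_id, "")
  totals <- rowSums(read_matrix(table))[match(ids, table$otus$otu_id)]
  totals[is.na(totals)] <- 0
  ord <- order(-totals, ids)
  claimed <- character(0)
  out <- list()
  for (i in ord) {
    a <- assignments[[i]]
    a$species <- setdiff(a$species, claimed)
    a$assigned <- length(a$species) > 0
    claimed <- c(claimed, a$species)
    if (a$assigned) out[[length(out) + 1L]] <- a
  }
  out
}
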