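# Local store of georeferenced species-occurrence records (a BISON-like
# repository read from Darwin-Core-style CSV), with per-record QC and
# capped, seeded querying.

#' QC a raw occurrence record
#'
#' Rejects records carrying a provider QC flag (apparently invalid or
#' mismatched coordinates/countries/continents), coordinates outside valid
#' ranges, missing coordinates, and the (0, 0) placeholder point.
#'
#' @param lat,lon numeric vectors of coordinates in degrees.
#' @param flagged logical vector of provider flags.
#' @return logical vector: `TRUE` for records that pass QC.
#' @export
qc_filter <- function(lat, lon, flagged = FALSE) {
  flagged <- as.logical(flagged)
  flagged[is.na(flagged)] <- FALSE
  ok <- !flagged &
    !is.na(lat) & !is.na(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180 &
    !(lat == 0 & lon == 0)
  ok
}

#' Build an occurrence store from a Darwin-Core-style CSV
#'
#' Expected columns: `scientificName`, `decimalLatitude`, `decimalLongitude`;
#' optional `TSN` (integer taxonomic serial number) and `flags` (truthy for
#' provider-flagged records).  Per-record QC ([qc_filter()]) is applied at
#' ingest; the ingest report (attribute `report`) counts accepted and
#' rejected rows.
#'
#' @param path CSV file path.
#' @param cap per-query record cap (default `1e5`).
#' @return an object of class `occurrence_store`.
#' @export
read_occurrences <- function(path, cap = 100000L) {
  if (!file.exists(path)) stop("occurrence CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("scientificName", "decimalLatitude", "decimalLongitude")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("occurrence CSV missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"TSN" %in% names(df)) df$TSN <- rep(NA_integer_, nrow(df))
  if (!"flags" %in% names(df)) df$flags <- rep(FALSE, nrow(df))
  occurrence_store(
    data.frame(species = as.character(df$scientificName),
               tsn = suppressWarnings(as.integer(df$TSN)),
               lat = as.numeric(df$decimalLatitude),
               lon = as.numeric(df$decimalLongitude),
               flagged = as.logical(df$flags) %in% TRUE,
               stringsAsFactors = FALSE),
    cap = cap)
}

#' Construct an occurrence store from a records data.frame
#'
#' @param records data.frame with columns `species`, `tsn` (optional, may be
#'   `NA`), `lat`, `lon`, `flagged` (optional).
#' @param cap per-query record cap (default `1e5`).
#' @return an `occurrence_store`; attribute `report` gives accepted/rejected
#'   counts (their sum equals the input row count).
#' @export
occurrence_store <- function(records, cap = 100000L) {
  stopifnot(is.data.frame(records),
            all(c("species", "lat", "lon") %in% names(records)))
  if (!"tsn" %in% names(records)) records$tsn <- NA_integer_
  if (!"flagged" %in% names(records)) records$flagged <- FALSE
  total <- nrow(records)
  ok <- qc_filter(records$lat, records$lon, records$flagged)
  clean <- records[ok, c("species", "tsn", "lat", "lon"), drop = FALSE]
  rownames(clean) <- NULL
  structure(list(records = clean,
                 by_name = split(seq_len(nrow(clean)), clean$species),
                 by_tsn = split(seq_len(nrow(clean)),
                                clean$tsn),  # drops NA keys
                 cap = as.integer(cap)),
            class = "occurrence_store",
            report = c(total = total, accepted = sum(ok),
                       rejected = total - sum(ok)))
}

#' @export
print.occurrence_store <- function(x, ...) {
  cat(sprintf("<occurrence_store> %d records, %d species, cap %d\n",
              nrow(x$records), length(x$by_name), x$cap))
  invisible(x)
}

#' Query occurrence records for a species
#'
#' Looks up by taxonomic serial number first when one is supplied, falling
#' back to the binomial.  When more records match than the store's cap, a
#' uniform random subsample of exactly `cap` records is drawn with the given
#' seed, so repeated queries are reproducible.  An absent species yields an
#' empty result (some species produce no georeferenced occurrences).
#'
#' @param store an `occurrence_store`.
#' @param species normalized binomial.
#' @param tsn optional integer identifier, tried before the name.
#' @param seed integer seed for the over-cap subsample.
#' @return data.frame of occurrence records (possibly 0 rows).
#' @export
query_occurrences <- function(store, species, tsn = NULL, seed = 1L) {
  stopifnot(inherits(store, "occurrence_store"))
  idx <- NULL
  if (!is.null(tsn) && !is.na(tsn))
    idx <- store$by_tsn[[as.character(tsn)]]
  if (is.null(idx)) idx <- store$by_name[[species]]
  if (is.null(idx)) return(store$records[integer(0), , drop = FALSE])
  if (length(idx) > store$cap) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
    idx <- sort(sample(idx, store$cap))
  }
  out <- store$records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
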