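test_that("name normalization trims to species and drops placeholders", {
  expect_equal(normalize_name("Pinus strobus var. chiapensis"),
               "Pinus strobus")
  expect_equal(normalize_name("Quercus alba"), "Quercus alba")
  expect_equal(normalize_name("quercus ALBA subsp. alba"), "Quercus alba")
  expect_true(is.na(normalize_name("uncultured plant")))
  expect_true(is.na(normalize_name("environmental sample")))
  expect_true(is.na(normalize_name("Quercus sp.")))
  expect_true(is.na(normalize_name("Quercus")))
  # idempotence over a batch of raw names
  raw <- c("Pinus strobus var. chiapensis", "Quercus alba", "Acer RUBRUM L.")
  once <- normalize_name(raw)
  expect_identical(normalize_name(once), once)
})

test_that("synonym mapping is a single-hop lookup", {
  map <- c("Betula alba" = "Betula pendula",
           "Betula pendula" = "Betula pubescens")
  expect_equal(apply_synonym_map("Betula alba", map), "Betula pendula")
  expect_equal(apply_synonym_map("Acer rubrum", map), "Acer rubrum")
  # chains are not followed: one hop only
  expect_equal(apply_synonym_map(apply_synonym_map("Betula alba", map), map),
               "Betula pubescens")  # two explicit hops differ from one
  expect_equal(apply_synonym_map("Betula alba", map), "Betula pendula")
  # data.frame form
  df <- data.frame(from = "Betula alba", to = "Betula pendula")
  expect_equal(apply_synonym_map("Betula alba", df), "Betula pendula")
})

test_that("species assignment is exact full-length containment, both strands", {
  ref <- data.frame(
    accession = c("R1", "R2", "R3"),
    marker = "ITS2",
    species_raw = c("Pinus strobus", "Pinus resinosa", "Acer rubrum"),
    sequence = c("GGGACGTACGTACGTCCC", "TTGACGTACGTACGTAAA",
                 "CCCCCCCCCCCCCCGGGG"),
    stringsAsFactors = FALSE)
  # contained in two Pinus references -> both species retained
  a <- assign_species("ACGTACGTACGT", ref, otu_id = "O1")
  expect_true(a$assigned)
  expect_setequal(a$species, c("Pinus resinosa", "Pinus strobus"))
  # identical to exactly one reference
  b <- assign_species("CCCCCCCCCCCCCCGGGG", ref)
  expect_equal(b$species, "Acer rubrum")
  # one mismatch anywhere -> unassigned
  c1 <- assign_species("ACGTACGTACTT", ref)
  expect_false(c1$assigned)
  expect_length(c1$species, 0)
  # reverse-complement containment also counts
  d <- assign_species(revcomp_chr("CCCCCCCCCCCCCCGGGG"), ref)
  expect_equal(d$species, "Acer rubrum")
  # empty reference warns and leaves the OTU unassigned
  expect_warning(e <- assign_species("ACGT", ref[0, ]), "empty reference")
  expect_false(e$assigned)
})

test_that("assignment agrees with a brute-force containment scan", {
  set.seed(21)
  cfg <- scenario_config(seed = 21, n_species = 15)
  pool <- gen_species_pool(cfg)
  ref <- pool_reference(pool)
  its <- ref[ref$marker == "ITS2", ]
  queries <- c(
    its$sequence[3],                                   # full record
    substr(its$sequence[5], 10, 120),                  # internal fragment
    revcomp_chr(its$sequence[7]),                      # opposite strand
    paste0(substr(its$sequence[2], 1, 50), "A"),       # 1-base corruption
    paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""))
  for (q in queries) {
    got <- assign_species(q, its)$species
    want <- sort(unique(normalize_name(
      its$species_raw[brute_assign(q, its$sequence)])))
    expect_equal(got, want)
  }
})

test_that("species dedup keeps the best-supported OTU and drops emptied ones", {
  tab <- toy_table(rbind(c(40, 40, 20), c(5, 4, 1), c(3, 3, 3)))
  asg <- list(
    list(otu_id = "O01", species = c("Pinus strobus"), assigned = TRUE),
    list(otu_id = "O02", species = c("Pinus strobus", "Acer rubrum"),
         assigned = TRUE),
    list(otu_id = "O03", species = c("Pinus strobus"), assigned = TRUE))
  out <- dedupe_species(asg, tab)
  ids <- vapply(out, function(a) a$otu_id, "")
  # O01 (100 reads) keeps the shared species; O02 falls back to its other
  # species; O03, left empty, is dropped from mapping
  expect_setequal(ids, c("O01", "O02"))
  expect_equal(out[[which(ids == "O01")]]$species, "Pinus strobus")
  expect_equal(out[[which(ids == "O02")]]$species, "Acer rubrum")

  # disjoint sets pass through unchanged
  asg2 <- list(
    list(otu_id = "O01", species = "Pinus strobus", assigned = TRUE),
    list(otu_id = "O02", species = "Acer rubrum", assigned = TRUE))
  out2 <- dedupe_species(asg2, tab)
  expect_length(out2, 2)

  # property: after dedup the union of species sets has no duplicates
  set.seed(33)
  spp <- paste("Genus", letters[1:8])
  for (i in 1:10) {
    n <- 6
    tabr <- toy_table(matrix(rpois(n * 3, 20), n, 3))
    asgr <- lapply(seq_len(n), function(j)
      list(otu_id = sprintf("O%02d", j),
           species = sample(spp, sample(1:3, 1)), assigned = TRUE))
    all_sp <- unlist(lapply(dedupe_species(asgr, tabr), `[[`, "species"))
    expect_false(any(duplicated(all_sp)))
  }
})
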