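test_that("cut geometry derives from site and offset under the mirror rule", {
  expect_equal(derive_overhang("CCATGG", 1),
               list(overhang = "CATG", end_type = "five_prime"))
  expect_equal(derive_overhang("GAGCTC", 5),
               list(overhang = "AGCT", end_type = "three_prime"))
  expect_equal(derive_overhang("CACGTG", 3),
               list(overhang = "", end_type = "blunt"))
  expect_error(derive_overhang("CCATGG", 7), "0\\.\\.6")
  expect_error(derive_overhang("CCATG", 1), "hexanucleotide")
  expect_error(derive_overhang("CCATGN", 1), "non-ACGT")
})

test_that("methylation context flags detect Dam and Dcm substrings", {
  expect_equal(methylation_flags("TGATCA"), c(dam = TRUE, dcm = FALSE))
  expect_equal(methylation_flags("CCTAGG"), c(dam = FALSE, dcm = FALSE))
  expect_equal(methylation_flags("CCTGGA"), c(dam = FALSE, dcm = TRUE))
})

test_that("enzyme rows parse, validate, and derive geometry", {
  es <- parse_enzyme_table(data.frame(
    name = "NcoI", site = "ccatgg", cohesive_end = "catg",
    stringsAsFactors = FALSE))
  expect_equal(es$site, "CCATGG")
  expect_equal(es$overhang, "CATG")
  expect_equal(es$end_type, "five_prime")
  expect_equal(es$cut_offset, 1L)
  expect_true(es$hybrid_eligible)
})

test_that("isoschizomers merge into one record reachable by any synonym", {
  es <- parse_enzyme_table(data.frame(
    name = c("SpeI", "AhlI"), site = c("ACTAGT", "ACTAGT"),
    cohesive_end = c("CTAG", "CTAG"), stringsAsFactors = FALSE))
  expect_equal(nrow(es), 1L)
  expect_equal(es$synonyms[[1]], "AhlI")
  expect_identical(enzyme_lookup(es, "AhlI"), enzyme_lookup(es, "SpeI"))
  expect_error(enzyme_lookup(es, "NoSuchEnzyme"), "unknown enzyme")
})

test_that("invalid rows are skipped with a report, not fatal", {
  df <- data.frame(
    name = c("BadEnz", "Short", "NonPal", "EcoRI"),
    site = c("GAATTN", "GAATT", "GGATCA", "GAATTC"),
    cohesive_end = c("AATT", "", "", "AATT"),
    stringsAsFactors = FALSE)
  expect_warning(es <- parse_enzyme_table(df), "skipped 3")
  expect_equal(es$name, "EcoRI")
  skipped <- attr(es, "skipped")
  expect_equal(skipped$name, c("BadEnz", "Short", "NonPal"))
  expect_match(skipped$reason[1], "ambiguous/invalid site")
})

test_that("inconsistent cohesive-end field is a record-level error", {
  expect_error(
    parse_enzyme_table(data.frame(name = "NcoI", site = "CCATGG",
                                  cohesive_end = "GATC",
                                  stringsAsFactors = FALSE)),
    "row 1 \\(NcoI\\).*inconsistent")
  expect_error(
    parse_enzyme_table(data.frame(name = "NcoI", stringsAsFactors = FALSE)),
    "missing mandatory column")
})

test_that("bundled fixture loads 12 merged enzymes with verified geometry", {
  es <- fix_es()
  expect_s3_class(es, "enzyme_set")
  expect_equal(nrow(es), 12L)
  expect_setequal(unlist(es$synonyms), c("AhlI", "Psp124BI", "Ksp22I", "AspA2I"))
  ## round-trip: derived geometry reproduces the table's cohesive-end field
  for (i in seq_len(nrow(es))) {
    g <- derive_overhang(es$site[i], es$cut_offset[i])
    expect_equal(g$overhang, es$overhang[i], info = es$name[i])
    expect_equal(g$end_type, es$end_type[i], info = es$name[i])
  }
  ## every hybrid-eligible site is its own reverse complement
  expect_true(all(es$site == naive_revcomp(es$site)))
  ## SacI is retained for mapping but not hybrid generation
  expect_false(enzyme_lookup(es, "SacI")$hybrid_eligible)
  expect_true(enzyme_lookup(es, "BclI")$dam_blocked)
  expect_false(enzyme_lookup(es, "BamHI")$dam_blocked)  # explicit override
})

test_that("parsing the serialised form reproduces the same enzyme set", {
  es <- fix_es()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enzyme_table(es, path)
  es2 <- read_enzyme_table(path)
  for (col in c("name", "site", "cut_offset", "end_type", "overhang",
                "dam_blocked", "dcm_blocked", "hybrid_eligible")) {
    expect_equal(es2[[col]], es[[col]], info = col)
  }
  expect_equal(lapply(es2$synonyms, sort), lapply(es$synonyms, sort))
})
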