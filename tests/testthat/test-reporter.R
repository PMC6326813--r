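test_that("construct places the test codon at ORF codon 21 in a G-free transcript", {
  rc <- build_construct("IAC")
  expect_equal(rc$test_codon_index, 21L)
  expect_equal(rc$orf[21L], "IAC")
  expect_equal(rc$orf[1L], "AUG")
  expect_false(grepl("G", rc$transcript_rna, fixed = TRUE))
  expect_true(grepl("I", rc$transcript_rna, fixed = TRUE))
  # transcript coordinates agree with the template-level codon index
  span <- test_codon_span(rc)
  expect_equal(substring(rc$transcript_rna, span[1L] + 1L, span[2L]),
               "IAC")
  # designed stop survives a stop-variant test codon
  rc2 <- build_construct("UAI")
  expect_equal(rc2$orf[21L], "UAI")
  expect_equal(length(rc2$orf), length(rc$orf))
})

test_that("mutated backbones are rejected", {
  bb <- reporter_backbone()
  expect_error(build_construct("IAC", backbone = sub("NNN", "NN", bb)),
               "NNN")
  expect_error(build_construct("IAC",
                               backbone = sub("TAATACGACTCACTATA", "TTT",
                                              bb)),
               "promoter")
  expect_error(build_construct("IAC", backbone = sub("ATG", "ATT", bb)),
               "backbone integrity")
})

test_that("validator reports out-of-window G codons and fails on window violations", {
  v <- validate_construct(build_construct("IAC"))
  expect_true(v$ok)
  expect_false(any(v$g_codons$in_measured_window))
  # the Ser spacer codon UCG is synonymous under every inosine decoding
  expect_equal(v$g_codons$classification[v$g_codons$codon == "UCG"],
               "synonymous")
  # FLAG codons (GAC/GAU) change product under some decodings
  expect_true(all(v$g_codons$classification[
    v$g_codons$codon %in% c("GAC", "GAU")] == "non_synonymous"))
  # inject a G into the measured spacer (TCATCATTC -> TCGTCATTC): hard fail
  bb_bad <- sub("AAATCATCATTC", "AAATCGTCATTC", reporter_backbone())
  expect_error(validate_construct(build_construct("IAC",
                                                  backbone = bb_bad)),
               "measured peptide window")
})

test_that("LysC digestion cleaves after K and honors missed cleavages", {
  expect_equal(digest_lysC("MDYKDDDDKSSK"), c("MDYK", "DDDDK", "SSK"))
  expect_equal(digest_lysC("AAAA"), "AAAA")
  expect_equal(digest_lysC("AAKA"), c("AAK", "A"))
  expect_equal(digest_lysC("MDYKDDDDKSSK", missed_cleavages = 1),
               c("MDYK", "MDYKDDDDK", "DDDDK", "DDDDKSSK", "SSK"))
  expect_error(digest_lysC("AAK", missed_cleavages = -1), "non-negative")
  # conservation at 0 missed cleavages, on a generated protein
  set.seed(42)
  prot <- paste(sample(c(names(inodecode:::AA_MONO)), 200, replace = TRUE),
                collapse = "")
  expect_equal(paste(digest_lysC(prot), collapse = ""), prot)
  # the reporter protein (I as G) releases the measured peptide
  rc <- build_construct("IAC")
  prot <- paste(translate_codon(
    chartr("I", "G", rc$orf[-length(rc$orf)])), collapse = "")
  expect_true("SSFYSLTSDSNISK" %in% digest_lysC(prot))
})

test_that("monoisotopic masses match an independent summation oracle", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-6)
  expect_equal(peptide_mass(""), 18.010565, tolerance = 1e-7)
  # frozen values computed with an independent proteomics mass calculator
  expect_equal(peptide_mass("PEPTIDE"), 799.35996, tolerance = 1e-6)
  expect_equal(peptide_mass("SSFYSLTSDSNISK"), 1534.71512,
               tolerance = 1e-6)
  # fixed carbamidomethylation on Cys, variable Met oxidation
  expect_equal(peptide_mass("C"), 121.01975 + 57.021464, tolerance = 1e-5)
  expect_equal(peptide_mass("C", carbamidomethyl = FALSE), 121.01975,
               tolerance = 1e-5)
  expect_equal(peptide_mass("M", oxidized_met = 1) - peptide_mass("M"),
               15.994915, tolerance = 1e-6)
  expect_error(peptide_mass("M", oxidized_met = 2), "oxidized_met")
  expect_error(peptide_mass("PEPTIDEZ"), "unknown residue")
  # random peptides against the oracle table
  set.seed(7)
  for (i in 1:10) {
    pep <- paste(sample(names(inodecode:::AA_MONO)[
      names(inodecode:::AA_MONO) != "C"], 12, replace = TRUE),
      collapse = "")
    expect_equal(peptide_mass(pep), oracle_peptide_mass(pep),
                 tolerance = 1e-4)
  }
})

test_that("expected species cover full-length classes, truncation and read-through", {
  sp <- expected_peptides("IAC")
  full <- sp[sp$species_class %in% c("primary", "alternative"), ]
  expect_setequal(full$amino_acid, c("D", "N", "Y"))
  expect_equal(full$sequence[full$amino_acid == "D"], "SSFYSLTSDSNISK")
  expect_equal(full$species_class[full$amino_acid == "D"], "primary")
  expect_equal(sp$sequence[sp$species_class == "truncated"], "SSFYSLTS")

  sp <- expected_peptides("UAI")
  expect_true("terminated" %in% sp$species_class)
  expect_equal(sp$sequence[sp$species_class == "terminated"], "SSFYSLTS")
  rt <- sp[sp$species_class == "readthrough", ]
  expect_equal(rt$amino_acid, "Y")
  expect_equal(rt$sequence, "SSFYSLTSYSNISK")

  sp <- expected_peptides("CUI")
  expect_equal(sum(sp$species_class == "primary"), 1L)
  expect_equal(sp$amino_acid[sp$species_class == "primary"], "L")
  expect_false(any(sp$species_class == "alternative"))
})

test_that("IAA and IAI both yield E- and K-containing full-length species", {
  for (cd in c("IAA", "IAI")) {
    sp <- expected_peptides(cd)
    aa <- sp$amino_acid[sp$species_class %in% c("primary", "alternative")]
    expect_true(all(c("E", "K") %in% aa), label = cd)
  }
})

test_that("Leu/Ile isobars are merged into one flagged quantification unit", {
  expect_warning(sp <- expected_peptides("IUA"), "isobaric")
  full <- sp[sp$species_class %in% c("primary", "alternative"), ]
  expect_true(any(grepl("/", full$amino_acid)))
  expect_true(any(full$isobaric))
  # masses of remaining distinct full-length species differ by >= 0.01 Da
  expect_true(all(dist(full$monoisotopic_mass) >= 0.01))
})

test_that("all distinct full-length species differ in mass or carry the isobar flag", {
  for (cd in enumerate_inosine_codons()) {
    sp <- suppressWarnings(expected_peptides(cd))
    full <- sp[sp$species_class %in% c("primary", "alternative",
                                       "readthrough"), ]
    if (nrow(full) > 1L)
      expect_true(all(dist(full$monoisotopic_mass) >= 0.01), label = cd)
  }
})
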