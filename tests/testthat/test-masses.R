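test_that("monoisotopic_mass reproduces known compositions", {
  # biotinamidocaproyl adduct left by sulfo-NHS-LC-biotin
  expect_equal(monoisotopic_mass("C16H25N3O3S"), 339.1617, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(c(H = 2, O = 1)), 18.01056, tolerance = 1e-5)
  expect_identical(monoisotopic_mass(elemental_composition(integer(0))), 0)
})

test_that("compositions reject unknown elements and negative counts", {
  expect_error(elemental_composition(c(Xx = 1)), "Xx")
  expect_error(elemental_composition(c(C = -1)), "non-negative")
  expect_error(parse_formula("C2H3!"), "parse")
})

test_that("peptide_mass matches independent residue summation", {
  expect_equal(peptide_mass("NMLIHGR"), oracle_peptide_mass("NMLIHGR"),
               tolerance = 1e-3)
  # fixed carbamidomethyl adds the iodoacetamide delta
  cam <- mod_carbamidomethyl()
  expect_equal(cam$delta_mono, 57.02146, tolerance = 1e-4)
  seqg <- "GVELCFPENETPPEGK"
  expect_equal(
    peptide_mass(seqg, list(list(position = 5L, mod = cam))),
    peptide_mass(seqg) + 57.02146, tolerance = 1e-4)
})

test_that("peptide_mass rejects mods on disallowed residues", {
  err <- expect_error(
    peptide_mass("AGHR", list(list(position = 2L, mod = mod_biotin_lc()))))
  expect_match(conditionMessage(err), "position 2")
  expect_match(conditionMessage(err), "G")
  expect_error(peptide_mass("AXG"), "X")
})

test_that("modification deltas are additive for random peptides", {
  set.seed(11)
  bio <- mod_biotin_lc()
  for (i in 1:20) {
    sq <- random_sequence(sample(5:25, 1))
    ks <- which(strsplit(sq, "")[[1]] == "K")
    if (length(ks) == 0L) next
    picked <- ks[sample.int(length(ks), sample.int(length(ks), 1))]
    mods <- lapply(picked, function(p) list(position = p, mod = bio))
    expect_equal(peptide_mass(sq, mods) - peptide_mass(sq),
                 length(picked) * bio$delta_mono, tolerance = 1e-9)
  }
})

test_that("peptide mass is concatenation-consistent", {
  set.seed(12)
  for (i in 1:20) {
    a <- random_sequence(sample(2:15, 1))
    b <- random_sequence(sample(2:15, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - WATER_MASS,
                 tolerance = 1e-9)
  }
})

test_that("mz_from_mass follows the proton-adduct definition", {
  M <- 1234.5678
  expect_equal(mz_from_mass(M, 1L), M + 1.007276, tolerance = 1e-5)
  expect_equal(mz_from_mass(M, 2L), (M + 2 * 1.007276) / 2, tolerance = 1e-5)
  expect_equal(mz_from_mass(peptide_mass("NMLIHGR"), 1L),
               oracle_peptide_mass("NMLIHGR") + ORACLE_PROTON,
               tolerance = 1e-3)
  expect_error(mz_from_mass(M, 0L), "charge")
  # strictly decreasing in charge for M > proton mass
  zs <- 1:6
  expect_true(all(diff(mz_from_mass(M, zs)) < 0))
  expect_equal(mass_from_mz(mz_from_mass(M, 3L), 3L), M, tolerance = 1e-9)
})

test_that("protein-level label shift is stoichiometric", {
  expect_equal(protein_label_shift(175) / 1000, 59.35, tolerance = 0.01)
  expect_identical(protein_label_shift(0), 0)
  expect_equal(protein_label_shift(1), 339.1617, tolerance = 1e-4)
  expect_error(protein_label_shift(-1), "non-negative")
})

test_that("modification tables round-trip through TSV", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(name = c("biotin-LC", "carbamidomethyl", "custom"),
                   targets = c("K", "C", "ST"),
                   composition_or_delta = c("C16H25N3O3S", "C2H3NO", "79.96633"),
                   blocks_cleavage = c(TRUE, FALSE, FALSE),
                   mode = c("variable", "fixed", "variable"))
  utils::write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  mods <- read_mod_table(tf)
  expect_length(mods, 3)
  expect_equal(mods[[1]]$delta_mono, 339.1617, tolerance = 1e-4)
  expect_true(mods[[1]]$blocks_cleavage)
  expect_equal(mods[[3]]$targets, c("S", "T"))
  expect_equal(mods[[3]]$delta_mono, 79.96633)
})
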