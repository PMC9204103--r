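test_that("cleavage_sites applies the K/R-not-before-P rule", {
  expect_identical(cleavage_sites(protein_record("p", "AKPR")), integer(0))
  expect_identical(cleavage_sites(protein_record("p", "AAAA")), integer(0))
  p <- protein_record("p", "GVELCFPENETPPEGKNMLIHGR")
  expect_identical(cleavage_sites(p), 16L)
  # offsets shift the labels, not the cuts
  p2 <- protein_record("p", "GVELCFPENETPPEGKNMLIHGR", numbering_offset = 1979L)
  expect_identical(cleavage_sites(p2), 1994L)
})

test_that("a biotinylated lysine suppresses the tryptic cut", {
  p <- protein_record("atr", "GVELCFPENETPPEGKNMLIHGR",
                      numbering_offset = 1979L)
  unmod <- digest(p, max_missed = 0L)
  expect_length(unmod, 2L)
  expect_setequal(vapply(unmod, `[[`, character(1), "sequence"),
                  c("GVELCFPENETPPEGK", "NMLIHGR"))
  prot <- digest(p, mod_state = list(list(position = 1994L,
                                          mod = mod_biotin_lc())),
                 max_missed = 0L)
  expect_length(prot, 1L)
  expect_identical(prot[[1]]$sequence, "GVELCFPENETPPEGKNMLIHGR")
  expect_true("biotin-LC" %in% prot[[1]]$mods$mod)
  # the blocked site is not a missed cleavage
  expect_identical(prot[[1]]$missed_cleavages, 0L)
})

test_that("an internal modified K is retained while the C-terminal K is cut", {
  p <- protein_record("bh3", "VDMNQKSILWSALK", numbering_offset = 454L)
  out <- digest(p, mod_state = list(list(position = 459L,
                                         mod = mod_biotin_lc())),
                max_missed = 0L)
  expect_length(out, 1L)
  expect_identical(out[[1]]$sequence, "VDMNQKSILWSALK")
  expect_identical(out[[1]]$mods$position[out[[1]]$mods$mod == "biotin-LC"],
                   459L)
})

test_that("digest rejects a modification on a non-target residue", {
  p <- protein_record("p", "AGAR")
  expect_error(
    digest(p, mod_state = list(list(position = 2L, mod = mod_biotin_lc()))),
    "not allowed")
})

test_that("zero-missed unmodified digestion tiles the protein exactly", {
  set.seed(21)
  for (i in 1:10) {
    p <- protein_record("p", random_sequence(sample(20:60, 1)))
    forms <- digest(p, max_missed = 0L, fixed_mods = list())
    starts <- vapply(forms, `[[`, integer(1), "start")
    o <- order(starts)
    forms <- forms[o]
    expect_identical(forms[[1]]$start, 1L)
    expect_identical(forms[[length(forms)]]$end, nchar(p$sequence))
    if (length(forms) > 1L)
      for (k in 2:length(forms))
        expect_identical(forms[[k]]$start, forms[[k - 1]]$end + 1L)
    # mass conservation over the partition
    expect_equal(sum(vapply(forms, peptide_form_mass, numeric(1))),
                 peptide_mass(p$sequence) + (length(forms) - 1) * WATER_MASS,
                 tolerance = 1e-6)
  }
})

test_that("raising max_missed never removes peptides", {
  set.seed(22)
  for (i in 1:5) {
    p <- protein_record("p", random_sequence(40))
    k0 <- modform_keys(digest(p, max_missed = 0L, fixed_mods = list()))
    k1 <- modform_keys(digest(p, max_missed = 1L, fixed_mods = list()))
    k2 <- modform_keys(digest(p, max_missed = 2L, fixed_mods = list()))
    expect_true(all(k0 %in% k1))
    expect_true(all(k1 %in% k2))
  }
})

test_that("enumerate_modforms equals the brute-force oracle", {
  # worked example: AKGKR with one allowed missed cleavage
  p <- protein_record("p", "AKGKR")
  got <- modform_keys(enumerate_modforms(p, max_missed = 1L, max_var_mods = 2L,
                                         fixed_mods = list()))
  expect_identical(got, oracle_enumerate_keys("AKGKR", 1L, 2L))
  set.seed(23)
  for (i in 1:15) {
    sq <- random_sequence(sample(8:30, 1))
    mm <- sample(0:2, 1); mv <- sample(0:3, 1)
    p <- protein_record("p", sq)
    got <- modform_keys(enumerate_modforms(p, max_missed = mm,
                                           max_var_mods = mv,
                                           fixed_mods = list()))
    expect_identical(got, oracle_enumerate_keys(sq, mm, mv))
  }
})

test_that("enumeration degenerates correctly", {
  p <- protein_record("p", "AGSTRLLNDK")
  # no variable mods -> identical to a plain digest
  expect_identical(
    modform_keys(enumerate_modforms(p, variable_mods = list(),
                                    max_missed = 1L, fixed_mods = list())),
    modform_keys(digest(p, max_missed = 1L, fixed_mods = list())))
  # no lysines -> biotin hypotheses change nothing
  q <- protein_record("q", "AGSTRLLNDR")
  expect_identical(
    modform_keys(enumerate_modforms(q, max_missed = 1L, fixed_mods = list())),
    modform_keys(enumerate_modforms(q, variable_mods = list(),
                                    max_missed = 1L, fixed_mods = list())))
})

test_that("the combinatorial cap aborts with a helpful message", {
  p <- protein_record("p", strrep("AKGK", 10))
  expect_error(enumerate_modforms(p, max_missed = 2L, max_var_mods = 5L,
                                  cap = 10L),
               "max_var_mods")
})

test_that("peptide_table reports coordinates, mods and masses", {
  p <- protein_record("atr", "GVELCFPENETPPEGKNMLIHGR",
                      numbering_offset = 1979L)
  tab <- peptide_table(digest(p, max_missed = 0L))
  expect_identical(nrow(tab), 2L)
  g <- tab[tab$sequence == "GVELCFPENETPPEGK", ]
  expect_identical(g$start, 1979L)
  expect_identical(g$end, 1994L)
  expect_match(g$mods, "carbamidomethyl@1983")
  expect_equal(g$neutral_mass,
               oracle_peptide_mass("GVELCFPENETPPEGK", 57.02146),
               tolerance = 1e-3)
})
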