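pep_unmod <- function(seq, id = "p", offset = 1L) {
  p <- protein_record(id, seq, numbering_offset = offset)
  peptide_form(p, offset, offset + nchar(seq) - 1L)
}

pep_with_biotin <- function(seq, at_local, offset = 1L) {
  p <- protein_record("p", seq, numbering_offset = offset)
  peptide_form(p, offset, offset + nchar(seq) - 1L,
               data.frame(position = offset + at_local - 1L,
                          mod = "biotin-LC"))
}

test_that("y1 of an R-terminated peptide has the canonical mass", {
  fr <- fragment_ions(pep_unmod("NMLIHGR"))
  y1 <- fr$mz[fr$series == "y" & fr$index == 1]
  expect_equal(y1, 175.1190, tolerance = 1e-3)
})

test_that("a biotinylated residue shifts exactly the bracketing ions", {
  mod <- pep_with_biotin("QKAESLQISLEYSGLK", 2L, offset = 468L)
  un <- pep_unmod("QKAESLQISLEYSGLK", offset = 468L)
  fm <- fragment_ions(mod); fu <- fragment_ions(un)
  b2m <- fm$mz[fm$series == "b" & fm$index == 2]
  b2u <- fu$mz[fu$series == "b" & fu$index == 2]
  expect_equal(b2m - b2u, 339.1617, tolerance = 1e-3)
  # b1 precedes the modified K: unshifted
  b1m <- fm$mz[fm$series == "b" & fm$index == 1]
  b1u <- fu$mz[fu$series == "b" & fu$index == 1]
  expect_equal(b1m, b1u, tolerance = 1e-9)
})

test_that("b/y ladders satisfy complementarity on random peptides", {
  set.seed(41)
  for (i in 1:15) {
    sq <- random_sequence(sample(4:20, 1))
    pf <- pep_unmod(sq)
    M <- peptide_form_mass(pf)
    fr <- fragment_ions(pf)
    n <- nchar(sq)
    for (idx in seq_len(n - 1L)) {
      b <- fr$mz[fr$series == "b" & fr$index == idx]
      y <- fr$mz[fr$series == "y" & fr$index == n - idx]
      expect_equal(b + y, M + 2 * 1.007276, tolerance = 1e-5)
    }
  }
})

test_that("site-determining ions are the b/y ions between the two sites", {
  sq <- "VKAESKQISLEYSG"   # 14-mer, K at local 2 and 6
  pf <- pep_with_biotin(sq, 2L)
  sdi <- site_determining_ions(pf, 2L, 6L)
  b_idx <- sort(sdi$siteA$index[sdi$siteA$series == "b"])
  y_idx <- sort(sdi$siteA$index[sdi$siteA$series == "y"])
  expect_identical(b_idx, 2:5)
  expect_identical(y_idx, 9:12)
  # adjacent sites give exactly one differing b and one y
  sq2 <- "AKKGSTL"
  pf2 <- pep_with_biotin(sq2, 2L)
  sdi2 <- site_determining_ions(pf2, 2L, 3L)
  expect_identical(nrow(sdi2$siteA[sdi2$siteA$series == "b", ]), 1L)
  expect_identical(nrow(sdi2$siteA[sdi2$siteA$series == "y", ]), 1L)
  # sites at the extremes differ over the whole ladder
  sq3 <- "KAGSTLK"
  pf3 <- pep_with_biotin(sq3, 1L)
  sdi3 <- site_determining_ions(pf3, 1L, 7L)
  expect_identical(sort(sdi3$siteA$index[sdi3$siteA$series == "b"]), 1:6)
  expect_identical(sort(sdi3$siteA$index[sdi3$siteA$series == "y"]), 1:6)
  expect_error(site_determining_ions(pf, 2L, 2L), "differ")
})

test_that("a clean one-site ladder is localized with high confidence", {
  sq <- "VKAESKQISLEYSG"
  pf <- pep_with_biotin(sq, 2L)
  frags <- fragment_ions(pf)   # full ladder for mod at K2
  sp <- spectrum_from_fragments(frags)
  res <- ascore(sp, pf, c(2L, 6L))
  expect_identical(res$best_site, 2L)
  expect_gt(res$delta_ascore, 19)
  # cross-check the binomial tail behind the score at the chosen depth:
  # the winner's score is the tail probability of its matched
  # site-determining ions, and the runner-up's score (winner minus delta)
  # must equal the tail of some attainable match count
  sdi <- site_determining_ions(pf, 2L, 6L)
  n_sdi <- nrow(sdi$siteA)
  p <- res$depth / 100
  score_best <- -10 * log10(oracle_binom_tail(res$matched_sdi, n_sdi, p))
  attainable <- vapply(0:n_sdi, function(k)
    -10 * log10(oracle_binom_tail(k, n_sdi, p)), numeric(1))
  expect_lte(res$delta_ascore, score_best + 1e-9)
  expect_lt(min(abs(attainable - (score_best - res$delta_ascore))), 1e-6)
})

test_that("symmetric evidence yields a zero delta and empty spectra score zero", {
  sq <- "VKAESKQISLEYSG"
  pf <- pep_with_biotin(sq, 2L)
  fA <- fragment_ions(pep_with_biotin(sq, 2L))
  fB <- fragment_ions(pep_with_biotin(sq, 6L))
  both <- rbind(fA, fB)
  sp <- peak_list(both$mz, rep(10, nrow(both)), level = "MS2",
                  precursor_mz = 1000, mz_range = NULL)
  res <- ascore(sp, pf, c(2L, 6L))
  expect_equal(res$delta_ascore, 0, tolerance = 1e-9)
  empty <- peak_list(numeric(0), numeric(0), level = "MS2", mz_range = NULL)
  res0 <- ascore(empty, pf, c(2L, 6L))
  expect_identical(res0$delta_ascore, 0)
  expect_true(all(res0$site_scores == 0))
})

test_that("candidate order does not change the localization", {
  sq <- "KAGSKTLNDKGW"
  pf <- pep_with_biotin(sq, 5L)
  sp <- spectrum_from_fragments(fragment_ions(pf))
  r1 <- ascore(sp, pf, c(1L, 5L, 10L))
  r2 <- ascore(sp, pf, c(10L, 1L, 5L))
  expect_identical(r1$best_site, r2$best_site)
  expect_identical(r1$delta_ascore, r2$delta_ascore)
  expect_identical(r1$best_site, 5L)
  expect_gte(r1$delta_ascore, 0)
})

test_that("single-candidate peptides are unambiguous by construction", {
  pf <- pep_with_biotin("VDMNQKSILWSALK", 6L, offset = 454L)
  res <- ascore(peak_list(500, 1, level = "MS2", mz_range = NULL), pf, 459L)
  expect_true(res$unambiguous)
  expect_identical(res$best_site, 459L)
  expect_identical(res$delta_ascore, Inf)
})

test_that("the internal lysine wins over the cleaved C-terminal lysine", {
  # simulated spectrum of the blocked-cleavage peptide with biotin on the
  # internal K; the C-terminal K competes as an alternative hypothesis
  pf <- pep_with_biotin("VDMNQKSILWSALK", 6L, offset = 454L)
  sp <- spectrum_from_fragments(fragment_ions(pf))
  res <- ascore(sp, pf, c(459L, 467L))
  expect_identical(res$best_site, 459L)
  expect_gt(res$delta_ascore, 19)
})

test_that("distractor-only peaks cannot manufacture confidence", {
  sq <- "VKAESKQISLEYSG"
  pf <- pep_with_biotin(sq, 2L)
  frags <- fragment_ions(pf)
  sp1 <- spectrum_from_fragments(frags)
  res1 <- ascore(sp1, pf, c(2L, 6L))
  # add peaks matching neither hypothesis, weaker than the signal
  set.seed(42)
  noise_mz <- runif(30, 150, 1500)
  sp2 <- peak_list(c(frags$mz, noise_mz),
                   c(rev(seq_len(nrow(frags))) * 10, rep(1, 30)),
                   level = "MS2", precursor_mz = 1000, mz_range = NULL)
  res2 <- ascore(sp2, pf, c(2L, 6L))
  expect_identical(res2$best_site, res1$best_site)
  # fixed depth granularity: the delta cannot jump upward by more than the
  # score of one extra chance match
  expect_lte(res2$delta_ascore, res1$delta_ascore + 1e-6)
})
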