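loc_result <- function(pf, site, delta, unambiguous = FALSE) {
  structure(list(peptide = pf, candidate_sites = site, site_scores = numeric(0),
                 best_site = site, runner_up = integer(0),
                 delta_ascore = delta, unambiguous = unambiguous,
                 depth = 1L, matched_sdi = 0L),
            class = "SiteLocalizationResult")
}

test_that("accessibility maps apply the confidence and witness filters", {
  p <- protein_record("atr", "GVELCFPENETPPEGKNMLIHGR",
                      numbering_offset = 1979L)
  pf <- peptide_form(p, 1979L, 2001L,
                     data.frame(position = 1994L, mod = "biotin-LC"))
  m1 <- build_accessibility_map(NULL, list(loc_result(pf, 1994L, 40)), p,
                                state_label = "trans")
  expect_identical(m1$modified$residue, 1994L)
  # below threshold -> empty map
  m2 <- build_accessibility_map(NULL, list(loc_result(pf, 1994L, 5)), p)
  expect_identical(nrow(m2$modified), 0L)
  # unambiguous counts as confident regardless of delta
  m3 <- build_accessibility_map(NULL,
                                list(loc_result(pf, 1994L, 0, TRUE)), p)
  expect_identical(m3$modified$residue, 1994L)
  # witness threshold
  m4 <- build_accessibility_map(NULL,
                                list(loc_result(pf, 1994L, 40),
                                     loc_result(pf, 1994L, 25)), p,
                                min_witnesses = 2L)
  expect_identical(m4$modified$n_spectra, 2L)
  m5 <- build_accessibility_map(NULL, list(loc_result(pf, 1994L, 40)), p,
                                min_witnesses = 2L)
  expect_identical(nrow(m5$modified), 0L)
})

test_that("raising the confidence threshold never grows a map", {
  p <- protein_record("p", "AGKSTKLNDKR")
  pfs <- lapply(c(3L, 6L, 10L), function(k)
    peptide_form(p, 1L, 11L, data.frame(position = k, mod = "biotin-LC")))
  locs <- list(loc_result(pfs[[1]], 3L, 10), loc_result(pfs[[2]], 6L, 25),
               loc_result(pfs[[3]], 10L, 50))
  sizes <- vapply(c(0, 15, 30, 60), function(th)
    nrow(build_accessibility_map(NULL, locs, p,
                                 min_delta_ascore = th)$modified),
    integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("conflicting protein ids are rejected", {
  p <- protein_record("p", "AGKSTR")
  q <- protein_record("q", "AGKSTR")
  pf <- peptide_form(q, 1L, 6L, data.frame(position = 3L, mod = "biotin-LC"))
  expect_error(build_accessibility_map(NULL, list(loc_result(pf, 3L, 40)), p),
               "conflicting")
})

test_that("the published differential worked example is reproduced", {
  shared <- c(350L, 600L, 2589L)
  cis <- accessibility_map(c(shared, 459L, 469L), "cis", "ATR")
  trans <- accessibility_map(c(shared, 818L, 1005L, 1057L, 1703L, 1994L,
                               2200L, 2413L), "trans", "ATR")
  rep <- compare_states(cis, trans)
  expect_identical(rep$unique_to_A, c(459L, 469L))
  expect_identical(rep$unique_to_B,
                   c(818L, 1005L, 1057L, 1703L, 1994L, 2200L, 2413L))
  expect_identical(rep$shared, shared)
  # mirror symmetry
  rev <- compare_states(trans, cis)
  expect_identical(rev$unique_to_A, rep$unique_to_B)
  expect_identical(rev$unique_to_B, rep$unique_to_A)
  # partition: pairwise disjoint, union covers everything
  allpos <- c(rep$unique_to_A, rep$unique_to_B, rep$shared)
  expect_identical(anyDuplicated(allpos), 0L)
  expect_setequal(allpos, union(cis$modified$residue, trans$modified$residue))
})

test_that("identical and disjoint maps degenerate correctly", {
  a <- accessibility_map(c(1L, 5L), "a", "P")
  b <- accessibility_map(c(1L, 5L), "b", "P")
  r <- compare_states(a, b)
  expect_length(r$unique_to_A, 0L)
  expect_length(r$unique_to_B, 0L)
  d <- compare_states(a, accessibility_map(c(7L, 9L), "c", "P"))
  expect_length(d$shared, 0L)
  expect_identical(d$unique_to_A, c(1L, 5L))
  expect_identical(d$unique_to_B, c(7L, 9L))
  expect_error(compare_states(a, accessibility_map(1L, "x", "other")),
               "different proteins")
})

test_that("replicate pooling unions or intersects evidence", {
  wt <- accessibility_map(c(459L, 469L, 600L), "WT", "ATR")
  s428a <- accessibility_map(c(459L, 600L), "S428A", "ATR")
  expect_identical(pool_maps(list(wt, s428a))$modified$residue,
                   c(459L, 469L, 600L))
  expect_identical(pool_maps(list(wt, s428a),
                             rule = "intersection")$modified$residue,
                   c(459L, 600L))
})

test_that("domain annotation distinguishes core, flank and unassigned", {
  expect_identical(domain_of(469L), "BH3")
  expect_identical(domain_of(459L), "flank:BH3")         # 2 below BH3 start
  expect_identical(domain_of(2413L), "KD")
  expect_identical(domain_of(459L, flank_window = 1L), "unassigned")
  expect_identical(domain_of(100L), "unassigned")
  cis <- accessibility_map(c(459L, 469L), "cis", "ATR")
  trans <- accessibility_map(2413L, "trans", "ATR")
  ann <- annotate_domains(compare_states(cis, trans))
  expect_identical(ann$domain[ann$residue == 469L], "BH3")
  expect_identical(ann$domain[ann$residue == 459L], "flank:BH3")
  expect_identical(ann$domain[ann$residue == 2413L], "KD")
  tal <- attr(ann, "tally")
  expect_identical(sum(tal$n), nrow(ann))
})

test_that("printed peptide lists are counted by their lowercase marks", {
  fix <- atr_table2_fixture()
  trans <- count_modified_in_printed_list(fix[fix$isoform == "trans", ])
  cis <- count_modified_in_printed_list(fix[fix$isoform == "cis", ])
  expect_identical(trans$n_with_modified_k, 2L)
  expect_identical(cis$n_with_modified_k, 1L)
  expect_identical(count_modified_in_printed_list(c("AGKR", "LLK"))$n_with_modified_k,
                   0L)
  expect_error(count_modified_in_printed_list("AGxKR"), "unknown lowercase")
})
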