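# Accessors for the bundled worked-example data: published peptide lists
# and modified-lysine calls for the ATR cis/trans footprinting comparison,
# transcribed into plain-text tables under inst/extdata.

#' Bundled ATR worked-example tables
#'
#' \code{atr_table2_fixture()} returns the published dimer-interface peptide
#' lists for the trans and cis isoforms, sequences as printed with lowercase
#' \code{k} marking a biotin-modified lysine; the printed residue ranges are
#' kept as labels (some are internally inconsistent with the peptide
#' lengths and must not be used as coordinates).
#' \code{atr_modified_lysine_calls()} returns the per-isoform
#' modified-lysine call lists (the two cis-unique and seven trans-unique
#' residues, plus the jointly modified lysine near the kinase substrate
#' entry groove). \code{atr_domain_table()} returns the two published
#' domain boundaries (BH3-like domain and kinase domain).
#'
#' @return Data.frames; see \code{\link{read_peptide_fixture}} and
#'   \code{\link{read_domain_table}} for the schemas.
#' @export
atr_table2_fixture <- function() {
  read_peptide_fixture(system.file("extdata", "atr_table2_peptides.tsv",
                                   package = "footprintr", mustWork = TRUE))
}

#' @rdname atr_table2_fixture
#' @export
atr_modified_lysine_calls <- function() {
  utils::read.delim(system.file("extdata", "atr_fig2_modified_lysines.tsv",
                                package = "footprintr", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' @rdname atr_table2_fixture
#' @export
atr_domain_table <- function() {
  read_domain_table(system.file("extdata", "atr_domains.tsv",
                                package = "footprintr", mustWork = TRUE))
}
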