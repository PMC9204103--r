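# Pipeline orchestration: enumerate candidate modforms -> PMF-match each
# state's MS1 spectrum -> localize the biotin on every matched modified
# peptide with its MS/MS spectrum -> build per-state accessibility maps ->
# differential comparison -> domain annotation. Every artifact is written
# to the output directory and listed, with a checksum, in a run manifest.

#' Analyze one state's spectra against a protein
#'
#' @param protein A \code{ProteinRecord}.
#' @param ms1 MS1 \code{PeakList} of this state.
#' @param ms2 List of MS2 \code{PeakList}s (precursor m/z set) for this
#'   state.
#' @param state_label State name.
#' @param candidates Optional pre-enumerated list of \code{PeptideForm};
#'   computed by \code{\link{enumerate_modforms}} if NULL.
#' @param tol_ppm MS1 match tolerance (ppm).
#' @param charge_states MS1 charge states to consider.
#' @param fragment_tol MS/MS match tolerance (Da).
#' @param min_delta_ascore,min_witnesses Accessibility-call thresholds.
#' @param precursor_tol Tolerance (Da) linking an MS2 precursor to its MS1
#'   peak.
#' @param mod The ambiguous modification being localized.
#' @param ... Passed to \code{\link{enumerate_modforms}}.
#' @return List with \code{matches}, \code{localizations}, \code{map}, and
#'   \code{coverage}.
#' @export
analyze_state <- function(protein, ms1, ms2 = list(), state_label = "state",
                          candidates = NULL, tol_ppm = 50,
                          charge_states = c(1L, 2L), fragment_tol = 0.5,
                          min_delta_ascore = 19, min_witnesses = 1L,
                          precursor_tol = 0.02, mod = mod_biotin_lc(), ...) {
  if (is.null(candidates))
    candidates <- enumerate_modforms(protein, variable_mods = list(mod), ...)
  res <- match_pmf(candidates, ms1, tol_ppm = tol_ppm,
                   charge_states = charge_states)
  assigned <- res$assigned
  localizations <- list()
  if (nrow(assigned) > 0L) {
    prec <- if (length(ms2) > 0L)
      vapply(ms2, function(p) attr(p, "precursor_mz"), numeric(1))
    else numeric(0)
    for (r in seq_len(nrow(assigned))) {
      hit <- which(abs(prec - assigned$observed_mz[r]) <= precursor_tol)
      if (length(hit) == 0L) next
      # isobaric MS1 candidates are indistinguishable by ppm alone; the
      # linked MS/MS spectrum adjudicates: re-rank this peak's in-tolerance
      # candidates by fraction of matched ladder ions
      rows <- res$all_matches[res$all_matches$peak_index ==
                                assigned$peak_index[r], , drop = FALSE]
      if (nrow(rows) > 1L) {
        best <- .ms2_rescore(rows, candidates, ms2[[hit[1]]], fragment_tol)
        if (!is.null(best)) assigned[r, ] <- rows[best, ]
      }
      if (!grepl(mod$name, assigned$mods[r], fixed = TRUE)) next
      form <- candidates[[assigned$candidate_index[r]]]
      cand_sites <- .candidate_sites(protein, form, mod)
      for (h in hit) {
        localizations[[length(localizations) + 1L]] <-
          ascore(ms2[[h]], form, cand_sites, window_tol_da = fragment_tol,
                 mod = mod)
      }
    }
  }
  map <- build_accessibility_map(assigned, localizations, protein,
                                 state_label = state_label,
                                 min_delta_ascore = min_delta_ascore,
                                 min_witnesses = min_witnesses)
  list(matches = res, localizations = localizations, map = map,
       coverage = sequence_coverage(assigned, protein))
}

# fraction of a candidate's b/y ladder matched by the spectrum; ties keep
# the ppm ordering of `rows` (already best-first for the assigned peak)
.ms2_rescore <- function(rows, candidates, spectrum, fragment_tol) {
  if (nrow(spectrum) == 0L) return(NULL)
  obs <- sort(spectrum$mz)
  frac <- vapply(seq_len(nrow(rows)), function(k) {
    form <- candidates[[rows$candidate_index[k]]]
    if (nchar(form$sequence) < 2L) return(0)
    theo <- fragment_ions(form)$mz
    .count_matches(theo, obs, fragment_tol) / length(theo)
  }, numeric(1))
  ord <- order(-frac, abs(rows$error_ppm))
  ord[1]
}

# candidate sites for localization: target residues of the peptide, minus a
# C-terminal K that was produced by cleavage (it cannot carry the blocking
# mod -- trypsin cut there)
.candidate_sites <- function(protein, form, mod) {
  res <- strsplit(form$sequence, "")[[1]]
  pos <- which(res %in% mod$targets) + form$start - 1L
  n_prot <- protein$numbering_offset + nchar(protein$sequence) - 1L
  if (isTRUE(mod$blocks_cleavage) && form$end < n_prot)
    pos <- setdiff(pos, form$end)
  pos
}

#' Run the full two-state footprinting comparison
#'
#' Accepts either a \code{SyntheticConfig} (the experiment is simulated,
#' analyzed, and scored against its own ground truth) or explicit inputs
#' (protein plus per-state MS1/MS2 peak lists).
#'
#' @param config A \code{SyntheticConfig}, or NULL when explicit inputs are
#'   given.
#' @param protein,ms1,ms2 Explicit inputs: a \code{ProteinRecord}; named
#'   lists (one entry per state) of MS1 \code{PeakList} and of lists of MS2
#'   \code{PeakList}s.
#' @param domains Domain table (data.frame name/start/end).
#' @param flank_window Domain flank width.
#' @param out_dir Output directory for artifacts and the run manifest;
#'   NULL writes nothing.
#' @param tol_ppm,charge_states,fragment_tol,min_delta_ascore,min_witnesses
#'   Analysis thresholds (see \code{\link{analyze_state}}).
#' @param ... Passed to \code{\link{enumerate_modforms}}.
#' @return List with per-state results (\code{states}), the
#'   \code{DifferentialReport} (\code{report}), the domain annotation
#'   (\code{annotated}), and, for synthetic runs, \code{recovery} metrics
#'   and the simulation (\code{sim}).
#' @export
run_footprint_pipeline <- function(config = NULL, protein = NULL,
                                   ms1 = NULL, ms2 = NULL,
                                   domains = default_domains(),
                                   flank_window = 5L, out_dir = NULL,
                                   tol_ppm = 50, charge_states = c(1L, 2L),
                                   fragment_tol = NULL,
                                   min_delta_ascore = 19,
                                   min_witnesses = 1L, ...) {
  sim <- NULL
  if (!is.null(config)) {
    sim <- simulate_experiment(config)
    protein <- sim$protein
    ms1 <- sim$ms1
    ms2 <- sim$ms2
    if (is.null(fragment_tol)) fragment_tol <- config$fragment_tol
  }
  if (is.null(fragment_tol)) fragment_tol <- 0.5
  if (is.null(protein) || is.null(ms1))
    stop("either a synthetic config or explicit protein + ms1 inputs required")
  states <- names(ms1)
  if (length(states) != 2L) stop("exactly two states required")

  candidates <- enumerate_modforms(protein, ...)
  results <- lapply(states, function(s)
    analyze_state(protein, ms1[[s]], if (is.null(ms2)) list() else ms2[[s]],
                  state_label = s, candidates = candidates,
                  tol_ppm = tol_ppm, charge_states = charge_states,
                  fragment_tol = fragment_tol,
                  min_delta_ascore = min_delta_ascore,
                  min_witnesses = min_witnesses))
  names(results) <- states

  report <- compare_states(results[[1]]$map, results[[2]]$map)
  annotated <- annotate_domains(report, domains, flank_window)
  out <- list(states = results, report = report, annotated = annotated,
              sim = sim)
  if (!is.null(sim)) {
    maps <- lapply(results, `[[`, "map")
    out$recovery <- evaluate_recovery(sim$truth, report, maps)
  }
  if (!is.null(out_dir))
    .write_pipeline_artifacts(out, out_dir, protein,
                              list(tol_ppm = tol_ppm,
                                   charge_states = charge_states,
                                   fragment_tol = fragment_tol,
                                   min_delta_ascore = min_delta_ascore,
                                   min_witnesses = min_witnesses,
                                   flank_window = flank_window,
                                   seed = if (!is.null(config)) config$seed))
  out
}

.write_pipeline_artifacts <- function(out, out_dir, protein, params) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in names(out$states)) {
    f1 <- file.path(out_dir, paste0("matches_", s, ".tsv"))
    write_report(out$states[[s]]$matches$assigned, f1)
    f2 <- file.path(out_dir, paste0("localizations_", s, ".tsv"))
    write_report(localization_table(out$states[[s]]$localizations,
                                    params$min_delta_ascore), f2)
    files <- c(files, f1, f2)
  }
  f3 <- file.path(out_dir, "differential.tsv")
  write_report(out$annotated, f3)
  f4 <- file.path(out_dir, "differential.json")
  jsonlite::write_json(
    list(protein_id = out$report$protein_id,
         state_A = out$report$state_A, state_B = out$report$state_B,
         unique_to_A = out$report$unique_to_A,
         unique_to_B = out$report$unique_to_B, shared = out$report$shared),
    f4, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f3, f4)
  manifest <- list(
    protein = list(id = protein$id, length = nchar(protein$sequence),
                   numbering_offset = protein$numbering_offset),
    parameters = params,
    outputs = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
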