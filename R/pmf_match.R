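# Peptide-mass-fingerprint matching: theoretical digest masses vs an MS1
# peak list. MALDI spectra are dominated by singly protonated species, so
# the default charge set is {1}; ESI-style data can widen it.

#' Match candidate peptides against an MS1 peak list
#'
#' Every (peak, candidate, charge) combination within \code{tol_ppm} is
#' recorded; each peak is then assigned its single best candidate by
#' absolute ppm error, with ties broken by fewer modifications, then fewer
#' missed cleavages, then lexicographic sequence (a total order, so the
#' assignment is deterministic). The full many-to-many list is kept for
#' diagnostics.
#'
#' @param candidates List of \code{PeptideForm} (non-empty).
#' @param peaks An MS1 \code{PeakList}.
#' @param tol_ppm Mass tolerance in ppm (default 50, typical for
#'   reflector-mode MALDI-TOF MS1).
#' @param charge_states Integer charge states to consider (default 1).
#' @param mod_registry Mod-name registry for mass computation.
#' @return List with \code{assigned} (one row per matched peak) and
#'   \code{all_matches} (every in-tolerance combination); both data.frames
#'   with columns peak_index, observed_mz, theoretical_mz, error_ppm,
#'   charge, candidate_index, protein_id, start, end, sequence, mods,
#'   missed_cleavages.
#' @export
match_pmf <- function(candidates, peaks, tol_ppm = 50, charge_states = 1L,
                      mod_registry = .default_mod_registry()) {
  if (length(candidates) == 0L) stop("candidate list must be non-empty")
  stopifnot(tol_ppm > 0)
  empty <- data.frame(peak_index = integer(0), observed_mz = numeric(0),
                      theoretical_mz = numeric(0), error_ppm = numeric(0),
                      charge = integer(0), candidate_index = integer(0),
                      protein_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      mods = character(0), missed_cleavages = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L) {
    warning("empty peak list; no matches")
    return(list(assigned = empty, all_matches = empty))
  }
  tab <- peptide_table(candidates, mod_registry)
  rows <- list()
  for (z in sort(unique(as.integer(charge_states)))) {
    theo <- mz_from_mass(tab$neutral_mass, z)
    o <- order(theo)
    theo_s <- theo[o]
    for (p in seq_len(nrow(peaks))) {
      obs <- peaks$mz[p]
      tol_da <- obs * tol_ppm * 1e-6
      lo <- findInterval(obs - tol_da, theo_s) + 1L
      hi <- findInterval(obs + tol_da, theo_s)
      if (hi < lo) next
      idx <- o[lo:hi]
      ppm <- (obs - theo[idx]) / theo[idx] * 1e6
      keep <- abs(ppm) <= tol_ppm
      if (!any(keep)) next
      idx <- idx[keep]; ppm <- ppm[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        peak_index = p, observed_mz = obs, theoretical_mz = theo[idx],
        error_ppm = ppm, charge = z, candidate_index = idx,
        protein_id = tab$protein_id[idx], start = tab$start[idx],
        end = tab$end[idx], sequence = tab$sequence[idx],
        mods = tab$mods[idx], missed_cleavages = tab$missed_cleavages[idx],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(list(assigned = empty, all_matches = empty))
  all_matches <- do.call(rbind, rows)
  n_mods <- lengths(regmatches(all_matches$mods,
                               gregexpr("@", all_matches$mods)))
  ord <- order(all_matches$peak_index, abs(all_matches$error_ppm), n_mods,
               all_matches$missed_cleavages, all_matches$sequence)
  all_sorted <- all_matches[ord, , drop = FALSE]
  assigned <- all_sorted[!duplicated(all_sorted$peak_index), , drop = FALSE]
  rownames(assigned) <- NULL
  rownames(all_matches) <- NULL
  list(assigned = assigned, all_matches = all_matches)
}

#' Residue-level sequence coverage of matched peptides
#'
#' @param matches data.frame of matches (the \code{assigned} table of
#'   \code{\link{match_pmf}}), or a list of \code{PeptideForm}.
#' @param protein The \code{ProteinRecord} the matches refer to.
#' @return Fraction of protein residues covered by at least one matched
#'   peptide, in [0, 1].
#' @export
sequence_coverage <- function(matches, protein) {
  n <- nchar(protein$sequence)
  covered <- rep(FALSE, n)
  if (is.data.frame(matches)) {
    if (nrow(matches) > 0L) {
      m <- matches[matches$protein_id == protein$id, , drop = FALSE]
      for (k in seq_len(nrow(m))) {
        i <- .to_index(protein, m$start[k]); j <- .to_index(protein, m$end[k])
        covered[max(1L, i):min(n, j)] <- TRUE
      }
    }
  } else {
    for (f in matches) {
      if (f$protein_id != protein$id) next
      i <- .to_index(protein, f$start); j <- .to_index(protein, f$end)
      covered[max(1L, i):min(n, j)] <- TRUE
    }
  }
  mean(covered)
}
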