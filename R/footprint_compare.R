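# Differential surface accessibility. Per conformational state, confidently
# localized biotin-lysines are pooled into an accessibility map; comparing
# two maps yields the lysines unique to each state (the footprinting
# readout: a residue labeled in one conformer but protected in the other),
# annotated by protein domain.

#' Build a per-state accessibility map
#'
#' A lysine is called modified iff at least \code{min_witnesses} spectra
#' support it with \code{delta_ascore >= min_delta_ascore}; unambiguous
#' localizations (single-candidate peptides) count as confident.
#'
#' @param matches Assigned match table from \code{\link{match_pmf}} (used to
#'   check protein identity; may be NULL).
#' @param localizations List of \code{SiteLocalizationResult}.
#' @param protein The \code{ProteinRecord} of this state.
#' @param state_label Name of the state (e.g. "cis", "trans").
#' @param min_delta_ascore Localization confidence threshold (default 19).
#' @param min_witnesses Minimum supporting spectra per site (default 1).
#' @return An \code{AccessibilityMap}: list(state_label, protein_id,
#'   modified = data.frame(residue, n_spectra, best_delta_ascore, peptides)).
#' @export
build_accessibility_map <- function(matches = NULL, localizations, protein,
                                    state_label = "state",
                                    min_delta_ascore = 19,
                                    min_witnesses = 1L) {
  ids <- unique(c(
    if (!is.null(matches) && nrow(matches) > 0L) matches$protein_id,
    vapply(localizations, function(r) r$peptide$protein_id, character(1))
  ))
  if (length(ids) > 0L && any(ids != protein$id))
    stop("conflicting protein ids: ", paste(unique(ids), collapse = ", "),
         " vs ", protein$id)
  kpos <- lysine_positions(protein)
  ev <- list()
  for (r in localizations) {
    confident <- r$unambiguous || r$delta_ascore >= min_delta_ascore
    if (!confident) next
    for (site in r$best_site) {
      key <- as.character(site)
      if (!site %in% kpos)
        stop("localized site ", site, " is not a lysine of ", protein$id)
      e <- ev[[key]]
      if (is.null(e)) e <- list(n = 0L, best = -Inf, pep = character(0))
      e$n <- e$n + 1L
      e$best <- max(e$best, r$delta_ascore)
      e$pep <- union(e$pep, r$peptide$sequence)
      ev[[key]] <- e
    }
  }
  keep <- names(ev)[vapply(ev, function(e) e$n >= min_witnesses, logical(1))]
  keep <- keep[order(as.integer(keep))]
  modified <- data.frame(
    residue = as.integer(keep),
    n_spectra = vapply(ev[keep], function(e) e$n, integer(1)),
    best_delta_ascore = vapply(ev[keep], function(e) e$best, numeric(1)),
    peptides = vapply(ev[keep], function(e) paste(e$pep, collapse = ";"),
                      character(1)),
    stringsAsFactors = FALSE
  )
  rownames(modified) <- NULL
  structure(list(state_label = state_label, protein_id = protein$id,
                 modified = modified),
            class = "AccessibilityMap")
}

#' Construct an accessibility map directly from residue calls
#'
#' For fixture data (published modified-lysine call lists) where spectra are
#' not re-derived.
#'
#' @param residues Integer vector of modified lysine positions.
#' @param state_label State name.
#' @param protein_id Protein id.
#' @return An \code{AccessibilityMap}.
#' @export
accessibility_map <- function(residues, state_label = "state",
                              protein_id = "protein") {
  residues <- sort(unique(as.integer(residues)))
  structure(list(state_label = state_label, protein_id = protein_id,
                 modified = data.frame(residue = residues,
                                       n_spectra = rep(1L, length(residues)),
                                       best_delta_ascore = rep(Inf, length(residues)),
                                       peptides = rep("", length(residues)),
                                       stringsAsFactors = FALSE)),
            class = "AccessibilityMap")
}

#' @export
print.AccessibilityMap <- function(x, ...) {
  cat(sprintf("AccessibilityMap '%s' (%s): %d modified lysine(s)\n",
              x$state_label, x$protein_id, nrow(x$modified)))
  if (nrow(x$modified) > 0L)
    cat(" ", paste0("K", x$modified$residue, collapse = ", "), "\n")
  invisible(x)
}

#' Pool accessibility maps of replicate states
#'
#' @param maps List of \code{AccessibilityMap} of the same protein.
#' @param rule "union" (a site counts if seen in any replicate; default,
#'   matching joint reporting of equivalent states) or "intersection".
#' @param state_label Label for the pooled map.
#' @return An \code{AccessibilityMap}.
#' @export
pool_maps <- function(maps, rule = c("union", "intersection"),
                      state_label = "pooled") {
  rule <- match.arg(rule)
  pid <- unique(vapply(maps, `[[`, character(1), "protein_id"))
  if (length(pid) != 1L) stop("maps refer to different proteins")
  sets <- lapply(maps, function(m) m$modified$residue)
  res <- if (rule == "union") Reduce(union, sets) else Reduce(intersect, sets)
  accessibility_map(res, state_label, pid)
}

#' Compare two accessibility maps
#'
#' @param mapA,mapB \code{AccessibilityMap}s of the same protein.
#' @return A \code{DifferentialReport}: list(state_A, state_B, unique_to_A,
#'   unique_to_B, shared) with sorted integer residue sets.
#' @export
compare_states <- function(mapA, mapB) {
  if (mapA$protein_id != mapB$protein_id)
    stop("maps refer to different proteins: ", mapA$protein_id, " vs ",
         mapB$protein_id)
  a <- mapA$modified$residue; b <- mapB$modified$residue
  structure(list(protein_id = mapA$protein_id,
                 state_A = mapA$state_label, state_B = mapB$state_label,
                 unique_to_A = sort(setdiff(a, b)),
                 unique_to_B = sort(setdiff(b, a)),
                 shared = sort(intersect(a, b))),
            class = "DifferentialReport")
}

#' @export
print.DifferentialReport <- function(x, ...) {
  cat(sprintf("DifferentialReport %s: %s vs %s\n", x$protein_id, x$state_A,
              x$state_B))
  cat(sprintf("  unique to %s (%d): %s\n", x$state_A, length(x$unique_to_A),
              paste0("K", x$unique_to_A, collapse = ", ")))
  cat(sprintf("  unique to %s (%d): %s\n", x$state_B, length(x$unique_to_B),
              paste0("K", x$unique_to_B, collapse = ", ")))
  cat(sprintf("  shared (%d): %s\n", length(x$shared),
              paste0("K", x$shared, collapse = ", ")))
  invisible(x)
}

#' Default domain table
#'
#' Only boundaries published for the studied kinase ship as defaults: the
#' BH3-like domain (aa 461-474) and the kinase domain (aa 2206-2615). All
#' other domains must be user-supplied.
#'
#' @return data.frame(name, start, end).
#' @export
default_domains <- function() {
  data.frame(name = c("BH3", "KD"), start = c(461L, 2206L),
             end = c(474L, 2615L), stringsAsFactors = FALSE)
}

#' Assign residues to domains
#'
#' A residue inside a domain is labeled with the domain name; within
#' \code{flank_window} residues of a boundary it is labeled
#' \code{"flank:<name>"}; otherwise \code{"unassigned"}.
#'
#' @param residues Integer positions.
#' @param domains data.frame(name, start, end).
#' @param flank_window Flank width in residues (default 5).
#' @return Character vector of labels, same length as \code{residues}.
#' @export
domain_of <- function(residues, domains = default_domains(), flank_window = 5L) {
  vapply(as.integer(residues), function(p) {
    inside <- which(domains$start <= p & p <= domains$end)
    if (length(inside) > 0L) return(domains$name[inside[1]])
    near <- which(domains$start - flank_window <= p & p < domains$start |
                  domains$end < p & p <= domains$end + flank_window)
    if (length(near) > 0L) return(paste0("flank:", domains$name[near[1]]))
    "unassigned"
  }, character(1))
}

#' Annotate a differential report by protein domain
#'
#' @param report A \code{DifferentialReport}.
#' @param domains data.frame(name, start, end).
#' @param flank_window Flank width (default 5).
#' @return data.frame(state, residue, classification, domain) with one row
#'   per evidenced residue, plus a per-domain tally in attribute
#'   \code{"tally"}.
#' @export
annotate_domains <- function(report, domains = default_domains(),
                             flank_window = 5L) {
  rows <- rbind(
    data.frame(state = report$state_A, residue = report$unique_to_A,
               classification = paste0("unique_to_", report$state_A)),
    data.frame(state = report$state_B, residue = report$unique_to_B,
               classification = paste0("unique_to_", report$state_B)),
    if (length(report$shared) > 0L)
      data.frame(state = "both", residue = report$shared,
                 classification = "shared")
  )
  if (is.null(rows) || nrow(rows) == 0L)
    return(data.frame(state = character(0), residue = integer(0),
                      classification = character(0), domain = character(0),
                      stringsAsFactors = FALSE))
  rows$domain <- domain_of(rows$residue, domains, flank_window)
  tally <- stats::aggregate(residue ~ classification + domain, rows, length)
  names(tally)[names(tally) == "residue"] <- "n"
  attr(rows, "tally") <- tally
  rows
}

#' Count modified peptides in a printed peptide list
#'
#' Published peptide tables mark biotin-modified lysines with a lowercase
#' \code{k} (and carbamidomethyl cysteines with a lowercase \code{c}). Any
#' other lowercase letter is an unknown mark and rejected.
#'
#' @param fixture data.frame with a \code{sequence} column (see
#'   \code{\link{read_peptide_fixture}}), or a character vector of printed
#'   sequences.
#' @return list(n_peptides, n_with_modified_k).
#' @export
count_modified_in_printed_list <- function(fixture) {
  seqs <- if (is.data.frame(fixture)) fixture$sequence else as.character(fixture)
  low <- unlist(regmatches(seqs, gregexpr("[a-z]", seqs)))
  bad <- setdiff(unique(low), c("k", "c"))
  if (length(bad) > 0L)
    stop("unknown lowercase mark(s) in printed list: ",
         paste(bad, collapse = ", "))
  list(n_peptides = length(seqs),
       n_with_modified_k = sum(grepl("k", seqs, fixed = TRUE)))
}
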