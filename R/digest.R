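# Modification-aware in-silico trypsin digestion. The footprinting signal
# rides on one rule: a biotinylated lysine is no longer a substrate for
# trypsin, so the cut it would have produced disappears and the two flanking
# tryptic peptides fuse into a single "digestion-protected" peptide carrying
# the adduct. That blocked site is not a missed cleavage -- it is not a
# candidate site at all -- which keeps missed-cleavage filters meaningful.

#' Construct a protein record
#'
#' @param id Protein identifier.
#' @param sequence Residue string (uppercased; 20-letter alphabet only).
#' @param numbering_offset Position label of the first residue (default 1).
#'   The construct studied here numbers a FLAG methionine as 1 with the
#'   first native residue labeled 2; offsets let peptide coordinates follow
#'   the author-defined numbering.
#' @return A \code{ProteinRecord} list with fields id, sequence,
#'   numbering_offset.
#' @export
protein_record <- function(id, sequence, numbering_offset = 1L) {
  sequence <- toupper(sequence)
  res <- .check_sequence(sequence)
  if (length(res) == 0L) stop("protein sequence must be non-empty")
  out <- list(id = as.character(id), sequence = sequence,
              numbering_offset = as.integer(numbering_offset))
  class(out) <- "ProteinRecord"
  out
}

#' @export
print.ProteinRecord <- function(x, ...) {
  cat("ProteinRecord", x$id, "(", nchar(x$sequence), "aa, residues",
      x$numbering_offset, "-", x$numbering_offset + nchar(x$sequence) - 1L,
      ")\n")
  invisible(x)
}

#' Lysine positions of a protein (in protein numbering)
#' @param protein A \code{ProteinRecord}.
#' @return Integer vector of position labels of all K residues.
#' @export
lysine_positions <- function(protein) {
  idx <- which(strsplit(protein$sequence, "")[[1]] == "K")
  idx + protein$numbering_offset - 1L
}

# label <-> internal 1-based index
.to_index <- function(protein, pos) as.integer(pos) - protein$numbering_offset + 1L
.to_label <- function(protein, idx) as.integer(idx) + protein$numbering_offset - 1L

#' Tryptic cleavage sites of a protein
#'
#' Trypsin cuts C-terminal to K or R, suppressed when the next residue is
#' proline. Returned positions are the residues after which the cut occurs,
#' in protein numbering; the C-terminus is not a site.
#'
#' @param protein A \code{ProteinRecord}.
#' @return Ordered integer vector of cut positions (possibly empty).
#' @export
cleavage_sites <- function(protein) {
  res <- strsplit(protein$sequence, "")[[1]]
  n <- length(res)
  if (n < 2L) return(integer(0))
  p <- which(res[-n] %in% c("K", "R"))
  p <- p[res[p + 1L] != "P"]
  .to_label(protein, p)
}

.mods_df <- function(positions = integer(0), names = character(0)) {
  data.frame(position = as.integer(positions), mod = as.character(names),
             stringsAsFactors = FALSE)
}

#' Construct a peptide form
#'
#' Coordinates are 1-based inclusive in protein numbering. \code{mods} is a
#' data.frame with columns \code{position} and \code{mod} (name).
#'
#' @param protein \code{ProteinRecord} the peptide derives from.
#' @param start,end Position labels of the first/last residue.
#' @param mods data.frame(position, mod).
#' @param missed_cleavages Number of internal candidate cleavage sites
#'   (blocked sites excluded).
#' @return A \code{PeptideForm} list.
#' @export
peptide_form <- function(protein, start, end, mods = .mods_df(),
                         missed_cleavages = 0L) {
  i <- .to_index(protein, start); j <- .to_index(protein, end)
  stopifnot(i >= 1L, j <= nchar(protein$sequence), i <= j)
  out <- list(protein_id = protein$id, start = as.integer(start),
              end = as.integer(end),
              sequence = substr(protein$sequence, i, j),
              mods = mods[order(mods$position), , drop = FALSE],
              missed_cleavages = as.integer(missed_cleavages))
  class(out) <- "PeptideForm"
  out
}

#' @export
print.PeptideForm <- function(x, ...) {
  mtxt <- if (nrow(x$mods) == 0L) "" else
    paste0(" [", paste(x$mods$mod, "@", x$mods$position, collapse = ", "), "]")
  cat(sprintf("%s %d-%d %s%s (mc=%d)\n", x$protein_id, x$start, x$end,
              x$sequence, mtxt, x$missed_cleavages))
  invisible(x)
}

# Registry lookup for mod names used inside peptide forms.
.default_mod_registry <- function(extra = list()) {
  reg <- list("biotin-LC" = mod_biotin_lc(),
              "carbamidomethyl" = mod_carbamidomethyl())
  for (m in extra) reg[[m$name]] <- m
  reg
}

#' Neutral mass of a peptide form
#'
#' @param pf A \code{PeptideForm}.
#' @param mod_registry Named list of \code{ModificationDef} resolving the
#'   mod names stored in the form.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_form_mass <- function(pf, mod_registry = .default_mod_registry()) {
  mods <- lapply(seq_len(nrow(pf$mods)), function(k) {
    nm <- pf$mods$mod[k]
    md <- mod_registry[[nm]]
    if (is.null(md)) stop("unknown modification name: ", nm)
    list(position = pf$mods$position[k] - pf$start + 1L, mod = md)
  })
  peptide_mass(pf$sequence, mods)
}

.validate_mod_state <- function(protein, mod_state) {
  res <- strsplit(protein$sequence, "")[[1]]
  for (m in mod_state) {
    idx <- .to_index(protein, m$position)
    if (idx < 1L || idx > length(res))
      stop("modification position ", m$position, " outside protein")
    if (!res[idx] %in% m$mod$targets)
      stop("modification '", m$mod$name, "' not allowed on residue '",
           res[idx], "' at position ", m$position)
  }
  invisible(TRUE)
}

#' Digest a protein under a fixed modification state
#'
#' Cuts at every tryptic site that does not carry a cleavage-blocking
#' modification. Peptides spanning a blocked site carry the modification and
#' do not count it toward \code{missed_cleavages}; unblocked sites may be
#' skipped up to \code{max_missed}. Fixed modifications (carbamidomethyl-C
#' by default) are attached to every target residue.
#'
#' @param protein A \code{ProteinRecord}.
#' @param mod_state List of \code{list(position =, mod = ModificationDef)}:
#'   the variable modifications actually present on the protein.
#' @param max_missed Maximum skipped (unblocked) cleavage sites per peptide.
#' @param fixed_mods List of fixed \code{ModificationDef}s; default
#'   carbamidomethyl on C. Use \code{list()} to disable.
#' @param min_length Minimum peptide length to report (default 1).
#' @return List of \code{PeptideForm}.
#' @export
digest <- function(protein, mod_state = list(), max_missed = 2L,
                   fixed_mods = list(mod_carbamidomethyl()),
                   min_length = 1L) {
  stopifnot(max_missed >= 0L)
  .validate_mod_state(protein, mod_state)
  res <- strsplit(protein$sequence, "")[[1]]
  n <- length(res)
  sites <- .to_index(protein, cleavage_sites(protein))
  mod_pos <- vapply(mod_state, function(m) .to_index(protein, m$position), integer(1))
  blocking <- vapply(mod_state, function(m) isTRUE(m$mod$blocks_cleavage), logical(1))
  blocked <- mod_pos[blocking]
  open_sites <- setdiff(sites, blocked)

  bounds <- c(0L, open_sites, n)   # cut after these indices
  nb <- length(bounds)
  out <- list()
  for (a in seq_len(nb - 1L)) {
    for (b in (a + 1L):nb) {
      missed <- b - a - 1L
      if (missed > max_missed) break
      i <- bounds[a] + 1L; j <- bounds[b]
      if (j - i + 1L < min_length) next
      out[[length(out) + 1L]] <- .make_form(protein, res, i, j, missed,
                                            mod_state, mod_pos, fixed_mods)
    }
  }
  out
}

.make_form <- function(protein, res, i, j, missed, mod_state, mod_pos, fixed_mods) {
  sel <- which(mod_pos >= i & mod_pos <= j)
  positions <- mod_pos[sel]
  names <- vapply(mod_state[sel], function(m) m$mod$name, character(1))
  for (fm in fixed_mods) {
    hit <- which(res[i:j] %in% fm$targets) + i - 1L
    positions <- c(positions, hit)
    names <- c(names, rep(fm$name, length(hit)))
  }
  peptide_form(protein, .to_label(protein, i), .to_label(protein, j),
               .mods_df(.to_label(protein, positions), names), missed)
}

#' Enumerate all candidate modified peptide forms for search
#'
#' Takes the union over all variable-modification hypotheses of
#' \code{\link{digest}} results, deduplicated by (start, end, mod multiset).
#' Every internal lysine of an emitted peptide is either modified (a blocked
#' site) or counted as a missed cleavage; a peptide's C-terminal K is never
#' carrying a cleavage-blocking modification (it could not have been cut
#' there otherwise).
#'
#' @param protein A \code{ProteinRecord}.
#' @param variable_mods List of variable \code{ModificationDef}s
#'   (default: biotin-LC on K).
#' @param max_missed Maximum missed (unblocked) cleavages.
#' @param max_var_mods Maximum variable modifications per peptide (default 5:
#'   saturating labeling routinely fuses several blocked sites into one
#'   peptide).
#' @param fixed_mods Fixed modifications (default carbamidomethyl-C).
#' @param min_length Minimum peptide length.
#' @param cap Maximum number of forms to emit; exceeding it is an error
#'   suggesting a lower \code{max_var_mods}.
#' @return List of \code{PeptideForm}.
#' @export
enumerate_modforms <- function(protein, variable_mods = list(mod_biotin_lc()),
                               max_missed = 2L, max_var_mods = 5L,
                               fixed_mods = list(mod_carbamidomethyl()),
                               min_length = 1L, cap = 50000L) {
  stopifnot(max_missed >= 0L, max_var_mods >= 0L)
  res <- strsplit(protein$sequence, "")[[1]]
  n <- length(res)
  site_idx <- .to_index(protein, cleavage_sites(protein))
  is_site <- rep(FALSE, n); is_site[site_idx] <- TRUE

  blocking_mods <- Filter(function(m) isTRUE(m$blocks_cleavage), variable_mods)

  out <- list()
  seen <- new.env(parent = emptyenv())
  # start boundaries: 0 or any tryptic site (the residue before the peptide
  # must be cuttable, i.e. unmodified in the generating hypothesis -- always
  # realizable since it lies outside the peptide)
  starts <- c(0L, site_idx)
  for (s0 in starts) {
    i <- s0 + 1L
    if (i > n) next
    # walk forward over ends: any tryptic site, or the protein C-terminus
    ends <- c(site_idx[site_idx >= i], if (!is_site[n]) n else integer(0))
    ends <- sort(unique(c(ends, n)))
    for (j in ends) {
      if (j < i || j - i + 1L < min_length) next
      internal <- site_idx[site_idx >= i & site_idx < j]
      if (length(internal) > max_missed + max_var_mods) break
      # choose, per blocking mod, which internal target sites are blocked;
      # remaining internal sites are missed cleavages
      hyp <- .site_hypotheses(res, internal, blocking_mods, max_missed,
                              max_var_mods)
      if (is.null(hyp)) next
      for (h in hyp) {
        # variable mods on the remaining (non-cleavage-site) targets in
        # [i, j]: any residue for non-blocking mods; for blocking mods only
        # non-site targets (K before P, or a protein-terminal K that was
        # never a cut candidate)
        plain_sets <- .plain_hypotheses(res, i, j, variable_mods,
                                        max_var_mods - length(h$mod_pos),
                                        is_site)
        for (ps in plain_sets) {
          positions <- c(h$mod_pos, ps$pos)
          names <- c(h$mod_name, ps$name)
          key <- paste(i, j, paste(sort(paste(positions, names)), collapse = ";"),
                       sep = "|")
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          if (length(out) >= cap)
            stop("modform cap (", cap, ") exceeded at ", length(out),
                 " forms; lower max_var_mods or max_missed")
          mstate <- c(
            lapply(seq_along(h$mod_pos), function(k)
              list(position = .to_label(protein, h$mod_pos[k]),
                   mod = h$mod_def[[k]])),
            lapply(seq_along(ps$pos), function(k)
              list(position = .to_label(protein, ps$pos[k]),
                   mod = ps$def[[k]]))
          )
          mod_posv <- vapply(mstate, function(m) .to_index(protein, m$position),
                             integer(1))
          out[[length(out) + 1L]] <-
            .make_form(protein, res, i, j, h$missed, mstate, mod_posv, fixed_mods)
        }
      }
    }
  }
  out
}

# All ways to assign blocking mods to internal cleavage sites of [i, j):
# each internal site is either blocked by a targeting mod or missed.
.site_hypotheses <- function(res, internal, blocking_mods, max_missed,
                             max_var_mods) {
  if (length(internal) == 0L)
    return(list(list(mod_pos = integer(0), mod_name = character(0),
                     mod_def = list(), missed = 0L)))
  # which blocking mods can sit on each internal site
  choices <- lapply(internal, function(p) {
    mods_here <- Filter(function(m) res[p] %in% m$targets, blocking_mods)
    c(list(NULL), mods_here)   # NULL = left unmodified (missed cleavage)
  })
  grids <- expand.grid(lapply(choices, seq_along))
  hyp <- list()
  for (r in seq_len(nrow(grids))) {
    sel <- as.integer(grids[r, ])
    mods <- mapply(function(ch, s) ch[[s]], choices, sel, SIMPLIFY = FALSE)
    blocked <- !vapply(mods, is.null, logical(1))
    missed <- sum(!blocked)
    if (missed > max_missed || sum(blocked) > max_var_mods) next
    hyp[[length(hyp) + 1L]] <- list(
      mod_pos = internal[blocked],
      mod_name = vapply(mods[blocked], function(m) m$name, character(1)),
      mod_def = mods[blocked],
      missed = missed
    )
  }
  if (length(hyp) == 0L) NULL else hyp
}

# Subsets of variable mods on non-cleavage-site targets within [i, j].
.plain_hypotheses <- function(res, i, j, variable_mods, budget, is_site) {
  empty <- list(list(pos = integer(0), name = character(0), def = list()))
  if (length(variable_mods) == 0L || budget <= 0L) return(empty)
  slots <- list()
  for (m in variable_mods) {
    hit <- which(res[i:j] %in% m$targets) + i - 1L
    if (isTRUE(m$blocks_cleavage)) hit <- hit[!is_site[hit]]
    for (p in hit) slots[[length(slots) + 1L]] <- list(pos = p, def = m)
  }
  if (length(slots) == 0L) return(empty)
  out <- empty
  ns <- length(slots)
  for (size in seq_len(min(budget, ns))) {
    cmb <- utils::combn(ns, size, simplify = FALSE)
    for (cc in cmb) {
      out[[length(out) + 1L]] <- list(
        pos = vapply(slots[cc], `[[`, integer(1), "pos"),
        name = vapply(slots[cc], function(s) s$def$name, character(1)),
        def = lapply(slots[cc], `[[`, "def")
      )
    }
  }
  out
}

#' Tabulate peptide forms
#'
#' @param forms List of \code{PeptideForm}.
#' @param mod_registry Mod-name registry for mass computation.
#' @return data.frame with columns protein_id, start, end, sequence, mods
#'   (semicolon-joined \code{name@position}), missed_cleavages, neutral_mass.
#' @export
peptide_table <- function(forms, mod_registry = .default_mod_registry()) {
  if (length(forms) == 0L)
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      mods = character(0), missed_cleavages = integer(0),
                      neutral_mass = numeric(0)))
  data.frame(
    protein_id = vapply(forms, `[[`, character(1), "protein_id"),
    start = vapply(forms, `[[`, integer(1), "start"),
    end = vapply(forms, `[[`, integer(1), "end"),
    sequence = vapply(forms, `[[`, character(1), "sequence"),
    mods = vapply(forms, function(f)
      paste(sprintf("%s@%d", f$mods$mod, f$mods$position), collapse = ";"),
      character(1)),
    missed_cleavages = vapply(forms, `[[`, integer(1), "missed_cleavages"),
    neutral_mass = vapply(forms, peptide_form_mass, numeric(1),
                          mod_registry = mod_registry),
    stringsAsFactors = FALSE
  )
}
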