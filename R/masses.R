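# Monoisotopic mass arithmetic: elements, residues, modifications, peptides,
# charged species. Everything downstream (digestion, PMF matching, fragment
# ladders) is a sum over these constants, so they are defined once, here.

#' Monoisotopic atomic masses (Da)
#'
#' IUPAC monoisotopic masses of the elements occurring in unmodified and
#' biotinylated peptides. Stored to >= 6 decimals because the biotin adduct
#' is only reproducible monoisotopically.
#'
#' @format Named numeric vector (element symbol -> Da).
#' @export
ATOMIC_MONO <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

#' @rdname ATOMIC_MONO
#' @export
PROTON_MASS <- 1.007276467

#' @rdname ATOMIC_MONO
#' @export
WATER_MASS <- 2 * 1.0078250319 + 15.9949146221

# Residue elemental compositions (residue = amino acid minus water).
# Kept as formulas rather than pre-summed masses so that every mass in the
# package traces back to the same atomic constants.
RESIDUE_FORMULA <- list(
  G = c(C = 2L,  H = 3L,  N = 1L, O = 1L),
  A = c(C = 3L,  H = 5L,  N = 1L, O = 1L),
  S = c(C = 3L,  H = 5L,  N = 1L, O = 2L),
  P = c(C = 5L,  H = 7L,  N = 1L, O = 1L),
  V = c(C = 5L,  H = 9L,  N = 1L, O = 1L),
  T = c(C = 4L,  H = 7L,  N = 1L, O = 2L),
  C = c(C = 3L,  H = 5L,  N = 1L, O = 1L, S = 1L),
  L = c(C = 6L,  H = 11L, N = 1L, O = 1L),
  I = c(C = 6L,  H = 11L, N = 1L, O = 1L),
  N = c(C = 4L,  H = 6L,  N = 2L, O = 2L),
  D = c(C = 4L,  H = 5L,  N = 1L, O = 3L),
  Q = c(C = 5L,  H = 8L,  N = 2L, O = 2L),
  K = c(C = 6L,  H = 12L, N = 2L, O = 1L),
  E = c(C = 5L,  H = 7L,  N = 1L, O = 3L),
  M = c(C = 5L,  H = 9L,  N = 1L, O = 1L, S = 1L),
  H = c(C = 6L,  H = 7L,  N = 3L, O = 1L),
  F = c(C = 9L,  H = 9L,  N = 1L, O = 1L),
  R = c(C = 6L,  H = 12L, N = 4L, O = 1L),
  Y = c(C = 9L,  H = 9L,  N = 1L, O = 2L),
  W = c(C = 11L, H = 10L, N = 2L, O = 1L)
)

#' Construct an elemental composition
#'
#' @param counts Named integer vector or list, element symbol -> count.
#'   Only C, H, N, O, S, P are accepted; all counts must be non-negative.
#' @return An object of class \code{ElementalComposition} (named integer
#'   vector).
#' @examples
#' elemental_composition(c(H = 2, O = 1))
#' @export
elemental_composition <- function(counts) {
  counts <- unlist(counts)
  if (length(counts) == 0L) {
    out <- integer(0)
    class(out) <- "ElementalComposition"
    return(out)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("elemental composition requires named counts")
  unknown <- setdiff(names(counts), names(ATOMIC_MONO))
  if (length(unknown) > 0L)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers")
  out <- as.integer(counts)
  names(out) <- names(counts)
  class(out) <- "ElementalComposition"
  out
}

#' Parse a chemical formula string such as "C16H25N3O3S"
#'
#' @param formula Formula string; element symbols from {C,H,N,O,S,P},
#'   each optionally followed by a count.
#' @return An \code{ElementalComposition}.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!grepl("^([A-Z][a-z]?[0-9]*)*$", formula))
    stop("cannot parse formula: ", formula)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  elems <- sub("[0-9]*$", "", toks)
  cnts <- as.integer(ifelse(grepl("[0-9]", toks), sub("^[A-Za-z]+", "", toks), "1"))
  counts <- tapply(cnts, elems, sum)
  elemental_composition(counts)
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition An \code{ElementalComposition}, a named count vector,
#'   or a formula string.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C16H25N3O3S")  # biotinamidocaproyl adduct, 339.1617 Da
#' @export
monoisotopic_mass <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  if (!inherits(composition, "ElementalComposition"))
    composition <- elemental_composition(composition)
  if (length(composition) == 0L) return(0.0)
  sum(ATOMIC_MONO[names(composition)] * as.numeric(composition))
}

#' Define a peptide modification
#'
#' @param name Modification name.
#' @param targets Character vector of residue letters (and/or terminus
#'   markers \code{"nterm"}, \code{"cterm"}) the modification may sit on.
#' @param composition Optional formula string or composition; if given,
#'   \code{delta_mono} is computed from it.
#' @param delta_mono Monoisotopic mass shift in Da (ignored when
#'   \code{composition} is supplied).
#' @param blocks_cleavage Does the modification abolish trypsin cleavage at
#'   the modified residue?
#' @param mode \code{"fixed"} (applied to every target residue) or
#'   \code{"variable"} (a search hypothesis).
#' @return A \code{ModificationDef} list.
#' @export
modification_def <- function(name, targets, composition = NULL,
                             delta_mono = NULL, blocks_cleavage = FALSE,
                             mode = c("variable", "fixed")) {
  mode <- match.arg(mode)
  targets <- as.character(targets)
  if (length(targets) == 0L) stop("modification '", name, "': targets must be non-empty")
  if (!is.null(composition)) delta_mono <- monoisotopic_mass(composition)
  if (is.null(delta_mono) || !is.finite(delta_mono))
    stop("modification '", name, "': delta_mono must be finite")
  out <- list(name = name, targets = targets, delta_mono = delta_mono,
              blocks_cleavage = isTRUE(blocks_cleavage), mode = mode)
  class(out) <- "ModificationDef"
  out
}

#' Built-in modifications
#'
#' \code{mod_biotin_lc()} is the biotinamidocaproyl adduct left on a lysine
#' epsilon-amine by sulfo-NHS-LC-biotin (C16H25N3O3S, +339.1617 Da); it
#' blocks tryptic cleavage at the modified lysine. \code{mod_carbamidomethyl()}
#' is the iodoacetamide adduct on cysteine (C2H3NO, +57.0215 Da), applied as
#' a fixed modification by default.
#'
#' @return A \code{ModificationDef}.
#' @export
mod_biotin_lc <- function() {
  modification_def("biotin-LC", targets = "K", composition = "C16H25N3O3S",
                   blocks_cleavage = TRUE, mode = "variable")
}

#' @rdname mod_biotin_lc
#' @export
mod_carbamidomethyl <- function() {
  modification_def("carbamidomethyl", targets = "C", composition = "C2H3NO",
                   blocks_cleavage = FALSE, mode = "fixed")
}

.check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% names(RESIDUE_FORMULA))
  if (length(bad) > 0L)
    stop("illegal residue '", res[bad[1]], "' at position ", bad[1],
         " (ambiguity codes B/Z/X/U are rejected, not approximated)")
  res
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Sum of residue masses plus one water, plus the mass shifts of any
#' modifications. Modification positions are 1-based within the sequence and
#' must lie on residues the modification targets.
#'
#' @param sequence Peptide sequence over the 20-letter alphabet.
#' @param mods List of \code{list(position =, mod = ModificationDef)} entries
#'   (or an empty list).
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence, mods = list()) {
  res <- .check_sequence(sequence)
  if (length(res) == 0L) stop("empty peptide sequence")
  mass <- sum(vapply(res, function(r) monoisotopic_mass(RESIDUE_FORMULA[[r]]),
                     numeric(1))) + WATER_MASS
  for (m in mods) {
    pos <- m$position
    mod <- m$mod
    if (pos < 1L || pos > length(res))
      stop("modification position ", pos, " outside peptide 1..", length(res))
    if (!res[pos] %in% mod$targets)
      stop("modification '", mod$name, "' not allowed on residue '",
           res[pos], "' at position ", pos)
    mass <- mass + mod$delta_mono
  }
  mass
}

#' m/z of a protonated species
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge (number of adducted protons).
#' @return m/z = (M + z * m_proton) / z.
#' @export
mz_from_mass <- function(neutral_mass, charge = 1L) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  (neutral_mass + charge * PROTON_MASS) / charge
}

#' Neutral mass back from an observed m/z
#' @param mz Observed m/z.
#' @param charge Positive integer charge.
#' @return Neutral monoisotopic mass in Da.
#' @export
mass_from_mz <- function(mz, charge = 1L) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  mz * charge - charge * PROTON_MASS
}

#' Whole-protein mass shift at a given labeling stoichiometry
#'
#' For saturating NHS-biotin labeling, the intact-mass shift is simply the
#' number of labeled sites times the adduct mass (175 lysines x 339.16 Da
#' is approximately 59.35 kDa).
#'
#' @param n_sites Number of labeled sites (>= 0).
#' @param mod \code{ModificationDef}; default biotin-LC.
#' @return Mass shift in Da.
#' @export
protein_label_shift <- function(n_sites, mod = mod_biotin_lc()) {
  if (length(n_sites) != 1L || n_sites < 0 || n_sites != round(n_sites))
    stop("n_sites must be a single non-negative integer")
  n_sites * mod$delta_mono
}

#' Read a modification table (TSV or JSON)
#'
#' TSV columns: name, targets (residue letters, e.g. "K" or "KC"),
#' composition_or_delta (a formula string or a numeric Da shift),
#' blocks_cleavage (TRUE/FALSE), mode (fixed/variable).
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format "tsv" or "json".
#' @return List of \code{ModificationDef}.
#' @export
read_mod_table <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  rows <- if (format == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    cod <- as.character(r$composition_or_delta)
    num <- suppressWarnings(as.numeric(cod))
    modification_def(
      name = r$name,
      targets = strsplit(as.character(r$targets), "")[[1]],
      composition = if (is.na(num)) cod else NULL,
      delta_mono = if (is.na(num)) NULL else num,
      blocks_cleavage = as.logical(r$blocks_cleavage),
      mode = as.character(r$mode)
    )
  })
}
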