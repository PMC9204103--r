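# Independent oracles used to freeze expected values. These deliberately do
# NOT call the package's mass or digestion code paths.

# Literature monoisotopic residue masses (5 dp), summed directly.
ORACLE_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276

oracle_peptide_mass <- function(sequence, mod_deltas = 0) {
  sum(ORACLE_RESIDUE[strsplit(sequence, "")[[1]]]) + ORACLE_WATER +
    sum(mod_deltas)
}

# Cumulative binomial tail P(X >= k) by direct summation.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

# Brute-force enumeration of every peptide form satisfying the tryptic /
# blocked-cleavage rules, by direct substring scan. Returns a sorted key set
# "start|end|modpos,...|missed".
oracle_enumerate_keys <- function(sequence, max_missed, max_var) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_site <- vapply(seq_len(n), function(p)
    p < n && res[p] %in% c("K", "R") && res[p + 1] != "P", logical(1))
  sites <- which(is_site)
  starts <- sort(unique(c(1L, sites + 1L)))
  ends <- sort(unique(c(sites, n)))
  keys <- character(0)
  for (s in starts) {
    for (e in ends[ends >= s]) {
      internal <- sites[sites >= s & sites < e]
      modifiable <- which(res == "K")
      modifiable <- modifiable[modifiable >= s & modifiable <= e]
      modifiable <- modifiable[!(modifiable == e & is_site[e])]
      subsets <- list(integer(0))
      for (p in modifiable)
        subsets <- c(subsets, lapply(subsets, function(x) c(x, p)))
      for (M in subsets) {
        if (length(M) > max_var) next
        missed <- sum(!internal %in% M)
        if (missed > max_missed) next
        keys <- c(keys, paste(s, e, paste(sort(M), collapse = ","), missed,
                              sep = "|"))
      }
    }
  }
  sort(unique(keys))
}

modform_keys <- function(forms) {
  sort(unique(vapply(forms, function(f) {
    bp <- f$mods$position[f$mods$mod == "biotin-LC"]
    paste(f$start, f$end, paste(sort(bp), collapse = ","),
          f$missed_cleavages, sep = "|")
  }, character(1))))
}

random_sequence <- function(n, alphabet = names(ORACLE_RESIDUE)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# simple MS2 spectrum from a fragment table, unit intensities unless given
spectrum_from_fragments <- function(frags, intensity = NULL,
                                    precursor = 1000) {
  if (is.null(intensity)) intensity <- rev(seq_len(nrow(frags))) * 10
  peak_list(frags$mz, intensity, level = "MS2", precursor_mz = precursor,
            mz_range = NULL)
}
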