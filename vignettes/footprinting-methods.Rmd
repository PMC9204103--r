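---
title: "Covalent-labeling footprinting with footprintr: models, parameters, and design choices"
author: "footprintr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covalent-labeling footprinting with footprintr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintr)
```

## The experiment this package models

Covalent-labeling footprinting probes which parts of a protein's surface are
solvent accessible in a given conformational state. An amine-reactive
reagent (here sulfo-NHS-LC-biotin) acylates the epsilon-amines of exposed
lysines, adding a biotinamidocaproyl group of composition C16H25N3O3S
(+339.1617 Da monoisotopic) per site. The protein is then digested with
trypsin and the peptides are read out by MALDI-TOF MS1 and by MS/MS. Two
facts make the readout informative:

1. **A biotinylated lysine blocks trypsin.** The cut that would have
   occurred after that lysine disappears, so the two flanking tryptic
   peptides fuse into a single "digestion-protected" peptide carrying the
   adduct mass. Presence of the fused, shifted peptide (and absence of the
   two short ones) is direct evidence the lysine was exposed.
2. **b/y fragment ions localize the adduct.** In MS/MS, ions bracketing the
   modified residue shift by 339.16 Da, so the spectrum pins the adduct to
   one lysine among the candidates in the peptide.

Comparing the set of confidently modified lysines between two conformers —
here the cis and trans isomers of a peptidyl-prolyl bond, as in the ATR
Ser428-Pro429 system the bundled fixtures come from — yields a residue-level
map of where the surface changed: lysines labeled in one state but
protected in the other.

## Mass arithmetic

All masses are monoisotopic and are derived from one table of IUPAC atomic
masses (`ATOMIC_MONO`); residues are stored as elemental formulas and
summed, so every downstream quantity traces to the same constants. A
peptide's neutral mass is the residue sum plus one water plus modification
deltas; `mz_from_mass()` adds `charge` protons and divides. The two
built-in modifications are the biotin-LC adduct (`mod_biotin_lc()`, on K,
cleavage-blocking, variable) and carbamidomethyl (`mod_carbamidomethyl()`,
on C, fixed — the standard iodoacetamide alkylation applied during sample
preparation, on by default everywhere so theoretical and observed masses
agree). Ambiguity codes (B, Z, X, U) are rejected outright: a silently
wrong mass is worse than an error.

```{r}
monoisotopic_mass("C16H25N3O3S")        # biotin-LC adduct
protein_label_shift(175) / 1000          # saturating shift of a 175-K protein, kDa
```

## Digestion model

Trypsin cleaves after K or R except before proline. `digest()` takes an
explicit modification state; cleavage-blocking modifications remove their
site from the candidate set entirely, so a blocked site is *not* a missed
cleavage. This keeps `max_missed` (default 2, matching the multi-basic
peptides seen in published interface tables) meaningful under saturating
labeling, where many sites are blocked at once. `enumerate_modforms()`
generates the search space: the union over all placement hypotheses,
deduplicated, with every internal lysine of an emitted peptide either
modified (blocked) or counted as missed, and a peptide's C-terminal lysine
never carrying the blocking mod (trypsin could not have cut there
otherwise). The default cap of 5 variable mods per peptide was chosen
because saturating labeling routinely fuses runs of three or more blocked
lysines into one long peptide; a lower cap silently removes exactly the
peptides the experiment is about. Correctness of the enumeration is tested
against a brute-force substring oracle on random sequences.

Coordinates are 1-based inclusive in *protein numbering*:
`protein_record()` takes a `numbering_offset` (the label of the first
residue) so that constructs with tags — the fixtures' FLAG-tagged kinase
numbers its first native residue 2 — keep their published residue numbers.
Published residue-range labels in the bundled tables are internally
inconsistent with the peptide lengths in places; they are therefore carried
as labels only, never used as coordinates.

## MS1 matching and MS2 localization

`match_pmf()` performs peptide-mass-fingerprint matching: every
(peak, candidate, charge) pair within `tol_ppm` is recorded, and each peak
is assigned its best candidate by absolute ppm error with a total tie order
(fewer mods, fewer missed cleavages, lexicographic sequence), so matching
is deterministic. The default tolerance is 50 ppm and the default charge
set {1}, typical for reflector-mode MALDI-TOF; the pipeline widens the
charge set to {1, 2} because peptides fused across several blocked sites
can exceed a 3,500 m/z window singly protonated while their doubly
protonated ion is comfortably inside it. Within the pipeline, peaks that
have a linked MS/MS spectrum are additionally re-ranked by the fraction of
their b/y ladder matched in that spectrum: isobaric candidates a few ppm
apart are indistinguishable by mass alone, and the fragment ladder is the
standard arbiter.

Localization is scored with the Ascore construction: the spectrum is
filtered to its top-`d` peaks per 100-m/z window (`d` scanned over 1..10;
intensity ties at the cutoff are all kept, so identical evidence for two
sites is retained identically), chance matching is modeled as
Binomial(n, d/100) over the n predicted ions, each placement hypothesis is
scored as −10·log10 P(X ≥ k), the depth that best separates the top two
hypotheses is retained, and the reported `delta_ascore` is the score
difference computed on the site-determining ions only — the b ions between
the two sites and their complementary y ions. When the peptide carries k
copies of the modification the hypotheses are all size-k subsets of the
candidate sites; when the candidates are exhausted by the copies the result
is unambiguous by construction (sentinel `delta_ascore = Inf`). The
site-determining evidence decides the final call: the top pair is ordered
by the SDI score, which also guarantees `delta_ascore >= 0`. The default
fragment tolerance is 0.5 Da (TOF/ion-trap-class MS2) and the confident
threshold `delta_ascore > 19` corresponds to p < 0.0126, the conventional
certainty cutoff; both are exposed as parameters.

## Differential maps and domains

`build_accessibility_map()` calls a lysine modified when at least
`min_witnesses` spectra (default 1) support it at
`delta_ascore >= min_delta_ascore` (default 19), with unambiguous
localizations counting as confident. `compare_states()` takes set
differences and the intersection; `pool_maps()` can merge replicate states
first (union by default, matching how equivalent isoforms are reported
jointly). `annotate_domains()` labels each residue with its containing
domain, or `flank:<domain>` within `flank_window` residues of a boundary.
The flank default of 5 reconciles a residue being described as "within" a
domain whose printed boundary starts two residues away (K459 vs a BH3
domain printed as 461–474). Only the two domain boundaries actually
published for the fixture system ship as defaults (BH3 461–474, KD
2206–2615); all other domains must be user-supplied rather than guessed.

## The synthetic experiment

`simulate_experiment()` stands in for the study's deposited raw spectra.
Its defaults are the package's fixed study conditions, chosen once:

* **Protein**: 100 tryptic-sized segments of 4–6 residues, each ending in K
  or R with equal probability, interiors drawn from the 17 residues that
  neither add cut sites nor suppress one — about 50 lysines in a ~500-aa
  chain, the lysine density of a large HEAT-repeat protein.
* **Accessibility**: a shared core (each lysine accessible in both states
  with probability 0.35) plus 2 state-A-only and 7 state-B-only lysines —
  the shape of the published cis/trans result.
* **Labeling**: `label_efficiency = 0.9`, the saturating 1000-fold-excess
  regime; digestion is complete at unblocked sites.
* **MS1**: peaks at [M+H]+ (or [M+2H]2+ when the singly charged ion falls
  outside the 500–3,500 window), Gaussian mass error `ppm_sigma = 10`,
  per-peptide `detection_prob = 0.9`, and 20 uniform noise peaks across the
  window.
* **MS2**: b/y ladders for modified peptides with fragment dropout at 0.9,
  rank-correlated intensities (low-index ions strongest), and 10 noise
  peaks drawn below the median matched intensity, so the Ascore depth
  filter sees a plausible intensity ordering.

All randomness flows from the single `seed`; reruns are bit-identical. The
generator writes standard FASTA/TSV/MGF through the package's own I/O, so
synthetic runs exercise the real file path. What it does **not** emulate:
isotope envelopes, chemical noise structure, retention time, charge-state
envelopes beyond z = 2, and label-competition kinetics — so passing the
closed-loop tests demonstrates the inference logic is sound under the
stated noise model, not that real MALDI data of arbitrary quality will be
recovered as well.

`evaluate_recovery()` scores calls against ground truth with standard
precision/recall/F1 (precision of an empty call set is 1 by convention —
there are no false positives to penalize). Under the default noisy
conditions, recovery is limited mostly by the 0.9 per-peptide detection
probability; across 10 replicate seeds the mean F1 sits near 0.95, and in
the noise-free limit recovery is exact — a closed-loop identity the test
suite asserts.

## Geometry utility

`omega_angle()` computes the signed CA–C–N–CA dihedral with the standard
convention (verified against independent torsion implementations): the
angle is invariant under rigid motion and under atom-order reversal, and
negates under mirror reflection. `classify_isomer()` applies half-width
windows (30° by default) around 0° (cis) and ±180° (trans), with anything
between labeled twisted. `omega_from_pdb()` walks backbone ATOM records of
a PDB file (read with bio3d) and reports per-bond angles and classes —
enough to check which isomer a model is in; molecular dynamics and
free-energy work are out of scope.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run at desk scale: the default
synthetic protein (~500 aa, ~50 K) digests into roughly a thousand
candidate forms, and a full two-state pipeline run takes a couple of
seconds; the 10-replicate recovery study runs in under half a minute.
Fragment and peak m/z comparisons use absolute-Da tolerances at MS2
(0.5 Da) and ppm at MS1 (50 ppm); site-determining ions are identified by
an m/z difference above 1e-9 Da; binomial tails are floored at 1e-300
before the log. Degenerate inputs fail loudly: empty spectra give zero
scores and an ambiguous verdict, empty peak lists warn, unknown residues,
elements, lowercase marks and conflicting protein ids are errors.

## Known limitations

* MS1-only identifications carry no probabilistic score (no MOWSE/FDR);
  presence calls lean on the MS/MS-backed localization step instead.
* Localization considers b/y ions at charge 1–2 without neutral losses;
  adequate for a 339-Da lysine adduct, not for labile modifications.
* The differential map is qualitative (unique/shared sets); it does not
  model labeling-efficiency differences between states statistically.
* mzML/vendor formats are not read; MGF and two-column text cover the
  MALDI-style workflow the package targets.
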