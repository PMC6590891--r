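---
title: "Characterizing SLC6 transporters from sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing SLC6 transporters from sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slc6tools)
```

This vignette documents the models, parameter choices and numerical
conventions behind `slc6tools`, in the spirit of a methods section: what each
stage computes, what it assumes, and where the design was genuinely open.

## Hydropathy and transmembrane segments

The hydropathy profile is the unweighted sliding mean of the 1982
Kyte–Doolittle per-residue values (unitless, range −4.5 for Arg to +4.5 for
Ile; X scores 0), reported at window centres. Defaults are the classic
membrane-protein setting: window 19 residues, segment threshold 1.6. A
transmembrane (TM) segment is a maximal run of window centres at or above the
threshold; runs separated by fewer than `merge_gap = 5` centres are merged,
and merged runs shorter than `min_tm_len = 10` are discarded. All four values
are configuration-overridable because a "how many TM segments" claim is only
meaningful relative to them; the annotation report echoes the effective
configuration for provenance.

Topology is not inferred (positive-inside prediction is out of scope): the
N-terminal side is an input, `"in"` by default, the experimentally supported
SLC6 topology. Loop sides then alternate, which forces the C-terminus onto
the N-terminal side whenever the segment count is even, and the largest
extracellular loop — EL2 in SLC6 nomenclature, between TM3 and TM4 in the
canonical fold — is flagged.

Sequons are all matches of N-X-[S/T] with X ≠ P. The package reports the
3-residue motif interval; the literature often prints 4-residue spans
(e.g. "NLSD"), which start at the same asparagine. Masses are average
(isotope-abundance-weighted) residue masses plus one water, matching the
convention behind deposited "deduced molecular mass" figures; a sequence
containing X has no defined mass and errors rather than guessing.

## Pairwise alignment and similarity statistics

Global alignment is Needleman–Wunsch with Gotoh's three-state affine-gap
recursion, scored with BLOSUM62; a gap of length *k* costs
`gap_open + k * gap_extend` with defaults 10 and 0.5, the ClustalW protein
defaults. The traceback tie order is fixed (diagonal > up > left) so results
are bit-reproducible. The DP kernel is a small C++ routine shared by the
pairwise and the profile–profile aligner.

Percent identity counts identical aligned residue pairs; percent similarity
("BLOSUM62 homology") additionally counts pairs with a positive substitution
score. Columns containing a gap never count as matches. Published percentage
figures rarely state their denominator, so it is a parameter:
`aligned_columns` (both residues present; the default), `shorter_seq`, or
`all_columns`.

## Progressive multiple alignment

Guide-tree distances are fractional common 3-mer distances (1 − shared
unique 3-mers / (shorter length − 2)) — crude but deterministic and adequate
for grouping; the guide tree is UPGMA (`hclust`, average linkage). At each
internal node two blocks are aligned with the same affine DP over
count-weighted sum-of-pairs column scores in which gap characters contribute
nothing. Because column scores scale with the product of block sizes, the
gap penalties are scaled by the same factor — otherwise gaps become
progressively cheaper as blocks grow, an artefact that misplaces loop gaps.
With two sequences the procedure reduces exactly to the pairwise aligner.
Terminus trimming removes leading and trailing columns whose non-gap
occupancy is below `min_occupancy = 0.5`, up to the first and last passing
column, mirroring the practice of discarding hypervariable N/C termini
before tree building; interior columns are never touched.

## Binding-site projection and the ion-dependence call

The bundled fixture stores the LeuT sodium-coordination residues (Na1: A22,
G24, N27, T254; Na2: G20, V23, A351, T354, S355; PDB 2A65 chain numbering)
and the SERT chloride-site residues (Y121, S336, N368, S372; NP_001036.1
numbering). Storing the expected residue alongside each position lets a
mis-numbered template sequence be caught at load time rather than silently
shifting every projection.

Projection walks the template–query alignment maintaining both residue
counters; a template position aligned to a gap is `unaligned`. Statuses:
`identical`, `similar` (BLOSUM62 > 0, the same relation the similarity
statistic uses), otherwise `divergent`. The classification is a pure
function of the statuses:

* Na⁺: `dependent` iff every Na1 residue is identical or similar; any
  divergent or unaligned Na1 entry gives `undetermined`. (Na2 conservation is
  reported — x/5 identical — but does not gate the call: partial Na2
  conservation is the rule rather than the exception among NTTs.)
* Cl⁻: `dependent` iff all four chloride residues are identical — the
  pattern of strictly chloride-dependent transporters; `independent_candidate`
  when at least one aligned residue deviates — the pattern shared by the
  chloride-independent B⁰ transporters; `undetermined` when any entry is
  unaligned (conservative: a missing residue is not evidence of divergence).

The rationale string specifically notes a threonine at the
SERT-S336-equivalent position, the LeuT-like configuration mechanistically
associated with chloride independence.

The pairwise (template-vs-query) path is primary; an MSA-column path exists
only for the substrate-pocket conservation report. The published pocket
position list exists only as a supplementary figure image, so the bundled
pocket fixture is synthetic (named and documented as such) and serves to
exercise the report; a transcribed real fixture can be dropped in with the
same 4-column format.

## Phylogenetics

Distances are p-distances over both-non-gap columns, Poisson-corrected by
default (−ln(1 − p)); a saturated pair (p = 1) is an error rather than an
infinity. Neighbor joining follows Saitou–Nei's Q criterion with two fixed
conventions: ties on Q break toward the smallest (row, column) index pair,
and negative branch lengths are clamped to zero with the deficit moved onto
the sibling edge, preserving the joined pair's distance sum. Supports are
nonparametric bootstrap proportions: columns resampled with replacement,
NJ rebuilt per replicate, each internal edge of the full-data tree scored by
the fraction of replicates containing the same bipartition. This is a
deliberate, documented substitution for approximate-maximum-likelihood
trees with Shimodaira–Hasegawa local supports: the cluster structure is the
comparable surface, the support values are not numerically comparable.
Outgroup rooting requires a monophyletic outgroup (checked on a rooting at
an ingroup tip, which makes the question well-defined on an unrooted tree)
and never changes the bipartition set.

Cluster assignment finds the smallest clade of the rooted tree containing
the query and at least one labelled non-query leaf, labels the query by
majority (alphabetical tie-break), and reports the sister taxa plus whether
the clade is single-label ("nested").

## In silico PCR

A primer base matches a template base iff the template base is in the IUPAC
expansion of the primer code; degenerate template bases therefore count as
mismatches — conservative, and exact for the concrete templates the package
generates. The `anchor_3prime = 3` terminal bases must match exactly
regardless of `max_mismatch` (default 0): the standard polymerase-extension
specificity heuristic, standing in for the thermodynamics that are out of
scope. Hit coordinates follow the cloning convention in which a primer name
encodes the template position of its 5′ base — for a minus-strand hit this
is the rightmost footprint coordinate — so a product length is
`rev_pos − fwd_pos + 1` by pure arithmetic, with no template needed.

## Synthetic data: what it emulates, and what it does not

The generators produce data with exactly the statistical structure the
analyses assume, plus ground truth:

* `simulateFamily()` evolves a root protein down a tree under a
  uniform-replacement model: on a branch of length *b* each mutable site
  differs from its parent with probability 1 − e^(−b), replacements uniform
  over the other 19 residues; planted invariant columns never change. This
  gives closed-form expectations for recovery tests but is deliberately not
  an empirical substitution model — no rate heterogeneity beyond invariant
  sites, no indels, no compositional bias.
* `makeMembraneProtein()` tiles loop/TM regions. The TM alphabet {I, V, L}
  (KD ≥ 3.8) and loop alphabet {T, S, W, Y} (mean KD ≈ −0.93) were chosen
  once so that the 19-residue window mean crosses the 1.6 threshold within
  about one window centre of a true TM boundary: the midpoint of the two
  pool means is ≈ 1.62, so the called segment edge coincides with the
  planted edge to ±1 position and planted 21-residue segments are recovered
  with per-segment Jaccard ≥ 0.9 deterministically in expectation. Defaults
  (12 TM of 21 residues, 25-residue loops, a 60-residue EL2-like loop
  carrying two sequons and three cysteines) emulate the canonical SLC6
  architecture. Real membrane proteins have softer hydropathy contrast, TM
  length variation and amphipathic helices; passing these tests shows the
  caller is correct, not that it matches experimental topologies.
* `makeTemplateWithPrimers()` splices concrete realizations of (possibly
  degenerate) primers into a uniform ACGT background and records the
  realization, so mismatch counts are exact.

Every generator is a pure function of its seed.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale sizes chosen for
tight brute-force cross-checks: exhaustive alignment enumeration on all
length pairs up to 6 over a 4-letter alphabet; 50 random additive matrices
of 5–10 leaves for NJ topology recovery; 100 membrane-protein seeds; 100
bootstrap replicates on an 8-taxon family of length 300; 2-kb templates for
the 32-fold-degenerate primer against full degeneracy expansion. Floating
ties in the DP are resolved by the fixed state order; distances and supports
are plain doubles; branch lengths are clamped at zero rather than allowed
negative; Newick supports are written at two decimals.

## Known limitations

* No HMM-based TM prediction or signal-peptide detection; hydropathy-only
  calling is parameter-sensitive by design and says so.
* ClustalW is not reproduced exactly (no position-specific gap penalties, no
  sequence weighting); the MSA is adequate for conserved-column and
  tree-level conclusions, not for column-perfect reproduction of published
  alignments.
* Approximate-ML trees and SH supports are not implemented; bootstrap
  proportions are the support currency here.
* The ion-dependence call is a sequence-level heuristic over a handful of
  residues; it flags candidates, it does not replace electrophysiology.
* Melting temperatures, primer dimers and multiplex optimization are out of
  scope for the PCR module.
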