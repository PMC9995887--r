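---
title: "Methods: classifying plant PA2c-domain phospholipase families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying plant PA2c-domain phospholipase families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pa2c)
```

## The biological problem

Plant secretory phospholipase A2 (sPLA2) is a family of small secreted
enzymes that hydrolyze the sn-2 carboxyester bond of phospholipids. All
members share the PA2c domain, whose two short diagnostics are a
calcium-binding loop and a catalytic histidine–aspartate (HD) dyad.
Canonical plant sPLA2 proteins carry an N-terminal secretory signal peptide,
twelve cysteines (six disulfide bridges), the canonical calcium loop
`YGKYCGxxxxGC` and catalytic motif `DxCCxxHDxC`, and mature lengths of
roughly 90–191 residues; they split phylogenetically into an alpha and a
beta clade. A distinct family of PA2c-containing proteins — here called
PLA2-like — lacks the signal peptide, carries a long intrinsically
disordered N-terminal extension, variant motifs (`YGHYCGxxxxxGK`, with one
inserted residue, and `DxCCxxHDxG`) and only six cysteines, and forms a
third independent clade. This package implements the desk-scale machinery
to classify proteins into these families and to run the standard
comparative analyses around that classification: disulfide arithmetic,
NJ phylogeny with bootstrap monophyly tests, motif logos, promoter
cis-element counting, and clade-wise tissue expression summaries.

## Motif engine

Patterns are restricted to uppercase literals plus the lowercase wildcard
`x` — the only constructs the family diagnostics use; bracket classes and
`x(n)` repeats are a documented extension point, not implemented. The
ambiguity residue X satisfies a wildcard but never a literal, and the DNA
ambiguity N in promoters never matches anything: conservative matching, so
ambiguous gene models cannot create spurious diagnostic hits. All
overlapping matches are reported; consumers take the left-most match of
each kind, which makes every downstream decision deterministic. Some
sources print the catalytic motif as the stricter `DACCxxHDxC`; the engine
treats the general `DxCC…` form as canonical and records the `DACC…`
sub-case as a boolean feature rather than a separate pattern.

## Signal-peptide heuristic

Annotation-based signal-peptide calls are replaced by a transparent
hydrophobicity rule (Kyte–Doolittle scale): a protein has a signal peptide
iff it starts with M and some window of 8 consecutive residues with mean
hydropathy ≥ 1.6 begins within residues 2–12. The cleavage estimate is the
end of the maximal per-residue hydrophobic run (KD ≥ 1.6) seeded by that
window, plus 3, capped at position 35. Window width, threshold and onset
range are exposed as arguments. This is not a SignalP-class predictor and
is documented as a heuristic; the synthetic generator constructs peptides
that satisfy or violate it by design, so the closed-loop tests exercise the
rule rather than assume it.

## Classification cascade

1. Missing calcium loop or catalytic motif → `nonPA2c`.
2. Both motifs in the "like" variant and no signal peptide → `PLA2like`.
3. Both motifs canonical and a signal peptide → `sPLA2`; the alpha/beta
   clade is assigned by nearest-centroid mean global-alignment similarity
   (BLOSUM62, affine gaps open 10 / extend 1) against a small labeled
   reference panel, with an "unresolved" band when the margin between the
   clade means is below 2% of the per-query score range.
4. Mixed combinations take the family of the calcium-loop variant — the
   primary diagnostic — with `SP_CONFLICT` / `MOTIF_CONFLICT` flags.
   Conflicted sPLA2 calls still receive an alpha/beta clade by the same
   nearest-centroid rule: the clade decision is independent of whichever
   feature conflicted, and discarding it would turn every mutated signal
   peptide into an unresolvable record.

QC flags mark atypical cysteine censuses (canonical ≠ 12, PLA2-like ≠ 6)
and out-of-range lengths (canonical mature length outside 90–191, PLA2-like
total length outside 143–320). The alpha/beta split is phylogenetic in
origin — no sequence signature separates the clades — so the
nearest-centroid rule is an honest heuristic stand-in, flagged as such, and
`tree_placement_clade()` provides the alternative tree-based assignment
(NJ insertion next to a label-pure sibling subtree).

The cysteine census is counted from the domain start (calcium-loop match)
to the sequence end rather than over an exactly delimited domain, because
the family definitions count residues per protein without a window
definition; the choice is documented and the generator respects it.

## Disulfide arithmetic

Bridge counts are `floor(n_cys / 2)`: twelve cysteines support six
bridges, six support at most three. The bundled bridge template carries the
two pairs printed in the PLA2-like residue numbering — C140–C167 and
C166–C192 — plus four placeholder pairs marked unspecified, which are never
counted as retained: the remaining canonical pairings are not reliably
published in this numbering and are not invented. The apparent tension
between "six cysteines, up to three bridges" (census arithmetic) and "four
conserved cysteines forming two retained bridges" (structure-based
conservation) is represented as two separate quantities, not reconciled.

## Distances, NJ and bootstrap

Pairwise distances are mismatch fractions (p-distance) over non-gap columns
of a BLOSUM62 global alignment with affine gaps (open 10, extend 1), or of
a fixed reference alignment; an optional Poisson transform −ln(1 − p) is
capped at 5 when p ≥ 0.95. Trees are neighbor-joining (`ape::nj`), with
negative branch lengths clamped to zero and flagged. Bootstrap supports
resample alignment columns with replacement, one RNG stream keyed by
(seed, replicate index), and count recovered bipartitions of the base tree
(`ape::prop.clades`, unrooted). A clade is monophyletic iff some
bipartition separates exactly its leaves; the count is invariant to leaf
order and rooting. NJ plus standard bootstrap deliberately replaces
maximum-likelihood inference with ultrafast bootstrap: at the divergence
levels the generator produces, clade recovery is unambiguous, and the
package labels its method as NJ throughout.

## Sequence logos

Per-column information content follows Schneider–Stephens:
IC = log2(S) − H − e(n), with S the alphabet size, H the column entropy in
bits and e(n) = (S − 1)/(2 ln(2) n) the small-sample correction (applied by
default for blocks under 50 sequences); IC is clamped at zero and letter
heights are frequency × IC. Gaps are excluded from both the frequencies and
the per-column n.

## Promoter scanning

The element dictionary holds the consensus strings as conventionally
printed (G-box CACGTG, W-box TTGACC, ABRE TACGTG, the methyl-jasmonate
pair CGTCA/TGACG, and so on); elements named in the literature without a
printed consensus ship as disabled placeholders. Each consensus is matched
on the forward strand and as its reverse complement (strand "−"), IUPAC
codes expanding to their base sets; a locus hit on both strands (the G-box
is its own reverse complement) is a single occurrence, avoiding a
systematic ×2 for palindromes. Counts are clipped at 5 in the display copy
of the matrix, matching the 0-to-5 heatmap convention. Because the scanner
uses literal consensus strings rather than the proprietary matrices of
promoter-annotation servers, counts on real promoters will differ from
server output; correctness is defined against planted ground truth.

## Expression summaries

TPM matrices are summarized to clade × tissue means and maxima; presence
means TPM ≥ 1 (configurable), and a clade is "male-gametophyte dominant"
when its maximum over {anther, pollen, pollen tube} (configurable set)
exceeds its maximum elsewhere. The display transform is log2(TPM + 1).
Threshold and transform are standard conventions, not measured constants.

## The synthetic generator

The generator is the package's study condition, not a tuning dial. Three
fixed clade centroids live on a common aligned frame (signal peptide 16
columns, disordered extension 100, pre-loop 20, calcium loop 13, mid
segment 40, catalytic motif 10, tail up to 109); descendants arise by
point substitution at 0.05 per mutable site (default), with motif-literal
anchors and the counted cysteines immutable and substitutions never
introducing cysteine. That makes the "invariable" motif claim and the
12/6 cysteine censuses true by construction at any rate, which separates
correctness tests from robustness tests; a `protect = FALSE` mode exists
precisely to break those guarantees when robustness is the question.
Centroids are fixed constants (internal seed), mutually ~95% divergent
outside the anchors; per-sequence draws flow from the user seed and global
RNG state is always restored.

Choices a scientist should know about:

* Tail lengths are drawn so canonical mature lengths fall in 90–191.
  With the ~100-residue disordered extension the PLA2-like totals land in
  191–292, inside the documented 143–320 window but not reaching its lower
  half — reaching 143 would require shrinking the extension below ~100
  residues, which the family description does not support.
* Cores are indel-free within the frame, so the generator's reference
  alignment is exactly right for bootstrap column resampling. Real PA2c
  families have indels; this is a stated simplification, and the
  pairwise-alignment distance path exists for sequences without a
  reference alignment.
* The beta centroid tail ends in KTEL, the KxEL ER-retention variant
  reported for a subset of beta-clade members.
* Expression: alpha genes are identically 0 TPM in pollen and pollen tube;
  beta genes draw male-gametophyte tissues from the largest lognormal
  location (meanlog 5 vs 2 elsewhere); PLA2-like genes are ubiquitous at
  moderate levels (meanlog 2.5). Lognormal TPM with these gaps makes the
  qualitative claims (zero alpha presence, beta dominance) hold across
  seeds.
* Promoter backgrounds are uniform A/C/G/T with a rejection pass that
  rewrites accidental element matches before planting, so planted counts
  are exact ground truth. One planted locus can legitimately count for two
  elements when their consensus strings are reverse complements of each
  other (the methyl-jasmonate pair), and the generator's
  `expected_counts` accounts for that.

What passing these tests does **not** show: performance on real plant
proteomes, where signal peptides are diverse, indels are common, motif
variants exceed the two bundled forms, and promoter element annotation
requires position-weight matrices. The generator emulates the documented
family structure, not proteome-scale noise.

## Problem sizes and determinism

The bundled analyses run at desk scale by choice: families of 8 sequences
per clade, 100 bootstrap replicates, 2 kbp promoters, 600-sequence
classifier round-trips. Every random draw is keyed from an explicit seed
(`withr::with_seed`), so any entry point run twice with the same seed
writes byte-identical output files; the test suite asserts this.

## Interface

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` (simulate → classify → phylogeny → logos → promoters →
expression) are thin narrative drivers over the exported functions and
write their tables under `results/`. There is deliberately no shell
wrapper beyond these scripts — the functions are the API, and
`scripts/acceptance.R` recomputes the headline quantities end to end.
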