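# pa2c

Classification and comparative analysis of plant PA2c-domain phospholipase
families.

## The problem

Plant secretory phospholipase A2 (sPLA2) enzymes hydrolyze the *sn*-2
carboxyester bond of phospholipids. Every member carries the conserved PA2c
domain with two short diagnostics: a calcium-binding loop and a catalytic
histidine–aspartate (HD) dyad. Canonical sPLA2 proteins have an N-terminal
secretory signal peptide, the motifs `YGKYCGxxxxGC` and `DxCCxxHDxC`, twelve
cysteines (six disulfide bridges) and mature lengths of 90–191 residues,
and split phylogenetically into an **alpha** and a **beta** clade. A
distinct **PLA2-like** family lacks the signal peptide, carries a long
disordered N-terminal extension, the variant motifs `YGHYCGxxxxxGK` (one
inserted residue) and `DxCCxxHDxG`, and only six cysteines — at most three
bridges, of which the conserved pair C140–C167 / C166–C192 is retained.

`pa2c` implements the desk-scale pipeline for this biology, for anyone who
wants to classify PA2c proteins and reproduce the comparative analyses
around that classification:

* PROSITE-style motif scanning (literal + `x` wildcard grammar; the
  ambiguity residue X never satisfies a literal),
* a transparent Kyte–Doolittle signal-peptide heuristic (window 8, mean
  hydropathy ≥ 1.6, onset within residues 2–12),
* the family/clade classification cascade with QC flags, alpha/beta
  assignment by nearest-centroid global-alignment similarity (BLOSUM62,
  affine gaps 10/1) or by tree placement,
* cysteine census and disulfide-bridge arithmetic (`floor(n_cys/2)`),
* NJ phylogeny on p-distances with column-resampling bootstrap and
  label-monophyly tests,
* Schneider–Stephens sequence-logo information content
  (IC = log2 S − H − (S−1)/(2 ln 2 · n)),
* promoter cis-element counting over the printed consensus dictionary
  (G-box CACGTG, W-box TTGACC, ABRE TACGTG, …) with palindromes counted
  once per locus and display counts clipped at 5,
* clade-wise TPM expression summaries (presence at 1 TPM,
  male-gametophyte dominance),
* a seeded synthetic generator producing clade-faithful proteins,
  promoters with planted elements, and structured TPM matrices, so the
  whole pipeline is testable without any genome downloads.

## Worked example

```r
library(pa2c)

cfg <- generator_config(seed = 42)
prot <- make_protein("alpha", cfg)
prof <- feature_profile(prot)
c(sp = prof$has_signal_peptide, cys = prof$n_cys_domain,
  mature = prof$mature_length)
#>     sp    cys mature
#>      1     12    138

classify(prot)
#> CladeCall alpha_s42: family sPLA2, clade alpha

fam <- make_family(generator_config(seed = 7))
tree <- bootstrap_support(fam$alignment, n_reps = 100, seed = 7)
clade_monophyly(tree, fam$labels)$count
#> [1] 3
clade_support(tree, names(fam$labels)[fam$labels == "pla2like"])
#> [1] 100
```

The profile says the synthetic alpha protein has a detected signal peptide,
exactly twelve cysteines from the domain start onward, and a mature length
inside the canonical 90–191 window; the classifier then calls it canonical
sPLA2, alpha clade, no QC flags. The family run recovers all three clades
as monophyletic with 100% bootstrap support on the branches separating
them.

The full analysis narrative lives in `analysis/01_simulate.R` …
`06_expression.R`; each script prints what it found and writes its tables
under `results/`. For the model details and design choices, see
`vignettes/pa2c-methods.Rmd`.

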