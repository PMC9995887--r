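#!/usr/bin/env Rscript
## Per-column information content of the calcium-binding loop and catalytic
## motif blocks, separately for the canonical and PLA2-like families
## (sequence-logo numbers; anchors carry maximal IC by construction).

suppressMessages(library(pa2c))
aln <- read_fasta("results/family_alignment.fasta", "protein", aligned = TRUE)
truth <- utils::read.delim("results/family_labels.tsv")

## shared frame coordinates: CA block columns 137-149, CAT block 190-199
blocks <- list(ca = 137:149, cat = 190:199)
for (fam_name in c("canonical", "pla2like")) {
  rows <- if (fam_name == "canonical")
    aln[truth$id[truth$clade != "pla2like"]]
  else aln[truth$id[truth$clade == "pla2like"]]
  for (b in names(blocks)) {
    block <- substring(unname(rows), min(blocks[[b]]), max(blocks[[b]]))
    logo <- logo_from_block(block, "protein")
    out <- sprintf("results/logo_%s_%s.tsv", fam_name, b)
    write_logo_tsv(logo, out)
    message(sprintf("%s %s motif: mean IC %.2f bits, max %.2f (n=%d) -> %s",
                    fam_name, toupper(b), mean(logo$ic), max(logo$ic),
                    length(block), out))
  }
}
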