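#!/usr/bin/env Rscript
## Clade-wise expression summary of the simulated TPM matrix: presence calls
## at 1 TPM, the male-gametophyte dominance flag, and the log2(TPM+1)
## heatmap matrix. The expected qualitative pattern: alpha absent from
## pollen and pollen tube, beta strongest in the male gametophyte,
## PLA2-like ubiquitous.

suppressMessages(library(pa2c))
tpm <- read_expression_tsv("results/expression_tpm.tsv")
cl <- utils::read.delim("results/expression_clades.tsv")
clade_map <- stats::setNames(cl$clade, cl$gene)

sm <- summarize_expression(tpm, clade_map, threshold = 1)
write_matrix_tsv(sm$presence, "results/expression_presence.tsv", id_col = "clade")
write_matrix_tsv(heatmap_matrix(sm), "results/expression_heatmap.tsv",
                 id_col = "clade")

message(sprintf("alpha presence calls in pollen / pollen tube: %d / %d",
                sm$presence["alpha", "pollen"],
                sm$presence["alpha", "pollen tube"]))
message(sprintf("male-gametophyte dominant: %s",
                paste(names(sm$male_dominant)[sm$male_dominant], collapse = ", ")))
message(sprintf("max beta TPM in pollen %.0f vs max beta sporophytic %.0f",
                sm$max["beta", "pollen"],
                max(sm$max["beta", setdiff(colnames(sm$max), sm$male_tissues)])))
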