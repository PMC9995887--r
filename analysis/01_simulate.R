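#!/usr/bin/env Rscript
## Generate the synthetic study set: a three-clade PA2c protein family
## (8 sequences per clade at the default mutation rate), promoters with
## planted cis-elements, and a clade-structured TPM expression matrix.
## Everything downstream (02-06) reads from results/.

suppressMessages(library(pa2c))
dir.create("results", showWarnings = FALSE)
cfg <- generator_config(seed = 101)

fam <- make_family(cfg)
write_fasta(fam$records, "results/family.fasta")
write_fasta(fam$alignment, "results/family_alignment.fasta")
utils::write.table(
  data.frame(id = names(fam$labels), clade = unname(fam$labels)),
  "results/family_labels.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("family: %d proteins (%s), alignment width %d",
                length(fam$records),
                paste(names(table(fam$labels)), table(fam$labels),
                      sep = "=", collapse = ", "),
                unique(nchar(fam$alignment))))

## one promoter per canonical gene; hormone/light elements planted at known
## copy numbers, stress elements left to vary
plant_sets <- list(
  c("G-box" = 4L, "ABRE" = 2L),
  c("G-box" = 2L, "MeJA-TGACG" = 3L, "W-box" = 1L),
  c("MBS" = 2L, "MYC" = 2L, "WRE3" = 1L),
  c("G-box" = 7L, "ERE" = 1L)  # above the display clip of 5
)
promoters <- list(); truths <- list()
for (i in seq_along(plant_sets)) {
  pr <- make_promoter(plant_sets[[i]],
                      generator_config(seed = 200L + i),
                      id = sprintf("prom_%02d", i))
  promoters[[i]] <- pr$record
  truths[[i]] <- cbind(promoter = pr$record$id, pr$truth)
}
write_fasta(promoters, "results/promoters.fasta")
utils::write.table(do.call(rbind, truths), "results/promoter_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("promoters: %d x %d nt with %d planted loci",
                length(promoters), cfg$promoter_length,
                nrow(do.call(rbind, truths))))

ex <- make_expression(cfg)
write_matrix_tsv(ex$matrix, "results/expression_tpm.tsv", id_col = "gene")
utils::write.table(
  data.frame(gene = names(ex$clade_map), clade = unname(ex$clade_map)),
  "results/expression_clades.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("expression: %d genes x %d tissues (TPM)",
                nrow(ex$matrix), ncol(ex$matrix)))
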