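#!/usr/bin/env Rscript
## Scan the simulated family for the diagnostic motifs, extract feature
## profiles (signal peptide, cysteine census, KxEL, disorder proxy) and
## assign each protein to sPLA2-alpha / sPLA2-beta / PLA2-like.

suppressMessages(library(pa2c))
records <- read_fasta("results/family.fasta", "protein")
truth <- utils::read.delim("results/family_labels.tsv")

matches <- do.call(rbind, lapply(records, scan_motifs))
utils::write.table(matches, "results/motif_matches.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("motif scan: %d matches over %d proteins",
                nrow(matches), length(records)))

calls <- classify(records)
write_report(calls, "results/classification.json")
tab <- data.frame(
  id = vapply(calls, `[[`, "", "id"),
  family = vapply(calls, `[[`, "", "family"),
  clade = vapply(calls, `[[`, "", "clade"),
  n_cys = vapply(calls, function(x) x$evidence$n_cys_domain, 1L),
  flags = vapply(calls, function(x) paste(x$flags, collapse = ";"), "")
)
utils::write.table(tab, "results/classification.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

truth_clade <- ifelse(truth$clade == "pla2like", "PLA2like", "sPLA2")
acc_family <- mean(tab$family[match(truth$id, tab$id)] == truth_clade)
canon <- truth$clade %in% c("alpha", "beta")
acc_clade <- mean(tab$clade[match(truth$id[canon], tab$id)] == truth$clade[canon])
message(sprintf("family accuracy %.1f%%, alpha/beta accuracy %.1f%%",
                100 * acc_family, 100 * acc_clade))
message(sprintf("cysteine census: canonical %s, PLA2-like %s",
                paste(sort(unique(tab$n_cys[tab$family == "sPLA2"])), collapse = "/"),
                paste(sort(unique(tab$n_cys[tab$family == "PLA2like"])), collapse = "/")))
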