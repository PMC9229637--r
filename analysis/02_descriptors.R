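#!/usr/bin/env Rscript
# Conceptual-DFT reactivity descriptors for the halogen series: the iodine
# compounds should come out softest (smallest hardness / gap) and most
# electrophilic, mirroring the LUMO-lowering built into the series.

suppressMessages(library(halbind))
dir.create("results", showWarnings = FALSE)

orb <- read_orbitals_tsv("results/fixtures/orbitals.tsv")
tab <- descriptor_table(orb)
write_descriptors_tsv(tab, "results/descriptors.tsv")

cat("descriptor table:", nrow(tab), "compounds -> results/descriptors.tsv\n")
ref <- tab[tab$compound_id == "R", ]
cat(sprintf("reference: gap %.2f eV, hardness %.2f eV, omega %.2f eV\n",
            ref$gap, ref$eta, ref$omega))
soft <- tab[which.min(tab$eta), ]
cat(sprintf("softest compound: %s (hardness %.2f eV, omega %.2f eV)\n",
            soft$compound_id, soft$eta, soft$omega))
stopifnot(soft$eta < ref$eta, grepl("^I", soft$compound_id))
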