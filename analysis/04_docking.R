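#!/usr/bin/env Rscript
# Docking-score analysis: rank the series, convert free energies to
# inhibition constants, and test the F < Cl < Br < I class-mean trend.

suppressMessages(library(halbind))
dir.create("results", showWarnings = FALSE)

dock <- read_docking_tsv("results/fixtures/docking.tsv")
ranked <- annotate_ki(rank_ligands(dock))
write.table(ranked, "results/ranked.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

top <- ranked[1, ]
cat(sprintf("strongest binder: %s (dG %.2f kcal/mol, Ki %s)\n",
            top$compound_id, top$binding_energy, top$ki))
tr <- halogen_trend(dock)
cat("class means (kcal/mol):",
    paste(names(tr$means), round(tr$means, 2), sep = "=", collapse = ", "), "\n")
cat("F < Cl < Br < I trend:", tr$trend, "\n")
stopifnot(isTRUE(tr$trend), grepl("^I", top$compound_id))
cat("ranked table -> results/ranked.tsv\n")
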