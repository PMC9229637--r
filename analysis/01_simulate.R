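#!/usr/bin/env Rscript
# Generate the synthetic study inputs: frontier-orbital energies and docking
# scores for the halogen series, a docked complex with planted contacts, and
# a C-alpha trajectory with a quiet-binding-region fluctuation profile.
# Every artifact gets a *.truth.json sidecar carrying its ground truth.

suppressMessages(library(halbind))
seed <- 20240901L
dir <- "results/fixtures"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)

orb <- gen_orbital_table(seed = seed)
write.table(orb[, c("compound_id", "homo_ev", "lumo_ev")],
            file.path(dir, "orbitals.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(attr(orb, "truth"), file.path(dir, "orbitals.truth.json"),
                     auto_unbox = TRUE, digits = NA)

dock <- gen_docking_table(seed = seed)
write.table(dock, file.path(dir, "docking.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(attr(dock, "truth"), file.path(dir, "docking.truth.json"),
                     auto_unbox = TRUE, digits = NA)

cx <- gen_complex(seed = seed,
                  planted = list(halogen = c(3.1, 3.5, 3.8), hbond = c(2.9, 3.2),
                                 pi_pi = 3.8, pi_alkyl = 4.2))
write_complex_pdb(cx, file.path(dir, "complex.pdb"))
jsonlite::write_json(attr(cx, "truth"), file.path(dir, "complex.truth.json"),
                     auto_unbox = TRUE, digits = NA)

tr <- gen_trajectory(seed = seed, traj_frames = 200)
write_trajectory_pdb(tr, file.path(dir, "trajectory.pdb"))
jsonlite::write_json(as.list(attr(tr, "truth")$sigma),
                     file.path(dir, "trajectory.truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat("wrote synthetic inputs to", dir, "\n")
cat("  compounds:", nrow(orb), " docked complex atoms:",
    nrow(cx$receptor) + nrow(cx$ligand),
    " trajectory frames:", dim(tr$coords)[3], "\n")
cat("  planted contacts:",
    paste(names(attr(cx, "truth")$counts), attr(cx, "truth")$counts,
          sep = "=", collapse = ", "), "\n")
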