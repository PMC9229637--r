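# hand-built single-purpose fixtures; gen_complex covers the composite cases

test_that("halogen criterion is a strict < 4 A protein-H-to-halogen distance", {
  rec <- rbind(
    mk_atoms("HG11", "VAL", 143, c(0, 0, 3.5), "H"),
    mk_atoms("HG12", "VAL", 144, c(0, 0, -4.5), "H"),
    mk_atoms("HG13", "VAL", 145, c(4.0, 0, 0), "H"))
  lig <- mk_atoms("CL1", "LIG", 900, c(0, 0, 0), "Cl", TRUE)
  cx <- mk_complex(rec, lig)
  hits <- find_halogen_contacts(cx)
  expect_equal(nrow(hits), 1)                    # 4.5 outside; 4.0 NOT < 4
  expect_equal(hits$distance, 3.5)
  expect_equal(hits$residue, "Val143")

  wider <- find_halogen_contacts(cx, cutoff = 4.6)
  expect_equal(nrow(wider), 3)                   # monotone in the cutoff
  expect_equal(wider$distance, sort(wider$distance))
})

test_that("ligand without halogens yields no halogen contacts", {
  rec <- mk_atoms("HG11", "VAL", 143, c(0, 0, 2.5), "H")
  lig <- mk_atoms("C1", "LIG", 900, c(0, 0, 0), "C", TRUE)
  expect_equal(nrow(find_halogen_contacts(mk_complex(rec, lig))), 0)
})

test_that("hydrogen-free receptor returns empty halogen set with a warning flag", {
  rec <- mk_atoms("CA", "ALA", 10, c(0, 0, 3), "C")
  lig <- mk_atoms("CL1", "LIG", 900, c(0, 0, 0), "Cl", TRUE)
  hits <- find_halogen_contacts(mk_complex(rec, lig))
  expect_equal(nrow(hits), 0)
  expect_match(attr(hits, "warning"), "hydrogen")
})

test_that("hydrogen bonds require both the distance and the angle criterion", {
  # ligand C-O-H donor aimed at a receptor carbonyl O
  lig <- rbind(
    mk_atoms("C1", "LIG", 900, c(-1.36, 0, 0), "C", TRUE),
    mk_atoms("O1", "LIG", 900, c(0, 0, 0), "O", TRUE),
    mk_atoms("HO1", "LIG", 900, c(0.96, 0, 0), "H", TRUE))
  acceptor_at <- function(d_oo, angle_deg) {
    th <- angle_deg * pi / 180
    r <- 0.96 * cos(th) + sqrt(d_oo^2 - (0.96 * sin(th))^2)
    c(0.96, 0, 0) + r * c(-cos(th), sin(th), 0)
  }
  good <- mk_complex(mk_atoms("O", "GLY", 186, acceptor_at(2.9, 160), "O"), lig)
  hits <- find_hydrogen_bonds(good)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$distance, 2.9, tolerance = 1e-9)
  expect_equal(hits$angle, 160, tolerance = 1e-6)
  expect_equal(hits$residue, "Gly186")

  stretched <- mk_complex(mk_atoms("O", "GLY", 186, acceptor_at(3.6, 160), "O"), lig)
  expect_equal(nrow(find_hydrogen_bonds(stretched)), 0)

  bent <- mk_complex(mk_atoms("O", "GLY", 186, acceptor_at(2.9, 100), "O"), lig)
  expect_equal(nrow(find_hydrogen_bonds(bent)), 0)
})

test_that("pure-hydrocarbon ligand forms no hydrogen bonds", {
  rec <- mk_atoms("O", "GLY", 186, c(0, 0, 3), "O")
  lig <- rbind(mk_atoms("C1", "LIG", 900, c(0, 0, 0), "C", TRUE),
               mk_atoms("H1", "LIG", 900, c(1.09, 0, 0), "H", TRUE))
  expect_equal(nrow(find_hydrogen_bonds(mk_complex(rec, lig))), 0)
})

test_that("parallel and T-shaped stacked rings register as pi-pi", {
  lig <- mk_atoms(paste0("C", 1:6), "LIG", 900, t(hexagon_xyz()), "C", TRUE)
  phe <- function(center, tilt = 0) {
    xyz <- hexagon_xyz(center = c(0, 0, 0))
    if (tilt != 0) {
      R <- matrix(c(1, 0, 0, 0, cos(tilt), -sin(tilt),
                    0, sin(tilt), cos(tilt)), 3, byrow = TRUE)
      xyz <- xyz %*% t(R)
    }
    xyz <- sweep(xyz, 2, -center)
    mk_atoms(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), "PHE", 226,
             t(xyz), "C")
  }
  par_cx <- mk_complex(phe(c(0, 0, 3.8)), lig)
  hits <- find_pi_interactions(par_cx)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$kind, "pi_pi")
  expect_equal(hits$distance, 3.8, tolerance = 1e-9)
  expect_lt(hits$angle, 1e-6)

  tee_cx <- mk_complex(phe(c(0, 0, 5.0), tilt = pi / 2), lig)
  tee <- find_pi_interactions(tee_cx)
  expect_equal(tee$kind, "pi_pi")
  expect_equal(tee$angle, 90, tolerance = 1e-6)

  # 45-degree tilt falls outside both the parallel and T-shaped windows
  mid_cx <- mk_complex(phe(c(0, 0, 4.0), tilt = pi / 4), lig)
  expect_equal(nrow(find_pi_interactions(mid_cx)), 0)

  far_cx <- mk_complex(phe(c(0, 0, 5.6)), lig)
  expect_equal(nrow(find_pi_interactions(far_cx)), 0)
})

test_that("an aliphatic side-chain carbon near a ligand ring is pi-alkyl", {
  lig <- mk_atoms(paste0("C", 1:6), "LIG", 900, t(hexagon_xyz()), "C", TRUE)
  rec <- mk_atoms("CD1", "LEU", 149, c(0, 0, 4.0), "C")
  hits <- find_pi_interactions(mk_complex(rec, lig))
  expect_equal(hits$kind, "pi_alkyl")
  expect_equal(hits$distance, 4.0)
  expect_equal(hits$residue, "Leu149")

  # backbone CA and aromatic-residue carbons do not count as alkyl partners
  rec2 <- rbind(mk_atoms("CA", "LEU", 149, c(0, 0, 4.0), "C"),
                mk_atoms("CB", "PHE", 226, c(0, 0, -4.0), "C"))
  expect_equal(nrow(find_pi_interactions(mk_complex(rec2, lig))), 0)
})

test_that("complex without rings on either side yields no pi contacts", {
  rec <- mk_atoms("CD1", "LEU", 149, c(0, 0, 4), "C")
  lig <- mk_atoms("C1", "LIG", 900, c(0, 0, 0), "C", TRUE)
  expect_equal(nrow(find_pi_interactions(mk_complex(rec, lig))), 0)
})

test_that("profiler counts match planted ground truth and stay consistent", {
  cx <- gen_complex(seed = 1, planted = list(halogen = c(3.2, 3.8),
                                             hbond = 3.0, pi_pi = 3.8))
  rep <- profile_complex(cx)
  expect_equal(rep$counts[["halogen"]], 2)
  expect_equal(rep$counts[["hbond"]], 1)
  expect_equal(rep$counts[["pi_pi"]], 1)
  expect_equal(unname(rep$counts), as.integer(table(factor(
    rep$contacts$kind, levels = names(rep$counts)))))
  expect_false(any(vapply(rep$residues, anyDuplicated, integer(1)) > 0))
  expect_true(all(rep$contacts$distance > 0))
})

test_that("a halogen-free reference-style ligand reports zero halogen bonds", {
  cx <- gen_complex(seed = 2, planted = list(hbond = 3.0, pi_pi = 4.0),
                    decoys = FALSE)
  expect_false(any(cx$ligand$element %in% c("F", "Cl", "Br", "I")))
  rep <- profile_complex(cx)
  expect_equal(rep$counts[["halogen"]], 0)
})

test_that("profiling an empty ligand is an error", {
  rec <- mk_atoms("CA", "ALA", 1, c(0, 0, 0), "C")
  cx <- structure(list(receptor = rec, ligand = rec[0, ],
                       ligand_bonds = matrix(integer(), ncol = 2),
                       ligand_rings = list(), warnings = character()),
                  class = "complex3d")
  expect_error(profile_complex(cx), "empty ligand")
})

test_that("counts are invariant under rigid motion and monotone in cutoffs", {
  for (s in c(5, 23)) {
    cx <- gen_complex(seed = s)
    base <- profile_complex(cx)
    moved <- rigid_transform(cx, random_rotation(seed = s + 100),
                             c(12.3, -4.5, 6.7))
    expect_equal(profile_complex(moved)$counts, base$counts)

    wider <- profile_complex(cx, interaction_criteria(
      halogen_cutoff = 5, hbond_dmax = 4.2, pi_dcc_max = 6.5))
    expect_true(all(wider$counts >= base$counts))
  }
})

test_that("detector counts equal the brute-force oracle on generated complexes", {
  for (s in c(3, 14, 41)) {
    cx <- gen_complex(seed = s)
    expect_equal(nrow(find_halogen_contacts(cx)), bf_halogen_count(cx))
    expect_equal(nrow(find_hydrogen_bonds(cx)), bf_hbond_count(cx))
  }
})

test_that("sigma-hole mode applies the C-X...acceptor angle criterion", {
  # Cl on a carbon, acceptor dead ahead of the C-Cl axis (angle 180)
  lig <- rbind(mk_atoms("C1", "LIG", 900, c(-1.74, 0, 0), "C", TRUE),
               mk_atoms("CL1", "LIG", 900, c(0, 0, 0), "Cl", TRUE))
  head_on <- mk_atoms("O", "GLY", 186, c(3.0, 0, 0), "O")
  side_on <- mk_atoms("O", "GLY", 186, c(0, 3.0, 0), "O")   # angle 90
  expect_equal(nrow(find_halogen_contacts(mk_complex(head_on, lig),
                                          mode = "sigma-hole")), 1)
  expect_equal(nrow(find_halogen_contacts(mk_complex(side_on, lig),
                                          mode = "sigma-hole")), 0)
  # default protein-h mode sees no contact here (no receptor hydrogens)
  expect_equal(nrow(find_halogen_contacts(mk_complex(head_on, lig))), 0)
})

test_that("reports order contacts deterministically and embed criteria", {
  cx <- gen_complex(seed = 8)
  a <- profile_complex(cx)
  b <- profile_complex(cx)
  expect_identical(a$contacts, b$contacts)
  o <- order(a$contacts$kind, a$contacts$distance,
             a$contacts$resseq, a$contacts$serial)
  expect_equal(o, seq_len(nrow(a$contacts)))
  expect_equal(a$criteria$halogen_cutoff, 4.0)
  tf <- tempfile(fileext = ".json")
  write_interaction_report(a, tf)
  parsed <- jsonlite::read_json(tf)
  expect_equal(parsed$counts$halogen, a$counts[["halogen"]])
})
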