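# Geometric detection of the three noncovalent contact classes tabulated for
# docked halogenated inhibitors: hydrogen bonds, pi interactions, and
# protein-H-to-halogen contacts. All detectors are plain O(N^2) scans over
# Euclidean geometry; no spatial index, so results are exactly reproducible.

.HALOGENS <- c("F", "Cl", "Br", "I")

.AROMATIC_RING_ATOMS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

.ALIPHATIC_RES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "MET", "LYS", "ARG",
                    "THR", "CYS")
.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Residue label in the conventional "Val143" style
#' @param resname 3-letter residue name(s).
#' @param resseq residue number(s).
#' @return character labels.
#' @export
residue_label <- function(resname, resseq) {
  r <- toupper(trimws(resname))
  paste0(substr(r, 1, 1), tolower(substr(r, 2, nchar(r))), resseq)
}

#' Detection criteria for contact profiling
#'
#' Bundles the geometric cutoffs used by [profile_complex()]. The halogen
#' criterion (receptor hydrogen within `halogen_cutoff` of a ligand halogen,
#' strict) follows the docking-study definition; hydrogen-bond and pi criteria
#' are conventional defaults and are embedded verbatim in every report.
#'
#' @param halogen_cutoff halogen-contact distance cutoff, Angstrom (strict `<`).
#' @param hbond_dmax donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param hbond_angle_min minimum D-H...A angle, degrees (applied when the
#'   donor hydrogen is present).
#' @param pi_dcc_max max ring-centroid to partner distance, Angstrom.
#' @param pi_tilt_max max interplanar tilt for parallel stacking, degrees
#'   (angles within `90 - pi_tilt_max .. 90` count as T-shaped).
#' @param xb_mode `"protein-h"` (default; receptor-H-to-halogen distance) or
#'   `"sigma-hole"` (adds the crystallographic C-X...acceptor definition with
#'   an angle >= `xb_angle_min`).
#' @param xb_angle_min minimum C-X...A angle for sigma-hole mode, degrees.
#' @return list of class `interaction_criteria`.
#' @export
interaction_criteria <- function(halogen_cutoff = 4.0, hbond_dmax = 3.5,
                                 hbond_angle_min = 120, pi_dcc_max = 5.5,
                                 pi_tilt_max = 30,
                                 xb_mode = c("protein-h", "sigma-hole"),
                                 xb_angle_min = 140) {
  structure(list(halogen_cutoff = halogen_cutoff, hbond_dmax = hbond_dmax,
                 hbond_angle_min = hbond_angle_min, pi_dcc_max = pi_dcc_max,
                 pi_tilt_max = pi_tilt_max, xb_mode = match.arg(xb_mode),
                 xb_angle_min = xb_angle_min),
            class = "interaction_criteria")
}

.contact_df <- function(kind = character(), residue = character(),
                        receptor_atom = character(), ligand_atom = character(),
                        distance = numeric(), angle = numeric(),
                        resseq = integer(), serial = integer()) {
  data.frame(kind = kind, residue = residue, receptor_atom = receptor_atom,
             ligand_atom = ligand_atom, distance = distance, angle = angle,
             resseq = resseq, serial = serial, stringsAsFactors = FALSE)
}

.xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

.angle_deg <- function(a, vertex, b) {
  u <- a - vertex; v <- b - vertex
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

.sort_contacts <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$kind, df$distance, df$resseq, df$serial), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Find halogen contacts in a docked complex
#'
#' Default mode implements the screening criterion used for halogenated
#' inhibitor series: one contact per (receptor hydrogen, ligand halogen) pair
#' strictly closer than `cutoff` Angstrom. A pair at exactly `cutoff` is not
#' a contact. `mode = "sigma-hole"` instead applies the crystallographic
#' definition: ligand C-X directed at a receptor N/O/S acceptor within
#' `cutoff` and with C-X...A angle >= `angle_min`.
#'
#' @param cplx a `complex3d` from [read_complex()] or [gen_complex()].
#' @param cutoff distance cutoff, Angstrom (strict `<`).
#' @param mode `"protein-h"` or `"sigma-hole"`.
#' @param angle_min sigma-hole angle threshold, degrees.
#' @return contact data.frame sorted by distance (ties by residue number and
#'   atom serial), with attribute `warning` when the receptor has no
#'   hydrogens in protein-h mode.
#' @export
find_halogen_contacts <- function(cplx, cutoff = 4.0,
                                  mode = c("protein-h", "sigma-hole"),
                                  angle_min = 140) {
  mode <- match.arg(mode)
  lig <- cplx$ligand
  xi <- which(lig$element %in% .HALOGENS)
  out <- .contact_df()
  warn <- NULL
  if (mode == "protein-h") {
    rec <- cplx$receptor
    hi <- which(rec$element == "H")
    if (length(hi) == 0L)
      warn <- "receptor has no explicit hydrogens; halogen-contact count may be an undercount"
    if (length(hi) && length(xi)) {
      rh <- .xyz(rec[hi, , drop = FALSE])
      lx <- .xyz(lig[xi, , drop = FALSE])
      for (a in seq_along(hi)) for (b in seq_along(xi)) {
        d <- sqrt(sum((rh[a, ] - lx[b, ])^2))
        if (d < cutoff) {
          i <- hi[a]; j <- xi[b]
          out <- rbind(out, .contact_df(
            kind = "halogen",
            residue = residue_label(rec$resname[i], rec$resseq[i]),
            receptor_atom = rec$name[i], ligand_atom = lig$name[j],
            distance = d, angle = NA_real_,
            resseq = rec$resseq[i], serial = rec$serial[i]))
        }
      }
    }
  } else {
    rec <- cplx$receptor
    ai <- which(rec$element %in% c("N", "O", "S"))
    bonds <- cplx$ligand_bonds
    for (j in xi) {
      # carbon the halogen is bonded to (sigma-hole lies opposite this bond)
      nb <- c(bonds[bonds[, 1] == j, 2], bonds[bonds[, 2] == j, 1])
      nb <- nb[lig$element[nb] == "C"]
      if (length(nb) == 0L) next
      cpos <- .xyz(lig[nb[1], , drop = FALSE])[1, ]
      xpos <- .xyz(lig[j, , drop = FALSE])[1, ]
      for (i in ai) {
        apos <- .xyz(rec[i, , drop = FALSE])[1, ]
        d <- sqrt(sum((xpos - apos)^2))
        ang <- .angle_deg(cpos, xpos, apos)
        if (d < cutoff && ang >= angle_min) {
          out <- rbind(out, .contact_df(
            kind = "halogen",
            residue = residue_label(rec$resname[i], rec$resseq[i]),
            receptor_atom = rec$name[i], ligand_atom = lig$name[j],
            distance = d, angle = ang,
            resseq = rec$resseq[i], serial = rec$serial[i]))
        }
      }
    }
  }
  out <- out[order(out$distance, out$resseq, out$serial), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "warning") <- warn
  out
}

# hydrogens attached to each heavy atom (list of index vectors); receptor
# attachment is distance-based, ligand uses the inferred bond list
.attached_h <- function(atoms, bonds = NULL, h_max = 1.2) {
  n <- nrow(atoms)
  att <- rep(list(integer()), n)
  hi <- which(atoms$element == "H")
  if (length(hi) == 0L) return(att)
  if (!is.null(bonds) && nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      if (atoms$element[i] == "H" && atoms$element[j] != "H")
        att[[j]] <- c(att[[j]], i)
      else if (atoms$element[j] == "H" && atoms$element[i] != "H")
        att[[i]] <- c(att[[i]], j)
    }
  } else {
    xyz <- .xyz(atoms)
    heavy <- which(atoms$element != "H")
    for (h in hi) {
      d <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[h, ])^2))
      near <- heavy[d <= h_max]
      for (i in near) att[[i]] <- c(att[[i]], h)
    }
  }
  att
}

#' Find receptor-ligand hydrogen bonds
#'
#' Donors and acceptors are typed by element (N, O, S on both sides); a donor
#' must carry an explicit attached hydrogen (within 1.2 A), so united-atom
#' structures contribute acceptors only -- the complex-level warning about a
#' hydrogen-free receptor flags the resulting undercount. A bond requires
#' heavy-atom distance <= `d_max` and best D-H...A angle >= `angle_min`.
#' Each donor/acceptor pair is reported once; weak C-H donors are not
#' considered.
#'
#' @inheritParams find_halogen_contacts
#' @param d_max donor-acceptor heavy-atom cutoff, Angstrom.
#' @param angle_min minimum D-H...A angle, degrees.
#' @return contact data.frame (kind `"hbond"`).
#' @export
find_hydrogen_bonds <- function(cplx, d_max = 3.5, angle_min = 120) {
  rec <- cplx$receptor
  lig <- cplx$ligand
  rec_att <- .attached_h(rec)
  lig_att <- .attached_h(lig, cplx$ligand_bonds)
  rxyz <- .xyz(rec); lxyz <- .xyz(lig)
  out <- .contact_df()

  scan <- function(don_atoms, don_xyz, don_att,
                   acc_atoms, acc_xyz, rec_is_donor) {
    don <- which(don_atoms$element %in% c("N", "O", "S"))
    don <- don[vapply(don_att[don], length, 1L) > 0L]
    acc <- which(acc_atoms$element %in% c("N", "O", "S"))
    for (i in don) for (j in acc) {
      d <- sqrt(sum((don_xyz[i, ] - acc_xyz[j, ])^2))
      if (d > d_max) next
      hs <- don_att[[i]]
      ang <- max(vapply(hs, function(h)
        .angle_deg(don_xyz[i, ], don_xyz[h, ], acc_xyz[j, ]), numeric(1)))
      if (ang < angle_min) next
      ri <- if (rec_is_donor) i else j
      out <<- rbind(out, .contact_df(
        kind = "hbond",
        residue = residue_label(rec$resname[ri], rec$resseq[ri]),
        receptor_atom = rec$name[ri],
        ligand_atom = if (rec_is_donor) lig$name[j] else lig$name[i],
        distance = d, angle = ang,
        resseq = rec$resseq[ri], serial = rec$serial[ri]))
    }
  }
  scan(rec, rxyz, rec_att, lig, lxyz, rec_is_donor = TRUE)
  scan(lig, lxyz, lig_att, rec, rxyz, rec_is_donor = FALSE)
  .sort_contacts(out)
}

# receptor aromatic rings by canonical side-chain atom names
.receptor_rings <- function(rec) {
  rings <- list()
  keys <- unique(paste(rec$chain, rec$resseq, rec$resname, sep = "|"))
  for (key in keys) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    resname <- parts[3]
    defs <- .AROMATIC_RING_ATOMS[[resname]]
    if (is.null(defs)) next
    sel <- rec$chain == parts[1] & rec$resseq == as.integer(parts[2]) &
      rec$resname == resname
    for (names_k in defs) {
      idx <- match(names_k, ifelse(sel, rec$name, NA_character_))
      if (anyNA(idx)) next
      rings[[length(rings) + 1L]] <- list(
        idx = idx, resname = resname, resseq = as.integer(parts[2]),
        serial = min(rec$serial[idx]))
    }
  }
  rings
}

#' Find pi-stacking and pi-alkyl contacts
#'
#' Receptor aromatic rings are taken from PHE/TYR/TRP/HIS side chains by
#' canonical atom names; ligand rings come from [perceive_aromatic_rings()].
#' `pi_pi`: ring-centroid distance <= `dcc_max` and interplanar angle within
#' `tilt_max` of parallel (0 deg) or perpendicular (90 deg, T-shaped).
#' `pi_alkyl`: an sp3 carbon (aliphatic receptor side-chain carbon, or ligand
#' carbon bearing >= 3 hydrogens) within `dcc_max` of a ring centroid on the
#' opposite side. One contact per (ring, partner).
#'
#' @inheritParams find_halogen_contacts
#' @param dcc_max centroid distance cutoff, Angstrom.
#' @param tilt_max interplanar tilt tolerance, degrees.
#' @return contact data.frame (kinds `"pi_pi"`, `"pi_alkyl"`).
#' @export
find_pi_interactions <- function(cplx, dcc_max = 5.5, tilt_max = 30) {
  rec <- cplx$receptor
  lig <- cplx$ligand
  rxyz <- .xyz(rec); lxyz <- .xyz(lig)
  out <- .contact_df()

  rec_rings <- .receptor_rings(rec)
  lig_rings <- cplx$ligand_rings
  lig_geo <- lapply(lig_rings, function(r) ring_geometry(lxyz[r, , drop = FALSE]))
  rec_geo <- lapply(rec_rings, function(r) ring_geometry(rxyz[r$idx, , drop = FALSE]))

  # pi-pi stacking
  for (a in seq_along(rec_rings)) for (b in seq_along(lig_rings)) {
    d <- sqrt(sum((rec_geo[[a]]$centroid - lig_geo[[b]]$centroid)^2))
    if (d > dcc_max) next
    cosang <- abs(sum(rec_geo[[a]]$normal * lig_geo[[b]]$normal))
    ang <- acos(max(-1, min(1, cosang))) * 180 / pi
    if (ang <= tilt_max || ang >= 90 - tilt_max) {
      rr <- rec_rings[[a]]
      out <- rbind(out, .contact_df(
        kind = "pi_pi", residue = residue_label(rr$resname, rr$resseq),
        receptor_atom = paste0("ring(", rr$resname, ")"),
        ligand_atom = paste0("ring", b),
        distance = d, angle = ang, resseq = rr$resseq, serial = rr$serial))
    }
  }

  # receptor aliphatic side-chain carbons vs ligand ring centroids
  alk <- which(rec$element == "C" & rec$resname %in% .ALIPHATIC_RES &
                 !(rec$name %in% .BACKBONE_NAMES))
  for (i in alk) for (b in seq_along(lig_rings)) {
    d <- sqrt(sum((rxyz[i, ] - lig_geo[[b]]$centroid)^2))
    if (d <= dcc_max) {
      out <- rbind(out, .contact_df(
        kind = "pi_alkyl",
        residue = residue_label(rec$resname[i], rec$resseq[i]),
        receptor_atom = rec$name[i], ligand_atom = paste0("ring", b),
        distance = d, angle = NA_real_,
        resseq = rec$resseq[i], serial = rec$serial[i]))
    }
  }

  # ligand sp3 (>= 3 attached H) carbons vs receptor ring centroids
  lig_att <- .attached_h(lig, cplx$ligand_bonds)
  sp3 <- which(lig$element == "C" &
                 vapply(lig_att, length, 1L) >= 3L)
  for (j in sp3) for (a in seq_along(rec_rings)) {
    d <- sqrt(sum((lxyz[j, ] - rec_geo[[a]]$centroid)^2))
    if (d <= dcc_max) {
      rr <- rec_rings[[a]]
      out <- rbind(out, .contact_df(
        kind = "pi_alkyl", residue = residue_label(rr$resname, rr$resseq),
        receptor_atom = paste0("ring(", rr$resname, ")"),
        ligand_atom = lig$name[j],
        distance = d, angle = NA_real_, resseq = rr$resseq, serial = rr$serial))
    }
  }
  .sort_contacts(out)
}

#' Full noncovalent interaction profile of a docked complex
#'
#' Runs the hydrogen-bond, pi, and halogen detectors and assembles a report
#' with per-kind counts, per-kind interacting residue lists, the criteria
#' used, and both contact totals (unique contacts, and unique
#' kind-by-residue pairs).
#'
#' @param cplx a `complex3d`.
#' @param criteria an [interaction_criteria()] bundle.
#' @return object of class `interaction_report`: list with `contacts` (sorted
#'   by kind, distance, residue number, serial), `counts` (named integer:
#'   hbond, pi_pi, pi_alkyl, halogen), `residues` (per kind, ordered unique
#'   labels), `totals`, `criteria`, `warnings`.
#' @export
profile_complex <- function(cplx, criteria = interaction_criteria()) {
  if (!inherits(cplx, "complex3d")) stop("cplx must be a complex3d object")
  if (nrow(cplx$ligand) == 0L) stop("complex has an empty ligand")
  warnings <- character()
  hal <- find_halogen_contacts(cplx, cutoff = criteria$halogen_cutoff,
                               mode = criteria$xb_mode,
                               angle_min = criteria$xb_angle_min)
  if (!is.null(attr(hal, "warning")))
    warnings <- c(warnings, attr(hal, "warning"))
  hb <- find_hydrogen_bonds(cplx, d_max = criteria$hbond_dmax,
                            angle_min = criteria$hbond_angle_min)
  pp <- find_pi_interactions(cplx, dcc_max = criteria$pi_dcc_max,
                             tilt_max = criteria$pi_tilt_max)
  contacts <- .sort_contacts(rbind(hb, pp, hal))
  kinds <- c("hbond", "pi_pi", "pi_alkyl", "halogen")
  counts <- vapply(kinds, function(k) sum(contacts$kind == k), integer(1))
  residues <- lapply(kinds, function(k)
    unique(contacts$residue[contacts$kind == k]))
  names(residues) <- kinds
  totals <- c(contacts = nrow(contacts),
              residue_contacts = nrow(unique(contacts[, c("kind", "residue")])))
  structure(list(contacts = contacts, counts = counts, residues = residues,
                 totals = totals, criteria = unclass(criteria),
                 warnings = warnings),
            class = "interaction_report")
}

#' @export
print.interaction_report <- function(x, ...) {
  cat("interaction_report:", x$totals[["contacts"]], "contacts (",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), ")\n")
  for (k in names(x$residues))
    if (length(x$residues[[k]]))
      cat("  ", k, ": ", paste(x$residues[[k]], collapse = ", "), "\n", sep = "")
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Write an interaction report as JSON (with flat TSV contact export)
#'
#' @param report an `interaction_report`.
#' @param path JSON output path.
#' @param tsv optional path for a flat TSV of contacts.
#' @return `path`, invisibly.
#' @export
write_interaction_report <- function(report, path, tsv = NULL) {
  obj <- list(criteria = report$criteria,
              counts = as.list(report$counts),
              totals = as.list(report$totals),
              residues = report$residues,
              contacts = report$contacts[, c("kind", "residue", "receptor_atom",
                                             "ligand_atom", "distance", "angle")],
              warnings = report$warnings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(tsv))
    utils::write.table(report$contacts, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
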