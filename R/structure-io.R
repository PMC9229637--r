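# PDB complex I/O and chemical annotation (elements, bonds, rings).
# Parsing/writing is delegated to bio3d; annotation rules live here.

.AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
          "MSE","SEC","PYL")

.WATER <- c("HOH", "WAT", "H2O", "DOD")

# Covalent radii (Angstrom), Cordero et al. consensus values.
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84,
                Se = 1.20, Si = 1.11)

.ELEMENTS <- names(.COV_RADII)

#' Infer an element symbol from a PDB atom name
#'
#' Used when the element column (PDB columns 77-78) is blank. Rule: digits and
#' whitespace are stripped from the atom name; for standard amino-acid residues
#' the first remaining letter is the element (so `CA` in `ALA` is carbon, and
#' hydrogen names like `1HB` or `HG11` resolve to H); for other residues a
#' leading two-letter symbol (`CL`, `BR`, `SE`, `SI`) is recognized first,
#' then the single first letter.
#'
#' @param name atom name(s) as printed in the PDB file.
#' @param resname residue name(s), recycled.
#' @return character vector of element symbols.
#' @export
infer_element <- function(name, resname = "") {
  n <- length(name)
  resname <- rep_len(toupper(trimws(resname)), n)
  clean <- toupper(gsub("[^A-Za-z]", "", name))
  out <- character(n)
  two <- c(CL = "Cl", BR = "Br", SE = "Se", SI = "Si")
  for (i in seq_len(n)) {
    s <- clean[i]
    if (!nzchar(s)) { out[i] <- NA_character_; next }
    if (resname[i] %in% .AA3) {
      out[i] <- substr(s, 1, 1)
      # selenium in selenomethionine/selenocysteine
      if (substr(s, 1, 2) == "SE" && resname[i] %in% c("MSE", "SEC"))
        out[i] <- "Se"
    } else if (substr(s, 1, 2) %in% names(two)) {
      out[i] <- two[[substr(s, 1, 2)]]
    } else {
      out[i] <- substr(s, 1, 1)
    }
    if (out[i] %in% c("D")) out[i] <- "H"  # deuterium
  }
  out
}

.normalize_element <- function(elesy, name, resname) {
  e <- trimws(as.character(elesy))
  e <- ifelse(is.na(e) | !nzchar(e), NA_character_,
              paste0(toupper(substr(e, 1, 1)),
                     tolower(substr(e, 2, nchar(e)))))
  bad <- is.na(e) | !(e %in% .ELEMENTS)
  if (any(bad)) e[bad] <- infer_element(name[bad], resname[bad])
  e
}

.as_pdb_file <- function(pdb) {
  # Accept a path or character lines; bio3d wants a file.
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  tf <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), tf)
  tf
}

.atoms_from_bio3d <- function(at) {
  data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    resname = toupper(trimws(at$resid)),
    chain = ifelse(is.na(at$chain), " ", as.character(at$chain)),
    resseq = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    element = .normalize_element(at$elesy, at$elety, at$resid),
    is_hetatm = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses fixed-column PDB (via bio3d), keeps the first MODEL only, drops
#' waters and alternate locations other than blank/'A', splits ATOM records
#' into the receptor and HETATM records matching `ligand_resname` into the
#' ligand, and annotates the ligand with inferred bonds and aromatic rings.
#' Elements come from PDB columns 77-78 when present, else from
#' [infer_element()].
#'
#' @param pdb path to a PDB file, or the file content as a character string /
#'   vector of lines.
#' @param ligand_resname HETATM residue name of the ligand (e.g. `"LIG"`,
#'   `"EST"`).
#' @param bond_tol covalent-radius-sum multiplier for bond inference.
#' @param planarity_tol max out-of-plane deviation (Angstrom) for a ring to
#'   count as aromatic.
#' @return An object of class `complex3d`: list with `receptor` and `ligand`
#'   atom data.frames (columns serial, name, resname, chain, resseq, x, y, z,
#'   element, is_hetatm), `ligand_bonds` (2-column index matrix into the
#'   ligand table), `ligand_rings` (list of index vectors), and `warnings`.
#' @export
read_complex <- function(pdb, ligand_resname, bond_tol = 1.3,
                         planarity_tol = 0.15) {
  f <- .as_pdb_file(pdb)
  p <- tryCatch(bio3d::read.pdb(f, multi = FALSE, verbose = FALSE),
                error = function(e) stop("cannot parse PDB input: ",
                                         conditionMessage(e), call. = FALSE))
  at <- p$atom
  if (is.null(at) || nrow(at) == 0L) stop("PDB input contains no atoms")
  bad_xyz <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad_xyz))
    stop("malformed coordinates for atom record(s) ",
         paste(utils::head(at$eleno[bad_xyz], 5), collapse = ", "))
  # altloc: keep blank or 'A'
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  atoms <- .atoms_from_bio3d(at)
  atoms <- atoms[!(atoms$resname %in% .WATER), , drop = FALSE]

  receptor <- atoms[!atoms$is_hetatm, , drop = FALSE]
  het <- atoms[atoms$is_hetatm, , drop = FALSE]
  ligand <- het[het$resname == toupper(ligand_resname), , drop = FALSE]
  if (nrow(ligand) == 0L) {
    avail <- sort(unique(het$resname))
    stop("no HETATM residue named '", ligand_resname, "' found; available: ",
         if (length(avail)) paste(avail, collapse = ", ") else "(none)")
  }
  rownames(receptor) <- NULL
  rownames(ligand) <- NULL

  warnings <- character()
  if (!any(receptor$element == "H"))
    warnings <- c(warnings,
                  "receptor contains no explicit hydrogens; hydrogen-dependent contact detection will be incomplete")

  bonds <- infer_ligand_bonds(ligand, tol = bond_tol)
  rings <- perceive_aromatic_rings(ligand, bonds, planarity_tol = planarity_tol)
  structure(list(receptor = receptor, ligand = ligand,
                 ligand_bonds = bonds, ligand_rings = rings,
                 warnings = warnings),
            class = "complex3d")
}

#' @export
print.complex3d <- function(x, ...) {
  cat("complex3d:", nrow(x$receptor), "receptor atoms,",
      nrow(x$ligand), "ligand atoms (", x$ligand$resname[1], "),",
      nrow(x$ligand_bonds), "ligand bonds,",
      length(x$ligand_rings), "aromatic ring(s)\n")
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Write atoms (or a complex) to a PDB file
#'
#' Receptor atoms are written as ATOM records and ligand atoms as HETATM, with
#' the element symbol in columns 77-78. Coordinates are written at PDB
#' precision (3 decimals).
#'
#' @param x a `complex3d` object or a single atom data.frame (columns as in
#'   [read_complex()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(x, path) {
  atoms <- if (inherits(x, "complex3d")) rbind(x$receptor, x$ligand) else x
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = ifelse(atoms$is_hetatm, "HETATM", "ATOM"),
    resno = atoms$resseq, resid = atoms$resname,
    eleno = atoms$serial, elety = atoms$name,
    chain = atoms$chain, elesy = atoms$element
  )
  invisible(path)
}

#' Infer covalent bonds among ligand atoms
#'
#' Distance rule: two non-hydrogen atoms are bonded when their separation is
#' at most `tol` times the sum of their covalent radii; a hydrogen is bonded
#' to a heavy atom within `h_max` Angstrom. Hydrogen-hydrogen bonds and
#' near-overlapping pairs (< 0.4 A) are never bonded.
#'
#' @param ligand atom data.frame.
#' @param tol covalent-radius-sum multiplier (default 1.3).
#' @param h_max maximum H-to-heavy-atom bond length (default 1.2 A).
#' @return integer matrix with columns `i`, `j` (i < j), indices into `ligand`.
#' @export
infer_ligand_bonds <- function(ligand, tol = 1.3, h_max = 1.2) {
  n <- nrow(ligand)
  empty <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (n < 2L) return(empty)
  xyz <- as.matrix(ligand[, c("x", "y", "z")])
  elem <- ligand$element
  rad <- .COV_RADII[elem]
  rad[is.na(rad)] <- 0.77  # unknown elements treated as carbon-like
  d <- as.matrix(stats::dist(xyz))
  is_h <- elem == "H"
  lim <- tol * outer(rad, rad, `+`)
  lim[is_h, ] <- h_max
  lim[, is_h] <- h_max
  ok <- d <= lim & d >= 0.4
  ok[is_h, is_h] <- FALSE
  ok[lower.tri(ok, diag = TRUE)] <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  out <- cbind(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# All simple cycles of length 5 or 6 through the bond graph, each reported
# once (as a sorted member set). Depth-bounded DFS; ligand graphs are small.
.find_rings_5_6 <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(list())
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  found <- new.env(parent = emptyenv())
  walk <- function(start, path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == start && length(path) >= 5L) {
        key <- paste(sort(path), collapse = "-")
        if (is.null(found[[key]])) found[[key]] <- path
      } else if (nb > start && !(nb %in% path) && length(path) < 6L) {
        walk(start, c(path, nb))
      }
    }
  }
  for (s in seq_len(n_atoms)) if (length(adj[[s]]) >= 2L) walk(s, s)
  lapply(ls(found), function(k) found[[k]])
}

.best_fit_plane_dev <- function(xyz) {
  c0 <- colMeans(xyz)
  centered <- sweep(xyz, 2, c0)
  s <- svd(centered)
  normal <- s$v[, 3]
  max(abs(centered %*% normal))
}

#' Perceive flat 5/6-membered rings in a ligand
#'
#' Finds simple 5- and 6-membered cycles in the bond graph whose members are
#' sp2-eligible elements (C, N, O, S) and which deviate at most
#' `planarity_tol` from their best-fit plane; these are treated as aromatic
#' for pi-interaction detection.
#'
#' @param ligand atom data.frame.
#' @param bonds bond matrix from [infer_ligand_bonds()].
#' @param planarity_tol max out-of-plane deviation, Angstrom (default 0.15).
#' @return list of integer vectors (indices into `ligand`), each a ring.
#' @export
perceive_aromatic_rings <- function(ligand, bonds, planarity_tol = 0.15) {
  elig <- ligand$element %in% c("C", "N", "O", "S")
  keep <- bonds[elig[bonds[, 1]] & elig[bonds[, 2]], , drop = FALSE]
  cycles <- .find_rings_5_6(nrow(ligand), keep)
  xyz <- as.matrix(ligand[, c("x", "y", "z")])
  flat <- Filter(function(r) .best_fit_plane_dev(xyz[r, , drop = FALSE]) <=
                   planarity_tol, cycles)
  # stable order: by smallest member index
  flat[order(vapply(flat, min, numeric(1)))]
}

#' Ring centroid and unit normal
#'
#' @param xyz coordinate matrix of the ring atoms (rows = atoms).
#' @return list with `centroid` (length-3) and `normal` (unit length-3).
#' @keywords internal
ring_geometry <- function(xyz) {
  c0 <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, c0))
  list(centroid = c0, normal = s$v[, 3])
}
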