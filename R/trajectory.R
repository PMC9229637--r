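# Superposition (Kabsch) RMSD and multi-frame stability metrics (RMSD/RMSF).
# The Kabsch solver is authored here; bio3d's fit.xyz/rmsd serve only as an
# independent cross-check in the test suite.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `reference`: minimizes sqrt(sum ||R m_i + t - r_i||^2 / N) over all
#' rotations with determinant +1 (reflections are never returned; the sign of
#' the smallest singular direction is corrected when needed).
#'
#' @param mobile N x 3 coordinate matrix (Angstrom).
#' @param reference N x 3 coordinate matrix, same row order.
#' @param weights optional non-negative per-atom weights.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3) and
#'   `rmsd` (Angstrom). The fitted coordinates are
#'   `mobile %*% t(rotation) + translation` (row-wise).
#' @examples
#' m <- matrix(rnorm(12), 4, 3)
#' superpose_kabsch(m, m)$rmsd  # 0
#' @export
superpose_kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be N x 3 matrices of equal size")
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 atoms are required for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)

  mc <- colSums(mobile * w); rc <- colSums(reference * w)
  m0 <- sweep(mobile, 2, mc); r0 <- sweep(reference, 2, rc)
  if (svd(r0 * sqrt(w))$d[2] < 1e-8 * max(1, svd(r0 * sqrt(w))$d[1]))
    stop("degenerate reference: atoms are collinear")

  cov <- t(m0 * w) %*% r0
  s <- svd(cov)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- m0 %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - r0)^2)))
  list(rotation = rot, translation = as.numeric(rc - rot %*% mc), rmsd = rmsd)
}

#' Plain (no-fit) RMSD between two coordinate sets
#'
#' `sqrt(mean(||a_i - b_i||^2))` with no superposition; use on pre-aligned
#' frames or for pose-to-pose comparison in a common frame.
#'
#' @param a,b N x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_plain <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Construct a trajectory object
#'
#' @param coords N x 3 x F array, or list of F matrices (N x 3) with constant
#'   atom count and order.
#' @param atoms atom metadata data.frame (columns name, resname, resseq at
#'   minimum; optionally chain, element, serial, is_hetatm).
#' @param times optional per-frame times (ns).
#' @return object of class `md_trajectory` with elements `coords` (N x 3 x F),
#'   `atoms`, `times`.
#' @export
md_trajectory <- function(coords, atoms, times = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    dims <- vapply(coords, dim, integer(2))
    if (length(unique(dims[1, ])) != 1L)
      stop("all frames must have the same atom count")
    coords <- array(unlist(coords), dim = c(dims[1, 1], 3, length(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an N x 3 x F array")
  if (dim(coords)[1] < 1L || dim(coords)[3] < 1L)
    stop("trajectory needs at least one atom and one frame")
  if (nrow(atoms) != dim(coords)[1])
    stop("atom metadata does not match coordinate count")
  structure(list(coords = coords, atoms = atoms, times = times),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", dim(x$coords)[1], "atoms x", dim(x$coords)[3],
      "frames\n")
  invisible(x)
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL block is one frame; atom count and order must be constant.
#'
#' @param pdb path to a multi-model PDB file, or its text.
#' @return an `md_trajectory`.
#' @export
read_trajectory <- function(pdb) {
  f <- .as_pdb_file(pdb)
  p <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  atoms <- .atoms_from_bio3d(p$atom)
  xyz <- p$xyz                      # frames x 3N
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n <- nrow(atoms); fno <- nrow(xyz)
  coords <- array(NA_real_, dim = c(n, 3, fno))
  for (k in seq_len(fno))
    coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  md_trajectory(coords, atoms)
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj an `md_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$atoms
  if (is.null(a$chain)) a$chain <- "A"
  if (is.null(a$element)) a$element <- infer_element(a$name, a$resname)
  if (is.null(a$serial)) a$serial <- seq_len(nrow(a))
  if (is.null(a$is_hetatm)) a$is_hetatm <- FALSE
  fno <- dim(traj$coords)[3]
  xyz <- t(vapply(seq_len(fno),
                  function(k) as.numeric(t(traj$coords[, , k])),
                  numeric(3 * nrow(a))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$is_hetatm, "HETATM", "ATOM"),
                   resno = a$resseq, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, elesy = a$element)
  invisible(path)
}

#' Resolve an atom selection on trajectory metadata
#'
#' @param atoms atom metadata data.frame.
#' @param selection `"ca"` (alpha carbons of polymer residues), `"heavy"`
#'   (non-hydrogen), `"all"`, a logical vector, or an integer index vector.
#' @return integer indices.
#' @export
select_atoms <- function(atoms, selection = "ca") {
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.logical(selection)) return(which(selection))
  idx <- switch(selection,
    ca = which(atoms$name == "CA" &
                 (if (is.null(atoms$is_hetatm)) TRUE else !atoms$is_hetatm)),
    heavy = which(is.null(atoms$element) | atoms$element != "H"),
    all = seq_len(nrow(atoms)),
    stop("unknown selection '", selection, "'")
  )
  idx
}

#' Per-frame superposed RMSD of a trajectory
#'
#' Each frame's selected atoms are Kabsch-fitted to the reference frame's
#' before the RMSD is taken, so global rigid drift does not register.
#'
#' @param traj an `md_trajectory`.
#' @param selection see [select_atoms()]; default alpha carbons.
#' @param reference_frame frame index used as reference (default 1).
#' @return numeric vector of per-frame RMSD (Angstrom); the reference frame's
#'   entry is 0.
#' @export
trajectory_rmsd <- function(traj, selection = "ca", reference_frame = 1L) {
  sel <- select_atoms(traj$atoms, selection)
  if (length(sel) == 0L) stop("empty atom selection")
  fno <- dim(traj$coords)[3]
  if (reference_frame < 1L || reference_frame > fno)
    stop("reference_frame out of range")
  ref <- traj$coords[sel, , reference_frame, drop = FALSE][, , 1]
  vapply(seq_len(fno), function(k) {
    if (k == reference_frame) return(0)
    superpose_kabsch(traj$coords[sel, , k, drop = FALSE][, , 1], ref)$rmsd
  }, numeric(1))
}

#' Per-residue RMSF of a trajectory
#'
#' All frames are first fitted (on the selection) to the first frame; the
#' per-atom RMSF is `sqrt(mean_t ||x_i(t) - <x_i>||^2)` and the per-residue
#' value is the mean over that residue's selected atoms. For isotropic
#' Gaussian jitter of per-axis standard deviation sigma the expected RMSF is
#' sigma * sqrt(3).
#'
#' @inheritParams trajectory_rmsd
#' @return named numeric vector, one entry per residue (labels like
#'   `"Val143"`), with per-atom values in attribute `per_atom`.
#' @export
trajectory_rmsf <- function(traj, selection = "ca") {
  sel <- select_atoms(traj$atoms, selection)
  if (length(sel) == 0L) stop("empty atom selection")
  fno <- dim(traj$coords)[3]
  if (fno < 2L)
    stop("RMSF needs at least 2 frames (single-frame fluctuation is undefined)")
  ref <- traj$coords[sel, , 1, drop = FALSE][, , 1]
  fitted <- array(NA_real_, dim = c(length(sel), 3, fno))
  fitted[, , 1] <- ref
  for (k in 2:fno) {
    m <- traj$coords[sel, , k, drop = FALSE][, , 1]
    fit <- superpose_kabsch(m, ref)
    fitted[, , k] <- sweep(m %*% t(fit$rotation), 2, -fit$translation)
  }
  mean_pos <- apply(fitted, c(1, 2), mean)
  dev2 <- vapply(seq_len(fno),
                 function(k) rowSums((fitted[, , k] - mean_pos)^2),
                 numeric(length(sel)))
  if (is.null(dim(dev2))) dev2 <- matrix(dev2, nrow = length(sel))
  per_atom <- sqrt(rowMeans(dev2))
  lab <- residue_label(traj$atoms$resname[sel], traj$atoms$resseq[sel])
  per_res <- tapply(per_atom, factor(lab, levels = unique(lab)), mean)
  out <- as.numeric(per_res)
  names(out) <- names(per_res)
  attr(out, "per_atom") <- per_atom
  out
}

#' Stability summary over a set of trajectories
#'
#' Per complex: the (min, max) of the superposed RMSD series after an
#' equilibration skip, and the residues whose RMSF falls below
#' `stable_threshold` (flagged stable).
#'
#' @param traj_set named list of `md_trajectory` objects.
#' @param selection see [select_atoms()].
#' @param skip number of initial frames excluded from the RMSD range.
#' @param stable_threshold RMSF below which a residue is flagged stable
#'   (Angstrom).
#' @return list with `table` (data.frame complex_id, rmsd_min, rmsd_max,
#'   n_frames) and `stable_residues` (named list of character vectors).
#' @export
stability_summary <- function(traj_set, selection = "ca", skip = 0L,
                              stable_threshold = 1.0) {
  if (length(traj_set) == 0L) stop("empty trajectory set")
  ids <- names(traj_set)
  if (is.null(ids)) ids <- paste0("complex", seq_along(traj_set))
  rows <- list(); stable <- list()
  for (i in seq_along(traj_set)) {
    tr <- traj_set[[i]]
    series <- trajectory_rmsd(tr, selection)
    keep <- series[(skip + 1):length(series)]
    rmsf <- trajectory_rmsf(tr, selection)
    rows[[i]] <- data.frame(complex_id = ids[i], rmsd_min = min(keep),
                            rmsd_max = max(keep),
                            n_frames = length(series))
    stable[[ids[i]]] <- names(rmsf)[rmsf < stable_threshold]
  }
  list(table = do.call(rbind, rows), stable_residues = stable)
}
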