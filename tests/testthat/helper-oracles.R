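# Independent oracles and fixture builders. Everything here is deliberately
# naive (plain loops over all pairs, coarse-to-fine searches) and shares no
# code with the package implementation.

mk_atoms <- function(name, resname, resseq, xyz, element,
                     is_hetatm = FALSE, chain = "A", serial = NULL) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  n <- nrow(xyz)
  data.frame(serial = if (is.null(serial)) seq_len(n) else serial,
             name = rep_len(name, n), resname = rep_len(resname, n),
             chain = rep_len(chain, n), resseq = rep_len(resseq, n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = rep_len(element, n),
             is_hetatm = rep_len(is_hetatm, n), stringsAsFactors = FALSE)
}

# assemble a complex3d from receptor/ligand atom tables, renumbering serials
mk_complex <- function(receptor, ligand) {
  receptor$serial <- seq_len(nrow(receptor))
  ligand$serial <- nrow(receptor) + seq_len(nrow(ligand))
  ligand$is_hetatm <- TRUE
  bonds <- infer_ligand_bonds(ligand)
  rings <- perceive_aromatic_rings(ligand, bonds)
  structure(list(receptor = receptor, ligand = ligand, ligand_bonds = bonds,
                 ligand_rings = rings, warnings = character()),
            class = "complex3d")
}

# planar hexagon of carbons, edge length = radius
hexagon_xyz <- function(center = c(0, 0, 0), radius = 1.39, offset = 0) {
  ang <- (0:5) * pi / 3 + offset
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
        rep(center[3], 6))
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

# brute-force halogen count: every (receptor H, ligand halogen) pair < cutoff
bf_halogen_count <- function(cplx, cutoff = 4) {
  rec <- cplx$receptor; lig <- cplx$ligand
  n <- 0L
  for (i in seq_len(nrow(rec))) {
    if (rec$element[i] != "H") next
    for (j in seq_len(nrow(lig))) {
      if (!(lig$element[j] %in% c("F", "Cl", "Br", "I"))) next
      if (euclid(c(rec$x[i], rec$y[i], rec$z[i]),
                 c(lig$x[j], lig$y[j], lig$z[j])) < cutoff) n <- n + 1L
    }
  }
  n
}

# brute-force intermolecular H-bond count (donor = N/O/S with an explicit H
# within 1.2 A on its own side; angle via the best attached H)
bf_hbond_count <- function(cplx, d_max = 3.5, angle_min = 120) {
  sides <- list(r = cplx$receptor, l = cplx$ligand)
  xyz <- function(df, i) c(df$x[i], df$y[i], df$z[i])
  ang3 <- function(a, v, b) {
    u1 <- a - v; u2 <- b - v
    acos(max(-1, min(1, sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))))) * 180 / pi
  }
  count <- 0L
  for (ds in c("r", "l")) {
    don <- sides[[ds]]; acc <- sides[[setdiff(c("r", "l"), ds)]]
    for (i in which(don$element %in% c("N", "O", "S"))) {
      hs <- which(don$element == "H" &
                    sqrt((don$x - don$x[i])^2 + (don$y - don$y[i])^2 +
                           (don$z - don$z[i])^2) <= 1.2)
      if (length(hs) == 0L) next
      for (j in which(acc$element %in% c("N", "O", "S"))) {
        d <- euclid(xyz(don, i), xyz(acc, j))
        if (d > d_max) next
        best <- max(vapply(hs, function(h)
          ang3(xyz(don, i), xyz(don, h), xyz(acc, j)), numeric(1)))
        if (best < angle_min) next
        count <- count + 1L
      }
    }
  }
  count
}

# coarse-to-fine search over rotations (ZXZ Euler angles) for the minimum
# attainable RMSD; translation handled by centroid matching
grid_rmsd_oracle <- function(mobile, reference, levels = 5) {
  rotz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                               0, 0, 1), 3, byrow = TRUE)
  rotx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a),
                               0, sin(a), cos(a)), 3, byrow = TRUE)
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(reference, 2, colMeans(reference))
  score <- function(p) {
    R <- rotz(p[1]) %*% rotx(p[2]) %*% rotz(p[3])
    sqrt(mean(rowSums((m0 %*% t(R) - r0)^2)))
  }
  centre <- c(pi, pi / 2, pi)
  span <- c(pi, pi / 2, pi)
  best <- c(centre, score(centre))
  for (lev in seq_len(levels)) {
    grid <- expand.grid(a = seq(centre[1] - span[1], centre[1] + span[1], length.out = 9),
                        b = seq(centre[2] - span[2], centre[2] + span[2], length.out = 9),
                        c = seq(centre[3] - span[3], centre[3] + span[3], length.out = 9))
    vals <- apply(grid, 1, score)
    k <- which.min(vals)
    centre <- as.numeric(grid[k, ])
    if (vals[k] < best[4]) best <- c(centre, vals[k])
    span <- span / 4
  }
  best[4]
}
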