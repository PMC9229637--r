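test_that("Kabsch superposition removes rigid motion exactly", {
  set.seed(2)
  ref <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_kabsch(ref, ref)$rmsd, 0, tolerance = 1e-10)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, byrow = TRUE)
  moved <- sweep(ref %*% t(R), 2, -c(5, 0, 0))
  fit <- superpose_kabsch(moved, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  fitted <- sweep(moved %*% t(fit$rotation), 2, -fit$translation)
  expect_equal(fitted, ref, tolerance = 1e-8)
})

test_that("Kabsch RMSD agrees with a rotation-grid search oracle", {
  a <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 2, 0, 0.5, 0.5, 1.2), 4, 3, byrow = TRUE)
  b <- matrix(c(0.1, 0, 0, 1.4, 0.3, 0, -0.2, 1.9, 0.2, 0.6, 0.4, 1.0),
              4, 3, byrow = TRUE)
  got <- superpose_kabsch(a, b)$rmsd
  expect_equal(got, grid_rmsd_oracle(a, b), tolerance = 1e-3)
  # a second, asymmetric pair
  set.seed(9)
  c1 <- matrix(rnorm(12, sd = 2), 4, 3)
  c2 <- c1 + matrix(rnorm(12, sd = 0.3), 4, 3)
  expect_equal(superpose_kabsch(c1, c2)$rmsd, grid_rmsd_oracle(c1, c2),
               tolerance = 1e-3)
})

test_that("Kabsch agrees with the bio3d reference implementation", {
  set.seed(4)
  for (i in 1:5) {
    a <- matrix(rnorm(24), 8, 3)
    b <- a + matrix(rnorm(24, sd = 0.5), 8, 3)
    ours <- superpose_kabsch(a, b)$rmsd
    theirs <- bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)), fit = TRUE)
    expect_equal(ours, theirs, tolerance = 2e-3)  # bio3d reports 3 decimals
  }
})

test_that("rotation output is orthogonal with determinant +1, never a reflection", {
  set.seed(6)
  for (i in 1:20) {
    a <- matrix(rnorm(15), 5, 3)
    b <- matrix(rnorm(15), 5, 3)
    R <- superpose_kabsch(a, b)$rotation
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
  # a mirrored copy cannot be fitted to zero: reflections are forbidden
  a <- matrix(rnorm(15), 5, 3)
  mirrored <- a %*% diag(c(-1, 1, 1))
  expect_gt(superpose_kabsch(mirrored, a)$rmsd, 1e-3)
})

test_that("fitting never increases RMSD and is symmetric", {
  set.seed(8)
  for (i in 1:20) {
    a <- matrix(rnorm(21), 7, 3)
    b <- matrix(rnorm(21), 7, 3)
    expect_lte(superpose_kabsch(a, b)$rmsd, rmsd_plain(a, b) + 1e-12)
    expect_equal(superpose_kabsch(a, b)$rmsd, superpose_kabsch(b, a)$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("degenerate and mismatched inputs are rejected", {
  a <- matrix(rnorm(12), 4, 3)
  expect_error(superpose_kabsch(a, a[1:3, ][, 1:2]), "equal size")
  expect_error(superpose_kabsch(a[1:2, ], a[1:2, ]), "3 atoms")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose_kabsch(line + rnorm(15, sd = 1e-12), line), "collinear")
  expect_error(rmsd_plain(a, a[1:3, ]), "size")
})

test_that("plain RMSD matches hand arithmetic", {
  a <- matrix(0, 2, 3)
  expect_equal(rmsd_plain(a, a), 0)
  shifted <- matrix(c(1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(rmsd_plain(a, shifted), 1)
  two <- matrix(c(3, 0, 0, 0, 4, 0), 2, 3, byrow = TRUE)
  expect_equal(rmsd_plain(a, two), sqrt((9 + 16) / 2))
})

test_that("trajectory RMSD is zero for static or rigidly moved frames", {
  tr <- gen_trajectory(seed = 1, traj_frames = 8, sigma_profile = 0)
  expect_equal(trajectory_rmsd(tr), rep(0, 8), tolerance = 1e-8)

  drifted <- gen_trajectory(seed = 1, traj_frames = 8, sigma_profile = 0,
                            drift = TRUE)
  expect_equal(trajectory_rmsd(drifted), rep(0, 8), tolerance = 1e-8)
  # without fitting the drift is visible
  plain <- vapply(2:8, function(k)
    rmsd_plain(drifted$coords[, , k], drifted$coords[, , 1]), numeric(1))
  expect_true(any(plain > 0.01))
})

test_that("trajectory RMSD equals a direct per-frame evaluation", {
  tr <- gen_trajectory(seed = 5, traj_frames = 12)
  series <- trajectory_rmsd(tr)
  expect_equal(series[1], 0)
  sel <- which(tr$atoms$name == "CA")
  direct <- vapply(seq_len(12), function(k)
    superpose_kabsch(tr$coords[sel, , k], tr$coords[sel, , 1])$rmsd,
    numeric(1))
  direct[1] <- 0
  expect_equal(series, direct, tolerance = 1e-12)
  expect_error(trajectory_rmsd(tr, selection = integer()), "empty")
})

test_that("RMSF reproduces the two-point closed form and rejects single frames", {
  base <- gen_trajectory(seed = 1, traj_frames = 2, sigma_profile = 0)
  co <- base$coords
  d <- 0.7
  co[1, 1, 1] <- co[1, 1, 1] + d
  co[1, 1, 2] <- co[1, 1, 2] - d
  # fitting to frame 1 would absorb part of the displacement; pin the fit by
  # keeping all other atoms identical across frames (they dominate the fit)
  tr <- md_trajectory(co, base$atoms)
  rmsf <- trajectory_rmsf(tr)
  # per-frame fitting absorbs a small rigid component of the displacement
  expect_equal(unname(rmsf[1]), d, tolerance = 0.07)
  expect_true(all(rmsf[-1] < 0.05))

  one <- md_trajectory(co[, , 1, drop = FALSE], base$atoms)
  expect_error(trajectory_rmsf(one), "2 frames")
})

test_that("RMSF recovers the generator sigma via the sqrt(3) law", {
  tr <- gen_trajectory(seed = 2, traj_frames = 2000, sigma_profile = 0.5)
  rmsf <- trajectory_rmsf(tr)
  expect_equal(median(rmsf) / sqrt(3), 0.5, tolerance = 0.05)
})

test_that("RMSF agrees with the bio3d implementation on fitted frames", {
  tr <- gen_trajectory(seed = 3, traj_frames = 60)
  ours <- trajectory_rmsf(tr)
  # hand the same fitted coordinates to bio3d::rmsf
  sel <- which(tr$atoms$name == "CA")
  ref <- tr$coords[sel, , 1]
  xyz <- t(vapply(seq_len(60), function(k) {
    m <- tr$coords[sel, , k]
    f <- superpose_kabsch(m, ref)
    as.numeric(t(sweep(m %*% t(f$rotation), 2, -f$translation)))
  }, numeric(3 * length(sel))))
  theirs <- bio3d::rmsf(xyz)
  # bio3d divides by F - 1; rescale to the population form used here
  expect_equal(unname(attr(ours, "per_atom")) * sqrt(60 / 59), theirs,
               tolerance = 1e-3)
})

test_that("RMSF is invariant under a global rigid motion of all frames", {
  tr <- gen_trajectory(seed = 4, traj_frames = 40)
  moved <- rigid_transform(tr, random_rotation(9), c(3, -2, 8))
  expect_equal(trajectory_rmsf(moved), trajectory_rmsf(tr), tolerance = 1e-8)
})

test_that("stability summary reports ranges and flags quiet regions", {
  tr1 <- gen_trajectory(seed = 6, traj_frames = 40)
  out <- stability_summary(list(a = tr1, b = tr1), stable_threshold = 1.0)
  expect_equal(out$table$rmsd_min, rep(min(trajectory_rmsd(tr1)), 2))
  expect_equal(out$table$rmsd_max, rep(max(trajectory_rmsd(tr1)), 2))
  expect_identical(out$stable_residues$a, out$stable_residues$b)

  # the default sigma profile is quiet in 140-160 and 180-200
  stable_res <- as.integer(gsub("[^0-9]", "", out$stable_residues$a))
  expect_true(all(stable_res %in% c(140:160, 180:200)))
  expect_gt(length(stable_res), 30)

  # equilibration skip trims the range window
  series <- trajectory_rmsd(tr1)
  skipped <- stability_summary(list(a = tr1), skip = 10)
  expect_equal(skipped$table$rmsd_min, min(series[11:40]))
})

test_that("multi-model PDB trajectories round-trip through disk", {
  tr <- gen_trajectory(seed = 7, traj_frames = 5)
  tf <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, tf)
  back <- read_trajectory(tf)
  expect_equal(dim(back$coords), dim(tr$coords))
  expect_equal(back$coords, tr$coords, tolerance = 5e-4)
  expect_equal(back$atoms$resseq, tr$atoms$resseq)
  expect_equal(trajectory_rmsd(back), trajectory_rmsd(tr), tolerance = 1e-3)
})
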