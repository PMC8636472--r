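test_that("Kabsch superposition removes rigid motion exactly", {
  gq <- build_ideal_gq(c9_22mer())
  X <- as.matrix(gq$atom[, c("x", "y", "z")])
  self <- kabsch_superpose(X, X)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  moved <- sweep(X %*% t(rot_xyz(c(0.4, -1.2, 2.0))), 2, c(10, -4, 2), "+")
  fit <- kabsch_superpose(moved, X)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches the analytic noise expectation and bio3d", {
  set.seed(99)
  n <- 500
  X <- matrix(rnorm(3 * n, sd = 8), n, 3)
  noisy <- X + matrix(rnorm(3 * n, sd = 0.5), n, 3)
  moved <- sweep(noisy %*% t(rot_xyz(c(1, 0.2, -0.5))), 2, c(3, 3, 3), "+")
  fit <- kabsch_superpose(moved, X)
  expect_equal(fit$rmsd, 0.5 * sqrt(3), tolerance = 0.05)
  # independent cross-check: bio3d's fitting machinery
  ref_rmsd <- bio3d::rmsd(as.vector(t(X)), as.vector(t(moved)), fit = TRUE)
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-3)
  # degenerate selections are refused
  expect_error(kabsch_superpose(moved, X, selection = 1:2), "degenerate")
  line <- cbind(1:10, 0, 0)
  expect_error(kabsch_superpose(line + 0.0, line), "collinear")
})

test_that("static trajectories give zero RMSD and RMSF everywhere", {
  gq <- build_ideal_gq(c9_22mer())
  traj <- static_trajectory(gq, 5)
  rmsd <- per_residue_rmsd(traj)
  expect_true(all(abs(rmsd$per_residue$mean_rmsd_A) < 1e-9))
  rmsf <- per_residue_rmsf(traj)
  expect_true(all(abs(rmsf$rmsf_A) < 1e-9))
})

test_that("pure global rigid motion is removed by superposition", {
  gq <- build_ideal_gq(c9_22mer())
  traj <- gen_gq_trajectory(gq, 0, 0, n_frames = 10, rigid_motion = TRUE,
                            seed = 8)
  rmsd <- per_residue_rmsd(traj)
  expect_true(all(rmsd$per_residue$mean_rmsd_A < 1e-6))
  rmsf <- per_residue_rmsf(traj)
  expect_true(all(rmsf$rmsf_A < 1e-6))
})

test_that("trajectory statistics are invariant to a uniform rigid motion", {
  gq <- build_ideal_gq(c9_22mer())
  traj <- gen_gq_trajectory(gq, 0.2, 1.0, n_frames = 20, seed = 12)
  st1 <- traj_stats(traj)
  R <- rot_xyz(c(0.7, -0.2, 1.4)); tr <- c(-6, 2, 9)
  moved <- traj
  for (f in seq_len(length(traj)))
    moved$coords[, , f] <- sweep(traj$coords[, , f] %*% t(R), 2, tr, "+")
  st2 <- traj_stats(moved)
  expect_equal(st2$rmsd$per_residue$mean_rmsd_A,
               st1$rmsd$per_residue$mean_rmsd_A, tolerance = 1e-6)
  expect_equal(st2$rmsf$rmsf_A, st1$rmsf$rmsf_A, tolerance = 1e-6)
  expect_equal(st2$buckle$series, st1$buckle$series, tolerance = 1e-6)
})

test_that("RMSF of iid Gaussian jitter approaches sigma*sqrt(3)", {
  gq <- build_ideal_gq(c9_22mer())
  sigma <- 0.4
  traj <- gen_gq_trajectory(gq, sigma, sigma, n_frames = 500, seed = 21)
  rmsf <- per_residue_rmsf(traj)
  expect_equal(mean(rmsf$rmsf_A), sigma * sqrt(3), tolerance = 0.05 * sigma * sqrt(3))
})

test_that("loop/tetrad RMSF ratio recovers the generator sigma ratio", {
  gq <- build_ideal_gq(c9_22mer())
  traj <- gen_gq_trajectory(gq, sigma_tetrad = 0.2, sigma_loop = 1.0,
                            n_frames = 500, seed = 31)
  rmsf <- per_residue_rmsf(traj)
  is_g <- rmsf$resid == "DG"
  ratio <- mean(rmsf$rmsf_A[!is_g]) / mean(rmsf$rmsf_A[is_g])
  expect_lt(abs(ratio - 5) / 5, 0.15)
})

test_that("mobile loops dominate both RMSD and RMSF on synthetic output", {
  gq <- build_ideal_gq(c9_22mer())
  traj <- gen_gq_trajectory(gq, 0.2, 1.0, n_frames = 100, seed = 4)
  st <- traj_stats(traj)
  is_g <- st$rmsf$resid == "DG"
  expect_gt(mean(st$rmsf$rmsf_A[!is_g]), mean(st$rmsf$rmsf_A[is_g]))
  pr <- st$rmsd$per_residue
  expect_gt(mean(pr$mean_rmsd_A[!is_g]), mean(pr$mean_rmsd_A[is_g]))
})

test_that("buckle of a coplanar ideal model is zero and bounded in [0,90]", {
  gq <- build_ideal_gq(c9_22mer())
  buck <- tetrad_buckle_series(static_trajectory(gq, 3))
  expect_true(all(abs(buck$series) < 0.5))
  noisy <- gen_gq_trajectory(gq, 0.3, 0.8, n_frames = 50, seed = 2)
  bs <- tetrad_buckle_series(noisy)
  expect_true(all(bs$series >= 0 & bs$series <= 90))
  expect_identical(dim(bs$series), c(50L, 4L))
  expect_true(all(bs$summary$q1 <= bs$summary$median + 1e-12))
  expect_true(all(bs$summary$median <= bs$summary$q3 + 1e-12))
})

test_that("rotating one base reproduces an independent plane-angle computation", {
  gq <- build_ideal_gq(c9_22mer())
  tets <- detect_tetrads(gq)
  at <- gq$atom
  ring_names <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  # rotate base 1 of tetrad 1 by 12 degrees about an in-plane axis through
  # its ring centroid
  r1 <- tets[[1]]$residues[1, ]
  sel <- which(at$chain == r1$chain & at$resno == r1$resno &
                 at$elety %in% ring_names)
  X <- as.matrix(at[sel, c("x", "y", "z")])
  ctr <- colMeans(X)
  axis_in_plane <- svd(sweep(X, 2, ctr))$v[, 1]
  rot_about <- function(X, axis, theta, origin) {
    a <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
    sweep(sweep(X, 2, origin) %*% t(R), 2, origin, "+")
  }
  at[sel, c("x", "y", "z")] <- rot_about(X, axis_in_plane, 12 * pi / 180, ctr)
  bent <- gq_structure(at)
  buck <- tetrad_buckle_series(static_trajectory(bent, 2), tetrads = tets)

  # independent recomputation of the definition: mean over the 4 bases of
  # the angle between base-ring normal and tetrad mean-plane normal
  frame1 <- as.matrix(bent$atom[, c("x", "y", "z")])
  expected <- vapply(seq_len(4), function(t_idx) {
    rows <- lapply(seq_len(4), function(k)
      which(bent$atom$chain == tets[[t_idx]]$residues$chain[k] &
              bent$atom$resno == tets[[t_idx]]$residues$resno[k] &
              bent$atom$elety %in% ring_names))
    plane_normal <- function(Y) svd(sweep(Y, 2, colMeans(Y)))$v[, 3]
    tet_n <- plane_normal(frame1[unlist(rows), ])
    angs <- vapply(rows, function(r) {
      bn <- plane_normal(frame1[r, ])
      acos(min(1, abs(sum(bn * tet_n)))) * 180 / pi
    }, numeric(1))
    mean(angs)
  }, numeric(1))
  expect_equal(unname(buck$series[1, ]), expected, tolerance = 1e-9)
  # the perturbed tetrad moved away from planarity; the others did not
  expect_gt(buck$series[1, 1], 2)
  expect_true(all(buck$series[1, 2:4] < 0.5))
})

test_that("four symmetrically tilted bases give buckle equal to the tilt", {
  gq <- build_ideal_gq(c9_22mer())
  tets <- detect_tetrads(gq)
  at <- gq$atom
  ring_names <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  tilt <- 10 * pi / 180
  tt <- tets[[2]]
  for (k in seq_len(4)) {
    rk <- tt$residues[k, ]
    sel <- which(at$chain == rk$chain & at$resno == rk$resno &
                   at$elety %in% c(ring_names, "O6", "N2", "C1'"))
    X <- as.matrix(at[sel, c("x", "y", "z")])
    ctr <- colMeans(X[at$elety[sel] %in% ring_names, , drop = FALSE])
    # radial in-plane axis: from tetrad centroid through this base centroid
    axis <- ctr - tt$centroid
    axis <- axis - sum(axis * tt$normal) * tt$normal
    a <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    R <- diag(3) + sin(tilt) * K + (1 - cos(tilt)) * K %*% K
    at[sel, c("x", "y", "z")] <- sweep(sweep(X, 2, ctr) %*% t(R), 2, ctr, "+")
  }
  bent <- gq_structure(at)
  buck <- tetrad_buckle_series(static_trajectory(bent, 2), tetrads = tets)
  expect_equal(buck$series[1, 2], 10, tolerance = 0.5)
})

test_that("multi-model PDB round-trips a trajectory", {
  gq <- build_ideal_gq(c9_22mer())
  traj <- gen_gq_trajectory(gq, 0.1, 0.5, n_frames = 3, seed = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(traj, f)
  back <- read_multimodel_pdb(f)
  expect_identical(length(back), 3L)
  expect_equal(back$coords, round(traj$coords, 3), tolerance = 1e-9)
  expect_identical(back$topology$atom$elety, gq$atom$elety)

  single <- gq_trajectory(gq, traj$coords[, , 1, drop = FALSE])
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(single, f2)
  one <- read_multimodel_pdb(f2)
  expect_identical(length(one), 1L)
  expect_error(per_residue_rmsf(one), "single frame")
})

test_that("roster mismatch between models is a format error naming the model", {
  gq <- build_ideal_gq(c9_22mer())
  traj <- gen_gq_trajectory(gq, 0.1, 0.5, n_frames = 3, seed = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(traj, f)
  lines <- readLines(f)
  # drop one atom from the second model
  starts <- grep("^MODEL", lines)
  atom_in_2 <- which(seq_along(lines) > starts[2] & grepl("^ATOM", lines))[1]
  writeLines(lines[-atom_in_2], f)
  expect_error(read_multimodel_pdb(f), "model 2")
})
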