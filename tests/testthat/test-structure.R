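random_cloud <- function(n, spread = 10) {
  matrix(stats::rnorm(3 * n, sd = spread), n, 3)
}

apply_rigid <- function(xyz, rot, trans) {
  xyz %*% rot + matrix(trans, nrow(xyz), 3, byrow = TRUE)
}

test_that("superposing identical sets gives zero RMSD and the identity rotation", {
  set.seed(101)
  A <- random_cloud(25)
  fit <- kabsch_superpose(A, A)
  expect_equal(fit$global_rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  expect_equal(fit$tm_score, 1, tolerance = 1e-10)
})

test_that("a rigid motion is fully recovered (isometry invariance)", {
  set.seed(102)
  A <- random_cloud(40)
  rot90z <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  B <- apply_rigid(A, rot90z, c(5, -3, 12))
  fit <- kabsch_superpose(A, B)
  expect_equal(fit$global_rmsd, 0, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(fit$b_transformed, A, tolerance = 1e-8)
})

test_that("the fitted RMSD is optimal against random rigid motions", {
  set.seed(103)
  for (trial in 1:10) {
    A <- random_cloud(10)
    B <- A + matrix(stats::rnorm(30, sd = 1), 10, 3)
    fit <- kabsch_superpose(A, B)
    rand_rmsd <- vapply(1:200, function(i) {
      R <- geoadapt:::random_rotation()
      Bp <- apply_rigid(B, R, stats::runif(3, -5, 5))
      # optimal translation for a fixed rotation is centroid matching
      Bp <- sweep(Bp, 2, colMeans(Bp) - colMeans(A))
      sqrt(mean(rowSums((A - Bp)^2)))
    }, numeric(1))
    expect_true(all(fit$global_rmsd <= rand_rmsd + 1e-9))
  }
})

test_that("reflections are excluded and degenerate inputs are rejected", {
  set.seed(104)
  A <- random_cloud(12)
  B <- A %*% diag(c(-1, 1, 1))  # mirror image
  fit <- kabsch_superpose(A, B)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_gt(fit$global_rmsd, 0)
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "3 matched points")
  line <- cbind(1:10, 2 * (1:10), -(1:10))
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(A, A[1:10, ]), "matched")
})

test_that("RMSD and TM-score are invariant under rigid motions and symmetric in order", {
  set.seed(105)
  A <- random_cloud(30)
  B <- A + matrix(stats::rnorm(90, sd = 0.5), 30, 3)
  base <- kabsch_superpose(A, B)
  R <- geoadapt:::random_rotation()
  moved <- kabsch_superpose(apply_rigid(A, R, c(1, 2, 3)), B)
  expect_equal(moved$global_rmsd, base$global_rmsd, tolerance = 1e-8)
  expect_equal(moved$tm_score, base$tm_score, tolerance = 1e-8)
  swapped <- kabsch_superpose(B, A)
  expect_equal(swapped$global_rmsd, base$global_rmsd, tolerance = 1e-8)
})

test_that("kabsch agrees with the bio3d reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(106)
  A <- random_cloud(50)
  B <- apply_rigid(A, geoadapt:::random_rotation(), c(4, 4, 4)) +
    matrix(stats::rnorm(150, sd = 0.8), 50, 3)
  ours <- kabsch_superpose(A, B)$global_rmsd
  xyz_a <- as.vector(t(A)); xyz_b <- as.vector(t(B))
  fitted <- bio3d::fit.xyz(fixed = xyz_a, mobile = xyz_b,
                           fixed.inds = 1:150, mobile.inds = 1:150)
  ref <- bio3d::rmsd(xyz_a, fitted)
  expect_equal(ours, ref, tolerance = 1e-4)
})

test_that("TM-score follows the Zhang-Skolnick formula", {
  expect_equal(tm_score(rep(0, 407), 407), 1)
  expect_lt(tm_score(rep(1e6, 407), 407), 1e-6)
  d0 <- 1.24 * (407 - 15)^(1 / 3) - 1.8
  expect_equal(tm_score(rep(d0, 407), 407), 0.5)
  # small-length flooring keeps d0 at 0.5 A
  expect_equal(tm_score(rep(0.5, 10), 10), 0.5)
  expect_error(tm_score(numeric(0), 100), "Empty")
  expect_error(tm_score(c(-1, 1), 100), "non-negative")
})

test_that("deviation bins reproduce the blue/white/red colouring", {
  expect_identical(deviation_bins(c(0.1, 1, 3)), c("blue", "white", "red"))
  expect_identical(deviation_bins(rep(0, 5)), rep("blue", 5))
  set.seed(107)
  d <- abs(stats::rnorm(100, 1, 1))
  bins <- deviation_bins(d)
  expect_equal(sum(table(bins)), 100)         # partition
  expect_error(deviation_bins(c(-0.1, 1)), "non-negative")
  expect_error(deviation_bins(1, thresholds = c(2, 1)), "increasing")
})

test_that("generated structure pairs carry the planted perturbations", {
  # pure rigid pair
  p0 <- generate_structure_pair(60, seed = 5)
  expect_equal(kabsch_superpose(p0$a, p0$b)$global_rmsd, 0, tolerance = 1e-8)
  # planted displacements dominate the per-residue deviations
  p <- generate_structure_pair(200, n_perturbed = 20, displacement = 3, seed = 6)
  fit <- kabsch_superpose(p$a, p$b)
  top20 <- order(fit$per_residue_dev, decreasing = TRUE)[1:20]
  expect_gte(length(intersect(top20, p$perturbed_idx)), 16)  # >= 80% overlap
  # planted secondary-structure changes
  p2 <- generate_structure_pair(407, n_ss_changes = 11, seed = 7)
  expect_equal(ss_diff(p2$a, p2$b)$n_diff, 11L)
  # heme shift magnitude
  p3 <- generate_structure_pair(100, n_hemes = 6, heme_shift = 0.5, seed = 8)
  fit3 <- kabsch_superpose(p3$a, p3$b)
  hb <- p3$b$hemes %*% t(fit3$rotation) +
    matrix(fit3$translation, 6, 3, byrow = TRUE)
  shifts <- sqrt(rowSums((hb - p3$a$hemes)^2))
  expect_equal(mean(shifts), 0.5, tolerance = 0.05)
  expect_error(generate_structure_pair(2), "at least 3")
})

test_that("PDB + SS writer/reader round-trips a model", {
  skip_if_not_installed("bio3d")
  p <- generate_structure_pair(40, n_hemes = 4, seed = 9)
  d <- withr::local_tempdir()
  pdb <- file.path(d, "m.pdb"); ssf <- file.path(d, "m.ss")
  write_structure_pdb(p$a, pdb, ssf)
  back <- read_structure_pdb(pdb, ssf, id = "model_a")
  expect_equal(back$xyz, p$a$xyz, tolerance = 1e-3)
  expect_identical(back$ss, p$a$ss)
  expect_equal(back$hemes, p$a$hemes, tolerance = 1e-3)
})

test_that("structure model validation catches malformed input", {
  expect_error(structure_model("x", matrix(1, 2, 2), "HH"), "n x 3")
  expect_error(structure_model("x", matrix(1, 3, 3), "HH"), "one letter per residue")
  expect_error(structure_model("x", matrix(1, 3, 3), "HXZ"), "only H, E, C")
  expect_error(structure_model("x", matrix(c(1, Inf, rep(1, 7)), 3, 3), "HEC"),
               "finite")
})
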