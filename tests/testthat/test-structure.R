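# Coordinate model: chain building, superposition, ensembles.

test_that("ideal helix geometry: rise, CA-CA distance, H-bond pattern", {
  h <- ideal_helix(21)
  ca <- h$xyz[h$atom == "CA", ]
  dca <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(dca - 3.80) < 0.1))
  # least-squares axis through the CA atoms: axial extent / 20 residues
  ax <- prcomp(ca)$rotation[, 1]
  proj <- ca %*% ax
  expect_equal((max(proj) - min(proj)) / 20, 1.5, tolerance = 0.1 / 1.5)
  # i -> i+4 O...N hydrogen-bond geometry
  O <- h$xyz[h$atom == "O", ]
  N <- h$xyz[h$atom == "N", ]
  on <- sqrt(rowSums((O[1:17, ] - N[5:21, ])^2))
  expect_true(all(on > 2.8 & on < 3.2))
})

test_that("CA-CA spacing is fixed by trans-peptide geometry for any torsions", {
  set.seed(4)
  for (rep in 1:5) {
    s <- build_backbone(10, cbind(runif(10, -179, 180), runif(10, -179, 180)))
    ca <- s$xyz[s$atom == "CA", ]
    expect_true(all(abs(sqrt(rowSums(diff(ca)^2)) - 3.80) < 0.1))
  }
})

test_that("single-residue chain has ideal bond lengths", {
  s <- build_backbone(1, cbind(-57, -47))
  xyz <- s$xyz
  expect_equal(sqrt(sum((xyz[1, ] - xyz[2, ])^2)), 1.458, tolerance = 1e-6)
  expect_equal(sqrt(sum((xyz[2, ] - xyz[3, ])^2)), 1.525, tolerance = 1e-6)
})

test_that("build_backbone validates its inputs", {
  expect_error(build_backbone(5, cbind(rep(0, 4), rep(0, 4))), "length")
  expect_error(build_backbone(2, cbind(c(0, 200), c(0, 0))), "-180")
})

test_that("torsions are recovered exactly from built coordinates", {
  set.seed(9)
  di <- cbind(runif(8, -179, 180), runif(8, -179, 180))
  s <- build_backbone(8, di)
  tors <- backbone_dihedrals(s)
  expect_equal(tors[-1, "phi"], di[-1, 1], tolerance = 1e-8)
  expect_equal(tors[, "psi"], di[, 2], tolerance = 1e-8)
})

test_that("superpose recovers rigid motions and is symmetric", {
  s <- random_structure(10, seed = 2)
  expect_equal(superpose(s, s)$rmsd, 0, tolerance = 1e-9)
  R <- emnmr:::rot_about(c(1, 2, 0.5), 63)
  m <- s
  m$xyz <- t(R %*% t(s$xyz)) + matrix(c(4, -7, 2), nrow(s$xyz), 3, byrow = TRUE)
  expect_lt(superpose(m, s)$rmsd, 1e-6)
  n <- random_structure(10, seed = 5)
  expect_equal(superpose(m, n)$rmsd, superpose(n, m)$rmsd, tolerance = 1e-6)
})

test_that("superpose matches a grid+polish oracle on toy point sets", {
  set.seed(11)
  A <- matrix(rnorm(12, sd = 3), 4, 3)
  B <- matrix(rnorm(12, sd = 3), 4, 3)
  got <- superpose(A, B)$rmsd
  # oracle: coarse search over rotations, then numeric polish
  rmsd_of <- function(ang) {
    R <- emnmr:::rot_about(c(1, 0, 0), ang[1]) %*%
         emnmr:::rot_about(c(0, 1, 0), ang[2]) %*%
         emnmr:::rot_about(c(0, 0, 1), ang[3])
    Ar <- t(R %*% t(sweep(A, 2, colMeans(A))))
    Br <- sweep(B, 2, colMeans(B))
    sqrt(mean(rowSums((Ar - Br)^2)))
  }
  grid <- as.matrix(expand.grid(seq(0, 330, 30), seq(0, 330, 30), seq(0, 330, 30)))
  vals <- apply(grid, 1, rmsd_of)
  start <- grid[which.min(vals), ]
  pol <- optim(start, rmsd_of, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  expect_equal(got, pol$value, tolerance = 1e-4)
})

test_that("superpose agrees with the bio3d reference implementation", {
  s <- random_structure(15, seed = 3)
  m <- random_structure(15, seed = 8)
  got <- superpose(m, s, "CA")$rmsd
  sel <- which(s$atom == "CA")
  fx <- bio3d::fit.xyz(fixed = as.numeric(t(s$xyz[sel, ])),
                       mobile = as.numeric(t(m$xyz[sel, ])))
  ref <- bio3d::rmsd(as.numeric(t(s$xyz[sel, ])), fx)
  # bio3d rounds its RMSD to 3 decimals
  expect_equal(got, ref, tolerance = 1e-3)
})

test_that("superpose rejects degenerate selections", {
  A <- matrix(rnorm(6), 2, 3)
  expect_error(superpose(A, A), "at least 3")
})

test_that("bundle RMSD: rigid motions removed, permutation invariant, oracle", {
  s <- random_structure(10, seed = 6)
  e <- em_ensemble(list(s, s), c(0, 0))
  expect_equal(bundle_rmsd(e), 0, tolerance = 1e-9)
  m <- s
  R <- emnmr:::rot_about(c(0, 1, 1), 117)
  m$xyz <- t(R %*% t(s$xyz)) + matrix(c(1, 2, 3), nrow(s$xyz), 3, byrow = TRUE)
  expect_lt(bundle_rmsd(em_ensemble(list(s, m))), 1e-6)
  # one displaced atom: compare with the mean-structure definition directly
  d <- s
  d$xyz[5, ] <- d$xyz[5, ] + c(2, 0, 0)
  e2 <- em_ensemble(list(s, d))
  got <- bundle_rmsd(e2, selection = c("N", "CA", "C", "O"))
  sel <- which(s$atom %in% c("N", "CA", "C", "O"))
  # oracle: explicit iteration of (superpose to mean, recompute mean)
  mats <- list(s$xyz[sel, ], d$xyz[sel, ])
  mean_xyz <- Reduce(`+`, mats) / 2
  for (i in 1:100) {
    mats <- lapply(mats, function(m2) emnmr:::kabsch(m2, mean_xyz)$fitted)
    mean_xyz <- Reduce(`+`, mats) / 2
  }
  ref <- mean(sapply(mats, function(m2) sqrt(mean(rowSums((m2 - mean_xyz)^2)))))
  expect_equal(got, ref, tolerance = 1e-6)
  # permutation invariance
  s2 <- random_structure(10, seed = 20)
  s3 <- random_structure(10, seed = 21)
  e3 <- em_ensemble(list(s, s2, s3))
  e4 <- em_ensemble(list(s3, s, s2))
  # the mean-structure iteration stops at a 1e-4 A mean shift, so
  # permutation invariance holds to that scale
  expect_equal(bundle_rmsd(e3), bundle_rmsd(e4), tolerance = 1e-4)
})

test_that("single-conformer bundle RMSD is zero with a warning", {
  s <- random_structure(5)
  expect_warning(v <- bundle_rmsd(em_ensemble(list(s))), "single")
  expect_equal(v, 0)
})

test_that("ensemble construction validates topology and energies", {
  a <- random_structure(5); b <- random_structure(6)
  expect_error(em_ensemble(list(a, b)), "atom count")
  expect_error(em_ensemble(list(a, a), energies = 1), "length")
})

test_that("PDB round-trip preserves coordinates, ensembles use MODEL records", {
  s <- random_structure(7, seed = 13)
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(s, f)
  r <- read_structure_pdb(f)
  expect_equal(r$xyz, s$xyz, tolerance = 1e-3)  # PDB has 3 decimals
  e <- em_ensemble(list(s, random_structure(7, seed = 14)))
  f2 <- tempfile(fileext = ".pdb")
  write_structure_pdb(e, f2)
  expect_true(any(grepl("^MODEL", readLines(f2))))
  r2 <- read_structure_pdb(f2)
  expect_s3_class(r2, "em_ensemble")
  expect_length(r2$conformers, 2)
})
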