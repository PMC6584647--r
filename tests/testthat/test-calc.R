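# Target function, annealing engine, ranking, flexible fitting, convergence
# and disambiguation rule arithmetic.

test_that("target function: zero iff satisfied, worked violation, formula", {
  b <- mono3_bench()
  expect_equal(target_function(b$truth, b$restraints), 0)
  # one upper bound violated by exactly 1 A at unit weight
  s <- build_backbone(10, cbind(rep(-120, 10), rep(130, 10)))
  ca <- s$xyz[s$atom == "CA", ]
  d12 <- sqrt(sum((ca[1, ] - ca[5, ])^2))
  rs <- restraint_set(data.frame(id = 1, res_i = 1, atom_i = "CA",
                                 res_j = 5, atom_j = "CA",
                                 lower = 0, upper = d12 - 1,
                                 origin = "NOE", scope = "intra"))
  expect_equal(target_function(s, rs, tf_spec(w_steric = 0)), 1, tolerance = 1e-9)
})

test_that("target function matches an independent brute-force oracle", {
  for (seed in 1:20) {
    s <- random_structure(n = 12, seed = seed)
    rs <- random_restraints(n = 12, seed = seed + 100)
    expect_equal(target_function(s, rs), tf_oracle(s, rs), tolerance = 1e-9)
  }
})

test_that("analytic torsion gradients match finite differences", {
  set.seed(2)
  n <- 8
  phi <- runif(n, -170, 170); psi <- runif(n, -170, 170)
  rs <- random_restraints(n = 8, n_dist = 8, n_amb = 3, n_dih = 4, seed = 3)
  rc <- emnmr:::restraints_to_cpp(rs, n)
  w <- tf_spec()$weights
  gr <- emnmr:::tf_grad_cpp(phi, psi, n, rc$grp, rc$ai, rc$aj, rc$lower,
                            rc$upper, rc$dres, rc$dtyp, rc$dtarget, rc$dtol,
                            w, 2.5)
  f <- function(p, s) emnmr:::target_function_cpp(
    emnmr:::build_chain_cpp(p, s), n, rc$grp, rc$ai, rc$aj, rc$lower,
    rc$upper, rc$dres, rc$dtyp, rc$dtarget, rc$dtol, w, 2.5)
  h <- 1e-5
  for (i in seq_len(n)) {
    p1 <- phi; p1[i] <- p1[i] + h
    expect_equal(gr$gphi[i], (f(p1, psi) - f(phi, psi)) / h, tolerance = 1e-3)
    s1 <- psi; s1[i] <- s1[i] + h
    expect_equal(gr$gpsi[i], (f(phi, s1) - f(phi, psi)) / h, tolerance = 1e-3)
  }
})

test_that("annealing basics: no restraints, contradictions, reproducibility", {
  cfg <- protocol_config(n_conformers = 4, anneal_steps = 300, n_keep = 4, seed = 2)
  e0 <- anneal(8, restraint_set(), cfg)
  expect_true(all(e0$energies == 0))
  # contradictory bounds on one pair: TF bounded below by the analytic minimum
  d <- rbind(
    data.frame(id = 1, res_i = 2, atom_i = "CA", res_j = 7, atom_j = "CA",
               lower = 0, upper = 4, origin = "NOE", scope = "intra"),
    data.frame(id = 2, res_i = 2, atom_i = "CA", res_j = 7, atom_j = "CA",
               lower = 10, upper = 100, origin = "NOE", scope = "intra"))
  ec <- anneal(8, restraint_set(d), cfg)
  expect_true(all(ec$energies >= 9))
  # bitwise reproducibility given the seed
  e1 <- anneal(8, restraint_set(d), cfg, seed = 77)
  e2 <- anneal(8, restraint_set(d), cfg, seed = 77)
  expect_identical(e1$conformers[[1]]$xyz, e2$conformers[[1]]$xyz)
  expect_identical(e1$energies, e2$energies)
  e3 <- anneal(8, restraint_set(d), cfg, seed = 78)
  expect_false(identical(e1$conformers[[1]]$xyz, e3$conformers[[1]]$xyz))
  # restraints to absent residues are input errors
  bad <- data.frame(id = 1, res_i = 1, atom_i = "CA", res_j = 50, atom_j = "CA",
                    lower = 0, upper = 5, origin = "NOE", scope = "intra")
  expect_error(anneal(8, restraint_set(bad), cfg), "absent")
})

test_that("dihedral-restrained annealing reaches the target basin", {
  dih <- data.frame(resno = rep(2:12, each = 2), angle = rep(c("phi", "psi"), 11),
                    target = rep(c(-57, -47), 11), tolerance = 20)
  cfg <- protocol_config(n_conformers = 5, anneal_steps = 500, n_keep = 3, seed = 7)
  e <- anneal(12, restraint_set(dihedral = dih), cfg)
  expect_true(all(e$energies < 1e-6))
})

test_that("structure recovery from a complete short-distance restraint set", {
  f <- make_toy_fold(3, c(14, 12, 10), 5, seed = 2)
  s <- f$structure
  ca <- s$xyz[s$atom == "CA", ]
  D <- as.matrix(dist(ca))
  pr <- which(upper.tri(D) & D < 12 & abs(row(D) - col(D)) >= 2, arr.ind = TRUE)
  dd <- data.frame(id = seq_len(nrow(pr)), res_i = pr[, 1], atom_i = "CA",
                   res_j = pr[, 2], atom_j = "CA",
                   lower = pmax(0, D[pr] - 0.5), upper = D[pr] + 0.5,
                   origin = "NOE", scope = "intra")
  # distance-only folding cannot fix chirality, so recovery needs enough
  # conformers for several to land in the correct-handed basin
  cfg <- protocol_config(n_conformers = 100, anneal_steps = 4000, n_keep = 5, seed = 3)
  e <- anneal(s$n_res, restraint_set(dd), cfg)
  expect_lt(superpose(e$conformers[[1]], s, "CA")$rmsd, 2.0)
})

test_that("removing a restraint never increases any conformer's target function", {
  rs <- random_restraints(n = 10, n_dist = 12, n_amb = 3, n_dih = 5, seed = 9)
  cfg <- protocol_config(n_conformers = 3, anneal_steps = 300, n_keep = 3, seed = 4)
  ens <- anneal(10, rs, cfg)
  for (drop_id in c(1, 5, 9)) {
    d2 <- rs$distance[rs$distance$id != drop_id, , drop = FALSE]
    rs2 <- restraint_set(emnmr:::renumber_ids(d2), rs$dihedral)
    for (k in seq_along(ens$conformers)) {
      expect_lte(target_function(ens$conformers[[k]], rs2),
                 target_function(ens$conformers[[k]], rs) + 1e-12)
    }
  }
})

test_that("Pareto ranking prefers dominating hypotheses and drops diverged runs", {
  sc <- data.frame(id = 1:4,
                   tf = c(10, 10, 5, 1e9),
                   overlap_fraction = c(0.9, 0.4, 0.2, 0.1),
                   diverged = c(FALSE, FALSE, FALSE, TRUE))
  ranked <- emnmr:::rank_scorecards(sc)
  # identical TF: higher overlap ranks above
  r1 <- ranked$rank[ranked$id == 1]
  r2 <- ranked$rank[ranked$id == 2]
  expect_lt(r1, r2)
  # the diverged hypothesis is reported but unranked
  expect_true(is.na(ranked$rank[ranked$id == 4]))
  expect_equal(sum(!is.na(ranked$rank)), 3)
  # a hypothesis dominating on both axes ranks first
  sc2 <- data.frame(id = 1:3, tf = c(2, 5, 9),
                    overlap_fraction = c(0.95, 0.5, 0.4),
                    diverged = FALSE)
  expect_equal(emnmr:::rank_scorecards(sc2)$id[1], 1)
})

test_that("flexible fitting: stationary at the optimum, inert on flat maps,
           geometry preserved", {
  f <- make_toy_fold(3, c(12, 10, 9), 4, seed = 3)
  s <- f$structure
  map <- simulate_map(s, 8, voxel = 2)
  fit <- flexible_fit(s, map)
  expect_lt(coord_rmsd(fit, s, "CA"), 0.3)
  cors <- attr(fit, "correlation")
  expect_gte(cors["end"], cors["start"] - 1e-9)
  # constant map: zero gradient, structure unchanged (up to regularization)
  flat <- density_map(array(1, dim(map$grid)), map$voxel, map$origin, 8)
  fit2 <- flexible_fit(s, flat)
  expect_lt(coord_rmsd(fit2, s, "CA"), 0.1)
  # bond lengths within 2% of ideal after fitting a shifted start
  sh <- s
  sh$xyz <- sweep(s$xyz, 2, -c(2, 1, 0))
  fit3 <- flexible_fit(sh, map)
  nca <- sqrt(rowSums((fit3$xyz[fit3$atom == "N", ] -
                       fit3$xyz[fit3$atom == "CA", ])^2))
  expect_true(all(abs(nca - 1.458) / 1.458 < 0.02))
  expect_error(flexible_fit(sh, density_map(array(1, c(8, 8, 8)), 1,
                                            origin = c(500, 0, 0))), "outside")
})

test_that("flexible fitting recovers a small rigid displacement", {
  f <- make_toy_fold(3, c(12, 10, 9), 4, seed = 3)
  s <- f$structure
  map <- simulate_map(s, 8, voxel = 2)
  sh <- s
  sh$xyz <- sweep(s$xyz, 2, -c(3, 0, 0) / sqrt(1))
  cur <- sh
  for (i in 1:6) cur <- flexible_fit(cur, map)
  expect_lt(coord_rmsd(cur, s, "CA"), 1.0)
})

test_that("the 10%/3-cycle convergence rule: worked cases and exhaustive brute force", {
  expect_equal(converged_after(c(1.00, 0.95, 0.90, 0.88)), 4L)
  expect_true(is.na(converged_after(c(8, 4, 2, 1, 0.5, 0.25))))
  # exhaustive: all series of length <= 6 over a change grid, vs direct rule
  oracle <- function(x, tol = 0.1, need = 3) {
    run <- 0
    for (k in 2:length(x)) {
      run <- if (abs(x[k] - x[k - 1]) / x[k - 1] < tol) run + 1 else 0
      if (run >= need) return(k)
    }
    NA_integer_
  }
  ratios <- c(0.5, 0.92, 0.95, 1.05)
  for (len in 4:6) {
    grid <- expand.grid(rep(list(ratios), len - 1))
    for (r in seq_len(nrow(grid))) {
      x <- cumprod(c(2, as.numeric(grid[r, ])))
      expect_identical(converged_after(x), oracle(x))
    }
  }
})

test_that("the <8 A disambiguation rule: exhaustive candidate configurations", {
  s <- build_backbone(30, cbind(rep(-120, 30), rep(130, 30)))
  ens <- em_ensemble(list(s, s, s), 1:3)
  ca <- s$xyz[s$atom == "CA", ]
  dist_to <- function(j) sqrt(sum((ca[1, ] - ca[j, ])^2))
  # partner residues give a ladder of distances; enumerate all subsets sized 2..4
  partners <- c(2, 3, 4, 8, 15, 25)
  for (size in 2:4) {
    combos <- combn(partners, size)
    for (cc in seq_len(ncol(combos))) {
      js <- combos[, cc]
      d <- do.call(rbind, lapply(js, function(j)
        data.frame(id = 1, res_i = 1, atom_i = "CA", res_j = j, atom_j = "CA",
                   lower = 0, upper = 30, origin = "NOE", scope = "intra")))
      out <- disambiguate(restraint_set(d), ens, cutoff = 8)
      n_short <- sum(sapply(js, dist_to) < 8)
      if (n_short == 1) {
        expect_equal(out$n_resolved, 1)
        expect_equal(out$resolved$distance$res_j,
                     js[which(sapply(js, dist_to) < 8)])
      } else {
        expect_equal(out$n_resolved, 0)
      }
    }
  }
})
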