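# Restraint model, combinatorial assignment, disambiguation, bookkeeping,
# file dialects.

test_that("assignment counts follow the injective-placement formula", {
  # 8 sequence helices into 7 densities with 2-fold orientation each
  expect_equal(count_assignments(8, 7, oriented = TRUE), 5160960)
  expect_equal(count_assignments(2, 2), 2)
  expect_error(count_assignments(3, 4), "more densities")
  # closed form vs brute-force enumeration on random small instances
  set.seed(5)
  for (rep in 1:10) {
    ns <- sample(2:5, 1)
    nd <- sample(seq_len(ns), 1)
    expect_equal(count_assignments(ns, nd),
                 length(enumerate_oracle(ns, nd)))
  }
})

mk_seq_helices <- function(lengths_A) {
  n <- length(lengths_A)
  data.frame(start = seq_len(n) * 20, end = seq_len(n) * 20 + 5,
             central_residue = seq_len(n) * 20 + 2,
             length_res = round(lengths_A / 1.5), length_A = lengths_A)
}

mk_densities <- function(lengths, centers = NULL) {
  n <- length(lengths)
  if (is.null(centers)) centers <- matrix(seq_len(n) * 25, n, 3)
  data.frame(cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
             ax = 1, ay = 0, az = 0, length = lengths, score = 0.8)
}

test_that("enumeration is exhaustive, ordered and correctly pruned", {
  sh <- mk_seq_helices(c(30, 15, 15))
  dd <- mk_densities(c(31, 14))
  hyps <- enumerate_assignments(sh, dd, length_tol_A = 3, prune = TRUE)
  # the 30 A helix must take the 31 A density: 2 hypotheses remain of 6
  expect_length(hyps, 2)
  expect_true(all(vapply(hyps, function(h) h$mapping[1] == 1, logical(1))))
  # unpruned center-only 2x2
  hyps2 <- enumerate_assignments(mk_seq_helices(c(20, 20)), mk_densities(c(20, 20)),
                                 prune = FALSE)
  expect_length(hyps2, 2)
  # oriented mode multiplies by 2 per density
  hyps3 <- enumerate_assignments(mk_seq_helices(c(20, 20)), mk_densities(c(20, 20)),
                                 mode = "oriented", prune = FALSE)
  expect_length(hyps3, 8)
  expect_error(enumerate_assignments(mk_seq_helices(20), mk_densities(c(20, 20))),
               "more densities")
})

test_that("pruning is sound: every surviving mapping satisfies the tolerance,
           and none that satisfies it is lost", {
  set.seed(7)
  for (rep in 1:8) {
    ns <- sample(3:5, 1)
    nd <- sample(2:min(ns, 4), 1)
    sh <- mk_seq_helices(runif(ns, 10, 35))
    dd <- mk_densities(runif(nd, 10, 35))
    tol <- runif(1, 2, 8)
    hyps <- enumerate_assignments(sh, dd, length_tol_A = tol, prune = TRUE)
    ok <- outer(seq_len(nd), seq_len(ns), function(d, s)
      abs(sh$length_A[s] - dd$length[d]) <= tol)
    ref <- enumerate_oracle(ns, nd, ok)
    got <- lapply(hyps, `[[`, "mapping")
    expect_equal(length(got), length(ref))
    expect_true(all(mapply(identical, lapply(got, as.integer),
                           lapply(ref, as.integer))))
  }
})

test_that("helix-center pinning emits pairwise restraints bracketing the truth", {
  sh <- mk_seq_helices(rep(20, 5))
  set.seed(3)
  cen <- matrix(rnorm(15, sd = 15), 5, 3)
  dd <- mk_densities(rep(20, 5), centers = cen)
  hyp <- list(mapping = 1:5)
  rs <- hypothesis_to_restraints(hyp, dd, sh, tol = 0.5)
  expect_equal(n_distance_restraints(rs), choose(5, 2))
  expect_true(all(rs$distance$origin == "HELIX_CENTER"))
  # bounds bracket the center distances
  k <- 0
  for (a in 1:4) for (b in (a + 1):5) {
    k <- k + 1
    d <- sqrt(sum((cen[a, ] - cen[b, ])^2))
    expect_lte(rs$distance$lower[k], d)
    expect_gte(rs$distance$upper[k], d)
  }
  # two-density worked case
  dd2 <- mk_densities(c(20, 20), centers = matrix(c(0, 20, 0, 0, 0, 0), 2, 3))
  rs2 <- hypothesis_to_restraints(list(mapping = c(1, 2)), dd2,
                                  mk_seq_helices(c(20, 20)), tol = 0.5)
  expect_equal(rs2$distance$lower, 19.5)
  expect_equal(rs2$distance$upper, 20.5)
  # a single pinned helix yields nothing
  expect_equal(n_distance_restraints(
    hypothesis_to_restraints(list(mapping = 1), dd, sh)), 0)
})

test_that("fix_positions pins flagged residues with capped pair graphs", {
  s <- ideal_helix(12)
  rs <- fix_positions(s, c(3, 7), tol = 0.5, seed = 1)
  d <- rs$distance
  expect_true(all(d$origin == "EM_FIX"))
  expect_true(all(d$atom_i %in% c("N", "CA", "C")))
  # bounds are current distance +/- tol
  for (k in seq_len(nrow(d))) {
    ii <- emnmr:::atom_index0(d$res_i[k], d$atom_i[k]) + 1
    jj <- emnmr:::atom_index0(d$res_j[k], d$atom_j[k]) + 1
    dist <- sqrt(sum((s$xyz[ii, ] - s$xyz[jj, ])^2))
    expect_equal(d$upper[k], dist + 0.5, tolerance = 1e-9)
  }
  expect_equal(n_distance_restraints(fix_positions(s, integer(0))), 0)
  expect_error(fix_positions(s, 99), "not in structure")
  # capping: many flagged residues stay near-linear in restraint count
  s2 <- ideal_helix(30)
  rs2 <- fix_positions(s2, 1:30, max_near = 8, max_rand = 4, seed = 2)
  expect_lt(n_distance_restraints(rs2), 90 * 12)
  expect_gt(n_distance_restraints(rs2), 90 * 4)
})

test_that("annealing under regenerated position pins restores the pinned geometry", {
  f <- make_toy_fold(3, c(12, 10, 9), 4, seed = 5)
  s <- f$structure
  flagged <- 1:s$n_res
  emf <- fix_positions(s, flagged, tol = 0.5, seed = 3)
  cfg <- protocol_config(n_conformers = 6, anneal_steps = 1200, n_keep = 2, seed = 9)
  # gentle thermal noise: pairwise pins are chirality-blind, so a hot anneal
  # may legally converge to the mirror image; the restoration property holds
  # within the correct-handed basin
  ens <- anneal(s$n_res, emf, cfg, init = s, init_noise = 3, therm_noise = 0.5)
  best <- ens$conformers[[1]]
  expect_lt(superpose(best, s, "CA")$rmsd, 2 * 0.5)
})

test_that("disambiguation keeps the unique short candidate and never drops data", {
  # toy ensemble: two identical extended chains
  s <- build_backbone(20, cbind(rep(-120, 20), rep(130, 20)))
  ens <- em_ensemble(list(s, s), c(1, 2))
  mk <- function(pairs) {
    do.call(rbind, lapply(seq_along(pairs), function(g)
      data.frame(id = 99, res_i = pairs[[g]][1], atom_i = "CA",
                 res_j = pairs[[g]][2], atom_j = "CA",
                 lower = 0, upper = 7, origin = "NOE", scope = "intra")))
  }
  # candidates ~ |i-j| * 3.5 A in an extended chain: (1,2) short, (1,20) long
  rs <- restraint_set(mk(list(c(1, 2), c(1, 20))))
  out <- disambiguate(rs, ens, cutoff = 8)
  expect_equal(out$n_resolved, 1)
  expect_equal(out$resolved$distance$res_j, 2)
  expect_equal(n_distance_restraints(out$still_ambiguous), 0)
  # both candidates short: stays ambiguous
  rs2 <- restraint_set(mk(list(c(1, 2), c(2, 3))))
  out2 <- disambiguate(rs2, ens, cutoff = 8)
  expect_equal(out2$n_resolved, 0)
  expect_equal(n_distance_restraints(out2$still_ambiguous), 1)
  # missing atom is an input error naming the restraint
  rs3 <- restraint_set(mk(list(c(1, 2), c(1, 25))))
  expect_error(disambiguate(rs3, ens), "99")
})

test_that("disambiguation against a near-truth ensemble recovers true pairs", {
  b <- mono3_bench()
  sim <- simulate_restraints(b$truth, b$ss,
                             list(coverage = 0.9, ambiguity_rate = 0.5,
                                  decoy_count = 2), seed = 4)
  d <- sim$restraints$distance
  amb_ids <- unique(d$id[ave(d$id, d$id, FUN = length) > 1])
  amb <- restraint_set(emnmr:::renumber_ids(d[d$id %in% amb_ids, , drop = FALSE]))
  # ensemble: truth plus small torsion-noise replicas (RMSD to truth < 3 A)
  tors <- backbone_dihedrals(b$truth)
  set.seed(8)
  confs <- lapply(1:4, function(i) {
    tt <- tors; tt[1, 1] <- 0
    tt <- tt + matrix(rnorm(length(tt), 0, 1.5), nrow(tt), 2)
    st <- build_backbone(nrow(tt), emnmr:::wrap180(tt))
    superpose(st, b$truth, "CA")$mobile_fitted
  })
  expect_true(all(vapply(confs, function(s) superpose(s, b$truth, "CA")$rmsd,
                         numeric(1)) < 3))
  out <- disambiguate(amb, em_ensemble(confs, seq_along(confs)), cutoff = 8)
  res <- out$resolved$distance
  expect_gt(out$n_resolved, 0)
  expect_gte(mean(res$is_true), 0.95)
})

test_that("inter-subunit filtering conserves counts", {
  # a 524-restraint set with 8 labelled inter-subunit contacts leaves 516
  n <- 524
  d <- data.frame(id = 1:n, res_i = rep(1:40, length.out = n), atom_i = "CA",
                  res_j = rep(5:44, length.out = n), atom_j = "CA",
                  lower = 0, upper = 8, origin = "NOE", scope = "intra")
  dih <- data.frame(resno = 1:10, angle = "psi", target = -47, tolerance = 20)
  rs <- restraint_set(d, dih)
  labels <- sample(n, 8)
  out <- filter_intersubunit(rs, labels)
  expect_equal(out$removed, 8)
  expect_equal(n_distance_restraints(out$set), 516)
  expect_equal(nrow(out$set$dihedral), 10)
  # removed + kept = input
  expect_equal(out$removed + n_distance_restraints(out$set), n)
  expect_equal(filter_intersubunit(rs, integer(0))$removed, 0)
  expect_error(filter_intersubunit(rs, 9999), "unknown")
  all_out <- filter_intersubunit(rs, 1:n)
  expect_equal(n_distance_restraints(all_out$set), 0)
  expect_equal(nrow(all_out$set$dihedral), 10)
})

test_that("range classification uses the short/long convention at |i-j| = 4", {
  d <- data.frame(id = 1:2, res_i = c(10, 10), atom_i = "CA",
                  res_j = c(12, 14), atom_j = "CA",
                  lower = 0, upper = 8, origin = "NOE", scope = "intra")
  cc <- classify_restraints(restraint_set(d))
  expect_equal(cc$short_range, 1)   # |i-j| = 2
  expect_equal(cc$long_range, 1)    # |i-j| = 4
  b <- mono3_bench()
  sim <- simulate_restraints(b$truth, b$ss, list(coverage = 0.7,
                                                 ambiguity_rate = 0.3), seed = 2)
  cc2 <- classify_restraints(sim$restraints)
  expect_equal(cc2$total, cc2$short_range + cc2$long_range)
  expect_equal(cc2$total, cc2$unambiguous + cc2$ambiguous)
  expect_equal(cc2$total, sim$truth_table$total)
})

test_that("metal-site restraints: one per residue-center pair with the given bounds", {
  rs <- site_restraints(c(68, 182, 213, 235, 323), 2, bounds = c(2.0, 2.6))
  expect_equal(n_distance_restraints(rs), 10)
  expect_true(all(rs$distance$lower == 2.0))
  expect_true(all(rs$distance$upper == 2.6))
  expect_true(all(rs$distance$origin == "SITE"))
  expect_true(all(rs$distance$atom_i == "SC"))
  expect_equal(n_distance_restraints(site_restraints(1:5, 0, c(1, 2))), 0)
})

test_that("JSON round-trip is lossless; upl/aco dialects carry their fields", {
  rs <- random_restraints(n = 15, n_dist = 50, n_amb = 12, n_dih = 10, seed = 6)
  f <- tempfile(fileext = ".json")
  write_restraints(rs, f, "json")
  back <- read_restraints(f, "json")
  expect_equal(back$distance$upper, rs$distance$upper)
  expect_equal(back$distance$id, rs$distance$id)
  expect_equal(back$dihedral$target, rs$dihedral$target)
  # upl: one row per candidate, grouped ambiguity survives the round trip
  fu <- tempfile(fileext = ".upl")
  write_restraints(rs, fu, "upl")
  bu <- read_restraints(fu, "upl")
  cc0 <- classify_restraints(rs); cc1 <- classify_restraints(bu)
  expect_equal(cc1$total, cc0$total)
  expect_equal(cc1$ambiguous, cc0$ambiguous)
  expect_true(all(bu$distance$lower == 0))
  # worked upl row
  fu2 <- tempfile(fileext = ".upl")
  writeLines("  12 ALA  N    30 ALA  SC      8.00", fu2)
  one <- read_restraints(fu2, "upl")
  expect_equal(one$distance$upper, 8)
  expect_equal(one$distance$lower, 0)
  expect_equal(one$distance$res_j, 30)
  # aco round trip
  fa <- tempfile(fileext = ".aco")
  write_restraints(rs, fa, "aco")
  ba <- read_restraints(fa, "aco")
  expect_equal(nrow(ba$dihedral), nrow(rs$dihedral))
  expect_equal(ba$dihedral$tolerance, rs$dihedral$tolerance, tolerance = 0.2)
  # malformed rows carry a line number
  fbad <- tempfile()
  writeLines(c("  1 ALA N 2 ALA CA 5.0", "garbage row"), fbad)
  expect_error(read_restraints(fbad, "upl"), "line 2")
})
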