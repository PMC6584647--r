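# Synthetic benchmark generator: folds, restraints, composed cases.

test_that("toy folds: secondary structure, self-avoidance, determinism", {
  f <- make_toy_fold(3, 12, 5, seed = 4)
  runs <- rle(strsplit(f$ss, "")[[1]])
  expect_equal(sum(runs$values == "H" & runs$lengths == 12), 3)
  expect_gt(emnmr:::min_nonbonded_cpp(f$structure$xyz, f$structure$n_res, 2L), 2.5)
  f2 <- make_toy_fold(3, 12, 5, seed = 4)
  expect_identical(f$structure$xyz, f2$structure$xyz)
  f3 <- make_toy_fold(3, 12, 5, seed = 5)
  expect_false(identical(f$structure$xyz, f3$structure$xyz))
})

test_that("toy folds are compact relative to the ideal bundle", {
  f <- make_toy_fold(4, c(15, 13, 11, 9), 5, seed = 2)
  ca <- f$structure$xyz[f$structure$atom == "CA", ]
  rg <- sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
  expect_lt(rg, 1.2 * emnmr:::ideal_bundle_rg(c(15, 13, 11, 9), rep(5, 3)))
})

test_that("simulated restraints: truth satisfies everything at full coverage", {
  f <- make_toy_fold(3, c(14, 11, 9), 5, seed = 3)
  sim <- simulate_restraints(f$structure, f$ss,
                             list(coverage = 1, ambiguity_rate = 0), seed = 1)
  expect_equal(target_function(f$structure, sim$restraints), 0)
  # loop residues carry no dihedral restraints
  loops <- which(strsplit(f$ss, "")[[1]] == "C")
  expect_false(any(sim$restraints$dihedral$resno %in% loops))
})

test_that("ambiguous restraints contain the labelled true pair among decoys", {
  f <- make_toy_fold(3, c(14, 11, 9), 5, seed = 3)
  sim <- simulate_restraints(f$structure, f$ss,
                             list(coverage = 1, ambiguity_rate = 0.3,
                                  decoy_count = 2), seed = 2)
  d <- sim$restraints$distance
  for (id in unique(d$id[ave(d$id, d$id, FUN = length) > 1])) {
    rows <- d[d$id == id, ]
    expect_equal(nrow(rows), 3)          # true pair + 2 decoys
    expect_equal(sum(rows$is_true), 1)
  }
  # ambiguity never breaks satisfiability of the truth
  expect_equal(target_function(f$structure, sim$restraints), 0)
})

test_that("coverage sampling matches binomial expectations", {
  f <- make_toy_fold(4, c(16, 14, 12, 10), 5, seed = 6)
  all_c <- simulate_restraints(f$structure, f$ss, list(coverage = 1), seed = 1)
  n_all <- classify_restraints(all_c$restraints)$total
  half <- simulate_restraints(f$structure, f$ss, list(coverage = 0.5), seed = 7)
  n_half <- classify_restraints(half$restraints)$total
  ci <- qbinom(c(0.005, 0.995), n_all, 0.5)
  expect_gte(n_half, ci[1])
  expect_lte(n_half, ci[2])
})

test_that("benchmark cases regenerate bit-exactly and satisfy their restraints", {
  b <- mono3_bench()
  b2 <- make_benchmark("mono3", seed = 1)
  expect_identical(b$truth$xyz, b2$truth$xyz)
  expect_identical(b$restraints$distance, b2$restraints$distance)
  expect_identical(b$map$grid, b2$map$grid)
  expect_equal(target_function(b$truth, b$restraints), 0)
  expect_error(make_benchmark("nope"), "arg")
})

test_that("mono3: three detectable helices and 3! center-only hypotheses", {
  b <- mono3_bench()
  det <- detect_helices(mono3_map8(), min_length = 10)
  sh <- sequence_helices_from_ss(b$ss)
  sub <- head(det[order(-det$length), ], 3)
  hyps <- enumerate_assignments(sh, sub, prune = FALSE)
  expect_length(hyps, 6)
})

test_that("c3 assembly: inter-subunit restraints are labelled and genuinely
           violated in a single chain", {
  b <- fixture("c3", function() make_benchmark("c3", seed = 1))
  expect_equal(b$group$order, 3)
  expect_length(b$assembly, 3)
  expect_gt(length(b$inter_ids), 0)
  # single-chain evaluation of the full set (inter contacts included) is
  # violated; after filtering, the truth satisfies everything
  expect_gt(target_function(b$truth, b$restraints), 0)
  filt <- filter_intersubunit(b$restraints, b$inter_ids)
  expect_equal(target_function(b$truth, filt$set), 0)
  expect_equal(filt$removed, length(b$inter_ids))
})

test_that("benchmark directories carry the documented files", {
  b <- mono3_bench()
  dir <- tempfile("bench")
  write_benchmark(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("truth.pdb", "map.mrc", "restraints.json", "restraints.upl",
      "restraints.aco", "ss.txt", "manifest.json")))))
  # the written map reads back identically (float32)
  m <- read_map(file.path(dir, "map.mrc"))
  expect_equal(dim(m$grid), dim(b$map$grid))
  expect_equal(m$grid, b$map$grid, tolerance = 1e-6)
})
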