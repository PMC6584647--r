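# Symmetry groups and strict protomer replication.

test_that("identity-only group returns the protomer unchanged", {
  s <- random_structure(6)
  g <- symmetry_group(list(diag(3)))
  out <- apply_symmetry(s, g)
  expect_length(out, 1)
  expect_equal(out[[1]]$xyz, s$xyz)
})

test_that("C2 replication: chain 2 is exactly operator 2 of chain 1", {
  s <- random_structure(8, seed = 3)
  s$xyz <- sweep(s$xyz, 2, -c(15, 0, 0))  # off-axis
  g <- cyclic_group(2)
  out <- apply_symmetry(s, g)
  expect_length(out, 2)
  op2 <- g$operators[[2]]
  expected <- t(op2$R %*% t(out[[1]]$xyz))
  expect_equal(out[[2]]$xyz, expected, tolerance = 1e-9)
  expect_lt(superpose(out[[2]], em_structure(expected))$rmsd, 1e-9)
})

test_that("tetrahedral rotation group has order 12 and yields 12 chains", {
  g <- tetrahedral_group()
  expect_equal(g$order, 12)
  s <- random_structure(4, seed = 1)
  s$xyz <- sweep(s$xyz, 2, -c(20, 5, 9))
  expect_length(apply_symmetry(s, g), 12)
})

test_that("group validation: orthonormality, identity, closure", {
  bad <- diag(3); bad[1, 1] <- 1.2
  expect_error(symmetry_group(list(diag(3), bad)), "orthonormal")
  expect_error(symmetry_group(list(emnmr:::rot_about(c(0, 0, 1), 90))), "identity")
  # 120-degree rotation alone is not closed without its square
  expect_error(symmetry_group(list(diag(3), emnmr:::rot_about(c(0, 0, 1), 120))),
               "closed")
  expect_silent(validated <- cyclic_group(3))
})

test_that("extracting chain 1 after replication is the identity", {
  s <- random_structure(5, seed = 7)
  for (g in list(cyclic_group(3), tetrahedral_group())) {
    out <- apply_symmetry(s, g)
    expect_equal(out[[1]]$xyz, s$xyz, tolerance = 1e-12)
  }
})
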