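# Helix detection, subunit clustering, sequence helices.

test_that("a single ideal helix yields one detection with correct geometry", {
  h <- ideal_helix(21)
  m <- simulate_map(h, 8, voxel = 2)
  det <- detect_helices(m)
  expect_equal(nrow(det), 1)
  ca <- h$xyz[h$atom == "CA", ]
  true_axis <- prcomp(ca)$rotation[, 1]
  cosang <- abs(sum(det[1, c("ax", "ay", "az")] * true_axis))
  expect_lt(acos(min(cosang, 1)) * 180 / pi, 10)
  expect_lt(abs(det$length[1] - 30), 6)
  expect_lt(sqrt(sum((as.numeric(det[1, c("cx", "cy", "cz")]) - colMeans(ca))^2)), 3)
})

test_that("an all-zero map yields no detections", {
  m <- density_map(array(0, c(16, 16, 16)), 2)
  expect_equal(nrow(detect_helices(m)), 0)
})

test_that("a 3-helix bundle yields detections at the true helix positions", {
  b <- mono3_bench()
  det <- detect_helices(mono3_map8(), min_length = 10)
  sh <- sequence_helices_from_ss(b$ss)
  idx <- emnmr:::atom_index0(sh$central_residue, rep("CA", nrow(sh))) + 1L
  cen <- b$truth$xyz[idx, , drop = FALSE]
  expect_gte(nrow(det), 3)
  # every true helix center is matched by a detection within 4 A
  for (k in seq_len(3)) {
    dd <- apply(det[, c("cx", "cy", "cz")], 1, function(p)
      sqrt(sum((p - cen[k, ])^2)))
    expect_lt(min(dd), 4)
  }
})

test_that("detection is equivariant under rotating the structure", {
  h <- ideal_helix(18)
  R <- emnmr:::rot_about(c(1, 1, 0), 50)
  hr <- h
  hr$xyz <- t(R %*% t(h$xyz))
  d1 <- detect_helices(simulate_map(h, 8, voxel = 2))
  d2 <- detect_helices(simulate_map(hr, 8, voxel = 2))
  expect_equal(nrow(d1), 1)
  expect_equal(nrow(d2), 1)
  ax1r <- R %*% as.numeric(d1[1, c("ax", "ay", "az")])
  cosang <- abs(sum(ax1r * d2[1, c("ax", "ay", "az")]))
  expect_lt(acos(min(cosang, 1)) * 180 / pi, 12)
})

test_that("detected length grows with true helix length", {
  lens <- c(10, 14, 19)
  got <- sapply(lens, function(n) {
    h <- build_backbone(n, cbind(rep(-57, n), rep(-47, n)))
    det <- detect_helices(simulate_map(h, 8, voxel = 2), min_length = 5)
    det$length[1]
  })
  expect_true(all(diff(got) > 0))
})

test_that("clustering groups co-located helices and flags outliers", {
  # one dense group of 5
  set.seed(2)
  mk <- function(centers) {
    data.frame(cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
               ax = 1, ay = 0, az = 0, length = 20, score = 0.8)
  }
  one <- mk(matrix(rnorm(15, sd = 4), 5, 3))
  c1 <- cluster_into_subunits(one)
  expect_length(c1$clusters, 1)
  expect_equal(sort(c1$clusters[[1]]), 1:5)
  # C3-style: 3 groups of 5, far apart
  groups <- do.call(rbind, lapply(list(c(0, 0, 0), c(60, 0, 0), c(0, 60, 0)),
                                  function(o) sweep(matrix(rnorm(15, sd = 4), 5, 3), 2, -o)))
  c3 <- cluster_into_subunits(mk(groups), expected_per_subunit = 5)
  expect_length(c3$clusters, 3)
  expect_true(all(vapply(c3$clusters, length, integer(1)) == 5))
  # an isolated helix far from everything is noise
  iso <- rbind(one, mk(matrix(c(500, 500, 500), 1, 3)))
  ci <- cluster_into_subunits(iso)
  expect_true(6 %in% which(ci$assignment == 0) ||
              !(6 %in% unlist(ci$clusters[vapply(ci$clusters, length, integer(1)) > 1])))
})

test_that("clustering partitions the non-noise input exactly once", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(15, sd = 3), 5, 3),
               sweep(matrix(rnorm(15, sd = 3), 5, 3), 2, -c(50, 0, 0)))
  h <- data.frame(cx = pts[, 1], cy = pts[, 2], cz = pts[, 3],
                  ax = 0, ay = 0, az = 1, length = 15, score = 0.7)
  cl <- cluster_into_subunits(h)
  members <- unlist(cl$clusters)
  expect_equal(sort(members), setdiff(seq_len(10), which(cl$assignment == 0)))
  expect_false(any(duplicated(members)))
})

test_that("sequence helices: runs, centers, ordering", {
  one <- sequence_helices_from_ss("CCHHHHHHCC")
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 3)
  expect_equal(one$end, 8)
  expect_equal(one$central_residue, 5)
  expect_equal(one$length_A, 9)
  expect_equal(nrow(sequence_helices_from_ss(strrep("C", 30))), 0)
  # eight runs: 12, 9, 9, 5, 4, 4, 4, 4 with coil separators
  runs <- c(12, 9, 9, 5, 4, 4, 4, 4)
  ss <- paste(vapply(runs, function(k) paste0(strrep("H", k), "CC"), ""),
              collapse = "")
  sh <- sequence_helices_from_ss(ss)
  expect_equal(nrow(sh), 8)
  expect_equal(sh$length_res, sort(runs, decreasing = TRUE))
  # ties ordered by start index
  ties <- sh[sh$length_res == 4, ]
  expect_true(all(diff(ties$start) > 0))
  expect_error(sequence_helices_from_ss("HHXX"), "H, E, C")
  expect_error(sequence_helices_from_ss("HHHH", min_len_res = 3))
})
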