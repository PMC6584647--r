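# Density maps: MRC I/O, Gaussian simulation, Fourier truncation,
# correlation scores.

test_that("MRC round-trip preserves grid, voxel and origin", {
  set.seed(1)
  # write once to land on float32 values, then round-trip must be exact
  g0 <- array(rnorm(16^3), c(16, 16, 16))
  m0 <- density_map(g0, voxel = 1.5, origin = c(-3, 2, 7.5))
  f <- tempfile(fileext = ".mrc")
  write_map(m0, f)
  m1 <- read_map(f)
  f2 <- tempfile(fileext = ".mrc")
  write_map(m1, f2)
  m2 <- read_map(f2)
  expect_identical(m2$grid, m1$grid)
  expect_equal(m1$voxel, 1.5, tolerance = 1e-6)
  expect_equal(m1$origin, c(-3, 2, 7.5), tolerance = 1e-5)
  expect_equal(m1$grid, g0, tolerance = 1e-6)
})

test_that("non-cubic grids are preserved", {
  g <- array(runif(16 * 20 * 24), c(16, 20, 24))
  f <- tempfile(fileext = ".mrc")
  write_map(density_map(g, 2), f)
  expect_equal(dim(read_map(f)$grid), c(16L, 20L, 24L))
})

test_that("malformed MRC files produce format errors, not crashes", {
  g <- array(runif(8^3), c(8, 8, 8))
  f <- tempfile(fileext = ".mrc")
  write_map(density_map(g, 2), f)
  full <- readBin(f, "raw", n = file.size(f))
  f2 <- tempfile(fileext = ".mrc")
  writeBin(full[1:(1024 + 100)], f2)   # truncated mid-payload
  expect_error(read_map(f2), "truncated")
  bad <- full
  bad[13] <- as.raw(9)                  # MODE word
  f3 <- tempfile(fileext = ".mrc")
  writeBin(bad, f3)
  expect_error(read_map(f3), "MODE")
})

test_that("simulated map: single-atom Gaussian profile and linearity", {
  atom <- matrix(c(0, 0, 0), 1, 3)
  m <- simulate_map(atom, resolution = 6, voxel = 1)
  sigma <- emnmr:::resolution_sigma(6)
  # global maximum at the voxel nearest the atom
  imax <- which(m$grid == max(m$grid), arr.ind = TRUE)[1, ]
  pos <- m$origin + (imax - 1) * m$voxel
  expect_true(all(abs(pos) < m$voxel / 2 + 1e-9))
  # profile matches the stated Gaussian
  d <- dim(m$grid)
  ax <- m$origin[1] + (seq_len(d[1]) - 1) * m$voxel
  iy <- which.min(abs(m$origin[2] + (seq_len(d[2]) - 1) * m$voxel))
  iz <- which.min(abs(m$origin[3] + (seq_len(d[3]) - 1) * m$voxel))
  prof <- m$grid[, iy, iz]
  expected <- exp(-ax^2 / (2 * sigma^2))
  expect_equal(prof, expected, tolerance = 1e-6)
  # doubling the atoms doubles every voxel
  m2 <- simulate_map(rbind(atom, atom), resolution = 6, voxel = 1, grid_like = m)
  expect_equal(m2$grid, 2 * m$grid, tolerance = 1e-9)
})

test_that("simulated map integral matches atom count x kernel integral", {
  s <- ideal_helix(10)
  m <- simulate_map(s, resolution = 8, voxel = 2)
  sigma <- emnmr:::resolution_sigma(8)
  kernel_integral <- (2 * pi * sigma^2)^(3 / 2)
  got <- sum(m$grid) * m$voxel^3
  expect_equal(got, nrow(s$xyz) * kernel_integral, tolerance = 0.01)
})

test_that("self-correlation of a simulated map is 1", {
  s <- ideal_helix(10)
  a <- simulate_map(s, 8, voxel = 2)
  b <- simulate_map(s, 8, voxel = 2)
  expect_equal(map_correlation(a, b), 1, tolerance = 1e-9)
})

test_that("fourier truncation: no-op beyond Nyquist, projection, idempotent", {
  s <- ideal_helix(8)
  # a 16 A map on a 1 A grid is band-limited far below Nyquist: a cutoff at
  # the Nyquist resolution removes nothing
  m_bl <- simulate_map(s, 16, voxel = 1)
  noop <- fourier_truncate(m_bl, 2 * m_bl$voxel)
  expect_equal(noop$grid, m_bl$grid, tolerance = 1e-6 * max(m_bl$grid))
  m <- simulate_map(s, 6, voxel = 1.5)
  tr <- fourier_truncate(m, 10)
  expect_lte(sum(tr$grid^2), sum(m$grid^2) + 1e-9)
  tr2 <- fourier_truncate(tr, 10)
  expect_equal(tr2$grid, tr$grid, tolerance = 1e-6)
  expect_error(fourier_truncate(m, 1), "Nyquist")
})

test_that("sharp truncation approximates Gaussian low-pass on a toy fold", {
  b <- mono3_bench()
  tr <- fourier_truncate(b$map, 8)
  direct <- simulate_map(b$truth, 8, grid_like = b$map)
  mask <- direct$grid > 1e-3 * max(direct$grid)
  expect_gt(cor(tr$grid[mask], direct$grid[mask]), 0.95)
})

test_that("map correlation limits and independence null", {
  s <- ideal_helix(8)
  a <- simulate_map(s, 8, voxel = 2)
  expect_equal(map_correlation(a, a), 1, tolerance = 1e-12)
  b <- a
  b$grid <- -a$grid
  mask <- a$grid > 1e-6 * max(a$grid)
  expect_equal(map_correlation(a, b, mask = mask), -1, tolerance = 1e-12)
  set.seed(42)
  n <- c(22, 22, 22)
  x <- density_map(array(rnorm(prod(n)), n), 1)
  y <- density_map(array(rnorm(prod(n)), n), 1)
  mask <- array(TRUE, n)
  expect_lt(abs(map_correlation(x, y, mask = mask)), 3 / sqrt(prod(n)))
  z <- density_map(array(1, n), 1)
  expect_error(map_correlation(z, z, mask = mask), "variance")
})

test_that("correlation after resampling different grids stays near 1", {
  s <- ideal_helix(10)
  a <- simulate_map(s, 8, voxel = 2)
  b <- simulate_map(s, 8, voxel = 1.6)
  expect_gt(map_correlation(a, b), 0.98)
})

test_that("per-residue overlap separates placed and displaced structures", {
  b <- mono3_bench()
  m8 <- mono3_map8()
  ov <- per_residue_overlap(b$truth, m8, 8)
  expect_false(any(ov$outside))
  expect_true(all(ov$correlation > 0.7))
  shifted <- b$truth
  shifted$xyz <- sweep(shifted$xyz, 2, -c(20, 0, 0))
  ov2 <- per_residue_overlap(shifted, m8, 8)
  expect_lt(mean(ov2$correlation), 0.2)
  # overlap fraction = share of residues above the threshold
  expect_equal(overlap_fraction(ov, 0.7), mean(ov$correlation > 0.7))
})

test_that("per-residue overlap is invariant under adding a constant to the map", {
  b <- mono3_bench()
  m8 <- mono3_map8()
  ov <- per_residue_overlap(b$truth, m8, 8, residues = 1:10)
  m8c <- m8
  m8c$grid <- m8$grid + 5
  ov2 <- per_residue_overlap(b$truth, m8c, 8, residues = 1:10)
  expect_equal(ov2$correlation, ov$correlation, tolerance = 1e-9)
})

test_that("residues outside the map are flagged, not an error", {
  b <- mono3_bench()
  m8 <- mono3_map8()
  far <- b$truth
  far$xyz <- sweep(far$xyz, 2, -c(500, 0, 0))
  ov <- per_residue_overlap(far, m8, 8, residues = 1:3)
  expect_true(all(ov$outside))
  expect_true(all(ov$correlation == -1))
})
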