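# Density maps: MRC/CCP4 I/O, Gaussian-kernel map simulation, Fourier-space
# resolution truncation, and map/model correlation scores.
#
# Grid convention: 3D array with the X axis fastest (R's native array layout),
# isotropic voxel size, `origin` = Angstrom position of the first voxel center.

#' Density map object
#'
#' @param grid 3D numeric array of density values (X fastest).
#' @param voxel isotropic voxel size in Angstrom.
#' @param origin position (Angstrom) of the center of voxel [1,1,1].
#' @param nominal_resolution nominal resolution in Angstrom (metadata).
#' @return object of class \code{density_map}.
#' @export
density_map <- function(grid, voxel, origin = c(0, 0, 0),
                        nominal_resolution = NA_real_) {
  if (length(dim(grid)) != 3) stop("grid must be a 3D array")
  if (!all(is.finite(grid))) stop("grid values must be finite")
  if (!is.numeric(voxel) || voxel <= 0) stop("voxel must be positive")
  structure(list(grid = grid, voxel = voxel, origin = as.numeric(origin),
                 nominal_resolution = nominal_resolution),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("density_map: %d x %d x %d voxels, %.3g A/voxel, origin (%.1f, %.1f, %.1f), nominal %.3g A\n",
              d[1], d[2], d[3], x$voxel, x$origin[1], x$origin[2], x$origin[3],
              x$nominal_resolution))
  invisible(x)
}

# ---------------------------------------------------------------------------
# MRC 2014 I/O (mode 2, float32). Origin precedence on read: the ORIGIN
# header words are used when any is nonzero, otherwise NX/NY/NZSTART * voxel.

#' Write a density map in MRC/CCP4 2014 format (mode 2)
#' @param map a \code{density_map}.
#' @param path output file.
#' @export
write_map <- function(map, path) {
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wint(d)                               # NX NY NZ
  wint(2)                               # MODE 2 = float32
  wint(c(0, 0, 0))                      # NXSTART NYSTART NZSTART
  wint(d)                               # MX MY MZ
  wflt(d * map$voxel)                   # CELLA
  wflt(c(90, 90, 90))                   # CELLB
  wint(c(1, 2, 3))                      # MAPC MAPR MAPS
  wflt(c(min(map$grid), max(map$grid), mean(map$grid)))
  wint(1)                               # ISPG
  wint(0)                               # NSYMBT
  wint(rep(0, 25))                      # EXTRA
  wflt(map$origin)                      # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wflt(sd(as.numeric(map$grid)))        # RMS
  wint(0)                               # NLABL
  writeBin(raw(800), con)               # labels
  writeBin(as.numeric(map$grid), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC/CCP4 map (mode 2)
#' @param path MRC file.
#' @return a \code{density_map}; the nominal resolution is NA (not stored in
#'   the format) and can be set by the caller.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rflt <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  d <- rint(3)
  if (length(d) < 3 || any(d <= 0) || any(d > 4096))
    stop("malformed MRC header: invalid NX/NY/NZ")
  mode <- rint(1)
  if (!identical(mode, 2L)) stop("malformed MRC header: MODE must be 2 (float32), got ", mode)
  nstart <- rint(3)
  m <- rint(3)
  cella <- rflt(3)
  rflt(3)                               # CELLB
  mapcrs <- rint(3)
  if (!identical(mapcrs, 1:3))
    stop("malformed MRC header: MAPC/MAPR/MAPS must be 1,2,3")
  rflt(3)                               # DMIN DMAX DMEAN
  rint(1); nsymbt <- rint(1)
  rint(25)
  orig <- rflt(3)
  maptag <- readChar(con, nchars = 4, useBytes = TRUE)
  if (!identical(substr(maptag, 1, 3), "MAP"))
    stop("malformed MRC header: missing MAP tag")
  readBin(con, "raw", n = 4)            # MACHST
  rflt(1); rint(1)
  readBin(con, "raw", n = 800)
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  vox <- cella[1] / m[1]
  voxyz <- cella / m
  if (max(abs(voxyz - vox)) > 1e-4 * vox)
    stop("malformed MRC header: anisotropic voxel size not supported")
  n <- prod(d)
  vals <- rflt(n)
  if (length(vals) < n) stop("MRC payload truncated: expected ", n,
                             " voxels, got ", length(vals))
  if (all(abs(orig) < 1e-12)) orig <- nstart * vox
  density_map(array(vals, dim = d), voxel = vox, origin = orig)
}

# ---------------------------------------------------------------------------

# Gaussian kernel width for a nominal resolution: the kernel's Fourier
# amplitude falls to one half at spatial frequency 1/resolution.
resolution_sigma <- function(resolution) resolution * sqrt(log(2) / 2) / pi

#' Simulate a density map from a structure
#'
#' Sum of per-atom 3D Gaussians whose Fourier amplitude falls to one half at
#' spatial frequency 1/resolution. The grid extends at least 2*resolution
#' beyond the structure's bounding box.
#'
#' @param structure an \code{em_structure}, a list of them (an assembly), or
#'   a plain coordinate matrix.
#' @param resolution nominal resolution in Angstrom (>= 2*voxel).
#' @param voxel voxel size in Angstrom.
#' @param atoms atom names to include (default all six slots).
#' @param grid_like optional \code{density_map} whose grid geometry is reused
#'   (needed when maps must share a grid for correlation).
#' @return a \code{density_map}.
#' @export
simulate_map <- function(structure, resolution, voxel = 2,
                         atoms = ATOM_SLOTS, grid_like = NULL) {
  xyz <- gather_coords(structure, atoms)
  if (nrow(xyz) == 0) stop("empty structure")
  if (resolution < 2 * voxel) stop("resolution must be >= 2*voxel")
  sigma <- resolution_sigma(resolution)
  if (is.null(grid_like)) {
    pad <- 2 * resolution
    lo <- apply(xyz, 2, min) - pad
    hi <- apply(xyz, 2, max) + pad
    dims <- as.integer(ceiling((hi - lo) / voxel)) + 1L
    origin <- lo
  } else {
    dims <- dim(grid_like$grid)
    origin <- grid_like$origin
    voxel <- grid_like$voxel
  }
  g <- simulate_map_cpp(xyz, as.integer(dims), origin, voxel, sigma, 4.5)
  density_map(array(g, dim = dims), voxel = voxel, origin = origin,
              nominal_resolution = resolution)
}

gather_coords <- function(structure, atoms = ATOM_SLOTS) {
  if (inherits(structure, "em_structure")) {
    structure$xyz[select_atoms(structure, atoms), , drop = FALSE]
  } else if (is.list(structure) && all(vapply(structure, inherits, logical(1), "em_structure"))) {
    do.call(rbind, lapply(structure, function(s)
      s$xyz[select_atoms(s, atoms), , drop = FALSE]))
  } else {
    as.matrix(structure)
  }
}

#' Low-pass a map by sharp Fourier truncation
#'
#' Zeroes all Fourier amplitudes at spatial frequency above 1/target
#' resolution. A raised-cosine roll-off of 10 percent width is available to
#' suppress ringing.
#'
#' @param map a \code{density_map}.
#' @param target_resolution target resolution in Angstrom (>= 2*voxel).
#' @param soft_edge if TRUE, apply a raised-cosine edge of 10 percent relative
#'   width instead of a sharp cutoff.
#' @return the truncated \code{density_map} (nominal resolution updated).
#' @export
fourier_truncate <- function(map, target_resolution, soft_edge = FALSE) {
  if (target_resolution < 2 * map$voxel)
    stop("target resolution finer than the grid Nyquist limit (2*voxel)")
  d <- dim(map$grid)
  fr <- function(n) {
    k <- c(seq(0, floor(n / 2)), seq(-(n - floor(n / 2) - 1), -1)) / (n * map$voxel)
    k
  }
  fx <- fr(d[1]); fy <- fr(d[2]); fz <- fr(d[3])
  f2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  fcut <- 1 / target_resolution
  F <- fft(map$grid)
  if (soft_edge) {
    w <- 0.1 * fcut
    fmag <- sqrt(f2)
    filt <- ifelse(fmag <= fcut - w, 1,
                   ifelse(fmag >= fcut + w, 0,
                          0.5 * (1 + cos(pi * (fmag - fcut + w) / (2 * w)))))
    F <- F * filt
  } else {
    F[f2 > fcut^2] <- 0
  }
  out <- Re(fft(F, inverse = TRUE)) / prod(d)
  density_map(array(out, dim = d), voxel = map$voxel, origin = map$origin,
              nominal_resolution = target_resolution)
}

#' Resample a map onto another map's grid (trilinear, lossy)
#' @param map map to resample.
#' @param like map providing the target grid geometry.
#' @return a \code{density_map} on \code{like}'s grid.
#' @export
resample_map <- function(map, like) {
  d <- dim(like$grid)
  ax <- like$origin[1] + (seq_len(d[1]) - 1) * like$voxel
  ay <- like$origin[2] + (seq_len(d[2]) - 1) * like$voxel
  az <- like$origin[3] + (seq_len(d[3]) - 1) * like$voxel
  pts <- cbind(rep(ax, times = d[2] * d[3]),
               rep(rep(ay, each = d[1]), times = d[3]),
               rep(az, each = d[1] * d[2]))
  v <- interp_map_cpp(as.numeric(map$grid), dim(map$grid), map$origin,
                      map$voxel, pts)
  density_map(array(v, dim = d), voxel = like$voxel, origin = like$origin,
              nominal_resolution = map$nominal_resolution)
}

#' Pearson correlation between two maps
#'
#' Maps on different grids are first resampled (trilinear) onto the grid of
#' \code{a}. The default mask keeps voxels where either map exceeds 1e-6 of
#' its maximum.
#'
#' @param a,b \code{density_map}s.
#' @param mask optional logical array on the grid of \code{a}.
#' @return correlation in [-1, 1].
#' @export
map_correlation <- function(a, b, mask = NULL) {
  if (!identical(dim(a$grid), dim(b$grid)) ||
      max(abs(a$origin - b$origin)) > 1e-9 || abs(a$voxel - b$voxel) > 1e-12)
    b <- resample_map(b, a)
  if (is.null(mask))
    mask <- (a$grid > 1e-6 * max(a$grid)) | (b$grid > 1e-6 * max(b$grid))
  if (sum(mask) < 10) stop("mask selects fewer than 10 voxels")
  va <- a$grid[mask]; vb <- b$grid[mask]
  if (sd(va) == 0 || sd(vb) == 0)
    stop("undefined correlation: zero variance inside mask")
  cor(va, vb)
}

#' Per-residue overlap with an experimental map
#'
#' For each residue, a map is simulated from its backbone N, CA, C, O atoms
#' at the stated resolution on the experimental grid and correlated with the
#' experimental map inside the residue's own density support (voxels above
#' \code{mask_level} of the residue-map maximum). The correlation is the uncentered
#' cross-correlation (the convention of the standard map-fitting tools: a
#' residue sitting in solid density scores near 1, a residue in empty space
#' near 0) computed after subtracting the experimental map's background
#' level (its global median), which makes the score invariant under adding a
#' constant to the experimental map. Residues outside the map get
#' correlation -1 and an outside flag instead of an error.
#'
#' @param structure an \code{em_structure}.
#' @param map the experimental \code{density_map}.
#' @param resolution resolution (Angstrom) for the in-silico residue maps.
#' @param residues residue numbers to score (default all).
#' @param mask_level fraction of the residue-map maximum defining its support
#'   (default 0.3: the core region around the backbone).
#' @return data.frame with columns resno, correlation, outside.
#' @export
per_residue_overlap <- function(structure, map, resolution, residues = NULL,
                                mask_level = 0.3) {
  if (is.null(residues)) residues <- seq_len(structure$n_res)
  sigma <- resolution_sigma(resolution)
  dims <- dim(map$grid)
  gvec <- as.numeric(map$grid)
  bg <- median(gvec)
  out <- data.frame(resno = residues, correlation = NA_real_, outside = FALSE)
  for (k in seq_along(residues)) {
    r <- residues[k]
    idx <- atom_index0(rep(r, 4), c("N", "CA", "C", "O")) + 1L
    loc <- gauss_local_cpp(structure$xyz[idx, , drop = FALSE], dims,
                           map$origin, map$voxel, sigma, 4.5)
    if (length(loc$val) < 10) {
      out$correlation[k] <- -1; out$outside[k] <- TRUE
      next
    }
    m <- loc$val > mask_level * max(loc$val)
    if (sum(m) < 10) {
      out$correlation[k] <- -1; out$outside[k] <- TRUE
      next
    }
    va <- loc$val[m]
    vb <- gvec[loc$idx[m]] - bg
    den <- sqrt(sum(va^2) * sum(vb^2))
    if (den == 0) {
      out$correlation[k] <- -1; out$outside[k] <- TRUE
    } else {
      out$correlation[k] <- sum(va * vb) / den
    }
  }
  out
}

#' Fraction of residues with good map overlap
#' @param overlap data.frame from \code{per_residue_overlap}.
#' @param threshold correlation threshold (default 0.7).
#' @return fraction in [0, 1].
#' @export
overlap_fraction <- function(overlap, threshold = 0.7) {
  mean(overlap$correlation > threshold)
}
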