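# Feature detection: alpha-helical rod densities in medium-resolution maps,
# clustering of helices into subunits, and helical stretches from NMR
# secondary structure.

fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # hemisphere: z in (0, 1)
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Detect alpha-helical densities in a map
#'
#' Cross-correlates a solid-cylinder template (radius 2.5 A, length 10 A)
#' against the map over a grid of orientations (angular spacing well below
#' 15 degrees), keeps local score maxima above a threshold, refines each
#' candidate's axis by density-weighted principal components, measures the
#' rod length from the half-maximum extent of the axial density profile, and
#' merges collinear overlapping segments. Axis polarity is deliberately not
#' assigned (the sign of the axis is arbitrary).
#'
#' @param map a \code{density_map} with nominal resolution in [4, 12] A
#'   (medium resolution; helices appear as solid rods).
#' @param min_length minimum reported rod length in Angstrom (default 12).
#' @param score_threshold normalized cross-correlation threshold for seeds
#'   (default 0.55).
#' @param n_orientations number of template orientations on the hemisphere
#'   (default 160, about 11-degree spacing).
#' @return data.frame with one row per detected helix: center (cx, cy, cz),
#'   unit axis (ax, ay, az), length (A), score; sorted by length descending.
#' @export
detect_helices <- function(map, min_length = 12, score_threshold = 0.55,
                           n_orientations = 160) {
  g <- map$grid
  if (max(g) - min(g) < 1e-12) return(empty_helix_df())
  d <- dim(g)
  vox <- map$voxel
  gz <- (g - mean(g)) / sd(g)

  # spherical support shared by all orientations
  rad_t <- 2.5; len_t <- 10
  rsup <- sqrt((len_t / 2)^2 + 5^2) + vox  # support includes a background shell
  w <- ceiling(rsup / vox)
  off <- as.matrix(expand.grid(x = -w:w, y = -w:w, z = -w:w)) * vox
  insup <- sqrt(rowSums(off^2)) <= rsup
  off <- off[insup, , drop = FALSE]
  offi <- round(off / vox)
  nsup <- nrow(off)

  # embed a value vector at the support offsets into a wrapped full-size array
  embed_full <- function(vals) {
    arr <- array(0, d)
    ix <- (offi[, 1] %% d[1]) + 1
    iy <- (offi[, 2] %% d[2]) + 1
    iz <- (offi[, 3] %% d[3]) + 1
    arr[cbind(ix, iy, iz)] <- vals
    arr
  }

  Fg <- fft(gz)
  Fg2 <- fft(gz^2)
  Fs <- fft(embed_full(rep(1, nsup)))
  sum_m <- Re(fft(Fg * Conj(Fs), inverse = TRUE)) / prod(d)
  sum_m2 <- Re(fft(Fg2 * Conj(Fs), inverse = TRUE)) / prod(d)
  local_ss <- pmax(sum_m2 - sum_m^2 / nsup, 1e-9)

  dirs <- fibonacci_hemisphere(n_orientations)
  best <- array(-Inf, d)
  bestdir <- array(0L, d)
  for (k in seq_len(n_orientations)) {
    u <- dirs[k, ]
    ax <- off %*% u
    rad2 <- rowSums(off^2) - ax^2
    tv <- as.numeric(abs(ax) <= len_t / 2 & rad2 <= rad_t^2)
    tv <- tv - mean(tv)
    tnorm <- sqrt(sum(tv^2))
    if (tnorm < 1e-9) next
    Ft <- fft(embed_full(tv))
    num <- Re(fft(Fg * Conj(Ft), inverse = TRUE)) / prod(d)
    ncc <- num / (tnorm * sqrt(local_ss))
    upd <- ncc > best
    best[upd] <- ncc[upd]
    bestdir[upd] <- k
  }

  cand <- which(best > score_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_helix_df())
  sc <- best[cand]
  ord <- order(sc, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]
  pos <- sweep((cand - 1) * vox, 2, -map$origin)  # world coords of voxel centers

  # greedy suppression: a seed is absorbed if close to an accepted seed's axis
  acc <- integer(0)
  for (i in seq_len(nrow(pos))) {
    ok <- TRUE
    for (j in acc) {
      dp <- pos[i, ] - pos[j, ]
      uj <- dirs[bestdir[cand[j, , drop = FALSE]], ]
      axial <- sum(dp * uj)
      perp <- sqrt(max(sum(dp^2) - axial^2, 0))
      if (perp < 3.5 && abs(axial) < 40) { ok <- FALSE; break }
      if (sqrt(sum(dp^2)) < 5) { ok <- FALSE; break }
    }
    if (ok) acc <- c(acc, i)
  }

  segs <- lapply(acc, function(i) {
    refine_rod(map, pos[i, ], dirs[bestdir[cand[i, , drop = FALSE]], ], sc[i],
               rad_t)
  })
  segs <- do.call(rbind, segs)
  segs <- merge_collinear(segs)
  # end-blur correction: the half-maximum extent of a blurred rod overshoots
  # the CA span by roughly two kernel widths
  segs$length <- pmax(segs$length - 4, 0)
  segs <- dedup_centerlines(segs)
  segs <- segs[segs$length >= min_length, , drop = FALSE]
  segs <- segs[order(-segs$length), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

# discard rods whose centerline mostly runs inside an already-accepted rod
# (oblique template hits crossing through packed helix density); acceptance
# in score order, so well-centered rods displace oblique hybrids
dedup_centerlines <- function(segs, radius = 3.5, frac = 0.45) {
  if (nrow(segs) <= 1) return(segs)
  segs <- segs[order(-segs$score), , drop = FALSE]
  keep <- logical(nrow(segs))
  pts <- function(r) {
    u <- as.numeric(segs[r, c("ax", "ay", "az")])
    cen <- as.numeric(segs[r, c("cx", "cy", "cz")])
    ts <- seq(-segs$length[r] / 2, segs$length[r] / 2, by = 1)
    sweep(outer(ts, u), 2, cen, `+`)
  }
  dist_to_seg <- function(P, r) {
    u <- as.numeric(segs[r, c("ax", "ay", "az")])
    cen <- as.numeric(segs[r, c("cx", "cy", "cz")])
    dp <- sweep(P, 2, cen)
    ax <- dp %*% u
    ax_cl <- pmin(pmax(ax, -segs$length[r] / 2), segs$length[r] / 2)
    sqrt(rowSums((dp - outer(as.numeric(ax_cl), u))^2))
  }
  for (i in seq_len(nrow(segs))) {
    P <- pts(i)
    covered <- rep(FALSE, nrow(P))
    for (j in which(keep)) {
      covered <- covered | (dist_to_seg(P, j) < radius)
    }
    keep[i] <- mean(covered) < frac
  }
  segs[keep, , drop = FALSE]
}

empty_helix_df <- function() {
  data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
             ax = numeric(0), ay = numeric(0), az = numeric(0),
             length = numeric(0), score = numeric(0))
}

# refine axis by density-weighted PCA inside a cylinder, then measure the
# half-maximum extent of the axial mean-density profile
refine_rod <- function(map, center, axis, score, rad_t) {
  dims <- dim(map$grid)
  gvec <- as.numeric(map$grid)
  for (it in 1:3) {
    # sample points in a tube around the current axis
    ts <- seq(-8, 8, by = map$voxel / 2)
    ring <- expand.grid(r = c(0, 1.25, 2.5), a = seq(0, 300, by = 60) * pi / 180)
    perp <- orthobasis(axis)
    n_ring <- nrow(ring)
    P <- matrix(0, length(ts) * n_ring, 3)
    row <- 1
    for (t in ts) {
      p0 <- center + t * axis
      for (q in seq_len(n_ring)) {
        dirp <- cos(ring$a[q]) * perp[, 1] + sin(ring$a[q]) * perp[, 2]
        P[row, ] <- p0 + ring$r[q] * dirp
        row <- row + 1
      }
    }
    wts <- interp_map_cpp(gvec, dims, map$origin, map$voxel, P)
    wts <- pmax(wts, 0)
    if (sum(wts) < 1e-9) break
    cen_new <- colSums(P * wts) / sum(wts)
    Pc <- sweep(P, 2, cen_new)
    C <- crossprod(Pc * sqrt(wts))
    ev <- eigen(C, symmetric = TRUE)
    ax_new <- ev$vectors[, 1]
    if (sum(ax_new * axis) < 0) ax_new <- -ax_new
    center <- cen_new
    axis <- ax_new / sqrt(sum(ax_new^2))
  }
  # axial profile: mean density in a disc of radius rad_t
  perp <- orthobasis(axis)
  ts <- seq(-30, 30, by = 0.5)
  disc <- expand.grid(r = c(0, 1.25, 2.5), a = seq(0, 300, by = 60) * pi / 180)
  prof <- vapply(ts, function(t) {
    p0 <- center + t * axis
    dirs <- outer(cos(disc$a), perp[, 1]) + outer(sin(disc$a), perp[, 2])
    P <- sweep(dirs * disc$r, 2, p0, `+`)
    mean(interp_map_cpp(gvec, dims, map$origin, map$voxel, P))
  }, numeric(1))
  p0v <- prof[ts == 0]
  half <- 0.5 * p0v
  inside <- prof >= half
  i0 <- which(ts == 0)
  lo <- i0; while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(ts) && inside[hi + 1]) hi <- hi + 1
  ext_lo <- ts[lo]; ext_hi <- ts[hi]
  len <- ext_hi - ext_lo
  cen <- center + (ext_hi + ext_lo) / 2 * axis
  data.frame(cx = cen[1], cy = cen[2], cz = cen[3],
             ax = axis[1], ay = axis[2], az = axis[3],
             length = len, score = score)
}

orthobasis <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  cbind(e1, e2)
}

merge_collinear <- function(segs, ang_tol = 20, perp_tol = 3) {
  if (nrow(segs) <= 1) return(segs)
  merged <- TRUE
  while (merged && nrow(segs) > 1) {
    merged <- FALSE
    for (i in seq_len(nrow(segs) - 1)) {
      for (j in (i + 1):nrow(segs)) {
        ui <- as.numeric(segs[i, c("ax", "ay", "az")])
        uj <- as.numeric(segs[j, c("ax", "ay", "az")])
        if (abs(sum(ui * uj)) < cos(ang_tol * pi / 180)) next
        ci <- as.numeric(segs[i, c("cx", "cy", "cz")])
        cj <- as.numeric(segs[j, c("cx", "cy", "cz")])
        dp <- cj - ci
        axial <- sum(dp * ui)
        perp <- sqrt(max(sum(dp^2) - axial^2, 0))
        if (perp > perp_tol) next
        # overlap of the two axial intervals on segment i's axis
        hi_i <- segs$length[i] / 2
        lo_j <- axial - segs$length[j] / 2
        hi_j <- axial + segs$length[j] / 2
        if (lo_j > hi_i + 2 || hi_j < -hi_i - 2) next
        lo <- min(-hi_i, lo_j); hi <- max(hi_i, hi_j)
        cen <- ci + (lo + hi) / 2 * ui
        segs$cx[i] <- cen[1]; segs$cy[i] <- cen[2]; segs$cz[i] <- cen[3]
        segs$length[i] <- hi - lo
        segs$score[i] <- max(segs$score[i], segs$score[j])
        segs <- segs[-j, , drop = FALSE]
        merged <- TRUE
        break
      }
      if (merged) break
    }
  }
  segs
}

# ---------------------------------------------------------------------------

#' Cluster detected helices into subunits
#'
#' Density-based clustering (DBSCAN) on helix centers. The neighborhood
#' radius is chosen automatically by scanning radii and taking the middle of
#' the longest plateau of constant positive cluster count. If
#' \code{expected_per_subunit} is given and the DBSCAN partition violates it,
#' the method falls back to k-medoids with k = n/expected.
#'
#' @param helices data.frame from \code{detect_helices} (>= 1 row).
#' @param expected_per_subunit optional expected helix count per subunit.
#' @param eps optional fixed DBSCAN radius (Angstrom); skips the auto scan.
#' @param min_pts DBSCAN core-point minimum (default 2).
#' @return list with \code{assignment} (integer per helix, 0 = noise) and
#'   \code{clusters} (list of row-index vectors).
#' @export
cluster_into_subunits <- function(helices, expected_per_subunit = NULL,
                                  eps = NULL, min_pts = 2) {
  n <- nrow(helices)
  if (n < 1) stop("need at least one helix")
  X <- as.matrix(helices[, c("cx", "cy", "cz")])
  if (n == 1) return(list(assignment = 1L, clusters = list(1L)))
  D <- as.matrix(dist(X))
  if (is.null(eps)) {
    dvals <- sort(unique(round(D[upper.tri(D)], 3)))
    cand <- seq(max(min(dvals), 1e-3), max(dvals), length.out = 80)
    counts <- vapply(cand, function(e) {
      a <- dbscan_basic(D, e, min_pts)
      length(unique(a[a > 0]))
    }, integer(1))
    # longest run of constant positive cluster count
    r <- rle(counts)
    valid <- which(r$values >= 1)
    if (length(valid) == 0) valid <- seq_along(r$values)
    best <- valid[which.max(r$lengths[valid])]
    pos <- cumsum(r$lengths)
    i1 <- if (best == 1) 1 else pos[best - 1] + 1
    eps <- cand[floor((i1 + pos[best]) / 2)]
  }
  a <- dbscan_basic(D, eps, min_pts)
  if (!is.null(expected_per_subunit)) {
    sizes <- table(a[a > 0])
    if (length(sizes) == 0 || any(sizes != expected_per_subunit)) {
      k <- max(1, round(n / expected_per_subunit))
      pm <- cluster::pam(X, k = k)
      a <- as.integer(pm$clustering)
    }
  }
  clusters <- lapply(sort(unique(a[a > 0])), function(k) which(a == k))
  list(assignment = a, clusters = clusters)
}

# classic DBSCAN on a precomputed distance matrix
dbscan_basic <- function(D, eps, min_pts) {
  n <- nrow(D)
  labels <- rep(0L, n)       # 0 = unvisited/noise
  visited <- rep(FALSE, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- which(D[i, ] <= eps)
    if (length(nb) < min_pts) next     # noise (may be claimed later)
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nb2 <- which(D[j, ] <= eps)
        if (length(nb2) >= min_pts) queue <- c(queue, setdiff(nb2, j))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

# ---------------------------------------------------------------------------

#' Helical stretches from a secondary-structure string
#'
#' Maximal runs of H of at least \code{min_len_res} residues. The central
#' residue is start + floor((length-1)/2); the physical length uses the
#' 1.5 A/residue helical rise.
#'
#' @param ss per-residue secondary-structure string over \{H, E, C\}.
#' @param min_len_res minimum helix length in residues (>= 4).
#' @return data.frame (start, end, central_residue, length_res, length_A)
#'   sorted by length descending, ties by start index.
#' @export
sequence_helices_from_ss <- function(ss, min_len_res = 4) {
  stopifnot(min_len_res >= 4)
  v <- strsplit(ss, "")[[1]]
  if (!all(v %in% c("H", "E", "C")))
    stop("secondary-structure string must contain only H, E, C")
  r <- rle(v == "H")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len_res
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$length_res <- out$end - out$start + 1
  out$central_residue <- out$start + (out$length_res - 1) %/% 2
  out$length_A <- out$length_res * 1.5
  out <- out[order(-out$length_res, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("start", "end", "central_residue", "length_res", "length_A")]
}
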