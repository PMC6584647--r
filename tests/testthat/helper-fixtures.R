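# Shared fixtures, built once per test session.

.fx <- new.env()

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

ideal_helix <- function(n = 21) {
  fixture(paste0("helix", n), function()
    build_backbone(n, cbind(rep(-57, n), rep(-47, n))))
}

mono3_bench <- function() fixture("mono3", function() make_benchmark("mono3", seed = 1))
mono5_bench <- function() fixture("mono5", function() make_benchmark("mono5", seed = 1))

mono3_map8 <- function() fixture("mono3_map8", function()
  fourier_truncate(mono3_bench()$map, 8))

# small random structure for oracle tests
random_structure <- function(n = 12, seed = 1) {
  set.seed(seed)
  di <- cbind(runif(n, -179, 180), runif(n, -179, 180))
  build_backbone(n, di)
}

# random restraint set referencing an n-residue topology
random_restraints <- function(n = 12, n_dist = 15, n_amb = 5, n_dih = 6, seed = 1) {
  set.seed(seed)
  atoms <- c("N", "CA", "C", "O", "CB", "SC")
  mk_rows <- function(id, k) {
    data.frame(id = id,
               res_i = sample(n, k, replace = TRUE),
               atom_i = sample(atoms, k, replace = TRUE),
               res_j = sample(n, k, replace = TRUE),
               atom_j = sample(atoms, k, replace = TRUE),
               lower = 0, upper = NA, origin = "NOE", scope = "intra")
  }
  rows <- list()
  for (i in seq_len(n_dist)) {
    k <- if (i <= n_amb) sample(2:4, 1) else 1
    r <- mk_rows(i, k)
    lo <- runif(1, 0, 3)
    r$lower <- lo
    r$upper <- lo + runif(1, 0.5, 8)
    rows[[i]] <- r
  }
  dih <- data.frame(resno = sample(n, n_dih, replace = TRUE),
                    angle = sample(c("phi", "psi"), n_dih, replace = TRUE),
                    target = runif(n_dih, -179, 180),
                    tolerance = runif(n_dih, 5, 30))
  restraint_set(do.call(rbind, rows), dih)
}

# pure-R brute-force target function (independent oracle)
tf_oracle <- function(structure, rset, spec = tf_spec()) {
  w <- spec$weights
  xyz <- structure$xyz
  idx <- function(r, a) 6 * (r - 1) + match(a, c("N", "CA", "C", "O", "CB", "SC"))
  tf <- 0
  d <- rset$distance
  for (id in unique(d$id)) {
    rows <- d[d$id == id, , drop = FALSE]
    dists <- sapply(seq_len(nrow(rows)), function(k)
      sqrt(sum((xyz[idx(rows$res_i[k], rows$atom_i[k]), ] -
                xyz[idx(rows$res_j[k], rows$atom_j[k]), ])^2)))
    deff <- if (length(dists) == 1) dists else sum(dists^-6)^(-1 / 6)
    if (deff > rows$upper[1]) tf <- tf + w[1] * (deff - rows$upper[1])^2
    if (deff < rows$lower[1]) tf <- tf + w[2] * (rows$lower[1] - deff)^2
  }
  tors <- backbone_dihedrals(structure)
  for (k in seq_len(nrow(rset$dihedral))) {
    dh <- rset$dihedral[k, ]
    if (dh$angle == "phi" && dh$resno == 1) next
    ang <- tors[dh$resno, dh$angle]
    v <- abs(emnmr:::wrap180(ang - dh$target)) - dh$tolerance
    if (v > 0) tf <- tf + w[3] * v^2
  }
  # steric: CA and SC atoms, sequence separation >= 2
  sel <- which(structure$atom %in% c("CA", "SC"))
  for (a in seq_along(sel)) for (b in seq_along(sel)) {
    if (b <= a) next
    ra <- structure$resno[sel[a]]; rb <- structure$resno[sel[b]]
    if (abs(rb - ra) < 2) next
    dd <- sqrt(sum((xyz[sel[a], ] - xyz[sel[b], ])^2))
    if (dd < spec$steric_radius) tf <- tf + w[4] * (spec$steric_radius - dd)^2
  }
  unname(tf)
}

# brute-force injective enumeration (independent oracle for assignment counts)
enumerate_oracle <- function(n_seq, n_dens, ok = NULL) {
  maps <- list()
  rec <- function(depth, used, cur) {
    if (depth > n_dens) { maps[[length(maps) + 1]] <<- cur; return() }
    for (s in seq_len(n_seq)) {
      if (s %in% used) next
      if (!is.null(ok) && !ok[depth, s]) next
      rec(depth + 1, c(used, s), c(cur, s))
    }
  }
  rec(1, integer(0), integer(0))
  maps
}
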