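# Synthetic benchmark generator: ground-truth helical-bundle folds, density
# maps, and restraint sets with the statistical structure the protocol
# assumes (sparse sub-8 A contacts, partial ambiguity, optional
# inter-subunit contamination).

#' Generate a compact helical-bundle fold
#'
#' Ideal alpha-helices (phi, psi = -57, -47) joined by loops whose torsions
#' are drawn from allowed coil regions. Loops are built best-of-K per loop
#' (seeded): candidate torsion sets are scored by compactness and clash
#' rejection, and the whole fold is rejected unless the minimum non-bonded
#' atom distance exceeds 2.5 A and the radius of gyration stays below
#' 1.2 x that of an ideal packed bundle of the same helices.
#'
#' @param n_helices number of helices (>= 1).
#' @param helix_len_res helix lengths in residues (recycled).
#' @param loop_len_res loop lengths in residues (recycled).
#' @param seed RNG seed; output is deterministic per seed.
#' @param max_restarts fold-level rejection cap.
#' @param n_cand loop candidates tried per loop.
#' @return list with \code{structure} (an \code{em_structure}) and
#'   \code{ss} (secondary-structure string over H/C).
#' @export
make_toy_fold <- function(n_helices, helix_len_res = 12, loop_len_res = 5,
                          seed = 1, max_restarts = 400, n_cand = 60) {
  stopifnot(n_helices >= 1)
  hl <- rep_len(helix_len_res, n_helices)
  ll <- rep_len(loop_len_res, max(n_helices - 1, 0))
  ss <- character(0)
  for (i in seq_len(n_helices)) {
    ss <- c(ss, rep("H", hl[i]))
    if (i < n_helices) ss <- c(ss, rep("C", ll[i]))
  }
  n <- length(ss)
  rg_max <- 1.2 * ideal_bundle_rg(hl, ll)
  set.seed(seed)
  coil_basins <- matrix(c(-65, 145, -120, 130, -75, 160, -100, -10, -150, 155),
                        ncol = 2, byrow = TRUE)
  for (attempt in seq_len(max_restarts)) {
    dihed <- matrix(0, n, 2)
    dihed[ss == "H", 1] <- -57
    dihed[ss == "H", 2] <- -47
    pos <- 1
    ok <- TRUE
    for (i in seq_len(n_helices)) {
      pos <- pos + hl[i]
      if (i == n_helices) break
      loop_idx <- seq(pos, pos + ll[i] - 1)
      # look ahead through the whole next helix so clashes are caught early
      built_to <- loop_idx[length(loop_idx)] + hl[i + 1]
      best_sc <- Inf; best_ang <- NULL
      for (cand in seq_len(n_cand)) {
        bas <- coil_basins[sample.int(nrow(coil_basins), ll[i], replace = TRUE), ,
                           drop = FALSE]
        ang <- bas + matrix(rnorm(2 * ll[i], 0, 18), ll[i], 2)
        ang <- wrap180(ang)
        trial <- dihed
        trial[loop_idx, ] <- ang
        sub <- trial[seq_len(built_to), , drop = FALSE]
        xyz <- build_chain_cpp(sub[, 1], sub[, 2])
        if (min_nonbonded_cpp(xyz, built_to, 2L) <= 2.5) next
        ca <- xyz[6 * (seq_len(built_to) - 1) + 2, , drop = FALSE]
        rg <- sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
        if (rg < best_sc) { best_sc <- rg; best_ang <- ang }
      }
      if (is.null(best_ang)) { ok <- FALSE; break }
      dihed[loop_idx, ] <- best_ang
      pos <- pos + ll[i]
    }
    if (!ok) next
    xyz <- build_chain_cpp(dihed[, 1], dihed[, 2])
    if (min_nonbonded_cpp(xyz, n, 2L) <= 2.5) next
    ca <- xyz[6 * (seq_len(n) - 1) + 2, , drop = FALSE]
    rg <- sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
    if (rg >= rg_max) next
    s <- em_structure(xyz, sequence = rep("A", n))
    s$xyz <- sweep(s$xyz, 2, colMeans(s$xyz))  # center at origin
    return(list(structure = s, ss = paste(ss, collapse = ""),
                dihedrals = dihed, attempts = attempt))
  }
  stop("fold generation failed after ", max_restarts,
       " restarts; try shorter helices, longer loops or another seed")
}

# radius of gyration of an idealized packed bundle: helix rods of
# 1.5 A/residue on a ring with 10.5 A nearest-neighbor spacing, with loop
# residues as crossover points just beyond the rod ends
ideal_bundle_rg <- function(hl, ll = rep(5, max(length(hl) - 1, 0)),
                            spacing = 10.5) {
  nh <- length(hl)
  if (nh == 1) { x <- 0; y <- 0 } else {
    ang <- 2 * pi * (seq_len(nh) - 1) / nh
    R <- spacing / (2 * sin(pi / nh))
    x <- R * cos(ang); y <- R * sin(ang)
  }
  pts <- list()
  for (i in seq_len(nh)) {
    z <- seq(-hl[i] * 1.5 / 2, hl[i] * 1.5 / 2, length.out = hl[i])
    pts[[i]] <- cbind(x[i], y[i], z)
  }
  zmax <- max(hl) * 1.5 / 2
  for (i in seq_along(ll)) {
    j <- min(i + 1, nh)
    zi <- if (i %% 2 == 1) zmax + 2 else -zmax - 2
    pts[[length(pts) + 1]] <- cbind(rep((x[i] + x[j]) / 2, ll[i]),
                                    (y[i] + y[j]) / 2, zi)
  }
  P <- do.call(rbind, pts)
  sqrt(mean(rowSums(sweep(P, 2, colMeans(P))^2)))
}

#' Simulate NMR-style restraints from a ground-truth structure
#'
#' Candidate contacts are amide-amide, amide-methyl and methyl-methyl pairs
#' (atom classes N and SC) at sequence separation >= 2 and distance below
#' \code{contact_cutoff}. A seeded \code{coverage} fraction becomes distance
#' restraints with upper = true distance + \code{bound_padding} and lower 0.
#' An \code{ambiguity_rate} fraction is made ambiguous by adding
#' \code{decoy_count} same-class decoy pairs (the true pair is always in the
#' candidate list and is labelled). On assemblies, an
#' \code{inter_subunit_rate} fraction of emitted restraints is replaced by
#' genuine cross-chain contacts and labelled inter-subunit. Helix residues
#' get dihedral restraints at the true (phi, psi) +/- 20 degrees; loops get
#' none.
#'
#' @param truth an \code{em_structure} (the single-chain ground truth).
#' @param ss secondary-structure string for \code{truth}.
#' @param params list: contact_cutoff (8), coverage (0.6), ambiguity_rate
#'   (0.2), decoy_count (2), inter_subunit_rate (0), bound_padding (0.5),
#'   dihedral_tol (20).
#' @param seed RNG seed.
#' @param assembly optional list of chains (the symmetric assembly) used to
#'   harvest genuine inter-subunit contacts.
#' @return list: \code{restraints} (\code{restraint_set}; distance rows carry
#'   an \code{is_true} truth label), \code{inter_ids} (ids of inter-subunit
#'   restraints), \code{truth_table} (bookkeeping counts).
#' @export
simulate_restraints <- function(truth, ss, params = list(), seed = 1,
                                assembly = NULL) {
  p <- modifyList(list(contact_cutoff = 8, coverage = 0.6, ambiguity_rate = 0.2,
                       decoy_count = 2, inter_subunit_rate = 0,
                       bound_padding = 0.5, dihedral_tol = 20), params)
  stopifnot(p$coverage >= 0, p$coverage <= 1,
            p$ambiguity_rate >= 0, p$ambiguity_rate <= 1,
            p$inter_subunit_rate >= 0, p$inter_subunit_rate <= 1)
  set.seed(seed)
  n <- truth$n_res
  cls <- expand.grid(resno = seq_len(n), atom = c("N", "SC"),
                     stringsAsFactors = FALSE)
  idx <- atom_index0(cls$resno, cls$atom) + 1L
  X <- truth$xyz[idx, , drop = FALSE]
  D <- as.matrix(dist(X))
  sep <- abs(outer(cls$resno, cls$resno, `-`))
  cand <- which(upper.tri(D) & D < p$contact_cutoff & sep >= 2, arr.ind = TRUE)
  if (nrow(cand) == 0) stop("no contacts under the cutoff; fold too extended")
  take <- runif(nrow(cand)) < p$coverage
  cand <- cand[take, , drop = FALSE]
  if (nrow(cand) == 0) stop("coverage selected no contacts; raise coverage")
  rows <- list()
  inter_ids <- integer(0)
  n_inter <- if (!is.null(assembly) && length(assembly) > 1)
    sum(runif(nrow(cand)) < p$inter_subunit_rate) else 0
  make_amb <- runif(nrow(cand)) < p$ambiguity_rate
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    d <- D[i, j]
    base <- data.frame(id = k, res_i = cls$resno[i], atom_i = cls$atom[i],
                       res_j = cls$resno[j], atom_j = cls$atom[j],
                       lower = 0, upper = d + p$bound_padding,
                       origin = if (cls$atom[i] == "SC" && cls$atom[j] == "SC")
                         "NOE" else "RFDR",
                       scope = "intra", is_true = TRUE)
    if (make_amb[k]) {
      pool_i <- setdiff(which(cls$atom == cls$atom[i]), c(i, j))
      pool_j <- setdiff(which(cls$atom == cls$atom[j]), c(i, j))
      dec <- cbind(sample(pool_i, p$decoy_count), sample(pool_j, p$decoy_count))
      decrows <- data.frame(id = k, res_i = cls$resno[dec[, 1]],
                            atom_i = cls$atom[dec[, 1]],
                            res_j = cls$resno[dec[, 2]],
                            atom_j = cls$atom[dec[, 2]],
                            lower = 0, upper = d + p$bound_padding,
                            origin = base$origin, scope = "intra",
                            is_true = FALSE)
      grprows <- rbind(base, decrows)
      grprows <- grprows[sample.int(nrow(grprows)), , drop = FALSE]
      rows[[k]] <- grprows
    } else {
      rows[[k]] <- base
    }
  }
  # replace a quota of restraints by genuine cross-chain contacts
  if (n_inter > 0) {
    Xa <- lapply(assembly, function(s) s$xyz[idx, , drop = FALSE])
    inter_pairs <- list()
    for (ci in 2:length(assembly)) {
      DD <- as.matrix(proxy_cross_dist(Xa[[1]], Xa[[ci]]))
      hits <- which(DD < p$contact_cutoff, arr.ind = TRUE)
      if (nrow(hits) > 0) {
        # only pairs whose intra-chain distance genuinely violates the bound
        # (a cross-peak misread as intra-chain implies a wrong long distance)
        intra <- D[hits]
        keep_h <- intra > DD[hits] + p$bound_padding + 1
        hits <- hits[keep_h, , drop = FALSE]
      }
      if (nrow(hits) > 0)
        inter_pairs[[length(inter_pairs) + 1]] <-
          cbind(hits, d = DD[hits], chain = ci)
    }
    if (length(inter_pairs) > 0) {
      ip <- do.call(rbind, inter_pairs)
      pick <- ip[sample.int(nrow(ip), min(n_inter, nrow(ip))), , drop = FALSE]
      repl <- sample(seq_along(rows), nrow(pick))
      for (q in seq_len(nrow(pick))) {
        k <- repl[q]
        i <- pick[q, 1]; j <- pick[q, 2]
        rows[[k]] <- data.frame(id = k, res_i = cls$resno[i], atom_i = cls$atom[i],
                                res_j = cls$resno[j], atom_j = cls$atom[j],
                                lower = 0, upper = pick[q, "d"] + p$bound_padding,
                                origin = "NOE", scope = "inter", is_true = TRUE)
        inter_ids <- c(inter_ids, k)
      }
    }
  }
  dd <- renumber_ids(do.call(rbind, rows))
  inter_ids <- unique(dd$id[dd$scope == "inter"])
  tors <- backbone_dihedrals(truth)
  hres <- which(strsplit(ss, "")[[1]] == "H")
  dih <- do.call(rbind, lapply(hres, function(r) {
    out <- data.frame(resno = r, angle = c("phi", "psi"),
                      target = wrap180(c(tors[r, "phi"], tors[r, "psi"])),
                      tolerance = p$dihedral_tol)
    if (r == 1) out <- out[out$angle != "phi", , drop = FALSE]
    out
  }))
  rs <- restraint_set(dd, dih)
  cc <- classify_restraints(rs)
  list(restraints = rs, inter_ids = inter_ids,
       truth_table = c(cc, list(n_inter = length(inter_ids))))
}

proxy_cross_dist <- function(A, B) {
  sqrt(outer(rowSums(A^2), rep(1, nrow(B))) +
       outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B))
}

#' Standard benchmark cases
#'
#' Composes fold, optional symmetric assembly, simulated map (4.1 A nominal,
#' from which working maps are obtained by Fourier truncation), and restraint
#' set. Shipped cases: \code{mono3} (1 chain, 3 helices), \code{mono5}
#' (1 chain, 5 helices, the step-1 regime), \code{c3} (C3 trimer, 5 helices
#' per chain, with inter-subunit contacts).
#'
#' @param case "mono3", "mono5" or "c3".
#' @param seed RNG seed; the case regenerates bit-exactly from
#'   (case, seed, params).
#' @param params overrides passed to \code{simulate_restraints}.
#' @return list of class \code{em_benchmark}: truth, ss, map (4.1 A), group,
#'   assembly (NULL for monomers), restraints, inter_ids, manifest.
#' @export
make_benchmark <- function(case = c("mono3", "mono5", "c3"), seed = 1,
                           params = list()) {
  case <- match.arg(case)
  spec <- switch(case,
    mono3 = list(n_helices = 3, helix_len = c(16, 12, 9), loop = 5, sym = 1),
    mono5 = list(n_helices = 5, helix_len = c(19, 16, 13, 10, 8), loop = 5, sym = 1),
    c3    = list(n_helices = 5, helix_len = c(19, 16, 13, 10, 8), loop = 5, sym = 3))
  fold <- make_toy_fold(spec$n_helices, spec$helix_len, spec$loop,
                        seed = substream_seed(seed, paste0("fold-", case)))
  truth <- fold$structure
  group <- NULL; assembly <- NULL
  map_source <- truth
  if (spec$sym > 1) {
    group <- cyclic_group(spec$sym)
    # push the protomer off-axis to the tightest clash-free packing (keeps a
    # genuine interface so inter-subunit contacts under 8 A exist)
    for (off in seq(14, 60, by = 2)) {
      t <- truth
      t$xyz <- sweep(truth$xyz, 2, -c(off, 0, 0))
      asm <- apply_symmetry(t, group)
      dmin <- min(proxy_cross_dist(asm[[1]]$xyz, asm[[2]]$xyz))
      if (dmin > 3) { truth <- t; assembly <- asm; break }
    }
    if (is.null(assembly)) stop("could not place clash-free symmetric assembly")
    map_source <- assembly
  }
  map <- simulate_map(map_source, resolution = 4.1, voxel = 1.6)
  sim <- simulate_restraints(truth, fold$ss,
                             params = modifyList(
                               list(inter_subunit_rate = if (spec$sym > 1) 0.05 else 0),
                               params),
                             seed = substream_seed(seed, paste0("restr-", case)),
                             assembly = assembly)
  out <- list(case = case, truth = truth, ss = fold$ss, map = map,
              group = group, assembly = assembly,
              restraints = sim$restraints, inter_ids = sim$inter_ids,
              manifest = list(case = case, seed = seed, params = params,
                              helix_len = spec$helix_len, loop = spec$loop,
                              sym = spec$sym, voxel = 1.6, map_resolution = 4.1))
  class(out) <- "em_benchmark"
  out
}

#' Write a benchmark case to a directory
#'
#' Writes truth.pdb, map.mrc, restraints.json (+ .upl/.aco exports), ss.txt
#' and manifest.json.
#'
#' @param bench an \code{em_benchmark}.
#' @param dir output directory (created if absent).
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_structure_pdb(bench$truth, file.path(dir, "truth.pdb"))
  write_map(bench$map, file.path(dir, "map.mrc"))
  write_restraints(bench$restraints, file.path(dir, "restraints.json"), "json")
  write_restraints(bench$restraints, file.path(dir, "restraints.upl"), "upl")
  write_restraints(bench$restraints, file.path(dir, "restraints.aco"), "aco")
  writeLines(bench$ss, file.path(dir, "ss.txt"))
  jsonlite::write_json(bench$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
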