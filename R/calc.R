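# Computational engines: restraint target function, torsion-space restrained
# simulated annealing, hypothesis ranking, and density-gradient flexible
# fitting.

#' Target-function specification
#'
#' Flat-bottom quadratic penalties: upper/lower distance-bound violations,
#' dihedral violations beyond the tolerance, and steric overlap below a
#' minimum approach distance (evaluated over CA and SC atoms at sequence
#' separation >= 2). Ambiguous distances use the r^-6-summed effective
#' distance over candidates.
#'
#' @param w_upper,w_lower,w_dihedral,w_steric nonnegative term weights
#'   (dihedral violations are in degrees; its default weight 0.05 puts a
#'   5-degree violation on the scale of a 1 A distance violation).
#' @param steric_radius minimum approach distance in Angstrom (default 2.5).
#' @return object of class \code{tf_spec}.
#' @export
tf_spec <- function(w_upper = 1, w_lower = 1, w_dihedral = 0.05,
                    w_steric = 1, steric_radius = 2.5) {
  w <- c(w_upper, w_lower, w_dihedral, w_steric)
  if (any(w < 0) || all(w == 0)) stop("weights must be >= 0 with at least one positive")
  structure(list(weights = w, steric_radius = steric_radius), class = "tf_spec")
}

#' Restraint target function of a structure
#'
#' @param structure an \code{em_structure}.
#' @param rset a \code{restraint_set}.
#' @param spec a \code{tf_spec}.
#' @return nonnegative target-function value; 0 iff every restraint is
#'   satisfied and no steric overlap exists.
#' @export
target_function <- function(structure, rset, spec = tf_spec()) {
  rc <- restraints_to_cpp(rset, structure$n_res)
  target_function_cpp(structure$xyz, structure$n_res,
                      rc$grp, rc$ai, rc$aj, rc$lower, rc$upper,
                      rc$dres, rc$dtyp, rc$dtarget, rc$dtol,
                      spec$weights, spec$steric_radius)
}

#' Restrained simulated annealing in torsion space
#'
#' Computes an ensemble of conformers by simulated annealing over backbone
#' torsions with ideal covalent geometry guaranteed by construction. Each
#' conformer starts from random seeded (phi, psi), runs \code{anneal_steps}
#' Metropolis moves under a geometric temperature schedule, then a zero-
#' temperature quench of half that length. The \code{n_keep} lowest-target-
#' function conformers are returned sorted ascending. Fully reproducible
#' given the seed. Conformers whose final target function exceeds
#' 1e6 x (restraint count) are flagged divergent; a run with more than half
#' flagged is marked diverged.
#'
#' @param sequence one-letter codes or residue count.
#' @param rset \code{restraint_set} (must reference the sequence topology).
#' @param config \code{protocol_config} (n_conformers, anneal_steps, n_keep,
#'   seed).
#' @param spec \code{tf_spec}.
#' @param seed optional override of config$seed.
#' @param init optional starting point: an \code{em_structure} (or n x 2
#'   torsion matrix). When given, every conformer starts from these torsions
#'   perturbed by \code{init_noise} degrees instead of from random torsions.
#' @param init_noise per-angle start perturbation in degrees (default 20).
#' @param therm_noise hot-phase thermal noise amplitude in degrees (default:
#'   6 for random starts, 2.5 for seeded starts; use smaller values for
#'   gentle local refinement).
#' @return \code{em_ensemble} with attributes \code{diverged} (logical),
#'   \code{n_diverged}, \code{all_energies}.
#' @export
anneal <- function(sequence, rset, config = protocol_config(),
                   spec = tf_spec(), seed = NULL, init = NULL,
                   init_noise = 20, therm_noise = NULL) {
  if (is.numeric(sequence) && length(sequence) == 1)
    sequence <- rep("A", as.integer(sequence))
  n_res <- length(sequence)
  rc <- restraints_to_cpp(rset, n_res)
  n_restr <- max(1, length(rc$lower) + length(rc$dres))
  if (is.null(seed)) seed <- substream_seed(config$seed, "anneal")
  init_phi <- numeric(0); init_psi <- numeric(0)
  if (!is.null(init)) {
    tors <- if (inherits(init, "em_structure")) backbone_dihedrals(init)
            else as.matrix(init)
    stopifnot(nrow(tors) == n_res)
    init_phi <- tors[, 1]; init_phi[1] <- 0
    init_psi <- tors[, 2]
  }
  res <- anneal_cpp(n_res, rc$grp, rc$ai, rc$aj, rc$lower, rc$upper,
                    rc$dres, rc$dtyp, rc$dtarget, rc$dtol,
                    spec$weights, spec$steric_radius,
                    config$n_conformers, config$anneal_steps, config$n_keep,
                    as.integer(seed), 1e6 * n_restr,
                    init_phi, init_psi, init_noise,
                    if (!is.null(therm_noise)) therm_noise
                    else if (is.null(init)) 6.0 else 2.5)
  confs <- lapply(res$coords, em_structure, sequence = sequence)
  ens <- em_ensemble(confs, res$energies)
  attr(ens, "n_diverged") <- sum(res$diverged)
  attr(ens, "diverged") <- mean(res$diverged) > 0.5
  attr(ens, "all_energies") <- res$all_energies
  ens
}

#' Score and rank assignment hypotheses
#'
#' Each hypothesis is scored by (i) the mean target function over its kept
#' conformers and (ii) the overlap fraction: the share of assigned-helix
#' residues whose per-residue correlation with the helices-only region of
#' the experimental map exceeds the threshold, averaged over the kept
#' lowest-energy conformers (each placed by rigid superposition of its
#' pinned helix-center CAs onto the density centers; averaging over the
#' retained bundle rather than a single conformer makes the score robust to
#' conformer noise). Diverged runs are excluded from the ranking but kept in
#' the report. Ranking: Pareto dominance on (low TF, high overlap), ties
#' broken by the min-max-normalized score sum, then by hypothesis id.
#'
#' @param hypotheses list from \code{enumerate_assignments}.
#' @param ensembles list of \code{em_ensemble}s, one per hypothesis.
#' @param map experimental \code{density_map} (working resolution).
#' @param densities detected-helix table the hypotheses refer to.
#' @param seq_helices sequence-helix table.
#' @param config \code{protocol_config}.
#' @return data.frame (one row per hypothesis) with columns id, tf,
#'   overlap_fraction, diverged, rank (NA for diverged), ordered by rank.
#' @export
score_and_rank <- function(hypotheses, ensembles, map, densities, seq_helices,
                           config = protocol_config()) {
  stopifnot(length(hypotheses) == length(ensembles))
  res_rows <- lapply(seq_along(hypotheses), function(i) {
    hyp <- hypotheses[[i]]
    ens <- ensembles[[i]]
    diverged <- isTRUE(attr(ens, "diverged"))
    tfm <- mean(ens$energies)
    ov <- NA_real_
    if (!diverged) {
      use <- order(ens$energies)[seq_len(min(length(ens$conformers), 5))]
      ov <- mean(vapply(use, function(k)
        hypothesis_overlap(hyp, ens$conformers[[k]], map, densities,
                           seq_helices, threshold = config$overlap_threshold),
        numeric(1)))
    }
    data.frame(id = if (!is.null(hyp$id)) hyp$id else i, tf = tfm,
               overlap_fraction = ov, diverged = diverged)
  })
  rank_scorecards(do.call(rbind, res_rows))
}

# Pareto dominance on (low TF, high overlap); ties by min-max normalized
# score sum, then hypothesis id; diverged rows stay unranked
rank_scorecards <- function(sc) {
  ok <- which(!sc$diverged & is.finite(sc$tf))
  sc$rank <- NA_integer_
  if (length(ok) > 0) {
    tfv <- sc$tf[ok]; ovv <- sc$overlap_fraction[ok]
    dominated <- vapply(seq_along(ok), function(a) {
      any(tfv <= tfv[a] & ovv >= ovv[a] & (tfv < tfv[a] | ovv > ovv[a]))
    }, logical(1))
    rtf <- (tfv - min(tfv)) / max(max(tfv) - min(tfv), 1e-12)
    rov <- (max(ovv) - ovv) / max(max(ovv) - min(ovv), 1e-12)
    key <- order(dominated, rtf + rov, sc$id[ok])
    sc$rank[ok[key]] <- seq_along(ok)
  }
  sc[order(is.na(sc$rank), sc$rank), , drop = FALSE]
}

# overlap fraction of assigned helix residues against the helices-only map
# region, after placing the conformer by its pinned CAs
hypothesis_overlap <- function(hyp, conformer, map, densities, seq_helices,
                               threshold = 0.7) {
  nd <- length(hyp$mapping)
  cen <- as.matrix(densities[seq_len(nd), c("cx", "cy", "cz")])
  pin_res <- seq_helices$central_residue[hyp$mapping]
  idx <- atom_index0(pin_res, rep("CA", nd)) + 1L
  if (nd >= 3) {
    k <- kabsch(conformer$xyz[idx, , drop = FALSE], cen)
    s <- conformer
    s$xyz <- t(k$R %*% t(conformer$xyz)) +
      matrix(k$t, nrow(conformer$xyz), 3, byrow = TRUE)
  } else s <- conformer
  helix_res <- unlist(lapply(hyp$mapping, function(m)
    seq(seq_helices$start[m], seq_helices$end[m])))
  hmask <- helices_mask(map, densities[seq_len(nd), , drop = FALSE])
  masked <- map
  masked$grid <- map$grid * hmask
  ov <- per_residue_overlap(s, masked, map$nominal_resolution,
                            residues = helix_res)
  mean(ov$correlation > threshold)
}

# soft cylinder mask (radius 5 A) around detected helices
helices_mask <- function(map, densities) {
  d <- dim(map$grid)
  ax <- map$origin[1] + (seq_len(d[1]) - 1) * map$voxel
  ay <- map$origin[2] + (seq_len(d[2]) - 1) * map$voxel
  az <- map$origin[3] + (seq_len(d[3]) - 1) * map$voxel
  X <- rep(ax, times = d[2] * d[3])
  Y <- rep(rep(ay, each = d[1]), times = d[3])
  Z <- rep(az, each = d[1] * d[2])
  m <- rep(FALSE, length(X))
  for (r in seq_len(nrow(densities))) {
    cen <- as.numeric(densities[r, c("cx", "cy", "cz")])
    u <- as.numeric(densities[r, c("ax", "ay", "az")])
    dx <- X - cen[1]; dy <- Y - cen[2]; dz <- Z - cen[3]
    axial <- dx * u[1] + dy * u[2] + dz * u[3]
    perp2 <- dx^2 + dy^2 + dz^2 - axial^2
    m <- m | (abs(axial) <= densities$length[r] / 2 + 3 & perp2 <= 25)
  }
  array(as.numeric(m), dim = d)
}

#' Flexible fitting of a structure into a density map
#'
#' Moves atoms along the interpolated density gradient with a two-tier
#' elastic-network tether: strong springs between atoms of the same or
#' adjacent residues (preserving local covalent frames and hence backbone
#' torsions) and weak springs between all other pairs closer than
#' \code{en_cutoff} in the start conformation (limiting global distortion
#' while allowing collective motion). Snapshots are scored by model-to-map
#' correlation; the best-correlating snapshot is kept, so the overall
#' correlation never decreases relative to the start. A final
#' bond-projection pass restores covalent bond lengths to within 2 percent
#' of ideal.
#'
#' @param structure an \code{em_structure} placed inside the map.
#' @param map target \code{density_map}.
#' @param n_steps gradient-flow steps (default 150).
#' @param step step size (default 0.3).
#' @param k_elastic weak-tier spring constant (default 0.03).
#' @param k_local strong-tier (local geometry) spring constant (default 0.5).
#' @param w_map gradient weight (default 1).
#' @param en_cutoff elastic-network distance cutoff in Angstrom.
#' @return the fitted \code{em_structure}, with attribute \code{correlation}
#'   = c(start, end) model-to-map correlations.
#' @export
flexible_fit <- function(structure, map, n_steps = 150, step = 0.3,
                         k_elastic = 0.03, k_local = 0.5, w_map = 1,
                         en_cutoff = 10) {
  xyz <- structure$xyz
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  glo <- map$origin; ghi <- map$origin + (dim(map$grid) - 1) * map$voxel
  if (any(lo < glo - 4 * map$voxel) || any(hi > ghi + 4 * map$voxel))
    stop("structure lies outside the map")
  D <- as.matrix(dist(xyz))
  pr <- which(upper.tri(D) & D < en_cutoff, arr.ind = TRUE)
  sep <- abs(structure$resno[pr[, 1]] - structure$resno[pr[, 2]])
  kk <- ifelse(sep <= 1, k_local, k_elastic)
  snaps <- flexfit_cpp(xyz, as.numeric(map$grid), dim(map$grid), map$origin,
                       map$voxel, pr[, 1] - 1L, pr[, 2] - 1L, D[pr],
                       kk, w_map, n_steps, step, every = 10L)
  res_n <- structure$n_res
  cors <- vapply(snaps, function(m) {
    sim <- simulate_map(m, map$nominal_resolution, grid_like = map)
    model_map_correlation_grid(sim, map)
  }, numeric(1))
  best <- which.max(cors)
  # stop semantics: later snapshots with < 1e-4 extra gain do not displace
  # an earlier, equally good one
  for (k in seq_along(cors)) {
    if (cors[k] >= cors[best] - 1e-4) { best <- k; break }
  }
  out <- structure
  out$xyz <- regularize_bonds_cpp(snaps[[best]], res_n, 60L)
  attr(out, "correlation") <- c(start = cors[1], end = max(cors[1], cors[best]))
  out
}

# correlation of a simulated model map with the experimental map over the
# model's support
model_map_correlation_grid <- function(sim, map) {
  mask <- sim$grid > 1e-3 * max(sim$grid)
  if (sum(mask) < 10) return(-1)
  va <- sim$grid[mask]; vb <- map$grid[mask]
  if (sd(va) == 0 || sd(vb) == 0) return(-1)
  cor(va, vb)
}

#' Model-to-map correlation
#'
#' Simulates a map from the structure on the experimental grid at the map's
#' nominal resolution and computes the Pearson correlation over the model's
#' density support.
#'
#' @param structure an \code{em_structure} or list of them.
#' @param map experimental \code{density_map}.
#' @param resolution optional resolution override.
#' @return correlation in [-1, 1].
#' @export
model_map_correlation <- function(structure, map, resolution = NULL) {
  if (is.null(resolution)) resolution <- map$nominal_resolution
  sim <- simulate_map(structure, resolution, grid_like = map)
  model_map_correlation_grid(sim, map)
}
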