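# Iterative refinement: step 2 (flexible fitting + growing restraint pools)
# and step 3 (symmetry-replicated real-space refinement against a schedule of
# progressively higher-resolution maps).

#' Convergence detector for a bundle-RMSD series
#'
#' The series is converged once \code{cycles} consecutive relative changes
#' |x_k - x_(k-1)| / x_(k-1) are below \code{rel_tol}.
#'
#' @param series numeric vector of per-cycle bundle RMSDs.
#' @param rel_tol relative-change threshold (default 0.10).
#' @param cycles required consecutive converged changes (default 3).
#' @return 1-based index of the series element at which convergence is
#'   established, or NA if never.
#' @export
converged_after <- function(series, rel_tol = 0.10, cycles = 3) {
  if (length(series) < cycles + 1) return(NA_integer_)
  rel <- abs(diff(series)) / head(series, -1)
  ok <- rel < rel_tol
  run <- 0L
  for (k in seq_along(ok)) {
    run <- if (ok[k]) run + 1L else 0L
    if (run >= cycles) return(k + 1L)
  }
  NA_integer_
}

#' Step 2: iterative flexible fitting with growing restraints
#'
#' Starting from a placed seed model, repeats cycles of (i) flexible fitting
#' of the current lowest-TF conformer into the working-resolution map,
#' (ii) per-residue overlap scoring, (iii) regeneration of EM_FIX pairwise
#' position restraints for residues above the overlap threshold, (iv)
#' disambiguation of the ambiguous restraint pool against the current
#' ensemble, and (v) restrained annealing with the grown restraint set.
#' EM_FIX restraints are regenerated each cycle (never accumulated).
#' Disambiguation is likewise re-derived each cycle from the full ambiguous
#' pool (correct resolutions persist through re-derivation; a wrong early
#' call self-corrects) and is attempted only once the ensemble bundle RMSD
#' is below 3 A. Terminates on the 10-percent / 3-cycle bundle-RMSD rule or
#' at the hard cycle cap; the reported result is the most precise cycle.
#'
#' @param seed_structure placed \code{em_structure} from step 1 (in the map
#'   frame).
#' @param map working-resolution \code{density_map}.
#' @param unambiguous \code{restraint_set}: spectrally unambiguous distance
#'   restraints plus dihedral restraints.
#' @param ambiguous \code{restraint_set}: the ambiguous pool.
#' @param config \code{protocol_config}.
#' @param spec \code{tf_spec}.
#' @param seed_ensemble optional ensemble used for the first cycle's
#'   disambiguation (e.g. the step-1 ensemble).
#' @param max_cycles hard cap (default 20; must be positive).
#' @return list: \code{ensemble} (last anneal), \code{structure} (last fitted
#'   lowest-TF conformer, map frame), \code{restraints} (final calculation
#'   set), \code{resolved} (persisted resolved restraints), \code{log}
#'   (per-cycle data.frame), \code{converged}.
#' @export
iterate_step2 <- function(seed_structure, map, unambiguous,
                          ambiguous = restraint_set(),
                          config = protocol_config(), spec = tf_spec(),
                          seed_ensemble = NULL, max_cycles = 12) {
  if (max_cycles <= 0) stop("max_cycles must be positive")
  current <- seed_structure
  ens <- seed_ensemble
  resolved_pool <- restraint_set()
  ambiguous_pool <- ambiguous
  rms_series <- numeric(0)
  log_rows <- list()
  cycles <- list()
  prev_bundle <- Inf
  for (cyc in seq_len(max_cycles)) {
    fitted <- project_to_torsions(flexible_fit(current, map))
    ov <- per_residue_overlap(fitted, map, map$nominal_resolution)
    flagged <- ov$resno[ov$correlation > config$overlap_threshold]
    emfix <- fix_positions(fitted, flagged, tol = config$fix_tolerance,
                           seed = substream_seed(config$seed, paste0("emfix", cyc)))
    # ambiguous restraints are re-resolved each cycle against the current
    # ensemble (self-correcting), and only once the ensemble is precise
    # enough (< 3 A bundle) for the distance measurements to be trustworthy
    resolved_pool <- restraint_set()
    still_pool <- ambiguous_pool
    if (!is.null(ens) && n_distance_restraints(ambiguous_pool) > 0 &&
        prev_bundle < 3) {
      da <- disambiguate(ambiguous_pool, ens, cutoff = config$disambig_cutoff,
                         n_models = config$n_keep)
      resolved_pool <- da$resolved
      still_pool <- da$still_ambiguous
    }
    # unresolved ambiguous restraints stay OUT of the calculation set: used
    # as r^-6 groups they reward decoy contacts and distort the fold, which
    # is why hard disambiguation converges better
    full <- merge_restraints(unambiguous, resolved_pool, emfix)
    ens <- anneal(fitted$sequence, full, config, spec,
                  seed = substream_seed(config$seed, paste0("step2-", cyc)),
                  init = fitted, init_noise = 5, therm_noise = 1.5)
    best <- ens$conformers[[which.min(ens$energies)]]
    current <- superpose(best, fitted, selection = "CA")$mobile_fitted
    prev_bundle <- bundle_rmsd(ens)
    rms_series <- c(rms_series, prev_bundle)
    cycles[[cyc]] <- list(ensemble = ens, structure = current, restraints = full,
                          resolved = resolved_pool, bundle = prev_bundle,
                          corr = model_map_correlation(current, map))
    log_rows[[cyc]] <- data.frame(
      cycle = cyc, bundle_rmsd = prev_bundle,
      correlation = cycles[[cyc]]$corr,
      n_flagged = length(flagged),
      n_emfix = n_distance_restraints(emfix),
      n_resolved = n_distance_restraints(resolved_pool))
    if (!is.na(converged_after(rms_series, config$convergence_rel_tol,
                               config$convergence_cycles))) break
  }
  conv <- !is.na(converged_after(rms_series, config$convergence_rel_tol,
                                 config$convergence_cycles))
  # the reported model is the most precise cycle (lowest bundle RMSD) among
  # those whose map agreement is near the best observed: precision alone can
  # prefer a tightly-converged but misfitted batch
  corrs <- vapply(cycles, `[[`, numeric(1), "corr")
  eligible <- which(corrs >= max(corrs) - 0.02)
  pick <- cycles[[eligible[which.min(rms_series[eligible])]]]
  list(ensemble = pick$ensemble, structure = pick$structure,
       restraints = pick$restraints, resolved = pick$resolved,
       ambiguous = ambiguous_pool,
       log = do.call(rbind, log_rows), converged = conv,
       best_cycle = which.min(rms_series))
}

#' Step 3: symmetry-replicated real-space refinement
#'
#' Refines a protomer against the full map under strict symmetry: every
#' chain is the exact operator image of the protomer at all times. First a
#' small rigid-body search (translations plus rotations about the symmetry
#' axes) maximizes the assembly-to-map correlation. Then, per resolution of
#' the schedule (coarse to fine), the protomer is (i) flexibly fitted into
#' the map at that resolution (density-gradient flow with an elastic-network
#' tether), (ii) its well-placed residues (per-residue overlap above the
#' threshold) are encoded as pairwise position restraints, and (iii) an
#' ensemble of \code{n_structures} seeded conformers is re-annealed under
#' all NMR restraints plus those position restraints, starting from the
#' fitted model. The lowest-target-function conformer, placed back into the
#' map frame, seeds the next resolution. The combination minimizes restraint
#' violations while driving the model into progressively finer density.
#'
#' @param protomer placed \code{em_structure} (map frame), e.g. from step 2.
#' @param map full-assembly \code{density_map} at its native resolution.
#' @param group \code{symmetry_group}.
#' @param rset all NMR restraints (single-chain).
#' @param config \code{protocol_config}; \code{resolution_schedule} must not
#'   go finer than the map's nominal resolution.
#' @param spec \code{tf_spec}.
#' @param n_steps annealing moves per conformer (default config$anneal_steps).
#' @return list: \code{ensemble} (final-resolution conformers in the map
#'   frame, target function ascending), \code{protomer} (best), \code{assembly}
#'   (chains of the best protomer), \code{log} (per-resolution record).
#' @export
refine_step3 <- function(protomer, map, group = symmetry_group(list(diag(3))),
                         rset, config = protocol_config(), spec = tf_spec(),
                         n_steps = NULL) {
  sched <- config$resolution_schedule
  if (!is.na(map$nominal_resolution) && any(sched < map$nominal_resolution - 1e-9))
    stop("resolution schedule finer than the map's nominal resolution")
  if (is.null(n_steps)) n_steps <- config$anneal_steps
  nmr <- drop_virtual(rset)

  # rigid-body placement: small translation grid + rotations about symmetry axes
  current <- rigid_place(protomer, map, group)

  # overlap flagging is calibrated at the 8 A working resolution (per-residue
  # correlations at finer resolutions are too strict for a ~2 A model)
  flag_res <- max(sched[1], 8)
  flag_map <- if (abs(flag_res - ifelse(is.na(map$nominal_resolution), flag_res,
                                        map$nominal_resolution)) < 1e-9) map
              else fourier_truncate(map, flag_res)
  log_rows <- list()
  rc <- restraints_to_cpp(nmr, protomer$n_res)
  opm <- ops_matrix(group)
  w_map <- 2
  # schedule-sanity trust region: refinement at a finer resolution is only
  # accepted if it does not degrade the model-to-map correlation measured at
  # the coarsest (working) resolution
  cor_ref <- function(s) model_map_correlation(apply_symmetry(s, group), flag_map)
  cur_cor <- cor_ref(current)
  for (ri in seq_along(sched)) {
    mapk <- if (!is.na(map$nominal_resolution) &&
                abs(sched[ri] - map$nominal_resolution) < 1e-9) map
            else fourier_truncate(map, sched[ri])
    mapk <- normalize_map(mapk)
    # alternate Cartesian fitting with joint torsion+pose gradient descent
    # on E = TF + w_map * sum(-rho): the fit escapes the GD's local minima
    # and vice versa
    cand <- current
    for (mc in 1:2) {
      cand <- project_to_torsions(flexible_fit(cand, mapk))
      cand <- gd_refine(cand, mapk, rc, opm, spec, w_map)
    }
    cc <- cor_ref(cand)
    accepted <- cc >= cur_cor - 0.005
    if (accepted) { current <- cand; cur_cor <- max(cur_cor, cc) }
    log_rows[[ri]] <- data.frame(
      resolution = sched[ri], accepted = accepted,
      tf = target_function(current, nmr, spec),
      correlation = model_map_correlation(apply_symmetry(current, group), mapk))
  }
  # ensemble stage at the final resolution: seeded map-aware annealing with a
  # loose leash (pins on well-placed residues, tol 2 x fix tolerance) so the
  # conformers explore register shifts without melting the fold
  mapf <- normalize_map(if (!is.na(map$nominal_resolution) &&
                            abs(sched[length(sched)] - map$nominal_resolution) < 1e-9)
                          map else fourier_truncate(map, sched[length(sched)]))
  ov <- per_residue_overlap(current, flag_map, flag_res)
  cores <- ov$resno[ov$correlation > config$overlap_threshold]
  pins <- fix_positions(current, cores, tol = 2 * config$fix_tolerance,
                        seed = substream_seed(config$seed, "s3pins"))
  full <- merge_restraints(nmr, pins)
  rcp <- restraints_to_cpp(full, protomer$n_res)
  tors <- backbone_dihedrals(current)
  phi <- tors[, 1]; phi[1] <- 0
  loc <- build_chain_cpp(phi, tors[, 2])
  kk <- kabsch(sweep(loc, 2, colMeans(loc)), current$xyz)
  cen <- colMeans(current$xyz)
  n_out <- max(config$n_structures, 2)
  n_try <- max(2 * n_out, 8L)
  am <- anneal_map_cpp(phi, tors[, 2], kk$R, cen, c(0, 0, 0),
                       rcp$grp, rcp$ai, rcp$aj, rcp$lower, rcp$upper,
                       rcp$dres, rcp$dtyp, rcp$dtarget, rcp$dtol,
                       spec$weights, spec$steric_radius,
                       as.numeric(mapf$grid), dim(mapf$grid), mapf$origin,
                       mapf$voxel, opm, w_map,
                       n_try, as.integer(n_steps), n_try,
                       substream_seed(config$seed, "step3-ens"), 0.6, 0.6)
  confs <- list(); energies <- numeric(0)
  for (k in seq_len(n_try)) {
    q <- quench_map_cpp(am$phi[[k]], am$psi[[k]], kk$R, cen, c(0, 0, 0),
                        rcp$grp, rcp$ai, rcp$aj, rcp$lower, rcp$upper,
                        rcp$dres, rcp$dtyp, rcp$dtarget, rcp$dtol,
                        spec$weights, spec$steric_radius,
                        as.numeric(mapf$grid), dim(mapf$grid), mapf$origin,
                        mapf$voxel, opm, w_map, 300L)
    confs[[k]] <- em_structure(q$coords, sequence = current$sequence,
                               chain = current$chain)
    energies[k] <- q$energy
  }
  # keep the lowest-energy quenched conformers that pass the same
  # coarse-correlation trust region; the guarded current model is always a
  # candidate, so the ensemble stage can never degrade the result
  pass <- vapply(confs, function(s) cor_ref(s) >= cur_cor - 0.005, logical(1))
  confs <- c(list(current), confs[pass])
  energies <- c(gd_energy(current, mapf, rcp, opm, spec, w_map),
                energies[pass])
  ord <- head(order(energies), n_out)
  final <- em_ensemble(confs[ord], energies[ord])
  current <- final$conformers[[1]]
  cur_cor <- max(cur_cor, cor_ref(current))
  log_rows[[length(log_rows) + 1]] <- data.frame(
    resolution = sched[length(sched)], accepted = any(pass),
    tf = target_function(current, nmr, spec),
    correlation = model_map_correlation(apply_symmetry(current, group), mapf))
  list(ensemble = final,
       protomer = current,
       assembly = apply_symmetry(current, group),
       log = do.call(rbind, log_rows))
}

# combined energy TF + w_map * sum(-rho) of a placed structure
gd_energy <- function(s, mapk, rc, opm, spec, w_map) {
  tors <- backbone_dihedrals(s)
  phi <- tors[, 1]; phi[1] <- 0
  loc <- build_chain_cpp(phi, tors[, 2])
  kk <- kabsch(sweep(loc, 2, colMeans(loc)), s$xyz)
  q <- quench_map_cpp(phi, tors[, 2], kk$R, colMeans(s$xyz), c(0, 0, 0),
                      rc$grp, rc$ai, rc$aj, rc$lower, rc$upper,
                      rc$dres, rc$dtyp, rc$dtarget, rc$dtol,
                      spec$weights, spec$steric_radius,
                      as.numeric(mapk$grid), dim(mapk$grid), mapk$origin,
                      mapk$voxel, opm, w_map, 0L)
  q$energy
}

# joint torsion + rigid-pose backtracking gradient descent against a map
gd_refine <- function(s, mapk, rc, opm, spec, w_map, iters = 400) {
  tors <- backbone_dihedrals(s)
  phi <- tors[, 1]; phi[1] <- 0
  loc <- build_chain_cpp(phi, tors[, 2])
  kk <- kabsch(sweep(loc, 2, colMeans(loc)), s$xyz)
  q <- quench_map_cpp(phi, tors[, 2], kk$R, colMeans(s$xyz), c(0, 0, 0),
                      rc$grp, rc$ai, rc$aj, rc$lower, rc$upper,
                      rc$dres, rc$dtyp, rc$dtarget, rc$dtol,
                      spec$weights, spec$steric_radius,
                      as.numeric(mapk$grid), dim(mapk$grid), mapk$origin,
                      mapk$voxel, opm, w_map, as.integer(iters))
  em_structure(q$coords, sequence = s$sequence, chain = s$chain)
}

# scale a map so its peak level is ~1 (makes map-energy weights transferable)
normalize_map <- function(map) {
  sc <- quantile(abs(map$grid), 0.999)
  if (sc > 0) map$grid <- map$grid / sc
  map
}

drop_virtual <- function(rset) {
  d <- rset$distance
  if (nrow(d) > 0) d <- d[d$res_i >= 1 & d$res_j >= 1, , drop = FALSE]
  restraint_set(renumber_ids(d), rset$dihedral)
}

# small rigid-body search maximizing assembly-to-map correlation
rigid_place <- function(protomer, map, group, trans_grid = c(-2, 0, 2),
                        rot_grid = c(-4, 0, 4)) {
  axes <- unique_axes(group)
  cen <- colMeans(protomer$xyz)
  best <- protomer
  best_cor <- -Inf
  cands <- list(list(R = diag(3)))
  for (ax in axes) for (ang in rot_grid) {
    if (ang != 0) cands <- c(cands, list(list(R = rot_about(ax, ang))))
  }
  for (cand in cands) {
    base <- protomer
    base$xyz <- t(cand$R %*% t(protomer$xyz))
    for (dx in trans_grid) for (dy in trans_grid) for (dz in trans_grid) {
      s <- base
      s$xyz <- sweep(base$xyz, 2, -c(dx, dy, dz))
      cc <- tryCatch(model_map_correlation(apply_symmetry(s, group), map),
                     error = function(e) -Inf)
      if (cc > best_cor) { best_cor <- cc; best <- s }
    }
  }
  attr(best, "placement_correlation") <- best_cor
  best
}

# rotation axes of the non-identity operators (for the rigid search)
unique_axes <- function(group) {
  axes <- list()
  for (op in group$operators) {
    R <- op$R
    if (max(abs(R - diag(3))) < 1e-8) next
    ev <- eigen(R)
    k <- which.min(abs(ev$values - 1))
    ax <- Re(ev$vectors[, k])
    ax <- ax / sqrt(sum(ax^2))
    dup <- any(vapply(axes, function(a) abs(sum(a * ax)) > 0.999, logical(1)))
    if (!dup) axes[[length(axes) + 1]] <- ax
  }
  if (length(axes) == 0) axes <- list(c(0, 0, 1))
  axes
}
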