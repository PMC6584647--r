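# Coordinate model: reduced-backbone structures, conformer ensembles,
# superposition and bundle precision.

ATOM_SLOTS <- c("N", "CA", "C", "O", "CB", "SC")

#' Reduced-backbone structure
#'
#' A structure holds one chain at reduced representation: per residue the
#' backbone N, CA, C, O atoms plus CB and a single side-chain centroid
#' pseudo-atom SC (the carrier of methyl-borne distance restraints).
#'
#' @param xyz numeric matrix (6 * n_res) x 3 of coordinates in Angstrom,
#'   ordered residue-by-residue with atom slots N, CA, C, O, CB, SC.
#' @param sequence character vector of one-letter residue codes (recycled to
#'   the residue count if length 1).
#' @param chain single chain identifier.
#' @return object of class \code{em_structure}.
#' @export
em_structure <- function(xyz, sequence = "A", chain = "A") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 || nrow(xyz) %% 6 != 0)
    stop("xyz must be a (6*n_res) x 3 matrix in N,CA,C,O,CB,SC slot order")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  n_res <- nrow(xyz) / 6
  if (length(sequence) == 1) sequence <- rep(sequence, n_res)
  if (length(sequence) != n_res) stop("sequence length must equal residue count")
  structure(list(xyz = unname(xyz),
                 n_res = as.integer(n_res),
                 atom = rep(ATOM_SLOTS, n_res),
                 resno = rep(seq_len(n_res), each = 6),
                 sequence = sequence,
                 chain = chain),
            class = "em_structure")
}

#' @export
print.em_structure <- function(x, ...) {
  cat(sprintf("em_structure: %d residues (%d atoms), chain %s\n",
              x$n_res, nrow(x$xyz), x$chain))
  invisible(x)
}

# 0-based atom index for C++ kernels
atom_index0 <- function(resno, atom) {
  slot <- match(atom, ATOM_SLOTS)
  if (anyNA(slot)) stop("unknown atom name: ", paste(atom[is.na(slot)], collapse = ", "))
  6L * (as.integer(resno) - 1L) + slot - 1L
}

# rows of structure$xyz for an atom-name selection
select_atoms <- function(structure, selection = "CA") {
  which(structure$atom %in% selection)
}

#' Build an ideal-geometry backbone from torsion angles
#'
#' Constructs a chain with ideal trans-peptide covalent geometry (omega fixed
#' at 180 degrees) from per-residue phi/psi torsions. The phi of the first
#' residue is undefined and ignored; the psi of the last residue only orients
#' its carbonyl oxygen.
#'
#' @param sequence one-letter residue codes, or a single integer residue count.
#' @param dihedrals numeric matrix n x 2 of (phi, psi) in degrees, angles in
#'   (-180, 180].
#' @param chain chain identifier.
#' @return an \code{em_structure}.
#' @examples
#' helix <- build_backbone(21, cbind(rep(-57, 21), rep(-47, 21)))
#' @export
build_backbone <- function(sequence, dihedrals, chain = "A") {
  if (is.numeric(sequence) && length(sequence) == 1) {
    n <- as.integer(sequence); sequence <- rep("A", n)
  }
  n <- length(sequence)
  dihedrals <- as.matrix(dihedrals)
  if (nrow(dihedrals) != n || ncol(dihedrals) != 2)
    stop("dihedrals must be an n x 2 (phi, psi) matrix matching the sequence length")
  if (any(!is.finite(dihedrals)) || any(dihedrals <= -180) || any(dihedrals > 180))
    stop("dihedral angles must lie in (-180, 180]")
  xyz <- build_chain_cpp(dihedrals[, 1], dihedrals[, 2])
  em_structure(xyz, sequence = sequence, chain = chain)
}

#' Backbone torsions of a structure
#'
#' @param structure an \code{em_structure}.
#' @return n x 2 matrix of (phi, psi) in degrees; phi of residue 1 is NA.
#' @export
backbone_dihedrals <- function(structure) {
  out <- dihedrals_from_coords_cpp(structure$xyz, structure$n_res)
  colnames(out) <- c("phi", "psi")
  out
}

#' Project a structure onto the ideal-geometry torsion manifold
#'
#' Extracts backbone torsions, rebuilds an ideal-geometry chain from them,
#' then refines the torsions by gradient descent against tight pairwise
#' distance restraints to the input coordinates (which removes the drift
#' that naive torsion extraction accumulates from residual bond-angle and
#' omega deviations), and superposes the result onto the input. Useful
#' after Cartesian manipulation (e.g. flexible fitting) so that downstream
#' torsion-space calculations start from a state consistent with the
#' coordinates.
#'
#' @param structure an \code{em_structure}.
#' @param refine_iters gradient-descent iterations (default 300; 0 skips the
#'   refinement).
#' @return an \code{em_structure} on the torsion manifold, superposed onto
#'   the input (CA atoms).
#' @export
project_to_torsions <- function(structure, refine_iters = 300) {
  tors <- backbone_dihedrals(structure)
  p <- tors[, 1]; p[1] <- 0
  s <- tors[, 2]
  if (refine_iters > 0) {
    pins <- fix_positions(structure, seq_len(structure$n_res), tol = 0.05,
                          max_near = 8, max_rand = 4, seed = 0L)
    rc <- restraints_to_cpp(pins, structure$n_res)
    q <- quench_cpp(p, s, structure$n_res, rc$grp, rc$ai, rc$aj, rc$lower,
                    rc$upper, rc$dres, rc$dtyp, rc$dtarget, rc$dtol,
                    tf_spec()$weights, 2.5, as.integer(refine_iters))
    p <- q$phi; s <- q$psi
  }
  rebuilt <- em_structure(build_chain_cpp(p, s),
                          sequence = structure$sequence,
                          chain = structure$chain)
  superpose(rebuilt, structure, "CA")$mobile_fitted
}

# Kabsch superposition of paired coordinate sets (rows paired)
kabsch <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cr - as.vector(R %*% cm)
  fitted <- t(R %*% t(mobile)) + matrix(t, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rmsd = rmsd, R = R, t = t, fitted = fitted)
}

#' Least-squares rigid-body superposition
#'
#' Optimal (Kabsch) superposition of \code{mobile} onto \code{reference} over
#' a paired atom selection.
#'
#' @param mobile,reference \code{em_structure}s with equal residue counts, or
#'   plain paired coordinate matrices.
#' @param selection atom names used for the fit (default CA).
#' @return list with \code{rmsd} (Angstrom), rotation \code{R}, translation
#'   \code{t}, and \code{mobile_fitted} (the transformed mobile object).
#' @export
superpose <- function(mobile, reference, selection = "CA") {
  if (inherits(mobile, "em_structure")) {
    im <- select_atoms(mobile, selection)
    ir <- select_atoms(reference, selection)
    if (length(im) != length(ir)) stop("selections yield unequal atom counts")
    if (length(im) < 3) stop("need at least 3 paired atoms to superpose")
    k <- kabsch(mobile$xyz[im, , drop = FALSE], reference$xyz[ir, , drop = FALSE])
    fitted <- mobile
    fitted$xyz <- t(k$R %*% t(mobile$xyz)) +
      matrix(k$t, nrow(mobile$xyz), 3, byrow = TRUE)
    list(rmsd = k$rmsd, R = k$R, t = k$t, mobile_fitted = fitted)
  } else {
    mobile <- as.matrix(mobile); reference <- as.matrix(reference)
    if (nrow(mobile) != nrow(reference)) stop("selections yield unequal atom counts")
    if (nrow(mobile) < 3) stop("need at least 3 paired atoms to superpose")
    k <- kabsch(mobile, reference)
    list(rmsd = k$rmsd, R = k$R, t = k$t, mobile_fitted = k$fitted)
  }
}

#' RMSD between two structures without refitting
#' @param a,b structures with identical topology.
#' @param selection atom names to compare.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b, selection = c("N", "CA", "C", "O")) {
  ia <- select_atoms(a, selection); ib <- select_atoms(b, selection)
  sqrt(mean(rowSums((a$xyz[ia, , drop = FALSE] - b$xyz[ib, , drop = FALSE])^2)))
}

#' Conformer ensemble
#'
#' @param conformers list of \code{em_structure}s sharing one topology.
#' @param energies target-function value per conformer.
#' @return object of class \code{em_ensemble}.
#' @export
em_ensemble <- function(conformers, energies = rep(NA_real_, length(conformers))) {
  if (length(conformers) < 1) stop("empty ensemble")
  n <- vapply(conformers, function(s) nrow(s$xyz), integer(1))
  if (length(unique(n)) != 1) stop("conformers differ in atom count")
  if (length(energies) != length(conformers))
    stop("energies length must equal conformer count")
  structure(list(conformers = conformers, energies = energies),
            class = "em_ensemble")
}

#' @export
print.em_ensemble <- function(x, ...) {
  cat(sprintf("em_ensemble: %d conformers of %d residues; TF range [%.3g, %.3g]\n",
              length(x$conformers), x$conformers[[1]]$n_res,
              suppressWarnings(min(x$energies)), suppressWarnings(max(x$energies))))
  invisible(x)
}

#' Ensemble precision (bundle RMSD to the mean structure)
#'
#' Iteratively superposes every conformer onto the evolving mean coordinates
#' until the mean moves by less than 1e-4 Angstrom, then reports the mean
#' RMSD of the conformers to that mean. Invariant under rigid motion of any
#' conformer.
#'
#' @param ensemble an \code{em_ensemble}.
#' @param selection atom names entering the superposition and the RMSD.
#' @param max_iter safety cap on mean-structure iterations.
#' @return bundle RMSD in Angstrom (0 for a single conformer, with a warning).
#' @export
bundle_rmsd <- function(ensemble, selection = c("N", "CA", "C", "O"),
                        max_iter = 50) {
  confs <- ensemble$conformers
  if (length(confs) == 1) {
    warning("single conformer: bundle RMSD defined as 0")
    return(0)
  }
  sel <- select_atoms(confs[[1]], selection)
  mats <- lapply(confs, function(s) s$xyz[sel, , drop = FALSE])
  ref <- mats[[1]]
  mats <- lapply(mats, function(m) kabsch(m, ref)$fitted)
  mean_xyz <- Reduce(`+`, mats) / length(mats)
  for (it in seq_len(max_iter)) {
    mats <- lapply(mats, function(m) kabsch(m, mean_xyz)$fitted)
    new_mean <- Reduce(`+`, mats) / length(mats)
    shift <- sqrt(mean(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < 1e-4) break
  }
  mean(vapply(mats, function(m) sqrt(mean(rowSums((m - mean_xyz)^2))), numeric(1)))
}

#' Mean structure of an ensemble (after iterative superposition)
#' @inheritParams bundle_rmsd
#' @return an \code{em_structure} with mean coordinates over all atoms.
#' @export
mean_structure <- function(ensemble, max_iter = 50) {
  confs <- ensemble$conformers
  mats <- lapply(confs, function(s) s$xyz)
  ref <- mats[[1]]
  mats <- lapply(mats, function(m) kabsch(m, ref)$fitted)
  mean_xyz <- Reduce(`+`, mats) / length(mats)
  for (it in seq_len(max_iter)) {
    mats <- lapply(mats, function(m) kabsch(m, mean_xyz)$fitted)
    new_mean <- Reduce(`+`, mats) / length(mats)
    shift <- sqrt(mean(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < 1e-4) break
  }
  out <- confs[[1]]
  out$xyz <- mean_xyz
  out
}

# ---------------------------------------------------------------------------
# PDB input/output (via bio3d); SC pseudo-atoms are written as HETATM "SC"
# so files stay parseable by standard tools.

#' Write a structure (or ensemble) as PDB
#'
#' Backbone and CB atoms are written as ATOM records; the SC side-chain
#' centroid pseudo-atom is written as a HETATM named \code{SC}. Ensembles
#' become multi-MODEL files.
#'
#' @param x an \code{em_structure} or \code{em_ensemble}.
#' @param path output file.
#' @export
write_structure_pdb <- function(x, path) {
  if (inherits(x, "em_ensemble")) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(x$conformers)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(pdb_records(x$conformers[[i]]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  writeLines(c(pdb_records(x), "END"), path)
  invisible(path)
}

aa1to3 <- function(a) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- tab[a]
  out[is.na(out)] <- "ALA"
  unname(out)
}

pdb_records <- function(s) {
  n <- nrow(s$xyz)
  res3 <- aa1to3(s$sequence)[s$resno]
  het <- s$atom == "SC"
  sprintf("%-6s%5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          ifelse(het, "HETATM", "ATOM"), seq_len(n),
          formatC(s$atom, width = 3, flag = "-"), res3, s$chain, s$resno,
          s$xyz[, 1], s$xyz[, 2], s$xyz[, 3], 1, 0)
}

#' Read a reduced-backbone PDB written by this package
#'
#' Uses bio3d for parsing; atoms are reordered into the canonical
#' N, CA, C, O, CB, SC slot order. Multi-MODEL files return an ensemble.
#'
#' @param path PDB file.
#' @return an \code{em_structure} or \code{em_ensemble}.
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nm <- trimws(at$elety)
  keep <- nm %in% ATOM_SLOTS
  at <- at[keep, , drop = FALSE]
  nm <- nm[keep]
  resnos <- sort(unique(at$resno))
  slot_of <- match(nm, ATOM_SLOTS)
  ord <- order(match(at$resno, resnos), slot_of)
  at <- at[ord, , drop = FALSE]
  n_res <- length(resnos)
  if (nrow(at) != 6 * n_res) stop("file does not contain the full 6-atom residue model")
  nmodel <- dim(pdb$xyz)[1]
  seq1 <- rep("A", n_res)
  build1 <- function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE][ord, , drop = FALSE]
    em_structure(xyz, sequence = seq1, chain = at$chain[1])
  }
  if (is.null(nmodel) || nmodel == 1) return(build1(1))
  if (nmodel == 1) build1(1)
  else em_ensemble(lapply(seq_len(nmodel), build1))
}
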