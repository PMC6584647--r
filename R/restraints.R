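# Restraint data model, combinatorial helix-to-density assignment, real-space
# information encoded as distance restraints, disambiguation and bookkeeping.
#
# Distance restraints are stored as a data.frame with one row per candidate
# atom pair; candidates of one (possibly ambiguous) restraint share an `id`.
# Columns: id, res_i, atom_i, res_j, atom_j, lower, upper, origin, scope,
# is_true (optional generator truth label).

RESTRAINT_ORIGINS <- c("NOE", "RFDR", "DARR", "EM_FIX", "HELIX_CENTER", "SITE")

#' Restraint set
#'
#' @param distance data.frame of distance-restraint candidate rows (see
#'   package details); may be empty.
#' @param dihedral data.frame with columns resno, angle ("phi"/"psi"),
#'   target, tolerance (degrees); may be empty.
#' @return object of class \code{restraint_set}.
#' @export
restraint_set <- function(distance = empty_distance_df(),
                          dihedral = empty_dihedral_df()) {
  distance <- as.data.frame(distance)
  dihedral <- as.data.frame(dihedral)
  if (nrow(distance) > 0) {
    stopifnot(all(c("id", "res_i", "atom_i", "res_j", "atom_j",
                    "lower", "upper", "origin") %in% names(distance)))
    if (any(distance$lower < 0) || any(distance$upper < distance$lower))
      stop("distance bounds must satisfy 0 <= lower <= upper")
    if (!all(distance$origin %in% RESTRAINT_ORIGINS))
      stop("unknown restraint origin tag")
    if (is.null(distance$scope)) distance$scope <- "unknown"
  }
  if (nrow(dihedral) > 0) {
    stopifnot(all(c("resno", "angle", "target", "tolerance") %in% names(dihedral)))
    if (any(dihedral$tolerance <= 0)) stop("dihedral tolerance must be positive")
    if (any(dihedral$target <= -180 | dihedral$target > 180))
      stop("dihedral targets must lie in (-180, 180]")
  }
  structure(list(distance = distance, dihedral = dihedral),
            class = "restraint_set")
}

empty_distance_df <- function() {
  data.frame(id = integer(0), res_i = integer(0), atom_i = character(0),
             res_j = integer(0), atom_j = character(0),
             lower = numeric(0), upper = numeric(0),
             origin = character(0), scope = character(0))
}

empty_dihedral_df <- function() {
  data.frame(resno = integer(0), angle = character(0),
             target = numeric(0), tolerance = numeric(0))
}

#' @export
print.restraint_set <- function(x, ...) {
  cc <- classify_restraints(x)
  cat(sprintf("restraint_set: %d distance restraints (%d ambiguous), %d dihedral restraints\n",
              cc$total, cc$ambiguous, cc$dihedral))
  invisible(x)
}

n_distance_restraints <- function(rset) length(unique(rset$distance$id))

# relabel ids to 1..n in first-appearance order
renumber_ids <- function(df) {
  if (nrow(df) == 0) return(df)
  df$id <- match(df$id, unique(df$id))
  df
}

#' Merge restraint sets
#' @param ... \code{restraint_set}s.
#' @return one \code{restraint_set} with distance ids renumbered.
#' @export
merge_restraints <- function(...) {
  sets <- list(...)
  dist <- list(); dih <- list()
  off <- 0L
  for (s in sets) {
    d <- s$distance
    if (nrow(d) > 0) {
      d$id <- match(d$id, unique(d$id)) + off
      off <- off + length(unique(d$id))
      dist[[length(dist) + 1]] <- d
    }
    if (nrow(s$dihedral) > 0) dih[[length(dih) + 1]] <- s$dihedral
  }
  restraint_set(
    if (length(dist)) do.call(rbind_fill, dist) else empty_distance_df(),
    if (length(dih)) do.call(rbind, dih) else empty_dihedral_df())
}

rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, dfs)
}

# ---------------------------------------------------------------------------
# combinatorial helix-to-density assignment

#' Closed-form count of helix-to-density assignments
#'
#' Injective placements of sequence helices into density features:
#' n_seq!/(n_seq - n_dens)! ordered arrangements, times 2 per density when
#' helix orientation is distinguished.
#'
#' @param n_seq number of sequence helices.
#' @param n_dens number of density features (<= n_seq).
#' @param oriented whether each placement also carries a 2-fold orientation.
#' @return the count (numeric, exact for desk-scale sizes).
#' @export
count_assignments <- function(n_seq, n_dens, oriented = FALSE) {
  if (n_dens > n_seq) stop("more densities than sequence helices")
  base <- prod(seq(n_seq, by = -1, length.out = n_dens))
  if (oriented) base * 2^n_dens else base
}

#' Enumerate helix-to-density assignment hypotheses
#'
#' All injective mappings from density features to sequence helices, in
#' deterministic lexicographic order (by density index, then sequence-helix
#' index). With \code{prune = TRUE}, mappings are discarded when any assigned
#' pair differs in length by more than \code{length_tol_A} (sequence length
#' in Angstrom uses the 1.5 A/residue rise). Orientation flags (oriented
#' mode) multiply each mapping by 2 per density; with center-only placement
#' they carry no geometric meaning and exist to reproduce the raw
#' combinatorial count.
#'
#' @param seq_helices data.frame from \code{sequence_helices_from_ss}.
#' @param densities data.frame from \code{detect_helices}.
#' @param mode "center" (default) or "oriented".
#' @param length_tol_A pruning tolerance in Angstrom (default 6).
#' @param prune apply the length-match pruning rule.
#' @param max_hypotheses guard against materializing astronomically many
#'   hypotheses (use \code{count_assignments} for counting).
#' @return list of hypotheses: each has \code{mapping} (sequence-helix row
#'   per density row) and, in oriented mode, \code{orientation} (logicals).
#' @export
enumerate_assignments <- function(seq_helices, densities,
                                  mode = c("center", "oriented"),
                                  length_tol_A = 6, prune = TRUE,
                                  max_hypotheses = 200000) {
  mode <- match.arg(mode)
  n_d <- nrow(densities); n_s <- nrow(seq_helices)
  if (n_d < 1) stop("need at least one density feature")
  if (n_d > n_s) stop("more densities than sequence helices")
  raw <- count_assignments(n_s, n_d, mode == "oriented")
  if (!prune && raw > max_hypotheses)
    stop("unpruned enumeration would materialize ", raw,
         " hypotheses; use count_assignments() or enable pruning")
  ok_pair <- outer(seq_len(n_d), seq_len(n_s), function(d, s)
    abs(seq_helices$length_A[s] - densities$length[d]) <= length_tol_A)
  maps <- list()
  assign_rec <- function(depth, used, cur) {
    if (depth > n_d) {
      maps[[length(maps) + 1]] <<- cur
      return(invisible())
    }
    for (s in seq_len(n_s)) {
      if (used[s]) next
      if (prune && !ok_pair[depth, s]) next
      used[s] <- TRUE
      assign_rec(depth + 1, used, c(cur, s))
      used[s] <- FALSE
      if (length(maps) > max_hypotheses)
        stop("hypothesis count exceeds max_hypotheses (", max_hypotheses, ")")
    }
  }
  assign_rec(1, rep(FALSE, n_s), integer(0))
  hyps <- lapply(maps, function(m) list(mapping = m, orientation = NULL))
  if (mode == "oriented") {
    hyps <- unlist(lapply(hyps, function(h) {
      lapply(seq_len(2^n_d) - 1, function(bits) {
        h$orientation <- as.logical(bitwAnd(bitwShiftR(bits, seq_len(n_d) - 1), 1))
        h
      })
    }), recursive = FALSE)
  }
  for (i in seq_along(hyps)) hyps[[i]]$id <- i
  hyps
}

#' Distance restraints pinning assigned helix centers
#'
#' For an assignment hypothesis, the CA atom of the central residue of each
#' assigned sequence helix is pinned to its density center. Real-space pin
#' positions are encoded relatively: one distance restraint per pair of
#' pinned atoms with bounds equal to the Euclidean distance between the two
#' density centers plus/minus the tolerance (the model keeps global
#' translational/rotational freedom).
#'
#' @param hyp one hypothesis from \code{enumerate_assignments}.
#' @param densities,seq_helices the tables the hypothesis refers to.
#' @param tol half-width of the bounds in Angstrom (default 0.5).
#' @return \code{restraint_set} with choose(n, 2) HELIX_CENTER restraints.
#' @export
hypothesis_to_restraints <- function(hyp, densities, seq_helices, tol = 0.5) {
  nd <- length(hyp$mapping)
  if (nd < 2) return(restraint_set())
  cen <- as.matrix(densities[seq_len(nd), c("cx", "cy", "cz")])
  res <- seq_helices$central_residue[hyp$mapping]
  rows <- list()
  id <- 0L
  for (a in seq_len(nd - 1)) for (b in (a + 1):nd) {
    d <- sqrt(sum((cen[a, ] - cen[b, ])^2))
    id <- id + 1L
    rows[[id]] <- data.frame(id = id, res_i = res[a], atom_i = "CA",
                             res_j = res[b], atom_j = "CA",
                             lower = max(0, d - tol), upper = d + tol,
                             origin = "HELIX_CENTER", scope = "intra")
  }
  restraint_set(do.call(rbind, rows))
}

#' Pin well-placed residues by pairwise distance restraints
#'
#' Encodes the current positions of flagged residues (those with good map
#' overlap) as pairwise distance restraints among their backbone N, CA, C
#' atoms with bounds current distance +/- tol. The all-pairs graph is capped:
#' per atom, the \code{max_near} nearest flagged atoms plus \code{max_rand}
#' random longer-range partners (seeded) are kept, which preserves generic
#' rigidity at linear cost.
#'
#' @param structure the structure whose geometry is pinned.
#' @param flagged_residues residue numbers to pin.
#' @param tol bound half-width (default 0.5 A).
#' @param max_near nearest-neighbor quota per atom (default 8).
#' @param max_rand random long-range quota per atom (default 4).
#' @param seed seed for the random quota.
#' @return \code{restraint_set} of EM_FIX restraints.
#' @export
fix_positions <- function(structure, flagged_residues, tol = 0.5,
                          max_near = 8, max_rand = 4, seed = 1L) {
  if (length(flagged_residues) == 0) return(restraint_set())
  bad <- setdiff(flagged_residues, seq_len(structure$n_res))
  if (length(bad) > 0) stop("flagged residues not in structure: ",
                            paste(bad, collapse = ", "))
  atoms <- c("N", "CA", "C")
  tab <- expand.grid(atom = atoms, resno = sort(flagged_residues),
                     stringsAsFactors = FALSE)[, c(2, 1)]
  idx <- atom_index0(tab$resno, tab$atom) + 1L
  X <- structure$xyz[idx, , drop = FALSE]
  n <- nrow(X)
  if (n < 2) return(restraint_set())
  D <- as.matrix(dist(X))
  pairs <- matrix(integer(0), 0, 2)
  set.seed(seed)
  for (a in seq_len(n)) {
    others <- setdiff(seq_len(n), a)
    ord <- others[order(D[a, others])]
    near <- head(ord, max_near)
    rest <- setdiff(ord, near)
    rnd <- if (length(rest) > 0 && max_rand > 0)
      rest[sample.int(length(rest), min(max_rand, length(rest)))] else integer(0)
    sel <- c(near, rnd)
    pairs <- rbind(pairs, cbind(pmin(a, sel), pmax(a, sel)))
  }
  pairs <- unique(pairs)
  d <- D[pairs]
  df <- data.frame(id = seq_len(nrow(pairs)),
                   res_i = tab$resno[pairs[, 1]], atom_i = tab$atom[pairs[, 1]],
                   res_j = tab$resno[pairs[, 2]], atom_j = tab$atom[pairs[, 2]],
                   lower = pmax(0, d - tol), upper = d + tol,
                   origin = "EM_FIX", scope = "intra")
  restraint_set(df)
}

#' Disambiguate ambiguous restraints against intermediate structures
#'
#' For each ambiguous restraint, every candidate's distance is measured as
#' the median over the \code{n_models} lowest-energy conformers. If exactly
#' one candidate is shorter than \code{cutoff}, the restraint is resolved to
#' that candidate; otherwise it stays ambiguous. No restraint is dropped.
#'
#' @param rset \code{restraint_set} whose ambiguous distance restraints are
#'   to be resolved.
#' @param ensemble \code{em_ensemble} of intermediate structures.
#' @param cutoff "short" distance threshold in Angstrom (default 8).
#' @param n_models number of lowest-energy conformers used (default 10).
#' @return list with \code{resolved} and \code{still_ambiguous}
#'   (restraint_sets) plus \code{n_resolved}.
#' @export
disambiguate <- function(rset, ensemble, cutoff = 8, n_models = 10) {
  stopifnot(cutoff > 0, length(ensemble$conformers) >= 1)
  d <- rset$distance
  ord <- order(ensemble$energies)
  use <- ord[seq_len(min(n_models, length(ord)))]
  confs <- ensemble$conformers[use]
  nres <- confs[[1]]$n_res
  if (nrow(d) > 0) {
    bad <- d$res_i > nres | d$res_j > nres | d$res_i < 1 | d$res_j < 1
    if (any(bad))
      stop("restraint id ", d$id[which(bad)[1]],
           " references atoms absent from the ensemble topology")
  }
  resolved_rows <- list(); still_rows <- list()
  for (rid in unique(d$id)) {
    rows <- d[d$id == rid, , drop = FALSE]
    if (nrow(rows) == 1) next  # already unambiguous; untouched
    med <- vapply(seq_len(nrow(rows)), function(k) {
      ii <- atom_index0(rows$res_i[k], rows$atom_i[k]) + 1L
      jj <- atom_index0(rows$res_j[k], rows$atom_j[k]) + 1L
      median(vapply(confs, function(s)
        sqrt(sum((s$xyz[ii, ] - s$xyz[jj, ])^2)), numeric(1)))
    }, numeric(1))
    short <- which(med < cutoff)
    if (length(short) == 1) {
      resolved_rows[[length(resolved_rows) + 1]] <- rows[short, , drop = FALSE]
    } else {
      still_rows[[length(still_rows) + 1]] <- rows
    }
  }
  resolved <- if (length(resolved_rows))
    restraint_set(renumber_ids(do.call(rbind, resolved_rows))) else restraint_set()
  still <- if (length(still_rows))
    restraint_set(renumber_ids(do.call(rbind, still_rows))) else restraint_set()
  list(resolved = resolved, still_ambiguous = still,
       n_resolved = n_distance_restraints(resolved))
}

#' Remove labelled inter-subunit restraints from a single-chain set
#'
#' @param rset \code{restraint_set}.
#' @param labels distance-restraint ids known to be inter-subunit contacts.
#' @return list with \code{set} (filtered restraint_set, dihedrals untouched)
#'   and \code{removed} (count).
#' @export
filter_intersubunit <- function(rset, labels) {
  d <- rset$distance
  unknown <- setdiff(labels, d$id)
  if (length(unknown) > 0)
    stop("unknown restraint id(s): ", paste(unknown, collapse = ", "))
  keep <- !(d$id %in% labels)
  out <- restraint_set(renumber_ids(d[keep, , drop = FALSE]), rset$dihedral)
  list(set = out, removed = length(unique(d$id[!keep])))
}

#' Tally restraints by range, ambiguity and origin
#'
#' Sequence separation uses the convention short-range |i-j| < 4 and
#' long-range |i-j| >= 4 (ambiguous restraints are classified by their first
#' candidate).
#'
#' @param rset \code{restraint_set}.
#' @return list of counts: total, short_range, long_range, unambiguous,
#'   ambiguous, by_origin, dihedral.
#' @export
classify_restraints <- function(rset) {
  d <- rset$distance
  if (nrow(d) == 0) {
    return(list(total = 0L, short_range = 0L, long_range = 0L,
                unambiguous = 0L, ambiguous = 0L,
                by_origin = integer(0), dihedral = nrow(rset$dihedral)))
  }
  first <- d[!duplicated(d$id), , drop = FALSE]
  sep <- abs(first$res_i - first$res_j)
  n_cand <- table(d$id)[as.character(first$id)]
  list(total = nrow(first),
       short_range = sum(sep < 4),
       long_range = sum(sep >= 4),
       unambiguous = sum(n_cand == 1),
       ambiguous = sum(n_cand > 1),
       by_origin = vapply(split(first$id, first$origin), length, integer(1)),
       dihedral = nrow(rset$dihedral))
}

#' Generous restraints to virtual metal-site centers
#'
#' Emits one restraint from each listed residue's side-chain centroid to each
#' of \code{n_centers} virtual site atoms with the given bounds. Virtual
#' centers are encoded with negative residue indices (-1, -2, ...) and atom
#' name "X"; they are bookkeeping for the final refinement stage and are not
#' evaluated by the torsion-space target function.
#'
#' @param site_residues chelating residue numbers.
#' @param n_centers number of metal centers.
#' @param bounds length-2 numeric (lower, upper) in Angstrom.
#' @return \code{restraint_set} of SITE restraints.
#' @export
site_restraints <- function(site_residues, n_centers, bounds) {
  stopifnot(length(bounds) == 2, bounds[1] >= 0, bounds[2] >= bounds[1])
  if (n_centers == 0 || length(site_residues) == 0) return(restraint_set())
  combos <- expand.grid(res = site_residues, center = seq_len(n_centers))
  df <- data.frame(id = seq_len(nrow(combos)),
                   res_i = combos$res, atom_i = "SC",
                   res_j = -combos$center, atom_j = "X",
                   lower = bounds[1], upper = bounds[2],
                   origin = "SITE", scope = "intra")
  restraint_set(df)
}

# ---------------------------------------------------------------------------
# file dialects

#' Write restraints
#'
#' Three dialects: \code{json} is lossless; \code{upl} writes distance rows
#' (res#, resname, atom, res#, resname, atom, upper) with ambiguous
#' candidates sharing a trailing \code{#group <id>} comment; \code{aco}
#' writes dihedral rows (res#, resname, angle, lower, upper).
#'
#' @param rset \code{restraint_set}.
#' @param path output file.
#' @param dialect "json", "upl" or "aco".
#' @param sequence optional one-letter sequence for residue names (ALA
#'   otherwise).
#' @export
write_restraints <- function(rset, path, dialect = c("json", "upl", "aco"),
                             sequence = NULL) {
  dialect <- match.arg(dialect)
  resname <- function(r) {
    if (is.null(sequence)) rep("ALA", length(r))
    else aa1to3(sequence[pmax(r, 1)])
  }
  if (dialect == "json") {
    jsonlite::write_json(list(distance = rset$distance, dihedral = rset$dihedral),
                         path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  } else if (dialect == "upl") {
    d <- rset$distance
    ncand <- if (nrow(d)) ave(d$id, d$id, FUN = length) else integer(0)
    lines <- sprintf("%4d %-4s %-4s %4d %-4s %-4s %8.2f%s",
                     d$res_i, resname(d$res_i), d$atom_i,
                     d$res_j, resname(d$res_j), d$atom_j, d$upper,
                     ifelse(ncand > 1, sprintf("  #group %d", d$id), ""))
    writeLines(lines, path)
  } else {
    dh <- rset$dihedral
    lines <- sprintf("%4d %-4s %-4s %8.1f %8.1f",
                     dh$resno, resname(dh$resno), toupper(dh$angle),
                     dh$target - dh$tolerance, dh$target + dh$tolerance)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read restraints
#' @param path input file.
#' @param dialect "json", "upl" or "aco".
#' @return \code{restraint_set}. The .upl dialect yields lower = 0; .aco rows
#'   are converted to target = midpoint, tolerance = half-width.
#' @export
read_restraints <- function(path, dialect = c("json", "upl", "aco")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    dd <- if (length(x$distance)) as.data.frame(x$distance) else empty_distance_df()
    hh <- if (length(x$dihedral)) as.data.frame(x$dihedral) else empty_dihedral_df()
    return(restraint_set(dd, hh))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "upl") {
    rows <- lapply(seq_along(lines), function(i) {
      ln <- lines[i]
      grp <- NA_integer_
      if (grepl("#group", ln)) {
        grp <- as.integer(sub(".*#group\\s+(\\d+).*", "\\1", ln))
        ln <- sub("#.*$", "", ln)
      }
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 7) stop("malformed .upl row at line ", i, ": ", lines[i])
      up <- suppressWarnings(as.numeric(f[7]))
      r1 <- suppressWarnings(as.integer(f[1])); r2 <- suppressWarnings(as.integer(f[4]))
      if (is.na(up) || is.na(r1) || is.na(r2))
        stop("malformed .upl row at line ", i, ": ", lines[i])
      data.frame(line = i, res_i = r1, atom_i = f[3], res_j = r2, atom_j = f[6],
                 upper = up, grp = grp)
    })
    rows <- do.call(rbind, rows)
    # regroup: rows with a #group comment share ids; others get fresh ids
    gid <- ifelse(is.na(rows$grp), paste0("solo", rows$line), paste0("g", rows$grp))
    df <- data.frame(id = match(gid, unique(gid)),
                     res_i = rows$res_i, atom_i = rows$atom_i,
                     res_j = rows$res_j, atom_j = rows$atom_j,
                     lower = 0, upper = rows$upper,
                     origin = "NOE", scope = "unknown")
    df <- df[order(df$id), , drop = FALSE]
    return(restraint_set(df))
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 5) stop("malformed .aco row at line ", i, ": ", lines[i])
    lo <- suppressWarnings(as.numeric(f[4])); hi <- suppressWarnings(as.numeric(f[5]))
    r <- suppressWarnings(as.integer(f[1]))
    if (is.na(lo) || is.na(hi) || is.na(r))
      stop("malformed .aco row at line ", i, ": ", lines[i])
    data.frame(resno = r, angle = tolower(f[3]),
               target = wrap180((lo + hi) / 2), tolerance = (hi - lo) / 2)
  })
  restraint_set(dihedral = do.call(rbind, rows))
}

# ---------------------------------------------------------------------------
# conversion to the flattened arrays used by the C++ kernels

restraints_to_cpp <- function(rset, n_res) {
  d <- rset$distance
  if (nrow(d) > 0 && any(d$res_j < 1 | d$res_i < 1))
    stop("virtual-site restraints cannot be evaluated by the torsion-space target function")
  if (nrow(d) > 0 && any(d$res_i > n_res | d$res_j > n_res))
    stop("restraint references a residue absent from the topology")
  if (nrow(d) > 0) {
    ids <- unique(d$id)
    ord <- order(match(d$id, ids))
    d <- d[ord, , drop = FALSE]
    grp <- c(0L, cumsum(as.integer(table(factor(d$id, levels = ids)))))
    first <- d[!duplicated(d$id), , drop = FALSE]
    ai <- atom_index0(d$res_i, d$atom_i)
    aj <- atom_index0(d$res_j, d$atom_j)
    lower <- first$lower; upper <- first$upper
  } else {
    grp <- 0L; ai <- integer(0); aj <- integer(0)
    lower <- numeric(0); upper <- numeric(0)
  }
  dh <- rset$dihedral
  if (nrow(dh) > 0 && any(dh$resno > n_res))
    stop("dihedral restraint references a residue absent from the topology")
  list(grp = as.integer(grp), ai = as.integer(ai), aj = as.integer(aj),
       lower = lower, upper = upper,
       dres = as.integer(if (nrow(dh)) dh$resno - 1L else integer(0)),
       dtyp = as.integer(if (nrow(dh)) ifelse(dh$angle == "phi", 0L, 1L) else integer(0)),
       dtarget = if (nrow(dh)) dh$target else numeric(0),
       dtol = if (nrow(dh)) dh$tolerance else numeric(0))
}
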