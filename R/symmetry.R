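# Point-group symmetry: operator sets and strict replication of a protomer.

#' Symmetry group of rigid-body operators
#'
#' @param rotations list of 3x3 rotation matrices (must include the identity
#'   and be closed under composition).
#' @param translations optional list of length-3 translation vectors
#'   (default: all zero).
#' @return object of class \code{symmetry_group} with fields
#'   \code{operators} (list of list(R, t)) and \code{order}.
#' @export
symmetry_group <- function(rotations, translations = NULL) {
  n <- length(rotations)
  if (is.null(translations)) translations <- replicate(n, c(0, 0, 0), simplify = FALSE)
  ops <- Map(function(R, t) list(R = unname(as.matrix(R)), t = as.numeric(t)),
             rotations, translations)
  g <- structure(list(operators = ops, order = n), class = "symmetry_group")
  validate_symmetry_group(g)
  g
}

validate_symmetry_group <- function(g, tol = 1e-6) {
  has_identity <- FALSE
  for (op in g$operators) {
    R <- op$R
    if (max(abs(crossprod(R) - diag(3))) > tol)
      stop("non-orthonormal rotation in symmetry group")
    if (max(abs(R - diag(3))) < tol && max(abs(op$t)) < tol) has_identity <- TRUE
  }
  if (!has_identity) stop("symmetry group must contain the identity")
  # closure under composition (rotation parts)
  for (a in g$operators) for (b in g$operators) {
    Rc <- a$R %*% b$R
    ok <- any(vapply(g$operators, function(op) max(abs(op$R - Rc)) < 1e-5, logical(1)))
    if (!ok) stop("symmetry group not closed under composition")
  }
  invisible(TRUE)
}

rot_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a); C <- 1 - ca
  matrix(c(ca + u[1]^2 * C, u[1] * u[2] * C - u[3] * sa, u[1] * u[3] * C + u[2] * sa,
           u[2] * u[1] * C + u[3] * sa, ca + u[2]^2 * C, u[2] * u[3] * C - u[1] * sa,
           u[3] * u[1] * C - u[2] * sa, u[3] * u[2] * C + u[1] * sa, ca + u[3]^2 * C),
         3, 3, byrow = TRUE)
}

#' Cyclic symmetry group Cn about an axis
#' @param n group order.
#' @param axis rotation axis (default z).
#' @return a \code{symmetry_group} of order n.
#' @export
cyclic_group <- function(n, axis = c(0, 0, 1)) {
  symmetry_group(lapply(seq_len(n) - 1, function(k) rot_about(axis, 360 * k / n)))
}

#' Tetrahedral rotation group (order 12)
#'
#' The rotation group of the tetrahedron: identity, eight 120-degree
#' rotations about the four body diagonals, and three 180-degree rotations
#' about the coordinate axes. A dodecameric assembly with this symmetry has
#' 12 equivalent chains.
#'
#' @return a \code{symmetry_group} of order 12.
#' @export
tetrahedral_group <- function() {
  diag3 <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  rots <- list(diag(3))
  for (ax in diag3) for (ang in c(120, 240)) rots <- c(rots, list(rot_about(ax, ang)))
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
    rots <- c(rots, list(rot_about(ax, 180)))
  symmetry_group(rots)
}

#' Replicate a protomer by a symmetry group
#'
#' Chain k of the result is operator k applied to the protomer, exactly.
#'
#' @param protomer an \code{em_structure}.
#' @param group a \code{symmetry_group}.
#' @return list of \code{em_structure}s, one per operator, chain ids A, B, ...
#' @export
apply_symmetry <- function(protomer, group) {
  validate_symmetry_group(group)
  ids <- c(LETTERS, letters)
  lapply(seq_along(group$operators), function(k) {
    op <- group$operators[[k]]
    s <- protomer
    s$xyz <- t(op$R %*% t(protomer$xyz)) +
      matrix(op$t, nrow(protomer$xyz), 3, byrow = TRUE)
    s$chain <- ids[((k - 1) %% length(ids)) + 1]
    s
  })
}

# operators as a row-stacked (3*n) x 4 matrix [R | t] for the C++ kernels
ops_matrix <- function(group) {
  do.call(rbind, lapply(group$operators, function(op) cbind(op$R, op$t)))
}
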