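#' Unit cell
#'
#' Construct a crystallographic unit cell from its six parameters.
#'
#' @param a,b,c Cell edges in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `mr_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = unname(a), b = unname(b), c = unname(c), alpha = unname(alpha),
         beta = unname(beta), gamma = unname(gamma))
  if (any(!is.finite(p))) stop("cell parameters must be finite")
  if (any(p[1:3] <= 0)) stop("cell edges must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) stop("cell angles must lie in (0, 180)")
  cell <- as.list(p)
  class(cell) <- "mr_cell"
  if (cell_volume(cell) <= 0) stop("degenerate cell: non-positive volume")
  cell
}

#' @export
print.mr_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Orthogonalization matrix, PDB convention: a along x, b in the xy plane.
# Columns map fractional -> orthogonal Angstrom.
#' Fractional/orthogonal conversion matrices
#' @param cell An `mr_cell`.
#' @return 3x3 matrix mapping fractional to orthogonal coordinates.
#' @export
orth_matrix <- function(cell) {
  ca <- cos(deg2rad(cell$alpha)); cb <- cos(deg2rad(cell$beta))
  cg <- cos(deg2rad(cell$gamma)); sg <- sin(deg2rad(cell$gamma))
  v <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  matrix(c(cell$a, 0, 0,
           cell$b * cg, cell$b * sg, 0,
           cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * v / sg),
         nrow = 3, ncol = 3)
}

#' @rdname orth_matrix
#' @export
frac_matrix <- function(cell) solve(orth_matrix(cell))

#' Cell volume in cubic Angstrom
#' @param cell An `mr_cell`.
#' @export
cell_volume <- function(cell) {
  ca <- cos(deg2rad(cell$alpha)); cb <- cos(deg2rad(cell$beta)); cg <- cos(deg2rad(cell$gamma))
  cell$a * cell$b * cell$c * sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
}

#' Space-group symmetry operators
#'
#' Built-in operator lists for P1, P21 (unique axis b) and P212121.
#' Other groups can be supplied as explicit operator lists via
#' [symmetry_ops_from_list()].
#'
#' @param name Space-group label: one of `"P1"`, `"P21"`, `"P212121"`.
#' @return An object of class `mr_symops`: list with `name` and `ops`, each op
#'   a list with a 3x3 integer rotation `R` and fractional translation `t`
#'   acting on fractional coordinates as `R %*% x + t`.
#' @export
spacegroup <- function(name) {
  key <- gsub("[ ()]", "", toupper(name))
  op <- function(R, t) list(R = matrix(R, 3, 3, byrow = TRUE), t = t)
  ops <- switch(key,
    "P1" = list(op(c(1,0,0, 0,1,0, 0,0,1), c(0, 0, 0))),
    "P21" = list(
      op(c(1,0,0, 0,1,0, 0,0,1),   c(0, 0, 0)),
      op(c(-1,0,0, 0,1,0, 0,0,-1), c(0, 0.5, 0))),
    "P212121" = list(
      op(c(1,0,0, 0,1,0, 0,0,1),    c(0, 0, 0)),
      op(c(1,0,0, 0,-1,0, 0,0,-1),  c(0.5, 0.5, 0)),
      op(c(-1,0,0, 0,1,0, 0,0,-1),  c(0, 0.5, 0.5)),
      op(c(-1,0,0, 0,-1,0, 0,0,1),  c(0.5, 0, 0.5))),
    stop("unknown space group '", name,
         "'; built-ins are P1, P21, P212121 (others via symmetry_ops_from_list)")
  )
  structure(list(name = name, ops = ops), class = "mr_symops")
}

#' @param name Label for the group.
#' @param ops List of `list(R = 3x3 matrix, t = length-3 numeric)` operators.
#' @rdname spacegroup
#' @export
symmetry_ops_from_list <- function(name, ops) {
  stopifnot(length(ops) >= 1)
  ops <- lapply(ops, function(o) list(R = matrix(as.numeric(o$R), 3, 3), t = as.numeric(o$t)))
  has_identity <- any(vapply(ops, function(o)
    max(abs(o$R - diag(3))) < 1e-9 && max(abs(o$t %% 1)) < 1e-9, logical(1)))
  if (!has_identity) stop("operator list must contain the identity")
  structure(list(name = name, ops = ops), class = "mr_symops")
}

#' @export
print.mr_symops <- function(x, ...) {
  cat(sprintf("space group %s (%d operators)\n", x$name, length(x$ops)))
  invisible(x)
}

n_symops <- function(sym) length(sym$ops)

## ---- rotations -------------------------------------------------------------

#' Rotation matrix from zyz Euler angles (degrees)
#'
#' Active rotation `Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`.
#' @param alpha,beta,gamma Euler angles in degrees.
#' @export
euler_zyz <- function(alpha, beta, gamma) {
  rz <- function(t) {
    c <- cos(t); s <- sin(t)
    matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
  }
  ry <- function(t) {
    c <- cos(t); s <- sin(t)
    matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
  }
  rz(deg2rad(alpha)) %*% ry(deg2rad(beta)) %*% rz(deg2rad(gamma))
}

#' Angular distance between two rotations, in degrees
#' @param r1,r2 3x3 rotation matrices.
#' @export
rotation_angle_between <- function(r1, r2) {
  tr <- sum(diag(crossprod(r1, r2)))
  rad2deg(acos(pmin(1, pmax(-1, (tr - 1) / 2))))
}

# Deduplicated zyz Euler grid: at beta = 0 or 180 only alpha + gamma matters.
euler_grid <- function(step) {
  stopifnot(step > 0)
  alphas <- seq(0, 360 - step, by = step)
  betas <- seq(0, 180, by = step)
  grid <- expand.grid(alpha = alphas, beta = betas, gamma = alphas,
                      KEEP.OUT.ATTRS = FALSE)
  keep <- !(grid$beta %in% c(0, 180)) | grid$gamma == 0
  grid <- grid[keep, , drop = FALSE]
  # collapse numerically identical matrices (polar redundancy, step dividing 180)
  key <- vapply(seq_len(nrow(grid)), function(i) {
    paste(round(euler_zyz(grid$alpha[i], grid$beta[i], grid$gamma[i]), 6), collapse = ",")
  }, character(1))
  grid[!duplicated(key), , drop = FALSE]
}

## ---- superposition ---------------------------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the rmsd between
#' `mobile` and `reference` atoms, paired by (chain, seqnum, atom name).
#'
#' @param mobile,reference `mr_model` objects.
#' @param selection Character vector of atom names to match (default the
#'   protein main chain `N, CA, C, O`); `NULL` matches all names.
#' @return List of class `mr_superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom over matched atoms after the
#'   transform), `n_matched`. Apply as `x_new = rotation %*% x + translation`.
#' @export
superpose <- function(mobile, reference, selection = c("N", "CA", "C", "O")) {
  pair <- match_atoms(mobile, reference, selection)
  if (nrow(pair$a) < 3) stop("need at least 3 matched atoms, got ", nrow(pair$a))
  kabsch_fit(as.matrix(pair$a[, c("x", "y", "z")]),
             as.matrix(pair$b[, c("x", "y", "z")]))
}

match_atoms <- function(mobile, reference, selection = NULL) {
  a <- mobile; b <- reference
  if (!is.null(selection)) {
    a <- a[a$atom %in% selection, , drop = FALSE]
    b <- b[b$atom %in% selection, , drop = FALSE]
  }
  ka <- paste(a$chain, a$seqnum, a$atom, sep = "|")
  kb <- paste(b$chain, b$seqnum, b$atom, sep = "|")
  i <- match(kb, ka)
  keep <- !is.na(i)
  list(a = a[i[keep], , drop = FALSE], b = b[keep, , drop = FALSE])
}

# P, Q: n x 3 matrices of mobile / reference coordinates.
kabsch_fit <- function(P, Q) {
  n <- nrow(P)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  span <- svd(P0)$d
  if (span[2] < 1e-8) warning("degenerate (collinear) coordinates in superposition")
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.vector(R %*% cp)
  moved <- P %*% t(R) + matrix(t, n, 3, byrow = TRUE)
  structure(list(rotation = R, translation = t,
                 rmsd = sqrt(mean(rowSums((moved - Q)^2))), n_matched = n),
            class = "mr_superposition")
}

#' @export
print.mr_superposition <- function(x, ...) {
  cat(sprintf("superposition: %d atoms matched, rmsd %.4f A\n", x$n_matched, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to a model
#' @param model An `mr_model`.
#' @param rotation 3x3 matrix (orthogonal coordinates).
#' @param translation Length-3 shift in Angstrom.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

## ---- internal coordinates --------------------------------------------------

vnorm <- function(v) sqrt(sum(v^2))

bond_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  rad2deg(acos(pmin(1, pmax(-1, sum(u * v) / (vnorm(u) * vnorm(v))))))
}

dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3], b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3], b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3], n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- b2 / vnorm(b2)
  rad2deg(atan2(sum(m1 / vnorm(b2) * n2), sum(n1 * n2))) * -1
}

# Natural-extension-reference-frame placement: position a new atom at given
# bond length from c, bond angle (b-c-new) and dihedral (a-b-c-new), degrees.
place_atom <- function(a, b, c, length, angle, dihedral) {
  th <- deg2rad(angle); ph <- deg2rad(dihedral)
  bc <- c - b; bc <- bc / vnorm(bc)
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3], ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / vnorm(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3], n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-length * cos(th), length * sin(th) * cos(ph), length * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
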