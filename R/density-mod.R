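#' Detect non-crystallographic symmetry operators from a model
#'
#' Every ordered pair of chains with matching sequence (>= 90% identity over
#' shared residue numbers, >= 3 shared residues) yields the CA-superposition
#' operator mapping the source chain onto the target chain; pairs with
#' superposition rmsd above 2.0 A are discarded.
#'
#' @param model `mr_model`.
#' @param max_rmsd Discard threshold, Angstrom.
#' @return List of operators `list(rotation, translation, source_chain,
#'   target_chain, rmsd)`; empty when no pair qualifies.
#' @export
find_ncs_operators <- function(model, max_rmsd = 2.0) {
  chains <- unique(model$chain)
  ops <- list()
  if (length(chains) < 2) return(ops)
  for (src in chains) for (dst in chains) {
    if (src == dst) next
    a <- model[model$chain == src & model$atom == "CA", , drop = FALSE]
    b <- model[model$chain == dst & model$atom == "CA", , drop = FALSE]
    shared <- intersect(a$seqnum, b$seqnum)
    if (length(shared) < 3) next
    ra <- a$resname[match(shared, a$seqnum)]
    rb <- b$resname[match(shared, b$seqnum)]
    if (mean(ra == rb) < 0.9) next
    fit <- kabsch_fit(as.matrix(a[match(shared, a$seqnum), c("x", "y", "z")]),
                      as.matrix(b[match(shared, b$seqnum), c("x", "y", "z")]))
    if (fit$rmsd > max_rmsd) next
    ops[[length(ops) + 1]] <- list(rotation = fit$rotation,
                                   translation = fit$translation,
                                   source_chain = src, target_chain = dst,
                                   rmsd = fit$rmsd)
  }
  ops
}

# Restrict an operator list to those sharing the first operator's source
# chain (the reference copy): the form every consumer of a single-reference
# averaging or replication step needs.
reference_ops <- function(ops) {
  if (!length(ops)) return(ops)
  src <- ops[[1]]$source_chain
  Filter(function(o) o$source_chain == src, ops)
}

ncs_identity_op <- function(chain = "A") {
  list(rotation = diag(3), translation = c(0, 0, 0),
       source_chain = chain, target_chain = chain, rmsd = 0)
}

# Logical grid mask of points within `radius` of any atom of `model`, periodic.
region_mask <- function(map, model, radius = 5) {
  dims <- dim(map$grid)
  O <- orth_matrix(map$cell)
  xf <- model_fractional(model, map$cell)
  sel <- array(FALSE, dim = dims)
  spacing <- c(map$cell$a, map$cell$b, map$cell$c) / dims
  for (i in seq_len(nrow(xf))) {
    ctr <- xf[i, ] %% 1
    w <- ceiling(radius / spacing)
    rng <- lapply(1:3, function(ax)
      (round(ctr[ax] * dims[ax]) - w[ax]):(round(ctr[ax] * dims[ax]) + w[ax]))
    g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    df <- sweep(g, 2, dims, "/") - matrix(ctr, nrow(g), 3, byrow = TRUE)
    ok <- rowSums((df %*% t(O))^2) <= radius^2
    gi <- sweep(g[ok, , drop = FALSE], 2, dims, "%%") + 1
    sel[gi] <- TRUE
  }
  sel
}

# Minimum distance from each grid point to any atom of `model`, cut off at
# `radius` (Inf beyond), periodic. Also records the unwrapped fractional
# coordinate of each in-range point in the frame where the model sits at its
# true (unwrapped) Cartesian position -- required when mapping points through
# non-crystallographic operators, for which a lattice wrap is not a symmetry.
region_dist <- function(map, model, radius = 5) {
  dims <- dim(map$grid)
  O <- orth_matrix(map$cell)
  xf <- model_fractional(model, map$cell)
  dd <- array(Inf, dim = dims)
  uf <- matrix(NA_real_, prod(dims), 3)
  spacing <- c(map$cell$a, map$cell$b, map$cell$c) / dims
  for (i in seq_len(nrow(xf))) {
    ctr <- xf[i, ] %% 1
    L <- xf[i, ] - ctr   # lattice offset of the true atom position
    w <- ceiling(radius / spacing)
    rng <- lapply(1:3, function(ax)
      (round(ctr[ax] * dims[ax]) - w[ax]):(round(ctr[ax] * dims[ax]) + w[ax]))
    g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    gf <- sweep(g, 2, dims, "/")
    df <- gf - matrix(ctr, nrow(g), 3, byrow = TRUE)
    r <- sqrt(rowSums((df %*% t(O))^2))
    ok <- r <= radius
    gi <- sweep(g[ok, , drop = FALSE], 2, dims, "%%") + 1
    lin <- gi[, 1] + dims[1] * (gi[, 2] - 1) + dims[1] * dims[2] * (gi[, 3] - 1)
    upd <- r[ok] < dd[lin]
    dd[lin[upd]] <- r[ok][upd]
    uf[lin[upd], ] <- sweep(gf[ok, , drop = FALSE][upd, , drop = FALSE], 2, L, "+")
  }
  list(dist = dd, unwrapped_frac = uf)
}

# Grid points (linear indices + fractional coords) within `radius` of any
# atom of `center_model`, periodic; optionally excluding the neighborhood of
# another model.
region_points <- function(map, center_model, radius = 5, exclude = NULL,
                          exclude_radius = radius) {
  sel <- region_mask(map, center_model, radius)
  if (!is.null(exclude)) sel <- sel & !region_mask(map, exclude, exclude_radius)
  idx <- which(sel)
  ijk <- arrayInd(idx, dim(map$grid))
  list(lin = idx, frac = sweep(ijk - 1, 2, dim(map$grid), "/"))
}

# Exact band-limited upsampling by reciprocal-space zero padding.
upsample_map <- function(map, factor = 2) {
  d <- dim(map$grid)
  d2 <- d * factor
  Fg <- fft(map$grid, inverse = TRUE) / prod(d)
  big <- array(0i, dim = d2)
  ax_idx <- function(n, n2) {
    pos <- 0:floor(n / 2)
    nneg <- n - floor(n / 2) - 1
    neg <- if (nneg > 0) (n2 - nneg + 1):n2 else integer(0)
    src_neg <- if (nneg > 0) (floor(n / 2) + 2):n else integer(0)
    list(src = c(pos + 1, src_neg), dst = c(pos + 1, neg))
  }
  ix <- ax_idx(d[1], d2[1]); iy <- ax_idx(d[2], d2[2]); iz <- ax_idx(d[3], d2[3])
  big[ix$dst, iy$dst, iz$dst] <- Fg[ix$src, iy$src, iz$src]
  out <- map
  out$grid <- Re(fft(big))
  out
}

#' Average a map over non-crystallographic symmetry operators
#'
#' Within the union of 5 A spheres around the reference copy's atoms
#' (minus any other copy's neighborhood, so no point mixes two molecular
#' environments), each point is replaced by the mean of the map sampled
#' (tricubic, periodic wrap) at the point itself and at its images under
#' every operator; the averaged values are then written back into every
#' copy's region. Points outside all regions are unchanged.
#'
#' @param map `mr_map`.
#' @param ops Operators from [find_ncs_operators()] mapping the reference
#'   copy onto the other copies.
#' @param mask_center `mr_model` defining the reference region (one copy).
#' @param radius Region radius around atoms, Angstrom.
#' @return Averaged `mr_map`.
#' @export
ncs_average <- function(map, ops, mask_center, radius = 5) {
  stopifnot(length(ops) >= 1)
  O <- orth_matrix(map$cell); Fm <- frac_matrix(map$cell)
  is_ident <- function(op) max(abs(op$rotation - diag(3))) < 1e-12 &&
    max(abs(op$translation)) < 1e-12
  live <- Filter(Negate(is_ident), ops)
  if (!length(live)) return(map)
  dims <- dim(map$grid)
  margin <- 3.6 * max(c(map$cell$a, map$cell$b, map$cell$c) / dims)
  copies <- lapply(live, function(op)
    transform_model(mask_center, op$rotation, op$translation))
  reg <- ncs_region_points(map, live, mask_center, radius, margin)
  # heavily overlapping copies can leave no invariant core; nothing to average
  if (!length(reg$lin)) return(map)
  cart <- reg$frac %*% t(O)   # unwrapped Cartesian positions
  acc <- map$grid[reg$lin]
  for (op in live) {
    moved <- cart %*% t(op$rotation) +
      matrix(op$translation, nrow(cart), 3, byrow = TRUE)
    acc <- acc + interpolate_map_cubic(map, moved %*% t(Fm))
  }
  n_terms <- length(live) + 1
  out <- map
  out$grid[reg$lin] <- acc / n_terms
  # each copy region gets the NCS average computed directly from the input
  # map, via the unwrapped preimage under its operator; overlap between
  # dilated regions is resolved by nearest-copy ownership so the preimage
  # used at every written point is unambiguous
  dists <- lapply(copies, function(cp) region_dist(map, cp, radius + margin))
  owner <- array(0L, dims)
  best <- array(Inf, dims)
  for (i in seq_along(live)) {
    upd <- dists[[i]]$dist < best
    owner[upd] <- i
    best[upd] <- dists[[i]]$dist[upd]
  }
  owner[reg$lin] <- 0L   # the core region keeps its reference-frame values
  for (i in seq_along(live)) {
    op <- live[[i]]
    lin <- which(owner == i)
    if (!length(lin)) next
    cfrac <- dists[[i]]$unwrapped_frac[lin, , drop = FALSE]
    p0 <- (cfrac %*% t(O) -
           matrix(op$translation, length(lin), 3, byrow = TRUE)) %*%
      op$rotation   # inverse rotation: R^T
    acc2 <- interpolate_map_cubic(map, p0 %*% t(Fm))
    for (op2 in live) {
      moved <- p0 %*% t(op2$rotation) +
        matrix(op2$translation, nrow(p0), 3, byrow = TRUE)
      acc2 <- acc2 + interpolate_map_cubic(map, moved %*% t(Fm))
    }
    out$grid[lin] <- acc2 / n_terms
  }
  out
}

#' Grid indices of the NCS averaging region
#'
#' The invariant core around the reference copy: points within `radius` of
#' its atoms whose images under every operator stay clear of all other
#' copies' neighborhoods (so averaging never mixes molecular environments).
#'
#' @inheritParams ncs_average
#' @return List `lin` (linear grid indices), `frac` (unwrapped fractional
#'   coordinates in the reference copy's frame).
#' @export
ncs_region <- function(map, ops, mask_center, radius = 5) {
  is_ident <- function(op) max(abs(op$rotation - diag(3))) < 1e-12 &&
    max(abs(op$translation)) < 1e-12
  live <- Filter(Negate(is_ident), ops)
  margin <- 3.6 * max(c(map$cell$a, map$cell$b, map$cell$c) / dim(map$grid))
  ncs_region_points(map, live, mask_center, radius, margin)
}

# Core region: near the reference copy, excluding (with margin) every point
# whose own position or any image could touch a different copy's territory.
ncs_region_points <- function(map, live, mask_center, radius, margin) {
  copies <- lapply(live, function(op)
    transform_model(mask_center, op$rotation, op$translation))
  # other copies, plus preimages of the reference copy and of other copies
  # under each operator
  excl <- do.call(rbind, c(copies, lapply(seq_along(live), function(i) {
    op <- live[[i]]
    backs <- c(list(mask_center), copies[-i])
    do.call(rbind, lapply(backs, function(m)
      transform_model(m, t(op$rotation),
                      -as.vector(t(op$rotation) %*% op$translation))))
  })))
  rd <- region_dist(map, mask_center, radius)
  sel <- is.finite(rd$dist) & !region_mask(map, excl, radius + margin)
  idx <- which(sel)
  list(lin = idx, frac = rd$unwrapped_frac[idx, , drop = FALSE])
}

#' Solvent flattening and NCS averaging with phase recombination
#'
#' Classical density modification: per cycle the solvent mask (points more
#' than `mask_radius` from any model atom, trimmed or grown by density-value
#' ranking to match `solvent_fraction`) is flattened to its mean, NCS
#' averaging is applied when operators are present, and the map is rebuilt
#' from amplitudes reset to the scaled observed values with phases
#' `arg(w F_mod + (1-w) F_start)`. Phase-only modification: work and free
#' amplitudes are treated identically.
#'
#' @param start_map `mr_map` (model-phased start, e.g. 2Fo-Fc).
#' @param refl `mr_reflections` with `f_obs` and `f_calc` phases.
#' @param model `mr_model` defining the protein region.
#' @param solvent_fraction Fraction of the cell to flatten, in \[0.2, 0.8\].
#' @param n_cycles Number of cycles (0 returns the start map unchanged).
#' @param ops NCS operators (possibly empty list).
#' @param w Recombination weight for the modified structure factors.
#' @param mask_radius Protein mask distance, Angstrom.
#' @return Density-modified `mr_map` (mean zero).
#' @export
density_modify <- function(start_map, refl, model, solvent_fraction,
                           n_cycles = 5, ops = list(), w = 0.5,
                           mask_radius = 4) {
  stopifnot(solvent_fraction >= 0.2, solvent_fraction <= 0.8)
  if (n_cycles == 0) return(start_map)
  cell <- start_map$cell
  dims <- dim(start_map$grid)
  H <- as.matrix(refl[, c("h", "k", "l")])
  lin <- {
    idx <- sweep(H, 2, dims, "%%") + 1
    idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
  }
  fobs_sc <- refl$f_obs
  f_start <- map_coefficients(start_map, H, lin)
  protein <- region_points(start_map, model, mask_radius)
  far <- rep(TRUE, prod(dims)); far[protein$lin] <- FALSE
  n_solv <- round(solvent_fraction * prod(dims))
  map <- start_map
  prev_mask <- NULL
  for (cy in seq_len(n_cycles)) {
    g <- as.vector(map$grid)
    ord_far <- which(far)[order(g[far])]
    if (length(ord_far) >= n_solv) {
      solv <- ord_far[seq_len(n_solv)]
    } else {
      ord_near <- which(!far)[order(g[!far])]
      solv <- c(ord_far, ord_near[seq_len(n_solv - length(ord_far))])
    }
    if (!is.null(prev_mask) && length(prev_mask) == length(solv)) {
      churn <- mean(!(solv %in% prev_mask))
      if (cy > 2 && churn > 0.5) {
        warning("solvent mask oscillating; stopping density modification early")
        break
      }
    }
    prev_mask <- solv
    g[solv] <- mean(g[solv])
    map$grid <- array(g, dim = dims)
    if (length(ops)) {
      rops <- reference_ops(ops)
      ref_chain <- rops[[1]]$source_chain
      map <- ncs_average(map, rops,
                         model[model$chain == ref_chain, , drop = FALSE])
    }
    f_mod <- map_coefficients(map, H, lin)
    f_comb <- w * f_mod + (1 - w) * f_start
    ph <- f_comb / ifelse(Mod(f_comb) > 0, Mod(f_comb), 1)
    map <- synthesize_map(H, fobs_sc * ph, cell, min(refl$d))
  }
  map
}

# Forward transform of a map restricted to the given reflections.
map_coefficients <- function(map, H, lin = NULL) {
  dims <- dim(map$grid)
  Fg <- fft(map$grid, inverse = TRUE) * cell_volume(map$cell) / prod(dims)
  if (is.null(lin)) {
    idx <- sweep(H, 2, dims, "%%") + 1
    lin <- idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
  }
  Fg[lin]
}

#' Average standardized maps
#'
#' Each map is standardized (zero mean, unit variance) then averaged
#' pointwise; permutation-invariant.
#'
#' @param maps List of `mr_map` on identical grids.
#' @return `mr_map`.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  dims <- dim(maps[[1]]$grid)
  acc <- array(0, dim = dims)
  for (m in maps) {
    if (!identical(dim(m$grid), dims)) stop("map grids differ")
    acc <- acc + standardize_map(m)$grid
  }
  out <- maps[[1]]
  out$grid <- acc / length(maps)
  out
}
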