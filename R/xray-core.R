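# 4-Gaussian + constant scattering-factor coefficients (C, N, O, S).
# f(s) = sum_i a_i exp(-b_i s^2 / 4) + c  with s = 1/d (so s/2 = sin(theta)/lambda).
FORM_FACTORS <- list(
  C = list(a = c(2.3100, 1.0200, 1.5886, 0.8650),
           b = c(20.8439, 10.2075, 0.5687, 51.6512), c = 0.2156),
  N = list(a = c(12.2126, 3.1322, 2.0125, 1.1663),
           b = c(0.0057, 9.8933, 28.9975, 0.5826), c = -11.5290),
  O = list(a = c(3.0485, 2.2868, 1.5463, 0.8670),
           b = c(13.2771, 5.7011, 0.3239, 32.9089), c = 0.2508),
  S = list(a = c(6.9053, 5.2034, 1.4379, 1.5863),
           b = c(1.4679, 22.2151, 0.2536, 56.1720), c = 0.8669))

form_factor <- function(element, s) {
  ff <- FORM_FACTORS[[toupper(element)]]
  if (is.null(ff)) stop("no form factors for element '", element,
                        "' (available: C, N, O, S)")
  out <- rep(ff$c, length(s))
  for (i in 1:4) out <- out + ff$a[i] * exp(-ff$b[i] * s^2 / 4)
  out
}

## ---- reflection sets -------------------------------------------------------

new_reflections <- function(df, cell, sym) {
  df <- as.data.frame(df)
  stopifnot(all(c("h", "k", "l") %in% names(df)))
  if (anyDuplicated(df[, c("h", "k", "l")])) stop("duplicate Miller indices")
  if (!is.null(df$f_obs) && any(df$f_obs < 0)) stop("negative observed amplitude")
  if (is.null(df$d)) df$d <- d_spacing(as.matrix(df[, c("h", "k", "l")]), cell)
  structure(df, class = c("mr_reflections", "data.frame"),
            cell = cell, sym = sym)
}

# keep the crystal frame attached through data.frame subsetting
#' @export
`[.mr_reflections` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "cell") <- attr(x, "cell")
    attr(out, "sym") <- attr(x, "sym")
    class(out) <- class(x)
  }
  out
}

#' @export
print.mr_reflections <- function(x, ...) {
  cat(sprintf("reflection set: %d reflections, d range %.2f-%.2f A%s%s\n",
              nrow(x), max(x$d), min(x$d),
              if (!is.null(x$f_obs)) ", f_obs" else "",
              if (!is.null(x$f_calc)) ", f_calc" else ""))
  invisible(x)
}

d_spacing <- function(hkl, cell) {
  sv <- hkl %*% frac_matrix(cell)   # rows: h %*% O^-1 = reciprocal vector
  1 / sqrt(rowSums(sv^2))
}

# True iff reflection is systematically absent for the group: some op with
# R^T h = h and fractional h.t not an integer.
systematic_absent <- function(hkl, sym) {
  absent <- rep(FALSE, nrow(hkl))
  for (op in sym$ops) {
    fixed <- rowSums(abs(hkl %*% op$R - hkl)) < 1e-9
    ph <- (hkl %*% op$t) %% 1
    absent <- absent | (fixed & pmin(ph, 1 - ph) > 1e-9)
  }
  absent
}

#' Generate the unique reflection list to a resolution limit
#'
#' One hemisphere of reciprocal space (Friedel mates implied), origin and
#' systematically absent reflections excluded.
#'
#' @param cell `mr_cell`.
#' @param sym `mr_symops`.
#' @param d_min High-resolution limit in Angstrom.
#' @return `mr_reflections` with columns h, k, l, d.
#' @export
generate_hkl <- function(cell, sym, d_min) {
  stopifnot(d_min > 0)
  hmax <- ceiling(cell$a / d_min); kmax <- ceiling(cell$b / d_min)
  lmax <- ceiling(cell$c / d_min)
  g <- as.matrix(expand.grid(h = 0:hmax, k = -kmax:kmax, l = -lmax:lmax))
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g <- g[keep, , drop = FALSE]
  d <- d_spacing(g, cell)
  g <- g[d >= d_min, , drop = FALSE]
  d <- d[d >= d_min]
  ok <- !systematic_absent(g, sym)
  new_reflections(data.frame(h = g[ok, 1], k = g[ok, 2], l = g[ok, 3], d = d[ok]),
                  cell, sym)
}

## ---- structure factors -----------------------------------------------------

model_fractional <- function(model, cell) {
  as.matrix(model[, c("x", "y", "z")]) %*% t(frac_matrix(cell))
}

#' Structure factors by direct summation
#'
#' `F(h) = sum_sym sum_atoms f_elem(s) occ exp(-B s^2/4) exp(2 pi i h.x)`,
#' exact within float tolerance; the oracle for [sf_fft()].
#'
#' @param model `mr_model` (orthogonal Angstrom coordinates).
#' @param cell `mr_cell`.
#' @param sym `mr_symops`.
#' @param hkl `mr_reflections` or 3-column integer matrix.
#' @return Complex vector of structure factors, one per reflection.
#' @export
sf_direct <- function(model, cell, sym, hkl) {
  H <- if (inherits(hkl, "data.frame")) as.matrix(hkl[, c("h", "k", "l")]) else hkl
  s <- 1 / d_spacing(H, cell)
  xf <- model_fractional(model, cell)
  # weight matrix: nrefl x natoms
  W <- matrix(0, nrow(H), nrow(model))
  for (el in unique(model$element)) {
    f <- form_factor(el, s)
    idx <- which(model$element == el)
    W[, idx] <- f
  }
  W <- W * exp(outer(-s^2 / 4, model$b)) *
    matrix(model$occ, nrow(H), nrow(model), byrow = TRUE)
  F <- complex(real = rep(0, nrow(H)))
  for (op in sym$ops) {
    xs <- xf %*% t(op$R) + matrix(op$t, nrow(xf), 3, byrow = TRUE)
    phase <- exp(2i * pi * (H %*% t(xs)))
    F <- F + rowSums(W * phase)
  }
  unname(F)
}

# FFT grid sizes: smallest integer >= n with only factors 2, 3, 5.
next235 <- function(n) {
  good <- function(x) { for (p in c(2, 3, 5)) while (x %% p == 0) x <- x / p; x == 1 }
  while (!good(n)) n <- n + 1
  n
}

map_grid_dims <- function(cell, d_min, per_axis = 3) {
  vapply(c(cell$a, cell$b, cell$c),
         function(e) next235(max(4, ceiling(e / (d_min / per_axis)))), numeric(1))
}

# Sample the model's electron density on the grid (P1-expanded over sym ops),
# with an extra smearing B added to every Gaussian for anti-aliasing; callers
# divide the transform by exp(-b_extra s^2/4) to undo it exactly.
sample_density <- function(model, cell, sym, dims, b_extra) {
  O <- orth_matrix(cell)
  rho <- array(0, dim = dims)
  xf <- model_fractional(model, cell)
  spacing <- c(cell$a, cell$b, cell$c) / dims   # per-axis fractional step in A (approx)
  for (op in sym$ops) {
    xs <- xf %*% t(op$R) + matrix(op$t, nrow(xf), 3, byrow = TRUE)
    xs <- xs %% 1
    for (i in seq_len(nrow(xs))) {
      ff <- FORM_FACTORS[[toupper(model$element[i])]]
      a <- c(ff$a, ff$c)
      b <- c(ff$b, 0) + model$b[i] + b_extra
      rcut <- 0.65 * sqrt(max(b)) + 0.5
      ctr <- xs[i, ]
      rng <- lapply(1:3, function(ax) {
        w <- ceiling(rcut / spacing[ax])
        (round(ctr[ax] * dims[ax]) - w):(round(ctr[ax] * dims[ax]) + w)
      })
      g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      df <- sweep(g, 2, dims, "/") - matrix(ctr, nrow(g), 3, byrow = TRUE)
      dxyz <- df %*% t(O)
      r2 <- rowSums(dxyz^2)
      sel <- r2 <= rcut^2
      if (!any(sel)) next
      dens <- rep(0, sum(sel))
      for (k in seq_along(a)) {
        dens <- dens + a[k] * (4 * pi / b[k])^1.5 * exp(-4 * pi^2 * r2[sel] / b[k])
      }
      dens <- dens * model$occ[i]
      ijk <- g[sel, , drop = FALSE]
      ijk <- sweep(ijk, 2, dims, "%%") + 1
      lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1) + dims[1] * dims[2] * (ijk[, 3] - 1)
      # accumulate (duplicate linear indices impossible within one atom's box)
      rho[lin] <- rho[lin] + dens
    }
  }
  rho
}

#' Structure factors via FFT of sampled density
#'
#' Atom densities (Gaussian profiles from the packaged form factors) are
#' sampled on a grid of spacing about `d_min/3` per axis, transformed and the
#' anti-aliasing smearing divided out.
#'
#' @inheritParams sf_direct
#' @param d_min Resolution limit, Angstrom.
#' @param b_extra Anti-aliasing smearing B added during sampling and removed
#'   exactly afterwards (Angstrom^2).
#' @param hkl Optional reflection list; defaults to [generate_hkl()].
#' @return `mr_reflections` with complex `f_calc`.
#' @export
sf_fft <- function(model, cell, sym, d_min, b_extra = 30, hkl = NULL) {
  dims <- map_grid_dims(cell, d_min)
  if (any(d_min <= 2 * c(cell$a, cell$b, cell$c) / dims / 1.49))
    stop("grid too coarse for d_min")
  refl <- hkl %||% generate_hkl(cell, sym, d_min)
  rho <- sample_density(model, cell, sym, dims, b_extra)
  Fg <- fft(rho, inverse = TRUE) * cell_volume(cell) / prod(dims)
  H <- as.matrix(refl[, c("h", "k", "l")])
  idx <- sweep(H, 2, dims, "%%") + 1
  lin <- idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
  s <- 1 / refl$d
  refl$f_calc <- Fg[lin] / exp(-b_extra * s^2 / 4)
  refl
}

## ---- scaling and R factors -------------------------------------------------

#' Fit overall scale/B and compute R factors
#'
#' Fits k and overall B minimizing `sum((f_obs - k exp(-B s^2/4) |f_calc|)^2)`
#' over the working set, then reports
#' `R = sum|f_obs - k exp(-B s^2/4) |f_calc|| / sum f_obs` on the working and
#' free sets separately.
#'
#' @param refl `mr_reflections` with `f_obs` and `f_calc`.
#' @return List of class `mr_rfactors`: `r_work`, `r_free`, `scale`,
#'   `b_overall` (`r_free` is `NA` when no free flags are present).
#' @export
scale_and_r <- function(refl) {
  if (is.null(refl$f_obs) || is.null(refl$f_calc))
    stop("need both f_obs and f_calc")
  fo <- refl$f_obs; fc <- Mod(refl$f_calc); s2 <- (1 / refl$d)^2
  free <- if (!is.null(refl$free)) as.logical(refl$free) else rep(FALSE, nrow(refl))
  work <- !free
  if (!any(work)) stop("empty working set")
  kfit <- function(B, sel) {
    g <- exp(-B * s2[sel] / 4) * fc[sel]
    sum(fo[sel] * g) / sum(g^2)
  }
  obj <- function(B) {
    k <- kfit(B, work)
    sum((fo[work] - k * exp(-B * s2[work] / 4) * fc[work])^2)
  }
  B <- stats::optimize(obj, c(-100, 300))$minimum
  if (obj(0) <= obj(B)) B <- 0   # prefer the trivial scale when it is as good
  k <- kfit(B, work)
  pred <- k * exp(-B * s2 / 4) * fc
  r_of <- function(sel) if (any(sel)) sum(abs(fo[sel] - pred[sel])) / sum(fo[sel]) else NA_real_
  structure(list(r_work = r_of(work), r_free = if (any(free)) r_of(free) else NA_real_,
                 scale = k, b_overall = B),
            class = "mr_rfactors")
}

#' @export
print.mr_rfactors <- function(x, ...) {
  cat(sprintf("R_work %.4f  R_free %s  k %.3f  B %.1f\n", x$r_work,
              ifelse(is.na(x$r_free), "NA", sprintf("%.4f", x$r_free)),
              x$scale, x$b_overall))
  invisible(x)
}

#' Assign cross-validation (free) flags
#'
#' Deterministic under `seed`; one reflection is chosen per consecutive block
#' of about `1/fraction` reflections, so the realized fraction is within one
#' reflection of target per block.
#'
#' @param refl `mr_reflections` (at least 10 rows).
#' @param fraction Target free fraction in (0, 0.5).
#' @param seed Integer seed.
#' @export
assign_free_flags <- function(refl, fraction = 0.05, seed) {
  stopifnot(fraction > 0, fraction < 0.5)
  if (nrow(refl) < 10) stop("need at least 10 reflections for free flags")
  m <- max(2L, as.integer(round(1 / fraction)))
  n <- nrow(refl)
  free <- rep(FALSE, n)
  with_seed(seed, {
    starts <- seq(1, n, by = m)
    for (st in starts) {
      en <- min(st + m - 1, n)
      len <- en - st + 1
      if (len == m || stats::runif(1) < len / m)
        free[st - 1 + sample.int(len, 1)] <- TRUE
    }
  })
  refl$free <- free
  refl
}

## ---- maps ------------------------------------------------------------------

new_map <- function(grid, cell) {
  stopifnot(length(dim(grid)) == 3, all(dim(grid) >= 2))
  structure(list(grid = grid, cell = cell,
                 spacing = c(cell$a, cell$b, cell$c) / dim(grid)),
            class = "mr_map")
}

#' @export
print.mr_map <- function(x, ...) {
  cat(sprintf("density map %dx%dx%d, spacing %.2f/%.2f/%.2f A\n",
              dim(x$grid)[1], dim(x$grid)[2], dim(x$grid)[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Standardize a map to zero mean, unit variance
#' @param map `mr_map`.
#' @export
standardize_map <- function(map) {
  g <- map$grid
  sdv <- stats::sd(as.vector(g))
  if (sdv == 0) stop("zero-variance map")
  map$grid <- (g - mean(g)) / sdv
  map
}

#' Fourier synthesis of an electron-density map
#'
#' Computes `fo`, `two_fo_fc` (i.e. `2 m Fo - D Fc` reduced to plain
#' `2 Fo - Fc` with overall k/B scaling) or `fc` coefficients with
#' model phases, and transforms to a real-space grid with mean zero.
#'
#' @param refl `mr_reflections` with `f_calc` (phases) and, for observed-kind
#'   maps, `f_obs`.
#' @param kind One of `"fo"`, `"two_fo_fc"`, `"fc"`.
#' @param d_min Optional grid resolution (default the data limit).
#' @return `mr_map` on the standard grid for this cell/d_min.
#' @export
compute_map <- function(refl, kind = c("two_fo_fc", "fo", "fc"), d_min = NULL) {
  kind <- match.arg(kind)
  if (is.null(refl$f_calc)) stop("missing phases: f_calc not present")
  cell <- attr(refl, "cell")
  d_min <- d_min %||% min(refl$d)
  fc <- refl$f_calc
  if (!is.null(refl$f_obs)) {
    sc <- scale_and_r(refl)
    fc <- sc$scale * exp(-sc$b_overall * (1 / refl$d)^2 / 4) * fc
  }
  ph <- fc / ifelse(Mod(fc) > 0, Mod(fc), 1)
  coef <- switch(kind,
    fo = { if (is.null(refl$f_obs)) stop("fo map needs f_obs"); refl$f_obs * ph },
    two_fo_fc = { if (is.null(refl$f_obs)) stop("2Fo-Fc map needs f_obs")
                  (2 * refl$f_obs - Mod(fc)) * ph },
    fc = fc)
  synthesize_map(as.matrix(refl[, c("h", "k", "l")]), coef, cell, d_min)
}

synthesize_map <- function(H, coef, cell, d_min) {
  dims <- map_grid_dims(cell, d_min)
  Fg <- array(0i, dim = dims)
  put <- function(hkl, v) {
    idx <- sweep(hkl, 2, dims, "%%") + 1
    lin <- idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
    Fg[lin] <<- v
  }
  put(H, coef)
  put(-H, Conj(coef))
  rho <- Re(fft(Fg)) / cell_volume(cell)
  new_map(rho - mean(rho), cell)
}

#' Pearson correlation between two maps on identical grids
#' @param a,b `mr_map` objects with identical grid dimensions.
#' @export
map_correlation <- function(a, b) {
  if (!identical(dim(a$grid), dim(b$grid))) stop("map grids differ")
  va <- as.vector(a$grid); vb <- as.vector(b$grid)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) stop("zero-variance map")
  stats::cor(va, vb)
}

# Trilinear interpolation of map values at fractional coordinates (periodic).
interpolate_map <- function(map, frac) {
  dims <- dim(map$grid)
  out <- numeric(nrow(frac))
  g <- sweep(frac %% 1, 2, dims, "*")
  i0 <- floor(g); fr <- g - i0
  val <- function(di, dj, dk) {
    ii <- (i0[, 1] + di) %% dims[1] + 1
    jj <- (i0[, 2] + dj) %% dims[2] + 1
    kk <- (i0[, 3] + dk) %% dims[3] + 1
    map$grid[cbind(ii, jj, kk)]
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fr[, 1] else 1 - fr[, 1]) *
         (if (dj) fr[, 2] else 1 - fr[, 2]) *
         (if (dk) fr[, 3] else 1 - fr[, 3])
    out <- out + w * val(di, dj, dk)
  }
  out
}

# Tricubic (Catmull-Rom) interpolation, periodic; local, so robust for maps
# that are no longer band-limited (e.g. after masking).
interpolate_map_cubic <- function(map, frac) {
  dims <- dim(map$grid)
  g <- sweep(frac %% 1, 2, dims, "*")
  i0 <- floor(g); fr <- g - i0
  cr_w <- function(t) {
    t2 <- t * t; t3 <- t2 * t
    cbind(-0.5 * t3 + t2 - 0.5 * t,
          1.5 * t3 - 2.5 * t2 + 1,
          -1.5 * t3 + 2 * t2 + 0.5 * t,
          0.5 * t3 - 0.5 * t2)
  }
  wx <- cr_w(fr[, 1]); wy <- cr_w(fr[, 2]); wz <- cr_w(fr[, 3])
  out <- numeric(nrow(frac))
  for (a in 1:4) {
    ii <- (i0[, 1] + a - 2) %% dims[1] + 1
    for (b in 1:4) {
      jj <- (i0[, 2] + b - 2) %% dims[2] + 1
      wab <- wx[, a] * wy[, b]
      for (cc in 1:4) {
        kk <- (i0[, 3] + cc - 2) %% dims[3] + 1
        out <- out + wab * wz[, cc] * map$grid[cbind(ii, jj, kk)]
      }
    }
  }
  out
}

#' Model-to-map real-space fit scores
#'
#' The map is standardized; each atom contributes the occupancy-weighted
#' trilinearly interpolated density at its center. Residue scores are
#' occupancy-weighted means over the residue's atoms; the overall score is the
#' mean over residues. Higher is better.
#'
#' @param model `mr_model` (wrapped periodically into the cell).
#' @param map `mr_map`.
#' @return List: `per_residue` (data.frame chain, seqnum, score), `overall`,
#'   `per_atom`.
#' @export
real_space_fit <- function(model, map) {
  map <- standardize_map(map)
  frac <- model_fractional(model, map$cell)
  v <- interpolate_map(map, frac)
  key <- paste(model$chain, model$seqnum)
  num <- tapply(v * model$occ, key, sum)
  den <- tapply(model$occ, key, sum)
  if (any(den == 0)) stop("residue with zero total occupancy")
  first <- !duplicated(key)
  per <- data.frame(chain = model$chain[first], seqnum = model$seqnum[first])
  per$score <- as.numeric((num / den)[paste(per$chain, per$seqnum)])
  list(per_residue = per, overall = mean(per$score), per_atom = unname(v))
}

## ---- reflection file I/O ---------------------------------------------------

#' Read/write reflections as columnar text (h k l F SIGF FREE)
#'
#' @param path File path. Lines starting with `#` are ignored; a FREE column
#'   of 0/1 is optional.
#' @param cell `mr_cell` for d-spacings.
#' @param sym `mr_symops`.
#' @return `mr_reflections` with `f_obs`, `sigma` and optional `free`.
#' @export
read_reflections <- function(path, cell, sym) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(df) < 5) stop("expected columns: h k l F SIGF [FREE]")
  names(df)[1:5] <- c("h", "k", "l", "f_obs", "sigma")
  if (ncol(df) >= 6) { names(df)[6] <- "free"; df$free <- df$free != 0 }
  new_reflections(df[, intersect(c("h", "k", "l", "f_obs", "sigma", "free"),
                                 names(df))], cell, sym)
}

#' @param refl `mr_reflections` to write.
#' @rdname read_reflections
#' @export
write_reflections <- function(refl, path) {
  free <- if (!is.null(refl$free)) as.integer(refl$free) else 0L
  lines <- sprintf("%4d %4d %4d %12.4f %12.4f %2d",
                   refl$h, refl$k, refl$l, refl$f_obs,
                   refl$sigma %||% (0.05 * refl$f_obs), free)
  writeLines(c("#  h    k    l         FOBS         SIGF FREE", lines), path)
  invisible(path)
}
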