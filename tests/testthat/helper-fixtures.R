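# Shared fixtures (built once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small, fast P1 helix crystal with noise-free amplitudes
small_crystal <- function() cached("small_crystal", {
  spec <- fixture_spec(n_res = 14, fold = "helix", d_min = 3.0,
                       noise_frac = 0, seed = 21)
  tgt <- make_target(spec)
  refl <- sf_fft(tgt$model, tgt$cell, tgt$sym, 3.0)
  refl$f_obs <- Mod(refl$f_calc)
  refl$f_calc <- NULL
  refl <- assign_free_flags(refl, 0.05, 77)
  list(model = tgt$model, cell = tgt$cell, sym = tgt$sym, refl = refl)
})

# the standard study fixture (homolog template, noisy amplitudes)
standard_fixture <- function() cached("standard_fixture",
  make_mr_fixture(fixture_spec(seed = 101)))

# independent quaternion-method rigid superposition (Horn 1987), used as the
# oracle for the SVD-based implementation
quaternion_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  S <- crossprod(P0, Q0)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  t <- cq - as.vector(R %*% cp)
  moved <- P %*% t(R) + matrix(t, nrow(P), 3, byrow = TRUE)
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

# raw (no re-superposition) main-chain rmsd between two models
raw_mainchain_rmsd <- function(a, b) {
  pair <- micromr:::match_atoms(a, b, c("N", "CA", "C"))
  sqrt(mean(rowSums((as.matrix(pair$a[, c("x", "y", "z")]) -
                     as.matrix(pair$b[, c("x", "y", "z")]))^2)))
}

# toy 3-residue model with known coordinates for interpolation oracles
toy_tripeptide <- function() {
  tor <- data.frame(phi = c(NA, -57, -57), psi = c(-47, -47, NA),
                    omega = c(180, 180, NA))
  build_backbone(tor, c("ALA", "SER", "LEU"))
}

# independent oracle: intersect atom names, then close the set under the
# target topology's parent relation
intersection_oracle <- function(template_res, target_res) {
  ttop <- get_topology(target_res)
  stop_ <- names(get_topology(template_res))
  kept <- character(0)
  repeat {
    add <- setdiff(names(ttop)[vapply(names(ttop), function(a) {
      a %in% stop_ && (ttop[[a]] == "" || ttop[[a]] %in% kept)
    }, logical(1))], kept)
    if (!length(add)) break
    kept <- c(kept, add)
  }
  sort(kept)
}


ncs4 <- function() cached("ncs4", {
  spec <- fixture_spec(n_res = 12, fold = "helix", n_copies = 4, d_min = 3.0,
                       noise_frac = 0, seed = 2)
  tgt <- make_target(spec)
  refl <- sf_fft(tgt$model, tgt$cell, tgt$sym, 3.0)
  refl$f_obs <- Mod(refl$f_calc)
  map <- compute_map(refl, "fc")
  ops <- find_ncs_operators(tgt$model)
  list(tgt = tgt, refl = refl, map = map, ops = ops,
       chA = tgt$model[tgt$model$chain == "A", ],
       opsA = Filter(function(o) o$source_chain == "A", ops))
})

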