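#' Score weights for the combined geometry + density target
#'
#' The default geometry weight is chosen so that, on the standard synthetic
#' fixture, a correct ideal-geometry model is a stationary point of the
#' combined score in its own map (the density term alone would pull atoms
#' into series-termination ripples).
#'
#' @param w_geom,w_dens Non-negative weights (not both zero).
#' @export
score_weights <- function(w_geom = 4, w_dens = 1) {
  stopifnot(w_geom >= 0, w_dens >= 0, w_geom + w_dens > 0)
  list(w_geom = w_geom, w_dens = w_dens)
}

#' Monte-Carlo rebuild parameters
#'
#' Desk-scale defaults: 20 trajectories of 300 steps (a documented scale-down
#' from the thousands of models a production structure-modeling run would
#' build), loops up to 8 residues, temperature giving roughly 30% acceptance
#' on the standard synthetic fixture.
#'
#' @param n_models Independent MC trajectories.
#' @param n_steps MC steps per trajectory.
#' @param temperature Starting Metropolis acceptance scale (score units);
#'   annealed linearly to a tenth of this value over the trajectory.
#' @param max_loop_len Longest gap built as a loop, residues.
#' @param seed Integer seed; trajectory i uses `seed + i`.
#' @export
rebuild_params <- function(n_models = 20, n_steps = 300, temperature = 0.4,
                           max_loop_len = 8, seed = 1) {
  stopifnot(n_models >= 1, n_steps >= 0, temperature > 0)
  list(n_models = n_models, n_steps = n_steps, temperature = temperature,
       max_loop_len = max_loop_len, seed = seed)
}

## ---- fragment library ------------------------------------------------------

#' Packaged backbone fragment library
#'
#' A synthetic torsion library standing in for PDB-derived fragments:
#' canonical helix / strand / polyproline / turn / loop torsion triplets and
#' 9-mers plus seeded jittered variants (about 200 entries). Deterministic.
#'
#' @param n_variants Jittered variants per archetype and length.
#' @return Object of class `mr_fragment_library`: list of entries with
#'   `length`, `tag`, `phi`, `psi`, `omega`.
#' @export
default_fragment_library <- function(n_variants = 16) {
  arch3 <- list(helix = "helix", strand = "strand", ppii = "ppii",
                turn1 = "turn1", turn2 = "turn2", loop = "loop")
  arch9 <- list(helix = rep("helix", 9), strand = rep("strand", 9),
                helix_turn = c(rep("helix", 5), "turn1", "turn2", rep("helix", 2)),
                turn_helix = c("loop", "turn1", "turn2", rep("helix", 6)),
                hairpin = c(rep("strand", 3), "turn1", "turn2", "turn1",
                            rep("strand", 3)))
  entries <- list()
  with_seed(900001, {
    add <- function(classes, tag) {
      n <- length(classes)
      for (v in seq_len(n_variants)) {
        phi <- psi <- numeric(n)
        for (i in seq_len(n)) {
          ct <- CANONICAL_TORSIONS[[classes[i]]]
          jit <- if (v == 1) c(0, 0) else stats::rnorm(2, 0, 10)
          phi[i] <- ct["phi"] + jit[1]; psi[i] <- ct["psi"] + jit[2]
        }
        entries[[length(entries) + 1]] <<- list(
          length = n, tag = tag, phi = phi, psi = psi, omega = rep(180, n))
      }
    }
    for (nm in names(arch3)) add(rep(nm, 3), nm)
    for (nm in names(arch9)) add(arch9[[nm]], nm)
  })
  structure(list(entries = entries), class = "mr_fragment_library")
}

#' @export
print.mr_fragment_library <- function(x, ...) {
  lens <- vapply(x$entries, `[[`, numeric(1), "length")
  cat(sprintf("fragment library: %d entries (%d 3-mers, %d 9-mers)\n",
              length(lens), sum(lens == 3), sum(lens == 9)))
  invisible(x)
}

#' Read/write a fragment library as JSON
#' @param lib `mr_fragment_library`.
#' @param path File path.
#' @export
write_fragment_library <- function(lib, path) {
  jsonlite::write_json(lib$entries, path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' @rdname write_fragment_library
#' @export
read_fragment_library <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    list(length = e$length, tag = e$tag, phi = unlist(e$phi),
         psi = unlist(e$psi), omega = unlist(e$omega))
  })
  structure(list(entries = entries), class = "mr_fragment_library")
}

lib_pick <- function(lib, len) {
  cand <- Filter(function(e) e$length >= len, lib$entries)
  if (!length(cand)) stop("fragment library has no entries of length >= ", len)
  e <- cand[[sample.int(length(cand), 1)]]
  list(phi = e$phi[seq_len(len)], psi = e$psi[seq_len(len)],
       omega = e$omega[seq_len(len)])
}

## ---- chain state -----------------------------------------------------------

# Matrix-based backbone state for fast scoring/rebuilding of one chain.
chain_state <- function(model, chain) {
  m <- model[model$chain == chain, , drop = FALSE]
  sq <- sort(unique(m$seqnum))
  n <- length(sq)
  get <- function(nm) {
    out <- matrix(NA_real_, n, 3)
    sub <- m[m$atom == nm, , drop = FALSE]
    out[match(sub$seqnum, sq), ] <- as.matrix(sub[, c("x", "y", "z")])
    out
  }
  first <- m[!duplicated(m$seqnum), , drop = FALSE]
  list(chain = chain, seqnum = sq,
       resname = first$resname[match(sq, first$seqnum)],
       b = first$b[match(sq, first$seqnum)],
       N = get("N"), CA = get("CA"), C = get("C"), O = get("O"), CB = get("CB"))
}

state_to_model <- function(states, label = "") {
  rows <- list()
  for (st in states) {
    for (i in seq_along(st$seqnum)) {
      nm <- c("N", "CA", "C", "O", "CB")
      el <- c("N", "C", "C", "O", "C")
      for (k in seq_along(nm)) {
        xyz <- st[[nm[k]]][i, ]
        if (anyNA(xyz)) next
        rows[[length(rows) + 1]] <- data.frame(
          chain = st$chain, resname = st$resname[i], seqnum = st$seqnum[i],
          atom = nm[k], element = el[k], x = xyz[1], y = xyz[2], z = xyz[3],
          occ = 1, b = st$b[i])
      }
    }
  }
  mr_model(do.call(rbind, rows), label = label)
}

state_coords <- function(st) {
  xs <- rbind(st$N, st$CA, st$C, st$O, st$CB)
  xs[!is.na(xs[, 1]), , drop = FALSE]
}

## ---- geometry scoring ------------------------------------------------------

#' Geometry quality of a model
#'
#' A compact physical-plausibility surrogate: rms bond-length deviation from
#' ideal values (A), rms bond-angle deviation (degrees), count of non-bonded
#' atom pairs closer than 2.4 A (pairs from non-adjacent residues), and the
#' fraction of residues with backbone torsions outside broad allowed regions.
#'
#' @param model `mr_model` (backbone + CB).
#' @return List `bond_dev`, `angle_dev`, `clash`, `rama_outliers`.
#' @export
geometry_score <- function(model) {
  geometry_score_states(lapply(unique(model$chain),
                               function(ch) chain_state(model, ch)),
                        clash = count_clashes(model))
}

geometry_score_states <- function(states, clash = NULL) {
  bond_sq <- ang_sq <- numeric(0)
  rama_bad <- 0; rama_tot <- 0
  for (st in states) {
    n <- length(st$seqnum)
    len <- function(a, b) sqrt(rowSums((a - b)^2))
    dev <- c(len(st$N, st$CA) - IDEAL$n_ca,
             len(st$CA, st$C) - IDEAL$ca_c,
             len(st$C, st$O) - IDEAL$c_o,
             len(st$CA, st$CB) - IDEAL$ca_cb)
    consec <- which(diff(st$seqnum) == 1)
    if (length(consec))
      dev <- c(dev, len(st$C[consec, , drop = FALSE],
                        st$N[consec + 1, , drop = FALSE]) - IDEAL$c_n)
    bond_sq <- c(bond_sq, dev[!is.na(dev)]^2)
    angv <- function(a, b, c) {
      u <- a - b; v <- c - b
      cosv <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
      rad2deg(acos(pmin(1, pmax(-1, cosv))))
    }
    adev <- c(angv(st$N, st$CA, st$C) - IDEAL$ang_n_ca_c,
              angv(st$CA, st$C, st$O) - IDEAL$ang_ca_c_o)
    if (length(consec)) {
      adev <- c(adev,
                angv(st$CA[consec, , drop = FALSE], st$C[consec, , drop = FALSE],
                     st$N[consec + 1, , drop = FALSE]) - IDEAL$ang_ca_c_n,
                angv(st$C[consec, , drop = FALSE], st$N[consec + 1, , drop = FALSE],
                     st$CA[consec + 1, , drop = FALSE]) - IDEAL$ang_c_n_ca)
    }
    ang_sq <- c(ang_sq, adev[!is.na(adev)]^2)
    tor <- state_torsions(st)
    ok <- rama_allowed(tor$phi, tor$psi)
    rama_bad <- rama_bad + sum(!ok, na.rm = TRUE)
    rama_tot <- rama_tot + sum(!is.na(tor$phi) & !is.na(tor$psi))
  }
  list(bond_dev = if (length(bond_sq)) sqrt(mean(bond_sq)) else 0,
       angle_dev = if (length(ang_sq)) sqrt(mean(ang_sq)) else 0,
       clash = clash %||% count_clashes_states(states),
       rama_outliers = if (rama_tot) rama_bad / rama_tot else 0)
}

state_atom_table <- function(states) {
  xyz <- NULL; chain <- character(0); seqnum <- integer(0)
  for (st in states) {
    for (nm in c("N", "CA", "C", "O", "CB")) {
      keep <- !is.na(st[[nm]][, 1])
      if (!any(keep)) next
      xyz <- rbind(xyz, st[[nm]][keep, , drop = FALSE])
      chain <- c(chain, rep(st$chain, sum(keep)))
      seqnum <- c(seqnum, st$seqnum[keep])
    }
  }
  list(xyz = xyz, chain = chain, seqnum = seqnum)
}

count_clashes_states <- function(states, cutoff = 2.4) {
  at <- state_atom_table(states)
  count_clashes_xyz(at$xyz, at$chain, at$seqnum, cutoff)
}

count_clashes_xyz <- function(xyz, chain, seqnum, cutoff = 2.4) {
  n <- nrow(xyz)
  if (n < 2) return(0L)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  near <- d2 < cutoff^2
  excluded <- outer(chain, chain, "==") & abs(outer(seqnum, seqnum, "-")) <= 1
  near[excluded] <- FALSE
  near[lower.tri(near, diag = TRUE)] <- FALSE
  sum(near)
}

# Combined score evaluated directly on chain states (the MC inner loop).
score_states <- function(states, n_gaps, mapstd, w) {
  g <- geometry_score_states(states)
  dens <- 0
  if (w$w_dens > 0) {
    at <- state_atom_table(states)
    v <- interpolate_map(mapstd, at$xyz %*% t(frac_matrix(mapstd$cell)))
    key <- paste(at$chain, at$seqnum)
    per <- tapply(v, key, mean)
    dens <- mean(per)
    if (n_gaps > 0) dens <- dens * length(per) / (length(per) + n_gaps)
  }
  w$w_dens * dens -
    w$w_geom * (g$bond_dev + g$angle_dev / 50 + g$clash + 2 * g$rama_outliers)
}

state_torsions <- function(st) {
  n <- length(st$seqnum)
  phi <- psi <- rep(NA_real_, n)
  if (n >= 2) for (i in seq_len(n)) {
    if (i > 1 && st$seqnum[i] - st$seqnum[i - 1] == 1 &&
        !anyNA(c(st$C[i - 1, ], st$N[i, ], st$CA[i, ], st$C[i, ])))
      phi[i] <- dihedral_angle(st$C[i - 1, ], st$N[i, ], st$CA[i, ], st$C[i, ])
    if (i < n && st$seqnum[i + 1] - st$seqnum[i] == 1 &&
        !anyNA(c(st$N[i, ], st$CA[i, ], st$C[i, ], st$N[i + 1, ])))
      psi[i] <- dihedral_angle(st$N[i, ], st$CA[i, ], st$C[i, ], st$N[i + 1, ])
  }
  list(phi = phi, psi = psi)
}

# Broad allowed torsion regions: the generous left half-plane basin plus the
# left-handed helix box.
rama_allowed <- function(phi, psi) {
  general <- phi >= -180 & phi <= -20
  lalpha <- phi >= 20 & phi <= 100 & psi >= -30 & psi <= 110
  out <- general | lalpha
  out[is.na(phi) | is.na(psi)] <- NA
  out
}

count_clashes <- function(model, cutoff = 2.4) {
  count_clashes_xyz(as.matrix(model[, c("x", "y", "z")]), model$chain,
                    model$seqnum, cutoff)
}

#' Combined geometry + density score
#'
#' `w_dens * real_space_fit(model, map)$overall -
#'  w_geom * (bond_dev + angle_dev/50 + clash + 2*rama_outliers)`;
#' higher is better, deterministic.
#'
#' @param model `mr_model`.
#' @param map `mr_map` (standardized internally).
#' @param w [score_weights()].
#' @export
combined_score <- function(model, map, w = score_weights()) {
  if (nrow(model) == 0) stop("empty model")
  g <- geometry_score(model)
  dens <- if (w$w_dens > 0) real_space_fit(model, map)$overall else 0
  # unbuilt gap residues (the `gaps` attribute) contribute zero density fit,
  # so completing the model is rewarded the way added correct atoms lower an
  # R factor
  gaps <- attr(model, "gaps")
  if (length(gaps)) {
    n_res <- length(unique(paste(model$chain, model$seqnum)))
    dens <- dens * n_res / (n_res + length(gaps))
  }
  w$w_dens * dens -
    w$w_geom * (g$bond_dev + g$angle_dev / 50 + g$clash + 2 * g$rama_outliers)
}

## ---- CCD loop closure ------------------------------------------------------

# Cyclic coordinate descent: adjust the phi/psi pivots of a freshly built
# k-residue stretch so that the predicted next-residue N/CA meet their
# targets. N, CA, C are k x 3 matrices of the built atoms. Returns adjusted
# matrices plus the predicted anchor atoms.
ccd_close <- function(N, CA, C, targetN, targetCA, psi_last, sweeps = 4) {
  k <- nrow(N)
  pred <- function() {
    pN <- place_atom(N[k, ], CA[k, ], C[k, ], IDEAL$c_n, IDEAL$ang_ca_c_n, psi_last)
    pCA <- place_atom(CA[k, ], C[k, ], pN, IDEAL$n_ca, IDEAL$ang_c_n_ca, 180)
    rbind(pN, pCA)
  }
  targets <- rbind(targetN, targetCA)
  rotate_downstream <- function(origin, axis, theta, from_res, include_C_of) {
    R <- rotation_about_axis(axis, rad2deg(theta))
    rot <- function(x) as.vector(R %*% (x - origin)) + origin
    if (!is.na(include_C_of)) C[include_C_of, ] <<- rot(C[include_C_of, ])
    if (from_res <= k) for (i in from_res:k) {
      N[i, ] <<- rot(N[i, ]); CA[i, ] <<- rot(CA[i, ]); C[i, ] <<- rot(C[i, ])
    }
  }
  best_theta <- function(origin, axis, moving) {
    A <- 0; B <- 0
    for (j in seq_len(nrow(moving))) {
      m <- moving[j, ] - origin; t <- targets[j, ] - origin
      mp <- m - sum(m * axis) * axis
      tp <- t - sum(t * axis) * axis
      A <- A + sum(tp * mp)
      B <- B + sum(tp * c(axis[2] * mp[3] - axis[3] * mp[2],
                          axis[3] * mp[1] - axis[1] * mp[3],
                          axis[1] * mp[2] - axis[2] * mp[1]))
    }
    atan2(B, A)
  }
  for (sw in seq_len(sweeps)) {
    for (i in seq_len(k)) {
      # phi pivot: N_i -> CA_i (moves C_i and residues i+1..k)
      axis <- CA[i, ] - N[i, ]; axis <- axis / vnorm(axis)
      th <- best_theta(CA[i, ], axis, pred())
      rotate_downstream(CA[i, ], axis, th, i + 1, i)
      # psi pivot: CA_i -> C_i (moves residues i+1..k)
      axis <- C[i, ] - CA[i, ]; axis <- axis / vnorm(axis)
      th <- best_theta(C[i, ], axis, pred())
      rotate_downstream(C[i, ], axis, th, i + 1, NA)
    }
  }
  p <- pred()
  closure <- sqrt(mean(c(sum((p[1, ] - targetN)^2), sum((p[2, ] - targetCA)^2))))
  list(N = N, CA = CA, C = C, closure = closure)
}

## ---- window rebuilding -----------------------------------------------------

# Rebuild residues si..ei of a chain state from the anchor residue si-1 using
# the supplied torsions, closing internal windows onto the downstream residue
# by cyclic coordinate descent; returns the new state or NULL when closure
# exceeds `closure_tol`.
propose_window <- function(st, si, ei, frag, closure_tol = 0.5) {
  n <- length(st$seqnum)
  if (si < 2) return(NULL)
  if (anyNA(c(st$N[si - 1, ], st$CA[si - 1, ], st$C[si - 1, ]))) return(NULL)
  k <- ei - si + 1
  tor <- state_torsions(st)
  psi_prev <- tor$psi[si - 1]
  if (is.na(psi_prev)) psi_prev <- -45
  built <- grow_stretch(st$N[si - 1, ], st$CA[si - 1, ], st$C[si - 1, ],
                        psi_prev, frag, k)
  internal <- ei < n && st$seqnum[ei + 1] - st$seqnum[ei] == 1 &&
    !anyNA(c(st$N[ei + 1, ], st$CA[ei + 1, ]))
  if (internal) {
    cc <- ccd_close(built$N, built$CA, built$C, st$N[ei + 1, ], st$CA[ei + 1, ],
                    psi_last = frag$psi[k])
    if (cc$closure > closure_tol) return(NULL)
    built$N <- cc$N; built$CA <- cc$CA; built$C <- cc$C
    built <- distribute_residual(built, st$N[ei + 1, ], frag$psi[k])
  }
  new <- st
  idx <- si:ei
  new$N[idx, ] <- built$N; new$CA[idx, ] <- built$CA; new$C[idx, ] <- built$C
  fin <- finish_stretch(built, next_N = if (internal) st$N[ei + 1, ] else NULL,
                        psi_fallback = frag$psi, resnames = st$resname[idx])
  new$O[idx, ] <- fin$O
  has_cb <- !is.na(st$CB[idx, 1]) | toupper(st$resname[idx]) != "GLY"
  new$CB[idx, ][has_cb, ] <- fin$CB[has_cb, , drop = FALSE]
  new
}

# Chain extension of k residues from an anchor triad with fragment torsions.
grow_stretch <- function(prevN, prevCA, prevC, psi_prev, frag, k) {
  N <- CA <- C <- matrix(NA_real_, k, 3)
  for (i in seq_len(k)) {
    N[i, ] <- place_atom(prevN, prevCA, prevC, IDEAL$c_n, IDEAL$ang_ca_c_n, psi_prev)
    CA[i, ] <- place_atom(prevCA, prevC, N[i, ], IDEAL$n_ca, IDEAL$ang_c_n_ca,
                          frag$omega[i])
    C[i, ] <- place_atom(prevC, N[i, ], CA[i, ], IDEAL$ca_c, IDEAL$ang_n_ca_c,
                         frag$phi[i])
    prevN <- N[i, ]; prevCA <- CA[i, ]; prevC <- C[i, ]
    psi_prev <- frag$psi[i]
  }
  list(N = N, CA = CA, C = C)
}

# Spread any remaining closure residual linearly along the stretch.
distribute_residual <- function(built, targetN, psi_last) {
  k <- nrow(built$N)
  predN <- place_atom(built$N[k, ], built$CA[k, ], built$C[k, ],
                      IDEAL$c_n, IDEAL$ang_ca_c_n, psi_last)
  e <- targetN - predN
  for (i in seq_len(k)) {
    corr <- e * (i / (k + 1))
    built$N[i, ] <- built$N[i, ] + corr
    built$CA[i, ] <- built$CA[i, ] + corr
    built$C[i, ] <- built$C[i, ] + corr
  }
  built
}

# Carbonyl O and CB for a rebuilt stretch (O from the actual psi when the
# next N exists).
finish_stretch <- function(built, next_N, psi_fallback, resnames) {
  k <- nrow(built$N)
  O <- CB <- matrix(NA_real_, k, 3)
  for (i in seq_len(k)) {
    nn <- if (i < k) built$N[i + 1, ] else next_N
    psi <- if (!is.null(nn))
      dihedral_angle(built$N[i, ], built$CA[i, ], built$C[i, ], nn)
    else psi_fallback[i]
    O[i, ] <- place_atom(built$N[i, ], built$CA[i, ], built$C[i, ],
                         IDEAL$c_o, IDEAL$ang_ca_c_o, psi + 180)
    if (toupper(resnames[i]) != "GLY")
      CB[i, ] <- place_cb(built$N[i, ], built$CA[i, ], built$C[i, ])
  }
  list(O = O, CB = CB)
}

# Build `gap_seqnums` missing residues after state index ai (CCD-closed onto
# the following residue); returns the new state or NULL.
propose_loop <- function(st, ai, gap_seqnums, resnames, frag,
                         closure_tol = 0.5) {
  k <- length(gap_seqnums)
  n <- length(st$seqnum)
  if (ai < 1 || ai >= n) return(NULL)
  if (anyNA(c(st$N[ai, ], st$CA[ai, ], st$C[ai, ]))) return(NULL)
  tor <- state_torsions(st)
  psi_prev <- tor$psi[ai]
  if (is.na(psi_prev)) psi_prev <- -45
  built <- grow_stretch(st$N[ai, ], st$CA[ai, ], st$C[ai, ], psi_prev, frag, k)
  nx <- ai + 1
  closed <- FALSE
  if (nx <= n && !anyNA(c(st$N[nx, ], st$CA[nx, ]))) {
    cc <- ccd_close(built$N, built$CA, built$C, st$N[nx, ], st$CA[nx, ],
                    psi_last = frag$psi[k])
    if (cc$closure > closure_tol) return(NULL)
    built$N <- cc$N; built$CA <- cc$CA; built$C <- cc$C
    built <- distribute_residual(built, st$N[nx, ], frag$psi[k])
    closed <- TRUE
  }
  fin <- finish_stretch(built, next_N = if (closed) st$N[nx, ] else NULL,
                        psi_fallback = frag$psi, resnames = resnames)
  ins <- function(M, Mn) rbind(M[seq_len(ai), , drop = FALSE], Mn,
                               M[seq(ai + 1, n), , drop = FALSE])
  new <- st
  new$seqnum <- c(st$seqnum[seq_len(ai)], gap_seqnums, st$seqnum[seq(ai + 1, n)])
  new$resname <- c(st$resname[seq_len(ai)], resnames, st$resname[seq(ai + 1, n)])
  new$b <- c(st$b[seq_len(ai)], rep(st$b[ai], k), st$b[seq(ai + 1, n)])
  new$N <- ins(st$N, built$N); new$CA <- ins(st$CA, built$CA)
  new$C <- ins(st$C, built$C); new$O <- ins(st$O, fin$O)
  new$CB <- ins(st$CB, fin$CB)
  new
}

## ---- Monte-Carlo rebuild ---------------------------------------------------

#' Density-guided Monte-Carlo fragment rebuilding
#'
#' Runs `params$n_models` independent trajectories (trajectory i seeded
#' `seed + i`). Each step picks a random rebuild window (3 residues, or 9 for
#' long segments) or an unbuilt gap (from the `gaps` attribute, up to
#' `max_loop_len` residues), proposes fragment torsions rebuilt by
#' ideal-geometry chain extension with endpoint closure (<= 0.5 A for
#' segment-internal windows; free chain ends exempt), and accepts by
#' Metropolis on the combined score.
#'
#' @param model `mr_model` (contiguous segments of >= 3 residues).
#' @param map `mr_map` the rebuild is scored against.
#' @param lib [default_fragment_library()].
#' @param params [rebuild_params()].
#' @param w [score_weights()].
#' @param focus_seqnums Optional residue numbers; when given, windows are
#'   restricted to those overlapping them.
#' @return List of `params$n_models` end-of-trajectory models, each with
#'   attribute `score`.
#' @export
rebuild_model <- function(model, map, lib, params = rebuild_params(),
                          w = score_weights(), focus_seqnums = NULL) {
  mapstd <- standardize_map(map)
  chains <- unique(model$chain)
  gaps <- attr(model, "gaps") %||% integer(0)
  target_seq <- attr(model, "target_seq")
  out <- vector("list", params$n_models)
  for (tr in seq_len(params$n_models)) {
    out[[tr]] <- with_seed(params$seed + tr, {
      states <- lapply(chains, function(ch) chain_state(model, ch))
      gaps_tr <- gaps
      cur_score <- score_states(states, length(gaps_tr), mapstd, w)
      n_acc <- 0L; n_prop <- 0L
      for (step in seq_len(params$n_steps)) {
        ci <- if (length(states) > 1) sample.int(length(states), 1) else 1L
        st <- states[[ci]]
        move <- propose_move(st, lib, gaps_tr, target_seq, params, focus_seqnums)
        if (is.null(move)) next
        cand_states <- states
        cand_states[[ci]] <- move
        cand_gaps <- setdiff(gaps_tr, move$built %||% integer(0))
        cand_score <- score_states(cand_states, length(cand_gaps), mapstd, w)
        n_prop <- n_prop + 1L
        d <- cand_score - cur_score
        # linear annealing toward a tenth of the starting temperature, so
        # trajectories explore early and settle near a local optimum
        temp <- params$temperature *
          (1 - 0.9 * (step - 1) / max(1, params$n_steps - 1))
        if (d >= 0 || stats::runif(1) < exp(d / temp)) {
          n_acc <- n_acc + 1L
          states <- cand_states
          cur_score <- cand_score
          gaps_tr <- cand_gaps
        }
      }
      cur <- state_to_model(states, label = attr(model, "label") %||% "")
      attr(cur, "accept_rate") <- if (n_prop) n_acc / n_prop else NA_real_
      attr(cur, "score") <- cur_score
      attr(cur, "gaps") <- gaps_tr
      attr(cur, "target_seq") <- target_seq
      cur
    })
  }
  out
}

# One random proposal: a window rebuild or a gap (loop) build.
propose_move <- function(st, lib, gaps, target_seq, params, focus_seqnums) {
  n <- length(st$seqnum)
  # candidate gap builds: runs of missing numbers anchored inside this chain
  gap_runs <- list()
  if (length(gaps) && !is.null(target_seq)) {
    runs <- split(sort(gaps), cumsum(c(1, diff(sort(gaps))) != 1))
    for (r in runs) {
      if (length(r) > params$max_loop_len) next
      ai <- match(min(r) - 1, st$seqnum)
      if (!is.na(ai)) gap_runs[[length(gap_runs) + 1]] <- list(ai = ai, run = r)
    }
  }
  # candidate rebuild windows: 3-mers (and 9-mers in long segments)
  starts3 <- which(seq_len(n) >= 2 & seq_len(n) + 2 <= n)
  starts3 <- starts3[st$seqnum[starts3 + 2] - st$seqnum[starts3] == 2]
  starts9 <- which(seq_len(n) >= 2 & seq_len(n) + 8 <= n)
  starts9 <- starts9[st$seqnum[starts9 + 8] - st$seqnum[starts9] == 8]
  if (!is.null(focus_seqnums)) {
    touches <- function(s, len) any((st$seqnum[s] + 0:(len - 1)) %in% focus_seqnums)
    starts3 <- starts3[vapply(starts3, touches, logical(1), len = 3)]
    starts9 <- starts9[vapply(starts9, touches, logical(1), len = 9)]
  }
  n_win <- length(starts3) + length(starts9)
  if (!length(gap_runs) && !n_win) return(NULL)
  # unbuilt gaps are the scarcer, higher-value moves: try them half the time
  if (length(gap_runs) && (!n_win || stats::runif(1) < 0.5)) {
    gr <- gap_runs[[sample.int(length(gap_runs), 1)]]
    res1 <- strsplit(target_seq, "")[[1]][gr$run]
    # closure is the bottleneck for loop insertion; sample fragments until
    # one closes (looser tolerance than window splices, the residual is
    # distributed along the loop)
    for (try in 1:10) {
      new <- propose_loop(st, gr$ai, gr$run, aa_three(res1),
                          lib_pick(lib, length(gr$run)), closure_tol = 1.0)
      if (!is.null(new)) {
        new$built <- gr$run
        return(new)
      }
    }
    return(NULL)
  }
  if (!n_win) return(NULL)
  pick <- sample.int(n_win, 1)
  if (pick <= length(starts3)) {
    si <- starts3[pick]
    propose_window(st, si, si + 2, lib_pick(lib, 3))
  } else {
    si <- starts9[pick - length(starts3)]
    propose_window(st, si, si + 8, lib_pick(lib, 9))
  }
}

#' Rebuild one NCS copy and replicate it to all copies
#'
#' The reference copy (source chain of the operators) is rebuilt against the
#' map; the best-scoring result is copied through each operator, replacing
#' every target chain, so the output has exact (idealized) NCS.
#'
#' @param model Multi-copy `mr_model`.
#' @param map `mr_map`.
#' @param ops Operators from [find_ncs_operators()] with a common source
#'   chain (identity-only lists are allowed and mean "single copy").
#' @param lib,params,w As in [rebuild_model()].
#' @return Rebuilt `mr_model` with exact NCS.
#' @export
rebuild_with_ncs <- function(model, map, ops, lib, params = rebuild_params(),
                             w = score_weights()) {
  is_ident <- function(op) max(abs(op$rotation - diag(3))) < 1e-12 &&
    max(abs(op$translation)) < 1e-12
  ops <- reference_ops(ops)
  live <- Filter(Negate(is_ident), ops)
  ref_chain <- if (length(ops)) ops[[1]]$source_chain else model$chain[1]
  if (length(live)) {
    tgt <- unique(vapply(live, `[[`, character(1), "target_chain"))
    if (!all(c(ref_chain, tgt) %in% unique(model$chain)))
      stop("operators inconsistent with model chains")
  }
  ref <- model[model$chain == ref_chain, , drop = FALSE]
  attr(ref, "gaps") <- attr(model, "gaps")
  attr(ref, "target_seq") <- attr(model, "target_seq")
  builds <- rebuild_model(ref, map, lib, params, w)
  best <- builds[[which.max(vapply(builds, attr, numeric(1), "score"))]]
  pieces <- list(best)
  for (op in live) {
    cp <- transform_model(best, op$rotation, op$translation)
    cp$chain <- op$target_chain
    pieces[[length(pieces) + 1]] <- cp
  }
  keep <- model[!(model$chain %in% c(ref_chain,
                                     vapply(live, `[[`, character(1),
                                            "target_chain"))), , drop = FALSE]
  if (nrow(keep)) pieces[[length(pieces) + 1]] <- keep
  out <- mr_model(do.call(rbind, pieces), label = attr(model, "label") %||% "")
  attr(out, "gaps") <- attr(best, "gaps")
  attr(out, "target_seq") <- attr(model, "target_seq")
  attr(out, "cell") <- attr(model, "cell")
  out
}

## ---- real-space refinement -------------------------------------------------

#' Real-space refinement of atomic coordinates
#'
#' Maximizes the combined score over all coordinates by gradient ascent with
#' a backtracking line search on the true score (analytic gradients for the
#' density and bond/angle restraint terms; clash and torsion-region terms
#' enter through the acceptance test). The per-iteration shift of any atom is
#' capped at 0.5 A, and the score never decreases.
#'
#' @param model `mr_model`.
#' @param map `mr_map`.
#' @param w [score_weights()].
#' @param max_iter Maximum gradient iterations.
#' @return Refined `mr_model` with attribute `score`.
#' @export
refine_real_space <- function(model, map, w = score_weights(), max_iter = 50,
                              upsample = 3) {
  # refine on a band-limited upsampled grid: the trilinear score landscape on
  # the raw synthesis grid has its maxima at grid nodes, which would lock
  # atoms to the grid
  mapstd <- standardize_map(if (upsample > 1) upsample_map(map, upsample) else map)
  cur <- model
  cur_score <- combined_score(cur, mapstd, w)
  if (!is.finite(cur_score)) stop("non-finite starting score")
  # stage 1: rigid-body fit (geometry-invariant, so pure density gain)
  if (w$w_dens > 0) {
    ctr <- colMeans(as.matrix(cur[, c("x", "y", "z")]))
    rb_obj <- function(p) {
      R <- euler_zyz(p[1], p[2], p[3])
      m <- transform_model(cur, R, ctr - as.vector(R %*% ctr) + p[4:6])
      -real_space_fit(m, mapstd)$overall
    }
    opt <- stats::optim(rep(0, 6), rb_obj, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-7))
    R <- euler_zyz(opt$par[1], opt$par[2], opt$par[3])
    cand <- transform_model(cur, R, ctr - as.vector(R %*% ctr) + opt$par[4:6])
    cand_score <- combined_score(cand, mapstd, w)
    # a material-gain threshold keeps the rigid stage from chasing the tiny
    # series-termination offset of the density optimum at convergence
    if (is.finite(cand_score) && cand_score > cur_score + 0.02) {
      cur <- cand; cur_score <- cand_score
    }
  }
  step <- 0.25
  topo <- geometry_topology(cur)
  for (it in seq_len(max_iter)) {
    g <- score_gradient(cur, mapstd, w, topo)
    gmax <- max(sqrt(rowSums(g^2)))
    if (gmax < 1e-8) break
    improved <- FALSE
    s <- min(step, 0.5 / gmax)
    for (try in 1:8) {
      cand <- cur
      cand$x <- cur$x + s * g[, 1]
      cand$y <- cur$y + s * g[, 2]
      cand$z <- cur$z + s * g[, 3]
      cand_score <- combined_score(cand, mapstd, w)
      if (is.finite(cand_score) && cand_score > cur_score) {
        cur <- cand; cur_score <- cand_score
        step <- s * 2
        improved <- TRUE
        break
      }
      s <- s / 2
    }
    if (!improved) break
  }
  attr(cur, "score") <- cur_score
  cur
}

# Gradient of the smooth part of the combined score w.r.t. all coordinates.
score_gradient <- function(model, mapstd, w, topo = geometry_topology(model)) {
  n <- nrow(model)
  g <- matrix(0, n, 3)
  if (w$w_dens > 0) {
    frac <- model_fractional(model, mapstd$cell)
    dg <- interpolate_map_gradient(mapstd, frac)   # d value / d frac
    dcart <- dg %*% frac_matrix(mapstd$cell)        # chain rule to Cartesian
    key <- paste(model$chain, model$seqnum)
    occ_sum <- as.numeric(tapply(model$occ, key, sum)[key])
    n_res <- length(unique(key))
    g <- g + w$w_dens * (model$occ / occ_sum / n_res) * dcart
  }
  if (w$w_geom > 0) {
    g <- g - w$w_geom * geometry_gradient(model, topo)
  }
  g
}

# Bond and angle index tables for a model (precomputed once per refinement).
geometry_topology <- function(model) {
  key <- paste(model$chain, model$seqnum, model$atom)
  look <- function(ch, sq, at) match(paste(ch, sq, at), key)
  bonds <- NULL; angles <- NULL
  for (ch in unique(model$chain)) {
    sq <- sort(unique(model$seqnum[model$chain == ch]))
    iN <- look(ch, sq, "N"); iCA <- look(ch, sq, "CA"); iC <- look(ch, sq, "C")
    iO <- look(ch, sq, "O"); iCB <- look(ch, sq, "CB")
    nxt <- match(sq + 1, sq)
    iN2 <- iN[nxt]; iCA2 <- iCA[nxt]
    add_b <- function(i, j, l0) {
      ok <- !is.na(i) & !is.na(j)
      bonds <<- rbind(bonds, cbind(i[ok], j[ok], l0))
    }
    add_a <- function(i, j, k, a0) {
      ok <- !is.na(i) & !is.na(j) & !is.na(k)
      angles <<- rbind(angles, cbind(i[ok], j[ok], k[ok], a0))
    }
    add_b(iN, iCA, IDEAL$n_ca); add_b(iCA, iC, IDEAL$ca_c)
    add_b(iC, iO, IDEAL$c_o); add_b(iCA, iCB, IDEAL$ca_cb)
    add_b(iC, iN2, IDEAL$c_n)
    add_a(iN, iCA, iC, IDEAL$ang_n_ca_c)
    add_a(iCA, iC, iO, IDEAL$ang_ca_c_o)
    add_a(iCA, iC, iN2, IDEAL$ang_ca_c_n)
    add_a(iC, iN2, iCA2, IDEAL$ang_c_n_ca)
  }
  list(bonds = bonds, angles = angles)
}

# Gradient (d/dxyz) of bond_dev + angle_dev/50 (the smooth geometry terms),
# fully vectorized over the precomputed topology.
geometry_gradient <- function(model, topo = geometry_topology(model)) {
  n <- nrow(model)
  xyz <- as.matrix(model[, c("x", "y", "z")])
  g <- matrix(0, n, 3)
  accum <- function(g, idx, contrib) {
    for (ax in 1:3) {
      v <- rowsum(contrib[, ax], idx)
      rows <- as.integer(rownames(v))
      g[rows, ax] <- g[rows, ax] + v[, 1]
    }
    g
  }
  B <- topo$bonds
  if (!is.null(B) && nrow(B)) {
    d <- xyz[B[, 1], , drop = FALSE] - xyz[B[, 2], , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    dev <- len - B[, 3]
    rms <- sqrt(mean(dev^2))
    if (rms > 1e-12) {
      coef <- dev / (nrow(B) * rms)
      u <- d / len
      g <- accum(g, B[, 1], coef * u)
      g <- accum(g, B[, 2], -coef * u)
    }
  }
  A <- topo$angles
  if (!is.null(A) && nrow(A)) {
    p1 <- xyz[A[, 1], , drop = FALSE]
    p2 <- xyz[A[, 2], , drop = FALSE]
    p3 <- xyz[A[, 3], , drop = FALSE]
    u <- p1 - p2; v <- p3 - p2
    lu <- sqrt(rowSums(u^2)); lv <- sqrt(rowSums(v^2))
    cosv <- rowSums(u * v) / (lu * lv)
    cosv <- pmin(1 - 1e-9, pmax(-1 + 1e-9, cosv))
    th <- acos(cosv)
    dev <- rad2deg(th) - A[, 4]
    rms <- sqrt(mean(dev^2))
    if (rms > 1e-12) {
      sinv <- sqrt(1 - cosv^2)
      dth_du <- -(v / (lu * lv) - cosv * u / lu^2) / sinv
      dth_dv <- -(u / (lu * lv) - cosv * v / lv^2) / sinv
      coef <- rad2deg(1) * dev / (nrow(A) * rms) / 50
      g1 <- coef * dth_du
      g3 <- coef * dth_dv
      g <- accum(g, A[, 1], g1)
      g <- accum(g, A[, 3], g3)
      g <- accum(g, A[, 2], -g1 - g3)
    }
  }
  g
}

# Trilinear interpolation gradient w.r.t. fractional coordinates.
interpolate_map_gradient <- function(map, frac) {
  dims <- dim(map$grid)
  g <- sweep(frac %% 1, 2, dims, "*")
  i0 <- floor(g); fr <- g - i0
  out <- matrix(0, nrow(frac), 3)
  val <- function(di, dj, dk) {
    ii <- (i0[, 1] + di) %% dims[1] + 1
    jj <- (i0[, 2] + dj) %% dims[2] + 1
    kk <- (i0[, 3] + dk) %% dims[3] + 1
    map$grid[cbind(ii, jj, kk)]
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    v <- val(di, dj, dk)
    wx <- if (di) fr[, 1] else 1 - fr[, 1]
    wy <- if (dj) fr[, 2] else 1 - fr[, 2]
    wz <- if (dk) fr[, 3] else 1 - fr[, 3]
    sx <- if (di) 1 else -1
    sy <- if (dj) 1 else -1
    sz <- if (dk) 1 else -1
    out[, 1] <- out[, 1] + sx * wy * wz * v * dims[1]
    out[, 2] <- out[, 2] + sy * wx * wz * v * dims[2]
    out[, 3] <- out[, 3] + sz * wx * wy * v * dims[3]
  }
  out
}

## ---- model selection and pruning -------------------------------------------

#' Select top models by amplitude correlation
#'
#' Models are scored by `cor(f_obs, |f_calc|)` after structure-factor
#' calculation (the same common criterion used to rescore molecular
#' replacement solutions); the top `n` are returned in stable order.
#'
#' @param models List of `mr_model`.
#' @param refl `mr_reflections` with `f_obs`.
#' @param cell,sym Crystal frame.
#' @param n Number to keep (default 2).
#' @return List of the top models, each with attribute `amp_cor`.
#' @export
select_top_models <- function(models, refl, cell, sym, n = 2) {
  stopifnot(n >= 1)
  if (n > length(models)) {
    warning("asked for ", n, " models but only ", length(models), " given")
    n <- length(models)
  }
  H <- as.matrix(refl[, c("h", "k", "l")])
  sc <- vapply(models, function(m)
    stats::cor(refl$f_obs, Mod(sf_direct(m, cell, sym, H))), numeric(1))
  ord <- order(-sc)
  out <- models[ord[seq_len(n)]]
  for (i in seq_len(n)) attr(out[[i]], "amp_cor") <- sc[ord[i]]
  out
}

#' Drop chains that could not be assigned to the target sequence
#'
#' Chains flagged unassigned (all residues UNK) are removed before further
#' rebuilding, which requires sequence knowledge.
#'
#' @param model `mr_model`.
#' @param target_seq Target sequence (unused in the decision, kept for the
#'   call signature symmetry with the rebuild steps).
#' @export
discard_unassigned <- function(model, target_seq = NULL) {
  keep <- vapply(unique(model$chain), function(ch)
    !all(model$resname[model$chain == ch] == "UNK"), logical(1))
  kept <- unique(model$chain)[keep]
  out <- model[model$chain %in% kept, , drop = FALSE]
  for (a in c("gaps", "target_seq", "cell", "spacegroup_name"))
    attr(out, a) <- attr(model, a)
  out
}

## ---- autobuild iteration ---------------------------------------------------

#' Iterative autobuilding against the data
#'
#' Cycles of structure-factor calculation, scaling, 2Fo-Fc synthesis,
#' density modification, Monte-Carlo rebuilding of the worst-fitting 20% of
#' residues, real-space refinement, and pruning of residues fitting worse
#' than (mean - 2 sd). Iterates until the working R changes by less than
#' `r_tol`, the cycle limit is reached, or R has risen three cycles in a row;
#' the lowest-R model and its density-modified map are returned.
#'
#' @param model Placed `mr_model`.
#' @param refl `mr_reflections` with `f_obs` and free flags.
#' @param lib,params,w As in [rebuild_model()].
#' @param r_tol Convergence tolerance on R_work.
#' @param max_cycles Cycle limit.
#' @param dm_cycles Density-modification cycles per autobuild cycle.
#' @param verbose Print per-cycle R values.
#' @return List `model`, `map`, `report` ([scale_and_r()] of the best cycle),
#'   `history` (per-cycle data.frame).
#' @export
autobuild_iterate <- function(model, refl, lib, params = rebuild_params(),
                              w = score_weights(), r_tol = 0.005,
                              max_cycles = 5, dm_cycles = 3, verbose = FALSE) {
  cell <- attr(refl, "cell"); sym <- attr(refl, "sym")
  d_min <- min(refl$d)
  hist <- data.frame()
  best <- NULL
  prev_r <- NA
  rises <- 0
  cur <- model
  for (cy in seq_len(max_cycles)) {
    fc <- sf_fft(cur, cell, sym, d_min, hkl = refl)
    rfl <- refl
    rfl$f_calc <- fc$f_calc
    rep <- scale_and_r(rfl)
    map <- compute_map(rfl, "two_fo_fc")
    ops <- find_ncs_operators(cur)
    solv <- solvent_fraction_of(cur, cell, sym)
    dm <- density_modify(map, rfl, cur, solv, n_cycles = dm_cycles, ops = ops)
    if (is.null(best) || rep$r_work < best$report$r_work)
      best <- list(model = cur, map = dm, report = rep)
    hist <- rbind(hist, data.frame(cycle = cy, r_work = rep$r_work,
                                   r_free = rep$r_free))
    if (verbose) message(sprintf("cycle %d: R_work %.4f R_free %.4f",
                                 cy, rep$r_work, rep$r_free))
    if (!is.na(prev_r)) {
      if (abs(rep$r_work - prev_r) < r_tol) break
      rises <- if (rep$r_work > prev_r) rises + 1 else 0
      if (rises >= 3) break
    }
    prev_r <- rep$r_work
    if (cy == max_cycles) break
    # rebuild the worst-fitting 20% of residues, then refine
    fit <- real_space_fit(cur, dm)
    worst <- fit$per_residue$seqnum[order(fit$per_residue$score)]
    worst <- worst[seq_len(max(1, floor(0.2 * length(worst))))]
    p_in <- params
    p_in$n_models <- min(params$n_models, 4)
    p_in$n_steps <- max(20, round(params$n_steps / 3))
    p_in$seed <- params$seed + 97 * cy
    builds <- rebuild_model(cur, dm, lib, p_in, w, focus_seqnums = worst)
    cand <- builds[[which.max(vapply(builds, attr, numeric(1), "score"))]]
    cand <- refine_real_space(cand, dm, w)
    # prune residues fitting much worse than the rest
    fit2 <- real_space_fit(cand, dm)
    thr <- mean(fit2$per_residue$score) - 2 * stats::sd(fit2$per_residue$score)
    bad <- fit2$per_residue[fit2$per_residue$score < thr, , drop = FALSE]
    if (nrow(bad) && nrow(bad) < length(unique(paste(cand$chain, cand$seqnum)))) {
      drop <- paste(cand$chain, cand$seqnum) %in% paste(bad$chain, bad$seqnum)
      pruned <- cand[!drop, , drop = FALSE]
      for (a in c("gaps", "target_seq")) attr(pruned, a) <- attr(cand, a)
      cand <- pruned
    }
    cur <- cand
  }
  list(model = best$model, map = best$map, report = best$report, history = hist)
}

#' Matthews solvent fraction of a model in its cell
#' @param model,cell,sym Crystal content.
#' @export
solvent_fraction_of <- function(model, cell, sym) {
  vm <- cell_volume(cell) / (n_symops(sym) * model_mass(model))
  min(0.8, max(0.2, 1 - 1.23 / vm))
}
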