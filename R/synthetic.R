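# Residue alphabet used by the generators: the 18 standard types other than
# GLY and PRO, whose special backbones the toy fixtures do not exercise.
SYNTH_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "H", "I", "L", "K",
                    "M", "F", "S", "T", "W", "Y", "V")

#' Specification of a synthetic toy crystal
#'
#' Defaults are the package's standard study conditions: a 30-residue
#' helix-turn-helix in P1, one copy, 2.5 A data with 5% relative amplitude
#' noise, templates perturbed to 1.5 A main-chain rmsd at 30% sequence
#' identity (emulating the marginal-template regime where density-guided
#' rebuilding matters).
#'
#' @param n_res Residues per chain.
#' @param fold `"helix"` or `"helix-turn-helix"`.
#' @param spacegroup Space-group label (built-ins: P1, P21, P212121).
#' @param n_copies Copies in the asymmetric unit.
#' @param d_min Resolution limit, Angstrom (>= 1.5).
#' @param noise_frac Relative Gaussian amplitude noise.
#' @param perturb_rmsd Target template main-chain rmsd, Angstrom.
#' @param identity Target template sequence identity, (0, 1].
#' @param seed Integer seed; all fixture randomness derives from it.
#' @return List of class `mr_fixture_spec`.
#' @export
fixture_spec <- function(n_res = 30, fold = "helix-turn-helix", spacegroup = "P1",
                         n_copies = 1, d_min = 2.5, noise_frac = 0.05,
                         perturb_rmsd = 1.5, identity = 0.3, seed = 1) {
  stopifnot(d_min >= 1.5, perturb_rmsd >= 0, identity > 0, identity <= 1,
            n_res >= 6, n_copies >= 1)
  structure(list(n_res = n_res, fold = fold, spacegroup = spacegroup,
                 n_copies = n_copies, d_min = d_min, noise_frac = noise_frac,
                 perturb_rmsd = perturb_rmsd, identity = identity, seed = seed),
            class = "mr_fixture_spec")
}

fold_torsions <- function(n_res, fold) {
  jit <- function(x, s = 3) x + stats::rnorm(length(x), 0, s)
  phi <- rep(CANONICAL_TORSIONS$helix["phi"], n_res)
  psi <- rep(CANONICAL_TORSIONS$helix["psi"], n_res)
  if (fold == "helix-turn-helix") {
    t0 <- floor(n_res * 0.45)
    turn <- t0:(t0 + 3)
    pool <- CANONICAL_TORSIONS[c("turn1", "turn2", "loop", "ppii")]
    for (i in turn) {
      pick <- pool[[sample.int(length(pool), 1)]]
      phi[i] <- jit(pick["phi"], 10); psi[i] <- jit(pick["psi"], 10)
    }
  } else if (fold != "helix") stop("unknown fold '", fold, "'")
  data.frame(phi = jit(phi), psi = jit(psi), omega = rep(180, n_res))
}

#' Generate a toy crystal: model, cell and symmetry
#'
#' Builds ideal-geometry chain(s) from canonical torsions (seeded jitter,
#' randomized turn torsions), places extra copies by random rigid motions
#' without clashes, and sizes a cell for roughly 50% solvent.
#'
#' @param spec `mr_fixture_spec`.
#' @return List `model` (`mr_model`), `cell`, `sym`, plus `ncs` (list of the
#'   generating rigid motions for copies beyond the first).
#' @export
make_target <- function(spec) {
  sym <- spacegroup(spec$spacegroup)
  for (attempt in 0:9) {
    res <- with_seed(derive_seed(spec$seed, "synth", attempt), {
      seq3 <- aa_three(sample(SYNTH_ALPHABET, spec$n_res, replace = TRUE))
      chain1 <- build_backbone(fold_torsions(spec$n_res, spec$fold), seq3)
      chains <- list(chain1)
      ncs <- list()
      if (spec$n_copies > 1) {
        for (ci in 2:spec$n_copies) {
          ok <- FALSE
          for (try in 1:50) {
            ax <- stats::rnorm(3); ax <- ax / vnorm(ax)
            ang <- stats::runif(1, 30, 330)
            R <- rotation_about_axis(ax, ang)
            ctr <- colMeans(as.matrix(chain1[, c("x", "y", "z")]))
            dir <- stats::rnorm(3); dir <- dir / vnorm(dir)
            shift <- ctr - as.vector(R %*% ctr) + dir * stats::runif(1, 16, 22)
            cand <- transform_model(chain1, R, shift)
            cand$chain <- LETTERS[ci]
            if (min_intermodel_dist(do.call(rbind, chains), cand) > 4.5) {
              chains[[ci]] <- cand
              ncs[[length(ncs) + 1]] <- list(rotation = R, translation = shift,
                                             source_chain = "A",
                                             target_chain = LETTERS[ci])
              ok <- TRUE; break
            }
          }
          if (!ok) return(NULL)
        }
      }
      model <- mr_model(do.call(rbind, chains), label = "synthetic target")
      list(model = model, ncs = ncs)
    })
    if (!is.null(res)) {
      model <- res$model
      cell <- size_cell(model, sym, spec$n_copies)
      ctr_before <- colMeans(as.matrix(model[, c("x", "y", "z")]))
      model <- center_in_cell(model, cell, sym)
      shift <- colMeans(as.matrix(model[, c("x", "y", "z")])) - ctr_before
      # re-express generating motions in the shifted frame
      ncs <- lapply(res$ncs, function(o) {
        o$translation <- o$translation + shift - as.vector(o$rotation %*% shift)
        o
      })
      attr(model, "cell") <- cell
      attr(model, "spacegroup_name") <- sym$name
      return(list(model = model, cell = cell, sym = sym, ncs = ncs))
    }
  }
  stop("could not pack ", spec$n_copies, " copies without clashes in 10 attempts")
}

rotation_about_axis <- function(axis, angle_deg) {
  t <- deg2rad(angle_deg); c <- cos(t); s <- sin(t)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(c + x^2*(1-c),   x*y*(1-c) - z*s, x*z*(1-c) + y*s,
           x*y*(1-c) + z*s, c + y^2*(1-c),   y*z*(1-c) - x*s,
           x*z*(1-c) - y*s, y*z*(1-c) + x*s, c + z^2*(1-c)),
         3, 3, byrow = TRUE)
}

min_intermodel_dist <- function(a, b) {
  xa <- as.matrix(a[, c("x", "y", "z")]); xb <- as.matrix(b[, c("x", "y", "z")])
  min(sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)))
}

# Cell sized for ~50% solvent via the Matthews relation, at least bounding
# box + margin on every axis so the molecule (and its symmetry mates, for the
# primitive built-in groups) fits without overlap.
size_cell <- function(model, sym, n_copies) {
  mass <- model_mass(model)
  vol_target <- 2.46 * mass * n_symops(sym)   # Vm at 50% solvent, Da -> A^3
  xyz <- as.matrix(model[, c("x", "y", "z")])
  box <- apply(xyz, 2, function(v) diff(range(v))) + 7.0
  scale_factor <- max(1, (vol_target / prod(box))^(1 / 3))
  dims <- box * scale_factor
  if (n_symops(sym) > 1) dims <- pmax(dims, 2 * (box - 3.0))
  unit_cell(dims[1], dims[2], dims[3])
}

center_in_cell <- function(model, cell, sym) {
  ctr_target <- as.vector(orth_matrix(cell) %*%
                          (if (n_symops(sym) > 1) c(0.25, 0.25, 0.25) else c(0.5, 0.5, 0.5)))
  ctr <- colMeans(as.matrix(model[, c("x", "y", "z")]))
  transform_model(model, diag(3), ctr_target - ctr)
}

#' Simulate observed amplitudes from a model
#'
#' `f_obs = |F_calc| (1 + eps)`, `eps ~ N(0, noise_frac)`, clipped at zero;
#' `sigma = noise_frac * f_obs`; 5% free flags.
#'
#' @param model,cell,sym Crystal content.
#' @param d_min Resolution limit.
#' @param noise_frac Relative amplitude noise.
#' @param seed Integer seed.
#' @return `mr_reflections` with `f_obs`, `sigma`, `free` (no phases).
#' @export
simulate_fobs <- function(model, cell, sym, d_min, noise_frac = 0.05, seed = 1) {
  refl <- sf_fft(model, cell, sym, d_min)
  f <- Mod(refl$f_calc)
  eps <- with_seed(derive_seed(seed, "noise"), stats::rnorm(length(f), 0, noise_frac))
  refl$f_obs <- pmax(0, f * (1 + eps))
  refl$sigma <- noise_frac * refl$f_obs
  refl$f_calc <- NULL
  assign_free_flags(refl, 0.05, derive_seed(seed, "free"))
}

#' Perturb a model to a target main-chain rmsd
#'
#' Smooth, low-frequency torsion-space perturbation rebuilt through
#' ideal-geometry chain extension, rigidly re-superposed on the input and
#' rescaled until the achieved main-chain rmsd is within 10% of target.
#' Correlated (not i.i.d.) displacements keep rigid placement meaningful at
#' 1.5-2 A rmsd, mirroring real homolog divergence.
#'
#' @param model `mr_model` (backbone + CB).
#' @param perturb_rmsd Target main-chain rmsd, Angstrom.
#' @param seed Integer seed.
#' @return Perturbed `mr_model` (ideal geometry, same residues).
#' @export
perturb_model <- function(model, perturb_rmsd, seed) {
  stopifnot(perturb_rmsd >= 0)
  if (perturb_rmsd == 0) return(model)
  out <- list()
  for (ch in unique(model$chain)) {
    sub <- model[model$chain == ch, , drop = FALSE]
    tor <- extract_torsions(model, ch)
    n <- nrow(tor)
    field <- with_seed(derive_seed(seed, "perturb", match(ch, unique(model$chain))), {
      t <- seq_len(n) / n
      f <- function() {
        v <- rep(0, n)
        for (k in 1:3) v <- v + stats::rnorm(1) * sin(2 * pi * (k * t + stats::runif(1)))
        v
      }
      list(dphi = f(), dpsi = f())
    })
    amp <- perturb_rmsd * 2.5   # starting guess, degrees per A of target rmsd
    for (iter in 1:20) {
      t2 <- tor
      t2$phi <- tor$phi + amp * field$dphi
      t2$psi <- tor$psi + amp * field$dpsi
      reb <- build_backbone(t2, resnames = model_sequence(model, ch), chain = ch,
                            seqnums = tor$seqnum, b = sub$b[1])
      fit <- superpose(reb, sub, selection = c("N", "CA", "C", "O"))
      reb <- transform_model(reb, fit$rotation, fit$translation)
      if (abs(fit$rmsd - perturb_rmsd) <= 0.1 * perturb_rmsd) {
        out[[ch]] <- reb
        break
      }
      amp <- amp * perturb_rmsd / max(fit$rmsd, 1e-6)
      if (iter == 20) stop("could not reach target rmsd ", perturb_rmsd,
                           " within 20 rescale iterations (got ", round(fit$rmsd, 2), ")")
    }
  }
  m <- mr_model(do.call(rbind, out), label = "perturbed")
  attr(m, "cell") <- attr(model, "cell")
  attr(m, "spacegroup_name") <- attr(model, "spacegroup_name")
  m
}

#' Generate a homolog sequence and its alignment to the target
#'
#' Random substitutions at non-conserved positions to reach the target
#' identity, plus 0-2 short deletions (1-3 residues) in the homolog, which
#' become gaps to be rebuilt as loops.
#'
#' @param seq Target sequence (1-letter string).
#' @param identity Target fractional identity over aligned columns.
#' @param seed Integer seed.
#' @return List `sequence` (homolog, ungapped), `alignment`
#'   (`mr_alignment`), `deleted` (target positions absent from the homolog).
#' @export
make_homolog <- function(seq, identity, seed) {
  stopifnot(identity > 0, identity <= 1)
  letters1 <- strsplit(toupper(seq), "")[[1]]
  n <- length(letters1)
  with_seed(derive_seed(seed, "homolog"), {
    hom <- letters1
    nmut <- round((1 - identity) * n)
    if (nmut > 0) {
      pos <- sample.int(n, nmut)
      for (p in pos) hom[p] <- sample(setdiff(SYNTH_ALPHABET, hom[p]), 1)
    }
    deleted <- integer(0)
    if (identity < 1) {
      for (k in seq_len(sample(0:2, 1))) {
        len <- sample(1:3, 1)
        st <- sample.int(n - len - 2, 1) + 1
        deleted <- union(deleted, st:(st + len - 1))
      }
    }
    tgt_aln <- paste(letters1, collapse = "")
    hom_aln <- hom
    hom_aln[deleted] <- "-"
    aln_text <- c(">target", tgt_aln, ">template", paste(hom_aln, collapse = ""))
    list(sequence = paste(hom[setdiff(seq_len(n), deleted)], collapse = ""),
         alignment = parse_alignment(aln_text),
         deleted = sort(deleted))
  })
}

#' Assemble the complete synthetic molecular-replacement fixture
#'
#' The full study setup: the true crystal, simulated amplitudes, a homolog
#' template (perturbed geometry, mutated sequence, short deletions) and the
#' target/template alignment. The template is written in the true pose
#' (placed-model conventions); callers wanting a search problem apply their
#' own rigid scramble.
#'
#' @param spec `mr_fixture_spec`.
#' @return List: `truth` (model/cell/sym/ncs), `refl`, `template`
#'   (`mr_model`, numbered along the homolog sequence), `alignment`,
#'   `target_seq`.
#' @export
make_mr_fixture <- function(spec) {
  tgt <- make_target(spec)
  refl <- simulate_fobs(tgt$model, tgt$cell, tgt$sym, spec$d_min,
                        spec$noise_frac, spec$seed)
  target_seq <- paste(aa_one(model_sequence(tgt$model, tgt$model$chain[1])),
                      collapse = "")
  hom <- make_homolog(target_seq, spec$identity, spec$seed)
  pert <- perturb_model(tgt$model[tgt$model$chain == tgt$model$chain[1], ,
                                  drop = FALSE],
                        spec$perturb_rmsd, spec$seed)
  # template: homolog residue types and numbering (deleted positions removed)
  keep <- !(pert$seqnum - min(pert$seqnum) + 1) %in% hom$deleted
  tmpl <- pert[keep, , drop = FALSE]
  old_pos <- tmpl$seqnum - min(pert$seqnum) + 1
  hom_letters <- strsplit(hom$sequence, "")[[1]]
  new_num <- match(old_pos, setdiff(seq_len(nchar(target_seq)), hom$deleted))
  tmpl$seqnum <- new_num
  tmpl$resname <- aa_three(hom_letters[new_num])
  tmpl <- mr_model(tmpl, label = "synthetic homolog template")
  attr(tmpl, "cell") <- tgt$cell
  attr(tmpl, "spacegroup_name") <- tgt$sym$name
  list(truth = tgt, refl = refl, template = tmpl, alignment = hom$alignment,
       target_seq = target_seq, spec = spec)
}
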