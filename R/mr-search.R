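# Structure factors for a single symmetry operator (no sym summation).
sf_one_op <- function(model, cell, op, H, s) {
  xf <- model_fractional(model, cell)
  xs <- xf %*% t(op$R) + matrix(op$t, nrow(xf), 3, byrow = TRUE)
  W <- matrix(0, nrow(H), nrow(model))
  for (el in unique(model$element)) {
    W[, model$element == el] <- form_factor(el, s)
  }
  W <- W * exp(outer(-s^2 / 4, model$b)) *
    matrix(model$occ, nrow(H), nrow(model), byrow = TRUE)
  unname(rowSums(W * exp(2i * pi * (H %*% t(xs)))))
}

# Orientation-independent part of the translation scan: per symmetry op, the
# complex phase factors exp(2 pi i (R_s^T h) . delta) for every grid offset.
translation_context <- function(refl, sym, grid_step) {
  if (abs(1 / grid_step - round(1 / grid_step)) > 1e-9)
    stop("grid_step must divide 1 evenly")
  m <- round(1 / grid_step)
  if (m^3 > 64^3) stop("translation grid of ", m, "^3 points exceeds the desk ",
                       "budget guard (64^3); override by coarsening grid_step")
  fr <- seq(0, 1 - grid_step, by = grid_step)
  grid <- as.matrix(expand.grid(tz = fr, ty = fr, tx = fr))[, 3:1]
  H <- as.matrix(refl[, c("h", "k", "l")])
  phases <- lapply(sym$ops, function(op) exp(2i * pi * ((H %*% op$R) %*% t(grid))))
  list(grid = grid, H = H, s = 1 / refl$d, phases = phases,
       fobs2 = refl$f_obs^2)
}

#' Translation search for an oriented search model
#'
#' Scans a fractional translation grid; each offset is scored by the Pearson
#' correlation between squared observed amplitudes and squared calculated
#' amplitudes of (fixed model + shifted search model), the classic
#' correlation translation-function target. Ranked by score descending, ties
#' broken by lexicographic offset.
#'
#' @param oriented `mr_model` with the search orientation already applied.
#' @param refl `mr_reflections` with `f_obs`.
#' @param cell,sym Crystal frame.
#' @param grid_step Fractional step; must divide 1 evenly (guarded at 64^3
#'   points).
#' @param fixed Optional already-placed `mr_model` kept static.
#' @param context Precomputed [translation_context] (internal reuse).
#' @return data.frame of placements: tx, ty, tz (fractional, in \[0,1)),
#'   score; ordered best first.
#' @export
translation_search <- function(oriented, refl, cell, sym, grid_step = 0.125,
                               fixed = NULL, context = NULL) {
  ctx <- context %||% translation_context(refl, sym, grid_step)
  f_fix <- if (is.null(fixed)) 0i else sf_direct(fixed, cell, sym, ctx$H)
  single_op_p1 <- length(sym$ops) == 1 && is.null(fixed)
  if (single_op_p1) {
    fc <- sf_one_op(oriented, cell, sym$ops[[1]], ctx$H, ctx$s)
    sc <- stats::cor(ctx$fobs2, Mod(fc)^2)
    scores <- rep(sc, nrow(ctx$grid))
  } else {
    Ftot <- matrix(f_fix, length(ctx$s), nrow(ctx$grid))
    for (i in seq_along(sym$ops)) {
      f0 <- sf_one_op(oriented, cell, sym$ops[[i]], ctx$H, ctx$s)
      Ftot <- Ftot + f0 * ctx$phases[[i]]
    }
    I <- Mod(Ftot)^2
    scores <- suppressWarnings(as.vector(stats::cor(ctx$fobs2, I)))
    scores[!is.finite(scores)] <- -1
  }
  out <- data.frame(tx = ctx$grid[, 1], ty = ctx$grid[, 2], tz = ctx$grid[, 3],
                    score = scores)
  out[order(-out$score, out$tx, out$ty, out$tz), , drop = FALSE]
}

place_model <- function(search, cell, rotation, frac_shift, chain_ids = NULL) {
  ctr <- colMeans(as.matrix(search[, c("x", "y", "z")]))
  m <- transform_model(search, rotation, -as.vector(rotation %*% ctr))
  m <- transform_model(m, diag(3), as.vector(orth_matrix(cell) %*% frac_shift))
  if (!is.null(chain_ids)) {
    map <- stats::setNames(chain_ids, unique(m$chain))
    m$chain <- unname(map[m$chain])
  }
  m
}

#' Molecular replacement: rotation grid plus translation search
#'
#' For each (search model, copy-number hypothesis) pair, enumerates a
#' deduplicated zyz Euler grid, runs the translation search for every
#' orientation, and places copies sequentially — each placed copy joins the
#' fixed set for the next. Solutions are ranked by score.
#'
#' @param search_models List of `mr_model` search models (or a single model).
#' @param refl `mr_reflections` with `f_obs`.
#' @param cell,sym Crystal frame.
#' @param hypotheses List of copy-number hypotheses (see [enumerate_copies()]);
#'   a plain integer is accepted as a single n-copy hypothesis.
#' @param rot_step Euler grid step, degrees.
#' @param fixed Optional pre-placed fixed `mr_model`.
#' @param grid_step Fractional translation step.
#' @param score_floor Solutions scoring at or below this are dropped.
#' @return List of solutions, each `list(placements, combined_model, score,
#'   r_after_placement, search_model_index, hypothesis)`, ranked by score;
#'   empty with a message when nothing clears the floor.
#' @export
run_mr <- function(search_models, refl, cell, sym, hypotheses = list(1L),
                   rot_step = 15, fixed = NULL, grid_step = 0.125,
                   score_floor = 0.0) {
  if (inherits(search_models, "mr_model")) search_models <- list(search_models)
  hypotheses <- lapply(hypotheses, function(h)
    if (is.numeric(h)) list(n_copies = as.integer(h), solvent_fraction = NA,
                            uses_multimer = FALSE) else h)
  stopifnot(length(search_models) >= 1, length(hypotheses) >= 1)
  grid <- euler_grid(rot_step)
  ctx <- translation_context(refl, sym, grid_step)
  solutions <- list()
  for (mi in seq_along(search_models)) {
    search <- search_models[[mi]]
    ctr <- colMeans(as.matrix(search[, c("x", "y", "z")]))
    centered <- transform_model(search, diag(3), -ctr)
    nch <- length(unique(search$chain))
    # a search model built for a specific hypothesis is searched under that
    # hypothesis only
    own_hyp <- attr(search, "hypothesis")
    hyp_list <- if (!is.null(own_hyp)) list(own_hyp) else hypotheses
    for (hi in seq_along(hyp_list)) {
      hyp <- hyp_list[[hi]]
      n_place <- hyp$n_copies
      if (isTRUE(attr(search, "uses_multimer")) || isTRUE(hyp$uses_multimer))
        n_place <- n_place / nch
      if (n_place < 1 || n_place != round(n_place)) next
      fixed_now <- fixed
      placements <- list()
      sol_score <- -Inf
      for (copy in seq_len(n_place)) {
        best <- NULL
        for (gi in seq_len(nrow(grid))) {
          R <- euler_zyz(grid$alpha[gi], grid$beta[gi], grid$gamma[gi])
          oriented <- transform_model(centered, R)
          ts <- translation_search(oriented, refl, cell, sym,
                                   grid_step = grid_step, fixed = fixed_now,
                                   context = ctx)
          if (is.null(best) || ts$score[1] > best$score) {
            best <- list(euler = c(grid$alpha[gi], grid$beta[gi], grid$gamma[gi]),
                         rotation = R,
                         translation = as.numeric(ts[1, c("tx", "ty", "tz")]),
                         score = ts$score[1], n_copy_index = copy)
          }
        }
        chain_ids <- LETTERS[(length(placements) * nch + 1):(length(placements) * nch + nch)]
        placed <- place_model(centered, cell, best$rotation, best$translation,
                              chain_ids = chain_ids)
        fixed_now <- if (is.null(fixed_now)) placed else
          mr_model(rbind(fixed_now, placed))
        placements[[copy]] <- best
        sol_score <- best$score
      }
      combined <- fixed_now
      if (!is.null(fixed)) {
        fixed_keys <- paste(fixed$chain, fixed$seqnum, fixed$atom)
        keep <- !(paste(combined$chain, combined$seqnum, combined$atom) %in% fixed_keys)
        combined <- combined[keep, , drop = FALSE]
      }
      rfl <- refl
      rfl$f_calc <- sf_direct(fixed_now, cell, sym, as.matrix(refl[, c("h", "k", "l")]))
      rep <- scale_and_r(rfl)
      solutions[[length(solutions) + 1]] <-
        list(placements = placements, combined_model = combined,
             score = sol_score, r_after_placement = rep$r_work,
             search_model_index = mi, hypothesis = hyp)
    }
  }
  solutions <- solutions[order(-vapply(solutions, `[[`, numeric(1), "score"))]
  keep <- vapply(solutions, function(s) s$score > score_floor, logical(1))
  if (!any(keep)) {
    message("no molecular replacement solution above score floor ", score_floor)
    return(list())
  }
  solutions[keep]
}

#' Rescore molecular replacement solutions under a common criterion
#'
#' All combined models are rescored with one shared B-factor inflation
#' (the stand-in for rescoring under a single assumed template rmsd) by the
#' amplitude correlation `cor(f_obs, |f_calc|)`, then re-ranked (stable sort).
#'
#' @param solutions List from [run_mr()].
#' @param refl `mr_reflections` with `f_obs`.
#' @param cell,sym Crystal frame.
#' @param b_inflate Shared B inflation, Angstrom^2.
#' @return Solutions re-ranked by the common score (stored as `rescore`).
#' @export
rescore_solutions <- function(solutions, refl, cell, sym, b_inflate = 0) {
  if (!length(solutions)) return(solutions)
  H <- as.matrix(refl[, c("h", "k", "l")])
  sc <- vapply(solutions, function(sol) {
    m <- sol$combined_model
    m$b <- m$b + b_inflate
    stats::cor(refl$f_obs, Mod(sf_direct(m, attr(refl, "cell"), sym, H)))
  }, numeric(1))
  for (i in seq_along(solutions)) solutions[[i]]$rescore <- sc[i]
  solutions[order(-sc)]
}

#' Write solutions as PDB plus JSON sidecar
#' @param solutions List from [run_mr()].
#' @param dir Output directory.
#' @param cell,sym Crystal frame for the PDB CRYST1 records.
#' @export
write_solutions <- function(solutions, dir, cell, sym) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(solutions)) {
    sol <- solutions[[i]]
    write_model(sol$combined_model, file.path(dir, sprintf("solution_%02d.pdb", i)),
                cell = cell, spacegroup_name = sym$name)
    side <- list(score = sol$score, r_after_placement = sol$r_after_placement,
                 rescore = sol$rescore %||% NULL, hypothesis = sol$hypothesis,
                 placements = lapply(sol$placements, function(p)
                   list(euler_zyz = p$euler, translation = p$translation,
                        score = p$score, n_copy_index = p$n_copy_index)))
    jsonlite::write_json(side, file.path(dir, sprintf("solution_%02d.json", i)),
                         auto_unbox = TRUE, digits = 8)
  }
  invisible(dir)
}
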