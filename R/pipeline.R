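#' Pipeline configuration
#'
#' Collects inputs and parameters for the full molecular-replacement and
#' rebuilding workflow. Inputs may be in-memory objects (as produced by the
#' synthetic fixture generator) or file paths (PDB / paired FASTA / columnar
#' reflection text), which are read on demand.
#'
#' @param mode `"from_alignment"` (template + alignment, molecular
#'   replacement runs) or `"from_placed_model"` (model already placed; the
#'   search step is skipped entirely).
#' @param refl `mr_reflections` with `f_obs` (+ free flags), or a file path.
#' @param cell,spacegroup Crystal frame (`mr_cell` / label); taken from the
#'   template or placed model's CRYST1 when omitted.
#' @param template Template `mr_model` or PDB path (alignment mode).
#' @param alignment `mr_alignment` or paired-FASTA path (alignment mode).
#' @param placed_model Placed `mr_model` or PDB path (placed-model mode).
#' @param prerefine Run the geometry-only pre-search rebuild of the template
#'   (structure optimization without reference to the data).
#' @param rot_step,grid_step Search grid resolutions (degrees / fractional).
#' @param params [rebuild_params()].
#' @param weights [score_weights()].
#' @param b_inflate Common B inflation for solution rescoring.
#' @param n_copies Copy count for the search (integer); `NULL` enumerates
#'   all plausible counts via the Matthews relation (capped at
#'   `max_hypotheses`, in order of solvent-fraction plausibility).
#' @param max_hypotheses Cap on enumerated copy-number hypotheses.
#' @param mr_d_min Resolution cutoff for the molecular replacement search
#'   (searching at moderate resolution is faster and no less selective);
#'   the full data are used everywhere else.
#' @param n_average Density-modified maps averaged in step 5.
#' @param r_tol Outer-loop convergence tolerance on R_work.
#' @param max_outer Maximum outer (steps 4-6) cycles.
#' @param autobuild_cycles Cycle limit inside the autobuild stage.
#' @param dm_cycles Density-modification cycles per map.
#' @param seed Master seed; every stage derives its stream from it.
#' @param outdir Output directory for artifacts (`NULL`: nothing written).
#' @param truth_model Optional reference `mr_model` for map-correlation
#'   diagnostics in the run history.
#' @return List of class `mr_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("from_alignment", "from_placed_model"),
                            refl, cell = NULL, spacegroup = NULL,
                            template = NULL, alignment = NULL,
                            placed_model = NULL, prerefine = FALSE,
                            rot_step = 30, grid_step = 0.125,
                            params = rebuild_params(),
                            weights = score_weights(), b_inflate = 30,
                            n_copies = NULL, max_hypotheses = 3,
                            mr_d_min = 3.5,
                            n_average = 4, r_tol = 0.005, max_outer = 3,
                            autobuild_cycles = 3, dm_cycles = 3,
                            seed = 1, outdir = NULL, truth_model = NULL) {
  mode <- match.arg(mode)
  if (mode == "from_alignment" && (is.null(template) || is.null(alignment)))
    stop("alignment mode needs both a template and an alignment")
  if (mode == "from_placed_model" && is.null(placed_model))
    stop("placed-model mode needs a placed model")
  if (mode == "from_placed_model" && (!is.null(template) || !is.null(alignment)))
    stop("exactly one of alignment-mode or placed-model-mode inputs may be given")
  structure(list(mode = mode, refl = refl, cell = cell,
                 spacegroup = spacegroup, template = template,
                 alignment = alignment, placed_model = placed_model,
                 prerefine = prerefine, rot_step = rot_step,
                 grid_step = grid_step, params = params, weights = weights,
                 b_inflate = b_inflate, n_copies = n_copies,
                 max_hypotheses = max_hypotheses, mr_d_min = mr_d_min,
                 n_average = n_average, r_tol = r_tol,
                 max_outer = max_outer, autobuild_cycles = autobuild_cycles,
                 dm_cycles = dm_cycles, seed = seed, outdir = outdir,
                 truth_model = truth_model),
            class = "mr_pipeline_config")
}

resolve_model <- function(x) {
  if (is.character(x)) read_model(x) else x
}

#' Run the full molecular-replacement and rebuilding pipeline
#'
#' Executes template editing, the optional geometry-only pre-search
#' refinement, molecular replacement with common-criterion rescoring,
#' refinement and density modification, NCS-aware density-guided rebuilding
#' with map averaging, and iterative autobuilding; the steps from refinement
#' onward are repeated until R_work stops changing or the outer-cycle limit
#' is reached. In placed-model mode the search stage is never invoked.
#'
#' @param config [pipeline_config()].
#' @return List of class `mr_run_result`: `best_model`, `best_map`, `report`,
#'   `history` (one row per logged cycle: stage, cycle, r_work, r_free,
#'   map_cc), `solutions` (molecular replacement summary, alignment mode),
#'   `log` (list of stage event records), `status`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mr_pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    log[[length(log) + 1]] <<- rec
    if (!is.null(config$outdir))
      append_jsonl(file.path(config$outdir, "run_log.jsonl"), rec)
    invisible(NULL)
  }
  if (!is.null(config$outdir))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  history <- data.frame()
  solutions <- NULL
  status <- "ok"

  result <- tryCatch({
  # ---- inputs ----
  tmpl <- if (!is.null(config$template)) resolve_model(config$template)
  placed0 <- if (!is.null(config$placed_model)) resolve_model(config$placed_model)
  anchor_model <- tmpl %||% placed0
  cell <- config$cell %||% attr(anchor_model, "cell")
  if (is.null(cell)) stop("no unit cell: supply `cell` or a CRYST1 record")
  sgname <- config$spacegroup %||% attr(anchor_model, "spacegroup_name") %||% "P1"
  sym <- if (inherits(sgname, "mr_symops")) sgname else spacegroup(sgname)
  refl <- if (is.character(config$refl))
    read_reflections(config$refl, cell, sym) else config$refl
  if (is.null(refl$free))
    refl <- assign_free_flags(refl, 0.05, derive_seed(config$seed, "free"))
  aln <- if (is.character(config$alignment))
    parse_alignment(config$alignment) else config$alignment
  lib <- default_fragment_library()
  w <- config$weights
  d_min <- min(refl$d)
  truth_map <- if (!is.null(config$truth_model)) {
    rt <- refl
    rt$f_calc <- sf_fft(config$truth_model, cell, sym, d_min, hkl = refl)$f_calc
    compute_map(rt, "fc")
  }
  sf_of <- function(m) {
    r <- refl
    r$f_calc <- sf_fft(m, cell, sym, d_min, hkl = refl)$f_calc
    r
  }
  # refine under the default and a loosened geometry weight and keep the
  # model with the lower working R -- the usual restraint-weight-vs-R
  # optimization, needed because the stiff default that protects correct
  # models also immobilizes marginal ones
  refine_by_r <- function(m, map) {
    r_in <- scale_and_r(sf_of(m))$r_work
    c1 <- refine_real_space(m, map, w)
    r1 <- scale_and_r(sf_of(c1))$r_work
    if (r1 < r_in - 1e-4) return(c1)
    c2 <- refine_real_space(m, map, score_weights(w_geom = w$w_geom / 3,
                                                  w_dens = w$w_dens))
    r2 <- scale_and_r(sf_of(c2))$r_work
    if (r2 < r1) c2 else c1
  }
  cc_of <- function(map) if (is.null(truth_map)) NA_real_ else
    map_correlation(map, truth_map)
  tick <- function(stage, cycle, rep, map = NULL) {
    history <<- rbind(history, data.frame(
      stage = stage, cycle = cycle, r_work = rep$r_work, r_free = rep$r_free,
      map_cc = if (is.null(map)) NA_real_ else cc_of(map)))
  }
    # ---- step 1: template editing ----
    if (config$mode == "from_alignment") {
      model <- edit_template(tmpl, aln)
      note("edit_template", n_res = length(unique(model$seqnum)),
           gaps = length(attr(model, "gaps")))
      # ---- step 2: optional pre-search geometry-only refinement ----
      if (isTRUE(config$prerefine)) {
        p2 <- config$params
        p2$n_models <- min(p2$n_models, 6)
        p2$seed <- derive_seed(config$seed, "prerefine")
        dummy <- new_map(array(0, dim = c(4, 4, 4)), cell)
        pre <- rebuild_model(model, dummy, lib, p2,
                             score_weights(w_geom = w$w_geom, w_dens = 0))
        best_pre <- pre[[which.max(vapply(pre, attr, numeric(1), "score"))]]
        note("prerefine", score = attr(best_pre, "score"))
        model <- best_pre
      } else note("prerefine", skipped = TRUE)
      # ---- step 3: molecular replacement ----
      if (!is.null(config$n_copies)) {
        vm <- cell_volume(cell) /
          (n_symops(sym) * config$n_copies * model_mass(model))
        hyps <- list(list(n_copies = as.integer(config$n_copies),
                          solvent_fraction = 1 - 1.23 / vm,
                          uses_multimer = FALSE))
      } else {
        hyps <- enumerate_copies(cell, sym, model_mass(model))
        if (length(hyps) > config$max_hypotheses)
          hyps <- hyps[seq_len(config$max_hypotheses)]
        if (!length(hyps)) hyps <- list(list(n_copies = 1L,
                                             solvent_fraction = 0.5,
                                             uses_multimer = FALSE))
      }
      searches <- build_multimers(model, 1L, hyps)
      refl_mr <- refl[refl$d >= min(max(d_min, config$mr_d_min), max(refl$d)), ,
                      drop = FALSE]
      sols <- run_mr(searches, refl_mr, cell, sym, hyps,
                     rot_step = config$rot_step, grid_step = config$grid_step)
      if (!length(sols)) stop("molecular replacement found no solution")
      sols <- rescore_solutions(sols, refl_mr, cell, sym, config$b_inflate)
      solutions <- lapply(sols, function(s)
        list(score = s$score, rescore = s$rescore,
             r_after_placement = s$r_after_placement,
             n_copies = s$hypothesis$n_copies))
      note("mr_search", n_solutions = length(sols),
           top_score = sols[[1]]$score,
           r_after_placement = sols[[1]]$r_after_placement)
      placed <- sols[[1]]$combined_model
      # partial-solution fallback: rerun with the good copies fixed
      good <- vapply(sols[[1]]$placements, function(p) p$score > 0, logical(1))
      if (!all(good)) {
        keep_chains <- unique(placed$chain)[good]
        fixed <- placed[placed$chain %in% keep_chains, , drop = FALSE]
        n_missing <- sum(!good)
        note("mr_partial_fallback", refitting = n_missing)
        sols2 <- run_mr(list(model), refl_mr, cell, sym, list(n_missing),
                        rot_step = config$rot_step,
                        grid_step = config$grid_step, fixed = fixed)
        if (length(sols2))
          placed <- mr_model(rbind(fixed, sols2[[1]]$combined_model))
      }
      for (a in c("gaps", "target_seq")) attr(placed, a) <- attr(model, a)
      model <- placed
    } else {
      model <- placed0
      note("placed_model_input", n_chains = length(unique(model$chain)))
    }
    best <- NULL

    # ---- outer loop over steps 4-6 ----
    update_best <- function(model, map, rep) {
      if (is.null(best) || rep$r_work < best$report$r_work)
        best <<- list(model = model, map = map, report = rep)
    }
    prev_best_r <- NA
    for (outer in seq_len(config$max_outer)) {
      solv <- solvent_fraction_of(model, cell, sym)
      # step 4: refine + density-modified map
      r4 <- sf_of(model)
      map4 <- compute_map(r4, "two_fo_fc")
      ops <- find_ncs_operators(model)
      dm4 <- density_modify(map4, r4, model, solv, n_cycles = config$dm_cycles,
                            ops = ops)
      model <- refine_by_r(model, dm4)
      r4 <- sf_of(model)
      rep4 <- scale_and_r(r4)
      dm4 <- density_modify(compute_map(r4, "two_fo_fc"), r4, model, solv,
                            n_cycles = config$dm_cycles, ops = ops)
      tick("refine_dm", outer, rep4, dm4)
      note("refine_dm", cycle = outer, r_work = rep4$r_work,
           r_free = rep4$r_free, n_ncs_ops = length(ops))
      update_best(model, dm4, rep4)
      # step 5: density-guided rebuild, top-model selection, map averaging
      p5 <- config$params
      p5$seed <- derive_seed(config$seed, "rebuild", outer)
      if (length(ops)) {
        built <- list(rebuild_with_ncs(model, dm4, ops, lib, p5, w))
      } else {
        built <- rebuild_model(model, dm4, lib, p5, w)
      }
      top <- select_top_models(built, refl, cell, sym,
                               n = min(config$n_average, length(built)))
      dmmaps <- lapply(top, function(m) {
        mref <- refine_real_space(m, dm4, w)
        rr <- sf_of(mref)
        density_modify(compute_map(rr, "two_fo_fc"), rr, mref, solv,
                       n_cycles = config$dm_cycles,
                       ops = find_ncs_operators(mref))
      })
      avg <- average_maps(dmmaps)
      model5 <- refine_by_r(top[[1]], avg)
      rep5 <- scale_and_r(sf_of(model5))
      tick("rebuild_average", outer, rep5, avg)
      note("rebuild_average", cycle = outer, n_built = length(built),
           n_averaged = length(dmmaps), r_work = rep5$r_work)
      update_best(model5, avg, rep5)
      # step 6: autobuild iteration, started from the better of the refined
      # and rebuilt models ("the model with the lowest R-value is saved")
      start6 <- if (rep5$r_work < rep4$r_work) model5 else model
      p6 <- config$params
      p6$seed <- derive_seed(config$seed, "autobuild", outer)
      ab <- autobuild_iterate(start6, refl, lib, p6, w, r_tol = config$r_tol,
                              max_cycles = config$autobuild_cycles,
                              dm_cycles = config$dm_cycles)
      for (k in seq_len(nrow(ab$history)))
        tick("autobuild", outer, list(r_work = ab$history$r_work[k],
                                      r_free = ab$history$r_free[k]))
      note("autobuild", cycle = outer, r_work = ab$report$r_work,
           r_free = ab$report$r_free)
      update_best(ab$model, ab$map, ab$report)
      model <- best$model
      if (!is.na(prev_best_r) && prev_best_r - best$report$r_work < config$r_tol) {
        note("outer_converged", cycle = outer)
        break
      }
      # a cycle that could not improve on its own starting R is a fixed point
      if (is.na(prev_best_r) && rep4$r_work - best$report$r_work < config$r_tol) {
        note("outer_converged", cycle = outer, fixed_point = TRUE)
        break
      }
      prev_best_r <- best$report$r_work
    }
    best
  }, error = function(e) {
    status <<- paste0("failed: ", conditionMessage(e))
    note("error", message = conditionMessage(e))
    NULL
  })

  if (is.null(result)) {
    out <- list(best_model = NULL, best_map = NULL, report = NULL,
                history = history, solutions = solutions, log = log,
                status = status)
    class(out) <- "mr_run_result"
    return(out)
  }
  if (!is.null(config$outdir)) {
    write_model(result$model, file.path(config$outdir, "best_model.pdb"),
                cell = cell, spacegroup_name = sym$name)
    write_map_mrc(result$map, file.path(config$outdir, "best_map.ccp4"))
    jsonlite::write_json(
      list(r_work = result$report$r_work, r_free = result$report$r_free,
           scale = result$report$scale, b_overall = result$report$b_overall,
           status = status),
      file.path(config$outdir, "report.json"), auto_unbox = TRUE, digits = 8)
  }
  out <- list(best_model = result$model, best_map = result$map,
              report = result$report, history = history,
              solutions = solutions, log = log, status = status)
  class(out) <- "mr_run_result"
  out
}

#' @export
print.mr_run_result <- function(x, ...) {
  cat("pipeline run:", x$status, "\n")
  if (!is.null(x$report))
    cat(sprintf("  best R_work %.4f  R_free %.4f over %d logged cycles\n",
                x$report$r_work, x$report$r_free, nrow(x$history)))
  invisible(x)
}

#' Write the synthetic fixture to files
#'
#' Writes target.pdb (truth), template.pdb, alignment.fasta, refl.txt and
#' truth.json (poses, NCS operators, perturbation summary) for a fixture
#' specification — the file-based face of the synthetic module.
#'
#' @param spec [fixture_spec()].
#' @param dir Output directory.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- make_mr_fixture(spec)
  write_model(fx$truth$model, file.path(dir, "target.pdb"),
              cell = fx$truth$cell, spacegroup_name = fx$truth$sym$name)
  write_model(fx$template, file.path(dir, "template.pdb"),
              cell = fx$truth$cell, spacegroup_name = fx$truth$sym$name)
  writeLines(c(">target", attr_or(fx$alignment$target_seq),
               ">template", attr_or(fx$alignment$template_seq)),
             file.path(dir, "alignment.fasta"))
  write_reflections(fx$refl, file.path(dir, "refl.txt"))
  fit <- superpose(fx$template, fx$truth$model)
  jsonlite::write_json(list(
    spec = unclass(spec),
    template_mainchain_rmsd = fit$rmsd,
    identity = fx$alignment$identity,
    ncs = lapply(fx$truth$ncs, function(o)
      list(rotation = as.vector(o$rotation), translation = o$translation,
           source_chain = o$source_chain, target_chain = o$target_chain))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = 8)
  invisible(dir)
}

attr_or <- function(x) as.character(x)
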