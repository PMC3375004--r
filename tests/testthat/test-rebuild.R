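rebuild_fixture <- function() cached("rebuild_fixture", {
  spec <- fixture_spec(n_res = 16, fold = "helix", d_min = 3.0,
                       noise_frac = 0, seed = 13)
  tgt <- make_target(spec)
  refl <- sf_fft(tgt$model, tgt$cell, tgt$sym, 3.0)
  refl$f_obs <- Mod(refl$f_calc)
  map <- compute_map(refl, "fc")
  list(tgt = tgt, refl = refl, map = map)
})

test_that("fragment library has both lengths, complete torsions, determinism", {
  lib <- default_fragment_library()
  lens <- vapply(lib$entries, `[[`, numeric(1), "length")
  expect_true(all(lens %in% c(3, 9)))
  expect_gt(sum(lens == 3), 50)
  expect_gt(sum(lens == 9), 50)
  for (e in lib$entries[c(1, 50, 100)]) {
    expect_equal(length(e$phi), e$length)
    expect_equal(length(e$psi), e$length)
    expect_true(all(is.finite(c(e$phi, e$psi, e$omega))))
  }
  expect_identical(default_fragment_library(), lib)
  f <- withr::local_tempfile(fileext = ".json")
  write_fragment_library(lib, f)
  lib2 <- read_fragment_library(f)
  expect_equal(length(lib2$entries), length(lib$entries))
  expect_equal(lib2$entries[[5]]$phi, lib$entries[[5]]$phi, tolerance = 1e-5)
})

test_that("combined score ranks correct models above damaged ones", {
  fx <- rebuild_fixture()
  w <- score_weights()
  s_true <- combined_score(fx$tgt$model, fx$map, w)
  damaged <- fx$tgt$model
  i <- which(damaged$atom == "CA")[5]
  damaged$x[i] <- damaged$x[i] + 2
  expect_gt(s_true, combined_score(damaged, fx$map, w))
  # density weight zero decouples the score from the map entirely
  w0 <- score_weights(w_geom = 1, w_dens = 0)
  pert_map <- fx$map
  pert_map$grid <- fx$map$grid + array(rnorm(length(fx$map$grid)),
                                       dim = dim(fx$map$grid))
  expect_equal(combined_score(fx$tgt$model, fx$map, w0),
               combined_score(fx$tgt$model, pert_map, w0))
  expect_error(combined_score(fx$tgt$model[0, ], fx$map, w), "empty")
})

test_that("combined score equals the hand-built weighted component sum", {
  fx <- rebuild_fixture()
  toy <- fx$tgt$model[fx$tgt$model$seqnum %in% 3:5, ]
  w <- score_weights(w_geom = 2.5, w_dens = 1.5)
  g <- geometry_score(toy)
  dens <- real_space_fit(toy, fx$map)$overall
  byhand <- 1.5 * dens -
    2.5 * (g$bond_dev + g$angle_dev / 50 + g$clash + 2 * g$rama_outliers)
  expect_equal(combined_score(toy, fx$map, w), byhand, tolerance = 1e-12)
})

test_that("geometry score flags distorted bonds, clashes and torsions", {
  fx <- rebuild_fixture()
  g0 <- geometry_score(fx$tgt$model)
  expect_lt(g0$bond_dev, 0.01)
  expect_equal(g0$clash, 0)
  squeezed <- fx$tgt$model
  i <- which(squeezed$seqnum == 10 & squeezed$atom == "CB")
  j <- which(squeezed$seqnum == 3 & squeezed$atom == "CB")
  squeezed[i, c("x", "y", "z")] <- squeezed[j, c("x", "y", "z")] + 0.5
  g1 <- geometry_score(squeezed)
  expect_gt(g1$clash, 0)
  expect_gt(g1$bond_dev, g0$bond_dev)
})

test_that("zero-step rebuild returns the input and seeds are reproducible", {
  fx <- rebuild_fixture()
  lib <- default_fragment_library()
  p0 <- rebuild_params(n_models = 2, n_steps = 0, seed = 5)
  out <- rebuild_model(fx$tgt$model, fx$map, lib, p0)
  for (m in out) {
    expect_equal(as.matrix(m[, c("x", "y", "z")]),
                 as.matrix(fx$tgt$model[, c("x", "y", "z")]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  p <- rebuild_params(n_models = 2, n_steps = 40, seed = 5)
  a <- rebuild_model(fx$tgt$model, fx$map, lib, p)
  b <- rebuild_model(fx$tgt$model, fx$map, lib, p)
  expect_identical(lapply(a, function(m) m$x), lapply(b, function(m) m$x))
  expect_identical(vapply(a, attr, numeric(1), "score"),
                   vapply(b, attr, numeric(1), "score"))
})

test_that("near-zero temperature accepts only score-improving moves", {
  fx <- rebuild_fixture()
  lib <- default_fragment_library()
  pert <- perturb_model(fx$tgt$model, 1.0, seed = 9)
  w <- score_weights()
  s0 <- combined_score(pert, fx$map, w)
  p <- rebuild_params(n_models = 3, n_steps = 60, temperature = 1e-9, seed = 7)
  out <- rebuild_model(pert, fx$map, lib, p, w)
  for (m in out) expect_gte(attr(m, "score"), s0 - 1e-9)
})

test_that("rebuilding builds short gaps and improves a perturbed model", {
  fx <- rebuild_fixture()
  lib <- default_fragment_library()
  pert <- perturb_model(fx$tgt$model, 1.0, seed = 4)
  gap <- 7:10
  partial <- pert[!(pert$seqnum %in% gap), ]
  attr(partial, "gaps") <- gap
  attr(partial, "target_seq") <-
    paste(micromr:::aa_one(micromr:::model_sequence(fx$tgt$model)),
          collapse = "")
  w <- score_weights()
  p <- rebuild_params(n_models = 8, n_steps = 200, seed = 3)
  builds <- rebuild_model(partial, fx$map, lib, p, w)
  best <- builds[[which.max(vapply(builds, attr, numeric(1), "score"))]]
  expect_true(all(gap %in% best$seqnum))
  # the completed best model beats the perturbed-complete starting state
  expect_lt(raw_mainchain_rmsd(best, fx$tgt$model),
            raw_mainchain_rmsd(pert, fx$tgt$model))
  # built gap residues land near the truth
  expect_lt(raw_mainchain_rmsd(best[best$seqnum %in% gap, ], fx$tgt$model), 1.5)
  # the trajectory population explores improved states
  expect_lt(min(vapply(builds, raw_mainchain_rmsd, numeric(1),
                       b = fx$tgt$model)),
            raw_mainchain_rmsd(pert, fx$tgt$model))
  expect_error(rebuild_model(partial, fx$map,
                             structure(list(entries = list()),
                                       class = "mr_fragment_library"), p, w),
               "length")
})

test_that("NCS rebuild replicates one copy exactly to all copies", {
  spec <- fixture_spec(n_res = 10, fold = "helix", n_copies = 2, d_min = 3.0,
                       noise_frac = 0, seed = 6)
  t2 <- make_target(spec)
  refl <- sf_fft(t2$model, t2$cell, t2$sym, 3.0)
  refl$f_obs <- Mod(refl$f_calc)
  map <- compute_map(refl, "fc")
  ops <- Filter(function(o) o$source_chain == "A", find_ncs_operators(t2$model))
  lib <- default_fragment_library()
  # perturb the reference copy only
  pert <- t2$model
  asel <- pert$chain == "A"
  pA <- perturb_model(pert[asel, ], 0.8, seed = 3)
  pert <- mr_model(rbind(pA, pert[!asel, ]))
  p <- rebuild_params(n_models = 3, n_steps = 60, seed = 2)
  out <- rebuild_with_ncs(pert, map, ops, lib, p)
  # exact idealized NCS: copies superpose to numerical zero
  a <- out[out$chain == "A", ]
  b <- out[out$chain == "B", ]
  op <- ops[[1]]
  moved <- transform_model(a, op$rotation, op$translation)
  moved$chain <- "B"
  expect_lt(raw_mainchain_rmsd(moved, b), 1e-6)
  # identity-only operators behave like a plain single-copy rebuild
  id_out <- rebuild_with_ncs(pert[pert$chain == "A", ], map,
                             list(micromr:::ncs_identity_op("A")), lib, p)
  expect_equal(sort(unique(id_out$chain)), "A")
  expect_error(rebuild_with_ncs(pert, map, list(list(
    rotation = diag(3), translation = c(50, 0, 0),
    source_chain = "A", target_chain = "Z", rmsd = 0)), lib, p),
    "inconsistent")
})

test_that("real-space refinement ascends, stays put at optima, recovers shifts", {
  fx <- rebuild_fixture()
  w <- score_weights()
  ref1 <- refine_real_space(fx$tgt$model, fx$map, w, max_iter = 30)
  shift <- max(sqrt((ref1$x - fx$tgt$model$x)^2 +
                    (ref1$y - fx$tgt$model$y)^2 +
                    (ref1$z - fx$tgt$model$z)^2))
  expect_lt(shift, 0.05)
  disp <- transform_model(fx$tgt$model, diag(3), c(0.35, 0.25, 0.2))
  s_in <- combined_score(disp, fx$map, w)
  ref2 <- refine_real_space(disp, fx$map, w, max_iter = 60)
  expect_gte(attr(ref2, "score"),
             combined_score(disp, standardize_map(micromr:::upsample_map(fx$map, 3)), w))
  expect_lt(raw_mainchain_rmsd(ref2, fx$tgt$model), 0.2)
  # the ascent property holds from a damaged start too
  bad <- perturb_model(fx$tgt$model, 1.0, seed = 12)
  s_bad <- combined_score(bad, standardize_map(micromr:::upsample_map(fx$map, 3)), w)
  ref3 <- refine_real_space(bad, fx$map, w, max_iter = 20)
  expect_gte(attr(ref3, "score"), s_bad)
})

test_that("top-model selection uses amplitude correlation, stable order", {
  fx <- rebuild_fixture()
  far <- perturb_model(fx$tgt$model, 2.5, seed = 8)
  models <- list(far, fx$tgt$model)
  top <- select_top_models(models, fx$refl, fx$tgt$cell, fx$tgt$sym, n = 2)
  expect_equal(attr(top[[1]], "amp_cor") > attr(top[[2]], "amp_cor"), TRUE)
  expect_lt(superpose(top[[1]], fx$tgt$model)$rmsd, 1e-9)
  expect_warning(select_top_models(models, fx$refl, fx$tgt$cell, fx$tgt$sym,
                                   n = 5), "only 2")
})

test_that("unassigned (all-UNK) chains are discarded, others kept", {
  fx <- rebuild_fixture()
  unk <- fx$tgt$model
  unk$chain <- "U"
  unk$resname <- "UNK"
  both <- mr_model(rbind(fx$tgt$model, unk))
  out <- discard_unassigned(both)
  expect_equal(unique(out$chain), "A")
  expect_equal(nrow(out), nrow(fx$tgt$model))
  # all assigned: unchanged
  expect_equal(nrow(discard_unassigned(fx$tgt$model)), nrow(fx$tgt$model))
})

test_that("autobuild keeps the lowest-R model and reports its history", {
  fx <- rebuild_fixture()
  lib <- default_fragment_library()
  refl <- fx$refl
  refl$free <- rep(c(TRUE, rep(FALSE, 19)), length.out = nrow(refl))
  p <- rebuild_params(n_models = 2, n_steps = 30, seed = 5)
  res <- autobuild_iterate(fx$tgt$model, refl, lib, p, max_cycles = 2,
                           dm_cycles = 1)
  expect_lt(res$report$r_work, 0.05)
  expect_equal(res$report$r_work, min(res$history$r_work), tolerance = 1e-12)
  expect_true(all(c("cycle", "r_work", "r_free") %in% names(res$history)))
})
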