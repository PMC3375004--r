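test_that("NCS operator detection recovers exact generating motions", {
  fx <- ncs4()
  expect_equal(length(fx$ops), 12)  # all ordered pairs of 4 identical chains
  gen <- fx$tgt$ncs[[1]]
  found <- Filter(function(o) o$source_chain == "A" && o$target_chain == "B",
                  fx$ops)[[1]]
  expect_equal(found$rotation, gen$rotation, tolerance = 1e-9)
  expect_equal(found$translation, gen$translation, tolerance = 1e-6)
  expect_lt(found$rmsd, 1e-9)
  # single chain: nothing to find
  expect_equal(length(find_ncs_operators(fx$chA)), 0)
})

test_that("NCS operators compose consistently (closure)", {
  fx <- ncs4()
  get <- function(s, d) Filter(function(o) o$source_chain == s &&
                                 o$target_chain == d, fx$ops)[[1]]
  ab <- get("A", "B"); bc <- get("B", "C"); ac <- get("A", "C")
  expect_equal(bc$rotation %*% ab$rotation, ac$rotation, tolerance = 1e-3)
  expect_equal(as.vector(bc$rotation %*% ab$translation) + bc$translation,
               ac$translation, tolerance = 1e-3)
})

test_that("operator detection respects the sequence and rmsd filters", {
  fx <- ncs4()
  mutated <- fx$tgt$model
  bsel <- mutated$chain == "B"
  mutated$resname[bsel] <- rev(sort(mutated$resname[bsel]))[
    match(mutated$seqnum[bsel], sort(unique(mutated$seqnum[bsel])))]
  # heavy mutation of chain B drops all pairs involving it unless identity >= 90%
  ops <- find_ncs_operators(mutated)
  idents <- vapply(ops, function(o) o$source_chain != "B" &&
                     o$target_chain != "B", logical(1))
  if (length(ops)) expect_true(all(idents))
})

test_that("averaging an exactly symmetric map leaves it unchanged", {
  fx <- ncs4()
  reg <- ncs_region(fx$map, fx$opsA, fx$chA)
  avg <- ncs_average(fx$map, fx$opsA, fx$chA)
  expect_gt(stats::cor(fx$map$grid[reg$lin], avg$grid[reg$lin]), 0.999)
  # identity-only operator list: exact no-op
  id_ops <- list(micromr:::ncs_identity_op("A"))
  expect_identical(ncs_average(fx$map, id_ops, fx$chA)$grid, fx$map$grid)
})

test_that("NCS averaging is idempotent within interpolation tolerance", {
  fx <- ncs4()
  reg <- ncs_region(fx$map, fx$opsA, fx$chA)
  avg <- ncs_average(fx$map, fx$opsA, fx$chA)
  avg2 <- ncs_average(avg, fx$opsA, fx$chA)
  expect_gt(stats::cor(avg$grid[reg$lin], avg2$grid[reg$lin]), 0.999)
})

test_that("four-fold averaging cuts region noise by about half", {
  fx <- ncs4()
  reg <- ncs_region(fx$map, fx$opsA, fx$chA)
  sigma <- stats::sd(as.vector(fx$map$grid))
  set.seed(42)
  noisy <- fx$map
  noisy$grid <- fx$map$grid + array(rnorm(length(fx$map$grid), 0, sigma),
                                    dim = dim(fx$map$grid))
  avg <- ncs_average(noisy, fx$opsA, fx$chA)
  err <- sqrt(mean((avg$grid[reg$lin] - fx$map$grid[reg$lin])^2)) / sigma
  expect_lte(err, 0.6)
})

test_that("density modification sharpens a perturbed-model map", {
  sc <- small_crystal()
  refl_t <- sf_fft(sc$model, sc$cell, sc$sym, 3.0)
  refl_t$f_obs <- Mod(refl_t$f_calc)
  true_map <- compute_map(refl_t, "fc")
  pert <- perturb_model(sc$model, 1.5, seed = 6)
  refl_p <- sc$refl
  refl_p$f_calc <- sf_fft(pert, sc$cell, sc$sym, 3.0, hkl = sc$refl)$f_calc
  start <- compute_map(refl_p, "two_fo_fc")
  solv <- solvent_fraction_of(pert, sc$cell, sc$sym)
  dm <- density_modify(start, refl_p, pert, solv, n_cycles = 5)
  expect_gt(map_correlation(dm, true_map), map_correlation(start, true_map))
  # zero cycles: untouched
  expect_identical(density_modify(start, refl_p, pert, solv, n_cycles = 0),
                   start)
  expect_error(density_modify(start, refl_p, pert, 0.1), "solvent_fraction")
})

test_that("density modification is phase-only and near a fixed point with true phases", {
  sc <- small_crystal()
  refl <- sf_fft(sc$model, sc$cell, sc$sym, 3.0)
  refl$f_obs <- Mod(refl$f_calc)
  refl$free <- rep(c(TRUE, rep(FALSE, 19)), length.out = nrow(refl))
  start <- compute_map(refl, "two_fo_fc")
  solv <- solvent_fraction_of(sc$model, sc$cell, sc$sym)
  dm <- density_modify(start, refl, sc$model, solv, n_cycles = 5)
  # perfect phases in: little degradation after 5 cycles
  expect_gt(map_correlation(dm, start), 0.98)
  # amplitudes of every output coefficient equal (scaled) f_obs: work and
  # free sets treated identically
  H <- as.matrix(refl[, c("h", "k", "l")])
  co <- micromr:::map_coefficients(dm, H)
  ratio_work <- Mod(co)[!refl$free] / refl$f_obs[!refl$free]
  ratio_free <- Mod(co)[refl$free] / refl$f_obs[refl$free]
  expect_equal(mean(ratio_work), mean(ratio_free), tolerance = 1e-6)
  expect_lt(stats::sd(c(ratio_work, ratio_free)), 1e-6)
})

test_that("map averaging standardizes, commutes and cancels negations", {
  sc <- small_crystal()
  refl <- sf_fft(sc$model, sc$cell, sc$sym, 3.0)
  refl$f_obs <- Mod(refl$f_calc)
  a <- compute_map(refl, "fc")
  one <- average_maps(list(a))
  expect_equal(one$grid, standardize_map(a)$grid, tolerance = 1e-12)
  neg <- a; neg$grid <- -a$grid
  zero <- average_maps(list(a, neg))
  expect_lt(max(abs(zero$grid)), 1e-12)
  b <- a; b$grid <- a$grid + array(rnorm(length(a$grid)), dim = dim(a$grid))
  c1 <- a; c1$grid <- a$grid + array(rnorm(length(a$grid)), dim = dim(a$grid))
  expect_equal(average_maps(list(a, b, c1))$grid,
               average_maps(list(c1, a, b))$grid, tolerance = 1e-12)
  bad <- new_map(array(0, dim = c(4, 4, 4)), sc$cell)
  expect_error(average_maps(list(a, bad)), "grids differ")
})

test_that("averaging maps with independent noise beats every input", {
  sc <- small_crystal()
  refl <- sf_fft(sc$model, sc$cell, sc$sym, 3.0)
  refl$f_obs <- Mod(refl$f_calc)
  signal <- compute_map(refl, "fc")
  for (seed in 1:5) {
    set.seed(seed)
    sigma <- stats::sd(as.vector(signal$grid))
    inputs <- lapply(1:4, function(i) {
      m <- signal
      m$grid <- m$grid + array(rnorm(length(m$grid), 0, sigma),
                               dim = dim(m$grid))
      m
    })
    avg <- average_maps(inputs)
    cc_inputs <- vapply(inputs, map_correlation, numeric(1), b = signal)
    expect_gt(map_correlation(avg, signal), max(cc_inputs))
  }
})
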