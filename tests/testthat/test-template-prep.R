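test_that("paired-FASTA alignments parse with correct pairs and identity", {
  a <- parse_alignment(c(">t", "ACD", ">s", "ACD"))
  expect_equal(nrow(a$pairs), 3)
  expect_equal(a$identity, 1.0)

  b <- parse_alignment(c(">t", "AC-D", ">s", "ACED"))
  expect_equal(b$pairs[, "target"], c(1, 2, 3))
  expect_equal(b$pairs[, "template"], c(1, 2, 4))
  expect_equal(b$identity, 1.0)

  expect_error(parse_alignment(c(">t", "ACDE", ">s", "ACD")), "lengths differ")
  expect_error(parse_alignment(c(">t", "---", ">s", "ACD")), "zero aligned")
  expect_error(parse_alignment(c(">t", "ACD")), "two FASTA records")
})

test_that("alignment identity equals a direct column-count oracle", {
  set.seed(11)
  for (rep in 1:3) {
    n <- 50
    tg <- sample(c("A", "C", "D", "E", "F"), n, replace = TRUE)
    tp <- ifelse(runif(n) < 0.3, tg, sample(c("G", "H", "I", "K"), n, TRUE))
    gaps <- sample(n, 5)
    tp[gaps] <- "-"
    a <- parse_alignment(c(">t", paste(tg, collapse = ""),
                           ">s", paste(tp, collapse = "")))
    cols <- tp != "-"
    expect_equal(a$identity, mean(tg[cols] == tp[cols]))
    expect_equal(nrow(a$pairs), sum(cols))
    expect_true(all(diff(a$pairs[, 1]) > 0) && all(diff(a$pairs[, 2]) > 0))
  }
})

make_full_residue <- function(resname, seqnum = 1) {
  top <- get_topology(resname)
  data.frame(chain = "A", resname = resname, seqnum = seqnum,
             atom = names(top), element = substr(names(top), 1, 1),
             x = seq_along(top), y = 0, z = 0, occ = 1, b = 10)
}

test_that("template editing renames, renumbers and prunes side chains", {
  tmpl <- mr_model(rbind(make_full_residue("LYS", 1),
                         make_full_residue("LYS", 2)))
  aln <- parse_alignment(c(">t", "GS", ">s", "KK"))
  ed <- edit_template(tmpl, aln)
  expect_equal(sort(ed$atom[ed$seqnum == 1]), c("C", "CA", "N", "O"))  # GLY
  expect_equal(sort(ed$atom[ed$seqnum == 2]), c("C", "CA", "CB", "N", "O"))  # SER
  expect_equal(unique(ed$resname), c("GLY", "SER"))
  expect_equal(length(attr(ed, "gaps")), 0)
})

test_that("identical sequences leave the template atoms unchanged", {
  tmpl <- mr_model(make_full_residue("TRP", 1))
  aln <- parse_alignment(c(">t", "W", ">s", "W"))
  ed <- edit_template(tmpl, aln)
  expect_equal(sort(ed$atom), sort(tmpl$atom))
  expect_equal(unique(ed$seqnum), 1)  # renumbered to target numbering
})

test_that("editing records unaligned target positions as gaps", {
  tmpl <- mr_model(rbind(make_full_residue("ALA", 1),
                         make_full_residue("VAL", 2)))
  aln <- parse_alignment(c(">t", "AGV", ">s", "A-V"))
  ed <- edit_template(tmpl, aln)
  expect_equal(attr(ed, "gaps"), 2L)
  expect_equal(unique(ed$seqnum), c(1L, 3L))
  expect_error(edit_template(tmpl, parse_alignment(c(">t", "AVW", ">s", "AVW"))),
               "missing from template")
})

test_that("pruning matches the set-intersection oracle on sampled pairs", {
  types <- setdiff(names(micromr:::residue_topology), "UNK")
  set.seed(3)
  pairs <- cbind(sample(types, 25, TRUE), sample(types, 25, TRUE))
  for (i in seq_len(nrow(pairs))) {
    tmpl <- mr_model(make_full_residue(pairs[i, 1]))
    aln_txt <- c(">t", micromr:::aa_one(pairs[i, 2]),
                 ">s", micromr:::aa_one(pairs[i, 1]))
    ed <- edit_template(tmpl, parse_alignment(aln_txt))
    expect_equal(sort(ed$atom), intersection_oracle(pairs[i, 1], pairs[i, 2]),
                 info = paste(pairs[i, ], collapse = "->"))
  }
})

test_that("copy-number enumeration inverts the Matthews relation", {
  sym <- spacegroup("P1")
  mass <- 5000
  # cell sized so n = 1 gives exactly 50% solvent: V = 2.46 * mass
  side <- (2.46 * mass)^(1 / 3)
  hyp <- enumerate_copies(unit_cell(side, side, side), sym, mass)
  expect_equal(length(hyp), 1)
  expect_equal(hyp[[1]]$n_copies, 1)
  expect_equal(hyp[[1]]$solvent_fraction, 0.5, tolerance = 1e-9)
  # doubled volume: the admissible set matches the hand-derived one
  # (solvent(n) = 1 - 0.25 n, so n = 1, 2, 3 lie in [0.20, 0.80])
  side2 <- (2 * 2.46 * mass)^(1 / 3)
  hyp2 <- enumerate_copies(unit_cell(side2, side2, side2), sym, mass)
  ns <- sort(vapply(hyp2, `[[`, numeric(1), "n_copies"))
  expect_equal(ns, c(1, 2, 3))
  for (h in hyp2)
    expect_equal(h$solvent_fraction, 1 - 0.25 * h$n_copies, tolerance = 1e-9)
  # all solvent fractions admissible and ordered by closeness to 0.5
  sf <- vapply(hyp2, `[[`, numeric(1), "solvent_fraction")
  expect_true(all(sf >= 0.2 & sf <= 0.8))
  expect_true(!is.unsorted(abs(sf - 0.5)))
  # too-small cell: nothing fits
  expect_warning(out <- enumerate_copies(unit_cell(5, 5, 5), sym, mass),
                 "no admissible")
  expect_equal(length(out), 0)
})

test_that("enumeration is independent of symmetry operator order", {
  sym <- spacegroup("P212121")
  sym_rev <- sym; sym_rev$ops <- rev(sym$ops)
  cell <- unit_cell(40, 45, 50)
  expect_identical(enumerate_copies(cell, sym, 4000),
                   enumerate_copies(cell, sym_rev, 4000))
})

test_that("multimer search models follow the divisibility rule", {
  dimer <- mr_model(rbind(make_full_residue("ALA", 1),
                          transform(make_full_residue("ALA", 1), chain = "B",
                                    x = make_full_residue("ALA", 1)$x + 20)))
  hyp4 <- list(list(n_copies = 4L, solvent_fraction = 0.5, uses_multimer = FALSE))
  out <- build_multimers(dimer, 2L, hyp4)
  expect_equal(length(out), 2)   # monomer and dimer
  expect_equal(length(unique(out[[1]]$chain)), 1)
  expect_equal(length(unique(out[[2]]$chain)), 2)
  expect_true(attr(out[[2]], "uses_multimer"))

  hyp3 <- list(list(n_copies = 3L, solvent_fraction = 0.5, uses_multimer = FALSE))
  expect_equal(length(build_multimers(dimer, 2L, hyp3)), 1)  # monomer only
  mono <- mr_model(make_full_residue("ALA", 1))
  expect_equal(length(build_multimers(mono, 1L, hyp4)), 1)
  expect_error(build_multimers(mono, 2L, hyp4), "exceeds chains")
})
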