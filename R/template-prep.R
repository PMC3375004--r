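AA1 <- c(A="ALA", R="ARG", N="ASN", D="ASP", C="CYS", Q="GLN", E="GLU",
         G="GLY", H="HIS", I="ILE", L="LEU", K="LYS", M="MET", F="PHE",
         P="PRO", S="SER", T="THR", W="TRP", Y="TYR", V="VAL", X="UNK")
AA3 <- setNames(names(AA1), AA1)

aa_three <- function(one) {
  out <- AA1[toupper(one)]
  out[is.na(out)] <- "UNK"
  unname(out)
}
aa_one <- function(three) {
  out <- AA3[toupper(three)]
  out[is.na(out)] <- "X"
  unname(out)
}

# Heavy-atom topology per residue type: atom name -> parent along the bonded
# tree (main chain N-CA-C(-O), side chain rooted at CB). Element is the first
# letter of the atom name for these names.
residue_topology <- local({
  mc <- c(N = "", CA = "N", C = "CA", O = "C")
  side <- list(
    ALA = c(CB = "CA"),
    ARG = c(CB="CA", CG="CB", CD="CG", NE="CD", CZ="NE", NH1="CZ", NH2="CZ"),
    ASN = c(CB="CA", CG="CB", OD1="CG", ND2="CG"),
    ASP = c(CB="CA", CG="CB", OD1="CG", OD2="CG"),
    CYS = c(CB="CA", SG="CB"),
    GLN = c(CB="CA", CG="CB", CD="CG", OE1="CD", NE2="CD"),
    GLU = c(CB="CA", CG="CB", CD="CG", OE1="CD", OE2="CD"),
    GLY = c(),
    HIS = c(CB="CA", CG="CB", ND1="CG", CD2="CG", CE1="ND1", NE2="CD2"),
    ILE = c(CB="CA", CG1="CB", CG2="CB", CD1="CG1"),
    LEU = c(CB="CA", CG="CB", CD1="CG", CD2="CG"),
    LYS = c(CB="CA", CG="CB", CD="CG", CE="CD", NZ="CE"),
    MET = c(CB="CA", CG="CB", SD="CG", CE="SD"),
    PHE = c(CB="CA", CG="CB", CD1="CG", CD2="CG", CE1="CD1", CE2="CD2", CZ="CE1"),
    PRO = c(CB="CA", CG="CB", CD="CG"),
    SER = c(CB="CA", OG="CB"),
    THR = c(CB="CA", OG1="CB", CG2="CB"),
    TRP = c(CB="CA", CG="CB", CD1="CG", CD2="CG", NE1="CD1", CE2="CD2",
            CE3="CD2", CZ2="CE2", CZ3="CE3", CH2="CZ2"),
    TYR = c(CB="CA", CG="CB", CD1="CG", CD2="CG", CE1="CD1", CE2="CD2",
            CZ="CE1", OH="CZ"),
    VAL = c(CB="CA", CG1="CB", CG2="CB"),
    UNK = c(CB = "CA"))
  lapply(side, function(s) c(mc, s))
})

#' Residue heavy-atom topology table
#'
#' @param resname 3-letter residue code (20 standard types or UNK).
#' @return Named character vector mapping each heavy-atom name to its parent
#'   atom along the bonded tree ("" for the root N).
#' @export
get_topology <- function(resname) {
  t <- residue_topology[[toupper(resname)]]
  if (is.null(t)) stop("no topology for residue type ", resname)
  t
}

#' Parse a paired-FASTA target/template alignment
#'
#' Two aligned records of equal length, target first. Every column where both
#' records are non-gap becomes an aligned pair (target position, template
#' position), positions counted along the ungapped sequences.
#'
#' @param path Path to the alignment file (or a character vector of its lines).
#' @return Object of class `mr_alignment`: `target_seq` / `template_seq`
#'   (aligned, with `-` gaps), `pairs` (2-column matrix), `identity` (fraction
#'   identical over aligned columns).
#' @export
parse_alignment <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) != 2) stop("alignment must contain exactly two FASTA records (target first)")
  seqs <- vapply(seq_along(hdr), function(i) {
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    toupper(paste(lines[(hdr[i] + 1):to], collapse = ""))
  }, character(1))
  if (nchar(seqs[1]) != nchar(seqs[2]))
    stop("aligned lengths differ: ", nchar(seqs[1]), " vs ", nchar(seqs[2]))
  tg <- strsplit(seqs[1], "")[[1]]
  tp <- strsplit(seqs[2], "")[[1]]
  gap <- function(x) x %in% c("-", ".")
  ti <- cumsum(!gap(tg)); si <- cumsum(!gap(tp))
  both <- !gap(tg) & !gap(tp)
  if (!any(both)) stop("zero aligned columns")
  pairs <- cbind(target = ti[both], template = si[both])
  structure(list(target_seq = seqs[1], template_seq = seqs[2], pairs = pairs,
                 identity = mean(tg[both] == tp[both])),
            class = "mr_alignment")
}

#' @export
print.mr_alignment <- function(x, ...) {
  cat(sprintf("alignment: %d aligned columns, identity %.1f%%\n",
              nrow(x$pairs), 100 * x$identity))
  invisible(x)
}

#' Edit a template model to match the target sequence
#'
#' Aligned template residues are kept, renamed to the target residue type and
#' renumbered to target numbering; side chains are pruned to the atoms shared
#' between template and target residue topologies along the bonded tree
#' (main-chain N, CA, C, O always kept; CB kept unless the target residue is
#' glycine). Unaligned template residues are deleted. Target positions with no
#' template residue are recorded in the `gaps` attribute.
#'
#' @param template `mr_model` (first chain used if several; residues numbered
#'   along the ungapped template sequence).
#' @param aln `mr_alignment` from [parse_alignment()].
#' @param chain Template chain to edit (default the first).
#' @return Edited `mr_model` with attribute `gaps` (integer target positions
#'   missing from the template) and `target_seq` (ungapped 1-letter target).
#' @export
edit_template <- function(template, aln, chain = NULL) {
  chain <- chain %||% template$chain[1]
  tm <- template[template$chain == chain, , drop = FALSE]
  target_plain <- gsub("[-.]", "", aln$target_seq)
  target_res <- aa_three(strsplit(target_plain, "")[[1]])
  out <- vector("list", nrow(aln$pairs))
  for (i in seq_len(nrow(aln$pairs))) {
    ti <- aln$pairs[i, 1]; ts <- aln$pairs[i, 2]
    res <- tm[tm$seqnum == ts, , drop = FALSE]
    if (nrow(res) == 0) stop("aligned residue ", ts, " missing from template model")
    res <- prune_residue(res, target_res[ti])
    res$seqnum <- ti
    out[[i]] <- res
  }
  m <- do.call(rbind, out)
  m <- mr_model(m, label = paste0(attr(template, "label") %||% "template", ":edited"))
  attr(m, "gaps") <- setdiff(seq_along(target_res), aln$pairs[, 1])
  attr(m, "target_seq") <- target_plain
  attr(m, "cell") <- attr(template, "cell")
  m
}

# Keep atoms present in both topologies with all ancestors kept (tree-closed
# intersection); rename the residue to the target type.
prune_residue <- function(res, target_resname) {
  ttop <- get_topology(target_resname)
  stop_ <- get_topology(res$resname[1])
  kept <- character(0)
  for (a in names(ttop)) {
    p <- ttop[[a]]
    if ((a %in% names(stop_)) && (p == "" || p %in% kept)) kept <- c(kept, a)
  }
  res <- res[res$atom %in% kept, , drop = FALSE]
  res$resname <- target_resname
  res
}

#' Enumerate plausible copy numbers via the Matthews relation
#'
#' For each copy count n, the Matthews volume is
#' `Vm = V_cell / (n_sym * n * mass)` and the solvent fraction
#' `1 - 1.23 / Vm`; counts with solvent fraction in \[0.20, 0.80\] are
#' admissible, ordered by closeness of the solvent fraction to 0.50.
#'
#' @param cell `mr_cell`.
#' @param sym `mr_symops`.
#' @param target_mass Molecular mass of one copy, Dalton.
#' @return List of hypotheses `list(n_copies, solvent_fraction, uses_multimer)`,
#'   possibly empty (with a warning) when no count fits.
#' @export
enumerate_copies <- function(cell, sym, target_mass) {
  stopifnot(target_mass > 0)
  V <- cell_volume(cell)
  nmax <- max(1, floor(V / (n_symops(sym) * target_mass * 1.23 / 0.8)))
  hyp <- list()
  for (n in seq_len(nmax)) {
    vm <- V / (n_symops(sym) * n * target_mass)
    solv <- 1 - 1.23 / vm
    if (solv >= 0.20 && solv <= 0.80)
      hyp[[length(hyp) + 1]] <- list(n_copies = n, solvent_fraction = solv,
                                     uses_multimer = FALSE)
  }
  if (!length(hyp)) {
    warning("no admissible copy number for this cell/mass")
    return(list())
  }
  hyp[order(vapply(hyp, function(h) abs(h$solvent_fraction - 0.5), numeric(1)))]
}

# approximate residue masses (Da) for Matthews estimates
residue_mass <- function(resname) {
  masses <- c(ALA=71.08, ARG=156.19, ASN=114.10, ASP=115.09, CYS=103.14,
              GLN=128.13, GLU=129.12, GLY=57.05, HIS=137.14, ILE=113.16,
              LEU=113.16, LYS=128.17, MET=131.19, PHE=147.18, PRO=97.12,
              SER=87.08, THR=101.10, TRP=186.21, TYR=163.18, VAL=99.13,
              UNK=110.0)
  out <- masses[toupper(resname)]
  out[is.na(out)] <- 110.0
  unname(out)
}

#' Sum residue masses of a model, Dalton
#' @param model `mr_model`.
#' @export
model_mass <- function(model) sum(residue_mass(model_sequence(model)))

#' Enumerate monomer/multimer search models per copy-number hypothesis
#'
#' When the copy count hypothesized for the asymmetric unit is a multiple of
#' the template's own assembly size, the template multimer is tried as a
#' search model alongside the monomer; otherwise only the monomer.
#'
#' @param edited Edited template `mr_model` (carrying
#'   `template_assembly_count` chains when > 1).
#' @param template_assembly_count Copies in the template's own assembly.
#' @param hypotheses List from [enumerate_copies()].
#' @return List of search models; each has attributes `hypothesis` and
#'   `uses_multimer`.
#' @export
build_multimers <- function(edited, template_assembly_count, hypotheses) {
  stopifnot(template_assembly_count >= 1)
  chains <- unique(edited$chain)
  if (template_assembly_count > length(chains))
    stop("assembly count ", template_assembly_count, " exceeds chains present (",
         length(chains), ")")
  monomer <- edited[edited$chain == chains[1], , drop = FALSE]
  out <- list()
  for (h in hypotheses) {
    add <- function(model, multi) {
      attr(model, "hypothesis") <- h
      attr(model, "uses_multimer") <- multi
      out[[length(out) + 1]] <<- model
    }
    add(monomer, FALSE)
    if (template_assembly_count > 1 && h$n_copies %% template_assembly_count == 0) {
      multimer <- edited[edited$chain %in% chains[seq_len(template_assembly_count)], ,
                         drop = FALSE]
      h2 <- h; h2$uses_multimer <- TRUE
      attr(multimer, "hypothesis") <- h2
      attr(multimer, "uses_multimer") <- TRUE
      out[[length(out) + 1]] <- multimer
    }
  }
  out
}
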