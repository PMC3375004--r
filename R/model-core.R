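STANDARD_RESNAMES <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS",
                       "ILE","LEU","LYS","MET","PHE","PRO","SER","THR","TRP",
                       "TYR","VAL","UNK")

#' Build a model from an atom table
#'
#' The model container is a flat atom table (one row per atom) carrying the
#' chain / residue / atom hierarchy in its columns, in the style of the
#' field's PDB toolkits.
#'
#' @param atoms data.frame with columns `chain`, `resname`, `seqnum`, `atom`,
#'   `element`, `x`, `y`, `z`, and optionally `occ` (default 1) and `b`
#'   (default 20).
#' @param label Free-text label.
#' @return Object of class `mr_model` (a data.frame).
#' @export
mr_model <- function(atoms, label = "") {
  need <- c("chain", "resname", "seqnum", "atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 20
  atoms <- as.data.frame(atoms)[, c(need, "occ", "b")]
  atoms$chain <- as.character(atoms$chain)
  atoms$resname <- as.character(atoms$resname)
  atoms$seqnum <- as.integer(atoms$seqnum)
  atoms$atom <- as.character(atoms$atom)
  atoms$element <- as.character(atoms$element)
  rownames(atoms) <- NULL
  m <- structure(atoms, class = c("mr_model", "data.frame"))
  attr(m, "label") <- label
  validate_model(m)
  m
}

validate_model <- function(m) {
  if (nrow(m) == 0) stop("empty model")
  if (any(!nzchar(m$element))) stop("atoms with empty element symbol")
  if (any(m$occ < 0 | m$occ > 1)) stop("occupancies must lie in [0, 1]")
  if (any(m$b < 0)) stop("B-factors must be non-negative")
  key <- paste(m$chain, m$seqnum, m$atom)
  if (anyDuplicated(key)) stop("duplicate atom name within a residue: ",
                               key[duplicated(key)][1])
  for (ch in unique(m$chain)) {
    sq <- unique(m$seqnum[m$chain == ch])
    if (any(diff(sq) <= 0)) stop("residue numbering not strictly increasing in chain ", ch)
  }
  invisible(m)
}

#' @export
print.mr_model <- function(x, ...) {
  ch <- unique(x$chain)
  cat(sprintf("mr_model '%s': %d chain(s), %d residues, %d atoms\n",
              attr(x, "label") %||% "", length(ch),
              length(unique(paste(x$chain, x$seqnum))), nrow(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

model_sequence <- function(model, chain = NULL) {
  m <- if (is.null(chain)) model else model[model$chain == chain, , drop = FALSE]
  ca <- m[m$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$chain, ca$seqnum), , drop = FALSE]
  ca$resname
}

split_residues <- function(model) {
  split(seq_len(nrow(model)), paste(model$chain, formatC(model$seqnum, width = 8, flag = "0")))
}

## ---- PDB I/O ---------------------------------------------------------------

#' Read a PDB-format coordinate file
#'
#' Parses ATOM/HETATM records into an [mr_model()]. Insertion codes are
#' rejected; alternate locations are collapsed to the highest-occupancy
#' conformer (ties broken by altloc letter order). A CRYST1 record, when
#' present, is attached as attributes `cell` and `spacegroup_name`.
#'
#' @param path Path to a PDB file.
#' @return `mr_model`, possibly with `cell` / `spacegroup_name` attributes.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(idx)) stop("empty model: no ATOM/HETATM records in ", path)
  ln <- lines[idx]
  field <- function(from, to) trimws(substr(ln, from, to))
  numfield <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(field(from, to)))
    if (anyNA(v)) {
      bad <- idx[which(is.na(v))[1]]
      stop(sprintf("parse error at line %d: bad %s field", bad, what))
    }
    v
  }
  icode <- field(27, 27)
  if (any(nzchar(icode))) {
    stop(sprintf("parse error at line %d: insertion codes are not supported",
                 idx[which(nzchar(icode))[1]]))
  }
  at <- data.frame(
    atom = field(13, 16),
    altloc = field(17, 17),
    resname = field(18, 20),
    chain = field(22, 22),
    seqnum = as.integer(numfield(23, 26, "residue number")),
    x = numfield(31, 38, "x"), y = numfield(39, 46, "y"), z = numfield(47, 54, "z"),
    occ = numfield(55, 60, "occupancy"), b = numfield(61, 66, "B-factor"),
    element = field(77, 78),
    stringsAsFactors = FALSE)
  no_el <- !nzchar(at$element)
  at$element[no_el] <- substr(gsub("[^A-Za-z].*$", "", at$atom[no_el]), 1, 1)
  # altloc collapse: highest occupancy wins, ties to earliest altloc letter
  has_alt <- nzchar(at$altloc)
  if (any(has_alt)) {
    key <- paste(at$chain, at$seqnum, at$atom)
    ord <- order(key, -at$occ, at$altloc)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$seqnum, at$atom)), , drop = FALSE]
  }
  at$chain[!nzchar(at$chain)] <- "A"
  at <- at[order(match(at$chain, unique(at$chain))), , drop = FALSE]
  m <- mr_model(at[, c("chain", "resname", "seqnum", "atom", "element",
                       "x", "y", "z", "occ", "b")],
                label = basename(path))
  cr <- lines[rec == "CRYST1"]
  if (length(cr)) {
    v <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                                       substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                                       substr(cr[1], 41, 47), substr(cr[1], 48, 54))))
    if (!anyNA(v)) {
      attr(m, "cell") <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
      attr(m, "spacegroup_name") <- trimws(substr(cr[1], 56, 66))
    }
  }
  m
}

#' Write a model in PDB format
#'
#' Fixed-width ATOM records, coordinates to 3 decimals; TER after each chain
#' and END at the end. A `cell` attribute (with optional `spacegroup_name`)
#' is written as a CRYST1 record.
#'
#' @param model An `mr_model`.
#' @param path Output path.
#' @param cell Optional `mr_cell` overriding the model's `cell` attribute.
#' @param spacegroup_name Optional space-group label for CRYST1.
#' @export
write_model <- function(model, path, cell = attr(model, "cell"),
                        spacegroup_name = attr(model, "spacegroup_name")) {
  validate_model(model)
  out <- character(0)
  if (!is.null(cell)) {
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
                   spacegroup_name %||% "P 1", 1L)
  }
  serial <- 0L
  for (ch in unique(model$chain)) {
    sub <- model[model$chain == ch, , drop = FALSE]
    nm <- ifelse(nchar(sub$atom) < 4 & nchar(sub$element) == 1,
                 sprintf(" %-3s", sub$atom), sprintf("%-4s", sub$atom))
    serials <- serial + seq_len(nrow(sub))
    out <- c(out, sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serials %% 100000L, nm, sub$resname, ch, sub$seqnum,
      sub$x, sub$y, sub$z, sub$occ, sub$b, sub$element))
    serial <- serial + nrow(sub)
    out <- c(out, sprintf("TER   %5d      %-3s %1s%4d",
                          (serial + 1L) %% 100000L, sub$resname[nrow(sub)], ch,
                          sub$seqnum[nrow(sub)]))
    serial <- serial + 1L
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
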