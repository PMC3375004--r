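# Evaluate expr with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

# Stable per-stage seed derivation from one run seed (kept below 2^31).
derive_seed <- function(seed, stage, i = 0L) {
  (as.numeric(seed) * 7919 + match(stage, c(
    "synth", "free", "prerefine", "mr", "densmod", "rebuild", "autobuild",
    "perturb", "homolog", "noise", "misc")) * 104729 + as.numeric(i) * 13) %%
    2147483629
}

#' Write a density map in CCP4/MRC format
#'
#' Minimal mode-2 (float32) MRC writer/reader for the package's own maps.
#'
#' @param map `mr_map`.
#' @param path Output path.
#' @export
write_map_mrc <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(map$grid)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)              # NX NY NZ
  wi(2)              # MODE float32
  wi(c(0, 0, 0))     # NXSTART..
  wi(d)              # MX MY MZ
  wf(c(map$cell$a, map$cell$b, map$cell$c,
       map$cell$alpha, map$cell$beta, map$cell$gamma))
  wi(c(1, 2, 3))     # axis order
  wf(c(min(map$grid), max(map$grid), mean(map$grid)))
  wi(c(1, 0))        # ISPG, NSYMBT
  wi(rep(0, 25))     # extra
  wf(c(0, 0, 0))     # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(map$grid)))
  wi(0)              # NLABL
  writeBin(raw(800), con)
  wf(as.vector(map$grid))
  invisible(path)
}

#' @param path Path to an MRC file written by [write_map_mrc()].
#' @rdname write_map_mrc
#' @export
read_map_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported MRC mode ", mode)
  ri(3); ri(3)
  cp <- rf(6)
  seek(con, 1024)
  grid <- array(rf(prod(d)), dim = d)
  new_map(grid, unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6]))
}

append_jsonl <- function(path, record) {
  if (is.null(path)) return(invisible(NULL))
  cat(jsonlite::toJSON(record, auto_unbox = TRUE, digits = 8), "\n",
      file = path, append = TRUE, sep = "")
  invisible(NULL)
}
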