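# Ideal main-chain geometry (Engh/Huber-style averages, Angstrom / degrees).
IDEAL <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5)

# Canonical backbone torsion pairs by secondary-structure class.
CANONICAL_TORSIONS <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -120, psi = 130),
  ppii = c(phi = -75, psi = 145),
  turn1 = c(phi = -60, psi = -30),
  turn2 = c(phi = -90, psi = 0),
  loop = c(phi = -80, psi = 80))

#' Build an ideal-geometry backbone from torsions
#'
#' Chain extension with ideal bond lengths/angles (NeRF construction):
#' atoms N, CA, C, O per residue plus CB for non-glycine.
#'
#' @param torsions data.frame with columns `phi`, `psi`, `omega` (degrees);
#'   `phi[1]` and the final `psi`/`omega` may be `NA`.
#' @param resnames Character vector of 3-letter residue types (recycled).
#' @param chain Chain identifier.
#' @param seqnums Residue numbers (default 1..n).
#' @param b B-factor for all atoms.
#' @return `mr_model`.
#' @export
build_backbone <- function(torsions, resnames = "ALA", chain = "A",
                           seqnums = seq_len(nrow(torsions)), b = 15) {
  n <- nrow(torsions)
  resnames <- rep_len(resnames, n)
  phi <- torsions$phi; psi <- torsions$psi
  omega <- if (is.null(torsions$omega)) rep(180, n) else torsions$omega
  omega[is.na(omega)] <- 180
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(IDEAL$n_ca, 0, 0)
  C[1, ] <- place_atom(c(0, -1, 0), N[1, ], CA[1, ], IDEAL$ca_c, IDEAL$ang_n_ca_c, 60)
  if (n > 1) for (i in 1:(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], IDEAL$c_n, IDEAL$ang_ca_c_n,
                             ifelse(is.na(psi[i]), -45, psi[i]))
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], IDEAL$n_ca,
                              IDEAL$ang_c_n_ca, omega[i])
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], IDEAL$ca_c,
                             IDEAL$ang_n_ca_c,
                             ifelse(is.na(phi[i + 1]), -60, phi[i + 1]))
  }
  rows <- list()
  for (i in seq_len(n)) {
    O <- place_atom(N[i, ], CA[i, ], C[i, ], IDEAL$c_o, IDEAL$ang_ca_c_o,
                    ifelse(is.na(psi[i]), -45, psi[i]) + 180)
    at <- data.frame(atom = c("N", "CA", "C", "O"),
                     element = c("N", "C", "C", "O"),
                     x = c(N[i, 1], CA[i, 1], C[i, 1], O[1]),
                     y = c(N[i, 2], CA[i, 2], C[i, 2], O[2]),
                     z = c(N[i, 3], CA[i, 3], C[i, 3], O[3]))
    if (toupper(resnames[i]) != "GLY") {
      CB <- place_cb(N[i, ], CA[i, ], C[i, ])
      at <- rbind(at, data.frame(atom = "CB", element = "C",
                                 x = CB[1], y = CB[2], z = CB[3]))
    }
    at$chain <- chain; at$resname <- resnames[i]; at$seqnum <- seqnums[i]
    rows[[i]] <- at
  }
  df <- do.call(rbind, rows)
  df$occ <- 1; df$b <- b
  mr_model(df)
}

# CB for an L-amino acid from its own N, CA, C.
place_cb <- function(N, CA, C) {
  u1 <- (N - CA) / vnorm(N - CA)
  u2 <- (C - CA) / vnorm(C - CA)
  bis <- -(u1 + u2); bis <- bis / vnorm(bis)
  perp <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
  perp <- perp / vnorm(perp)
  # ~50 degrees out of the N-CA-C plane, on the L side
  CA + IDEAL$ca_cb * (cos(deg2rad(52)) * bis - sin(deg2rad(52)) * perp)
}

#' Extract backbone torsions from a model chain
#'
#' @param model `mr_model` with N/CA/C atoms.
#' @param chain Chain id (default first).
#' @return data.frame `seqnum`, `phi`, `psi`, `omega` (`NA` at chain ends).
#' @export
extract_torsions <- function(model, chain = NULL) {
  chain <- chain %||% model$chain[1]
  m <- model[model$chain == chain, , drop = FALSE]
  sq <- sort(unique(m$seqnum))
  get <- function(i, nm) {
    r <- m[m$seqnum == sq[i] & m$atom == nm, c("x", "y", "z")]
    if (nrow(r) != 1) return(NULL)
    as.numeric(r)
  }
  n <- length(sq)
  out <- data.frame(seqnum = sq, phi = NA_real_, psi = NA_real_, omega = NA_real_)
  for (i in seq_len(n)) {
    Ni <- get(i, "N"); CAi <- get(i, "CA"); Ci <- get(i, "C")
    if (i > 1) {
      Cp <- get(i - 1, "C")
      if (!is.null(Cp) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci))
        out$phi[i] <- dihedral_angle(Cp, Ni, CAi, Ci)
    }
    if (i < n) {
      Nn <- get(i + 1, "N"); CAn <- get(i + 1, "CA")
      if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Nn)) {
        out$psi[i] <- dihedral_angle(Ni, CAi, Ci, Nn)
        if (!is.null(CAn)) out$omega[i] <- dihedral_angle(CAi, Ci, Nn, CAn)
      }
    }
  }
  out
}
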