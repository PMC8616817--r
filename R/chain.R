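# Torsion-driven all-atom chain builder (NeRF).  Backbone is built from
# (phi, psi) with ideal bond lengths/angles and trans peptide bonds;
# sidechain heavy atoms follow the per-residue z-matrices in topology.R.
# Used by the synthetic fold generator, the freely rotating chain null model
# and nothing else -- real structures come from coordinate files.

BB_GEO <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
               a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
               a_ca_c_o = 120.5)

# Evaluate a z-matrix dihedral spec ("x1", "x2+120", "122.5") given chi values.
eval_dih <- function(spec, chi) {
  m <- regmatches(spec, regexec("^x([0-9])([+-][0-9.]+)?$", spec))[[1]]
  if (length(m) == 0L) return(as.numeric(spec))
  v <- chi[as.integer(m[2])]
  if (nzchar(m[3])) v <- v + as.numeric(m[3])
  v
}

#' Build an all-atom conformer from backbone and sidechain torsions
#'
#' @param sequence character vector of 3-letter residue codes.
#' @param phi,psi backbone torsions in degrees (length of sequence; phi of
#'   the first residue is unused).
#' @param chi list of per-residue chi vectors (recycled defaults of -60 used
#'   where missing); proline ring torsions are fixed internally.
#' @param omega peptide torsion (default 180, trans).
#' @param chain,start chain id and first residue number.
#' @param hydrogens add ideal-geometry protons (default TRUE).
#' @return an \code{nmr_conformer}.
#' @export
build_conformer <- function(sequence, phi, psi, chi = NULL, omega = 180,
                            chain = "A", start = 1L, hydrogens = TRUE) {
  n <- length(sequence)
  check_resname(sequence)
  stopifnot(length(phi) == n, length(psi) == n)
  g <- BB_GEO
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- place_internal(N[i, ], CA[i, ], C[i, ], g$b_c_n,
                                   g$a_ca_c_n, psi[i])
      CA[i + 1, ] <- place_internal(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca,
                                    g$a_c_n_ca, omega)
      C[i + 1, ] <- place_internal(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c,
                                   g$a_n_ca_c, phi[i + 1])
    }
    O[i, ] <- place_internal(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                             psi[i] + 180)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rt <- sequence[i]
    topo <- residue_topology(rt)
    pos <- list(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    xi <- if (rt == "PRO") c(20, -10, -60, -60) else {
      v <- if (!is.null(chi) && length(chi) >= i && !is.null(chi[[i]])) chi[[i]] else numeric(0)
      c(v, rep(-60, 4))[1:4]
    }
    z <- topo$zmat
    if (!is.null(z)) {
      for (k in seq_len(nrow(z))) {
        pos[[z$name[k]]] <- place_internal(pos[[z$aref[k]]], pos[[z$bref[k]]],
                                           pos[[z$parent[k]]], z$r[k],
                                           z$theta[k], eval_dih(z$dih[k], xi))
      }
    }
    nm <- names(pos)
    xyz <- do.call(rbind, pos)
    rows[[i]] <- data.frame(chain = chain, resno = start + i - 1L,
                            resname = rt, atom = nm,
                            elem = atom_element(nm),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  cf <- new_conformer(do.call(rbind, rows))
  if (hydrogens) cf <- add_hydrogens(cf)
  cf
}

# One freely rotating chain conformer: fixed covalent geometry, torsions
# drawn uniformly (proline phi pinned near -65).  Consumes the current RNG
# stream.
free_chain_conformer <- function(sequence, chain = "A", start = 1L,
                                 hydrogens = TRUE) {
  n <- length(sequence)
  phi <- stats::runif(n, -180, 180)
  psi <- stats::runif(n, -180, 180)
  phi[sequence == "PRO"] <- -65
  chi <- lapply(seq_len(n), function(i) stats::runif(4, -180, 180))
  build_conformer(sequence, phi, psi, chi, chain = chain, start = start,
                  hydrogens = hydrogens)
}
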