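# Self-contained synthetic NMR test world: a procedurally built toy fold
# (helix-turn-helix with a short extended tail), random-coil-based chemical
# shifts, NOESY peaks generated from the true short-distance network, decoy
# models at controlled accuracy, and forward-calculated RDCs.  Every output
# is a pure function of (config, seed).

#' Configuration of the synthetic benchmark world
#'
#' @param n_residues chain length (10..200).
#' @param seed RNG seed (mandatory; every stochastic output is a pure
#'   function of config + seed).
#' @param d_max NOE detection cutoff in Angstrom.
#' @param peak_dropout fraction of true peaks removed (exchange broadening,
#'   overlap losses), in [0, 1).
#' @param artifact_peak_rate extra artifact peaks as a fraction of the true
#'   peak count (>= 0).
#' @param shift_jitter s.d. (ppm) of the per-group measurement jitter, also
#'   applied to peak positions.
#' @param shift_dispersion s.d. (ppm, 1H scale) of the deterministic
#'   per-residue structural dispersion added to the random-coil means;
#'   heavy-atom nuclei use 8x this value.  Real assignment tables are
#'   dispersed by the fold, so this is part of the stated world, not noise;
#'   set it to 0 to get the bare tabulated means.
#' @param coordinate_noise_levels decoy accuracy ladder: target backbone
#'   RMSD (A) of the smooth coordinate perturbation.
#' @param prochiral_ambiguous collapse Leu/Val isopropyl methyl pairs to one
#'   shared shift with NMR-STAR ambiguity code 2 (the common situation when
#'   no stereospecific assignment is available).
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(n_residues = 40L, seed, d_max = 5.0,
                         peak_dropout = 0, artifact_peak_rate = 0,
                         shift_jitter = 0, shift_dispersion = 0.15,
                         coordinate_noise_levels = c(0, 0.5, 1, 2, 4),
                         prochiral_ambiguous = TRUE) {
  if (missing(seed)) data_error("synth_config requires an explicit seed")
  if (n_residues < 10L || n_residues > 200L)
    data_error("n_residues must be in [10, 200]")
  if (peak_dropout < 0 || peak_dropout >= 1)
    data_error("peak_dropout must be in [0, 1)")
  if (artifact_peak_rate < 0) data_error("artifact_peak_rate must be >= 0")
  structure(list(n_residues = as.integer(n_residues), seed = as.integer(seed),
                 d_max = d_max, peak_dropout = peak_dropout,
                 artifact_peak_rate = artifact_peak_rate,
                 shift_jitter = shift_jitter,
                 shift_dispersion = shift_dispersion,
                 coordinate_noise_levels = coordinate_noise_levels,
                 prochiral_ambiguous = prochiral_ambiguous),
            class = "synth_config")
}

# residue-type motif tiled to the requested length; guarantees Val, Phe,
# Leu, Ile, Tyr, Gly so all pseudoatom code paths are exercised
SYNTH_MOTIF <- c("MET", "LYS", "VAL", "LEU", "PHE", "GLU", "ALA", "ILE",
                 "SER", "THR", "ASP", "TYR", "ARG", "LEU", "GLY", "ASN",
                 "GLN", "ALA", "LYS", "VAL")

synth_sequence <- function(n) rep_len(SYNTH_MOTIF, n)

# backbone torsions of the toy fold: helix 1, a 4-residue reversing turn,
# helix 2, and a 4-residue extended (strand-like) C-terminal tail
toyfold_torsions <- function(n) {
  phi <- rep(-57, n); psi <- rep(-47, n)
  tail <- 4L
  turn <- 4L
  h1 <- (n - turn - tail) %/% 2L
  tstart <- h1 + 1L
  tphi <- c(-115, -5, -95, -70)
  tpsi <- c(-110, 135, -130, -80)
  phi[tstart:(tstart + 3L)] <- tphi
  psi[tstart:(tstart + 3L)] <- tpsi
  if (tail > 0L) {
    phi[(n - tail + 1L):n] <- -120
    psi[(n - tail + 1L):n] <- 120
  }
  list(phi = phi, psi = psi)
}

#' Build the synthetic toy-fold structure
#'
#' Deterministic for a fixed seed (the seed only adds +/- 2 degree torsion
#' jitter).  Contains methyl, prochiral, and aromatic residues by
#' construction, with chi1 rotamers chosen greedily to avoid steric clashes.
#'
#' @param config a \code{\link{synth_config}}.
#' @return a protonated \code{nmr_conformer} (the "true" structure).
#' @export
make_structure <- function(config) {
  n <- config$n_residues
  seq3 <- synth_sequence(n)
  tor <- toyfold_torsions(n)
  with_seed(config$seed * 7L + 1L, {
    phi <- tor$phi + stats::runif(n, -2, 2)
    psi <- tor$psi + stats::runif(n, -2, 2)
    cf <- build_clash_relaxed(seq3, phi, psi)
    cf
  })
}

# build with greedy chi1/chi2 rotamer search to relieve sidechain clashes
build_clash_relaxed <- function(seq3, phi, psi) {
  n <- length(seq3)
  chi <- lapply(seq_len(n), function(i) c(-60, -60, -60, -60))
  cf <- build_conformer(seq3, phi, psi, chi, hydrogens = FALSE)
  x3_opts <- c(-60, 180, 60)
  for (pass in 1:6) {
    cl <- clash_residues(cf)
    if (length(cl) == 0L) break
    for (i in cl) {
      best <- NULL; best_min <- -Inf
      for (x1 in c(-60, 180, 60)) {
        for (x2 in c(-60, 180, 60)) {
          for (x3 in (if (n_chi(seq3[i]) >= 3L) x3_opts else -60)) {
            trial <- chi
            trial[[i]][1:3] <- c(x1, x2, x3)
            cf_t <- rebuild_sidechain(cf, seq3, i, trial[[i]])
            m <- min_noncovalent_dist(cf_t, i)
            if (m > best_min) { best_min <- m; best <- trial; cf_best <- cf_t }
          }
        }
      }
      chi <- best
      cf <- cf_best
    }
  }
  add_hydrogens(cf)
}

BB_ATOMS <- c("N", "CA", "C", "O")

# non-covalent heavy-pair mask: same residue, or adjacent residues where
# either atom is backbone (1-2/1-3/1-4 through the peptide bond)
noncov_mask <- function(hv) {
  dres <- abs(outer(hv$resno, hv$resno, "-"))
  bb <- hv$atom %in% BB_ATOMS
  either_bb <- outer(bb, bb, "|")
  dres == 0L | (dres == 1L & either_bb)
}

# residues involved in heavy-atom clashes (< 2.4 A non-covalent)
clash_residues <- function(cf, cutoff = 2.4) {
  hv <- cf[cf$elem != "H", , drop = FALSE]
  D <- as.matrix(stats::dist(coords(hv)))
  near <- D < cutoff & upper.tri(D)
  near[noncov_mask(hv)] <- FALSE
  idx <- which(near, arr.ind = TRUE)
  sort(unique(c(hv$resno[idx[, 1]], hv$resno[idx[, 2]])))
}

min_noncovalent_dist <- function(cf, resno) {
  hv <- cf[cf$elem != "H", , drop = FALSE]
  sel <- hv$resno == resno & !(hv$atom %in% BB_ATOMS)
  if (!any(sel)) return(Inf)
  other <- hv$resno != resno &
    !(abs(hv$resno - resno) == 1L & hv$atom %in% BB_ATOMS)
  if (!any(other)) return(Inf)
  P <- coords(hv)
  min(fields_dist(P[sel, , drop = FALSE], P[other, , drop = FALSE]))
}

fields_dist <- function(A, B) {
  # pairwise Euclidean distances between row sets
  sqrt(pmax(0, outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
}

# recompute the sidechain heavy atoms of residue i for new chi values
rebuild_sidechain <- function(cf, seq3, i, chi_i) {
  rt <- seq3[i]
  topo <- residue_topology(rt)
  z <- topo$zmat
  if (is.null(z)) return(cf)
  rows <- which(cf$resno == sort(unique(cf$resno))[i])
  pos <- list()
  for (k in rows) pos[[cf$atom[k]]] <- c(cf$x[k], cf$y[k], cf$z[k])
  xi <- if (rt == "PRO") c(20, -10, -60, -60) else c(chi_i, rep(-60, 4))[1:4]
  for (k in seq_len(nrow(z))) {
    pos[[z$name[k]]] <- place_internal(pos[[z$aref[k]]], pos[[z$bref[k]]],
                                       pos[[z$parent[k]]], z$r[k],
                                       z$theta[k], eval_dih(z$dih[k], xi))
  }
  for (k in rows) {
    p <- pos[[cf$atom[k]]]
    cf$x[k] <- p[1]; cf$y[k] <- p[2]; cf$z[k] <- p[3]
  }
  cf
}

# jitter-sharing group of an atom (degenerate protons share one shift draw)
shift_group_key <- function(rt, atom) {
  topo <- residue_topology(rt)
  pi_ <- match(atom, topo$protons$name)
  if (!is.na(pi_)) {
    par <- topo$protons$parent[pi_]
    if (sum(topo$protons$parent == par) == 3L) return(par)  # methyl
  }
  if (rt %in% c("PHE", "TYR")) {
    if (atom %in% c("HD1", "HD2")) return("HDring")
    if (atom %in% c("HE1", "HE2")) return("HEring")
    if (atom %in% c("CD1", "CD2")) return("CDring")
    if (atom %in% c("CE1", "CE2")) return("CEring")
  }
  atom
}

#' Generate the chemical-shift assignment table for a synthetic structure
#'
#' Per-(residue, atom) random-coil means from the shipped table plus seeded
#' jitter shared within each degenerate group.  Exchange-broadened protons
#' (hydroxyl, sulfhydryl, lysine/arginine terminal NH, His ring NH, the
#' N-terminal amine) are not assigned, as in real tables.  Covers 100% of
#' the remaining (observable) protons plus the attached 13C/15N nuclei.
#'
#' @param conformer the (protonated) synthetic structure.
#' @param config a \code{\link{synth_config}}.
#' @return a \code{shift_table}.
#' @export
make_shifts <- function(conformer, config) {
  rc <- random_coil_table()
  res <- unique(conformer[, c("chain", "resno", "resname")])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  first <- res$resno[1]
  rows <- list()
  with_seed(config$seed * 7L + 2L, {
    for (r in seq_len(nrow(res))) {
      rt <- res$resname[r]; rn <- res$resno[r]; ch <- res$chain[r]
      tab <- rc[rc$resname == rt, , drop = FALSE]
      if (rn == first) tab <- tab[tab$atom != "H", , drop = FALSE]
      if (nrow(tab) == 0L) next
      gk <- vapply(tab$atom, function(a) shift_group_key(rt, a), "")
      ug <- unique(gk)
      z_disp <- stats::rnorm(length(ug)); names(z_disp) <- ug
      z_jit <- stats::rnorm(length(ug)); names(z_jit) <- ug
      is_h <- grepl("^H", tab$atom)
      nucl_scale <- ifelse(is_h, 1, 8)
      val <- tab$shift +
        z_disp[gk] * config$shift_dispersion * nucl_scale +
        z_jit[gk] * config$shift_jitter * nucl_scale
      amb <- rep(1L, nrow(tab))
      if (config$prochiral_ambiguous && rt %in% c("LEU", "VAL")) {
        pair <- if (rt == "LEU") c("HD1", "HD2") else c("HG1", "HG2")
        m1 <- grepl(paste0("^", pair[1], "[0-9]$"), tab$atom)
        m2 <- grepl(paste0("^", pair[2], "[0-9]$"), tab$atom)
        shared <- mean(c(val[m1][1], val[m2][1]))
        val[m1 | m2] <- shared
        amb[m1 | m2] <- 2L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resno = rn, resname = rt, atom = tab$atom,
        shift = val, ambiguity = amb, stringsAsFactors = FALSE)
    }
  })
  new_shift_table(do.call(rbind, rows))
}

.rc_env <- new.env(parent = emptyenv())
random_coil_table <- function() {
  if (is.null(.rc_env$tab)) {
    path <- system.file("extdata", "random_coil_shifts.tsv", package = "rpfdp")
    .rc_env$tab <- utils::read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
  }
  .rc_env$tab
}

#' Generate a NOESY peak list from the true distance network
#'
#' One cross peak per site pair with summation distance <= d_max, positions
#' at the assigned shifts (+/- jitter), intensity proportional to d^-6;
#' seeded dropout removes true peaks and seeded artifact peaks are added at
#' uniform random positions inside the observed shift range.
#'
#' @param conformer the true structure (protonated).
#' @param shifts its \code{shift_table}.
#' @param config a \code{\link{synth_config}}.
#' @param type "2D" (H,H), "C3D" (H, C_edit, H_acq) or "N3D".
#' @return a \code{peak_list}.
#' @export
make_noesy <- function(conformer, shifts, config, type = c("2D", "C3D", "N3D")) {
  type <- match.arg(type)
  sites <- build_proton_sites(conformer, shifts)
  D <- site_distance_matrix(sites, conformer)
  ut <- which(upper.tri(D) & D <= config$d_max, arr.ind = TRUE)
  s1 <- vapply(sites$member_shift[ut[, 1]], function(s) s[1], 1.0)
  s2 <- vapply(sites$member_shift[ut[, 2]], function(s) s[1], 1.0)
  inten <- D[ut]^-6 * 1e6
  hv <- site_heavy_shifts(sites, shifts)
  helem <- vapply(sites$heavy, function(h) substring(h[1], 1, 1), "")

  with_seed(config$seed * 7L + 3L, {
    if (type == "2D") {
      pos <- cbind(s1, s2)
      types <- c("H_indirect", "H_acq")
    } else {
      eelem <- if (type == "C3D") "C" else "N"
      keep1 <- helem[ut[, 2]] == eelem & lengths(hv[ut[, 2]]) > 0
      keep2 <- helem[ut[, 1]] == eelem & lengths(hv[ut[, 1]]) > 0
      pos <- rbind(
        cbind(s1[keep1], vapply(hv[ut[keep1, 2]], function(h) h[1], 1.0),
              s2[keep1]),
        cbind(s2[keep2], vapply(hv[ut[keep2, 1]], function(h) h[1], 1.0),
              s1[keep2]))
      inten <- c(inten[keep1], inten[keep2])
      types <- c("H_indirect", if (type == "C3D") "C_edit" else "N_edit",
                 "H_acq")
    }
    if (config$shift_jitter > 0)
      pos <- pos + stats::rnorm(length(pos), 0, config$shift_jitter)
    nt <- nrow(pos)
    keep <- stats::runif(nt) >= config$peak_dropout
    pos <- pos[keep, , drop = FALSE]
    inten <- inten[keep]
    n_art <- round(config$artifact_peak_rate * nt)
    if (n_art > 0) {
      hrange <- range(unlist(sites$member_shift))
      art <- matrix(stats::runif(n_art * ncol(pos)), n_art, ncol(pos))
      for (k in seq_len(ncol(pos))) {
        rg <- if (types[k] %in% c("H_acq", "H_indirect")) hrange else
          range(unlist(hv[lengths(hv) > 0]))
        art[, k] <- rg[1] + art[, k] * diff(rg)
      }
      pos <- rbind(pos, art)
      inten <- c(inten, stats::runif(n_art, min(inten), stats::median(inten)))
    }
    new_peak_list(seq_len(nrow(pos)), pos, types, inten,
                  label = sprintf("synth_%s", type), dialect = "tsv")
  })
}

#' Generate decoy models at controlled accuracy
#'
#' Decoys are built in torsion space: the backbone and sidechain torsions
#' measured from the true structure are perturbed by Gaussian noise whose
#' magnitude is iteratively rescaled to hit the target backbone RMSD, and
#' the chain is rebuilt at ideal covalent geometry.  Local geometry is thus
#' perfect at every accuracy level, as in real prediction models -- errors
#' show up as displaced segments and (at high levels) interpenetrating,
#' unsupported contacts.  A freely rotating chain decoy (random coil) is
#' appended.
#'
#' @param conformer the true structure.
#' @param config a \code{\link{synth_config}} (levels from
#'   \code{coordinate_noise_levels}).
#' @return list of entries \code{list(conformer, level, rmsd)}; the chain
#'   decoy has level \code{Inf}.
#' @export
make_decoys <- function(conformer, config) {
  seq3 <- conformer$resname[!duplicated(conformer$resno)]
  with_seed(config$seed * 7L + 4L, {
    out <- lapply(config$coordinate_noise_levels, function(lv) {
      dc <- perturb_torsions(conformer, lv)
      list(conformer = dc, level = lv,
           rmsd = backbone_rmsd(dc, conformer))
    })
    chain_cf <- free_chain_conformer(seq3, chain = conformer$chain[1],
                                     start = min(conformer$resno))
    out[[length(out) + 1L]] <- list(conformer = chain_cf, level = Inf,
                                    rmsd = backbone_rmsd(chain_cf, conformer))
    out
  })
}

# measure backbone and chi torsions of a conformer (assumes one chain,
# contiguous numbering, ideal-topology atom names)
measure_torsions <- function(cf) {
  resnos <- sort(unique(cf$resno))
  n <- length(resnos)
  key <- split(seq_len(nrow(cf)), cf$resno)
  pos <- function(rn, a) {
    ii <- key[[as.character(rn)]]
    i <- ii[cf$atom[ii] == a]
    if (length(i) == 0L) return(NULL)
    c(cf$x[i[1]], cf$y[i[1]], cf$z[i[1]])
  }
  phi <- rep(-57, n); psi <- rep(-47, n)
  chi <- vector("list", n)
  seq3 <- cf$resname[!duplicated(cf$resno)]
  for (k in seq_len(n)) {
    rn <- resnos[k]
    if (k > 1L)
      phi[k] <- dihedral_angle(pos(rn - 1L, "C"), pos(rn, "N"),
                               pos(rn, "CA"), pos(rn, "C"))
    if (k < n)
      psi[k] <- dihedral_angle(pos(rn, "N"), pos(rn, "CA"),
                               pos(rn, "C"), pos(rn + 1L, "N"))
    z <- residue_topology(seq3[k])$zmat
    xi <- rep(-60, 4)
    if (!is.null(z)) {
      for (r in seq_len(nrow(z))) {
        m <- regmatches(z$dih[r], regexec("^x([0-9])$", z$dih[r]))[[1]]
        if (length(m) == 2L) {
          p4 <- lapply(c(z$aref[r], z$bref[r], z$parent[r], z$name[r]),
                       function(a) pos(rn, a))
          if (!any(vapply(p4, is.null, TRUE)))
            xi[as.integer(m[2])] <- dihedral_angle(p4[[1]], p4[[2]],
                                                   p4[[3]], p4[[4]])
        }
      }
    }
    chi[[k]] <- xi
  }
  list(phi = phi, psi = psi, chi = chi, seq3 = seq3,
       chain = cf$chain[1], start = resnos[1])
}

#' Build a jittered ensemble around the true structure
#'
#' n independent torsion-space decoys at one accuracy level, mimicking an
#' NMR-style conformer bundle.  Used by the ensemble-uplift benchmark.
#'
#' @param conformer the true structure.
#' @param config a \code{\link{synth_config}} (seed stream).
#' @param n number of conformers.
#' @param level target backbone RMSD (A) of each conformer.
#' @return an \code{nmr_ensemble}.
#' @export
make_jittered_ensemble <- function(conformer, config, n = 10L, level = 1.0) {
  with_seed(config$seed * 7L + 5L, {
    new_ensemble(lapply(seq_len(n), function(k)
      perturb_torsions(conformer, level)))
  })
}

# Torsion-noise decoy rescaled to a target backbone RMSD.  The torsion
# rebuild has no steric term, so a draw can thread the chain through itself;
# since real models at moderate RMSD do not interpenetrate, draws whose
# non-covalent heavy atoms approach closer than 1.5 A are redrawn (up to 12
# tries; the least-clashing draw is kept otherwise).
perturb_torsions <- function(cf, level, min_clash = 1.5, max_tries = 12L) {
  if (level == 0) return(cf)
  tor <- measure_torsions(cf)
  n <- length(tor$phi)
  best <- NULL; best_min <- -Inf
  # lever-arm compensation: a torsion at residue i rotates every residue
  # beyond i, so iid noise concentrates global error into mid-chain hinge
  # modes.  Down-weighting by the downstream segment size distributes the
  # deformation along the chain, as in real moderately inaccurate models.
  lever <- 1 / sqrt(pmax(1L, n - seq_len(n) + 1L))
  lever <- lever / sqrt(mean(lever^2))
  for (try in seq_len(max_tries)) {
    ephi <- stats::rnorm(n) * lever; epsi <- stats::rnorm(n) * lever
    echi <- matrix(stats::rnorm(n * 4), n, 4)
    scale <- level * 1.5  # deg torsion sd per A target RMSD, refined below
    dc <- NULL
    for (it in 1:4) {
      chi <- lapply(seq_len(n), function(i) tor$chi[[i]] + scale * 3 * echi[i, ])
      dc <- build_conformer(tor$seq3, tor$phi + scale * ephi,
                            tor$psi + scale * epsi, chi,
                            chain = tor$chain, start = tor$start,
                            hydrogens = FALSE)
      r <- backbone_rmsd(dc, cf)
      if (abs(r - level) < 0.02 * level) break
      scale <- scale * level / r
    }
    hv <- dc[dc$elem != "H", , drop = FALSE]
    D <- as.matrix(stats::dist(coords(hv)))
    D[noncov_mask(hv)] <- Inf
    m <- min(D)
    if (m > best_min) { best_min <- m; best <- dc }
    if (m >= min_clash) break
  }
  add_hydrogens(best)
}

#' Backbone (N, CA, C) RMSD after optimal superposition
#' @param model,ref conformers sharing residue numbering.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(model, ref) {
  bbsel <- function(cf) {
    s <- cf[cf$atom %in% c("N", "CA", "C"), , drop = FALSE]
    s[order(s$chain, s$resno, match(s$atom, c("N", "CA", "C"))), , drop = FALSE]
  }
  A <- bbsel(model); B <- bbsel(ref)
  key <- intersect(atom_key(A$chain, A$resno, A$atom),
                   atom_key(B$chain, B$resno, B$atom))
  A <- A[match(key, atom_key(A$chain, A$resno, A$atom)), ]
  B <- B[match(key, atom_key(B$chain, B$resno, B$atom)), ]
  fit_rmsd(coords(A), coords(B))
}

#' Forward-calculate synthetic RDCs
#'
#' @param conformer the true structure (protonated).
#' @param da,rh,rotation alignment tensor: axial component (Hz, N-HN
#'   frame), rhombicity, and orientation (3x3 rotation).
#' @param noise s.d. of additive Gaussian noise (Hz).
#' @param seed RNG seed.
#' @param type coupling type: "NH" (backbone amides), "CAHA" or "CAC".
#' @return an \code{rdc_table}.
#' @export
make_rdcs <- function(conformer, da = 12, rh = 0.3, rotation = diag(3),
                      noise = 0, seed = 1L, type = c("NH", "CAHA", "CAC")) {
  type <- match.arg(type)
  S <- tensor_from_da_rh(da, rh, rotation)
  ab <- switch(type, NH = c("N", "H"), CAHA = c("CA", "HA"),
               CAC = c("CA", "C"))
  tab <- rdc_type_scale_table()
  scale <- tab$scale[tab$type == type]
  res <- unique(conformer[, c("chain", "resno", "resname")])
  keys <- atom_key(conformer$chain, conformer$resno, conformer$atom)
  ok <- !is.na(match(atom_key(res$chain, res$resno, ab[1]), keys)) &
    !is.na(match(atom_key(res$chain, res$resno, ab[2]), keys))
  res <- res[ok, , drop = FALSE]
  rd <- data.frame(chain_a = res$chain, resno_a = res$resno,
                   resname_a = res$resname, atom_a = ab[1],
                   chain_b = res$chain, resno_b = res$resno,
                   resname_b = res$resname, atom_b = ab[2],
                   d_obs = 0, weight = 1, stringsAsFactors = FALSE)
  u <- rdc_vectors(conformer, rd)
  d <- scale * rowSums((u %*% S) * u)
  if (noise > 0) d <- d + with_seed(seed, stats::rnorm(length(d), 0, noise))
  rd$d_obs <- d
  new_rdc_table(rd)
}
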