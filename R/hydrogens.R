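# Ideal-geometry hydrogen builder.  Protons are placed from the heavy-atom
# frame with ideal bond lengths and angles; methyl, ammonium and hydroxyl
# rotors are set to the staggered (anti) conformation.  No energy terms, no
# flip-state optimization: models with distorted heavy-atom geometry get
# protons skipped with a named warning rather than a hard failure.

H_BOND <- c(C = 1.09, Csp2 = 1.08, N = 1.01, O = 0.96, S = 1.34)
HCH_HALF_ANGLE <- 53.9   # half of the ideal H-C-H methylene angle

#' Add missing hydrogens to a conformer at ideal covalent geometry
#'
#' Existing protons are preserved untouched.  Residues with missing heavy
#' atoms have their dependent protons skipped (warning class
#' \code{rpfdp_warning_missing_heavy}); degenerate frames (collinear heavy
#' atoms) skip the affected proton with a warning of class
#' \code{rpfdp_warning_collinear}.
#'
#' @param conformer an \code{nmr_conformer} (or ensemble, protonated
#'   per conformer).
#' @return the conformer (or ensemble) with a full proton set.
#' @export
add_hydrogens <- function(conformer) {
  if (inherits(conformer, "nmr_ensemble"))
    return(new_ensemble(lapply(conformer, add_hydrogens)))
  cf <- conformer
  check_resname(cf$resname)
  xyz <- coords(cf)
  rkey <- paste(cf$chain, cf$resno)
  groups <- split(seq_len(nrow(cf)), rkey)
  res <- cf[!duplicated(rkey), c("chain", "resno", "resname"), drop = FALSE]
  res$key <- rkey[!duplicated(rkey)]
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  # per-residue named position lists (fast local lookup)
  poslist <- lapply(groups, function(ii)
    setNames(lapply(ii, function(i) xyz[i, ]), cf$atom[ii]))
  new_rows <- list()
  miss_heavy <- character(0)
  collinear <- character(0)

  for (r in seq_len(nrow(res))) {
    ch <- res$chain[r]; rn <- res$resno[r]; rt <- res$resname[r]
    topo <- residue_topology(rt)
    nb <- heavy_neighbors(topo)
    rpos <- poslist[[res$key[r]]]
    getpos <- function(chain, resno, atom) {
      if (resno == rn) return(rpos[[atom]])
      poslist[[paste(chain, resno)]][[atom]]
    }
    prev_c <- poslist[[paste(ch, rn - 1L)]][["C"]]
    parents <- unique(topo$protons$parent)
    for (par in parents) {
      pnames <- topo$protons$name[topo$protons$parent == par]
      if (all(pnames %in% names(rpos))) next  # fully protonated
      P <- rpos[[par]]
      if (is.null(P)) {
        miss_heavy <- c(miss_heavy, sprintf("%s.%d.%s", ch, rn, par))
        next
      }
      nbs <- nb[[par]]
      nb_pos <- rpos[nbs[nbs %in% names(rpos)]]
      nb_names <- names(nb_pos)
      # inter-residue neighbor: preceding carbonyl C bonded to this N
      nterm <- FALSE
      if (par == "N") {
        if (!is.null(prev_c)) {
          nb_pos <- c(nb_pos, list(prev_c))
          nb_names <- c(nb_names, "C-1")
        } else nterm <- TRUE
      }
      if (length(nb_pos) == 0L) {
        miss_heavy <- c(miss_heavy, sprintf("%s.%d.%s", ch, rn, par))
        next
      }
      elem <- atom_element(par)
      sp2 <- par %in% topo$sp2 && !nterm
      nH <- length(pnames)
      bond <- if (elem == "C" && sp2) H_BOND[["Csp2"]] else H_BOND[[elem]]
      placed <- place_protons(P, par, nb_pos, nb_names, elem, sp2, nH, bond,
                              nb, ch, rn, getpos, nterm)
      if (is.null(placed)) {
        collinear <- c(collinear, sprintf("%s.%d.%s", ch, rn, par))
        next
      }
      for (k in seq_len(nH)) {
        hname <- pnames[k]
        if (hname %in% names(rpos)) next  # keep existing
        if (k > nrow(placed)) next
        new_rows[[length(new_rows) + 1L]] <-
          list(chain = ch, resno = rn, resname = rt, atom = hname,
               x = placed[k, 1], y = placed[k, 2], z = placed[k, 3])
      }
    }
  }

  if (length(miss_heavy) > 0L)
    named_warning(sprintf("missing heavy atoms; dependent protons skipped: %s",
                          paste(unique(miss_heavy), collapse = ", ")),
                  "rpfdp_warning_missing_heavy")
  if (length(collinear) > 0L)
    named_warning(sprintf("degenerate (collinear) frame; proton(s) skipped at: %s",
                          paste(unique(collinear), collapse = ", ")),
                  "rpfdp_warning_collinear")
  if (length(new_rows) == 0L) return(cf)
  gv <- function(f, mode) vapply(new_rows, `[[`, vector(mode, 1L), f)
  add <- data.frame(chain = gv("chain", "character"),
                    resno = gv("resno", "integer"),
                    resname = gv("resname", "character"),
                    atom = gv("atom", "character"), elem = "H",
                    x = gv("x", "numeric"), y = gv("y", "numeric"),
                    z = gv("z", "numeric"), stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(cf), add)
  ord <- order(out$chain, out$resno)
  new_conformer(out[ord, , drop = FALSE])
}

# Returns an nH x 3 matrix of proton positions, or NULL on a degenerate frame.
place_protons <- function(P, par, nb_pos, nb_names, elem, sp2, nH, bond,
                          nb, ch, rn, getpos, nterm) {
  units <- lapply(nb_pos, function(q) unit(q - P))
  if (any(vapply(units, is.null, TRUE))) return(NULL)

  # reference atom two bonds out, for torsion placement (rotors, NH2, OH)
  frame_ref <- function(prefer_o = FALSE) {
    B_name <- nb_names[1]
    B <- nb_pos[[1]]
    cands <- if (B_name == "C-1") character(0) else setdiff(nb[[B_name]], par)
    cands <- cands[vapply(cands, function(a) {
      q <- getpos(ch, rn, a)
      !is.null(q) && vnorm(q - P) > 1e-6
    }, TRUE)]
    A_name <- NULL
    if (prefer_o && any(startsWith(cands, "O"))) {
      A_name <- cands[startsWith(cands, "O")][1]
    } else if (length(cands) > 0L) A_name <- cands[1]
    if (is.null(A_name)) return(NULL)
    list(A = getpos(ch, rn, A_name), B = B)
  }

  if (nterm && nH == 1L) {
    # single representative amine proton: anti to the carbonyl
    CA <- getpos(ch, rn, "CA"); C <- getpos(ch, rn, "C")
    if (is.null(CA) || is.null(C)) return(NULL)
    H <- place_internal(C, CA, P, bond, 109.5, 180)
    return(if (is.null(H)) NULL else matrix(H, 1, 3))
  }

  if (nH == 1L && length(units) >= 3L) {            # sp3 CH (CA, CB of Val...)
    d <- -(units[[1]] + units[[2]] + units[[3]])
    d <- unit(d)
    if (is.null(d)) return(NULL)
    return(matrix(P + bond * d, 1, 3))
  }
  if (nH == 1L && length(units) == 2L) {            # sp2 / ring CH, amide NH
    d <- unit(-(units[[1]] + units[[2]]))
    if (is.null(d)) return(NULL)
    return(matrix(P + bond * d, 1, 3))
  }
  if (nH == 2L && length(units) == 2L && !sp2) {    # methylene
    b <- unit(-(units[[1]] + units[[2]]))
    n <- unit(vcross(units[[1]], units[[2]]))
    if (is.null(b) || is.null(n)) return(NULL)
    a <- HCH_HALF_ANGLE * pi / 180
    H1 <- P + bond * (cos(a) * b + sin(a) * n)
    H2 <- P + bond * (cos(a) * b - sin(a) * n)
    return(rbind(H1, H2))
  }
  if (nH == 2L && length(units) == 1L && sp2) {     # planar NH2
    fr <- frame_ref(prefer_o = TRUE)
    if (is.null(fr)) return(NULL)
    H1 <- place_internal(fr$A, fr$B, P, bond, 120, 180)
    H2 <- place_internal(fr$A, fr$B, P, bond, 120, 0)
    if (is.null(H1) || is.null(H2)) return(NULL)
    return(rbind(H1, H2))
  }
  if (nH == 3L && length(units) == 1L) {            # methyl / ammonium rotor
    fr <- frame_ref()
    if (is.null(fr)) return(NULL)
    H <- lapply(c(180, 300, 60), function(dh)
      place_internal(fr$A, fr$B, P, bond, 109.47, dh))
    if (any(vapply(H, is.null, TRUE))) return(NULL)
    return(do.call(rbind, H))
  }
  if (nH == 1L && length(units) == 1L) {            # hydroxyl / sulfhydryl
    fr <- frame_ref()
    if (is.null(fr)) return(NULL)
    ang <- if (elem == "S") 96 else 108.5
    H <- place_internal(fr$A, fr$B, P, bond, ang, 180)
    return(if (is.null(H)) NULL else matrix(H, 1, 3))
  }
  NULL
}
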