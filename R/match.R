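# Ambiguous NOE graph: every shift-compatible site-pair assignment for every
# NOESY cross peak, under the chemical-shift match tolerances.

#' Chemical-shift match tolerances
#'
#' @param tol_h 1H tolerance (ppm).
#' @param tol_c 13C tolerance (ppm), for C-edited dimensions.
#' @param tol_n 15N tolerance (ppm), for N-edited dimensions.
#' @return a \code{match_tolerance} list.
#' @export
match_tolerance <- function(tol_h = 0.03, tol_c = 0.4, tol_n = 0.4) {
  if (any(c(tol_h, tol_c, tol_n) < 0))
    data_error("tolerances must be non-negative")
  structure(list(tol_h = tol_h, tol_c = tol_c, tol_n = tol_n),
            class = "match_tolerance")
}

# heavy-atom shifts attached to each site: list of numeric vectors, plus the
# element of the attached heavy atom(s)
site_heavy_shifts <- function(sites, shifts) {
  skey <- atom_key(shifts$chain, shifts$resno, shifts$atom)
  lapply(seq_len(n_sites(sites)), function(k) {
    t <- sites$table[k, ]
    idx <- match(atom_key(t$chain, t$resno, sites$heavy[[k]]), skey)
    shifts$shift[idx[!is.na(idx)]]
  })
}

#' Match NOESY peaks to candidate proton-pair assignments
#'
#' A candidate pair (a, b) is retained for a peak when both 1H positions
#' fall within \code{tol_h} of the site shifts and, for an edited spectrum,
#' the shift of the heavy atom covalently attached to the
#' acquisition-dimension proton matches within \code{tol_c} / \code{tol_n}.
#' Symmetric duplicates are collapsed and self pairs excluded.  Peaks whose
#' two 1H positions coincide within \code{tol_h} are dropped as diagonal
#' artifacts and reported separately.
#'
#' @param peaks a \code{peak_list}.
#' @param shifts a \code{shift_table} (also supplies heavy-atom shifts for
#'   edited dimensions).
#' @param sites a \code{proton_sites} object built from the same shifts.
#' @param tol a \code{\link{match_tolerance}}.
#' @return an \code{ambiguous_noe_graph}: per-peak candidate site-pair
#'   matrices, plus \code{unmatched_peaks} and \code{diagonal_peaks} id
#'   vectors.
#' @export
match_peaks <- function(peaks, shifts, sites, tol = match_tolerance()) {
  if (nrow(shifts) == 0L) data_error("empty shift table")
  hd <- which(peaks$dim_types %in% c("H_acq", "H_indirect"))
  if (length(hd) != 2L) data_error("peak list must have two 1H dimensions")
  acq <- which(peaks$dim_types == "H_acq")
  ind <- setdiff(hd, acq)
  if (length(acq) == 0L) { acq <- hd[2]; ind <- hd[1] }
  ed <- which(peaks$dim_types %in% c("C_edit", "N_edit"))

  ns <- n_sites(sites)
  # flattened member-shift lookup: value -> site
  sv <- unlist(sites$member_shift)
  si <- rep(seq_len(ns), lengths(sites$member_shift))
  hv <- site_heavy_shifts(sites, shifts)
  helem <- vapply(sites$heavy, function(h) substring(h[1], 1, 1), "")

  npk <- n_peaks(peaks)
  cands <- vector("list", npk)
  unmatched <- integer(0)
  diagonal <- integer(0)
  for (p in seq_len(npk)) {
    pos <- peaks$positions[p, ]
    if (abs(pos[ind] - pos[acq]) < tol$tol_h) {
      diagonal <- c(diagonal, peaks$peak_id[p])
      next
    }
    m_ind <- unique(si[abs(sv - pos[ind]) <= tol$tol_h])
    m_acq <- unique(si[abs(sv - pos[acq]) <= tol$tol_h])
    if (length(ed) == 1L) {
      ety <- peaks$dim_types[ed]
      etol <- if (ety == "C_edit") tol$tol_c else tol$tol_n
      eelem <- if (ety == "C_edit") "C" else "N"
      ok <- vapply(m_acq, function(s) {
        helem[s] == eelem && length(hv[[s]]) > 0L &&
          min(abs(hv[[s]] - pos[ed])) <= etol
      }, TRUE)
      m_acq <- m_acq[ok]
    }
    if (length(m_ind) == 0L || length(m_acq) == 0L) {
      unmatched <- c(unmatched, peaks$peak_id[p])
      next
    }
    pr <- expand.grid(a = m_ind, b = m_acq)
    pr <- pr[pr$a != pr$b, , drop = FALSE]
    if (nrow(pr) == 0L) {
      unmatched <- c(unmatched, peaks$peak_id[p])
      next
    }
    ij <- cbind(pmin(pr$a, pr$b), pmax(pr$a, pr$b))
    ij <- ij[!duplicated(ij), , drop = FALSE]
    cands[[p]] <- ij
  }
  matched <- which(!vapply(cands, is.null, TRUE))
  structure(list(candidates = cands[matched],
                 peak_id = peaks$peak_id[matched],
                 unmatched_peaks = unmatched,
                 diagonal_peaks = diagonal,
                 sites = sites, tol = tol),
            class = "ambiguous_noe_graph")
}

#' @export
print.ambiguous_noe_graph <- function(x, ...) {
  cat(sprintf(paste0("<ambiguous NOE graph: %d matched peaks ",
                     "(%d unmatched, %d diagonal), %d sites>\n"),
              length(x$peak_id), length(x$unmatched_peaks),
              length(x$diagonal_peaks), n_sites(x$sites)))
  invisible(x)
}

# union of all candidate pairs as an n x n logical matrix (symmetric)
candidate_union <- function(anoe, ns = n_sites(anoe$sites)) {
  U <- matrix(FALSE, ns, ns)
  for (ij in anoe$candidates) {
    U[ij] <- TRUE
    U[ij[, c(2, 1), drop = FALSE]] <- TRUE
  }
  U
}
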