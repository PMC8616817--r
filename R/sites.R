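# Proton sites: the nodes shared by the model-side distance graph and the
# data-side ambiguous NOE graph.  Degenerate protons are grouped into
# pseudoatom sites: methyls (3), prochiral methylenes / sidechain NH2 without
# stereospecific assignment (2), symmetric Phe/Tyr ring positions (2), and
# Leu/Val isopropyl pairs with a single shared assignment (6).

new_proton_sites <- function(table, members, member_shift, heavy, unmapped = NULL) {
  structure(list(table = table, members = members,
                 member_shift = member_shift, heavy = heavy,
                 unmapped = unmapped %||% character(0)),
            class = "proton_sites")
}

n_sites <- function(sites) nrow(sites$table)

#' @export
print.proton_sites <- function(x, ...) {
  cat(sprintf("<proton sites: %d sites over %d residues (%d pseudoatom groups)>\n",
              n_sites(x), length(unique(paste(x$table$chain, x$table$resno))),
              sum(x$table$n_members > 1L)))
  invisible(x)
}

# pseudoatom representative name from a parent heavy atom: CB -> QB, CD1 -> QD1
pseudo_name <- function(parent) paste0("Q", substring(parent, 2))

#' Group assigned protons into pseudoatom sites
#'
#' Builds the proton-site collection from a shift table alone (topology-based
#' grouping; no coordinates needed).  Grouping rules: methyl protons always
#' form one site; prochiral methylene and sidechain NH2 pairs merge when
#' their shifts coincide or both carry NMR-STAR ambiguity code 2; symmetric
#' Phe/Tyr ring positions (HD1/HD2, HE1/HE2) merge under the same condition;
#' Leu/Val isopropyl methyl pairs sharing one shift (or flagged ambiguity 2)
#' merge into a single six-proton site.
#'
#' @param shifts a \code{shift_table}.
#' @return a \code{proton_sites} object.
#' @export
sites_from_shifts <- function(shifts) {
  hrows <- shifts[grepl("^H", shifts$atom), , drop = FALSE]
  res <- unique(hrows[, c("chain", "resno", "resname")])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  tab <- list(); members <- list(); mshift <- list(); heavy <- list()
  dead <- integer(0)

  add_site <- function(ch, rn, rt, rep, mem, sh, par) {
    k <- length(members) + 1L
    tab[[k]] <<- data.frame(chain = ch, resno = rn, resname = rt, rep = rep,
                            n_members = length(mem), stringsAsFactors = FALSE)
    members[[k]] <<- mem
    mshift[[k]] <<- unique(sh)
    heavy[[k]] <<- unique(par)
  }

  for (r in seq_len(nrow(res))) {
    ch <- res$chain[r]; rn <- res$resno[r]; rt <- res$resname[r]
    topo <- residue_topology(rt)
    rows <- hrows[hrows$chain == ch & hrows$resno == rn, , drop = FALSE]
    rows <- rows[rows$atom %in% topo$protons$name, , drop = FALSE]
    if (nrow(rows) == 0L) next
    parent <- topo$protons$parent[match(rows$atom, topo$protons$name)]
    done <- rep(FALSE, nrow(rows))
    methyl_sites <- list()  # parent -> site index (for isopropyl merge)

    for (par in unique(parent)) {
      sel <- which(parent == par)
      n_topo <- sum(topo$protons$parent == par)
      if (n_topo == 3L) {                       # methyl / ammonium
        add_site(ch, rn, rt, pseudo_name(par), rows$atom[sel],
                 rows$shift[sel], par)
        methyl_sites[[par]] <- length(members)
        done[sel] <- TRUE
      } else if (n_topo == 2L && length(sel) == 2L) {   # prochiral pair
        same <- isTRUE(all.equal(rows$shift[sel][1], rows$shift[sel][2])) ||
          all(rows$ambiguity[sel] == 2L)
        if (same) {
          add_site(ch, rn, rt, pseudo_name(par), rows$atom[sel],
                   rows$shift[sel], par)
          done[sel] <- TRUE
        }
      }
    }

    # symmetric aromatic ring pairs of Phe/Tyr (different parents)
    if (rt %in% c("PHE", "TYR")) {
      for (pr in list(c("HD1", "HD2"), c("HE1", "HE2"))) {
        sel <- which(rows$atom %in% pr & !done)
        if (length(sel) == 2L) {
          same <- isTRUE(all.equal(rows$shift[sel][1], rows$shift[sel][2])) ||
            all(rows$ambiguity[sel] == 2L)
          if (same) {
            add_site(ch, rn, rt, paste0("Q", substring(pr[1], 2, 2)),
                     rows$atom[sel], rows$shift[sel], parent[sel])
            done[sel] <- TRUE
          }
        }
      }
    }

    # Leu/Val isopropyl merge of the two methyl sites
    iso <- switch(rt, LEU = c("CD1", "CD2"), VAL = c("CG1", "CG2"), NULL)
    if (!is.null(iso) && all(iso %in% names(methyl_sites))) {
      i1 <- methyl_sites[[iso[1]]]; i2 <- methyl_sites[[iso[2]]]
      amb <- rows$ambiguity[parent %in% iso]
      same <- isTRUE(all.equal(mshift[[i1]], mshift[[i2]])) || all(amb == 2L)
      if (same) {
        tab[[i1]]$rep <- paste0("QQ", substring(iso[1], 2, 2))
        tab[[i1]]$n_members <- 6L
        members[[i1]] <- c(members[[i1]], members[[i2]])
        mshift[[i1]] <- unique(c(mshift[[i1]], mshift[[i2]]))
        heavy[[i1]] <- unique(c(heavy[[i1]], heavy[[i2]]))
        dead <- c(dead, i2)
      }
    }

    # everything left: singletons
    for (k in which(!done)) {
      add_site(ch, rn, rt, rows$atom[k], rows$atom[k], rows$shift[k],
               parent[k])
    }
  }

  keep <- !(seq_along(tab) %in% dead)
  tab <- tab[keep]; members <- members[keep]
  mshift <- mshift[keep]; heavy <- heavy[keep]
  table <- do.call(rbind, tab)
  table$site_id <- seq_len(nrow(table))
  table <- table[, c("site_id", "chain", "resno", "resname", "rep", "n_members")]
  new_proton_sites(table, members, mshift, heavy)
}

#' Build proton sites for a conformer from its shift assignments
#'
#' Wraps \code{\link{sites_from_shifts}} and cross-checks the model: shift
#' table protons absent from the (protonated) conformer are recorded as
#' unmapped assignments (dropped from their site, never fatal).
#'
#' @param conformer a protonated \code{nmr_conformer} (or ensemble; the first
#'   conformer defines the atom set).
#' @param shifts a \code{shift_table}.
#' @return a \code{proton_sites} object whose \code{unmapped} field lists
#'   assignment keys with no counterpart in the model.
#' @export
build_proton_sites <- function(conformer, shifts) {
  cf <- if (inherits(conformer, "nmr_ensemble")) conformer[[1]] else conformer
  sites <- sites_from_shifts(shifts)
  have <- atom_key(cf$chain, cf$resno, cf$atom)
  unmapped <- character(0)
  keep <- logical(n_sites(sites))
  for (k in seq_len(n_sites(sites))) {
    t <- sites$table[k, ]
    keys <- atom_key(t$chain, t$resno, sites$members[[k]])
    ok <- keys %in% have
    unmapped <- c(unmapped, keys[!ok])
    if (any(!ok)) sites$members[[k]] <- sites$members[[k]][ok]
    keep[k] <- any(ok)
  }
  sites$table <- sites$table[keep, , drop = FALSE]
  sites$members <- sites$members[keep]
  sites$member_shift <- sites$member_shift[keep]
  sites$heavy <- sites$heavy[keep]
  sites$table$site_id <- seq_len(nrow(sites$table))
  rownames(sites$table) <- NULL
  sites$unmapped <- unmapped
  sites
}

# n_protons x n_sites membership indicator and the matching proton rows of a
# conformer; site order follows sites$table.
site_membership <- function(sites, cf) {
  keys <- atom_key(cf$chain, cf$resno, cf$atom)
  rows <- integer(0); col <- integer(0)
  for (k in seq_len(n_sites(sites))) {
    t <- sites$table[k, ]
    idx <- match(atom_key(t$chain, t$resno, sites$members[[k]]), keys)
    idx <- idx[!is.na(idx)]
    rows <- c(rows, idx)
    col <- c(col, rep(k, length(idx)))
  }
  A <- matrix(0, nrow(cf), n_sites(sites))
  A[cbind(rows, col)] <- 1
  A
}
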