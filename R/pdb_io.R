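# PDB coordinate I/O.  A conformer is a data.frame (class "nmr_conformer")
# with columns chain, resno, resname, atom, elem, x, y, z; an ensemble is a
# list of conformers (class "nmr_ensemble").  Author residue numbering is kept
# as-is.  No suitable coordinate reader ships with the supported R stack, so
# the fixed-column ATOM/MODEL subset of the format is parsed here directly.

new_conformer <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("nmr_conformer", "data.frame")
  df
}

new_ensemble <- function(confs) {
  structure(confs, class = "nmr_ensemble")
}

as_ensemble <- function(x) {
  if (inherits(x, "nmr_ensemble")) return(x)
  if (inherits(x, "nmr_conformer")) return(new_ensemble(list(x)))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "nmr_conformer")))
    return(new_ensemble(x))
  data_error("expected a conformer or an ensemble of conformers")
}

#' Read protein coordinates from a PDB file
#'
#' Parses ATOM records (protein residues only), honouring MODEL/ENDMDL
#' blocks.  Hydrogens are retained when present.  Alternate locations are
#' resolved to the highest-occupancy copy (ties broken towards altloc "A").
#' PDB v2-style hydrogen names (e.g. "1HB", "2HB1") are normalized to the
#' IUPAC/BMRB convention used throughout the package.
#'
#' @param path path to a PDB file.
#' @param model_index optional 1-based index of a single MODEL to return.
#' @return an object of class \code{nmr_ensemble}: a list with one
#'   \code{nmr_conformer} data.frame per MODEL (a single-element list when the
#'   file has no MODEL records).  If the conformers of an ensemble do not
#'   share an identical atom set, a warning of class
#'   \code{rpfdp_warning_ensemble_mismatch} is raised.
#' @export
read_coordinates <- function(path, model_index = NULL) {
  if (!file.exists(path))
    data_error(sprintf("cannot read coordinate file: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  models <- list()
  cur <- integer(0)
  in_model <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      in_model <- TRUE
      cur <- integer(0)
    } else if (startsWith(r, "ENDMDL")) {
      models[[length(models) + 1L]] <- cur
      cur <- integer(0)
      in_model <- FALSE
    } else if (r == "ATOM  ") {
      cur <- c(cur, i)
    }
  }
  if (length(cur) > 0L || length(models) == 0L)
    models[[length(models) + 1L]] <- cur

  parse_block <- function(idx) {
    if (length(idx) == 0L) return(NULL)
    ln <- lines[idx]
    atom <- trimws(substring(ln, 13, 16))
    altloc <- substring(ln, 17, 17)
    resname <- trimws(substring(ln, 18, 20))
    chain <- trimws(substring(ln, 22, 22))
    chain[chain == ""] <- "A"
    resno <- as.integer(substring(ln, 23, 26))
    x <- as.numeric(substring(ln, 31, 38))
    y <- as.numeric(substring(ln, 39, 46))
    z <- as.numeric(substring(ln, 47, 54))
    occ <- suppressWarnings(as.numeric(substring(ln, 55, 60)))
    occ[is.na(occ)] <- 1
    keep <- resname %in% AA3
    if (!any(keep)) return(NULL)
    df <- data.frame(chain = chain[keep], resno = resno[keep],
                     resname = resname[keep], atom = atom[keep],
                     altloc = altloc[keep], occ = occ[keep],
                     x = x[keep], y = y[keep], z = z[keep],
                     stringsAsFactors = FALSE)
    df$atom <- normalize_h_names(df$atom, df$resname)
    # altloc: keep highest occupancy, tie -> lowest altloc code ("A" wins)
    key <- atom_key(df$chain, df$resno, df$atom)
    if (anyDuplicated(key)) {
      ord <- order(key, -df$occ, df$altloc)
      df <- df[ord, , drop = FALSE]
      df <- df[!duplicated(atom_key(df$chain, df$resno, df$atom)), , drop = FALSE]
      df <- df[order(match(atom_key(df$chain, df$resno, df$atom), unique(key))), ,
               drop = FALSE]
    }
    df$elem <- atom_element(df$atom)
    new_conformer(df[, c("chain", "resno", "resname", "atom", "elem",
                         "x", "y", "z")])
  }

  confs <- Filter(Negate(is.null), lapply(models, parse_block))
  if (length(confs) == 0L)
    data_error(sprintf("no protein atoms found in %s", path))
  if (!is.null(model_index)) {
    if (model_index < 1L || model_index > length(confs))
      data_error(sprintf("model_index %d absent: file has %d model(s)",
                         model_index, length(confs)))
    confs <- confs[model_index]
  }
  if (length(confs) > 1L) {
    keys <- lapply(confs, function(cf) sort(atom_key(cf$chain, cf$resno, cf$atom)))
    if (!all(vapply(keys[-1], identical, TRUE, keys[[1]])))
      named_warning("conformers in ensemble do not share an identical atom set",
                    "rpfdp_warning_ensemble_mismatch")
  }
  new_ensemble(confs)
}

#' Write one or more conformers to a PDB file
#'
#' Ensembles are written as MODEL/ENDMDL blocks.
#'
#' @param x a conformer or ensemble.
#' @param path output file path.
#' @export
write_pdb <- function(x, path) {
  ens <- as_ensemble(x)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(ens) > 1L
  for (m in seq_along(ens)) {
    cf <- ens[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    nm <- cf$atom
    # PDB column 13 is reserved for 2-char element symbols; left-pad
    # 1-3 char names by one space, except 4-char hydrogens.
    pad <- ifelse(nchar(nm) >= 4, nm, sprintf(" %-3s", nm))
    lines <- sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(cf)), pad, " ", cf$resname, cf$chain, cf$resno, " ",
      cf$x, cf$y, cf$z, 1, 0, cf$elem)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Translate PDB v2 / v3 hydrogen-name variants to IUPAC/BMRB names.
# Handles rotated digits ("1HB" -> "HB1", "2HG1" -> "HG12") and the
# methylene offset (old HB1/HB2 -> HB2/HB3 where the residue topology has
# no HB1), plus 2HA/1HA of glycine.
normalize_h_names <- function(atom, resname) {
  out <- atom
  rot <- grepl("^[0-9]H", atom)
  out[rot] <- paste0(substring(atom[rot], 2), substring(atom[rot], 1, 1))
  for (rn in unique(resname)) {
    if (!(rn %in% AA3)) next
    topo <- residue_topology(rn)
    valid <- c(topo$heavy, topo$protons$name, "OXT", "H1", "H2", "H3")
    sel <- which(resname == rn)
    bad <- sel[!(out[sel] %in% valid) & grepl("^H", out[sel])]
    for (i in bad) {
      # old-style methylene numbering is one lower than IUPAC
      m <- regmatches(out[i], regexec("^(H[A-Z]+[0-9]?)([0-9])$", out[i]))[[1]]
      if (length(m) == 3L) {
        cand <- paste0(m[2], as.integer(m[3]) + 1L)
        if (cand %in% topo$protons$name) out[i] <- cand
      } else if (out[i] == "HA1" && rn == "GLY") {
        out[i] <- "HA2"
      }
    }
  }
  out
}

# xyz coordinate matrix of a conformer (n x 3)
coords <- function(cf) cbind(cf$x, cf$y, cf$z)

#' @export
print.nmr_conformer <- function(x, ...) {
  cat(sprintf("<conformer: %d atoms, %d residues, chain(s) %s>\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' @export
print.nmr_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble: %d conformer(s), %d atoms each>\n",
              length(x), nrow(x[[1]])))
  invisible(x)
}
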