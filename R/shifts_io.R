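# Chemical-shift assignment tables.  A shift table is a data.frame (class
# "shift_table") with columns chain, resno, resname, atom, shift, ambiguity.
# Two dialects are read: a simple TSV and the NMR-STAR v3 Atom_chem_shift
# loop (minimal reader: Comp_index_ID, Comp_ID, Atom_ID, Val, Ambiguity_code).

new_shift_table <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("shift_table", "data.frame")
  df
}

#' Read a chemical-shift assignment table
#'
#' @param path input file.
#' @param dialect "tsv" (columns chain, resno, resname, atom, shift,
#'   ambiguity) or "nmrstar" (v3 Atom_chem_shift loop).  Defaults to
#'   sniffing: files containing a \code{loop_} keyword are treated as
#'   NMR-STAR.
#' @return a \code{shift_table} data.frame.  Atom names are normalized to
#'   IUPAC/BMRB nomenclature; exact duplicate rows are collapsed; duplicate
#'   atoms with conflicting shifts raise an error of class
#'   \code{rpfdp_data_error}.
#' @export
read_shift_table <- function(path, dialect = c("auto", "tsv", "nmrstar")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    data_error(sprintf("cannot read shift table: %s", path))
  if (dialect == "auto") {
    head <- readLines(path, n = 50L, warn = FALSE)
    dialect <- if (any(grepl("^\\s*loop_", head))) "nmrstar" else "tsv"
  }
  df <- if (dialect == "tsv") read_shift_tsv(path) else read_shift_star(path)
  validate_shift_table(df)
}

read_shift_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chain", "resno", "resname", "atom", "shift")
  if (!all(need %in% names(df)))
    data_error(sprintf("shift TSV must have columns %s", paste(need, collapse = ", ")))
  if (is.null(df$ambiguity)) df$ambiguity <- 1L
  df[, c("chain", "resno", "resname", "atom", "shift", "ambiguity")]
}

# Minimal NMR-STAR v3 loop reader for the assigned chemical shift list.
read_shift_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (lines[i] == "loop_") {
      j <- i + 1L
      tags <- character(0)
      while (j <= n && startsWith(lines[j], "_")) {
        tags <- c(tags, lines[j])
        j <- j + 1L
      }
      if (any(grepl("Atom_chem_shift", tags))) {
        short <- sub("^_Atom_chem_shift\\.", "", tags)
        rows <- list()
        while (j <= n && lines[j] != "stop_" && lines[j] != "") {
          if (!startsWith(lines[j], "#")) {
            toks <- scan(text = lines[j], what = character(), quiet = TRUE)
            if (length(toks) == length(tags)) rows[[length(rows) + 1L]] <- toks
          }
          j <- j + 1L
        }
        if (length(rows) == 0L)
          data_error("empty Atom_chem_shift loop")
        m <- do.call(rbind, rows)
        colnames(m) <- short
        need <- c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val")
        if (!all(need %in% short))
          data_error("Atom_chem_shift loop lacks required tags")
        amb <- if ("Ambiguity_code" %in% short) {
          a <- suppressWarnings(as.integer(m[, "Ambiguity_code"]))
          ifelse(is.na(a), 1L, a)
        } else 1L
        chain <- if ("Entity_assembly_ID" %in% short) m[, "Entity_assembly_ID"] else "A"
        chain[chain %in% c(".", "?")] <- "A"
        return(data.frame(chain = chain,
                          resno = as.integer(m[, "Comp_index_ID"]),
                          resname = toupper(m[, "Comp_ID"]),
                          atom = m[, "Atom_ID"],
                          shift = as.numeric(m[, "Val"]),
                          ambiguity = amb,
                          stringsAsFactors = FALSE))
      }
      i <- j
    }
    i <- i + 1L
  }
  data_error("no Atom_chem_shift loop found in NMR-STAR file")
}

validate_shift_table <- function(df) {
  check_resname(df$resname)
  if (any(!is.finite(df$shift)))
    data_error("non-finite chemical shift value")
  df$atom <- normalize_h_names(df$atom, df$resname)
  # collapse exact duplicates, reject conflicting ones
  key <- atom_key(df$chain, df$resno, df$atom)
  if (anyDuplicated(key)) {
    dup <- split(seq_len(nrow(df)), key)
    keep <- integer(0)
    for (idx in dup) {
      if (length(unique(df$shift[idx])) > 1L)
        data_error(sprintf("conflicting duplicate shifts for %s",
                           key[idx[1]]))
      keep <- c(keep, idx[1])
    }
    df <- df[sort(keep), , drop = FALSE]
  }
  new_shift_table(df)
}

#' Write a shift table as TSV
#' @param shifts a \code{shift_table}.
#' @param path output path.
#' @export
write_shift_table <- function(shifts, path) {
  df <- as.data.frame(shifts)
  df$shift <- sprintf("%.17g", df$shift)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fast lookup environment: atom key -> row index
shift_index <- function(shifts) {
  key <- atom_key(shifts$chain, shifts$resno, shifts$atom)
  setNames(seq_along(key), key)
}
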