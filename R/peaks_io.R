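# NOESY peak lists.  A peak_list holds per-dimension ppm positions for each
# cross peak plus dimension typing (H_acq, H_indirect, C_edit, N_edit).
# Supported dialects: XEASY ".peaks", Sparky ".list" and an in-house TSV.

DIM_TYPES <- c("H_acq", "H_indirect", "C_edit", "N_edit")

new_peak_list <- function(peak_id, positions, dim_types, intensity = NULL,
                          label = "", dialect = "tsv") {
  positions <- as.matrix(positions)
  if (length(dim_types) != ncol(positions))
    data_error("dimension count mismatch with declared dimension types")
  if (!all(dim_types %in% DIM_TYPES))
    data_error(sprintf("dimension types must be drawn from {%s}",
                       paste(DIM_TYPES, collapse = ", ")))
  if (sum(dim_types %in% c("H_acq", "H_indirect")) != 2L)
    data_error("a NOESY peak list needs exactly two 1H dimensions")
  if (nrow(positions) > 0L && any(!is.finite(positions)))
    data_error("non-finite peak position")
  if (anyDuplicated(peak_id))
    data_error("peak ids must be unique within a list")
  if (is.null(intensity)) intensity <- rep(NA_real_, nrow(positions))
  structure(list(peak_id = as.integer(peak_id), positions = positions,
                 dim_types = dim_types, intensity = as.numeric(intensity),
                 label = label, dialect = dialect),
            class = "peak_list")
}

n_peaks <- function(pl) nrow(pl$positions)

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak list '%s': %d peaks, %dD (%s), dialect %s>\n",
              x$label, n_peaks(x), length(x$dim_types),
              paste(x$dim_types, collapse = "/"), x$dialect))
  invisible(x)
}

#' Read a NOESY peak list
#'
#' @param path input file.
#' @param dialect "xeasy", "sparky", "tsv" or "auto" (sniffed from the
#'   extension and first line).
#' @param dim_types character vector typing each dimension, drawn from
#'   \code{H_acq}, \code{H_indirect}, \code{C_edit}, \code{N_edit}.
#'   Mandatory for Sparky; for XEASY and TSV it overrides what the file
#'   header declares.  Exactly two dimensions must be 1H.
#' @return a \code{peak_list}.  Assignment columns present in XEASY or
#'   Sparky files are ignored; positions and intensities are kept.
#' @export
read_peaklist <- function(path, dialect = c("auto", "xeasy", "sparky", "tsv"),
                          dim_types = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    data_error(sprintf("cannot read peak list: %s", path))
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    first <- readLines(path, n = 1L, warn = FALSE)
    dialect <- if (ext == "peaks" || grepl("Number of dimensions", first)) {
      "xeasy"
    } else if (ext == "list" || grepl("Assignment", first)) {
      "sparky"
    } else "tsv"
  }
  switch(dialect,
         xeasy = read_peaks_xeasy(path, dim_types),
         sparky = read_peaks_sparky(path, dim_types),
         tsv = read_peaks_tsv(path, dim_types))
}

# Guess dimension types from axis names (XEASY INAME / TSV header): axes
# named C*/N* are heavy edited dimensions; of the 1H axes the last is taken
# as the acquisition dimension.
guess_dim_types <- function(axis_names) {
  first <- toupper(substring(trimws(axis_names), 1, 1))
  ty <- rep(NA_character_, length(first))
  ty[first == "C"] <- "C_edit"
  ty[first == "N"] <- "N_edit"
  hs <- which(first %in% c("H", "Q"))
  if (length(hs) != 2L)
    data_error("cannot infer dimension types; pass dim_types explicitly")
  ty[hs] <- c("H_indirect", "H_acq")
  ty
}

read_peaks_xeasy <- function(path, dim_types = NULL) {
  lines <- readLines(path, warn = FALSE)
  ndl <- grep("Number of dimensions", lines, value = TRUE)
  if (length(ndl) == 0L)
    data_error("XEASY peak file lacks a 'Number of dimensions' header")
  nd <- as.integer(sub(".*Number of dimensions\\s+", "", ndl[1]))
  inames <- lines[grepl("^#INAME", lines)]
  if (is.null(dim_types)) {
    if (length(inames) == nd) {
      axes <- vapply(strsplit(inames, "\\s+"), function(t) t[3], "")
      dim_types <- guess_dim_types(axes)
    } else {
      data_error("XEASY file lacks #INAME axis labels; pass dim_types")
    }
  }
  if (length(dim_types) != nd)
    data_error("dimension count mismatch with declared dimension types")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L)
    return(new_peak_list(integer(0), matrix(numeric(0), 0, nd), dim_types,
                         label = basename(path), dialect = "xeasy"))
  toks <- strsplit(trimws(body), "\\s+")
  id <- vapply(toks, function(t) as.integer(t[1]), 1L)
  pos <- t(vapply(toks, function(t) as.numeric(t[2:(1 + nd)]), numeric(nd)))
  if (nd == 1L) pos <- matrix(pos, ncol = 1L)
  vol <- vapply(toks, function(t) {
    v <- suppressWarnings(as.numeric(t[nd + 4L]))
    if (length(v) == 0L || is.na(v)) NA_real_ else v
  }, 1.0)
  new_peak_list(id, pos, dim_types, vol, label = basename(path),
                dialect = "xeasy")
}

read_peaks_sparky <- function(path, dim_types = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- grepl("Assignment", lines[1])
  nd <- if (header) {
    sum(grepl("^w[0-9]+$", strsplit(trimws(lines[1]), "\\s+")[[1]]))
  } else if (!is.null(dim_types)) {
    length(dim_types)
  } else {
    data_error("headerless Sparky list: pass dim_types")
  }
  if (is.null(dim_types))
    data_error("Sparky lists carry no axis typing; pass dim_types")
  if (length(dim_types) != nd)
    data_error("dimension count mismatch with declared dimension types")
  body <- lines[if (header) -1L else TRUE]
  if (length(body) == 0L)
    return(new_peak_list(integer(0), matrix(numeric(0), 0, nd), dim_types,
                         label = basename(path), dialect = "sparky"))
  toks <- strsplit(trimws(body), "\\s+")
  pos <- t(vapply(toks, function(t) as.numeric(t[2:(1 + nd)]), numeric(nd)))
  if (nd == 1L) pos <- matrix(pos, ncol = 1L)
  height <- vapply(toks, function(t) {
    if (length(t) >= nd + 2L) suppressWarnings(as.numeric(t[nd + 2L])) else NA_real_
  }, 1.0)
  new_peak_list(seq_along(body), pos, dim_types, height,
                label = basename(path), dialect = "sparky")
}

read_peaks_tsv <- function(path, dim_types = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  file_types <- NULL
  if (startsWith(first, "# dim_types")) {
    file_types <- strsplit(trimws(sub("# dim_types", "", first)), "\\s+")[[1]]
  }
  dim_types <- dim_types %||% file_types
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  poscols <- grep("^pos_", names(df))
  if (is.null(dim_types))
    data_error("peak TSV lacks a '# dim_types' header; pass dim_types")
  if (length(poscols) != length(dim_types))
    data_error("dimension count mismatch with declared dimension types")
  inten <- if ("intensity" %in% names(df)) df$intensity else NULL
  new_peak_list(df$peak_id, as.matrix(df[, poscols, drop = FALSE]), dim_types,
                inten, label = basename(path), dialect = "tsv")
}

#' Write a peak list
#'
#' @param pl a \code{peak_list}.
#' @param path output path.
#' @param dialect output dialect; "tsv" (default, lossless round-trip),
#'   "xeasy" or "sparky".
#' @export
write_peaklist <- function(pl, path, dialect = c("tsv", "xeasy", "sparky")) {
  dialect <- match.arg(dialect)
  nd <- length(pl$dim_types)
  if (dialect == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("# dim_types", paste(pl$dim_types, collapse = " ")), con)
    df <- data.frame(peak_id = pl$peak_id)
    for (k in seq_len(nd)) df[[paste0("pos_", k)]] <- sprintf("%.17g", pl$positions[, k])
    df$intensity <- sprintf("%.17g", pl$intensity)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
  } else if (dialect == "xeasy") {
    axes <- ifelse(pl$dim_types == "C_edit", "C",
                   ifelse(pl$dim_types == "N_edit", "N", "H"))
    axes[pl$dim_types == "H_acq"] <- "HN"
    hdr <- c(sprintf("# Number of dimensions %d", nd),
             sprintf("#INAME %d %s", seq_len(nd), axes))
    vol <- ifelse(is.na(pl$intensity), 0, pl$intensity)
    pos <- apply(pl$positions, 1, function(p) paste(sprintf("%8.3f", p),
                                                    collapse = " "))
    rows <- sprintf("%4d %s 1 U %12.5e %9.2e e 0 0", pl$peak_id, pos, vol, 0)
    writeLines(c(hdr, rows), path)
  } else {
    hdr <- paste(c("      Assignment", sprintf("%10s", paste0("w", seq_len(nd))),
                   "    Height"), collapse = "")
    asg <- paste(rep("?", nd), collapse = "-")
    pos <- apply(pl$positions, 1, function(p) paste(sprintf("%10.3f", p),
                                                    collapse = ""))
    vol <- ifelse(is.na(pl$intensity), 0, pl$intensity)
    rows <- sprintf("%16s%s %10.3e", asg, pos, vol)
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}
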