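# Residual dipolar coupling tables: TSV with one row per measured coupling,
# both atoms given as full references so inter-residue couplings (e.g. C'-N)
# are expressible.

new_rdc_table <- function(df) {
  if (any(!is.finite(df$d_obs)))
    data_error("non-finite observed coupling")
  if (any(df$weight <= 0))
    data_error("RDC weights must be positive")
  same <- df$chain_a == df$chain_b & df$resno_a == df$resno_b &
    df$atom_a == df$atom_b
  if (any(same))
    data_error("RDC record with identical atoms on both ends")
  rownames(df) <- NULL
  class(df) <- c("rdc_table", "data.frame")
  df
}

#' Read an RDC table (TSV)
#'
#' Columns: chain_a, resno_a, resname_a, atom_a, chain_b, resno_b,
#' resname_b, atom_b, d_obs (Hz), weight (optional, default 1).
#'
#' @param path input file.
#' @return an \code{rdc_table} data.frame.
#' @export
read_rdc_table <- function(path) {
  if (!file.exists(path))
    data_error(sprintf("cannot read RDC table: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chain_a", "resno_a", "resname_a", "atom_a",
            "chain_b", "resno_b", "resname_b", "atom_b", "d_obs")
  if (!all(need %in% names(df)))
    data_error(sprintf("RDC TSV must have columns %s",
                       paste(need, collapse = ", ")))
  if (is.null(df$weight)) df$weight <- 1
  df$atom_a <- normalize_h_names(df$atom_a, df$resname_a)
  df$atom_b <- normalize_h_names(df$atom_b, df$resname_b)
  new_rdc_table(df[, c(need, "weight")])
}

#' Write an RDC table (TSV)
#' @param rdcs an \code{rdc_table}.
#' @param path output path.
#' @export
write_rdc_table <- function(rdcs, path) {
  df <- as.data.frame(rdcs)
  df$d_obs <- sprintf("%.17g", df$d_obs)
  df$weight <- sprintf("%.17g", df$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
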