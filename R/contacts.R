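# Ambiguous contact lists: the NOESY-derived restraint format handed to
# structure-prediction groups.  Each NOESY cross peak is expanded to every
# shift-compatible proton-pair (site-pair) assignment, ranked by total
# chemical-shift mismatch.  Pure shift matching -- no coordinates involved.

#' Generate an ambiguous contact list from peaks and shifts
#'
#' @param peaks a \code{peak_list}.
#' @param shifts a \code{shift_table}.
#' @param tol a \code{\link{match_tolerance}}.
#' @return a \code{contact_list} data.frame with columns peak_id,
#'   dim_positions (comma-joined ppm), candidate_rank, atom_a, atom_b
#'   (site labels "chain.resno.resname.name").  Candidates are ranked by
#'   increasing summed shift mismatch, ties broken lexicographically -- the
#'   ordering is stable under rewrite.
#' @export
generate_contacts <- function(peaks, shifts, tol = match_tolerance()) {
  sites <- sites_from_shifts(shifts)
  anoe <- match_peaks(peaks, shifts, sites, tol)
  hd <- which(peaks$dim_types %in% c("H_acq", "H_indirect"))
  lab <- sprintf("%s.%d.%s.%s", sites$table$chain, sites$table$resno,
                 sites$table$resname, sites$table$rep)
  rows <- list()
  pk_idx <- match(anoe$peak_id, peaks$peak_id)
  for (k in seq_along(anoe$peak_id)) {
    ij <- anoe$candidates[[k]]
    pos <- peaks$positions[pk_idx[k], ]
    hp <- pos[hd]
    err <- vapply(seq_len(nrow(ij)), function(r) {
      sa <- sites$member_shift[[ij[r, 1]]]
      sb <- sites$member_shift[[ij[r, 2]]]
      e1 <- min(abs(sa - hp[1])) + min(abs(sb - hp[2]))
      e2 <- min(abs(sa - hp[2])) + min(abs(sb - hp[1]))
      min(e1, e2)
    }, 1.0)
    la <- lab[ij[, 1]]; lb <- lab[ij[, 2]]
    ord <- order(err, la, lb)
    rows[[k]] <- data.frame(
      peak_id = anoe$peak_id[k],
      dim_positions = paste(sprintf("%.3f", pos), collapse = ","),
      candidate_rank = seq_along(ord),
      atom_a = la[ord], atom_b = lb[ord], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    data_error("no peak matched any candidate pair; contact list is empty")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contact_list", "data.frame")
  out
}

#' Write an ambiguous contact list (TSV)
#'
#' One record per candidate assignment; bit-exact round-trippable via
#' \code{\link{read_contact_list}}.
#'
#' @param contacts a \code{contact_list}.
#' @param path output path.
#' @export
write_contact_list <- function(contacts, path) {
  if (nrow(contacts) == 0L) data_error("contact list is empty")
  utils::write.table(as.data.frame(contacts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an ambiguous contact list (TSV)
#' @param path input path.
#' @return a \code{contact_list} data.frame.
#' @export
read_contact_list <- function(path) {
  if (!file.exists(path))
    data_error(sprintf("cannot read contact list: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(dim_positions = "character"))
  class(df) <- c("contact_list", "data.frame")
  df
}
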