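# Model-side distance network: pseudoatom r^-6 summation distances and the
# short-distance graph G at cutoff d_NOE_max.
#
# Summation distance between two proton groups:
#   d_sum = ( sum_i sum_j <r_ij^-6> )^(-1/6)
# where <.> averages each pair term across ensemble conformers before the
# -1/6 power (uniform-relaxation assumption).  For singletons and a single
# conformer this reduces to the Euclidean distance.  Interproton distances
# below 0.5 A (clashes in physically unreasonable models) are floored to
# 0.5 A with a warning instead of failing, so such models still score.

CLASH_FLOOR <- 0.5

# Mean r^-6 matrix over the member protons of all sites, plus bookkeeping.
# Returns list(r6 = n_sel x n_sel matrix, A = membership for selected rows).
proton_r6_matrix <- function(sites, ens) {
  ens <- as_ensemble(ens)
  A0 <- site_membership(sites, ens[[1]])
  sel <- which(rowSums(A0) > 0)
  A <- A0[sel, , drop = FALSE]
  keys <- atom_key(ens[[1]]$chain[sel], ens[[1]]$resno[sel], ens[[1]]$atom[sel])
  acc <- NULL
  clashed <- FALSE
  for (cf in ens) {
    idx <- match(keys, atom_key(cf$chain, cf$resno, cf$atom))
    if (anyNA(idx))
      data_error("conformers do not share the site proton set")
    P <- coords(cf)[idx, , drop = FALSE]
    d2 <- as.matrix(stats::dist(P))^2
    low <- d2 < CLASH_FLOOR^2
    diag(low) <- FALSE
    if (any(low)) {
      clashed <- TRUE
      d2[low] <- CLASH_FLOOR^2
    }
    r6 <- 1 / (d2 * d2 * d2)
    diag(r6) <- 0
    acc <- if (is.null(acc)) r6 else acc + r6
  }
  if (clashed)
    named_warning(sprintf(
      "interproton distance(s) < %.1f A floored to %.1f A (clashing model)",
      CLASH_FLOOR, CLASH_FLOOR), "rpfdp_warning_clash")
  list(r6 = acc / length(ens), A = A)
}

# n_sites x n_sites summation distance matrix (diagonal NA).
site_distance_matrix <- function(sites, ens) {
  pr <- proton_r6_matrix(sites, ens)
  S <- crossprod(pr$A, pr$r6 %*% pr$A)
  # members within one site contribute to the diagonal only; zero it
  D <- S^(-1 / 6)
  diag(D) <- NA_real_
  D
}

#' Pseudoatom summation distance between two proton sites
#'
#' @param sites a \code{proton_sites} object.
#' @param i,j site ids (rows of \code{sites$table}).
#' @param conformers a conformer or ensemble supplying coordinates; for an
#'   ensemble each pair term r^-6 is averaged across conformers before the
#'   -1/6 power.
#' @return distance in Angstrom; never exceeds the minimum member-pair
#'   distance.
#' @export
summation_distance <- function(sites, i, j, conformers) {
  if (i == j || length(intersect(sites$members[[i]], sites$members[[j]])) > 0 &&
      sites$table$resno[i] == sites$table$resno[j] &&
      sites$table$chain[i] == sites$table$chain[j])
    data_error("summation distance requires two disjoint sites")
  ens <- as_ensemble(conformers)
  t1 <- sites$table[i, ]; t2 <- sites$table[j, ]
  k1 <- atom_key(t1$chain, t1$resno, sites$members[[i]])
  k2 <- atom_key(t2$chain, t2$resno, sites$members[[j]])
  acc <- 0
  for (cf in ens) {
    keys <- atom_key(cf$chain, cf$resno, cf$atom)
    i1 <- match(k1, keys); i2 <- match(k2, keys)
    if (anyNA(i1) || anyNA(i2))
      data_error("site member protons missing from conformer coordinates")
    P1 <- coords(cf)[i1, , drop = FALSE]
    P2 <- coords(cf)[i2, , drop = FALSE]
    for (a in seq_len(nrow(P1))) {
      d <- sqrt(rowSums(sweep(P2, 2, P1[a, ])^2))
      if (any(d < CLASH_FLOOR)) {
        named_warning(sprintf("clash (< %.1f A) between %s and %s; floored",
                              CLASH_FLOOR, k1[a], k2[which.min(d)]),
                      "rpfdp_warning_clash")
        d <- pmax(d, CLASH_FLOOR)
      }
      acc <- acc + sum(d^-6)
    }
  }
  (acc / length(ens))^(-1 / 6)
}

#' Build the model distance graph G
#'
#' Connects every pair of proton sites whose summation distance is at most
#' \code{d_max}.
#'
#' @param sites a \code{proton_sites} object.
#' @param conformers conformer or ensemble (ensemble-averaged distances).
#' @param d_max cutoff d_NOE_max in Angstrom (default 5.0; 7.0 is the usual
#'   choice for perdeuterated samples).
#' @return an object of class \code{model_distance_graph}: list with the
#'   sites, the full summation-distance matrix \code{d}, an \code{edges}
#'   data.frame (i, j, d_sum with i < j) and \code{d_max}.
#' @export
build_distance_graph <- function(sites, conformers, d_max = 5.0) {
  if (d_max <= 0) data_error("d_max must be positive")
  D <- site_distance_matrix(sites, conformers)
  ut <- which(upper.tri(D) & D <= d_max, arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2],
                      d_sum = D[ut])
  structure(list(sites = sites, d = D, edges = edges, d_max = d_max),
            class = "model_distance_graph")
}

#' @export
print.model_distance_graph <- function(x, ...) {
  cat(sprintf("<distance graph: %d sites, %d edges at d_max = %.2f A>\n",
              n_sites(x$sites), nrow(x$edges), x$d_max))
  invisible(x)
}
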