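# TP/FP/FN classification of a model distance graph against the ambiguous
# NOE graph, and the d^-6 weighted precision.
#
# Peak-level (recall side): a matched peak is a true positive when at least
# one of its candidate site pairs is an edge of G; a false negative when it
# has candidates but none is an edge.  Edge-level (precision side): a model
# edge is a true-positive edge when some peak lists it among its candidates,
# a false-positive edge otherwise.  Unmatched and diagonal peaks never enter
# the counts.  True negatives (site pairs in neither graph) are counted and
# reported but consumed by no score.

#' Classify peaks and model edges
#'
#' @param graph_model a \code{model_distance_graph}.
#' @param graph_anoe an \code{ambiguous_noe_graph} over the same proton
#'   sites.
#' @return list with counts (\code{tp}, \code{fn}, \code{fp}, \code{tn}),
#'   the per-peak status, TP/FP edge tables (with \code{d_sum}), and the
#'   candidate-union matrix.
#' @export
classify_noe <- function(graph_model, graph_anoe) {
  ns <- n_sites(graph_model$sites)
  if (ns != n_sites(graph_anoe$sites) ||
      !identical(graph_model$sites$table$rep, graph_anoe$sites$table$rep))
    data_error("model graph and NOE graph are over different site universes")
  D <- graph_model$d
  dmax <- graph_model$d_max
  E <- !is.na(D) & D <= dmax
  U <- candidate_union(graph_anoe, ns)

  status <- vapply(graph_anoe$candidates, function(ij) {
    if (any(E[ij])) "tp" else "fn"
  }, "")
  ut <- upper.tri(E)
  tp_idx <- which(E & U & ut, arr.ind = TRUE)
  fp_idx <- which(E & !U & ut, arr.ind = TRUE)
  tn <- sum(!E & !U & ut)
  tp_edges <- data.frame(i = tp_idx[, 1], j = tp_idx[, 2], d_sum = D[tp_idx])
  fp_edges <- data.frame(i = fp_idx[, 1], j = fp_idx[, 2], d_sum = D[fp_idx])
  list(tp = sum(status == "tp"), fn = sum(status == "fn"),
       fp = nrow(fp_edges), tn = tn, peak_status = status,
       peak_id = graph_anoe$peak_id,
       tp_edges = tp_edges, fp_edges = fp_edges, U = U, E = E)
}

#' Distance-weighted precision
#'
#' precision_w = sum_TP d^-6 / (sum_TP d^-6 + sum_FP d^-6).  The r^-6
#' weighting curbs the dominance of the many weak long-distance pairs near
#' the detection limit.
#'
#' @param tp_edges,fp_edges edge tables carrying \code{d_sum} (as returned
#'   by \code{\link{classify_noe}}).
#' @return a fraction in [0, 1]; 1 when there are no FP edges.
#' @export
precision_weighted <- function(tp_edges, fp_edges) {
  wtp <- sum(tp_edges$d_sum^-6)
  wfp <- sum(fp_edges$d_sum^-6)
  if (wtp + wfp == 0) return(NA_real_)
  wtp / (wtp + wfp)
}

# recall / weighted precision / F for one classification
rpf_from_classification <- function(cl) {
  recall <- if (cl$tp + cl$fn > 0) cl$tp / (cl$tp + cl$fn) else NA_real_
  prec <- precision_weighted(cl$tp_edges, cl$fp_edges)
  f <- if (!is.na(recall) && !is.na(prec) && (recall + prec) > 0) {
    2 * recall * prec / (recall + prec)
  } else 0
  list(recall = recall, precision_w = prec, f_measure = f)
}

# Per-residue violation maps.  FN peaks: each candidate pair adds
# 1/n_candidates to both residues of the pair.  FP edges: +1 to each residue
# of the edge.
violation_maps <- function(cl, anoe, sites) {
  resof <- sites$table$resno
  rec <- numeric(0); prec <- numeric(0)
  bump <- function(map, res, amt) {
    key <- as.character(res)
    map[key] <- (if (key %in% names(map)) map[key] else 0) + amt
    map
  }
  cand <- anoe$candidates
  for (p in which(cl$peak_status == "fn")) {
    ij <- cand[[p]]
    amt <- 1 / nrow(ij)
    for (r in seq_len(nrow(ij))) {
      rs <- unique(resof[c(ij[r, 1], ij[r, 2])])
      for (q in rs) rec <- bump(rec, q, amt)
    }
  }
  if (nrow(cl$fp_edges) > 0) {
    for (r in seq_len(nrow(cl$fp_edges))) {
      rs <- unique(resof[c(cl$fp_edges$i[r], cl$fp_edges$j[r])])
      for (q in rs) prec <- bump(prec, q, 1)
    }
  }
  list(recall_viol = rec, precision_viol = prec)
}
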