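# Upper and lower bounds of the F-measure used to normalize DP.
#
# F(G_ideal): recall is 1 by definition; precision is the d^-6 weighted
# fraction of the local network G_local (all 2- and 3-bond proton pairs)
# that has a supporting peak -- the completeness of the NOESY data.
#
# F(G_free): the F-measure expected for a freely rotating polypeptide chain
# (fixed covalent geometry, uniform torsions), estimated as the mean
# single-conformer F over a seeded Monte-Carlo ensemble of M chains.

# Geminal/vicinal proton pairs of the assigned protons, as site-id pairs.
local_site_pairs <- function(sites) {
  tab <- sites$table
  out <- list()
  res <- unique(tab[, c("chain", "resno", "resname")])
  for (r in seq_len(nrow(res))) {
    ch <- res$chain[r]; rn <- res$resno[r]; rt <- res$resname[r]
    topo <- residue_topology(rt)
    nb <- heavy_neighbors(topo)
    ks <- which(tab$chain == ch & tab$resno == rn)
    if (length(ks) < 2L) next
    # proton -> site map for this residue
    pmap <- list()
    for (k in ks) for (m in sites$members[[k]]) pmap[[m]] <- k
    pt <- topo$protons
    pt <- pt[pt$name %in% names(pmap), , drop = FALSE]
    if (nrow(pt) < 2L) next
    for (a in seq_len(nrow(pt) - 1L)) {
      for (b in (a + 1L):nrow(pt)) {
        pa <- pt$parent[a]; pb <- pt$parent[b]
        if (pa == pb || pb %in% nb[[pa]]) {
          sa <- pmap[[pt$name[a]]]; sb <- pmap[[pt$name[b]]]
          if (sa != sb) out[[length(out) + 1L]] <- c(min(sa, sb), max(sa, sb))
        }
      }
    }
  }
  if (length(out) == 0L) return(matrix(integer(0), 0, 2))
  m <- unique(do.call(rbind, out))
  m
}

#' Upper bound F(G_ideal) from NOESY data completeness
#'
#' @param graph_anoe an \code{ambiguous_noe_graph}.
#' @param graph_model a \code{model_distance_graph} over the same sites
#'   (supplies the d^-6 weights of the local pairs; local geometry is
#'   essentially model-independent).
#' @return list with \code{f_ideal} and \code{precision_local}.
#' @export
f_ideal <- function(graph_anoe, graph_model) {
  sites <- graph_anoe$sites
  lp <- local_site_pairs(sites)
  if (nrow(lp) == 0L) return(list(f_ideal = 1, precision_local = 1))
  U <- candidate_union(graph_anoe)
  d <- graph_model$d[lp]
  w <- d^-6
  supported <- U[lp]
  p_local <- sum(w[supported]) / sum(w)
  list(f_ideal = 2 * p_local / (1 + p_local), precision_local = p_local)
}

# Precompute the flattened candidate-pair index used by the fast scorer.
flatten_candidates <- function(anoe) {
  if (length(anoe$candidates) == 0L)
    return(list(ij = matrix(integer(0), 0, 2), pid = integer(0)))
  ij <- do.call(rbind, anoe$candidates)
  pid <- rep(seq_along(anoe$candidates),
             vapply(anoe$candidates, nrow, 1L))
  list(ij = ij, pid = pid)
}

# recall / weighted precision / F from a site distance matrix alone
fast_f <- function(D, d_max, flat, U) {
  E <- !is.na(D) & D <= d_max
  hit <- E[flat$ij]
  tp_peak <- tapply(hit, flat$pid, any)
  recall <- mean(tp_peak)
  ut <- upper.tri(D)
  W <- D^-6
  wtp <- sum(W[E & U & ut])
  wfp <- sum(W[E & !U & ut])
  prec <- if (wtp + wfp > 0) wtp / (wtp + wfp) else 0
  f <- if (recall + prec > 0) 2 * recall * prec / (recall + prec) else 0
  c(recall = recall, precision_w = prec, f = f)
}

#' Lower bound F(G_free) from a freely rotating chain null model
#'
#' Draws \code{m} freely rotating chain conformers of the assigned sequence
#' (uniform torsions over fixed covalent geometry), scores each against the
#' ambiguous NOE graph, and returns the mean F.  Deterministic for a fixed
#' seed.
#'
#' @param shifts the \code{shift_table} (defines the sequence; residues with
#'   no assignment inside the assigned range are modelled as alanine).
#' @param graph_anoe the \code{ambiguous_noe_graph} the models are scored
#'   against.
#' @param d_max distance cutoff in Angstrom.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param m ensemble size (default 200).
#' @return list with \code{f_free}, per-conformer \code{f_values}, and
#'   \code{m}.
#' @export
f_free <- function(shifts, graph_anoe, d_max = 5.0, seed = 1L, m = 200L) {
  sites <- graph_anoe$sites
  seq3 <- sequence_from_shifts(shifts)
  flat <- flatten_candidates(graph_anoe)
  U <- candidate_union(graph_anoe)
  fs <- with_seed(seed, {
    vapply(seq_len(m), function(k) {
      cf <- free_chain_conformer(seq3$resname, chain = seq3$chain[1],
                                 start = seq3$resno[1])
      D <- suppressWarnings(site_distance_matrix(sites, cf))
      fast_f(D, d_max, flat, U)[["f"]]
    }, 1.0)
  })
  list(f_free = mean(fs), f_values = fs, m = m)
}

# contiguous residue table (chain, resno, resname) from a shift table
sequence_from_shifts <- function(shifts) {
  res <- unique(shifts[, c("chain", "resno", "resname")])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  ch <- res$chain[1]
  rng <- seq(min(res$resno), max(res$resno))
  rn <- res$resname[match(rng, res$resno)]
  rn[is.na(rn)] <- "ALA"
  data.frame(chain = ch, resno = rng, resname = rn, stringsAsFactors = FALSE)
}
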