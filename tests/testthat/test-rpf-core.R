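# Peak matching, TP/FP/FN classification, weighted precision, F bounds, DP.

test_that("N-edited peak matching reproduces the brute-force candidate set", {
  sh <- rpfdp:::new_shift_table(data.frame(
    chain = "A", resno = c(15L, 15L, 3L, 7L),
    resname = c("ARG", "ARG", "LYS", "GLU"),
    atom = c("H", "N", "HA", "HA"),
    shift = c(8.21, 120.5, 3.40, 3.43), ambiguity = 1L,
    stringsAsFactors = FALSE))
  sites <- sites_from_shifts(sh)
  pl <- rpfdp:::new_peak_list(1L, matrix(c(8.20, 120.4, 3.41), 1, 3),
                              c("H_acq", "N_edit", "H_indirect"))
  tol <- match_tolerance(0.03, 0.4, 0.4)
  anoe <- match_peaks(pl, sh, sites, tol)
  expect_length(anoe$candidates, 1L)
  got <- anoe$candidates[[1]]
  lab <- sites$table$rep
  pairs <- apply(got, 1, function(r) paste(sort(lab[r]), collapse = "+"))
  # brute force over all site pairs under the same rule
  expect_setequal(pairs, c("H+HA", "H+HA"))
  expect_equal(nrow(got), 2L)    # (R15 H, K3 HA) and (R15 H, E7 HA)
  resn <- apply(got, 1, function(r) sort(sites$table$resno[r]))
  expect_setequal(apply(resn, 2, paste, collapse = "-"), c("3-15", "7-15"))

  # a peak far from every shift goes to unmatched_peaks
  pl2 <- rpfdp:::new_peak_list(1L, matrix(c(1.0, 120.4, 13.0), 1, 3),
                               c("H_acq", "N_edit", "H_indirect"))
  anoe2 <- match_peaks(pl2, sh, sites, tol)
  expect_length(anoe2$candidates, 0L)
  expect_equal(anoe2$unmatched_peaks, 1L)

  # heavy-atom filter: N shift off by > tol_n kills the candidate
  pl3 <- rpfdp:::new_peak_list(1L, matrix(c(8.20, 115.0, 3.41), 1, 3),
                               c("H_acq", "N_edit", "H_indirect"))
  expect_length(match_peaks(pl3, sh, sites, tol)$candidates, 0L)
})

test_that("zero tolerance on exact synthetic shifts recovers generating pairs", {
  w <- fx_world(12, 3)
  sites <- build_proton_sites(w$truth, w$shifts)
  anoe <- match_peaks(w$peaks, w$shifts, sites, match_tolerance(0, 0, 0))
  expect_equal(length(anoe$candidates), rpfdp:::n_peaks(w$peaks))
  D <- rpfdp:::site_distance_matrix(sites, w$truth)
  # every peak's top candidate set includes a true short pair
  ok <- vapply(anoe$candidates, function(ij) any(D[ij] <= w$cfg$d_max), TRUE)
  expect_true(all(ok))
})

test_that("diagonal peaks are dropped and reported separately", {
  sh <- rpfdp:::new_shift_table(data.frame(
    chain = "A", resno = 1:2, resname = "ALA", atom = "HA",
    shift = c(4.10, 4.50), ambiguity = 1L, stringsAsFactors = FALSE))
  sites <- sites_from_shifts(sh)
  pl <- rpfdp:::new_peak_list(1:2, rbind(c(4.10, 4.105), c(4.10, 4.50)),
                              c("H_indirect", "H_acq"))
  anoe <- match_peaks(pl, sh, sites, match_tolerance(0.03, 0.4, 0.4))
  expect_equal(anoe$diagonal_peaks, 1L)
  expect_length(anoe$peak_id, 1L)
})

test_that("classification implements the any-candidate TP rule and FP edges", {
  ts <- tiny_sites_world()
  sites <- build_proton_sites(ts$cf, ts$shifts)   # 6 singleton sites
  ns <- rpfdp:::n_sites(sites)
  D <- rpfdp:::site_distance_matrix(sites, ts$cf)
  gm <- build_distance_graph(sites, ts$cf, d_max = 4.2)
  gm$d <- D
  # candidates: peak 1 -> sole true pair; peak 2 -> {false pair, true pair}
  idx <- function(rn, a) which(sites$table$resno == rn & sites$table$rep == a)
  cand <- list(rbind(c(idx(2, "H"), idx(2, "HA"))),
               rbind(sort(c(idx(2, "H"), idx(7, "HA")))[c(1, 2)],
                     c(idx(3, "H"), idx(3, "HA"))))
  cand[[2]] <- rbind(c(min(idx(2, "H"), idx(7, "HA")),
                       max(idx(2, "H"), idx(7, "HA"))),
                     c(idx(3, "H"), idx(3, "HA")))
  anoe <- structure(list(candidates = cand, peak_id = 1:2,
                         unmatched_peaks = integer(0),
                         diagonal_peaks = integer(0), sites = sites,
                         tol = match_tolerance()),
                    class = "ambiguous_noe_graph")
  cl <- classify_noe(gm, anoe)
  expect_equal(cl$tp, 2L)     # peak 2 is TP because one candidate is an edge
  expect_equal(cl$fn, 0L)
  # model edges not supported by any peak are FP
  expect_equal(cl$fp, nrow(gm$edges) - 2L)
  # a peak whose only candidates are long pairs is FN
  anoe$candidates <- list(rbind(c(idx(2, "H"), idx(7, "HA"))))
  anoe$peak_id <- 1L
  cl2 <- classify_noe(gm, anoe)
  expect_equal(cl2$tp, 0L)
  expect_equal(cl2$fn, 1L)
})

test_that("weighted precision follows the d^-6 arithmetic oracle", {
  e <- function(d) data.frame(i = seq_along(d), j = seq_along(d) + 1, d_sum = d)
  none <- e(numeric(0))
  expect_equal(precision_weighted(e(2.5), none), 1)
  expect_equal(precision_weighted(e(2.5), e(2.5)), 0.5)
  expect_equal(precision_weighted(e(2), e(4)), 64 / 65)
})

test_that("F bounds: ideal from local-pair completeness, free is seeded and convergent", {
  # half the local pairs supported at equal weights -> precision 0.5, F = 2/3
  ts <- tiny_sites_world()
  sites <- build_proton_sites(ts$cf, ts$shifts)
  lp <- rpfdp:::local_site_pairs(sites)    # H-HA geminal-range pairs per residue
  expect_true(nrow(lp) >= 2L)
  D <- matrix(2.5, rpfdp:::n_sites(sites), rpfdp:::n_sites(sites))
  diag(D) <- NA
  gm <- structure(list(sites = sites, d = D, d_max = 5),
                  class = "model_distance_graph")
  k <- nrow(lp) %/% 2L
  sup <- lp[seq_len(k), , drop = FALSE]
  anoe <- structure(list(candidates = lapply(seq_len(nrow(sup)), function(q)
    sup[q, , drop = FALSE]), peak_id = seq_len(nrow(sup)),
    unmatched_peaks = integer(0), diagonal_peaks = integer(0),
    sites = sites, tol = match_tolerance()),
    class = "ambiguous_noe_graph")
  fi <- f_ideal(anoe, gm)
  # equal weights: precision = supported fraction; F = harmonic mean with 1
  p_expect <- k / nrow(lp)
  expect_equal(fi$precision_local, p_expect)
  expect_equal(fi$f_ideal, 2 * p_expect / (1 + p_expect))

  # complete support -> f_ideal = 1 (noise-free synthetic world)
  sess <- fx_bench_session()
  r <- score_model(sess, fx_bench()$truth)$conformer[[1]]
  expect_equal(r$f_ideal, 1)

  # f_free: seeded determinism and convergence in M
  w <- fx_world(12, 3)
  sites_w <- sites_from_shifts(w$shifts)
  anoe_w <- match_peaks(w$peaks, w$shifts, sites_w, match_tolerance(0, 0, 0))
  a <- f_free(w$shifts, anoe_w, d_max = 5, seed = 11, m = 40)
  b <- f_free(w$shifts, anoe_w, d_max = 5, seed = 11, m = 40)
  expect_identical(a$f_free, b$f_free)
  big <- f_free(w$shifts, anoe_w, d_max = 5, seed = 12, m = 80)
  expect_lt(abs(a$f_free - big$f_free), 0.1)
})

test_that("score_rpf composes: self-scoring is perfect, errors are named", {
  w <- fx_world(12, 3)
  rs <- score_rpf(w$truth, w$shifts, w$peaks, tol = match_tolerance(0, 0, 0),
                  d_max = 5, seed = 5, f_free_m = 30)
  r <- rs$conformer[[1]]
  expect_equal(r$recall, 1)
  expect_equal(r$precision_w, 1)
  expect_equal(r$f_measure, 1)
  expect_equal(r$dp, 1)                      # F = F_ideal exactly -> DP = 1
  expect_true(r$f_free < 1 && r$f_free > 0)

  # empty usable peak set is a named error (recall undefined)
  empty <- rpfdp:::new_peak_list(1L, matrix(c(30, 30), 1, 2),
                                 c("H_indirect", "H_acq"))
  expect_error(score_rpf(w$truth, w$shifts, empty, seed = 1, f_free_m = 5),
               class = "rpfdp_no_usable_peaks")
})

test_that("per-residue violation maps attribute FN fractionally and FP per edge", {
  ts <- tiny_sites_world()
  sites <- build_proton_sites(ts$cf, ts$shifts)
  D <- rpfdp:::site_distance_matrix(sites, ts$cf)
  gm <- structure(list(sites = sites, d = D, d_max = 1.2),
                  class = "model_distance_graph")
  idx <- function(rn, a) which(sites$table$resno == rn & sites$table$rep == a)
  # one FN peak with two candidate pairs spanning residues (2,3) and (2,7)
  cand <- list(rbind(c(idx(2, "H"), idx(3, "HA")),
                     c(idx(2, "H"), idx(7, "HA"))))
  cand[[1]] <- t(apply(cand[[1]], 1, sort))
  anoe <- structure(list(candidates = cand, peak_id = 1L,
                         unmatched_peaks = integer(0),
                         diagonal_peaks = integer(0), sites = sites,
                         tol = match_tolerance()),
                    class = "ambiguous_noe_graph")
  cl <- classify_noe(gm, anoe)
  expect_equal(cl$fn, 1L)
  maps <- rpfdp:::violation_maps(cl, anoe, sites)
  expect_equal(unname(maps$recall_viol["2"]), 1.0)    # in both pairs: 2 * 1/2
  expect_equal(unname(maps$recall_viol["3"]), 0.5)
  expect_equal(unname(maps$recall_viol["7"]), 0.5)
  # FP edges increment both residues by 1
  expect_true(all(maps$precision_viol >= 1 | length(maps$precision_viol) == 0))
})

test_that("report writers emit JSON and violation TSV", {
  w <- fx_world(12, 3)
  rs <- score_rpf(w$truth, w$shifts, w$peaks, tol = match_tolerance(0, 0, 0),
                  seed = 5, f_free_m = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_rpf_report(rs, f, meta = list(config_hash = "abc"))
  obj <- jsonlite::read_json(f)
  expect_equal(obj$conformers[[1]]$dp, 1)
  expect_equal(obj$config_hash, "abc")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_violation_tsv(rs$conformer[[1]], f2)
  expect_true(file.exists(f2))
})
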