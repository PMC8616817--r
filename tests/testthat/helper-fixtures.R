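# Shared fixtures, memoized so expensive synthetic worlds are built once per
# test run.  Everything is generated in code; no stored data files.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# small synthetic world for unit tests
fx_world <- function(n = 20L, seed = 7L, ...) {
  key <- paste0("world_", n, "_", seed, "_",
                paste(unlist(list(...)), collapse = "_"))
  memo(key, function() {
    cfg <- synth_config(n_residues = n, seed = seed, ...)
    truth <- make_structure(cfg)
    shifts <- make_shifts(truth, cfg)
    peaks <- make_noesy(truth, shifts, cfg, type = "2D")
    list(cfg = cfg, truth = truth, shifts = shifts, peaks = peaks)
  })
}

# the acceptance fixture: 40 residues, seed 17, no dropout/artifacts/jitter
fx_bench <- function() fx_world(n = 40L, seed = 17L)

# its scoring session (exact matching, tolerance 0; M = 200 chain null)
fx_bench_session <- function() {
  memo("bench_session", function() {
    w <- fx_bench()
    rpf_session(w$shifts, w$peaks, tol = match_tolerance(0, 0, 0),
                d_max = 5, seed = 17L, f_free_m = 200L)
  })
}

# a tiny hand-made conformer: one chain, arbitrary proton positions
tiny_sites_world <- function() {
  # three residues; protons placed on a line for easy distance arithmetic
  cf <- new_tiny_conformer(data.frame(
    resno = c(2, 2, 3, 3, 7, 7),
    resname = "ALA",
    atom = c("H", "HA", "H", "HA", "H", "HA"),
    x = c(0, 1, 4, 5, 8, 9), y = 0, z = 0))
  sh <- data.frame(chain = "A", resno = cf$resno, resname = cf$resname,
                   atom = cf$atom,
                   shift = c(8.0, 4.0, 8.5, 3.9, 7.5, 4.4),
                   ambiguity = 1L, stringsAsFactors = FALSE)
  list(cf = cf, shifts = rpfdp:::new_shift_table(sh))
}

new_tiny_conformer <- function(df) {
  df$chain <- "A"
  df$elem <- substring(df$atom, 1, 1)
  rpfdp:::new_conformer(df[, c("chain", "resno", "resname", "atom", "elem",
                               "x", "y", "z")])
}

# brute-force reference classifier: direct O(n^2) loops over site pairs and
# per-peak candidate scans, using summation_distance() on raw coordinates --
# independent of the matrix fast path in classify_noe()
brute_force_classify <- function(sites, conformer, anoe, d_max) {
  ns <- rpfdp:::n_sites(sites)
  dmat <- matrix(NA_real_, ns, ns)
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      dmat[i, j] <- dmat[j, i] <-
        suppressWarnings(summation_distance(sites, i, j, conformer))
    }
  }
  supported <- matrix(FALSE, ns, ns)
  tp <- 0L; fn <- 0L
  for (k in seq_along(anoe$candidates)) {
    ij <- anoe$candidates[[k]]
    hit <- FALSE
    for (r in seq_len(nrow(ij))) {
      supported[ij[r, 1], ij[r, 2]] <- TRUE
      supported[ij[r, 2], ij[r, 1]] <- TRUE
      if (dmat[ij[r, 1], ij[r, 2]] <= d_max) hit <- TRUE
    }
    if (hit) tp <- tp + 1L else fn <- fn + 1L
  }
  fp <- 0L; wtp <- 0; wfp <- 0
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      if (dmat[i, j] <= d_max) {
        if (supported[i, j]) {
          wtp <- wtp + dmat[i, j]^-6
        } else {
          fp <- fp + 1L
          wfp <- wfp + dmat[i, j]^-6
        }
      }
    }
  }
  list(tp = tp, fn = fn, fp = fp, precision_w = wtp / (wtp + wfp))
}
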