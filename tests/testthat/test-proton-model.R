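# Hydrogen building, pseudoatom grouping, summation distances, distance graph.

test_that("hydrogens are placed at ideal bond lengths and kept if present", {
  w <- fx_world(12, 3)
  heavy <- w$truth[w$truth$elem != "H", ]
  class(heavy) <- class(w$truth)
  prot <- add_hydrogens(heavy)
  # every topology proton except the N-terminal amide is placed
  for (rn in c(2, 5)) {
    rt <- prot$resname[prot$resno == rn][1]
    topo <- rpfdp:::residue_topology(rt)
    expect_setequal(intersect(topo$protons$name, prot$atom[prot$resno == rn]),
                    topo$protons$name)
  }
  g <- function(rn, a) {
    i <- which(prot$resno == rn & prot$atom == a)
    c(prot$x[i], prot$y[i], prot$z[i])
  }
  expect_equal(rpfdp:::vnorm(g(2, "HA") - g(2, "CA")), 1.09, tolerance = 1e-6)
  expect_equal(rpfdp:::vnorm(g(2, "H") - g(2, "N")), 1.01, tolerance = 1e-6)

  # already-protonated input returned unchanged (atom count invariant)
  again <- add_hydrogens(w$truth)
  expect_equal(nrow(again), nrow(w$truth))
  expect_equal(again$x, w$truth$x)
})

test_that("degenerate frames and missing heavy atoms skip protons with named warnings", {
  # collinear N-CA-C: the amide H frame is degenerate
  cf <- new_tiny_conformer(data.frame(
    resno = 1, resname = "GLY",
    atom = c("N", "CA", "C", "O"),
    x = c(0, 1.458, 2.9, 3.5), y = c(0, 0, 0, 1), z = 0))
  cf2 <- new_tiny_conformer(data.frame(
    resno = 2, resname = "GLY", atom = c("N", "CA", "C", "O"),
    x = c(4.2, 5.0, 6.0, 6.5), y = c(0, 0, 0, 1), z = 0))
  both <- rpfdp:::new_conformer(rbind(as.data.frame(cf), as.data.frame(cf2)))
  # residue 2 amide frame: N collinear with CA and C(prev) here? construct:
  # make CA(2) collinear with N(2) and C(1)
  both$x[both$resno == 2 & both$atom == "CA"] <- 5.5
  both$y[both$resno == 2 & both$atom == "CA"] <- 0
  expect_warning(add_hydrogens(both), class = "rpfdp_warning_collinear")

  # missing sidechain heavy atoms: dependent protons skipped, named warning
  w <- fx_world(12, 3)
  broken <- w$truth[!(w$truth$resno == 3 & w$truth$atom == "CB") &
                    w$truth$elem != "H", ]
  class(broken) <- class(w$truth)
  expect_warning(prot <- add_hydrogens(broken),
                 class = "rpfdp_warning_missing_heavy")
  expect_false(any(prot$resno == 3 & prot$atom == "HB"))
})

test_that("pseudoatom grouping follows shift degeneracy and ambiguity codes", {
  mk <- function(atoms, shifts, amb, resname = "VAL") {
    rpfdp:::new_shift_table(data.frame(
      chain = "A", resno = 9L, resname = resname, atom = atoms,
      shift = shifts, ambiguity = amb, stringsAsFactors = FALSE))
  }
  # Val isopropyl, both methyls 0.91, ambiguity 2 -> one 6-member site
  sh <- mk(c(paste0("HG1", 1:3), paste0("HG2", 1:3)), rep(0.91, 6), 2L)
  s <- sites_from_shifts(sh)
  expect_equal(rpfdp:::n_sites(s), 1L)
  expect_equal(s$table$n_members, 6L)
  expect_equal(s$table$rep, "QQG")

  # distinct methyl shifts, stereospecific -> two 3-member sites
  sh2 <- mk(c(paste0("HG1", 1:3), paste0("HG2", 1:3)),
            rep(c(0.94, 0.88), each = 3), 1L)
  s2 <- sites_from_shifts(sh2)
  expect_equal(rpfdp:::n_sites(s2), 2L)
  expect_setequal(s2$table$rep, c("QG1", "QG2"))

  # Gly HA2/HA3 distinct, ambiguity 1 -> singletons
  sh3 <- mk(c("HA2", "HA3"), c(3.96, 3.90), 1L, resname = "GLY")
  s3 <- sites_from_shifts(sh3)
  expect_equal(rpfdp:::n_sites(s3), 2L)
  expect_true(all(s3$table$n_members == 1L))

  # identical methylene shifts -> merged prochiral site
  sh4 <- mk(c("HA2", "HA3"), c(3.93, 3.93), 1L, resname = "GLY")
  s4 <- sites_from_shifts(sh4)
  expect_equal(rpfdp:::n_sites(s4), 1L)
  expect_equal(s4$table$rep, "QA")

  # Phe ring with one shift per position pair -> merged QD/QE
  sh5 <- rpfdp:::new_shift_table(data.frame(
    chain = "A", resno = 4L, resname = "PHE",
    atom = c("HD1", "HD2", "HE1", "HE2", "HZ"),
    shift = c(7.28, 7.28, 7.38, 7.38, 7.32), ambiguity = 1L,
    stringsAsFactors = FALSE))
  s5 <- sites_from_shifts(sh5)
  expect_setequal(s5$table$rep, c("QD", "QE", "HZ"))

  # assignment with no counterpart in the model -> unmapped, not fatal
  w <- fx_world(12, 3)
  drop1 <- which(w$truth$resno == 2 & w$truth$atom == "HA")[1]
  cf_missing <- w$truth[-drop1, ]
  class(cf_missing) <- class(w$truth)
  s6 <- build_proton_sites(cf_missing, w$shifts)
  expect_true(any(grepl("\\.2\\.HA$", s6$unmapped)))
})

test_that("summation distances match the closed-form r^-6 oracle", {
  # sites: three protons on a line at x = 0, 3, 3 (two singletons + pair)
  cf1 <- new_tiny_conformer(data.frame(
    resno = c(1, 5, 5), resname = c("ALA", "GLY", "GLY"),
    atom = c("HA", "HA2", "HA3"),
    x = c(0, 3, 3), y = c(0, 0, 0.001), z = 0))
  sh <- rpfdp:::new_shift_table(data.frame(
    chain = "A", resno = c(1, 5, 5), resname = c("ALA", "GLY", "GLY"),
    atom = c("HA", "HA2", "HA3"), shift = c(4.1, 3.9, 3.9),
    ambiguity = 1L, stringsAsFactors = FALSE))
  sites <- build_proton_sites(cf1, sh)     # singleton + merged Gly pair
  expect_equal(rpfdp:::n_sites(sites), 2L)
  d <- summation_distance(sites, 1, 2, cf1)
  # oracle: two members both ~3.0 A from the singleton
  expect_equal(d, (2 * 3^-6)^(-1 / 6), tolerance = 1e-4)
  expect_equal(summation_distance(sites, 2, 1, cf1), d)  # symmetric
  expect_lt(d, 3.0001)                      # never exceeds min pair distance

  # ensemble averaging: pair at 3 A and 5 A in two conformers
  cf_a <- new_tiny_conformer(data.frame(resno = c(1, 5), resname = c("ALA", "ALA"),
                                        atom = c("HA", "HA"), x = c(0, 3), y = 0, z = 0))
  cf_b <- cf_a; cf_b$x[2] <- 5
  sh2 <- rpfdp:::new_shift_table(data.frame(
    chain = "A", resno = c(1, 5), resname = "ALA", atom = "HA",
    shift = c(4.1, 4.3), ambiguity = 1L, stringsAsFactors = FALSE))
  sites2 <- build_proton_sites(cf_a, sh2)
  dens <- summation_distance(sites2, 1, 2, rpfdp:::new_ensemble(list(cf_a, cf_b)))
  expect_equal(dens, ((3^-6 + 5^-6) / 2)^(-1 / 6), tolerance = 1e-9)
  # single conformer, singletons: Euclidean to 1e-9
  expect_equal(summation_distance(sites2, 1, 2, cf_a), 3, tolerance = 1e-9)
  expect_error(summation_distance(sites2, 1, 1, cf_a), "disjoint")
})

test_that("distance graph contains all and only pairs within d_max", {
  cf <- new_tiny_conformer(data.frame(
    resno = c(1, 5, 9), resname = "ALA", atom = "HA",
    x = c(0, 4, 8), y = 0, z = 0))
  sh <- rpfdp:::new_shift_table(data.frame(
    chain = "A", resno = c(1, 5, 9), resname = "ALA", atom = "HA",
    shift = c(4.1, 4.2, 4.3), ambiguity = 1L, stringsAsFactors = FALSE))
  sites <- build_proton_sites(cf, sh)
  gr <- build_distance_graph(sites, cf, d_max = 5)
  expect_equal(nrow(gr$edges), 2L)
  expect_setequal(paste(gr$edges$i, gr$edges$j), c("1 2", "2 3"))
  expect_equal(nrow(build_distance_graph(sites, cf, d_max = 0.1)$edges), 0L)
  expect_error(build_distance_graph(sites, cf, d_max = -1), "positive")
})

test_that("graph edges equal a brute-force all-pairs oracle; cutoff is monotone", {
  w <- fx_world(12, 3)
  sh <- w$shifts[w$shifts$resno <= 6 & grepl("^H", w$shifts$atom), ]
  class(sh) <- class(w$shifts)
  sites <- build_proton_sites(w$truth, sh)
  gr5 <- build_distance_graph(sites, w$truth, d_max = 5)
  # brute force via summation_distance on raw coordinates
  ns <- rpfdp:::n_sites(sites)
  brute <- character(0)
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    if (suppressWarnings(summation_distance(sites, i, j, w$truth)) <= 5)
      brute <- c(brute, paste(i, j))
  }
  expect_setequal(paste(gr5$edges$i, gr5$edges$j), brute)
  gr7 <- build_distance_graph(sites, w$truth, d_max = 7)
  expect_true(all(paste(gr5$edges$i, gr5$edges$j) %in%
                    paste(gr7$edges$i, gr7$edges$j)))
})
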