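# I/O: PDB coordinates, shift tables (TSV + NMR-STAR), peak lists (XEASY,
# Sparky, TSV), RDC tables, contact lists.

test_that("PDB write/read round-trips single conformers and ensembles", {
  w <- fx_world(12, 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(w$truth, f)
  ens <- read_coordinates(f)
  expect_length(ens, 1L)
  expect_equal(nrow(ens[[1]]), nrow(w$truth))
  expect_equal(ens[[1]]$atom, w$truth$atom)
  expect_equal(ens[[1]]$x, w$truth$x, tolerance = 1e-3)

  # 5-model ensemble
  cfg <- w$cfg
  ens5 <- make_jittered_ensemble(w$truth, cfg, n = 5, level = 0.5)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens5, f2)
  back <- read_coordinates(f2)
  expect_length(back, 5L)
  expect_true(all(vapply(back, nrow, 1L) == nrow(back[[1]])))
  one <- read_coordinates(f2, model_index = 3)
  expect_length(one, 1L)
  expect_equal(one[[1]]$x, back[[3]]$x)
  expect_error(read_coordinates(f2, model_index = 9), "absent")
})

test_that("PDB reader resolves altlocs, normalizes H names, rejects junk", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   9.000   9.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      4 1HB  ALA A   1       2.000   1.000   0.000  1.00  0.00           H",
    "HETATM    5  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  cf <- read_coordinates(f)[[1]]
  expect_equal(nrow(cf), 3L)                        # one N survives, water dropped
  expect_equal(cf$x[cf$atom == "N"], 9.0)           # higher occupancy altloc B
  expect_true("HB1" %in% cf$atom)                   # 1HB -> HB1

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f2)
  expect_error(read_coordinates(f2), "no protein atoms")
  expect_error(read_coordinates(file.path(tempdir(), "nope.pdb")),
               class = "rpfdp_data_error")
})

test_that("ensembles with mismatched atom sets raise a named warning", {
  w <- fx_world(12, 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  cf2 <- w$truth[-5, ]
  class(cf2) <- class(w$truth)
  write_pdb(rpfdp:::new_ensemble(list(w$truth, cf2)), f)
  expect_warning(read_coordinates(f), class = "rpfdp_warning_ensemble_mismatch")
})

test_that("shift TSV round-trips; duplicates collapse; conflicts reject", {
  w <- fx_world(12, 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_shift_table(w$shifts, f)
  back <- read_shift_table(f, dialect = "tsv")
  expect_equal(as.data.frame(back), as.data.frame(w$shifts))

  df <- data.frame(chain = "A", resno = 15L, resname = "ALA",
                   atom = c("HB1", "HB2", "HB3", "HB1"),
                   shift = c(1.39, 1.39, 1.39, 1.39), ambiguity = 1L)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  sh <- read_shift_table(f2)
  expect_equal(nrow(sh), 3L)       # exact duplicate collapsed
  sites <- sites_from_shifts(sh)   # one methyl pseudoatom
  expect_equal(rpfdp:::n_sites(sites), 1L)
  expect_equal(sites$table$rep, "QB")
  expect_equal(sites$table$n_members, 3L)

  df$shift[4] <- 1.99
  utils::write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_shift_table(f2), "conflicting")

  df$resname <- "XYZ"
  utils::write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_shift_table(f2), class = "rpfdp_unknown_residue")
})

test_that("minimal NMR-STAR shift loop is parsed with ambiguity codes", {
  star <- c(
    "data_synth", "save_assigned_chemical_shifts", "loop_",
    "_Atom_chem_shift.ID", "_Atom_chem_shift.Comp_index_ID",
    "_Atom_chem_shift.Comp_ID", "_Atom_chem_shift.Atom_ID",
    "_Atom_chem_shift.Val", "_Atom_chem_shift.Ambiguity_code",
    "1 5 LEU HD11 0.85 2", "2 5 LEU HD21 0.85 2", "3 5 LEU H 8.11 1",
    "4 6 ALA HB1 1.39 1",
    "stop_", "save_")
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(star, f)
  sh <- read_shift_table(f)                       # dialect sniffed
  # hand-parsed reference for the same fixture
  expect_equal(nrow(sh), 4L)
  expect_equal(sh$ambiguity[sh$atom == "HD11"], 2L)
  expect_equal(sh$ambiguity[sh$atom == "H"], 1L)
  expect_equal(sh$shift[sh$atom == "HB1"], 1.39)
  expect_equal(sh$resname, c("LEU", "LEU", "LEU", "ALA"))
})

test_that("Sparky, XEASY and TSV peak dialects parse; errors are typed", {
  sp <- c("      Assignment        w1        w2    Height",
          sprintf("         ?-?  %8.3f  %8.3f  %8.1f", seq(7.1, 7.7, 0.1),
                  seq(1.1, 1.7, 0.1), 100 * 1:7))
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(sp, f)
  pl <- read_peaklist(f, dim_types = c("H_indirect", "H_acq"))
  expect_s3_class(pl, "peak_list")
  expect_equal(rpfdp:::n_peaks(pl), 7L)
  expect_equal(pl$positions[3, ], c(7.3, 1.3), ignore_attr = TRUE)
  expect_equal(pl$intensity[7], 700)
  expect_error(read_peaklist(f, dim_types = c("H_indirect", "C_edit", "H_acq")),
               "mismatch")

  xe <- c("# Number of dimensions 3", "#INAME 1 H", "#INAME 2 C", "#INAME 3 HN",
          " 1  4.321 56.70  8.210 1 U 1.20e+05 0.00e+00 e 0 101 102 103",
          " 2  1.390 19.20  8.110 1 U 3.00e+04 0.00e+00 e 0 0 0 0")
  f2 <- withr::local_tempfile(fileext = ".peaks")
  writeLines(xe, f2)
  px <- read_peaklist(f2)                          # dialect + types sniffed
  expect_equal(px$dim_types, c("H_indirect", "C_edit", "H_acq"))
  expect_equal(px$positions[1, 2], 56.70)
  expect_equal(px$intensity[2], 3e4)

  # empty peak section is a valid (empty) list
  writeLines(c("# Number of dimensions 2", "#INAME 1 H", "#INAME 2 HN"), f2)
  expect_equal(rpfdp:::n_peaks(read_peaklist(f2)), 0L)

  # TSV round trip is lossless
  w <- fx_world(12, 3)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_peaklist(w$peaks, f3)
  back <- read_peaklist(f3)
  expect_identical(back$positions, w$peaks$positions, ignore_attr = TRUE)
  expect_equal(back$dim_types, w$peaks$dim_types)
  expect_equal(back$intensity, w$peaks$intensity)

  # xeasy writer/reader keep ids and positions (3 decimals)
  f4 <- withr::local_tempfile(fileext = ".peaks")
  write_peaklist(w$peaks, f4, dialect = "xeasy")
  bx <- read_peaklist(f4)
  expect_equal(bx$peak_id, w$peaks$peak_id)
  expect_equal(bx$positions, w$peaks$positions, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("RDC tables round-trip and enforce invariants", {
  w <- fx_world(12, 3)
  rd <- make_rdcs(w$truth, noise = 0.5, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rdc_table(rd, f)
  back <- read_rdc_table(f)
  expect_equal(as.data.frame(back), as.data.frame(rd))

  bad <- as.data.frame(rd)
  bad$weight[1] <- 0
  expect_error(rpfdp:::new_rdc_table(bad), "positive")
  bad2 <- as.data.frame(rd)
  bad2$atom_b[1] <- bad2$atom_a[1]
  expect_error(rpfdp:::new_rdc_table(bad2), "identical atoms")
})

test_that("contact lists: expansion, stable ordering, exact round-trip", {
  sh <- rpfdp:::new_shift_table(data.frame(
    chain = "A", resno = c(15L, 3L, 7L), resname = c("ARG", "LYS", "GLU"),
    atom = c("H", "HA", "HA"), shift = c(8.21, 3.40, 3.43), ambiguity = 1L,
    stringsAsFactors = FALSE))
  pl <- rpfdp:::new_peak_list(1L, matrix(c(8.20, 3.41), 1, 2),
                              c("H_indirect", "H_acq"))
  ct <- generate_contacts(pl, sh, match_tolerance(0.03, 0.4, 0.4))
  expect_equal(nrow(ct), 2L)                       # 1 peak, 2 candidates
  expect_equal(unique(ct$peak_id), 1L)
  # ranked by shift mismatch: K3 HA (0.01+0.01) before E7 HA (0.01+0.02)
  r1 <- ct[ct$candidate_rank == 1, ]
  expect_true(any(grepl("3\\.LYS\\.HA", c(r1$atom_a, r1$atom_b))))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_list(ct, f)
  back <- read_contact_list(f)
  expect_equal(as.data.frame(back), as.data.frame(ct))
  # rewrite of the read-back table is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_contact_list(back, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_error(write_contact_list(ct[0, ], f), "empty")
})
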