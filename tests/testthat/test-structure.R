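# structure container, file round-trips, residue classification and scalar
# sequence/crystal-form properties

test_that("synthetic structures survive a PDB write/read round trip", {
  toy <- make_toy_structure(toy_structure_spec(seed = 3))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$structure, path)
  back <- read_structure(path)
  expect_identical(back$atoms$name, toy$structure$atoms$name)
  expect_identical(back$atoms$res_name, toy$structure$atoms$res_name)
  expect_identical(back$atoms$res_seq, toy$structure$atoms$res_seq)
  expect_identical(back$atoms$is_hetero, toy$structure$atoms$is_hetero)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(toy$structure$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # classification survives the round trip too
  expect_identical(residue_table(back)$class, residue_table(toy$structure)$class)
})

test_that("reading rejects empty or unparseable files", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(read_structure(empty), "empty|parse")
  expect_error(read_structure("/no/such/file.pdb"), "not found")
})

test_that("HELIX/SHEET records populate per-residue labels and the rest default to other", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HELIX    1   1 ALA A    1  ALA A    2  1",
    "SHEET    1   A 1 GLY A   3  GLY A   3  0",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   4      11.400   0.000   0.000  1.00  0.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(unname(ss_labels(s)), c("H", "H", "E", "other"))
})

test_that("altloc resolution keeps the highest-occupancy conformer, ties to A", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       8.000   0.000   0.000  0.50  0.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 9)   # higher occupancy
  expect_equal(s$atoms$x[s$atoms$name == "CB"], 1)   # tie -> altloc A
})

test_that("residue classification matches a per-letter tally and is order invariant", {
  set.seed(42)
  letters1 <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                       "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                     100, replace = TRUE)
  seqstr <- paste(letters1, collapse = "")
  cl <- classify_residues(seqstr)
  tally <- table(letters1)
  cnt <- function(set) sum(tally[names(tally) %in% set])
  sch <- residue_class_scheme()
  expect_equal(unname(cl$counts["proline"]), cnt(sch$proline))
  expect_equal(unname(cl$counts["charged"]), cnt(sch$charged))
  expect_equal(unname(cl$counts["polar"]), cnt(sch$polar))
  expect_equal(unname(cl$counts["hydrophobic"]), cnt(sch$hydrophobic))
  expect_equal(cl$denominator, 100L)
  # reordering the sequence changes nothing
  cl2 <- classify_residues(paste(rev(letters1), collapse = ""))
  expect_equal(cl2$counts, cl$counts)
  # each category is bounded by the sequence length
  expect_true(all(cl$counts <= 100))
})

test_that("empty sequences yield zero counts and unknown codes error in strict mode", {
  cl <- classify_residues("")
  expect_true(all(cl$counts == 0))
  expect_error(classify_residues("AXA"), "unknown residue")
  expect_warning(cl3 <- classify_residues("AXA", strict = FALSE), "other")
  expect_equal(unname(cl3$counts["other"]), 1L)
})

test_that("Matthews coefficient and solvent content follow the cell-volume arithmetic", {
  # orthorhombic oracle: V = 1e6 A^3, z*mass = 2e5 -> V_M = 5, solvent 75.4%
  ms <- matthews_and_solvent(100, 100, 100, z = 1, mass = 2e5)
  expect_equal(ms$v_m, 5.0)
  expect_equal(ms$solvent_pct, 75.4)
  # clamp boundary
  expect_warning(z <- solvent_from_vm(1.0), "clamped")
  expect_equal(z$solvent_pct, 0)
  expect_equal(solvent_from_vm(1.23)$solvent_pct, 0)
  # doubling mass halves V_M exactly
  ms2 <- matthews_and_solvent(100, 100, 100, z = 1, mass = 4e5)
  expect_equal(ms2$v_m, ms$v_m / 2)
  # solvent strictly increasing in V_M above the clamp
  vms <- seq(1.3, 5, by = 0.1)
  sp <- vapply(vms, function(v) solvent_from_vm(v)$solvent_pct, numeric(1))
  expect_true(all(diff(sp) > 0))
  # triclinic cell volume agrees with the determinant formula
  ang <- c(80, 95, 102) * pi / 180
  G <- matrix(c(50^2, 50 * 60 * cos(ang[3]), 50 * 70 * cos(ang[2]),
                50 * 60 * cos(ang[3]), 60^2, 60 * 70 * cos(ang[1]),
                50 * 70 * cos(ang[2]), 60 * 70 * cos(ang[1]), 70^2), 3)
  vol <- sqrt(det(G))
  mt <- matthews_and_solvent(50, 60, 70, 80, 95, 102, z = 2, mass = 3e4)
  expect_equal(mt$v_m, vol / (2 * 3e4), tolerance = 1e-12)
})

test_that("extinction coefficients follow the Trp/Tyr/cystine formula", {
  expect_equal(extinction_coefficient(strrep("A", 20)), 0)
  expect_equal(extinction_coefficient("WWYY"), 2 * 5500 + 2 * 1490)
  expect_equal(extinction_coefficient("WCCW", cystine_mode = "oxidized"),
               2 * 5500 + 125)
  expect_equal(extinction_coefficient("WCCW"), 2 * 5500)  # reduced default
  expect_error(sequence_record("ABZ"), "non-standard")
})
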