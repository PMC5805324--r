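# interaction detection under geometric criteria, profiles and scaled
# comparison tables

toy <- make_toy_structure(toy_structure_spec(seed = 5))

test_that("planted interactions are recovered exactly and decoys rejected", {
  ints <- detect_interactions(toy$structure)
  man <- toy$manifest
  counts <- table(factor(ints$kind, levels = names(man$counts)))
  expect_equal(as.integer(counts), unname(unlist(man$counts)),
               ignore_attr = TRUE)
  # every planted salt bridge appears as a detected ionic residue pair
  ionic <- ints[ints$kind == "ionic", ]
  pair_of <- function(x) paste(pmin(x$res1, x$res2), pmax(x$res1, x$res2))
  planted <- vapply(man$ionic, function(b)
    paste(min(b$res1, b$res2), max(b$res1, b$res2)), character(1))
  expect_setequal(pair_of(ionic), planted)
  # decoys generate no record in any class
  decoy_res <- unlist(lapply(man$ionic_decoys, function(b) c(b$res1, b$res2)))
  expect_false(any(ints$res1 %in% decoy_res | ints$res2 %in% decoy_res))
})

test_that("detection agrees with an exhaustive pair-scan oracle", {
  sm <- make_toy_structure(toy_structure_spec(
    n_salt_bridges = 3, n_salt_decoys = 2, n_hbonds = 2, n_hbond_decoys = 1,
    n_weak_hbonds = 2, n_weak_decoys = 2, n_hydrophobic = 3,
    n_hydrophobic_decoys = 1, n_aromatic = 2, n_aromatic_decoys = 1,
    zinc = TRUE, ligand = FALSE, cleft_inside = 0, cleft_outside = 0,
    seed = 9))
  got <- detect_interactions(sm$structure)
  want <- oracle_interaction_counts(sm$structure)
  for (k in names(want))
    expect_equal(sum(got$kind == k), unname(want[k]), label = k)
})

test_that("weak hydrogen bonds require the 3.6-3.9 A window and 90-130 deg angle", {
  ints <- detect_interactions(toy$structure)
  wk <- ints[ints$kind == "weak_hbond", ]
  expect_true(all(wk$distance >= 3.6 & wk$distance <= 3.9))
  expect_true(all(wk$angle > 90 & wk$angle < 130))
  # widening the window to start lower picks up the short decoys
  crit2 <- interaction_criteria(weak_dmin = 3.0)
  wk2 <- detect_interactions(toy$structure, crit2)
  expect_gte(sum(wk2$kind == "weak_hbond"), nrow(wk))
})

test_that("counts are monotone in the distance cut-offs", {
  base <- detect_interactions(toy$structure)
  for (arg in c("hbond_dmax", "ionic_dmax", "hydrophobic_dmax",
                "aromatic_dmax")) {
    cr <- do.call(interaction_criteria, setNames(list(5.0), arg))
    more <- detect_interactions(toy$structure, cr)
    kinds <- c(hbond_dmax = "hbond", ionic_dmax = "ionic",
               hydrophobic_dmax = "hydrophobic", aromatic_dmax = "aromatic")
    expect_gte(sum(more$kind == kinds[[arg]]), sum(base$kind == kinds[[arg]]))
  }
})

test_that("interaction sets are invariant under rigid motion", {
  moved <- rigid_motion(toy$structure)
  i1 <- detect_interactions(toy$structure)
  i2 <- detect_interactions(moved)
  ord <- function(x) x[order(x$kind, x$res1, x$atom1, x$res2, x$atom2), ]
  a <- ord(i1); b <- ord(i2)
  expect_equal(a$kind, b$kind)
  expect_equal(a$res1, b$res1)
  expect_equal(a$distance, b$distance, tolerance = 1e-9)
})

test_that("atoms beyond every cut-off produce no interaction", {
  atoms <- data.frame(
    serial = 1:2, name = c("OE1", "NZ"), element = c("O", "N"),
    altloc = "", res_name = c("GLU", "LYS"), chain = "A",
    res_seq = c(1L, 5L), icode = "", x = c(0, 5), y = 0, z = 0,
    occupancy = 1, b_factor = 0, is_hetero = FALSE)
  s <- new_structure(atoms)
  expect_equal(nrow(detect_interactions(s)), 0L)
})

test_that("profile densities and category percentages use the right denominators", {
  p <- structure_profile_from_counts(c(hbond = 741), n_resolved = 647)
  expect_equal(unname(p$relative["hbond"]), 741 / 647)
  expect_equal(round(unname(p$relative["hbond"]), 3), 1.145)
  # helix/sheet percentages from planted ss labels
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- c("HELIX    1   1 ALA A    1  ALA A    6  1",
             "SHEET    1   A 1 ALA A   7  ALA A  10  0",
             vapply(1:20, function(i) sprintf(
               "ATOM    %3d  CA  ALA A %3d    %8.3f   0.000   0.000  1.00  0.00           C",
               i, i, i * 8.0), character(1)), "END")
  writeLines(lines, path)
  s <- read_structure(path)
  pr <- structure_profile(s, name = "toy20")
  expect_equal(unname(pr$relative["helix"]), 30)
  expect_equal(unname(pr$relative["sheet"]), 20)
  expect_equal(pr$n_resolved, 20L)
  # full-length denominator rescales residue categories only
  pr2 <- structure_profile(s, denominator = "full_length", full_length = 40)
  expect_equal(unname(pr2$relative["helix"]), 15)
  expect_equal(unname(pr2$relative["hbond"]), unname(pr$relative["hbond"]))
})

test_that("zero interactions give all-zero densities", {
  atoms <- data.frame(
    serial = 1:3, name = "CA", element = "C", altloc = "",
    res_name = "GLY", chain = "A", res_seq = 1:3 * 2L, icode = "",
    x = c(0, 30, 60), y = 0, z = 0, occupancy = 1, b_factor = 0,
    is_hetero = FALSE)
  p <- structure_profile(new_structure(atoms))
  expect_true(all(p$relative[c("hbond", "weak_hbond", "ionic",
                               "hydrophobic", "aromatic")] == 0))
})

test_that("scaled comparison maps the larger relative value to 100", {
  p1 <- structure_profile_from_counts(c(helix = 374, weak_hbond = 502), 647,
                                      name = "meso")
  p2 <- structure_profile_from_counts(c(helix = 332, weak_hbond = 431), 524,
                                      name = "thermo")
  tab <- compare_profiles(p1, p2)
  helix <- tab[tab$category == "helix", ]
  expect_lte(abs(helix$rel1 - 57.80), 0.01)
  expect_equal(round(helix$rel2, 2), 63.36)
  expect_equal(round(helix$scaled1, 1), 91.2)
  expect_equal(helix$scaled2, 100)
  weak <- tab[tab$category == "weak_hbond", ]
  expect_equal(round(weak$scaled1, 1), 94.3)
  # identical profiles scale to (100, 100) everywhere
  tab2 <- compare_profiles(p1, p1)
  expect_true(all(tab2$scaled1 == 100 & tab2$scaled2 == 100))
  # swapping arguments swaps columns
  tab3 <- compare_profiles(p2, p1)
  expect_equal(tab3$scaled1, tab$scaled2)
  expect_equal(tab3$scaled2, tab$scaled1)
  # per-row maximum is always 100 and ratios are preserved
  expect_true(all(pmax(tab$scaled1, tab$scaled2) == 100))
  expect_equal(tab$scaled1 / tab$scaled2, tab$rel1 / tab$rel2)
  # mismatched categories are an error
  expect_error(compare_profiles(
    p1, structure_profile_from_counts(c(helix = 1), 10)), "categories")
})

test_that("the comparison TSV mirrors the published column layout", {
  p1 <- structure_profile_from_counts(c(helix = 374), 647, name = "a")
  p2 <- structure_profile_from_counts(c(helix = 332), 524, name = "b")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_comparison_tsv(compare_profiles(p1, p2), path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(hdr, c("Category", "Abs.", "Rel. (%)", "Abs.", "Rel. (%)",
                      "Scaled (%)", "Scaled (%)"))
})
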