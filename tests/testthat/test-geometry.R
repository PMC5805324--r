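# static geometry: distances, gyration radius, superposition, conformers,
# ligand contacts, zinc site

toy <- make_toy_structure(toy_structure_spec(seed = 2))

test_that("domain distances reproduce the planted marker geometry", {
  dd <- domain_distances(toy$structure)
  expect_equal(unname(dd["d1"]), 22.6, tolerance = 1e-9)
  expect_equal(unname(dd["d2"]), 18, tolerance = 1e-9)
  # triangle inequality with the 142-330 distance
  d13 <- domain_distances(toy$structure, pairs = list(c(142, 330)))
  expect_lte(dd["d1"], dd["d2"] + d13)
  # identical selectors give zero, missing CA errors
  expect_equal(unname(domain_distances(toy$structure,
                                       pairs = list(c(142, 142)))), 0)
  expect_error(domain_distances(toy$structure, pairs = list(c(142, 999))),
               "residue 999")
  # Pythagoras on a constructed pair
  atoms <- data.frame(serial = 1:2, name = "CA", element = "C", altloc = "",
                      res_name = "GLY", chain = "A", res_seq = c(1L, 3L),
                      icode = "", x = c(0, 3), y = c(0, 4), z = 0,
                      occupancy = 1, b_factor = 0, is_hetero = FALSE)
  expect_equal(unname(domain_distances(new_structure(atoms),
                                       pairs = list(c(1, 3)))), 5)
})

test_that("radius of gyration matches the definition", {
  expect_equal(radius_of_gyration(rbind(c(1, 2, 3))), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  set.seed(13)
  pts <- matrix(rnorm(300), 100)
  ctr <- colMeans(pts)
  oracle <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
  expect_equal(radius_of_gyration(pts), oracle, tolerance = 1e-9)
  # mass weighting shifts the centroid
  m <- c(3, 1)
  two <- rbind(c(0, 0, 0), c(4, 0, 0))
  ctrm <- c(1, 0, 0)
  expect_equal(radius_of_gyration(two, m),
               sqrt((3 * 1 + 1 * 9) / 4), tolerance = 1e-12)
  expect_error(radius_of_gyration(matrix(0, 0, 3)), "empty")
})

test_that("Kabsch superposition recovers constructed rigid motions", {
  set.seed(7)
  A <- matrix(rnorm(45), 15)
  expect_equal(superpose_rmsd(A, A)$rmsd, 0, tolerance = 1e-12)
  expect_equal(superpose_rmsd(A, A)$rotation, diag(3), tolerance = 1e-8)
  # 90 deg rotation about z plus translation
  R90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  B <- A %*% t(R90) + matrix(c(3, -1, 2), 15, 3, byrow = TRUE)
  fit <- superpose_rmsd(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # symmetric in its arguments and cross-checked against bio3d
  expect_equal(superpose_rmsd(B, A)$rmsd, fit$rmsd, tolerance = 1e-9)
  noisy <- B + matrix(rnorm(45, sd = 0.3), 15)
  ours <- superpose_rmsd(A, noisy)$rmsd
  ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(noisy)), fit = TRUE)
  expect_equal(round(ours, 3), ref)  # bio3d reports rmsd to 3 decimals
  # degenerate input errors
  line <- cbind(1:5, 0, 0)
  expect_error(superpose_rmsd(line, line), "degenerate")
  expect_error(superpose_rmsd(A[1:2, ], A[1:2, ]), "at least 3")
})

test_that("conformer classification assigns the nearest reference within tolerance", {
  sch <- conformer_scheme(c("WT_E", "WT_c", "WT_o"),
                          d1 = c(22.6, 15.4, 23.5), d2 = c(18, 14, 21),
                          tolerance = 1)
  expect_equal(classify_conformer(c(d1 = 22.6, d2 = 18), sch), "WT_E")
  expect_equal(classify_conformer(c(d1 = 30, d2 = 30), sch), "unassigned")
  # idempotent / deterministic
  snap <- c(d1 = 15.0, d2 = 14.2)
  expect_equal(classify_conformer(snap, sch), classify_conformer(snap, sch))
  # tie broken by scheme order
  tie <- conformer_scheme(c("first", "second"), d1 = c(10, 12),
                          d2 = c(10, 10), tolerance = 2)
  expect_equal(classify_conformer(c(d1 = 11, d2 = 10), tie), "first")
  expect_error(conformer_scheme(c("x", "x"), 1:2, 1:2), "unique")
})

test_that("ligand polar contacts match the planted contact set", {
  lc <- ligand_polar_contacts(toy$structure, ligand = c(801, 802))
  expect_equal(nrow(lc), 4L)
  expect_equal(lc$distance, c(2.7, 2.8, 2.8, 3.1), tolerance = 1e-9)
  expect_setequal(lc$partner_name, c("ARG", "LYS", "LEU"))
  expect_equal(sum(lc$partner_name == "ARG"), 2L)
  # the 3.6 A decoy appears only when the cut-off admits it
  lc2 <- ligand_polar_contacts(toy$structure, ligand = c(801, 802),
                               dmax = 3.7)
  expect_equal(nrow(lc2), 5L)
  expect_true("SER" %in% lc2$partner_name)
  expect_error(ligand_polar_contacts(toy$structure, ligand = 999),
               "matches no atoms")
})

test_that("the zinc site reports coordination number and carboxylate denticity", {
  zs <- zinc_site(toy$structure)
  man <- toy$manifest$zinc
  expect_equal(zs$coordination_number, man$expected_cn)
  expect_equal(unname(zs$denticity[man$glu]), "bi")
  expect_equal(zs$n_water, 1L)
  expect_false(man$decoy_water %in% zs$ligands$res)
  # tightening the cut-off drops the longest ligand (mono denticity)
  zs2 <- zinc_site(toy$structure, cutoff = 2.2)
  expect_lt(zs2$coordination_number, zs$coordination_number)
  expect_equal(unname(zs2$denticity[man$glu]), "mono")
  # degenerate cut-off
  expect_equal(zinc_site(toy$structure, cutoff = 0.1)$coordination_number, 0L)
  # structures without zinc error
  nozn <- make_toy_structure(toy_structure_spec(zinc = FALSE, seed = 2))
  expect_error(zinc_site(nozn$structure), "no zinc")
})

test_that("geometry is invariant under rigid motion", {
  moved <- rigid_motion(toy$structure, angle = 63, axis = c(2, -1, 1),
                        shift = c(-4, 9, 12))
  expect_equal(domain_distances(moved), domain_distances(toy$structure),
               tolerance = 1e-9)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(toy$structure),
               tolerance = 1e-9)
  expect_equal(zinc_site(moved)$coordination_number,
               zinc_site(toy$structure)$coordination_number)
  expect_equal(zinc_site(moved)$denticity, zinc_site(toy$structure)$denticity)
})
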