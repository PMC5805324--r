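# trajectory analytics against generator ground truth

tr <- make_breathing_trajectory(trajectory_spec(seed = 7))
traj <- tr$trajectory
man <- tr$manifest

test_that("geometry traces realise the planted d1 schedule", {
  gt <- geometry_trace(traj)
  expect_equal(gt$d1, man$d1, tolerance = 1e-9)
  expect_equal(gt$d2, man$d2, tolerance = 1e-9)
  # sinusoidal schedule: extremes recovered within 0.1 A
  sine <- make_breathing_trajectory(trajectory_spec(
    n_frames = 100,
    d1_series = 16.5 + 5.5 * sin(seq(0, 4 * pi, length.out = 100)),
    seed = 7))
  gts <- geometry_trace(sine$trajectory)
  expect_lt(abs(min(gts$d1) - 11), 0.1)
  expect_lt(abs(max(gts$d1) - 22), 0.1)
  # a single-frame trajectory equals the static geometry
  toy <- make_toy_structure(toy_structure_spec(seed = 7))
  t1 <- trajectory(toy$structure)
  g1 <- geometry_trace(t1)
  expect_equal(c(g1$d1, g1$d2),
               unname(domain_distances(toy$structure)), tolerance = 1e-12)
  # constant coordinates give zero variance
  tc <- trajectory(toy$structure,
                   frames = rep(list(as.matrix(
                     toy$structure$atoms[, c("x", "y", "z")])), 5))
  gc_ <- geometry_trace(tc)
  expect_equal(var(gc_$d1), 0)
  expect_equal(var(gc_$rg), 0)
})

test_that("hydrogen-bond populations equal the planted occupancies", {
  hb <- hbond_populations(traj, ligand = c(801, 802))
  # per-residue sums: Arg bonds at 100% + 100% -> 200%
  arg <- hb$population[hb$res_name == "ARG" & hb$role == "donor"]
  expect_equal(arg, 200)
  lys <- hb$population[hb$res_name == "LYS" & hb$role == "donor"]
  expect_equal(lys, 60)
  leu <- hb$population[hb$res_name == "LEU" & hb$role == "acceptor"]
  expect_equal(leu, 40)
  expect_equal(attr(hb, "angle_definition"), "heavy_atom_antecedent")
  # per-bond detail matches the manifest frame counts exactly
  bonds <- attr(hb, "bonds")
  expect_setequal(round(bonds$population * man$n_frames / 100),
                  man$hbonds$frames_present)
  # 40% occupancy reported as 40.0 at one decimal
  expect_equal(sprintf("%.1f", leu), "40.0")
})

test_that("population bookkeeping conserves bond-frames at threshold zero", {
  hb <- hbond_populations(traj, ligand = c(801, 802), threshold = 0)
  bonds <- attr(hb, "bonds")
  total_bond_frames <- sum(bonds$population) * man$n_frames / 100
  expect_equal(total_bond_frames, sum(man$hbonds$frames_present),
               tolerance = 1e-9)
  # aggregation preserves the total (each bond has exactly one protein side)
  expect_equal(sum(hb$population), sum(bonds$population), tolerance = 1e-9)
})

test_that("populations are invariant under frame reordering", {
  set.seed(3)
  perm <- sample(n_frames(traj))
  tr2 <- trajectory(traj$topology, frames = traj$frames[perm])
  hb1 <- hbond_populations(traj, ligand = c(801, 802))
  hb2 <- hbond_populations(tr2, ligand = c(801, 802))
  expect_equal(hb1, hb2, ignore_attr = TRUE)
})

test_that("zinc dynamics recover the denticity switch frame", {
  zd <- zinc_dynamics(traj)
  glu <- man$base$zinc$glu
  states <- zd$denticity$state[zd$denticity$residue == glu]
  sw <- man$denticity_switch_frame
  expect_equal(states, c(rep("bi", sw), rep("mono", man$n_frames - sw)))
  fr <- zd$summary
  expect_equal(fr$fraction[fr$residue == glu & fr$state == "bi"],
               sw / man$n_frames)
  # degenerate cut-off: empty shell in every frame
  zd0 <- zinc_dynamics(traj, cutoff = 1e-6)
  expect_true(all(zd0$series$cn == 0))
  # repeated static frames give a constant coordination number
  toy <- make_toy_structure(toy_structure_spec(seed = 4))
  tc <- trajectory(toy$structure,
                   frames = rep(list(as.matrix(
                     toy$structure$atoms[, c("x", "y", "z")])), 4))
  expect_equal(length(unique(zinc_dynamics(tc)$series$cn)), 1L)
})

test_that("water residence counts match the planted schedule and filter", {
  wr <- water_residence(traj, min_frames = 20)
  planted <- man$zinc_water_frames
  got <- setNames(wr$table$frames_present, wr$table$water)
  expect_equal(got[names(planted)], planted)
  # the 200-frame omission rule on a long planted schedule
  long <- make_breathing_trajectory(trajectory_spec(
    n_frames = 1000, zinc_water_fractions = c(0.5, 0.25, 0.1), seed = 8))
  wl <- water_residence(long$trajectory, min_frames = 200)
  pl <- long$manifest$zinc_water_frames
  expect_equal(unname(pl), c(500, 250, 100))
  expect_true(all(names(pl)[pl >= 200] %in% wl$report$water))
  expect_false(names(pl)[pl < 200] %in% wl$report$water)
  # full-presence water counts every frame
  expect_equal(max(wr$table$frames_present), man$n_frames)
})

test_that("cleft-water counts and the expulsion energy follow the phase schedule", {
  cw <- cleft_waters(traj, residues = man$cleft$lining_residues,
                     radius = man$cleft$radius)
  means <- tapply(cw, man$phase, mean)
  expect_equal(unname(means["open"]), man$cleft$n_open)
  expect_equal(unname(means["closed"]), man$cleft$n_closed)
  en <- expulsion_energy(means[["open"]], means[["closed"]])
  expect_equal(unname(en), c(60, 115))
  # fixed-centre counting against a point-in-sphere oracle on one frame
  s1 <- get_frame(traj, 1)
  ctr <- man$cleft$center
  wat <- s1$atoms[s1$atoms$res_name == "HOH" & s1$atoms$element == "O", ]
  oracle <- sum(sqrt((wat$x - ctr[1])^2 + (wat$y - ctr[2])^2 +
                       (wat$z - ctr[3])^2) <= man$cleft$radius)
  expect_equal(cleft_waters(s1, centers = rbind(ctr),
                            radius = man$cleft$radius), oracle)
})

test_that("expulsion energy handles equal and inverted phase counts", {
  expect_equal(unname(expulsion_energy(40, 40)), c(0, 0))
  expect_warning(en <- expulsion_energy(40, 90), "signed")
  expect_equal(unname(en), c(-60, -115))
})

test_that("aMD boost parameters follow the linear recipe", {
  p <- amd_boost_params(-50000, 1000, n_res = 524, n_atoms = 40000)
  expect_equal(p$E_t, 1000 + 524)
  expect_equal(p$E_T, -50000 + 0.1 * 40000)
  expect_equal(p$alpha_t, 524 / 5)
  expect_equal(p$alpha_T, 4000)
  # zero boost parameters leave the means untouched
  p0 <- amd_boost_params(-100, -10, 50, 500, e_r = 0, e_a = 0)
  expect_equal(p0$E_t, -10)
  expect_equal(p0$E_T, -100)
  expect_gte(p$E_t, p$mean_dih_E)
})

test_that("interval energy summaries tile the series and reaggregate exactly", {
  series <- c(rep(-80, 50), rep(-90, 50))
  sm <- interval_energy_summary(series, 50)
  expect_equal(sm$mean, c(-80, -90))
  expect_equal(sm$sd, c(0, 0))
  expect_equal(sm$formatted[1], "-80.0 (±0.0)")
  # constant series
  smc <- interval_energy_summary(rep(-5.5, 30), 10)
  expect_true(all(smc$mean == -5.5 & smc$sd == 0))
  # weighted interval means reproduce the global mean to 1e-9
  set.seed(21)
  es <- rnorm(137, -86, 9.8)
  smr <- interval_energy_summary(es, 25)
  expect_equal(sum(smr$mean * smr$n) / sum(smr$n), mean(es),
               tolerance = 1e-9)
  expect_true(smr$partial[nrow(smr)])
  expect_false(any(smr$partial[-nrow(smr)]))
  # a series shorter than one interval is a single flagged partial
  sp <- interval_energy_summary(c(-1, -2), 10)
  expect_equal(nrow(sp), 1L)
  expect_true(sp$partial)
  expect_error(interval_energy_summary(1:10, 1), ">= 2")
})

test_that("formatted interval output follows the mean (±SD) convention", {
  sm <- interval_energy_summary(c(-96, -76, -86, -86), 4)
  expect_match(sm$formatted, "^-86.0 \\(±", all = TRUE)
})
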