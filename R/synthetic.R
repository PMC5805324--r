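# Seeded synthetic-data generators with ground-truth manifests.
#
# Toy structures are chemically minimal (backbone fragments plus the
# functional side-chain atoms an interaction class needs) and deliberately
# non-physical: planted features satisfy the default geometric criteria
# with a margin, decoys violate them with a margin, and unrelated features
# live in well-separated grid cells so they cannot interact.

#' Specification for a synthetic toy structure
#'
#' Planted feature counts and geometries for [make_toy_structure()].  Every
#' planted interaction satisfies the default [interaction_criteria()] with a
#' margin; every decoy violates them with a margin.
#'
#' @param n_salt_bridges,n_salt_decoys Glu/Arg pairs at 3.2 A (planted) and
#'   4.5 A (decoys).
#' @param n_hbonds,n_hbond_decoys backbone N-H...O pairs at 2.9 / 4.4 A.
#' @param n_weak_hbonds,n_weak_decoys C-H...O pairs at 3.75 A, 110 deg;
#'   decoys alternate below-window distance (3.3 A) and out-of-window angle
#'   (150 deg).
#' @param n_hydrophobic,n_hydrophobic_decoys apolar CB pairs at 3.6 / 4.3 A.
#' @param n_aromatic,n_aromatic_decoys stacked Phe ring pairs at 3.6 / 5.0 A.
#' @param zinc include a zinc site (2 His, 1 bidentate Glu, 1 water at
#'   2.0-2.3 A, plus a second-shell decoy water at 3.0 A)?
#' @param ligand include a bound hetero dipeptide with planted polar
#'   contacts at `ligand_contacts` and one decoy at 3.6 A?
#' @param ligand_contacts planted ligand-protein polar contact distances, A.
#' @param cleft_inside,cleft_outside waters placed inside / outside the
#'   cleft region (sphere of `cleft_radius` around the cleft centre).
#' @param cleft_radius cleft sphere radius, A.
#' @param d1,d2 planted marker distances: residues 142, 330, 404 carry CA
#'   atoms with `|CA142 - CA404| = d1` and `|CA330 - CA404| = d2`.
#' @param seed RNG seed (placement jitter).
#' @return list of class `toy_structure_spec`.
#' @export
toy_structure_spec <- function(n_salt_bridges = 7, n_salt_decoys = 4,
                               n_hbonds = 4, n_hbond_decoys = 2,
                               n_weak_hbonds = 3, n_weak_decoys = 2,
                               n_hydrophobic = 6, n_hydrophobic_decoys = 3,
                               n_aromatic = 2, n_aromatic_decoys = 1,
                               zinc = TRUE, ligand = TRUE,
                               ligand_contacts = c(2.7, 2.8, 2.8, 3.1),
                               cleft_inside = 12, cleft_outside = 8,
                               cleft_radius = 8,
                               d1 = 22.6, d2 = 18, seed = 1) {
  spec <- as.list(environment())
  class(spec) <- "toy_structure_spec"
  spec
}

# mutable builder for atom tables
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$serial <- 0L
  env$resno <- 0L
  env
}

next_resno <- function(bld) {
  repeat {
    bld$resno <- bld$resno + 2L  # gap of 2 avoids covalent-neighbour masking
    if (!bld$resno %in% c(142, 330, 404)) return(bld$resno)
  }
}

add_residue <- function(bld, res_name, names, elements, xyz, res_seq = NULL,
                        hetero = FALSE, chain = "A") {
  if (is.null(res_seq)) res_seq <- next_resno(bld)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  for (k in seq_along(names)) {
    bld$serial <- bld$serial + 1L
    bld$rows[[length(bld$rows) + 1L]] <- data.frame(
      serial = bld$serial, name = names[k], element = elements[k],
      altloc = "", res_name = res_name, chain = chain, res_seq = res_seq,
      icode = "", x = xyz[k, 1], y = xyz[k, 2], z = xyz[k, 3],
      occupancy = 1, b_factor = 0, is_hetero = hetero,
      stringsAsFactors = FALSE)
  }
  res_seq
}

build_atoms <- function(bld) do.call(rbind, bld$rows)

# deterministic sequence of well-separated cell origins (30 A grid, y >= 0)
cell_origin <- function(i) {
  c((i %% 10L) * 30, 30 + ((i %/% 10L) %% 10L) * 30, (i %/% 100L) * 30)
}

#' Generate a synthetic toy structure with a ground-truth manifest
#'
#' Builds a `cleft_structure` realising the planted features of a
#' [toy_structure_spec()] and a manifest listing every planted interaction,
#' decoy, site and marker for oracle tests.  Generation is fully
#' deterministic in the spec seed.
#'
#' @param spec a [toy_structure_spec()].
#' @return list with `structure` (a `cleft_structure`) and `manifest`.
#' @export
make_toy_structure <- function(spec = toy_structure_spec()) {
  stopifnot(inherits(spec, "toy_structure_spec"))
  with_seed(spec$seed, build_toy_structure(spec))
}

build_toy_structure <- function(spec) {
  bld <- new_builder()
  cell <- 0L
  take_cell <- function() {
    o <- cell_origin(cell) + runif(3, -0.05, 0.05)
    cell <<- cell + 1L
    o
  }
  man <- list(ionic = list(), ionic_decoys = list(), hbond = list(),
              hbond_decoys = list(), weak_hbond = list(),
              weak_hbond_decoys = list(), hydrophobic = list(),
              hydrophobic_decoys = list(), aromatic = list(),
              aromatic_decoys = list())
  key_of <- function(res) paste0("A:", res)

  salt_unit <- function(d, record) {
    o <- take_cell()
    rg <- add_residue(bld, "GLU", c("CA", "CD", "OE1", "OE2"),
                      c("C", "C", "O", "O"),
                      rbind(o + c(-1.25, 2.8, 0), o + c(-1.25, 0, 0),
                            o + c(0, 0, 0), o + c(-1.85, -1.10, 0)))
    ra <- add_residue(bld, "ARG", c("CA", "CZ", "NH1"), c("C", "C", "N"),
                      rbind(o + c(d + 2.5, 1.5, 0),
                            o + c(d - 0.665, 1.152, 0), o + c(d, 0, 0)))
    list(res1 = key_of(rg), res2 = key_of(ra), distance = d)
  }
  for (i in seq_len(spec$n_salt_bridges))
    man$ionic[[i]] <- salt_unit(3.2)
  for (i in seq_len(spec$n_salt_decoys))
    man$ionic_decoys[[i]] <- salt_unit(4.5)

  hbond_unit <- function(d) {
    o <- take_cell()
    rd <- add_residue(bld, "ALA", c("N", "CA"), c("N", "C"),
                      rbind(o + c(0, 0, 0), o + c(1.45, 0, 0)))
    ra <- add_residue(bld, "ALA", c("O", "C", "CA"), c("O", "C", "C"),
                      rbind(o + c(-d, 0, 0), o + c(-d - 1.23, 0, 0),
                            o + c(-d - 2.3, 1.2, 0)))
    list(donor_res = key_of(rd), acceptor_res = key_of(ra), distance = d)
  }
  for (i in seq_len(spec$n_hbonds)) man$hbond[[i]] <- hbond_unit(2.9)
  for (i in seq_len(spec$n_hbond_decoys))
    man$hbond_decoys[[i]] <- hbond_unit(4.4)

  weak_unit <- function(d, theta, donor_names = c("CA", "N"),
                        donor_elems = c("C", "N")) {
    o <- take_cell()
    u <- c(-cos(theta * pi / 180), sin(theta * pi / 180), 0)
    blen <- if (donor_elems[2] == "N") 1.45 else 1.52
    rd <- add_residue(bld, "GLY", donor_names, donor_elems,
                      rbind(o + c(0, 0, 0), o + blen * u))
    ra <- add_residue(bld, "ALA", c("O", "C", "CA"), c("O", "C", "C"),
                      rbind(o + c(-d, 0, 0), o + c(-d - 1.23, 0, 0),
                            o + c(-d - 2.3, 1.2, 0)))
    list(donor_res = key_of(rd), acceptor_res = key_of(ra), distance = d,
         angle = theta)
  }
  for (i in seq_len(spec$n_weak_hbonds))
    man$weak_hbond[[i]] <- weak_unit(3.75, 110)
  for (i in seq_len(spec$n_weak_decoys))
    man$weak_hbond_decoys[[i]] <- if (i %% 2 == 1)
      weak_unit(3.3, 110) else
        weak_unit(3.75, 150, donor_names = c("CA", "C"),
                  donor_elems = c("C", "C"))

  hydro_unit <- function(d) {
    o <- take_cell()
    r1 <- add_residue(bld, "ALA", c("CA", "CB"), c("C", "C"),
                      rbind(o + c(-1.53, 0, 0), o + c(0, 0, 0)))
    r2 <- add_residue(bld, "ALA", c("CB", "CA"), c("C", "C"),
                      rbind(o + c(d, 0, 0), o + c(d + 1.53, 0, 0)))
    list(res1 = key_of(r1), res2 = key_of(r2), distance = d)
  }
  for (i in seq_len(spec$n_hydrophobic))
    man$hydrophobic[[i]] <- hydro_unit(3.6)
  for (i in seq_len(spec$n_hydrophobic_decoys))
    man$hydrophobic_decoys[[i]] <- hydro_unit(4.3)

  ring_xyz <- function(o, z) {
    ang <- seq(0, 300, by = 60) * pi / 180
    cbind(o[1] + 1.39 * cos(ang), o[2] + 1.39 * sin(ang), o[3] + z)
  }
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  arom_unit <- function(dz) {
    o <- take_cell()
    r1 <- add_residue(bld, "PHE", ring_names, rep("C", 6), ring_xyz(o, 0))
    r2 <- add_residue(bld, "PHE", ring_names, rep("C", 6), ring_xyz(o, dz))
    list(res1 = key_of(r1), res2 = key_of(r2), distance = dz)
  }
  for (i in seq_len(spec$n_aromatic)) man$aromatic[[i]] <- arom_unit(3.6)
  for (i in seq_len(spec$n_aromatic_decoys))
    man$aromatic_decoys[[i]] <- arom_unit(5.0)

  if (isTRUE(spec$zinc)) {
    o <- take_cell()
    zn_res <- add_residue(bld, "ZN", "ZN", "ZN", rbind(o), res_seq = 901,
                          hetero = TRUE)
    ne_a <- o + c(2.10, 0, 0)
    ce_a <- ne_a + 1.33 * c(-0.724, 0.690, 0)  # antecedent aimed at the Glu
    h1 <- add_residue(bld, "HIS", c("NE2", "CE1"), c("N", "C"),
                      rbind(ne_a, ce_a))
    ne_b <- o + c(-2.15, 0, 0)
    ce_b <- ne_b + 1.33 * c(0.732, 0.681, 0)
    h2 <- add_residue(bld, "HIS", c("NE2", "CE1"), c("N", "C"),
                      rbind(ne_b, ce_b))
    ge <- add_residue(bld, "GLU", c("CD", "OE1", "OE2"), c("C", "O", "O"),
                      rbind(o + c(0, 2.5, 0.8), o + c(0, 2.0, 0),
                            o + c(0, 1.55, 1.70)))
    w1 <- add_residue(bld, "HOH", "O", "O", rbind(o + c(0, -2.20, 0)),
                      res_seq = 910, hetero = TRUE)
    w2 <- add_residue(bld, "HOH", "O", "O", rbind(o + c(0, 0, 3.0)),
                      res_seq = 911, hetero = TRUE)
    man$zinc <- list(zinc = key_of(901), his = c(key_of(h1), key_of(h2)),
                     glu = key_of(ge), glu_denticity = "bi",
                     water = key_of(910), decoy_water = key_of(911),
                     expected_cn = 5, center = o)
  }

  if (isTRUE(spec$ligand)) {
    o <- take_cell()
    La <- o + c(0, 0, 0); Lb <- o + c(6, 0, 0)
    Lc <- o + c(0, 6, 0); Ld <- o + c(6, 6, 0)
    l1 <- add_residue(bld, "ALA", c("O", "N"), c("O", "N"),
                      rbind(La, Lc), res_seq = 801, hetero = TRUE)
    l2 <- add_residue(bld, "LYS", c("O", "N"), c("O", "N"),
                      rbind(Lb, Ld), res_seq = 802, hetero = TRUE)
    dd <- spec$ligand_contacts
    arg <- add_residue(bld, "ARG", c("NH1", "NH2"), c("N", "N"),
                       rbind(La + c(0, 0, dd[1]), Lb + c(0, 0, dd[2])),
                       res_seq = 450)
    lys <- add_residue(bld, "LYS", "NZ", "N", rbind(Lc + c(0, 0, dd[3])),
                       res_seq = 346)
    leu <- add_residue(bld, "LEU", c("O", "C"), c("O", "C"),
                       rbind(Ld + c(0, 0, dd[4]), Ld + c(1.23, 0, dd[4])),
                       res_seq = 318)
    ser <- add_residue(bld, "SER", "OG", "O", rbind(La + c(0, 0, -3.6)))
    man$ligand <- list(
      residues = c(key_of(801), key_of(802)),
      contacts = data.frame(
        partner_res = c(key_of(450), key_of(450), key_of(346), key_of(318)),
        partner_atom = c("NH1", "NH2", "NZ", "O"),
        ligand_res = c(key_of(801), key_of(802), key_of(801), key_of(802)),
        ligand_atom = c("O", "O", "N", "N"),
        distance = dd, stringsAsFactors = FALSE),
      decoy = list(partner_res = key_of(ser), distance = 3.6))
  }

  if (spec$cleft_inside + spec$cleft_outside > 0) {
    o <- take_cell()
    g1 <- add_residue(bld, "GLY", "CA", "C", rbind(o + c(-1, 0, 0)))
    g2 <- add_residue(bld, "GLY", "CA", "C", rbind(o + c(1, 0, 0)))
    inside_keys <- character(0)
    r_in <- spec$cleft_radius - 2
    for (i in seq_len(spec$cleft_inside)) {
      repeat {
        p <- runif(3, -r_in, r_in)
        if (vec_norm(p) <= r_in) break
      }
      wr <- add_residue(bld, "HOH", "O", "O", rbind(o + p),
                        res_seq = 1000 + i, hetero = TRUE)
      inside_keys <- c(inside_keys, key_of(wr))
    }
    outside_keys <- character(0)
    for (i in seq_len(spec$cleft_outside)) {
      u <- rnorm(3); u <- u / vec_norm(u)
      r <- spec$cleft_radius + 4 + runif(1, 0, 4)
      wr <- add_residue(bld, "HOH", "O", "O", rbind(o + r * u),
                        res_seq = 1100 + i, hetero = TRUE)
      outside_keys <- c(outside_keys, key_of(wr))
    }
    man$cleft <- list(center = o, radius = spec$cleft_radius,
                      lining_residues = c(g1, g2),
                      n_inside = spec$cleft_inside,
                      n_outside = spec$cleft_outside,
                      inside = inside_keys, outside = outside_keys)
  }

  # d1/d2 marker residues, isolated at y = -100
  e142 <- c(0, -100, 0)
  k404 <- c(spec$d1, -100, 0)
  e330 <- k404 + spec$d2 * c(-cos(pi / 3), sin(pi / 3), 0)
  add_residue(bld, "GLU", "CA", "C", rbind(e142), res_seq = 142)
  add_residue(bld, "GLU", "CA", "C", rbind(e330), res_seq = 330)
  add_residue(bld, "LYS", "CA", "C", rbind(k404), res_seq = 404)
  man$markers <- list(d1 = spec$d1, d2 = spec$d2,
                      residues = c(142, 330, 404))

  man$counts <- list(ionic = spec$n_salt_bridges, hbond = spec$n_hbonds,
                     weak_hbond = spec$n_weak_hbonds,
                     hydrophobic = spec$n_hydrophobic,
                     aromatic = spec$n_aromatic)
  man$seed <- spec$seed
  list(structure = new_structure(build_atoms(bld)), manifest = man)
}

#' Specification for a synthetic breathing trajectory
#'
#' Defines an open/closed phase schedule with exact per-frame d1 targets,
#' exact hydrogen-bond occupancies for the planted ligand-protein contacts,
#' cleft-water counts per phase, zinc-water residence fractions and a
#' carboxylate denticity switch frame, on top of a [toy_structure_spec()].
#'
#' @param base a [toy_structure_spec()] (must include zinc, ligand and cleft
#'   waters for the corresponding schedules to be realisable).
#' @param n_frames number of frames.
#' @param phase_labels character vector (length `n_frames`) of `"open"` /
#'   `"closed"`; default: first half open, second half closed.
#' @param d1_open,d1_closed d1 targets per phase, Angstrom.
#' @param d1_series optional explicit per-frame d1 series overriding the
#'   phase targets (e.g. a sinusoid).
#' @param hbond_occupancy occupancies (fractions of frames present) for the
#'   planted ligand-protein polar contacts, recycled/truncated to the four
#'   planted bonds.
#' @param cleft_open,cleft_closed cleft-water counts per phase; requires
#'   `base$cleft_inside >= cleft_open >= cleft_closed`.
#' @param zinc_water_fractions residence fractions for zinc-shell waters
#'   (first entry re-uses the structural zinc water; extras are created).
#' @param denticity_switch_frame last frame of bidentate Glu coordination
#'   (default `round(0.35 * n_frames)`); thereafter monodentate.
#' @param seed RNG seed.
#' @return list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(base = toy_structure_spec(cleft_inside = 90,
                                                      cleft_outside = 10),
                            n_frames = 100, phase_labels = NULL,
                            d1_open = 22.6, d1_closed = 15.4,
                            d1_series = NULL,
                            hbond_occupancy = c(1, 1, 0.6, 0.4),
                            cleft_open = 90, cleft_closed = 40,
                            zinc_water_fractions = c(1, 0.5, 0.25),
                            denticity_switch_frame = NULL, seed = 7) {
  if (is.null(phase_labels))
    phase_labels <- rep(c("open", "closed"),
                        c(ceiling(n_frames / 2), floor(n_frames / 2)))
  if (length(phase_labels) != n_frames)
    stop2("phase_labels must have length n_frames")
  if (!is.null(d1_series) && length(d1_series) != n_frames)
    stop2("d1_series must have length n_frames")
  if (is.null(denticity_switch_frame))
    denticity_switch_frame <- round(0.35 * n_frames)
  if (cleft_closed > cleft_open)
    stop2("cleft_closed must be <= cleft_open")
  if (cleft_open > base$cleft_inside)
    stop2("base spec places too few cleft waters for cleft_open")
  spec <- as.list(environment())
  class(spec) <- "trajectory_spec"
  spec
}

#' Generate a synthetic breathing trajectory with a ground-truth manifest
#'
#' Frames realise the d1 schedule exactly (the 404 marker slides along the
#' line to marker 142), planted ligand-protein hydrogen bonds are present in
#' exactly `round(occupancy * n_frames)` frames, cleft-water counts equal
#' the phase targets in every frame, zinc-shell waters reside for exactly
#' `round(fraction * n_frames)` frames, and the Glu carboxylate coordinates
#' the zinc bidentately up to the switch frame and monodentately after.
#'
#' @param spec a [trajectory_spec()].
#' @return list with `trajectory` (a `cleft_trajectory`) and `manifest`.
#' @export
make_breathing_trajectory <- function(spec = trajectory_spec()) {
  stopifnot(inherits(spec, "trajectory_spec"))
  with_seed(spec$seed, build_breathing_trajectory(spec))
}

build_breathing_trajectory <- function(spec) {
  toy <- build_toy_structure(spec$base)
  s <- toy$structure
  man0 <- toy$manifest
  a <- s$atoms
  akey <- res_key(a$chain, a$res_seq, a$icode)
  n <- spec$n_frames
  base <- as.matrix(a[, c("x", "y", "z")])

  # additional zinc-shell waters for the residence schedule
  extra <- length(spec$zinc_water_fractions) - 1L
  if (extra > 0 && is.null(man0$zinc))
    stop2("zinc_water_fractions need a zinc site in the base spec")
  if (extra > 0) {
    ctr <- man0$zinc$center
    dirs <- rbind(c(0, -1, 1), c(-1, -1, 0), c(1, -1, -1), c(1, 1, 1))
    bld <- new_builder()
    bld$serial <- max(a$serial)
    for (k in seq_len(extra)) {
      u <- dirs[(k - 1L) %% nrow(dirs) + 1L, ]
      u <- u / vec_norm(u)
      add_residue(bld, "HOH", "O", "O", rbind(ctr + 8 * u),
                  res_seq = 920 + k, hetero = TRUE)
    }
    a <- rbind(a, build_atoms(bld))
    s <- new_structure(a, ss = s$ss)
    akey <- res_key(a$chain, a$res_seq, a$icode)
    base <- as.matrix(a[, c("x", "y", "z")])
  }

  d1_t <- if (!is.null(spec$d1_series)) spec$d1_series else
    ifelse(spec$phase_labels == "open", spec$d1_open, spec$d1_closed)
  i142 <- which(a$res_seq == 142 & a$name == "CA")
  i404 <- which(a$res_seq == 404 & a$name == "CA")
  i330 <- which(a$res_seq == 330 & a$name == "CA")
  u14 <- base[i404, ] - base[i142, ]
  u14 <- u14 / vec_norm(u14)

  # ligand-protein bond realisation: per bond the mobile protein atoms
  occ <- rep_len(spec$hbond_occupancy, 4)
  if (is.null(man0$ligand)) stop2("hbond_occupancy needs a ligand in the base spec")
  ct <- man0$ligand$contacts
  mobile <- list(
    which(akey == ct$partner_res[1] & a$name == "NH1"),
    which(akey == ct$partner_res[2] & a$name == "NH2"),
    which(akey == ct$partner_res[3] & a$name == "NZ"),
    which(akey == ct$partner_res[4]))  # whole Leu residue
  n_present <- round(occ * n)

  # cleft waters expelled per phase: always down to cleft_open, further
  # down to cleft_closed in closed frames
  if (is.null(man0$cleft)) stop2("cleft schedules need cleft waters in the base spec")
  inside <- man0$cleft$inside
  drop_always <- head(inside, man0$cleft$n_inside - spec$cleft_open)
  drop_closed <- head(inside, man0$cleft$n_inside - spec$cleft_closed)
  expel_open <- which(akey %in% drop_always)
  expel_closed <- which(akey %in% drop_closed)

  # zinc waters: first fraction re-uses the structural water
  zw_idx <- list()
  zw_frames <- integer(0)
  if (length(spec$zinc_water_fractions)) {
    zctr <- man0$zinc$center
    keys <- c(man0$zinc$water,
              if (extra > 0) paste0("A:", 920 + seq_len(extra)))
    for (k in seq_along(spec$zinc_water_fractions)) {
      zw_idx[[k]] <- which(akey == keys[k])
      zw_frames[k] <- round(spec$zinc_water_fractions[k] * n)
    }
    names(zw_frames) <- keys
  }
  ioe2 <- which(akey == man0$zinc$glu & a$name == "OE2")
  oe2_out <- man0$zinc$center +
    (base[ioe2, ] - man0$zinc$center) * (4.3 / 2.3)

  frames <- vector("list", n)
  for (f in seq_len(n)) {
    co <- base
    co[i404, ] <- co[i142, ] + d1_t[f] * u14
    for (b in seq_len(4)) {
      # present: partner pulled to 2.8 A (inside the 3.0 A population
      # cut-off); absent: pushed 5 A away
      co[mobile[[b]], 3] <- co[mobile[[b]], 3] +
        (if (f <= n_present[b]) 2.8 - ct$distance[b] else 5)
    }
    if (length(expel_open) && spec$phase_labels[f] == "open")
      co[expel_open, 1] <- co[expel_open, 1] + 3 * man0$cleft$radius
    if (length(expel_closed) && spec$phase_labels[f] == "closed")
      co[expel_closed, 1] <- co[expel_closed, 1] + 3 * man0$cleft$radius
    for (k in seq_along(zw_idx)) {
      i <- zw_idx[[k]]
      zin <- f <= zw_frames[k]
      u <- base[i, ] - man0$zinc$center
      u <- u / vec_norm(u)
      co[i, ] <- man0$zinc$center + (if (zin) 2.2 else 8) * u
    }
    if (f > spec$denticity_switch_frame) co[ioe2, ] <- oe2_out
    frames[[f]] <- co
  }
  d2_t <- vapply(frames, function(co) vec_norm(co[i330, ] - co[i404, ]),
                 numeric(1))
  man <- list(
    base = man0, n_frames = n, phase = spec$phase_labels,
    d1 = d1_t, d2 = d2_t,
    hbonds = data.frame(ct, occupancy = occ, frames_present = n_present),
    cleft = list(n_open = spec$cleft_open, n_closed = spec$cleft_closed,
                 center = man0$cleft$center, radius = man0$cleft$radius,
                 lining_residues = man0$cleft$lining_residues),
    zinc_water_frames = zw_frames,
    denticity_switch_frame = spec$denticity_switch_frame,
    seed = spec$seed)
  list(trajectory = trajectory(s, frames = frames), manifest = man)
}

#' Specification for synthetic Michaelis-Menten rate data
#'
#' Defaults emulate the preferred-substrate assay conditions: nine substrate
#' concentrations spanning 5-300 uM, KM = 35.2 uM, kcat = 3.07 1/s,
#' multiplicative Gaussian noise.
#'
#' @param km true Michaelis constant, uM.
#' @param kcat true turnover number, 1/s.
#' @param enzyme_conc enzyme concentration, uM.
#' @param concentrations substrate grid, uM.
#' @param noise_sd relative (multiplicative) Gaussian noise SD.
#' @param n_replicates number of replicate datasets.
#' @param seed RNG seed.
#' @return list of class `kinetic_spec`.
#' @export
kinetic_spec <- function(km = 35.2, kcat = 3.07, enzyme_conc = 0.01,
                         concentrations = c(5, 10, 20, 40, 60, 100, 150,
                                            200, 300),
                         noise_sd = 0.05, n_replicates = 3, seed = 11) {
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  if (any(concentrations <= 0)) stop2("concentrations must be positive")
  spec <- as.list(environment())
  class(spec) <- "kinetic_spec"
  spec
}

#' Generate synthetic Michaelis-Menten rate datasets
#'
#' Rates follow `v = kcat * E * S / (KM + S) * (1 + eps)` with
#' `eps ~ N(0, noise_sd)`, fully determined by the spec seed.
#'
#' @param spec a [kinetic_spec()].
#' @return list with `data` (data.frame `substrate_uM`, `rate`, `rep`) and
#'   `truth` (list `km`, `kcat`, `vmax`, `enzyme_conc`).
#' @export
make_kinetic_dataset <- function(spec = kinetic_spec()) {
  stopifnot(inherits(spec, "kinetic_spec"))
  vmax <- spec$kcat * spec$enzyme_conc
  data <- with_seed(spec$seed, {
    do.call(rbind, lapply(seq_len(spec$n_replicates), function(r) {
      S <- spec$concentrations
      v0 <- vmax * S / (spec$km + S)
      data.frame(substrate_uM = S,
                 rate = v0 * (1 + rnorm(length(S), 0, spec$noise_sd)),
                 rep = r)
    }))
  })
  list(data = data,
       truth = list(km = spec$km, kcat = spec$kcat, vmax = vmax,
                    enzyme_conc = spec$enzyme_conc),
       spec = spec)
}
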