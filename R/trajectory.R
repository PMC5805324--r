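# Per-frame analytics over trajectories: geometry traces, hydrogen-bond
# populations, zinc-coordination dynamics, water residence, cleft-water
# counting, aMD boost parameters and interval energy summaries.

#' Construct a trajectory
#'
#' A trajectory couples a topology (a `cleft_structure`) with an ordered set
#' of coordinate frames.  The native on-disk format is multi-model PDB
#' (see [write_structure()]); [read_trajectory()] reads one back.
#'
#' @param topology a `cleft_structure`; its own coordinates become frame 1
#'   unless `frames` is given.
#' @param frames optional list of n_atoms x 3 coordinate matrices replacing
#'   the topology's model set.
#' @param frame_interval time between frames (metadata, arbitrary units).
#' @return A `cleft_trajectory`.
#' @export
trajectory <- function(topology, frames = NULL, frame_interval = 1) {
  n <- nrow(topology$atoms)
  if (is.null(frames))
    frames <- c(list(as.matrix(topology$atoms[, c("x", "y", "z")])),
                topology$models)
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop2("every frame must be an n_atoms x 3 matrix matching the topology")
  if (length(frames) == 0L) stop2("trajectory needs at least one frame")
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval),
            class = "cleft_trajectory")
}

#' @export
print.cleft_trajectory <- function(x, ...) {
  cat("<cleft_trajectory>", length(x$frames), "frames x",
      nrow(x$topology$atoms), "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cleft_trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Read a trajectory from a multi-model PDB file
#' @param path file path.
#' @param frame_interval time between frames (metadata).
#' @return A `cleft_trajectory`.
#' @export
read_trajectory <- function(path, frame_interval = 1) {
  s <- read_structure(path)
  trajectory(s, frame_interval = frame_interval)
}

#' Write a trajectory as multi-model PDB
#' @param traj a `cleft_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  s <- traj$topology
  co <- traj$frames[[1]]
  s$atoms$x <- co[, 1]; s$atoms$y <- co[, 2]; s$atoms$z <- co[, 3]
  s$models <- traj$frames[-1]
  write_structure(s, path)
}

#' Extract one frame as a structure
#' @param traj a `cleft_trajectory`.
#' @param i frame index.
#' @return A `cleft_structure` with the frame's coordinates.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop2("frame index out of range")
  s <- traj$topology
  co <- traj$frames[[i]]
  s$atoms$x <- co[, 1]; s$atoms$y <- co[, 2]; s$atoms$z <- co[, 3]
  s$models <- list()
  s
}

#' Per-frame geometry trace (d1, d2, R_g)
#'
#' Traces the inter-domain distance coordinates and the backbone radius of
#' gyration over a trajectory.
#'
#' @param traj a `cleft_trajectory`.
#' @param pairs residue pairs for [domain_distances()].
#' @param atom atom name for the distances.
#' @return data.frame with columns `frame`, `d1`, `d2`, ..., `rg`.
#' @export
geometry_trace <- function(traj, pairs = list(c(142, 404), c(330, 404)),
                           atom = "CA") {
  s <- traj$topology
  idx <- lapply(pairs, function(p)
    c(atom_index(s, p[1], atom), atom_index(s, p[2], atom)))
  rt <- residue_table(s)
  akey <- res_key(s$atoms$chain, s$atoms$res_seq, s$atoms$icode)
  bb <- akey %in% rt$key[rt$class == "polymer"] &
    s$atoms$name %in% c("N", "CA", "C", "O")
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    co <- traj$frames[[f]]
    dd <- vapply(idx, function(ij) vec_norm(co[ij[1], ] - co[ij[2], ]),
                 numeric(1))
    c(frame = f, setNames(dd, paste0("d", seq_along(dd))),
      rg = radius_of_gyration(co[bb, , drop = FALSE]))
  })
  as.data.frame(do.call(rbind, rows))
}

# donor/acceptor index sets for one side of a ligand/protein partition;
# hetero/non-standard (ligand) residues fall back to all N/O as both roles
# since their protonation is not knowable from the topology
partition_roles <- function(atoms, idx, chemistry) {
  sub <- atoms[idx, , drop = FALSE]
  std <- sub$res_name %in% AA3 & !sub$is_hetero
  roles <- atom_roles(sub, chemistry)
  don <- idx[roles$donor[roles$donor %in% which(std)]]
  acc <- idx[roles$acceptor[roles$acceptor %in% which(std)]]
  gen <- idx[!std & toupper(sub$element) %in% c("N", "O")]
  list(donor = sort(unique(c(don, gen))), acceptor = sort(unique(c(acc, gen))))
}

#' Hydrogen-bond populations over a trajectory
#'
#' For every donor-acceptor pair across a ligand/protein partition, the
#' population is the percentage of frames in which the bond is present
#' (`100 * N(frames with bond) / N(frames)`).  Populations are aggregated
#' per protein residue and role by summation, so a residue accepting through
#' two oxygens simultaneously can exceed 100%.  Entries below the report
#' threshold are omitted.
#'
#' With hydrogens present in the topology, a bond requires donor-acceptor
#' distance <= `dmax` and a D-H...A angle >= `angle_min`; without hydrogens
#' the angle is measured at the donor heavy atom against its antecedent
#' (> 90 deg), and the output is flagged accordingly.
#'
#' @param traj a `cleft_trajectory`.
#' @param ligand residue selector for the ligand side: residue keys or
#'   residue numbers (hetero residues).
#' @param dmax donor-acceptor distance cut-off, Angstrom (default 3.0).
#' @param angle_min D-H...A angle cut-off, degrees (default 135; used only
#'   when hydrogens are present).
#' @param threshold report threshold in percent (default 5); bonds and
#'   residue sums below it are omitted.
#' @param chemistry see [default_chemistry()].
#' @return data.frame `residue`, `res_name`, `role`, `population` (percent),
#'   with per-bond detail in `attr(, "bonds")` and the angle definition in
#'   `attr(, "angle_definition")`.
#' @export
hbond_populations <- function(traj, ligand, dmax = 3.0, angle_min = 135,
                              threshold = 5, chemistry = default_chemistry()) {
  s <- traj$topology
  a <- s$atoms
  akey <- res_key(a$chain, a$res_seq, a$icode)
  sel_lig <- if (is.character(ligand)) which(akey %in% ligand) else
    which(a$res_seq %in% ligand & a$is_hetero)
  if (!length(sel_lig)) stop2("ligand selector matches no atoms")
  rt <- residue_table(s)
  sel_prot <- which(akey %in% rt$key[rt$class == "polymer"])
  lig <- partition_roles(a, sel_lig, chemistry)
  pro <- partition_roles(a, sel_prot, chemistry)
  cand <- rbind(
    expand.grid(don = lig$donor, acc = pro$acceptor),
    expand.grid(don = pro$donor, acc = lig$acceptor))
  if (!nrow(cand)) stop2("no donor/acceptor candidates across the partition")

  has_h <- any(toupper(a$element) == "H")
  coords0 <- as.matrix(a[, c("x", "y", "z")])
  ante <- if (has_h) NULL else
    antecedent_index(a, cand$don, coords0)

  nf <- n_frames(traj)
  present <- integer(nrow(cand))
  for (f in seq_len(nf)) {
    co <- traj$frames[[f]]
    dv <- sqrt(rowSums((co[cand$don, , drop = FALSE] -
                          co[cand$acc, , drop = FALSE])^2))
    ok <- dv <= dmax
    if (has_h) {
      hidx <- which(toupper(a$element) == "H")
      for (k in which(ok)) {
        hh <- hidx[sqrt(rowSums((co[hidx, , drop = FALSE] -
                                   matrix(co[cand$don[k], ], length(hidx), 3,
                                          byrow = TRUE))^2)) <= 1.25]
        ok[k] <- length(hh) > 0 && any(vapply(hh, function(h)
          vertex_angle(co[h, ], co[cand$don[k], ], co[cand$acc[k], ]) >=
            angle_min, logical(1)))
      }
    } else {
      for (k in which(ok & !is.na(ante))) {
        ok[k] <- vertex_angle(co[cand$don[k], ], co[ante[k], ],
                              co[cand$acc[k], ]) > 90
      }
    }
    present <- present + ok
  }
  pop <- 100 * present / nf
  keep <- pop > 0
  bonds <- data.frame(
    donor_res = akey[cand$don[keep]], donor_atom = a$name[cand$don[keep]],
    acceptor_res = akey[cand$acc[keep]],
    acceptor_atom = a$name[cand$acc[keep]],
    population = pop[keep], stringsAsFactors = FALSE)

  # aggregate on the protein side: residue x role
  prot_keys <- akey[sel_prot]
  rows <- rbind(
    data.frame(residue = bonds$acceptor_res, role = "acceptor",
               population = bonds$population,
               stringsAsFactors = FALSE)[bonds$acceptor_res %in% prot_keys, ],
    data.frame(residue = bonds$donor_res, role = "donor",
               population = bonds$population,
               stringsAsFactors = FALSE)[bonds$donor_res %in% prot_keys, ])
  agg <- if (nrow(rows))
    aggregate(population ~ residue + role, rows, sum) else
      data.frame(residue = character(0), role = character(0),
                 population = numeric(0))
  agg <- agg[agg$population >= threshold, , drop = FALSE]
  agg$res_name <- a$res_name[match(agg$residue, akey)]
  agg <- agg[order(agg$role, agg$residue), c("residue", "res_name", "role",
                                             "population")]
  rownames(agg) <- NULL
  attr(agg, "bonds") <- bonds
  attr(agg, "angle_definition") <-
    if (has_h) "explicit_hydrogen" else "heavy_atom_antecedent"
  attr(agg, "n_frames") <- nf
  agg
}

#' Zinc-coordination dynamics over a trajectory
#'
#' Per-frame coordination number and water count of the zinc first shell,
#' plus a denticity timeline (`none` / `mono` / `bi`) for every carboxylate
#' residue that ever coordinates, and the fraction of frames spent in each
#' denticity state.
#'
#' @param traj a `cleft_trajectory`.
#' @param cutoff first-shell cut-off, Angstrom (default 2.6).
#' @return list with `series` (data.frame `frame`, `cn`, `n_water`),
#'   `denticity` (data.frame `frame`, `residue`, `state`) and `summary`
#'   (data.frame `residue`, `state`, `fraction`).
#' @export
zinc_dynamics <- function(traj, cutoff = 2.6) {
  s <- traj$topology
  a <- s$atoms
  akey <- res_key(a$chain, a$res_seq, a$icode)
  zn <- which(toupper(a$element) == "ZN")
  if (length(zn) != 1L) stop2("topology must contain exactly one zinc atom")
  rt <- residue_table(s)
  cls <- rt$class[match(akey, rt$key)]
  cand <- which((cls == "polymer" & toupper(a$element) %in% c("N", "O")) |
                  (cls == "water" & toupper(a$element) == "O"))
  carbox <- unique(akey[cand][a$res_name[cand] %in% names(CARBOXYLATE_O)])
  series <- vector("list", n_frames(traj))
  dent <- vector("list", n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    co <- traj$frames[[f]]
    dd <- sqrt(colSums((t(co[cand, , drop = FALSE]) - co[zn, ])^2))
    insh <- dd <= cutoff
    series[[f]] <- data.frame(
      frame = f, cn = sum(insh),
      n_water = sum(insh & a$res_name[cand] %in% WATER_NAMES))
    if (length(carbox)) {
      st <- vapply(carbox, function(res) {
        rn <- a$res_name[cand][akey[cand] == res][1]
        oxy <- CARBOXYLATE_O[[rn]]
        n_in <- sum(insh & akey[cand] == res & a$name[cand] %in% oxy)
        c("none", "mono", "bi")[min(n_in, 2) + 1]
      }, character(1))
      dent[[f]] <- data.frame(frame = f, residue = carbox, state = st,
                              stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  series <- do.call(rbind, series)
  dent <- if (length(carbox)) do.call(rbind, dent) else
    data.frame(frame = integer(0), residue = character(0),
               state = character(0))
  # only carboxylates that ever coordinate are of interest
  ever <- unique(dent$residue[dent$state != "none"])
  dent <- dent[dent$residue %in% ever, , drop = FALSE]
  rownames(dent) <- NULL
  summ <- if (nrow(dent)) {
    tt <- as.data.frame(table(dent$residue, dent$state) / n_frames(traj))
    names(tt) <- c("residue", "state", "fraction")
    tt[tt$fraction > 0, , drop = FALSE]
  } else data.frame(residue = character(0), state = character(0),
                    fraction = numeric(0))
  list(series = series, denticity = dent, summary = summ, cutoff = cutoff)
}

#' Water residence in the zinc coordination sphere
#'
#' Counts, per water molecule, the number of frames its oxygen spends within
#' a cut-off of the zinc ion.  Waters below `min_frames` are omitted from
#' the report (all counts remain available in `table`).
#'
#' @param traj a `cleft_trajectory`.
#' @param cutoff distance cut-off, Angstrom (default 2.6).
#' @param min_frames report omission threshold in frames (default 200).
#' @return list with `table` (all waters, `water`, `frames_present`),
#'   `report` (filtered), `min_frames`, `total_frames`.
#' @export
water_residence <- function(traj, cutoff = 2.6, min_frames = 200) {
  s <- traj$topology
  a <- s$atoms
  akey <- res_key(a$chain, a$res_seq, a$icode)
  zn <- which(toupper(a$element) == "ZN")
  if (length(zn) != 1L) stop2("topology must contain exactly one zinc atom")
  wat <- which(a$res_name %in% WATER_NAMES & toupper(a$element) == "O")
  counts <- integer(length(wat))
  for (f in seq_len(n_frames(traj))) {
    co <- traj$frames[[f]]
    dd <- sqrt(colSums((t(co[wat, , drop = FALSE]) - co[zn, ])^2))
    counts <- counts + (dd <= cutoff)
  }
  tab <- data.frame(water = akey[wat], frames_present = counts,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$frames_present), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       report = tab[tab$frames_present >= min_frames, , drop = FALSE],
       min_frames = min_frames, total_frames = n_frames(traj))
}

#' Count waters in the inter-domain cleft
#'
#' The cleft region is a union of spheres of radius `radius` around either
#' fixed points (`centers`) or the C-alpha positions of user-listed
#' cleft-lining residues (`residues`, re-evaluated per frame).  A water is
#' inside when its oxygen lies within any sphere.
#'
#' @param x a `cleft_trajectory` or `cleft_structure`.
#' @param centers k x 3 matrix of fixed sphere centres, or `NULL`.
#' @param residues residue numbers whose C-alpha atoms define the centres.
#' @param radius sphere radius, Angstrom (default 8).
#' @return integer vector of per-frame counts (length 1 for a structure).
#' @export
cleft_waters <- function(x, centers = NULL, residues = NULL, radius = 8) {
  traj <- if (inherits(x, "cleft_structure")) trajectory(x) else x
  s <- traj$topology
  a <- s$atoms
  if (is.null(centers) && is.null(residues))
    stop2("give either fixed `centers` or cleft-lining `residues`")
  wat <- which(a$res_name %in% WATER_NAMES & toupper(a$element) == "O")
  ridx <- if (!is.null(residues))
    vapply(residues, function(r) atom_index(s, r, "CA"), integer(1)) else NULL
  vapply(seq_len(n_frames(traj)), function(f) {
    co <- traj$frames[[f]]
    ctr <- if (is.null(ridx)) as.matrix(centers) else
      co[ridx, , drop = FALSE]
    if (!length(wat)) return(0L)
    inside <- rep(FALSE, length(wat))
    for (k in seq_len(nrow(ctr))) {
      dd <- sqrt(colSums((t(co[wat, , drop = FALSE]) - ctr[k, ])^2))
      inside <- inside | dd <= radius
    }
    sum(inside)
  }, integer(1))
}

#' Water-expulsion energy estimate
#'
#' Multiplies the change in cleft-water count between the open and closed
#' phase by a literature per-water release energy range.
#'
#' @param n_open,n_closed mean cleft-water counts in the open and closed
#'   phase.
#' @param e_lo,e_hi per-water release energy bounds, kcal/mol (defaults 1.2
#'   and 2.3).
#' @return numeric vector `c(lo, hi)` in kcal/mol.  A negative water change
#'   gives a signed result with a warning.
#' @export
expulsion_energy <- function(n_open, n_closed, e_lo = 1.2, e_hi = 2.3) {
  if (e_hi < e_lo) stop2("e_hi must be >= e_lo")
  dn <- n_open - n_closed
  if (dn < 0) warn2("n_open < n_closed: signed energy estimate returned")
  c(lo = dn * e_lo, hi = dn * e_hi)
}

#' Accelerated-MD dual-boost parameters
#'
#' Thresholds and roughness parameters for dual-boost accelerated MD from
#' average energies of a conventional run: the torsional threshold is
#' `mean_dih_E + e_r * n_res` and the total-potential threshold
#' `mean_total_E + e_a * n_atoms`, with `alpha_t = e_r * n_res / 5` and
#' `alpha_T = e_a * n_atoms` following the conventional recipe.
#'
#' @param mean_total_E,mean_dih_E average total / dihedral potential energy,
#'   kcal/mol.
#' @param n_res,n_atoms residue and atom counts of the system.
#' @param e_r energy per residue, kcal/mol (default 1).
#' @param e_a energy per atom, kcal/mol (default 0.1).
#' @return list of class `amd_params` with `E_t`, `E_T`, `alpha_t`,
#'   `alpha_T` and the inputs.
#' @export
amd_boost_params <- function(mean_total_E, mean_dih_E, n_res, n_atoms,
                             e_r = 1, e_a = 0.1) {
  if (n_res < 1 || n_atoms < 1) stop2("n_res and n_atoms must be >= 1")
  structure(list(mean_total_E = mean_total_E, mean_dih_E = mean_dih_E,
                 n_res = n_res, n_atoms = n_atoms, e_r = e_r, e_a = e_a,
                 E_t = mean_dih_E + e_r * n_res,
                 E_T = mean_total_E + e_a * n_atoms,
                 alpha_t = e_r * n_res / 5,
                 alpha_T = e_a * n_atoms),
            class = "amd_params")
}

#' @export
print.amd_params <- function(x, ...) {
  cat("aMD dual-boost parameters (kcal/mol):\n")
  cat(sprintf("  E_t = %.2f  alpha_t = %.2f\n", x$E_t, x$alpha_t))
  cat(sprintf("  E_T = %.2f  alpha_T = %.2f\n", x$E_T, x$alpha_T))
  invisible(x)
}

#' Interval summary of a per-frame energy series
#'
#' Tiles a per-frame energy series (e.g. end-point binding energies supplied
#' by an external MM-PBSA/MM-GBSA run) into consecutive intervals and
#' reports mean and sample SD per interval, formatted `"mean (+-SD)"`.
#'
#' @param series numeric vector of per-frame energies, kcal/mol.
#' @param interval_frames frames per interval (>= 2).
#' @return data.frame `interval`, `start`, `end`, `n`, `mean`, `sd`,
#'   `partial`, `formatted`.  A series shorter than one interval yields a
#'   single interval flagged partial.
#' @export
interval_energy_summary <- function(series, interval_frames) {
  if (interval_frames < 2) stop2("interval_frames must be >= 2")
  n <- length(series)
  if (n == 0L) stop2("empty energy series")
  starts <- seq(1, n, by = interval_frames)
  rows <- lapply(seq_along(starts), function(k) {
    i0 <- starts[k]; i1 <- min(i0 + interval_frames - 1, n)
    x <- series[i0:i1]
    data.frame(interval = k, start = i0, end = i1, n = length(x),
               mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_,
               partial = length(x) < interval_frames)
  })
  out <- do.call(rbind, rows)
  out$formatted <- sprintf("%.1f (±%.1f)", out$mean,
                           ifelse(is.na(out$sd), 0, out$sd))
  out
}

#' Read a per-frame energy series from CSV/TSV
#'
#' Accepts a single-column file or a labelled-column table.
#'
#' @param path file path (delimiter sniffed from the extension: `.csv` vs
#'   tab-separated otherwise).
#' @param column column name or index (default: first numeric column).
#' @return numeric vector.
#' @export
read_energy_series <- function(path, column = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (is.null(column)) {
    num <- vapply(df, is.numeric, logical(1))
    if (!any(num)) stop2("no numeric column in ", path)
    column <- names(df)[which(num)[1]]
  }
  as.numeric(df[[column]])
}
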