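# Geometric non-covalent interaction detection and thermostability
# comparison profiles.

#' Geometric criteria for interaction detection
#'
#' Distance and angle cut-offs per interaction class.  Defaults: hydrogen
#' bonds at donor-acceptor distance <= 3.9 A with the angle at the donor
#' (between donor->antecedent and donor->acceptor directions) > 90 deg; weak
#' C-H hydrogen bonds in 3.6-3.9 A with 90 deg < theta < 130 deg; ionic,
#' hydrophobic and aromatic contacts at <= 4 A.
#'
#' @param hbond_dmax,hbond_theta_min hydrogen-bond cut-offs (A, degrees).
#' @param weak_dmin,weak_dmax,weak_theta_lo,weak_theta_hi weak (C-H) bond
#'   window (A, degrees).
#' @param ionic_dmax,hydrophobic_dmax,aromatic_dmax distance cut-offs (A).
#' @return list of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_dmax = 3.9, hbond_theta_min = 90,
                                 weak_dmin = 3.6, weak_dmax = 3.9,
                                 weak_theta_lo = 90, weak_theta_hi = 130,
                                 ionic_dmax = 4.0, hydrophobic_dmax = 4.0,
                                 aromatic_dmax = 4.0) {
  cr <- list(hbond_dmax = hbond_dmax, hbond_theta_min = hbond_theta_min,
             weak_dmin = weak_dmin, weak_dmax = weak_dmax,
             weak_theta_lo = weak_theta_lo, weak_theta_hi = weak_theta_hi,
             ionic_dmax = ionic_dmax, hydrophobic_dmax = hydrophobic_dmax,
             aromatic_dmax = aromatic_dmax)
  ds <- unlist(cr[c("hbond_dmax", "weak_dmin", "weak_dmax", "ionic_dmax",
                    "hydrophobic_dmax", "aromatic_dmax")])
  if (any(ds <= 0)) stop2("all distance cut-offs must be positive")
  if (weak_dmin > weak_dmax) stop2("weak_dmin must be <= weak_dmax")
  ang <- unlist(cr[c("hbond_theta_min", "weak_theta_lo", "weak_theta_hi")])
  if (any(ang < 0 | ang > 180)) stop2("angle bounds must lie in [0, 180]")
  class(cr) <- "interaction_criteria"
  cr
}

# index pairs (i, j) with dist(A[i,], B[j,]) <= dmax; returns matrix + dist
pairs_within <- function(A, B, dmax) {
  if (nrow(A) == 0L || nrow(B) == 0L)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= dmax^2, arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2], d = sqrt(d2[hit]))
}

# per-atom roles for the polymer atoms of a structure
atom_roles <- function(atoms, chemistry) {
  rn <- atoms$res_name
  nm <- atoms$name
  el <- toupper(atoms$element)
  in_set <- function(dict) {
    hit <- logical(nrow(atoms))
    for (res in names(dict)) hit <- hit | (rn == res & nm %in% dict[[res]])
    hit
  }
  donor <- (nm == "N" & rn != "PRO" & el == "N") | in_set(chemistry$donors)
  acceptor <- (nm %in% c("O", "OXT") & el == "O") | in_set(chemistry$acceptors)
  cdonor <- el == "C"
  pos <- in_set(chemistry$positive)
  neg <- in_set(chemistry$negative)
  apolar <- in_set(chemistry$apolar)
  list(donor = which(donor), acceptor = which(acceptor),
       cdonor = which(cdonor), pos = which(pos), neg = which(neg),
       apolar = which(apolar))
}

# rings as a list of atom-index vectors (only complete rings kept)
ring_list <- function(atoms, chemistry) {
  rings <- list()
  key <- res_key(atoms$chain, atoms$res_seq, atoms$icode)
  for (res in names(chemistry$rings)) {
    sel <- which(atoms$res_name == res)
    if (!length(sel)) next
    for (k in unique(key[sel])) {
      at <- sel[key[sel] == k]
      for (ring in chemistry$rings[[res]]) {
        idx <- at[match(ring, atoms$name[at])]
        if (!anyNA(idx)) rings[[length(rings) + 1L]] <-
            list(idx = idx, key = k)
      }
    }
  }
  rings
}

# nearest same-residue heavy atom within bonding distance (the antecedent
# used for donor angles); NA when the residue carries no bonded neighbour
antecedent_index <- function(atoms, idx, coords) {
  key <- res_key(atoms$chain, atoms$res_seq, atoms$icode)
  out <- rep(NA_integer_, length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    same <- which(key == key[i])
    same <- same[same != i]
    if (!length(same)) next
    dd <- sqrt(colSums((t(coords[same, , drop = FALSE]) - coords[i, ])^2))
    ok <- which(dd <= 1.9)
    if (length(ok)) out[k] <- same[ok[which.min(dd[ok])]]
  }
  out
}

#' Detect non-covalent interactions in a structure
#'
#' Scans the polymer atoms of a structure for hydrogen bonds, weak (C-H)
#' hydrogen bonds, ionic interactions, hydrophobic contacts and aromatic
#' contacts under explicit geometric criteria.  Structures without hydrogens
#' are the norm here, so donor angles are measured at the donor heavy atom
#' between the donor->antecedent and donor->acceptor directions.
#'
#' Counting conventions: hydrogen bonds and hydrophobic contacts are counted
#' per atom pair, ionic interactions once per residue pair, aromatic contacts
#' once per ring pair.  Intra-residue pairs and backbone pairs of
#' sequence-adjacent residues (covalent neighbourhood) are excluded, and
#' atom pairs between two rings already counted as an aromatic contact are
#' excluded from the hydrophobic count.
#'
#' @param s a `cleft_structure`.
#' @param criteria an [interaction_criteria()] object.
#' @param chemistry atom-role dictionaries, see [default_chemistry()].
#' @return data.frame of interactions with columns `kind`, `res1`, `atom1`,
#'   `res2`, `atom2`, `distance`, `angle` (NA where no angle applies); `res*`
#'   are residue keys `chain:number`.
#' @export
detect_interactions <- function(s, criteria = interaction_criteria(),
                                chemistry = default_chemistry()) {
  rt <- residue_table(s)
  poly_keys <- rt$key[rt$class == "polymer"]
  akey <- res_key(s$atoms$chain, s$atoms$res_seq, s$atoms$icode)
  atoms <- s$atoms[akey %in% poly_keys, , drop = FALSE]
  if (nrow(atoms) == 0L) return(empty_interactions())
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  key <- res_key(atoms$chain, atoms$res_seq, atoms$icode)
  roles <- atom_roles(atoms, chemistry)
  bb <- atoms$name %in% c("N", "CA", "C", "O", "OXT")

  covalent_neighbours <- function(i, j) {
    same_chain <- atoms$chain[i] == atoms$chain[j]
    adj <- same_chain & abs(atoms$res_seq[i] - atoms$res_seq[j]) == 1L
    adj & bb[i] & bb[j]
  }
  rec <- function(kind, i, j, d, angle = NA_real_) {
    data.frame(kind = kind,
               res1 = key[i], atom1 = atoms$name[i],
               res2 = key[j], atom2 = atoms$name[j],
               distance = d, angle = angle, stringsAsFactors = FALSE)
  }
  out <- list()

  # hydrogen bonds (N/O donor -> N/O acceptor)
  don <- roles$donor; acc <- roles$acceptor
  ph <- pairs_within(coords[don, , drop = FALSE], coords[acc, , drop = FALSE],
                     criteria$hbond_dmax)
  if (nrow(ph)) {
    i <- don[ph$i]; j <- acc[ph$j]
    keep <- key[i] != key[j] & !covalent_neighbours(i, j) & i != j
    i <- i[keep]; j <- j[keep]; d <- ph$d[keep]
    ante <- antecedent_index(atoms, i, coords)
    theta <- rep(NA_real_, length(i))
    has <- !is.na(ante)
    theta[has] <- vapply(which(has), function(k)
      vertex_angle(coords[i[k], ], coords[ante[k], ], coords[j[k], ]),
      numeric(1))
    ok <- is.na(theta) | theta > criteria$hbond_theta_min
    i <- i[ok]; j <- j[ok]; d <- d[ok]; theta <- theta[ok]
    pair_id <- paste(pmin(i, j), pmax(i, j))
    first <- !duplicated(pair_id)
    out$hbond <- rec("hbond", i[first], j[first], d[first], theta[first])
  }

  # weak C-H...A hydrogen bonds
  cd <- roles$cdonor
  pw <- pairs_within(coords[cd, , drop = FALSE], coords[acc, , drop = FALSE],
                     criteria$weak_dmax)
  if (nrow(pw)) {
    i <- cd[pw$i]; j <- acc[pw$j]; d <- pw$d
    keep <- d >= criteria$weak_dmin & key[i] != key[j] &
      !covalent_neighbours(i, j)
    i <- i[keep]; j <- j[keep]; d <- d[keep]
    if (length(i)) {
      ante <- antecedent_index(atoms, i, coords)
      theta <- rep(NA_real_, length(i))
      has <- !is.na(ante)
      theta[has] <- vapply(which(has), function(k)
        vertex_angle(coords[i[k], ], coords[ante[k], ], coords[j[k], ]),
        numeric(1))
      ok <- is.na(theta) |
        (theta > criteria$weak_theta_lo & theta < criteria$weak_theta_hi)
      i <- i[ok]; j <- j[ok]; d <- d[ok]; theta <- theta[ok]
      if (length(i)) {
        pair_id <- paste(pmin(i, j), pmax(i, j))
        first <- !duplicated(pair_id)
        out$weak <- rec("weak_hbond", i[first], j[first], d[first],
                        theta[first])
      }
    }
  }

  # ionic: opposite formal charges, once per residue pair
  pi_ <- pairs_within(coords[roles$neg, , drop = FALSE],
                      coords[roles$pos, , drop = FALSE], criteria$ionic_dmax)
  if (nrow(pi_)) {
    i <- roles$neg[pi_$i]; j <- roles$pos[pi_$j]; d <- pi_$d
    keep <- key[i] != key[j]
    i <- i[keep]; j <- j[keep]; d <- d[keep]
    if (length(i)) {
      rp <- paste(pmin(match(key[i], poly_keys), match(key[j], poly_keys)),
                  pmax(match(key[i], poly_keys), match(key[j], poly_keys)))
      ord <- order(rp, d)
      first <- !duplicated(rp[ord])
      sel <- ord[first]
      out$ionic <- rec("ionic", i[sel], j[sel], d[sel])
    }
  }

  # aromatic: once per ring pair with any cross atom pair within cut-off
  rings <- ring_list(atoms, chemistry)
  aromatic_atom_pairs <- character(0)
  if (length(rings) >= 2L) {
    hits <- list()
    for (r1 in seq_len(length(rings) - 1L)) {
      for (r2 in seq((r1 + 1L), length(rings))) {
        if (rings[[r1]]$key == rings[[r2]]$key) next
        pp <- pairs_within(coords[rings[[r1]]$idx, , drop = FALSE],
                           coords[rings[[r2]]$idx, , drop = FALSE],
                           criteria$aromatic_dmax)
        if (nrow(pp)) {
          kmin <- which.min(pp$d)
          i <- rings[[r1]]$idx[pp$i[kmin]]; j <- rings[[r2]]$idx[pp$j[kmin]]
          hits[[length(hits) + 1L]] <- rec("aromatic", i, j, pp$d[kmin])
          g <- expand.grid(rings[[r1]]$idx, rings[[r2]]$idx)
          aromatic_atom_pairs <- c(aromatic_atom_pairs,
                                   paste(pmin(g[, 1], g[, 2]),
                                         pmax(g[, 1], g[, 2])))
        }
      }
    }
    if (length(hits)) out$aromatic <- do.call(rbind, hits)
  }

  # hydrophobic: apolar carbon pairs, minus counted aromatic ring pairs
  ap <- roles$apolar
  pa <- pairs_within(coords[ap, , drop = FALSE], coords[ap, , drop = FALSE],
                     criteria$hydrophobic_dmax)
  if (nrow(pa)) {
    i <- ap[pa$i]; j <- ap[pa$j]; d <- pa$d
    keep <- i < j & key[i] != key[j]
    i <- i[keep]; j <- j[keep]; d <- d[keep]
    if (length(i)) {
      pid <- paste(i, j)
      keep2 <- !(pid %in% aromatic_atom_pairs)
      if (any(keep2)) out$hydrophobic <-
          rec("hydrophobic", i[keep2], j[keep2], d[keep2])
    }
  }

  res <- do.call(rbind, unname(out))
  if (is.null(res)) empty_interactions() else {
    rownames(res) <- NULL
    res
  }
}

empty_interactions <- function() {
  data.frame(kind = character(0), res1 = character(0), atom1 = character(0),
             res2 = character(0), atom2 = character(0),
             distance = numeric(0), angle = numeric(0),
             stringsAsFactors = FALSE)
}

PROFILE_CATEGORIES <- c("helix", "sheet", "proline", "polar", "charged",
                        "hydrophobic_res", "hbond", "weak_hbond", "ionic",
                        "hydrophobic", "aromatic")
RESIDUE_CATEGORIES <- PROFILE_CATEGORIES[1:6]

#' Thermostability structure profile
#'
#' Absolute counts and relative values for the standard comparison
#' categories: residues in helix / sheet, proline / polar / charged /
#' hydrophobic residues (percent of the denominator) and hydrogen bonds,
#' weak hydrogen bonds, ionic, hydrophobic and aromatic contacts (count per
#' residue of the denominator).
#'
#' The default denominator is the number of resolved polymer residues;
#' `denominator = "full_length"` (with `full_length` given) divides the
#' residue-category percentages by the full sequence length instead.
#'
#' @param s a `cleft_structure`.
#' @param criteria an [interaction_criteria()] object.
#' @param chemistry see [default_chemistry()].
#' @param scheme residue-class scheme, see [residue_class_scheme()].
#' @param denominator `"resolved"` or `"full_length"`.
#' @param full_length full sequence length (required for
#'   `denominator = "full_length"`).
#' @param name label used in reports.
#' @return A `structure_profile` object.
#' @export
structure_profile <- function(s, criteria = interaction_criteria(),
                              chemistry = default_chemistry(),
                              scheme = residue_class_scheme(),
                              denominator = c("resolved", "full_length"),
                              full_length = NULL, name = "structure") {
  denominator <- match.arg(denominator)
  nres <- n_resolved(s)
  ss <- ss_labels(s)
  comp <- classify_residues(s, scheme = scheme, strict = FALSE)
  ints <- detect_interactions(s, criteria, chemistry)
  counts <- c(helix = sum(ss == "H"), sheet = sum(ss == "E"),
              proline = unname(comp$counts["proline"]),
              polar = unname(comp$counts["polar"]),
              charged = unname(comp$counts["charged"]),
              hydrophobic_res = unname(comp$counts["hydrophobic"]),
              hbond = sum(ints$kind == "hbond"),
              weak_hbond = sum(ints$kind == "weak_hbond"),
              ionic = sum(ints$kind == "ionic"),
              hydrophobic = sum(ints$kind == "hydrophobic"),
              aromatic = sum(ints$kind == "aromatic"))
  structure_profile_from_counts(counts, n_resolved = nres,
                                denominator = denominator,
                                full_length = full_length, name = name)
}

#' Build a structure profile from pre-tabulated counts
#'
#' Computes the relative values (percentages for residue categories,
#' per-residue densities for interaction classes) from absolute counts, e.g.
#' taken from a published comparison table.
#'
#' @param counts named numeric vector over (a subset of) the categories
#'   `helix`, `sheet`, `proline`, `polar`, `charged`, `hydrophobic_res`,
#'   `hbond`, `weak_hbond`, `ionic`, `hydrophobic`, `aromatic`.
#' @param n_resolved resolved polymer residue count (the default denominator).
#' @param denominator `"resolved"` or `"full_length"`.
#' @param full_length full sequence length for the `"full_length"` policy.
#' @param name profile label.
#' @return A `structure_profile` object with elements `counts`, `relative`,
#'   `n_resolved`, `denominator` (the number actually divided by) and `name`.
#' @export
structure_profile_from_counts <- function(counts, n_resolved,
                                          denominator = c("resolved",
                                                          "full_length"),
                                          full_length = NULL,
                                          name = "structure") {
  denominator <- match.arg(denominator)
  if (denominator == "full_length" && is.null(full_length))
    stop2("full_length must be given for denominator = 'full_length'")
  res_denom <- if (denominator == "full_length") full_length else n_resolved
  if (res_denom == 0 || n_resolved == 0) stop2("zero denominator")
  cats <- intersect(PROFILE_CATEGORIES, names(counts))
  counts <- counts[cats]
  relative <- ifelse(cats %in% RESIDUE_CATEGORIES,
                     100 * counts / res_denom,
                     counts / n_resolved)
  names(relative) <- cats
  structure(list(name = name, counts = counts, relative = relative,
                 n_resolved = n_resolved, denominator = res_denom,
                 denominator_policy = denominator),
            class = "structure_profile")
}

#' @export
print.structure_profile <- function(x, ...) {
  cat("<structure_profile>", x$name, "- n_resolved:", x$n_resolved, "\n")
  df <- data.frame(category = names(x$counts),
                   abs = unname(x$counts),
                   rel = round(unname(x$relative),
                               ifelse(names(x$counts) %in% RESIDUE_CATEGORIES,
                                      1, 3)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Scaled cross-structure comparison of two profiles
#'
#' For each category present in both profiles, scales the pair of relative
#' values so that the larger one maps to 100 (the "relative occurrence"
#' convention of thermostability comparison tables).  Scaling is computed
#' from unrounded relative values.
#'
#' @param p1,p2 `structure_profile` objects.
#' @return A `comparison_table`: data.frame with columns `category`, `abs1`,
#'   `rel1`, `abs2`, `rel2`, `scaled1`, `scaled2`, carrying the profile names
#'   as attributes.
#' @export
compare_profiles <- function(p1, p2) {
  cats <- names(p1$counts)
  if (!setequal(cats, names(p2$counts)))
    stop2("profiles cover different categories: ",
          paste(union(setdiff(cats, names(p2$counts)),
                      setdiff(names(p2$counts), cats)), collapse = ", "))
  cats <- intersect(PROFILE_CATEGORIES, cats)
  r1 <- p1$relative[cats]; r2 <- p2$relative[cats]
  mx <- pmax(r1, r2)
  sc1 <- ifelse(mx > 0, 100 * r1 / mx, 100)
  sc2 <- ifelse(mx > 0, 100 * r2 / mx, 100)
  out <- data.frame(category = cats,
                    abs1 = unname(p1$counts[cats]), rel1 = unname(r1),
                    abs2 = unname(p2$counts[cats]), rel2 = unname(r2),
                    scaled1 = unname(sc1), scaled2 = unname(sc2),
                    stringsAsFactors = FALSE)
  attr(out, "names1") <- p1$name
  attr(out, "names2") <- p2$name
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Structural factors comparison:", attr(x, "names1"), "vs",
      attr(x, "names2"), "\n")
  df <- as.data.frame(x)
  isres <- df$category %in% RESIDUE_CATEGORIES
  df$rel1 <- round(df$rel1, ifelse(isres, 2, 3))
  df$rel2 <- round(df$rel2, ifelse(isres, 2, 3))
  df$scaled1 <- round(df$scaled1, 1)
  df$scaled2 <- round(df$scaled2, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a comparison table as TSV
#'
#' Column layout mirrors the published comparison tables: per structure an
#' absolute and a relative column, then the scaled relative-occurrence pair.
#' Percentages are rounded to 1 decimal at this presentation layer only,
#' densities to 3.
#'
#' @param tab a `comparison_table` from [compare_profiles()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(tab, path) {
  df <- as.data.frame(tab)
  isres <- df$category %in% RESIDUE_CATEGORIES
  out <- data.frame(Category = df$category,
                    Abs.1 = df$abs1,
                    Rel.1 = round(df$rel1, ifelse(isres, 2, 3)),
                    Abs.2 = df$abs2,
                    Rel.2 = round(df$rel2, ifelse(isres, 2, 3)),
                    Scaled.1 = round(df$scaled1, 1),
                    Scaled.2 = round(df$scaled2, 1))
  names(out) <- c("Category", "Abs.", "Rel. (%)", "Abs.", "Rel. (%)",
                  "Scaled (%)", "Scaled (%)")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
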