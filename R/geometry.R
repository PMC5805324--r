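# Static-structure geometry: inter-domain distance coordinates, radius of
# gyration, Kabsch superposition, conformer classes, ligand polar contacts
# and the zinc coordination sphere.

coords_of <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

# locate one atom by residue number (+ optional chain) and atom name
atom_index <- function(s, res_seq, name = "CA", chain = NULL) {
  a <- s$atoms
  hit <- which(a$res_seq == res_seq & a$name == name &
                 (if (is.null(chain)) TRUE else a$chain == chain))
  if (!length(hit))
    stop2("no atom '", name, "' in residue ", res_seq,
          if (!is.null(chain)) paste0(" chain ", chain))
  hit[1]
}

#' Inter-domain distance coordinates d1 and d2
#'
#' Euclidean C-alpha-to-C-alpha distances used as compactness / mutual
#' orientation coordinates of a two-domain enzyme.  The default residue
#' pairs, 142-404 (d1) and 330-404 (d2), are bound to the thermophilic
#' DPP III author numbering and can be overridden for other proteins.
#'
#' @param s a `cleft_structure`.
#' @param pairs list of two integer vectors `c(res_a, res_b)`.
#' @param atom atom name used for the distance (default `"CA"`).
#' @return named numeric vector `c(d1 = ..., d2 = ...)` in Angstrom.
#' @export
domain_distances <- function(s, pairs = list(c(142, 404), c(330, 404)),
                             atom = "CA") {
  co <- coords_of(s)
  out <- vapply(pairs, function(p) {
    i <- atom_index(s, p[1], atom)
    j <- atom_index(s, p[2], atom)
    vec_norm(co[i, ] - co[j, ])
  }, numeric(1))
  names(out) <- paste0("d", seq_along(pairs))
  out
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of a coordinate set from its
#' centroid; unit masses by default (the convention for backbone-atom R_g
#' traces).
#'
#' @param coords n x 3 coordinate matrix, or a `cleft_structure` (backbone
#'   atoms N, CA, C, O of polymer residues are used).
#' @param masses optional weights, length n.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  if (inherits(coords, "cleft_structure")) {
    s <- coords
    rt <- residue_table(s)
    akey <- res_key(s$atoms$chain, s$atoms$res_seq, s$atoms$icode)
    sel <- akey %in% rt$key[rt$class == "polymer"] &
      s$atoms$name %in% c("N", "CA", "C", "O")
    coords <- coords_of(s)[sel, , drop = FALSE]
  }
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop2("empty coordinate set")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  w <- masses / sum(masses)
  ctr <- colSums(coords * w)
  sqrt(sum(w * rowSums((coords - matrix(ctr, nrow(coords), 3,
                                        byrow = TRUE))^2)))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation (det = +1) and translation mapping `b` onto `a`
#' over a given correspondence, with the post-fit RMSD.
#'
#' @param a,b n x 3 coordinate matrices.
#' @param correspondence 2-column integer matrix of paired row indices
#'   (rows of `a`, rows of `b`); defaults to the identity pairing.
#' @return list with `rmsd` (Angstrom), `rotation` (3 x 3, det +1) and
#'   `translation` (length 3): `b[j, ] %*% rotation + translation`
#'   superposes onto `a[i, ]`.
#' @export
superpose_rmsd <- function(a, b, correspondence = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(correspondence)) {
    if (nrow(a) != nrow(b)) stop2("sets differ in size; give a correspondence")
    correspondence <- cbind(seq_len(nrow(a)), seq_len(nrow(b)))
  }
  P <- a[correspondence[, 1], , drop = FALSE]
  Q <- b[correspondence[, 2], , drop = FALSE]
  if (nrow(P) < 3) stop2("need at least 3 paired atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Qc) %*% Pc
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop2("degenerate (collinear) coordinate set: superposition undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)  # row-vector convention: Qc %*% R approximates Pc
  rmsd <- sqrt(mean(rowSums((Pc - Qc %*% R)^2)))
  list(rmsd = rmsd, rotation = R, translation = as.numeric(cp - cq %*% R))
}

#' Read a residue correspondence file
#'
#' Two-column TSV of paired residue numbers (first structure, second
#' structure), as produced from a sequence alignment.
#'
#' @param path TSV path, optionally with a header.
#' @return 2-column integer matrix.
#' @export
read_correspondence <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("res_a", "res_b"),
                   comment.char = "#", stringsAsFactors = FALSE)
  df <- df[!is.na(suppressWarnings(as.integer(df$res_a))), , drop = FALSE]
  cbind(as.integer(df$res_a), as.integer(df$res_b))
}

#' Conformer classification scheme
#'
#' Labelled reference points in the (d1, d2) plane, e.g. the crystal form
#' and the open / closed forms seen in simulation, plus a tolerance.
#'
#' @param labels character vector of unique class labels.
#' @param d1,d2 reference coordinates, Angstrom.
#' @param tolerance assignment radius in the (d1, d2) plane, Angstrom.
#' @return A `conformer_scheme` object.
#' @export
conformer_scheme <- function(labels, d1, d2, tolerance = 1.5) {
  if (anyDuplicated(labels)) stop2("conformer labels must be unique")
  if (tolerance <= 0) stop2("tolerance must be positive")
  structure(list(ref = data.frame(label = labels, d1 = d1, d2 = d2,
                                  stringsAsFactors = FALSE),
                 tolerance = tolerance),
            class = "conformer_scheme")
}

#' Classify a geometry snapshot into a conformer class
#'
#' Assigns the nearest reference point in the Euclidean (d1, d2) metric if
#' it lies within the scheme tolerance, else `"unassigned"`.  Ties are
#' broken by scheme order.
#'
#' @param snap numeric vector (or list) with elements `d1` and `d2`.
#' @param scheme a [conformer_scheme()].
#' @return class label, or `"unassigned"`.
#' @export
classify_conformer <- function(snap, scheme) {
  if (nrow(scheme$ref) == 0L) stop2("empty conformer scheme")
  d <- sqrt((scheme$ref$d1 - snap[["d1"]])^2 +
              (scheme$ref$d2 - snap[["d2"]])^2)
  i <- which.min(d)  # which.min returns the first index on ties
  if (d[i] <= scheme$tolerance) scheme$ref$label[i] else "unassigned"
}

#' Polar contacts between a bound ligand and the protein
#'
#' All nitrogen/oxygen atom pairs between a selected ligand residue (or
#' residues) and the polymer within a distance cut-off, sorted by distance.
#'
#' @param s a `cleft_structure`.
#' @param ligand residue selector: a vector of residue keys (`"A:801"`) or
#'   residue numbers of the ligand residues.
#' @param dmax distance cut-off, Angstrom (default 3.2).
#' @return data.frame with `partner_res`, `partner_name`, `partner_atom`,
#'   `ligand_res`, `ligand_atom`, `distance`, sorted by distance.
#' @export
ligand_polar_contacts <- function(s, ligand, dmax = 3.2) {
  if (dmax <= 0) stop2("dmax must be positive")
  a <- s$atoms
  akey <- res_key(a$chain, a$res_seq, a$icode)
  sel_lig <- if (is.character(ligand)) akey %in% ligand else
    a$res_seq %in% ligand & a$is_hetero
  if (!any(sel_lig)) stop2("ligand selector matches no atoms")
  rt <- residue_table(s)
  sel_prot <- akey %in% rt$key[rt$class == "polymer"]
  no <- toupper(a$element) %in% c("N", "O")
  li <- which(sel_lig & no); pi_ <- which(sel_prot & no)
  co <- coords_of(s)
  pp <- pairs_within(co[li, , drop = FALSE], co[pi_, , drop = FALSE], dmax)
  i <- li[pp$i]; j <- pi_[pp$j]
  out <- data.frame(partner_res = akey[j], partner_name = a$res_name[j],
                    partner_atom = a$name[j],
                    ligand_res = akey[i], ligand_atom = a$name[i],
                    distance = pp$d, stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}

#' Zinc coordination sphere
#'
#' Ligand atoms (protein N/O and water O) within a cut-off of the zinc ion,
#' the coordination number, and the denticity of each coordinating
#' carboxylate (Glu/Asp): `"bi"` when both carboxylate oxygens are within
#' the cut-off, `"mono"` when exactly one is, `"none"` otherwise.
#'
#' @param s a `cleft_structure` (or single trajectory frame).
#' @param cutoff first-shell distance cut-off, Angstrom (default 2.6).
#' @param zinc optional residue key of the zinc to use when several are
#'   present.
#' @return A `zinc_site` object: list with `zinc` (residue key), `ligands`
#'   (data.frame `res`, `res_name`, `atom`, `element`, `distance`),
#'   `coordination_number`, `denticity` (named character vector over
#'   coordinating carboxylate residues), `n_water`, `cutoff`.
#' @export
zinc_site <- function(s, cutoff = 2.6, zinc = NULL) {
  a <- s$atoms
  akey <- res_key(a$chain, a$res_seq, a$icode)
  zn <- which(toupper(a$element) == "ZN")
  if (!length(zn)) stop2("no zinc atom in structure")
  if (!is.null(zinc)) zn <- zn[akey[zn] %in% zinc]
  if (length(zn) != 1L)
    stop2("structure has ", length(zn),
          " zinc atoms; select one via `zinc = <residue key>`")
  co <- coords_of(s)
  rt <- residue_table(s)
  cls <- rt$class[match(akey, rt$key)]
  cand <- which((cls == "polymer" & toupper(a$element) %in% c("N", "O")) |
                  (cls == "water" & toupper(a$element) == "O"))
  dd <- sqrt(colSums((t(co[cand, , drop = FALSE]) - co[zn, ])^2))
  lig_all <- data.frame(res = akey[cand], res_name = a$res_name[cand],
                        atom = a$name[cand], element = toupper(a$element[cand]),
                        distance = dd, stringsAsFactors = FALSE)
  lig <- lig_all[lig_all$distance <= cutoff, , drop = FALSE]
  lig <- lig[order(lig$distance), , drop = FALSE]
  # denticity per carboxylate residue with >= 1 coordinating oxygen
  dent <- character(0)
  for (res in unique(lig$res[lig$res_name %in% names(CARBOXYLATE_O)])) {
    rn <- lig$res_name[lig$res == res][1]
    oxy <- CARBOXYLATE_O[[rn]]
    n_in <- sum(lig_all$res == res & lig_all$atom %in% oxy &
                  lig_all$distance <= cutoff)
    dent[res] <- c("none", "mono", "bi")[min(n_in, 2) + 1]
  }
  structure(list(zinc = akey[zn], ligands = lig,
                 coordination_number = nrow(lig),
                 denticity = dent,
                 n_water = sum(lig$res_name %in% WATER_NAMES),
                 cutoff = cutoff),
            class = "zinc_site")
}

#' @export
print.zinc_site <- function(x, ...) {
  cat("<zinc_site>", x$zinc, "- CN", x$coordination_number,
      "at cutoff", x$cutoff, "A\n")
  print(x$ligands, row.names = FALSE)
  if (length(x$denticity))
    cat("denticity:", paste(names(x$denticity), x$denticity, sep = " = ",
                            collapse = ", "), "\n")
  invisible(x)
}
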