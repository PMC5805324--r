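# Atomic structure container and scalar sequence/crystal-form properties.

#' Construct a structure object from an atom table
#'
#' The central container of the package: an atom table in author numbering
#' plus optional extra coordinate models and per-residue secondary-structure
#' labels.  Most users will obtain one from [read_structure()] or
#' [make_toy_structure()] rather than call this directly.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `altloc`, `res_name`, `chain`, `res_seq`, `icode`, `x`, `y`, `z`,
#'   `occupancy`, `b_factor`, `is_hetero`.
#' @param models optional list of additional n_atoms x 3 coordinate matrices
#'   (model 1 lives in `atoms`); used for multi-model files.
#' @param ss optional data.frame `chain`, `res_seq`, `icode`, `label` with
#'   labels in `H` (helix), `E` (sheet), `other`; residues not listed default
#'   to `"other"`.
#' @return An object of class `cleft_structure`.
#' @export
new_structure <- function(atoms, models = NULL, ss = NULL) {
  req <- c("serial", "name", "element", "altloc", "res_name", "chain",
           "res_seq", "icode", "x", "y", "z", "occupancy", "b_factor",
           "is_hetero")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop2("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop2("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop2("non-finite coordinates in atom table")
  if (any(is.na(atoms$element) | atoms$element == ""))
    stop2("every atom needs an element symbol")
  if (anyDuplicated(atoms$serial)) stop2("atom serial numbers must be unique within a model")
  atoms$serial <- as.integer(atoms$serial)
  atoms$res_seq <- as.integer(atoms$res_seq)
  rownames(atoms) <- NULL
  s <- structure(list(atoms = atoms, models = models %||% list(), ss = ss),
                 class = "cleft_structure")
  s
}

res_key <- function(chain, res_seq, icode) {
  ic <- ifelse(is.na(icode) | icode == "", "", icode)
  paste0(chain, ":", res_seq, ic)
}

#' Residue-level summary of a structure
#'
#' One row per residue with its classification into `polymer` (standard
#' amino acid from ATOM records), `ligand` (other HETATM groups, including
#' hetero peptides), `metal` (single metal-ion residues) or `water`.
#'
#' @param s a `cleft_structure`.
#' @return data.frame with columns `key`, `chain`, `res_seq`, `icode`,
#'   `res_name`, `class`, `n_atoms`.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- res_key(a$chain, a$res_seq, a$icode)
  first <- !duplicated(key)
  rt <- data.frame(key = key[first], chain = a$chain[first],
                   res_seq = a$res_seq[first], icode = a$icode[first],
                   res_name = a$res_name[first],
                   stringsAsFactors = FALSE)
  rt$n_atoms <- as.integer(table(key)[rt$key])
  het <- tapply(a$is_hetero, key, any)[rt$key]
  cls <- rep("ligand", nrow(rt))
  cls[rt$res_name %in% WATER_NAMES] <- "water"
  is_metal <- rt$n_atoms == 1L &
    toupper(a$element[first]) %in% METAL_ELEMENTS
  cls[is_metal] <- "metal"
  cls[!het & rt$res_name %in% AA3] <- "polymer"
  rt$class <- cls
  rt
}

#' @export
print.cleft_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("<cleft_structure>", nrow(x$atoms), "atoms,",
      length(x$models) + 1L, "model(s)\n")
  cat("  residues:", paste(names(table(rt$class)), table(rt$class),
                           collapse = ", ", sep = " = "), "\n")
  invisible(x)
}

#' Number of resolved polymer residues
#'
#' Count of polymer residues with at least one resolved atom; the default
#' denominator for interaction densities and residue-category percentages.
#'
#' @param s a `cleft_structure`.
#' @return integer.
#' @export
n_resolved <- function(s) {
  sum(residue_table(s)$class == "polymer")
}

#' Per-residue secondary structure labels
#'
#' @param s a `cleft_structure`.
#' @return character vector over polymer residues (in atom order), values in
#'   `H`, `E`, `other`.
#' @export
ss_labels <- function(s) {
  rt <- residue_table(s)
  rt <- rt[rt$class == "polymer", ]
  lab <- rep("other", nrow(rt))
  if (!is.null(s$ss) && nrow(s$ss)) {
    k <- res_key(s$ss$chain, s$ss$res_seq, s$ss$icode)
    m <- match(rt$key, k)
    lab[!is.na(m)] <- s$ss$label[m[!is.na(m)]]
  }
  names(lab) <- rt$key
  lab
}

# expand HELIX/SHEET start-end records into a per-residue ss table
ss_from_ranges <- function(helix, sheet) {
  rows <- list()
  expand <- function(tab, lab) {
    if (is.null(tab) || length(tab$start) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(tab$start), function(i) {
      data.frame(chain = tab$chain[i],
                 res_seq = seq(tab$start[i], tab$end[i]),
                 icode = "", label = lab, stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(expand(helix, "H"), expand(sheet, "E"))
  if (is.null(out)) NULL else out
}

#' Read a structure from PDB or mmCIF
#'
#' Thin wrapper over `bio3d::read.pdb()` / `bio3d::read.cif()`.  Hydrogens
#' are dropped, alternate locations are resolved to the highest-occupancy
#' conformer (ties broken in favour of altloc `A`), multi-model files yield
#' extra coordinate models in file order, and HELIX/SHEET records populate
#' per-residue secondary-structure labels.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `cleft_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  p <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                         verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop2("could not parse ", format, " file '", path,
                              "': ", conditionMessage(e)))
  a <- p$atom
  if (is.null(a) || nrow(a) == 0L) stop2("empty structure: no atoms in ", path)
  atoms <- data.frame(
    serial = a$eleno, name = a$elety,
    element = toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                             substr(gsub("[0-9]", "", a$elety), 1, 1),
                             a$elesy)),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    res_name = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
    res_seq = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    is_hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
  keep <- !(atoms$element %in% c("H", "D"))
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0L) stop2("empty structure after hydrogen removal")
  # altloc: highest occupancy wins; ties prefer 'A'
  akey <- paste(res_key(atoms$chain, atoms$res_seq, atoms$icode), atoms$name)
  ord <- order(akey, -atoms$occupancy,
               ifelse(atoms$altloc == "", 0L, match(atoms$altloc, LETTERS)))
  atoms <- atoms[ord, ][!duplicated(akey[ord]), , drop = FALSE]
  atoms <- atoms[order(match(atoms$serial, a$eleno[keep])), , drop = FALSE]

  models <- list()
  if (!is.null(p$xyz) && is.matrix(p$xyz) && nrow(p$xyz) > 1) {
    idx <- match(atoms$serial, a$eleno)  # rows kept, original order
    for (m in 2:nrow(p$xyz)) {
      mm <- matrix(p$xyz[m, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
      models[[length(models) + 1L]] <- mm
    }
  }
  ss <- ss_from_ranges(p$helix, p$sheet)
  new_structure(atoms, models = models, ss = ss)
}

#' Write a structure (or its models) as PDB
#'
#' Single-model structures are written as a flat record list; structures with
#' extra models are written as multi-model PDB (`MODEL`/`ENDMDL` blocks), the
#' native trajectory format of this package.  Records are formatted by
#' `bio3d::write.pdb()`.
#'
#' @param s a `cleft_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  write_one <- function(xyz, file) {
    bio3d::write.pdb(file = file, xyz = as.numeric(t(xyz)),
                     type = ifelse(a$is_hetero, "HETATM", "ATOM"),
                     resno = a$res_seq, resid = a$res_name,
                     eleno = a$serial, elety = a$name, chain = a$chain,
                     insert = ifelse(a$icode == "", NA, a$icode),
                     alt = ifelse(a$altloc == "", NA, a$altloc),
                     o = a$occupancy, b = a$b_factor, elesy = a$element)
  }
  coords0 <- as.matrix(a[, c("x", "y", "z")])
  if (length(s$models) == 0L) {
    write_one(coords0, path)
    return(invisible(path))
  }
  all_models <- c(list(coords0), s$models)
  blocks <- character(0)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  for (i in seq_along(all_models)) {
    write_one(all_models[[i]], tf)
    lines <- readLines(tf)
    lines <- lines[grepl("^(ATOM|HETATM)", lines)]
    blocks <- c(blocks, sprintf("MODEL     %4d", i), lines, "ENDMDL")
  }
  writeLines(c(blocks, "END"), path)
  invisible(path)
}

#' Read a sequence record
#'
#' Accepts either a FASTA file (first record, via `bio3d::read.fasta()`) or a
#' plain 1-letter string.  Only the 20 standard amino-acid codes are allowed.
#'
#' @param x file path to a FASTA file, or a character string of residues.
#' @param id record id used when `x` is a plain string.
#' @return list with `id`, `sequence`, `length` (class `sequence_record`).
#' @export
sequence_record <- function(x, id = "seq") {
  if (length(x) == 1L && file.exists(x) && grepl("[./]", x)) {
    fa <- bio3d::read.fasta(x)
    seqc <- toupper(fa$ali[1, ])
    seqc <- seqc[seqc != "-"]
    id <- rownames(fa$ali)[1]
  } else {
    seqc <- strsplit(toupper(paste(x, collapse = "")), "")[[1]]
  }
  bad <- setdiff(unique(seqc), unname(AA1))
  if (length(bad)) stop2("non-standard residue code(s): ", paste(bad, collapse = ", "))
  structure(list(id = id, sequence = paste(seqc, collapse = ""),
                 length = length(seqc)),
            class = "sequence_record")
}

#' Residue-class composition of a sequence or structure
#'
#' Tallies residues into the four category axes used in thermostability
#' comparisons: proline, charged, polar and hydrophobic.  The charged set
#' defaults to Glu/Arg/Lys; all sets are overridable via `scheme`.
#'
#' @param x a `sequence_record`, a plain sequence string, or a
#'   `cleft_structure` (polymer residues are used).
#' @param scheme named list of 1-letter residue sets, entries `proline`,
#'   `charged`, `polar`, `hydrophobic`.
#' @param strict if `TRUE`, unknown residue codes are an error; otherwise
#'   they are counted as `other` with a warning.
#' @return list with `counts` (named integer vector incl. `other`),
#'   `denominator` (number of residues tallied) and `scheme`.
#' @export
classify_residues <- function(x, scheme = residue_class_scheme(),
                              strict = TRUE) {
  if (inherits(x, "cleft_structure")) {
    rt <- residue_table(x)
    rn <- rt$res_name[rt$class == "polymer"]
    letters1 <- unname(AA1[rn])
    letters1[is.na(letters1)] <- "?"
  } else {
    if (inherits(x, "sequence_record")) x <- x$sequence
    letters1 <- strsplit(toupper(paste(x, collapse = "")), "")[[1]]
  }
  known <- letters1 %in% unname(AA1)
  if (any(!known)) {
    if (strict) stop2("unknown residue code(s): ",
                      paste(unique(letters1[!known]), collapse = ", "))
    warn2(sum(!known), " unknown residue(s) counted as 'other'")
  }
  counts <- vapply(scheme, function(set) sum(letters1 %in% set), integer(1))
  counts <- c(counts, other = sum(!known))
  list(counts = counts, denominator = length(letters1), scheme = scheme)
}

#' Default residue-class scheme
#'
#' Charged follows the Glu/Arg/Lys convention of thermostability comparisons;
#' polar and hydrophobic sets are explicit package defaults (the categories
#' are conventional, not universal) and may be overridden.
#'
#' @param proline,charged,polar,hydrophobic character vectors of 1-letter codes.
#' @return named list of residue sets.
#' @export
residue_class_scheme <- function(proline = "P",
                                 charged = c("E", "R", "K"),
                                 polar = c("S", "T", "N", "Q", "Y", "C", "H"),
                                 hydrophobic = c("A", "V", "L", "I", "M", "F",
                                                 "W", "P")) {
  list(proline = proline, charged = charged, polar = polar,
       hydrophobic = hydrophobic)
}

#' Matthews coefficient and solvent content
#'
#' Computes the crystal volume per Dalton, `V_M = V / (z * mass)` with `V`
#' from the general triclinic cell-volume formula, and the solvent fraction
#' `1 - 1.23 / V_M` (clamped to `[0, 1]`).
#'
#' @param a,b,c cell edge lengths, Angstrom.
#' @param alpha,beta,gamma cell angles, degrees.
#' @param z molecules per unit cell.
#' @param mass molecular mass, Da.
#' @return list with `v_m` (A^3/Da), `solvent_fraction` and `solvent_pct`.
#' @export
matthews_and_solvent <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                                 z, mass) {
  if (any(c(a, b, c) <= 0)) stop2("cell lengths must be positive")
  if (z < 1) stop2("z must be >= 1")
  if (mass <= 0) stop2("mass must be positive")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  vol <- a * b * c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  v_m <- vol / (z * mass)
  solvent_from_vm(v_m)
}

#' Solvent content from a Matthews coefficient
#'
#' @param v_m Matthews coefficient, A^3/Da.
#' @return list with `v_m`, `solvent_fraction`, `solvent_pct`.
#' @export
solvent_from_vm <- function(v_m) {
  sf <- 1 - 1.23 / v_m
  if (sf < 0) {
    warn2("V_M below 1.23 A^3/Da: solvent content clamped to 0")
    sf <- 0
  }
  sf <- min(sf, 1)
  list(v_m = v_m, solvent_fraction = sf, solvent_pct = 100 * sf)
}

#' Molar extinction coefficient at 280 nm
#'
#' Standard heavy-chromophore formula: `5500 * nTrp + 1490 * nTyr`, plus
#' `125` per cystine pair in `"oxidized"` mode (pairs = `floor(nCys / 2)`).
#'
#' @param seq a `sequence_record` or sequence string.
#' @param cystine_mode `"reduced"` (default) or `"oxidized"`.
#' @return extinction coefficient, 1/(M cm).
#' @export
extinction_coefficient <- function(seq, cystine_mode = c("reduced", "oxidized")) {
  cystine_mode <- match.arg(cystine_mode)
  if (!inherits(seq, "sequence_record")) seq <- sequence_record(seq)
  sc <- strsplit(seq$sequence, "")[[1]]
  eps <- 5500 * sum(sc == "W") + 1490 * sum(sc == "Y")
  if (cystine_mode == "oxidized") eps <- eps + 125 * (sum(sc == "C") %/% 2)
  eps
}
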