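# Independent brute-force oracles used to validate the detectors on small
# synthetic structures.  These deliberately re-derive everything with plain
# double loops and literal rules, sharing no code path with the package's
# vectorised implementations.

oracle_coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

oracle_polymer_idx <- function(s) {
  rt <- residue_table(s)
  keys <- rt$key[rt$class == "polymer"]
  which(paste0(s$atoms$chain, ":", s$atoms$res_seq,
               ifelse(s$atoms$icode == "", "", s$atoms$icode)) %in% keys)
}

oracle_dist <- function(co, i, j) sqrt(sum((co[i, ] - co[j, ])^2))

oracle_angle <- function(co, at, p1, p2) {
  u <- co[p1, ] - co[at, ]; v <- co[p2, ] - co[at, ]
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, ct))) * 180 / pi
}

# nearest same-residue atom within 1.9 A
oracle_antecedent <- function(s, co, i) {
  a <- s$atoms
  same <- which(a$chain == a$chain[i] & a$res_seq == a$res_seq[i] &
                  a$icode == a$icode[i])
  same <- same[same != i]
  best <- NA_integer_; bd <- 1.9
  for (j in same) {
    d <- oracle_dist(co, i, j)
    if (d <= bd) { bd <- d; best <- j }
  }
  best
}

# counts per interaction class by exhaustive pair scan
oracle_interaction_counts <- function(s, chemistry = default_chemistry()) {
  co <- oracle_coords(s)
  a <- s$atoms
  poly <- oracle_polymer_idx(s)
  in_dict <- function(i, dict) {
    d <- dict[[a$res_name[i]]]
    !is.null(d) && a$name[i] %in% d
  }
  is_donor <- function(i) (a$name[i] == "N" && a$res_name[i] != "PRO") ||
    in_dict(i, chemistry$donors)
  is_acc <- function(i) a$name[i] %in% c("O", "OXT") &&
    toupper(a$element[i]) == "O" || in_dict(i, chemistry$acceptors)
  same_res <- function(i, j) a$chain[i] == a$chain[j] &&
    a$res_seq[i] == a$res_seq[j] && a$icode[i] == a$icode[j]
  backbone <- c("N", "CA", "C", "O", "OXT")
  cov_adj <- function(i, j) a$chain[i] == a$chain[j] &&
    abs(a$res_seq[i] - a$res_seq[j]) == 1 &&
    a$name[i] %in% backbone && a$name[j] %in% backbone

  n_hb <- 0L; n_weak <- 0L; n_ionic <- 0L; n_hyd <- 0L; n_arom <- 0L
  seen_hb <- character(0); seen_weak <- character(0)
  seen_ionic <- character(0)

  for (i in poly) for (j in poly) {
    if (i == j || same_res(i, j) || cov_adj(i, j)) next
    d <- oracle_dist(co, i, j)
    # regular H-bond, donor i -> acceptor j
    if (is_donor(i) && is_acc(j) && d <= 3.9) {
      ante <- oracle_antecedent(s, co, i)
      ok <- is.na(ante) || oracle_angle(co, i, ante, j) > 90
      pid <- paste(min(i, j), max(i, j))
      if (ok && !(pid %in% seen_hb)) { n_hb <- n_hb + 1L; seen_hb <- c(seen_hb, pid) }
    }
    # weak C-H...A bond
    if (toupper(a$element[i]) == "C" && is_acc(j) && d >= 3.6 && d <= 3.9) {
      ante <- oracle_antecedent(s, co, i)
      ok <- is.na(ante) ||
        (oracle_angle(co, i, ante, j) > 90 && oracle_angle(co, i, ante, j) < 130)
      pid <- paste(min(i, j), max(i, j))
      if (ok && !(pid %in% seen_weak)) { n_weak <- n_weak + 1L; seen_weak <- c(seen_weak, pid) }
    }
    # ionic, once per residue pair
    if (in_dict(i, chemistry$negative) && in_dict(j, chemistry$positive) &&
        d <= 4.0) {
      rid <- paste(sort(c(paste(a$chain[i], a$res_seq[i]),
                          paste(a$chain[j], a$res_seq[j]))), collapse = "|")
      if (!(rid %in% seen_ionic)) { n_ionic <- n_ionic + 1L; seen_ionic <- c(seen_ionic, rid) }
    }
  }

  # aromatic ring pairs
  ring_atoms <- list()
  for (i in poly) {
    rr <- chemistry$rings[[a$res_name[i]]]
    if (is.null(rr)) next
    for (ri in seq_along(rr)) {
      if (a$name[i] %in% rr[[ri]]) {
        k <- paste(a$chain[i], a$res_seq[i], ri)
        ring_atoms[[k]] <- c(ring_atoms[[k]], i)
      }
    }
  }
  ring_atoms <- Filter(function(v) length(v) >= 5, ring_atoms)
  arom_pairs <- character(0)
  kk <- names(ring_atoms)
  if (length(ring_atoms) >= 2) {
    for (p in seq_len(length(ring_atoms) - 1)) for (q in seq((p + 1), length(ring_atoms))) {
      resp <- sub(" \\d+$", "", kk[p]); resq <- sub(" \\d+$", "", kk[q])
      if (resp == resq) next
      found <- FALSE
      for (i in ring_atoms[[p]]) for (j in ring_atoms[[q]])
        if (oracle_dist(co, i, j) <= 4.0) found <- TRUE
      if (found) {
        n_arom <- n_arom + 1L
        for (i in ring_atoms[[p]]) for (j in ring_atoms[[q]])
          arom_pairs <- c(arom_pairs, paste(min(i, j), max(i, j)))
      }
    }
  }

  for (ii in seq_along(poly)) for (jj in seq_len(length(poly))) {
    i <- poly[ii]; j <- poly[jj]
    if (i >= j || same_res(i, j)) next
    if (in_dict(i, chemistry$apolar) && in_dict(j, chemistry$apolar) &&
        oracle_dist(co, i, j) <= 4.0 &&
        !(paste(i, j) %in% arom_pairs))
      n_hyd <- n_hyd + 1L
  }

  c(hbond = n_hb, weak_hbond = n_weak, ionic = n_ionic,
    hydrophobic = n_hyd, aromatic = n_arom)
}

# apply a rigid motion (rotation about an arbitrary axis + translation)
rigid_motion <- function(s, angle = 37, axis = c(1, 2, 3),
                         shift = c(11, -7, 5)) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  co <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- co[, 1] + shift[1]
  s$atoms$y <- co[, 2] + shift[2]
  s$atoms$z <- co[, 3] + shift[3]
  if (length(s$models))
    s$models <- lapply(s$models, function(m)
      sweep(m %*% t(R), 2, -shift))
  s
}

# coarse grid-search least-squares Michaelis-Menten oracle
grid_mm_fit <- function(S, v, km_grid = seq(5, 100, by = 0.5),
                        vmax_grid = NULL) {
  if (is.null(vmax_grid)) vmax_grid <- seq(0.5, 1.5, by = 0.01) * max(v)
  best <- c(km = NA, vmax = NA); bsse <- Inf
  for (km in km_grid) for (vm in vmax_grid) {
    sse <- sum((v - vm * S / (km + S))^2)
    if (sse < bsse) { bsse <- sse; best <- c(km = km, vmax = vm) }
  }
  best
}
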