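# Brute-force reference implementations: explicit all-pairs scans with
# scalar geometry, independent of the package's vectorized detector paths.

o_dist <- function(a, b) sqrt(sum((a - b)^2))

o_angle <- function(a, b, c) {
  u <- a - b; w <- c - b
  acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
}

o_neighbors <- function(sys) {
  nb <- vector("list", nrow(sys$atoms))
  b <- sys$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b[k, 1]]] <- c(nb[[b[k, 1]]], b[k, 2])
    nb[[b[k, 2]]] <- c(nb[[b[k, 2]]], b[k, 1])
  }
  nb
}

o_hbond_energy <- function(d, dang, aang, p) {
  dist_f <- max(0, min(1, (p$hbond_d_zero - max(d, p$hbond_d_full)) /
                         (p$hbond_d_zero - p$hbond_d_full)))
  af <- function(th) max(0, min(1, (th - p$hbond_angle_min) /
                                  (180 - p$hbond_angle_min)))
  p$hbond_optimum_energy * dist_f * af(dang) * af(aang)
}

# every donor-H...acceptor triple across the two partition sets
oracle_hbonds <- function(sys, coords, pair, p) {
  a <- sys$atoms
  nb <- o_neighbors(sys)
  out <- list()
  for (parts in list(c(1, 2), c(2, 1))) {
    don_part <- pair[[parts[1]]]; acc_part <- pair[[parts[2]]]
    donors <- which(a$elesy %in% c("N", "O") & a$partition %in% don_part)
    acceptors <- which(a$elesy %in% c("N", "O") & a$partition %in% acc_part)
    for (d in donors) {
      hs <- nb[[d]][a$elesy[nb[[d]]] == "H"]
      for (h in hs) for (ac in acceptors) {
        if (ac == d) next
        dist <- o_dist(coords[h, ], coords[ac, ])
        if (dist >= p$hbond_d_zero) next
        dang <- o_angle(coords[d, ], coords[h, ], coords[ac, ])
        heavy_nb <- nb[[ac]][a$elesy[nb[[ac]]] != "H"]
        aang <- if (length(heavy_nb))
          o_angle(coords[h, ], coords[ac, ], coords[heavy_nb[1], ]) else 180
        e <- o_hbond_energy(dist, dang, aang, p)
        if (e >= p$hbond_threshold) {
          ep <- if (parts[1] == 1) c(d, ac) else c(ac, d)
          out[[length(out) + 1L]] <- data.frame(atom_a = ep[1], atom_b = ep[2],
                                                donor = d, acceptor = ac,
                                                energy = e)
        }
      }
    }
  }
  if (!length(out)) return(data.frame(atom_a = integer(0), atom_b = integer(0),
                                      donor = integer(0), acceptor = integer(0),
                                      energy = numeric(0)))
  unique(do.call(rbind, out))
}

oracle_hp <- function(sys, coords, pair, p) {
  a <- sys$atoms
  ia <- which(a$partition %in% pair$a & a$hydrophobic)
  ib <- which(a$partition %in% pair$b & a$hydrophobic)
  out <- list()
  for (i in ia) for (j in ib) {
    if (o_dist(coords[i, ], coords[j, ]) <= p$hp_cutoff)
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

o_group_centers <- function(sys, coords) {
  cg <- sys$charge_groups
  t(vapply(cg$group, function(g) {
    m <- which(sys$atoms$charge_group %in% g & sys$atoms$elesy != "H")
    colMeans(coords[m, , drop = FALSE])
  }, numeric(3)))
}

oracle_ionic <- function(sys, coords, pair, p) {
  cg <- sys$charge_groups
  cen <- o_group_centers(sys, coords)
  out <- list()
  for (i in which(cg$partition %in% pair$a & cg$charge != 0))
    for (j in which(cg$partition %in% pair$b & cg$charge != 0)) {
      if (cg$charge[i] * cg$charge[j] < 0 &&
          o_dist(cen[i, ], cen[j, ]) <= p$ionic_cutoff)
        out[[length(out) + 1L]] <- c(cg$rep_atom[i], cg$rep_atom[j])
    }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

oracle_water_bridges <- function(sys, coords, p) {
  a <- sys$atoms
  hb_r <- oracle_hbonds(sys, coords, list(a = "receptor", b = "water"), p)
  hb_l <- oracle_hbonds(sys, coords, list(a = "ligand", b = "water"), p)
  out <- list()
  for (w in intersect(hb_r$atom_b, hb_l$atom_b)) {
    for (re in unique(hb_r$atom_a[hb_r$atom_b == w]))
      for (le in unique(hb_l$atom_a[hb_l$atom_b == w]))
        out[[length(out) + 1L]] <- c(w, re, le)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3))
  do.call(rbind, out)
}

oracle_ionic_bridges <- function(sys, coords, p) {
  a <- sys$atoms
  cg <- sys$charge_groups
  cen <- o_group_centers(sys, coords)
  out <- list()
  for (ct in which(a$partition == "cation")) {
    rr <- integer(0); ll <- integer(0)
    for (g in seq_len(nrow(cg))) {
      if (cg$charge[g] >= 0) next
      d <- o_dist(coords[ct, ], cen[g, ])
      if (d <= p$ionic_cutoff) {
        if (cg$partition[g] == "receptor") rr <- c(rr, cg$rep_atom[g])
        if (cg$partition[g] == "ligand") ll <- c(ll, cg$rep_atom[g])
      }
    }
    for (re in rr) for (le in ll)
      out[[length(out) + 1L]] <- c(ct, re, le)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3))
  do.call(rbind, out)
}

pair_key <- function(m) if (nrow(m)) sort(apply(m, 1, paste, collapse = " ")) else character(0)
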