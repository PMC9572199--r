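# ---- event planting --------------------------------------------------------

# side-chain donor / acceptor / hydrophobic atoms usable per receptor type
slot_roles <- list(
  HBo = list(resids = c("SER", "TYR", "GLN", "LYS", "ARG"),
             atoms = list(SER = c(D = "OG", H = "HG"),
                          TYR = c(D = "OH", H = "HH"),
                          GLN = c(D = "NE2", H = "HE2"),
                          LYS = c(D = "NZ", H = "HZ"),
                          ARG = c(D = "NH1", H = "HH1"))),
  HP = list(resids = c("LEU", "ALA"),
            atoms = list(LEU = c(C = "CD1"), ALA = c(C = "CB"))),
  ionic = list(resids = c("LYS", "ARG")),
  water_bridge = list(resids = c("GLU", "ASP"),
                      atoms = list(GLU = c(A = "OE2", NB = "CD"),
                                   ASP = c(A = "OD2", NB = "CG"))),
  ionic_bridge = list(resids = c("GLU", "ASP"))
)

# planting directions for a sulfate/carboxylate group: members stacked so
# that the group center lands on `target` with the oxygens facing away from
# the receptor surface below
plant_group_positions <- function(sys, lig_group, target) {
  cg <- sys$charge_groups
  members <- which(sys$atoms$charge_group %in% cg$group[lig_group])
  el <- sys$atoms$elety[members]
  if ("S" %in% el) {
    dirs <- rbind(c(0, 0.33, 0.94), c(0, 0.33, -0.94), c(0.94, 0.33, 0))
    s_pos <- target - 1.45 * colMeans(dirs)
    pos <- rbind(s_pos, sweep(1.45 * dirs, 2, s_pos, "+"))
    ord <- match(c("S", "O1S", "O2S", "O3S"), el)
  } else {
    c6 <- target - c(0, 0.467, 0)
    pos <- rbind(c6, c6 + c(-1.07, 0.7, 0), c6 + c(1.07, 0.7, 0))
    ord <- match(c("C6", "O6A", "O6B"), el)
  }
  list(atoms = members[ord], pos = pos)
}

mer_unit <- function(sys, mer, what) {
  a <- sys$atoms
  sel <- which(a$partition == "ligand" & a$resno == mer)
  resid <- a$resid[sel[1]]
  pick <- function(nm) sel[match(nm, a$elety[sel])]
  if (what == "hydroxyl") {
    if (resid == "NGA") list(A = pick("O3"), HA = pick("HO3"), C = pick("C3"))
    else list(A = pick("O2"), HA = pick("HO2"), C = pick("C2"))
  } else if (what == "hp") {
    list(C = if (resid == "NGA") pick("CME") else pick("C4"))
  } else {  # charge group
    rep_name <- if (resid == "NGA") "S" else "C6"
    gid <- a$charge_group[pick(rep_name)]
    list(group = which(sys$charge_groups$group == gid))
  }
}

slot_atom <- function(sys, resno, elety) {
  a <- sys$atoms
  idx <- which(a$partition == "receptor" & a$resno == resno & a$elety == elety)
  if (!length(idx)) stop("slot atom not found: residue ", resno, " ", elety)
  idx[1]
}

# greedy assignment of receptor slots, ligand mers and mediators to events
allocate_events <- function(spec, sys) {
  ev <- spec$planted_events
  if (is.null(ev) || !nrow(ev)) return(list())
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  a <- sys$atoms
  slots <- unique(a$resno[a$partition == "receptor" &
                            a$resno <= min(13, spec$n_receptor_residues)])
  slot_resid <- vapply(slots, function(r) a$resid[a$partition == "receptor" &
                                                    a$resno == r][1], character(1))
  waters <- unique(a$resno[a$partition == "water"])
  cations <- which(a$partition == "cation")
  busy <- list(slot = list(), mer = list(), water = list(), cation = list())
  overlaps <- function(kind, id, s, e) {
    iv <- busy[[kind]][[as.character(id)]]
    !is.null(iv) && any(s <= iv[, 2] & e >= iv[, 1])
  }
  claim <- function(kind, id, s, e) {
    key <- as.character(id)
    busy[[kind]][[key]] <<- rbind(busy[[kind]][[key]], c(s, e))
  }
  out <- vector("list", nrow(ev))
  for (k in seq_len(nrow(ev))) {
    type <- ev$type[k]; s <- ev$start[k]; e <- ev$end[k]
    role <- slot_roles[[type]]
    slot <- NA_integer_
    for (r in role$resids) {
      cand <- slots[slot_resid == r]
      cand <- cand[!vapply(cand, function(x) overlaps("slot", x, s, e), logical(1))]
      if (length(cand)) { slot <- cand[1]; break }
    }
    if (is.na(slot)) stop("no free receptor slot for planted ", type, " event")
    unit_kind <- switch(type, HBo = "hydroxyl", water_bridge = "hydroxyl",
                        HP = "hp", "group")
    mer <- NA_integer_
    for (m in seq_len(spec$n_mers)) {
      if (!overlaps("mer", m, s, e)) { mer <- m; break }
    }
    if (is.na(mer)) stop("no free ligand mer for planted ", type, " event")
    mediator <- NA_integer_
    if (type == "water_bridge") {
      free_w <- waters[!vapply(waters, function(w) overlaps("water", w, s, e),
                               logical(1))]
      if (!length(free_w)) stop("no free water mediator for planted event")
      mediator <- free_w[length(free_w)]  # use far-end waters as mediators
      claim("water", mediator, s, e)
    } else if (type == "ionic_bridge") {
      free_c <- cations[!vapply(cations, function(cc) overlaps("cation", cc, s, e),
                                logical(1))]
      if (!length(free_c)) stop("no free cation mediator for planted event")
      mediator <- free_c[length(free_c)]
      claim("cation", mediator, s, e)
    }
    claim("slot", slot, s, e)
    claim("mer", mer, s, e)
    out[[k]] <- list(type = type, start = s, end = e, slot = slot,
                     slot_resid = slot_resid[slots == slot][1], mer = mer,
                     mediator = mediator)
  }
  out
}

# receptor-side charge-group center for a slot (from base coordinates)
slot_group_center <- function(sys, base, resno) {
  a <- sys$atoms
  rep_name <- switch(a$resid[a$partition == "receptor" & a$resno == resno][1],
                     LYS = "NZ", ARG = "CZ", GLU = "CD", ASP = "CG")
  gid <- a$charge_group[slot_atom(sys, resno, rep_name)]
  members <- which(a$charge_group %in% gid & a$elesy != "H")
  colMeans(base[members, , drop = FALSE])
}

# resolve one event into moved-atom positions and its ledger endpoints
plant_event <- function(sys, base, ev, params) {
  a <- sys$atoms
  type <- ev$type
  if (type == "HBo") {
    da <- slot_roles$HBo$atoms[[ev$slot_resid]]
    D <- slot_atom(sys, ev$slot, da[["D"]]); H <- slot_atom(sys, ev$slot, da[["H"]])
    unit <- mer_unit(sys, ev$mer, "hydroxyl")
    u <- unitv(base[H, ] - base[D, ])
    A <- base[H, ] + 1.9 * u
    list(atoms = c(unit$A, unit$HA, unit$C),
         pos = rbind(A, A + 0.96 * perp_unit(u), A + 1.43 * u),
         receptor_atom = D, ligand_atom = unit$A, mediator = NA_integer_,
         class_label = NA_character_)
  } else if (type == "HP") {
    Ratom <- slot_atom(sys, ev$slot, slot_roles$HP$atoms[[ev$slot_resid]][["C"]])
    unit <- mer_unit(sys, ev$mer, "hp")
    list(atoms = unit$C, pos = rbind(base[Ratom, ] + c(0, 3.8, 0)),
         receptor_atom = Ratom, ligand_atom = unit$C, mediator = NA_integer_,
         class_label = NA_character_)
  } else if (type == "ionic") {
    rc <- slot_group_center(sys, base, ev$slot)
    unit <- mer_unit(sys, ev$mer, "group")
    pl <- plant_group_positions(sys, unit$group, rc + c(0, 4.2, 0))
    rep_name <- if (ev$slot_resid == "LYS") "NZ" else "CZ"
    list(atoms = pl$atoms, pos = pl$pos,
         receptor_atom = slot_atom(sys, ev$slot, rep_name),
         ligand_atom = sys$charge_groups$rep_atom[unit$group],
         mediator = NA_integer_, class_label = NA_character_)
  } else if (type == "water_bridge") {
    wa <- slot_roles$water_bridge$atoms[[ev$slot_resid]]
    P <- slot_atom(sys, ev$slot, wa[["A"]]); NB <- slot_atom(sys, ev$slot, wa[["NB"]])
    unit <- mer_unit(sys, ev$mer, "hydroxyl")
    wsel <- which(a$partition == "water" & a$resno == ev$mediator)
    WO <- wsel[a$elety[wsel] == "O"]
    WH1 <- wsel[a$elety[wsel] == "H1"]; WH2 <- wsel[a$elety[wsel] == "H2"]
    dir <- unitv(base[P, ] - base[NB, ])
    perp <- perp_unit_prefer_z(dir)
    wo <- base[P, ] + 2.8 * dir
    dir2 <- unitv(0.25 * dir + 0.968 * perp)
    A <- wo + 2.8 * dir2
    perp2 <- unitv(cross3(dir2, dir))
    list(atoms = c(WO, WH1, WH2, unit$A, unit$HA, unit$C),
         pos = rbind(wo, wo - 0.96 * dir, wo + 0.96 * dir2,
                     A, A + 0.96 * perp2, A + 1.43 * dir2),
         receptor_atom = P, ligand_atom = unit$A, mediator = WO,
         class_label = paste(a$elesy[P], "W", a$elesy[unit$A], sep = "-"))
  } else {  # ionic_bridge
    rc <- slot_group_center(sys, base, ev$slot)
    unit <- mer_unit(sys, ev$mer, "group")
    cat_pos <- rc + c(0, 4.2, 0)
    pl <- plant_group_positions(sys, unit$group, cat_pos + c(0, 4.2, 0))
    rep_name <- if (ev$slot_resid == "GLU") "CD" else "CG"
    rec_rep <- slot_atom(sys, ev$slot, rep_name)
    lig_rep <- sys$charge_groups$rep_atom[unit$group]
    list(atoms = c(ev$mediator, pl$atoms), pos = rbind(cat_pos, pl$pos),
         receptor_atom = rec_rep, ligand_atom = lig_rep,
         mediator = ev$mediator,
         class_label = paste(a$elesy[rec_rep], a$elesy[ev$mediator],
                             a$elesy[lig_rep], sep = "-"))
  }
}

# prefer the out-of-plane z direction when it is orthogonal to `dir`
perp_unit_prefer_z <- function(dir) {
  z <- c(0, 0, 1)
  w <- z - sum(z * dir) * dir
  if (sqrt(sum(w^2)) < 1e-6) perp_unit(dir) else unitv(w)
}

# geometric self-check: the planted configuration must satisfy its
# detector's predicate with at least a 10% margin
check_event_margin <- function(sys, coords, ev, planted, params) {
  type <- ev$type
  ok <- switch(type,
    HBo = {
      hb <- detect_hbonds(sys, coords, list(a = "receptor", b = "ligand"), params)
      any(hb$atom_a == planted$receptor_atom & hb$atom_b == planted$ligand_atom &
            hb$energy >= 1.1 * params$hbond_threshold)
    },
    HP = {
      d <- sqrt(sum((coords[planted$receptor_atom, ] - coords[planted$ligand_atom, ])^2))
      d <= 0.9 * params$hp_cutoff
    },
    ionic = {
      io <- detect_ionic(sys, coords, list(a = "receptor", b = "ligand"), params)
      any(io$atom_a == planted$receptor_atom & io$atom_b == planted$ligand_atom &
            io$distance <= 0.9 * params$ionic_cutoff)
    },
    water_bridge = {
      wb <- detect_water_bridges(sys, coords, params)
      any(wb$mediator == planted$mediator &
            wb$receptor_endpoint == planted$receptor_atom &
            wb$ligand_endpoint == planted$ligand_atom)
    },
    ionic_bridge = {
      ib <- detect_ionic_bridges(sys, coords, params)
      any(ib$mediator == planted$mediator &
            ib$receptor_endpoint == planted$receptor_atom &
            ib$ligand_endpoint == planted$ligand_atom)
    })
  if (!ok) stop("planted ", type, " event failed its geometric self-check")
  invisible(TRUE)
}

#' Generate a synthetic trajectory with planted ground truth
#'
#' Builds the system described by the spec, lays out a kinematic trajectory
#' (static receptor, rigid ligand oscillation, optional Gaussian jitter),
#' plants the requested interaction events on the receptor's exposed
#' side-chain row with a geometric margin, and returns the trajectory
#' together with a per-frame event ledger. Solvent and ions are
#' rejection-sampled away from the solutes and the planting zone so that a
#' noiseless fixture contains exactly the planted interactions.
#'
#' @param spec A [fixture_spec()].
#' @param params [analysis_params()] used for the generation-time
#'   self-check of every planted event.
#' @return Object of class `gag_fixture`: list with `traj` (a
#'   [trajectory()]), `ledger` (data frame: `frame`, `time_ps`, `type`,
#'   `receptor_atom`, `ligand_atom`, `mediator`, `class_label`), `spec`,
#'   and `events` (the resolved allocations).
#' @export
generate_trajectory <- function(spec, params = analysis_params()) {
  set.seed(spec$rng_seed)
  rec_origin <- c(15, 60, 15)
  lig_origin <- c(25, 82, 15)
  rec <- build_receptor(spec$n_receptor_residues, rec_origin)
  lig <- build_ligand(spec$ligand_isomer, spec$n_mers, lig_origin)
  solute <- rbind(rec, lig)
  exclusion <- rbind(rec_origin + c(-6, -1, -6),
                     rec_origin + c(12 * 4 + 6, 16, 6))
  solvent <- build_solvent(spec, as.matrix(solute[, c("x", "y", "z")]), exclusion)
  atoms <- rbind(solute, solvent)
  sys <- mol_system(atoms)
  base <- sys_coords(sys)
  events <- allocate_events(spec, sys)
  planted <- lapply(events, function(ev) plant_event(sys, base, ev, params))
  # self-check each planted configuration on a clean frame
  for (k in seq_along(events)) {
    xyz <- base
    xyz[planted[[k]]$atoms, ] <- planted[[k]]$pos
    check_event_margin(sys, xyz, events[[k]], planted[[k]], params)
  }
  nf <- spec$n_frames
  na <- nrow(base)
  lig_idx <- which(sys$atoms$partition == "ligand")
  coords <- array(NA_real_, dim = c(na, 3, nf))
  ledger <- vector("list", length(events))
  for (f in seq_len(nf)) {
    xyz <- base
    xyz[lig_idx, 1] <- xyz[lig_idx, 1] +
      spec$ligand_motion_amp * sin(2 * pi * (f - 1) / nf)
    for (k in seq_along(events)) {
      if (f >= events[[k]]$start && f <= events[[k]]$end)
        xyz[planted[[k]]$atoms, ] <- planted[[k]]$pos
    }
    coords[, , f] <- xyz
  }
  if (spec$jitter_sigma > 0)
    coords <- coords + stats::rnorm(length(coords), 0, spec$jitter_sigma)
  times <- spec$frame_interval_ps * seq_len(nf)
  for (k in seq_along(events)) {
    fr <- events[[k]]$start:events[[k]]$end
    ledger[[k]] <- data.frame(
      frame = fr, time_ps = times[fr], type = events[[k]]$type,
      receptor_atom = planted[[k]]$receptor_atom,
      ligand_atom = planted[[k]]$ligand_atom,
      mediator = planted[[k]]$mediator,
      class_label = planted[[k]]$class_label)
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(frame = integer(0), time_ps = numeric(0), type = character(0),
               receptor_atom = integer(0), ligand_atom = integer(0),
               mediator = integer(0), class_label = character(0))
  ledger <- ledger[order(ledger$frame, ledger$type), ]
  rownames(ledger) <- NULL
  structure(list(traj = trajectory(sys, times, coords), ledger = ledger,
                 spec = spec, events = events), class = "gag_fixture")
}

#' @export
print.gag_fixture <- function(x, ...) {
  cat(sprintf("synthetic fixture: %d atoms, %d frames, %d planted events (%d frame-events)\n",
              n_atoms(x$traj$system), n_frames(x$traj), length(x$events),
              nrow(x$ledger)))
  invisible(x)
}

#' Compare detector output against a ground-truth ledger
#'
#' Runs all five detectors on every frame and matches the detected
#' (frame, type, endpoints, mediator) tuples against the ledger.
#'
#' @param traj A [trajectory()].
#' @param ledger Ledger data frame from [generate_trajectory()].
#' @param params [analysis_params()].
#' @param types Event types to evaluate.
#' @return List with `per_type` (type, n_true, n_detected, n_matched,
#'   precision, recall) and overall `precision` and `recall`.
#' @export
validate_ledger <- function(traj, ledger, params = analysis_params(),
                            types = c("HBo", "HP", "ionic", "water_bridge",
                                      "ionic_bridge")) {
  sys <- traj$system
  topo <- hb_topology(sys)
  key <- function(frame, type, ra, la, med) {
    if (!length(ra)) return(character(0))
    paste(frame, type, ra, la, ifelse(is.na(med), 0L, med))
  }
  det <- character(0)
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    pr <- list(a = "receptor", b = "ligand")
    if ("HBo" %in% types) {
      hb <- detect_hbonds(sys, xyz, pr, params, topo)
      det <- c(det, key(f, "HBo", hb$atom_a, hb$atom_b, NA))
    }
    if ("HP" %in% types) {
      hp <- detect_hydrophobic(sys, xyz, pr, params)
      det <- c(det, key(f, "HP", hp$atom_a, hp$atom_b, NA))
    }
    if ("ionic" %in% types) {
      io <- detect_ionic(sys, xyz, pr, params)
      det <- c(det, key(f, "ionic", io$atom_a, io$atom_b, NA))
    }
    if ("water_bridge" %in% types) {
      wb <- detect_water_bridges(sys, xyz, params, topo)
      det <- c(det, key(f, "water_bridge", wb$receptor_endpoint,
                        wb$ligand_endpoint, wb$mediator))
    }
    if ("ionic_bridge" %in% types) {
      ib <- detect_ionic_bridges(sys, xyz, params, topo = topo)
      det <- c(det, key(f, "ionic_bridge", ib$receptor_endpoint,
                        ib$ligand_endpoint, ib$mediator))
    }
  }
  led <- ledger[ledger$type %in% types, , drop = FALSE]
  truth <- key(led$frame, led$type, led$receptor_atom, led$ligand_atom,
               led$mediator)
  per_type <- do.call(rbind, lapply(types, function(tt) {
    tk <- truth[led$type == tt]
    dk <- det[grepl(paste0(" ", tt, " "), det, fixed = TRUE)]
    nm <- length(intersect(unique(dk), unique(tk)))
    data.frame(type = tt, n_true = length(tk), n_detected = length(dk),
               n_matched = sum(dk %in% tk),
               precision = if (length(dk)) sum(dk %in% tk) / length(dk) else NA_real_,
               recall = if (length(tk)) sum(tk %in% dk) / length(tk) else NA_real_)
  }))
  list(per_type = per_type,
       precision = if (length(det)) sum(det %in% truth) / length(det) else NA_real_,
       recall = if (length(truth)) sum(truth %in% det) / length(truth) else NA_real_)
}

#' Write a fixture to disk as plain-text files
#'
#' @param fix A `gag_fixture` from [generate_trajectory()].
#' @param dir Output directory (created if needed). Writes
#'   `trajectory.pdb` (multi-model), `ledger.tsv` and `spec.yaml`.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(fix$traj$system, file.path(dir, "trajectory.pdb"),
                  fix$traj$coords)
  utils::write.table(fix$ledger, file.path(dir, "ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sp <- fix$spec
  sp$planted_events <- if (!is.null(sp$planted_events))
    lapply(seq_len(nrow(sp$planted_events)), function(i)
      as.list(sp$planted_events[i, ]))
  yaml::write_yaml(unclass(sp), file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Synthetic per-frame component-energy terms
#'
#' Produces a six-component energy table with optional linear drift and
#' Gaussian noise on the complex potential energy, for exercising the
#' binding-energy accounting.
#'
#' @param n_frames Number of frames.
#' @param frame_interval_ps Frame spacing, ps.
#' @param base Named list of the six baseline terms (kJ/mol).
#' @param drift Linear drift applied to `Epc`, kJ/mol per frame.
#' @param noise_sd Gaussian noise SD on `Epc`, kJ/mol.
#' @param rng_seed Seed for the noise.
#' @return Data frame with `time_ps` and the six term columns.
#' @export
synth_energy_terms <- function(n_frames = 1400, frame_interval_ps = 100,
                               base = list(Epr = -40000, Epl = -8000,
                                           Esr = 9000, Esl = 3000,
                                           Epc = -50000, Esc = 10000),
                               drift = 0, noise_sd = 0, rng_seed = 1L) {
  set.seed(rng_seed)
  f <- seq_len(n_frames)
  out <- data.frame(time_ps = frame_interval_ps * f)
  for (nm in c("Epr", "Epl", "Esr", "Esl", "Epc", "Esc"))
    out[[nm]] <- rep(base[[nm]], n_frames)
  out$Epc <- out$Epc + drift * (f - 1) +
    if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd) else 0
  out
}
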