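#' Synthetic fixture specification
#'
#' Describes a desk-scale two-solute system: a multi-domain reduced
#' receptor, a sulfated polysaccharide ligand of alternating
#' N-acetylgalactosamine / glucuronic-acid mers, explicit water and a salt
#' of one cation species, inside a rectangular box. Trajectories generated
#' from a spec are kinematic: a static receptor, a gently oscillating rigid
#' ligand, per-atom Gaussian jitter, and interactions planted at known
#' frames with a ground-truth ledger.
#'
#' @param n_receptor_residues Receptor chain length (default 60; use 585
#'   for the full-scale protein).
#' @param ligand_isomer `"CS4"` or `"CS6"`: position of the sulfate on the
#'   N-acetylgalactosamine mer (C4 vs C6).
#' @param n_mers Number of sugar mers (even; default 12, full scale 24).
#' @param n_waters,n_cations,n_anions Solvent/ion counts.
#' @param cation_species `"Na"`, `"Ca"` or `"Mg"`.
#' @param box Box dimensions in Angstrom (default 120 x 110 x 110).
#' @param n_frames Number of stored frames (ignored when `duration_ps` is
#'   given).
#' @param frame_interval_ps Time between stored frames, ps (default 100).
#' @param duration_ps Optional total simulated time; the frame count is
#'   `floor(duration_ps / frame_interval_ps)` (140000 ps at 100 ps spacing
#'   gives 1400 frames).
#' @param jitter_sigma Per-atom, per-frame Gaussian positional noise, Angstrom.
#' @param ligand_motion_amp Amplitude of the rigid ligand oscillation, Angstrom.
#' @param planted_events Data frame with columns `type` (HBo, HP, ionic,
#'   water_bridge, ionic_bridge), `start`, `end` (frame indices,
#'   inclusive); `NULL` for none. See [default_event_schedule()].
#' @param rng_seed Integer seed; generation is bit-reproducible given the
#'   seed.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_receptor_residues = 60,
                         ligand_isomer = c("CS4", "CS6"),
                         n_mers = 12,
                         n_waters = 500,
                         n_cations = 20,
                         n_anions = 40,
                         cation_species = c("Ca", "Na", "Mg"),
                         box = c(120, 110, 110),
                         n_frames = 200,
                         frame_interval_ps = 100,
                         duration_ps = NULL,
                         jitter_sigma = 0,
                         ligand_motion_amp = 1.0,
                         planted_events = NULL,
                         rng_seed = 1L) {
  ligand_isomer <- match.arg(ligand_isomer)
  cation_species <- match.arg(cation_species)
  if (!is.null(duration_ps)) n_frames <- floor(duration_ps / frame_interval_ps)
  if (n_frames < 1) stop("need at least one frame")
  if (n_mers %% 2 != 0 || n_mers < 2)
    stop("n_mers must be even (alternating disaccharide units)")
  if (any(box <= 0)) stop("box dimensions must be positive")
  if (!is.null(planted_events)) {
    stopifnot(all(c("type", "start", "end") %in% names(planted_events)))
    if (!all(planted_events$type %in%
             c("HBo", "HP", "ionic", "water_bridge", "ionic_bridge")))
      stop("unknown planted event type")
    if (any(planted_events$start < 1 | planted_events$end > n_frames |
            planted_events$start > planted_events$end))
      stop("planted event frame range outside trajectory")
  }
  structure(list(
    n_receptor_residues = as.integer(n_receptor_residues),
    ligand_isomer = ligand_isomer, n_mers = as.integer(n_mers),
    n_waters = as.integer(n_waters), n_cations = as.integer(n_cations),
    n_anions = as.integer(n_anions), cation_species = cation_species,
    box = box, n_frames = as.integer(n_frames),
    frame_interval_ps = frame_interval_ps, jitter_sigma = jitter_sigma,
    ligand_motion_amp = ligand_motion_amp, planted_events = planted_events,
    rng_seed = as.integer(rng_seed)), class = "fixture_spec")
}

#' Default planted-event schedule
#'
#' Three staggered occurrences of each of the five event types, with frame
#' windows scaled to the trajectory length.
#'
#' @param n_frames Trajectory length in frames.
#' @return Data frame with `type`, `start`, `end`.
#' @export
default_event_schedule <- function(n_frames = 200) {
  w <- function(a, b) c(max(1L, as.integer(round(a * n_frames))),
                        min(n_frames, as.integer(round(b * n_frames))))
  rows <- list(
    c("HBo", w(0.055, 0.25)), c("HBo", w(0.405, 0.60)), c("HBo", w(0.755, 0.95)),
    c("HP", w(0.105, 0.30)), c("HP", w(0.455, 0.65)), c("HP", w(0.805, 1.00)),
    c("ionic", w(0.055, 0.25)), c("ionic", w(0.405, 0.60)), c("ionic", w(0.755, 0.95)),
    c("water_bridge", w(0.105, 0.30)), c("water_bridge", w(0.455, 0.65)),
    c("water_bridge", w(0.805, 1.00)),
    c("ionic_bridge", w(0.155, 0.35)), c("ionic_bridge", w(0.505, 0.70)),
    c("ionic_bridge", w(0.855, 1.00))
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(type = r[1], start = as.integer(r[2]), end = as.integer(r[3]))))
  out
}

# ---- building blocks -------------------------------------------------------

atom_row <- function(elety, elesy, resid, resno, chain, xyz, partition) {
  data.frame(elety = elety, elesy = elesy, resid = resid, resno = resno,
             chain = chain, x = xyz[1], y = xyz[2], z = xyz[3],
             partition = partition, stringsAsFactors = FALSE)
}

# reduced-residue templates; `s` flips the side chain to +y (exposed row)
receptor_motif <- function() {
  c("LYS", "SER", "GLU", "LEU", "ARG", "GLN", "ASP", "ALA", "TYR", "GLY",
    "LYS", "SER", "GLU")
}

residue_atoms <- function(resname, resno, ca, s) {
  bb <- list(
    c("N", "N", -1.2, -0.8 * s, 0),
    c("H", "H", -1.2, (-0.8 - 1.01) * s, 0),
    c("CA", "C", 0, 0, 0),
    c("C", "C", 1.2, -0.8 * s, 0),
    c("O", "O", 1.2, (-0.8 - 0.7) * s, 1.0)
  )
  sc <- switch(resname,
    LYS = list(c("NZ", "N", 0, 1.5 * s, 0), c("HZ", "H", 0, 2.51 * s, 0)),
    ARG = list(c("CZ", "C", 0, 1.5 * s, 0), c("NH1", "N", 0, 2.83 * s, 0),
               c("HH1", "H", 0, 3.84 * s, 0)),
    GLU = list(c("CD", "C", 0, 1.5 * s, 0), c("OE1", "O", -1.07, 2.2 * s, 0),
               c("OE2", "O", 1.07, 2.2 * s, 0)),
    ASP = list(c("CG", "C", 0, 1.5 * s, 0), c("OD1", "O", -1.07, 2.2 * s, 0),
               c("OD2", "O", 1.07, 2.2 * s, 0)),
    LEU = list(c("CD1", "C", 0, 1.5 * s, 0)),
    SER = list(c("OG", "O", 0, 1.5 * s, 0), c("HG", "H", 0, 2.46 * s, 0)),
    GLN = list(c("CD", "C", 0, 1.5 * s, 0), c("OE1", "O", -1.07, 2.2 * s, 0),
               c("NE2", "N", 1.07, 2.2 * s, 0), c("HE2", "H", 1.07, 3.21 * s, 0)),
    ALA = list(c("CB", "C", 0, 1.5 * s, 0)),
    TYR = list(c("OH", "O", 0, 1.5 * s, 0), c("HH", "H", 0, 2.46 * s, 0)),
    GLY = list()
  )
  rows <- lapply(c(bb, sc), function(a)
    atom_row(a[1], a[2], resname, resno, "A",
             ca + as.numeric(a[3:5]), "receptor"))
  do.call(rbind, rows)
}

#' Build the reduced receptor fragment
#'
#' Residues are laid on a serpentine grid (13 per row, 13 rows per layer,
#' 4 / 6 / 6 Angstrom spacings) with one pseudo-atom side chain per
#' residue; the first row's side chains point outward (+y) and serve as the
#' exposed binding surface where interactions are planted. The repeating
#' 13-residue sequence motif mixes donors, hydrophobics and charged types.
#'
#' @param n_residues Chain length.
#' @param origin Position of the first alpha carbon.
#' @return Atom table (see [mol_system()]).
#' @export
build_receptor <- function(n_residues = 60, origin = c(15, 60, 15)) {
  motif <- receptor_motif()
  rows <- lapply(seq_len(n_residues), function(i) {
    col <- (i - 1) %% 13
    row_global <- (i - 1) %/% 13
    layer <- row_global %/% 13
    row <- row_global %% 13
    ca <- origin + c(4 * col, -6 * row, 6 * layer)
    s <- if (row_global == 0) 1 else -1
    residue_atoms(motif[(i - 1) %% 13 + 1], i, ca, s)
  })
  do.call(rbind, rows)
}

sulfate_dirs <- function() {
  rbind(c(0, 0.94, 0.33), c(0, -0.94, 0.33), c(0.94, 0, 0.33))
}

#' Build the sulfated polysaccharide ligand fragment
#'
#' An idealized extended chain of alternating N-acetylgalactosamine
#' (`NGA`, odd mers) and glucuronic-acid (`GCU`, even mers) rings, 5.2
#' Angstrom apart. Every `NGA` carries one sulfate group, attached at C4
#' for the 4-sulfated isomer and at C6 for the 6-sulfated one; every `GCU`
#' carries one carboxylate. Oxygen-class labels follow the contact-map
#' scheme (`SO4-`, `COO-`, ring `O`, hydroxyls `O3`/`O13`/`O14`).
#'
#' @param isomer `"CS4"` or `"CS6"`.
#' @param n_mers Even number of mers.
#' @param origin Center of the first ring.
#' @return Atom table (see [mol_system()]).
#' @export
build_ligand <- function(isomer = c("CS4", "CS6"), n_mers = 12,
                         origin = c(25, 82, 15)) {
  isomer <- match.arg(isomer)
  if (n_mers %% 2 != 0 || n_mers < 2)
    stop("n_mers must be even (alternating disaccharide units)")
  ring <- list(C1 = c(-1.5, 0, 0), C2 = c(-0.75, -1.3, 0), C3 = c(0.75, -1.3, 0),
               C4 = c(1.5, 0, 0), C5 = c(0.75, 1.3, 0), O5 = c(-0.75, 1.3, 0))
  mk <- function(names_el, resid, resno, offs, cen) {
    do.call(rbind, lapply(seq_along(offs), function(k)
      atom_row(names_el[[k]][1], names_el[[k]][2], resid, resno, "B",
               cen + offs[[k]], "ligand")))
  }
  out <- lapply(seq_len(n_mers), function(m) {
    cen <- origin + c((m - 1) * 5.2, 0, 0)
    ring_rows <- mk(lapply(names(ring), function(n)
      c(n, substr(n, 1, 1))), if (m %% 2 == 1) "NGA" else "GCU", m, ring, cen)
    if (m %% 2 == 1) {  # N-acetylgalactosamine
      extra_off <- list(ring$C2 + c(0, 0, 1.5),                 # CME
                        ring$C3 + c(0, 0, -1.43),               # O3
                        ring$C3 + c(0, 0, -2.39))               # HO3
      extra_nm <- list(c("CME", "C"), c("O3", "O"), c("HO3", "H"))
      att <- if (isomer == "CS4") ring$C4 else ring$C5 + c(0, 0, 1.5)
      if (isomer == "CS6") {  # C6 carbon carries the sulfate
        extra_off <- c(extra_off, list(ring$C5 + c(0, 0, 1.5)))
        extra_nm <- c(extra_nm, list(c("C6", "C")))
      } else {                # bare exocyclic carbon
        extra_off <- c(extra_off, list(ring$C5 + c(0, 0, 1.5)))
        extra_nm <- c(extra_nm, list(c("C6", "C")))
      }
      ester <- att + c(0, 0, 1.43)
      spos <- att + c(0, 0, 3.03)
      extra_off <- c(extra_off, list(ester, spos,
                                     spos + 1.45 * sulfate_dirs()[1, ],
                                     spos + 1.45 * sulfate_dirs()[2, ],
                                     spos + 1.45 * sulfate_dirs()[3, ]))
      extra_nm <- c(extra_nm, list(c(if (isomer == "CS4") "O4" else "O6", "O"),
                                   c("S", "S"), c("O1S", "O"), c("O2S", "O"),
                                   c("O3S", "O")))
      rbind(ring_rows, mk(extra_nm, "NGA", m, extra_off, cen))
    } else {            # glucuronic acid
      c6 <- ring$C5 + c(0, 0, 1.5)
      extra_off <- list(c6, c6 + c(-1.07, 0, 0.7), c6 + c(1.07, 0, 0.7),
                        ring$C2 + c(0, 0, -1.43), ring$C2 + c(0, 0, -2.39),
                        ring$C3 + c(0, 0, 1.43), ring$C3 + c(0, 0, 2.39))
      extra_nm <- list(c("C6", "C"), c("O6A", "O"), c("O6B", "O"),
                       c("O2", "O"), c("HO2", "H"), c("O3", "O"), c("HO3", "H"))
      rbind(ring_rows, mk(extra_nm, "GCU", m, extra_off, cen))
    }
  })
  do.call(rbind, out)
}

# rejection-sample points in the box with minimum-distance constraints
sample_points <- function(n, box, margin, avoid, min_avoid, min_self,
                          max_tries = 20000) {
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("box too small: could not place solvent/ion positions")
    p <- stats::runif(3, margin, box - margin)
    if (nrow(avoid) && min(vnorm(sweep(avoid, 2, p))) < min_avoid) next
    if (placed > 0 &&
        min(vnorm(sweep(pts[seq_len(placed), , drop = FALSE], 2, p))) < min_self)
      next
    placed <- placed + 1L
    pts[placed, ] <- p
  }
  pts
}

build_solvent <- function(spec, solute_xyz, exclusion_box) {
  # keep solvent and ions away from solutes and from the planting zone so
  # that noiseless fixtures contain exactly the planted interactions
  in_zone <- function(p) all(p >= exclusion_box[1, ]) && all(p <= exclusion_box[2, ])
  avoid <- solute_xyz
  sample_clear <- function(n, min_avoid, min_self, extra_avoid = NULL) {
    av <- if (is.null(extra_avoid)) avoid else rbind(avoid, extra_avoid)
    got <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(got) < n) {
      tries <- tries + 1L
      if (tries > 40000L)
        stop("box too small: could not place solvent/ion positions")
      p <- sample_points(1, spec$box, 5, rbind(av, got), min_avoid,
                         min_self)
      if (in_zone(p[1, ])) next
      got <- rbind(got, p)
    }
    got
  }
  rows <- list()
  wat_o <- NULL
  if (spec$n_waters > 0) {
    wat_o <- sample_clear(spec$n_waters, 4.0, 3.0)
    for (w in seq_len(spec$n_waters)) {
      u <- unitv(stats::rnorm(3))
      perp <- perp_unit(u)
      h2dir <- unitv(-0.25 * u + 0.968 * perp)
      rows[[length(rows) + 1L]] <- rbind(
        atom_row("O", "O", "HOH", w, "W", wat_o[w, ], "water"),
        atom_row("H1", "H", "HOH", w, "W", wat_o[w, ] + 0.96 * u, "water"),
        atom_row("H2", "H", "HOH", w, "W", wat_o[w, ] + 0.96 * h2dir, "water"))
    }
  }
  ion_avoid <- rbind(solute_xyz, wat_o)
  if (spec$n_cations > 0) {
    cat_pos <- sample_clear(spec$n_cations, 6.0, 3.5, wat_o)
    resid <- toupper(spec$cation_species)
    for (k in seq_len(spec$n_cations))
      rows[[length(rows) + 1L]] <-
        atom_row(resid, spec$cation_species, resid, k, "I", cat_pos[k, ], "cation")
  } else cat_pos <- NULL
  if (spec$n_anions > 0) {
    an_pos <- sample_clear(spec$n_anions, 4.0, 3.5, rbind(wat_o, cat_pos))
    for (k in seq_len(spec$n_anions))
      rows[[length(rows) + 1L]] <-
        atom_row("CL", "Cl", "CL", spec$n_cations + k, "I", an_pos[k, ], "anion")
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# any unit vector orthogonal to u
perp_unit <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(v - sum(v * u) * u)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
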