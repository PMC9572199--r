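#' Hydrogen-bond energy model
#'
#' Distance- and angle-gated energy with a configurable optimum (default
#' 25 kJ/mol). The distance factor is 1 up to `hbond_d_full` (2.1 A),
#' ramps linearly to 0 at `hbond_d_zero` (2.6 A); each angular factor ramps
#' linearly from 0 at `hbond_angle_min` (100 deg) to 1 at 180 deg. A bond is
#' *counted* downstream when the energy reaches the threshold (default 25%
#' of the optimum, 6.25 kJ/mol).
#'
#' @param d_HA Hydrogen...acceptor distance, Angstrom (vectorized).
#' @param donor_angle Donor-H...acceptor angle at the hydrogen, degrees.
#' @param acceptor_angle H...acceptor-antecedent angle at the acceptor,
#'   degrees (180 when the acceptor has no bonded neighbor).
#' @param params [analysis_params()].
#' @return Energy in kJ/mol, in `[0, optimum]`.
#' @examples
#' hbond_energy(2.0, 180, 180)    # 25
#' hbond_energy(2.475, 180, 180)  # 6.25, the counting threshold
#' @export
hbond_energy <- function(d_HA, donor_angle, acceptor_angle = 180,
                         params = analysis_params()) {
  stopifnot(all(d_HA > 0))
  dist_f <- clamp01((params$hbond_d_zero - pmax(d_HA, params$hbond_d_full)) /
                      (params$hbond_d_zero - params$hbond_d_full))
  ang_f <- function(th) clamp01((th - params$hbond_angle_min) /
                                  (180 - params$hbond_angle_min))
  params$hbond_optimum_energy * dist_f * ang_f(donor_angle) * ang_f(acceptor_angle)
}

# donor table (heavy atom + its hydrogens) and acceptor table (N/O plus the
# first bonded heavy neighbor, NA if none) -- topology-only, cached per system
hb_topology <- function(sys) {
  a <- sys$atoms
  nb <- neighbor_list(sys)
  el <- a$elesy
  donors <- list()
  for (i in which(el %in% c("N", "O"))) {
    hs <- nb[[i]][el[nb[[i]]] == "H"]
    if (length(hs)) donors[[length(donors) + 1L]] <- cbind(d = i, h = hs)
  }
  donors <- if (length(donors)) do.call(rbind, donors) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("d", "h")))
  acc <- which(el %in% c("N", "O"))
  acc_nb <- vapply(acc, function(i) {
    heavy <- nb[[i]][el[nb[[i]]] != "H"]
    if (length(heavy)) heavy[1] else NA_integer_
  }, integer(1))
  list(donors = donors, acceptors = acc, acceptor_neighbor = acc_nb)
}

hb_one_direction <- function(sys, coords, topo, don_part, acc_part, params) {
  a <- sys$atoms
  dsel <- topo$donors[a$partition[topo$donors[, "d"]] %in% don_part, , drop = FALSE]
  asel <- a$partition[topo$acceptors] %in% acc_part
  acc <- topo$acceptors[asel]
  accnb <- topo$acceptor_neighbor[asel]
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      energy = numeric(0))
  if (!nrow(dsel) || !length(acc)) return(empty)
  dmat <- cross_dist(coords[dsel[, "h"], , drop = FALSE],
                     coords[acc, , drop = FALSE])
  hit <- which(dmat < params$hbond_d_zero, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  di <- dsel[hit[, 1], "d"]; hi <- dsel[hit[, 1], "h"]; ai <- acc[hit[, 2]]
  keep <- di != ai
  di <- di[keep]; hi <- hi[keep]; ai <- ai[keep]; hit <- hit[keep, , drop = FALSE]
  if (!length(di)) return(empty)
  dang <- angle_deg(coords[di, , drop = FALSE], coords[hi, , drop = FALSE],
                    coords[ai, , drop = FALSE])
  anb <- accnb[hit[, 2]]
  aang <- rep(180, length(ai))
  has_nb <- !is.na(anb)
  if (any(has_nb))
    aang[has_nb] <- angle_deg(coords[hi[has_nb], , drop = FALSE],
                              coords[ai[has_nb], , drop = FALSE],
                              coords[anb[has_nb], , drop = FALSE])
  d_ha <- dmat[cbind(hit[, 1], hit[, 2])]
  e <- hbond_energy(d_ha, dang, aang, params)
  sel <- e >= params$hbond_threshold
  data.frame(donor = di[sel], hydrogen = hi[sel], acceptor = ai[sel],
             distance = d_ha[sel], energy = e[sel])
}

#' Detect hydrogen bonds between two partitions in one frame
#'
#' Scans every donor-H...acceptor triple across the two partition sets in
#' both directions and keeps triples whose [hbond_energy()] reaches the
#' counting threshold. Donors are N/O atoms with a bonded hydrogen;
#' acceptors are N/O atoms.
#'
#' @param sys A [mol_system()].
#' @param coords n x 3 coordinate matrix for the frame.
#' @param pair List with character vectors `a` and `b` of partition labels
#'   (e.g. `list(a = "receptor", b = "ligand")`); for hydration counts use
#'   `list(a = c("receptor", "ligand"), b = "water")`.
#' @param params [analysis_params()].
#' @param topo Optional cached topology from the internal derivation (reused
#'   across frames by the census functions).
#' @return Data frame with one row per bond: `type`, `atom_a`/`atom_b`
#'   (heavy endpoints in partition sets a and b), `donor`, `hydrogen`,
#'   `acceptor`, `distance` (H...A, Angstrom), `energy` (kJ/mol).
#' @export
detect_hbonds <- function(sys, coords, pair = list(a = "receptor", b = "ligand"),
                          params = analysis_params(), topo = NULL) {
  if (nrow(coords) != n_atoms(sys)) stop("coords/system atom count mismatch")
  if (is.null(topo)) topo <- hb_topology(sys)
  fwd <- hb_one_direction(sys, coords, topo, pair$a, pair$b, params)
  rev <- hb_one_direction(sys, coords, topo, pair$b, pair$a, params)
  out <- rbind(
    if (nrow(fwd)) data.frame(atom_a = fwd$donor, atom_b = fwd$acceptor, fwd),
    if (nrow(rev)) data.frame(atom_a = rev$acceptor, atom_b = rev$donor, rev)
  )
  if (is.null(out))
    out <- data.frame(atom_a = integer(0), atom_b = integer(0),
                      donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      energy = numeric(0))
  out <- unique(out)
  cbind(type = rep("HBo", nrow(out)), out)
}

#' Detect hydrophobic contacts between receptor and ligand in one frame
#'
#' All atom pairs across the two partitions with both hydrophobic flags set
#' and center distance at or below `hp_cutoff`.
#'
#' @inheritParams detect_hbonds
#' @return Data frame with columns `type`, `atom_a`, `atom_b`, `distance`.
#' @export
detect_hydrophobic <- function(sys, coords,
                               pair = list(a = "receptor", b = "ligand"),
                               params = analysis_params(), topo = NULL) {
  if (nrow(coords) != n_atoms(sys)) stop("coords/system atom count mismatch")
  a <- sys$atoms
  ia <- which(a$partition %in% pair$a & a$hydrophobic)
  ib <- which(a$partition %in% pair$b & a$hydrophobic)
  empty <- data.frame(type = character(0), atom_a = integer(0),
                      atom_b = integer(0), distance = numeric(0))
  if (!length(ia) || !length(ib)) return(empty)
  d <- cross_dist(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE])
  hit <- which(d <= params$hp_cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  data.frame(type = "HP", atom_a = ia[hit[, 1]], atom_b = ib[hit[, 2]],
             distance = d[cbind(hit[, 1], hit[, 2])])
}

#' Detect ionic interactions between receptor and ligand in one frame
#'
#' All charge-group pairs across the two partitions with opposite formal
#' charges and group-center distance at or below `ionic_cutoff`. Group
#' centers are means of member heavy atoms; groups with zero formal charge
#' are skipped.
#'
#' @inheritParams detect_hbonds
#' @return Data frame with columns `type`, `group_a`, `group_b`, `atom_a`,
#'   `atom_b` (representative heavy atoms), `distance`.
#' @export
detect_ionic <- function(sys, coords, pair = list(a = "receptor", b = "ligand"),
                         params = analysis_params(), topo = NULL) {
  if (nrow(coords) != n_atoms(sys)) stop("coords/system atom count mismatch")
  cg <- sys$charge_groups
  empty <- data.frame(type = character(0), group_a = integer(0),
                      group_b = integer(0), atom_a = integer(0),
                      atom_b = integer(0), distance = numeric(0))
  if (is.null(cg) || !nrow(cg)) return(empty)
  centers <- charge_group_centers(sys, coords)
  ga <- which(cg$partition %in% pair$a & cg$charge != 0)
  gb <- which(cg$partition %in% pair$b & cg$charge != 0)
  if (!length(ga) || !length(gb)) return(empty)
  d <- cross_dist(centers[ga, , drop = FALSE], centers[gb, , drop = FALSE])
  opp <- outer(cg$charge[ga], cg$charge[gb], "*") < 0
  hit <- which(d <= params$ionic_cutoff & opp, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  ra <- ga[hit[, 1]]; rb <- gb[hit[, 2]]
  data.frame(type = "ionic", group_a = cg$group[ra], group_b = cg$group[rb],
             atom_a = cg$rep_atom[ra], atom_b = cg$rep_atom[rb],
             distance = d[cbind(hit[, 1], hit[, 2])])
}

#' Per-frame interaction records for a whole trajectory
#'
#' Runs the requested detectors on every frame and stacks the records with
#' `frame` and `time_ps` columns.
#'
#' @param traj A [trajectory()].
#' @param types Subset of `c("HBo", "HP", "ionic")`.
#' @param pair Partition pair passed to the detectors.
#' @param params [analysis_params()].
#' @return Data frame of interaction records.
#' @export
interaction_records <- function(traj, types = c("HBo", "HP", "ionic"),
                                pair = list(a = "receptor", b = "ligand"),
                                params = analysis_params()) {
  sys <- traj$system
  topo <- hb_topology(sys)
  out <- vector("list", n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    recs <- list()
    if ("HBo" %in% types)
      recs$hbo <- detect_hbonds(sys, xyz, pair, params, topo)[, c("type", "atom_a", "atom_b", "distance", "energy")]
    if ("HP" %in% types) {
      hp <- detect_hydrophobic(sys, xyz, pair, params)
      if (nrow(hp) || is.null(recs$hbo)) hp$energy <- rep(NA_real_, nrow(hp))
      recs$hp <- hp
    }
    if ("ionic" %in% types) {
      io <- detect_ionic(sys, xyz, pair, params)[, c("type", "atom_a", "atom_b", "distance")]
      io$energy <- rep(NA_real_, nrow(io))
      recs$ionic <- io
    }
    recs <- lapply(recs, function(r) { if (!"energy" %in% names(r)) r$energy <- numeric(0); r })
    fr <- do.call(rbind, recs)
    if (nrow(fr)) {
      fr$frame <- f
      fr$time_ps <- traj$times[f]
      out[[f]] <- fr
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(type = character(0), atom_a = integer(0),
                      atom_b = integer(0), distance = numeric(0),
                      energy = numeric(0), frame = integer(0),
                      time_ps = numeric(0))
  rownames(res) <- NULL
  res
}

# shared windowing convention: time strictly greater than the equilibration
# time, up to and including window_end
in_window <- function(times, params) {
  times > params$equilibration_time & times <= params$window_end
}

summarize_counts <- function(per_frame, times, params, by) {
  sel <- in_window(times, params)
  if (!any(sel)) stop("analysis window contains no frames")
  agg <- lapply(split(per_frame[sel, "count"], per_frame[sel, by, drop = FALSE]),
                function(x) c(mean = mean(x), sd2 = 2 * sd_pop(x)))
  keys <- unique(per_frame[sel, by, drop = FALSE])
  keys <- keys[order(do.call(paste, keys)), , drop = FALSE]
  vals <- do.call(rbind, agg[do.call(paste, c(keys, sep = "."))])
  out <- cbind(keys, mean = vals[, "mean"], sd2 = vals[, "sd2"],
               n_frames = length(unique(per_frame$frame[sel])))
  rownames(out) <- NULL
  out
}

#' Interaction census over a trajectory
#'
#' Per-frame counts of each interaction type plus windowed summary
#' statistics (mean and doubled population standard deviation over frames
#' inside the analysis window).
#'
#' @inheritParams interaction_records
#' @return List with `records` (all per-frame records), `per_frame`
#'   (frame x type counts, zero-filled) and `summary` (type, mean, sd2,
#'   n_frames).
#' @export
census <- function(traj, types = c("HBo", "HP", "ionic"),
                   pair = list(a = "receptor", b = "ligand"),
                   params = analysis_params()) {
  if (!any(in_window(traj$times, params)))
    stop("analysis window contains no frames")
  recs <- interaction_records(traj, types, pair, params)
  grid <- expand.grid(frame = seq_len(n_frames(traj)), type = types,
                      stringsAsFactors = FALSE)
  cnt <- table(factor(recs$frame, levels = seq_len(n_frames(traj))),
               factor(recs$type, levels = types))
  per_frame <- data.frame(grid, time_ps = traj$times[grid$frame],
                          count = as.vector(cnt))
  summary <- summarize_counts(per_frame, per_frame$time_ps, params, "type")
  list(records = recs, per_frame = per_frame, summary = summary)
}
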