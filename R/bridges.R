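# heavy endpoint of a solute-water hydrogen bond: the donor heavy atom when
# the solute donates, else the acceptor atom itself
solute_endpoint <- function(hb) hb$atom_a

#' Detect water bridges in one frame
#'
#' A water bridge exists when one water molecule simultaneously forms a
#' counted hydrogen bond (per [detect_hbonds()]) to a receptor atom and to a
#' ligand atom. Every (water, receptor endpoint, ligand endpoint)
#' combination yields one record; a single water can therefore mediate
#' several bridges. The class label joins the element symbols of the two
#' solute heavy endpoints through "W" (e.g. `"O-W-O"`).
#'
#' @inheritParams detect_hbonds
#' @return Data frame with columns `kind`, `mediator` (water oxygen atom
#'   index), `receptor_endpoint`, `ligand_endpoint` (heavy atoms),
#'   `class_label`.
#' @export
detect_water_bridges <- function(sys, coords, params = analysis_params(),
                                 topo = NULL) {
  if (is.null(topo)) topo <- hb_topology(sys)
  a <- sys$atoms
  empty <- data.frame(kind = character(0), mediator = integer(0),
                      receptor_endpoint = integer(0),
                      ligand_endpoint = integer(0), class_label = character(0))
  if (!any(a$partition == "water")) return(empty)
  hb_r <- detect_hbonds(sys, coords, list(a = "receptor", b = "water"), params, topo)
  hb_l <- detect_hbonds(sys, coords, list(a = "ligand", b = "water"), params, topo)
  if (!nrow(hb_r) || !nrow(hb_l)) return(empty)
  # identify the water molecule by its oxygen atom
  water_o <- function(hb) {
    w <- hb$atom_b  # water-side heavy endpoint (the oxygen: O is the only
    w               # heavy atom of a water triplet)
  }
  wr <- water_o(hb_r); wl <- water_o(hb_l)
  shared <- intersect(wr, wl)
  if (!length(shared)) return(empty)
  out <- list()
  for (w in shared) {
    re <- unique(solute_endpoint(hb_r[wr == w, , drop = FALSE]))
    le <- unique(solute_endpoint(hb_l[wl == w, , drop = FALSE]))
    combo <- expand.grid(receptor_endpoint = re, ligand_endpoint = le)
    combo$mediator <- w
    out[[length(out) + 1L]] <- combo
  }
  out <- do.call(rbind, out)
  data.frame(kind = "water", mediator = out$mediator,
             receptor_endpoint = out$receptor_endpoint,
             ligand_endpoint = out$ligand_endpoint,
             class_label = paste(a$elesy[out$receptor_endpoint], "W",
                                 a$elesy[out$ligand_endpoint], sep = "-"))
}

#' Detect ionic (cation) bridges in one frame
#'
#' A cation bridges the solutes when it sits within `ionic_cutoff` of the
#' center of a negatively charged receptor group and of a negatively
#' charged ligand group at the same time (the same distance convention as
#' [detect_ionic()]). Anions never mediate. The class label joins the
#' element of each group's representative heavy atom through the cation
#' species, e.g. `"C-Ca-C"` for a glutamate carboxylate bridged by calcium
#' to a sugar carboxylate, or `"S-Ca-C"` when the ligand side is a sulfate.
#'
#' Setting `coordination_classes` additionally admits single ligand oxygen
#' atoms of those classes as coordination endpoints (label element `O`).
#'
#' @inheritParams detect_hbonds
#' @param coordination_classes Character vector of ligand `oxygen_class`
#'   labels whose single oxygen atoms may serve as ligand-side endpoints;
#'   empty by default (charge groups only).
#' @return Data frame with columns `kind`, `mediator` (cation atom index),
#'   `receptor_endpoint`, `ligand_endpoint` (representative heavy atoms),
#'   `class_label`.
#' @export
detect_ionic_bridges <- function(sys, coords, params = analysis_params(),
                                 coordination_classes = character(0),
                                 topo = NULL) {
  a <- sys$atoms
  cg <- sys$charge_groups
  empty <- data.frame(kind = character(0), mediator = integer(0),
                      receptor_endpoint = integer(0),
                      ligand_endpoint = integer(0), class_label = character(0))
  cations <- which(a$partition == "cation")
  if (!length(cations) || is.null(cg) || !nrow(cg)) return(empty)
  centers <- charge_group_centers(sys, coords)
  neg_r <- which(cg$partition == "receptor" & cg$charge < 0)
  neg_l <- which(cg$partition == "ligand" & cg$charge < 0)
  lig_ep <- data.frame(atom = cg$rep_atom[neg_l],
                       center = I(centers[neg_l, , drop = FALSE]))
  if (length(coordination_classes)) {
    extra <- which(a$partition == "ligand" &
                     a$oxygen_class %in% coordination_classes &
                     a$elesy == "O" &
                     (is.na(a$charge_group) | !a$charge_group %in% cg$group[neg_l]))
    if (length(extra))
      lig_ep <- rbind(lig_ep, data.frame(atom = extra,
                                         center = I(coords[extra, , drop = FALSE])))
  }
  if (!length(neg_r) || !nrow(lig_ep)) return(empty)
  cat_xyz <- coords[cations, , drop = FALSE]
  d_r <- cross_dist(cat_xyz, centers[neg_r, , drop = FALSE])
  d_l <- cross_dist(cat_xyz, as.matrix(lig_ep$center))
  out <- list()
  for (k in seq_along(cations)) {
    rr <- which(d_r[k, ] <= params$ionic_cutoff)
    ll <- which(d_l[k, ] <= params$ionic_cutoff)
    if (!length(rr) || !length(ll)) next
    combo <- expand.grid(r = rr, l = ll)
    out[[length(out) + 1L]] <- data.frame(
      mediator = cations[k],
      receptor_endpoint = cg$rep_atom[neg_r[combo$r]],
      ligand_endpoint = lig_ep$atom[combo$l])
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  data.frame(kind = "ionic", out,
             class_label = paste(a$elesy[out$receptor_endpoint],
                                 a$elesy[out$mediator],
                                 a$elesy[out$ligand_endpoint], sep = "-"))
}

#' Per-frame bridge records for a whole trajectory
#'
#' @param traj A [trajectory()].
#' @param kinds Subset of `c("water", "ionic")`.
#' @param params [analysis_params()].
#' @param coordination_classes Passed to [detect_ionic_bridges()].
#' @return Data frame of bridge records with `frame` and `time_ps`.
#' @export
bridge_records <- function(traj, kinds = c("water", "ionic"),
                           params = analysis_params(),
                           coordination_classes = character(0)) {
  sys <- traj$system
  topo <- hb_topology(sys)
  out <- vector("list", n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    recs <- list()
    if ("water" %in% kinds)
      recs$w <- detect_water_bridges(sys, xyz, params, topo)
    if ("ionic" %in% kinds)
      recs$i <- detect_ionic_bridges(sys, xyz, params, coordination_classes, topo)
    fr <- do.call(rbind, recs)
    if (!is.null(fr) && nrow(fr)) {
      fr$frame <- f
      fr$time_ps <- traj$times[f]
      out[[f]] <- fr
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(kind = character(0), mediator = integer(0),
                      receptor_endpoint = integer(0),
                      ligand_endpoint = integer(0),
                      class_label = character(0), frame = integer(0),
                      time_ps = numeric(0))
  rownames(res) <- NULL
  res
}

#' Bridge census over a trajectory
#'
#' Windowed mean and doubled population standard deviation of per-frame
#' bridge counts, split by kind and by class label.
#'
#' @inheritParams bridge_records
#' @return List with `records`, `per_frame` (frame x kind counts),
#'   `summary` (per kind) and `class_summary` (per kind x class label).
#' @export
bridge_census <- function(traj, kinds = c("water", "ionic"),
                          params = analysis_params(),
                          coordination_classes = character(0)) {
  if (!any(in_window(traj$times, params)))
    stop("analysis window contains no frames")
  recs <- bridge_records(traj, kinds, params, coordination_classes)
  frames <- seq_len(n_frames(traj))
  cnt <- table(factor(recs$frame, levels = frames),
               factor(recs$kind, levels = kinds))
  per_frame <- data.frame(expand.grid(frame = frames, kind = kinds,
                                      stringsAsFactors = FALSE),
                          count = as.vector(cnt))
  per_frame$time_ps <- traj$times[per_frame$frame]
  summary <- summarize_counts(per_frame, per_frame$time_ps, params, "kind")
  classes <- sort(unique(recs$class_label))
  class_summary <- NULL
  if (length(classes)) {
    cls_cnt <- table(factor(recs$frame, levels = frames),
                     factor(recs$class_label, levels = classes))
    pf <- data.frame(expand.grid(frame = frames, class_label = classes,
                                 stringsAsFactors = FALSE),
                     count = as.vector(cls_cnt))
    pf$time_ps <- traj$times[pf$frame]
    pf$kind <- recs$kind[match(pf$class_label, recs$class_label)]
    class_summary <- summarize_counts(pf, pf$time_ps, params,
                                      c("kind", "class_label"))
  }
  list(records = recs, per_frame = per_frame, summary = summary,
       class_summary = class_summary)
}
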