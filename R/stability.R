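#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' selected atoms of a mobile and a reference coordinate set, via the
#' singular value decomposition of the cross-covariance matrix.
#'
#' @param mobile n x 3 coordinate matrix to move.
#' @param reference n x 3 coordinate matrix to match.
#' @param sel Integer/logical selection of rows used for the fit (default
#'   all). At least 3 non-collinear atoms are required.
#' @param rmsd_sel Selection over which the returned RMSD is evaluated
#'   (default: the fit selection).
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom) and `coords` (the transformed mobile set). The
#'   transform maps mobile as `coords = mobile %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference, sel = seq_len(nrow(mobile)),
                      rmsd_sel = sel) {
  m <- mobile[sel, , drop = FALSE]
  r <- reference[sel, , drop = FALSE]
  if (nrow(m) != nrow(r)) stop("selection sizes differ")
  if (nrow(m) < 3) stop("need at least 3 atoms to superpose")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  if (qr(mc)$rank < 2) stop("degenerate (collinear) selection")
  h <- crossprod(mc, rc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- sweep(mobile %*% t(rot), 2, trans, "+")
  dev <- fitted[rmsd_sel, , drop = FALSE] - reference[rmsd_sel, , drop = FALSE]
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums(dev^2))), coords = fitted)
}

#' Backbone selection for superposition and RMSD
#'
#' Protein backbone atoms (N, CA, C, O of receptor residues) plus the
#' ligand ring atoms (ring carbons and the ring oxygen).
#'
#' @param sys A [mol_system()].
#' @return Integer atom indices.
#' @export
backbone_selection <- function(sys) {
  a <- sys$atoms
  prot <- a$partition == "receptor" & a$elety %in% c("N", "CA", "C", "O")
  ring <- a$partition == "ligand" &
    (a$elety %in% c("C1", "C2", "C3", "C4", "C5") | a$elety == "O5")
  which(prot | ring)
}

#' RMSD time series against a reference frame
#'
#' Each frame is optimally superposed onto the reference frame over the fit
#' selection; the minimized RMSD is reported per frame.
#'
#' @param traj A [trajectory()].
#' @param reference_frame Frame index used as reference (default 1).
#' @param sel Fit selection (default [backbone_selection()]).
#' @param rmsd_sel Selection the RMSD is evaluated over (default `sel`).
#' @return Data frame with `frame`, `time_ps`, `rmsd`.
#' @export
rmsd_series <- function(traj, reference_frame = 1,
                        sel = backbone_selection(traj$system),
                        rmsd_sel = sel) {
  ref <- frame_coords(traj, reference_frame)
  r <- vapply(seq_len(n_frames(traj)), function(f) {
    superpose(frame_coords(traj, f), ref, sel, rmsd_sel)$rmsd
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times, rmsd = r)
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames inside the window are first superposed onto the reference frame
#' over `superpose_sel` (receptor backbone by default, removing global
#' tumbling), then each atom's RMSF is the square root of the time-mean
#' squared deviation from its time-mean position.
#'
#' @param traj A [trajectory()].
#' @param params [analysis_params()] supplying the window; set
#'   `window = NULL` to use it, or pass an explicit `c(t0, t1)` window
#'   (frames with `t0 < time <= t1`).
#' @param window Optional explicit time window in ps.
#' @param superpose_sel Selection for the pre-superposition; `NULL` skips
#'   superposition (frames used as stored).
#' @param reference_frame Reference for the superposition.
#' @return Object of class `rmsf_profile`: data frame with `atom`,
#'   `partition`, `resno`, `rmsf`.
#' @export
rmsf <- function(traj, params = analysis_params(), window = NULL,
                 superpose_sel = {
                   a <- traj$system$atoms
                   which(a$partition == "receptor" & a$elety %in% c("N", "CA", "C", "O"))
                 },
                 reference_frame = 1) {
  if (is.null(window))
    frames <- which(in_window(traj$times, params))
  else
    frames <- which(traj$times > window[1] & traj$times <= window[2])
  if (!length(frames)) stop("analysis window contains no frames")
  ref <- frame_coords(traj, reference_frame)
  na <- n_atoms(traj$system)
  sum_x <- matrix(0, na, 3)
  sum_x2 <- numeric(na)
  stack <- array(NA_real_, dim = c(na, 3, length(frames)))
  for (k in seq_along(frames)) {
    xyz <- frame_coords(traj, frames[k])
    if (!is.null(superpose_sel) && length(superpose_sel) >= 3)
      xyz <- superpose(xyz, ref, superpose_sel)$coords
    stack[, , k] <- xyz
  }
  mean_pos <- apply(stack, c(1, 2), mean)
  dim(mean_pos) <- c(na, 3)
  dev2 <- vapply(seq_along(frames), function(k)
    rowSums((matrix(stack[, , k], na, 3) - mean_pos)^2), numeric(na))
  dim(dev2) <- c(na, length(frames))
  prof <- data.frame(atom = seq_len(na),
                     partition = traj$system$atoms$partition,
                     resno = traj$system$atoms$resno,
                     rmsf = sqrt(rowMeans(as.matrix(dev2))))
  class(prof) <- c("rmsf_profile", "data.frame")
  prof
}

#' Summed RMSF by receptor subdomain and ligand mer group
#'
#' Sums per-atom RMSF values over the atoms of each receptor subdomain and
#' each ligand mer group; multiple profiles (realizations) are summed
#' together, matching the convention of aggregating fluctuation totals over
#' independent runs.
#'
#' @param profiles A single [rmsf()] profile or a list of them.
#' @param domain_scheme A [domain_scheme()] for the receptor.
#' @param mer_scheme A [mer_group_scheme()] for the ligand (mer index taken
#'   as the ligand residue index).
#' @return Data frame with `part` ("receptor"/"ligand"), `group` and
#'   `rmsf_sum`.
#' @export
rmsf_group_sums <- function(profiles, domain_scheme = gaginter::domain_scheme(),
                            mer_scheme = mer_group_scheme()) {
  if (inherits(profiles, "rmsf_profile")) profiles <- list(profiles)
  acc <- list()
  for (p in profiles) {
    rec <- p[p$partition == "receptor", ]
    rec$group <- assign_domain(rec$resno, domain_scheme)
    lig <- p[p$partition == "ligand", ]
    if (nrow(lig)) lig$group <- as.character(assign_mer_group(lig$resno, mer_scheme))
    acc[[length(acc) + 1L]] <- rbind(
      data.frame(part = "receptor", group = rec$group, rmsf = rec$rmsf),
      if (nrow(lig)) data.frame(part = "ligand", group = lig$group, rmsf = lig$rmsf)
    )
  }
  all <- do.call(rbind, acc)
  out <- aggregate(rmsf ~ part + group, data = all, FUN = sum)
  names(out)[names(out) == "rmsf"] <- "rmsf_sum"
  out[order(out$part, out$group), ]
}

#' Equilibration onset of an RMSD series
#'
#' In `"fixed"` mode (default) returns the configured equilibration time.
#' In `"auto"` mode smooths the series with a rolling mean of
#' `window_frames` frames and returns the first time from which the
#' absolute change of the rolling mean between consecutive windows stays
#' below `tol`; if no plateau is found a warning is issued and the
#' configured value is returned.
#'
#' @param series Data frame from [rmsd_series()] (columns `time_ps`, `rmsd`).
#' @param params [analysis_params()].
#' @param mode `"fixed"` or `"auto"`.
#' @param tol Plateau tolerance in Angstrom per window step.
#' @param window_frames Rolling-window length in frames.
#' @return Onset time in ps.
#' @export
equilibration_onset <- function(series, params = analysis_params(),
                                mode = c("fixed", "auto"), tol = 0.1,
                                window_frames = 10) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(params$equilibration_time)
  if (nrow(series) < 2 * window_frames)
    stop("series too short for auto mode: need at least two windows")
  roll <- stats::filter(series$rmsd, rep(1 / window_frames, window_frames),
                        sides = 1)
  roll <- roll[!is.na(roll)]
  dstep <- abs(diff(roll))
  flat <- dstep <= tol
  # earliest window start from which the rolling mean stays flat
  ok <- rev(cumprod(rev(flat))) == 1
  if (!any(ok)) {
    warning("no plateau found; falling back to configured equilibration time")
    return(params$equilibration_time)
  }
  series$time_ps[which(ok)[1]]
}
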