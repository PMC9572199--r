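#' Analysis parameters
#'
#' Bundles every tunable threshold used by the interaction detectors, the
#' bridge detectors, the surface-area solvation term and the windowed
#' statistics. The hydrogen-bond model has a 25 kJ/mol optimum; a bond is
#' counted when its energy exceeds 25% of that optimum, i.e. 6.25 kJ/mol.
#'
#' @param hbond_optimum_energy Optimum (maximal) hydrogen-bond energy, kJ/mol.
#' @param hbond_threshold_fraction Fraction of the optimum below which a
#'   candidate hydrogen bond is not counted.
#' @param hbond_threshold Counting threshold in kJ/mol; by default derived as
#'   `hbond_optimum_energy * hbond_threshold_fraction`.
#' @param hbond_d_full H...acceptor distance (Angstrom) up to which the
#'   distance factor of the energy model stays at 1.
#' @param hbond_d_zero H...acceptor distance at which the energy reaches 0;
#'   the energy ramps linearly between `hbond_d_full` and `hbond_d_zero`.
#' @param hbond_angle_min Donor/acceptor angle (degrees) below which the
#'   angular factor is 0; the factor ramps linearly to 1 at 180 degrees.
#' @param hp_cutoff Hydrophobic contact cutoff between heavy-atom centers, Angstrom.
#' @param ionic_cutoff Ionic contact cutoff between charge-group centers, Angstrom.
#' @param sasa_probe_radius Solvent probe radius, Angstrom.
#' @param sasa_n_points Sphere test points per atom for the surface algorithm.
#' @param sasa_cost Cost of exposing one square Angstrom to solvent, kJ/(mol A^2).
#' @param equilibration_time Start of the analysis window, ps. Frames with
#'   time strictly greater than this are included.
#' @param window_end End of the analysis window, ps (inclusive).
#' @param rng_seed Integer seed for any stochastic step.
#' @return An object of class `analysis_params` (a validated list).
#' @examples
#' p <- analysis_params()
#' p$hbond_threshold  # 6.25 kJ/mol
#' @export
analysis_params <- function(hbond_optimum_energy = 25,
                            hbond_threshold_fraction = 0.25,
                            hbond_threshold = hbond_optimum_energy * hbond_threshold_fraction,
                            hbond_d_full = 2.1,
                            hbond_d_zero = 2.6,
                            hbond_angle_min = 100,
                            hp_cutoff = 4.5,
                            ionic_cutoff = 5.0,
                            sasa_probe_radius = 1.4,
                            sasa_n_points = 960,
                            sasa_cost = 0.65,
                            equilibration_time = 40000,
                            window_end = 140000,
                            rng_seed = 1L) {
  p <- list(
    hbond_optimum_energy = hbond_optimum_energy,
    hbond_threshold_fraction = hbond_threshold_fraction,
    hbond_threshold = hbond_threshold,
    hbond_d_full = hbond_d_full,
    hbond_d_zero = hbond_d_zero,
    hbond_angle_min = hbond_angle_min,
    hp_cutoff = hp_cutoff,
    ionic_cutoff = ionic_cutoff,
    sasa_probe_radius = sasa_probe_radius,
    sasa_n_points = as.integer(sasa_n_points),
    sasa_cost = sasa_cost,
    equilibration_time = equilibration_time,
    window_end = window_end,
    rng_seed = as.integer(rng_seed)
  )
  if (p$hbond_threshold > p$hbond_optimum_energy)
    stop("hbond_threshold must not exceed hbond_optimum_energy")
  if (p$hp_cutoff <= 0 || p$ionic_cutoff <= 0)
    stop("distance cutoffs must be positive")
  if (p$hbond_d_full >= p$hbond_d_zero)
    stop("hbond_d_full must be smaller than hbond_d_zero")
  if (p$equilibration_time >= p$window_end)
    stop("equilibration_time must precede window_end")
  structure(p, class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Analysis parameters\n")
  cat(sprintf("  H-bond: optimum %g kJ/mol, threshold %g kJ/mol (ramp %g-%g A, angle min %g deg)\n",
              x$hbond_optimum_energy, x$hbond_threshold,
              x$hbond_d_full, x$hbond_d_zero, x$hbond_angle_min))
  cat(sprintf("  Cutoffs: hydrophobic %g A, ionic %g A\n", x$hp_cutoff, x$ionic_cutoff))
  cat(sprintf("  SASA: probe %g A, %d points, cost %g kJ/(mol A^2)\n",
              x$sasa_probe_radius, x$sasa_n_points, x$sasa_cost))
  cat(sprintf("  Window: %g-%g ps\n", x$equilibration_time, x$window_end))
  invisible(x)
}
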