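# van der Waals radii (Angstrom) for the surface calculation
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               Na = 2.27, Mg = 1.73, Ca = 2.31, Cl = 1.75)

# deterministic, nearly uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Places test points on the expanded sphere (van der Waals radius + probe)
#' of every atom and counts the fraction not buried inside any neighboring
#' expanded sphere.
#'
#' @param coords n x 3 coordinate matrix, or a [mol_system()] (elements and
#'   coordinates taken from it, hydrogens included).
#' @param elements Element symbols per atom (ignored when `coords` is a
#'   system).
#' @param probe_radius Solvent probe radius, Angstrom.
#' @param n_points Test points per atom.
#' @param radii Named radius table; unknown elements raise an error.
#' @return List with `total` (Angstrom^2) and `per_atom`.
#' @examples
#' s <- sasa(matrix(0, 1, 3), "C")
#' all.equal(s$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-12)
#' @export
sasa <- function(coords, elements = NULL, probe_radius = 1.4, n_points = 960,
                 radii = vdw_radii) {
  if (inherits(coords, "mol_system")) {
    elements <- coords$atoms$elesy
    coords <- sys_coords(coords)
  }
  coords <- matrix(coords, ncol = 3)
  r <- radii[elements]
  if (anyNA(r)) stop("no radius for element(s): ",
                     paste(unique(elements[is.na(r)]), collapse = ", "))
  re <- unname(r + probe_radius)
  pts <- sphere_points(n_points)
  n <- nrow(coords)
  per_atom <- numeric(n)
  d <- cross_dist(coords, coords)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < re[i] + re & seq_len(n) != i)
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * re[i]^2
      next
    }
    surf <- sweep(pts * re[i], 2, coords[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(surf, 2, coords[j, ])^2)
      buried <- buried | dj2 < re[j]^2
      if (all(buried)) break
    }
    per_atom[i] <- 4 * pi * re[i]^2 * mean(!buried)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Surface-area solvation energy
#'
#' The cost of exposing one square Angstrom to the solvent, 0.65 kJ/mol by
#' default, times the total accessible area.
#'
#' @param sasa_total Total accessible area, Angstrom^2.
#' @param cost Exposure cost, kJ/(mol Angstrom^2).
#' @return Solvation energy, kJ/mol.
#' @examples
#' solvation_energy(100)  # 65
#' @export
solvation_energy <- function(sasa_total, cost = 0.65) {
  stopifnot(all(sasa_total >= 0))
  sasa_total * cost
}

#' Binding-energy accounting
#'
#' `Ebind = Epr + Epl + Esr + Esl - Epc - Esc`: the potential energies of
#' the separated receptor and ligand plus their solvation energies, minus
#' the potential and solvation energies of the complex. The energy of
#' binding `EoB = -Ebind` is negative for favorable binding; lower EoB
#' means stronger binding. Because the solvation terms carry a
#' receptor-dependent constant, EoB values are comparative, not absolute.
#'
#' @param terms Data frame (or list) with numeric elements `Epr`, `Epl`,
#'   `Esr`, `Esl`, `Epc`, `Esc` (kJ/mol), vectorized over frames.
#' @return Data frame with `Ebind` and `EoB`.
#' @export
binding_energy <- function(terms) {
  need <- c("Epr", "Epl", "Esr", "Esl", "Epc", "Esc")
  if (!all(need %in% names(terms)))
    stop("terms must contain: ", paste(need, collapse = ", "))
  vals <- lapply(terms[need], as.numeric)
  if (any(!vapply(vals, function(v) all(is.finite(v)), logical(1))))
    stop("all energy terms must be finite")
  eb <- vals$Epr + vals$Epl + vals$Esr + vals$Esl - vals$Epc - vals$Esc
  data.frame(Ebind = eb, EoB = -eb)
}

#' Read a per-frame component-energy table
#'
#' Tab-separated file with columns `time_ps`, `Epr`, `Epl`, `Esr`, `Esl`,
#' `Epc`, `Esc` (kJ/mol).
#'
#' @param path TSV file path.
#' @return Data frame of energy terms.
#' @export
read_energy_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("time_ps", "Epr", "Epl", "Esr", "Esl", "Epc", "Esc")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("energy table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab
}

#' Write a per-frame component-energy table
#' @param terms Data frame as accepted by [read_energy_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(terms, path) {
  need <- c("time_ps", "Epr", "Epl", "Esr", "Esl", "Epc", "Esc")
  missing_cols <- setdiff(need, names(terms))
  if (length(missing_cols))
    stop("energy table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  utils::write.table(terms[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-frame binding-energy series
#'
#' @param terms Energy-term table with a `time_ps` column (see
#'   [read_energy_table()]).
#' @param params [analysis_params()] supplying the analysis window.
#' @return Object of class `binding_energy_series`: list with `times`,
#'   `eob`, and window statistics `mean`, `sd2` (doubled population SD) and
#'   `n_frames`.
#' @export
binding_energy_series <- function(terms, params = analysis_params()) {
  be <- binding_energy(terms)
  w <- window_average(be$EoB, terms$time_ps, params)
  structure(list(times = terms$time_ps, eob = be$EoB, ebind = be$Ebind,
                 mean = w$mean, sd2 = w$sd2, n_frames = w$n),
            class = "binding_energy_series")
}

#' @export
print.binding_energy_series <- function(x, ...) {
  cat(sprintf("binding-energy series: %d frames; window mean %.1f +/- %.1f kJ/mol (2xSD, %d frames)\n",
              length(x$eob), x$mean, x$sd2, x$n_frames))
  invisible(x)
}

#' Windowed mean and doubled standard deviation
#'
#' Statistics over frames with `equilibration_time < time <= window_end`;
#' the standard deviation is the population SD and is reported doubled,
#' matching the error-bar convention of the censuses.
#'
#' @param values Numeric per-frame values.
#' @param times Frame times, ps.
#' @param params [analysis_params()].
#' @return List with `mean`, `sd2`, `n`.
#' @export
window_average <- function(values, times, params = analysis_params()) {
  sel <- in_window(times, params)
  if (!any(sel)) stop("analysis window contains no frames")
  x <- values[sel]
  list(mean = mean(x), sd2 = 2 * sd_pop(x), n = sum(sel))
}

#' Rank complexes by mean energy of binding
#'
#' Averages each complex's windowed EoB means across its solution
#' conditions, sorts ascending (most negative, i.e. strongest bound,
#' first), and attaches docking ranks. Ties keep the input order of
#' complex ids.
#'
#' @param eob_means Data frame with columns `complex` (id), `eob`
#'   (windowed mean EoB per solution), and optionally `solution`.
#' @param docking_ranks Optional data frame with columns `complex`, `rank`.
#' @param sites Optional data frame with columns `complex`, `sites`,
#'   `strongest` carried through to the output.
#' @return Object of class `rank_table`: data frame with `md_rank`,
#'   `complex`, `mean_eob`, `sd2` (doubled SD across solutions, NA for a
#'   single solution), `docking_rank`.
#' @export
rank_complexes <- function(eob_means, docking_ranks = NULL, sites = NULL) {
  if (!nrow(eob_means)) stop("no complexes to rank")
  agg <- aggregate(eob ~ complex, data = eob_means, FUN = mean)
  spread <- aggregate(eob ~ complex, data = eob_means,
                      FUN = function(x) if (length(x) > 1) 2 * sd_pop(x) else NA_real_)
  ord <- order(agg$eob, match(agg$complex, unique(eob_means$complex)))
  out <- data.frame(md_rank = seq_along(ord),
                    complex = agg$complex[ord],
                    mean_eob = agg$eob[ord],
                    sd2 = spread$eob[ord])
  out$docking_rank <- if (is.null(docking_ranks)) NA_integer_ else
    docking_ranks$rank[match(out$complex, docking_ranks$complex)]
  if (!is.null(sites)) {
    m <- match(out$complex, sites$complex)
    out$sites <- sites$sites[m]
    out$strongest <- sites$strongest[m]
  }
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Isomer binding-strength contrast
#'
#' Percentage by which the 4-sulfated isomer binds more strongly than the
#' 6-sulfated one: `100 * (|m4| - |m6|) / |m4|`, where each `m` is the
#' grand mean of the per-complex EoB values of a rank table.
#'
#' @param rank_cs4,rank_cs6 [rank_complexes()] tables for the two isomers.
#' @return Percent difference (positive when the CS-4 complexes are bound
#'   more strongly).
#' @export
isomer_contrast <- function(rank_cs4, rank_cs6) {
  if (!nrow(rank_cs4) || !nrow(rank_cs6)) stop("empty rank table")
  m4 <- mean(rank_cs4$mean_eob)
  m6 <- mean(rank_cs6$mean_eob)
  if (abs(m4) < .Machine$double.eps) stop("contrast undefined: zero CS-4 grand mean")
  100 * (abs(m4) - abs(m6)) / abs(m4)
}

#' Published per-complex binding energies of the albumin-chondroitin system
#'
#' Reported windowed-mean energies of binding (kJ/mol, averaged over the
#' post-equilibration window and over the three salt solutions) for the ten
#' docked complexes of each chondroitin sulfate isomer, with docking ranks
#' and binding-site strings. Shipped as a plain-text reference table.
#'
#' @return Data frame with columns `isomer`, `md_rank`, `dock_rank`,
#'   `eob`, `sd`, `sites`, `strongest`.
#' @export
reference_eob <- function() {
  path <- system.file("extdata", "cs_eob_reference.tsv", package = "gaginter",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Toy pairwise nonbonded energy
#'
#' Minimal Coulomb plus Lennard-Jones evaluator used for fixture
#' self-consistency checks of the accounting pipeline; not a force field.
#'
#' @param coords n x 3 coordinates, Angstrom.
#' @param charges Partial charges, e.
#' @param epsilon LJ well depth, kJ/mol (scalar or per atom; combined by
#'   geometric mean).
#' @param sigma LJ diameter, Angstrom (combined by arithmetic mean).
#' @param ke Coulomb constant in kJ/mol * Angstrom / e^2.
#' @return Total pairwise energy, kJ/mol.
#' @export
pairwise_energy <- function(coords, charges, epsilon = 0.5, sigma = 3.0,
                            ke = 1389.35) {
  n <- nrow(coords)
  if (n < 2) return(0)
  eps <- rep_len(epsilon, n); sig <- rep_len(sigma, n)
  e <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- sqrt(rowSums(sweep(coords[j, , drop = FALSE], 2, coords[i, ])^2))
    sij <- (sig[i] + sig[j]) / 2
    eij <- sqrt(eps[i] * eps[j])
    sr6 <- (sij / d)^6
    e <- e + sum(ke * charges[i] * charges[j] / d + 4 * eij * (sr6^2 - sr6))
  }
  e
}
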