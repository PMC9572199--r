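#' Contact map of ligand oxygen classes versus receptor amino acids
#'
#' Aggregates in-window interaction or bridge events into a count matrix
#' whose rows are the ligand oxygen classes and whose columns are the 20
#' amino-acid types. Hydrogen-bond records contribute through their heavy
#' endpoints; water-bridge records contribute one count at the
#' (ligand-endpoint class, receptor-endpoint residue) cell. Ligand atoms
#' without a class are tallied under `"other"` (with a message).
#'
#' @param events Record data frame from [interaction_records()] (kind
#'   `"HBo"`, `"HP"`, `"ionic"`) or [bridge_records()] (kind `"water"`,
#'   `"ionic"` bridges), carrying a `time_ps` column.
#' @param sys The [mol_system()] the records refer to.
#' @param kind Which event kind to aggregate (matched against `type` or
#'   bridge `kind`).
#' @param params [analysis_params()] supplying the window.
#' @param classes Row labels (default [oxygen_classes()]).
#' @param residues Column labels (default [amino_acids()]).
#' @return Object of class `contact_matrix`: an integer matrix with
#'   `kind` and `window` attributes.
#' @export
contact_map <- function(events, sys, kind = "HBo",
                        params = analysis_params(),
                        classes = oxygen_classes(), residues = amino_acids()) {
  m <- matrix(0L, length(classes), length(residues),
              dimnames = list(classes, residues))
  if (nrow(events)) {
    kcol <- if ("type" %in% names(events) && kind %in% events$type) "type"
            else "kind"
    ev <- events[events[[kcol]] == kind & in_window(events$time_ps, params), ,
                 drop = FALSE]
    if (nrow(ev)) {
      lig_atom <- if ("ligand_endpoint" %in% names(ev)) ev$ligand_endpoint else ev$atom_b
      rec_atom <- if ("receptor_endpoint" %in% names(ev)) ev$receptor_endpoint else ev$atom_a
      cls <- sys$atoms$oxygen_class[lig_atom]
      if (anyNA(cls)) message(sum(is.na(cls)), " event(s) with unclassed ligand atom counted under 'other'")
      cls[is.na(cls) | !cls %in% classes] <- "other"
      res <- sys$atoms$resid[rec_atom]
      keep <- res %in% residues
      tab <- table(factor(cls[keep], levels = classes),
                   factor(res[keep], levels = residues))
      m <- m + unclass(tab)
    }
  }
  structure(m, kind = kind,
            window = c(params$equilibration_time, params$window_end),
            class = c("contact_matrix", class(m)))
}

#' Plot a contact map as a heatmap
#' @param x A [contact_map()].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.contact_matrix <- function(x, ...) {
  m <- t(unclass(x)[rev(seq_len(nrow(x))), , drop = FALSE])
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m, axes = FALSE,
                  xlab = "amino acid", ylab = "oxygen class",
                  main = paste("contact map:", attr(x, "kind")), ...)
  graphics::axis(1, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(ncol(m)), colnames(m), las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Binding-site summary by receptor subdomain
#'
#' Counts in-window events per receptor subdomain, lists the involved
#' subdomains in canonical order as a hyphenated site string, and flags the
#' subdomain with the most events (ties flagged jointly, with a warning).
#'
#' @param events Record data frame (direct interactions and/or bridges);
#'   receptor endpoints resolved through `atom_a`/`receptor_endpoint`.
#' @param sys The [mol_system()].
#' @param scheme A [domain_scheme()] matching the receptor chain length.
#' @param params [analysis_params()] supplying the window; `NULL` to count
#'   all events.
#' @return List with `counts` (named by subdomain), `sites` (string like
#'   `"IB-IIIA-IIIB"`), `strongest` (character vector).
#' @export
binding_site_summary <- function(events, sys, scheme = domain_scheme(),
                                 params = analysis_params()) {
  if (!is.null(params) && nrow(events))
    events <- events[in_window(events$time_ps, params), , drop = FALSE]
  counts <- stats::setNames(integer(length(subdomain_levels())), subdomain_levels())
  if (nrow(events)) {
    rec_atom <- if ("receptor_endpoint" %in% names(events))
      events$receptor_endpoint else events$atom_a
    sub <- assign_domain(sys$atoms$resno[rec_atom], scheme)
    tab <- table(factor(sub[sub != "unassigned"], levels = subdomain_levels()))
    counts <- counts + as.integer(tab)
    names(counts) <- subdomain_levels()
  }
  present <- names(counts)[counts > 0]
  strongest <- character(0)
  if (any(counts > 0)) {
    strongest <- names(counts)[counts == max(counts)]
    if (length(strongest) > 1)
      warning("tie for the strongest-bound subdomain: ",
              paste(strongest, collapse = ", "))
  }
  list(counts = counts, sites = paste(present, collapse = "-"),
       strongest = strongest)
}

pipeline_stages <- c("stability", "interactions", "bridges", "energetics",
                     "maps", "summary")

#' Run the full analysis pipeline on a fixture or trajectory
#'
#' Executes the requested stages in order (stability, interactions,
#' bridges, energetics, maps, summary), writes TSV/JSON outputs and a
#' provenance log (seed, parameters, input hashes) into the output
#' directory. Re-running with an identical configuration reproduces the
#' summary bit-for-bit.
#'
#' @param config Either a YAML file path or a list with elements:
#'   `fixture` (a [fixture_spec()] or list of its arguments) or
#'   `trajectory` (path to a multi-model PDB), optional `energy_table`
#'   (TSV path), `params` (list of [analysis_params()] arguments),
#'   `stages` (subset of the stage names; default all applicable),
#'   `out_dir` (output directory).
#' @return Invisibly, a list with the stage results and the summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% pipeline_stages
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown))
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "))
  out_dir <- config$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(analysis_params, config$params %||% list())
  prov <- list(run_at = "deterministic", seed = params$rng_seed,
               params = unclass(params), stages = stages)
  ledger <- NULL
  if (!is.null(config$fixture)) {
    spec <- if (inherits(config$fixture, "fixture_spec")) config$fixture else
      do.call(fixture_spec, config$fixture)
    fix <- generate_trajectory(spec, params)
    traj <- fix$traj
    ledger <- fix$ledger
    prov$fixture_seed <- spec$rng_seed
  } else if (!is.null(config$trajectory)) {
    traj <- read_trajectory(config$trajectory)
    prov$input_md5 <- unname(tools::md5sum(config$trajectory))
  } else stop("config needs either a fixture spec or a trajectory path")
  # clip the analysis window to short trajectories
  if (params$equilibration_time >= max(traj$times)) {
    params$equilibration_time <- stats::quantile(traj$times, 0.2, names = FALSE)
    params$window_end <- max(traj$times)
  }
  res <- list()
  tsv <- function(x, name) utils::write.table(
    x, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  if ("stability" %in% stages) {
    rs <- rmsd_series(traj)
    prof <- rmsf(traj, params)
    res$stability <- list(rmsd = rs, rmsf = prof)
    tsv(rs, "rmsd.tsv")
    tsv(prof, "rmsf.tsv")
  }
  if ("interactions" %in% stages) {
    res$census <- census(traj, params = params)
    tsv(res$census$records, "interactions.tsv")
    tsv(res$census$summary, "interaction_summary.tsv")
  }
  if ("bridges" %in% stages) {
    res$bridges <- bridge_census(traj, params = params)
    tsv(res$bridges$records, "bridges.tsv")
    tsv(res$bridges$summary, "bridge_summary.tsv")
  }
  if ("energetics" %in% stages && !is.null(config$energy_table)) {
    terms <- read_energy_table(config$energy_table)
    res$energy <- binding_energy_series(terms, params)
    tsv(data.frame(time_ps = res$energy$times, eob = res$energy$eob),
        "eob_series.tsv")
    prov$input_md5_energy <- unname(tools::md5sum(config$energy_table))
  }
  if ("maps" %in% stages && !is.null(res$census)) {
    cm <- contact_map(res$census$records, traj$system, "HBo", params)
    res$contact_map <- cm
    tsv(data.frame(oxygen_class = rownames(cm), unclass(cm),
                   check.names = FALSE), "contact_map_hbo.tsv")
  }
  if ("summary" %in% stages) {
    summ <- list(
      n_frames = n_frames(traj), n_atoms = n_atoms(traj$system),
      window = c(params$equilibration_time, params$window_end))
    if (!is.null(res$census)) {
      summ$interactions <- as.list(stats::setNames(res$census$summary$mean,
                                                   res$census$summary$type))
      bs <- binding_site_summary(res$census$records, traj$system,
                                 domain_scheme(max(traj$system$atoms$resno[
                                   traj$system$atoms$partition == "receptor"])),
                                 params)
      summ$binding_sites <- bs$sites
      summ$strongest_site <- bs$strongest
    }
    if (!is.null(res$bridges))
      summ$bridges <- as.list(stats::setNames(res$bridges$summary$mean,
                                              res$bridges$summary$kind))
    if (!is.null(res$energy))
      summ$eob <- list(mean = res$energy$mean, sd2 = res$energy$sd2)
    res$summary <- summ
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(ledger)) tsv(ledger, "ledger.tsv")
  invisible(res)
}
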