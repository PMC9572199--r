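#' Molecular system container
#'
#' A `mol_system` holds an atom table, a bond list, and derived annotations
#' (partition, hydrophobicity flags, charge groups, ligand oxygen classes).
#' Atoms are identified by their 1-based row index throughout the package.
#'
#' @param atoms Data frame with columns `elety` (atom name), `elesy`
#'   (element symbol), `resid` (residue/mer code), `resno` (1-based residue
#'   index within its chain), `chain`, `x`, `y`, `z`, `partition` (one of
#'   receptor, ligand, water, cation, anion). Optional columns:
#'   `hydrophobic`, `charge_group`, `oxygen_class`.
#' @param bonds Two-column integer matrix of bonded atom-index pairs, or
#'   `NULL` to infer bonds from covalent distances.
#' @param charge_groups Data frame describing formal-charge groups (columns
#'   `group`, `charge`, `rep_atom`), or `NULL` to derive from residue rules.
#' @param annotate If `TRUE` (default) fill in missing bond, hydrophobicity,
#'   charge-group and oxygen-class annotations from the built-in rules.
#' @return Object of class `mol_system`.
#' @export
mol_system <- function(atoms, bonds = NULL, charge_groups = NULL, annotate = TRUE) {
  req <- c("elety", "elesy", "resid", "resno", "chain", "x", "y", "z", "partition")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (any(atoms$elesy == "" | is.na(atoms$elesy)))
    stop("every atom needs an element symbol")
  if (any(atoms$resno < 1)) stop("residue indices are 1-based")
  bad <- setdiff(unique(atoms$partition), c("receptor", "ligand", "water", "cation", "anion"))
  if (length(bad)) stop("unknown partition label(s): ", paste(bad, collapse = ", "))
  ion_el <- atoms$elesy[atoms$partition == "cation"]
  if (length(ion_el) && !all(ion_el %in% c("Na", "Ca", "Mg")))
    stop("cation partition may only contain Na, Ca, Mg")
  an_el <- atoms$elesy[atoms$partition == "anion"]
  if (length(an_el) && !all(an_el %in% "Cl"))
    stop("anion partition may only contain Cl")
  rownames(atoms) <- NULL
  sys <- structure(list(atoms = atoms, bonds = bonds, charge_groups = charge_groups),
                   class = "mol_system")
  if (is.null(bonds)) sys$bonds <- infer_bonds(atoms)
  check_water_triplets(sys)
  if (annotate) {
    if (is.null(atoms$hydrophobic)) sys <- annotate_hydrophobic(sys)
    if (is.null(atoms$oxygen_class)) sys <- annotate_oxygen_classes(sys)
    if (is.null(charge_groups)) sys <- assign_charge_groups(sys)
  }
  sys
}

#' @export
print.mol_system <- function(x, ...) {
  tab <- table(x$atoms$partition)
  cat(sprintf("mol_system: %d atoms, %d bonds\n", nrow(x$atoms), nrow(x$bonds)))
  cat("  partitions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$charge_groups))
    cat(sprintf("  charge groups: %d\n", nrow(x$charge_groups)))
  invisible(x)
}

n_atoms <- function(sys) nrow(sys$atoms)

sys_coords <- function(sys) as.matrix(sys$atoms[, c("x", "y", "z")])

# covalent radii (Angstrom) used for distance-based bond inference
covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, Na = 1.66, Mg = 1.41, Ca = 1.76, Cl = 1.02)

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of covalent
#' radii plus a 0.45 Angstrom tolerance. H-H pairs and pairs involving
#' monatomic-ion partitions are never bonded. Intended for the clean,
#' idealized geometries this package reads and writes; not a general-purpose
#' perception algorithm.
#'
#' @param atoms Atom table (see [mol_system()]).
#' @return Two-column integer matrix of bonded pairs (i < j).
#' @export
infer_bonds <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- atoms$elesy
  r <- covalent_radii[el]
  if (anyNA(r)) stop("no covalent radius for element(s): ",
                     paste(unique(el[is.na(r)]), collapse = ", "))
  bondable <- !(atoms$partition %in% c("cation", "anion"))
  idx <- which(bondable)
  if (length(idx) < 2) return(matrix(integer(0), ncol = 2))
  # cell-list over a coarse grid keeps this near-linear
  maxcut <- max(r[idx]) * 2 + 0.45
  cell <- floor(xyz[idx, , drop = FALSE] / maxcut)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cells <- split(seq_along(idx), key)
  cell_of <- match(key, names(cells))
  ucell <- do.call(rbind, lapply(strsplit(names(cells), " "), as.numeric))
  pairs_i <- integer(0); pairs_j <- integer(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (ci in seq_along(cells)) {
    a <- cells[[ci]]
    neigh_keys <- paste(ucell[ci, 1] + offs[, 1], ucell[ci, 2] + offs[, 2],
                        ucell[ci, 3] + offs[, 3])
    b <- unlist(cells[intersect(neigh_keys, names(cells))], use.names = FALSE)
    if (!length(b)) next
    d <- cross_dist(xyz[idx[a], , drop = FALSE], xyz[idx[b], , drop = FALSE])
    cut <- outer(r[idx[a]], r[idx[b]], "+") + 0.45
    hit <- which(d < cut & d > 1e-6, arr.ind = TRUE)
    if (nrow(hit)) {
      pairs_i <- c(pairs_i, idx[a[hit[, 1]]])
      pairs_j <- c(pairs_j, idx[b[hit[, 2]]])
    }
  }
  keep <- pairs_i < pairs_j
  bonds <- unique(cbind(pairs_i[keep], pairs_j[keep]))
  if (nrow(bonds)) {
    hh <- el[bonds[, 1]] == "H" & el[bonds[, 2]] == "H"
    bonds <- bonds[!hh, , drop = FALSE]
  }
  colnames(bonds) <- c("i", "j")
  bonds
}

# adjacency list: neighbors of every atom
neighbor_list <- function(sys) {
  nb <- vector("list", n_atoms(sys))
  b <- sys$bonds
  if (!is.null(b) && nrow(b)) {
    for (k in seq_len(nrow(b))) {
      nb[[b[k, 1]]] <- c(nb[[b[k, 1]]], b[k, 2])
      nb[[b[k, 2]]] <- c(nb[[b[k, 2]]], b[k, 1])
    }
  }
  nb
}

check_water_triplets <- function(sys) {
  w <- sys$atoms[sys$atoms$partition == "water", ]
  if (!nrow(w)) return(invisible(TRUE))
  byres <- split(w$elesy, paste(w$chain, w$resno))
  ok <- vapply(byres, function(e) sum(e == "O") == 1 && sum(e == "H") == 2 && length(e) == 3,
               logical(1))
  if (!all(ok)) stop("water partition must consist of O-H-H triplets")
  invisible(TRUE)
}

#' Flag hydrophobic atoms
#'
#' Rule: a carbon or sulfur atom is hydrophobic when all of its bonded
#' neighbors are carbon, sulfur or hydrogen (vacuously true for an isolated
#' pseudo-atom). All other atoms are polar.
#'
#' @param sys A [mol_system()].
#' @return The system with a logical `hydrophobic` atom column.
#' @export
annotate_hydrophobic <- function(sys) {
  el <- sys$atoms$elesy
  nb <- neighbor_list(sys)
  hyd <- vapply(seq_along(el), function(i) {
    if (!el[i] %in% c("C", "S")) return(FALSE)
    all(el[nb[[i]]] %in% c("C", "S", "H"))
  }, logical(1))
  sys$atoms$hydrophobic <- hyd
  sys
}

# residue-name + atom-name -> oxygen class rules for the two sugar mers
oxygen_class_rules <- function() {
  list(
    NGA = c(O5 = "O", O3 = "O3", O4 = "SO4-", O6 = "SO4-",
            S = "SO4-", O1S = "SO4-", O2S = "SO4-", O3S = "SO4-"),
    GCU = c(O5 = "O", O2 = "O13", O3 = "O14",
            C6 = "COO-", O6A = "COO-", O6B = "COO-")
  )
}

#' Label ligand oxygen classes
#'
#' Assigns the contact-map class of every ligand atom from its mer type and
#' atom name (sulfate group and its ester oxygen -> `SO4-`, carboxylate ->
#' `COO-`, ring oxygen -> `O`, numbered hydroxyls -> `O3`/`O13`/`O14`).
#' Non-ligand atoms and atoms with no rule get `NA`.
#'
#' @param sys A [mol_system()].
#' @return The system with an `oxygen_class` atom column.
#' @export
annotate_oxygen_classes <- function(sys) {
  a <- sys$atoms
  cls <- rep(NA_character_, nrow(a))
  rules <- oxygen_class_rules()
  lig <- which(a$partition == "ligand")
  for (i in lig) {
    r <- rules[[a$resid[i]]]
    if (!is.null(r) && a$elety[i] %in% names(r)) cls[i] <- r[[a$elety[i]]]
  }
  sys$atoms$oxygen_class <- cls
  sys
}

#' Assign formal charge groups
#'
#' Built-in rules: Arg guanidinium (+1, representative CZ), Lys ammonium
#' (+1, NZ), Asp/Glu carboxylate (-1, CG/CD), ligand sulfate (-1, S),
#' ligand carboxylate (-1, C6), and monatomic ions (Na +1, Ca/Mg +2, Cl -1).
#' Each group's representative heavy atom supplies the element used in
#' bridge class labels; the group center is the mean of member heavy atoms.
#'
#' @param sys A [mol_system()].
#' @return The system with a `charge_group` atom column and a
#'   `charge_groups` table (columns `group`, `charge`, `rep_atom`, `partition`).
#' @export
assign_charge_groups <- function(sys) {
  a <- sys$atoms
  grp <- rep(NA_integer_, nrow(a))
  groups <- list()
  gid <- 0L
  add_group <- function(members, charge, rep_atom) {
    gid <<- gid + 1L
    grp[members] <<- gid
    groups[[gid]] <<- data.frame(group = gid, charge = charge, rep_atom = rep_atom)
  }
  res_rules <- list(
    ARG = list(atoms = c("CZ", "NH1", "NH2", "NE"), charge = +1, rep = "CZ"),
    LYS = list(atoms = "NZ", charge = +1, rep = "NZ"),
    ASP = list(atoms = c("CG", "OD1", "OD2"), charge = -1, rep = "CG"),
    GLU = list(atoms = c("CD", "OE1", "OE2"), charge = -1, rep = "CD"),
    NGA = list(atoms = c("S", "O1S", "O2S", "O3S"), charge = -1, rep = "S"),
    GCU = list(atoms = c("C6", "O6A", "O6B"), charge = -1, rep = "C6")
  )
  solute <- a$partition %in% c("receptor", "ligand")
  key <- paste(a$chain, a$resno)
  for (res in split(which(solute), key[solute])) {
    rule <- res_rules[[a$resid[res[1]]]]
    if (is.null(rule)) next
    members <- res[a$elety[res] %in% rule$atoms]
    if (!length(members)) next
    rep_atom <- res[a$elety[res] == rule$rep]
    if (!length(rep_atom)) rep_atom <- members[1]
    add_group(members, rule$charge, rep_atom[1])
  }
  ion_charge <- c(Na = +1, Ca = +2, Mg = +2, Cl = -1)
  for (i in which(a$partition %in% c("cation", "anion")))
    add_group(i, ion_charge[[a$elesy[i]]], i)
  sys$atoms$charge_group <- grp
  cg <- if (length(groups)) do.call(rbind, groups) else
    data.frame(group = integer(0), charge = numeric(0), rep_atom = integer(0))
  cg$partition <- if (nrow(cg)) a$partition[cg$rep_atom] else character(0)
  sys$charge_groups <- cg
  sys
}

# per-frame geometric centers of charge groups (heavy atoms only)
charge_group_centers <- function(sys, coords) {
  cg <- sys$charge_groups
  if (is.null(cg) || !nrow(cg)) return(matrix(numeric(0), ncol = 3))
  grp <- sys$atoms$charge_group
  heavy <- sys$atoms$elesy != "H"
  sel <- which(!is.na(grp) & heavy)
  f <- factor(grp[sel], levels = cg$group)
  cnt <- as.vector(table(f))
  sums <- rowsum(coords[sel, , drop = FALSE], f)
  sums / cnt
}

#' Default residue-name to partition rules
#'
#' @param fallback Partition assigned to unmatched residue names, or `NULL`
#'   (default) to raise a classification error on unknown names.
#' @return A list with elements `map` (named character vector) and `fallback`.
#' @export
partition_rules <- function(fallback = NULL) {
  map <- c(
    stats::setNames(rep("receptor", 20), amino_acids()),
    NGA = "ligand", GCU = "ligand",
    HOH = "water", WAT = "water", TIP = "water",
    "NA" = "cation", CA = "cation", MG = "cation",
    CL = "anion"
  )
  list(map = map, fallback = fallback)
}

normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
}

#' Read an annotated structure from a PDB file
#'
#' Reads ATOM/HETATM records (first MODEL only; see [read_trajectory()] for
#' multi-model files), classifies every residue into a partition via
#' `rules`, and runs the annotation pipeline (bond inference,
#' hydrophobicity, oxygen classes, charge groups).
#'
#' @param path PDB file path.
#' @param rules Partition rules from [partition_rules()].
#' @return A [mol_system()].
#' @export
read_structure <- function(path, rules = partition_rules()) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms_from_pdb(pdb, rules)
}

atoms_from_pdb <- function(pdb, rules) {
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(trimws(el) == "")) {
    el <- substr(trimws(at$elety), 1, 1)  # fall back to first letter of name
  }
  el <- normalize_element(el)
  part <- unname(rules$map[trimws(at$resid)])
  unknown <- is.na(part)
  if (any(unknown)) {
    if (is.null(rules$fallback))
      stop("no partition rule for residue name(s): ",
           paste(unique(trimws(at$resid)[unknown]), collapse = ", "))
    part[unknown] <- rules$fallback
  }
  atoms <- data.frame(
    elety = trimws(at$elety), elesy = el, resid = trimws(at$resid),
    resno = at$resno, chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z, partition = part,
    stringsAsFactors = FALSE
  )
  mol_system(atoms)
}

#' Write a structure (or trajectory) as a PDB file
#'
#' Writes standard fixed-width ATOM records; multi-frame input produces a
#' multi-model file (MODEL/ENDMDL). Coordinates are written at PDB precision
#' (3 decimals).
#'
#' @param sys A [mol_system()].
#' @param path Output file path.
#' @param coords Either `NULL` (use the system's own coordinates), a single
#'   n x 3 matrix, or a n x 3 x n_frames array.
#' @return `path`, invisibly.
#' @export
write_structure <- function(sys, path, coords = NULL) {
  a <- sys$atoms
  if (is.null(coords)) coords <- sys_coords(sys)
  if (length(dim(coords)) == 2) coords <- array(coords, dim = c(dim(coords), 1))
  n_frames <- dim(coords)[3]
  el <- toupper(a$elesy)
  # atom-name column: element-aligned per PDB convention
  name_fmt <- ifelse(nchar(a$elety) >= 4, a$elety,
                     ifelse(nchar(el) == 2, sprintf("%-4s", a$elety),
                            sprintf(" %-3s", a$elety)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  multi <- n_frames > 1
  for (f in seq_len(n_frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000, name_fmt, "", substr(a$resid, 1, 3), a$chain,
      a$resno %% 10000, "", coords[, 1, f], coords[, 2, f], coords[, 3, f],
      1, 0, el)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Trajectory container
#'
#' @param system A [mol_system()] providing the topology and annotations.
#' @param times Strictly increasing frame times in ps.
#' @param coords n_atoms x 3 x n_frames coordinate array (Angstrom).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(system, times, coords) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != n_atoms(system))
    stop("frame atom count does not match the system")
  if (dim(coords)[3] != length(times))
    stop("number of frames does not match times")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(system = system, times = as.numeric(times), coords = coords),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, t = %g..%g ps\n",
              n_atoms(x$system), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

n_frames <- function(traj) length(traj$times)

frame_coords <- function(traj, frame) traj$coords[, , frame]

#' Read a multi-model PDB file as a trajectory
#'
#' @param path Multi-model PDB file.
#' @param rules Partition rules from [partition_rules()].
#' @param times Frame times in ps; default `frame_interval * (1:n_frames)`.
#' @param frame_interval Spacing used to build default times (ps).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, rules = partition_rules(), times = NULL,
                            frame_interval = 100) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sys <- atoms_from_pdb(pdb, rules)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  na <- n_atoms(sys)
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  if (is.null(times)) times <- frame_interval * seq_len(nf)
  trajectory(sys, times, coords)
}
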