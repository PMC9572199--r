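#' Serum-albumin domain scheme
#'
#' Residue ranges (1-based, inclusive) of the six subdomains of human serum
#' albumin: IA 5-107, IB 108-197, IIA 198-296, IIB 297-382, IIIA 383-494,
#' IIIB 495-569, grouped into parent domains I (5-197), II (198-382) and
#' III (383-569). Residues outside 5-569 (the leading 1-4 and the C-terminal
#' 570-585 of the 585-residue chain) map to "unassigned" but still take part
#' in interaction detection.
#'
#' For reduced fixtures with fewer residues, `n_residues` rescales the
#' boundaries proportionally so the six subdomains keep their relative sizes.
#'
#' @param n_residues Chain length the scheme applies to (default 585).
#' @return An object of class `domain_scheme`: a data frame with columns
#'   `subdomain`, `domain`, `start`, `end`.
#' @export
domain_scheme <- function(n_residues = 585) {
  full <- data.frame(
    subdomain = c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB"),
    domain    = c("I", "I", "II", "II", "III", "III"),
    start     = c(5, 108, 198, 297, 383, 495),
    end       = c(107, 197, 296, 382, 494, 569),
    stringsAsFactors = FALSE
  )
  if (n_residues != 585) {
    scale <- n_residues / 585
    b <- round(c(full$start, 570) * scale)
    b <- pmax(b, 1)
    full$start <- b[1:6]
    full$end <- c(b[2:6] - 1, min(b[7] - 1, n_residues))
    if (any(full$end < full$start)) stop("too few residues to scale the domain scheme")
  }
  structure(full, class = c("domain_scheme", "data.frame"))
}

#' Assign a residue to its subdomain
#'
#' @param residue_index 1-based residue index (vectorized).
#' @param scheme A [domain_scheme()].
#' @return Character vector of subdomain labels, `"unassigned"` outside all
#'   ranges.
#' @examples
#' assign_domain(100)  # "IA"
#' assign_domain(383)  # "IIIA"
#' @export
assign_domain <- function(residue_index, scheme = domain_scheme()) {
  stopifnot(all(residue_index >= 1))
  out <- rep("unassigned", length(residue_index))
  for (i in seq_len(nrow(scheme))) {
    hit <- residue_index >= scheme$start[i] & residue_index <= scheme$end[i]
    out[hit] <- scheme$subdomain[i]
  }
  out
}

#' Canonical subdomain ordering
#' @return Character vector IA, IB, IIA, IIB, IIIA, IIIB.
#' @export
subdomain_levels <- function() c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB")

#' Sugar mer grouping scheme
#'
#' The ligand mers are pooled into consecutive triplets for fluctuation
#' summaries: 24 mers give eight groups of three.
#'
#' @param n_mers Number of mers in the chain (must be divisible by
#'   `mers_per_group`).
#' @param mers_per_group Mers pooled per group (default 3).
#' @return Object of class `mer_group_scheme`.
#' @export
mer_group_scheme <- function(n_mers = 24, mers_per_group = 3) {
  if (n_mers %% mers_per_group != 0)
    stop("n_mers must be divisible by mers_per_group")
  structure(list(n_mers = as.integer(n_mers),
                 mers_per_group = as.integer(mers_per_group),
                 n_groups = as.integer(n_mers / mers_per_group)),
            class = "mer_group_scheme")
}

#' Assign a mer to its group
#'
#' @param mer_index Mer index in 1..n_mers (vectorized).
#' @param scheme A [mer_group_scheme()].
#' @return Integer group indices (ceiling of mer/mers_per_group).
#' @examples
#' assign_mer_group(10)  # 4
#' @export
assign_mer_group <- function(mer_index, scheme = mer_group_scheme()) {
  if (any(mer_index < 1 | mer_index > scheme$n_mers))
    stop("mer_index out of range 1..", scheme$n_mers)
  as.integer(ceiling(mer_index / scheme$mers_per_group))
}

#' Ligand oxygen classes
#'
#' Canonical row labels of the contact maps: the sulfate and carboxylate
#' groups, the ring oxygen class and the numbered hydroxyl oxygens of the
#' disaccharide unit, plus a catch-all.
#' @return Character vector of class labels.
#' @export
oxygen_classes <- function() c("SO4-", "COO-", "O", "O3", "O13", "O14", "other")

#' Standard amino-acid three-letter codes (contact-map columns)
#' @return Character vector of 20 residue codes.
#' @export
amino_acids <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}
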