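# Hand-built miniature systems for constructed detector cases.

# rows: list of c(elety, elesy, resid, resno, chain, partition); coords matrix
toy_system <- function(rows, coords) {
  atoms <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(elety = r[1], elesy = r[2], resid = r[3],
               resno = as.integer(r[4]), chain = r[5],
               x = coords[i, 1], y = coords[i, 2], z = coords[i, 3],
               partition = r[6], stringsAsFactors = FALSE)
  }))
  mol_system(atoms)
}

# n donor (Ser hydroxyl) / acceptor (sugar hydroxyl oxygen) pairs, 10 A apart
pair_system <- function(n_pairs) {
  rows <- list(); xyz <- NULL
  for (i in seq_len(n_pairs)) {
    rows <- c(rows, list(
      c("OG", "O", "SER", i, "A", "receptor"),
      c("HG", "H", "SER", i, "A", "receptor"),
      c("O3", "O", "NGA", i, "B", "ligand")))
    xyz <- rbind(xyz, c(10 * i, 0, 0), c(10 * i, 0.96, 0), c(10 * i, 2.86, 0))
  }
  list(sys = toy_system(rows, xyz), base = xyz)
}

small_fixture_spec <- function(seed, n_frames = 40, jitter = 0, ...) {
  fixture_spec(n_receptor_residues = 26, n_mers = 6, n_waters = 25,
               n_cations = 5, n_anions = 5, n_frames = n_frames,
               jitter_sigma = jitter,
               planted_events = default_event_schedule(n_frames),
               rng_seed = seed, ...)
}

# a fixture reused across several test files (generated once per run)
shared_fixture <- local({
  fix <- NULL
  function() {
    if (is.null(fix))
      fix <<- generate_trajectory(
        fixture_spec(n_waters = 80, n_cations = 8, n_anions = 10,
                     n_frames = 50, planted_events = default_event_schedule(50),
                     rng_seed = 7L))
    fix
  }
})
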