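test_that("hydrogen-bond energy model hits the documented anchor points", {
  expect_equal(hbond_energy(2.0, 180, 180), 25)
  expect_equal(hbond_energy(2.475, 180, 180), 6.25)  # the counting threshold
  expect_equal(hbond_energy(3.0, 180, 180), 0)
  expect_equal(hbond_energy(2.0, 99, 180), 0)        # donor angle gate
  expect_equal(hbond_energy(2.0, 180, 99), 0)
  # non-increasing in distance beyond the flat region
  d <- seq(2.1, 3.0, by = 0.05)
  expect_true(all(diff(hbond_energy(d, 180, 180)) <= 0))
  expect_true(all(hbond_energy(runif(50, 0.5, 4), runif(50, 0, 180),
                               runif(50, 0, 180)) >= 0))
})

test_that("hydrophobic detection gates on both flags and the cutoff", {
  rows <- list(c("CB", "C", "ALA", 1, "A", "receptor"),
               c("CME", "C", "NGA", 1, "B", "ligand"),
               c("O3", "O", "NGA", 1, "B", "ligand"))
  sys <- toy_system(rows, rbind(c(0, 0, 0), c(4, 0, 0), c(0, 3, 0)))
  hp <- detect_hydrophobic(sys, sys_coords(sys))
  expect_equal(nrow(hp), 1)           # C...C at 4.0 within the 4.5 cutoff
  expect_equal(hp$distance, 4.0)
  expect_equal(hp$atom_b, 2L)         # the polar oxygen at 3.0 is excluded
  far <- sys_coords(sys); far[2, 1] <- 5
  expect_equal(nrow(detect_hydrophobic(sys, far)), 0)
})

test_that("ionic detection uses opposite group charges and center distance", {
  rows <- list(c("NZ", "N", "LYS", 1, "A", "receptor"),
               c("S", "S", "NGA", 1, "B", "ligand"),
               c("O1S", "O", "NGA", 1, "B", "ligand"),
               c("O2S", "O", "NGA", 1, "B", "ligand"),
               c("O3S", "O", "NGA", 1, "B", "ligand"))
  s_pos <- c(4, 0, 0)
  xyz <- rbind(c(0, 0, 0), s_pos, s_pos + c(1.2, 0.6, 0), s_pos + c(-1.2, 0.6, 0),
               s_pos + c(0, -0.6, 1.2))
  sys <- toy_system(rows, xyz)
  io <- detect_ionic(sys, sys_coords(sys))
  expect_equal(nrow(io), 1)
  expect_equal(io$atom_a, 1L)
  expect_equal(io$atom_b, 2L)  # representative heavy atom is the sulfur
  expect_equal(io$distance, o_dist(c(0, 0, 0), colMeans(xyz[2:5, ])))
  # same-sign pair: a positive guanidinium on the ligand side is not counted
  rows2 <- list(c("NZ", "N", "LYS", 1, "A", "receptor"),
                c("CZ", "C", "ARG", 1, "B", "ligand"),
                c("NH1", "N", "ARG", 1, "B", "ligand"))
  sys2 <- toy_system(rows2, rbind(c(0, 0, 0), c(3, 0, 0), c(3, 1.33, 0)))
  expect_equal(nrow(detect_ionic(sys2, sys_coords(sys2))), 0)
})

test_that("planted fixtures are recovered exactly by the vectorized detectors", {
  fix <- shared_fixture()
  v <- validate_ledger(fix$traj, fix$ledger)
  expect_equal(v$precision, 1)
  expect_equal(v$recall, 1)
  expect_true(all(v$per_type$precision == 1))
  expect_true(all(v$per_type$recall == 1))
})

test_that("an empty partition yields empty record sets, not errors", {
  sp <- pair_system(2)
  hb <- detect_hbonds(sp$sys, sp$base, list(a = "receptor", b = "cation"))
  expect_equal(nrow(hb), 0)
  expect_error(detect_hbonds(sp$sys, sp$base[-1, , drop = FALSE]), "mismatch")
})

test_that("solute-water hydrogen-bond counts match the planted bridge ledger", {
  # every planted water bridge contributes exactly two solute-water bonds
  spec <- fixture_spec(n_waters = 30, n_cations = 3, n_anions = 3, n_frames = 20,
                       planted_events = data.frame(
                         type = c("water_bridge", "water_bridge"),
                         start = c(3, 8), end = c(12, 17)), rng_seed = 9L)
  fix <- generate_trajectory(spec)
  sys <- fix$traj$system
  topo <- gaginter:::hb_topology(sys)
  for (f in c(1, 5, 10, 15, 20)) {
    hb <- detect_hbonds(sys, frame_coords(fix$traj, f),
                        list(a = c("receptor", "ligand"), b = "water"),
                        topo = topo)
    expect_equal(nrow(hb), 2 * sum(fix$ledger$frame == f))
  }
})

test_that("detector output is symmetric under swapping the partition labels", {
  fix <- shared_fixture()
  xyz <- frame_coords(fix$traj, 10)
  sys <- fix$traj$system
  fwd <- detect_hbonds(sys, xyz, list(a = "receptor", b = "ligand"))
  rev <- detect_hbonds(sys, xyz, list(a = "ligand", b = "receptor"))
  expect_equal(sort(paste(fwd$atom_a, fwd$atom_b)),
               sort(paste(rev$atom_b, rev$atom_a)))
  fhp <- detect_hydrophobic(sys, xyz, list(a = "receptor", b = "ligand"))
  rhp <- detect_hydrophobic(sys, xyz, list(a = "ligand", b = "receptor"))
  expect_equal(sort(paste(fhp$atom_a, fhp$atom_b)),
               sort(paste(rhp$atom_b, rhp$atom_a)))
})

test_that("raising the threshold or cutoffs moves counts the right way", {
  fix <- shared_fixture()
  xyz <- frame_coords(fix$traj, 10)
  sys <- fix$traj$system
  loose <- analysis_params()
  strict <- analysis_params(hbond_threshold = 12, hp_cutoff = 3.5,
                            ionic_cutoff = 3.5)
  wide <- analysis_params(hp_cutoff = 6, ionic_cutoff = 7)
  expect_lte(nrow(detect_hbonds(sys, xyz, params = strict)),
             nrow(detect_hbonds(sys, xyz, params = loose)))
  expect_lte(nrow(detect_hydrophobic(sys, xyz, params = strict)),
             nrow(detect_hydrophobic(sys, xyz, params = loose)))
  expect_gte(nrow(detect_hydrophobic(sys, xyz, params = wide)),
             nrow(detect_hydrophobic(sys, xyz, params = loose)))
  expect_gte(nrow(detect_ionic(sys, xyz, params = wide)),
             nrow(detect_ionic(sys, xyz, params = loose)))
})

test_that("census statistics match closed forms on constructed count series", {
  # six donor/acceptor pairs; two of them break on odd frames: counts 6,4,6,4...
  sp <- pair_system(6)
  nf <- 20
  coords <- array(rep(sp$base, nf), dim = c(nrow(sp$base), 3, nf))
  for (f in seq(1, nf, by = 2)) {
    coords[c(15, 18), 2, f] <- 30  # acceptors of pairs 5 and 6 moved far away
  }
  traj <- trajectory(sp$sys, 1:nf, coords)
  p <- analysis_params(equilibration_time = 0, window_end = nf)
  cs <- census(traj, types = "HBo", params = p)
  expect_equal(cs$per_frame$count, rep(c(4, 6), nf / 2))
  expect_equal(cs$summary$mean, 5)
  expect_equal(cs$summary$sd2, 2)  # doubled population SD of {4,6}
  # constant series: zero spread
  traj2 <- trajectory(sp$sys, 1:nf, array(rep(sp$base, nf),
                                          dim = c(nrow(sp$base), 3, nf)))
  cs2 <- census(traj2, types = "HBo", params = p)
  expect_equal(cs2$summary$mean, 6)
  expect_equal(cs2$summary$sd2, 0)
  expect_error(census(traj2, types = "HBo",
                      params = analysis_params(equilibration_time = 1000,
                                               window_end = 2000)),
               "no frames")
})

test_that("the save-point window keeps exactly the frames after equilibration", {
  times <- 100 * (1:1400)  # 140 ns stored every 100 ps
  p <- analysis_params()
  w <- window_average(rep(1, 1400), times, p)
  expect_equal(w$n, 1000)  # strictly greater than 40 ns, up to 140 ns
})

test_that("detectors agree with the brute-force scan on random jittered fixtures", {
  p <- analysis_params()
  for (seed in 1:3) {
    fix <- generate_trajectory(small_fixture_spec(seed, n_frames = 8,
                                                  jitter = 0.5))
    sys <- fix$traj$system
    for (f in c(2, 5, 8)) {
      xyz <- frame_coords(fix$traj, f)
      hb <- detect_hbonds(sys, xyz, params = p)
      ob <- oracle_hbonds(sys, xyz, list(a = "receptor", b = "ligand"), p)
      expect_equal(sort(paste(hb$atom_a, hb$atom_b)),
                   sort(paste(ob$atom_a, ob$atom_b)))
      hp <- detect_hydrophobic(sys, xyz, params = p)
      expect_equal(sort(paste(hp$atom_a, hp$atom_b)),
                   pair_key(oracle_hp(sys, xyz, list(a = "receptor", b = "ligand"), p)))
      io <- detect_ionic(sys, xyz, params = p)
      expect_equal(sort(paste(io$atom_a, io$atom_b)),
                   pair_key(oracle_ionic(sys, xyz, list(a = "receptor", b = "ligand"), p)))
    }
  }
})
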