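# a receptor carboxylate, a sugar hydroxyl, and one water placed between
# them with both hydrogens donating
bridge_toy <- function(water_near = TRUE, second_water = FALSE) {
  rows <- list(c("CD", "C", "GLU", 1, "A", "receptor"),
               c("OE1", "O", "GLU", 1, "A", "receptor"),
               c("OE2", "O", "GLU", 1, "A", "receptor"),
               c("O3", "O", "NGA", 1, "B", "ligand"),
               c("O", "O", "HOH", 1, "W", "water"),
               c("H1", "H", "HOH", 1, "W", "water"),
               c("H2", "H", "HOH", 1, "W", "water"))
  xyz <- rbind(c(0, -1.3, 0),      # CD
               c(0, 0, 0),         # OE1 (bridged endpoint)
               c(1.07, -2, 0),     # OE2
               c(0, 5.6, 0),       # ligand hydroxyl oxygen
               c(0, 2.8, 0),       # water oxygen
               c(0, 1.84, 0),      # H toward the receptor
               c(0, 3.76, 0))      # H toward the ligand
  if (!water_near) xyz[4, ] <- c(0, 40, 0)
  if (second_water) {
    rows <- c(rows, list(c("O2", "O", "GCU", 2, "B", "ligand"),
                         c("O", "O", "HOH", 2, "W", "water"),
                         c("H1", "H", "HOH", 2, "W", "water"),
                         c("H2", "H", "HOH", 2, "W", "water")))
    xyz <- rbind(xyz, c(1.07, -2 - 5.6, 0), c(1.07, -2 - 2.8, 0),
                 c(1.07, -2 - 1.84, 0), c(1.07, -2 - 3.76, 0))
  }
  toy_system(rows, xyz)
}

test_that("a water donating to both solutes forms exactly one bridge", {
  sys <- bridge_toy()
  wb <- detect_water_bridges(sys, sys_coords(sys))
  expect_equal(nrow(wb), 1)
  expect_equal(wb$mediator, 5L)
  expect_equal(wb$receptor_endpoint, 2L)
  expect_equal(wb$ligand_endpoint, 4L)
  expect_equal(wb$class_label, "O-W-O")
})

test_that("a one-sided water contact is not a bridge", {
  sys <- bridge_toy(water_near = FALSE)
  expect_equal(nrow(detect_water_bridges(sys, sys_coords(sys))), 0)
  # the receptor-side hydrogen bond is still there
  hb <- detect_hbonds(sys, sys_coords(sys), list(a = "receptor", b = "water"))
  expect_equal(nrow(hb), 1)
})

test_that("two waters each bridging once give two records", {
  sys <- bridge_toy(second_water = TRUE)
  wb <- detect_water_bridges(sys, sys_coords(sys))
  expect_equal(nrow(wb), 2)
  expect_equal(sort(unique(wb$mediator)), c(5L, 9L))
})

test_that("cations bridge oppositely charged groups; anions never mediate", {
  rows <- list(c("CD", "C", "GLU", 1, "A", "receptor"),
               c("OE1", "O", "GLU", 1, "A", "receptor"),
               c("OE2", "O", "GLU", 1, "A", "receptor"),
               c("C6", "C", "GCU", 1, "B", "ligand"),
               c("O6A", "O", "GCU", 1, "B", "ligand"),
               c("O6B", "O", "GCU", 1, "B", "ligand"),
               c("CA", "Ca", "CA", 1, "I", "cation"))
  glu <- rbind(c(0, 0, 0), c(-1.07, 0.7, 0), c(1.07, 0.7, 0))
  coo <- rbind(c(0, 8.4, 0), c(-1.07, 9.1, 0), c(1.07, 9.1, 0))
  xyz <- rbind(glu, coo, c(0, 4.35, 0))
  sys <- toy_system(rows, xyz)
  ib <- detect_ionic_bridges(sys, sys_coords(sys))
  expect_equal(nrow(ib), 1)
  expect_equal(ib$class_label, "C-Ca-C")
  expect_equal(ib$receptor_endpoint, 1L)
  expect_equal(ib$ligand_endpoint, 4L)
  # replace the calcium by a chloride: no mediation
  rows[[7]] <- c("CL", "Cl", "CL", 1, "I", "anion")
  sys2 <- toy_system(rows, xyz)
  expect_equal(nrow(detect_ionic_bridges(sys2, sys_coords(sys2))), 0)
})

test_that("single oxygen endpoints are opt-in coordination sites (C-Ca-O class)", {
  rows <- list(c("CG", "C", "ASP", 1, "A", "receptor"),
               c("OD1", "O", "ASP", 1, "A", "receptor"),
               c("OD2", "O", "ASP", 1, "A", "receptor"),
               c("O5", "O", "GCU", 1, "B", "ligand"),
               c("CA", "Ca", "CA", 1, "I", "cation"))
  xyz <- rbind(c(0, 0, 0), c(-1.07, 0.7, 0), c(1.07, 0.7, 0),
               c(0, 8.4, 0), c(0, 4.35, 0))
  sys <- toy_system(rows, xyz)
  expect_equal(nrow(detect_ionic_bridges(sys, sys_coords(sys))), 0)
  ib <- detect_ionic_bridges(sys, sys_coords(sys), coordination_classes = "O")
  expect_equal(nrow(ib), 1)
  expect_equal(ib$class_label, "C-Ca-O")
})

test_that("every bridge decomposes into its two independently detected legs", {
  fix <- shared_fixture()
  sys <- fix$traj$system
  for (f in unique(fix$ledger$frame[fix$ledger$type %in%
                                    c("water_bridge", "ionic_bridge")])[1:5]) {
    xyz <- frame_coords(fix$traj, f)
    wb <- detect_water_bridges(sys, xyz)
    if (nrow(wb)) {
      hb_r <- detect_hbonds(sys, xyz, list(a = "receptor", b = "water"))
      hb_l <- detect_hbonds(sys, xyz, list(a = "ligand", b = "water"))
      for (i in seq_len(nrow(wb))) {
        expect_true(any(hb_r$atom_a == wb$receptor_endpoint[i] &
                          hb_r$atom_b == wb$mediator[i]))
        expect_true(any(hb_l$atom_a == wb$ligand_endpoint[i] &
                          hb_l$atom_b == wb$mediator[i]))
      }
    }
    ib <- detect_ionic_bridges(sys, xyz)
    if (nrow(ib)) {
      io_r <- detect_ionic(sys, xyz, list(a = "cation", b = "receptor"))
      io_l <- detect_ionic(sys, xyz, list(a = "cation", b = "ligand"))
      for (i in seq_len(nrow(ib))) {
        expect_true(any(io_r$atom_a == ib$mediator[i] &
                          io_r$atom_b == ib$receptor_endpoint[i]))
        expect_true(any(io_l$atom_a == ib$mediator[i] &
                          io_l$atom_b == ib$ligand_endpoint[i]))
      }
    }
  }
})

test_that("bridge detectors agree with the brute-force scan on jittered fixtures", {
  p <- analysis_params()
  for (seed in 4:5) {
    fix <- generate_trajectory(small_fixture_spec(seed, n_frames = 8,
                                                  jitter = 0.5))
    sys <- fix$traj$system
    for (f in c(3, 6)) {
      xyz <- frame_coords(fix$traj, f)
      wb <- detect_water_bridges(sys, xyz, p)
      expect_equal(sort(paste(wb$mediator, wb$receptor_endpoint,
                              wb$ligand_endpoint)),
                   pair_key(oracle_water_bridges(sys, xyz, p)))
      ib <- detect_ionic_bridges(sys, xyz, p)
      expect_equal(sort(paste(ib$mediator, ib$receptor_endpoint,
                              ib$ligand_endpoint)),
                   pair_key(oracle_ionic_bridges(sys, xyz, p)))
    }
  }
})

test_that("bridge census tallies classes against the planted ledger", {
  fix <- shared_fixture()
  p <- analysis_params(equilibration_time = 0,
                       window_end = max(fix$traj$times))
  bc <- bridge_census(fix$traj, params = p)
  led <- fix$ledger[fix$ledger$type %in% c("water_bridge", "ionic_bridge"), ]
  led_kind <- ifelse(led$type == "water_bridge", "water", "ionic")
  for (k in c("water", "ionic")) {
    expect_equal(sum(bc$per_frame$count[bc$per_frame$kind == k]),
                 sum(led_kind == k))
  }
  expect_equal(sort(unique(bc$records$class_label)),
               sort(unique(led$class_label)))
  # per-class windowed totals equal the ledger tallies
  for (cl in unique(led$class_label))
    expect_equal(sum(bc$records$class_label == cl), sum(led$class_label == cl))
})

test_that("an all-zero schedule gives an all-zero bridge summary", {
  spec <- fixture_spec(n_waters = 12, n_cations = 2, n_anions = 2, n_frames = 6,
                       rng_seed = 8L)
  fix <- generate_trajectory(spec)
  p <- analysis_params(equilibration_time = 0, window_end = 600)
  bc <- bridge_census(fix$traj, params = p)
  expect_true(all(bc$summary$mean == 0))
  expect_true(all(bc$summary$sd2 == 0))
})
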