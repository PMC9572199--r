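random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

test_that("superposition removes rigid motion and returns a proper rotation", {
  set.seed(1)
  ref <- matrix(rnorm(60), 20, 3)
  s0 <- superpose(ref, ref)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  shifted <- sweep(ref, 2, c(5, 0, 0), "+")
  expect_equal(superpose(shifted, ref)$rmsd, 0, tolerance = 1e-12)
  mob <- ref %*% t(random_rotation()) + matrix(rnorm(3), 20, 3, byrow = TRUE)
  s <- superpose(mob, ref)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("a single displaced atom gives the d/sqrt(N) deviation law", {
  set.seed(2)
  for (n in c(10, 50)) {
    ref <- matrix(rnorm(3 * n), n, 3)
    mob <- ref
    d <- runif(1, 0.1, 2)
    mob[n, ] <- mob[n, ] + d * c(1, 0, 0)
    s <- superpose(mob, ref, sel = seq_len(n - 1), rmsd_sel = seq_len(n))
    expect_equal(s$rmsd, d / sqrt(n), tolerance = 1e-6)
  }
})

test_that("the fitted deviation is minimal over random rigid alternatives", {
  set.seed(3)
  ref <- matrix(rnorm(45), 15, 3)
  mob <- ref + matrix(rnorm(45, sd = 0.3), 15, 3)
  best <- superpose(mob, ref)$rmsd
  for (k in 1:100) {
    alt <- mob %*% t(random_rotation()) + matrix(rnorm(3), 15, 3, byrow = TRUE)
    raw <- sqrt(mean(rowSums((alt - ref)^2)))
    expect_gte(raw, best - 1e-9)
  }
})

test_that("superposed deviations agree with an independent reference fit", {
  set.seed(4)
  ref <- matrix(rnorm(90), 30, 3)
  mob <- ref %*% t(random_rotation()) + matrix(rnorm(90, sd = 0.4), 30, 3) +
    matrix(c(3, -1, 2), 30, 3, byrow = TRUE)
  ours <- superpose(mob, ref)$rmsd
  ref_xyz <- as.vector(t(ref))
  mob_xyz <- as.vector(t(mob))
  fitted <- bio3d::fit.xyz(fixed = ref_xyz, mobile = mob_xyz,
                           fixed.inds = 1:90, mobile.inds = 1:90)
  theirs <- bio3d::rmsd(ref_xyz, fitted)  # reported at 3 decimals
  expect_equal(ours, theirs, tolerance = 1e-3)
})

# a bare 60-atom chain for trajectory-level statistics
bare_traj <- function(coords_list, times = seq_along(coords_list)) {
  n <- nrow(coords_list[[1]])
  rows <- lapply(seq_len(n), function(i) c("CB", "C", "ALA", i, "A", "receptor"))
  sys <- toy_system(rows, coords_list[[1]])
  arr <- array(unlist(coords_list), dim = c(n, 3, length(coords_list)))
  trajectory(sys, times, arr)
}

test_that("deviation series: static zero, drift-then-plateau closed form", {
  set.seed(5)
  base <- matrix(rnorm(180, sd = 4), 60, 3)
  static <- bare_traj(rep(list(base), 5))
  rs <- rmsd_series(static, sel = 1:60)
  expect_equal(rs$rmsd, rep(0, 5), tolerance = 1e-9)
  # one atom drifts linearly for 10 frames, then holds: the series plateaus
  # at the planted offset over sqrt(N) when fitted on the other atoms
  frames <- lapply(1:20, function(f) {
    x <- base
    x[60, 1] <- x[60, 1] + 0.2 * min(f - 1, 10)
    x
  })
  tr <- bare_traj(frames)
  rs2 <- rmsd_series(tr, sel = 1:59, rmsd_sel = 1:60)
  expect_equal(rs2$rmsd[12:20], rep(2 / sqrt(60), 9), tolerance = 1e-9)
  expect_true(all(diff(rs2$rmsd[1:11]) > 0))
})

test_that("isotropic jitter gives a sigma*sqrt(3) deviation plateau", {
  set.seed(6)
  n <- 2000; sigma <- 0.5
  base <- matrix(runif(3 * n, 0, 50), n, 3)
  frames <- c(list(base), lapply(1:8, function(f)
    base + matrix(rnorm(3 * n, sd = sigma), n, 3)))
  tr <- bare_traj(frames)
  rs <- rmsd_series(tr, sel = seq_len(n))
  expect_equal(mean(rs$rmsd[-1]), sigma * sqrt(3), tolerance = 0.1 * sigma * sqrt(3))
})

test_that("fluctuation profile: static zero, two-point oscillation equals the amplitude", {
  base <- matrix(c(0, 0, 0), 1, 3)
  a <- 0.7
  frames <- lapply(1:6, function(f) matrix(c(a * (-1)^f, 0, 0), 1, 3))
  tr <- bare_traj(frames)
  prof <- rmsf(tr, window = c(0, 10), superpose_sel = NULL)
  expect_equal(prof$rmsf, a, tolerance = 1e-12)
  static <- bare_traj(rep(list(matrix(rnorm(30), 10, 3)), 4))
  prof0 <- rmsf(static, window = c(0, 10), superpose_sel = NULL)
  expect_equal(prof0$rmsf, rep(0, 10), tolerance = 1e-12)
})

test_that("fluctuations are invariant to a global rigid motion of all frames", {
  set.seed(7)
  base <- matrix(rnorm(90), 30, 3)
  frames <- lapply(1:6, function(f) base + matrix(rnorm(90, sd = 0.2), 30, 3))
  tr1 <- bare_traj(frames)
  rot <- random_rotation()
  frames2 <- lapply(frames, function(x)
    x %*% t(rot) + matrix(c(10, -4, 2), 30, 3, byrow = TRUE))
  tr2 <- bare_traj(frames2)
  p1 <- rmsf(tr1, window = c(0, 10), superpose_sel = 1:30)
  p2 <- rmsf(tr2, window = c(0, 10), superpose_sel = 1:30)
  expect_equal(p1$rmsf, p2$rmsf, tolerance = 1e-6)
})

test_that("group sums conserve the per-atom fluctuation totals", {
  fix <- shared_fixture()
  prof <- rmsf(fix$traj, window = c(0, max(fix$traj$times)))
  n_res <- fix$spec$n_receptor_residues
  sums <- rmsf_group_sums(prof, domain_scheme(n_res),
                          mer_group_scheme(fix$spec$n_mers, 3))
  rec <- prof[prof$partition == "receptor", ]
  assigned <- assign_domain(rec$resno, domain_scheme(n_res)) != "unassigned"
  expect_equal(sum(sums$rmsf_sum[sums$part == "receptor"]),
               sum(rec$rmsf[assigned]))
  lig <- prof[prof$partition == "ligand", ]
  expect_equal(sum(sums$rmsf_sum[sums$part == "ligand"]), sum(lig$rmsf))
  # each mer group covers its mers exactly once
  expect_equal(nrow(sums[sums$part == "ligand", ]), fix$spec$n_mers / 3)
})

test_that("equilibration onset: fixed default, flat series, and a step at 40 ns", {
  p <- analysis_params()
  series <- data.frame(time_ps = 100 * (1:1400), rmsd = rnorm(1400))
  expect_equal(equilibration_onset(series, p), 40000)
  flat <- data.frame(time_ps = 100 * (1:100), rmsd = rep(2.7, 100))
  expect_equal(equilibration_onset(flat, p, mode = "auto"), 100)
  step <- data.frame(time_ps = 100 * (1:1400),
                     rmsd = c(rep(3, 400), rep(1, 1000)))
  onset <- equilibration_onset(step, p, mode = "auto", tol = 0.05,
                               window_frames = 10)
  expect_lte(abs(onset - 40000), 11 * 100)
  rising <- data.frame(time_ps = 100 * (1:100), rmsd = 1:100)
  expect_warning(out <- equilibration_onset(rising, p, mode = "auto",
                                            tol = 1e-6),
                 "no plateau")
  expect_equal(out, 40000)
})
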