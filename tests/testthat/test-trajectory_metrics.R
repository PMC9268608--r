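test_that("RMSD handles identity, rigid motion and the hand-computed case", {
  base <- cbind(c(0, 3, 0, 1), c(0, 0, 4, 1), c(0, 0, 0, 2))
  static <- line_trajectory(list(base, base, base))
  expect_equal(unclass(rmsd_series(static))[1:3], rep(0, 3),
               ignore_attr = TRUE)

  # a rigidly rotated + translated copy superposes back to zero
  set.seed(31)
  moved <- rigid_motion(base, random_rotation(), c(5, -2, 7))
  traj <- line_trajectory(list(base, moved))
  expect_lt(rmsd_series(traj, superpose = TRUE)[2], 1e-9)

  # two atoms displaced by (1,0,0) and (0,1,0): RMSD = sqrt((1+1)/2) = 1
  a <- rbind(c(0, 0, 0), c(10, 0, 0))
  b <- rbind(c(1, 0, 0), c(10, 1, 0))
  two <- line_trajectory(list(a, b))
  expect_equal(unname(rmsd_series(two, superpose = FALSE)[2]), 1.0)

  expect_error(rmsd_series(static, reference = 9), "out of range")
})

test_that("superposed RMSD never exceeds unsuperposed RMSD", {
  set.seed(14)
  frames <- lapply(1:10, function(i) {
    matrix(rnorm(30, sd = 3), 10, 3)
  })
  traj <- line_trajectory(frames)
  fit <- rmsd_series(traj, superpose = TRUE)
  raw <- rmsd_series(traj, superpose = FALSE)
  expect_true(all(fit <= raw + 1e-12))
})

test_that("RMSD and superposition agree with the bio3d reference", {
  set.seed(77)
  frames <- lapply(1:6, function(i) matrix(rnorm(24, sd = 2), 8, 3))
  traj <- line_trajectory(frames)
  ours <- rmsd_series(traj, superpose = TRUE)
  xyz <- t(vapply(frames, function(m) as.numeric(t(m)), numeric(24)))
  ref <- bio3d::rmsd(xyz[1, ], xyz, fit = TRUE)  # bio3d rounds to 3 dp
  expect_equal(unclass(ours), as.numeric(ref), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("RMSF is zero for static structures and flags planted mobility", {
  base <- helix_scaffold_for_tests(30)
  static <- line_trajectory(list(base, base, base))
  expect_equal(unname(rmsf_profile(static)), rep(0, 30))

  # residues 10-20 jittering at twice the amplitude must carry the 11
  # largest RMSF values
  sd_vec <- rep(0.2, 30); sd_vec[10:20] <- 0.4
  cfg <- traj_sim_config(n_residues = 30, n_frames = 800,
                         fluctuation_sd = sd_vec, seed = 4)
  free <- generate_trajectory_pair(cfg)$free
  prof <- rmsf_profile(free)
  expect_equal(sort(order(prof, decreasing = TRUE)[1:11]), 10:20)
})

test_that("RMSF recovers planted isotropic amplitudes as sigma*sqrt(3)", {
  cfg <- traj_sim_config(n_residues = 40, n_frames = 5000,
                         fluctuation_sd = 0.3, seed = 6)
  free <- generate_trajectory_pair(cfg)$free
  prof <- rmsf_profile(free)
  expect_equal(unname(prof), rep(0.3 * sqrt(3), 40), tolerance = 0.05)
})

test_that("RMSF is invariant under a global rigid motion of every frame", {
  set.seed(19)
  cfg <- traj_sim_config(n_residues = 12, n_frames = 50, seed = 9)
  free <- generate_trajectory_pair(cfg)$free
  rot <- random_rotation(); shift <- c(3, -8, 2)
  moved <- free
  for (f in seq_len(n_frames(free))) {
    moved$coords[, , f] <- rigid_motion(free$coords[, , f], rot, shift)
  }
  expect_equal(rmsf_profile(moved), rmsf_profile(free), tolerance = 1e-9)
})

test_that("COM distance series reproduces explicit geometries", {
  # symmetric two-atom protein centred at origin; ligand at constant
  # (3,4,0) offset: distance 5 every frame (3-4-5 triangle)
  frames <- lapply(1:5, function(f) {
    rbind(c(-2, 0, 0), c(2, 0, 0), c(3, 4, 0))
  })
  traj <- line_trajectory(frames, ligand = TRUE)
  ds <- com_distance_series(traj)
  expect_equal(ds$distance, rep(5, 5))
  expect_equal(ds$slope, 0)

  # ligand pinned at the protein centre of mass: all zeros
  frames0 <- lapply(1:4, function(f) rbind(c(-1, 0, 0), c(1, 0, 0),
                                           c(0, 0, 0)))
  expect_equal(com_distance_series(line_trajectory(frames0,
                                                   ligand = TRUE))$distance,
               rep(0, 4))

  noligand <- line_trajectory(list(matrix(0, 2, 3)))
  expect_error(com_distance_series(noligand), "no ligand")
})

test_that("COM distance slope recovers a planted dissociation drift", {
  cfg <- traj_sim_config(n_residues = 30, n_frames = 300, time_step = 1,
                         fluctuation_sd = 0.2, ligand_drift = 0.05,
                         seed = 13)
  bound <- generate_trajectory_pair(cfg)$bound
  ds <- com_distance_series(bound)
  expect_equal(ds$slope, 0.05, tolerance = 0.1)

  cfg0 <- traj_sim_config(n_residues = 30, n_frames = 300,
                          fluctuation_sd = 0.2, ligand_drift = 0, seed = 13)
  still <- com_distance_series(generate_trajectory_pair(cfg0)$bound)
  expect_lt(abs(still$slope), 5e-3)
})

test_that("residue distance profiles match explicit coordinates and are
           linear in the window", {
  # three equal-mass residues on one axis at 0, 5, 10: COM at x = 5
  one <- list(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)))
  prof <- residue_distance_profile(line_trajectory(one), window = "all")
  expect_equal(prof$d, c(5, 0, 5))

  cfg <- traj_sim_config(n_residues = 8, n_frames = 9, seed = 3)
  free <- generate_trajectory_pair(cfg)$free
  full <- residue_distance_profile(free, window = "all")
  h1 <- residue_distance_profile(free, window = 1:4)
  h2 <- residue_distance_profile(free, window = 5:9)
  expect_equal(full$d, (4 * h1$d + 5 * h2$d) / 9)
  # default window is the final third
  expect_equal(attr(residue_distance_profile(free), "window"), 7:9)
})

test_that("delta-d profiles classify, negate under swap, and validate", {
  prof <- function(d, state) {
    out <- data.frame(residue = seq_along(d), d = d)
    attr(out, "state") <- state
    class(out) <- c("residue_distance_profile", "data.frame")
    out
  }
  bound <- prof(c(12.5, 10.0, 7.0), "ligand-bound")
  free <- prof(c(10.0, 10.0, 9.5), "ligand-free")
  dd <- delta_d_profile(bound, free, threshold = 2)
  expect_equal(dd$delta_d, c(2.5, 0, -2.5))
  expect_equal(dd$class, c("further", "unchanged", "closer"))

  # identical states: all zero / unchanged
  same <- delta_d_profile(bound, bound)
  expect_equal(same$delta_d, rep(0, 3))
  expect_equal(unique(same$class), "unchanged")

  # antisymmetry
  swapped <- delta_d_profile(free, bound, threshold = 2)
  expect_equal(swapped$delta_d, -dd$delta_d)
  expect_equal(swapped$class, c("closer", "unchanged", "further"))

  # threshold is strict: |delta d| equal to the threshold is unchanged
  edge <- delta_d_profile(prof(c(12, 8), "b"), prof(c(10, 10), "f"),
                          threshold = 2)
  expect_equal(edge$class, c("unchanged", "unchanged"))

  mism <- prof(c(1, 2), "f"); mism$residue <- c(1, 9)
  expect_error(delta_d_profile(bound, mism), "only in bound")
})

test_that("delta-d is invariant under rigid motion and recovers planted
           shifts without false positives", {
  cfg <- traj_sim_config(n_residues = 40, n_frames = 1000,
                         fluctuation_sd = 0.2,
                         planted_shift = c("15" = 3.0), seed = 17)
  pair <- generate_trajectory_pair(cfg)
  dd <- delta_d_profile(residue_distance_profile(pair$bound),
                        residue_distance_profile(pair$free))
  expect_equal(dd$class[dd$residue == 15], "further")
  expect_equal(unique(dd$class[dd$residue != 15]), "unchanged")

  # rigid motion of the bound trajectory leaves the profile unchanged
  set.seed(23)
  rot <- random_rotation(); shift <- c(-4, 6, 1)
  moved <- pair$bound
  for (f in seq_len(n_frames(moved))) {
    moved$coords[, , f] <- rigid_motion(pair$bound$coords[, , f], rot, shift)
  }
  dd2 <- delta_d_profile(residue_distance_profile(moved),
                         residue_distance_profile(pair$free))
  expect_equal(dd2$delta_d, dd$delta_d, tolerance = 1e-9)
})
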