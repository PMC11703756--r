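# Flip-flop detection, leaflet assignment, height distributions,
# orientation profiles.

cfg <- transition_config()

test_that("hysteresis detector confirms full transfers only", {
  ev <- detect_transitions(zdf(c(0.8, 0.2, -0.75, 0.1, 0.9)), cfg)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$direction, c("down", "up"))
  expect_equal(ev$time_ns, c(2, 4))          # first confirming sample
  expect_equal(ev$pre_index, c(1, 3))
  expect_equal(ev$post_index, c(3, 5))
  # opposite leaflet never confirmed
  expect_equal(nrow(detect_transitions(zdf(c(0.8, 0.5, -0.5, 0.6)), cfg)), 0)
  # constant trace
  expect_equal(nrow(detect_transitions(zdf(rep(0.9, 10)), cfg)), 0)
  # short / empty traces return empty, not an error
  expect_equal(nrow(detect_transitions(zdf(0.8), cfg)), 0)
  # species-specific threshold: 0.65 confirms for B (d = 0.6), not A (0.7)
  zB <- zdf(c(0.65, -0.65), species = "B")
  expect_equal(nrow(detect_transitions(zB, cfg)), 1)
  expect_equal(nrow(detect_transitions(zdf(c(0.65, -0.65)), cfg)), 0)
  expect_error(detect_transitions(zdf(0.5, species = "X"), cfg),
               "no transition threshold")
})

test_that("negating a trace flips directions but keeps the count", {
  set.seed(1)
  for (i in 1:20) {
    z <- random_ztrace(200)
    a <- detect_transitions(zdf(z), cfg)
    b <- detect_transitions(zdf(-z), cfg)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a))
      expect_equal(b$direction, ifelse(a$direction == "up", "down", "up"))
  }
})

test_that("detector equals the dead-zone automaton oracle on random traces", {
  set.seed(99)
  for (i in 1:2000) {
    len <- sample(2:300, 1)
    d <- runif(1, 0.3, 1.0)
    z <- random_ztrace(len, scale = runif(1, 0.3, 1.5))
    ev <- detect_transitions(zdf(z), transition_config(c(A = d)))
    or <- oracle_transitions(z, d)
    expect_identical(nrow(ev), length(or$index))
    expect_identical(ev$post_index, or$index)
    if (length(or$index))
      expect_identical(ev$direction, ifelse(or$dir > 0, "up", "down"))
  }
})

test_that("sub-threshold insertions never change the event count", {
  set.seed(7)
  for (i in 1:30) {
    z <- random_ztrace(150)
    n0 <- nrow(detect_transitions(zdf(z), cfg))
    # inject sub-threshold samples at random positions
    z2 <- as.list(z)
    for (k in 1:40)
      z2 <- append(z2, runif(1, -0.69, 0.69),
                   after = sample(0:length(z2), 1))
    z2 <- unlist(z2)
    expect_equal(nrow(detect_transitions(zdf(z2), cfg)), n0)
  }
})

test_that("time reversal keeps the count and reverses directions", {
  set.seed(13)
  for (i in 1:30) {
    z <- random_ztrace(200)
    a <- detect_transitions(zdf(z), cfg)
    b <- detect_transitions(zdf(rev(z)), cfg)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a))
      expect_equal(b$direction,
                   rev(ifelse(a$direction == "up", "down", "up")))
  }
})

test_that("downsampling can only lose events, never create them", {
  set.seed(21)
  for (i in 1:25) {
    z <- random_ztrace(400)
    n0 <- nrow(detect_transitions(zdf(z), cfg))
    for (stride in c(2, 3, 7)) {
      zi <- z[seq(1, length(z), by = stride)]
      expect_lte(nrow(detect_transitions(zdf(zi), cfg)), n0)
    }
  }
})

test_that("replica averaging follows the fractional-count convention", {
  z_one <- c(0.8, -0.8)   # one transition
  z_zero <- c(0.8, 0.8)   # none
  zt <- rbind(cbind(zdf(z_one), replica = 1L),
              cbind(zdf(z_zero), replica = 2L))
  sm <- summarize_transitions(zt, cfg)
  expect_equal(sm$per_species$mean_count, 0.5)
  # single replica with 4 events stays 4.0
  z4 <- c(0.9, -0.9, 0.9, -0.9, 0.9)
  expect_equal(summarize_transitions(zdf(z4), cfg)$per_species$mean_count, 4)
  # mixed observation lengths warn and average per-replica rates
  zt2 <- rbind(cbind(zdf(z_one), replica = 1L),
               cbind(zdf(c(z_zero, 0.8, 0.8)), replica = 2L))
  expect_warning(sm2 <- summarize_transitions(zt2, cfg), "mixed observation")
  expect_equal(sm2$per_species$rate_per_us, mean(c(1 / 0.001, 0)))
})

test_that("summary on generator output matches the ground truth counts", {
  p <- langevin_params(barrier_height = 3, n_steps = 20000L,
                       frame_stride = 1L)
  s <- simulate_solute_trajectories(p, sim_composition(c(A = 2)), seed = 31)
  sm <- summarize_transitions(s$ztraces, cfg)
  expect_equal(sort(sm$per_molecule$count),
               sort(unname(s$ground_truth$transition_counts)))
})

test_that("leaflet assignment honours the instantaneous and confirmed policies", {
  z <- c(0.8, 0.1, -0.8)
  expect_equal(assign_leaflet(zdf(z), cfg, "confirmed"),
               c("upper", "upper", "lower"))
  expect_equal(assign_leaflet(zdf(z), cfg, "instantaneous"),
               c("upper", "upper", "lower"))
  expect_equal(assign_leaflet(zdf(c(0.1, -0.2, 0.3)), cfg, "confirmed"),
               rep("undetermined", 3))
  expect_equal(assign_leaflet(zdf(c(0, 0.2)), cfg, "instantaneous")[1],
               "undetermined")
})

test_that("height histograms normalize and fold as specified", {
  # all samples at one height: intensity-sensitive mass in the 0.7 bin
  h <- height_histogram(zdf(rep(0.7, 50)), mode = "intensity_sensitive")
  expect_equal(sum(h$prob), 1)
  expect_equal(sum(h$prob[h$breaks[-1] >= 0.7 - 1e-9 &
                          h$breaks[-1] <= 0.75 + 1e-9]), 1)
  # mirror-symmetric samples: tie broken to the positive half
  set.seed(3)
  zsym_half <- rnorm(500, 1, 0.2)
  zsym <- c(zsym_half, -zsym_half)
  hs <- height_histogram(zdf(zsym), mode = "intensity_sensitive")
  expect_equal(hs$winning_half, "positive")
  hp <- height_histogram(zdf(zsym_half[zsym_half > 0]),
                         mode = "intensity_sensitive")
  expect_equal(hs$prob, hp$prob, tolerance = 1e-12)
  # winning share equals the winning half's pre-normalization mass
  set.seed(4)
  z2 <- c(rnorm(700, 0.9, 0.25), rnorm(300, -0.9, 0.25))
  h2 <- height_histogram(zdf(z2), mode = "intensity_sensitive")
  expect_equal(h2$winning_share, mean(z2 > 0))
  expect_equal(sum(h2$prob), 1)
  hf <- height_histogram(zdf(z2), mode = "full_z")
  expect_equal(sum(hf$prob), 1)
})

test_that("parabolic refinement locates the mode below the bin width", {
  # known bin counts 100 / 120 / 110 around the max: the parabola vertex
  # sits at mid + (1/6) * bin_width
  z <- c(rep(0.98, 100), rep(1.03, 120), rep(1.08, 110))
  h <- height_histogram(zdf(z), bin_width = 0.05, mode = "full_z")
  expect_equal(histogram_peak(h), 1.025)
  expect_equal(histogram_peak(h, refine = TRUE), 1.025 + 0.05 / 6)
  # and on smooth data it recovers a sub-bin mode location
  set.seed(5)
  zr <- rnorm(2e5, 1.02, 0.2)
  hr <- height_histogram(zdf(zr), bin_width = 0.05, mode = "full_z")
  expect_lt(abs(histogram_peak(hr, refine = TRUE) - 1.02), 0.01)
})

test_that("intensity-sensitive fold matches the brute-force oracle bin-for-bin", {
  set.seed(8)
  for (i in 1:20) {
    up_share <- runif(1, 0.55, 0.9)
    n <- 2000
    z <- c(rnorm(round(n * up_share), 1, 0.3),
           rnorm(n - round(n * up_share), -1, 0.3))
    h <- height_histogram(zdf(z), bin_width = 0.05,
                          mode = "intensity_sensitive")
    expect_equal(h$prob, oracle_fold_histogram(z, 0.05), tolerance = 1e-12)
  }
})

test_that("same-leaflet conditioning keeps only co-resident frames", {
  z1 <- c(0.9, 0.8, -0.9, 0.7, -0.8)
  z2 <- c(0.9, -0.8, -0.9, 0.6, 0.8)
  h <- height_histogram(zdf(z1), mode = "full_z",
                        conditioning = "same_leaflet", partner = zdf(z2))
  expect_equal(h$n_samples, 3)  # frames 1, 3, 4
  expect_error(
    height_histogram(zdf(c(0.5, 0.4)), conditioning = "same_leaflet",
                     partner = zdf(c(-0.5, -0.4))),
    "removed all samples")
  expect_error(height_histogram(zdf(z1), conditioning = "same_leaflet"),
               "partner")
})

test_that("orientation profile recovers axis alignment by height", {
  # molecule with two atoms; axis along +z in frames 1-2, in-plane in frame 3
  mk <- function(axis_vecs, com_z) {
    frames <- lapply(seq_along(com_z), function(f) {
      a1 <- c(2, 2, com_z[f] - axis_vecs[[f]][3] / 2)
      a2 <- a1 + axis_vecs[[f]]
      rbind(a1, a2, c(1, 1, 1.9), c(1, 2, -1.9))
    })
    make_traj(frames, species = c("LIG", "LIG", "P", "P"),
              molecule_id = c(1L, 1L, 1001L, 1002L),
              atom_name = c("C1", "C2", "P", "P"))
  }
  traj <- mk(list(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)), c(1.5, 1.4, 0.1))
  prof <- orientation_profile(traj, 1, c("C1", "C2"), bin_width = 1)
  expect_equal(prof$mean_abs_cos[prof$z_mid > 1], 1)
  expect_equal(prof$mean_abs_cos[prof$z_mid < 1], 0)
  # degenerate axis errors
  traj0 <- mk(list(c(0, 0, 0)), 1)
  expect_error(orientation_profile(traj0, 1, c("C1", "C2")), "degenerate")
})

test_that("synthetic z-dependent orientation rule is recovered within noise", {
  # axis tilts towards the plane near the head groups, orthogonal at centre:
  # |cos theta| = 1 - 0.8 * (|z| / 1.9)
  set.seed(55)
  zs <- runif(400, -1.8, 1.8)
  frames <- lapply(zs, function(zc) {
    c_target <- 1 - 0.8 * abs(zc) / 1.9
    theta <- acos(c_target)
    axis <- c(sin(theta), 0, cos(theta)) * 0.5
    a1 <- c(2, 2, zc - axis[3] / 2)
    rbind(a1, a1 + axis, c(1, 1, 1.9), c(1, 2, -1.9))
  })
  traj <- make_traj(frames, species = c("LIG", "LIG", "P", "P"),
                    molecule_id = c(1L, 1L, 1001L, 1002L),
                    atom_name = c("C1", "C2", "P", "P"))
  prof <- orientation_profile(traj, 1, c("C1", "C2"), bin_width = 0.4)
  expected <- 1 - 0.8 * abs(prof$z_mid) / 1.9
  ok <- prof$count >= 10
  expect_true(all(abs(prof$mean_abs_cos[ok] - expected[ok]) < 0.12))
})
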