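# Langevin bilayer-mimetic generator and synthetic trace generators.

short_params <- function(...) {
  langevin_params(n_steps = 50000L, frame_stride = 10L, ...)
}

test_that("parameter validation rejects unstable or degenerate setups", {
  expect_error(langevin_params(timestep = 1, normal_diffusion = 1),
               "unstable")
  expect_error(langevin_params(box_z = 3), "box_z")
  expect_error(sim_composition(c(A = 0)), "count")
  expect_error(sim_composition(c(A = 1), thresholds = c(B = 0.6)),
               "threshold")
  expect_error(sim_composition(c(A = 2), interactions = list(
    list(pair = c("A", "A"), epsilon = -1, sigma_r = 0.5, sigma_z = 0.3))),
    "epsilon")
})

test_that("identical (params, comp, seed) give bit-identical output", {
  p <- langevin_params(n_steps = 5000L)
  comp <- sim_composition(c(A = 2), interactions = list(
    list(pair = c("A", "A"), epsilon = 2, sigma_r = 0.6, sigma_z = 0.35,
         kappa = 1)))
  a <- simulate_solute_trajectories(p, comp, seed = 11)
  b <- simulate_solute_trajectories(p, comp, seed = 11)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$ztraces, b$ztraces)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_solute_trajectories(p, comp, seed = 12)
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))
})

test_that("flat potential gives a symmetric stationary mean (|mean z| < 3 SEM)", {
  p <- short_params(barrier_height = 0)
  s <- simulate_solute_trajectories(p, sim_composition(c(A = 1)), seed = 5)
  z <- s$ztraces$z_nm
  # decorrelated subsample for an honest SEM
  zi <- z[seq(1, length(z), by = 200)]
  expect_lt(abs(mean(zi)), 3 * sd(zi) / sqrt(length(zi)))
})

test_that("transition count decreases with barrier height (Kramers-like)", {
  comp <- sim_composition(c(A = 1))
  n4 <- vapply(1:6, function(i)
    simulate_solute_trajectories(short_params(barrier_height = 4), comp,
                                 seed = 40 + i)$ground_truth$transition_counts,
    numeric(1))
  n10 <- vapply(1:6, function(i)
    simulate_solute_trajectories(short_params(barrier_height = 10), comp,
                                 seed = 40 + i)$ground_truth$transition_counts,
    numeric(1))
  expect_lt(mean(n10), mean(n4))
})

test_that("a strongly coupled partner suppresses transitions and shifts |z| outward", {
  p <- short_params(barrier_height = 4)
  alone <- sim_composition(c(A = 1))
  paired <- sim_composition(c(A = 2), interactions = list(
    list(pair = c("A", "A"), epsilon = 6, sigma_r = 0.6, sigma_z = 0.35,
         kappa = 2)))
  cnt_a <- cnt_p <- absz_a <- absz_p <- numeric(0)
  for (i in 1:8) {
    sa <- simulate_solute_trajectories(p, alone, seed = 300 + i)
    sp <- simulate_solute_trajectories(p, paired, seed = 300 + i)
    cnt_a <- c(cnt_a, sa$ground_truth$transition_counts)
    cnt_p <- c(cnt_p, mean(sp$ground_truth$transition_counts))
    absz_a <- c(absz_a, mean(abs(sa$ztraces$z_nm)))
    absz_p <- c(absz_p, mean(abs(sp$ztraces$z_nm)))
  }
  expect_lt(mean(cnt_p), mean(cnt_a))
  expect_gt(mean(absz_p), mean(absz_a))
  # paired particles really are in contact a substantial part of the time
  sp <- simulate_solute_trajectories(p, paired, seed = 300)
  expect_gt(sp$ground_truth$contact_fraction[1, 2], 0.2)
})

test_that("ground truth equals the detector run at full resolution", {
  p <- langevin_params(barrier_height = 3, n_steps = 20000L,
                       frame_stride = 1L)
  s <- simulate_solute_trajectories(p, sim_composition(c(A = 1)), seed = 77)
  ev <- detect_transitions(s$ztraces[s$ztraces$molecule_id == 1, ],
                           transition_config())
  truth <- s$ground_truth$transitions[[1]]
  # frame 1 is the initial state; events and times must agree exactly
  expect_equal(nrow(ev), nrow(truth))
  expect_equal(ev$time_ns, truth$time_ns)
  expect_equal(ev$direction, truth$direction)
})

test_that("uncoupled particles have uncorrelated z-traces", {
  p <- short_params(barrier_height = 1)
  s <- simulate_solute_trajectories(p, sim_composition(c(A = 2)), seed = 9)
  z1 <- s$ztraces$z_nm[s$ztraces$molecule_id == 1]
  z2 <- s$ztraces$z_nm[s$ztraces$molecule_id == 2]
  k <- seq(1, length(z1), by = 100)  # decorrelate in time
  r <- cor(z1[k], z2[k])
  expect_lt(abs(r), 3 / sqrt(length(k)))
})

test_that("stationary z-histogram matches exp(-U) (KS, alpha = 0.01)", {
  p <- langevin_params(barrier_height = 2, n_steps = 100000L,
                       frame_stride = 10L)
  comp <- sim_composition(c(A = 1))
  zs <- unlist(lapply(1:6, function(i) {
    s <- simulate_solute_trajectories(p, comp, seed = 7000 + i)
    z <- s$ztraces$z_nm
    z[seq(500, length(z), by = 500)]  # one sample per 50 ns
  }))
  kt <- suppressWarnings(stats::ks.test(zs, stationary_cdf(2)))
  expect_gt(kt$p.value, 0.01)
})

# ---- fluorescence and area generators ----------------------------------

test_that("zero-rate fluorescence traces stay at baseline", {
  fl <- simulate_fluorescence_traces(3, "quench", rate_per_min = 0,
                                     noise_sd = 0, seed = 1)
  expect_true(all(fl$traces$intensity == fl$i0))
})

test_that("noise-free quench trace recovers the transport fraction exactly", {
  fl <- simulate_fluorescence_traces(1, "quench", transport_fraction = 0.6,
                                     rate_per_min = 5, noise_sd = 0,
                                     seed = 1)
  tr <- fl$traces
  pct <- percent_transport_quench(tr, i_mean = fl$i0,
                                  addition_time_min = fl$addition_time_min)
  expect_equal(as.numeric(pct), 60, tolerance = 1e-6)
})

test_that("transport fractions are recovered within 5 points RMSE at 2% noise", {
  fl <- simulate_fluorescence_traces(50, "quench",
                                     transport_fraction = runif(50),
                                     rate_per_min = 1, noise_sd = 2,
                                     seed = 2024)
  est <- vapply(split(fl$traces, fl$traces$guv_id), function(tr)
    as.numeric(percent_transport_quench(tr, fl$i0, fl$addition_time_min)),
    numeric(1))
  truth <- fl$truth$transport_fraction * 100
  expect_gt(cor(est, truth), 0.98)
  expect_lt(sqrt(mean((est - truth)^2)), 5)
})

test_that("area generator produces classifiable lysing and stable traces", {
  expect_error(simulate_area_traces(0), "n must be")
  ar <- simulate_area_traces(20, lysing = rep(c(TRUE, FALSE), 10),
                             noise_frac = 0.02, seed = 3)
  calls <- vapply(split(ar$traces, ar$traces$guv_id),
                  function(tr) detect_lysis(tr)$lysed, logical(1))
  expect_equal(unname(calls), ar$truth$lysing)
})
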