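test_that("noise-free uncoupled simulation is exactly linear in time", {
  m <- phase_model(2.1, D = 0)
  sim <- simulate_phase_model(m, dt = 0.01, n_steps = 500, seed = 1)
  expect_equal(sim$phi_1, 2.1 * sim$time, tolerance = 1e-12)
  expect_equal(phase_velocity(sim), rep(2.1, 500), tolerance = 1e-10)
})

test_that("a deterministic Adler pair locks at psi = arcsin(delta_omega / K)", {
  ## dpsi/dt = 0.05 - 0.1 sin(psi): stable fixed point arcsin(0.5)
  m <- phase_model(c(1.05, 1.0), D = 0,
                   couplings = list(coupling_term(1, 2, 1, 1, a = 0, b = 0.1)))
  sim <- simulate_phase_model(m, dt = 0.005, n_steps = 4e4, seed = 1)
  psi <- phase_difference(sim$phi_1, sim$phi_2, 1, 1)  # phi_2 - phi_1
  ## target 1 is faster by 0.05 and is pulled by 0.1 sin(phi_2 - phi_1)
  tail_psi <- utils::tail(psi, 1000)
  expect_equal(mean(tail_psi), -asin(0.5), tolerance = 1e-3)
})

test_that("Euler-Maruyama at D = 0 converges at first order against an ODE oracle", {
  m <- phase_model(c(1.0, 1.4), D = 0,
                   couplings = list(coupling_term(1, 2, 1, 1, a = 0.05, b = 0.2)))
  rhs <- function(t, s, p) {
    list(c(1.0 + 0.05 * cos(s[2] - s[1]) + 0.2 * sin(s[2] - s[1]), 1.4))
  }
  t_end <- 10
  ref <- deSolve::ode(c(0, 0), c(0, t_end), rhs, NULL, rtol = 1e-12, atol = 1e-12)
  err <- vapply(c(0.02, 0.01), function(dt) {
    sim <- simulate_phase_model(m, dt = dt, n_steps = round(t_end / dt), seed = 1)
    abs(sim$phi_1[nrow(sim)] - ref[2, 2])
  }, numeric(1))
  expect_gt(err[1] / err[2], 1.6)
  expect_lt(err[1] / err[2], 2.6)
})

test_that("phase histograms are normalised densities with the expected shapes", {
  set.seed(3)
  h_u <- phase_histogram(runif(2e4, 0, 2 * pi), n_bins = 30)
  expect_equal(sum(h_u$density * (h_u$bin_right - h_u$bin_left)), 1, tolerance = 1e-12)
  expect_lt(max(abs(h_u$density - 1 / (2 * pi))), 0.03)
  ## delta-like locked data: essentially all mass in two adjacent bins
  h_d <- phase_histogram(rnorm(5000, pi, 0.05), n_bins = 30)
  top2 <- sort(h_d$density, decreasing = TRUE)[1:2]
  expect_gt(sum(top2) * (2 * pi / 30), 0.9)
  expect_equal(sum(h_d$density * (h_d$bin_right - h_d$bin_left)), 1, tolerance = 1e-12)
  expect_error(phase_histogram(numeric(0)), "Empty")
  expect_error(phase_histogram(1, n_bins = 1), "n_bins")
})

test_that("ablation zeroes couplings, keeps frequencies and noise, and is idempotent", {
  m <- drive_pair_model()
  ab <- ablate_edges(m, tibble::tibble(target = "theta", source = "s"))
  expect_equal(length(ab$couplings[[1]]$a), 0L)
  expect_equal(length(ab$couplings[[2]]$a), 1L)
  expect_equal(ab$omega_hat, m$omega_hat)
  expect_equal(ab$D, m$D)
  expect_equal(ablate_edges(ab, tibble::tibble(target = "theta", source = "s")), ab)
  expect_error(ablate_edges(m, tibble::tibble(target = "s", source = "zzz")),
               "Unknown")
  ## both directions removed: independent drifting pair, flat histogram
  ab2 <- ablate_edges(m, tibble::tibble(target = c("theta", "s"),
                                        source = c("s", "theta")))
  sim <- simulate_phase_model(ab2, dt = 0.01, n_steps = 1e5, seed = 5,
                              burn_in = 10000)
  h <- phase_histogram(phase_difference(sim$theta, sim$s))
  expect_lt(l1_to_uniform(h), 0.25)
})

test_that("the three-oscillator fixture carries its ground truth and locking structure", {
  fx <- three_oscillator_fixture(n_steps = 5e4, seed = 3)
  expect_equal(length(fx$model$couplings), 4L)
  nonzero <- vapply(fx$model$couplings, function(tm) length(tm$a) > 0, logical(1))
  expect_true(all(nonzero))
  ## zero noise, couplings removed: velocities are exactly the natural frequencies
  bare <- ablate_edges(fx$model, tibble::tibble(
    target = c("phi_1", "phi_2", "phi_2", "phi_3"),
    source = c("phi_3", "phi_1", "phi_3", "phi_2")))
  bare$D <- rep(0, 3)
  simb <- simulate_phase_model(bare, dt = 0.01, n_steps = 100, seed = 1)
  expect_equal(unname(colMeans(diff(as.matrix(simb[, -1])) / 0.01)),
               c(0.9, 2.1, 1.1), tolerance = 1e-12)
  ## near-1:2 relation of the fast oscillator to both slow ones
  v <- colMeans(diff(as.matrix(fx$phases[, -1])) / 0.01)
  expect_equal(unname(v[["phi_2"]] / v[["phi_1"]]), 2, tolerance = 0.15)
  expect_equal(unname(v[["phi_2"]] / v[["phi_3"]]), 2, tolerance = 0.15)
  ## deterministic given the seed
  fx2 <- three_oscillator_fixture(n_steps = 5e4, seed = 3)
  expect_identical(fx$phases, fx2$phases)
})

test_that("simulating the re-estimated model reproduces the phase-difference histogram", {
  m <- drive_pair_model()
  sim <- simulate_phase_model(m, dt = 0.01, n_steps = 1e5, seed = 7,
                              burn_in = 10000)
  edges <- edge_hypotheses(c("theta", "s"), c("s", "theta"))
  fit <- estimate_model(sim, edges, M_max = 3)
  sim2 <- simulate_phase_model(fit$model, dt = 0.01, n_steps = 1e5, seed = 8,
                               burn_in = 10000)
  h1 <- phase_histogram(phase_difference(sim$theta, sim$s))
  h2 <- phase_histogram(phase_difference(sim2$theta, sim2$s))
  expect_lt(histogram_l1(h1, h2), 0.1)
})
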