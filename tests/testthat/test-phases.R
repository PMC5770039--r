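test_that("protophase of a pure tone advances at the tone frequency and is scale invariant", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  sig <- tibble::tibble(time = t, x = cos(2 * pi * 5 * t), x3 = 3.7 * cos(2 * pi * 5 * t))
  pp <- analytic_protophase(sig, "x")
  core <- 200:(nrow(pp) - 200)  # away from transform edge effects
  inst_f <- diff(unwrap_phase(pp$theta[core])) * fs / (2 * pi)
  expect_equal(mean(inst_f), 5, tolerance = 0.01)
  expect_equal(mean(pp$amplitude[core]), 1, tolerance = 0.01)
  pp3 <- analytic_protophase(sig, "x3")
  expect_equal(pp3$theta[core], pp$theta[core], tolerance = 1e-8)
  expect_equal(mean(pp3$amplitude[core]), 3.7, tolerance = 0.05)

  expect_error(analytic_protophase(tibble::tibble(time = t, x = rep(2, length(t))), "x"),
               "no oscillation")
  bad <- sig; bad$x[5] <- NA
  expect_error(analytic_protophase(bad, "x"), "NA")
})

test_that("circular density estimation recovers harmonics and matches a histogram oracle", {
  set.seed(7)
  th_u <- runif(1e5, 0, 2 * pi)
  d_u <- estimate_density(th_u, n_harmonics = 5)
  expect_lt(max(abs(c(d_u$cos_coef, d_u$sin_coef))), 0.02)

  th_c <- sample_cosine_density(1e5, seed = 11)
  d_c <- estimate_density(th_c, n_harmonics = 5)
  ## density (1 + 0.5 cos)/2pi has first circular moment E cos(theta) = 0.25,
  ## i.e. density cosine harmonic 2 * c1 = 0.5
  expect_equal(2 * d_c$cos_coef[1], 0.5, tolerance = 0.05)
  ## histogram-based density oracle on a coarse grid
  h <- graphics::hist(th_c, breaks = seq(0, 2 * pi, length.out = 41), plot = FALSE)
  d_on_mids <- approx(d_c$grid, d_c$density, xout = h$mids)$y
  expect_lt(max(abs(d_on_mids - h$density)), 0.05)

  d0 <- estimate_density(th_c, n_harmonics = 0)
  expect_equal(d0$density, rep(1 / (2 * pi), length(d0$grid)), tolerance = 1e-12)
  expect_error(estimate_density(numeric(0)), "Empty")
})

test_that("protophase correction is the identity for uniform density and matches closed forms", {
  th <- seq(0, 30, by = 0.01)  # several turns, unwrapped
  unif <- estimate_density(runif(1000, 0, 2 * pi), n_harmonics = 0)
  phi <- protophase_to_phase(th, unif)$phi
  expect_equal(phi, th, tolerance = 1e-9)

  ## cosine-perturbed density: phi(theta) = theta + 0.5 sin(theta)
  d_c <- estimate_density(sample_cosine_density(2e5, seed = 3), n_harmonics = 8)
  th_grid <- seq(0, 2 * pi - 1e-9, length.out = 200)
  phi_est <- protophase_to_phase(th_grid, d_c)$phi
  expect_equal(phi_est, th_grid + 0.5 * sin(th_grid), tolerance = 0.02)

  ## quadrature oracle: 2 pi * trapezoid integral of the estimated density
  ## on an independent fine grid
  for (th0 in c(0.7, pi, 5.1)) {
    g <- seq(0, th0, length.out = 20001)
    fg <- approx(d_c$grid, d_c$density, xout = g)$y
    q <- 2 * pi * sum((fg[-1] + fg[-length(fg)]) / 2) * (g[2] - g[1])
    expect_equal(protophase_to_phase(th0, d_c)$phi, q, tolerance = 1e-4)
  }

  ## winding is preserved: each full turn of theta adds 2 pi to phi
  turns <- floor(th / (2 * pi))
  expect_equal(floor(phi / (2 * pi) + 1e-9), turns)
})

test_that("correction makes the wrapped phase of a relaxation oscillator more uniform", {
  traj <- simulate_circuit(vdp_params(coupling = FALSE), duration = 2, dt = 5e-5)
  traj <- traj[traj$time > 0.3, ]
  pp <- analytic_protophase(traj, "x1")
  phi <- protophase_to_phase(pp)$phi
  ks_theta <- ks_uniform_circle(pp$theta)
  ks_phi <- ks_uniform_circle(phi)
  expect_lt(ks_phi, ks_theta)
  ## same winding number
  expect_equal(floor(max(unwrap_phase(pp$theta)) / (2 * pi)),
               floor(max(phi) / (2 * pi)))
})

test_that("phase velocity is the forward difference and inverts cumulative summation", {
  dt <- 0.02
  phi <- 2.1 * seq(0, 10, by = dt)
  expect_equal(phase_velocity(phi, dt), rep(2.1, length(phi) - 1L))
  set.seed(1)
  incr <- rnorm(500)
  path <- cumsum(c(0, incr))
  expect_equal(phase_velocity(path, 1), incr)
  expect_error(phase_velocity(phi, -0.1), "positive")
  expect_error(phase_velocity(phi[1], 0.1), "2 samples")
})

test_that("zero-phase shifts add constants and respect periodicity", {
  ph <- tibble::tibble(time = seq(0, 1, by = 0.01), phi = seq(0, 20, length.out = 101))
  expect_identical(shift_zero_phase(ph, 0), ph)
  sh <- shift_zero_phase(ph, pi / 6)
  expect_equal(sh$phi - ph$phi, rep(pi / 6, nrow(ph)))
  full <- shift_zero_phase(ph, 2 * pi)
  expect_equal(full$phi %% (2 * pi), ph$phi %% (2 * pi), tolerance = 1e-12)
  expect_error(shift_zero_phase(ph, Inf), "finite")
})

test_that("bandpass passes in-band tones and the envelope mode recovers AM modulation", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  tone <- tibble::tibble(time = t, x = sin(2 * pi * 4.5 * t))
  bp <- bandpass_and_envelope(tone, 3, 6, mode = "band")
  core <- round(0.25 * length(t)):round(0.75 * length(t))
  expect_gt(sd(bp$x[core]) / sd(tone$x[core]), 0.95)

  ## AM carrier: band-filtered envelope tracks the band-filtered modulation
  a <- 1 + 0.4 * cos(2 * pi * 2 * t)
  am <- tibble::tibble(time = t, x = a * cos(2 * pi * 100 * t))
  env <- bandpass_and_envelope(am, 1, 3, mode = "envelope")
  ref <- bandpass_and_envelope(tibble::tibble(time = t, x = a), 1, 3, mode = "band")
  expect_lt(sqrt(mean((env$x[core] - ref$x[core])^2)) / sd(ref$x[core]), 0.05)

  expect_error(bandpass_and_envelope(tone, 6, 3), "Invalid band")
  expect_error(bandpass_and_envelope(tone, 3, 400), "Invalid band")
})
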