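test_that("the simulation benchmark recovers the generating network", {
  rep1 <- run_simulation_benchmark(n_steps = 1e5, seed = 11)
  known <- !is.na(rep1$recovery$truth)
  expect_true(all(rep1$recovery$within_3sd[known]))
  expect_equal(rep1$orders$M_selected, rep1$orders$M_true)
  ## absent couplings carry far less power than the weakest true coupling
  pw <- dplyr::inner_join(rep1$powers, rep1$orders, by = c("target", "source"))
  min_true <- min(pw$power[pw$M_true > 0])
  expect_lt(max(pw$power[pw$M_true == 0], 0), 0.1 * min_true)
  ## deterministic given the seed
  rep2 <- run_simulation_benchmark(n_steps = 1e5, seed = 11)
  expect_identical(rep1$recovery$estimate, rep2$recovery$estimate)
})

test_that("the circuit benchmark matches adjoint theory and reproduces histograms", {
  rep <- run_circuit_benchmark("same-freq", duration = 16, fs = 5000, seed = 2)
  tms <- rep$fit$model$couplings
  tgt <- vapply(tms, function(tm) rep$fit$model$labels[tm$target], character(1))
  M_rev <- length(tms[[which(tgt == "x1")]]$a)
  M_fwd <- length(tms[[which(tgt == "x2")]]$a)
  expect_equal(M_rev, 0L)   # nothing feeds back into oscillator 1
  expect_gt(M_fwd, 0L)
  expect_lt(rep$l1[["estimated"]], 0.1)
  ## estimated coupling function overlays the adjoint-method function
  th <- rep$theory$table
  cc <- coupling_curves(rep$fit)
  est <- cc[cc$target == "x2", ]
  g_th <- th$gamma - mean(th$gamma)
  g_est <- approx(est$psi, est$estimate - mean(est$estimate), xout = th$psi)$y
  amp <- (max(g_th) - min(g_th)) / 2
  expect_lt(sqrt(mean((g_th - g_est)^2)) / amp, 0.15)
  ## independent oracle: binned mean of dpsi/dt against psi reproduces the
  ## theoretical shape (dpsi/dt = const - Gamma(psi) + noise)
  dt <- 1 / 5000
  psi <- phase_difference(rep$phases$x2, rep$phases$x1, 1, 1)
  v <- diff(psi) / dt
  pw <- utils::head(psi, -1) %% (2 * pi)
  bins <- cut(pw, seq(0, 2 * pi, length.out = 25), include.lowest = TRUE)
  emp <- tapply(v, bins, mean)
  mid <- seq(0, 2 * pi, length.out = 25)[-25] + pi / 24
  g_mid <- approx(c(th$psi, 2 * pi), c(th$gamma, th$gamma[1]), xout = mid)$y
  g_mid <- g_mid - mean(g_mid)
  g_emp <- -(emp - mean(emp))
  expect_lt(sqrt(mean((g_emp - g_mid)^2)) / ((max(g_mid) - min(g_mid)) / 2), 0.15)
})

test_that("the cross-frequency circuit couples only slow to fast at 1:2", {
  rep <- run_circuit_benchmark("cross-freq", duration = 16, fs = 5000, seed = 3)
  tms <- rep$fit$model$couplings
  tgt <- vapply(tms, function(tm) rep$fit$model$labels[tm$target], character(1))
  expect_equal(length(tms[[which(tgt == "x1")]]$a), 0L)
  expect_gt(length(tms[[which(tgt == "x2")]]$a), 0L)
  expect_lt(rep$l1[["estimated"]], 0.1)
})

test_that("rhythm-pair analysis flags the unidirectional drive in synthetic signals", {
  ## stimulus rhythm (4.5 Hz) entrains a slightly detuned oscillation with
  ## marginal locking (occasional phase slips give full psi coverage)
  fs <- 100
  m <- phase_model(c(2 * pi * 4.2, 2 * pi * 4.5), D = c(0.5, 0.5),
                   couplings = list(coupling_term(1, 2, 1, 1, a = 0, b = 2)),
                   labels = c("eeg", "stim"))
  sim <- simulate_phase_model(m, dt = 1 / fs, n_steps = 12000, seed = 17,
                              burn_in = 2000)
  sig <- tibble::tibble(time = sim$time,
                        eeg = cos(sim$eeg) + 0.1 * sin(2 * pi * 17 * sim$time),
                        stim = cos(sim$stim))
  res <- run_rhythm_pairs(sig, target = "eeg", source = "stim",
                          target_band = c(3, 6), source_band = c(3, 6),
                          n_surrogates = 19, seed = 5)
  p_fwd <- res$powers$power[res$powers$direction == "eeg<-stim"]
  p_rev <- res$powers$power[res$powers$direction == "stim<-eeg"]
  expect_gt(p_fwd, 5 * max(p_rev, 1e-6))
  expect_lt(histogram_l1(res$histograms$data, res$histograms$fitted), 0.4)
  ## only the forward ablation destroys the locking
  expect_lt(l1_to_uniform(res$histograms$ablate_forward), 0.3)
  expect_lt(l1_to_uniform(res$histograms$ablate_forward),
            0.5 * l1_to_uniform(res$histograms$data))
  expect_gt(l1_to_uniform(res$histograms$ablate_reverse),
            l1_to_uniform(res$histograms$ablate_forward))
  expect_lte(attr(res$surrogates, "p_value"), 0.1)
})

test_that("1:2 hypotheses build the prosody-style phase difference", {
  set.seed(8)
  ph <- tibble::tibble(time = seq(0, 9.99, by = 0.01),
                       theta = cumsum(rnorm(1000, 0.02)),
                       pros = cumsum(rnorm(1000, 0.01)))
  prob <- build_problem(ph, "theta",
                        edge_hypotheses("theta", "pros", p_i = 2L, p_j = 1L, M = 1L))
  psi <- 2 * ph$pros - ph$theta
  expect_equal(prob$X[, "cos1[theta<-pros(2:1)]"], cos(psi)[-length(psi)])
})

test_that("manifests and phase files round-trip through disk", {
  cfg <- list(input = "phases.csv", mmax = 3, edges = "a<-b:1:1")
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(cfg, path, seed = 7)
  man <- jsonlite::read_json(path)
  expect_equal(man$config$mmax, 3)
  expect_equal(man$seed, 7)
  expect_match(man$config_md5, "^[0-9a-f]{32}$")

  ph <- tibble::tibble(time = seq(0, 0.99, by = 0.01), phi_1 = seq(0, 9.9, length.out = 100))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_phases(ph, csv)
  back <- read_signals(csv)
  expect_equal(back$time, ph$time)
  expect_equal(back$phi_1_rad, ph$phi_1)
})
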