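make_phases <- function(mat, dt = 0.01, labels = NULL) {
  labels <- labels %||% paste0("phi_", seq_len(ncol(mat)))
  out <- tibble::tibble(time = (seq_len(nrow(mat)) - 1L) * dt)
  for (k in seq_len(ncol(mat))) out[[labels[k]]] <- mat[, k]
  out
}

test_that("design matrices have one intercept plus 2M Fourier columns per edge", {
  set.seed(1)
  ph <- make_phases(cbind(cumsum(rnorm(50, 0.01)), cumsum(rnorm(50, 0.02)),
                          cumsum(rnorm(50, 0.01))))
  p0 <- build_problem(ph, "phi_1", edge_hypotheses(character(), character()))
  expect_equal(ncol(p0$X), 1L)
  expect_true(all(p0$X[, 1] == 1))
  p1 <- build_problem(ph, "phi_1",
                      edge_hypotheses("phi_1", "phi_2", M = 1L))
  expect_equal(ncol(p1$X), 3L)
  ## fast-oscillator target with one M=1 and one M=2 edge: 1 + 2 + 4 columns
  p2 <- build_problem(ph, "phi_2",
                      edge_hypotheses(c("phi_2", "phi_2"), c("phi_1", "phi_3"),
                                      p_i = 2L, p_j = 1L, M = c(1L, 2L)))
  expect_equal(ncol(p2$X), 7L)
  expect_equal(nrow(p2$X), length(p2$y))
  ## feature columns hold cos/sin of the generalised phase difference
  psi <- 2 * ph$phi_1 - ph$phi_2
  expect_equal(p2$X[, 2], cos(psi)[-length(psi)])
})

test_that("posterior mean converges to ordinary least squares under a flat prior", {
  set.seed(5)
  n <- 30
  X <- cbind(1, rnorm(n), runif(n))
  y <- drop(X %*% c(0.5, -0.3, 1.2)) + rnorm(n, sd = 0.3)
  prob <- structure(list(y = y, X = X, dt = 0.1,
                         labels = c("(Intercept)", "a", "b")),
                    class = "phase_regression")
  post <- fit_posterior(prob, nig_prior(variance = 1e6))
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_equal(post$chi, ols, tolerance = 1e-4)
  ## with no rows the posterior equals the prior
  prob0 <- structure(list(y = numeric(0), X = X[0, , drop = FALSE], dt = 0.1,
                          labels = colnames(X)),
                     class = "phase_regression")
  post0 <- fit_posterior(prob0, nig_prior(variance = 4, alpha = 2, beta = 3))
  expect_equal(post0$chi, rep(0, 3))
  expect_equal(diag(post0$Sigma), rep(4, 3))
  expect_equal(c(post0$alpha, post0$beta), c(2, 3))
  ## collinear columns under an effectively flat prior are flagged
  probc <- structure(list(y = y, X = cbind(X, X[, 2]), dt = 0.1,
                          labels = c(colnames(X), "dup")),
                     class = "phase_regression")
  expect_error(fit_posterior(probc, nig_prior(variance = 1e18)), "[Ss]ingular")
})

test_that("log evidence is parameter-point independent and matches numerical marginalisation", {
  set.seed(42)
  n <- 6
  X <- cbind(1, rnorm(n))
  y <- 0.5 + 0.3 * X[, 2] + rnorm(n, sd = 0.4)
  prob <- structure(list(y = y, X = X, dt = 0.1, labels = c("(Intercept)", "x")),
                    class = "phase_regression")
  spec <- nig_prior(chi0 = 0, variance = 2, alpha = 2, beta = 1)
  post <- fit_posterior(prob, spec)
  ev <- log_evidence(prob, spec, post)
  for (pt in list(list(w = c(0.1, -0.2), sigma2 = 0.7),
                  list(w = c(2, 2), sigma2 = 3),
                  list(w = post$chi, sigma2 = post$beta / post$alpha))) {
    expect_equal(log_evidence(prob, spec, post, at = pt), ev, tolerance = 1e-8)
  }
  oracle <- evidence_quadrature(y, X, spec)
  expect_equal(ev, oracle, tolerance = 1e-3)
})

test_that("evidence favours the simpler model on coupling-free noise data", {
  n_rep <- 100
  wins <- 0L
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    T <- 500
    dt <- 0.01
    phi_t <- cumsum(c(0, 1.0 * dt + rnorm(T, sd = 0.1 * sqrt(dt))))
    phi_s <- cumsum(c(0, 1.3 * dt + rnorm(T, sd = 0.1 * sqrt(dt))))
    ph <- make_phases(cbind(phi_t, phi_s), dt = dt)
    e <- edge_hypotheses("phi_1", "phi_2", M = 0L)
    p0 <- build_problem(ph, "phi_1", e)
    e$M <- 3L
    p3 <- build_problem(ph, "phi_1", e)
    ev0 <- log_evidence(p0, nig_prior(), fit_posterior(p0, nig_prior()))
    ev3 <- log_evidence(p3, nig_prior(), fit_posterior(p3, nig_prior()))
    if (ev0 >= ev3) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("evidence is invariant to the order in which edges are listed", {
  fx <- three_oscillator_fixture(n_steps = 5000, seed = 8)
  e12 <- edge_hypotheses(c("phi_2", "phi_2"), c("phi_1", "phi_3"),
                         p_i = 2L, p_j = 1L, M = c(1L, 2L))
  e21 <- e12[2:1, ]
  ev <- function(e) {
    p <- build_problem(fx$phases, "phi_2", e)
    log_evidence(p, nig_prior(), fit_posterior(p, nig_prior()))
  }
  expect_equal(ev(e12), ev(e21), tolerance = 1e-8)
})

test_that("order selection finds a single sine coupling reliably and rejects noise edges", {
  ## pure-noise pair: M = 0 selected
  for (seed in 1:3) {
    set.seed(seed)
    T <- 5000; dt <- 0.01
    ph <- make_phases(cbind(cumsum(c(0, 1.0 * dt + rnorm(T, sd = 0.1 * sqrt(dt)))),
                            cumsum(c(0, 1.3 * dt + rnorm(T, sd = 0.1 * sqrt(dt))))),
                      dt = dt)
    sel <- select_orders(ph, "phi_1", edge_hypotheses("phi_1", "phi_2"), M_max = 3)
    expect_equal(unname(sel$selected), 0L)
  }
  ## sine coupling of amplitude 0.1 at D = 0.005, T = 1e5: M = 1 selected
  m <- phase_model(c(1.0, 1.3), D = 0.005,
                   couplings = list(coupling_term(1, 2, 1, 1, a = 0, b = 0.1)))
  hits <- 0L
  for (seed in 1:20) {
    sim <- simulate_phase_model(m, dt = 0.01, n_steps = 1e5, seed = seed)
    sel <- select_orders(sim, "phi_1", edge_hypotheses("phi_1", "phi_2"), M_max = 3)
    if (unname(sel$selected) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("independent oscillators are estimated as uncoupled with near-zero power", {
  m <- phase_model(c(1.0, 1.27), D = 0.005)
  sim <- simulate_phase_model(m, dt = 0.01, n_steps = 2e4, seed = 13)
  edges <- edge_hypotheses(c("phi_1", "phi_2"), c("phi_2", "phi_1"))
  fit <- estimate_model(sim, edges, M_max = 3)
  for (tm in fit$model$couplings) {
    expect_equal(length(tm$a), 0L)
    expect_equal(coupling_power(tm), 0)
  }
})

test_that("trial boundaries mask cross-trial velocity samples", {
  set.seed(2)
  ph <- make_phases(cbind(cumsum(rnorm(100, 0.01)), cumsum(rnorm(100, 0.01))))
  ph$trial <- rep(1:4, each = 25)
  prob <- build_problem(ph, "phi_1", edge_hypotheses("phi_1", "phi_2", M = 1L))
  expect_equal(length(prob$y), 99L - 3L)
})
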