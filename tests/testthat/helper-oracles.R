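## Independent numerical oracles used across the suite.

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

## Brute-force marginal likelihood for a 2-coefficient Gaussian inverse-gamma
## regression: dense 2-D grid over the coefficients and log-spaced quadrature
## over the noise variance. Independent of the package's closed-form route.
evidence_quadrature <- function(y, X, spec,
                                w_lim = 8, n_w = 400, n_s = 400,
                                s_lim = c(1e-3, 1e3)) {
  stopifnot(ncol(X) == 2L)
  n <- length(y)
  v0 <- spec$variance
  wg <- seq(-w_lim, w_lim, length.out = n_w)
  dw <- wg[2] - wg[1]
  W <- as.matrix(expand.grid(w1 = wg, w2 = wg))
  resid2 <- colSums((y - X %*% t(W))^2)
  wq <- rowSums((W - spec$chi0)^2)
  s2g <- exp(seq(log(s_lim[1]), log(s_lim[2]), length.out = n_s))
  dls <- diff(log(s2g))[1]
  per_s2 <- vapply(s2g, function(s2) {
    ll <- -0.5 * n * log(2 * pi * s2) - resid2 / (2 * s2)
    lp <- -log(2 * pi * s2) - 0.5 * log(v0^2) - wq / (2 * v0 * s2)
    logsumexp(ll + lp) + 2 * log(dw)
  }, numeric(1))
  lig <- spec$alpha * log(spec$beta) - lgamma(spec$alpha) -
    (spec$alpha + 1) * log(s2g) - spec$beta / s2g
  logsumexp(per_s2 + lig + log(s2g)) + log(dls)
}

## Rejection sampler from the circular density (1 + 0.5 cos(theta)) / (2 pi).
sample_cosine_density <- function(n, seed = 1) {
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    th <- runif(2 * n, 0, 2 * pi)
    u <- runif(2 * n, 0, 1.5)
    out <- c(out, th[u < 1 + 0.5 * cos(th)])
  }
  out[seq_len(n)]
}

## Two-oscillator driver/driven model mimicking a stimulus rhythm entraining
## an oscillation: strong forward coupling, weak reverse coupling. The
## detuning is large enough that the uncoupled pair drifts through several
## full cycles over the simulated records.
drive_pair_model <- function(K_fwd = 0.3, K_rev = 0.03, omega = c(1.0, 1.1),
                             D = 0.01) {
  phase_model(
    omega_hat = omega, D = D,
    couplings = list(
      coupling_term(1, 2, 1, 1, a = 0, b = K_fwd),
      coupling_term(2, 1, 1, 1, a = 0, b = K_rev)
    ),
    labels = c("theta", "s"))
}

ks_uniform_circle <- function(x) {
  suppressWarnings(stats::ks.test(x %% (2 * pi), "punif", 0, 2 * pi)$statistic)
}

l1_to_uniform <- function(h) {
  sum(abs(h$density - 1 / (2 * pi)) * (h$bin_right - h$bin_left))
}
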