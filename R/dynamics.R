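#' Simulate a stochastic phase-oscillator network (Euler-Maruyama)
#'
#' Integrates `dphi_i = [omega_hat_i + sum_j Gamma_ij(psi_ij)] dt +
#' sqrt(2 D_i dt) xi` with independent standard-normal increments `xi`. Each
#' oscillator draws from its own substream derived from `seed`, so adding an
#' oscillator never changes the noise of the others.
#'
#' @param model a [phase_model()].
#' @param dt time step.
#' @param n_steps number of steps (output has `n_steps - burn_in + 1` rows).
#' @param seed integer seed.
#' @param init initial phases (rad), default 0.
#' @param burn_in steps discarded from the start (default 0; the bundled
#'   fixtures use 10% of `n_steps`).
#' @param noise_mode `"unit-time"`: the model's `D` is a continuous-time
#'   noise strength and increments have sd `sqrt(2 D dt)` (default);
#'   `"per-step"`: increments have sd `sqrt(2 D)` regardless of `dt`.
#' @return Phase tibble: `time` plus one unwrapped-phase column per
#'   oscillator, named by the model's labels.
#' @examples
#' m <- phase_model(2.1, D = 0)
#' sim <- simulate_phase_model(m, dt = 0.01, n_steps = 100, seed = 1)
#' @export
simulate_phase_model <- function(model, dt = 0.01, n_steps = 1e4L, seed = 1L,
                                 init = NULL, burn_in = 0L,
                                 noise_mode = c("unit-time", "per-step")) {
  noise_mode <- match.arg(noise_mode)
  if (dt <= 0) abort("`dt` must be positive.")
  if (burn_in >= n_steps) abort("`burn_in` must be smaller than `n_steps`.")
  n <- length(model$omega_hat)
  init <- rep_len(init %||% 0, n)
  sdv <- if (noise_mode == "unit-time") sqrt(2 * model$D * dt) else sqrt(2 * model$D)
  ## one substream per oscillator: adding oscillators never perturbs others
  noise <- matrix(0, n_steps, n)
  for (i in seq_len(n)) {
    set.seed((as.integer(seed) * 1009L + i * 7919L) %% .Machine$integer.max)
    noise[, i] <- rnorm(n_steps, sd = sdv[i])
  }
  edges <- model$couplings
  tgt <- vapply(edges, `[[`, numeric(1), "target")
  phi <- matrix(0, n_steps + 1L, n)
  phi[1L, ] <- init
  state <- init
  for (s in seq_len(n_steps)) {
    drift <- model$omega_hat
    for (e in seq_along(edges)) {
      tm <- edges[[e]]
      psi <- tm$p_i * state[tm$source] - tm$p_j * state[tm$target]
      drift[tgt[e]] <- drift[tgt[e]] + eval_coupling(tm, psi)
    }
    state <- state + drift * dt + noise[s, ]
    phi[s + 1L, ] <- state
  }
  rows <- seq.int(burn_in + 1L, n_steps + 1L)
  out <- tibble(time = (rows - 1L) * dt)
  for (i in seq_len(n)) out[[model$labels[i]]] <- phi[rows, i]
  out
}

#' Phase-difference histogram on the circle
#'
#' Wraps `psi` to `[0, 2 pi)` and bins it into a normalised density (the
#' densities integrate to 1 over the circle). Locked regimes give peaked
#' histograms; independent oscillators give flat ones.
#'
#' @param psi numeric vector of phase differences (rad, any branch).
#' @param n_bins number of equal bins (default 30).
#' @return A `psi_histogram` tibble with columns `bin_left`, `bin_right`,
#'   `mid`, `density`; the sample size is in attribute `n_samples`.
#' @export
phase_histogram <- function(psi, n_bins = 30L) {
  if (length(psi) == 0L) abort("Empty input.")
  if (n_bins < 2L) abort("`n_bins` must be >= 2.")
  br <- seq(0, 2 * pi, length.out = n_bins + 1L)
  h <- graphics::hist(wrap_2pi(psi), breaks = br, plot = FALSE)
  out <- tibble(bin_left = br[-length(br)], bin_right = br[-1L],
                mid = h$mids, density = h$density)
  attr(out, "n_samples") <- length(psi)
  class(out) <- c("psi_histogram", class(out))
  out
}

#' L1 distance between two phase-difference histograms
#'
#' `int |f - g| dpsi` over the circle, computed bin-wise; both histograms
#' must share the same binning. Identical distributions give 0, disjoint
#' ones 2.
#'
#' @param h1,h2 `psi_histogram` objects with equal bins.
#' @return Scalar in `[0, 2]`.
#' @export
histogram_l1 <- function(h1, h2) {
  if (nrow(h1) != nrow(h2)) abort("Histograms use different binnings.")
  sum(abs(h1$density - h2$density) * (h1$bin_right - h1$bin_left))
}

#' Zero out selected coupling functions
#'
#' Returns a copy of the model in which the listed directed couplings are
#' identically zero (`M = 0`); natural frequencies and noise strengths are
#' untouched. Used for ablation experiments asking which coupling sustains a
#' phase-locking state.
#'
#' @param model a [phase_model()].
#' @param edges tibble or data frame with `target` and `source` columns
#'   (labels or indices) naming the couplings to remove.
#' @return The ablated `phase_model`.
#' @export
ablate_edges <- function(model, edges) {
  resolve <- function(x) if (is.numeric(x)) as.integer(x) else match(x, model$labels)
  tg <- resolve(edges$target); src <- resolve(edges$source)
  if (anyNA(tg) || anyNA(src)) abort("Unknown oscillator label in `edges`.")
  for (e in seq_along(tg)) {
    hit <- FALSE
    for (k in seq_along(model$couplings)) {
      tm <- model$couplings[[k]]
      if (tm$target == tg[e] && tm$source == src[e]) {
        model$couplings[[k]]$a <- numeric(0)
        model$couplings[[k]]$b <- numeric(0)
        hit <- TRUE
      }
    }
    if (!hit) abort(sprintf("No coupling %s -> %s in the model.",
                            format(edges$source[e]), format(edges$target[e])))
  }
  model
}

#' Three-oscillator cross-frequency benchmark network
#'
#' The reference network of one fast and two slow oscillators used to
#' validate the estimator:
#' \itemize{
#'   \item `dphi1/dt = 0.9 + 0.1 sin(phi3 - phi1) + eta1`
#'   \item `dphi2/dt = 2.1 + 0.1 sin(2 phi1 - phi2) +
#'          0.05[sin(2 phi3 - phi2) + sin(2(2 phi3 - phi2))] + eta2`
#'   \item `dphi3/dt = 1.1 + 0.05 cos(phi2 - 2 phi3) + eta3`
#' }
#' with independent white noise of standard deviation 0.1 (continuous-time
#' intensity; `D = 0.005`). Oscillators 1 and 3 run near 1:2 resonance with
#' oscillator 2, and four of the six directed couplings are present.
#'
#' @param n_steps Euler-Maruyama steps (default 1e5).
#' @param dt time step (default 0.01).
#' @param seed integer seed.
#' @param noise_sd noise intensity (default 0.1); `noise_mode` as in
#'   [simulate_phase_model()].
#' @param burn_in steps discarded (default 10% of `n_steps`).
#' @param noise_mode see [simulate_phase_model()].
#' @return List with `phases` (tibble), `model` (the generating
#'   [phase_model()]) and `edges` (the full 6-edge hypothesis set with the
#'   resonant winding pairs, `M` free, for [estimate_model()]).
#' @export
three_oscillator_fixture <- function(n_steps = 1e5L, dt = 0.01, seed = 1L,
                                     noise_sd = 0.1,
                                     burn_in = round(0.1 * n_steps),
                                     noise_mode = c("unit-time", "per-step")) {
  noise_mode <- match.arg(noise_mode)
  D <- noise_sd^2 / 2
  model <- phase_model(
    omega_hat = c(0.9, 2.1, 1.1),
    D = D,
    couplings = list(
      coupling_term(1, 3, 1, 1, a = 0,            b = 0.1),
      coupling_term(2, 1, 2, 1, a = 0,            b = 0.1),
      coupling_term(2, 3, 2, 1, a = c(0, 0),      b = c(0.05, 0.05)),
      coupling_term(3, 2, 1, 2, a = 0.05,         b = 0)
    ))
  phases <- simulate_phase_model(model, dt = dt, n_steps = n_steps,
                                 seed = seed, burn_in = burn_in,
                                 noise_mode = noise_mode)
  edges <- edge_hypotheses(
    target = c("phi_1", "phi_1", "phi_2", "phi_2", "phi_3", "phi_3"),
    source = c("phi_2", "phi_3", "phi_1", "phi_3", "phi_1", "phi_2"),
    p_i = c(1L, 1L, 2L, 2L, 1L, 1L),
    p_j = c(2L, 1L, 1L, 1L, 1L, 2L)
  )
  list(phases = phases, model = model, edges = edges)
}
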