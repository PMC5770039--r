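#' Coupling-function curves of a fitted model, with uncertainty
#'
#' Evaluates each fitted coupling function on a `psi` grid together with a
#' pointwise posterior band (+/- `level` posterior standard deviations of the
#' function value) and, optionally, the generating model's curve.
#'
#' @param fit a `phase_fit` from [estimate_model()].
#' @param truth optional [phase_model()] with the generating couplings.
#' @param n_psi grid size.
#' @param level half-width of the band in posterior sd units (default 2).
#' @return Tibble with columns `edge`, `target`, `source`, `psi`,
#'   `estimate`, `lower`, `upper` and (when `truth` is given) `truth`.
#' @export
coupling_curves <- function(fit, truth = NULL, n_psi = 181L, level = 2) {
  psi <- seq(0, 2 * pi, length.out = n_psi)
  purrr::map_dfr(names(fit$fits), function(tg) {
    f <- fit$fits[[tg]]
    purrr::map_dfr(seq_len(nrow(f$edges)), function(e) {
      key <- edge_key(f$edges[e, ])
      M <- f$edges$M[e]
      est <- numeric(n_psi)
      sdv <- numeric(n_psi)
      if (M > 0L) {
        cols <- c(vapply(1:M, function(m) sprintf("cos%d[%s]", m, key), ""),
                  vapply(1:M, function(m) sprintf("sin%d[%s]", m, key), ""))
        idx <- match(cols, f$problem_labels)
        G <- cbind(do.call(cbind, lapply(1:M, function(m) cos(m * psi))),
                   do.call(cbind, lapply(1:M, function(m) sin(m * psi))))
        est <- drop(G %*% f$posterior$chi[idx])
        Svv <- f$posterior$Sigma[idx, idx, drop = FALSE] * f$sigma2
        sdv <- sqrt(rowSums((G %*% Svv) * G))
      }
      out <- tibble(edge = key, target = tg, source = f$edges$source[e],
                    psi = psi, estimate = est,
                    lower = est - level * sdv, upper = est + level * sdv)
      if (!is.null(truth)) {
        tv <- numeric(n_psi)
        for (tm in truth$couplings) {
          if (truth$labels[tm$target] == tg &&
              truth$labels[tm$source] == f$edges$source[e]) {
            tv <- eval_coupling(tm, psi)
          }
        }
        out$truth <- tv
      }
      out
    })
  })
}

#' Benchmark: recover the three-oscillator network from simulated data
#'
#' Simulates the reference three-oscillator network, estimates the full
#' six-edge model with evidence-selected orders, and reports coefficient
#' recovery (truth, posterior mean, posterior sd), order selection and the
#' estimated-versus-true coupling curves. Deterministic given `seed`.
#'
#' @param n_steps,dt,seed,noise_sd forwarded to
#'   [three_oscillator_fixture()].
#' @param M_max forwarded to [estimate_model()].
#' @param prior a [nig_prior()].
#' @return List with elements `fit`, `truth`, `recovery` (coefficient
#'   tibble), `orders` (selected vs true order per edge), `curves`
#'   (overlay tibble) and `powers` (per-edge fitted coupling power).
#' @export
run_simulation_benchmark <- function(n_steps = 1e5L, dt = 0.01, seed = 1L,
                                     noise_sd = 0.1, M_max = 3L,
                                     prior = nig_prior()) {
  fx <- three_oscillator_fixture(n_steps = n_steps, dt = dt, seed = seed,
                                 noise_sd = noise_sd)
  fit <- estimate_model(fx$phases, fx$edges, M_max = M_max, prior = prior)
  truth <- fx$model
  labels <- truth$labels
  true_term <- function(tg, src) {
    for (tm in truth$couplings) {
      if (labels[tm$target] == tg && labels[tm$source] == src) return(tm)
    }
    NULL
  }
  rec <- purrr::map_dfr(names(fit$fits), function(tg) {
    f <- fit$fits[[tg]]
    sdv <- sqrt(f$sigma2 * diag(f$posterior$Sigma))
    rows <- tibble(term = f$problem_labels, estimate = f$posterior$chi,
                   std.error = sdv, oscillator = tg)
    idx <- match(tg, labels)
    rows$truth <- NA_real_
    rows$truth[rows$term == "(Intercept)"] <- truth$omega_hat[idx]
    for (e in seq_len(nrow(f$edges))) {
      key <- edge_key(f$edges[e, ])
      tt <- true_term(tg, f$edges$source[e])
      for (m in seq_len(f$edges$M[e])) {
        a_t <- if (!is.null(tt) && m <= length(tt$a)) tt$a[m] else 0
        b_t <- if (!is.null(tt) && m <= length(tt$b)) tt$b[m] else 0
        rows$truth[rows$term == sprintf("cos%d[%s]", m, key)] <- a_t
        rows$truth[rows$term == sprintf("sin%d[%s]", m, key)] <- b_t
      }
    }
    rows
  })
  rec$within_3sd <- abs(rec$estimate - rec$truth) < 3 * rec$std.error
  orders <- fx$edges
  orders$M_true <- vapply(seq_len(nrow(orders)), function(e) {
    tt <- true_term(orders$target[e], orders$source[e])
    if (is.null(tt)) 0L else length(tt$a)
  }, integer(1))
  orders$M_selected <- vapply(seq_len(nrow(orders)), function(e) {
    f <- fit$fits[[orders$target[e]]]
    f$edges$M[f$edges$source == orders$source[e]]
  }, integer(1))
  powers <- orders
  powers$power <- vapply(seq_len(nrow(powers)), function(e) {
    for (tm in fit$model$couplings) {
      if (labels[tm$target] == powers$target[e] &&
          labels[tm$source] == powers$source[e]) return(coupling_power(tm))
    }
    0
  }, numeric(1))
  list(fit = fit, truth = truth,
       recovery = rec,
       orders = orders[, c("target", "source", "M_true", "M_selected")],
       curves = coupling_curves(fit, truth = truth),
       powers = powers[, c("target", "source", "power")])
}

#' Benchmark: circuit ground truth versus estimated coupling
#'
#' Simulates the two-oscillator circuit (with weak dynamical noise standing
#' in for the disturbances of a physical board), converts the recorded
#' voltages to corrected phases (zero-phase references shifted by pi/6 and
#' pi/10 to the theoretical peak-of-x definition), estimates both directed
#' couplings, computes the adjoint-method theoretical coupling, and compares
#' phase-difference histograms of the data against simulations of the
#' estimated and theoretical phase models.
#'
#' @param preset `"same-freq"` or `"cross-freq"` (see [vdp_preset()]).
#' @param duration record length (s).
#' @param fs analysis sampling rate (Hz).
#' @param process_noise_sd circuit disturbance intensity (V/sqrt(s)).
#' @param seed integer seed.
#' @param M_max forwarded to [estimate_model()].
#' @param n_bins histogram bins.
#' @return List with `fit`, `theory` (the `coupling_table` for the driven
#'   direction), `sens` (both phase sensitivities), `histograms`
#'   (experimental / estimated / theoretical `psi_histogram`s), `l1`
#'   (distances to the experimental histogram) and `edges`.
#' @export
run_circuit_benchmark <- function(preset = c("same-freq", "cross-freq"),
                                  duration = 16, fs = 5000,
                                  process_noise_sd = 0.7, seed = 1L,
                                  M_max = 3L, n_bins = 30L) {
  preset <- match.arg(preset)
  params <- vdp_preset(preset)
  pr <- if (preset == "same-freq") c(1L, 1L) else c(2L, 1L)  # p_i:p_j for 2 <- 1
  traj <- simulate_circuit(params, duration = duration, dt = 1 / fs,
                           process_noise_sd = process_noise_sd, seed = seed)
  traj <- traj[traj$time > 0.5, c("time", "x1", "x2")]
  phases <- extract_phase(traj, channels = c("x1", "x2"))
  phases$x1 <- phases$x1 + pi / 6
  phases$x2 <- phases$x2 + pi / 10
  edges <- edge_hypotheses(target = c("x2", "x1"), source = c("x1", "x2"),
                           p_i = c(pr[1], pr[2]), p_j = c(pr[2], pr[1]))
  fit <- estimate_model(phases, edges, M_max = M_max)
  sens1 <- adjoint_sensitivity(params, 1L)
  sens2 <- adjoint_sensitivity(params, 2L)
  theory <- theoretical_coupling(sens2, sens1, pr[1], pr[2],
                                 gain = circuit_coupling_gain(params, 2L))
  ## psi = p_i phi_1 - p_j phi_2
  psi_exp <- phase_difference(phases$x2, phases$x1, pr[1], pr[2])
  h_exp <- phase_histogram(psi_exp, n_bins)
  sim_est <- simulate_phase_model(fit$model, dt = 1 / fs,
                                  n_steps = nrow(phases), seed = seed + 1L,
                                  burn_in = round(0.1 * nrow(phases)))
  h_est <- phase_histogram(
    phase_difference(sim_est$x2, sim_est$x1, pr[1], pr[2]), n_bins)
  ## theoretical model: adjoint coupling, estimated frequencies and noise
  th_model <- fit$model
  for (k in seq_along(th_model$couplings)) {
    tm <- th_model$couplings[[k]]
    if (th_model$labels[tm$target] == "x2") {
      th_model$couplings[[k]]$a <- theory$term$a
      th_model$couplings[[k]]$b <- theory$term$b
    } else {
      th_model$couplings[[k]]$a <- numeric(0)
      th_model$couplings[[k]]$b <- numeric(0)
    }
  }
  sim_th <- simulate_phase_model(th_model, dt = 1 / fs,
                                 n_steps = nrow(phases), seed = seed + 2L,
                                 burn_in = round(0.1 * nrow(phases)))
  h_th <- phase_histogram(
    phase_difference(sim_th$x2, sim_th$x1, pr[1], pr[2]), n_bins)
  list(fit = fit, theory = theory, sens = list(sens1, sens2),
       histograms = list(experimental = h_exp, estimated = h_est,
                         theoretical = h_th),
       l1 = c(estimated = histogram_l1(h_exp, h_est),
              theoretical = histogram_l1(h_exp, h_th)),
       edges = edges, phases = phases)
}

#' Analyse a driven-rhythm pair (external rhythm and oscillator)
#'
#' End-to-end pipeline for two-channel data such as a band-limited neural
#' oscillation and a stimulus envelope: band-filter (or envelope-extract)
#' each channel, convert to corrected phases, estimate both directed
#' couplings with evidence-selected orders, run coupling-ablation
#' simulations, and test the forward coupling against time-shift surrogates.
#'
#' @param data signal tibble with the two channels.
#' @param target,source channel names (target = the driven oscillator).
#' @param target_band,source_band numeric `c(low, high)` in Hz, or `NULL` to
#'   skip filtering for that channel.
#' @param source_mode `"band"` or `"envelope"` preprocessing for the source
#'   channel (see [bandpass_and_envelope()]).
#' @param p_i,p_j winding pair for the target <- source edge
#'   (`psi = p_i phi_source - p_j phi_target`; e.g. `p_i = 2, p_j = 1` for a
#'   slow rhythm driving at 1:2).
#' @param M_max,prior forwarded to [estimate_model()].
#' @param n_surrogates surrogate replicates (default 50).
#' @param n_bins histogram bins.
#' @param seed integer seed.
#' @param fs sampling rate (Hz); inferred from `time` when absent.
#' @return List with `fit`, `powers` (directed coupling powers), `histograms`
#'   (data, fitted-model, and the two single-edge ablations), `surrogates`
#'   (a `surrogate_ensemble` for the forward edge) and `phases`.
#' @export
run_rhythm_pairs <- function(data, target, source,
                             target_band = NULL, source_band = NULL,
                             source_mode = c("band", "envelope"),
                             p_i = 1L, p_j = 1L, M_max = 3L,
                             prior = nig_prior(), n_surrogates = 50L,
                             n_bins = 30L, seed = 1L, fs = NULL) {
  source_mode <- match.arg(source_mode)
  dt <- infer_dt(data, fs)
  work <- data
  if (!is.null(target_band)) {
    work <- bandpass_and_envelope(work, target_band[1], target_band[2],
                                  mode = "band", channels = target, fs = 1 / dt)
  }
  if (!is.null(source_band)) {
    work <- bandpass_and_envelope(work, source_band[1], source_band[2],
                                  mode = source_mode, channels = source,
                                  fs = 1 / dt)
  }
  phases <- extract_phase(work, channels = c(target, source), fs = 1 / dt)
  edges <- edge_hypotheses(target = c(target, source),
                           source = c(source, target),
                           p_i = c(p_i, p_j), p_j = c(p_j, p_i))
  fit <- estimate_model(phases, edges, M_max = M_max, prior = prior)
  powers <- tibble(
    direction = c(paste0(target, "<-", source), paste0(source, "<-", target)),
    power = vapply(fit$model$couplings, coupling_power, numeric(1))[
      order(match(vapply(fit$model$couplings, function(tm)
        fit$model$labels[tm$target], character(1)), c(target, source)))]
  )
  psi_data <- phase_difference(phases[[target]], phases[[source]], p_i, p_j)
  n_sim <- nrow(phases)
  sim_h <- function(model, sd_off) {
    sim <- simulate_phase_model(model, dt = dt, n_steps = n_sim,
                                seed = seed + sd_off,
                                burn_in = round(0.1 * n_sim))
    phase_histogram(phase_difference(sim[[target]], sim[[source]], p_i, p_j),
                    n_bins)
  }
  rev_edge <- tibble(target = character(), source = character())
  rev_edge[1L, ] <- list(source, target)
  fwd_edge <- tibble(target = character(), source = character())
  fwd_edge[1L, ] <- list(target, source)
  histograms <- list(
    data = phase_histogram(psi_data, n_bins),
    fitted = sim_h(fit$model, 1L),
    ablate_reverse = sim_h(ablate_edges(fit$model, rev_edge), 2L),
    ablate_forward = sim_h(ablate_edges(fit$model, fwd_edge), 3L)
  )
  surrogates <- surrogate_scan(phases, edges[1L, ],
                               n_replicates = n_surrogates, M_max = M_max,
                               prior = prior, seed = seed)
  list(fit = fit, powers = powers, histograms = histograms,
       surrogates = surrogates, phases = phases)
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records the configuration, seed, package and R versions and a checksum of
#' the configuration, sufficient to reproduce deterministic outputs.
#'
#' @param config named list of run parameters (must be JSON-serialisable).
#' @param path output JSON path.
#' @param seed the seed used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, seed = NULL) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    config = config,
    seed = seed,
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("phasecoupler")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
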