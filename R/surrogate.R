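#' Time-shift surrogate of a phase series
#'
#' Destroys the temporal relationship between channels while preserving each
#' channel's marginal wrapped-phase distribution: the wrapped phase track is
#' circularly shifted by `shift_samples` and re-unwrapped. When the phase
#' tibble carries a `trial` column and `mode = "per-trial"`, each trial is
#' shifted circularly within itself.
#'
#' @param phases phase tibble.
#' @param channel column to shift.
#' @param shift_samples integer shift, `|shift| <` record (or trial) length.
#' @param mode `"record"` (whole-record circular shift, default) or
#'   `"per-trial"`.
#' @return The phase tibble with the shifted channel.
#' @export
time_shift <- function(phases, channel, shift_samples,
                       mode = c("record", "per-trial")) {
  mode <- match.arg(mode)
  phi <- phases[[channel]]
  if (is.null(phi)) abort(paste0("Unknown channel: ", channel))
  shift_one <- function(x, k) {
    n <- length(x)
    if (abs(k) >= n) abort("Shift must be smaller than the record length.")
    w <- wrap_2pi(x)
    idx <- ((seq_len(n) - 1L + k) %% n) + 1L
    out <- unwrap_phase(w[idx])
    ## keep the original winding anchor so a zero shift is the identity
    out + 2 * pi * floor(x[1L] / (2 * pi))
  }
  if (mode == "per-trial" && "trial" %in% names(phases)) {
    out <- phi
    for (tr in unique(phases$trial)) {
      sel <- phases$trial == tr
      out[sel] <- shift_one(phi[sel], shift_samples)
    }
    phases[[channel]] <- out
  } else {
    phases[[channel]] <- shift_one(phi, shift_samples)
  }
  phases
}

#' Surrogate scan: null distribution of order selection and coupling power
#'
#' Repeatedly time-shifts the source channel, re-runs the evidence-based
#' order selection and the posterior fit for one directed edge, and records
#' the selected Fourier order and the coupling power of each surrogate. With
#' truly coupled data the original selection has `M > 0` and its power sits
#' in the upper tail of the surrogate power distribution; shifted data
#' select `M = 0` most often.
#'
#' @param phases phase tibble with the target and source channels.
#' @param edge a single-row [edge_hypotheses()] tibble (the directed edge
#'   under test; `M` ignored).
#' @param n_replicates number of surrogates (default 100).
#' @param M_max largest Fourier order considered.
#' @param prior a [nig_prior()].
#' @param seed integer seed for the shift draws.
#' @param shift_range shifts are drawn uniformly from this fraction range of
#'   the record length (default 10-90%, avoiding near-identity shifts).
#' @param mode shift mode, see [time_shift()].
#' @param fs sampling rate (Hz); inferred from `time` when absent.
#' @return A `surrogate_ensemble`: tibble with one row per replicate
#'   (`replicate`, `shift`, `M`, `power`) plus attributes `original`
#'   (list with the unshifted `M` and `power`) and `p_value` (empirical,
#'   `(1 + #{surrogate power >= original}) / (1 + n)`).
#' @export
surrogate_scan <- function(phases, edge, n_replicates = 100L, M_max = 3L,
                           prior = nig_prior(), seed = 1L,
                           shift_range = c(0.1, 0.9),
                           mode = c("record", "per-trial"), fs = NULL) {
  mode <- match.arg(mode)
  if (n_replicates < 1L) abort("`n_replicates` must be >= 1.")
  if (nrow(edge) != 1L) abort("`edge` must be a single directed edge.")
  dt <- infer_dt(phases, fs)
  fit_edge <- function(ph) {
    sel <- select_orders(ph, edge$target, edge, M_max = M_max,
                         prior = prior, fs = 1 / dt)
    M <- unname(sel$selected[1L])
    pw <- 0
    if (M > 0L) {
      e_fit <- edge
      e_fit$M <- M
      prob <- build_problem(ph, edge$target, e_fit, fs = 1 / dt)
      post <- fit_posterior(prob, prior)
      a <- post$chi[seq(2, by = 2, length.out = M)]
      b <- post$chi[seq(3, by = 2, length.out = M)]
      pw <- pi * sum(a^2 + b^2)
    }
    list(M = M, power = pw)
  }
  orig <- fit_edge(phases)
  n_len <- nrow(phases)
  set.seed(as.integer(seed))
  shifts <- sample.int(floor(shift_range[2] * n_len) -
                         ceiling(shift_range[1] * n_len) + 1L,
                       n_replicates, replace = TRUE) +
    ceiling(shift_range[1] * n_len) - 1L
  res <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    ph <- time_shift(phases, edge$source, shifts[r], mode = mode)
    f <- fit_edge(ph)
    tibble(replicate = r, shift = shifts[r], M = f$M, power = f$power)
  })
  attr(res, "original") <- orig
  attr(res, "p_value") <- (1 + sum(res$power >= orig$power)) / (1 + n_replicates)
  class(res) <- c("surrogate_ensemble", class(res))
  res
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  o <- attr(x, "original")
  cat(sprintf("<surrogate_ensemble> %d replicates; original M = %d, power = %.4g, p = %.4g\n",
              nrow(x), o$M, o$power, attr(x, "p_value")))
  NextMethod()
}
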