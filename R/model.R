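#' Directed n:m coupling term as a truncated Fourier series
#'
#' A coupling term describes the frequency modulation that a source oscillator
#' exerts on a target oscillator as a 2*pi-periodic function of the
#' generalised phase difference `psi = p_i * phi_source - p_j * phi_target`,
#' expanded as `sum_m a[m] cos(m psi) + b[m] sin(m psi)`. The constant Fourier
#' component is not stored here: it is unidentifiable from the target's
#' effective natural frequency and is absorbed into `omega_hat`.
#'
#' @param target,source 1-based oscillator indices (or labels resolved later);
#'   must differ.
#' @param p_i,p_j positive integer winding numbers; the pair is reduced by its
#'   greatest common divisor.
#' @param a,b numeric vectors of equal length `M` holding the cosine and sine
#'   coefficients (rad per unit time) for harmonics `m = 1..M`. Empty vectors
#'   give the null coupling (`M = 0`).
#' @return A `coupling_term` object.
#' @examples
#' tm <- coupling_term(1, 3, a = 0, b = 0.1)
#' eval_coupling(tm, pi / 2)
#' @export
coupling_term <- function(target, source, p_i = 1L, p_j = 1L,
                          a = numeric(), b = numeric()) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have the same length (one entry per harmonic).")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    abort("Fourier coefficients must be finite.")
  }
  p_i <- as.integer(p_i); p_j <- as.integer(p_j)
  if (p_i < 1L || p_j < 1L) abort("Winding numbers must be positive integers.")
  g <- gcd(p_i, p_j)
  if (identical(target, source)) abort("Self-coupling is not allowed.")
  structure(
    list(target = target, source = source,
         p_i = p_i %/% g, p_j = p_j %/% g,
         a = as.numeric(a), b = as.numeric(b)),
    class = "coupling_term"
  )
}

gcd <- function(a, b) if (b == 0L) a else gcd(b, a %% b)

#' @export
print.coupling_term <- function(x, ...) {
  cat(sprintf("<coupling_term> %s -> %s, psi = %d*phi_src - %d*phi_tgt, M = %d\n",
              format(x$source), format(x$target), x$p_i, x$p_j, length(x$a)))
  if (length(x$a)) {
    cat("  a:", signif(x$a, 4), "\n  b:", signif(x$b, 4), "\n")
  }
  invisible(x)
}

#' Evaluate a coupling function at given phase differences
#'
#' Computes `sum_m a[m] cos(m psi) + b[m] sin(m psi)`. The result is
#' 2*pi-periodic in `psi` and is zero everywhere for `M = 0` terms.
#'
#' @param term a [coupling_term()].
#' @param psi numeric vector of phase differences (rad).
#' @return Numeric vector of frequency modulations (rad per unit time).
#' @export
eval_coupling <- function(term, psi) {
  M <- length(term$a)
  out <- numeric(length(psi))
  for (m in seq_len(M)) {
    out <- out + term$a[m] * cos(m * psi) + term$b[m] * sin(m * psi)
  }
  out
}

#' Coupling power: integral of the squared coupling function
#'
#' The power of a directed coupling, `int_0^{2pi} |Gamma(psi)|^2 dpsi`, used
#' as a scalar coupling-strength summary against surrogate nulls. For a
#' truncated Fourier series without constant term the integral is exactly
#' `pi * sum_m (a[m]^2 + b[m]^2)` by orthogonality of the harmonics.
#'
#' @param term a [coupling_term()].
#' @return Nonnegative scalar (rad^2 per squared unit time).
#' @export
coupling_power <- function(term) {
  pi * sum(term$a^2 + term$b^2)
}

#' Generalised phase difference between two phase series
#'
#' For an n:m interaction with winding pair `(p_i, p_j)` the relevant phase
#' difference driving the target `i` from the source `j` is
#' `psi(t) = p_i * phi_j(t) - p_j * phi_i(t)`, evaluated on unwrapped phases.
#'
#' @param phi_i,phi_j numeric vectors of unwrapped phases (rad), equal length;
#'   `phi_i` is the target's phase, `phi_j` the source's.
#' @param p_i,p_j positive integer winding numbers.
#' @return Numeric vector `psi` (rad, unwrapped).
#' @examples
#' phase_difference(c(0, 1, 2), c(0, 2, 4), p_i = 1, p_j = 2)
#' @export
phase_difference <- function(phi_i, phi_j, p_i = 1L, p_j = 1L) {
  if (length(phi_i) != length(phi_j)) {
    abort("`phi_i` and `phi_j` must have the same length.")
  }
  p_i * phi_j - p_j * phi_i
}

#' Detect the locking winding pair from mean phase velocities
#'
#' Picks the reduced integer pair `(p_i, p_j)` with both entries at most
#' `max_order` that minimises the relative frequency mismatch
#' `|p_i * wbar_j - p_j * wbar_i| / (p_i * wbar_j)`, where `wbar` are the
#' mean phase velocities of the two series. A pair is only accepted when the
#' mismatch is below `tol` (the phase model presumes near-resonance); an
#' ambiguous tie between distinct reduced pairs is an error.
#'
#' @param phi_i,phi_j unwrapped phase vectors (target and source).
#' @param dt sampling interval (s).
#' @param max_order largest admissible winding number.
#' @param tol maximal admissible relative mismatch (default 5%).
#' @return Integer vector `c(p_i, p_j)`.
#' @export
detect_winding <- function(phi_i, phi_j, dt, max_order = 7L, tol = 0.05) {
  if (max_order < 1L) abort("`max_order` must be at least 1.")
  wi <- mean(diff(phi_i)) / dt
  wj <- mean(diff(phi_j)) / dt
  cand <- expand.grid(p_i = seq_len(max_order), p_j = seq_len(max_order))
  red <- mapply(gcd, cand$p_i, cand$p_j)
  cand <- cand[red == 1L, , drop = FALSE]
  mism <- abs(cand$p_i * wj - cand$p_j * wi) / abs(cand$p_i * wj)
  best <- min(mism)
  if (best > tol) {
    abort(sprintf(
      "No winding pair up to order %d matches the velocity ratio %.4g within %.1f%%.",
      max_order, wi / wj, 100 * tol))
  }
  hits <- which(mism < best + 1e-12)
  if (length(hits) > 1L) {
    abort(paste0("Ambiguous winding pair; candidates: ",
                 paste(sprintf("(%d,%d)", cand$p_i[hits], cand$p_j[hits]),
                       collapse = ", ")))
  }
  c(p_i = cand$p_i[hits], p_j = cand$p_j[hits])
}

#' Construct a phase-oscillator network model
#'
#' A phase model holds, per oscillator, the effective natural frequency
#' `omega_hat` (intrinsic frequency plus the constant Fourier component of all
#' incoming couplings, which the regression cannot separate), the noise
#' strength `D` (so the stochastic term has intensity `sqrt(2 D)`), and a list
#' of incoming [coupling_term()]s. Frequencies are in rad per unit time.
#'
#' @param omega_hat numeric vector of effective natural frequencies.
#' @param D numeric vector of noise strengths (rad^2 per unit time),
#'   recycled to the number of oscillators.
#' @param couplings list of [coupling_term()]s with integer `target`/`source`
#'   indices into `omega_hat`.
#' @param labels optional character labels, default `"phi_1"`, ...
#' @return A `phase_model` object.
#' @examples
#' m <- phase_model(c(0.9, 1.1), D = 0.005,
#'                  couplings = list(coupling_term(1, 2, b = 0.1)))
#' m
#' @export
phase_model <- function(omega_hat, D = 0, couplings = list(), labels = NULL) {
  n <- length(omega_hat)
  D <- rep_len(as.numeric(D), n)
  if (any(D < 0)) abort("Noise strengths must be nonnegative.")
  labels <- labels %||% paste0("phi_", seq_len(n))
  for (tm in couplings) {
    if (!inherits(tm, "coupling_term")) abort("`couplings` must hold coupling_term objects.")
    if (tm$target < 1 || tm$target > n || tm$source < 1 || tm$source > n) {
      abort("Coupling indices out of range.")
    }
  }
  key <- vapply(couplings, function(tm)
    paste(tm$target, tm$source, tm$p_i, tm$p_j), character(1))
  if (anyDuplicated(key)) abort("Duplicate coupling for the same (target, source, p) triple.")
  structure(list(omega_hat = as.numeric(omega_hat), D = D,
                 couplings = couplings, labels = labels),
            class = "phase_model")
}

#' @export
print.phase_model <- function(x, ...) {
  cat(sprintf("<phase_model> %d oscillators, %d directed couplings\n",
              length(x$omega_hat), length(x$couplings)))
  cat("  omega_hat:", signif(x$omega_hat, 5), "\n")
  cat("  D:        ", signif(x$D, 5), "\n")
  for (tm in x$couplings) print(tm)
  invisible(x)
}

#' Tidy a phase model into a coupling-coefficient table
#'
#' @param x a [phase_model()].
#' @param ... unused.
#' @return A tibble with one row per coupling harmonic (plus one `omega_hat`
#'   and one `D` row per oscillator).
#' @method tidy phase_model
#' @export
tidy.phase_model <- function(x, ...) {
  n <- length(x$omega_hat)
  base <- tibble(
    oscillator = rep(x$labels, 2L),
    term = rep(c("omega_hat", "D"), each = n),
    harmonic = NA_integer_, source = NA_character_,
    estimate = c(x$omega_hat, x$D)
  )
  rows <- purrr::map_dfr(x$couplings, function(tm) {
    M <- length(tm$a)
    if (M == 0L) {
      return(tibble(oscillator = x$labels[tm$target],
                    term = sprintf("gamma[%s<-%s]", x$labels[tm$target], x$labels[tm$source]),
                    harmonic = 0L, source = x$labels[tm$source], estimate = 0))
    }
    tibble(
      oscillator = x$labels[tm$target],
      term = paste0(rep(c("cos", "sin"), each = M), seq_len(M),
                    sprintf("[%s<-%s]", x$labels[tm$target], x$labels[tm$source])),
      harmonic = rep(seq_len(M), 2L),
      source = x$labels[tm$source],
      estimate = c(tm$a, tm$b)
    )
  })
  dplyr::bind_rows(base, rows)
}

#' Write / read a phase model as JSON
#'
#' The on-disk schema is a JSON document with an `oscillators` array; each
#' entry has `label`, `omega_hat_rad_s`, `D` and a `couplings` array of
#' `{source, p_i, p_j, a, b}` objects. The round trip is lossless.
#'
#' @param model a [phase_model()].
#' @param path file path.
#' @return `write_phase_model()` returns `path` invisibly;
#'   `read_phase_model()` returns a [phase_model()].
#' @export
write_phase_model <- function(model, path) {
  osc <- lapply(seq_along(model$omega_hat), function(i) {
    cps <- Filter(function(tm) tm$target == i, model$couplings)
    list(
      label = model$labels[i],
      omega_hat_rad_s = model$omega_hat[i],
      D = model$D[i],
      couplings = lapply(cps, function(tm)
        list(source = tm$source, p_i = tm$p_i, p_j = tm$p_j,
             a = as.list(tm$a), b = as.list(tm$b)))
    )
  })
  jsonlite::write_json(list(oscillators = osc), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phase_model
#' @export
read_phase_model <- function(path) {
  doc <- jsonlite::read_json(path)
  osc <- doc$oscillators
  couplings <- list()
  for (i in seq_along(osc)) {
    for (cp in osc[[i]]$couplings) {
      couplings[[length(couplings) + 1L]] <- coupling_term(
        target = i, source = cp$source, p_i = cp$p_i, p_j = cp$p_j,
        a = unlist(cp$a) %||% numeric(), b = unlist(cp$b) %||% numeric())
    }
  }
  phase_model(
    omega_hat = vapply(osc, function(o) o$omega_hat_rad_s, numeric(1)),
    D = vapply(osc, function(o) o$D, numeric(1)),
    couplings = couplings,
    labels = vapply(osc, function(o) o$label, character(1))
  )
}
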