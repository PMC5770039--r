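#' Component values of the two-oscillator van der Pol circuit
#'
#' Parameters of the electronic-circuit model
#' \itemize{
#'   \item `dx_i/dt = y_i / (R1 C_i)` (+ coupling into `x_2`)
#'   \item `dy_i/dt = (10 V_i - x_i^2) y_i / (100 R2 C_i) - x_i / (R1 C_i) +
#'          b_i / (R1 C_i)`
#' }
#' with unidirectional coupling `- x_1^2 / (10 R_coupling C2)` added to
#' `dx_2/dt`. The asymmetry term `b` models the slight imbalance of the
#' physical circuit; the reference component values reproduce limit-cycle
#' frequencies of about 142.3 Hz (oscillator 1), 146.6 Hz (oscillator 2) and,
#' with `C1` doubled (cross-frequency preset), 71.1 Hz, only when `b = 0.4`
#' acts on oscillator 1 — hence the default `b = c(0.4, 0)`.
#'
#' @param R1,R2,R_coupling resistances (Ohm).
#' @param C1,C2 capacitances (F).
#' @param V1,V2 bias voltages (V).
#' @param b per-oscillator asymmetry (V), length 2.
#' @param coupling logical: engage the 1 -> 2 coupling resistor.
#' @return A `vdp_params` list.
#' @export
vdp_params <- function(R1 = 1e5, R2 = 1e3, R_coupling = 1e6,
                       C1 = 1e-8, C2 = 1e-8, V1 = 0.115, V2 = 0.12,
                       b = c(0.4, 0), coupling = TRUE) {
  if (any(c(R1, R2, R_coupling, C1, C2) <= 0)) {
    abort("Resistances and capacitances must be positive.")
  }
  structure(list(R1 = R1, R2 = R2, R_coupling = R_coupling, C1 = C1, C2 = C2,
                 V1 = V1, V2 = V2, b = rep_len(b, 2L), coupling = coupling),
            class = "vdp_params")
}

#' @rdname vdp_params
#' @param preset `"same-freq"` (both near 146 Hz / 142 Hz) or `"cross-freq"`
#'   (`C1` doubled to 0.02 uF, halving oscillator 1's frequency to ~71 Hz for
#'   1:2 locking).
#' @export
vdp_preset <- function(preset = c("same-freq", "cross-freq")) {
  preset <- match.arg(preset)
  p <- vdp_params()
  if (preset == "cross-freq") p$C1 <- 2e-8
  p
}

## Right-hand side; state = (x1, y1, x2, y2).
vdp_rhs <- function(t, s, p) {
  k1 <- 1 / (p$R1 * p$C1); g1 <- 1 / (100 * p$R2 * p$C1)
  k2 <- 1 / (p$R1 * p$C2); g2 <- 1 / (100 * p$R2 * p$C2)
  cpl <- if (isTRUE(p$coupling)) s[1]^2 / (10 * p$R_coupling * p$C2) else 0
  list(c(
    k1 * s[2],
    g1 * (10 * p$V1 - s[1]^2) * s[2] - k1 * s[1] + k1 * p$b[1],
    k2 * s[4] - cpl,
    g2 * (10 * p$V2 - s[3]^2) * s[4] - k2 * s[3] + k2 * p$b[2]
  ))
}

## Single-oscillator RHS used for limit-cycle / adjoint work.
osc_rhs_fun <- function(p, oscillator) {
  C <- if (oscillator == 1L) p$C1 else p$C2
  V <- if (oscillator == 1L) p$V1 else p$V2
  b <- p$b[oscillator]
  k <- 1 / (p$R1 * C); g <- 1 / (100 * p$R2 * C)
  list(
    f = function(s) c(k * s[2], g * (10 * V - s[1]^2) * s[2] - k * s[1] + k * b),
    jac = function(s) matrix(c(0, -2 * g * s[1] * s[2] - k,
                               k, g * (10 * V - s[1]^2)),
                             2L, 2L),
    k = k, g = g, V = V, b = b
  )
}

#' Simulate the van der Pol circuit
#'
#' Integrates the four-state circuit ODEs. With `process_noise_sd = 0` an
#' adaptive solver (lsoda, rtol 1e-8) is used; a positive value adds
#' white-noise forcing of that intensity (V per sqrt s) to both `y`
#' equations via fixed-step Euler-Maruyama with internal substeps, emulating
#' the small uncontrolled disturbances of a physical circuit.
#' `noise_sd` adds observation noise to the recorded `x` channels only.
#'
#' @param params a [vdp_params()].
#' @param duration record length (s).
#' @param dt output sampling interval (s), default 1/15000.
#' @param noise_sd observation noise sd on `x1`, `x2` (V).
#' @param process_noise_sd dynamical noise intensity (V/sqrt(s)).
#' @param seed seed for the noise streams.
#' @param init initial state `(x1, y1, x2, y2)`.
#' @return Tibble with columns `time`, `x1`, `y1`, `x2`, `y2`.
#' @export
simulate_circuit <- function(params, duration = 1, dt = 1 / 15000,
                             noise_sd = 0, process_noise_sd = 0, seed = 1L,
                             init = c(0.5, 0, -0.5, 0)) {
  if (duration <= 0 || dt <= 0) abort("`duration` and `dt` must be positive.")
  times <- seq(0, duration, by = dt)
  if (process_noise_sd == 0) {
    out <- deSolve::ode(y = init, times = times, parms = params,
                        func = vdp_rhs, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    if (nrow(out) < length(times) || !all(is.finite(out))) {
      abort("Circuit integration diverged.")
    }
    tb <- tibble(time = out[, 1], x1 = out[, 2], y1 = out[, 3],
                 x2 = out[, 4], y2 = out[, 5])
  } else {
    n_sub <- max(1L, ceiling(dt / 2e-5))
    h <- dt / n_sub
    set.seed(as.integer(seed))
    p <- params
    k1 <- 1 / (p$R1 * p$C1); g1 <- 1 / (100 * p$R2 * p$C1)
    k2 <- 1 / (p$R1 * p$C2); g2 <- 1 / (100 * p$R2 * p$C2)
    gain <- if (isTRUE(p$coupling)) 1 / (10 * p$R_coupling * p$C2) else 0
    s <- init
    nt <- length(times)
    rec <- matrix(0, nt, 4L)
    rec[1L, ] <- s
    sdh <- process_noise_sd * sqrt(h)
    for (i in 2:nt) {
      for (j in seq_len(n_sub)) {
        dx1 <- k1 * s[2]
        dy1 <- g1 * (10 * p$V1 - s[1]^2) * s[2] - k1 * s[1] + k1 * p$b[1]
        dx2 <- k2 * s[4] - gain * s[1]^2
        dy2 <- g2 * (10 * p$V2 - s[3]^2) * s[4] - k2 * s[3] + k2 * p$b[2]
        s <- s + c(dx1, dy1, dx2, dy2) * h +
          c(0, rnorm(1, sd = sdh), 0, rnorm(1, sd = sdh))
      }
      if (!all(is.finite(s))) abort("Circuit integration diverged.")
      rec[i, ] <- s
    }
    tb <- tibble(time = times, x1 = rec[, 1], y1 = rec[, 2],
                 x2 = rec[, 3], y2 = rec[, 4])
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed) + 1L)
    tb$x1 <- tb$x1 + rnorm(nrow(tb), sd = noise_sd)
    tb$x2 <- tb$x2 + rnorm(nrow(tb), sd = noise_sd)
  }
  tb
}

#' Mean cycle rate from upward zero crossings
#'
#' Measures the oscillation frequency of one channel as the mean rate of
#' upward zero crossings of the mean-removed signal after discarding an
#' initial transient, with linear interpolation between samples.
#'
#' @param traj tibble with a `time` column (e.g. from [simulate_circuit()]).
#' @param channel channel name (default `"x1"`).
#' @param transient_s transient to discard (s).
#' @return Frequency (Hz).
#' @export
measure_frequency <- function(traj, channel = "x1", transient_s = 0.5) {
  keep <- traj$time > transient_s
  x <- traj[[channel]][keep]
  tt <- traj$time[keep]
  if (is.null(x)) abort(paste0("Unknown channel: ", channel))
  x <- x - mean(x)
  i <- which(x[-length(x)] < 0 & x[-1L] >= 0)
  if (length(i) < 3L) abort("Fewer than 3 upward zero crossings after the transient.")
  tc <- tt[i] + (tt[i + 1L] - tt[i]) * (-x[i]) / (x[i + 1L] - x[i])
  (length(tc) - 1L) / (tc[length(tc)] - tc[1L])
}

## Locate x-peak times (y crossing 0 downward with x > 0) on a dense path.
peak_times <- function(tt, x, y) {
  i <- which(y[-length(y)] > 0 & y[-1L] <= 0 & x[-length(x)] > 0)
  tt[i] + (tt[i + 1L] - tt[i]) * y[i] / (y[i] - y[i + 1L])
}

#' Phase sensitivity of one circuit oscillator by the adjoint method
#'
#' Finds the limit cycle of one (uncoupled) circuit oscillator, anchors zero
#' phase at the peak of `x`, and integrates the adjoint variational equation
#' `dZ/dt = -J(X(t))' Z` backward in time over the periodic orbit until the
#' periodic solution is reached, normalised so that `Z(phi) . F(X(phi)) =
#' omega` everywhere. `Z` is the infinitesimal phase response curve: the
#' gradient of the asymptotic phase along the cycle, which converts a weak
#' state-space perturbation into a phase velocity perturbation.
#'
#' @param params a [vdp_params()].
#' @param oscillator 1 or 2.
#' @param n_grid number of phase grid points (default 256).
#' @return A `phase_sensitivity` list: `phi` (grid on `[0, 2 pi)`), `X`
#'   (`n_grid` x 2 limit-cycle states), `Z` (`n_grid` x 2 sensitivities),
#'   `omega` (rad/s), `period` (s), and `residual` (max relative
#'   normalisation error).
#' @export
adjoint_sensitivity <- function(params, oscillator = 1L, n_grid = 256L) {
  osc <- osc_rhs_fun(params, oscillator)
  rhs <- function(t, s, p) list(osc$f(s))
  ## settle onto the limit cycle
  settle <- deSolve::ode(c(0.5, 0), seq(0, 0.4, by = 1e-4), rhs, NULL,
                         method = "lsoda", rtol = 1e-10, atol = 1e-12)
  s0 <- settle[nrow(settle), 2:3]
  if (!all(is.finite(s0)) || max(abs(settle[, 2])) < 1e-3) {
    abort("No limit cycle: trajectory decays toward rest.")
  }
  ## dense pass to find x-peak times and the period
  dense_t <- seq(0, 0.12, by = 1e-6)
  dp <- deSolve::ode(s0, dense_t, rhs, NULL, method = "lsoda",
                     rtol = 1e-11, atol = 1e-13)
  pk <- peak_times(dp[, 1], dp[, 2], dp[, 3])
  if (length(pk) < 4L) abort("No limit cycle: too few cycles detected.")
  period <- (pk[length(pk)] - pk[1L]) / (length(pk) - 1L)
  omega <- 2 * pi / period
  ## state exactly at an x-peak: integrate from the nearest dense sample
  i0 <- max(which(dp[, 1] <= pk[2L]))
  frac <- pk[2L] - dp[i0, 1]
  st <- deSolve::ode(dp[i0, 2:3], c(0, frac), rhs, NULL, method = "lsoda",
                     rtol = 1e-12, atol = 1e-14)[2L, 2:3]
  ## one period, fine orbit for interpolation
  n_fine <- 4096L
  tt <- seq(0, period, length.out = n_fine + 1L)
  orb <- deSolve::ode(st, tt, rhs, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-13)
  ## periodic interpolants (pad one period each side)
  pad <- c(tt - period, tt[-1L], tt[-1L] + period)
  xs <- splinefun(pad, c(orb[, 2], orb[-1L, 2], orb[-1L, 2]))
  ys <- splinefun(pad, c(orb[, 3], orb[-1L, 3], orb[-1L, 3]))
  orbit_state <- function(t) {
    tm <- t %% period
    c(xs(tm), ys(tm))
  }
  ## adjoint, integrated backward in time: s = -t
  adj_rhs <- function(s, z, p) {
    X <- orbit_state(-s)
    list(drop(t(osc$jac(X)) %*% z))
  }
  normalize <- function(z, X) z * omega / sum(z * osc$f(X))
  z <- normalize(c(1, 0), orbit_state(0))
  for (rep in 1:12) {
    sol <- deSolve::ode(z, c(0, period), adj_rhs, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    z_new <- normalize(sol[2L, 2:3], orbit_state(0))
    if (sqrt(sum((z_new - z)^2)) < 1e-10 * sqrt(sum(z_new^2))) {
      z <- z_new
      break
    }
    z <- z_new
  }
  ## final backward pass sampled on the phase grid
  s_out <- seq(0, period, length.out = n_grid + 1L)
  sol <- deSolve::ode(z, s_out, adj_rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  ## s = k*period/n maps to t = -s, i.e. phase 2*pi - 2*pi*k/n
  Z <- matrix(0, n_grid, 2L)
  X <- matrix(0, n_grid, 2L)
  phi <- 2 * pi * (seq_len(n_grid) - 1L) / n_grid
  Z[1L, ] <- sol[1L, 2:3]
  X[1L, ] <- orbit_state(0)
  for (kk in 2:n_grid) {
    Z[kk, ] <- sol[n_grid + 2L - kk, 2:3]
    X[kk, ] <- orbit_state(period * (kk - 1L) / n_grid)
  }
  resid <- vapply(seq_len(n_grid), function(kk)
    abs(sum(Z[kk, ] * osc$f(X[kk, ])) - omega) / omega, numeric(1))
  structure(list(phi = phi, X = X, Z = Z, omega = omega, period = period,
                 residual = max(resid), oscillator = oscillator),
            class = "phase_sensitivity")
}

#' @export
print.phase_sensitivity <- function(x, ...) {
  cat(sprintf("<phase_sensitivity> oscillator %d: f = %.4g Hz, %d grid points, max |Z.F - w|/w = %.2g\n",
              x$oscillator, x$omega / (2 * pi), length(x$phi), x$residual))
  invisible(x)
}

#' Theoretical coupling function by torus averaging
#'
#' Combines the target oscillator's phase sensitivity with the coupling
#' vector field to obtain the reduced phase-coupling function. The circuit's
#' coupling enters only the target's `x` equation as `gain * x_source^2`, so
#' `Gamma(psi) = (1/(2 pi p_i)) int_0^{2 pi p_i} Z_x(theta) * gain *
#' x_source((psi + p_j theta) / p_i)^2 dtheta`,
#' averaging over the `p_i:p_j` locked torus (for 1:2 locking `theta` runs
#' over two fast periods / one slow period). The result is tabulated on a
#' `psi` grid and also fitted with a truncated Fourier series; its constant
#' component is reported separately (it shifts the effective natural
#' frequency and is not part of the coupling term).
#'
#' @param sens_target `phase_sensitivity` of the driven oscillator.
#' @param sens_source `phase_sensitivity` of the driving oscillator (its
#'   orbit supplies `x_source`).
#' @param p_i,p_j winding pair of the locking (`psi = p_i phi_source -
#'   p_j phi_target`).
#' @param gain coupling gain multiplying `x_source^2` in the target's `x`
#'   equation; use [circuit_coupling_gain()] for the circuit's value.
#' @param n_psi size of the `psi` grid (default 128).
#' @param fourier_order Fourier order of the fitted series (default 5).
#' @param ratio_tol maximal relative mismatch between `p_i omega_source` and
#'   `p_j omega_target` (default 5%).
#' @return A `coupling_table`: list with `table` (tibble `psi`, `gamma`),
#'   `a0` (constant component, rad/s) and `term` (a [coupling_term()] of the
#'   fitted harmonics).
#' @export
theoretical_coupling <- function(sens_target, sens_source, p_i = 1L, p_j = 1L,
                                 gain = 0, n_psi = 128L, fourier_order = 5L,
                                 ratio_tol = 0.05) {
  mism <- abs(p_i * sens_source$omega - p_j * sens_target$omega) /
    (p_i * sens_source$omega)
  if (mism > ratio_tol) {
    abort(sprintf("Frequency ratio is %.3g away (relative) from %d:%d locking.",
                  mism, p_i, p_j))
  }
  Zx <- splinefun(c(sens_target$phi, 2 * pi), c(sens_target$Z[, 1], sens_target$Z[1, 1]),
                  method = "periodic")
  xs <- splinefun(c(sens_source$phi, 2 * pi), c(sens_source$X[, 1], sens_source$X[1, 1]),
                  method = "periodic")
  psi <- 2 * pi * (seq_len(n_psi) - 1L) / n_psi
  n_th <- 512L * p_i
  th <- seq(0, 2 * pi * p_i, length.out = n_th + 1L)[-(n_th + 1L)]
  zx <- Zx(th %% (2 * pi))
  gamma <- vapply(psi, function(ps) {
    src <- xs(((ps + p_j * th) / p_i) %% (2 * pi))
    mean(zx * gain * src^2)
  }, numeric(1))
  ## Fourier fit of the tabulated function
  Xf <- cbind(1, do.call(cbind, lapply(seq_len(fourier_order), function(m)
    cbind(cos(m * psi), sin(m * psi)))))
  cf <- drop(qr.solve(Xf, gamma))
  a <- cf[seq(2, by = 2, length.out = fourier_order)]
  b <- cf[seq(3, by = 2, length.out = fourier_order)]
  structure(
    list(table = tibble(psi = psi, gamma = gamma), a0 = cf[1],
         term = coupling_term(2L, 1L, p_i, p_j, a = a, b = b),
         p_i = p_i, p_j = p_j),
    class = "coupling_table")
}

#' @rdname theoretical_coupling
#' @param params a [vdp_params()].
#' @param target index of the driven oscillator; only oscillator 2 receives
#'   coupling in the circuit, so the gain is `-1/(10 R_coupling C2)` for
#'   `target = 2` and 0 otherwise.
#' @export
circuit_coupling_gain <- function(params, target = 2L) {
  if (target == 2L && isTRUE(params$coupling)) {
    -1 / (10 * params$R_coupling * params$C2)
  } else {
    0
  }
}
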