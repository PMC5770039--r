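#' Gaussian inverse-gamma prior specification
#'
#' The coupling regression uses the conjugate Gaussian inverse-gamma prior:
#' coefficients `w | sigma2 ~ N(chi0, sigma2 * Sigma0)` with
#' `Sigma0 = variance * I`, and `sigma2 ~ IG(alpha, beta)` where `sigma2` is
#' the per-sample variance of the phase-velocity noise. The defaults are
#' weakly informative but proper (a proper prior is required for the model
#' evidence to be finite).
#'
#' @param chi0 prior coefficient mean (scalar, recycled).
#' @param variance prior coefficient variance scale (default 100).
#' @param alpha,beta inverse-gamma shape and scale (default 1e-2 each).
#' @return A `nig_spec` object.
#' @export
nig_prior <- function(chi0 = 0, variance = 100, alpha = 1e-2, beta = 1e-2) {
  if (variance <= 0 || alpha <= 0 || beta <= 0) {
    abort("`variance`, `alpha` and `beta` must be positive.")
  }
  structure(list(chi0 = chi0, variance = variance, alpha = alpha, beta = beta),
            class = "nig_spec")
}

materialize_prior <- function(spec, k, labels = NULL) {
  structure(
    list(chi = rep_len(spec$chi0, k),
         Sigma = diag(spec$variance, k),
         alpha = spec$alpha, beta = spec$beta,
         n = 0L, labels = labels),
    class = "nig_state")
}

#' @export
print.nig_state <- function(x, ...) {
  cat(sprintf("<nig_state> k = %d coefficients, alpha = %.4g, beta = %.4g, n = %d\n",
              length(x$chi), x$alpha, x$beta, x$n))
  invisible(x)
}

#' Edge hypothesis table
#'
#' Declares candidate directed couplings for the estimator. `target` and
#' `source` are oscillator labels (phase-column names) or indices; the
#' winding pair defines `psi = p_i * phi_source - p_j * phi_target`. `M` may
#' be `NA` to let [select_orders()] choose the Fourier order by evidence.
#'
#' @param target,source vectors of oscillator labels or indices.
#' @param p_i,p_j integer winding numbers (recycled).
#' @param M Fourier orders, `NA` for "select by evidence".
#' @return A tibble with one row per directed edge.
#' @export
edge_hypotheses <- function(target, source, p_i = 1L, p_j = 1L, M = NA_integer_) {
  tibble(target = target, source = source,
         p_i = as.integer(p_i), p_j = as.integer(p_j),
         M = as.integer(M))
}

phase_columns <- function(phases) setdiff(names(phases), c("time", "trial"))

resolve_label <- function(x, labels) {
  if (is.numeric(x)) return(labels[x])
  if (!all(x %in% labels)) {
    abort(paste0("Unknown oscillator(s): ", paste(setdiff(x, labels), collapse = ", ")))
  }
  x
}

edge_key <- function(edges) {
  sprintf("%s<-%s(%d:%d)", edges$target, edges$source, edges$p_i, edges$p_j)
}

## Rows of the regression: velocity tau pairs features at t_tau. Rows whose
## forward difference crosses a trial boundary are dropped.
velocity_rows <- function(phases) {
  T <- nrow(phases)
  keep <- rep(TRUE, T - 1L)
  if ("trial" %in% names(phases)) {
    keep <- phases$trial[-T] == phases$trial[-1L]
  }
  keep
}

#' Build the phase-velocity regression problem
#'
#' Assembles the linear model in which the forward-difference phase velocity
#' of the target oscillator is regressed on an intercept (the effective
#' natural frequency) and, per hypothesised edge, the Fourier features
#' `cos(m psi)`, `sin(m psi)`, `m = 1..M`, of the generalised phase
#' difference.
#'
#' @param phases phase tibble: `time` plus one unwrapped-phase column per
#'   oscillator (and optionally a `trial` column; velocities spanning trial
#'   boundaries are masked out).
#' @param target target oscillator (label or index).
#' @param edges an [edge_hypotheses()] tibble with concrete `M` values
#'   targeting `target`.
#' @param fs sampling rate (Hz); inferred from `time` when absent.
#' @return A `phase_regression` list with elements `y`, `X`, `dt`, `labels`.
#' @export
build_problem <- function(phases, target, edges, fs = NULL) {
  dt <- infer_dt(phases, fs)
  labels <- phase_columns(phases)
  target <- resolve_label(target, labels)
  edges$target <- resolve_label(edges$target, labels)
  edges$source <- resolve_label(edges$source, labels)
  edges <- edges[edges$target == target, , drop = FALSE]
  if (any(is.na(edges$M))) abort("All edges need a concrete Fourier order M.")
  keep <- velocity_rows(phases)
  y <- (diff(phases[[target]]) / dt)[keep]
  cols <- list("(Intercept)" = rep(1, length(y)))
  keys <- edge_key(edges)
  for (e in seq_len(nrow(edges))) {
    psi <- phase_difference(phases[[edges$target[e]]], phases[[edges$source[e]]],
                            edges$p_i[e], edges$p_j[e])
    psi <- utils::head(psi, -1L)[keep]
    for (m in seq_len(edges$M[e])) {
      cols[[sprintf("cos%d[%s]", m, keys[e])]] <- cos(m * psi)
      cols[[sprintf("sin%d[%s]", m, keys[e])]] <- sin(m * psi)
    }
  }
  X <- do.call(cbind, cols)
  structure(list(y = y, X = X, dt = dt, labels = colnames(X),
                 target = target, edges = edges),
            class = "phase_regression")
}

#' Conjugate posterior update of the Gaussian inverse-gamma state
#'
#' Closed-form Bayesian update for the linear model
#' `y = X w + e`, `e ~ N(0, sigma2 I)` with prior
#' `w | sigma2 ~ N(chi_old, sigma2 Sigma_old)`, `sigma2 ~ IG(alpha_old, beta_old)`:
#' \itemize{
#'   \item `Sigma_new = (Sigma_old^-1 + X'X)^-1`
#'   \item `chi_new = Sigma_new (Sigma_old^-1 chi_old + X'y)`
#'   \item `alpha_new = alpha_old + n/2`
#'   \item `beta_new = beta_old + (y'y + chi_old' Sigma_old^-1 chi_old -
#'          chi_new' Sigma_new^-1 chi_new) / 2`
#' }
#' Point estimates are the posterior means: coefficients `chi_new` and noise
#' variance `beta_new / (alpha_new - 1)`. The velocity-noise variance maps to
#' the continuous-time noise strength as `D = sigma2 * dt / 2` (an
#' Euler-Maruyama increment of intensity `sqrt(2 D)` leaves a velocity
#' residual of variance `2 D / dt`).
#'
#' @param prob a `phase_regression` from [build_problem()].
#' @param prior a `nig_spec` from [nig_prior()], or a `nig_state` to continue
#'   updating.
#' @return A `nig_state` with fields `chi`, `Sigma`, `alpha`, `beta`.
#' @export
fit_posterior <- function(prob, prior = nig_prior()) {
  k <- ncol(prob$X)
  st <- if (inherits(prior, "nig_spec")) {
    materialize_prior(prior, k, prob$labels)
  } else prior
  if (length(st$chi) != k) abort("Prior dimension does not match the design matrix.")
  S0_inv <- chol2inv(chol(st$Sigma))
  XtX <- crossprod(prob$X)
  Sn_inv <- S0_inv + XtX
  R <- tryCatch(chol(Sn_inv), error = function(e)
    abort(paste0("Singular posterior update; collinear columns among: ",
                 paste(prob$labels, collapse = ", "))))
  Sn <- chol2inv(R)
  chi_n <- drop(Sn %*% (S0_inv %*% st$chi + crossprod(prob$X, prob$y)))
  n <- length(prob$y)
  alpha_n <- st$alpha + n / 2
  beta_n <- st$beta + 0.5 * (sum(prob$y^2) +
                             drop(crossprod(st$chi, S0_inv %*% st$chi)) -
                             drop(crossprod(chi_n, Sn_inv %*% chi_n)))
  structure(list(chi = chi_n, Sigma = Sn, alpha = alpha_n, beta = beta_n,
                 n = st$n + n, labels = prob$labels),
            class = "nig_state")
}

log_dmvnorm_scaled <- function(w, chi, Sigma, sigma2) {
  k <- length(w)
  R <- chol(Sigma)
  z <- backsolve(R, w - chi, transpose = TRUE)
  -0.5 * k * log(2 * pi * sigma2) - sum(log(diag(R))) -
    0.5 * sum(z^2) / sigma2
}

log_dinvgamma <- function(x, alpha, beta) {
  alpha * log(beta) - lgamma(alpha) - (alpha + 1) * log(x) - beta / x
}

#' Logarithmic model evidence
#'
#' The marginal likelihood of the phase-velocity data under one choice of
#' Fourier orders, computed through the identity
#' `log p(y) = log[ L(y | w, sigma2) p(w, sigma2) / p(w, sigma2 | y) ]`,
#' which holds at every parameter point `(w, sigma2)` because prior and
#' posterior are conjugate. The largest evidence across candidate orders
#' selects the model.
#'
#' @param prob a `phase_regression`.
#' @param prior the `nig_state` prior actually used (or a `nig_spec`).
#' @param posterior the `nig_state` returned by [fit_posterior()] for
#'   `(prob, prior)`.
#' @param at optional evaluation point, a list with elements `w` and
#'   `sigma2`; defaults to the posterior mean coefficients and posterior mode
#'   variance. The value is invariant to this choice.
#' @return The log evidence (scalar).
#' @export
log_evidence <- function(prob, prior, posterior, at = NULL) {
  k <- ncol(prob$X)
  if (inherits(prior, "nig_spec")) prior <- materialize_prior(prior, k, prob$labels)
  if (length(prior$chi) != k || length(posterior$chi) != k) {
    abort("Prior/posterior dimensions are inconsistent with the problem.")
  }
  w <- at$w %||% posterior$chi
  sigma2 <- at$sigma2 %||% (posterior$beta / (posterior$alpha + 1))
  mu <- drop(prob$X %*% w)
  loglik <- sum(stats::dnorm(prob$y, mu, sqrt(sigma2), log = TRUE))
  logprior <- log_dmvnorm_scaled(w, prior$chi, prior$Sigma, sigma2) +
    log_dinvgamma(sigma2, prior$alpha, prior$beta)
  logpost <- log_dmvnorm_scaled(w, posterior$chi, posterior$Sigma, sigma2) +
    log_dinvgamma(sigma2, posterior$alpha, posterior$beta)
  loglik + logprior - logpost
}

## Cached features for one target: psi and harmonics up to M_max per edge.
feature_cache <- function(phases, target, edges, M_max, dt) {
  keep <- velocity_rows(phases)
  y <- (diff(phases[[target]]) / dt)[keep]
  keys <- edge_key(edges)
  feats <- lapply(seq_len(nrow(edges)), function(e) {
    psi <- phase_difference(phases[[edges$target[e]]], phases[[edges$source[e]]],
                            edges$p_i[e], edges$p_j[e])
    psi <- utils::head(psi, -1L)[keep]
    cols <- list()
    for (m in seq_len(M_max)) {
      cols[[sprintf("cos%d[%s]", m, keys[e])]] <- cos(m * psi)
      cols[[sprintf("sin%d[%s]", m, keys[e])]] <- sin(m * psi)
    }
    cols
  })
  list(y = y, feats = feats, keys = keys, n = length(y))
}

fit_assignment <- function(cache, Ms, prior_spec, dt, target, edges) {
  cols <- list("(Intercept)" = rep(1, cache$n))
  for (e in seq_along(cache$feats)) {
    if (Ms[e] > 0L) {
      cols <- c(cols, cache$feats[[e]][seq_len(2L * Ms[e])])
    }
  }
  X <- do.call(cbind, cols)
  prob <- structure(list(y = cache$y, X = X, dt = dt, labels = colnames(X),
                         target = target, edges = edges),
                    class = "phase_regression")
  prior <- materialize_prior(prior_spec, ncol(X), prob$labels)
  post <- fit_posterior(prob, prior)
  list(prob = prob, prior = prior, posterior = post,
       evidence = log_evidence(prob, prior, post))
}

#' Select Fourier orders by maximising the model evidence
#'
#' Searches over per-edge Fourier orders `M in {0, ..., M_max}` for one
#' target oscillator and keeps the assignment with the largest logarithmic
#' evidence. With at most two candidate edges the search is exhaustive over
#' the full grid; with more edges a deterministic coordinate ascent from the
#' all-zero assignment is used (each pass re-optimises one edge's order until
#' no single-edge change improves the evidence). Ties are broken toward the
#' smaller total order.
#'
#' @param phases phase tibble (see [build_problem()]).
#' @param target target oscillator (label or index).
#' @param edges [edge_hypotheses()] rows targeting `target` (`M` ignored).
#' @param M_max largest order considered per edge (default 3).
#' @param prior a [nig_prior()] specification.
#' @param fs sampling rate (Hz); inferred from `time` when absent.
#' @return An `evidence_result`: list with `grid` (tibble of visited
#'   assignments and their log evidence), `selected` (named integer vector)
#'   and `exhaustive` flag.
#' @export
select_orders <- function(phases, target, edges, M_max = 3L,
                          prior = nig_prior(), fs = NULL) {
  if (M_max < 0L) abort("`M_max` must be >= 0.")
  dt <- infer_dt(phases, fs)
  labels <- phase_columns(phases)
  target <- resolve_label(target, labels)
  edges$target <- resolve_label(edges$target, labels)
  edges$source <- resolve_label(edges$source, labels)
  edges <- edges[edges$target == target, , drop = FALSE]
  ne <- nrow(edges)
  cache <- feature_cache(phases, target, edges, M_max, dt)
  evals <- new.env(parent = emptyenv())
  eval_Ms <- function(Ms) {
    key <- paste(Ms, collapse = ",")
    if (is.null(evals[[key]])) {
      evals[[key]] <- fit_assignment(cache, Ms, prior, dt, target, edges)$evidence
    }
    evals[[key]]
  }
  exhaustive <- ne <= 2L
  if (ne == 0L) {
    selected <- integer(0)
    eval_Ms(integer(0))
  } else if (exhaustive) {
    grid <- as.matrix(expand.grid(rep(list(0:M_max), ne)))
    ev <- apply(grid, 1L, eval_Ms)
    best <- max(ev)
    hits <- which(ev >= best - 1e-9)
    hits <- hits[order(rowSums(grid[hits, , drop = FALSE]))]
    selected <- as.integer(grid[hits[1L], ])
  } else {
    selected <- rep(0L, ne)
    repeat {
      changed <- FALSE
      for (e in seq_len(ne)) {
        cur <- eval_Ms(selected)
        cand <- selected
        for (m in 0:M_max) {
          cand[e] <- m
          if (eval_Ms(cand) > cur + 1e-9) {
            selected <- cand
            cur <- eval_Ms(cand)
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  names(selected) <- cache$keys
  visited <- ls(evals)
  grid_tb <- purrr::map_dfr(visited, function(key) {
    Ms <- if (nzchar(key)) as.integer(strsplit(key, ",")[[1]]) else integer(0)
    row <- as.list(Ms)
    names(row) <- if (length(Ms)) paste0("M[", cache$keys, "]") else character(0)
    row$log_evidence <- evals[[key]]
    as_tibble(row)
  })
  grid_tb <- dplyr::arrange(grid_tb, dplyr::desc(.data$log_evidence))
  structure(list(grid = grid_tb, selected = selected, target = target,
                 exhaustive = exhaustive),
            class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  cat(sprintf("<evidence_result> target %s (%s search)\n", x$target,
              if (x$exhaustive) "exhaustive" else "coordinate-ascent"))
  cat("  selected:", paste(sprintf("%s=%d", names(x$selected), x$selected),
                           collapse = ", "), "\n")
  print(utils::head(x$grid, 5))
  invisible(x)
}

#' Estimate a phase-oscillator network model from phase time series
#'
#' For every target oscillator appearing in `edges`: select the Fourier order
#' of each incoming coupling by model evidence (unless fixed via `M`), fit the
#' conjugate Bayesian regression at the selected orders and collect the
#' posterior-mean natural frequency, coupling coefficients and noise strength
#' into a [phase_model()].
#'
#' @param phases phase tibble: `time` plus one unwrapped-phase column per
#'   oscillator (optional `trial` column masks cross-trial velocities).
#' @param edges [edge_hypotheses()] tibble; rows with `M = NA` get their
#'   order selected by evidence, rows with concrete `M` are fixed.
#' @param M_max largest order considered when selecting (default 3).
#' @param prior a [nig_prior()] specification.
#' @param fs sampling rate (Hz); inferred from `time` when absent.
#' @param targets oscillators to fit (default: all phase columns; oscillators
#'   without incoming edges get an intercept-only fit).
#' @return A `phase_fit` object; see [tidy.phase_fit()], [glance.phase_fit()],
#'   [autoplot.phase_fit()]. The fitted network is in `$model`.
#' @examples
#' \donttest{
#' fx <- three_oscillator_fixture(n_steps = 20000, seed = 1)
#' fit <- estimate_model(fx$phases, fx$edges, M_max = 2)
#' glance(fit)
#' }
#' @export
estimate_model <- function(phases, edges, M_max = 3L, prior = nig_prior(),
                           fs = NULL, targets = NULL) {
  dt <- infer_dt(phases, fs)
  labels <- phase_columns(phases)
  edges$target <- resolve_label(edges$target, labels)
  edges$source <- resolve_label(edges$source, labels)
  targets <- resolve_label(targets %||% labels, labels)
  fits <- list()
  omega_hat <- numeric(length(labels))
  D <- numeric(length(labels))
  couplings <- list()
  for (tg in targets) {
    e_t <- edges[edges$target == tg, , drop = FALSE]
    free <- is.na(e_t$M)
    sel <- NULL
    if (any(free)) {
      sel <- select_orders(phases, tg, e_t[free, , drop = FALSE],
                           M_max = M_max, prior = prior, fs = 1 / dt)
      e_t$M[free] <- sel$selected
    }
    prob <- build_problem(phases, tg, e_t, fs = 1 / dt)
    prior_st <- materialize_prior(prior, ncol(prob$X), prob$labels)
    post <- fit_posterior(prob, prior_st)
    ev <- log_evidence(prob, prior_st, post)
    idx <- match(tg, labels)
    omega_hat[idx] <- post$chi[1L]
    sigma2 <- post$beta / (post$alpha - 1)
    D[idx] <- sigma2 * dt / 2
    keys <- edge_key(e_t)
    for (e in seq_len(nrow(e_t))) {
      M <- e_t$M[e]
      a <- b <- numeric(0)
      if (M > 0L) {
        a <- post$chi[match(sprintf("cos%d[%s]", 1:M, keys[e]), prob$labels)]
        b <- post$chi[match(sprintf("sin%d[%s]", 1:M, keys[e]), prob$labels)]
      }
      couplings[[length(couplings) + 1L]] <- coupling_term(
        target = match(tg, labels), source = match(e_t$source[e], labels),
        p_i = e_t$p_i[e], p_j = e_t$p_j[e], a = a, b = b)
    }
    fits[[tg]] <- list(posterior = post, problem_labels = prob$labels,
                       log_evidence = ev, evidence = sel,
                       edges = e_t, sigma2 = sigma2, nobs = length(prob$y))
  }
  model <- phase_model(omega_hat, D, couplings, labels = labels)
  structure(list(model = model, fits = fits, dt = dt, labels = labels,
                 targets = targets),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf("<phase_fit> %d oscillators fitted (dt = %.4g)\n",
              length(x$targets), x$dt))
  print(x$model)
  invisible(x)
}

#' Tidy a fitted phase model
#'
#' @param x a `phase_fit` from [estimate_model()].
#' @param ... unused.
#' @return A tibble with one row per regression coefficient: `oscillator`,
#'   `term`, `estimate` (posterior mean) and `std.error` (posterior standard
#'   deviation under the posterior-mean noise variance).
#' @method tidy phase_fit
#' @export
tidy.phase_fit <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(tg) {
    f <- x$fits[[tg]]
    tibble(
      oscillator = tg,
      term = f$problem_labels,
      estimate = f$posterior$chi,
      std.error = sqrt(f$sigma2 * diag(f$posterior$Sigma))
    )
  })
}

#' One-line-per-oscillator summary of a phase fit
#'
#' @param x a `phase_fit`.
#' @param ... unused.
#' @return A tibble with, per fitted oscillator: `omega_hat` (rad per unit
#'   time), `noise_D`, `noise_intensity` (`sqrt(2 D)`), `sigma2`,
#'   `log_evidence` and `nobs`.
#' @method glance phase_fit
#' @export
glance.phase_fit <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(tg) {
    f <- x$fits[[tg]]
    idx <- match(tg, x$labels)
    tibble(
      oscillator = tg,
      omega_hat = x$model$omega_hat[idx],
      noise_D = x$model$D[idx],
      noise_intensity = sqrt(2 * x$model$D[idx]),
      sigma2 = f$sigma2,
      log_evidence = f$log_evidence,
      nobs = f$nobs
    )
  })
}
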