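---
title: "Inferring phase-coupling functions from rhythmic time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring phase-coupling functions from rhythmic time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Many rhythmic systems — neural oscillations, speech envelopes, electronic
oscillators — can be reduced, when coupling is weak, to a network of phase
equations. `phasecoupler` fits the stochastic phase model

$$
\frac{d\phi_i}{dt} \;=\; \hat\omega_i \;+\;
\sum_{j \ne i} \Gamma_{ij}\!\big(\psi_{ij}\big) \;+\; \eta_i(t),
\qquad
\psi_{ij} = p_i\,\phi_j - p_j\,\phi_i ,
$$

where $\hat\omega_i$ is the effective natural frequency, $\Gamma_{ij}$ is a
$2\pi$-periodic coupling function expanded as a truncated Fourier series of
order $M_{ij}$, the integer winding pair $(p_i, p_j)$ describes $p_i\!:\!p_j$
cross-frequency locking (e.g. a slow prosodic rhythm locking 1:2 to a theta
oscillation), and $\eta_i$ is white noise with
$\langle\eta_i(t)\eta_j(t')\rangle = 2 D_i\,\delta_{ij}\,\delta(t - t')$.
The constant Fourier component of each coupling function is not identifiable
separately from $\hat\omega_i$, so the two are stored only as their sum —
the regression has a single intercept per oscillator.

Three estimation stages mirror the package's modules:

1. **Phases** (`extract_phase()` and friends). The analytic signal
   $A e^{i\theta} = s + i\,\mathcal H[s]$ gives a *protophase* $\theta$,
   whose wrapped distribution is generally non-uniform and
   parameterisation-dependent. The transformation
   $\phi(\theta) = 2\pi \int_0^{\theta} f(\theta')\,d\theta'$, with $f$ the
   stationary circular density of $\theta$, produces a phase that advances
   uniformly for an unperturbed oscillator.
2. **Regression** (`estimate_model()`). The forward-difference phase
   velocity is regressed on an intercept and the features
   $\cos(m\psi), \sin(m\psi)$ with a conjugate Gaussian inverse-gamma prior,
   giving closed-form posteriors and a closed-form marginal likelihood.
3. **Model selection** (`select_orders()`). The Fourier order of every
   directed edge is chosen by maximising the logarithmic evidence
   $\log p(y) = \log\big[L(y\,|\,w,\sigma^2)\,p(w,\sigma^2)\,/\,
   p(w,\sigma^2\,|\,y)\big]$, an identity valid at every parameter point
   under conjugacy. $M = 0$ means "no coupling": evidence-based selection is
   the package's detector of absent interactions.

## A worked network recovery

```{r}
library(phasecoupler)

fx <- three_oscillator_fixture(n_steps = 1e5, dt = 0.01, seed = 1)
fit <- estimate_model(fx$phases, fx$edges, M_max = 3)
glance(fit)
tidy(fit)
autoplot(fit, truth = fx$model)
```

The bundled benchmark network has one fast oscillator (natural frequency
2.1) driven 1:2 by two slow ones (0.9 and 1.1), four true directed
couplings with amplitudes 0.05–0.1, and noise intensity 0.1. At the
reference conditions ($10^5$ Euler–Maruyama steps, $dt = 0.01$) the fit
recovers every generating coefficient within posterior uncertainty, selects
the generating Fourier orders, and returns $M=0$ for both absent edges.

## Parameters that matter

- **`M_max`** (default 3): the largest Fourier order tried per edge. The
  evidence penalises complexity, so a generous `M_max` mainly costs compute;
  with at most two candidate edges per target the search is exhaustive,
  beyond that a deterministic coordinate ascent from the all-zero assignment
  is used (ties broken toward smaller total order).
- **Prior** (`nig_prior()`): coefficients $w\,|\,\sigma^2 \sim
  N(0, 100\,\sigma^2 I)$ and $\sigma^2 \sim IG(10^{-2}, 10^{-2})$. Weakly
  informative but proper — a proper prior is required for the evidence to be
  finite. Results on the bundled fixtures are insensitive to an order of
  magnitude either way; the update rule accepts any `nig_prior()`.
- **Winding pair** $(p_i, p_j)$: assumed known from the rhythms under study
  (1:1 for same-band pairs, 1:2 for prosody/theta-style locking);
  `detect_winding()` recovers it from mean phase velocities when in doubt,
  refusing ratios further than 5% from every admissible resonance.
- **Density estimator** for the protophase correction: Fourier series from
  empirical circular moments, order 10, evaluated on a 2048-point grid,
  clipped at $10^{-6}$ and renormalised. Clipping keeps $\phi(\theta)$
  strictly increasing even for strongly non-sinusoidal (relaxation-type)
  waveforms.
- **Edge margins**: one period of each channel's dominant frequency is
  discarded at both record ends before density estimation, where the
  analytic signal is unreliable.
- **Noise bookkeeping**: the regression estimates the per-sample velocity
  noise variance $\sigma^2$; because an Euler–Maruyama increment of
  intensity $\sqrt{2D}$ leaves a velocity residual of variance $2D/dt$, the
  reported noise strength is $D = \sigma^2 dt / 2$ and the continuous-time
  intensity $\sqrt{2D} = \sqrt{\sigma^2 dt}$. On the benchmark network this
  recovers the generating intensity 0.1. The network simulator reads
  "noise intensity" the same way; a `per-step` mode (increment sd
  independent of `dt`) is available for data whose noise is genuinely
  discrete-time.

## Ground truth from a circuit model

The two-oscillator van der Pol circuit model provides physical-style ground
truth: its coupling functions can be derived independently of the estimator
by the adjoint method. `adjoint_sensitivity()` finds the limit cycle,
anchors zero phase at the voltage peak, and integrates the adjoint
variational equation backward in time with the normalisation
$Z(\phi)\cdot F(X(\phi)) = \omega$; `theoretical_coupling()` averages
$Z \cdot G$ over the locked torus (two fast periods per slow period for 1:2
locking). `run_circuit_benchmark()` closes the loop: simulate the circuit,
extract phases, estimate, and compare against the adjoint result and against
phase-difference histograms of re-simulated fitted models.

Two modelling choices deserve note. First, the component values are the
standard ones ($R_1 = 100\,$kΩ, $R_2 = 1\,$kΩ, $R_{coupling} = 1\,$MΩ,
$C_1 = C_2 = 0.01\,$µF, $V_1 = 0.115\,$V, $V_2 = 0.12\,$V), and the
asymmetry term $b = 0.4$ is applied to **oscillator 1**: with that
assignment the model reproduces the reference limit-cycle frequencies
(142.3 Hz, 146.6 Hz, and 71.1 Hz with $C_1$ doubled) to a fraction of a
percent, and doubling $C_1$ exactly halves oscillator 1's frequency by the
time-rescaling symmetry of its equations. Theoretical frequencies are
computed with the (weak) coupling disengaged. Second, because the
deterministic circuit locks rigidly — and a rigidly locked pair visits only
one phase difference, leaving the coupling function unidentifiable away
from it — the benchmark adds weak white-noise forcing
(0.7 V/$\sqrt{\mathrm s}$) to both $y$ equations, standing in for the small
uncontrolled disturbances any physical board exhibits. The intensity was
chosen once so that the phase difference diffuses through the full circle
over a 16 s record while the locking statistics stay clearly peaked.

## Surrogates and ablation

Whether an estimated coupling is real is decided against a time-shift null:
`surrogate_scan()` circularly shifts the wrapped source phase (uniformly
between 10% and 90% of the record, avoiding near-identity shifts),
re-runs order selection and the fit, and records the selected $M$ and the
coupling power $\int_0^{2\pi} |\Gamma(\psi)|^2 d\psi = \pi\sum_m (a_m^2 +
b_m^2)$. Shifting preserves each channel's wrapped-phase marginal but
destroys temporal coupling, so for genuinely coupled data the null's order
histogram peaks at $M = 0$ while the original selects $M > 0$ and its power
falls in the upper tail (empirical $p = (1 + \#\{\text{surrogate} \ge
\text{original}\})/(1 + n)$). For trial-structured records shifts can be
drawn per trial; trial boundaries also mask velocity samples that would
span two trials during fitting. `ablate_edges()` asks the complementary
dynamical question: re-simulating the fitted model with one directed
coupling zeroed shows which edge actually sustains the locking — removing
the dominant edge flattens the phase-difference histogram, removing a weak
reverse edge leaves it essentially unchanged.

## What the synthetic data do and do not show

The generators emulate: cross-frequency ($p_i\!:\!p_j$) locking, marginal
locking with phase slips, white dynamical noise, non-sinusoidal waveforms
(circuit), narrowband filtering and envelope extraction
(`bandpass_and_envelope()`, 4th-order zero-phase Butterworth), and
unidirectional driving with a known ground-truth direction. They do not
emulate: nonstationary or event-locked dynamics, phase resetting by strong
inputs, coloured or shared measurement noise, volume conduction between
channels, or phase–amplitude coupling (the phase model cannot express it).
Passing tests therefore demonstrate correctness of the estimator under the
model's own assumptions, not that any particular real recording satisfies
those assumptions; the surrogate machinery exists precisely because real
data must earn their coupling claims against a null.

## Numerical choices and degenerate inputs

- Unwrapping interprets jumps above $\pi$ as wraps; sampling must be fast
  relative to the oscillation (true of all bundled settings).
- The regression row at time $t_\tau$ pairs features $\psi(t_\tau)$ with the
  velocity $(\phi(t_{\tau+1}) - \phi(t_\tau))/dt$, Euler-consistent with the
  simulator's likelihood.
- Posterior updates use Cholesky factorisations; collinear feature columns
  under an effectively flat prior raise an error naming the columns.
- Simulation noise uses one substream per oscillator (derived
  deterministically from the seed), so enlarging a network never perturbs
  the noise of existing oscillators.
- Problem sizes in the test-suite: $10^5$-step phase simulations, 16 s
  circuit records at 5 kHz, 128–256-point adjoint grids, 19–20 surrogate
  replicates — each chosen as the smallest scale at which the corresponding
  statistical property is comfortably resolved.
- Degenerate inputs error early: constant signals ("no oscillation"),
  NaNs, empty protophase tracks, invalid bands, non-normalisable densities,
  shifts exceeding the record, unknown channels or edges.

## Known limitations

- Rigid (noise-free) synchronisation leaves $\Gamma$ unidentifiable away
  from the visited phase difference; the estimator returns a fit, but only
  the locally constrained part is meaningful. Check $\psi$ coverage first.
- One winding pair per directed edge: exotic multi-resonance interactions
  are outside the model class, as are amplitude dynamics and
  phase–amplitude coupling.
- Coordinate-ascent order selection beyond two edges per target is an
  approximation to the exhaustive evidence search; every bundled benchmark
  has at most two candidate edges per target, where the search is exhaustive.
- The evidence compares models on the same rows; comparing fits across
  different preprocessing (margins, bands) is not meaningful.
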