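---
title: "Reaction-diffusion autocorrelation functions for FCS: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-diffusion autocorrelation functions for FCS: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsrd)
```

## The model

Fluorescence correlation spectroscopy (FCS) monitors the autocorrelation
$G(t)$ of fluorescence fluctuations from a femtolitre-scale Gaussian focal
volume (beam radius $L$, axial size $H$, aspect ratio $\omega = H/L$).  In a
dilute solution at equilibrium a dye $B$ binds reversibly to a macromolecule
$A$ forming a fluorescent complex $C$:

$$A + B \underset{k_-}{\overset{k_+}{\rightleftharpoons}} C,$$

with equal diffusion coefficients for macromolecule and complex,
$D_A = D_C = D \ll D_B$.  Concentration fluctuations relax by coupled
reaction and diffusion; linearising about equilibrium gives rates
$k_A = k_+\bar C_B$, $k_B = k_+\bar C_A$, $k_C = k_-$.

The three linearised transport equations decouple under the species
transformation

* species 1 $= \delta C_A + \delta C_C$ (total macromolecule) — diffuses
  freely with $D$;
* species 2 $= \delta C_B$ (free dye);
* species 3 $= (k_C\,\delta C_C - k_A\,\delta C_A)/k_{32}$,

where species 2 and 3 obey the transport equations of a two-state
interconversion $2 \rightleftharpoons 3$ with rates $k_{23} = k_B$ and
$k_{32} = k_A + k_C$, chemical relaxation rate $R = k_{23} + k_{32}$ and
bound fraction $\beta = k_{23}/R$.  Detailed balance makes the equal-time
cross-correlations of species 1, 2, 3 vanish, with effective amplitudes
$\bar C_1 = k_A \bar C_C / k_{32}$, $\bar C_2 = \bar C_B$,
$\bar C_3 = k_C \bar C_C / k_{32}$ (so $\bar C_1 + \bar C_3 = \bar C_C$ and
$\bar C_3/\bar C_2 = k_{23}/k_{32}$); `fcs_params()` performs this
bookkeeping and validates detailed balance as an input contract (relative
tolerance $10^{-10}$; it is never silently repaired).

## Exact G(t) by occupation-time averaging

A dye switching between free ($D_B$) and bound ($D$) states accumulates
mean-squared displacement according to the *fraction* $\rho$ of the lag it
spent bound, because the Fourier-space propagator stays Gaussian with
effective coefficient $D_\rho = (1-\rho) D_B + \rho D$.  Each correlation
component is therefore an average of the single-species autocorrelation

$$G_s(\chi) = (1+\chi)^{-1} (1+\chi/\omega^2)^{-1/2}, \qquad
  \chi = t/\tau_\rho,\ \ \tau_\rho = L^2/(4 D_\rho),$$

over the occupation-time density $\Phi_{i'j'}(t, \rho)$ of a two-state
Markov chain conditioned on its initial and final states:

* $\Phi_{22}$ carries an atom $e^{-k_{23}t}$ at $\rho = 0$ (paths that never
  bind) plus a continuous part
  $b\sqrt{u/w}\,I_1(\zeta)e^{-u-w}$ with $u = k_{23}t(1-\rho)$,
  $w = k_{32}t\rho$, $\zeta = 2\sqrt{uw}$;
* $\Phi_{33}$ mirrors it with an atom $e^{-k_{32}t}$ at $\rho = 1$;
* the cross densities are $k_{23}t\,I_0(\zeta)e^{-u-w}$ and
  $k_{32}t\,I_0(\zeta)e^{-u-w}$, identical after normalisation.

These are the same Bessel structures as the Skellam distribution of the net
number of transitions (`skellam_pmf()`).  Atoms plus continuous part
integrate to the two-state propagator probabilities ("masses"), which are
the prefactors of the exact components; `exact_average_gs()` treats the
atoms analytically and integrates the continuous part by adaptive
quadrature.  $G(t)$ is assembled from the five components with the quantum
yields $Q_1 = Q_3 = Q_C$, $Q_2 = Q_B$ and mean molecule numbers
(`full_acf()`); $G_{11}(t) = G_s(t/\tau_D)$ is free diffusion.

Two identities guard the transcription everywhere in the test suite:
$G_{i'j'}(0) = \delta_{i'j'}$ and $(1-\beta)G_{32}(t) = \beta G_{23}(t)$,
plus a Gillespie Monte-Carlo oracle (`sample_occupation()`) that reproduces
every average by brute force.

## The closed form: moment expansion

The continuous part of each density concentrates around $\beta$ with
$\sigma^2 \sim 2\beta(1-\beta)/(Rt)$ as $Rt \to \infty$.  Expanding
$G_s(t/\tau_\rho)$ to second order around the *mean* occupation fraction of
the continuous part gives the closed form (`approx_average_gs()`):

$$\langle G_s \rangle \approx \text{atom terms} +
  m_c\left[G_s(t/\tau_{i'j'}) + \tfrac12 G_s''(t/\tau_{i'j'})
  \left(\tfrac{t}{\tau_\Delta}\right)^2 \sigma_{i'j'}^2\right],$$

with $\tau_{i'j'}^{-1} = (1-\langle\rho\rangle)\tau_B^{-1} +
\langle\rho\rangle\tau_D^{-1}$ and $\tau_\Delta^{-1} = \tau_B^{-1} -
\tau_D^{-1}$.  Exactly two terms are kept.  The atoms are *not* folded into
the moments: keeping the never-switching paths as exact exponential
prefactors roughly halves the worst-case error (folding them in doubles it
and visibly contradicts the validity boundaries below).  The first and
second moments of every density are closed forms obtained by convolving the
two-state propagator; below $Rt = 0.02$ a series to $O((Rt)^6)$ replaces
them because numerator and denominator both vanish in that limit and
double-precision cancellation would otherwise exceed $10^{-9}$.
`first_order_average_gs()` keeps only the first term (fast-reaction form).

## Limiting regimes

* **Effective diffusion** ($R \to \infty$): a single species with
  $D_\beta = (1-\beta)D_B + \beta D$ and effective yield
  $Q_\beta = (1-\beta)Q_B + \beta Q_C$ (`effective_diffusion_acf()`).  The
  curve depends on the equilibrium constant only — the rates are not
  identifiable there, which the fitting layer detects (below).
* **Two-component diffusion** ($R \to 0$): free dye plus complex with no
  exchange (`two_component_acf()`).
* **Slow reaction** ($\tau_B k_{23} \ll 1$, $\tau_D k_{32} \ll 1$, lags
  $t \ll 1/\gamma$ with $\gamma = \sqrt{k_{23}k_{32}}$): two-component
  diffusion with exponentially depleted amplitudes plus cross terms
  $\propto k_{23}\,t$ coupling reaction and diffusion through the uniform
  average of $G_s(t/\tau_\rho)$, available in closed form via the
  antiderivative of $G_s$ (`slow_reaction_acf()`).
* **Fast diffusion over immobile sites** ($D = 0$, $\tau_B \to 0$):
  $G_s$ acts as a weight concentrating at $\rho = 1$; each average is
  approximated by the density evaluated at the $G_s$-weighted mean
  occupation fraction (`fast_diffusion_acf()`), and the regime crosses over
  to effective diffusion at $t_t = 4\beta^2(1-\beta)^2/(R^2\tau_B)$
  (`transition_time()`).  The component-level validity window of this
  pointwise approximation is narrow: it holds while the exponential
  amplitude $e^{-k_{32}t}$ still dominates the polynomial bulk term of
  $G_{33}$ (about one decade of lags beyond $10/\gamma$ at
  $R\tau_B = 10^{-3}$); the assembled $G(t)$ is far less sensitive.  The
  tests assert the measured windows, not a blanket claim.

## Validity diagnostics

`relative_deviation()` computes $\Delta_r = (\text{approx} -
\text{exact})/\text{exact}$ per component; lags where the exact average has
decayed below $10^{-12}$ are excluded (the ratio is meaningless there).
`accuracy()` maximises $|\Delta_r|$ over components and a log time grid;
the expansion is considered valid when this stays below $\epsilon = 0.01$.
`limiting_v()` bisects on $v = 1/(k_{23}\tau_B) + 1/(k_{32}\tau_D)$ for the
boundary $v_L(\tau_B/\tau_D)$, with an inner maximisation over a 25-point
$\beta$ grid refined near $\beta_{\min} = \tau_D/(\tau_D+\tau_B)$ (where
$\gamma(\beta)$ at fixed $v$ is smallest) and 48 log-spaced lags in
$[10^{-2}, 10^3]\tau_B$; bisection stops at 2% — the precision of the
quoted boundary values.

Two inner protocols are exposed, because they genuinely differ at small
$\tau_B/\tau_D$:

* `beta_scan = "full"` (default): the genuine worst case over all $\beta$.
  At $\tau_B/\tau_D = 1/6$ this yields $v_L \approx 1.8$, with the worst
  point near $\beta = 0.5$.  At $\tau_B/\tau_D = 0.001$ the worst case
  migrates to the hybrid corner $\beta \in [0.95, 0.995]$
  ($k_{32} \ll k_{23}$), where the expansion's component averages are known
  to deteriorate, and the boundary drops to $v_L \approx 0.23$.
* `beta_scan = "beta_min"`: the worst-$\gamma$ argument, evaluating only at
  $\beta_{\min}$.  At $\tau_B/\tau_D = 0.001$ this gives
  $v_L \approx 0.48$; at $1/6$ it is considerably more permissive
  ($\approx 4.4$) because the true worst $\beta$ there is *not*
  $\beta_{\min}$.

Every exact average behind both numbers is verified against the Monte-Carlo
oracle.  The aspect ratio $\omega$ used for the published boundary curves is
not known; sweeping $\omega \in \{3, 5, 7\}$ moves $v_L(1/6)$ by about
$\pm 7\%$, and $\omega = 5$ is the package default.  `classify_regime()`
labels a parameter point (pure diffusion, hybrid, reaction-dominant, slow,
fast, effective-diffusion, intermediate; "much smaller" operationalised as
a ratio below 0.1) using an interpolation table precomputed with
`limiting_v()` at $\omega = 5$, so that a classification does not cost a
bisection; labels are advisory and the object carries the raw numbers —
$v > v_L$ does not automatically mean the expansion fails, since the
affected average may carry negligible weight in $G(t)$.

## Numerical choices

* **Bessel evaluation**: exponentially scaled $I_0, I_1$ with explicit
  exponential prefactors ($e^{\zeta-u-w} = e^{-(\sqrt u - \sqrt w)^2}$), so
  nothing overflows up to $Rt \sim 10^8$.  R's `besselI` underflows
  internally beyond scaled arguments of $\sim 1.5\times 10^5$; a Hankel
  asymptotic branch takes over at $5\times 10^4$ (relative error
  $\sim 10^{-19}$ at the crossover), and the Skellam pmf additionally uses
  Olver's uniform asymptotic for large orders.
* **Quadrature**: the continuous integrand is bracketed by the
  continuous-part moments (mean $\pm 40$ sd) so the concentrating peak at
  large $Rt$ cannot be missed, and split where $t/\tau_\rho$ crosses 3, 30
  and 300 so the boundary layer at $\rho \to 1$ (slow macromolecule,
  $t \gg \tau_B$) cannot be overlooked.  The adaptive path
  (`stats::integrate`, absolute tolerance $10^{-9}$, error raised on
  non-convergence) serves single evaluations; a fixed 160-node
  Gauss-Legendre path serves the validity sweeps and agrees with the
  adaptive one to $10^{-15}$ on smooth bracketed integrands.
* **Degenerate inputs**: $D = 0$ is first-class (`tau_D_inv = 0`
  internally, never a floating infinity in formulas); $D = D_B$ collapses
  $\tau_\rho$ to a constant and the expansion becomes exact (flagged
  `degenerate`); $D > D_B$ is rejected — the equal-coefficient assumption
  for $A$ and $C$ is itself doubtful beyond $D/D_B \approx 0.3$, and the
  validity machinery refuses ratios above 0.30.
* **Bounds**: convexity of $G_s(t/\tau_\rho)$ in $\rho$ gives rigorous
  brackets on every exact average — a Jensen lower bound at the mean
  occupation fraction and a chord upper bound mixing $G_s(t/\tau_B)$ and
  $G_s(t/\tau_D)$ — whose amplitudes are combinations of $e^{-k_{23}t}$ and
  $e^{-k_{32}t}$ (`avg_gs_bounds()`).

## Fitting and synthetic data

`fit_acf()` performs weighted nonlinear least squares (weights $1/\sigma^2$
when per-point errors are present, else uniform — documented as
approximate, since real FCS noise is lag-correlated) in unconstrained
coordinates: logs for positive parameters, a logit for $\beta$, and
$(\beta, R)$ instead of the strongly correlated $(k_{23}, k_{32})$; the
rates and their delta-method errors are derived on report.  Multi-start
uses seeded log-normal perturbations of the initial guess.  Standard errors
come from the Gauss-Newton curvature, but a locally well-conditioned
Hessian can hide a direction that is flat at the noise scale — on
effective-diffusion data every sufficiently large $R$ produces the same
curve, and the optimiser settles in a shallow noise-induced minimum.  Each
free parameter is therefore probed three log-units from the optimum; if the
objective rises by less than a 95% chi-square step the direction is flagged
non-identifiable and its reported uncertainty floored at the probe
distance.  One caveat remains: at weakly identifying parameter points (for
instance a strong inert species-1 background diluting the reaction
contrast) the chi-square surface is a long curved valley in $(\beta, R)$,
and the quadratic Gauss-Newton errors understate it even though the probe
does not trigger — standard sloppiness of multiparameter curve fits, worth
checking with a profile scan when the rates matter.

`synthesize_curve()` generates model curves on log-spaced lag grids (64
points per decade over $[10^{-3}, 10^4]\tau_B$ by default, the geometry of
hardware correlators) with seeded proportional or additive Gaussian noise.
The generator's default study point for recovery experiments is the
reference parameter set $(\tau_B/\tau_D, \beta, v) = (1/6, 1/2, 1)$ — i.e.
$R\tau_B = 7/3$ — with 1% proportional noise and 256 lags, squarely inside
the expansion's validity region.  What it does **not** emulate: detector
afterpulsing, triplet blinking, lag-correlated photon noise, finite-particle
and optical-saturation corrections.  A green recovery test therefore
establishes correctness of the estimator under the stated noise model, not
robustness to real detector physics.

## Known limitations

* Three distinct diffusion coefficients ($D_A \neq D_C$) are out of scope;
  so are non-Gaussian illumination profiles and position-dependent
  brightness.
* The fast-diffusion route is accurate component-wise only in its early
  window (above); use the exact engine beyond it.
* The published validity boundary at small $\tau_B/\tau_D$ corresponds to
  the $\beta_{\min}$ protocol; the package's default worst-case sweep is
  stricter there (0.23 vs 0.48 at a ratio of 0.001).  Both are available,
  and the discrepancy is documented rather than hidden.
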