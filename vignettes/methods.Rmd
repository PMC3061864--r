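---
title: "Models and numerical methods in photokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in photokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photokin)
```

This vignette is the package's account of the science it implements:
the kinetic and photoselection models, the assumptions behind them, the
numerical choices, and the places where the design was genuinely open.

# Global analysis of time-resolved data

## The model

A time-resolved experiment yields a matrix $D$ (delay times $\times$
detection channels). The working assumption of global analysis is that
$D$ is a *time-independent linear combination of a few time-dependent
populations*:
$$D(t, \lambda) \approx \sum_i c_i(t)\, A_i(\lambda) + c_0(\lambda),$$
with the populations $c_i(t)$ generated by a connectivity scheme of
first-order reactions, $\dot c = K c$, and the amplitudes
$A_i(\lambda)$ (the species- or decay-associated spectra) plus an
optional baseline $c_0$ free per channel. This assumption fails when a
spectral feature itself drifts in time (e.g. vibrational cooling
shifting a band); such data need explicit time-dependent line-shape
modelling, which is out of scope here.

Rate constants are shared across all channels; amplitudes are not. The
choice between a parallel and a sequential (or any target) scheme of
the same number of components changes only the spectra, never the
fitted rate constants or the residual — the schemes span the same
exponential space. `model_comparison()` exploits the converse: if a
parallel fit shows *compensating amplitudes* (two spectra that mirror
each other with opposite sign at the same channels), the parallel
interpretation is likely wrong. Compensation is detected by the
uncentred cosine similarity of two spectra rows dropping below $-0.5$
(pairs with a norm ratio under $0.1$ are ignored as negligible).
Centred correlation is deliberately *not* used: two non-overlapping
positive bands are anticorrelated after centring but do not compensate.

## Variable projection

The exponential model is separable: for fixed rates the optimal
spectra are a linear least-squares problem. The fitter therefore
optimises only the nonlinear parameters (log rate constants, optionally
IRF centre/width and chirp coefficients); at each evaluation the
spectra and offsets are eliminated exactly via QR factorisation
(`project_linear()`). Rates are fitted in log space, which enforces
positivity and evens out the conditioning between fast and slow
components. A rate fixed at exactly zero encodes a non-decaying
("Infinite") component and is not fitted.

One identifiability trap is built into the interface as a warning: a
scheme with a non-decaying species *and* a free per-channel offset has
an exactly rank-deficient design (the terminal concentration profile is
a linear combination of the other profiles and the constant), so the
spectra are returned as a minimum-norm solution and flagged. Rates and
the residual are unaffected. The package's own benchmark analyses
disable the offset for this reason.

Two engines are provided. The gradient engine is Levenberg–Marquardt
least squares (`minpack.lm::nls.lm`, convergence at relative SS or step
change below $10^{-10}$). The derivative-free pattern search polls
$\pm$ one mesh step per coordinate, expanding the mesh by 2 on success
and contracting by 0.5 on failure, starting at 25% of each bounded
parameter range (unbounded directions are capped at $\pm 6$ log-units
around the start for mesh sizing) and stopping when the mesh falls
below $10^{-6}$. Pattern search is slower but insensitive to local
gradients; the suite cross-checks that both engines reach the same
optimum on a single-exponential problem.

Standard errors are the linearised (Gauss–Newton) covariance
$(J^\top J)^{-1}\,\mathrm{SS}/\mathrm{dof}$ at the optimum, with $J$
the Jacobian of the projected residual with respect to the nonlinear
parameters only, mapped from log-rate to rate and lifetime scale by the
delta method. These errors assume independent residuals; under
correlated (structured) noise they undercover, which is why the
benchmark's noisy-recovery checks use the SVD-trace fit (below), whose
residuals carry the actual per-trace noise.

## Kinetics solver

`solve_concentrations()` solves $\dot c = K c$ by eigendecomposition
(the matrix exponential in closed form), which is exact and fast for
the small, diagonalisable $K$ of typical schemes. When eigenvalues
collide within $10^{-12}$ relative (equal-rate chains) or the
eigenvector basis is ill-conditioned, it falls back to a stiff
integrator (`deSolve::lsoda`) at the requested tolerance — default
$10^{-6}$, user-raisable to $10^{-12}$. Closed schemes (every sink an
explicit species) conserve total concentration to within
$10\times$ tolerance; that invariant is tested.

## IRF and chirp

A Gaussian IRF of FWHM $\Delta$
($\sigma = \Delta / (2\sqrt{2\ln 2})$) convolved with a decay mode
$e^{-kt}$ has the analytic form
$$c(t) = e^{-k(t-\mu) + k^2\sigma^2/2}\,
  \Phi\!\left(\tfrac{t-\mu}{\sigma} - k\sigma\right).$$
The naive product overflows for large $k\sigma$; on the rising side the
implementation evaluates the equivalent
$\tfrac12 e^{-u^2/2}\,\mathrm{erfcx}(z)$ with $u = (t-\mu)/\sigma$,
$z = (k\sigma - u)/\sqrt2$, where $\mathrm{erfcx}$ is computed through
the log-scale normal tail so that the form is stable for arbitrary
$k\sigma$ (verified in tests up to $k\sigma \sim 4000$).

Chirp — the wavelength dependence of time zero — is the polynomial
$\mu(\lambda) = t_0 + \sum_j a_j (\lambda - \lambda_c)^j$. The
wavelength offset is kept in the data's native channel units,
unnormalised; $\lambda_c$ defaults to the midpoint of the channel axis.
This convention is applied identically in simulation, estimation and
fitting, so coefficients round-trip. Estimation measures a per-channel
delay as the time of maximum absolute gradient of the
cross-correlation between the channel signal and a discrete unit step
(ties broken towards the earliest time), refines it by three-point
parabolic interpolation, and least-squares fits the polynomial; with
order 0 the single $t_0$ is the median onset, which is robust to a few
outlier channels. Because the gradient of that cross-correlation is the
signal itself, the estimator locates the signal *extremum*: it is
accurate to a fraction of a grid step when the response is IRF-limited
(the coherent-artifact configuration used for chirp calibration in
practice, and the default of `make_chirped_irf_dataset()`), and biased
by a kinetics-dependent constant for slow responses — a constant that
the fitted $t_0$ absorbs.

## SVD utilities

`significant_rank()` encodes the scree inspection habit as a ratio
heuristic: the rank is the position of the *last* gap
$s_r / s_{r+1} \ge$ `gap_factor` (default 10), so everything beyond it
continues a gap-free noise trend; if no such gap exists the result is 0
with a `no_gap` flag (pure noise). The default factor is conservative
on noisy data — at 10% noise the third benchmark singular value sits
about 3-fold above the noise tail, below the 10-fold default — which is
intentional: the heuristic should under-claim, and the CLI always
prints the scree for visual confirmation. Singular-vector signs carry
no physics; the convention (largest-magnitude element of each right
vector positive) only makes results deterministic.

Fitting the first $n$ left singular vectors (optionally scaled by
their singular values) condenses the data to a few noise-filtered
traces. Weighted and unweighted traces give identical rates — the
scaling is absorbed by the linear amplitudes — but the weighted form
better conditions the optimisation. Basis amplitudes from trace fits
have no enforced physical meaning.

# The synthetic benchmark

`make_benchmark()` generates the canonical test experiment: a
three-species sequential scheme with lifetimes 1.87 s and 34.8 s
feeding a long-lived product, 91 logarithmically spaced delays
(0.01–300 s; the grid's lower edge is the package's choice, placed one
decade below the fastest lifetime) and 100 channels. The basis spectra
are sums of one or two Gaussian bands with partial overlap near the
middle of the channel axis — chosen once so that a wrong (parallel)
model exhibits compensating amplitudes there; the exact band
parameters are recorded in `benchmark_spectra()` and tests depend only
on rank and recovery properties, not on the shapes.

Concentration profiles are computed by the exact matrix-exponential
path, so the noiseless matrix is numerically rank 3 (fourth singular
value at the floating-point floor, far below the $10^{-8}$ mark).
With noise, each component contributes
$(c_i(t) + \varepsilon_i(t))\,(S_i(\lambda) + \eta_i(t, \lambda))$:
Gaussian white noise at 10% of the profile maximum on each
concentration profile, and at 10% of the basis-spectrum maximum on the
spectrum, drawn fresh at every time point. The fresh-per-time draw is
deliberate: a single noisy-spectrum realisation would keep the matrix
at rank 3, with no noise floor in the singular spectrum, which is not
how a detector behaves. What this generator does *not* emulate:
correlated detector noise, baseline drift, or the pointing "jumps" of
real spectrometers — passing tests therefore demonstrate correctness
of the estimators under white noise, not robustness to systematic
artefacts.

Under these conditions the marginal sum-of-squares gain of a fourth
component in the 3-trace fits is of order 1% (pure over-fitting of
trace noise). How small that number comes out depends directly on the
noise bookkeeping of the generator — more or less trace noise moves it
— so it should be read as "minor compared to the >2-fold gain of the
third component", not as a universal constant.

# Photoselection and finite bleach

## Single pulse

All orientation integrals assume an isotropic sample, a linearly
polarised pump, and no rotational diffusion on the experiment's
timescale. With $p = \cos\theta$ the cosine of the angle between pump
polarisation and optical transition dipole, a pulse of dimensionless
excitation strength $x = I\sigma\Phi$ (photon flux density
[photons/cm²] × absorption cross-section [cm²/molecule] × quantum
yield) photolyses
$$f(p) = 1 - e^{-3xp^2}$$
of the molecules at that orientation; the factor 3 normalises the
orientational average of the weight to unity. A circular (degenerate
in-plane) absorber has $f = 1 - e^{-(3/2)x(1-p^2)}$ and, unlike the
linear case, bleaches even at $p = 0$. Ensemble averages integrate
uniformly over $p \in [0, 1]$.

The optical anisotropy of the photoselected ensemble,
$$r_\mathrm{opt}(x) = \frac{\langle f\,P_2(p)\rangle}{\langle f\rangle},$$
is 0.4 at vanishing power and decreases as intense pulses saturate the
favourable orientations. Its low-power series, obtained by Cauchy
division of the two averages, is
$r_\mathrm{opt} = 0.4\,(1 - \tfrac{27}{70}x + \tfrac{57}{700}x^2 - \dots)$.
The measured anisotropy of a probed dipole at angle $\beta$ to the
excited dipole is $r = r_\mathrm{opt}\,P_2(\cos\beta)$;
`extract_dipole_angle()` inverts this, returning the principal angle in
[0°, 90°] (the $\cos^2$ degeneracy makes $\beta$ and $180°-\beta$
indistinguishable) and refusing ratios outside the $P_2$ range, which
signal missing power or geometry corrections.

*Numerical choices.* Scalar ensemble averages use adaptive quadrature
(`stats::integrate`, relative tolerance $10^{-12}$). The `taylor`
method expands each saturating exponential as a truncated polynomial in
$p^2$ and integrates termwise against
$\int_0^1 p^{2m}\,dp = 1/(2m+1)$ and
$\int_0^1 p^{2m} P_2(p)\,dp = 2m/((2m+3)(2m+1))$. The default
truncation order 8 keeps Taylor/quadrature agreement well below
$10^{-6}$ for $x \le 0.1$; a 3-term anisotropy series (order 2) is the
classic low-power approximation but already deviates by
$\sim 6\times10^{-6}$ at $x = 0.1$ (its cubic coefficient is
$\approx 0.014 \times 0.4$), which is why the default order is higher.
Beyond $x = 1$ the Taylor path warns and falls back to quadrature.
Below $x = 10^{-9}$ the quadrature ratio is replaced by the series
limit to avoid 0/0 cancellation.

## Beams, depth, and units

Geometric inputs are SI (J, m); cross-sections are cm²/molecule and
fluxes photons/cm², the units the quantity $x$ is quoted in, with the
conversion internal. A top-hat beam of diameter $D$ has flux
$E\lambda/(hc) / (\pi D^2/4)$; the equal-energy Gaussian beam of FWHM
$= D$ has peak flux $\ln 2$ times that (equality of the 2-D intensity
integrals), and `beam_profile_fraction()` evaluates the local
photolysis along the radial profile. The transcription-sensitive
numeric factors (3, 3/2, $\ln 2$) live in one internal constants table,
so a correction would propagate everywhere at once.

When pump and probe are both Gaussian with FWHM ratio $R$, their
product is again Gaussian and the probe effectively samples a reduced
excitation; the correction factor is the product-profile width relative
to the probe width, $R/\sqrt{1+R^2}$ (0.71, 0.89, 0.95 at $R$ = 1, 2,
3), monotonically approaching 1 for a pump much wider than the probe.

Optically thick samples attenuate decadically,
$x(z) = x_0\,10^{-A z / d}$; `depth_average_anisotropy()` averages the
per-layer optical anisotropy uniformly over layer midpoints (an
unweighted depth average; weighting by the probed signal would require
probe-geometry assumptions the model does not make). The default 200
uniform layers agree with a $10^4$-layer computation to better than
$10^{-6}$ for $A \le 2$; `sample_geometry(n_layers =)` raises it.

## Multiple pulses

For a pump-dump(-probe) sequence the second pulse meets a ground state
that is both depleted and orientationally *non-random*. With recovery
fraction $G \in [0,1]$ (the fraction of initially photolysed molecules
back in the ground state at the inter-pulse delay), the ground state
available at orientation $p$ is $1 - (1-G) f_1(p)$, the pulse-II
photolysed fraction is that times $f_2(p)$, and the total excited
population adds the still-excited remainder $(1-G) f_1(p)$. Ensemble
quantities are always composed per orientation *first* and averaged
second — averaging first would discard exactly the orientation memory
the theory is about. Two stated identities pin the composition down:
full recovery reduces pulse II to the single-pulse expression, and a
zero-delay equal-power double pulse equals one pulse at doubled power.
Validity limits: no rotational diffusion between pulses, and pulse II
not resonant with higher excited states.

The pure-intermediate extraction assumes the pump-dump-probe surface
decomposes linearly,
$S_\mathrm{pdp} = S_\mathrm{pp} + g\,S_\mathrm{dp} + \varphi\,S_\mathrm{int}$,
with $g$ the ensemble ground fraction available to the dump (scaling
the fresh-sample dump-probe response) and $\varphi$ the
doubly-interacting (pumped-then-dumped) fraction. The synthetic
generator plants exactly this structure, so the extraction inverts it
to machine precision; on real data the decomposition is the modelling
assumption the user buys into.

# Known limitations

* Only first-order (linear) kinetics; no second-order or explicitly
  time-dependent rate laws, and no simultaneous fitting of several
  experiments.
* The IRF is Gaussian; coherent artefacts around time zero are not
  modelled.
* Anisotropy expressions ignore rotational diffusion; degenerate
  transitions are covered only by the closed-form
  $r(\alpha) = 0.1 - 0.3\sin^2\alpha$ limit curve.
* Linearised standard errors undercover when the residual noise is
  strongly correlated, as the benchmark's own noisy tests illustrate;
  trace-fit errors are the more honest quote there.

# Problem sizes used in the test-suite

The shipped tests run the full benchmark (91 × 100), 25-seed noisy
repeats of the 3-trace fits, quadrature/Taylor sweeps, and a
$10^4$-layer depth-averaging cross-check; the complete suite runs in
well under a minute on a single core, and the reproduction script
(`scripts/acceptance.R`) in a few seconds.
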