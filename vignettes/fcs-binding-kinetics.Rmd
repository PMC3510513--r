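---
title: "Models and methods: FCS binding and catalysis kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: FCS binding and catalysis kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcskinetics)
```

# The measurement problem

An RNA-guided pseudouridine synthase (an H/ACA ribonucleoprotein, RNP) binds
a short fluorescently labelled RNA substrate, isomerises the target uridine
to pseudouridine on the enzyme, and releases the modified product.
Fluorescence correlation spectroscopy (FCS) distinguishes free from
RNP-bound RNA by diffusion speed: a ~5 kDa free RNA diffuses through the
confocal volume roughly twice as fast as a ~100 kDa complex. Every analysis
in this package starts from the same primary observable, the fraction *p* of
labelled RNA that is enzyme-bound, read out from an autocorrelation curve.

The package provides four layers, each independently testable:

1. an autocorrelation mixture model and its fitting (`acf_mixture()`,
   `calibrate_reference()`, `fit_bound_fraction()`);
2. elementary kinetic and thermodynamic fits on *p* time series
   (`fit_association()`, `fit_kobs_line()`, `fit_dissociation()`,
   `fit_titration()`, `fit_single_turnover()`);
3. the coupled dissociation–catalysis–release analysis for slowly reacting
   complexes (`global_double_exp_fit()`, `kcat_from_amplitudes()`,
   `disentangle_rates()`), with exact forward models as oracles
   (`dilution_response()`, `simulate_linear_scheme()`);
4. seeded synthetic-data generators with known ground truth
   (`make_acf_curve()`, `make_association_experiment()`,
   `make_coupled_experiment()`, `make_titration()`).

# The autocorrelation mixture model

For a mixture of free (subscript 1) and bound (subscript 2) species with
equal molecular brightness,

$$G(t) = \frac{1}{N}\Big[(1-p)\,X_1(t)\,D_1(t) + p\,X_2(t)\,D_2(t)\Big],
\qquad
X_i(t) = 1 + K_i e^{-t/\tau_{Ti}},\qquad
D_i(t) = \frac{1}{(1 + t/\tau_{Di})\sqrt{1 + t/(\kappa^2\tau_{Di})}}.$$

*N* is the mean number of labelled molecules in the confocal volume,
$\tau_{Di}$ the characteristic 3-D diffusion times, and $(K_i, \tau_{Ti})$ a
fast photophysical (dark-state) relaxation of the dye.

Choices made where the experimental description is open:

* **3-D diffusion with fixed structure parameter.** The focal-volume
  axial-to-lateral ratio $\kappa$ is not identifiable from a single curve;
  we fix $\kappa = 5$ (a typical confocal value, configurable). Because the
  references and the mixture share $\kappa$, the extracted *p* is
  insensitive to its exact value.
* **Unnormalised photophysics factor** $1 + K e^{-t/\tau_T}$, treating *K*
  as an equilibrium amplitude; this is the natural reading when the
  dark-state process is described by an equilibrium constant.
* **Equal brightness** of free and bound species (one dye per RNA), so the
  mixture weights are molecular fractions.

Calibration follows the two-step protocol used at the bench: the species
parameters are first fit on pure references (*p* fixed at 0 or 1), then
frozen, leaving only *(N, p)* adjustable for mixed samples, with *p*
constrained to $[0,1]$. Fits are weighted by $1/\sigma^2$ when per-lag
errors are available, and multistarted from 8 log-spaced $\tau_D$ values;
the lowest SSR wins, ties broken by fewest iterations.

Synthetic curves use a quasi-logarithmic multi-tau lag grid (1 µs–1 s,
14 linearly spaced points per octave, ~280 lags), mirroring hardware
correlators.

**Identifiability limitation.** The precision of *p* collapses as the two
diffusion times approach each other. With the default grid and 2%
independent multiplicative noise, the standard error of *p* scales
empirically as $\approx 0.002/(\tau_{D2}/\tau_{D1} - 1)$: about 0.01 at the
realistic ratio 0.47/0.21, 0.04 at ratio 1.05, and above 0.1 only once the
ratio falls to ~1.02. Real correlator noise is correlated across lags, so
identifiability on real data is worse than this iid idealisation; the test
suite demonstrates the monotone degradation and the near-degenerate case.

# Elementary binding kinetics and thermodynamics

**Association.** After mixing enzyme (at $C_E \gg C_S$) with labelled RNA,
$p(t) = p_{eq}(1 - e^{-k_{obs}t})$ with
$k_{obs} = k_{on}C_E + k_{off}$. `simulate_association()` integrates the
full second-order ODE (no pseudo-first-order shortcut) and serves as the
oracle showing the exponential form is adequate at enzyme excess; fitted
$k_{obs}$ values are regressed on $C_E$ (`fit_kobs_line()`, weighted when
per-point SDs exist). The slope is $k_{on}$; the intercept is reported but
flagged low-confidence — an off-rate is measured by dilution, not by
extrapolation to zero enzyme. The association model admits a fixed nonzero
baseline $p(0)$; the default is 0 because mixing starts unbound.

**Dissociation.** A pre-formed complex is diluted ~4000-fold and the decay
is fit as $p(t) = p(0)e^{-k_{off}t}$. Normalisation by $p(0)$ is applied
only for display, never before fitting.

**Equilibrium titration.** Because the labelled RNA concentration (10 nM)
is not negligible against the tightest $K_d$ (~31 nM), the exact quadratic
(tight-binding) isotherm is used:

$$p = \frac{(C_S + C_E + K_d) - \sqrt{(C_S + C_E + K_d)^2 - 4C_SC_E}}{2C_S}.$$

The fit has one parameter ($K_d$; optionally a free saturation amplitude,
off by default). Initialisation interpolates the concentration at
half-saturation; every run records whether the SSR at the solution is below
the SSR at $2K_d$ and $K_d/2$. The quadratic and the ligand-excess
hyperbolic fit differ by ~5% at $C_S = 0.1K_d$ and converge linearly as
$C_S/K_d \to 0$ (measured in the tests).

**Rate initialisation.** Exponential-rate starts come from log-linear
regression of the appropriate tail/early fraction of the curve, then
three-fold bracketing multistarts; convergence tolerance is $10^{-12}$ on
the relative SSR change.

# The coupled dissociation–catalysis–release analysis

For a slowly reacting substrate–enzyme complex, a dilution chase monitors
three concurrent processes:

$$\mathrm{S + E} \xleftarrow{k_{off,S}} \mathrm{ES}
  \xrightarrow{k_{cat}} \mathrm{EP} \xrightarrow{k_{off,P}} \mathrm{E + P}$$

After strong dilution re-association is negligible (the simulator retains a
flag to switch it back on and check this at the ~0.5 nM post-dilution
concentrations), so the bound fraction obeys a linear ODE system with the
exact solution

$$p(t) = f_{S0}\Big(1 + \tfrac{k_{cat}}{\Delta}\Big)e^{-(k_{cat}+k_{off,S})t}
 + \Big(f_{P0} - \tfrac{f_{S0}k_{cat}}{\Delta}\Big)e^{-k_{off,P}t},
 \qquad \Delta = k_{off,P} - k_{cat} - k_{off,S},$$

where $f_{S0}$ and $f_{P0}$ are the bound substrate and product fractions
at the moment of dilution. The decay *rates* are exactly
$k_1 = k_{off,P}$ (fast) and $k_2 = k_{cat} + k_{off,S}$ (slow); only the
*amplitudes* differ from the simple reading $A_2 = f_{S0}$, $A_1 = f_{P0}$
by the conversion-flux cross term $f_{S0}k_{cat}/\Delta$.
`dilution_response()` returns the exact form, the two-term reading, and
their maximum deviation, so the approximation is always auditable; for the
default truth ($k_{cat} = 1.9\times10^{-4} \ll \Delta$) the deviation is
below 2% of $p(0)$. When $k_{off,P} = k_{cat} + k_{off,S}$ (relative
eigenvalue gap $< 10^{-9}$) the confluent $t e^{-kt}$ form is used and
flagged.

**Pre-dilution composition.** During incubation at enzyme excess the
substrate is essentially all bound, so the unmodified fraction is
$e^{-k_{cat}T}$. Accumulated product partitions between free and bound
states by exact mass action; we solve the quadratic against the enzyme
*not occupied by bound substrate* ($C_E - C_S e^{-k_{cat}T}$) rather than
using the $C_E/(C_E + K_d)$ approximation, because the available enzyme
(4–6 µM) is not far above every product $K_d$. Exactness costs nothing and
is validated against a bisection oracle at $10^{-10}$.

**Global fitting.** All chases (incubation times $T$ = 5–293 min by
default) are fit simultaneously to
$p_T(t) = A_1(T)e^{-k_1t} + A_2(T)e^{-k_2t}$ with the two rates shared and
per-curve amplitudes free — matching how such experiments are analysed in
practice, and deliberately *not* fitting the exact three-term model to data
(it is kept as the generator and oracle). Numerical choices: rates are
optimised as logarithms (positive by construction), amplitudes bounded
$[0, 1.2]$ to absorb noise overshoot, 8 deterministic multistarts including
one on the single-exponential manifold ($A_1 \approx 0$) so the nested
limit is always reachable; `k1` is by convention the faster rate. A
converged ratio $k_1/k_2 < 3$ warns about component separation; collapse
($k_1/k_2 < 1.05$) attaches a single-exponential fallback.

**Amplitude analysis.** $A_2(T) = b\,e^{-k_{cat}T}$ and
$A_1(T) = a(1 - e^{-k_{cat}T})$ — the growing component uses the
saturating complement, the physically implied form, with no floating
offset. The two estimates are combined as mean ± SD. Finally
`disentangle_rates()` reports $k_{off,P} = k_1$ and
$k_{off,S} = k_2 - k_{cat}$ with quadrature-propagated uncertainties, and
warns whenever $k_{cat}/(k_1 - k_2) > 0.2$, where the two-exponential
reading becomes unreliable (threshold ours).

**Model comparison.** The single- vs double-exponential choice is made by
an extra-sum-of-squares F test ($F = \frac{(SSR_1-SSR_2)/2}{SSR_2/(n-4)}$,
$\alpha = 0.05$); no specific statistic is prescribed by the experimental
convention, so the standard nested-model test was adopted. Simulations in
the test suite confirm type-I control under a pure single exponential and
>90% detection of the second phase at the 62-min design point.

The two routes to the modification rate — amplitude decay from dissociation
experiments versus the single-turnover activity fit
(`fit_single_turnover()`, $f(t) = 1 - e^{-kt}$, half-time $\ln 2/k$) — are
both implemented and reported side by side; they measure subtly different
things (the activity route conflates loading with chemistry) and the
package takes no side.

# What the synthetic data emulate — and what they do not

Generators are pure functions of (truth, noise spec including seed):
identical inputs give bit-identical output and the caller's RNG state is
untouched. Defaults encode the documented study conditions: substrate at
10 nM with enzyme at 0.125–0.75 µM for association (30 s cadence, 20 min,
from the stated 10–30 min monitoring and 30/60/180 s correlator windows);
2 µM substrate pre-incubated with 6 µM enzyme and diluted 4000-fold for
chases; incubation times {5, 62, 121, 177, 231, 293} min; titrations of
10 nM RNA with 10 nM–10 µM enzyme on 12 log-spaced points. Noise defaults —
σ = 0.02 absolute on bound fractions, 2% multiplicative on ACF amplitudes
(0.03 for titrations) — are engineering choices calibrated qualitatively to
published scatter; true experimental noise magnitudes are not reported, so
recovery tolerances of 10–20% are properties of these defaults, not claims
about the instrument. Noise can push *p* outside $[0,1]$; values are kept
unclipped and all fitters tolerate them.

Not emulated: photon-level statistics, correlated multi-tau noise,
afterpulsing, background, photobleaching, instrument drift, and temperature
dependence (everything is at the single 27 °C condition). Passing recovery
tests therefore demonstrates correctness of the estimators under an
idealised iid noise model, not instrument-level robustness.

Coupled chases are sampled every 30 s for the first 10 min, every 60 s to
1 h, then every 180 s, truncated when the noiseless signal falls below 5%
of $p(0)$ or at 3 h — mirroring how long such a chase is actually recorded.

# Numerical choices, in one place

* ODE integration: `deSolve::lsoda` (stiff-capable), rtol $10^{-10}$,
  atol $10^{-14}$ (in molar for concentration systems); rates in one scheme
  span four orders of magnitude.
* Nonlinear least squares: bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`), ftol/ptol $10^{-12}$, multistart with lowest-SSR
  selection, ties by fewest iterations; standard errors from the local
  curvature with residual-variance scaling (NA when a parameter sits on a
  bound and the curvature is singular).
* The apparent parameter sets never silently reconcile $K_d$ with
  $k_{off}/k_{on}$: measured apparent values may disagree and are stored
  independently.
* Internal units are SI (s, M); `uM()`, `nM()`, `minutes()`, `ms()` convert
  the bench idiom at the interface.
* Problem sizes in the shipped studies — 20 seeded replicates for rate/Kd
  recovery, 50 for diffusion-time recovery, 6 incubation times per coupled
  experiment — are the package's default study designs and complete in a
  few seconds on one core.

# Known limitations

* The bound-fraction standard error grows without bound as the diffusion
  times converge (see above); two-species FCS needs a mass ratio of several
  fold to be quantitative.
* The global double-exponential analysis assumes the two-exponential
  reading of the coupled scheme; the built-in deviation audit and the
  $k_{cat}/(k_1-k_2)$ warning quantify when that assumption frays.
* Titrations with all-low or all-high occupancies are rejected as
  unidentifiable rather than extrapolated.
* The F-test assumes independent Gaussian residuals; with correlated
  real-correlator noise its nominal size is approximate.
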