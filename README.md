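# fcskinetics

Quantitative binding and catalysis kinetics from fluorescence correlation
spectroscopy (FCS), for enzymes that bind, chemically convert, and release
an RNA ligand — the motivating system being an H/ACA ribonucleoprotein
pseudouridine synthase acting on a short labelled substrate RNA.

FCS reads the fraction *p* of labelled RNA bound to the (much larger)
enzyme from the autocorrelation of fluorescence fluctuations. This package
implements the full analysis chain on top of that observable, for
biophysicists who want reproducible, testable fits rather than one-off
spreadsheet curves:

* **Autocorrelation mixture model.** Two-component diffusion with
  photophysics,
  `G(t) = (1/N)[(1−p)X₁(t)D₁(t) + pX₂(t)D₂(t)]`,
  `Xᵢ(t) = 1 + Kᵢe^(−t/τ_Ti)`,
  `Dᵢ(t) = (1 + t/τ_Di)⁻¹(1 + t/(κ²τ_Di))^(−1/2)`;
  two-step calibration (fit references at p = 0 and p = 1, then freeze the
  species parameters and fit only N and p).
* **Elementary fits.** Single-exponential association
  (`p_eq(1 − e^(−k_obs t))`), the linear law `k_obs = k_on[E] + k_off`,
  single-exponential dissociation, the exact quadratic tight-binding
  isotherm for K_d, and single-turnover activity fits.
* **Coupled dissociation–catalysis–release analysis.** For a slowly
  reacting complex (S + E ⇌ ES → EP → E + P), dilution chases collected
  after several incubation times are fit *globally* to a double
  exponential with shared rates; the fast rate is the product off-rate
  k_off,P, the slow rate is k_cat + k_off,S, and fitting the amplitude
  decay across incubation times yields k_cat. Exact closed-form and ODE
  forward models back every fitting step as oracles.
* **Synthetic data.** Seeded generators reproduce every study design
  (association series, titrations, coupled chases, ACF curves) with known
  ground truth, so the entire pipeline is validated by parameter recovery.

## Worked example

Extract a bound fraction from a noisy synthetic autocorrelation curve, then
run the full coupled analysis at the documented ground truth
(k_off,S = 4.5×10⁻⁴, k_cat = 1.9×10⁻⁴, k_off,P = 6.4×10⁻³ s⁻¹):

```r
library(fcskinetics)

sp  <- reference_species()                       # tau_D 0.21 / 0.47 ms
mix <- fcs_mixture(N = 5, p = 0.6, free = sp$free, bound = sp$bound)
curve <- make_acf_curve(mix, noise_spec("multiplicative_gaussian", 0.02, 11))
fit_bound_fraction(curve, sp$free, sp$bound)
#> <fcs_fit> bound-fraction fit (N, p) with fixed species parameters
#>   N          5.00989  (SE 0.00995)
#>   p          0.603017  (SE 0.00307)
#>   SSR 256.959 over 280 points; converged: TRUE (5 iter)

ex  <- make_coupled_experiment(coupled_truth(),
                               noise = noise_spec(sigma = 0.02, seed = 3))
res <- analyze_coupled(ex)
res$global_fit
#> Global double-exponential dissociation fit
#>   k1 (fast) = 0.00669 +/- 0.00018 s^-1
#>   k2 (slow) = 0.0006395 +/- 8.1e-06 s^-1  (ratio 10.5)
#>   6 curves, 286 points, SSR 0.1068
res$rates
#> Rate set (SI units):
#>   koff_S  0.000460427
#>   kcat    0.000179057
#>   koff_P  0.00668994
```

The fitted bound fraction (0.603 ± 0.003) recovers the generating p = 0.6.
In the coupled analysis, the fast shared rate recovers the product
off-rate (6.7 vs 6.4 ×10⁻³ s⁻¹), the amplitude decay across incubation
times gives k_cat = 1.79 vs 1.9 ×10⁻⁴ s⁻¹, and the disentangled substrate
off-rate is 4.6 vs 4.5 ×10⁻⁴ s⁻¹ — all within the noise of a single
simulated experiment.

Named end-to-end studies (generate → fit → truth-vs-estimate report as
JSON/CSV/Markdown) are available via `run_scenario()`, or from a shell via
`inst/scripts/run-scenario.R`:

```r
run_scenario(list(scenario = "coupled", seed = 1, n_seeds = 3,
                  out_dir = "out"))
```

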