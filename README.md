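# pptrbruise

Depth profiling of traumatic bruises from pulsed photothermal radiometry
(PPTR) measurements, in R.

## The problem

A bruise is a blood pool between the dermal and subcutaneous layers that
slowly diffuses toward the surface while being broken down. Its *depth*
evolution is invisible to color photography and reflectance spectroscopy,
which integrate light over many tissue layers. PPTR resolves depth: after a
millisecond laser pulse (532 nm, absorbed superficially by hemoglobin and
melanin, or 1064 nm, penetrating millimeters), a mid-infrared camera records
the transient surface emission ΔS(t) at 1000 frames/s. The transient is
linked to the laser-induced initial temperature-depth profile ΔT(z, 0) by

    ΔS(t) = ∫ K(z, t) ΔT(z, 0) dz,        S = K T  (discretized)

where the kernel K combines 1-D heat diffusion (diffusivity
D = 0.11 mm²/s), convective surface loss (Robin coefficient
h = 0.02 mm⁻¹) and effective mid-IR emission attenuation (μ = 22.3 mm⁻¹).
Recovering T from S is a severely ill-posed inverse problem.

This package is aimed at biomedical-optics researchers working with PPTR
transients. It provides:

* the radiometric kernel in closed form, built from the Robin-boundary
  Green's function of the half-space heat equation
  (`build_kernel_matrix()`, `kernel_value()`, `greens_function()`);
* reconstruction by the **projected ν-method** — a semi-iterative
  regularization with a non-negativity constraint whose iteration count is
  the regularization parameter, stopped by the discrepancy principle or a
  fixed budget (`reconstruct_profile()`), with an NNLS reference solver
  (`nnls_profile()`);
* bruise statistics: trapezoidal integral under the profile (IUC), the
  bruise/healthy contrast ε = IUC_bruise/IUC_healthy − 1, peak detection,
  and ε time series with propagated dispersion (`integral_under_curve()`,
  `epsilon_series()`, `find_profile_peaks()`);
* a synthetic two-wavelength bruise study generator with retained ground
  truth, so the whole pipeline is testable end to end
  (`simulate_bruise_study()`, `run_bruise_study()`);
* tidyverse-native interfaces: tibbles in and out, `tidy()`/`glance()`
  methods, `autoplot()`/`plot_*()` figures, plus CSV/JSON file formats and
  a thin CLI (`inst/cli/pptr.R`).

## Worked example

Simulate one 532 nm bruise measurement three days after injury, reconstruct
the temperature-depth profile, and locate its peaks:

```r
library(pptrbruise)

k     <- build_kernel_matrix(depth_grid(400L, 2.0), time_grid(3.0))
truth <- bruise_profile(bruise_model(), 532, 72, k$depth_grid)
sig   <- average_signals(
  simulate_measurement(truth, k, noise_sd = 0.005, n_repeats = 5, seed = 1))
fit   <- reconstruct_profile(sig, k, stop_rule = "fixed_iterations",
                             max_iterations = 100)
glance(fit)
#> # A tibble: 1 × 7
#>   iterations_run converged final_residual_K noise_level_K    nu scale_used
#>            <int> <lgl>                <dbl>         <dbl> <dbl>      <dbl>
#> 1            100 FALSE                0.123            NA     1       4.28
#> # ℹ 1 more variable: iuc_K_mm <dbl>
find_profile_peaks(fit$profile)
#> # A tibble: 2 × 3
#>   depth_mm amplitude_K prominence_K
#>      <dbl>       <dbl>        <dbl>
#> 1   0.0528      0.397        0.186
#> 2   0.401       0.0949       0.0771
```

This uses the study's fixed 100-iteration budget (the default discrepancy
stop gives a smoother profile suited to integral statistics; the fixed
budget resolves the peak structure — see the vignette on matched
truncation). The two peaks are the epidermal melanin peak in the outermost
100 µm and the dermal blood pool, which at 72 h has migrated to ≈0.4 mm
(ground-truth profile maximum at 0.379 mm); the profile's IUC is the
absorbed-energy proxy that enters ε. A full study — six sessions over twelve days,
both wavelengths, 3–5 noisy repeats per site — runs with
`run_bruise_study(seed = 1)` and returns the reconstructed and ground-truth
ε trajectories.

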