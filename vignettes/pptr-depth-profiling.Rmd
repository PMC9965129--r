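---
title: "Depth profiling of bruises by pulsed photothermal radiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth profiling of bruises by pulsed photothermal radiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(pptrbruise)
library(dplyr)
```

## The measurement and its model

Pulsed photothermal radiometry (PPTR) probes the depth distribution of
absorbing structures in skin. A millisecond laser pulse (532 nm from a KTP
laser, or 1064 nm from an Nd:YAG laser) deposits heat wherever chromophores
— melanin, hemoglobin, water — absorb it, producing an initial temperature
rise $\Delta T(z, 0)$ versus depth $z$. The heat then diffuses, and a
mid-infrared camera records the transient change in surface emission
$\Delta S(t)$. The link between the two is linear:

$$\Delta S(t) = \int_0^\infty K(z, t)\, \Delta T(z, 0)\, dz,$$

where the kernel $K(z,t)$ combines three ingredients, each a package
parameter with a physical unit:

* thermal diffusivity of skin $D = 0.11\ \mathrm{mm^2/s}$
  (`diffusivity`) — sets how fast buried heat reaches the surface;
* reduced heat transfer coefficient $h = 0.02\ \mathrm{mm^{-1}}$
  (`heat_loss`) — the Robin boundary condition
  $\partial T/\partial z|_{z=0} = h\,T(0,t)$ describing convective loss to
  the air ($h = H/k$ in classical notation);
* effective mid-IR absorption $\mu = 22.3\ \mathrm{mm^{-1}}$
  (`ir_absorption`) — how deep below the surface the camera still "sees"
  tissue emission in its detection band.

`thermal_parameters()` carries these defaults. The package fixes the kernel
by its defining integral over the half-space Green's function with the
Robin boundary,

$$K(z,t) = \mu \int_0^\infty e^{-\mu z'}\, G(z', t \mid z)\, dz',$$

for which we derived a closed form in scaled complementary error functions
(`kernel_value()`). Three independent routes validate it in the test suite:
adaptive quadrature of the defining integral (agreement to $10^{-8}$
relative), an explicit finite-difference solution of the boundary-value
problem (to 0.5%), and physical invariants — with an insulated surface
($h = 0$) the kernel integrates to exactly 1 over depth at every time, and
as $t \to 0^+$ it collapses to the emission weight $\mu e^{-\mu z}$. The
approach to that short-time limit is $O(\mu\sqrt{Dt})$, i.e. the surface
value at $t = 10^{-6}\,$s still sits about 0.7% below $\mu$; the depth-decay
*rate*, however, equals $\mu$ to high accuracy already at that time, which
is what the acceptance script refits.

Discretized on a cell-centered depth grid ($z_j = (j + \tfrac12)\Delta z$,
400 cells by default) and a uniform 1000 frames-per-second time grid, the
model becomes $S = KT$ with $K_{ij} = K(z_j, t_i)\Delta z$
(`build_kernel_matrix()`, `forward_project()`). The 5 ms pulse is treated
as instantaneous: it is short compared with the 1 ms frame interval and
with heat diffusion across one reconstruction cell, so no pulse-shape
convolution is applied. The first sample sits one frame after the pulse,
avoiding the $t = 0$ kernel singularity. Default acquisitions follow the
two probe wavelengths: 3 s over 2.0 mm for 532 nm, 5 s over 3.0 mm for the
deeper-penetrating 1064 nm (`wavelength_defaults()`).

## The inverse problem

Reconstructing $T$ from $S$ is severely ill-posed: $K$ is a smoothing
operator of numerically defective rank, and camera noise is amplified
without regularization. The package implements the **projected
$\nu$-method** (`projected_nu_method()`, `reconstruct_profile()`): a
semi-iterative accelerated-Landweber scheme whose iteration count is the
regularization parameter, with the physically required non-negativity
imposed by clipping after each full iteration. The operator is pre-scaled
by $1.05\,\hat\sigma_{\max}$ (power iteration with a deterministic all-ones
start, `estimate_operator_norm()`) so the recursion is a contraction; the
5% margin guards against power-iteration underestimates. The solver is
deterministic: identical inputs give bit-identical results.

Choices the method leaves open, and what this package does:

* **Order $\nu = 1$** (default, exposed as an option): the standard choice
  in the semi-iterative regularization literature; higher orders accelerate
  further but roughen the semi-convergence minimum.
* **Initialization $x^0 = 0$**: zero is the natural prior for a temperature
  *change*.
* **Projection placement**: after every full iteration, not inside the
  momentum terms — the conventional "projected" variant, which keeps all
  iterates feasible.
* **Stopping**: by default the discrepancy principle
  $\|S - KT\| \le \tau \sqrt{n}\,\sigma_{noise}$ with $\tau = 1.2$; when no
  noise estimate is supplied, $\sigma_{noise}$ is taken as
  $\mathrm{mad}(\mathrm{diff}(S))/\sqrt 2$, which sees frame-to-frame
  camera noise but not the smooth transient. A fixed iteration budget is
  available for reproducibility, and the iteration count, residual history
  and stopping state are recorded in the returned `pptr_fit`.

`nnls_profile()` wraps a Lawson–Hanson active-set solver as an independent
reference for the same minimization; on small well-conditioned systems the
$\nu$-method must agree with it to $10^{-3}$ relative (it does, see the
tests), while on the full ill-posed problem unregularized NNLS is
noise-dominated and serves only as a contrast.

**Matched truncation for ratio statistics.** The bruise statistic
$\varepsilon$ (below) ratios integrals of two reconstructions. Early
stopping leaves a small truncation bias in each integral; the bias cancels
in the ratio only if both reconstructions are stopped at the *same*
iteration. A per-signal discrepancy stop fires at different counts on
bruised and healthy signals and leaves a site-dependent deficit, so
`reconstruct_study()` defaults to fixed per-wavelength budgets — 100
iterations at 532 nm, 600 at 1064 nm, whose signal encodes slower deep-heat
information — calibrated once on synthetic studies with known ground truth.
The discrepancy rule remains the default for single-profile work.

## Profile summaries

* `integral_under_curve()` — trapezoidal integral (IUC) of the profile over
  the full reconstruction range of the wavelength's grid, a proxy for the
  absorbed laser energy. The integration range is kept identical for
  bruised and healthy profiles, which is what matters for the ratio; the
  depth limit itself is a convention.
* `epsilon_ratio()` —
  $\varepsilon = \mathrm{IUC}_{bruise}/\mathrm{IUC}_{healthy} - 1$, the
  relative excess absorption at the bruised site.
* `epsilon_series()` — per-session $\varepsilon$ from repeat measurements,
  as a ratio of mean IUCs (the alternative, a mean of per-repeat ratios, is
  more variance-prone for small repeat counts); `epsilon_sd` comes from
  first-order error propagation of the repeat-IUC standard errors.
* `find_profile_peaks()` — local maxima filtered by topographic prominence
  (default 5% of the profile maximum, enough to reject reconstruction
  ripple while keeping the narrow epidermal peak), with parabolic depth
  refinement.
* `pool_depths()` — the dermal blood-pool depth as the windowed argmax
  below 0.15 mm depth; a prominence filter is fragile for the broad, low
  1064 nm pool feature riding on the epidermal tail, a plain argmax is not.

## The synthetic study generator

No in vivo data accompany the package, so `simulate_bruise_study()`
generates the complete study a measurement campaign would produce:
per-session bruised/healthy ground-truth profiles, forward-projected
signals, camera noise, and 3–5 repeats per site per session (the repeat
count drawn deterministically from the seed). Sessions default to
$\{24, 48, 96, 144, 192, 288\}$ h — daily at first, sparser as the bruise
heals.

Profiles are Gaussian mixtures, not light-transport simulations: the
reconstruction target is $\Delta T(z,0)$ itself, and mixtures reproduce the
reported peak structure with few parameters. The bruised site combines

* an epidermal melanin peak (0.06 mm deep, 0.03 mm SD, 0.6 K);
* a dermal blood pool whose center migrates linearly from 0.55 mm to
  0.30 mm over 168 h (hemoglobin diffusing toward the epidermal–dermal
  junction), with amplitude
  $A_b(\tau) = 0.3\,(1 - e^{-\tau/24\,\mathrm{h}})\,
  e^{-\max(0, \tau - 168\,\mathrm{h})/120\,\mathrm{h}}$ K — rising as blood
  extravasates, decaying as the bruise resolves;
* for 532 nm, a narrow pool width (0.15 mm SD) and an overall
  $e^{-z/0.35\,\mathrm{mm}}$ attenuation (green light only probes the
  superficial dermis); for 1064 nm, a broad pool (0.6 mm SD) extending
  beyond 2 mm, plus an optional wide swelling term at 1.5 mm decaying with
  a 72 h constant (edema, strongest right after injury).

The healthy reference adds a papillary-dermis vascular peak at 0.25 mm
(15% of the epidermal amplitude) and, for 1064 nm, a deep blood-net peak at
1.2 mm (25%). Camera noise is additive i.i.d. Gaussian per frame, 5 mK SD
by default — the minimal model consistent with frame-averaged photon noise
from a cooled mid-IR camera. One RNG stream per study with per-session
counter-offset substreams means adding a session never perturbs earlier
ones.

With these defaults the ground-truth 532 nm contrast trajectory spans
roughly 0.19–0.79 with its maximum at 144 h — i.e. tens of percent peaking
between days 3 and 6 — and the swelling variant pushes the first-session
1064 nm contrast to roughly 250%, far above the 532 nm value at the same
session. These were chosen once as emulation anchors of the reported
phenomenology. Two caveats: the generator does not emulate the several-K
temperature rise of a severe hematoma simultaneously with its contrast
ratio (a single Gaussian-mixture model with this healthy reference cannot
produce both, and the contrast phenomenology is what the pipeline is tested
on); and passing tests on this generator demonstrates correct inversion
and statistics on plausible profile shapes — not performance on real skin,
which adds lateral heterogeneity, calibration error, motion, and optical
properties that vary between subjects.

## Numerical choices

* The closed-form kernel evaluates every $e^{a}\,\mathrm{erfc}(b)$ product
  through the scaled complementary error function
  $\mathrm{erfcx}(b) = e^{b^2}\mathrm{erfc}(b)$, so nothing overflows even
  for $\mu^2 D t \gg 700$; `erfcx` itself uses the direct product below
  $x = 4$ and a 40-level continued fraction above, accurate to machine
  precision (validated in the tests against `erfc` identities and the
  asymptotic series).
* The defining-integral quadrature truncates the semi-infinite integral at
  $z' = z + 12/\mu + 6\sqrt{Dt}$, where both the emission weight and the
  Gaussian tail are below $10^{-8}$.
* Degenerate $\mu = h$ in the closed form is handled by the first-order
  limit of the bracketed erfcx difference.
* Power iteration uses a fixed all-ones start and a $10^{-6}$ relative
  tolerance; the zero matrix returns norm 0 and scaling fails loudly.
* Peak refinement clamps the parabolic vertex shift to half a cell — a
  flat-topped maximum makes the vertex formula ill-conditioned, but the
  true maximum still lies within the cell.
* Ties and plateaus: peak detection requires strict local maxima; flat
  profiles yield no peaks rather than arbitrary ones.

## Problem sizes

Full-resolution objects are used where the defaults matter: kernel shape
checks and the acceptance study run with 400 depth cells and 3000/5000
frames (the study reconstructs ~100 repeat signals in a few minutes on one
core). Unit tests of the solver and pipeline use scaled-down grids
(60–200 cells, 200 fps, shorter acquisitions) chosen so each property is
still exercised far from degeneracy.

## Known limitations

* One-dimensional heat flow only; the sufficiently-wide-beam (laterally
  homogeneous) approximation is assumed, and no frame-stack processing
  (sub-window averaging, hot-spot avoidance) is included — the package
  ingests already-averaged 1-D transients.
* The effective $\mu$ is a single band-averaged number; no spectral
  integration over the detection band.
* Each wavelength is inverted independently; no joint multi-wavelength
  regularization.
* $\varepsilon$ dispersion assumes independent repeats; drift within a
  session is not modeled.
* Axial resolution of any PPTR reconstruction degrades with depth; the
  package's recovery tolerances (±0.05 mm shallow, ±0.15 mm at 0.5 mm for
  532 nm, ±0.4 mm for the deep 1064 nm pool) reflect that, and nothing
  finer should be expected of the method.

## A worked example

```{r example, eval = FALSE}
k <- build_kernel_matrix(depth_grid(400L, 2.0), time_grid(3.0))
truth <- bruise_profile(bruise_model(), 532, 72, k$depth_grid)
sig <- average_signals(
  simulate_measurement(truth, k, noise_sd = 0.005, n_repeats = 5, seed = 1))
fit <- reconstruct_profile(sig, k, stop_rule = "fixed_iterations",
                           max_iterations = 100)
glance(fit)
find_profile_peaks(fit$profile)
autoplot(fit)
```
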