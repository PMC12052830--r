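---
title: "Localization precision of vortex-beam MINFLUX: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localization precision of vortex-beam MINFLUX}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vortexflux)
```

## The measurement being modelled

MINFLUX localizes a single fluorescent emitter by placing the dark center
of a doughnut-shaped excitation beam at a few positions around it — the
targeted coordinate pattern (TCP) — and reading out how the detected photon
counts distribute over those exposures. Because the intensity climbs away
from the vortex singularity, the count imbalance encodes the emitter
position, and it does so using far fewer photons than centroid-based
localization. This package quantifies the attainable precision of that
scheme when the excitation is a Laguerre–Gaussian (LG) vortex of arbitrary
azimuthal order `l`, rather than only the conventional first-order
doughnut.

The chain of models is:

1. **Beam.** An LG mode with azimuthal index `l`, radial index `p`, waist
   `w`. The `p = 0` intensity is `I(r) ∝ (2r²/w²)^{|l|} e^{−2r²/w²}`, zero
   on axis for `|l| ≥ 1` and growing as `r^{2|l|}` near the core; for
   `p > 0` the intensity is the squared modulus of the full LG amplitude
   (one source of truth rather than a second closed form). Intensities are
   normalized to unit peak; all detection probabilities are ratios of
   rates, so every downstream result is invariant to this choice (tested).
   The radial sensitivity `∂λ/∂r = (2λ/r)(|l| − 2r²/w²)` is the analytic
   kernel used for all Fisher-information gradients.
2. **Pattern.** Either the four-point TCP — three exposures equally spaced
   on a circle of *diameter* `L` plus one at the origin — or a `dim × dim`
   raster grid of side `L` (RASTMIN). The four-point geometry with a
   central exposure is what makes the closed-form central bound below exact,
   including its background factor; a four-on-ring variant is available for
   sensitivity analyses. The ring's angular offset (one exposure on +y) does
   not affect central results and is fixed and documented for maps.
3. **Photons.** Exposure rates `λ_k = β Iⁿ(r_e − r_k)` for `n`-photon
   excitation, a uniform background `ξ` per exposure, detection
   probabilities `p_k = (λ_k + ξ)/Σ(λ_j + ξ)`, and multinomial counts
   conditional on the total `N`. The multiphoton exponent is applied to the
   normalized intensity; the background is a detection-side rate and is not
   raised to `n`.

## Signal-to-background conventions

The SBR is total signal over total background across the TCP, referenced to
a centered emitter at an anchor pattern size. For the four-point TCP the
origin exposure carries no signal, which creates a genuine ambiguity in how
a nominal SBR maps to the background level `ξ`:

* `all_exposures` — the literal ratio: `ξ = (Σλ_k / K) / SBR = 3λ₀/(4·SBR)`.
* `signal_exposures` — background referenced to the mean of the three
  signal-carrying exposures: `ξ = λ₀ / SBR`.

Published central-precision figures at fixed `L` are consistent with the
second convention, while minimum-precision-over-`L`, field-of-view and
prior-informed figures are consistent with the first; no single convention
reproduces all of them. Both are therefore first-class model parameters,
`all_exposures` is the package default (it is the literal definition), and
every exported summary records the mode in use. `ξ` is frozen at the anchor
configuration and not re-derived as the emitter moves; holding `ξ` fixed
while the pattern shrinks is exactly what produces the SBR scaling law
`SBR_L = SBR_{L₀}(L/L₀)^{2|l|} e^{−(L²−L₀²)/2w²}` (tested against the
first-principles rate ratio).

## The bound and its closed form

With multinomial counts the Fisher information about the position is
`J = N Σ_k ∇p_k ∇p_kᵀ / p_k`, computed with analytic gradients (chain rule
through the radial sensitivity) and cross-checked against finite
differences to relative 1e-6 in the tests. The scalar bound is
`σ_r = √(Tr J⁻¹ / 2)`. At the center of the four-point TCP this reduces to

σ₀ = L/(2n√(2N)) · s/(|l| − L²/2w²),  s = √((1 + 3/(4·SBR))(1 + 1/SBR)),

where the SBR in `s` is the literal all-exposure ratio of the model at its
own pattern size. The numeric and closed-form routes agree to relative
1e-6 across `l = 1..3` and `L = 20..80 nm`, noiseless and with background.

**Dark-exposure subtlety.** An exposure with exactly zero probability (the
origin exposure, noiseless, emitter exactly at the core) is dropped from
the Fisher sum. For `|l| ≥ 2` its contribution vanishes in the limit, so
the bound is continuous there. For `|l| = 1` the limit of
`|∇p|²/p` is a nonzero constant: the idealized noiseless first-order model
has strictly more information arbitrarily close to the center than the
dropped-term value at the center. The dropped-term convention is the one
the closed form embodies, and any background restores continuity, so the
discontinuity is a property of the noiseless idealization only; a test
documents it rather than hiding it.

## Derived analyses

* **Optimal pattern size.** With background, shrinking `L` eventually
  collapses the SBR and the bound turns back up; the search scans `L` in
  1-nm steps and refines by golden section to 0.01 nm (ties toward smaller
  `L`). Noiseless models correctly report a boundary minimum instead.
* **Effective field of view.** The bound is anisotropic and not radially
  symmetric, so "the circular area where the CRB is below 4 nm" is read
  conservatively: the largest origin-centered circle whose *worst* azimuth
  (64 sampled) stays at or below the threshold, located by radial bisection
  to 0.01 nm. The azimuthal-mean variant is also available and is never
  smaller.
* **Raster grid dimension.** The RASTMIN grid dimension is treated as data.
  Calibrating it against the published minimum-CRB values selects a 4×4
  grid (minimum central bounds 1.956/1.339/0.941 nm for `l = 1..3`,
  matching 1.95/1.34/0.94), which also reproduces the published RASTMIN
  EFOV diameters to 0.03 nm. The published RASTMIN *central* bounds at
  `L = 50` (2.66/1.44/1.00 nm) are not reproduced by any single grid
  dimension in 3..6 — a 3×3 grid matches the `l = 2, 3` values but not
  `l = 1` — and remain an open inconsistency; the package default stays at
  the commonly pictured 5×5, with `dim` exposed everywhere.
* **Van Trees bound.** Prior knowledge (wide-field or confocal pre-scans)
  is modelled as an isotropic normal prior on the position; the bound uses
  `J_B = E_prior[J] + σ_prior⁻² I`. The prior expectation is a tensor
  Gauss–Hermite quadrature. A 50-nm prior spreads mass over hundreds of nm
  while the Fisher map varies on the ~10-nm pattern scale, so low orders
  under-resolve the integrand badly; the default is order 201 per axis with
  one automatic escalation to 301 and a warning if the two disagree beyond
  relative 2e-3. With no photons the bound equals the prior spread exactly,
  and it is monotone non-increasing in `N` (exact, since `E[J] ∝ N`).

## Monte-Carlo simulator

The simulator reproduces the standard verification experiment: a 3×3
emitter array with 5-nm spacing (a DNA-origami-like fixture from
`make_grid_array`), the TCP fixed at the array center, `N = 300` photons
per localization, `L = 50 nm`, SBR 4 under the `signal_exposures`
convention. Each trial draws one multinomial count vector and localizes by
maximum likelihood: a 1-nm coarse grid over the TCP bounding box inflated
1.5× (precomputed log-probabilities make this a single matrix product per
trial), then Nelder–Mead refinement from the best cell, ties to the first
maximum in scan order. No probability floor is applied — a count on a
zero-probability exposure is a `-Inf` likelihood by contract, which cannot
occur under background. Per-trial seeds derive from the master seed by a
counter, so runs are bit-reproducible and trials independent. The reported
figures are the per-emitter `RMSE = √(E|r̂−r|²/2)` (the 1/2 keeps it
commensurate with `σ_r`), their mean (the "average error"), and the overall
RMSE with its ratio to the aggregated CRB.

Default study sizes: 500 trials per emitter for the headline runs (the
Monte-Carlo standard error of an RMSE at 500 trials is ≈ 3%, and of the
9-emitter average ≈ 1%); 2000 trials reproduce the published setting when
wanted. With the TCP fixed at the origin the array-average bound exceeds
the central bound by ~5% for `l = 1` (the corner emitters sit on the rising
flank of the precision map), and the simulated average errors
(≈ 1.43/0.78/1.51 nm for four-point `l = 1, 2` and raster `l = 1`) track
those array-average bounds to within ~3%. The alternative protocol —
re-centering the TCP on each emitter — would reproduce the central bound
instead; published figures appear to mix the two readings, and the fixed
TCP is the documented choice here.

## What the generator does and does not emulate

The synthetic experiment captures photon shot noise (multinomial
partitioning at fixed `N`), uniform background, and arbitrary emitter
placement. It does not model blinking or bleaching kinetics, detector dead
time or afterpulsing, non-uniform background, drift or aberrations, or
iterative TCP re-centering. Passing tests therefore demonstrate estimator
efficiency and the correctness of the information-theoretic machinery under
the stated noise model, not instrument-level performance.

## Numerical choices

* Associated Laguerre polynomials by the stable three-term recurrence
  (vectorized; no installed package provides the associated form).
* Peak normalization constants in closed form for `p = 0`, by a dense scan
  plus golden-section polish for `p > 0`.
* Finite-difference oracles in the tests use central differences with
  `h = 1e-4·w` (beam derivatives) and `h = 1e-4 nm` (probability
  gradients), balancing truncation against round-off at double precision.
* Singular Fisher matrices (reciprocal condition below 1e-14) are flagged
  non-identifiable — `NA` in maps — rather than raised as errors or
  reported as infinities.
* EFOV bisection and the optimal-`L` golden section both terminate at
  0.01 nm, an order of magnitude below any reported digit.

## Known limitations

Strictly 2D (no axial information); scalar beam model (no high-NA vectorial
focal fields, polarization or aberrations); uniform background only; the
estimator search box is 1.5× the TCP, so emitters far outside the pattern
are out of scope, as in practice they would be handed to a coarser
localization stage first.
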