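# vortexflux

Localization-precision analysis and simulation for MINFLUX-type nanoscopy
with Laguerre–Gaussian vortex excitation beams of arbitrary order.

MINFLUX localizes a single fluorophore by probing it with the dark center of
a doughnut-shaped beam at a small set of positions (the *targeted coordinate
pattern*, TCP) and estimating the position from the relative photon counts.
`vortexflux` answers the design questions of such a measurement: how precise
can the estimate be (the Cramér–Rao bound), how does that depend on the
vortex order `l`, the pattern size `L`, the photon budget `N` and the
signal-to-background ratio (SBR), over how large a field of view the
precision holds, and how close a maximum-likelihood estimator gets to the
bound in practice.

## Model

The excitation is an LG mode with intensity
`I(r) ∝ (2r²/w²)^|l| · exp(−2r²/w²)` (waist `w`, `FWHM = √(2 ln 2)·w`);
near the core `I ∝ r^{2|l|}`, so a higher vortex order responds more steeply
to position. Exposure `k` of the TCP collects photons at rate
`λ_k = β·Iⁿ(r_e − r_k)` (`n`-photon excitation), a uniform background `ξ` is
set from the SBR convention `SBR = Σλ_k / (Kξ)` for a centered emitter, and
conditional on `N` detected photons the counts are multinomial with
`p_k = (λ_k + ξ)/Σ(λ_j + ξ)`. The Fisher information
`J = N·Σ_k ∇p_k ∇p_kᵀ / p_k` gives the bound `σ_r = √(Tr J⁻¹ / 2)`; for the
four-point TCP the central bound has the closed form

    σ₀ = L/(2n√(2N)) · s / (|l| − L²/2w²),
    s = √((1 + 3/(4·SBR))(1 + 1/SBR)),

so an `l`-order vortex improves the central precision slightly more than
`l`-fold. The package also provides the SBR–pattern-size scaling law, the
optimal-`L` search, CRB maps and effective-field-of-view (EFOV) diameters,
the Van Trees (Bayesian) bound under a Gaussian positional prior, and a
seeded Monte-Carlo simulator that draws multinomial counts and localizes by
maximum likelihood.

Because published MINFLUX numbers mix two readings of the SBR definition,
both are explicit here (`sbr_mode = "all_exposures"` or
`"signal_exposures"`); every output records which one was used.

## Worked example

```r
library(vortexflux)

beam <- vortex_beam(l = 2, w = 300)        # second-order vortex doughnut
tcp  <- four_point_tcp(50)                 # ring diameter L = 50 nm
m    <- photon_model(beam, tcp, N = 100, sbr = 4,
                     sbr_mode = "signal_exposures")

crb_sigma(c(0, 0), m)
#> CRB at (0.00, 0.00) nm: sigma_r = 1.1491 nm (axes 1.1491 / 1.1491 nm, angle 135.0 deg)
central_crb_closed_form(m)
#> [1] 1.149068

arr <- make_grid_array(3, 3, 5)            # 3x3 emitters, 5 nm apart
sim <- run_experiment(arr, photon_model(beam, tcp, N = 300, sbr = 4,
                                        sbr_mode = "signal_exposures"),
                      trials = 500, master_seed = 102)
sim
#> Monte-Carlo localization: 3x3 grid, 5 nm spacing, 500 trials/emitter (seed 102)
#>   average error: 0.766 nm (per-emitter RMSE 0.659-0.889 nm)
#>   overall RMSE: 0.769 nm vs CRB 0.772 nm (ratio 0.996)
```

The first two numbers are the theoretical localization bound at the pattern
center — 1.15 nm with 100 photons at SBR 4 — computed numerically and from
the closed form. The simulation shows that a maximum-likelihood estimator
using 300 photons per localization actually attains the bound: the
root-mean-square error across a 9-emitter array matches the aggregated CRB
to within Monte-Carlo error (ratio 0.996 in this run).

A thin CLI wraps the same functions
(`Rscript inst/scripts/vortexflux.R <task> --config run.yaml --out DIR`).

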