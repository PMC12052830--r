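## Shared fixtures for the test suite: the canonical doughnut beams and the
## reference measurement settings (w = 300 nm, L = 50 nm, N = 100, SBR = 4).

beam_l <- function(l, p = 0L, n = 1L) vortex_beam(l = l, p = p, w = 300, n = n)

minflux_model <- function(l = 1, sbr = Inf, sbr_mode = "all_exposures",
                          N = 100L, L = 50, n = 1L) {
  photon_model(beam_l(l, n = n), four_point_tcp(L), N = N, sbr = sbr,
               sbr_mode = sbr_mode)
}

rastmin_model <- function(l = 1, dim = 4L, sbr = Inf,
                          sbr_mode = "all_exposures", N = 100L, L = 50) {
  photon_model(beam_l(l), raster_tcp(L, dim = dim), N = N, sbr = sbr,
               sbr_mode = sbr_mode)
}

## Independent unnormalized doughnut intensity (p = 0), written directly from
## the closed form; used as an oracle against the package's implementation.
ref_intensity_raw <- function(r, l, w = 300) {
  u <- 2 * r^2 / w^2
  u^abs(l) * exp(-u)
}

rotate2 <- function(xy, angle) {
  c(cos(angle) * xy[1] - sin(angle) * xy[2],
    sin(angle) * xy[1] + cos(angle) * xy[2])
}
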