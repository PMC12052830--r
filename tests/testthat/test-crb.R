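test_that("Fisher matrix is symmetric PSD and matches the central closed form", {
  ## centered emitter in any symmetric pattern: diagonal, isotropic
  for (m in list(minflux_model(2, sbr = 4), rastmin_model(1, dim = 5, sbr = 4))) {
    J <- fisher_matrix(c(0, 0), m)
    expect_equal(J[1, 2], 0, tolerance = 1e-12 * J[1, 1])
    expect_equal(J[1, 1], J[2, 2], tolerance = 1e-10)
  }

  ## noiseless four-point, centered: J_xx = N g^2 / 2, g = (4/L)(|l| - L^2/2w^2)
  m <- minflux_model(1, N = 100, L = 50)
  g <- (4 / 50) * (1 - 50^2 / (2 * 300^2))
  expect_equal(fisher_matrix(c(0, 0), m)[1, 1], 100 * g^2 / 2,
               tolerance = 1e-9)

  ## PSD at random positions
  set.seed(7)
  for (i in 1:50) {
    m <- minflux_model(sample(1:3, 1), sbr = 4,
                       sbr_mode = sample(c("all_exposures", "signal_exposures"), 1))
    J <- fisher_matrix(runif(2, -40, 40), m)
    expect_equal(J[1, 2], J[2, 1])
    expect_true(all(eigen(J, symmetric = TRUE, only.values = TRUE)$values >= -1e-12))
  }
})

test_that("analytic probability gradients agree with finite differences", {
  ## finite-difference Fisher (differencing p_k) vs analytic, rel 1e-6
  fd_fisher <- function(emitter, model, h = 1e-4) {
    pk <- function(r) detection_probabilities(r, model)$p
    gx <- (pk(emitter + c(h, 0)) - pk(emitter - c(h, 0))) / (2 * h)
    gy <- (pk(emitter + c(0, h)) - pk(emitter - c(0, h))) / (2 * h)
    p <- pk(emitter)
    keep <- p > 0
    model$N * matrix(c(sum(gx[keep]^2 / p[keep]),
                       sum(gx[keep] * gy[keep] / p[keep]),
                       sum(gx[keep] * gy[keep] / p[keep]),
                       sum(gy[keep]^2 / p[keep])), 2, 2)
  }
  set.seed(11)
  models <- list(minflux_model(1, sbr = 4), minflux_model(3, sbr = 4),
                 minflux_model(2, sbr = 4, sbr_mode = "signal_exposures"),
                 rastmin_model(2, dim = 4, sbr = 4),
                 photon_model(vortex_beam(1, p = 1, w = 300), four_point_tcp(50), sbr = 4),
                 minflux_model(1, n = 2L, sbr = 4))
  for (m in models) {
    for (i in 1:4) {
      e <- runif(2, -20, 20) + c(1.3, -0.7)   # generic off-center positions
      expect_equal(fisher_matrix(e, m), fd_fisher(e, m), tolerance = 1e-6)
    }
  }
})

test_that("numeric central CRB equals the closed form across orders and sizes", {
  for (l in 1:3) {
    for (L in seq(20, 80, by = 5)) {
      m <- minflux_model(l, L = L)
      expect_equal(crb_sigma(c(0, 0), m)$sigma, central_crb_closed_form(m),
                   tolerance = 1e-6)
      mb <- minflux_model(l, L = L, sbr = 4, sbr_mode = "all_exposures")
      expect_equal(crb_sigma(c(0, 0), mb)$sigma, central_crb_closed_form(mb),
                   tolerance = 1e-6)
    }
  }
})

test_that("central CRB reproduces the reference values and scaling laws", {
  ## noiseless l = 1: L/(2 sqrt(2N)) / (1 - L^2/2w^2)
  expect_equal(crb_sigma(c(0, 0), minflux_model(1))$sigma,
               (50 / (2 * sqrt(200))) / (1 - 2500 / 180000), tolerance = 1e-9)
  ## with background, both conventions
  expect_equal(crb_sigma(c(0, 0), minflux_model(1, sbr = 4))$sigma,
               (50 / (2 * sqrt(200))) * sqrt(1.1875 * 1.25) / (1 - 2500 / 180000),
               tolerance = 1e-9)   # 2.184 nm
  expect_equal(crb_sigma(c(0, 0), minflux_model(1, sbr = 4,
                                                sbr_mode = "signal_exposures"))$sigma,
               2.31, tolerance = 0.005)

  ## l-fold improvement: noiseless ratio sigma(l=2)/sigma(l=1)
  s1 <- central_crb_closed_form(minflux_model(1))
  s2 <- central_crb_closed_form(minflux_model(2))
  expect_equal(s2 / s1, (1 - 2500 / 180000) / (2 - 2500 / 180000),
               tolerance = 1e-12)
  ## for L << w the improvement approaches |l|-fold
  s1s <- central_crb_closed_form(minflux_model(1, L = 5))
  s3s <- central_crb_closed_form(minflux_model(3, L = 5))
  expect_equal(s1s / s3s, 3, tolerance = 0.01)

  ## multiphoton order: sigma scales as 1/n at fixed everything else
  expect_equal(central_crb_closed_form(minflux_model(1, n = 2L)),
               central_crb_closed_form(minflux_model(1)) / 2, tolerance = 1e-12)
  expect_equal(crb_sigma(c(0, 0), minflux_model(2, n = 3L, sbr = 4))$sigma,
               crb_sigma(c(0, 0), minflux_model(2, sbr = 4))$sigma / 3,
               tolerance = 1e-9)

  ## closed-form domain: pattern larger than the crest diameter is rejected
  expect_error(central_crb_closed_form(minflux_model(1, L = 500)), "too large")
})

test_that("crb_sigma packages covariance, scalar bound and anisotropy coherently", {
  m <- minflux_model(2, sbr = 4)
  res <- crb_sigma(c(9, -4), m)
  expect_true(res$identifiable)
  expect_equal(res$covariance, solve(res$fisher))
  expect_equal(res$sigma, sqrt(sum(diag(res$covariance)) / 2))
  expect_true(res$eigenvalues[2] <= res$sigma^2 &&
                res$sigma^2 <= res$eigenvalues[1])
  expect_gt(crb_anisotropy(res), 1)           # off-center: anisotropic
  expect_equal(crb_anisotropy(crb_sigma(c(0, 0), m)), 1, tolerance = 1e-6)

  ## singular information is flagged, not thrown
  none <- photon_model(beam_l(1), four_point_tcp(50), N = 0L, sbr = 4)
  res0 <- crb_sigma(c(0, 0), none)
  expect_false(res0$identifiable)
  expect_true(is.na(res0$sigma))
})

test_that("dark-exposure information limit: continuous for l >= 2, not for l = 1", {
  ## noiseless l = 2: the center exposure's term vanishes as the emitter
  ## approaches the core, so the bound is continuous at the center
  m2 <- minflux_model(2)
  s0 <- crb_sigma(c(0, 0), m2)$sigma
  expect_equal(crb_sigma(c(1e-4, 0), m2)$sigma, s0, tolerance = 1e-6)

  ## noiseless l = 1: the limiting term is a nonzero constant, so the
  ## just-off-center Fisher information exceeds the central (dropped-term)
  ## value - the closed form deliberately matches the dropped-term reading
  m1 <- minflux_model(1)
  J0 <- fisher_matrix(c(0, 0), m1)[1, 1]
  Je <- fisher_matrix(c(1e-5, 0), m1)[1, 1]
  expect_gt(Je / J0, 1.2)
  ## with background the probability is never zero and continuity holds
  m1b <- minflux_model(1, sbr = 4)
  expect_equal(crb_sigma(c(1e-4, 0), m1b)$sigma,
               crb_sigma(c(0, 0), m1b)$sigma, tolerance = 1e-6)
})

test_that("precision maps inherit the pattern symmetries and grow off-center", {
  m <- minflux_model(1, sbr = 4)
  ## four-point bound invariant under 120 deg rotation of the emitter
  set.seed(3)
  for (i in 1:10) {
    e <- runif(2, -30, 30)
    expect_equal(crb_sigma(rotate2(e, 2 * pi / 3), m)$sigma,
                 crb_sigma(e, m)$sigma, tolerance = 1e-9)
  }
  ## raster bound invariant under 90 deg rotation
  mr <- rastmin_model(2, dim = 4, sbr = 4)
  for (i in 1:10) {
    e <- runif(2, -30, 30)
    expect_equal(crb_sigma(rotate2(e, pi / 2), mr)$sigma,
                 crb_sigma(e, mr)$sigma, tolerance = 1e-9)
  }

  map <- crb_map(m, roi_half_width = 10, grid_step = 5)
  expect_equal(nrow(map), 25L)
  expect_equal(map$sigma_nm[map$x_nm == 0 & map$y_nm == 0],
               crb_sigma(c(0, 0), m)$sigma)

  ## monotone growth along the +x ray out to the pattern scale
  prof <- crb_profile(m, seq(0, 25, by = 1))
  expect_true(all(diff(prof$sigma_nm) > 0))
  profr <- crb_profile(rastmin_model(1, dim = 4, sbr = 4), seq(0, 25, by = 1))
  expect_true(all(diff(profr$sigma_nm) > 0))
})

test_that("radial index leaves the central CRB nearly unchanged at small L", {
  ## same azimuthal order, p = 0 vs p = 1/2: tight agreement at small L,
  ## growing divergence with L, shrinking with |l|
  rel_gap <- function(l, p, L) {
    m0 <- photon_model(vortex_beam(l, 0, 300), four_point_tcp(L), sbr = 4)
    mp <- photon_model(vortex_beam(l, p, 300), four_point_tcp(L), sbr = 4)
    abs(crb_sigma(c(0, 0), mp)$sigma / crb_sigma(c(0, 0), m0)$sigma - 1)
  }
  for (l in 1:2) for (p in 1:2) {
    expect_lt(rel_gap(l, p, 20), 0.02)
    expect_lt(rel_gap(l, p, 20), rel_gap(l, p, 80))   # diverges as L grows
  }
  expect_lt(rel_gap(3, 1, 80), rel_gap(1, 1, 80))     # shrinks with order
})

test_that("EFOV is zero below the central bound and located by bisection", {
  m <- minflux_model(1, sbr = 4)
  expect_equal(efov_diameter(m, threshold = 1), 0)
  d <- efov_diameter(m, threshold = 4, n_azimuth = 16)
  expect_gt(d, 20)
  ## the worst-azimuth bound straddles the threshold at the boundary radius
  th <- 2 * pi * (0:15) / 16
  worst <- function(r) max(vapply(th, function(a)
    crb_sigma(r * c(cos(a), sin(a)), m)$sigma, numeric(1)))
  expect_lte(worst(d / 2 - 0.05), 4)
  expect_gte(worst(d / 2 + 0.05), 4)
  expect_lte(d, efov_diameter(m, threshold = 4, n_azimuth = 16, variant = "mean"))
})

test_that("optimal pattern size: interior minimum with background, boundary without", {
  res <- optimal_pattern_size(beam_l(1), "four_point", N = 100, sbr0 = 4,
                              L0 = 50, L_range = c(10, 100))
  expect_false(res$boundary)
  expect_true(res$L_star > 20 && res$L_star < 26)
  expect_equal(res$sigma_star, 1.64, tolerance = 0.01)
  ## minimum no worse than every coarse-scan point
  expect_lte(res$sigma_star, min(res$curve$sigma_nm) + 1e-9)

  noiseless <- optimal_pattern_size(beam_l(1), "four_point", N = 100,
                                    sbr0 = Inf, L0 = 50, L_range = c(10, 100))
  expect_true(noiseless$boundary)
  expect_equal(noiseless$L_star, 10)   # bound decreases monotonically with L
})

test_that("Van Trees bound: prior-only limit and monotone gain with photons", {
  m <- minflux_model(1, sbr = 4)
  m0 <- m; m0$N <- 0L
  expect_equal(bayesian_crb(m0, 50), 50)

  vals <- suppressWarnings(vapply(c(0L, 50L, 100L, 200L), function(N) {
    mm <- m; mm$N <- N
    bayesian_crb(mm, 50, order = 41L)
  }, numeric(1)))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[2], 50)
  expect_error(bayesian_crb(m, -3), "prior_sd")
})
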