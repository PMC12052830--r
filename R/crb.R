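#' Fisher information and Cramér-Rao bounds for MINFLUX localization
#'
#' Conditional on the total photon count N, the counts over the TCP are
#' multinomial with probabilities \eqn{p_k(r_e)}, and the Fisher information
#' about the emitter position is
#' \deqn{J(r_e) = N \sum_k \frac{1}{p_k}\, \nabla p_k\, \nabla p_k^T.}
#' The position-covariance of any unbiased estimator is bounded below by
#' \eqn{\Sigma = J^{-1}}, scalarized as \eqn{\sigma_r = \sqrt{Tr(\Sigma)/2}}
#' (the root of the arithmetic-mean eigenvalue). The gradients
#' \eqn{\nabla p_k} are computed analytically by the chain rule through the
#' beam's radial intensity derivative.
#'
#' Exposures with exactly zero detection probability (the origin exposure of
#' a noiseless four-point pattern probed with a centered emitter) are
#' excluded from the sum; this matches the closed-form central bound, which
#' likewise carries no information from the dark exposure.
#'
#' @param emitter length-2 numeric position (nm).
#' @param model a \code{\link{photon_model}}.
#' @return \code{fisher_matrix}: a 2x2 symmetric matrix (nm^-2).
#' @export
fisher_matrix <- function(emitter, model) {
  stopifnot(inherits(model, "photon_model"), length(emitter) == 2L)
  pos <- model$pattern$positions
  dx <- emitter[1] - pos[, 1]
  dy <- emitter[2] - pos[, 2]
  d <- sqrt(dx^2 + dy^2)
  beam <- model$beam
  I <- lg_intensity(d, beam)
  dIdr <- lg_intensity_deriv(d, beam)
  lam <- I^beam$n
  ## d(lambda)/dr = n I^{n-1} dI/dr; unit radial vector (dx, dy)/d (zero at
  ## d = 0, where the intensity gradient vanishes for every LG beam).
  dldr <- beam$n * ifelse(I > 0 | beam$n == 1, I^(beam$n - 1), 0) * dIdr
  ux <- ifelse(d > 0, dx / d, 0)
  uy <- ifelse(d > 0, dy / d, 0)
  glx <- dldr * ux
  gly <- dldr * uy
  tot <- lam + model$xi
  Tsum <- sum(tot)
  if (Tsum <= 0) stop("degenerate model: all rates are zero")
  p <- tot / Tsum
  gpx <- (glx * Tsum - tot * sum(glx)) / Tsum^2
  gpy <- (gly * Tsum - tot * sum(gly)) / Tsum^2
  keep <- p > 0
  J <- matrix(0, 2, 2)
  J[1, 1] <- sum(gpx[keep]^2 / p[keep])
  J[2, 2] <- sum(gpy[keep]^2 / p[keep])
  J[1, 2] <- J[2, 1] <- sum(gpx[keep] * gpy[keep] / p[keep])
  model$N * J
}

#' @rdname fisher_matrix
#'
#' @return \code{crb_sigma}: an object of class \code{crb_result} with
#'   elements \code{fisher}, \code{covariance} (the 2x2 lower bound, nm^2),
#'   \code{sigma} (\eqn{\sigma_r}, nm), \code{eigenvalues} (of the
#'   covariance bound, decreasing), \code{axis_angle} (radians, principal
#'   axis of the larger eigenvalue) and \code{identifiable}. A singular
#'   Fisher matrix is flagged (\code{identifiable = FALSE}, \code{sigma =
#'   NA}) rather than raised as an error.
#' @export
crb_sigma <- function(emitter, model) {
  J <- fisher_matrix(emitter, model)
  res <- list(emitter = as.numeric(emitter), fisher = J)
  if (!all(is.finite(J)) || rcond(J) < 1e-14) {
    res$identifiable <- FALSE
    res$covariance <- matrix(NA_real_, 2, 2)
    res$sigma <- NA_real_
    res$eigenvalues <- c(NA_real_, NA_real_)
    res$axis_angle <- NA_real_
  } else {
    S <- solve(J)
    ev <- eigen(S, symmetric = TRUE)
    res$identifiable <- TRUE
    res$covariance <- S
    res$sigma <- sqrt(sum(diag(S)) / 2)
    res$eigenvalues <- ev$values
    res$axis_angle <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  }
  class(res) <- "crb_result"
  res
}

#' @export
print.crb_result <- function(x, ...) {
  if (!x$identifiable) {
    cat("CRB: position not identifiable (singular Fisher matrix)\n")
  } else {
    cat(sprintf("CRB at (%.2f, %.2f) nm: sigma_r = %.4f nm (axes %.4f / %.4f nm, angle %.1f deg)\n",
                x$emitter[1], x$emitter[2], x$sigma,
                sqrt(x$eigenvalues[1]), sqrt(x$eigenvalues[2]),
                x$axis_angle * 180 / pi))
  }
  invisible(x)
}

#' Anisotropy of a CRB result
#'
#' Ratio of the principal standard deviations of the covariance bound
#' (>= 1); 1 means an isotropic bound, as at the center of a symmetric TCP.
#'
#' @param result a \code{crb_result}.
#' @return scalar ratio \eqn{\sigma_{max}/\sigma_{min}}.
#' @export
crb_anisotropy <- function(result) {
  stopifnot(inherits(result, "crb_result"))
  sqrt(result$eigenvalues[1] / result$eigenvalues[2])
}

#' Closed-form central CRB of the four-point pattern
#'
#' For the four-point TCP with a centered emitter the bound has the explicit
#' form
#' \deqn{\sigma_0 = \frac{L}{2 n \sqrt{2N}}\;
#'   \frac{s}{|l| - L^2/(2w^2)}, \qquad
#'   s = \sqrt{\Big(1 + \frac{3}{4\,SBR}\Big)\Big(1 + \frac{1}{SBR}\Big)},}
#' where the SBR entering \eqn{s} is the literal total-signal over
#' total-background ratio of the model at its own pattern size (for the
#' \code{signal_exposures} convention this effective ratio is 3/4 of the
#' nominal SBR). Requires \eqn{|l| \ge 1} and \eqn{L^2 < 2|l|w^2} (the ring
#' must sit inside the doughnut crest so that shrinking r increases every
#' ring rate).
#'
#' @param model a \code{photon_model} with a four-point pattern.
#' @return \eqn{\sigma_0} in nm.
#' @export
central_crb_closed_form <- function(model) {
  stopifnot(inherits(model, "photon_model"))
  if (model$pattern$kind != "four_point") {
    stop("closed form applies to the four-point pattern only")
  }
  beam <- model$beam
  la <- abs(beam$l)
  if (la < 1) stop("closed form requires a vortex beam (|l| >= 1)")
  L <- model$pattern$L
  denom <- la - L^2 / (2 * beam$w^2)
  if (denom <= 0) {
    stop("pattern too large for this vortex order: L^2 must be < 2|l|w^2")
  }
  if (is.infinite(model$sbr)) {
    s <- 1
  } else {
    lam0 <- lg_intensity(L / 2, beam)^beam$n
    sbr_eff <- 3 * lam0 / (4 * model$xi)   # literal Eq.-11 ratio at size L
    s <- sqrt((1 + 3 / (4 * sbr_eff)) * (1 + 1 / sbr_eff))
  }
  L / (2 * beam$n * sqrt(2 * model$N)) * s / denom
}

#' Map of the localization bound over the field of view
#'
#' Evaluates \eqn{\sigma_r} on a square grid of emitter positions, together
#' with the principal-axis standard deviations and orientation
#' (the bound is anisotropic away from the pattern center).
#'
#' @param model a \code{photon_model}.
#' @param roi_half_width half-width of the square region of interest, nm.
#' @param grid_step grid spacing, nm (> 0).
#' @return a \code{precision_map}: data frame with columns \code{x_nm},
#'   \code{y_nm}, \code{sigma_nm}, \code{sigma_max_nm}, \code{sigma_min_nm},
#'   \code{axis_angle_rad}; non-identifiable positions carry \code{NA}.
#' @export
crb_map <- function(model, roi_half_width, grid_step) {
  stopifnot(grid_step > 0, roi_half_width > 0)
  g <- seq(-roi_half_width, roi_half_width, by = grid_step)
  pts <- expand.grid(x_nm = g, y_nm = g)
  res <- lapply(seq_len(nrow(pts)), function(i) {
    r <- crb_sigma(c(pts$x_nm[i], pts$y_nm[i]), model)
    c(r$sigma, sqrt(r$eigenvalues[1]), sqrt(r$eigenvalues[2]), r$axis_angle)
  })
  res <- do.call(rbind, res)
  out <- cbind(pts, sigma_nm = res[, 1], sigma_max_nm = res[, 2],
               sigma_min_nm = res[, 3], axis_angle_rad = res[, 4])
  attr(out, "model") <- model
  class(out) <- c("precision_map", class(out))
  out
}

#' Radial profile of the bound along one direction
#'
#' 1D cut of the CRB map through the origin.
#'
#' @param model a \code{photon_model}.
#' @param radii numeric vector of signed distances from the origin, nm.
#' @param angle_deg direction of the cut in degrees (0 = +x axis).
#' @return data frame with \code{r_nm} and \code{sigma_nm}.
#' @export
crb_profile <- function(model, radii, angle_deg = 0) {
  th <- angle_deg * pi / 180
  sig <- vapply(radii, function(r) {
    crb_sigma(c(r * cos(th), r * sin(th)), model)$sigma
  }, numeric(1))
  data.frame(r_nm = radii, sigma_nm = sig)
}

#' Effective field of view
#'
#' Diameter of the largest origin-centered circle on which the bound stays
#' at or below \code{threshold} at every sampled azimuth (the bound is not
#' radially symmetric, so the worst azimuth is the conservative primary
#' definition; \code{variant = "mean"} uses the azimuthal mean instead).
#' The boundary radius is located by bisection to 0.01 nm.
#'
#' @param model a \code{photon_model}.
#' @param threshold precision threshold in nm (default 4).
#' @param n_azimuth number of azimuths sampled per radius.
#' @param variant \code{"worst"} (default) or \code{"mean"} azimuthal
#'   aggregation.
#' @param r_max search ceiling for the radius, nm.
#' @return EFOV diameter in nm (0 if the central bound already exceeds the
#'   threshold).
#' @export
efov_diameter <- function(model, threshold = 4, n_azimuth = 64L,
                          variant = c("worst", "mean"),
                          r_max = 2 * model$pattern$L) {
  variant <- match.arg(variant)
  th <- 2 * pi * (seq_len(n_azimuth) - 1) / n_azimuth
  agg <- function(r) {
    if (r == 0) return(crb_sigma(c(0, 0), model)$sigma)
    s <- vapply(th, function(a) {
      crb_sigma(c(r * cos(a), r * sin(a)), model)$sigma
    }, numeric(1))
    if (any(is.na(s))) return(Inf)
    if (variant == "worst") max(s) else mean(s)
  }
  if (agg(0) > threshold) return(0)
  lo <- 0
  hi <- r_max
  if (agg(hi) <= threshold) return(2 * hi)
  while (hi - lo > 0.005) {
    mid <- (lo + hi) / 2
    if (agg(mid) <= threshold) lo <- mid else hi <- mid
  }
  2 * (lo + hi) / 2
}

#' Optimal pattern size under background
#'
#' With background noise the central bound no longer improves monotonically
#' as the pattern shrinks: the SBR collapses at small L (see
#' \code{\link{scale_sbr}}), so an optimal L exists. This searches the given
#' range by a coarse 1-nm scan followed by golden-section refinement to
#' 0.01 nm, holding the SBR anchored at \code{(sbr0, L0)} and rescaling it
#' to each candidate L.
#'
#' @param beam a \code{vortex_beam}.
#' @param pattern_kind \code{"four_point"} or \code{"raster"}.
#' @param N photon budget.
#' @param sbr0 SBR at the anchor size \code{L0} (may be \code{Inf}).
#' @param L0 anchor size, nm.
#' @param L_range length-2 numeric search interval, nm.
#' @param sbr_mode background convention (see \code{\link{photon_model}}).
#' @param raster_dim grid dimension for the raster pattern.
#' @return list with \code{L_star}, \code{sigma_star} (nm), \code{boundary}
#'   (TRUE when the minimum sits on an endpoint of the range, as in the
#'   noiseless case where the bound decreases all the way to L -> 0) and
#'   \code{curve} (the coarse scan as a data frame).
#' @export
optimal_pattern_size <- function(beam, pattern_kind = c("four_point", "raster"),
                                 N = 100L, sbr0 = 4, L0 = 50,
                                 L_range = c(10, 100),
                                 sbr_mode = "all_exposures", raster_dim = 5L) {
  pattern_kind <- match.arg(pattern_kind)
  stopifnot(length(L_range) == 2L, L_range[1] > 0, L_range[2] > L_range[1])
  sigma_at <- function(L) {
    pat <- if (pattern_kind == "four_point") four_point_tcp(L)
           else raster_tcp(L, dim = raster_dim)
    sbr_L <- if (is.infinite(sbr0)) Inf else scale_sbr(L, L0, sbr0, beam)
    m <- photon_model(beam, pat, N = N, sbr = sbr_L, sbr_anchor_L = L,
                      sbr_mode = sbr_mode)
    crb_sigma(c(0, 0), m)$sigma
  }
  Ls <- seq(L_range[1], L_range[2], by = 1)
  sig <- vapply(Ls, sigma_at, numeric(1))
  i <- which.min(sig)
  boundary <- i == 1L || i == length(Ls)
  if (boundary) {
    return(list(L_star = Ls[i], sigma_star = sig[i], boundary = TRUE,
                curve = data.frame(L_nm = Ls, sigma_nm = sig)))
  }
  ## golden-section refinement inside the bracketing coarse cells
  a <- Ls[i - 1L]; b <- Ls[i + 1L]
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- sigma_at(x1); f2 <- sigma_at(x2)
  while (b - a > 0.01) {
    if (f1 <= f2) {   # tie-break toward smaller L
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- sigma_at(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- sigma_at(x2)
    }
  }
  L_star <- (a + b) / 2
  list(L_star = L_star, sigma_star = sigma_at(L_star), boundary = FALSE,
       curve = data.frame(L_nm = Ls, sigma_nm = sig))
}

#' Bayesian (Van Trees) localization bound under a positional prior
#'
#' When prior knowledge of the emitter position is available (wide-field
#' image, confocal pre-scan, an earlier MINFLUX round), the relevant bound
#' is the Van Trees / posterior Cramér-Rao bound. For an isotropic normal
#' prior with standard deviation \code{prior_sd} the Bayesian information
#' matrix is
#' \deqn{J_B = E_{prior}[J(r_e)] + \sigma_{prior}^{-2} I_2,}
#' and the bound is \eqn{\sqrt{Tr(J_B^{-1})/2}}. The prior expectation is
#' taken by tensor Gauss-Hermite quadrature. A 50-nm prior spreads mass over
#' hundreds of nm while the Fisher map varies on the 10-nm pattern scale, so
#' high orders are needed: the order is always escalated once (to
#' \code{order + 100}), the escalated result is returned, and a warning is
#' emitted if the two orders still disagree by more than relative 2e-3.
#'
#' @param model a \code{photon_model}; \code{N = 0} yields the prior-only
#'   bound \code{prior_sd}.
#' @param prior_sd prior standard deviation, nm (> 0).
#' @param order Gauss-Hermite order per axis (default 201).
#' @return the Bayesian bound in nm.
#' @export
bayesian_crb <- function(model, prior_sd, order = 201L) {
  stopifnot(inherits(model, "photon_model"))
  if (length(prior_sd) != 1L || !is.finite(prior_sd) || prior_sd <= 0) {
    stop("'prior_sd' must be a single positive standard deviation in nm")
  }
  bound_at <- function(ord) {
    gh <- pracma::gaussHermite(ord)
    EJ <- matrix(0, 2, 2)
    for (i in seq_along(gh$x)) {
      x <- sqrt(2) * prior_sd * gh$x[i]
      for (j in seq_along(gh$x)) {
        y <- sqrt(2) * prior_sd * gh$x[j]
        EJ <- EJ + gh$w[i] * gh$w[j] * fisher_matrix(c(x, y), model)
      }
    }
    EJ <- EJ / pi
    JB <- EJ + diag(2) / prior_sd^2
    sqrt(sum(diag(solve(JB))) / 2)
  }
  if (model$N == 0L) return(prior_sd)
  b1 <- bound_at(order)
  b2 <- bound_at(order + 100L)
  if (abs(b2 - b1) > 2e-3 * abs(b1)) {
    warning(sprintf(
      "Gauss-Hermite quadrature not fully converged (order %d vs %d: %.4g vs %.4g); using the higher order",
      order, order + 100L, b1, b2))
  }
  b2
}

#' Export a precision map or profile as CSV
#'
#' @param map a \code{precision_map} (or any data frame from
#'   \code{\link{crb_profile}}).
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
map_to_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
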