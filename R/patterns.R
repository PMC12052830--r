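#' Targeted coordinate patterns (TCPs)
#'
#' A TCP is the ordered set of beam-center positions visited during one
#' localization. Two standard geometries are supported: the four-point
#' MINFLUX pattern (three exposures equally spaced on a circle of diameter
#' \code{L} plus one at the origin) and the RASTMIN raster pattern
#' (\code{dim x dim} square grid of side \code{L}). Both are centered on the
#' origin.
#'
#' @name exposure_pattern
NULL

new_exposure_pattern <- function(kind, L, positions, dim = NA_integer_) {
  structure(
    list(kind = kind, L = as.numeric(L),
         positions = positions, dim = as.integer(dim)),
    class = "exposure_pattern"
  )
}

#' @export
print.exposure_pattern <- function(x, ...) {
  extra <- if (x$kind == "raster") sprintf(", %dx%d grid", x$dim, x$dim) else ""
  cat(sprintf("%s TCP: K = %d exposures, L = %g nm%s\n",
              x$kind, nrow(x$positions), x$L, extra))
  invisible(x)
}

#' Four-point MINFLUX pattern
#'
#' The conventional MINFLUX TCP: three exposures at radius \code{L/2}
#' (angles 90, 210, 330 degrees, i.e. one on the +y axis) plus one exposure
#' at the origin, so \code{K = 4}. The origin exposure probes the dark core
#' directly; with a centered emitter and no background it collects no
#' photons. The central-precision results are invariant to the ring's
#' angular offset.
#'
#' @param L pattern size in nm: the diameter of the exposure ring.
#' @param variant \code{"center"} (default: 3 ring + 1 origin exposure) or
#'   \code{"ring"} (4 equally spaced ring exposures, no origin exposure) for
#'   sensitivity analyses.
#' @return an \code{exposure_pattern} with the origin exposure last
#'   (\code{"center"} variant: rows 1-3 on the ring, row 4 at the origin).
#' @examples
#' four_point_tcp(50)
#' @export
four_point_tcp <- function(L, variant = c("center", "ring")) {
  variant <- match.arg(variant)
  if (length(L) != 1L || !is.finite(L) || L <= 0) {
    stop("'L' must be a single positive length in nm")
  }
  R <- L / 2
  if (variant == "center") {
    ang <- pi / 2 + 2 * pi * (0:2) / 3
    pos <- rbind(cbind(R * cos(ang), R * sin(ang)), c(0, 0))
  } else {
    ang <- pi / 2 + 2 * pi * (0:3) / 4
    pos <- cbind(R * cos(ang), R * sin(ang))
  }
  colnames(pos) <- c("x", "y")
  new_exposure_pattern("four_point", L, pos)
}

#' Raster-scan (RASTMIN) pattern
#'
#' A \code{dim x dim} square grid of beam positions with uniform spacing
#' \code{L/(dim - 1)}, spanning \code{[-L/2, L/2]^2} and centered at the
#' origin, scanned row by row.
#'
#' @param L side length of the grid in nm.
#' @param dim grid dimension (points per side), >= 2. Default 5.
#' @return an \code{exposure_pattern} with \code{dim^2} exposures.
#' @examples
#' raster_tcp(50, dim = 5)
#' @export
raster_tcp <- function(L, dim = 5L) {
  if (length(L) != 1L || !is.finite(L) || L <= 0) {
    stop("'L' must be a single positive length in nm")
  }
  if (length(dim) != 1L || dim != round(dim) || dim < 2) {
    stop("'dim' must be a single integer >= 2")
  }
  g <- seq(-L / 2, L / 2, length.out = dim)
  pos <- as.matrix(expand.grid(x = g, y = g))
  new_exposure_pattern("raster", L, pos, dim = dim)
}

#' Number of exposures in a pattern
#' @param pattern an \code{exposure_pattern}.
#' @return integer K.
#' @export
n_exposures <- function(pattern) nrow(pattern$positions)

#' Write / read a pattern as CSV
#'
#' Round-trips the beam-center coordinates through a plain CSV with columns
#' \code{index, x_nm, y_nm} so that runs can be reproduced outside R.
#'
#' @param pattern an \code{exposure_pattern}.
#' @param path file path.
#' @return \code{pattern_to_csv} returns \code{path} invisibly;
#'   \code{pattern_from_csv} returns a position matrix with the pattern
#'   metadata attached when recoverable.
#' @export
pattern_to_csv <- function(pattern, path) {
  df <- data.frame(index = seq_len(n_exposures(pattern)),
                   x_nm = pattern$positions[, 1],
                   y_nm = pattern$positions[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pattern_to_csv
#' @export
pattern_from_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("index", "x_nm", "y_nm") %in% names(df)))
  df <- df[order(df$index), ]
  pos <- cbind(x = df$x_nm, y = df$y_nm)
  pos
}
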