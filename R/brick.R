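#' Unbiased counting-brick specification
#'
#' An axis-aligned counting brick with the stereological
#' inclusion/exclusion rule: the three faces at the minimum of each axis
#' are inclusion faces, the three opposite faces exclusion faces, so that
#' a tiling of abutting bricks counts every particle exactly once.
#' Particles are reduced to one reference point each (e.g. the PSD
#' centroid), for which the rule is the half-open box
#' `origin <= p < origin + dims` on every axis.
#'
#' @param origin brick corner `c(x, y, z)` in um.
#' @param dims brick edge lengths `c(w, h, d)` in um; the default
#'   `c(10, 10, 1.5)` is the standard 150 um^3 brick.
#' @return An object of class `brick_spec` with a `volume_um3` field.
#' @examples
#' brick_spec()$volume_um3  # 150
#' @export
brick_spec <- function(origin = c(0, 0, 0), dims = c(10, 10, 1.5)) {
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("'origin' must be three finite coordinates", call. = FALSE)
  }
  if (length(dims) != 3L || any(!is.finite(dims)) || any(dims <= 0)) {
    stop("degenerate brick: all edge lengths must be > 0", call. = FALSE)
  }
  structure(list(origin = as.numeric(origin), dims = as.numeric(dims),
                 volume_um3 = prod(dims)),
            class = "brick_spec")
}

#' @export
print.brick_spec <- function(x, ...) {
  cat(sprintf("Counting brick %g x %g x %g um at (%g, %g, %g): %g um^3\n",
              x$dims[1], x$dims[2], x$dims[3], x$origin[1], x$origin[2],
              x$origin[3], x$volume_um3))
  invisible(x)
}

#' Count synapse reference points inside an unbiased brick
#'
#' @param points data.frame or matrix whose first three columns are x, y, z
#'   coordinates in um (the `x_um, y_um, z_um` scene format); may have zero
#'   rows.
#' @param brick a [brick_spec()].
#' @return Integer count of points with
#'   `origin <= p < origin + dims` component-wise (inclusion faces counted,
#'   exclusion faces not).
#' @export
brick_count <- function(points, brick) {
  if (!inherits(brick, "brick_spec")) {
    stop("'brick' must be a brick_spec", call. = FALSE)
  }
  p <- as.matrix(points)
  if (nrow(p) == 0L) return(0L)
  if (ncol(p) < 3L || any(!is.finite(p[, 1:3]))) {
    stop("'points' must have three finite coordinate columns",
         call. = FALSE)
  }
  lo <- brick$origin
  hi <- brick$origin + brick$dims
  inside <- p[, 1L] >= lo[1L] & p[, 1L] < hi[1L] &
    p[, 2L] >= lo[2L] & p[, 2L] < hi[2L] &
    p[, 3L] >= lo[3L] & p[, 3L] < hi[3L]
  sum(inside)
}

#' Spine density from brick counts
#'
#' Density per tissue volume: counts are converted to densities per brick
#' and averaged, giving one value per sample — the statistical unit for
#' between-condition comparisons.
#'
#' @param counts integer vector of per-brick counts (>= 1 brick).
#' @param brick_volume brick volume in um^3 (> 0).
#' @return Density in um^-3.
#' @examples
#' spine_density(c(10, 20), 150)  # 0.1
#' @export
spine_density <- function(counts, brick_volume) {
  if (length(counts) == 0L || any(!is.finite(counts)) || any(counts < 0)) {
    stop("'counts' must be >= 1 non-negative brick counts", call. = FALSE)
  }
  check_scalar(brick_volume, "brick_volume", positive = TRUE)
  mean(counts / brick_volume)
}
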