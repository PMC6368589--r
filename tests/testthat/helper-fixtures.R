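# shared fixture builders and independent oracles

square_vertices <- function(side = 1, x0 = 0, y0 = 0) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side))
}

# a record table built by hand (not via the generator)
make_records <- function(volume, psd_area = volume * 0.5,
                         psd_core = psd_area * 0.03,
                         condition = "control", has_ser = FALSE,
                         perforated = FALSE, id = NULL) {
  n <- length(volume)
  data.frame(
    id = if (is.null(id)) sprintf("sp%03d", seq_len(n)) else id,
    sample_id = "s1",
    condition = rep_len(condition, n),
    volume_um3 = volume,
    psd_area_um2 = psd_area,
    psd_core_volume_um3 = psd_core,
    has_ser = rep_len(has_ser, n),
    has_spine_apparatus = FALSE,
    perforated = rep_len(perforated, n),
    n_synapses = 1L,
    stringsAsFactors = FALSE)
}

# build a local_corr_profile object directly (for region-extraction logic)
fake_profile <- function(mean_p, volumes = seq_along(mean_p) / 100,
                         alpha = 0.05) {
  out <- data.frame(id = sprintf("sp%03d", seq_along(mean_p)),
                    volume_um3 = volumes,
                    mean_rho = 0.5, mean_p = mean_p,
                    n_windows = 1L, n_degenerate = 0,
                    significant = mean_p < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("local_corr_profile", "data.frame")
  attr(out, "parameter") <- "psd_area"
  attr(out, "alpha") <- alpha
  out
}

# voxelisation oracle for convex polygons: midpoint rasterisation.
# Convex test: point is inside iff it is on the same side of every edge.
raster_polygon_area <- function(v, h) {
  n <- nrow(v)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  gx <- seq(xr[1] + h / 2, xr[2], by = h)
  gy <- seq(yr[1] + h / 2, yr[2], by = h)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (v[j, 1] - v[i, 1]) * (pts[, 2] - v[i, 2]) -
      (v[j, 2] - v[i, 2]) * (pts[, 1] - v[i, 1])
    inside <- inside & cr >= 0
  }
  sum(inside) * h^2
}

# ensure counter-clockwise orientation (raster oracle assumes it)
ccw <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (s < 0) v[rev(seq_len(nrow(v))), ] else v
}

regular_polygon <- function(n, r = 1, cx = 0, cy = 0, phase = 0) {
  ang <- phase + seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of labelings
enum_mw_p <- function(a, b) {
  n1 <- length(a)
  pool <- c(a, b)
  r <- rank(pool)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(length(pool), n1)
  Us <- apply(cmb, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

# exact two-sided Spearman p by enumeration of all n! rank permutations
enum_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- all_permutations(length(x))
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
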