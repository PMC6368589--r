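#' Configuration for the synthetic spine-population generator
#'
#' Parameterises a generative model with the statistical structure the
#' downstream analysis assumes: log-normal spine volumes, a power-law
#' (log-log linear) coupling between spine volume and PSD surface area with
#' a configurable mid-volume decoupling band implemented as residual
#' variance inflation, PSD-core volume tightly coupled to PSD area, SER
#' (smooth endoplasmic reticulum) probability increasing with volume, and
#' cLTP effects in which PSD parameters grow in all spines while spine
#' volume grows only in SER-containing spines.
#'
#' Defaults emulate the study conditions of the serial block-face EM
#' dataset the analysis was designed for: 119 control and 138 potentiated
#' spines from 4 organotypic slices per condition, volumes centred near
#' 0.08 um^3 spanning roughly 0.01-1 um^3, a decoupling band at
#' 0.04-0.1 um^3 holding about a third of the population, and cLTP factors
#' calibrated so that group comparisons at these sample sizes give rank
#' statistics of the magnitude observed in that dataset.
#'
#' @param n_control,n_cltp number of spines per condition.
#' @param logV_mean,logV_sd mean and sd of log10 spine volume (um^3).
#' @param slope_a,intercept_b log-log coupling of PSD area to spine volume:
#'   `log10(A) = slope_a * log10(V) + intercept_b + noise`.
#' @param noise_sd_base residual sd (log10 units) outside the decoupling
#'   band.
#' @param noise_sd_band inflated residual sd inside the band.
#' @param band_lo,band_hi bounds (um^3) of the decoupling band.
#' @param core_area_ratio effective PSD-core thickness (um): core volume is
#'   generated as `core_area_ratio * A` up to log-normal noise.
#' @param core_noise_sd residual sd (log10) of the core-volume/area coupling.
#' @param ser_logit_b0,ser_logit_b1 logistic-regression coefficients of
#'   P(SER) on log10 volume.
#' @param cltp_psd_factor multiplicative PSD growth (area and core volume)
#'   applied to every cLTP spine.
#' @param cltp_spine_factor_ser spine-volume growth factor applied under
#'   cLTP only to SER-containing spines.
#' @param cltp_band_lo,cltp_band_hi bounds (um^3) of the decoupling band
#'   for potentiated spines; narrower than the control band by default,
#'   encoding the re-coupling of PSD size to spine volume under cLTP.
#' @param perf_prob_ser,perf_prob_noser PSD perforation probabilities for
#'   spines with and without SER.
#' @param apparatus_prob probability that a SER-containing spine carries a
#'   spine apparatus (stacked SER).
#' @param n_samples_per_condition number of tissue samples (slices) the
#'   spines are attributed to, round-robin.
#' @param seed RNG seed; the same seed reproduces the population exactly.
#' @return An object of class `synth_config`.
#' @seealso [generate_population()]
#' @export
synth_config <- function(n_control = 119L, n_cltp = 138L,
                         logV_mean = -1.1, logV_sd = 0.45,
                         slope_a = 0.9, intercept_b = -0.3,
                         noise_sd_base = 0.02, noise_sd_band = 0.30,
                         band_lo = 0.04, band_hi = 0.10,
                         core_area_ratio = 0.03, core_noise_sd = 0.02,
                         ser_logit_b0 = 3.5, ser_logit_b1 = 3.0,
                         cltp_psd_factor = 1.8,
                         cltp_spine_factor_ser = 1.7,
                         cltp_band_lo = 0.048, cltp_band_hi = 0.073,
                         perf_prob_ser = 0.25, perf_prob_noser = 0.01,
                         apparatus_prob = 0.4,
                         n_samples_per_condition = 4L,
                         seed = 1L) {
  check_scalar(n_control, "n_control", positive = TRUE, integer = TRUE)
  check_scalar(n_cltp, "n_cltp", positive = TRUE, integer = TRUE)
  check_scalar(logV_sd, "logV_sd", positive = TRUE)
  check_scalar(noise_sd_base, "noise_sd_base", positive = TRUE)
  check_scalar(noise_sd_band, "noise_sd_band", positive = TRUE)
  check_scalar(band_lo, "band_lo", positive = TRUE)
  check_scalar(band_hi, "band_hi", positive = TRUE)
  if (band_lo >= band_hi) {
    stop("invalid decoupling band: need 0 < band_lo < band_hi (got [",
         band_lo, ", ", band_hi, "])", call. = FALSE)
  }
  check_scalar(core_area_ratio, "core_area_ratio", positive = TRUE)
  check_scalar(core_noise_sd, "core_noise_sd", positive = TRUE)
  check_scalar(cltp_psd_factor, "cltp_psd_factor", positive = TRUE)
  check_scalar(cltp_spine_factor_ser, "cltp_spine_factor_ser",
               positive = TRUE)
  check_scalar(cltp_band_lo, "cltp_band_lo", positive = TRUE)
  check_scalar(cltp_band_hi, "cltp_band_hi", positive = TRUE)
  if (cltp_band_lo >= cltp_band_hi) {
    stop("invalid cLTP decoupling band: need cltp_band_lo < cltp_band_hi",
         call. = FALSE)
  }
  check_probability(perf_prob_ser, "perf_prob_ser")
  check_probability(perf_prob_noser, "perf_prob_noser")
  check_probability(apparatus_prob, "apparatus_prob")
  check_scalar(n_samples_per_condition, "n_samples_per_condition",
               positive = TRUE, integer = TRUE)
  cfg <- list(
    n_control = as.integer(n_control), n_cltp = as.integer(n_cltp),
    logV_mean = logV_mean, logV_sd = logV_sd,
    slope_a = slope_a, intercept_b = intercept_b,
    noise_sd_base = noise_sd_base, noise_sd_band = noise_sd_band,
    band_lo = band_lo, band_hi = band_hi,
    core_area_ratio = core_area_ratio, core_noise_sd = core_noise_sd,
    ser_logit_b0 = ser_logit_b0, ser_logit_b1 = ser_logit_b1,
    cltp_psd_factor = cltp_psd_factor,
    cltp_spine_factor_ser = cltp_spine_factor_ser,
    cltp_band_lo = cltp_band_lo, cltp_band_hi = cltp_band_hi,
    perf_prob_ser = perf_prob_ser, perf_prob_noser = perf_prob_noser,
    apparatus_prob = apparatus_prob,
    n_samples_per_condition = as.integer(n_samples_per_condition),
    seed = seed)
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic spine-population configuration\n")
  cat(sprintf("  n: %d control + %d cLTP (seed %s)\n",
              x$n_control, x$n_cltp, format(x$seed)))
  cat(sprintf("  log10 V ~ N(%g, %g); A ~ V^%g * 10^%g\n",
              x$logV_mean, x$logV_sd, x$slope_a, x$intercept_b))
  cat(sprintf("  decoupling band [%g, %g] um^3: residual sd %g -> %g\n",
              x$band_lo, x$band_hi, x$noise_sd_base, x$noise_sd_band))
  cat(sprintf("  cLTP: PSD x%g (all), V x%g (SER spines only)\n",
              x$cltp_psd_factor, x$cltp_spine_factor_ser))
  invisible(x)
}

#' Generate a synthetic spine population
#'
#' Draws a per-spine morphometry table from the generative model described
#' in [synth_config()].  SER status is drawn from the logistic model on the
#' pre-potentiation volume; cLTP growth is then applied (PSD area and core
#' volume in every potentiated spine, spine volume only in SER-containing
#' spines) and the PSD/volume coupling noise is assigned according to
#' whether the final volume falls in the decoupling band.
#'
#' @param config a [synth_config()] object.
#' @return A data.frame of spine records with columns
#'   `id, sample_id, condition, volume_um3, psd_area_um2,
#'   psd_core_volume_um3, has_ser, has_spine_apparatus, perforated,
#'   n_synapses`.
#' @examples
#' pop <- generate_population(synth_config(seed = 7))
#' table(pop$condition)
#' @export
generate_population <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("'config' must be a synth_config object", call. = FALSE)
  }
  with_seed(config$seed, {
    gen <- function(n, condition, id_offset) {
      logV <- rnorm(n, config$logV_mean, config$logV_sd)
      ser <- runif(n) < plogis(config$ser_logit_b0 +
                                 config$ser_logit_b1 * logV)
      if (condition == "cltp") {
        logV <- logV + ifelse(ser, log10(config$cltp_spine_factor_ser), 0)
      }
      V <- 10^logV
      if (condition == "cltp") {
        in_band <- V >= config$cltp_band_lo & V <= config$cltp_band_hi
      } else {
        in_band <- V >= config$band_lo & V <= config$band_hi
      }
      eps <- rnorm(n, 0, ifelse(in_band, config$noise_sd_band,
                                config$noise_sd_base))
      logA <- config$slope_a * logV + config$intercept_b + eps
      if (condition == "cltp") logA <- logA + log10(config$cltp_psd_factor)
      A <- 10^logA
      # core volume derives from the (already potentiated) PSD area, so the
      # cLTP factor propagates once
      Vp <- 10^(logA + log10(config$core_area_ratio) +
                  rnorm(n, 0, config$core_noise_sd))
      apparatus <- ser & (runif(n) < config$apparatus_prob)
      perforated <- runif(n) < ifelse(ser, config$perf_prob_ser,
                                      config$perf_prob_noser)
      data.frame(
        id = sprintf("%s_%04d", condition, id_offset + seq_len(n)),
        sample_id = sprintf("%s_s%d", condition,
                            1L + (seq_len(n) - 1L) %%
                              config$n_samples_per_condition),
        condition = condition,
        volume_um3 = V,
        psd_area_um2 = A,
        psd_core_volume_um3 = Vp,
        has_ser = ser,
        has_spine_apparatus = apparatus,
        perforated = perforated,
        n_synapses = 1L,
        stringsAsFactors = FALSE)
    }
    out <- rbind(gen(config$n_control, "control", 0L),
                 gen(config$n_cltp, "cltp", 0L))
    rownames(out) <- NULL
    out
  })
}

#' Generate a serial-section trace stack for one spine
#'
#' Builds a synthetic [trace_stack()] emulating what a manual annotator
#' produces: the spine as spheroid cross-section polygons (closed traces,
#' label `"spine"`) on consecutive sections, and the PSD as open polylines
#' (label `"psd_core"`) on the top sections.  Contours are scaled so that
#' Cavalieri summation (area x thickness per section) recovers the target
#' spine volume, and polyline lengths so that length x thickness summation
#' recovers the target PSD area; both up to polygon discretisation error
#' (well under 1%).
#'
#' @param record a single spine record (one-row data.frame or list) with at
#'   least `volume_um3` and `psd_area_um2`; an `id` is used as object id if
#'   present.
#' @param thickness section thickness in um (plausible EM range, e.g.
#'   0.05-0.07).
#' @param seed RNG seed controlling the in-plane orientation jitter.
#' @param n_vertices vertices per cross-section polygon.
#' @return A [trace_stack()].
#' @export
generate_contour_stacks <- function(record, thickness, seed = NULL,
                                    n_vertices = 64L) {
  check_scalar(thickness, "thickness", positive = TRUE)
  V <- record$volume_um3
  A <- record$psd_area_um2
  check_scalar(V, "record$volume_um3", positive = TRUE)
  check_scalar(A, "record$psd_area_um2", positive = TRUE)
  object_id <- if (!is.null(record$id)) as.character(record$id) else "spine"
  with_seed(seed, {
    r <- (3 * V / (4 * pi))^(1 / 3)
    # slab midpoints inside the sphere
    z <- if (r > thickness / 2) {
      zz <- seq(-r + thickness / 2, r, by = thickness)
      zz[abs(zz) < r]
    } else {
      numeric(0)
    }
    theta0 <- runif(1, 0, 2 * pi)
    cx <- runif(1, -0.1, 0.1)
    cy <- runif(1, -0.1, 0.1)
    traces <- list()
    if (length(z) == 0L) {
      # degenerate: thinner than one section; one contour carries all volume
      rho <- sqrt(V / (thickness * pi))
      z <- 0
      radii <- rho
    } else {
      radii <- sqrt(pmax(r^2 - z^2, 0))
      # regular n-gon of circumradius rho has area (n/2) rho^2 sin(2 pi/n);
      # rescale so summed area x thickness hits V exactly
      ngon_area <- function(rho) {
        (n_vertices / 2) * rho^2 * sin(2 * pi / n_vertices)
      }
      total <- sum(ngon_area(radii)) * thickness
      radii <- radii * sqrt(V / total)
    }
    ang <- theta0 + seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    for (k in seq_along(z)) {
      traces[[length(traces) + 1L]] <- trace_contour(
        section_index = k - 1L,
        kind = "closed_polygon",
        label = "spine",
        vertices = cbind(cx + radii[k] * cos(ang),
                         cy + radii[k] * sin(ang)))
    }
    # PSD open polylines on up to 3 top sections, total length A / thickness
    n_psd <- min(3L, length(z))
    total_len <- A / thickness
    seg_len <- total_len / n_psd
    psd_sections <- rev(seq_along(z))[seq_len(n_psd)] - 1L
    for (k in seq_len(n_psd)) {
      phi <- theta0 + k
      x0 <- cx - seg_len / 2 * cos(phi)
      y0 <- cy - seg_len / 2 * sin(phi)
      traces[[length(traces) + 1L]] <- trace_contour(
        section_index = psd_sections[k],
        kind = "open_polyline",
        label = "psd_core",
        vertices = rbind(c(x0, y0),
                         c(x0 + seg_len * cos(phi),
                           y0 + seg_len * sin(phi))))
    }
    trace_stack(object_id = object_id, traces = traces,
                section_thickness = thickness)
  })
}

#' Generate a homogeneous-Poisson synapse scene
#'
#' Simulates synapse reference locations (e.g. PSD centroids) as a
#' homogeneous Poisson point process inside an axis-aligned box, the
#' ground-truth scene for unbiased-brick counting tests.
#'
#' @param intensity expected points per um^3 (>= 0).
#' @param box_dims box edge lengths `c(w, h, d)` in um.
#' @param box_origin box corner, default the origin.
#' @param seed RNG seed.
#' @return A data.frame with columns `x_um, y_um, z_um` (possibly 0 rows).
#' @export
generate_brick_scene <- function(intensity, box_dims,
                                 box_origin = c(0, 0, 0), seed = NULL) {
  if (!is.numeric(intensity) || length(intensity) != 1L ||
      !is.finite(intensity) || intensity < 0) {
    stop("'intensity' must be a single non-negative number", call. = FALSE)
  }
  if (length(box_dims) != 3L || any(!is.finite(box_dims)) ||
      any(box_dims <= 0)) {
    stop("'box_dims' must be three positive edge lengths", call. = FALSE)
  }
  if (length(box_origin) != 3L || any(!is.finite(box_origin))) {
    stop("'box_origin' must be three finite coordinates", call. = FALSE)
  }
  with_seed(seed, {
    n <- rpois(1L, intensity * prod(box_dims))
    data.frame(
      x_um = box_origin[1] + runif(n) * box_dims[1],
      y_um = box_origin[2] + runif(n) * box_dims[2],
      z_um = box_origin[3] + runif(n) * box_dims[3])
  })
}
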