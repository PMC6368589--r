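test_that("polygon area handles the elementary shapes", {
  expect_equal(polygon_area(square_vertices()), 1.0)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  # orientation and starting vertex do not matter
  sq <- square_vertices()
  expect_equal(polygon_area(sq[4:1, ]), 1.0)
  expect_equal(polygon_area(sq[c(3, 4, 1, 2), ]), 1.0)
  # duplicated closing vertex tolerated
  expect_equal(polygon_area(rbind(sq, sq[1, ])), 1.0)
})

test_that("degenerate polygons are rejected with diagnostics", {
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "at least 3")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon_area(bowtie), "self-intersecting")
})

test_that("polygon area agrees with a rejection-sampling estimate", {
  set.seed(77)
  # random convex 12-gon: sorted angles on a noisy circle
  ang <- sort(runif(12, 0, 2 * pi))
  v <- cbind(cos(ang), sin(ang))
  a <- polygon_area(v)
  # Monte-Carlo hit counting in the bounding box
  n_mc <- 1e6
  pts <- cbind(runif(n_mc, -1, 1), runif(n_mc, -1, 1))
  vc <- ccw(v)
  inside <- rep(TRUE, n_mc)
  for (i in seq_len(nrow(vc))) {
    j <- if (i == nrow(vc)) 1L else i + 1L
    cr <- (vc[j, 1] - vc[i, 1]) * (pts[, 2] - vc[i, 2]) -
      (vc[j, 2] - vc[i, 2]) * (pts[, 1] - vc[i, 1])
    inside <- inside & cr >= 0
  }
  a_mc <- 4 * mean(inside)
  expect_lt(abs(a - a_mc) / a, 0.01)
})

test_that("Cavalieri volume sums area times thickness per section", {
  traces <- lapply(0:2, function(k) {
    trace_contour(k, "closed_polygon", square_vertices(), label = "spine")
  })
  st <- trace_stack("obj", traces, 0.05)
  expect_equal(measure_volume(st, "spine"), 0.15)
  st1 <- trace_stack("obj", list(
    trace_contour(0, "closed_polygon",
                  square_vertices(side = sqrt(0.02)), label = "spine")),
    0.06)
  expect_equal(measure_volume(st1, "spine"), 0.0012)
})

test_that("sliced sphere volume approaches the analytic value", {
  r <- 0.3; t <- 0.01
  z <- seq(-r + t / 2, r, by = t)
  z <- z[abs(z) < r]
  traces <- lapply(seq_along(z), function(k) {
    trace_contour(k - 1L, "closed_polygon",
                  regular_polygon(256, sqrt(r^2 - z[k]^2)),
                  label = "spine")
  })
  st <- trace_stack("sphere", traces, t)
  expect_lt(abs(measure_volume(st) - 4 / 3 * pi * r^3) /
              (4 / 3 * pi * r^3), 0.02)
})

test_that("open traces under a volume label are ignored with a warning", {
  st <- trace_stack("obj", list(
    trace_contour(0, "closed_polygon", square_vertices(), label = "spine"),
    trace_contour(1, "open_polyline", rbind(c(0, 0), c(1, 0)),
                  label = "spine")), 0.05)
  expect_warning(v <- measure_volume(st, "spine"), "open")
  expect_equal(v, 0.05)
  st2 <- trace_stack("obj", list(
    trace_contour(0, "closed_polygon", square_vertices(),
                  label = "spine")), 0.05)
  expect_error(measure_volume(st2, "psd_core"), "no traces")
})

test_that("PSD area mixes perpendicular polylines and parallel outlines", {
  mk <- function(traces) trace_stack("psd", traces, 0.06)
  line1 <- trace_contour(0, "open_polyline",
                         rbind(c(0, 0), c(0.2, 0)), label = "psd_core")
  line2 <- trace_contour(1, "open_polyline",
                         rbind(c(0, 0), c(0, 0.3)), label = "psd_core")
  parallel <- trace_contour(2, "closed_polygon",
                            square_vertices(side = 0.2), label = "psd_core")
  expect_equal(measure_psd_area(mk(list(line1, line2))), 0.03)
  expect_equal(measure_psd_area(mk(list(parallel))), 0.04)
  expect_equal(measure_psd_area(mk(list(line1, line2, parallel))), 0.07)
  expect_error(measure_psd_area(mk(list(trace_contour(
    0, "closed_polygon", square_vertices(), label = "spine")))),
    "psd_core")
})

test_that("cylindrical diameters thickness estimation", {
  expect_equal(estimate_section_thickness(
    data.frame(diameter_um = 0.30, span_sections = 5))$thickness_um, 0.06)
  est <- estimate_section_thickness(
    data.frame(diameter_um = c(0.30, 0.35), span_sections = c(5, 5)))
  expect_equal(est$thickness_um, 0.065)
  expect_equal(est$per_observation$estimate_um, c(0.060, 0.070))
  expect_error(estimate_section_thickness(data.frame()), "non-empty")
  expect_error(estimate_section_thickness(
    data.frame(diameter_um = 0.3, span_sections = 0)), "span")
})

test_that("thickness estimate recovers a simulated sectioning", {
  set.seed(5)
  t_true <- 0.055
  obs <- do.call(rbind, lapply(1:200, function(i) {
    d <- runif(1, 0.2, 0.5)
    z0 <- runif(1, 0, t_true)
    # sections [k t, (k+1) t); a section shows the object only when the
    # overlap exceeds half a section (a thin cap sliver is not
    # recognisable as the organelle)
    ks <- 0:ceiling((z0 + d) / t_true)
    overlap <- pmin((ks + 1) * t_true, z0 + d) - pmax(ks * t_true, z0)
    s <- sum(overlap > t_true / 2)
    data.frame(diameter_um = d, span_sections = s)
  }))
  est <- estimate_section_thickness(obs)$thickness_um
  expect_lt(abs(est - t_true) / t_true, 0.10)
})

test_that("multisynaptic merging sums PSDs and OR-combines flags", {
  base <- make_records(volume = rep(0.2, 2),
                       psd_area = c(0.02, 0.03),
                       psd_core = c(0.001, 0.002),
                       id = rep("spA", 2))
  base$has_ser <- c(TRUE, FALSE)
  merged <- merge_multisynaptic(base)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$psd_area_um2, 0.05)
  expect_equal(merged$psd_core_volume_um3, 0.003)
  expect_equal(merged$n_synapses, 2L)
  expect_true(merged$has_ser)
  # identity on a single record
  single <- make_records(0.1, id = "spB")
  expect_equal(merge_multisynaptic(single), single)
  # three synapses
  tri <- make_records(rep(0.3, 3), psd_area = rep(0.02, 3),
                      psd_core = rep(0.001, 3), id = rep("spC", 3))
  expect_equal(merge_multisynaptic(tri)$psd_core_volume_um3, 0.003)
  # conflicting volumes rejected
  bad <- make_records(c(0.2, 0.25), id = rep("spD", 2))
  expect_error(merge_multisynaptic(bad), "conflicting")
})

test_that("measurements are invariant under rigid transforms and scale
           as k^3 / k^2", {
  rec <- list(id = "sp", volume_um3 = 0.12, psd_area_um2 = 0.05)
  st <- generate_contour_stacks(rec, 0.05, seed = 8)
  th <- 0.7
  rot <- function(v) cbind(cos(th) * v[, 1] - sin(th) * v[, 2] + 3,
                           sin(th) * v[, 1] + cos(th) * v[, 2] - 1)
  st_rot <- st
  st_rot$traces <- lapply(st$traces, function(tr) {
    tr$vertices <- rot(tr$vertices); tr
  })
  expect_equal(measure_volume(st_rot), measure_volume(st),
               tolerance = 1e-12)
  expect_equal(measure_psd_area(st_rot), measure_psd_area(st),
               tolerance = 1e-12)
  k <- 2.5
  st_k <- st
  st_k$traces <- lapply(st$traces, function(tr) {
    tr$vertices <- tr$vertices * k; tr
  })
  st_k$section_thickness <- st$section_thickness * k
  expect_equal(measure_volume(st_k), k^3 * measure_volume(st),
               tolerance = 1e-12)
  expect_equal(measure_psd_area(st_k), k^2 * measure_psd_area(st),
               tolerance = 1e-12)
})

test_that("splitting a polygon into adjacent parts conserves volume", {
  whole <- trace_stack("w", list(
    trace_contour(0, "closed_polygon", square_vertices(side = 1),
                  label = "spine")), 0.05)
  split2 <- trace_stack("s", list(
    trace_contour(0, "closed_polygon",
                  rbind(c(0, 0), c(0.4, 0), c(0.4, 1), c(0, 1)),
                  label = "spine"),
    trace_contour(0, "closed_polygon",
                  rbind(c(0.4, 0), c(1, 0), c(1, 1), c(0.4, 1)),
                  label = "spine")), 0.05)
  expect_lt(abs(measure_volume(whole) - measure_volume(split2)), 1e-9)
})

test_that("Cavalieri volume matches a fine voxelisation oracle", {
  set.seed(13)
  t <- 0.05
  stacks <- lapply(1:3, function(k) {
    regular_polygon(24, r = runif(1, 0.2, 0.4),
                    cx = runif(1, -0.05, 0.05),
                    cy = runif(1, -0.05, 0.05),
                    phase = runif(1, 0, pi))
  })
  st <- trace_stack("conv", lapply(seq_along(stacks), function(k) {
    trace_contour(k - 1L, "closed_polygon", stacks[[k]], label = "spine")
  }), t)
  v_oracle <- sum(vapply(stacks, function(v) {
    raster_polygon_area(ccw(v), h = 5e-4)
  }, numeric(1))) * t
  v <- measure_volume(st)
  expect_lt(abs(v - v_oracle) / v_oracle, 0.005)
})

test_that("trace stacks round-trip through JSON exactly", {
  rec <- list(id = "rt", volume_um3 = 0.08, psd_area_um2 = 0.04)
  st <- generate_contour_stacks(rec, 0.06, seed = 15)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_trace_stack(st, path)
  st2 <- read_trace_stack(path)
  expect_equal(st2$object_id, st$object_id)
  expect_equal(st2$section_thickness, st$section_thickness)
  expect_equal(length(st2$traces), length(st$traces))
  expect_equal(measure_volume(st2), measure_volume(st))
  expect_equal(measure_psd_area(st2), measure_psd_area(st))
  for (k in seq_along(st$traces)) {
    expect_equal(st2$traces[[k]]$vertices, st$traces[[k]]$vertices)
    expect_equal(st2$traces[[k]]$kind, st$traces[[k]]$kind)
  }
})
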