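#' Construct a single serial-section trace
#'
#' A trace is one annotation drawn on one section: either a closed polygon
#' (spine or PSD-core cross-section outline) or an open polyline (PSD drawn
#' as a line where the PSD-core runs perpendicular to the section plane).
#'
#' @param section_index non-negative integer section number.
#' @param kind `"closed_polygon"` or `"open_polyline"`.
#' @param vertices ordered (x, y) coordinate matrix in um; a closed polygon
#'   needs >= 3 vertices (not self-intersecting), an open polyline >= 2.
#' @param label `"spine"` or `"psd_core"`.
#' @return An object of class `trace_contour`.
#' @export
trace_contour <- function(section_index, kind, vertices,
                          label = c("spine", "psd_core")) {
  check_scalar(section_index, "section_index", integer = TRUE, lo = 0)
  kind <- match.arg(kind, c("closed_polygon", "open_polyline"))
  label <- match.arg(label)
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || any(!is.finite(v))) {
    stop("'vertices' must be a finite two-column (x, y) matrix",
         call. = FALSE)
  }
  if (kind == "closed_polygon" && nrow(v) < 3L) {
    stop("a closed polygon needs at least 3 vertices", call. = FALSE)
  }
  if (kind == "open_polyline" && nrow(v) < 2L) {
    stop("an open polyline needs at least 2 vertices", call. = FALSE)
  }
  structure(list(section_index = as.integer(section_index), kind = kind,
                 label = label, vertices = unname(v)),
            class = "trace_contour")
}

#' Construct a trace stack
#'
#' The full set of traces for one reconstructed object across serial
#' sections, together with the section thickness.  Multiple traces per
#' section are allowed and are summed by the measurement functions.
#'
#' @param object_id identifier of the reconstructed object.
#' @param traces list of [trace_contour()] objects.
#' @param section_thickness section thickness t in um (> 0).
#' @return An object of class `trace_stack`.
#' @export
trace_stack <- function(object_id, traces, section_thickness) {
  check_scalar(section_thickness, "section_thickness", positive = TRUE)
  if (!is.list(traces) || length(traces) == 0L ||
      !all(vapply(traces, inherits, logical(1), "trace_contour"))) {
    stop("'traces' must be a non-empty list of trace_contour objects",
         call. = FALSE)
  }
  structure(list(object_id = as.character(object_id), traces = traces,
                 section_thickness = section_thickness),
            class = "trace_stack")
}

#' @export
print.trace_stack <- function(x, ...) {
  kinds <- vapply(x$traces, `[[`, character(1), "kind")
  cat(sprintf(
    "Trace stack '%s': %d traces (%d closed, %d open), t = %g um\n",
    x$object_id, length(x$traces), sum(kinds == "closed_polygon"),
    sum(kinds == "open_polyline"), x$section_thickness))
  invisible(x)
}

#' Planar polygon area (shoelace formula)
#'
#' Area of a simple (non-self-intersecting) closed polygon, independent of
#' vertex orientation and starting vertex.  A duplicated closing vertex is
#' tolerated and dropped.
#'
#' @param vertices (x, y) matrix of >= 3 vertices in um.
#' @return Area in um^2.
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || any(!is.finite(v))) {
    stop("'vertices' must be a finite two-column (x, y) matrix",
         call. = FALSE)
  }
  if (nrow(v) > 1L && all(v[1L, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  n <- nrow(v)
  if (n < 3L) stop("a polygon needs at least 3 vertices", call. = FALSE)
  si <- polygon_self_intersections(v)
  if (nrow(si)) {
    stop(sprintf(
      "polygon is self-intersecting (edge %d crosses edge %d)",
      si[1L, 1L], si[1L, 2L]), call. = FALSE)
  }
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

# proper crossings between non-adjacent edges; returns a 2-col matrix of
# offending edge index pairs (1-based)
polygon_self_intersections <- function(v) {
  n <- nrow(v)
  p1 <- v
  p2 <- v[c(2:n, 1L), , drop = FALSE]
  out <- matrix(integer(0), ncol = 2L)
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2L)) {
    # skip adjacent edges (shared vertex), incl. wrap-around for edge 1
    j <- setdiff((i + 2L):n, if (i == 1L) n else integer(0))
    if (!length(j)) next
    d1 <- orient(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p1[j, 1], p1[j, 2])
    d2 <- orient(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p2[j, 1], p2[j, 2])
    d3 <- orient(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2],
                 rep(p1[i, 1], length(j)), rep(p1[i, 2], length(j)))
    d4 <- orient(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2],
                 rep(p2[i, 1], length(j)), rep(p2[i, 2], length(j)))
    hit <- d1 * d2 < 0 & d3 * d4 < 0
    if (any(hit)) out <- rbind(out, cbind(i, j[hit]))
  }
  out
}

polyline_length <- function(v) {
  d <- diff(v)
  sum(sqrt(rowSums(d^2)))
}

#' Cavalieri volume from closed traces
#'
#' Spine or PSD-core volume measured the way serial-section reconstruction
#' software does: the polygon areas on each section are summed and
#' multiplied by the section thickness (Cavalieri estimator, no
#' interpolation between sections).
#'
#' @param stack a [trace_stack()].
#' @param label which traces to measure, `"spine"` (default) or
#'   `"psd_core"`.
#' @return Volume in um^3.
#' @export
measure_volume <- function(stack, label = "spine") {
  if (!inherits(stack, "trace_stack")) {
    stop("'stack' must be a trace_stack", call. = FALSE)
  }
  label <- match.arg(label, c("spine", "psd_core"))
  sel <- Filter(function(tr) tr$label == label, stack$traces)
  if (!length(sel)) {
    stop(sprintf("no traces with label '%s' in stack '%s'", label,
                 stack$object_id), call. = FALSE)
  }
  open <- vapply(sel, function(tr) tr$kind == "open_polyline", logical(1))
  if (any(open)) {
    warning(sprintf(
      "ignoring %d open trace(s) under label '%s' for volume measurement",
      sum(open), label), call. = FALSE)
    sel <- sel[!open]
  }
  if (!length(sel)) {
    stop(sprintf("no closed traces with label '%s' to measure", label),
         call. = FALSE)
  }
  areas <- vapply(sel, function(tr) polygon_area(tr$vertices), numeric(1))
  sum(areas) * stack$section_thickness
}

#' PSD surface area from PSD-core traces
#'
#' PSD area accumulated over sections: open polylines (PSD-core
#' perpendicular to the section plane) contribute length x thickness,
#' closed polygons labelled `psd_core` (PSD-core parallel to the section
#' plane, outlined rather than line-traced) contribute their planar area.
#' Both kinds may coexist in one stack and are summed.
#'
#' @param stack a [trace_stack()] containing `psd_core` traces.
#' @return PSD surface area in um^2.
#' @export
measure_psd_area <- function(stack) {
  if (!inherits(stack, "trace_stack")) {
    stop("'stack' must be a trace_stack", call. = FALSE)
  }
  sel <- Filter(function(tr) tr$label == "psd_core", stack$traces)
  if (!length(sel)) {
    stop(sprintf("no 'psd_core' traces in stack '%s'", stack$object_id),
         call. = FALSE)
  }
  contrib <- vapply(sel, function(tr) {
    if (tr$kind == "open_polyline") {
      polyline_length(tr$vertices) * stack$section_thickness
    } else {
      polygon_area(tr$vertices)
    }
  }, numeric(1))
  sum(contrib)
}

#' Section thickness by the cylindrical diameters method
#'
#' True section thickness estimated from organelles of approximately
#' cylindrical shape cut longitudinally: an object of in-plane diameter d
#' that spans s consecutive sections implies a thickness of about d / s.
#' Estimates are averaged arithmetically over observations; per-observation
#' values are returned for quality control.
#'
#' @param observations data.frame with columns `diameter_um` (> 0) and
#'   `span_sections` (integer >= 1).
#' @return A list with `thickness_um` (the mean estimate) and
#'   `per_observation` (the input with an `estimate_um` column).
#' @examples
#' estimate_section_thickness(
#'   data.frame(diameter_um = c(0.30, 0.35), span_sections = c(5, 5)))
#' @export
estimate_section_thickness <- function(observations) {
  if (!is.data.frame(observations) || nrow(observations) == 0L) {
    stop("'observations' must be a non-empty data.frame", call. = FALSE)
  }
  if (!all(c("diameter_um", "span_sections") %in% names(observations))) {
    stop("'observations' needs columns 'diameter_um' and 'span_sections'",
         call. = FALSE)
  }
  d <- observations$diameter_um
  s <- observations$span_sections
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("all diameters must be positive", call. = FALSE)
  }
  if (any(!is.finite(s)) || any(s < 1) || any(s != round(s))) {
    stop("all section spans must be integers >= 1", call. = FALSE)
  }
  per <- observations
  per$estimate_um <- d / s
  list(thickness_um = mean(per$estimate_um), per_observation = per)
}

#' Merge per-synapse records of a multisynaptic spine
#'
#' A spine contacted by several boutons has one PSD per synapse; its PSD
#' area and PSD-core volume are the sums over synapses, while the spine
#' volume is a property of the spine itself and must agree across the
#' per-synapse rows.  Annotation flags are OR-combined.
#'
#' @param records data.frame of per-synapse records sharing one spine `id`
#'   (same columns as [generate_population()] output).
#' @return A single-row data.frame with summed PSD measures and
#'   `n_synapses` set to the total synapse count.
#' @export
merge_multisynaptic <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data.frame", call. = FALSE)
  }
  if (length(unique(records$id)) != 1L) {
    stop("all records must share one spine id (got: ",
         paste(unique(records$id), collapse = ", "), ")", call. = FALSE)
  }
  v <- records$volume_um3
  if (diff(range(v)) > 1e-9 * max(abs(v))) {
    stop(sprintf(
      "conflicting spine volumes for id '%s': %s", records$id[1L],
      paste(format(v), collapse = ", ")), call. = FALSE)
  }
  out <- records[1L, , drop = FALSE]
  out$psd_area_um2 <- sum(records$psd_area_um2)
  out$psd_core_volume_um3 <- sum(records$psd_core_volume_um3)
  out$has_ser <- any(records$has_ser)
  out$has_spine_apparatus <- any(records$has_spine_apparatus)
  out$perforated <- any(records$perforated)
  out$n_synapses <- as.integer(sum(records$n_synapses))
  rownames(out) <- NULL
  out
}

#' Serialise a trace stack to JSON
#'
#' The on-disk format is
#' `{object_id, section_thickness, traces:[{section_index, kind, label,
#' vertices:[[x,y],...]}]}`; [read_trace_stack()] restores it exactly.
#'
#' @param stack a [trace_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_stack <- function(stack, path) {
  if (!inherits(stack, "trace_stack")) {
    stop("'stack' must be a trace_stack", call. = FALSE)
  }
  payload <- list(
    object_id = stack$object_id,
    section_thickness = stack$section_thickness,
    traces = lapply(stack$traces, function(tr) {
      list(section_index = tr$section_index, kind = tr$kind,
           label = tr$label, vertices = tr$vertices)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trace stack from JSON
#'
#' @param path file written by [write_trace_stack()] (or any file in the
#'   same dialect).
#' @return A [trace_stack()].
#' @export
read_trace_stack <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  for (field in c("object_id", "section_thickness", "traces")) {
    if (is.null(raw[[field]])) {
      stop(sprintf("trace-stack file '%s' is missing field '%s'", path,
                   field), call. = FALSE)
    }
  }
  tr_list <- raw$traces
  if (is.data.frame(tr_list)) {
    tr_list <- lapply(seq_len(nrow(tr_list)), function(i) {
      list(section_index = tr_list$section_index[i],
           kind = tr_list$kind[i], label = tr_list$label[i],
           vertices = tr_list$vertices[[i]])
    })
  }
  traces <- lapply(tr_list, function(tr) {
    trace_contour(section_index = tr$section_index, kind = tr$kind,
                  vertices = tr$vertices, label = tr$label)
  })
  trace_stack(object_id = raw$object_id, traces = traces,
              section_thickness = raw$section_thickness)
}
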