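# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards.  seed = NULL means "use the ambient RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number or NULL", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# scalar checks with readable failure messages
check_scalar <- function(x, name, positive = FALSE, integer = FALSE,
                         lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be a whole number (got %g)", name, x),
         call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("'%s' must be in [%g, %g] (got %g)", name, lo, hi, x),
         call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, name) {
  check_scalar(x, name, lo = 0, hi = 1)
}

# columns a per-spine record table must carry (also the CSV header)
record_columns <- function() {
  c("id", "sample_id", "condition", "volume_um3", "psd_area_um2",
    "psd_core_volume_um3", "has_ser", "has_spine_apparatus", "perforated",
    "n_synapses")
}

check_records <- function(records, require_condition = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data.frame of spine records",
         call. = FALSE)
  }
  missing <- setdiff(record_columns(), names(records))
  if (length(missing)) {
    stop("records table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(records$volume_um3) | records$volume_um3 <= 0)
  if (length(bad)) {
    stop("non-positive spine volume in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(records$psd_area_um2) | records$psd_area_um2 <= 0)
  if (length(bad)) {
    stop("non-positive PSD area in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(records$psd_core_volume_um3) |
                 records$psd_core_volume_um3 <= 0)
  if (length(bad)) {
    stop("non-positive PSD-core volume in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!records$condition %in% c("control", "cltp"))
  if (length(bad)) {
    stop("unknown condition in row(s): ", paste(bad, collapse = ", "),
         " (must be 'control' or 'cltp')", call. = FALSE)
  }
  bad <- which(records$has_spine_apparatus & !records$has_ser)
  if (length(bad)) {
    stop("spine apparatus without SER (invariant violated) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(records)
}
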