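#' Parameters of the sliding-window local Spearman procedure
#'
#' The local correlation profile is computed by centring, at each spine's
#' volume rank, one window of every size in `window_sizes`; each window is
#' resampled `n_boot` times without replacement to subsets of
#' `window size - subset_deficit` pairs; Spearman's rho and its p-value are
#' computed per subset and averaged over all subsets and window sizes
#' jointly.  The defaults are windows of 14-24 spines, 2500 resamples, and
#' a deficit of 4 (subsets of 10-20 pairs).
#'
#' @param window_sizes integer vector of window sizes (spines per window).
#' @param n_boot resamples per window.
#' @param subset_deficit how many pairs fewer than the window each resample
#'   contains.
#' @param alpha significance level for the local p-value (strict
#'   `mean_p < alpha`).
#' @param seed RNG seed for the resampling; `NULL` uses the ambient stream.
#' @param degenerate what a resample with constant values contributes:
#'   `"zero"` (rho 0, p 1, counted) or `"skip"` (dropped from the
#'   averages).
#' @return An object of class `local_corr_params`.
#' @export
local_corr_params <- function(window_sizes = 14:24, n_boot = 2500L,
                              subset_deficit = 4L, alpha = 0.05,
                              seed = NULL,
                              degenerate = c("zero", "skip")) {
  if (length(window_sizes) == 0L || any(window_sizes != round(window_sizes))) {
    stop("'window_sizes' must be a non-empty integer vector", call. = FALSE)
  }
  check_scalar(n_boot, "n_boot", positive = TRUE, integer = TRUE)
  check_scalar(subset_deficit, "subset_deficit", integer = TRUE, lo = 0)
  if (min(window_sizes) <= subset_deficit + 2) {
    stop(sprintf(
      "smallest window (%d) must exceed subset_deficit + 2 (%d)",
      min(window_sizes), subset_deficit + 2), call. = FALSE)
  }
  check_scalar(alpha, "alpha", lo = 0, hi = 1)
  if (alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be strictly between 0 and 1", call. = FALSE)
  }
  degenerate <- match.arg(degenerate)
  structure(list(window_sizes = sort(as.integer(window_sizes)),
                 n_boot = as.integer(n_boot),
                 subset_deficit = as.integer(subset_deficit),
                 alpha = alpha, seed = seed, degenerate = degenerate),
            class = "local_corr_params")
}

#' @export
print.local_corr_params <- function(x, ...) {
  cat(sprintf(
    "Local Spearman parameters: windows %d-%d, %d resamples of size window - %d, alpha %g\n",
    min(x$window_sizes), max(x$window_sizes), x$n_boot, x$subset_deficit,
    x$alpha))
  invisible(x)
}

#' Rank a paired dataset using the first variable as index
#'
#' Sorts the pairs by `x` (stably, so ties keep input order) and replaces
#' both variables by their ranks (ties receive average ranks).  This is the
#' preprocessing step of the local correlation procedure; because both
#' variables are reduced to ranks, every later stage is invariant under
#' strictly monotone transforms of either variable.
#'
#' @param x index variable (e.g. spine volumes).
#' @param y paired variable (e.g. PSD areas), same length.
#' @return A data.frame, in `x`-sorted order, with columns `index` (the
#'   original position), `x_rank` and `y_rank`.
#' @export
rank_by_index <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: length(x) = %d, length(y) = %d",
                 length(x), length(y)), call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  ord <- order(x)
  data.frame(index = ord,
             x_rank = rank(x[ord], ties.method = "average"),
             y_rank = rank(y[ord], ties.method = "average"))
}

#' Bootstrapped Spearman correlation of one window
#'
#' Draws `n_boot` subsets of `subset_size` distinct pairs (sampling without
#' replacement) from the window, computes Spearman's rho and its two-sided
#' p-value (t-distribution approximation on the subset size) for each, and
#' returns the arithmetic means.  Resamples in which either variable is
#' constant have no defined rank correlation; by default they contribute
#' rho = 0, p = 1 and are counted in `n_degenerate`.
#'
#' @param x,y the window's paired values.
#' @param subset_size resample size (>= 4, < window size).
#' @param n_boot number of resamples.
#' @param seed RNG seed; fixed seed gives identical output.
#' @param degenerate `"zero"` or `"skip"`, see [local_corr_params()].
#' @return A list with `mean_rho`, `mean_p`, `n_degenerate` and `n_used`.
#' @export
bootstrap_spearman <- function(x, y, subset_size, n_boot = 2500L,
                               seed = NULL,
                               degenerate = c("zero", "skip")) {
  degenerate <- match.arg(degenerate)
  w <- length(x)
  if (length(y) != w) stop("'x' and 'y' must have equal length", call. = FALSE)
  if (w < 4L) stop("window must hold at least 4 pairs", call. = FALSE)
  check_scalar(subset_size, "subset_size", positive = TRUE, integer = TRUE)
  if (subset_size >= w) {
    stop(sprintf("'subset_size' (%d) must be smaller than the window (%d)",
                 subset_size, w), call. = FALSE)
  }
  if (subset_size < 4L) stop("'subset_size' must be >= 4", call. = FALSE)
  check_scalar(n_boot, "n_boot", positive = TRUE, integer = TRUE)
  res <- with_seed(seed,
                   cpp_bootstrap_spearman(as.numeric(x), as.numeric(y),
                                          as.integer(subset_size),
                                          as.integer(n_boot),
                                          degenerate == "skip"))
  res
}

#' Local Spearman correlation profile across spine volumes
#'
#' The core of the analysis: for every spine, sliding windows of each size
#' in `params$window_sizes` are centred on the spine's volume rank (shifted
#' inward at the edges so every spine receives all window sizes), the
#' windowed pairs are bootstrapped as in [bootstrap_spearman()], and the
#' resulting rho and p values are averaged over all windows and resamples.
#' A spine is locally significant when its mean p falls below
#' `params$alpha`.
#'
#' @param records spine record table (see [generate_population()]).
#' @param parameter which coupling to profile: PSD area vs spine volume
#'   (`"psd_area"`), PSD-core volume vs spine volume
#'   (`"psd_core_volume"`), or PSD area vs PSD-core volume
#'   (`"psd_area_vs_core"`); windows are always formed along spine volume.
#' @param params a [local_corr_params()] object.
#' @return A data.frame of class `local_corr_profile`, ordered by volume,
#'   with columns `id, volume_um3, mean_rho, mean_p, n_windows,
#'   n_degenerate, significant`.
#' @export
local_profile <- function(records,
                          parameter = c("psd_area", "psd_core_volume",
                                        "psd_area_vs_core"),
                          params = local_corr_params()) {
  parameter <- match.arg(parameter)
  check_records(records)
  if (!inherits(params, "local_corr_params")) {
    stop("'params' must be a local_corr_params object", call. = FALSE)
  }
  n <- nrow(records)
  need <- max(params$window_sizes)
  if (n < need) {
    stop(sprintf(
      "too few records (%d) for the largest window: need at least %d",
      n, need), call. = FALSE)
  }
  ord <- order(records$volume_um3)  # stable: ties keep input order
  rec <- records[ord, , drop = FALSE]
  xy <- switch(parameter,
    psd_area = list(x = rec$volume_um3, y = rec$psd_area_um2),
    psd_core_volume = list(x = rec$volume_um3,
                           y = rec$psd_core_volume_um3),
    psd_area_vs_core = list(x = rec$psd_core_volume_um3,
                            y = rec$psd_area_um2))
  res <- with_seed(params$seed,
                   cpp_local_profile(as.numeric(xy$x), as.numeric(xy$y),
                                     params$window_sizes,
                                     params$subset_deficit,
                                     params$n_boot,
                                     params$degenerate == "skip"))
  out <- data.frame(id = rec$id,
                    volume_um3 = rec$volume_um3,
                    mean_rho = res$mean_rho,
                    mean_p = res$mean_p,
                    n_windows = res$n_windows,
                    n_degenerate = res$n_degenerate,
                    significant = res$mean_p < params$alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("local_corr_profile", "data.frame")
  attr(out, "parameter") <- parameter
  attr(out, "alpha") <- params$alpha
  attr(out, "params") <- params
  out
}

#' Volume ranges of non-significant local correlation
#'
#' Extracts, from a local correlation profile, the maximal contiguous runs
#' (in volume order) of spines whose mean local p is at or above `alpha` —
#' the "decoupling bands" where spine volume fails to predict PSD size.
#'
#' @param profile a [local_profile()] result.
#' @param alpha significance level; defaults to the one the profile was
#'   computed with.
#' @return A list with `bands` (data.frame `v_lo, v_hi, n_spines`),
#'   `n_decoupled`, `n_total` and `fraction`.
#' @export
nonsignificant_regions <- function(profile, alpha = NULL) {
  if (!inherits(profile, "local_corr_profile") || nrow(profile) == 0L) {
    stop("'profile' must be a non-empty local_corr_profile", call. = FALSE)
  }
  if (is.null(alpha)) alpha <- attr(profile, "alpha")
  nonsig <- profile$mean_p >= alpha
  runs <- rle(nonsig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  bands <- data.frame(
    v_lo = profile$volume_um3[starts[keep]],
    v_hi = profile$volume_um3[ends[keep]],
    n_spines = runs$lengths[keep])
  rownames(bands) <- NULL
  list(bands = bands,
       n_decoupled = sum(nonsig),
       n_total = nrow(profile),
       fraction = sum(nonsig) / nrow(profile))
}

#' Compare decoupled-spine counts between two profiles
#'
#' Builds the 2x2 table (locally significant vs not, by group) and applies
#' Pearson's chi-square test (no continuity correction), the test used to
#' compare how many spines sit in non-significant correlation ranges in
#' each condition.
#'
#' @param profile_a,profile_b two [local_profile()] results (e.g. control
#'   and cLTP).
#' @param labels group names for the output table.
#' @return A list with `statistic`, `df`, `p_value` and the 2x2 `table`.
#' @export
compare_decoupled_counts <- function(profile_a, profile_b,
                                     labels = c("A", "B")) {
  for (p in list(profile_a, profile_b)) {
    if (!inherits(p, "local_corr_profile") || nrow(p) == 0L) {
      stop("both profiles must be non-empty local_corr_profile objects",
           call. = FALSE)
    }
  }
  tab <- rbind(
    c(sum(profile_a$significant), sum(!profile_a$significant)),
    c(sum(profile_b$significant), sum(!profile_b$significant)))
  dimnames(tab) <- list(group = labels,
                        correlation = c("significant", "not_significant"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table (a zero marginal): counts ",
         paste(tab, collapse = ", "), call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}
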