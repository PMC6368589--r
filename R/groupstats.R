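#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' The workhorse comparison for the non-normally distributed morphometric
#' variables (spine volume, PSD area, PSD-core volume, ratios).  The exact
#' p-value is used for small samples (`min(n) <= 8`) without ties; larger
#' or tied samples use the tie-corrected normal approximation (no
#' continuity correction).  Both U and its complement U' = n1*n2 - U are
#' reported, since either convention appears in the literature.
#'
#' @param a,b numeric samples.
#' @return A list with `U`, `U_prime`, `p_value`, `n` and `method`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= 8L
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = FALSE))
  U <- unname(wt$statistic)
  list(U = U,
       U_prime = length(a) * length(b) - U,
       p_value = wt$p.value,
       n = c(length(a), length(b)),
       method = if (exact) "exact" else "normal approximation (tie-corrected)")
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' Used for variables that pass normality, notably the per-sample spine
#' densities (4 slices per condition giving df = 6).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return A list with `t`, `df` (`n1 + n2 - 2`) and `p_value`.
#' @export
t_test_unpaired <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  df <- length(a) + length(b) - 2L
  pooled_var <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = df, p_value = 1))
    }
    stop("zero pooled variance with unequal means: t undefined",
         call. = FALSE)
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Ordinary least squares on log10-log10 axes
#'
#' Fits the power-law (allometric) relation between two positive
#' morphometric variables as a straight line on log10 axes.
#'
#' @param x,y positive values (ids taken from names, if any).
#' @return An object of class `loglog_fit`: a list with `slope`,
#'   `intercept`, `residual_ss`, `n`, and the fitted `lm` as `model`.
#' @examples
#' f <- loglog_fit(c(1, 2, 4, 8), 10 * c(1, 2, 4, 8)^2)
#' c(f$slope, f$intercept)  # 2, 1
#' @export
loglog_fit <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  bad <- which(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0)
  if (length(bad)) {
    stop("non-positive value(s) at: ", paste(ids[bad], collapse = ", "),
         " (log-log fit needs positive data)", call. = FALSE)
  }
  d <- data.frame(lx = log10(x), ly = log10(y))
  m <- lm(ly ~ lx, data = d)
  structure(list(slope = unname(coef(m)[2L]),
                 intercept = unname(coef(m)[1L]),
                 residual_ss = sum(residuals(m)^2),
                 n = length(x),
                 model = m),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "log-log fit (n = %d): log10(y) = %.4f * log10(x) + %.4f, RSS = %.4g\n",
    x$n, x$slope, x$intercept, x$residual_ss))
  invisible(x)
}

#' ANCOVA comparison of two regression lines
#'
#' Tests whether two groups share a regression slope and, if so, whether
#' the lines differ in elevation.  The slope test compares the
#' separate-slopes model against the common-slope model,
#' `F = ((RSS_common - RSS_separate) / 1) / (RSS_separate / (n1 + n2 - 4))`;
#' the elevation test compares the common-slope model against a single
#' line, with denominator df `n1 + n2 - 3`.  By default both variables are
#' log10-transformed first (the allometric convention); set
#' `log_transform = FALSE` to compare on raw scale.
#'
#' @param x_a,y_a first group's data.
#' @param x_b,y_b second group's data.
#' @param log_transform log10-transform both axes first (default TRUE).
#' @return A list with `F_slope`, `df_slope`, `p_slope`, `F_elevation`,
#'   `df_elevation`, `p_elevation`, `slopes_homogeneous` (whether
#'   `p_slope >= 0.05`, i.e. the elevation test is interpretable) and the
#'   per-group `slopes`.
#' @export
ancova_compare <- function(x_a, y_a, x_b, y_b, log_transform = TRUE) {
  if (length(x_a) != length(y_a) || length(x_b) != length(y_b)) {
    stop("x/y length mismatch within a group", call. = FALSE)
  }
  if (length(x_a) < 3L || length(x_b) < 3L) {
    stop("each group needs at least 3 points", call. = FALSE)
  }
  if (log_transform) {
    if (any(c(x_a, y_a, x_b, y_b) <= 0)) {
      stop("log-log ANCOVA needs positive data", call. = FALSE)
    }
    x_a <- log10(x_a); y_a <- log10(y_a)
    x_b <- log10(x_b); y_b <- log10(y_b)
  }
  if (var(x_a) == 0 || var(x_b) == 0) {
    stop("degenerate x variance in a group: regression undefined",
         call. = FALSE)
  }
  n <- length(x_a) + length(x_b)
  d <- data.frame(x = c(x_a, x_b), y = c(y_a, y_b),
                  g = factor(rep(c("A", "B"), c(length(x_a), length(x_b)))))
  m_sep <- lm(y ~ x * g, data = d)    # separate slopes + intercepts
  m_par <- lm(y ~ x + g, data = d)    # common slope, separate elevations
  m_one <- lm(y ~ x, data = d)        # single line
  a_slope <- anova(m_par, m_sep)
  a_elev <- anova(m_one, m_par)
  F_slope <- a_slope$F[2L]
  F_elev <- a_elev$F[2L]
  p_slope <- a_slope$`Pr(>F)`[2L]
  co <- coef(m_sep)
  list(F_slope = F_slope, df_slope = c(1L, n - 4L), p_slope = p_slope,
       F_elevation = F_elev, df_elevation = c(1L, n - 3L),
       p_elevation = a_elev$`Pr(>F)`[2L],
       slopes_homogeneous = p_slope >= 0.05,
       slopes = c(A = unname(co["x"]), B = unname(co["x"] + co["x:gB"])))
}

#' Global Spearman rank correlation
#'
#' @param x,y paired values, n >= 3, neither constant.
#' @return A list with `rho`, `p_value` and `n` (two-sided p; exact for
#'   small untied samples, t approximation otherwise, as in
#'   [stats::cor.test()]).
#' @export
spearman_global <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("constant input: rank correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across >= 3 groups, followed by Dunn's
#' pairwise z tests on the pooled ranks,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with tie
#' term `T = sum(t^3 - t) / (12 (N - 1))`, Bonferroni-adjusted over the
#' compared pairs.
#'
#' @param groups named list of >= 3 numeric samples.
#' @param p_adjust multiplicity adjustment for the Dunn p-values (any
#'   [stats::p.adjust()] method; default `"bonferroni"`).
#' @return A list with `H`, `df`, `p_value` and a `dunn` data.frame
#'   (`group1, group2, z, p, p_adj`).
#' @export
kruskal_dunn <- function(groups, p_adjust = "bonferroni") {
  if (!is.list(groups) || length(groups) < 3L) {
    stop("'groups' must be a list of at least 3 samples", call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("all groups must be non-empty", call. = FALSE)
  if (any(sizes == 1L)) {
    warning("singleton group(s): ",
            paste(names(groups)[sizes == 1L], collapse = ", "),
            call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  if (length(unique(values)) == 1L) {
    kw <- list(H = 0, df = length(groups) - 1L, p_value = 1)
  } else {
    k <- kruskal.test(values, g)
    kw <- list(H = unname(k$statistic), df = unname(k$parameter),
               p_value = k$p.value)
  }
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  tie_tab <- table(values)
  Tie <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - Tie) * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  dunn <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     z = z, p = p,
                     p_adj = p.adjust(p, method = p_adjust))
  c(kw, list(dunn = dunn))
}

#' Per-spine PSD/volume ratio metrics
#'
#' Computes each spine's PSD-area-to-volume ratio A/V (um^-1) and
#' PSD-core-volume-to-volume ratio Vp/V (dimensionless), the quantities
#' whose increase under cLTP signals disproportionate PSD growth.  When
#' both conditions are present the ratios are compared with
#' [mann_whitney()].
#'
#' @param records spine record table.
#' @return A list with `per_spine` (id, condition, `av_ratio_per_um`,
#'   `vpv_ratio`), `medians` (per condition) and, when both conditions are
#'   present, `tests` (Mann-Whitney for each ratio).
#' @export
ratio_metrics <- function(records) {
  check_records(records)
  per <- data.frame(id = records$id, condition = records$condition,
                    av_ratio_per_um = records$psd_area_um2 /
                      records$volume_um3,
                    vpv_ratio = records$psd_core_volume_um3 /
                      records$volume_um3,
                    stringsAsFactors = FALSE)
  conds <- unique(per$condition)
  medians <- do.call(rbind, lapply(conds, function(cc) {
    sel <- per$condition == cc
    data.frame(condition = cc,
               median_av_ratio_per_um = median(per$av_ratio_per_um[sel]),
               median_vpv_ratio = median(per$vpv_ratio[sel]))
  }))
  out <- list(per_spine = per, medians = medians)
  if (all(c("control", "cltp") %in% conds)) {
    ctl <- per$condition == "control"
    out$tests <- list(
      av_ratio = mann_whitney(per$av_ratio_per_um[ctl],
                              per$av_ratio_per_um[!ctl]),
      vpv_ratio = mann_whitney(per$vpv_ratio[ctl], per$vpv_ratio[!ctl]))
  }
  out
}

#' Relative change of a parameter under cLTP, stratified by SER
#'
#' Because control and potentiated populations are different spines (no
#' per-spine baseline exists), the relative change of each cLTP spine is
#' defined against the median of the control spines in the same SER
#' stratum.  The two strata's relative values are then compared with
#' [mann_whitney()] — the comparison showing that spine growth is
#' concentrated in SER-containing spines.
#'
#' @param records spine record table containing both conditions in each
#'   SER stratum.
#' @param parameter which column to analyse: `"volume_um3"`,
#'   `"psd_area_um2"` or `"psd_core_volume_um3"`.
#' @return A list with `relative` (per cLTP spine: id, `has_ser`,
#'   `relative_value`), `stratum_control_medians` and `comparison`
#'   (Mann-Whitney, SER vs no-SER).
#' @export
relative_change <- function(records,
                            parameter = c("volume_um3", "psd_area_um2",
                                          "psd_core_volume_um3")) {
  parameter <- match.arg(parameter)
  check_records(records)
  strata <- c(FALSE, TRUE)
  med <- numeric(2)
  rel_list <- vector("list", 2)
  for (k in 1:2) {
    s <- strata[k]
    ctl <- records$condition == "control" & records$has_ser == s
    trt <- records$condition == "cltp" & records$has_ser == s
    if (!any(ctl) || !any(trt)) {
      stop(sprintf(
        "empty stratum: has_ser = %s must contain both conditions", s),
        call. = FALSE)
    }
    med[k] <- median(records[[parameter]][ctl])
    rel_list[[k]] <- data.frame(
      id = records$id[trt],
      has_ser = s,
      relative_value = records[[parameter]][trt] / med[k],
      stringsAsFactors = FALSE)
  }
  rel <- do.call(rbind, rel_list)
  rownames(rel) <- NULL
  list(relative = rel,
       stratum_control_medians = data.frame(has_ser = strata,
                                            control_median = med,
                                            row.names = NULL),
       comparison = mann_whitney(
         rel$relative_value[rel$has_ser],
         rel$relative_value[!rel$has_ser]))
}

#' Spine-volume frequency histogram
#'
#' Frequencies (%) of spines in fixed-width volume bins counted from zero,
#' left-closed right-open; the companion axis of the local-correlation
#' figures.  Frequencies sum to exactly 100.
#'
#' @param volumes numeric volumes (um^3) or a record table.
#' @param bin_width bin width in um^3 (default 0.05).
#' @return A data.frame with `bin_lo, bin_hi, count, frequency_pct`.
#' @export
volume_histogram <- function(volumes, bin_width = 0.05) {
  if (is.data.frame(volumes)) volumes <- volumes$volume_um3
  check_scalar(bin_width, "bin_width", positive = TRUE)
  if (length(volumes) == 0L || any(!is.finite(volumes)) ||
      any(volumes < 0)) {
    stop("'volumes' must be non-negative and non-empty", call. = FALSE)
  }
  idx <- floor(volumes / bin_width)
  n_bins <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = n_bins)
  data.frame(bin_lo = (seq_len(n_bins) - 1L) * bin_width,
             bin_hi = seq_len(n_bins) * bin_width,
             count = counts,
             frequency_pct = 100 * counts / length(volumes))
}

#' Descriptive summary of one group
#'
#' Reports both presentation conventions — mean +/- SEM and median +/- IQR
#' — together with a Shapiro-Wilk normality p-value so the caller can
#' display mean/SEM for normal samples and median/IQR otherwise.
#'
#' @param x numeric sample (n >= 1).
#' @return A list with `n, mean, sem, median, iqr, normality_p`
#'   (`normality_p` is `NA` when the test is not applicable: n < 3 or a
#'   constant sample).
#' @export
summarize_group <- function(x) {
  if (length(x) == 0L || any(!is.finite(x))) {
    stop("'x' must be non-empty and finite", call. = FALSE)
  }
  n <- length(x)
  normality_p <- NA_real_
  if (n >= 3L && n <= 5000L && length(unique(x)) > 1L) {
    normality_p <- shapiro.test(x)$p.value
  }
  list(n = n,
       mean = mean(x),
       sem = if (n >= 2L) sd(x) / sqrt(n) else NA_real_,
       median = median(x),
       iqr = IQR(x),
       normality_p = normality_p)
}
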