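test_that("Mann-Whitney matches the textbook landmarks", {
  a <- c(1, 5, 9, 13)
  r <- mann_whitney(a, a + 0.001)  # essentially identical, no ties
  expect_equal(r$U + r$U_prime, 16)
  r_id <- mann_whitney(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(r_id$U, 8)  # identical samples: U = n1 n2 / 2
  # complete separation
  r_sep <- mann_whitney(1:4, 11:14)
  expect_true(r_sep$U %in% c(0, 16))
  expect_equal(r_sep$U + r_sep$U_prime, 16)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney exact p matches exhaustive enumeration at 6/6", {
  set.seed(8)
  a <- round(rnorm(6, 0, 2), 3)
  b <- round(rnorm(6, 1, 2), 3)
  expect_equal(mann_whitney(a, b)$p_value, enum_mw_p(a, b),
               tolerance = 1e-12)
  # and a second draw with a stronger shift
  a2 <- round(rnorm(6, 0, 1), 3)
  b2 <- round(rnorm(6, 2, 1), 3)
  expect_equal(mann_whitney(a2, b2)$p_value, enum_mw_p(a2, b2),
               tolerance = 1e-12)
})

test_that("unpaired t-test: df, identity and textbook case", {
  set.seed(9)
  r <- t_test_unpaired(rnorm(4), rnorm(4))
  expect_equal(r$df, 6)
  same <- c(1.5, 2.5, 3.5)
  r2 <- t_test_unpaired(same, same)
  expect_equal(r2$t, 0)
  expect_equal(r2$p_value, 1)
  r3 <- t_test_unpaired(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r3$t, -1.224745, tolerance = 1e-6)
  expect_equal(r3$df, 4)
  expect_equal(t_test_unpaired(c(2, 2), c(2, 2))$t, 0)
  expect_error(t_test_unpaired(c(2, 2), c(3, 3)), "zero pooled variance")
})

test_that("log-log fit recovers exact power laws", {
  x <- c(1, 2, 4, 8, 16)
  f <- loglog_fit(x, 10 * x^2)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$residual_ss, 0, tolerance = 1e-20)
  # residual SS matches brute-force recomputation
  set.seed(14)
  x2 <- 10^runif(30, -2, 0)
  y2 <- x2^0.9 * 10^rnorm(30, 0, 0.1)
  f2 <- loglog_fit(x2, y2)
  rss <- sum((log10(y2) - (f2$intercept + f2$slope * log10(x2)))^2)
  expect_equal(f2$residual_ss, rss, tolerance = 1e-12)
  # outlier sensitivity smoke test
  y3 <- y2; y3[1] <- y3[1] * 100
  expect_false(isTRUE(all.equal(loglog_fit(x2, y3)$slope, f2$slope)))
  # non-positive input rejected with the offending id
  xx <- c(a = 1, b = -1, c = 2)
  expect_error(loglog_fit(xx, c(1, 1, 1)), "b")
})

test_that("ANCOVA degrees of freedom and degenerate cases", {
  set.seed(15)
  x1 <- 10^rnorm(119); y1 <- x1^0.8 * 10^rnorm(119, 0, 0.1)
  x2 <- 10^rnorm(138); y2 <- x2^1.1 * 10^rnorm(138, 0, 0.1)
  r <- ancova_compare(x1, y1, x2, y2)
  expect_equal(r$df_slope, c(1L, 253L))
  expect_equal(r$df_elevation, c(1L, 254L))
  # identical datasets duplicated: no slope difference at all
  r2 <- ancova_compare(x1, y1, x1, y1)
  expect_lt(abs(r2$F_slope), 1e-10)
  expect_error(ancova_compare(rep(2, 5), 1:5, x2, y2), "degenerate")
})

test_that("ANCOVA slope F matches the explicit RSS formula", {
  set.seed(16)
  n1 <- 40; n2 <- 50
  x1 <- rnorm(n1); y1 <- 1 + 0.5 * x1 + rnorm(n1, 0, 0.3)
  x2 <- rnorm(n2); y2 <- 0.5 + 1.5 * x2 + rnorm(n2, 0, 0.3)
  r <- ancova_compare(10^x1, 10^y1, 10^x2, 10^y2)
  fit1 <- lm(y1 ~ x1); fit2 <- lm(y2 ~ x2)
  rss_sep <- sum(residuals(fit1)^2) + sum(residuals(fit2)^2)
  g <- factor(rep(1:2, c(n1, n2)))
  rss_com <- sum(residuals(lm(c(y1, y2) ~ c(x1, x2) + g))^2)
  F_hand <- ((rss_com - rss_sep) / 1) / (rss_sep / (n1 + n2 - 4))
  expect_equal(r$F_slope, F_hand, tolerance = 1e-10)
  expect_false(r$slopes_homogeneous)
})

test_that("global Spearman handles monotone and exact small-sample cases", {
  x <- c(0.1, 0.4, 0.9, 2.2, 5.0)
  expect_equal(spearman_global(x, x^2)$rho, 1)
  expect_equal(spearman_global(x, -log(x))$rho, -1)
  set.seed(17)
  y <- rnorm(5)
  expect_equal(spearman_global(x, y)$p_value, enum_spearman_p(x, y),
               tolerance = 1e-12)
  expect_error(spearman_global(rep(1, 5), y), "constant")
})

test_that("Kruskal-Wallis + Dunn: identity, oracle and warnings", {
  same <- list(a = rep(2, 4), b = rep(2, 5), c = rep(2, 6))
  r <- kruskal_dunn(same)
  expect_equal(r$H, 0)
  expect_equal(r$p_value, 1)
  set.seed(18)
  g <- list(a = rnorm(8), b = rnorm(10, 1), c = rnorm(9, 2))
  r2 <- kruskal_dunn(g)
  expect_equal(r2$H, unname(kruskal.test(unlist(g),
    factor(rep(names(g), lengths(g))))$statistic))
  # Dunn z recomputed from the definition
  values <- unlist(g)
  ranks <- rank(values)
  N <- length(values)
  rb <- tapply(ranks, rep(names(g), lengths(g)), mean)
  tie_tab <- table(values)
  Tie <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  se_ab <- sqrt((N * (N + 1) / 12 - Tie) * (1 / 8 + 1 / 10))
  z_ab <- (rb[["a"]] - rb[["b"]]) / se_ab
  expect_equal(r2$dunn$z[r2$dunn$group1 == "a" & r2$dunn$group2 == "b"],
               z_ab, tolerance = 1e-12)
  expect_equal(r2$dunn$p_adj, pmin(1, r2$dunn$p * 3))
  expect_warning(kruskal_dunn(list(a = 1, b = rnorm(5), c = rnorm(5))),
                 "singleton")
  expect_error(kruskal_dunn(list(a = 1:3, b = 4:6)), "at least 3")
})

test_that("ratio metrics compute per-spine ratios and group medians", {
  rec <- make_records(volume = c(0.1, 0.2),
                      psd_area = c(0.05, 0.05),
                      psd_core = c(0.005, 0.01))
  r <- ratio_metrics(rec)
  expect_equal(r$per_spine$av_ratio_per_um, c(0.5, 0.25))
  expect_equal(r$per_spine$vpv_ratio, c(0.05, 0.05))
  # doubling A doubles A/V
  rec2 <- rec; rec2$psd_area_um2 <- rec$psd_area_um2 * 2
  expect_equal(ratio_metrics(rec2)$per_spine$av_ratio_per_um,
               2 * r$per_spine$av_ratio_per_um)
})

test_that("relative change is measured against the stratum control
           median", {
  ctl <- make_records(volume = c(1, 2, 3), condition = "control",
                      has_ser = TRUE)
  trt <- make_records(volume = c(2, 4), condition = "cltp", has_ser = TRUE,
                      id = c("t1", "t2"))
  ctl0 <- make_records(volume = c(1, 1), condition = "control",
                       has_ser = FALSE, id = c("c1", "c2"))
  trt0 <- make_records(volume = c(2, 2), condition = "cltp",
                       has_ser = FALSE, id = c("t3", "t4"))
  rc <- relative_change(rbind(ctl, trt, ctl0, trt0), "volume_um3")
  # control median of SER stratum is 2 -> relative values 1 and 2
  ser_rel <- rc$relative$relative_value[rc$relative$has_ser]
  expect_equal(sort(ser_rel), c(1, 2))
  expect_equal(rc$relative$relative_value[!rc$relative$has_ser], c(2, 2))
  expect_error(relative_change(rbind(ctl, trt), "volume_um3"),
               "empty stratum")
})

test_that("relative change recovers the injected cLTP growth factor", {
  cfg <- synth_config(n_control = 800, n_cltp = 800,
                      cltp_spine_factor_ser = 1.5, cltp_psd_factor = 1,
                      seed = 19)
  pop <- generate_population(cfg)
  rc <- relative_change(pop, "volume_um3")
  med_ser <- median(rc$relative$relative_value[rc$relative$has_ser])
  expect_lt(abs(med_ser - 1.5) / 1.5, 0.1)
})

test_that("volume histogram uses left-closed 0.05 bins summing to 100%", {
  h <- volume_histogram(c(0.01, 0.02, 0.07))
  expect_equal(h$count, c(2, 1))
  expect_equal(h$frequency_pct, c(200 / 3, 100 / 3))
  expect_equal(sum(h$frequency_pct), 100)
  # boundary value goes to the right bin (left-closed)
  h2 <- volume_histogram(c(0.049, 0.05))
  expect_equal(h2$count, c(1, 1))
  # brute-force binning oracle
  set.seed(20)
  v <- runif(500, 0, 0.9)
  h3 <- volume_histogram(v, bin_width = 0.05)
  for (k in seq_len(nrow(h3))) {
    expect_equal(h3$count[k],
                 sum(v >= h3$bin_lo[k] & v < h3$bin_hi[k]))
  }
  expect_equal(sum(h3$frequency_pct), 100)
})

test_that("group summaries report both display conventions", {
  s <- summarize_group(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$sem, 0.5773503, tolerance = 1e-6)
  s2 <- summarize_group(rep(4, 10))
  expect_equal(s2$sem, 0)
  expect_equal(s2$iqr, 0)
  expect_true(is.na(s2$normality_p))
  # IQR against a manually interpolated type-7 quantile
  set.seed(21)
  x <- rnorm(1000)
  xs <- sort(x)
  q7 <- function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(summarize_group(x)$iqr, q7(0.75) - q7(0.25),
               tolerance = 1e-12)
  # strongly non-normal data are flagged
  expect_lt(summarize_group(exp(rnorm(200, 0, 1.5)))$normality_p, 0.05)
})
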