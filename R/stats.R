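# Statistics module: paired BF-vs-EF comparisons, ratios, CVs, regressions,
# and the Table-1-style cohort report.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the paired differences `x - y`. Zero
#' differences are discarded (with a warning when all are zero, in which case
#' p = 1). Tied absolute differences receive mid-ranks. For n <= 25 non-zero
#' differences the exact null distribution of the statistic is computed by
#' convolution over the (doubled, hence integer) ranks — valid under ties —
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return List with `statistic` (sum of positive-difference ranks, V),
#'   `p.value`, `n` (non-zero differences) and `method`.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired (equal length)")
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) {
    warnf("all paired differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, n = 0,
                method = "degenerate (all differences zero)"))
  }
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  if (n <= 25) {
    dr <- as.integer(round(2 * r))       # doubled mid-ranks are integers
    f <- 1                               # counts over statistic values 0..sum
    for (w in dr) {
      g <- c(f, numeric(w)) + c(numeric(w), f)
      f <- g
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * W))
    cdf <- sum(probs[seq_len(w2 + 1L)])
    upper <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(cdf, upper))
    method <- "exact signed-rank (convolution)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = W, p.value = p, n = n, method = method)
}

#' Paired t-test for dependent samples
#'
#' Standard two-sided paired t on the differences, with explicit handling of
#' the degenerate zero-variance cases.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return List with `statistic` (t), `p.value`, `df`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired (equal length)")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stopf("paired t-test needs at least 2 complete pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      warnf("identical paired samples; t = 0, p = 1")
      return(list(statistic = 0, p.value = 1, df = n - 1))
    }
    warnf("zero variance of non-zero differences; p -> 0 limit")
    return(list(statistic = sign(mean(d)) * Inf, p.value = 0, df = n - 1))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter))
}

#' Ordinary least-squares regression with R-squared
#'
#' @param x predictor (e.g. theoretical conductivity), n >= 3, non-constant.
#' @param y response (e.g. experimental conductivity).
#' @return List with `slope`, `intercept`, `r2` (squared Pearson
#'   correlation).
#' @export
fit_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("regression needs at least 3 complete pairs")
  if (var(x) == 0) stopf("predictor has zero variance")
  cf <- coef(lm(y ~ x))
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r2 = unname(cor(x, y)^2))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric, n >= 2, non-zero mean.
#' @return The CV (dimensionless).
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stopf("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stopf("CV undefined for zero mean")
  sd(values) / m
}

#' Percent reduction between two means, rounded to integer percent
#'
#' `100 * (mean_ref - mean_new) / mean_ref`, rounded half away from zero.
#'
#' @param mean_ref reference mean (> 0), e.g. the bright-field count.
#' @param mean_new comparison mean, e.g. the epifluorescence count.
#' @return Integer percent.
#' @export
percent_reduction <- function(mean_ref, mean_new) {
  if (!is_number(mean_ref) || mean_ref <= 0) stopf("mean_ref must be > 0")
  p <- 100 * (mean_ref - mean_new) / mean_ref
  as.integer(sign(p) * floor(abs(p) + 0.5))
}

se <- function(x) sd(x) / sqrt(length(x))

#' Full bright-field versus epifluorescence comparison report
#'
#' Builds the Table-1-style comparison from per-segment hydraulic summaries:
#' per-position (apical / basal) and pooled means with standard errors and
#' paired tests for mean diameter, Kht, Khs and Khts; pooled conductive
#' vessel counts per type with integer percent reductions; per-segment
#' `100 * Kh / Kht` ratio means, their difference and CVs per criterion; and
#' the pooled `Kh ~ Kht` regression per criterion. The ratio cells store the
#' mean of per-segment ratios (never the ratio of mean conductivities).
#' Segments without an experimental conductivity are excluded (with a
#' warning) from the ratio, CV and regression blocks.
#'
#' @param dataset a `data.frame` of per-segment summaries (one row per
#'   segment, as produced by [analyze_cohort()]) or an `xylem_cohort_analysis`
#'   object. Optionally carries a pooled vessel table as attribute/element
#'   `vessels`.
#' @return An object of class `xylem_report`.
#' @export
compare_bf_ef <- function(dataset) {
  vessels <- NULL
  if (inherits(dataset, "xylem_cohort_analysis")) {
    vessels <- dataset$vessels
    dataset <- dataset$segments
  }
  seg <- as.data.frame(dataset)
  if (nrow(seg) < 2) stopf("the comparison needs at least 2 segments")

  groups <- list(apical = seg[seg$segment_type == "apical", ],
                 basal = seg[seg$segment_type == "basal", ],
                 pooled = seg)
  pars <- c(D = "mean_d", Kht = "kht", Khs = "khs", Khts = "khts")

  par_tab <- do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    do.call(rbind, lapply(names(pars), function(pn) {
      xb <- df[[paste0(pars[[pn]], "_bf")]]
      xe <- df[[paste0(pars[[pn]], "_ef")]]
      ok <- !is.na(xb) & !is.na(xe)
      xb <- xb[ok]; xe <- xe[ok]
      n <- length(xb)
      data.frame(group = g, parameter = pn, n = n,
                 mean_bf = if (n) mean(xb) else NA_real_,
                 se_bf = if (n > 1) se(xb) else NA_real_,
                 mean_ef = if (n) mean(xe) else NA_real_,
                 se_ef = if (n > 1) se(xe) else NA_real_,
                 p_ttest = if (n >= 2)
                   suppressWarnings(paired_ttest(xb, xe)$p.value)
                 else NA_real_,
                 p_wilcoxon = if (n >= 2)
                   suppressWarnings(paired_wilcoxon(xb, xe)$p.value)
                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))

  counts <- do.call(rbind, lapply(c(px = "n_px", mx = "n_mx",
                                    total = "n_total"), function(cn) {
    xb <- seg[[paste0(cn, "_bf")]]; xe <- seg[[paste0(cn, "_ef")]]
    data.frame(count = sub("n_", "", cn),
               mean_bf = mean(xb), se_bf = se(xb),
               mean_ef = mean(xe), se_ef = se(xe),
               pct_reduction = percent_reduction(mean(xb), mean(xe)),
               p_wilcoxon = suppressWarnings(paired_wilcoxon(xb, xe)$p.value),
               stringsAsFactors = FALSE)
  }))

  with_kh <- !is.na(seg$kh) & !is.na(seg$ratio_bf) & !is.na(seg$ratio_ef)
  if (any(!with_kh))
    warnf("%d segment(s) lack Kh or a conductive-vessel ratio; excluded from ratio/CV/regression blocks",
          sum(!with_kh))
  rs <- seg[with_kh, ]
  ratios <- list(
    n = nrow(rs),
    mean_bf = mean(rs$ratio_bf), se_bf = se(rs$ratio_bf),
    mean_ef = mean(rs$ratio_ef), se_ef = se(rs$ratio_ef),
    difference = mean(rs$ratio_ef) - mean(rs$ratio_bf),
    p_wilcoxon = suppressWarnings(
      paired_wilcoxon(rs$ratio_bf, rs$ratio_ef)$p.value),
    cv_bf = coefficient_of_variation(rs$ratio_bf),
    cv_ef = coefficient_of_variation(rs$ratio_ef))

  regression <- lapply(c(bf = "kht_bf", ef = "kht_ef"), function(kc)
    fit_regression(rs[[kc]], rs$kh))

  vessel_level <- NULL
  if (!is.null(vessels)) {
    vessel_level <- list(
      mean_d_bf = mean(vessels$diameter_um[vessels$conductive_bf]),
      n_bf = sum(vessels$conductive_bf),
      mean_d_ef = mean(vessels$diameter_um[vessels$conductive_ef]),
      n_ef = sum(vessels$conductive_ef))
  }

  structure(list(parameters = par_tab, counts = counts, ratios = ratios,
                 regression = regression, vessel_level = vessel_level,
                 n_segments = nrow(seg), segments = seg),
            class = "xylem_report")
}

#' @export
print.xylem_report <- function(x, digits = 4, ...) {
  cat(sprintf("Bright-field vs epifluorescence comparison (%d segments)\n",
              x$n_segments))
  cat("\n-- Per-segment parameters (mean +/- SE; paired tests) --\n")
  pt <- x$parameters
  pt[] <- lapply(pt, function(c) if (is.numeric(c)) signif(c, digits) else c)
  print(pt, row.names = FALSE)
  cat("\n-- Conductive vessel counts (pooled) --\n")
  ct <- x$counts
  ct[] <- lapply(ct, function(c) if (is.numeric(c)) signif(c, digits) else c)
  print(ct, row.names = FALSE)
  r <- x$ratios
  cat(sprintf("\n-- Kh/Kht ratio (per-segment means, n = %d) --\n", r$n))
  cat(sprintf("  BF: %.2f +/- %.2f %%   EF: %.2f +/- %.2f %%   difference %.2f %% (p = %.3g)\n",
              r$mean_bf, r$se_bf, r$mean_ef, r$se_ef, r$difference,
              r$p_wilcoxon))
  cat(sprintf("  CV of ratio: BF %.2f, EF %.2f\n", r$cv_bf, r$cv_ef))
  cat("\n-- Kh ~ Kht regression --\n")
  for (crit in c("bf", "ef")) {
    g <- x$regression[[crit]]
    cat(sprintf("  %s: slope %.3g, intercept %.3g, R2 = %.4f\n",
                toupper(crit), g$slope, g$intercept, g$r2))
  }
  if (!is.null(x$vessel_level))
    cat(sprintf("\n-- Vessel-level mean diameter --\n  BF-identified %.2f um (n = %d), EF-identified %.2f um (n = %d)\n",
                x$vessel_level$mean_d_bf, x$vessel_level$n_bf,
                x$vessel_level$mean_d_ef, x$vessel_level$n_ef))
  invisible(x)
}

#' @export
plot.xylem_report <- function(x, ...) {
  rs <- x$segments[!is.na(x$segments$kh), ]
  lim <- range(c(rs$kht_bf, rs$kht_ef, rs$kh), na.rm = TRUE)
  op <- graphics::par(mfrow = c(1, 2), pty = "s")
  on.exit(graphics::par(op))
  for (crit in c("bf", "ef")) {
    kx <- rs[[paste0("kht_", crit)]]
    graphics::plot(kx, rs$kh, log = "xy", xlim = lim, ylim = lim,
                   xlab = expression(K[ht] ~ (m^4 ~ MPa^-1 ~ s^-1)),
                   ylab = expression(K[h] ~ (m^4 ~ MPa^-1 ~ s^-1)),
                   main = sprintf("%s identification (R2 = %.3f)",
                                  toupper(crit), x$regression[[crit]]$r2),
                   pch = ifelse(rs$segment_type == "apical", 16, 1))
    graphics::abline(0, 1, lty = 2, col = "gray")
  }
  invisible(x)
}
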