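#' Fit the log-log conversion model for one group of pairs
#'
#' Fits `ln(c_R) = k * ln(c_I) + C0` by ordinary least squares, the model
#' behind every conversion function in this package: workplace dust
#' concentrations are approximately lognormal, so the regression is carried
#' out on natural logarithms, and back-transforming gives the power law
#' `c_R = c_I^k * exp(C0)`.
#'
#' Beyond the coefficients and their classical standard errors the fit
#' carries what retrospective use needs: the Pearson correlation R, R^2 and
#' the sample-size-adjusted R^2, the residual standard error `s_resid`, the
#' predictor summaries (`x_mean`, `Sxx`) and the range of the standard error
#' of the fitted mean, `s_fit(x) = s_resid * sqrt(1/n + (x - x_mean)^2/Sxx)`,
#' evaluated over the observed `ln(c_I)`: its minimum `s_resid*sqrt(1/n)` is
#' attained at the predictor mean, its maximum at the observed extremes.
#' Residual diagnostics: the Durbin-Watson statistic on residuals in
#' measurement-time order (ties broken by inhalable record id; `NA` for a
#' perfect fit), and optionally a Monte-Carlo Lilliefors normality p-value
#' when `seed` is given.
#'
#' @param pairs Data frame with numeric `ln_ci` and `ln_cr` columns (a pair
#'   table from [form_pairs()] or [generate_pairs()]); if `start` and
#'   `inhalable_id` columns are present they define the residual order for
#'   the Durbin-Watson statistic, otherwise row order is used.
#' @param group Optional group id stored in the result.
#' @param seed Seed for the Lilliefors Monte-Carlo null; `NULL` skips the
#'   normality test (`lilliefors_p = NA`).
#' @param n_mc Monte-Carlo replicates for the Lilliefors null.
#' @return An object of class `loglog_fit`.
#' @examples
#' x <- rnorm(50)
#' toy <- data.frame(ln_ci = x, ln_cr = 0.7 * x - 1)
#' fit_loglog(toy)  # noiseless: recovers k = 0.7, C0 = -1 exactly
#' @export
fit_loglog <- function(pairs, group = NULL, seed = NULL, n_mc = 2000) {
  x <- pairs$ln_ci
  y <- pairs$ln_cr
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs to fit, got ", n)
  if (anyNA(x) || anyNA(y)) stop("missing values in log-concentrations")
  if (var(x) == 0) stop("degenerate predictor: ln(c_I) has zero variance")

  fit <- lm(y ~ x)
  # summary.lm warns on a numerically perfect fit; that case is legitimate
  # here (noiseless synthetic data)
  cf <- suppressWarnings(summary(fit)$coefficients)
  k <- unname(cf["x", "Estimate"])
  C0 <- unname(cf["(Intercept)", "Estimate"])
  se_k <- unname(cf["x", "Std. Error"])
  se_C0 <- unname(cf["(Intercept)", "Std. Error"])
  R <- cor(x, y)
  R2 <- R^2
  s_resid <- sqrt(sum(fit$residuals^2) / (n - 2))
  x_mean <- mean(x)
  Sxx <- sum((x - x_mean)^2)
  s_fit <- s_resid * sqrt(1 / n + (x - x_mean)^2 / Sxx)

  ord <- seq_len(n)
  if (!is.null(pairs$start)) {
    tie <- if (!is.null(pairs$inhalable_id)) pairs$inhalable_id else ord
    ord <- order(pairs$start, tie)
  }
  res_ord <- fit$residuals[ord]
  # a numerically perfect fit leaves only rounding noise in the residuals;
  # the statistic is undefined there
  zero_tol <- 1e-10 * max(1, max(abs(y)))
  dw <- if (max(abs(res_ord)) <= zero_tol) NA_real_ else durbin_watson(res_ord)

  lp <- NA_real_
  if (!is.null(seed) && s_resid > 0) {
    lp <- lilliefors_normality(fit$residuals, n_mc = n_mc, seed = seed)
  }

  structure(
    list(
      group = group, n = n, k = k, C0 = C0, se_k = se_k, se_C0 = se_C0,
      R = R, R2 = R2, adj_R2 = adjusted_r2(R2, n),
      s_resid = s_resid, x_mean = x_mean, Sxx = Sxx,
      s_fit_min = s_resid * sqrt(1 / n), s_fit_max = max(s_fit),
      x_range = range(x), dw = dw, lilliefors_p = lp,
      residuals = unname(fit$residuals)
    ),
    class = "loglog_fit"
  )
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("Log-log conversion fit%s (n = %d)\n",
              if (!is.null(x$group)) paste0(" [group ", x$group, "]") else "",
              x$n))
  cat(sprintf("  k  = %.4f +/- %.4f\n", x$k, x$se_k))
  cat(sprintf("  C0 = %.4f +/- %.4f\n", x$C0, x$se_C0))
  cat(sprintf("  R = %.3f, adj. R^2 = %.3f\n", x$R, x$adj_R2))
  cat(sprintf("  s_fit range: %.4f - %.4f\n", x$s_fit_min, x$s_fit_max))
  cat(sprintf("  Durbin-Watson: %s, Lilliefors p: %s\n",
              format(x$dw, digits = 3), format(x$lilliefors_p, digits = 3)))
  cat(sprintf("  conversion: c_R = c_I^%.3f * exp(%.3f)\n", x$k, x$C0))
  invisible(x)
}

#' Sample-size-adjusted coefficient of determination
#'
#' `R^2 - (m / (n - m - 1)) * (1 - R^2)`, the Wherry-type adjustment for
#' the number of predictors `m` relative to the number of data pairs `n`.
#' With a single predictor and large n this is close to R^2 itself.
#'
#' @param R2 Coefficient of determination in `[0, 1]`.
#' @param n Number of data pairs.
#' @param m Number of predictors (1 for the conversion model).
#' @return Adjusted R^2.
#' @export
adjusted_r2 <- function(R2, n, m = 1) {
  if (R2 < 0 || R2 > 1) stop("R2 must be in [0, 1]")
  if (n <= m + 1) stop("need n > m + 1 for the adjustment")
  R2 - (m / (n - m - 1)) * (1 - R2)
}

#' Confidence band of the fitted regression mean
#'
#' Band for the fitted mean of `ln(c_R)` at given values of `ln(c_I)`:
#' center `k * ln_ci + C0`, half-width `z * s_fit(ln_ci)` with
#' `s_fit(x) = s_resid * sqrt(1/n + (x - x_mean)^2/Sxx)`. The band is
#' narrowest at the predictor mean and widens toward the extremes. For the
#' default 95% level the conventional z = 1.96 is used (group sizes are
#' large, so a normal quantile rather than a t-quantile).
#'
#' @param result A `loglog_fit`.
#' @param ln_ci Numeric vector of log inhalable concentrations.
#' @param level Confidence level in (0, 1).
#' @return Data frame with columns `ln_ci`, `fit`, `lower`, `upper`
#'   (log scale).
#' @export
confidence_band <- function(result, ln_ci, level = 0.95) {
  stopifnot(inherits(result, "loglog_fit"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- if (level == 0.95) 1.96 else qnorm((1 + level) / 2)
  center <- result$k * ln_ci + result$C0
  s_fit <- result$s_resid *
    sqrt(1 / result$n + (ln_ci - result$x_mean)^2 / result$Sxx)
  data.frame(ln_ci = ln_ci, fit = center,
             lower = center - z * s_fit, upper = center + z * s_fit)
}

#' Durbin-Watson statistic
#'
#' `sum((e_t - e_{t-1})^2) / sum(e_t^2)` over residuals in fit order;
#' values near 2 indicate no first-order autocorrelation, values near 0 or
#' 4 positive or negative autocorrelation.
#'
#' @param residuals Numeric vector of residuals in their natural
#'   (time) order, length >= 2.
#' @return The statistic, in `[0, 4]`.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need at least 2 residuals")
  if (all(residuals == 0)) stop("undefined: all residuals are zero")
  sum(diff(residuals)^2) / sum(residuals^2)
}

# Lilliefors statistic: Kolmogorov-Smirnov distance of x to a normal
# distribution with mean and sd estimated from x itself.
.lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Monte-Carlo null distribution for the Lilliefors statistic
#'
#' Simulates the distribution of the Lilliefors statistic under normality
#' for sample size `n` (the mean/sd estimation step is repeated on every
#' simulated sample, which is what distinguishes Lilliefors from the plain
#' Kolmogorov-Smirnov null). Precompute this once when testing many samples
#' of the same size.
#'
#' @param n Sample size.
#' @param n_mc Number of Monte-Carlo replicates.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return Numeric vector of `n_mc` null statistics.
#' @export
lilliefors_null_stats <- function(n, n_mc = 10000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vapply(seq_len(n_mc), function(i) .lilliefors_stat(rnorm(n)), numeric(1))
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' Tests a sample against a normal distribution with mean and standard
#' deviation estimated from the sample, with the p-value obtained from a
#' Monte-Carlo null rather than tabulated critical values:
#' `p = (1 + #{D_null >= D}) / (n_mc + 1)`. The test is location- and
#' scale-invariant by construction.
#'
#' @param residuals Numeric sample (length >= 5).
#' @param n_mc Number of Monte-Carlo null replicates.
#' @param seed Integer seed (mandatory unless `null_stats` is supplied).
#' @param null_stats Optional precomputed null statistics from
#'   [lilliefors_null_stats()] for `length(residuals)`.
#' @return Monte-Carlo p-value in (0, 1].
#' @export
lilliefors_normality <- function(residuals, n_mc = 10000, seed,
                                 null_stats = NULL) {
  n <- length(residuals)
  if (n < 5) stop("need at least 5 observations, got ", n)
  d <- .lilliefors_stat(residuals)
  if (is.null(null_stats)) {
    null_stats <- lilliefors_null_stats(n, n_mc = n_mc, seed = seed)
  }
  (1 + sum(null_stats >= d)) / (length(null_stats) + 1)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Fit conversion functions for every group at one taxonomy level
#'
#' Convenience wrapper: splits assigned pairs at the requested level with
#' [split_by_group()] and fits each group with at least `min_n` pairs,
#' returning a Table-2-style summary.
#'
#' @param pairs Assigned pair data frame.
#' @param level Taxonomy level passed to [split_by_group()].
#' @param min_n Minimum group size to fit.
#' @param seed Optional seed for Lilliefors p-values.
#' @return Data frame with one row per fitted group (n, R, adj_R2, C0,
#'   se_C0, k, se_k, s_fit_min, s_fit_max, dw, lilliefors_p) plus a
#'   `fits` attribute holding the `loglog_fit` objects.
#' @export
fit_by_group <- function(pairs, level = "heuristic", min_n = 10, seed = NULL) {
  groups <- split_by_group(pairs, level)
  groups <- groups[vapply(groups, nrow, integer(1)) >= min_n]
  fits <- lapply(names(groups), function(g) {
    fit_loglog(groups[[g]], group = g, seed = seed)
  })
  names(fits) <- names(groups)
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(group = f$group, n = f$n, R = f$R, adj_R2 = f$adj_R2,
               C0 = f$C0, se_C0 = f$se_C0, k = f$k, se_k = f$se_k,
               s_fit_min = f$s_fit_min, s_fit_max = f$s_fit_max,
               dw = f$dw, lilliefors_p = f$lilliefors_p,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}
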