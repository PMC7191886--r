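#' Construct a conversion function
#'
#' A conversion function maps an inhalable dust concentration to an
#' estimated respirable concentration through the power law
#' `c_R = c_I^k * exp(C0)`. Published entries (see [load_registry()]) carry
#' the coefficient standard errors and the range of the fit standard error
#' `s_fit`; a function derived from a fresh fit additionally carries
#' `x_mean`, `Sxx` and `s_resid`, allowing exact (rather than
#' minimum-width) uncertainty intervals.
#'
#' `k` must be positive; all published entries have `k` in (0, 1] and
#' negative `C0`, which together keep the predicted `c_R` below `c_I` over
#' the validity range. A `k` above 1 is allowed with a warning (it implies
#' a respirable share growing with concentration).
#'
#' @param k Power-law exponent (slope in log space), dimensionless.
#' @param C0 Intercept in log space (log mg m\eqn{^{-3}}).
#' @param se_k,se_C0 Standard errors of the coefficients.
#' @param n Number of pairs behind the fit.
#' @param s_fit_min,s_fit_max Range of the standard error of the fitted
#'   mean over the observed predictor values.
#' @param x_mean,Sxx,s_resid Predictor mean, predictor sum of squares and
#'   residual standard error (available for fresh fits only).
#' @param id,name Group id and human-readable name.
#' @param validity Validity range of `c_I` in mg m\eqn{^{-3}}.
#' @return An object of class `conversion_fn`.
#' @export
conversion_function <- function(k, C0, se_k = NA_real_, se_C0 = NA_real_,
                                n = NA_integer_, s_fit_min = NA_real_,
                                s_fit_max = NA_real_, x_mean = NULL,
                                Sxx = NULL, s_resid = NULL, id = NULL,
                                name = NULL, validity = c(0.01, 100)) {
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  if (k > 1) warning("k > 1: respirable share would grow with concentration")
  if (!is.finite(C0)) stop("C0 must be finite")
  structure(
    list(k = k, C0 = C0, se_k = se_k, se_C0 = se_C0, n = n,
         s_fit_min = s_fit_min, s_fit_max = s_fit_max,
         x_mean = x_mean, Sxx = Sxx, s_resid = s_resid,
         id = id, name = name, validity = validity),
    class = "conversion_fn"
  )
}

#' @export
print.conversion_fn <- function(x, ...) {
  label <- if (!is.null(x$id)) paste0(" [", x$id,
                                      if (!is.null(x$name)) paste0(": ", x$name),
                                      "]") else ""
  cat(sprintf("Conversion function%s\n", label))
  cat(sprintf("  c_R = c_I^%.3f * exp(%.3f)\n", x$k, x$C0))
  if (is.finite(x$s_fit_min)) {
    cat(sprintf("  s_fit range: %.4f - %.4f (n = %s)\n",
                x$s_fit_min, x$s_fit_max, format(x$n)))
  }
  cat(sprintf("  validity: c_I in [%g, %g] mg/m^3\n",
              x$validity[1], x$validity[2]))
  invisible(x)
}

#' Turn a fitted log-log model into a conversion function
#'
#' @param fit A `loglog_fit` from [fit_loglog()].
#' @param id,name Optional id/name (default: the fit's group).
#' @param validity Validity range of `c_I` in mg m\eqn{^{-3}}.
#' @return A `conversion_fn` carrying the full design summaries, so
#'   [convert_dust()] intervals are exact.
#' @export
as_conversion_fn <- function(fit, id = fit$group, name = NULL,
                             validity = c(0.01, 100)) {
  stopifnot(inherits(fit, "loglog_fit"))
  conversion_function(
    k = fit$k, C0 = fit$C0, se_k = fit$se_k, se_C0 = fit$se_C0, n = fit$n,
    s_fit_min = fit$s_fit_min, s_fit_max = fit$s_fit_max,
    x_mean = fit$x_mean, Sxx = fit$Sxx, s_resid = fit$s_resid,
    id = id, name = name, validity = validity
  )
}

.check_ci <- function(ci, fn) {
  if (any(!is.finite(ci)) || any(ci <= 0)) {
    stop("c_I must be positive and finite")
  }
  out_of_range <- ci < fn$validity[1] | ci > fn$validity[2]
  if (any(out_of_range)) {
    warning(sum(out_of_range), " value(s) of c_I outside the validity range [",
            fn$validity[1], ", ", fn$validity[2], "] mg/m^3; the conversion ",
            "function is extrapolating beyond the conditions it was fitted on")
  }
  invisible(ci)
}

#' Convert an inhalable to a respirable dust concentration
#'
#' Point estimate `c_R = c_I^k * exp(C0)` with a confidence interval
#' obtained by exponentiating the log-space band
#' `k*ln(c_I) + C0 +/- z * s_fit`. When the conversion function carries the
#' full design summaries (fresh fits), `s_fit` is evaluated exactly at
#' `ln(c_I)`; for published registry entries only the `s_fit` range is
#' available and the minimum is used, so the interval is a minimum-width
#' interval (attribute `interval = "minimum-width"`) — correct near the
#' predictor mean and optimistic toward the extremes.
#'
#' @param ci Inhalable concentration(s), mg m\eqn{^{-3}}; values outside
#'   the validity range are converted with a warning.
#' @param fn A `conversion_fn`.
#' @param level Confidence level; 0.95 uses z = 1.96.
#' @return Data frame with columns `ci`, `cr`, `lower`, `upper` and an
#'   `interval` attribute ("exact" or "minimum-width"; `NA` bounds when the
#'   function carries no uncertainty information).
#' @examples
#' reg <- load_registry()
#' convert_dust(10, registry_fn(reg, "alpha"))  # soldering: about 5 mg/m^3
#' @export
convert_dust <- function(ci, fn, level = 0.95) {
  stopifnot(inherits(fn, "conversion_fn"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  .check_ci(ci, fn)
  z <- if (level == 0.95) 1.96 else qnorm((1 + level) / 2)
  lx <- log(ci)
  center <- fn$k * lx + fn$C0
  if (!is.null(fn$s_resid) && !is.null(fn$x_mean) && !is.null(fn$Sxx)) {
    s_fit <- fn$s_resid * sqrt(1 / fn$n + (lx - fn$x_mean)^2 / fn$Sxx)
    kind <- "exact"
  } else if (is.finite(fn$s_fit_min)) {
    s_fit <- rep(fn$s_fit_min, length(lx))
    kind <- "minimum-width"
  } else {
    s_fit <- rep(NA_real_, length(lx))
    kind <- "none"
  }
  out <- data.frame(ci = ci, cr = exp(center),
                    lower = exp(center - z * s_fit),
                    upper = exp(center + z * s_fit))
  attr(out, "interval") <- kind
  out
}

#' Ratio of respirable to inhalable dust
#'
#' `c_R / c_I = c_I^(k-1) * exp(C0)`, strictly decreasing in `c_I` whenever
#' `k < 1`: the respirable share shrinks as total dust concentrations grow
#' (consistent with agglomeration at high concentrations). At
#' `c_I = 1 mg m^-3` the ratio equals `exp(C0)` for any `k`.
#'
#' @param ci Inhalable concentration(s), mg m\eqn{^{-3}}.
#' @param fn A `conversion_fn`.
#' @return Numeric vector of ratios.
#' @export
dust_ratio <- function(ci, fn) {
  stopifnot(inherits(fn, "conversion_fn"))
  if (any(!is.finite(ci)) || any(ci <= 0)) stop("c_I must be positive")
  ci^(fn$k - 1) * exp(fn$C0)
}

#' Inhalable concentration at which a given ratio is reached
#'
#' Closed-form inverse of [dust_ratio()]: for `k < 1` the ratio is strictly
#' decreasing, so `c_I = exp((ln(r) - C0) / (k - 1))` is the unique
#' concentration with `c_R / c_I = r`. Useful for checking at which
#' concentrations a literature conversion factor is compatible with a
#' power-law conversion function.
#'
#' @param target_ratio Ratio in (0, 1).
#' @param fn A `conversion_fn` with `k < 1`.
#' @return Inhalable concentration, mg m\eqn{^{-3}}.
#' @export
inverse_ratio <- function(target_ratio, fn) {
  stopifnot(inherits(fn, "conversion_fn"))
  if (any(target_ratio <= 0) || any(target_ratio >= 1)) {
    stop("target_ratio must be in (0, 1)")
  }
  if (fn$k == 1) stop("ratio is constant for k = 1, no inverse exists")
  exp((log(target_ratio) - fn$C0) / (fn$k - 1))
}

#' Inhalable sampling convention
#'
#' Percentage of airborne particles of aerodynamic diameter `D` (um) that
#' belongs to the inhalable fraction by the international sampling
#' convention: `I(D) = 50 * (1 + exp(-0.06 * D))`, defined for
#' `0 <= D <= 100` um, falling monotonically from 100% at `D = 0` toward
#' 50% at the 100-um limit.
#'
#' @param D Aerodynamic diameter(s) in um, within `[0, 100]`.
#' @return Percentage(s) in (50, 100].
#' @export
inhalable_convention <- function(D) {
  if (any(!is.finite(D)) || any(D < 0) || any(D > 100)) {
    stop("the inhalable convention is defined for D in [0, 100] um")
  }
  50 * (1 + exp(-0.06 * D))
}

# canonical serialization used for the registry transcription checksum
.registry_digest <- function(raw) {
  canon <- paste(
    apply(raw, 1, function(r) paste(trimws(r), collapse = "|")),
    collapse = "\n"
  )
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}

#' Load the published conversion-function registry
#'
#' The registry holds the published regression coefficients for all 21
#' groups: the entire data set ("0"), working-activity groups "1"-"6",
#' material groups "A"-"C", the four combined groups ("1-A", "2-B", "4-A",
#' "6-B") and the seven heuristic groups ("alpha"-"eta"). Coefficients are
#' stored exactly as printed; an MD5 digest of the canonical serialization
#' guards against transcription drift and is verified on every load.
#'
#' These functions were fitted on parallel workplace measurements from
#' German industry between 1998 and 2016; outside comparable conditions
#' they extrapolate.
#'
#' @param path Registry CSV (defaults to the file shipped with the package).
#' @param checksum_path File holding the expected MD5 digest.
#' @return Data frame of class `conversion_registry`.
#' @export
load_registry <- function(path = system.file("extdata",
                                             "conversion_registry.csv",
                                             package = "dustconv"),
                          checksum_path = paste0(path, ".md5")) {
  if (!nzchar(path) || !file.exists(path)) stop("registry file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (file.exists(checksum_path)) {
    expected <- trimws(readLines(checksum_path, n = 1))
    got <- .registry_digest(raw)
    if (!identical(got, expected)) {
      stop("registry corrupted: checksum mismatch (expected ", expected,
           ", got ", got, ")")
    }
  } else {
    warning("no checksum file found at ", checksum_path,
            "; registry transcription not verified")
  }
  reg <- raw
  for (col in c("R", "adj_R2", "C0", "se_C0", "k", "se_k",
                "s_fit_min", "s_fit_max")) {
    reg[[col]] <- as.numeric(reg[[col]])
  }
  reg$n <- as.integer(gsub("[^0-9]", "", reg$n))
  if (anyDuplicated(reg$id)) stop("registry corrupted: duplicate ids")
  class(reg) <- c("conversion_registry", class(reg))
  reg
}

#' Fetch one registry entry as a conversion function
#'
#' @param registry A `conversion_registry` from [load_registry()].
#' @param id Group id (e.g. `"gamma"`, `"2-B"`, `"0"`).
#' @return A `conversion_fn`.
#' @export
registry_fn <- function(registry, id) {
  stopifnot(inherits(registry, "conversion_registry"))
  row <- registry[registry$id == id, , drop = FALSE]
  if (nrow(row) != 1) stop("no registry entry with id '", id, "'")
  conversion_function(
    k = row$k, C0 = row$C0, se_k = row$se_k, se_C0 = row$se_C0, n = row$n,
    s_fit_min = row$s_fit_min, s_fit_max = row$s_fit_max,
    id = row$id, name = row$group
  )
}
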