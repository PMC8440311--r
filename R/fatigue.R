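#' Fatigue records
#'
#' @param sib strain index of bone per specimen (> 0).
#' @param n_f cycles to failure (>= 1); for runouts, the cycle ceiling.
#' @param runout logical flag: test stopped at the ceiling without failure.
#' @param label specimen ids.
#' @return A `fatigue_records` data frame with columns
#'   `specimen, sib, n_f, runout`.
#' @export
fatigue_records <- function(sib, n_f, runout = FALSE, label = NULL) {
  n <- length(sib)
  runout <- rep(as.logical(runout), length.out = n)
  if (is.null(label)) label <- sprintf("SP%02d", seq_len(n))
  if (any(sib <= 0)) stop_param("`sib` must be positive")
  if (any(n_f < 1)) stop_param("`n_f` must be >= 1")
  structure(data.frame(specimen = label, sib = sib, n_f = n_f,
                       runout = runout),
            class = c("fatigue_records", "data.frame"))
}

#' Read fatigue records from CSV
#'
#' Expects columns `specimen, sib, n_f, runout`.
#'
#' @param path CSV file path.
#' @return A [fatigue_records()] data frame.
#' @export
read_fatigue_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "sib", "n_f", "runout")
  if (!all(need %in% names(df)))
    stop_param("CSV must have columns ", paste(need, collapse = ", "))
  fatigue_records(df$sib, df$n_f, as.logical(df$runout), df$specimen)
}

#' Woehler (S-N) power-law regression of SIB on fatigue life
#'
#' Ordinary least squares of `log10(SIB)` on `log10(N_f)`, i.e. the
#' power law `SIB = a * N_f^b` linearized in log-log space. Runout
#' specimens (stopped at the cycle ceiling without failure) are excluded by
#' default, matching standard practice of plotting them apart from the fit;
#' `include_runouts = TRUE` refits treating them as failures for
#' sensitivity.
#'
#' @param records a [fatigue_records()] data frame.
#' @param include_runouts include runout records as failures.
#' @param log_base logarithm base used for the linearization (default 10;
#'   the slope `b` is base-invariant, `a` is not).
#' @return A `wohler_fit`: `a`, `b` (signed slope), `r2`, `r2_adj`,
#'   `p_value` (two-sided slope test on n-2 df), `n_used`, `sigma_log`
#'   (residual standard deviation in log10 units) and the underlying `lm`
#'   fit.
#' @export
fit_wohler <- function(records, include_runouts = FALSE, log_base = 10) {
  stopifnot(is.data.frame(records))
  use <- if (include_runouts) rep(TRUE, nrow(records)) else !records$runout
  d <- records[use, , drop = FALSE]
  if (sum(!d$runout | include_runouts) < 3 || nrow(d) < 3)
    stop_param("need at least 3 usable (non-runout) records")
  x <- log(d$n_f, base = log_base)
  y <- log(d$sib, base = log_base)
  if (length(unique(d$n_f)) < 2 || var(x) == 0)
    stop_param("zero variance in log(N_f): slope is undefined")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # noise-free data is legitimate here
  n <- nrow(d)
  r2 <- sm$r.squared
  structure(list(a = log_base^coef(fit)[[1]],
                 b = coef(fit)[[2]],
                 r2 = r2,
                 r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
                 p_value = sm$coefficients["x", "Pr(>|t|)"],
                 n_used = n,
                 sigma_log = sm$sigma,
                 log_base = log_base,
                 lm = fit,
                 data = d),
            class = "wohler_fit")
}

#' @export
print.wohler_fit <- function(x, ...) {
  cat(sprintf("<wohler_fit> SIB = %.4g * N_f^%.4g  (n = %d, R2 = %.3f, R2_adj = %.3f, p = %.3g)\n",
              x$a, x$b, x$n_used, x$r2, x$r2_adj, x$p_value))
  invisible(x)
}

#' Symmetric prediction bounds of a Woehler fit
#'
#' The t-based prediction interval of the log-linear regression, evaluated
#' on a grid of lives and exponentiated:
#' `yhat +/- t_{(1+level)/2, n-2} * s * sqrt(1 + 1/n + (x - xbar)^2 / Sxx)`.
#' The envelope is symmetric about the fitted line in log space and
#' narrowest at the mean log-life.
#'
#' @param fit a [fit_wohler()] result.
#' @param n_grid cycle values at which to evaluate the envelope.
#' @param level probability content (default 0.95).
#' @return Data frame `n_f, fit, lower, upper` (SIB units).
#' @export
prediction_bounds <- function(fit, n_grid, level = 0.95) {
  stopifnot(inherits(fit, "wohler_fit"))
  if (level <= 0 || level >= 1) stop_param("`level` must be in (0, 1)")
  if (fit$n_used <= 2) stop_param("need more than 2 points for bounds")
  newd <- data.frame(x = log(n_grid, base = fit$log_base))
  pr <- predict(fit$lm, newdata = newd, interval = "prediction",
                level = level)
  data.frame(n_f = n_grid,
             fit = fit$log_base^pr[, "fit"],
             lower = fit$log_base^pr[, "lwr"],
             upper = fit$log_base^pr[, "upr"])
}

#' 95% confidence interval of the Woehler exponent
#'
#' @param fit a [fit_wohler()] result.
#' @param level confidence level (default 0.95).
#' @return Length-2 numeric vector (lower, upper) for the slope `b`.
#' @export
wohler_slope_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "wohler_fit"))
  ci <- stats::confint(fit$lm, "x", level = level)
  as.numeric(ci)
}
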