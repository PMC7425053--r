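# Dose-response regression: Gompertz nonlinear least squares of relative
# enhancement against peak negative pressure, and ordinary least-squares
# linear fits with r^2.

#' Gompertz dose-response curve
#'
#' `y = c + A * exp(-exp(-k * (p - p0)))`: baseline offset `c`, asymptotic
#' rise `A`, rate `k` (per MPa), inflection pressure `p0` (MPa).
#'
#' @param p Pressures, MPa.
#' @param c,A,k,p0 Curve parameters.
#' @return Curve values.
#' @export
gompertz_curve <- function(p, c, A, k, p0) {
  c + A * exp(-exp(-k * (p - p0)))
}

#' Fit a Gompertz dose-response by Levenberg-Marquardt least squares
#'
#' Minimizes squared residuals of `y = c + A exp(-exp(-k (p - p0)))` with
#' the Levenberg-Marquardt algorithm, with a lower bound of zero on `c`,
#' `A`, and `k`.  Starting values follow a fixed quartile rule: `c` from the
#' minimum response, `A` from the response range, `p0` from the pressure at
#' which the response first crosses the mid-range, `k` from the pressure
#' spread — so the fit is deterministic for a given data set.  Reported fit
#' quality is the mean absolute percent error,
#' `MAPE = mean(|fit - obs| / obs) * 100`.
#'
#' @param pnp Pressures, MPa (>= 5 points over >= 3 distinct pressures).
#' @param ratio Relative enhancement responses.
#' @return An object of class `gompertz_fit`: `parameters` (named c, A, k,
#'   p0), `covariance`, `p_values`, `mape` (%), `fitted`, `converged`, and
#'   `diagnostics`.  Non-convergence or a boundary solution (`A` or `k` at
#'   zero) is reported with `converged = FALSE`, never silently.
#' @export
fit_gompertz <- function(pnp, ratio) {
  pnp <- as.numeric(pnp); ratio <- as.numeric(ratio)
  if (length(pnp) != length(ratio)) stop("pnp and ratio lengths differ")
  if (length(pnp) < 5L) stop("need at least 5 points")
  if (length(unique(pnp)) < 3L) stop("need at least 3 distinct pressures")

  c0 <- max(min(ratio), 0)
  A0 <- max(max(ratio) - min(ratio), 1e-3)
  mid <- c0 + A0 / 2
  ord <- order(pnp)
  above <- which(ratio[ord] >= mid)
  p00 <- if (length(above)) pnp[ord][above[1]] else stats::median(pnp)
  spread <- diff(stats::quantile(pnp, c(0.25, 0.75), names = FALSE))
  k0 <- 4 / max(spread, diff(range(pnp)) / 4, 1e-3)

  dat <- data.frame(p = pnp, y = ratio)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ cc + A * exp(-exp(-k * (p - p0))),
      data = dat,
      start = list(cc = c0, A = A0, k = k0, p0 = p00),
      lower = c(cc = 0, A = 0, k = 0, p0 = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(list(parameters = c(c = NA, A = NA, k = NA, p0 = NA),
                          covariance = NULL, p_values = NULL,
                          mape = NA_real_, fitted = NULL,
                          converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "gompertz_fit"))
  }

  est <- stats::coef(fit)
  names(est) <- c("c", "A", "k", "p0")
  fitted_y <- as.numeric(stats::fitted(fit))
  mape <- mean(abs(fitted_y - ratio) / abs(ratio)) * 100
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  pvals <- if (!is.null(sm)) {
    pv <- sm$coefficients[, "Pr(>|t|)"]
    names(pv) <- c("c", "A", "k", "p0"); pv
  } else NULL
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  boundary <- est[["A"]] <= 1e-8 || est[["k"]] <= 1e-8
  structure(list(parameters = est,
                 covariance = vc,
                 p_values = pvals,
                 mape = mape,
                 fitted = fitted_y,
                 converged = isTRUE(fit$convInfo$isConv) && !boundary,
                 diagnostics = if (boundary)
                   "parameter at boundary (A or k ~ 0)" else "ok"),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (all(is.na(x$parameters))) {
    cat("<gompertz_fit> failed:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<gompertz_fit> c=%.4g A=%.4g k=%.4g p0=%.4g  MAPE %.2f%%  converged: %s\n",
    x$parameters["c"], x$parameters["A"], x$parameters["k"],
    x$parameters["p0"], x$mape, x$converged))
  invisible(x)
}

#' Ordinary least-squares line with r-squared
#'
#' @param x,y Numeric vectors, `n >= 3`; `x` must have positive variance.
#' @return List with `slope`, `intercept`, `r_squared` (in `[0, 1]`), and `n`.
#' @export
linfit_r2 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  # direct 1 - RSS/TSS: avoids summary.lm noise on perfect fits, and a
  # constant response carries no explainable variance
  r2 <- if (stats::var(y) == 0) 0 else
    min(max(1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2), 0), 1)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = length(x))
}
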