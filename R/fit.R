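# Regression fitting of the three conversion-equation functional forms
# and the cross-regional slope-vs-mean-SOM power curve.  Ordinary fits
# only (no weighting): stats::lm for the linear/quadratic forms,
# minpack.lm::nlsLM for the power form with a log-log OLS start.

.new_fit <- function(form, coef, se, r_squared, n, residuals, fitted,
                     converged = NA, vcov = NULL, data = NULL) {
  structure(list(form = form, coefficients = coef, coefficient_se = se,
                 r_squared = r_squared, n = n, residuals = residuals,
                 fitted = fitted, converged = converged, vcov = vcov,
                 data = data),
            class = "oc_fit")
}

#' @export
print.oc_fit <- function(x, ...) {
  cat(sprintf("<oc_fit %s> n = %d, R^2 = %.4f%s\n", x$form, x$n,
              x$r_squared,
              if (isFALSE(x$converged)) " (NOT converged)" else ""))
  est <- unlist(x$coefficients)
  se <- unlist(x$coefficient_se)
  for (nm in names(est)) {
    cat(sprintf("  %-3s = %.6g (+/- %.3g)\n", nm, est[[nm]],
                if (nm %in% names(se)) se[[nm]] else NA_real_))
  }
  invisible(x)
}

.r_squared_centered <- function(observed, fitted) {
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) return(1)
  max(0, min(1, 1 - sum((observed - fitted)^2) / sst))
}

.check_xy <- function(x, y, min_n) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("som and oc must have equal length")
  if (any(is.na(x)) || any(is.na(y))) stop("som and oc must be non-missing")
  if (length(x) < min_n) stop("need at least ", min_n, " paired observations")
  invisible(TRUE)
}

#' Fit the linear conversion form OC = m * SOM + b
#'
#' Ordinary least squares of OC on SOM with coefficient standard errors
#' and centered R-squared.
#'
#' @param som,oc Paired numeric vectors in percent.
#' @return An `oc_fit` with coefficients `m` and `b`.
#' @examples
#' fit_linear(c(10, 20, 30), c(3, 8, 10))
#' @export
fit_linear <- function(som, oc) {
  .check_xy(som, oc, 3L)
  if (stats::var(som) == 0) stop("som has zero variance; slope undefined")
  fit <- stats::lm(oc ~ som)
  sm <- summary(fit)
  cf <- stats::coef(sm)
  .new_fit("linear",
           coef = list(m = unname(cf["som", 1]), b = unname(cf["(Intercept)", 1])),
           se = list(m = unname(cf["som", 2]), b = unname(cf["(Intercept)", 2])),
           r_squared = sm$r.squared, n = length(som),
           residuals = unname(stats::residuals(fit)),
           fitted = unname(stats::fitted(fit)),
           vcov = stats::vcov(fit)[c("som", "(Intercept)"),
                                   c("som", "(Intercept)")])
}

#' Fit the quadratic conversion form OC = a2 * SOM^2 + a1 * SOM + a0
#'
#' @param som,oc Paired numeric vectors in percent.
#' @param force_zero_intercept If `TRUE`, drop the intercept column
#'   (`a0 = 0`), the form of the published zero-intercept saltmarsh
#'   quadratic.
#' @return An `oc_fit` with coefficients `a2`, `a1`, `a0`.  R-squared is
#'   computed about the mean of `oc` in both cases, for comparability
#'   across forms.
#' @export
fit_quadratic <- function(som, oc, force_zero_intercept = FALSE) {
  .check_xy(som, oc, 4L)
  X <- if (force_zero_intercept) cbind(som2 = som^2, som = som)
       else cbind(som2 = som^2, som = som, one = 1)
  if (qr(X)$rank < ncol(X))
    stop("collinear design: quadratic coefficients not identifiable")
  fit <- if (force_zero_intercept) stats::lm(oc ~ 0 + I(som^2) + som)
         else stats::lm(oc ~ I(som^2) + som)
  sm <- summary(fit)
  cf <- stats::coef(sm)
  a0 <- if (force_zero_intercept) 0 else unname(cf["(Intercept)", 1])
  a0_se <- if (force_zero_intercept) NULL else unname(cf["(Intercept)", 2])
  se <- list(a2 = unname(cf["I(som^2)", 2]), a1 = unname(cf["som", 2]))
  if (!is.null(a0_se)) se$a0 <- a0_se
  fitted <- unname(stats::fitted(fit))
  .new_fit("quadratic",
           coef = list(a2 = unname(cf["I(som^2)", 1]),
                       a1 = unname(cf["som", 1]), a0 = a0),
           se = se,
           r_squared = .r_squared_centered(oc, fitted),
           n = length(som),
           residuals = unname(stats::residuals(fit)), fitted = fitted,
           vcov = stats::vcov(fit))
}

# Shared power-law engine: y = a * x^p by nonlinear least squares,
# initialized from log-log OLS; falls back to the log-log estimate with a
# warning if the NLS step fails.
.fit_power <- function(x, y, max_iter = 200, tol = 1e-8) {
  if (any(x <= 0) || any(y <= 0))
    stop("power fit requires strictly positive values")
  ll <- stats::lm(log(y) ~ log(x))
  start <- list(a = exp(unname(stats::coef(ll)[1])),
                p = unname(stats::coef(ll)[2]))
  dat <- data.frame(x = x, y = y)
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^p, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = max_iter, ftol = tol)),
    error = function(e) NULL)
  if (is.null(nls_fit)) {
    warning("nonlinear least squares did not converge; ",
            "returning the log-log estimate")
    fitted <- start$a * x^start$p
    ll_sm <- summary(ll)
    se <- list(a = start$a * unname(stats::coef(ll_sm)[1, 2]),
               p = unname(stats::coef(ll_sm)[2, 2]))
    return(.new_fit("power", coef = start, se = se,
                    r_squared = .r_squared_centered(y, fitted),
                    n = length(x), residuals = y - fitted, fitted = fitted,
                    converged = FALSE))
  }
  sm <- summary(nls_fit)
  cf <- stats::coef(sm)
  fitted <- unname(stats::fitted(nls_fit))
  .new_fit("power",
           coef = list(a = unname(cf["a", 1]), p = unname(cf["p", 1])),
           se = list(a = unname(cf["a", 2]), p = unname(cf["p", 2])),
           r_squared = .r_squared_centered(y, fitted),
           n = length(x), residuals = y - fitted, fitted = fitted,
           converged = TRUE, vcov = stats::vcov(nls_fit))
}

#' Fit the power conversion form OC = a * SOM^p
#'
#' Nonlinear least squares on the original (untransformed) scale,
#' initialized from a log-log OLS fit; R-squared is `1 - SSE/SST` on the
#' original scale so it is comparable with the linear and quadratic fits.
#'
#' @param som,oc Paired, strictly positive numeric vectors in percent.
#' @param max_iter,tol Optimizer controls (maximum iterations, relative
#'   tolerance).
#' @return An `oc_fit` with coefficients `a` and `p` and a `converged`
#'   flag.
#' @export
fit_power_oc <- function(som, oc, max_iter = 200, tol = 1e-8) {
  .check_xy(som, oc, 3L)
  .fit_power(som, oc, max_iter = max_iter, tol = tol)
}

#' Summarize a screened dataset by region
#'
#' Computes, for each region, the mean SOM (with standard error), sample
#' count, the regional linear conversion fit (slope, intercept,
#' R-squared), the region's CES label (modal value) and mean latitude.
#' Regions with fewer than 3 samples are dropped with a message.
#'
#' @param samples Data frame with columns `region`, `som`, `oc` and
#'   optionally `ces`, `sedimentary`, `latitude`.
#' @return Data frame with one row per region: `region`, `mean_som`,
#'   `se_som`, `n`, `slope`, `intercept`, `r_squared`, `ces`,
#'   `sedimentary`, `latitude`.
#' @export
region_summaries <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("region", "som", "oc") %in% names(samples)))
  regions <- unique(samples$region[!is.na(samples$region)])
  rows <- lapply(regions, function(rg) {
    d <- samples[!is.na(samples$region) & samples$region == rg, ]
    if (nrow(d) < 3L) {
      message("region '", rg, "' has fewer than 3 samples; skipped")
      return(NULL)
    }
    fit <- fit_linear(d$som, d$oc)
    modal <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_character_)
      names(sort(table(x), decreasing = TRUE))[1L]
    }
    data.frame(
      region = rg, mean_som = mean(d$som),
      se_som = stats::sd(d$som) / sqrt(nrow(d)), n = nrow(d),
      slope = fit$coefficients$m, intercept = fit$coefficients$b,
      r_squared = fit$r_squared,
      ces = if ("ces" %in% names(d)) modal(d$ces) else NA_character_,
      sedimentary = if ("sedimentary" %in% names(d)) modal(d$sedimentary)
                    else NA_character_,
      latitude = if ("latitude" %in% names(d)) mean(d$latitude) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the regional slope versus mean-SOM power curve
#'
#' Fits `slope = a * mean_som^p` across regions by the same nonlinear
#' least-squares routine as [fit_power_oc()].  This curve captures the
#' sharp initial rise of the conversion slope at low regional mean SOM
#' and its flattening toward high SOM, and supplies a rough conversion
#' slope for a region where only the mean SOM is known.
#'
#' @param summaries Data frame as returned by [region_summaries()]
#'   (columns `mean_som` and `slope`; at least 3 regions).
#' @return An `oc_fit` (power form) with the summaries attached as
#'   `data`.
#' @seealso [predict_slope()]
#' @export
fit_slope_vs_mean_som <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("mean_som", "slope") %in% names(summaries)))
  if (nrow(summaries) < 3L) stop("need at least 3 regions")
  if (stats::var(summaries$mean_som) == 0)
    stop("mean_som has zero variance across regions")
  fit <- .fit_power(summaries$mean_som, summaries$slope)
  fit$data <- summaries
  fit
}

#' Predict a conversion slope from regional mean SOM
#'
#' Evaluates the fitted power curve `a * mean_som^p`.  The predicted
#' slope implies a zero-intercept conversion equation, which empirical
#' regional fits rarely show exactly; treat it as a rough guide when no
#' better-tier equation is available.
#'
#' @param fit An `oc_fit` from [fit_slope_vs_mean_som()].
#' @param mean_som Regional mean SOM in percent (> 0), vectorized.
#' @param se If `TRUE`, also return a delta-method 1-SE band.
#' @return Numeric vector of predicted slopes, or (with `se = TRUE`) a
#'   data frame with columns `slope`, `se`, `lower`, `upper`.
#' @export
predict_slope <- function(fit, mean_som, se = FALSE) {
  stopifnot(inherits(fit, "oc_fit"), fit$form == "power")
  if (any(mean_som <= 0)) stop("mean_som must be positive")
  a <- fit$coefficients$a
  p <- fit$coefficients$p
  pred <- a * mean_som^p
  if (!se) return(pred)
  if (is.null(fit$vcov)) stop("fit carries no covariance; cannot form SE band")
  g <- cbind(mean_som^p, a * mean_som^p * log(mean_som))
  se_pred <- sqrt(rowSums((g %*% fit$vcov) * g))
  data.frame(slope = pred, se = se_pred,
             lower = pred - se_pred, upper = pred + se_pred)
}

#' Promote a fitted conversion to a registry equation
#'
#' Wraps an `oc_fit` as a [conversion_equation()] so freshly derived
#' regional equations can be added to a registry and used by
#' [select_equation()].
#'
#' @param fit An `oc_fit` from [fit_linear()], [fit_quadratic()] or
#'   [fit_power_oc()].
#' @param id,scope_level,scope_key,provenance Passed to
#'   [conversion_equation()].
#' @param som_validity_range Optional; defaults to the range of the data
#'   when the fit retains it, otherwise absent.
#' @return A [conversion_equation()].
#' @export
as_conversion_equation <- function(fit, id, scope_level, scope_key,
                                   provenance = "fitted",
                                   som_validity_range = NULL) {
  stopifnot(inherits(fit, "oc_fit"))
  conversion_equation(id = id, scope_level = scope_level,
                      scope_key = scope_key, form = fit$form,
                      coefficients = fit$coefficients,
                      coefficient_se = fit$coefficient_se,
                      r_squared = fit$r_squared, n = fit$n,
                      som_validity_range = som_validity_range,
                      provenance = provenance)
}
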