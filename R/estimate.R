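# The user-facing estimator: hierarchical equation selection, OC
# prediction with propagated uncertainty and clamping, depth-integrated
# stock computation, and paired stock comparison.

.tier_order <- c("regional", "ces", "sedimentary", "general",
                 "slope_from_mean_som")

#' Select the most appropriate conversion equation for a context
#'
#' Walks the selection hierarchy in order of decreasing accuracy:
#' a region-specific equation, then a coastal-environmental-setting (CES)
#' equation, then a sedimentary-setting equation, then the general
#' mangrove equation, and finally a slope derived from regional mean SOM
#' via the slope-vs-mean-SOM power curve.  Direct measurement of OC sits
#' above every tier and is handled by [predict_dataset_oc()].
#'
#' A carbonate-lagoon context (`ces = "CL"`) is served by the carbonate
#' open coast equation, the documented substitution for that unsampled
#' setting.
#'
#' @param registry An [equation_registry()].
#' @param context Named list with any of `region`, `ces`, `sedimentary`,
#'   `regional_mean_som`.  An empty context falls to the general tier.
#' @param general_form Which general equation to use at the general tier,
#'   `"linear"` (default) or `"quadratic"`.
#' @param slope_fit Optional `oc_fit` from [fit_slope_vs_mean_som()],
#'   required for the `slope_from_mean_som` tier.
#' @param tiers Tiers that may be used, in priority order; defaults to
#'   all.  Restrict to force a lower tier (e.g. to use the slope rule
#'   even though a general equation exists).
#' @return List with `equation` (a [conversion_equation()]) and `tier`.
#' @export
select_equation <- function(registry, context = list(),
                            general_form = c("linear", "quadratic"),
                            slope_fit = NULL, tiers = .tier_order) {
  stopifnot(inherits(registry, "equation_registry"))
  if (!length(registry$equations)) stop("empty registry")
  general_form <- match.arg(general_form)
  tiers <- match.arg(tiers, .tier_order, several.ok = TRUE)
  unknown <- setdiff(names(context),
                     c("region", "ces", "sedimentary", "regional_mean_som"))
  if (length(unknown))
    stop("unknown context key(s): ", paste(unknown, collapse = ", "))
  for (tier in tiers) {
    eq <- switch(tier,
      regional = if (!is.null(context$region)) {
        hits <- registry_find(registry, "region", context$region)
        if (length(hits)) hits[[1L]]
      },
      ces = if (!is.null(context$ces)) {
        key <- if (identical(context$ces, "CL")) "COC" else context$ces
        hits <- registry_find(registry, "ces", key)
        if (length(hits)) hits[[1L]]
      },
      sedimentary = if (!is.null(context$sedimentary)) {
        hits <- registry_find(registry, "sedimentary", context$sedimentary)
        if (length(hits)) hits[[1L]]
      },
      general = {
        hits <- Filter(function(e) e$form == general_form,
                       registry_find(registry, "general_mangrove"))
        if (length(hits)) hits[[1L]]
      },
      slope_from_mean_som = if (!is.null(context$regional_mean_som) &&
                                !is.null(slope_fit)) {
        m <- predict_slope(slope_fit, context$regional_mean_som)
        conversion_equation(
          id = sprintf("slope_from_mean_som_%.4g", context$regional_mean_som),
          scope_level = "general_mangrove", scope_key = "mangrove",
          form = "linear", coefficients = list(m = m, b = 0),
          provenance = "slope predicted from regional mean SOM; zero intercept assumed")
      })
    if (!is.null(eq)) return(list(equation = eq, tier = tier))
  }
  stop("no applicable equation for the given context and tiers")
}

#' Predict OC from SOM with one equation
#'
#' Evaluates the equation, propagates coefficient standard errors for the
#' linear form (`sqrt(som^2 * SE_m^2 + SE_b^2)`, ignoring slope-intercept
#' covariance, which published tables do not report), clamps negative
#' predictions to zero, and flags extrapolation beyond the equation's SOM
#' validity range.
#'
#' @param eq A [conversion_equation()].
#' @param som Numeric vector of SOM values in percent.
#' @param tier Tier label carried into the output (default
#'   the equation's scope level).
#' @param clamp If `TRUE` (default) negative raw predictions are clamped
#'   to 0.
#' @return Data frame with columns `som`, `equation_id`, `tier`,
#'   `oc_raw`, `oc`, `oc_se`, `extrapolated`, `clamped`.
#' @examples
#' reg <- load_builtin_registry()
#' estimate_oc(registry_get(reg, "ces_ce"), c(0, 40))
#' @export
estimate_oc <- function(eq, som, tier = NULL, clamp = TRUE) {
  stopifnot(inherits(eq, "conversion_equation"))
  raw <- evaluate_equation(eq, som)
  extrap <- attr(raw, "extrapolated")
  raw <- as.numeric(raw)
  se <- rep(NA_real_, length(som))
  if (eq$form == "linear" && !is.null(eq$coefficient_se)) {
    se_m <- eq$coefficient_se$m
    se_b <- if (is.null(eq$coefficient_se$b)) 0 else eq$coefficient_se$b
    if (!is.null(se_m)) se <- sqrt(som^2 * se_m^2 + se_b^2)
  }
  oc <- if (clamp) pmax(raw, 0) else raw
  data.frame(som = som, equation_id = eq$id,
             tier = if (is.null(tier)) eq$scope_level else tier,
             oc_raw = raw, oc = oc, oc_se = se,
             extrapolated = extrap, clamped = clamp & raw < 0)
}

#' Predict OC for a whole sample table through the selection hierarchy
#'
#' For each sample: a measured `oc` value is used directly (tier
#' `measured`); otherwise the equation chosen by [select_equation()] for
#' the sample's context (its `region`, `ces`, `sedimentary` columns,
#' falling back to the dataset-level `context`) is applied.
#'
#' @param samples Data frame with `som` and optionally `oc`, `region`,
#'   `ces`, `sedimentary`.
#' @param registry An [equation_registry()].
#' @param context Default context used where sample columns are missing.
#' @param ... Passed to [select_equation()].
#' @return `samples` with added columns `equation_id`, `tier`, `oc_raw`,
#'   `oc_est`, `oc_se`, `extrapolated`, `clamped`.  `oc_est` equals the
#'   measured `oc` where present.
#' @export
predict_dataset_oc <- function(samples, registry, context = list(), ...) {
  stopifnot(is.data.frame(samples), "som" %in% names(samples))
  n <- nrow(samples)
  out <- samples
  out$equation_id <- NA_character_
  out$tier <- NA_character_
  out$oc_raw <- NA_real_
  out$oc_est <- NA_real_
  out$oc_se <- NA_real_
  out$extrapolated <- FALSE
  out$clamped <- FALSE
  col_or_null <- function(d, nm, i) {
    if (nm %in% names(d) && !is.na(d[[nm]][i])) d[[nm]][i] else context[[nm]]
  }
  for (i in seq_len(n)) {
    if ("oc" %in% names(samples) && !is.na(samples$oc[i])) {
      out$tier[i] <- "measured"
      out$oc_est[i] <- samples$oc[i]
      out$oc_raw[i] <- samples$oc[i]
      out$oc_se[i] <- 0
      next
    }
    ctx <- list(region = col_or_null(samples, "region", i),
                ces = col_or_null(samples, "ces", i),
                sedimentary = col_or_null(samples, "sedimentary", i),
                regional_mean_som = context$regional_mean_som)
    ctx <- Filter(Negate(is.null), ctx)
    sel <- select_equation(registry, ctx, ...)
    pred <- estimate_oc(sel$equation, samples$som[i], tier = sel$tier)
    out$equation_id[i] <- pred$equation_id
    out$tier[i] <- pred$tier
    out$oc_raw[i] <- pred$oc_raw
    out$oc_est[i] <- pred$oc
    out$oc_se[i] <- pred$oc_se
    out$extrapolated[i] <- pred$extrapolated
    out$clamped[i] <- pred$clamped
  }
  out
}

#' Depth-integrated soil organic carbon stock for one core
#'
#' Stock over the profile down to `depth_limit` is the sum over depth
#' intervals of `(oc/100) * bulk_density * thickness`, in g cm^-2,
#' converted to Mg ha^-1 by the factor 100.  Intervals straddling the
#' depth limit are pro-rated by the in-limit fraction of their length.
#' The fraction of the profile above the limit not covered by any
#' interval is reported as `gap_fraction`.
#'
#' @param core Data frame for a single core with columns `depth_top`,
#'   `depth_bottom` (cm), `oc` (percent) and `bulk_density` (g cm^-3).
#'   Intervals must not overlap.
#' @param depth_limit Accounting depth in cm; default 100.
#' @return One-row data frame: `depth_limit`, `stock` (Mg ha^-1),
#'   `n_intervals` (intervals contributing), `gap_fraction`.
#' @examples
#' compute_stock(data.frame(depth_top = 0, depth_bottom = 100,
#'                          oc = 10, bulk_density = 0.5))  # 500 Mg/ha
#' @export
compute_stock <- function(core, depth_limit = 100) {
  stopifnot(is.data.frame(core),
            all(c("depth_top", "depth_bottom", "oc",
                  "bulk_density") %in% names(core)),
            is.numeric(depth_limit), depth_limit > 0)
  if (nrow(core) == 0L) {
    return(data.frame(depth_limit = depth_limit, stock = 0,
                      n_intervals = 0L, gap_fraction = 1))
  }
  if (any(core$depth_top >= core$depth_bottom))
    stop("each interval needs depth_top < depth_bottom")
  if (any(is.na(core$bulk_density)))
    stop("bulk density required for every interval used in a stock")
  ord <- order(core$depth_top)
  core <- core[ord, ]
  if (any(core$depth_top[-1L] < core$depth_bottom[-nrow(core)]))
    stop("overlapping depth intervals")
  top <- pmin(core$depth_top, depth_limit)
  bottom <- pmin(core$depth_bottom, depth_limit)
  thick <- pmax(bottom - top, 0)
  used <- thick > 0
  stock_gcm2 <- sum((core$oc[used] / 100) * core$bulk_density[used] *
                      thick[used])
  data.frame(depth_limit = depth_limit,
             stock = stock_gcm2 * 100,  # 1 g cm^-2 = 100 Mg ha^-1
             n_intervals = sum(used),
             gap_fraction = 1 - sum(thick) / depth_limit)
}

#' Per-core stocks for a whole dataset
#'
#' @param samples Data frame with `core_id`, `depth_top`, `depth_bottom`,
#'   `bulk_density` and an OC column (`oc_col`, default `"oc_est"`).
#' @param depth_limit Accounting depth in cm; default 100.
#' @param oc_col Name of the OC column to integrate.
#' @return Data frame with one row per core (`core_id` plus the
#'   [compute_stock()] columns).
#' @export
compute_stocks <- function(samples, depth_limit = 100, oc_col = "oc_est") {
  stopifnot(is.data.frame(samples),
            all(c("core_id", "depth_top", "depth_bottom",
                  "bulk_density") %in% names(samples)),
            oc_col %in% names(samples))
  rows <- lapply(split(samples, samples$core_id), function(d) {
    core <- data.frame(depth_top = d$depth_top,
                       depth_bottom = d$depth_bottom,
                       oc = d[[oc_col]], bulk_density = d$bulk_density)
    cbind(core_id = d$core_id[1L],
          compute_stock(core, depth_limit = depth_limit))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired comparison of two stock estimates
#'
#' Two-sided paired Wilcoxon signed-rank test between two stock series
#' for the same cores (e.g. stocks under two different conversion
#' equations), with medians and interquartile ranges.
#'
#' @param stock_a,stock_b Paired numeric vectors (same cores, same
#'   order), at least 5 pairs.
#' @return List with `statistic` (V), `p_value`, `n`, and a `summary`
#'   data frame of per-series median and IQR bounds.
#' @export
compare_stock_estimates <- function(stock_a, stock_b) {
  stopifnot(is.numeric(stock_a), is.numeric(stock_b))
  if (length(stock_a) != length(stock_b))
    stop("stock series must be paired (equal length)")
  if (any(is.na(stock_a)) || any(is.na(stock_b)))
    stop("stock series must be non-missing")
  n <- length(stock_a)
  if (n < 5L) stop("need at least 5 pairs")
  if (all(stock_a == stock_b)) {
    ht <- list(statistic = c(V = 0), p.value = 1)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(stock_a, stock_b,
                                              paired = TRUE,
                                              alternative = "two.sided"))
  }
  qa <- stats::quantile(stock_a, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- stats::quantile(stock_b, c(0.25, 0.5, 0.75), names = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
       summary = data.frame(series = c("a", "b"),
                            median = c(qa[2], qb[2]),
                            q25 = c(qa[1], qb[1]),
                            q75 = c(qa[3], qb[3])))
}
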