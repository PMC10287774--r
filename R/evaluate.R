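# Equation validation and group-comparison statistics: residual-vs-zero
# tests per region (Shapiro-Wilk gated t-test / Wilcoxon), sedimentary
# t-test, CES ANOVA with Tukey HSD letters, latitude regressions, and the
# SOM-binned latitudinal trend analysis.

#' Test a conversion equation's residuals against zero within one region
#'
#' Residuals are observed minus modeled OC.  A Shapiro-Wilk test on the
#' residuals gates the location test: if normality is not rejected at
#' `shapiro_alpha`, a one-sample t-test of the mean against zero is used
#' and the central tendency reported is the mean; otherwise a two-sided
#' one-sample Wilcoxon signed-rank test is used and the central tendency
#' is the median.  No transformation is applied before the gate.
#'
#' @param eq A [conversion_equation()].
#' @param samples Data frame of one region's samples with measured `oc`
#'   and `som` (and optionally `region`).
#' @param alpha Significance level for the difference-from-zero call.
#' @param shapiro_alpha Significance level of the normality gate.
#' @return One-row data frame: `region`, `equation_id`, `n`,
#'   `central_tendency`, `normality_p`, `test_used`
#'   (`one_sample_t` or `wilcoxon_signed_rank`), `p_value`,
#'   `different_from_zero`.
#' @export
validate_equation_on_region <- function(eq, samples, alpha = 0.05,
                                        shapiro_alpha = 0.05) {
  stopifnot(inherits(eq, "conversion_equation"), is.data.frame(samples),
            all(c("som", "oc") %in% names(samples)))
  n <- nrow(samples)
  if (n < 3L) stop("need at least 3 samples to test residuals")
  region <- if ("region" %in% names(samples)) {
    rg <- unique(samples$region)
    if (length(rg) > 1L) stop("samples span more than one region")
    as.character(rg)
  } else NA_character_
  resid <- samples$oc - as.numeric(evaluate_equation(eq, samples$som))
  # shapiro.test errors on constant input; identical residuals are
  # trivially symmetric, treat as the parametric path with p = 1
  if (stats::sd(resid) == 0) {
    ct <- mean(resid)
    p <- if (ct == 0) 1 else 0  # all residuals equal and nonzero
    return(data.frame(region = region, equation_id = eq$id, n = n,
                      central_tendency = ct, normality_p = NA_real_,
                      test_used = "one_sample_t", p_value = p,
                      different_from_zero = p < alpha))
  }
  norm_p <- stats::shapiro.test(resid)$p.value
  if (norm_p >= shapiro_alpha) {
    ht <- stats::t.test(resid, mu = 0)
    test_used <- "one_sample_t"
    ct <- mean(resid)
  } else {
    nz <- sum(resid != 0)
    exact <- nz <= 25 && !any(duplicated(abs(resid[resid != 0])))
    ht <- suppressWarnings(stats::wilcox.test(resid, mu = 0,
                                              alternative = "two.sided",
                                              exact = exact,
                                              correct = TRUE))
    test_used <- "wilcoxon_signed_rank"
    ct <- stats::median(resid)
  }
  data.frame(region = region, equation_id = eq$id, n = n,
             central_tendency = ct, normality_p = norm_p,
             test_used = test_used, p_value = ht$p.value,
             different_from_zero = ht$p.value < alpha)
}

#' Validate every equation of a family across all regions
#'
#' Convenience wrapper running [validate_equation_on_region()] for one or
#' more equations over each region of a dataset.  For scope level
#' `"region"` each region is tested with its own matching equation;
#' for other levels each region is tested with the equation matching its
#' label (`ces` or `sedimentary` column) or with the single supplied
#' equation.
#'
#' @param samples Screened data frame with `region`, `som`, `oc` and the
#'   label columns needed by `scope_level`.
#' @param registry An [equation_registry()].
#' @param scope_level Which equation family to validate.
#' @param alpha,shapiro_alpha Passed through.
#' @return Data frame of per-region reports (one row per region).
#' @export
validate_registry_on_regions <- function(samples, registry,
                                         scope_level = c("region", "ces",
                                                         "sedimentary",
                                                         "general_mangrove"),
                                         alpha = 0.05, shapiro_alpha = 0.05) {
  scope_level <- match.arg(scope_level)
  stopifnot(is.data.frame(samples), "region" %in% names(samples))
  regions <- unique(samples$region[!is.na(samples$region)])
  rows <- lapply(regions, function(rg) {
    d <- samples[!is.na(samples$region) & samples$region == rg, ]
    if (nrow(d) < 3L) return(NULL)
    key <- switch(scope_level,
      region = rg,
      ces = { k <- unique(d$ces[!is.na(d$ces)]); if (length(k)) k[1L] else NA },
      sedimentary = { k <- unique(d$sedimentary[!is.na(d$sedimentary)])
                      if (length(k)) k[1L] else NA },
      general_mangrove = "mangrove")
    if (is.na(key)) return(NULL)
    hits <- registry_find(registry, scope_level, key)
    if (scope_level == "general_mangrove") {
      hits <- Filter(function(e) e$form == "linear", hits)
    }
    if (!length(hits)) return(NULL)
    validate_equation_on_region(hits[[1L]], d, alpha = alpha,
                                shapiro_alpha = shapiro_alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize per-region residual reports for one equation family
#'
#' `abs_sum` is the sum over regions of the absolute central tendency of
#' the residuals; `abs_mean = abs_sum / n_regions`.  Lower values mean
#' the family tracks regional OC more closely.
#'
#' @param reports Data frame of [validate_equation_on_region()] rows, one
#'   per region (duplicate regions are an error).
#' @param equation_family Label for the family (free text).
#' @return One-row data frame: `equation_family`, `abs_sum`, `abs_mean`,
#'   `n_regions`, `n_not_different_from_zero`.
#' @export
summarize_validation <- function(reports, equation_family = "family") {
  stopifnot(is.data.frame(reports),
            all(c("region", "central_tendency",
                  "different_from_zero") %in% names(reports)))
  if (anyDuplicated(reports$region))
    stop("duplicate regions in validation reports")
  abs_sum <- sum(abs(reports$central_tendency))
  n <- nrow(reports)
  data.frame(equation_family = equation_family,
             abs_sum = abs_sum, abs_mean = abs_sum / n, n_regions = n,
             n_not_different_from_zero = sum(!reports$different_from_zero))
}

.ratio_or_stop <- function(samples) {
  stopifnot(all(c("som", "oc") %in% names(samples)))
  if (any(samples$som <= 0)) stop("som must be positive to form OC:SOM")
  samples$oc / samples$som
}

#' Compare OC:SOM between sedimentary settings
#'
#' Independent two-sample t-test (pooled variance) of per-sample OC:SOM
#' between carbonate and terrigenous settings.
#'
#' @param samples Data frame with `som`, `oc` and a `sedimentary` column
#'   with exactly two levels, each with at least 2 samples.
#' @return List with `t`, `df`, `p_value`, and `group_stats` (per-group
#'   mean, SE, n).
#' @export
compare_sedimentary <- function(samples) {
  stopifnot(is.data.frame(samples), "sedimentary" %in% names(samples))
  d <- samples[!is.na(samples$sedimentary), ]
  ratio <- .ratio_or_stop(d)
  g <- factor(d$sedimentary)
  if (nlevels(g) != 2L) stop("need exactly two sedimentary settings")
  if (any(table(g) < 2L)) stop("each sedimentary group needs n >= 2")
  ht <- stats::t.test(ratio ~ g, var.equal = TRUE)
  stats_by <- data.frame(
    group = levels(g),
    mean = tapply(ratio, g, mean),
    se = tapply(ratio, g, function(x) stats::sd(x) / sqrt(length(x))),
    n = as.integer(table(g)))
  rownames(stats_by) <- NULL
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, group_stats = stats_by)
}

# Compact letter display from a matrix of pairwise "not different" flags.
# Groups are ordered by decreasing mean; letters mark maximal runs of
# mutually indistinguishable groups (insert-and-absorb on sorted means).
.tukey_letters <- function(group_names, means, not_diff) {
  ord <- order(-means)
  k <- length(ord)
  sets <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(not_diff[ord[i:(j + 1)], ord[i:(j + 1)]]))
      j <- j + 1
    sets[[length(sets) + 1L]] <- ord[i:j]
  }
  # drop sets contained in an earlier set
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[i]]) < length(sets[[j]])) keep[i] <- FALSE
    }
  }
  sets <- unique(sets[keep])
  letters_out <- rep("", k)
  for (s in seq_along(sets)) {
    lab <- LETTERS[s]
    for (g in sets[[s]]) letters_out[g] <- paste0(letters_out[g], lab)
  }
  names(letters_out) <- group_names
  letters_out
}

#' Compare OC:SOM across coastal environmental settings
#'
#' One-way ANOVA of per-sample OC:SOM across CES groups, with Tukey HSD
#' post-hoc comparisons and a compact letter display (groups sharing a
#' letter are not significantly different at `alpha`).
#'
#' @param samples Data frame with `som`, `oc` and a `ces` column
#'   (at least 2 groups, each n >= 2).
#' @param alpha Significance level for the letters; default 0.05.
#' @return List with `F`, `df` (length 2), `p_value`, `tukey` (data frame
#'   of pairwise comparisons), `letters` (named character vector) and
#'   `group_stats`.
#' @export
compare_ces <- function(samples, alpha = 0.05) {
  stopifnot(is.data.frame(samples), "ces" %in% names(samples))
  d <- samples[!is.na(samples$ces), ]
  ratio <- .ratio_or_stop(d)
  g <- factor(d$ces)
  if (nlevels(g) < 2L) stop("need at least two CES groups")
  if (any(table(g) < 2L)) stop("each CES group needs n >= 2")
  dat <- data.frame(ratio = ratio, g = g)
  fit <- stats::aov(ratio ~ g, data = dat)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  means <- tapply(ratio, g, mean)
  not_diff <- diag(nlevels(g)) == 1
  dimnames(not_diff) <- list(levels(g), levels(g))
  for (r in seq_len(nrow(tukey))) {
    pair <- strsplit(tukey$comparison[r], "-", fixed = TRUE)[[1L]]
    nd <- tukey$p_adj[r] >= alpha
    not_diff[pair[1L], pair[2L]] <- nd
    not_diff[pair[2L], pair[1L]] <- nd
  }
  group_stats <- data.frame(
    group = levels(g), mean = as.numeric(means),
    se = as.numeric(tapply(ratio, g, function(x) stats::sd(x) / sqrt(length(x)))),
    n = as.integer(table(g)))
  list(F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
       p_value = an[1, "Pr(>F)"], tukey = tukey,
       letters = .tukey_letters(levels(g), as.numeric(means), not_diff),
       group_stats = group_stats)
}

#' Latitude regressions of regional slope and mean SOM
#'
#' Two simple linear regressions over a subset of regions (typically a
#' geologically coherent gradient): conversion slope on latitude, and
#' regional mean SOM on latitude.
#'
#' @param summaries Data frame from [region_summaries()] with a
#'   `latitude` column.
#' @param subset Optional character vector of region names to use;
#'   default all.
#' @return List with `slope_vs_latitude` and `mean_som_vs_latitude`,
#'   both `oc_fit` objects (linear form, coefficient `m` per degree).
#' @export
latitude_regressions <- function(summaries, subset = NULL) {
  stopifnot(is.data.frame(summaries),
            all(c("region", "latitude", "slope", "mean_som") %in%
                  names(summaries)))
  d <- if (is.null(subset)) summaries
       else summaries[summaries$region %in% subset, ]
  if (nrow(d) < 3L) stop("need at least 3 regions with latitude")
  if (any(is.na(d$latitude))) stop("missing latitudes in selected regions")
  if (stats::var(d$latitude) == 0) stop("latitude has zero variance")
  list(slope_vs_latitude = fit_linear(d$latitude, d$slope),
       mean_som_vs_latitude = fit_linear(d$latitude, d$mean_som))
}

#' Latitudinal OC:SOM trends within SOM increments
#'
#' Partitions samples into SOM bins (default 10-percent increments
#' \[0,10), \[10,20), ...), computes regional mean OC:SOM within each bin,
#' and regresses it on regional mean latitude.  Binning removes the
#' confounding of latitude with regional mineral-sediment (hence SOM)
#' content, isolating any residual latitudinal effect on OC:SOM.
#'
#' @param samples Data frame with `region`, `som`, `oc`, `latitude`.
#' @param bin_width SOM bin width in percent; default 10.
#' @param alpha Significance level used to select bins for the average
#'   slope; default 0.05.
#' @param min_regions Bins with fewer regions than this are skipped
#'   (logged in the output); default 3.
#' @return List with `bins` (per-bin data frame: `bin`, `n_regions`,
#'   `slope`, `se`, `p_value`, `significant`), `skipped` (character
#'   vector of skipped bins), `avg_slope_significant`,
#'   `avg_slope_all`, and `se_avg_significant` (delta-method SE of the
#'   average over significant bins).  Slopes are change in mean OC:SOM
#'   per degree latitude.
#' @export
binned_latitude_trends <- function(samples, bin_width = 10, alpha = 0.05,
                                   min_regions = 3L) {
  stopifnot(is.data.frame(samples),
            all(c("region", "som", "oc", "latitude") %in% names(samples)))
  ratio <- .ratio_or_stop(samples)
  bin <- floor(samples$som / bin_width)
  bin_label <- sprintf("[%g,%g)", bin * bin_width, (bin + 1) * bin_width)
  rows <- list()
  skipped <- character(0)
  for (b in sort(unique(bin))) {
    in_bin <- bin == b
    d <- data.frame(region = samples$region[in_bin],
                    ratio = ratio[in_bin],
                    latitude = samples$latitude[in_bin])
    agg <- do.call(rbind, lapply(split(d, d$region), function(x) {
      data.frame(ratio = mean(x$ratio), latitude = mean(x$latitude))
    }))
    lbl <- sprintf("[%g,%g)", b * bin_width, (b + 1) * bin_width)
    if (nrow(agg) < min_regions || stats::var(agg$latitude) == 0) {
      skipped <- c(skipped, lbl)
      next
    }
    fit <- fit_linear(agg$latitude, agg$ratio)
    tval <- fit$coefficients$m / fit$coefficient_se$m
    p <- 2 * stats::pt(-abs(tval), df = nrow(agg) - 2)
    rows[[length(rows) + 1L]] <- data.frame(
      bin = lbl, n_regions = nrow(agg), slope = fit$coefficients$m,
      se = fit$coefficient_se$m, p_value = p, significant = p < alpha)
  }
  bins <- do.call(rbind, rows)
  if (is.null(bins)) {
    return(list(bins = NULL, skipped = skipped,
                avg_slope_significant = NA_real_, avg_slope_all = NA_real_,
                se_avg_significant = NA_real_))
  }
  sig <- bins[bins$significant, , drop = FALSE]
  avg_sig <- if (nrow(sig)) mean(sig$slope) else NA_real_
  se_sig <- if (nrow(sig)) sqrt(sum(sig$se^2)) / nrow(sig) else NA_real_
  list(bins = bins, skipped = skipped,
       avg_slope_significant = avg_sig,
       avg_slope_all = mean(bins$slope),
       se_avg_significant = se_sig)
}
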