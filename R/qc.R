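# Two-stage outlier screening applied before any fitting: a physical
# bounds rule on the OC:SOM ratio, then an iterative modified Thompson
# tau test on the ratios within each region.

#' Remove samples with impossible OC:SOM ratios
#'
#' Organic carbon cannot exceed organic matter, and OC without SOM (or
#' non-positive OC) indicates an analysis error.  Samples with
#' `oc/som >= 1` or `oc/som <= 0` are removed; samples with `som == 0`
#' and a measured `oc` have an undefined ratio and are removed as well.
#'
#' @param samples Data frame of soil samples with numeric columns `som`
#'   and `oc` (percent of dry mass).
#' @return List with elements `kept` (data frame of retained samples) and
#'   `removed` (data frame of removed samples with an added `reason`
#'   column: `ratio_high`, `ratio_nonpositive`, or `undefined_ratio`).
#' @examples
#' d <- data.frame(som = c(10, 10, 10), oc = c(5, 12, 0))
#' filter_ratio_bounds(d)$removed$reason
#' @export
filter_ratio_bounds <- function(samples) {
  stopifnot(is.data.frame(samples), all(c("som", "oc") %in% names(samples)))
  if (nrow(samples) == 0L) {
    rem <- samples
    rem$reason <- character(0)
    return(list(kept = samples, removed = rem))
  }
  if (any(is.na(samples$som)) || any(is.na(samples$oc)))
    stop("som and oc must be non-missing for ratio screening")
  undefined <- samples$som == 0
  ratio <- ifelse(undefined, NA_real_, samples$oc / samples$som)
  reason <- rep(NA_character_, nrow(samples))
  reason[undefined] <- "undefined_ratio"
  reason[!undefined & ratio >= 1] <- "ratio_high"
  reason[!undefined & ratio <= 0] <- "ratio_nonpositive"
  drop <- !is.na(reason)
  removed <- samples[drop, , drop = FALSE]
  removed$reason <- reason[drop]
  list(kept = samples[!drop, , drop = FALSE], removed = removed)
}

#' Modified Thompson tau outlier filter
#'
#' Iteratively removes the single most deviant point while its absolute
#' deviation from the sample mean exceeds `tau * SD`, where
#' `tau = t * (n - 1) / (sqrt(n) * sqrt(n - 2 + t^2))` and `t` is the
#' two-sided Student-t critical value at level `alpha` with `n - 2`
#' degrees of freedom.  Iteration stops when no point exceeds the
#' threshold or fewer than 3 points remain.  Ties on the maximal
#' deviation are broken by input order (first occurrence removed).
#'
#' @param values Numeric vector.
#' @param alpha Significance level of the tau threshold; default 0.05.
#' @return List with `kept` and `removed` numeric vectors and
#'   `removed_index`, the positions of removed points in the input.
#' @examples
#' thompson_tau_filter(c(1, 1, 1, 1, 10))$removed  # 10
#' @export
thompson_tau_filter <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values), is.numeric(alpha), alpha > 0, alpha < 1)
  if (any(is.na(values))) stop("values must be non-missing")
  if (length(values) < 3L) {
    warning("fewer than 3 values; Thompson tau filter not applied")
    return(list(kept = values, removed = numeric(0),
                removed_index = integer(0)))
  }
  idx <- seq_along(values)
  x <- values
  removed_index <- integer(0)
  repeat {
    n <- length(x)
    if (n < 3L) break
    s <- stats::sd(x)
    if (s == 0) break
    tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
    tau <- tcrit * (n - 1) / (sqrt(n) * sqrt(n - 2 + tcrit^2))
    dev <- abs(x - mean(x))
    i <- which.max(dev)  # first maximum on ties
    if (dev[i] > tau * s) {
      removed_index <- c(removed_index, idx[i])
      x <- x[-i]
      idx <- idx[-i]
    } else break
  }
  list(kept = values[sort(idx)], removed = values[sort(removed_index)],
       removed_index = sort(removed_index))
}

#' Screen a soil-core dataset for outliers
#'
#' Applies [filter_ratio_bounds()] to the whole dataset, then
#' [thompson_tau_filter()] to the OC:SOM ratios within each region.
#' Samples without a region label pass the bounds stage but are exempt
#' from the tau stage (logged).
#'
#' @param samples Data frame with columns `som`, `oc` and `region`
#'   (region may contain `NA`).
#' @param tau_alpha Significance level for the tau stage; default 0.05.
#' @return List with `kept` (screened data frame) and `removal_log`
#'   (data frame with columns `row`, `region`, `stage`, `reason`,
#'   `value`; `stage` is `bounds`, `tau`, or `tau_exempt`).
#' @export
screen_dataset <- function(samples, tau_alpha = 0.05) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0L) {
    return(list(kept = samples,
                removal_log = data.frame(row = integer(0),
                                         region = character(0),
                                         stage = character(0),
                                         reason = character(0),
                                         value = numeric(0))))
  }
  stopifnot(all(c("som", "oc", "region") %in% names(samples)))
  samples$.row <- seq_len(nrow(samples))
  b <- filter_ratio_bounds(samples)
  log_rows <- list()
  if (nrow(b$removed)) {
    log_rows[[1L]] <- data.frame(
      row = b$removed$.row,
      region = as.character(b$removed$region),
      stage = "bounds", reason = b$removed$reason,
      value = ifelse(b$removed$som == 0, NA_real_,
                     b$removed$oc / b$removed$som))
  }
  kept <- b$kept
  no_region <- is.na(kept$region)
  if (any(no_region)) {
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      row = kept$.row[no_region], region = NA_character_,
      stage = "tau_exempt", reason = "region_missing",
      value = kept$oc[no_region] / kept$som[no_region])
  }
  drop_rows <- integer(0)
  for (rg in unique(kept$region[!no_region])) {
    in_rg <- which(!no_region & kept$region == rg)
    if (length(in_rg) < 3L) next
    ratio <- kept$oc[in_rg] / kept$som[in_rg]
    tt <- suppressWarnings(thompson_tau_filter(ratio, alpha = tau_alpha))
    if (length(tt$removed_index)) {
      rows <- in_rg[tt$removed_index]
      drop_rows <- c(drop_rows, rows)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        row = kept$.row[rows], region = as.character(rg),
        stage = "tau", reason = "tau_outlier", value = ratio[tt$removed_index])
    }
  }
  if (length(drop_rows)) kept <- kept[-drop_rows, , drop = FALSE]
  removal_log <- if (length(log_rows)) {
    out <- do.call(rbind, log_rows)
    out[order(out$row), , drop = FALSE]
  } else {
    data.frame(row = integer(0), region = character(0),
               stage = character(0), reason = character(0),
               value = numeric(0))
  }
  rownames(removal_log) <- NULL
  kept$.row <- NULL
  rownames(kept) <- NULL
  list(kept = kept, removal_log = removal_log)
}
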