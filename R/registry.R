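# Coefficient slots expected for each functional form.
.form_slots <- list(
  linear    = c("m", "b"),
  quadratic = c("a2", "a1", "a0"),
  power     = c("a", "p")
)

.scope_levels <- c("general_mangrove", "sedimentary", "ces", "region",
                   "literature_regional", "literature_ecosystem")

.ces_codes <- c("TD", "TE", "TL", "TOC", "CE", "COC")
.sedimentary_codes <- c("terrigenous", "carbonate")

#' Construct a SOM-to-OC conversion equation
#'
#' A conversion equation predicts soil organic carbon content (OC, percent
#' of dry mass) from loss-on-ignition soil organic matter (SOM, percent of
#' dry mass).  Three functional forms are supported: `linear`
#' (`OC = m * SOM + b`), `quadratic` (`OC = a2 * SOM^2 + a1 * SOM + a0`)
#' and `power` (`OC = a * SOM^p`).  All coefficients are stored on the
#' percent scale: SOM and OC range 0--100, and an intercept of 10 means
#' 10% OC at SOM = 0.
#'
#' Linear equations may omit the intercept (`b` absent), in which case the
#' equation is evaluated as a pure slope (`OC = m * SOM`); this is how
#' published equations whose intercept was not reported are stored.
#'
#' @param id Short unique identifier string.
#' @param scope_level One of `"general_mangrove"`, `"sedimentary"`,
#'   `"ces"`, `"region"`, `"literature_regional"`,
#'   `"literature_ecosystem"`.
#' @param scope_key Scope identifier: a region name, a coastal
#'   environmental setting code (`TD`, `TE`, `TL`, `TOC`, `CE`, `COC`),
#'   a sedimentary code (`terrigenous`, `carbonate`), or a free label.
#' @param form `"linear"`, `"quadratic"` or `"power"`.
#' @param coefficients Named list; names must match the form
#'   (`m`/`b` for linear, `a2`/`a1`/`a0` for quadratic, `a`/`p` for
#'   power).  A linear `b` may be omitted.
#' @param coefficient_se Optional named list of standard errors, same
#'   naming.
#' @param r_squared Optional coefficient of determination in \[0, 1\].
#' @param n Optional sample count behind the equation.
#' @param som_validity_range Optional length-2 numeric, the SOM range (%)
#'   the equation was derived over; predictions outside it are flagged as
#'   extrapolated.
#' @param provenance Free-text citation key.
#' @return An object of class `conversion_equation`.
#' @examples
#' eq <- conversion_equation("demo", "region", "Demo Bay", "linear",
#'                           list(m = 0.5, b = 0))
#' evaluate_equation(eq, c(10, 50))
#' @export
conversion_equation <- function(id, scope_level, scope_key, form,
                                coefficients, coefficient_se = NULL,
                                r_squared = NULL, n = NULL,
                                som_validity_range = NULL,
                                provenance = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  scope_level <- match.arg(scope_level, .scope_levels)
  form <- match.arg(form, names(.form_slots))
  slots <- .form_slots[[form]]
  cf <- as.list(coefficients)
  extra <- setdiff(names(cf), slots)
  if (length(extra)) {
    stop("coefficients ", paste(extra, collapse = ", "),
         " are not valid for form '", form, "'")
  }
  # the linear intercept is the only optional slot
  required <- if (form == "linear") "m" else slots
  missing_req <- setdiff(required, names(cf))
  if (length(missing_req)) {
    stop("form '", form, "' requires coefficient(s): ",
         paste(missing_req, collapse = ", "))
  }
  if (!all(vapply(cf, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1L)))) {
    stop("coefficients must be finite scalars")
  }
  if (!is.null(coefficient_se)) {
    se <- as.list(coefficient_se)
    bad <- setdiff(names(se), slots)
    if (length(bad)) stop("standard errors given for unknown slot(s): ",
                          paste(bad, collapse = ", "))
  } else {
    se <- NULL
  }
  if (!is.null(r_squared)) {
    stopifnot(is.numeric(r_squared), r_squared >= 0, r_squared <= 1)
  }
  if (!is.null(som_validity_range)) {
    som_validity_range <- as.numeric(som_validity_range)
    stopifnot(length(som_validity_range) == 2L,
              som_validity_range[1] <= som_validity_range[2])
  }
  structure(
    list(id = id, scope_level = scope_level, scope_key = scope_key,
         form = form, coefficients = cf, coefficient_se = se,
         r_squared = r_squared,
         n = if (is.null(n) || is.na(n)) NULL else as.integer(n),
         som_validity_range = som_validity_range,
         provenance = provenance),
    class = "conversion_equation")
}

#' @export
print.conversion_equation <- function(x, ...) {
  cf <- x$coefficients
  txt <- switch(x$form,
    linear = if (is.null(cf$b)) sprintf("OC = %.4g * SOM", cf$m)
             else sprintf("OC = %.4g * SOM %+.4g", cf$m, cf$b),
    quadratic = sprintf("OC = %.4g * SOM^2 %+.4g * SOM %+.4g",
                        cf$a2, cf$a1, cf$a0),
    power = sprintf("OC = %.4g * SOM^%.4g", cf$a, cf$p))
  cat(sprintf("<conversion_equation %s> [%s: %s]\n  %s\n",
              x$id, x$scope_level, x$scope_key, txt))
  if (!is.null(x$r_squared))
    cat(sprintf("  R^2 = %.3g%s\n", x$r_squared,
                if (!is.null(x$n)) sprintf(", n = %d", x$n) else ""))
  invisible(x)
}

#' Convert a regression intercept between percent and fraction conventions
#'
#' Published conversion equations report SOM and OC either as percentages
#' (0--100) or as decimal fractions (0--1).  The slope is identical under
#' both conventions, but the intercept scales: an intercept of 10 on the
#' percent scale corresponds to 0.10 on the fraction scale (both meaning
#' 10% OC at SOM = 0).
#'
#' @param b Intercept value.
#' @param from_convention,to_convention `"percent"` or `"fraction"`.
#' @return The intercept expressed in the target convention.
#' @examples
#' convert_intercept_units(10, "percent", "fraction")   # 0.10
#' convert_intercept_units(0.01, "fraction", "percent") # 1
#' @export
convert_intercept_units <- function(b, from_convention = c("percent", "fraction"),
                                    to_convention = c("percent", "fraction")) {
  from_convention <- match.arg(from_convention)
  to_convention <- match.arg(to_convention)
  if (from_convention == to_convention) return(b)
  if (from_convention == "percent") b / 100 else b * 100
}

#' Evaluate a conversion equation at given SOM values
#'
#' Returns the raw (unclamped) OC prediction in percent.  Negative
#' predictions are possible for equations with negative intercepts;
#' clamping to zero is the responsibility of [estimate_oc()].  A logical
#' attribute `"extrapolated"` marks SOM values outside the equation's
#' validity range (always `FALSE` when no range is recorded).
#'
#' @param eq A [conversion_equation()].
#' @param som Numeric vector of SOM values in percent (0--100).
#' @return Numeric vector of OC predictions (percent), with attribute
#'   `extrapolated`.
#' @examples
#' eq <- conversion_equation("demo", "region", "Demo", "linear",
#'                           list(m = 0.5, b = 0))
#' evaluate_equation(eq, 50)
#' @export
evaluate_equation <- function(eq, som) {
  stopifnot(inherits(eq, "conversion_equation"), is.numeric(som))
  if (any(som < 0 | som > 100, na.rm = TRUE))
    stop("som must lie in [0, 100]")
  cf <- eq$coefficients
  oc <- switch(eq$form,
    linear = cf$m * som + if (is.null(cf$b)) 0 else cf$b,
    quadratic = cf$a2 * som^2 + cf$a1 * som + cf$a0,
    power = cf$a * som^cf$p,
    stop("unknown functional form: ", eq$form))
  extrap <- if (is.null(eq$som_validity_range)) rep(FALSE, length(som)) else
    som < eq$som_validity_range[1] | som > eq$som_validity_range[2]
  attr(oc, "extrapolated") <- extrap
  oc
}

# ---------------------------------------------------------------------------
# Built-in registry
# ---------------------------------------------------------------------------

# Regional equations derived from the primary 17-region dataset.  Columns:
# region, CES code, slope, SE, intercept (%), SE, R^2, n.
.builtin_regional <- function() {
  txt <- "
region|ces|m|se_m|b|se_b|r2|n
St. Augustine|TL|0.283|0.012|-0.3|0.1|0.96|29
Apalachicola Bay|TL|0.392|0.016|-0.1|0.3|0.96|27
Waccasassa Bay|TOC|0.360|0.028|-2.8|0.9|0.87|28
Merritt Island|TL|0.460|0.009|-0.3|0.3|0.98|50
Tampa Bay|CE|0.427|0.016|-0.2|0.6|0.90|80
Charlotte Harbor|CE|0.465|0.015|1.2|0.7|0.96|43
Ten Thousand Islands|COC|0.442|0.019|0.9|1.0|0.75|183
Biscayne Bay|COC|0.439|0.032|1.5|1.5|0.88|29
Southwest Everglades|CE|0.515|0.006|-2.2|0.4|0.93|543
Southeast Everglades|CE|0.519|0.020|-4.5|1.1|0.95|36
Lower Keys|COC|0.521|0.033|-1.9|2.3|0.92|23
Laguna Gandoca|TL|0.687|0.036|-15.5|2.3|0.95|21
Marapanim|TD|0.240|0.038|0.1|0.5|0.80|12
Caravelas|TD|0.321|0.022|-2.1|0.5|0.86|36
Garapua|TOC|0.369|0.027|0.1|0.5|0.85|36
Ratones, Itapoa, & Guaratuba|TE|0.249|0.034|0.0|0.4|0.63|34
Sao Paulo State|TL|0.355|0.026|-0.7|0.5|0.85|36"
  utils::read.delim(text = txt, sep = "|", strip.white = TRUE)
}

.builtin_ces <- function() {
  txt <- "
ces|m|se_m|b|se_b|r2|n
CE|0.506|0.005|-1.7|0.3|0.94|702
COC|0.470|0.014|-0.6|0.7|0.82|235
TD|0.287|0.019|-1.2|0.4|0.84|48
TE|0.250|0.033|0.9|3.7|0.64|34
TL|0.472|0.007|-1.7|0.2|0.97|163
TOC|0.281|0.021|0.7|0.5|0.75|64"
  utils::read.delim(text = txt, sep = "|", strip.white = TRUE)
}

# Previously published region-specific mangrove equations (linear; some
# intercepts unreported and stored absent).
.builtin_literature <- function() {
  txt <- "
key|ces|m|b|r2|n|som_min|som_max|prov
Mui Ca Mau, Vietnam|TD|0.23|0.2|0.56|225|3|20|Tue2014
Chek Jawa, Singapore|TE|0.24|1.2|0.46|40|0|30|Phang2015
Hau Loc, Vietnam|TOC|0.25|-2.7|0.72|NA|2|11|VanHieu2017
Ceara State, Brazil|TE|0.27|NA|0.82|60|5|30|Nobrega2015
Can Gio, Vietnam|TD|0.35|-1.3|0.80|316|5|20|Dung2016
Sao Paulo State, Brazil|TL|0.35|-0.69|0.84|36|5|27|Rovai2021
Matang, Malaysia|NA|0.37|-0.1|0.61|103|20|55|Adame2018
Dong Rui, Vietnam|TOC|0.41|NA|0.79|30|3|17|Nguyen2019
Tampa Bay, FL USA|CE|0.42|NA|0.95|57|2|69|Radabaugh2018
Republic of Palau|COC|0.42|2.9|0.59|78|15|52|KauffmanDonato2012
Gazi Bay and Vanga, Kenya|NA|0.43|0.2|0.64|70|NA|NA|Gress2017
Chonburi Province, Thailand|TE|0.50|0.10|0.25|29|6|17|Chaikaew2017
Jervis Bay, Australia|TE|0.51|0.2|0.95|32|0|16|Owers2018
Muisne Island, Ecuador|NA|0.87|-5.8|0.89|NA|0|35|Delvecchia2014"
  utils::read.delim(text = txt, sep = "|", strip.white = TRUE,
                    na.strings = "NA")
}

.builtin_equations <- function() {
  eqs <- list()
  add <- function(e) eqs[[length(eqs) + 1L]] <<- e

  reg <- .builtin_regional()
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    add(conversion_equation(
      id = paste0("region_", gsub("[^a-z0-9]+", "_", tolower(r$region))),
      scope_level = "region", scope_key = r$region, form = "linear",
      coefficients = list(m = r$m, b = r$b),
      coefficient_se = list(m = r$se_m, b = r$se_b),
      r_squared = r$r2, n = r$n,
      provenance = paste0("primary dataset; CES ", r$ces)))
  }

  ces <- .builtin_ces()
  ces_names <- c(CE = "Carbonate Estuary", COC = "Carbonate Open Coast",
                 TD = "Terrigenous Delta", TE = "Terrigenous Estuary",
                 TL = "Terrigenous Lagoon", TOC = "Terrigenous Open Coast")
  for (i in seq_len(nrow(ces))) {
    r <- ces[i, ]
    add(conversion_equation(
      id = paste0("ces_", tolower(r$ces)),
      scope_level = "ces", scope_key = r$ces, form = "linear",
      coefficients = list(m = r$m, b = r$b),
      coefficient_se = list(m = r$se_m, b = r$se_b),
      r_squared = r$r2, n = r$n,
      provenance = paste0("primary dataset; ", ces_names[[r$ces]])))
  }

  # Sedimentary-setting quadratics
  add(conversion_equation(
    "sed_terrigenous", "sedimentary", "terrigenous", "quadratic",
    coefficients = list(a2 = 0.004, a1 = 0.217, a0 = 0.3),
    coefficient_se = list(a2 = 0.000, a1 = 0.022, a0 = 0.3),
    r_squared = 0.94, n = 309, provenance = "primary dataset"))
  add(conversion_equation(
    "sed_carbonate", "sedimentary", "carbonate", "quadratic",
    coefficients = list(a2 = 0.002, a1 = 0.326, a0 = 1.8),
    coefficient_se = list(a2 = 0.000, a1 = 0.019, a0 = 0.4),
    r_squared = 0.93, n = 937, provenance = "primary dataset"))

  # General mangrove equations from the aggregate dataset
  add(conversion_equation(
    "general_linear", "general_mangrove", "mangrove", "linear",
    coefficients = list(m = 0.511, b = -2.497),
    coefficient_se = list(m = 0.003, b = 0.174),
    r_squared = 0.95, n = 1246, som_validity_range = c(1.1, 87.1),
    provenance = "primary dataset, aggregate linear"))
  add(conversion_equation(
    "general_quadratic", "general_mangrove", "mangrove", "quadratic",
    coefficients = list(a2 = 0.001, a1 = 0.380, a0 = -0.425),
    coefficient_se = list(a2 = 0.000, a1 = 0.013, a0 = 0.262),
    r_squared = 0.95, n = 1246, som_validity_range = c(1.1, 87.1),
    provenance = "primary dataset, aggregate quadratic"))

  # Published general blue-carbon ecosystem equations.  The saltmarsh
  # quadratic of Craft et al. was originally published with variables on
  # the fraction scale; it is stored here re-expressed on the percent
  # scale (a2 divided by 100, a1 unchanged, zero intercept), the single
  # internal convention of this package.
  add(conversion_equation(
    "eco_saltmarsh_craft", "literature_ecosystem", "saltmarsh", "quadratic",
    coefficients = list(a2 = 0.0025, a1 = 0.40, a0 = 0),
    coefficient_se = list(a2 = 0.0003, a1 = 0.01),
    r_squared = 0.99, n = 250, som_validity_range = c(0, 73),
    provenance = "Craft1991 (fraction-scale original, percent-scale here)"))
  add(conversion_equation(
    "eco_saltmarsh_ouyang", "literature_ecosystem", "saltmarsh", "linear",
    coefficients = list(m = 0.52, b = -1.17),
    coefficient_se = list(m = 0.006, b = 0.12),
    r_squared = 0.99, n = 344, som_validity_range = c(0, 70),
    provenance = "OuyangLee2020"))
  add(conversion_equation(
    "eco_seagrass_low", "literature_ecosystem", "seagrass", "linear",
    coefficients = list(m = 0.40, b = -0.21),
    r_squared = 0.87, n = 1667, som_validity_range = c(0, 20),
    provenance = "Fourqurean2012, LOI < 20%"))
  add(conversion_equation(
    "eco_seagrass_high", "literature_ecosystem", "seagrass", "linear",
    coefficients = list(m = 0.43, b = -0.33),
    r_squared = 0.96, n = 1748, som_validity_range = c(0, 100),
    provenance = "Fourqurean2012, LOI > 20%"))
  add(conversion_equation(
    "eco_mangrove_ouyang", "literature_ecosystem", "mangrove", "power",
    coefficients = list(a = 0.21, p = 1.12),
    coefficient_se = list(a = 0.01, p = 0.02),
    r_squared = 0.86, n = 1534, som_validity_range = c(0, 80),
    provenance = "OuyangLee2020, global mangrove power form"))

  lit <- .builtin_literature()
  for (i in seq_len(nrow(lit))) {
    r <- lit[i, ]
    cf <- list(m = r$m)
    se <- NULL
    if (!is.na(r$b)) cf$b <- r$b
    rng <- if (!is.na(r$som_min)) c(r$som_min, r$som_max) else NULL
    prov <- r$prov
    if (r$prov == "KauffmanDonato2012") {
      # the Palau intercept (2.9) is published without a stated unit
      # convention; stored on the percent scale, the convention used for
      # every built-in equation.
      prov <- paste0(prov, "; intercept scale assumed percent")
    }
    add(conversion_equation(
      id = paste0("lit_", gsub("[^a-z0-9]+", "_", tolower(r$key))),
      scope_level = "literature_regional", scope_key = r$key,
      form = "linear", coefficients = cf,
      r_squared = r$r2, n = if (is.na(r$n)) NULL else r$n,
      som_validity_range = rng, provenance = prov))
  }
  eqs
}

#' Build an equation registry
#'
#' An `equation_registry` is an id-keyed collection of
#' [conversion_equation()] objects with lookup by scope level and scope
#' key.
#'
#' @param equations List of `conversion_equation` objects with unique ids.
#' @return An object of class `equation_registry`.
#' @export
equation_registry <- function(equations) {
  stopifnot(is.list(equations),
            all(vapply(equations, inherits, logical(1L),
                       "conversion_equation")))
  ids <- vapply(equations, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate equation ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(equations) <- ids
  structure(list(equations = equations), class = "equation_registry")
}

#' @export
print.equation_registry <- function(x, ...) {
  lv <- vapply(x$equations, `[[`, character(1L), "scope_level")
  cat(sprintf("<equation_registry: %d equations>\n", length(x$equations)))
  print(table(factor(lv, levels = .scope_levels)))
  invisible(x)
}

#' Load the built-in registry of published conversion equations
#'
#' Returns every SOM-to-OC conversion equation of the source framework:
#' 17 regional linear equations and 6 coastal-environmental-setting (CES)
#' linear equations from the primary 17-region dataset, the two
#' sedimentary-setting quadratics, the aggregate general mangrove linear
#' and quadratic equations, 5 published general blue-carbon ecosystem
#' equations (including the Craft saltmarsh zero-intercept quadratic and
#' the Ouyang--Lee global mangrove power equation), and 14 previously
#' published region-specific mangrove equations.  All coefficients are on
#' the percent scale.
#'
#' @return An [equation_registry()].
#' @examples
#' reg <- load_builtin_registry()
#' registry_get(reg, "ces_ce")
#' @export
load_builtin_registry <- function() {
  reg <- equation_registry(.builtin_equations())
  .registry_self_check(reg)
  reg
}

# Structural self-check: CES/sedimentary/general coverage and the printed
# slope ranges of the built-in linear equations.
.registry_self_check <- function(reg) {
  ces <- registry_find(reg, "ces")
  keys <- sort(vapply(ces, `[[`, character(1L), "scope_key"))
  stopifnot(identical(keys, sort(.ces_codes)))
  sed <- registry_find(reg, "sedimentary")
  stopifnot(length(sed) == 2L,
            all(vapply(sed, `[[`, character(1L), "form") == "quadratic"))
  gen <- registry_find(reg, "general_mangrove")
  stopifnot(sort(vapply(gen, `[[`, character(1L), "form")) ==
              c("linear", "quadratic"))
  lin <- Filter(function(e) e$form == "linear", reg$equations)
  m <- vapply(lin, function(e) e$coefficients$m, numeric(1L))
  stopifnot(all(m > 0 & m < 1))
  ces_m <- vapply(ces, function(e) e$coefficients$m, numeric(1L))
  stopifnot(min(ces_m) >= 0.250, max(ces_m) <= 0.506)
  reg_m <- vapply(registry_find(reg, "region"),
                  function(e) e$coefficients$m, numeric(1L))
  stopifnot(min(reg_m) >= 0.240, max(reg_m) <= 0.687)
  invisible(TRUE)
}

#' Retrieve one equation by id
#'
#' @param registry An [equation_registry()].
#' @param id Equation id.
#' @return A [conversion_equation()]; errors if absent.
#' @export
registry_get <- function(registry, id) {
  stopifnot(inherits(registry, "equation_registry"))
  eq <- registry$equations[[id]]
  if (is.null(eq)) stop("no equation with id '", id, "'")
  eq
}

#' Find equations by scope
#'
#' @param registry An [equation_registry()].
#' @param scope_level Scope level to filter on.
#' @param scope_key Optional scope key (e.g. a region name or CES code).
#' @return A list of matching [conversion_equation()] objects (possibly
#'   empty).
#' @export
registry_find <- function(registry, scope_level, scope_key = NULL) {
  stopifnot(inherits(registry, "equation_registry"))
  scope_level <- match.arg(scope_level, .scope_levels)
  hits <- Filter(function(e) e$scope_level == scope_level,
                 registry$equations)
  if (!is.null(scope_key)) {
    hits <- Filter(function(e) identical(e$scope_key, scope_key), hits)
  }
  unname(hits)
}

# ---------------------------------------------------------------------------
# Serialization: delimited table and YAML config, exact round-trip
# ---------------------------------------------------------------------------

.registry_columns <- c("id", "scope_level", "scope_key", "form",
                       "m", "b", "a2", "a1", "a0", "a", "p",
                       "se_m", "se_b", "se_a2", "se_a1", "se_a0",
                       "se_a", "se_p",
                       "r_squared", "n", "som_min", "som_max", "provenance")

# %.17g preserves doubles exactly through a text round-trip
.num_chr <- function(x) {
  if (is.null(x) || is.na(x)) NA_character_ else sprintf("%.17g", x)
}

#' Convert a registry to a one-row-per-equation data frame
#'
#' @param registry An [equation_registry()].
#' @return A data frame with one row per equation; absent coefficients
#'   are `NA`.
#' @export
registry_as_table <- function(registry) {
  stopifnot(inherits(registry, "equation_registry"))
  rows <- lapply(registry$equations, function(e) {
    row <- as.list(rep(NA_character_, length(.registry_columns)))
    names(row) <- .registry_columns
    row$id <- e$id
    row$scope_level <- e$scope_level
    row$scope_key <- e$scope_key
    row$form <- e$form
    for (nm in names(e$coefficients)) row[[nm]] <- .num_chr(e$coefficients[[nm]])
    for (nm in names(e$coefficient_se))
      row[[paste0("se_", nm)]] <- .num_chr(e$coefficient_se[[nm]])
    row$r_squared <- .num_chr(e$r_squared)
    row$n <- if (is.null(e$n)) NA_character_ else as.character(e$n)
    if (!is.null(e$som_validity_range)) {
      row$som_min <- .num_chr(e$som_validity_range[1])
      row$som_max <- .num_chr(e$som_validity_range[2])
    }
    row$provenance <- e$provenance
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.equation_from_row <- function(row) {
  num <- function(x) if (is.na(x)) NULL else as.numeric(x)
  slots <- .form_slots[[row$form]]
  cf <- list()
  se <- list()
  for (nm in slots) {
    v <- num(row[[nm]])
    if (!is.null(v)) cf[[nm]] <- v
    s <- num(row[[paste0("se_", nm)]])
    if (!is.null(s)) se[[nm]] <- s
  }
  rng <- if (!is.na(row$som_min)) c(as.numeric(row$som_min),
                                    as.numeric(row$som_max)) else NULL
  conversion_equation(
    id = row$id, scope_level = row$scope_level, scope_key = row$scope_key,
    form = row$form, coefficients = cf,
    coefficient_se = if (length(se)) se else NULL,
    r_squared = num(row$r_squared),
    n = if (is.na(row$n)) NULL else as.integer(row$n),
    som_validity_range = rng, provenance = row$provenance)
}

#' Write a registry to a delimited text file
#'
#' One equation per row, tab-separated; numeric fields are written with
#' full double precision so [read_registry()] reproduces the registry
#' exactly.
#'
#' @param registry An [equation_registry()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  tab <- registry_as_table(registry)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a registry from a delimited text file
#'
#' @param path File written by [write_registry()] (or hand-authored with
#'   the same header).
#' @return An [equation_registry()].
#' @export
read_registry <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           na.strings = "")
  missing_cols <- setdiff(.registry_columns, names(tab))
  if (length(missing_cols)) {
    stop("registry table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$provenance[is.na(tab$provenance)] <- ""
  eqs <- lapply(seq_len(nrow(tab)), function(i) .equation_from_row(tab[i, ]))
  equation_registry(eqs)
}

#' Write a registry as a YAML configuration file
#'
#' Numeric values are serialized with full precision (as strings) so the
#' round-trip through [read_registry_yaml()] is exact.
#'
#' @param registry An [equation_registry()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry_yaml <- function(registry, path) {
  stopifnot(inherits(registry, "equation_registry"))
  entries <- lapply(unname(registry$equations), function(e) {
    out <- list(id = e$id, scope_level = e$scope_level,
                scope_key = e$scope_key, form = e$form,
                coefficients = lapply(e$coefficients, .num_chr))
    if (!is.null(e$coefficient_se))
      out$coefficient_se <- lapply(e$coefficient_se, .num_chr)
    if (!is.null(e$r_squared)) out$r_squared <- .num_chr(e$r_squared)
    if (!is.null(e$n)) out$n <- e$n
    if (!is.null(e$som_validity_range))
      out$som_validity_range <- vapply(e$som_validity_range, .num_chr,
                                       character(1L))
    out$provenance <- e$provenance
    out
  })
  yaml::write_yaml(list(equations = entries), path)
  invisible(path)
}

#' Read a registry from a YAML configuration file
#'
#' @param path File written by [write_registry_yaml()].
#' @return An [equation_registry()].
#' @export
read_registry_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$equations)) stop("YAML registry must have an 'equations' key")
  eqs <- lapply(doc$equations, function(e) {
    conversion_equation(
      id = e$id, scope_level = e$scope_level, scope_key = e$scope_key,
      form = e$form,
      coefficients = lapply(e$coefficients, as.numeric),
      coefficient_se = if (!is.null(e$coefficient_se))
        lapply(e$coefficient_se, as.numeric) else NULL,
      r_squared = if (!is.null(e$r_squared)) as.numeric(e$r_squared) else NULL,
      n = e$n,
      som_validity_range = if (!is.null(e$som_validity_range))
        as.numeric(e$som_validity_range) else NULL,
      provenance = if (is.null(e$provenance)) "" else e$provenance)
  })
  equation_registry(eqs)
}
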