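# Loss-on-ignition arithmetic: SOM from the 550 degree C combustion step,
# CaCO3 from the sequential 550 -> 990 degree C step.

.check_masses <- function(dry_mass, mass_post_550, mass_post_990 = NULL) {
  stopifnot(is.numeric(dry_mass), is.numeric(mass_post_550))
  if (any(dry_mass <= 0)) stop("dry_mass must be positive")
  if (any(mass_post_550 > dry_mass)) {
    stop("mass after 550 degree C combustion exceeds dry mass; ",
         "check crucible bookkeeping")
  }
  if (any(mass_post_550 < 0)) stop("mass_post_550 must be non-negative")
  if (!is.null(mass_post_990)) {
    if (any(is.na(mass_post_990)))
      stop("mass_post_990 is required (sequential LOI)")
    if (any(mass_post_990 > mass_post_550)) {
      stop("mass after 990 degree C combustion exceeds mass after 550 ",
           "degree C; check crucible bookkeeping")
    }
    if (any(mass_post_990 < 0)) stop("mass_post_990 must be non-negative")
  }
  invisible(TRUE)
}

#' Soil organic matter content from loss-on-ignition masses
#'
#' SOM (% of dry mass) is the mass fraction lost during combustion of the
#' dried sample at 550 degrees C:
#' `SOM = 100 * (dry_mass - mass_post_550) / dry_mass`.
#'
#' Drying temperature (60--105 degrees C or freeze-drying) is sample
#' provenance and never enters the computation.
#'
#' @param dry_mass Sample mass after drying, in g (vectorized).
#' @param mass_post_550 Sample mass after combustion at 550 degrees C, g.
#' @return SOM in percent, in \[0, 100\].
#' @examples
#' compute_som(10, 5)        # 50
#' compute_som(8.00, 6.52)   # 18.5
#' @export
compute_som <- function(dry_mass, mass_post_550) {
  .check_masses(dry_mass, mass_post_550)
  100 * (dry_mass - mass_post_550) / dry_mass
}

#' Calcium carbonate content from sequential loss-on-ignition masses
#'
#' The mass lost between 550 and 990 degrees C is evolved CO2 from
#' carbonate decomposition.  CaCO3 content is
#' `100 * (mass_post_550 - mass_post_990) / dry_mass * stoich_factor`.
#' The default stoichiometric factor 100/44 converts CO2 mass to CaCO3
#' mass (molar masses 100 and 44 g/mol); the alternative convention 1.36
#' (carbonate-ion basis) can be supplied instead.
#'
#' @param dry_mass Sample mass after drying, g (vectorized).
#' @param mass_post_550 Mass after combustion at 550 degrees C, g.
#' @param mass_post_990 Mass after combustion at 990 degrees C, g.
#' @param stoich_factor Mass of carbonate per mass of CO2 evolved;
#'   default `100/44`.
#' @return CaCO3 in percent of dry mass.
#' @examples
#' compute_caco3(10, 8.00, 7.56)  # 10
#' @export
compute_caco3 <- function(dry_mass, mass_post_550, mass_post_990,
                          stoich_factor = 100 / 44) {
  if (missing(mass_post_990) || is.null(mass_post_990))
    stop("mass_post_990 is required (sequential LOI)")
  .check_masses(dry_mass, mass_post_550, mass_post_990)
  stopifnot(is.numeric(stoich_factor), stoich_factor > 0)
  100 * (mass_post_550 - mass_post_990) / dry_mass * stoich_factor
}

#' Append SOM and CaCO3 columns to a mass-measurement table
#'
#' @param masses Data frame with columns `dry_mass`, `mass_post_550` and
#'   optionally `mass_post_990` (all in g).  Any other columns are passed
#'   through unchanged.
#' @param stoich_factor Passed to [compute_caco3()].
#' @return The input with an added `som` column and, when `mass_post_990`
#'   is present, a `caco3` column (both percent of dry mass).
#' @export
loi_table <- function(masses, stoich_factor = 100 / 44) {
  stopifnot(is.data.frame(masses),
            all(c("dry_mass", "mass_post_550") %in% names(masses)))
  masses$som <- compute_som(masses$dry_mass, masses$mass_post_550)
  if ("mass_post_990" %in% names(masses)) {
    masses$caco3 <- compute_caco3(masses$dry_mass, masses$mass_post_550,
                                  masses$mass_post_990, stoich_factor)
  }
  masses
}
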