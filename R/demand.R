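# Demand proxy: tract-level anthropogenic CO2 emissions across seven
# sectors, converted to carbon mass. Sector outputs stay in kg CO2 until the
# final net-demand step, mirroring the unit flow of the published accounting.

.sector_cols <- c("De_kgCO2", "Dt_kgCO2", "Di_kgCO2", "Dc_kgCO2",
                  "Da_kgCO2", "Dr_kgCO2", "Dw_kgCO2")

#' Sectoral CO2 emissions per tract
#'
#' Applies per-unit emission intensities to tract demographics:
#' \itemize{
#'   \item electric: `I_e * E * P * nonrenewable_share * lbs_to_kg`
#'   \item transportation: `I_t * V * shortton_to_kg`
#'   \item industrial: `I_i * W_i * lbs_to_kg`
#'   \item commercial: `I_c * W_c * lbs_to_kg`
#'   \item agricultural: `I_a * A_a * m2_to_acre * lbs_to_kg`
#'   \item residential: `I_r * P * lbs_to_kg`
#'   \item waste: `I_w * P * lbs_to_kg`
#' }
#' Each sector is linear and homogeneous in its demographic driver.
#'
#' @param demographics Data frame with `population`, `vehicles`,
#'   `emp_industrial`, `emp_commercial`, `ag_land_m2` (and optionally
#'   `tract_id`).
#' @param intensities An [emission_intensities()].
#' @param conv Unit conversions, see [unit_conversions()].
#' @return Data frame with `tract_id` and the seven sector columns
#'   `De_kgCO2` (electric), `Dt_kgCO2` (transportation), `Di_kgCO2`
#'   (industrial), `Dc_kgCO2` (commercial), `Da_kgCO2` (agricultural),
#'   `Dr_kgCO2` (residential), `Dw_kgCO2` (waste).
#' @export
sector_emissions <- function(demographics,
                             intensities = emission_intensities(),
                             conv = unit_conversions()) {
  stopifnot(inherits(intensities, "emission_intensities"))
  need <- c("population", "vehicles", "emp_industrial", "emp_commercial",
            "ag_land_m2")
  missing <- setdiff(need, names(demographics))
  if (length(missing)) {
    stop("demographics table is missing: ", paste(missing, collapse = ", "))
  }
  d <- demographics
  vals <- unlist(d[need])
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("demographic inputs must be non-negative and complete")
  }
  i <- intensities
  lb <- conv$lbs_to_kg
  out <- data.frame(
    tract_id = if ("tract_id" %in% names(d)) as.character(d$tract_id)
               else as.character(seq_len(nrow(d))),
    De_kgCO2 = i$I_e * i$E_kwh_per_capita * d$population *
      i$nonrenewable_share * lb,
    Dt_kgCO2 = i$I_t * d$vehicles * conv$shortton_to_kg,
    Di_kgCO2 = i$I_i * d$emp_industrial * lb,
    Dc_kgCO2 = i$I_c * d$emp_commercial * lb,
    Da_kgCO2 = i$I_a * d$ag_land_m2 * conv$m2_to_acre * lb,
    Dr_kgCO2 = i$I_r * d$population * lb,
    Dw_kgCO2 = i$I_w * d$population * lb,
    stringsAsFactors = FALSE
  )
  out
}

#' Net demand for carbon sequestration
#'
#' Sums the seven sectoral CO2 emissions per tract and converts to carbon
#' mass with the CO2-to-C mass fraction (0.2729):
#' `D_net = (De + Dt + Di + Dc + Da + Dr + Dw) * co2_to_c`, in kgC.
#' Additive over tracts.
#'
#' @param sectors Output of [sector_emissions()] (all seven sector columns
#'   required).
#' @param conv Unit conversions, see [unit_conversions()].
#' @return Data frame with `tract_id` and `Dnet_kgC`.
#' @export
net_demand <- function(sectors, conv = unit_conversions()) {
  missing <- setdiff(.sector_cols, names(sectors))
  if (length(missing)) {
    stop("sector table is missing: ", paste(missing, collapse = ", "))
  }
  data.frame(
    tract_id = if ("tract_id" %in% names(sectors))
      as.character(sectors$tract_id) else as.character(seq_len(nrow(sectors))),
    Dnet_kgC = rowSums(sectors[.sector_cols]) * conv$co2_to_c,
    stringsAsFactors = FALSE
  )
}

#' Tract demand from demographics in one step
#'
#' Convenience wrapper: [sector_emissions()] followed by [net_demand()].
#'
#' @inheritParams sector_emissions
#' @return List with `sectors` (kg CO2 by sector and tract) and `per_tract`
#'   (`tract_id`, `Dnet_kgC`).
#' @export
tract_demand <- function(demographics, intensities = emission_intensities(),
                         conv = unit_conversions()) {
  sectors <- sector_emissions(demographics, intensities, conv)
  list(sectors = sectors, per_tract = net_demand(sectors, conv))
}
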