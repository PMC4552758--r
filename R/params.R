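# Default parameter tables: species-group allometry, abundances and growth
# rates for the Twin Cities study region, plus the dynamics and demand
# constants the one-year sequestration model and emissions proxy use.

.species_groups <- c("mb", "aa", "mo", "oh", "cl", "sp", "pi")

.species_group_labels <- c(
  mb = "soft maple/birch",
  aa = "aspen/alder/cottonwood/willow",
  mo = "hard maple/oak/hickory/beech",
  oh = "other hardwood",
  cl = "cedar/larch",
  sp = "spruce",
  pi = "pine"
)

#' Species groups recognised by the package
#'
#' Seven taxon groups used for allometry, growth and abundance tables:
#' soft maple/birch (`mb`), aspen/alder/cottonwood/willow (`aa`), hard
#' maple/oak/hickory/beech (`mo`), other hardwood (`oh`), cedar/larch (`cl`),
#' spruce (`sp`) and pine (`pi`).
#'
#' @return Character vector of group codes.
#' @export
species_groups <- function() .species_groups

#' Relative abundance of species groups by stratum
#'
#' Percent of trees belonging to each species group within each assignment
#' stratum. Developed land is stratified by region (northern Dakota, southern
#' Dakota, northern Ramsey, St. Paul Ramsey); undeveloped land uses a single
#' column regardless of region. Columns are field-survey estimates and may
#' not sum to exactly 100 after rounding; [assign_species()] normalises each
#' stratum before apportionment.
#'
#' @return Numeric matrix (7 groups x 5 strata) of percentages, class
#'   `abundance_table`.
#' @export
abundance_table <- function() {
  tab <- rbind(
    mb = c(12.82, 18.23, 17.47, 18.17, 11),
    aa = c(6.52, 6.99, 3.72, 0, 13),
    mo = c(5.19, 2.95, 0, 0, 14),
    oh = c(63.09, 54.91, 68, 76.64, 64),
    cl = c(8.29, 2.73, 5.35, 5.19, 0),
    sp = c(4.09, 14.19, 5.46, 0, 0),
    pi = c(0, 0, 0, 0, 1)
  )
  colnames(tab) <- c("N_Dakota", "S_Dakota", "N_Ramsey", "StPaul_Ramsey",
                     "undeveloped")
  class(tab) <- c("abundance_table", class(tab))
  tab
}

#' Allometric parameters for aboveground biomass
#'
#' Per species group, the intercept and slope of the log-log allometric
#' relation `B = exp(beta0 + beta1 * ln(dbh_cm))` predicting aboveground dry
#' biomass in kg from diameter at breast height in cm (valid for dbh >=
#' 2.5 cm), after the national-scale hardwood/softwood equations of Jenkins
#' and colleagues.
#'
#' @return Data frame with row names = group codes and columns `beta0`,
#'   `beta1`.
#' @export
allometry_params <- function() {
  data.frame(
    beta0 = c(mb = -1.9123, aa = -2.2094, mo = -2.0127, oh = -2.4800,
              cl = -2.0336, sp = -2.0773, pi = -2.5356),
    beta1 = c(mb = 2.3651, aa = 2.3867, mo = 2.4342, oh = 2.4835,
              cl = 2.2592, sp = 2.3323, pi = 2.4349)
  )
}

#' Average annual dbh growth rate by species group
#'
#' @return Named numeric vector, cm of dbh per year.
#' @export
growth_rates <- function() {
  c(mb = 0.152, aa = 0.406, mo = 0.328, oh = 0.282, cl = 0.185,
    sp = 0.348, pi = 0.345)
}

#' Carbon conversion constants
#'
#' @param root_to_shoot Belowground-to-aboveground biomass ratio used to
#'   scale aboveground to whole-tree biomass (default 0.26, all groups).
#' @param carbon_fraction Proportion of dry biomass that is carbon
#'   (default 0.5).
#' @param dbh_min_cm Lower validity bound of the allometric equations
#'   (default 2.5 cm).
#' @return List of constants, class `carbon_constants`.
#' @export
carbon_constants <- function(root_to_shoot = 0.26, carbon_fraction = 0.5,
                             dbh_min_cm = 2.5) {
  stopifnot(root_to_shoot >= 0, carbon_fraction > 0, carbon_fraction <= 1,
            dbh_min_cm > 0)
  structure(list(root_to_shoot = root_to_shoot,
                 carbon_fraction = carbon_fraction,
                 dbh_min_cm = dbh_min_cm),
            class = "carbon_constants")
}

#' Quality-control thresholds for tree records
#'
#' Records outside these bounds are treated as extraction artifacts: height
#' below the detection floor or above the regional big-tree maximum, or dbh /
#' crown width beyond the largest trees on record for the region. Lower
#' height bound is inclusive; upper bounds are exclusive (strictly greater
#' values are rejected).
#'
#' @param min_height_m,max_height_m Height bounds in m (defaults 3, 40).
#' @param max_dbh_m Maximum credible dbh in m (default 3.187).
#' @param max_crown_m Maximum credible crown width in m (default 42.672).
#' @return List of thresholds, class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_height_m = 3, max_height_m = 40,
                          max_dbh_m = 3.187, max_crown_m = 42.672) {
  stopifnot(min_height_m < max_height_m, max_dbh_m > 0, max_crown_m > 0)
  structure(list(min_height_m = min_height_m, max_height_m = max_height_m,
                 max_dbh_m = max_dbh_m, max_crown_m = max_crown_m),
            class = "qc_thresholds")
}

#' Annual tree mortality schedule by dbh class
#'
#' Size-dependent annual mortality probabilities from an eastern
#' broadleaf-forest urban study: 2.1% below 47 cm dbh, 2.9% for 47-61 cm,
#' 3.0% for 62-76 cm and 5.4% at 77 cm and above. The published classes
#' leave small gaps (e.g. 46-47 cm); classes here are contiguous,
#' `[0,47), [47,62), [62,77), [77,Inf)`, carrying each published rate to the
#' nearest boundary.
#'
#' @param lower_cm Ascending lower bounds of the dbh classes in cm, starting
#'   at 0.
#' @param rate Annual mortality probability per class.
#' @return Data frame with columns `lower_cm`, `upper_cm`, `rate`, class
#'   `mortality_schedule`.
#' @export
mortality_schedule <- function(lower_cm = c(0, 47, 62, 77),
                               rate = c(0.021, 0.029, 0.030, 0.054)) {
  stopifnot(length(lower_cm) == length(rate), !is.unsorted(lower_cm),
            lower_cm[1] == 0, all(rate >= 0), all(rate <= 1))
  out <- data.frame(lower_cm = lower_cm,
                    upper_cm = c(lower_cm[-1], Inf),
                    rate = rate)
  class(out) <- c("mortality_schedule", class(out))
  out
}

#' Decomposition parameters for dead trees
#'
#' First-year carbon release depends on what happens to a dead tree:
#' municipal removal and grinding (all stored carbon released within the
#' year), chipping to landscape mulch (80% released), or natural in-place
#' decay, where aboveground biomass loses `1 - exp(-k)` of its mass in the
#' first year and belowground biomass decomposes over a multi-year horizon
#' with 20% released in year one.
#'
#' @param k Exponential decomposition rate constant for downed wood
#'   (1/yr, default 0.062).
#' @param belowground_horizon_yr Years over which roots decompose
#'   (default 20).
#' @param belowground_first_year_fraction Fraction of root carbon released in
#'   year one (default 0.20).
#' @param mulch_first_year_fraction Fraction released in year one when
#'   chipped to mulch (default 0.80).
#' @param removed_first_year_fraction Fraction released in year one under
#'   municipal removal (default 1.00).
#' @return List, class `decay_params`.
#' @export
decay_params <- function(k = 0.062, belowground_horizon_yr = 20L,
                         belowground_first_year_fraction = 0.20,
                         mulch_first_year_fraction = 0.80,
                         removed_first_year_fraction = 1.00) {
  fr <- c(belowground_first_year_fraction, mulch_first_year_fraction,
          removed_first_year_fraction)
  stopifnot(k > 0, belowground_horizon_yr > 0, all(fr >= 0), all(fr <= 1))
  structure(list(k = k,
                 belowground_horizon_yr = as.integer(belowground_horizon_yr),
                 belowground_first_year_fraction = belowground_first_year_fraction,
                 mulch_first_year_fraction = mulch_first_year_fraction,
                 removed_first_year_fraction = removed_first_year_fraction),
            class = "decay_params")
}

#' Replanting policy by jurisdiction and land use
#'
#' Fraction of dead trees replaced with trees of the same size and species:
#' 15% inside the city with an active forestry unit (`st_paul`), 10% on
#' developed land elsewhere, 0% on undeveloped land.
#'
#' @param st_paul,other_developed,other_undeveloped Replanting rates in
#'   `[0, 1]`.
#' @return List, class `replant_policy`.
#' @export
replant_policy <- function(st_paul = 0.15, other_developed = 0.10,
                           other_undeveloped = 0) {
  r <- c(st_paul, other_developed, other_undeveloped)
  stopifnot(all(r >= 0), all(r <= 1))
  structure(list(st_paul = st_paul, other_developed = other_developed,
                 other_undeveloped = other_undeveloped),
            class = "replant_policy")
}

#' Fixed unit-conversion constants for the demand calculation
#'
#' @return List with `lbs_to_kg` (0.453592), `shortton_to_kg` (907.185),
#'   `m2_to_acre` (0.000247105) and `co2_to_c` (0.2729, the mass fraction of
#'   carbon in CO2).
#' @export
unit_conversions <- function() {
  structure(list(lbs_to_kg = 0.453592, shortton_to_kg = 907.185,
                 m2_to_acre = 0.000247105, co2_to_c = 0.2729),
            class = "unit_conversions")
}

#' Sectoral CO2 emission intensities
#'
#' Per-unit emission rates in the units state agencies publish them in
#' (pounds or short tons of CO2). The defaults are illustrative values, not
#' agency figures (which are not in the public domain of this package); they
#' are scaled so that study-area demographic totals produce sectoral
#' emissions of realistic magnitude. Supply your own values for real
#' analyses, e.g. via [read_emission_intensities()].
#'
#' @param I_e lbs CO2 per kWh of electricity consumed.
#' @param E_kwh_per_capita kWh consumed per person per year.
#' @param I_t Short tons CO2 per vehicle per year.
#' @param I_a lbs CO2 per acre of harvested agricultural land.
#' @param I_i lbs CO2 per industrial employee.
#' @param I_c lbs CO2 per commercial employee.
#' @param I_r lbs CO2 per capita (residential).
#' @param I_w lbs CO2 per capita (wastewater treatment).
#' @param nonrenewable_share Fraction of electricity from nonrenewable
#'   sources (default 0.70).
#' @return List, class `emission_intensities`.
#' @export
emission_intensities <- function(I_e = 2.0, E_kwh_per_capita = 25000,
                                 I_t = 10.5, I_a = 50000, I_i = 600,
                                 I_c = 30, I_r = 9250, I_w = 517,
                                 nonrenewable_share = 0.70) {
  vals <- c(I_e, E_kwh_per_capita, I_t, I_a, I_i, I_c, I_r, I_w)
  stopifnot(all(vals >= 0), nonrenewable_share >= 0, nonrenewable_share <= 1)
  structure(list(I_e = I_e, E_kwh_per_capita = E_kwh_per_capita, I_t = I_t,
                 I_a = I_a, I_i = I_i, I_c = I_c, I_r = I_r, I_w = I_w,
                 nonrenewable_share = nonrenewable_share),
            class = "emission_intensities")
}

#' Read emission intensities from a YAML file
#'
#' The file must provide the fields of [emission_intensities()] (extra fields
#' are ignored). See `inst/extdata/intensities_illustrative.yaml` for the
#' expected layout.
#'
#' @param path Path to a YAML file.
#' @return An `emission_intensities` object.
#' @export
read_emission_intensities <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- names(formals(emission_intensities))
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("intensities file is missing fields: ", paste(missing, collapse = ", "))
  }
  do.call(emission_intensities, raw[need])
}
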