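# Carbon storage: per-tree allometric biomass, whole-tree carbon, and
# tract-level aggregation. Tree tables carry dbh in metres; the allometric
# equations expect centimetres, and the metre-to-centimetre conversion
# happens in exactly one place, dbh_m_to_cm().

#' Convert dbh from metres (inventory units) to centimetres (allometry units)
#'
#' @param dbh_m Dbh in metres.
#' @return Dbh in centimetres.
#' @export
dbh_m_to_cm <- function(dbh_m) dbh_m * 100

#' Aboveground biomass from dbh
#'
#' Evaluates the taxon-group allometric power law
#' `B = exp(beta0 + beta1 * ln(dbh_cm))`, giving aboveground dry biomass in
#' kg. Valid for trees of `dbh_min_cm` (2.5 cm) and larger; strictly
#' increasing in dbh. Vectorised over `dbh_cm` and `species_group`.
#'
#' @param dbh_cm Diameter at breast height in cm.
#' @param species_group Group code(s), see [species_groups()].
#' @param params Allometric coefficients, see [allometry_params()].
#' @param dbh_min_cm Lower validity bound (default 2.5 cm).
#' @return Aboveground biomass in kg.
#' @export
aboveground_biomass <- function(dbh_cm, species_group,
                                params = allometry_params(),
                                dbh_min_cm = 2.5) {
  if (any(is.na(dbh_cm))) stop("dbh_cm contains missing values")
  if (any(dbh_cm < dbh_min_cm)) {
    stop("dbh below allometric range (< ", dbh_min_cm, " cm)")
  }
  unknown <- setdiff(unique(as.character(species_group)), rownames(params))
  if (length(unknown) || any(is.na(species_group))) {
    stop("unknown species group: ",
         paste(c(unknown, if (any(is.na(species_group))) "NA"), collapse = ", "))
  }
  b0 <- params[as.character(species_group), "beta0"]
  b1 <- params[as.character(species_group), "beta1"]
  exp(b0 + b1 * log(dbh_cm))
}

#' Whole-tree carbon from aboveground biomass
#'
#' Scales aboveground to whole-tree dry biomass with the root-to-shoot ratio
#' and converts to carbon mass with the carbon fraction:
#' `kgC = agb * (1 + root_to_shoot) * carbon_fraction`. Linear and
#' homogeneous in `agb_kg`.
#'
#' @param agb_kg Aboveground biomass in kg (non-negative).
#' @param constants A [carbon_constants()].
#' @return Stored carbon in kgC.
#' @export
tree_carbon <- function(agb_kg, constants = carbon_constants()) {
  stopifnot(inherits(constants, "carbon_constants"))
  if (any(is.na(agb_kg)) || any(agb_kg < 0)) {
    stop("aboveground biomass must be non-negative")
  }
  agb_kg * (1 + constants$root_to_shoot) * constants$carbon_fraction
}

#' Tract-level carbon storage
#'
#' Sums whole-tree carbon over trees in each tract. The study-area total is
#' the sum of tract values and is invariant under any re-partition of trees
#' into tracts.
#'
#' @param trees Tree records with `tract_id`, `dbh_m` and a non-missing
#'   `species_group`.
#' @param params Allometric coefficients, see [allometry_params()].
#' @param constants A [carbon_constants()].
#' @param tract_ids Optional tract ids to include in the output even when
#'   they hold no trees (reported with zero storage).
#' @return List with `per_tract` (data frame `tract_id`, `n_trees`,
#'   `storage_kgC`) and `total_kgC`.
#' @export
tract_storage <- function(trees, params = allometry_params(),
                          constants = carbon_constants(), tract_ids = NULL) {
  if (nrow(trees) > 0 && any(is.na(trees$species_group))) {
    stop("all trees must have a species group; run assign_species() first")
  }
  if (nrow(trees) > 0 && any(is.na(trees$tract_id))) {
    stop("all trees must have a tract_id")
  }
  ids <- sort(unique(c(as.character(tract_ids),
                       as.character(trees$tract_id))))
  per_tract <- data.frame(tract_id = ids,
                          n_trees = 0L,
                          storage_kgC = 0,
                          stringsAsFactors = FALSE)
  if (nrow(trees) > 0) {
    kgc <- tree_carbon(
      aboveground_biomass(dbh_m_to_cm(trees$dbh_m), trees$species_group,
                          params, constants$dbh_min_cm),
      constants
    )
    sums <- rowsum(kgc, group = as.character(trees$tract_id))
    counts <- table(as.character(trees$tract_id))
    per_tract$storage_kgC <- as.numeric(sums[match(ids, rownames(sums)), 1])
    per_tract$storage_kgC[is.na(per_tract$storage_kgC)] <- 0
    per_tract$n_trees <- as.integer(counts[ids])
    per_tract$n_trees[is.na(per_tract$n_trees)] <- 0L
  }
  list(per_tract = per_tract, total_kgC = sum(per_tract$storage_kgC))
}
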