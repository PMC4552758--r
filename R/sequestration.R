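# One-year carbon sequestration dynamics: size-dependent mortality, growth
# of survivors, first-year decomposition of the dead under three management
# regimes, replanting, and the net balance Cs = Cg - Cl + Cp.

# Sum per-tree values into a zero-filled per-tract vector.
.tract_sum <- function(values, tract_id, tract_ids) {
  ids <- sort(unique(c(as.character(tract_ids), as.character(tract_id))))
  out <- stats::setNames(numeric(length(ids)), ids)
  if (length(values)) {
    sums <- rowsum(values, group = as.character(tract_id))
    out[rownames(sums)] <- sums[, 1]
  }
  out
}

# Decomposition regime of a dead tree: municipal removal inside St. Paul,
# mulching on developed land elsewhere, natural decay otherwise.
.decay_regime <- function(jurisdiction, landuse) {
  ifelse(jurisdiction == "st_paul", "removed",
         ifelse(landuse == "developed", "mulched", "natural"))
}

# Replanting rate for a dead tree under the jurisdiction/land-use policy.
.replant_rate <- function(jurisdiction, landuse, policy) {
  ifelse(jurisdiction == "st_paul", policy$st_paul,
         ifelse(landuse == "developed", policy$other_developed,
                policy$other_undeveloped))
}

#' Sample one year of tree mortality
#'
#' Each tree independently dies with the annual probability of its dbh
#' class (seeded Bernoulli draws). The two returned sets partition the
#' input.
#'
#' @param trees Tree records with `dbh_m`.
#' @param schedule A [mortality_schedule()].
#' @param seed Integer seed.
#' @return List with `survivors` and `dead` (both subsets of `trees`).
#' @export
sample_mortality <- function(trees, schedule = mortality_schedule(),
                             seed = 1L) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  if (nrow(trees) == 0) return(list(survivors = trees, dead = trees))
  if (any(is.na(trees$dbh_m))) stop("trees have missing dbh")
  dbh_cm <- dbh_m_to_cm(trees$dbh_m)
  rate <- schedule$rate[findInterval(dbh_cm, schedule$lower_cm)]
  died <- with_seed(substream_seed(seed, "mortality"),
                    stats::runif(nrow(trees)) < rate)
  list(survivors = trees[!died, , drop = FALSE],
       dead = trees[died, , drop = FALSE])
}

#' Carbon gain from growth of surviving trees
#'
#' Adds each group's average annual dbh increment to the survivors, re-runs
#' the allometric equation and takes the carbon-mass difference:
#' `Cg = carbon_fraction * sum(B(dbh + delta) - B(dbh))`. By default only
#' aboveground biomass growth is counted (the published growth balance);
#' `include_root_growth = TRUE` also scales the increment by
#' `1 + root_to_shoot`.
#'
#' @param survivors Surviving trees with `species_group`, `dbh_m`,
#'   `tract_id`.
#' @param growth Named dbh growth rates in cm/yr, see [growth_rates()].
#' @param params Allometric coefficients.
#' @param constants A [carbon_constants()].
#' @param include_root_growth Also credit belowground growth (default
#'   FALSE).
#' @param tract_ids Optional tract ids to zero-fill.
#' @return Data frame `tract_id`, `Cg_kgC`.
#' @export
growth_gain <- function(survivors, growth = growth_rates(),
                        params = allometry_params(),
                        constants = carbon_constants(),
                        include_root_growth = FALSE, tract_ids = NULL) {
  cg <- numeric(0)
  if (nrow(survivors) > 0) {
    grp <- as.character(survivors$species_group)
    unknown <- setdiff(unique(grp), names(growth))
    if (length(unknown) || any(is.na(grp))) {
      stop("unknown species group in survivors: ",
           paste(unknown, collapse = ", "))
    }
    dbh1 <- dbh_m_to_cm(survivors$dbh_m)
    dbh2 <- dbh1 + growth[grp]
    db <- aboveground_biomass(dbh2, grp, params, constants$dbh_min_cm) -
      aboveground_biomass(dbh1, grp, params, constants$dbh_min_cm)
    scale <- if (include_root_growth) 1 + constants$root_to_shoot else 1
    cg <- constants$carbon_fraction * scale * db
  }
  v <- .tract_sum(cg, survivors$tract_id, tract_ids)
  data.frame(tract_id = names(v), Cg_kgC = unname(v),
             stringsAsFactors = FALSE)
}

#' Carbon remaining in downed wood after t years of decay
#'
#' Exponential decay of aboveground necromass:
#' `C_t = carbon_fraction * M * exp(-k * t)`, with `M` the initial
#' aboveground biomass (kg) and `k` the decomposition rate constant. At
#' `t = 0` this is simply the carbon content of the biomass; the function is
#' monotone decreasing in `t` and satisfies the decay semigroup property.
#'
#' @param M_kg Initial aboveground biomass in kg (non-negative).
#' @param t_yr Time since death in years (non-negative).
#' @param decay A [decay_params()].
#' @param carbon_fraction Carbon concentration of biomass (default 0.5,
#'   constant throughout decomposition).
#' @return Carbon remaining in kgC.
#' @export
remaining_carbon <- function(M_kg, t_yr, decay = decay_params(),
                             carbon_fraction = 0.5) {
  stopifnot(inherits(decay, "decay_params"))
  if (any(M_kg < 0)) stop("biomass must be non-negative")
  if (any(t_yr < 0)) stop("time since death must be non-negative")
  carbon_fraction * M_kg * exp(-decay$k * t_yr)
}

#' First-year carbon loss from dead-tree decomposition
#'
#' Sums the carbon released within a year of death, by management regime:
#' \itemize{
#'   \item `removed` (St. Paul jurisdiction): dead trees are removed and
#'     ground, releasing the whole-tree carbon at once:
#'     `0.5 * B_total * removed_fraction`.
#'   \item `mulched` (developed land outside St. Paul): chipped to landscape
#'     mulch, `0.5 * B_total * mulch_fraction`.
#'   \item `natural` (undeveloped land outside St. Paul): aboveground
#'     biomass decays exponentially, releasing `1 - exp(-k)` of its carbon in
#'     year one, while roots release their first-year fraction:
#'     `0.5 * (B_above * (1 - exp(-k)) + B_below * frac)`.
#' }
#' `B_total = B_above * (1 + root_to_shoot)` and
#' `B_below = B_above * root_to_shoot`.
#'
#' @param dead Dead trees with `species_group`, `dbh_m`, `tract_id`,
#'   `jurisdiction`, `landuse`.
#' @param decay A [decay_params()].
#' @param params Allometric coefficients.
#' @param constants A [carbon_constants()].
#' @param tract_ids Optional tract ids to zero-fill.
#' @return Data frame `tract_id`, `Cl_kgC` and per-regime columns
#'   `Cl_removed_kgC`, `Cl_mulched_kgC`, `Cl_natural_kgC`.
#' @export
decomposition_loss <- function(dead, decay = decay_params(),
                               params = allometry_params(),
                               constants = carbon_constants(),
                               tract_ids = NULL) {
  stopifnot(inherits(decay, "decay_params"))
  cl <- numeric(0)
  regime <- character(0)
  if (nrow(dead) > 0) {
    if (any(is.na(dead$jurisdiction)) || any(is.na(dead$landuse))) {
      stop("dead trees must carry jurisdiction and landuse labels")
    }
    b_above <- aboveground_biomass(dbh_m_to_cm(dead$dbh_m),
                                   dead$species_group, params,
                                   constants$dbh_min_cm)
    rts <- constants$root_to_shoot
    cf <- constants$carbon_fraction
    regime <- .decay_regime(dead$jurisdiction, dead$landuse)
    cl <- ifelse(
      regime == "removed",
      cf * b_above * (1 + rts) * decay$removed_first_year_fraction,
      ifelse(
        regime == "mulched",
        cf * b_above * (1 + rts) * decay$mulch_first_year_fraction,
        cf * (b_above * (1 - exp(-decay$k)) +
                b_above * rts * decay$belowground_first_year_fraction)
      )
    )
  }
  total <- .tract_sum(cl, dead$tract_id, tract_ids)
  out <- data.frame(tract_id = names(total), Cl_kgC = unname(total),
                    stringsAsFactors = FALSE)
  for (rg in c("removed", "mulched", "natural")) {
    sel <- regime == rg
    v <- .tract_sum(cl[sel], dead$tract_id[sel], out$tract_id)
    out[[paste0("Cl_", rg, "_kgC")]] <- unname(v[out$tract_id])
  }
  out
}

#' Carbon gain from replanting dead trees
#'
#' Within each (jurisdiction, land use) stratum, a seeded random selection of
#' `round(rate * n_dead)` dead trees is replaced with trees of the same size
#' and species; the gain is the whole-tree carbon of the replacements:
#' `Cp = carbon_fraction * sum(B_total)`.
#'
#' @param dead Dead trees with `species_group`, `dbh_m`, `tract_id`,
#'   `jurisdiction`, `landuse`, `tree_id`.
#' @param policy A [replant_policy()].
#' @param params Allometric coefficients.
#' @param constants A [carbon_constants()].
#' @param seed Integer seed.
#' @param tract_ids Optional tract ids to zero-fill.
#' @return List with `per_tract` (data frame `tract_id`, `Cp_kgC`) and
#'   `replanted_ids` (the `tree_id`s of replaced trees).
#' @export
replanting_gain <- function(dead, policy = replant_policy(),
                            params = allometry_params(),
                            constants = carbon_constants(), seed = 1L,
                            tract_ids = NULL) {
  stopifnot(inherits(policy, "replant_policy"))
  chosen <- integer(0)
  cp <- numeric(0)
  tract_of_chosen <- character(0)
  if (nrow(dead) > 0) {
    if (any(is.na(dead$jurisdiction)) || any(is.na(dead$landuse))) {
      stop("dead trees must carry jurisdiction and landuse labels")
    }
    stratum <- paste(dead$jurisdiction, dead$landuse, sep = "|")
    rate <- .replant_rate(dead$jurisdiction, dead$landuse, policy)
    chosen <- with_seed(substream_seed(seed, "replant"), {
      picks <- integer(0)
      for (s in sort(unique(stratum))) {
        idx <- which(stratum == s)
        k <- floor(rate[idx[1]] * length(idx) + 0.5)
        if (k > 0) picks <- c(picks, idx[sample.int(length(idx), k)])
      }
      picks
    })
    if (length(chosen)) {
      b_above <- aboveground_biomass(dbh_m_to_cm(dead$dbh_m[chosen]),
                                     dead$species_group[chosen], params,
                                     constants$dbh_min_cm)
      cp <- constants$carbon_fraction *
        b_above * (1 + constants$root_to_shoot)
      tract_of_chosen <- dead$tract_id[chosen]
    }
  }
  v <- .tract_sum(cp, tract_of_chosen,
                  c(as.character(tract_ids), as.character(dead$tract_id)))
  list(per_tract = data.frame(tract_id = names(v), Cp_kgC = unname(v),
                              stringsAsFactors = FALSE),
       replanted_ids = dead$tree_id[chosen])
}

#' Net annual carbon sequestration
#'
#' The single-year carbon balance `Cs = Cg - Cl + Cp`, per tract and in
#' total. Inputs may be scalars or named vectors keyed by tract id; keys
#' must agree. `Cs` may be negative where decomposition losses exceed
#' growth.
#'
#' @param Cg,Cl,Cp Growth gain, decomposition loss and replanting gain in
#'   kgC (scalars or identically named vectors).
#' @return List with `per_tract` (named vector of Cs) and `total`.
#' @export
net_sequestration <- function(Cg, Cl, Cp) {
  key <- function(x) sort(names(x))
  if (!identical(key(Cg), key(Cl)) || !identical(key(Cg), key(Cp))) {
    stop("Cg, Cl and Cp must be keyed by the same tract ids")
  }
  if (!is.null(names(Cg))) {
    Cl <- Cl[names(Cg)]
    Cp <- Cp[names(Cg)]
  }
  cs <- Cg - Cl + Cp
  list(per_tract = cs, total = sum(cs))
}

#' Simulate one year of forest dynamics
#'
#' Runs mortality, growth, decomposition and replanting on an assigned tree
#' inventory and returns the per-tract sequestration balance together with a
#' per-tree fate ledger. Every input tree is exactly one of survivor or
#' dead, replanted trees are a subset of the dead, and
#' `Cs = Cg - Cl + Cp` holds exactly per tract.
#'
#' @param trees Assigned tree records (non-missing `species_group`).
#' @param seed Integer master seed (substreams drive mortality and
#'   replanting).
#' @param schedule A [mortality_schedule()].
#' @param growth Named growth rates, see [growth_rates()].
#' @param decay A [decay_params()].
#' @param policy A [replant_policy()].
#' @param params Allometric coefficients.
#' @param constants A [carbon_constants()].
#' @param include_root_growth Credit belowground growth in Cg (default
#'   FALSE).
#' @param tract_ids Optional tract ids to zero-fill.
#' @return List of class `sequestration_result`: `per_tract` (data frame
#'   with `tract_id`, `Cg_kgC`, `Cl_kgC`, `Cp_kgC`, `Cs_kgC`), `totals`,
#'   `ledger` (per-tree `tree_id`, `tract_id`, `fate`, `replanted`) and
#'   `meta`.
#' @export
simulate_sequestration <- function(trees, seed = 1L,
                                   schedule = mortality_schedule(),
                                   growth = growth_rates(),
                                   decay = decay_params(),
                                   policy = replant_policy(),
                                   params = allometry_params(),
                                   constants = carbon_constants(),
                                   include_root_growth = FALSE,
                                   tract_ids = NULL) {
  if (nrow(trees) > 0 && any(is.na(trees$species_group))) {
    stop("all trees must have a species group; run assign_species() first")
  }
  ids <- sort(unique(c(as.character(tract_ids),
                       as.character(trees$tract_id))))
  mort <- sample_mortality(trees, schedule, seed)
  cg <- growth_gain(mort$survivors, growth, params, constants,
                    include_root_growth, ids)
  cl <- decomposition_loss(mort$dead, decay, params, constants, ids)
  cp <- replanting_gain(mort$dead, policy, params, constants, seed, ids)
  per_tract <- data.frame(tract_id = cg$tract_id,
                          Cg_kgC = cg$Cg_kgC,
                          Cl_kgC = cl$Cl_kgC[match(cg$tract_id, cl$tract_id)],
                          Cp_kgC = cp$per_tract$Cp_kgC[
                            match(cg$tract_id, cp$per_tract$tract_id)],
                          stringsAsFactors = FALSE)
  per_tract$Cs_kgC <- per_tract$Cg_kgC - per_tract$Cl_kgC + per_tract$Cp_kgC
  ledger <- data.frame(
    tree_id = c(mort$survivors$tree_id, mort$dead$tree_id),
    tract_id = c(mort$survivors$tract_id, mort$dead$tract_id),
    fate = c(rep("survived", nrow(mort$survivors)),
             rep("died", nrow(mort$dead))),
    replanted = c(rep(FALSE, nrow(mort$survivors)),
                  mort$dead$tree_id %in% cp$replanted_ids),
    stringsAsFactors = FALSE
  )
  structure(list(
    per_tract = per_tract,
    totals = list(Cg_kgC = sum(per_tract$Cg_kgC),
                  Cl_kgC = sum(per_tract$Cl_kgC),
                  Cp_kgC = sum(per_tract$Cp_kgC),
                  Cs_kgC = sum(per_tract$Cs_kgC),
                  n_trees = nrow(trees),
                  n_survived = nrow(mort$survivors),
                  n_died = nrow(mort$dead),
                  n_replanted = length(cp$replanted_ids)),
    ledger = ledger,
    meta = list(seed = seed, include_root_growth = include_root_growth)
  ), class = "sequestration_result")
}
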