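# Synthetic study-area generator: seeded tract geometries with demographics
# and tree inventories whose marginal statistics match the LiDAR-derived
# inventory the analysis is calibrated to.

#' Configuration for the synthetic study area
#'
#' Defaults encode the study conditions of the reference inventory: 223
#' census tracts, roughly 32,700 trees per tract (about 7.3 million trees),
#' attribute marginals matching the inventory summary statistics (height
#' mean 11.51 m SD 4.62, crown width 3.90 m SD 1.07, dbh 0.29 m SD 0.04,
#' range 0.24-0.83 m) and tract demographics whose study-area totals match
#' the census inputs of the demand model (e.g. population about 359,000).
#' Attributes are drawn from truncated normals moment-matched so that the
#' post-truncation mean/SD equal the configured values.
#'
#' @param n_tracts Number of tracts (positive integer).
#' @param trees_per_tract_mean Poisson mean of trees per tract.
#' @param height_mean_m,height_sd_m Height marginal (m).
#' @param height_min_m,height_max_m Height truncation bounds (m). The 3 m
#'   floor is the detection limit; the 45 m cap excludes extraction
#'   artifacts.
#' @param crown_mean_m,crown_sd_m,crown_min_m,crown_max_m Crown-width
#'   marginal and bounds (m).
#' @param dbh_mean_m,dbh_sd_m,dbh_min_m,dbh_max_m Dbh marginal and bounds (m).
#' @param developed_fraction Probability a tree stands on developed land.
#' @param outlier_fraction Fraction of trees given artifact heights above the
#'   cap (emulating feature-extraction errors, so QC filtering is
#'   exercised).
#' @param region_labels Stratum names for the regions of the study area.
#' @param demographic_ranges Named list of `c(min, max)` uniform bounds for
#'   tract-level `population`, `vehicles`, `emp_industrial`,
#'   `emp_commercial`, `ag_land_m2`.
#' @param tract_side_m Side length of the square tract polygons (m).
#' @param seed Integer master seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tracts = 223L,
                             trees_per_tract_mean = 32700,
                             height_mean_m = 11.51, height_sd_m = 4.62,
                             height_min_m = 3, height_max_m = 45,
                             crown_mean_m = 3.90, crown_sd_m = 1.07,
                             crown_min_m = 2.6, crown_max_m = 16.93,
                             dbh_mean_m = 0.29, dbh_sd_m = 0.04,
                             dbh_min_m = 0.24, dbh_max_m = 0.83,
                             developed_fraction = 0.75,
                             outlier_fraction = 0.005,
                             region_labels = c("N_Dakota", "S_Dakota",
                                               "N_Ramsey", "StPaul_Ramsey"),
                             demographic_ranges = list(
                               population = c(800, 2400),
                               vehicles = c(400, 1200),
                               emp_industrial = c(50, 220),
                               emp_commercial = c(150, 650),
                               ag_land_m2 = c(0, 3.6e6)
                             ),
                             tract_side_m = 2000,
                             seed = 1L) {
  if (!is.numeric(n_tracts) || length(n_tracts) != 1 || n_tracts < 1) {
    stop("n_tracts must be a positive integer")
  }
  stopifnot(trees_per_tract_mean > 0,
            height_sd_m >= 0, crown_sd_m >= 0, dbh_sd_m >= 0,
            dbh_min_m < dbh_max_m,
            height_min_m < height_max_m, crown_min_m < crown_max_m,
            developed_fraction >= 0, developed_fraction <= 1,
            outlier_fraction >= 0, outlier_fraction < 1,
            length(region_labels) >= 1, tract_side_m > 0)
  need <- c("population", "vehicles", "emp_industrial", "emp_commercial",
            "ag_land_m2")
  missing <- setdiff(need, names(demographic_ranges))
  if (length(missing)) {
    stop("demographic_ranges is missing: ", paste(missing, collapse = ", "))
  }
  for (nm in need) {
    rg <- demographic_ranges[[nm]]
    if (length(rg) != 2 || rg[1] > rg[2] || rg[1] < 0) {
      stop("demographic range for ", nm, " must be c(min, max) with 0 <= min <= max")
    }
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate synthetic census tracts with demographics
#'
#' Lays out `n_tracts` disjoint square polygons on a planar grid, assigns
#' each a region (near-equal contiguous blocks of the configured labels) and
#' a jurisdiction (`st_paul` for tracts in the `StPaul_Ramsey` region,
#' `other` elsewhere), and draws demographics uniformly within the
#' configured ranges. Count-valued demographics are rounded to integers.
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame of class `tract_set`: `tract_id`, rectangle bounds
#'   `xmin`/`ymin`/`xmax`/`ymax`, `region`, `jurisdiction` and the five
#'   demographic fields.
#' @export
generate_tracts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- as.integer(cfg$n_tracts)
  side <- cfg$tract_side_m
  ncols <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  xmin <- (idx %% ncols) * side
  ymin <- (idx %/% ncols) * side
  regions <- rep(cfg$region_labels,
                 each = ceiling(n / length(cfg$region_labels)))[seq_len(n)]
  jurisdiction <- ifelse(regions == "StPaul_Ramsey", "st_paul", "other")
  demo <- with_seed(substream_seed(cfg$seed, "tracts"), {
    draw <- function(rg, count) {
      v <- stats::runif(n, rg[1], rg[2])
      if (count) round(v) else v
    }
    data.frame(
      population = draw(cfg$demographic_ranges$population, TRUE),
      vehicles = draw(cfg$demographic_ranges$vehicles, TRUE),
      emp_industrial = draw(cfg$demographic_ranges$emp_industrial, TRUE),
      emp_commercial = draw(cfg$demographic_ranges$emp_commercial, TRUE),
      ag_land_m2 = draw(cfg$demographic_ranges$ag_land_m2, FALSE)
    )
  })
  out <- cbind(
    data.frame(tract_id = sprintf("T%04d", seq_len(n)),
               xmin = xmin, ymin = ymin,
               xmax = xmin + side, ymax = ymin + side,
               region = regions, jurisdiction = jurisdiction,
               stringsAsFactors = FALSE),
    demo
  )
  class(out) <- c("tract_set", class(out))
  out
}

.tree_columns <- c("tree_id", "tract_id", "x", "y", "height_m", "crown_m",
                   "dbh_m", "landuse", "region", "jurisdiction",
                   "species_group")

#' Generate a synthetic tree inventory
#'
#' Draws a Poisson number of trees per tract; heights, crown widths and dbh
#' come from independent moment-matched truncated normals, positions are
#' uniform within the tract polygon, land use is Bernoulli
#' (`developed_fraction`), and region/jurisdiction are inherited from the
#' tract. A configurable fraction of trees receives artifact heights above
#' the truncation cap to emulate feature-extraction errors. Species group is
#' left unset (`NA`) for [assign_species()].
#'
#' @param cfg A [synthetic_config()].
#' @param tracts A non-empty `tract_set` from [generate_tracts()].
#' @return Data frame of tree records (one row per tree).
#' @export
generate_trees <- function(cfg, tracts) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(tracts) || nrow(tracts) == 0) {
    stop("tracts must be a non-empty tract table")
  }
  hp <- truncnorm_match(cfg$height_mean_m, cfg$height_sd_m,
                        cfg$height_min_m, cfg$height_max_m)
  cp <- truncnorm_match(cfg$crown_mean_m, cfg$crown_sd_m,
                        cfg$crown_min_m, cfg$crown_max_m)
  dp <- truncnorm_match(cfg$dbh_mean_m, cfg$dbh_sd_m,
                        cfg$dbh_min_m, cfg$dbh_max_m)
  with_seed(substream_seed(cfg$seed, "trees"), {
    counts <- stats::rpois(nrow(tracts), cfg$trees_per_tract_mean)
    n <- sum(counts)
    if (n == 0) {
      out <- data.frame(tree_id = integer(), tract_id = character(),
                        x = numeric(), y = numeric(), height_m = numeric(),
                        crown_m = numeric(), dbh_m = numeric(),
                        landuse = character(), region = character(),
                        jurisdiction = character(),
                        species_group = character(),
                        stringsAsFactors = FALSE)
      return(out)
    }
    ti <- rep(seq_len(nrow(tracts)), counts)
    height <- rtrunc_norm(n, hp[["mu"]], hp[["sigma"]],
                          cfg$height_min_m, cfg$height_max_m)
    if (cfg$outlier_fraction > 0) {
      art <- stats::runif(n) < cfg$outlier_fraction
      height[art] <- stats::runif(sum(art), cfg$height_max_m + 1, 440)
    }
    crown <- rtrunc_norm(n, cp[["mu"]], cp[["sigma"]],
                         cfg$crown_min_m, cfg$crown_max_m)
    dbh <- rtrunc_norm(n, dp[["mu"]], dp[["sigma"]],
                       cfg$dbh_min_m, cfg$dbh_max_m)
    landuse <- ifelse(stats::runif(n) < cfg$developed_fraction,
                      "developed", "undeveloped")
    data.frame(
      tree_id = seq_len(n),
      tract_id = tracts$tract_id[ti],
      x = stats::runif(n, tracts$xmin[ti], tracts$xmax[ti]),
      y = stats::runif(n, tracts$ymin[ti], tracts$ymax[ti]),
      height_m = height, crown_m = crown, dbh_m = dbh,
      landuse = landuse,
      region = tracts$region[ti],
      jurisdiction = tracts$jurisdiction[ti],
      species_group = NA_character_,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate crown-width validation pairs
#'
#' Emulates an accuracy assessment in which crown widths of reference trees,
#' spread evenly across the observed size range, are measured independently
#' (e.g. from orthophotos) and compared with remotely predicted widths.
#' Measured widths are Uniform(`crown_min_m`, `crown_max_m`); predicted =
#' measured + Gaussian noise.
#'
#' @param n Number of pairs (at least 3).
#' @param noise_sd_m SD of the prediction error in m (0 gives a perfect
#'   prediction).
#' @param seed Integer seed.
#' @param crown_min_m,crown_max_m Range of true crown widths (m).
#' @return Data frame with columns `measured_crown_m`, `predicted_crown_m`.
#' @export
generate_validation_pairs <- function(n, noise_sd_m, seed,
                                      crown_min_m = 2.6, crown_max_m = 16.93) {
  if (n < 3) stop("at least 3 validation pairs are required")
  stopifnot(noise_sd_m >= 0, crown_min_m > 0, crown_min_m < crown_max_m)
  with_seed(substream_seed(seed, "pairs"), {
    measured <- stats::runif(n, crown_min_m, crown_max_m)
    predicted <- measured + stats::rnorm(n, 0, noise_sd_m)
    data.frame(measured_crown_m = measured, predicted_crown_m = predicted)
  })
}
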