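# Shared fixtures: a small deterministic study area and hand-built toy trees.

small_cfg <- function(n_tracts = 4, trees_per_tract_mean = 60, seed = 42,
                      outlier_fraction = 0, ...) {
  synthetic_config(n_tracts = n_tracts,
                   trees_per_tract_mean = trees_per_tract_mean,
                   outlier_fraction = outlier_fraction, seed = seed, ...)
}

small_inventory <- function(seed = 42, ...) {
  cfg <- small_cfg(seed = seed, ...)
  tracts <- generate_tracts(cfg)
  trees <- assign_species(filter_trees(generate_trees(cfg, tracts))$kept,
                          seed = seed)
  list(cfg = cfg, tracts = tracts, trees = trees)
}

# a hand-built tree record; defaults are in-range
toy_tree <- function(tree_id = 1L, tract_id = "A", height = 11.5,
                     crown = 3.9, dbh = 0.29, landuse = "developed",
                     region = "N_Dakota", jurisdiction = "other",
                     species = "oh") {
  data.frame(tree_id = tree_id, tract_id = tract_id, x = 0, y = 0,
             height_m = height, crown_m = crown, dbh_m = dbh,
             landuse = landuse, region = region, jurisdiction = jurisdiction,
             species_group = species, stringsAsFactors = FALSE)
}

toy_trees <- function(...) do.call(rbind, list(...))

# closed-form aboveground biomass, written independently of the package
agb_oracle <- function(dbh_cm, b0, b1) exp(b0 + b1 * log(dbh_cm))

# Brute-force Fisher partition: enumerate all ways to cut the sorted
# distinct values into k contiguous classes and minimise the weighted
# within-class sum of squares.
jenks_oracle <- function(values, k) {
  vals <- sort(unique(values))
  w <- as.numeric(table(factor(values, levels = vals)))
  m <- length(vals)
  ssd <- function(idx) {
    x <- rep(vals[idx], w[idx])
    sum((x - mean(x))^2)
  }
  if (k == 1) return(ssd(1:m))
  splits <- utils::combn(m - 1, k - 1, simplify = FALSE)
  best <- Inf
  for (s in splits) {
    bounds <- c(0, s, m)
    total <- sum(vapply(seq_len(k), function(c) {
      ssd((bounds[c] + 1):bounds[c + 1])
    }, numeric(1)))
    best <- min(best, total)
  }
  best
}
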