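# Inventory quality control, species-group assignment and crown-width
# validation.

#' Quality-filter tree records
#'
#' Partitions records into those within the credible attribute ranges and
#' those rejected as extraction artifacts. A record with any missing
#' attribute is rejected with reason `"incomplete"`; otherwise reasons name
#' the offending attribute(s) (`"height"`, `"dbh"`, `"crown"`, joined with
#' `";"`). The height floor is inclusive; upper bounds are exclusive.
#' Idempotent: filtering the kept set again changes nothing.
#'
#' @param trees Data frame with `height_m`, `dbh_m`, `crown_m` columns.
#' @param thresholds A [qc_thresholds()].
#' @return List with elements `kept` (rows passing QC) and `rejected` (rows
#'   failing, with an added `reason` column).
#' @export
filter_trees <- function(trees, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  need <- c("height_m", "dbh_m", "crown_m")
  missing <- setdiff(need, names(trees))
  if (length(missing)) {
    stop("trees table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(trees) == 0) {
    rejected <- trees
    rejected$reason <- character(0)
    return(list(kept = trees, rejected = rejected))
  }
  incomplete <- is.na(trees$height_m) | is.na(trees$dbh_m) | is.na(trees$crown_m)
  bad_height <- !incomplete & (trees$height_m < thresholds$min_height_m |
                                 trees$height_m > thresholds$max_height_m)
  bad_dbh <- !incomplete & trees$dbh_m > thresholds$max_dbh_m
  bad_crown <- !incomplete & trees$crown_m > thresholds$max_crown_m
  drop <- incomplete | bad_height | bad_dbh | bad_crown
  reason <- character(nrow(trees))
  reason[incomplete] <- "incomplete"
  flagged <- !incomplete & drop
  if (any(flagged)) {
    reason[flagged] <- vapply(which(flagged), function(i) {
      paste(c("height"[bad_height[i]], "dbh"[bad_dbh[i]],
              "crown"[bad_crown[i]]), collapse = ";")
    }, character(1))
  }
  rejected <- trees[drop, , drop = FALSE]
  rejected$reason <- reason[drop]
  list(kept = trees[!drop, , drop = FALSE], rejected = rejected)
}

#' Largest-remainder apportionment of n items over proportions
#'
#' Gives each category `floor(n * p)` items, then distributes the remaining
#' items by descending fractional remainder (ties broken by descending
#' proportion, then category order). Counts always sum to `n` and differ
#' from `n * p` by less than 1.
#'
#' @param n Number of items.
#' @param p Proportions (normalised internally).
#' @return Integer vector of counts, same names as `p`.
#' @export
largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  q <- n * p
  counts <- floor(q)
  r <- round(n - sum(counts))
  if (r > 0) {
    ord <- order(-(q - counts), -p, seq_along(p))
    counts[ord[seq_len(r)]] <- counts[ord[seq_len(r)]] + 1
  }
  stats::setNames(as.integer(counts), names(p))
}

#' Assign species groups by stratified random sampling
#'
#' Within each stratum (developed land crossed with region, or a single
#' undeveloped stratum), the number of trees assigned to each species group
#' is fixed by largest-remainder apportionment of the stratum's relative
#' abundances; which individual tree receives which group is a seeded random
#' permutation. Per-stratum counts therefore match the abundance table to
#' within one tree and are invariant to the input row order.
#'
#' @param trees Tree records with `landuse` and `region` columns.
#' @param table An [abundance_table()] whose columns cover every stratum
#'   present in `trees`.
#' @param seed Integer seed.
#' @return `trees` with `species_group` filled in.
#' @export
assign_species <- function(trees, table = abundance_table(), seed = 1L) {
  if (nrow(trees) == 0) return(trees)
  if (any(is.na(trees$landuse)) || any(is.na(trees$region))) {
    stop("every tree needs landuse and region for species assignment")
  }
  stratum <- ifelse(trees$landuse == "undeveloped", "undeveloped",
                    as.character(trees$region))
  missing <- setdiff(unique(stratum), colnames(table))
  if (length(missing)) {
    stop("abundance table lacks strata: ", paste(missing, collapse = ", "))
  }
  groups <- rownames(table)
  species <- character(nrow(trees))
  with_seed(substream_seed(seed, "species"), {
    for (s in sort(unique(stratum))) {
      idx <- which(stratum == s)
      counts <- largest_remainder(length(idx),
                                  stats::setNames(table[, s], groups))
      labels <- rep(groups, counts)
      species[idx] <- labels[sample.int(length(idx))]
    }
  })
  trees$species_group <- species
  trees
}

#' Validate predicted crown widths against measurements
#'
#' Ordinary least squares of measured on predicted crown width, with the
#' root-mean-squared residual and the mean prediction bias. This is the
#' accuracy metric used to judge whether remotely derived crown widths are
#' trustworthy proxies for field measurement.
#'
#' @param pairs Data frame with `measured_crown_m` and `predicted_crown_m`.
#' @return List with `slope`, `intercept`, `adjusted_r2`, `rmse_m`,
#'   `mean_bias_m` (mean of predicted minus measured) and `n`.
#' @export
validate_crown_width <- function(pairs) {
  stopifnot(all(c("measured_crown_m", "predicted_crown_m") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("at least 3 validation pairs are required")
  if (stats::var(pairs$predicted_crown_m) == 0) {
    stop("degenerate regression: predictor has zero variance")
  }
  fit <- stats::lm(measured_crown_m ~ predicted_crown_m, data = pairs)
  # summary.lm warns on exactly collinear (noiseless) input; the fit is valid
  adj_r2 <- suppressWarnings(summary(fit)$adj.r.squared)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    adjusted_r2 = adj_r2,
    rmse_m = sqrt(mean(stats::residuals(fit)^2)),
    mean_bias_m = mean(pairs$predicted_crown_m - pairs$measured_crown_m),
    n = nrow(pairs)
  )
}
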