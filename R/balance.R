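# Supply-to-demand ratio, Jenks natural-breaks classification, and map/table
# export.

#' Supply-to-demand ratio per tract
#'
#' `R = 100 * S / D_net` (percent), where `S` is net annual sequestration
#' supply and `D_net` the emissions-based demand, both in kgC/yr. Tracts
#' with zero demand get `NA` with a warning (the ratio is undefined there).
#' The study-area summary reports both the totals-based ratio
#' `100 * sum(S) / sum(D_net)` and the mean/SD of tract ratios; these are
#' different statistics and both are meaningful.
#'
#' @param S Named numeric vector of supply per tract (kgC/yr), or a scalar.
#' @param Dnet Demand per tract (kgC/yr), same names as `S`.
#' @return List with `per_tract` (data frame `tract_id`, `S_kgC`,
#'   `Dnet_kgC`, `R_percent`) and `summary` (totals, totals-based ratio,
#'   tract-mean and SD of ratios, counts).
#' @export
supply_demand_ratio <- function(S, Dnet) {
  if (!identical(sort(names(S)), sort(names(Dnet)))) {
    stop("S and Dnet must be keyed by the same tract ids")
  }
  if (any(Dnet < 0)) stop("demand must be non-negative")
  if (!is.null(names(S))) Dnet <- Dnet[names(S)]
  r <- ifelse(Dnet > 0, 100 * S / Dnet, NA_real_)
  if (any(Dnet == 0)) {
    warning(sum(Dnet == 0),
            " tract(s) have zero demand; their ratio is undefined (NA)")
  }
  ids <- if (is.null(names(S))) as.character(seq_along(S)) else names(S)
  per_tract <- data.frame(tract_id = ids, S_kgC = unname(S),
                          Dnet_kgC = unname(Dnet),
                          R_percent = unname(r), stringsAsFactors = FALSE)
  list(
    per_tract = per_tract,
    summary = list(
      S_total_kgC = sum(S),
      Dnet_total_kgC = sum(Dnet),
      R_total_percent = if (sum(Dnet) > 0) 100 * sum(S) / sum(Dnet)
                        else NA_real_,
      R_tract_mean_percent = mean(r, na.rm = TRUE),
      R_tract_sd_percent = stats::sd(r, na.rm = TRUE),
      n_tracts = length(S),
      n_undefined = sum(Dnet == 0)
    )
  )
}

#' Jenks natural-breaks classification
#'
#' Fisher's optimal univariate partition: splits the values into `k` classes
#' minimising the total within-class sum of squared deviations from class
#' means, via dynamic programming over the sorted distinct values (ties
#' always share a class). Deterministic; equal-cost partitions are resolved
#' toward the lowest upper boundary of the earliest differing class.
#'
#' @param values Numeric vector (no NAs).
#' @param k Number of classes, `1 <= k <=` number of distinct values.
#' @return List of class `jenks_classification`: `k`, `breaks` (ascending
#'   upper bound of each class, on the value scale), `classes` (class index
#'   per input value, 1-based) and `ssd` (the minimised within-class sum of
#'   squares).
#' @export
jenks_breaks <- function(values, k) {
  if (any(is.na(values))) stop("values must not contain NA")
  if (k < 1) stop("k must be at least 1")
  vals <- sort(unique(values))
  m <- length(vals)
  if (k > m) stop("k exceeds the number of distinct values")
  w <- as.numeric(table(factor(values, levels = vals)))
  cw <- cumsum(w)
  cwx <- cumsum(w * vals)
  cwx2 <- cumsum(w * vals^2)
  # within-class SSD of distinct values i..j, weighted by multiplicity
  cost <- function(i, j) {
    W <- cw[j] - if (i > 1) cw[i - 1] else 0
    Sx <- cwx[j] - if (i > 1) cwx[i - 1] else 0
    Sx2 <- cwx2[j] - if (i > 1) cwx2[i - 1] else 0
    Sx2 - Sx^2 / W
  }
  D <- matrix(Inf, nrow = m, ncol = k)
  back <- matrix(0L, nrow = m, ncol = k)
  D[, 1] <- vapply(seq_len(m), function(j) cost(1, j), numeric(1))
  if (k > 1) {
    for (cls in 2:k) {
      for (j in cls:m) {
        best <- Inf
        arg <- 0L
        for (s in (cls - 1):(j - 1)) {
          cand <- D[s, cls - 1] + cost(s + 1, j)
          if (cand < best - 1e-12) {
            best <- cand
            arg <- s
          }
        }
        D[j, cls] <- best
        back[j, cls] <- arg
      }
    }
  }
  # recover class upper boundaries
  uppers <- integer(k)
  j <- m
  for (cls in k:1) {
    uppers[cls] <- j
    j <- back[j, cls]
  }
  breaks <- vals[uppers]
  classes <- vapply(values, function(v) which(v <= breaks)[1], integer(1))
  structure(list(k = k, breaks = breaks, classes = classes,
                 ssd = D[m, k]),
            class = "jenks_classification")
}

#' Classify tract balances and export map products
#'
#' Joins the balance table with tract geometry, classifies the
#' supply-to-demand ratio with Jenks natural breaks (tracts with undefined
#' ratio are flagged, not classified), and writes a per-tract CSV, a tract
#' GeoJSON whose properties carry the balance fields and class, and a JSON
#' summary of study totals. Re-exporting identical inputs is byte-identical.
#'
#' @param balances Data frame with `tract_id`, `storage_kgC`, `Cg_kgC`,
#'   `Cl_kgC`, `Cp_kgC`, `Cs_kgC`, `Dnet_kgC`, `R_percent` (as assembled by
#'   [run_pipeline()]).
#' @param tracts A `tract_set` (for geometry); may be `NULL` to skip the
#'   GeoJSON.
#' @param k Number of Jenks classes (default 5).
#' @param out_dir Output directory (created if needed).
#' @param summary_extra Optional named list merged into the summary JSON
#'   (e.g. study-level ratio statistics).
#' @return Invisibly, a list with the classification, the augmented balance
#'   table and the written paths.
#' @export
classify_and_export <- function(balances, tracts = NULL, k = 5,
                                out_dir, summary_extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- !is.na(balances$R_percent)
  balances$jenks_class <- NA_integer_
  cls <- NULL
  if (sum(ok) > 0) {
    k_eff <- min(k, length(unique(balances$R_percent[ok])))
    cls <- jenks_breaks(balances$R_percent[ok], k_eff)
    balances$jenks_class[ok] <- cls$classes
  }
  csv_path <- file.path(out_dir, "tract_balance.csv")
  utils::write.csv(balances, csv_path, row.names = FALSE)
  geojson_path <- NULL
  if (!is.null(tracts)) {
    geojson_path <- file.path(out_dir, "tracts.geojson")
    props <- merge(tracts, balances, by = "tract_id", all.x = TRUE,
                   sort = TRUE)
    write_tracts_geojson(props, geojson_path,
                         property_cols = setdiff(names(props),
                                                 c("xmin", "ymin", "xmax",
                                                   "ymax")))
  }
  summary <- c(list(
    n_tracts = nrow(balances),
    storage_total_kgC = sum(balances$storage_kgC),
    Cg_total_kgC = sum(balances$Cg_kgC),
    Cl_total_kgC = sum(balances$Cl_kgC),
    Cp_total_kgC = sum(balances$Cp_kgC),
    Cs_total_kgC = sum(balances$Cs_kgC),
    Dnet_total_kgC = sum(balances$Dnet_kgC),
    n_subzero_ratio = sum(balances$R_percent < 0, na.rm = TRUE),
    jenks_k = if (is.null(cls)) NA_integer_ else cls$k,
    jenks_breaks = if (is.null(cls)) numeric(0) else cls$breaks
  ), summary_extra)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(classification = cls, balances = balances,
                 paths = list(csv = csv_path, geojson = geojson_path,
                              summary = summary_path)))
}
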