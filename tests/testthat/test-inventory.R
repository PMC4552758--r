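# Quality filtering, species-group apportionment and crown-width validation.

test_that("filter_trees partitions records and labels rejection reasons", {
  trees <- toy_trees(
    toy_tree(1, height = 41),              # above height cap
    toy_tree(2, height = 11.5),            # in range (inventory means)
    toy_tree(3, height = 2.5),             # below detection floor
    toy_tree(4, dbh = 3.5),                # implausible dbh
    toy_tree(5, crown = 50),               # implausible crown
    toy_tree(6, height = 45, dbh = 4, crown = 43),  # multiple reasons
    toy_tree(7, height = NA)               # incomplete record
  )
  out <- filter_trees(trees)
  expect_equal(out$kept$tree_id, 2)
  expect_setequal(out$rejected$tree_id, c(1, 3, 4, 5, 6, 7))
  expect_equal(nrow(out$kept) + nrow(out$rejected), nrow(trees))
  reason <- setNames(out$rejected$reason, out$rejected$tree_id)
  expect_equal(reason[["1"]], "height")
  expect_equal(reason[["3"]], "height")
  expect_equal(reason[["4"]], "dbh")
  expect_equal(reason[["5"]], "crown")
  expect_equal(reason[["6"]], "height;dbh;crown")
  expect_equal(reason[["7"]], "incomplete")
})

test_that("filter bounds are inclusive at the floor, exclusive above the caps", {
  th <- qc_thresholds()
  edge <- toy_trees(toy_tree(1, height = 3), toy_tree(2, height = 40),
                    toy_tree(3, dbh = 3.187), toy_tree(4, crown = 42.672))
  expect_equal(nrow(filter_trees(edge, th)$kept), 4)
})

test_that("filter_trees is idempotent and handles empty input", {
  inv <- small_inventory()
  once <- filter_trees(inv$trees)
  twice <- filter_trees(once$kept)
  expect_identical(once$kept, twice$kept)
  expect_equal(nrow(twice$rejected), 0)
  empty <- filter_trees(inv$trees[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$rejected), 0)
})

test_that("species counts follow largest-remainder apportionment of the table", {
  trees <- do.call(rbind, lapply(1:10000, function(i) {
    toy_tree(i, species = NA_character_)
  }))
  assigned <- assign_species(trees, seed = 1)
  counts <- table(factor(assigned$species_group, levels = species_groups()))
  # northern-Dakota developed column at n = 10000, apportioned exactly
  expect_equal(as.integer(counts),
               c(1282L, 652L, 519L, 6309L, 829L, 409L, 0L))
})

test_that("degenerate and single-tree strata apportion sensibly", {
  one <- assign_species(toy_tree(1, species = NA_character_), seed = 3)
  expect_equal(one$species_group, "oh")  # the stratum's most abundant group
  tab <- abundance_table()
  tab[, "N_Dakota"] <- c(0, 0, 0, 100, 0, 0, 0)
  many <- assign_species(
    do.call(rbind, lapply(1:50, function(i) toy_tree(i, species = NA))),
    table = tab, seed = 3)
  expect_true(all(many$species_group == "oh"))
})

test_that("per-stratum counts are order-invariant and within one tree of the table", {
  trees <- do.call(rbind, lapply(1:997, function(i) {
    toy_tree(i, species = NA_character_,
             landuse = c("developed", "undeveloped")[1 + i %% 2],
             region = c("N_Dakota", "S_Dakota")[1 + (i %% 4) %/% 2])
  }))
  a1 <- assign_species(trees, seed = 5)
  a2 <- assign_species(trees[sample.int(nrow(trees)), ], seed = 5)
  stratum <- function(df) ifelse(df$landuse == "undeveloped", "undeveloped",
                                 df$region)
  c1 <- table(stratum(a1), factor(a1$species_group, levels = species_groups()))
  c2 <- table(stratum(a2), factor(a2$species_group, levels = species_groups()))
  expect_equal(as.matrix(c1), as.matrix(c2))
  tab <- abundance_table()
  for (s in rownames(c1)) {
    p <- tab[, s] / sum(tab[, s])
    expect_true(all(abs(c1[s, species_groups()] - sum(c1[s, ]) * p) < 1))
  }
})

test_that("a stratum missing from the table raises a configuration error", {
  tr <- toy_tree(1, region = "Elsewhere", species = NA_character_)
  expect_error(assign_species(tr, seed = 1), "lacks strata")
})

test_that("crown-width regression recovers exact linear relationships", {
  x <- seq(2, 12, length.out = 50)
  perfect <- data.frame(measured_crown_m = x, predicted_crown_m = x)
  fit <- validate_crown_width(perfect)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$adjusted_r2, 1)
  expect_equal(fit$rmse_m, 0, tolerance = 1e-10)
  scaled <- data.frame(measured_crown_m = 2 * x, predicted_crown_m = x)
  fit2 <- validate_crown_width(scaled)
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  expect_equal(fit2$rmse_m, 0, tolerance = 1e-10)
  expect_equal(fit2$mean_bias_m, mean(x - 2 * x))
  degen <- data.frame(measured_crown_m = x, predicted_crown_m = rep(5, 50))
  expect_error(validate_crown_width(degen), "degenerate")
})

test_that("mean RMSE over seeds matches the closed-form OLS expectation", {
  # Oracle: with Gaussian noise sd sigma on the response of an OLS fit with
  # 2 parameters, RMSE^2 = sigma^2 * chi^2_(n-2) / n, so
  # E[RMSE] = sigma * sqrt(2/n) * Gamma((n-1)/2) / Gamma((n-2)/2).
  n <- 50; sigma <- 0.43; reps <- 200
  expected <- sigma * sqrt(2 / n) * exp(lgamma((n - 1) / 2) - lgamma((n - 2) / 2))
  x <- seq(2.6, 16.93, length.out = n)  # fixed design
  set.seed(101)
  rmses <- replicate(reps, {
    pairs <- data.frame(measured_crown_m = 1 + 0.9 * x + rnorm(n, 0, sigma),
                        predicted_crown_m = x)
    validate_crown_width(pairs)$rmse_m
  })
  expect_lt(abs(mean(rmses) - expected), 3 * sd(rmses) / sqrt(reps))
})

test_that("generator pairs at the calibrated noise level reproduce the survey RMSE", {
  rmses <- vapply(1:200, function(s) {
    validate_crown_width(generate_validation_pairs(50, 0.43, seed = s))$rmse_m
  }, numeric(1))
  # E[RMSE] ~= sqrt((n-2)/n) * sigma = 0.421 m at n = 50; the survey value
  # printed alongside it was 0.43 m
  expect_lt(abs(mean(rmses) - sqrt(48 / 50) * 0.43),
            3 * sd(rmses) / sqrt(200) + 0.01)
  expect_gt(mean(rmses), 0.35)
  expect_lt(mean(rmses), 0.48)
})
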