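# One-year dynamics: mortality sampling, growth gain, decay, replanting and
# the net balance.

test_that("mortality is binomial at the class rate", {
  trees <- do.call(rbind, lapply(1:10000, function(i) toy_tree(i, dbh = 0.30)))
  out <- sample_mortality(trees, seed = 21)
  n_dead <- nrow(out$dead)
  expect_lt(abs(n_dead - 10000 * 0.021),
            3 * sqrt(10000 * 0.021 * 0.979))
  expect_equal(nrow(out$survivors) + n_dead, 10000)
  expect_length(intersect(out$survivors$tree_id, out$dead$tree_id), 0)
})

test_that("degenerate mortality schedules kill none or all", {
  trees <- do.call(rbind, lapply(1:200, function(i) toy_tree(i)))
  none <- sample_mortality(trees, mortality_schedule(rate = rep(0, 4)), seed = 1)
  expect_equal(nrow(none$dead), 0)
  all_die <- sample_mortality(trees, mortality_schedule(rate = rep(1, 4)), seed = 1)
  expect_equal(nrow(all_die$survivors), 0)
})

test_that("dbh classes pick the published rates", {
  sched <- mortality_schedule()
  pick <- function(dbh_cm) sched$rate[findInterval(dbh_cm, sched$lower_cm)]
  expect_equal(pick(c(10, 30, 46.9)), rep(0.021, 3))
  expect_equal(pick(c(47, 61.9)), rep(0.029, 2))
  expect_equal(pick(c(62, 76.9)), rep(0.030, 2))
  expect_equal(pick(c(77, 120)), rep(0.054, 2))
})

test_that("growth gain matches the closed-form biomass difference", {
  tr <- toy_tree(1, dbh = 0.24, species = "oh")
  g <- growth_gain(tr)
  oracle <- 0.5 * (agb_oracle(24.282, -2.48, 2.4835) -
                     agb_oracle(24, -2.48, 2.4835))
  expect_equal(g$Cg_kgC, oracle, tolerance = 1e-12)
  # root growth switch scales by 1 + root:shoot
  g_root <- growth_gain(tr, include_root_growth = TRUE)
  expect_equal(g_root$Cg_kgC, oracle * 1.26, tolerance = 1e-12)
  # zero growth rates give zero gain; doubling survivors doubles the gain
  expect_equal(growth_gain(tr, growth = setNames(rep(0, 7), species_groups()))$Cg_kgC, 0)
  expect_equal(growth_gain(rbind(tr, tr))$Cg_kgC, 2 * g$Cg_kgC)
})

test_that("remaining carbon follows exponential decay", {
  expect_equal(remaining_carbon(100, 0), 50)
  expect_equal(remaining_carbon(100, 1), 50 * exp(-0.062), tolerance = 1e-12)
  expect_lt(remaining_carbon(100, 500), 1e-10)
  t <- seq(0, 30, by = 0.5)
  expect_true(all(diff(remaining_carbon(100, t)) < 0))
  expect_error(remaining_carbon(100, -1), "non-negative")
})

test_that("decay composes as a semigroup", {
  for (case in list(c(80, 1, 2), c(123.4, 0.3, 7.7), c(5, 10, 10))) {
    M <- case[1]; t1 <- case[2]; t2 <- case[3]
    direct <- remaining_carbon(M, t1 + t2)
    # carbon after t1, re-expressed as biomass, decayed another t2
    staged <- remaining_carbon(2 * remaining_carbon(M, t1), t2)
    expect_equal(direct, staged, tolerance = 1e-12)
  }
})

test_that("decomposition loss applies the right regime arithmetic", {
  dbh24 <- 0.24
  b <- agb_oracle(24, -2.48, 2.4835)
  # removal regime releases all whole-tree carbon in year one
  removed <- decomposition_loss(toy_tree(1, jurisdiction = "st_paul",
                                         dbh = dbh24))
  expect_equal(removed$Cl_kgC, 0.5 * b * 1.26, tolerance = 1e-12)
  expect_equal(removed$Cl_removed_kgC, removed$Cl_kgC)
  # natural regime: first-year exponential loss + 20% of roots
  natural <- decomposition_loss(toy_tree(1, jurisdiction = "other",
                                         landuse = "undeveloped", dbh = dbh24))
  expect_equal(natural$Cl_kgC,
               0.5 * (b * (1 - exp(-0.062)) + 0.26 * b * 0.20),
               tolerance = 1e-12)
  # mulch regime: 80% of whole-tree carbon
  mulched <- decomposition_loss(toy_tree(1, jurisdiction = "other",
                                         landuse = "developed", dbh = dbh24))
  expect_equal(mulched$Cl_kgC, 0.5 * b * 1.26 * 0.8, tolerance = 1e-12)
  # worked miniature: B_above = 100 kg in each regime
  # (values follow the published first-year fractions)
  expect_equal(0.5 * 126 * 1.0, 63)
  empty <- decomposition_loss(toy_tree(1)[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("replanting selects the policy fraction of dead trees", {
  dead <- do.call(rbind, lapply(1:100, function(i) {
    toy_tree(i, jurisdiction = "st_paul")
  }))
  rp <- replanting_gain(dead, seed = 13)
  expect_length(rp$replanted_ids, 15)
  # undeveloped land is never replanted
  dead_u <- do.call(rbind, lapply(1:40, function(i) {
    toy_tree(i, jurisdiction = "other", landuse = "undeveloped")
  }))
  rp_u <- replanting_gain(dead_u, seed = 13)
  expect_length(rp_u$replanted_ids, 0)
  expect_equal(sum(rp_u$per_tract$Cp_kgC), 0)
  # full replacement returns the whole-tree carbon of all dead trees
  rp_all <- replanting_gain(dead, replant_policy(st_paul = 1), seed = 13)
  b <- agb_oracle(29, -2.48, 2.4835)
  expect_equal(sum(rp_all$per_tract$Cp_kgC), 100 * 0.5 * 1.26 * b,
               tolerance = 1e-12)
})

test_that("net sequestration is the exact three-term balance", {
  out <- net_sequestration(49.3, 19.3, 3.4)
  expect_equal(out$total, 33.4)
  expect_equal(net_sequestration(5, 5, 0)$total, 0)
  expect_lt(net_sequestration(0, 2, 0)$total, 0)
  a <- c(A = 1, B = 2)
  expect_error(net_sequestration(a, c(A = 1, C = 2), c(A = 0, B = 0)),
               "same tract ids")
  # alignment by name, not position
  out2 <- net_sequestration(a, c(B = 1, A = 0.5), c(B = 0.25, A = 0))
  expect_equal(unname(out2$per_tract[c("A", "B")]), c(0.5, 1.25))
})

test_that("the year ledger conserves trees and the balance identity is exact", {
  inv <- small_inventory(trees_per_tract_mean = 300)
  res <- simulate_sequestration(inv$trees, seed = 77,
                                tract_ids = inv$tracts$tract_id)
  expect_setequal(res$ledger$tree_id, inv$trees$tree_id)
  expect_true(all(res$ledger$fate %in% c("survived", "died")))
  expect_true(all(res$ledger$fate[res$ledger$replanted] == "died"))
  expect_equal(res$per_tract$Cs_kgC,
               res$per_tract$Cg_kgC - res$per_tract$Cl_kgC +
                 res$per_tract$Cp_kgC)
  expect_equal(res$totals$Cs_kgC,
               res$totals$Cg_kgC - res$totals$Cl_kgC + res$totals$Cp_kgC,
               tolerance = 1e-12)
})

test_that("without mortality or replanting the balance is pure growth", {
  inv <- small_inventory(trees_per_tract_mean = 150)
  res <- simulate_sequestration(
    inv$trees, seed = 5,
    schedule = mortality_schedule(rate = rep(0, 4)),
    policy = replant_policy(0, 0, 0),
    tract_ids = inv$tracts$tract_id
  )
  g <- growth_gain(inv$trees, tract_ids = inv$tracts$tract_id)
  expect_equal(res$per_tract$Cs_kgC, g$Cg_kgC, tolerance = 1e-12)
  expect_equal(res$totals$Cl_kgC, 0)
  expect_equal(res$totals$Cp_kgC, 0)
})

test_that("Monte-Carlo decomposition loss matches its analytic expectation", {
  # natural-regime trees only; E[Cl] = sum_i rate_i * cl_i over Bernoulli deaths
  set.seed(99)
  trees <- do.call(rbind, lapply(1:400, function(i) {
    toy_tree(i, dbh = runif(1, 0.24, 0.83), jurisdiction = "other",
             landuse = "undeveloped")
  }))
  sched <- mortality_schedule()
  rate <- sched$rate[findInterval(trees$dbh_m * 100, sched$lower_cm)]
  b <- agb_oracle(trees$dbh_m * 100, -2.48, 2.4835)
  cl_tree <- 0.5 * (b * (1 - exp(-0.062)) + 0.26 * b * 0.20)
  expected <- sum(rate * cl_tree)
  sims <- vapply(1:200, function(s) {
    dead <- sample_mortality(trees, sched, seed = s)$dead
    sum(decomposition_loss(dead)$Cl_kgC)
  }, numeric(1))
  expect_lt(abs(mean(sims) - expected), 3 * sd(sims) / sqrt(200))
})
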