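test_that("quartile labels follow midpoint percentiles with ties down", {
  expect_equal(quartilize(1:8), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(sort(quartilize(c(10, 2, 7, 4))), 1:4)
  expect_error(quartilize(rep(3, 10)), class = "gutmets_degenerate_input")
  expect_error(quartilize(1:3), class = "gutmets_invalid_argument")
  withr::with_seed(71, {
    x <- rnorm(200)
    expect_equal(quartilize(x), quartilize(exp(x))) # monotone invariance
    expect_equal(as.integer(table(quartilize(x))), rep(50L, 4))
  })
})

test_that("group prevalence and pairwise tests behave at both extremes", {
  co <- generate_cohort(4000, seed = 72)
  res <- prevalence_by_group(co, co$spending_group)
  expect_equal(sum(res$groups$n), 4000)
  low <- res$groups$prevalence[res$groups$group == "low"]
  high <- res$groups$prevalence[res$groups$group == "high"]
  expect_gt(high - low, 5) # planted economic gradient
  lh <- res$pairwise[(res$pairwise$group1 == "low" &
                        res$pairwise$group2 == "high") |
                       (res$pairwise$group1 == "high" &
                          res$pairwise$group2 == "low"), ]
  expect_lt(lh$q, 0.05)

  # Identical composition: no pair significant.
  null_groups <- withr::with_seed(73, sample(rep(c("g1", "g2", "g3"),
                                                 length.out = 4000)))
  res_null <- prevalence_by_group(co, null_groups)
  expect_true(all(res_null$pairwise$q > 0.05))

  single <- prevalence_by_group(co, rep("only", 4000))
  expect_null(single$pairwise)
  expect_warning(prevalence_by_group(co, factor(rep("a", 4000),
                                                levels = c("a", "b"))),
                 "empty")
})

test_that("lifestyle correlations recover the configured signs", {
  co <- generate_cohort(4000, seed = 74)
  res <- lifestyle_correlations(co)
  get <- function(v) res[res$variable == v, ]
  expect_gt(get("sedentary")$rho, 0)
  expect_true(get("sedentary")$significant)
  expect_gt(get("diet_veg")$rho, 0)
  expect_true(get("diet_veg")$significant)
  expect_gt(get("diet_fruit")$rho, 0)
  expect_lt(get("diet_grain")$rho, 0)
  expect_true(get("diet_grain")$significant)
  expect_false(get("diet_meat")$significant)
  expect_lt(get("smoking")$rho, 0)

  # Uncoupled generator: nothing significant.
  cfg <- cohort_config(sedentary_spending_rho = 0,
                       diet = list(veg = c(17, 6, 0), fruit = c(8, 4, 0),
                                   grain = c(18, 6, 0), meat = c(9, 5, 0)),
                       smoking_spending = 0)
  co0 <- generate_cohort(2000, cfg, seed = 75)
  res0 <- lifestyle_correlations(co0,
                                 variables = c("sedentary", "diet_veg",
                                               "diet_fruit", "diet_grain",
                                               "diet_meat"))
  expect_true(all(!res0$significant))

  co$monotone <- rank(co$spending)
  perfect <- lifestyle_correlations(co, variables = "monotone")
  expect_equal(perfect$rho, 1)
  co$flat <- 1
  expect_warning(lifestyle_correlations(co, variables = c("flat",
                                                          "sedentary")),
                 "constant")
})

test_that("grid marginals reproduce the single-axis quartile prevalences", {
  sc <- small_scenario()
  idx <- compute_mets_index(sc$table,
                            effects_as_records(sc$effects))
  grid <- additive_risk_grid(idx, sc$cohort)
  expect_equal(sum(grid$cells$n), nrow(sc$cohort))
  merged <- grid$data
  for (q in 1:4) {
    direct <- 100 * mean(merged$mets[merged$index_q == q])
    from_cells <- with(grid$cells[grid$cells$index_q == q, ],
                       100 * sum(n_mets) / sum(n))
    expect_equal(from_cells, direct, tolerance = 1e-12)
  }
  expect_true(all(grid$cells$prevalence >= 0 & grid$cells$prevalence <= 100,
                  na.rm = TRUE))
  expect_equal(nrow(grid$pairwise), choose(16, 2))
  occ <- grid$occupancy
  sums <- tapply(occ$percent, occ$spending_group, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("a null grid stays near the overall prevalence", {
  co <- generate_cohort(2000, seed = 76)
  null_idx <- tibble::tibble(sample_id = co$sample_id,
                             mets_index = withr::with_seed(77, rnorm(2000)))
  co$sedentary <- withr::with_seed(78, sample(co$sedentary))
  grid <- additive_risk_grid(null_idx, co)
  overall <- 100 * mean(co$mets)
  expect_true(all(abs(grid$cells$prevalence - overall) < 12))
  expect_true(mean(grid$pairwise$q <= 0.05) <= 0.05 + 3 *
                sqrt(0.05 * 0.95 / nrow(grid$pairwise)))
})

test_that("a forced one-sample-per-cell grid gives 0/100 prevalences", {
  co <- generate_cohort(16, seed = 79)
  co$sedentary <- rep(1:4, each = 4) + (1:16) / 100
  idx <- tibble::tibble(sample_id = co$sample_id,
                        mets_index = rep(1:4, times = 4) + (16:1) / 100)
  grid <- additive_risk_grid(idx, co)
  expect_true(all(grid$cells$n == 1))
  expect_true(all(grid$cells$prevalence %in% c(0, 100)))
})

test_that("independent index and sedentary effects stack additively", {
  seed <- 3
  co <- generate_cohort(4000, seed = derive_seed(seed, "cohort"))
  oc <- otu_config(community_shift_sd = 0.8, dysbiosis_load_coupling = 0)
  prof <- otu_profile(150, oc, seed = derive_seed(seed, "profile"))
  eff <- plant_effects(prof, 40, magnitude_range = c(0.1, 0.25),
                       seed = derive_seed(seed, "effects"))
  tab <- generate_otu_table(co, eff, depth = 2000,
                            seed = derive_seed(seed, "counts"),
                            profile = prof, config = oc)
  idx <- compute_mets_index(tab, effects_as_records(eff))
  grid <- additive_risk_grid(idx, co)
  corners <- grid$corners
  expect_gt(corners$high_high, corners$high_index_low_sed)
  expect_gt(corners$high_high, corners$low_index_high_sed)
  expect_gt(corners$high_index_low_sed, corners$low_low)
  expect_gt(corners$low_index_high_sed, corners$low_low)
})
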