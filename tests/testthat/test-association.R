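test_that("prevalence filter keeps the inclusive boundary", {
  counts <- matrix(0L, 20, 3,
                   dimnames = list(sprintf("s%02d", 1:20), c("a", "b", "c")))
  counts[1:2, "a"] <- 5L   # exactly 10% of 20 samples
  counts[1, "b"] <- 5L     # 5%
  counts[, "c"] <- 1L      # everywhere
  counts[3:20, "a"] <- 0L
  tab <- otu_table(counts, tibble::tibble(otu_id = c("a", "b", "c"),
                                          taxonomy = "k__;p__;c__;o__;f__;g__;s__"))
  kept <- prevalence_filter(tab, 0.10)
  expect_setequal(colnames(kept$counts), c("a", "c"))
  expect_error(prevalence_filter(tab, 0), class = "gutmets_invalid_argument")
  only_rare <- otu_table(counts[, "b", drop = FALSE],
                         tibble::tibble(otu_id = "b",
                                        taxonomy = "k__;p__;c__;o__;f__;g__;s__"))
  expect_error(prevalence_filter(only_rare, 0.10),
               class = "gutmets_empty_result")
})

test_that("arcsine-square-root transform matches its closed form", {
  m <- matrix(c(0, 0.25, 0.75, 1), 2, 2)
  expect_equal(transform_abundance(m),
               matrix(c(0, asin(sqrt(0.25)), asin(sqrt(0.75)), pi / 2), 2, 2))
  expect_equal(transform_abundance(matrix(c(0.25, 0.75), 1))[1], pi / 6,
               tolerance = 1e-12)
})

test_that("beta equals the closed-form partial regression coefficient", {
  sc <- mets_scenario(n = 120, n_otus = 30, n_signal = 10, depth = 1000,
                      seed = 51)
  recs <- fit_associations(sc$table, sc$cohort, factors = "mets",
                           confounders = "age", factor_coding = "continuous")
  y_mat <- transform_abundance(sc$table)
  x <- as.numeric(sc$cohort$mets)
  x <- (x - mean(x)) / sd(x)
  age <- (sc$cohort$age - mean(sc$cohort$age)) / sd(sc$cohort$age)
  X <- cbind(1, x, age)
  for (k in c(1, 7, 30)) {
    beta_oracle <- solve(crossprod(X), crossprod(X, y_mat[, k]))[2]
    expect_equal(recs$beta[recs$otu_id == colnames(y_mat)[k]], beta_oracle,
                 tolerance = 1e-8)
    ref <- summary(lm(y_mat[, k] ~ x + age))
    expect_equal(recs$p[recs$otu_id == colnames(y_mat)[k]],
                 ref$coefficients["x", 4], tolerance = 1e-8)
  }
})

test_that("the engine is calibrated under the global null", {
  co <- generate_cohort(400, seed = 52)
  tab <- generate_otu_table(co, NULL, n_otus = 300, depth = 2000, seed = 53)
  recs <- fit_associations(prevalence_filter(tab), co)
  frac <- mean(recs$significant)
  m <- nrow(recs)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / m))
})

test_that("a single planted MetS effect is recovered with its sign", {
  co <- generate_cohort(2000, seed = 54)
  prof <- otu_profile(50, seed = 55)
  target <- prof$otu_id[which.min(abs(prof$log_base - median(prof$log_base)))]
  eff <- tibble::tibble(otu_id = target, factor = "mets", effect = 0.5,
                        direction = 1)
  tab <- generate_otu_table(co, eff, profile = prof, depth = 2000, seed = 56,
                            config = otu_config(confounder_fraction = 0))
  recs <- fit_associations(prevalence_filter(tab), co, factors = "mets")
  hit <- recs[recs$otu_id == target, ]
  expect_gt(hit$beta, 0)
  expect_lte(hit$q, 0.05)
})

test_that("confounder adjustment removes a purely age-driven association", {
  co <- generate_cohort(4000, cohort_config(risk_age = 0.45), seed = 31)
  prof <- otu_profile(100, seed = 32)
  cf <- tibble::tibble(otu_id = "OTU_00050", confounder = "age", effect = 1.5)
  tab <- generate_otu_table(co, NULL, depth = 5000, seed = 33,
                            profile = prof, confounder_effects = cf)
  filt <- prevalence_filter(tab)
  adjusted <- fit_associations(filt, co, factors = "mets")
  unadjusted <- fit_associations(filt, co, factors = "mets",
                                 confounders = c("gender", "region",
                                                 "bristol"))
  expect_lte(unadjusted$q[unadjusted$otu_id == "OTU_00050"], 0.05)
  expect_gt(adjusted$q[adjusted$otu_id == "OTU_00050"], 0.05)
})

test_that("boosted covariate screening keeps the forced factor estimate", {
  sc <- mets_scenario(n = 150, n_otus = 25, n_signal = 8, depth = 800,
                      seed = 57)
  plain <- fit_associations(sc$table, sc$cohort, factors = "mets")
  boosted <- fit_associations(sc$table, sc$cohort, factors = "mets",
                              selection = "boosted")
  merged <- dplyr::inner_join(plain, boosted, by = c("otu_id", "factor"))
  expect_equal(nrow(merged), 25)
  expect_gt(cor(merged$beta.x, merged$beta.y), 0.98)
})

test_that("aliased covariates are dropped with a warning", {
  sc <- mets_scenario(n = 80, n_otus = 20, n_signal = 5, depth = 500,
                      seed = 58)
  co <- sc$cohort
  co$copy_of_age <- co$age
  expect_warning(
    fit_associations(sc$table, co, factors = "mets",
                     confounders = c("age", "copy_of_age")),
    "aliased")
})

test_that("network summary reproduces the population direction counts", {
  recs <- population_network_fixture()
  net <- summarize_network(recs, rank = "phylum")
  expect_equal(net$totals$n_associations, 1243L)
  expect_equal(net$totals$n_negative, 676L)
  expect_equal(net$totals$n_positive, 567L)
  bact <- net$per_taxon[net$per_taxon$taxon == "Bacteroidetes", ]
  expect_equal(bact$n_total, 362L)
  expect_equal(bact$n_negative, 350L)
  expect_equal(bact$n_positive, 12L)
  prot <- net$per_taxon[net$per_taxon$taxon == "Proteobacteria", ]
  expect_equal(prot$n_total, 251L)
  expect_equal(prot$n_positive, 230L)
  # Raw per-factor counts keep the modelled sign (HDL not flipped here).
  hdl <- net$per_factor[net$per_factor$factor == "hdl", ]
  expect_equal(hdl$n_positive, 34L)
  expect_equal(hdl$n_negative, 16L)
  waist <- net$per_factor[net$per_factor$factor == "waist", ]
  expect_equal(waist$n_negative, 184L)
})

test_that("network totals are invariant to record order and label gaps", {
  recs <- population_network_fixture()
  shuffled <- recs[withr::with_seed(59, sample(nrow(recs))), ]
  net1 <- summarize_network(recs)
  net2 <- summarize_network(shuffled)
  expect_equal(net1$totals, net2$totals)
  expect_equal(dplyr::arrange(net1$per_taxon, .data$taxon),
               dplyr::arrange(net2$per_taxon, .data$taxon))

  recs$taxonomy[1] <- NA
  net3 <- summarize_network(recs)
  expect_true("Unassigned" %in% net3$per_taxon$taxon)
  expect_equal(net3$totals$n_associations, 1243L)

  empty <- summarize_network(recs[0, ])
  expect_equal(empty$totals$n_associations, 0L)
})
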