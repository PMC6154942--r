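index_fixture <- function() {
  counts <- rbind(A = c(p = 20L, n = 0L, z = 80L),
                  B = c(p = 0L, n = 20L, z = 80L),
                  C = c(p = 0L, n = 0L, z = 100L))
  tab <- otu_table(counts, tibble::tibble(otu_id = c("p", "n", "z"),
                                          taxonomy = "k__;p__;c__;o__;f__;g__;s__"))
  # weights: sign(beta) * |beta| * (-log10 q) = +1 and -1
  recs <- tibble::tibble(otu_id = c("p", "n"), taxonomy = NA,
                         factor = "mets", beta = c(1, -1), p = 0.01,
                         q = c(0.1, 0.1), n_used = 3L,
                         direction = c(1, -1), significant = TRUE)
  list(tab = tab, recs = recs)
}

test_that("the index accumulates signed weighted relative abundances", {
  fx <- index_fixture()
  idx <- compute_mets_index(fx$tab, fx$recs)
  w <- tidy(idx)
  expect_equal(w$weight[w$otu_id == "p"], 1)
  expect_equal(w$weight[w$otu_id == "n"], -1)
  expect_equal(idx$raw_index[idx$sample_id == "A"], 0.2)
  expect_equal(idx$raw_index[idx$sample_id == "B"], -0.2)
  # A sample with zero abundance on every associated OTU scores 0 before
  # standardization.
  expect_equal(idx$raw_index[idx$sample_id == "C"], 0)
  expect_equal(mean(idx$mets_index), 0, tolerance = 1e-12)
  expect_equal(sd(idx$mets_index), 1, tolerance = 1e-12)
})

test_that("HDL records flip valence and multi-factor weights add", {
  fx <- index_fixture()
  recs <- fx$recs
  recs$factor <- c("hdl", "mets")
  idx <- compute_mets_index(fx$tab, recs)
  w <- tidy(idx)
  # A positive HDL association is protective: weight becomes negative.
  expect_equal(w$weight[w$otu_id == "p"], -1)

  two <- dplyr::bind_rows(fx$recs,
                          tibble::tibble(otu_id = "p", taxonomy = NA,
                                         factor = "waist", beta = 1, p = 0.01,
                                         q = 0.1, n_used = 3L, direction = 1,
                                         significant = TRUE))
  idx2 <- compute_mets_index(fx$tab, two)
  expect_equal(tidy(idx2)$weight[tidy(idx2)$otu_id == "p"], 2)
})

test_that("the index is invariant to column order, zero-weight OTUs and scale", {
  fx <- index_fixture()
  idx <- compute_mets_index(fx$tab, fx$recs)
  perm <- subset_otu_cols <- fx$tab$counts[, c("z", "n", "p")]
  tab_perm <- otu_table(perm, fx$tab$taxonomy)
  idx_perm <- compute_mets_index(tab_perm, fx$recs)
  expect_equal(idx_perm$mets_index, idx$mets_index)

  doubled <- fx$recs
  doubled$beta <- doubled$beta * 2
  idx_doubled <- compute_mets_index(fx$tab, doubled)
  expect_equal(idx_doubled$mets_index, idx$mets_index, tolerance = 1e-12)

  expect_error(compute_mets_index(fx$tab, fx$recs[0, ]),
               class = "gutmets_empty_index")
  insig <- fx$recs
  insig$significant <- FALSE
  expect_error(compute_mets_index(fx$tab, insig),
               class = "gutmets_empty_index")
})

test_that("alternative weight modes change only the weighting rule", {
  fx <- index_fixture()
  recs <- fx$recs
  recs$beta <- c(2, -0.5)
  w_beta <- tidy(compute_mets_index(fx$tab, recs, weight_mode = "beta"))
  expect_equal(w_beta$weight[w_beta$otu_id == "p"], 2)
  w_logq <- tidy(compute_mets_index(fx$tab, recs, weight_mode = "logq"))
  expect_equal(w_logq$weight[w_logq$otu_id == "p"], 1)
})

test_that("MetS subjects score higher within every stratum", {
  sc <- small_scenario()
  fit <- fit_associations(prevalence_filter(sc$table), sc$cohort)
  idx <- compute_mets_index(prevalence_filter(sc$table), fit)
  val <- stratified_validation(idx, sc$cohort)
  expect_equal(nrow(val), 3)
  expect_true(all(val$median_mets > val$median_non_mets))
  expect_true(all(val$q < 0.05))

  # AUC above chance, growing with planted effect size.
  merged <- dplyr::inner_join(tibble::as_tibble(idx), sc$cohort,
                              by = "sample_id")
  auc_strong <- auc_score(merged$mets_index, merged$mets)
  expect_gt(auc_strong, 0.6)
  weak <- mets_scenario(n = 800, n_otus = 300, n_signal = 60, depth = 5000,
                        seed = 11, magnitude_range = c(0.1, 0.2))
  idx_weak <- compute_mets_index(weak$table, effects_as_records(weak$effects))
  mw <- dplyr::inner_join(tibble::as_tibble(idx_weak), weak$cohort,
                          by = "sample_id")
  expect_gt(auc_score(mw$mets_index, mw$mets), 0.5)
  expect_gt(auc_strong, auc_score(mw$mets_index, mw$mets))
})

test_that("degenerate strata are skipped or reduce to the whole cohort", {
  sc <- small_scenario()
  fit <- fit_associations(prevalence_filter(sc$table), sc$cohort)
  idx <- compute_mets_index(prevalence_filter(sc$table), fit)

  co_single <- sc$cohort
  co_single$one_level <- "all"
  val <- stratified_validation(idx, co_single, strata = "one_level")
  expect_equal(nrow(val), 1)
  whole <- wilcoxon_rank_sum(idx$mets_index[sc$cohort$mets],
                             idx$mets_index[!sc$cohort$mets])
  expect_equal(val$p, whole$p)

  shuffled <- idx
  shuffled$mets_index <- withr::with_seed(61, sample(shuffled$mets_index))
  val_null <- stratified_validation(shuffled, sc$cohort)
  expect_true(all(val_null$q > 0.05))
})

test_that("index-economics correlation behaves at the extremes", {
  sc <- small_scenario()
  ranks_idx <- tibble::tibble(sample_id = sc$cohort$sample_id,
                              mets_index = rank(sc$cohort$spending))
  res <- index_vs_economics(ranks_idx, sc$cohort, subset = "all")
  expect_equal(res$rho, 1)
  expect_error(index_vs_economics(ranks_idx[1:2, ], sc$cohort[1:2, ]),
               class = "gutmets_invalid_argument")
})
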