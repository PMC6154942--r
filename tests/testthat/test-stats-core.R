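# Brute-force oracles used to pin the self-implemented tests down.

# Exact two-sided rank-sum p by enumerating every assignment of the pooled
# observations to the first group.
wilcoxon_enum_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- combn(length(pooled), n1)
  ws <- apply(sets, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

chi_square_loop_oracle <- function(tab) {
  n <- sum(tab)
  x2 <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      x2 <- x2 + (tab[i, j] - e)^2 / e
    }
  }
  x2
}

spearman_rank_pearson_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2)) * sqrt(sum((ry - mean(ry))^2))
  num / den
}

bh_definition_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  sapply(seq_len(m), function(i) {
    ge <- which(p >= p[i] - 1e-15)
    min(1, min(m * p[ge] / r[ge]))
  })
}

test_that("exact rank-sum matches full enumeration, with and without ties", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  withr::with_seed(42, {
    for (i in 1:8) {
      n1 <- sample(2:6, 1)
      n2 <- sample(2:6, 1)
      x <- sample(1:8, n1, replace = TRUE) # ties likely
      y <- sample(1:8, n2, replace = TRUE)
      ours <- wilcoxon_rank_sum(x, y)
      expect_equal(ours$method, "exact")
      expect_equal(ours$statistic, sum(rank(c(x, y))[seq_len(n1)]),
                   tolerance = 1e-10)
      expect_equal(ours$p, wilcoxon_enum_oracle(x, y), tolerance = 1e-10)
    }
  })
})

test_that("rank-sum agrees with the base implementation when tie-free", {
  withr::with_seed(7, {
    for (i in 1:5) {
      x <- rnorm(6)
      y <- rnorm(7)
      ours <- wilcoxon_rank_sum(x, y)
      ref <- wilcox.test(x, y, exact = TRUE)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("normal approximation tracks the exact tail at moderate n", {
  # Exhaustive comparison over every achievable tie-free rank sum at
  # n1 = n2 = 8: the corrected normal approximation deviates from the
  # exact two-sided tail by at most ~0.011 (worst case at mid-range
  # statistics), and typically by far less.
  sets <- combn(16, 8)
  ws <- colSums(matrix((1:16)[sets], nrow = 8))
  tab <- table(ws)
  wvals <- as.integer(names(tab))
  cdf <- cumsum(as.numeric(tab)) / sum(tab)
  ccdf <- rev(cumsum(rev(as.numeric(tab)))) / sum(tab)
  exact2 <- pmin(1, 2 * pmin(cdf, ccdf))
  mu <- 8 * 17 / 2
  sig <- sqrt(8 * 8 / 12 * 17)
  z <- (wvals - mu - 0.5 * sign(wvals - mu)) / sig
  approx2 <- pmin(1, 2 * pnorm(-abs(z)))
  expect_lt(max(abs(exact2 - approx2)), 0.011)
  expect_lt(median(abs(exact2 - approx2)), 0.005)

  # The implementation's two branches reproduce this comparison.
  withr::with_seed(13, {
    x <- rnorm(8)
    y <- rnorm(8) + 0.5
    exact <- wilcoxon_rank_sum(x, y)$p
    approx <- wilcoxon_rank_sum(x, y, exact_limit = 0)$p
    expect_lt(abs(exact - approx), 0.011)
  })
})

test_that("identical groups give a rank-sum p near 1", {
  x <- c(3, 1, 4, 1, 5)
  expect_gt(wilcoxon_rank_sum(x, sample(x))$p, 0.9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3),
               class = "gutmets_invalid_argument")
})

test_that("chi-square statistic equals the O/E loop oracle", {
  expect_equal(chi_square(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square(matrix(10, 2, 2))$p, 1)
  withr::with_seed(3, {
    for (i in 1:10) {
      tab <- matrix(rpois(6, 20) + 1, 2, 3)
      ours <- chi_square(tab)
      expect_equal(ours$statistic, chi_square_loop_oracle(tab),
                   tolerance = 1e-10)
      ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("gender-by-MetS contingency from published counts is significant", {
  tab <- rbind(female = c(657, 3803 - 657), male = c(747, 3093 - 747))
  res <- chi_square(tab)
  expect_lt(res$p, 0.001)
})

test_that("Yates correction matches the base 2x2 default", {
  tab <- matrix(c(12, 5, 7, 15), 2, 2)
  ours <- chi_square(tab, correct = TRUE)
  ref <- chisq.test(tab)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, 2)),
               class = "gutmets_invalid_argument")
})

test_that("spearman rho equals the rank-pearson oracle under ties", {
  expect_equal(spearman_cor(1:10, 1:10)$rho, 1)
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)
  withr::with_seed(21, {
    for (i in 1:8) {
      x <- sample(1:6, 20, replace = TRUE)
      y <- x + sample(1:4, 20, replace = TRUE)
      ours <- spearman_cor(x, y)
      expect_equal(ours$rho, spearman_rank_pearson_oracle(x, y),
                   tolerance = 1e-10)
      ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
      expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-10)
    }
  })
  expect_error(spearman_cor(rep(1, 5), 1:5),
               class = "gutmets_undefined_correlation")
  expect_error(spearman_cor(1:2, 1:2), class = "gutmets_invalid_argument")
})

test_that("BH adjustment matches the step-up definition and base p.adjust", {
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(31, {
    for (i in 1:10) {
      p <- runif(sample(3:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
      expect_equal(q, bh_definition_oracle(p), tolerance = 1e-12)
      expect_true(all(q >= p))
      expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
  })
  expect_error(bh_adjust(c(0.5, 0)), class = "gutmets_invalid_argument")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "gutmets_invalid_argument")
})

test_that("percentages format at one decimal, half away from zero", {
  expect_equal(format_prevalence(657, 3803), "17.3")
  expect_equal(format_prevalence(1404, 6896), "20.4")
  expect_equal(format_prevalence(0, 100), "0.0")
  expect_equal(format_prevalence(1, 800), "0.1") # 0.125 rounds up
})

test_that("cohort summary reports per-gender rates with tests", {
  co <- generate_cohort(1500, seed = 9)
  summ <- cohort_summary(co)
  expect_setequal(summ$variable,
                  c("age", "waist", "bp", "tg", "hdl", "fbg", "mets"))
  mets_row <- summ[summ$variable == "mets", ]
  f <- co[co$gender == "female", ]
  expect_match(mets_row$female,
               sprintf("^%d \\(%s\\)$", sum(f$mets),
                       format_prevalence(sum(f$mets), nrow(f))))
  expect_true(all(is.finite(summ$p)))
  single <- co[co$gender == "female", ]
  expect_warning(s2 <- cohort_summary(single), "single-gender")
  expect_true(all(is.na(s2$p)))
})
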