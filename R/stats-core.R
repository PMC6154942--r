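# Elementary statistics implemented in-package: Wilcoxon rank-sum with
# exact tie-aware enumeration, Pearson chi-square, Spearman rank
# correlation and the Benjamini-Hochberg step-up adjustment. These are the
# building blocks of every comparison reported by the pipeline, so they are
# implemented here and verified against brute-force oracles rather than
# delegated.

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with midrank handling of ties. For
#' `n1 + n2 <= exact_limit` the null distribution of the rank-sum is
#' enumerated exactly (a subset-sum count over the doubled midranks);
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. The reported statistic is the rank sum of `x`.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_limit Largest `n1 + n2` for which the exact distribution is
#'   enumerated.
#' @return One-row tibble: `statistic` (rank sum of `x`), `p`, `n1`, `n2`,
#'   `method`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
wilcoxon_rank_sum <- function(x, y, exact_limit = 25) {
  if (length(x) == 0 || length(y) == 0) {
    abort_invalid_argument("both groups must be non-empty.")
  }
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= exact_limit) {
    # Exact enumeration over all C(n, n1) assignments via a subset-sum
    # count on 2*midranks (always integers).
    r2 <- as.integer(round(2 * r))
    smax <- sum(r2)
    # counts[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s.
    counts <- matrix(0, n1 + 1, smax + 1)
    counts[1, 1] <- 1
    processed <- 0
    for (item in r2) {
      processed <- processed + 1
      # k descends so each rank is used at most once per subset.
      for (k in seq(min(n1, processed), 1)) {
        nz <- which(counts[k, ] > 0)
        if (length(nz) > 0) {
          counts[k + 1, nz + item] <- counts[k + 1, nz + item] + counts[k, nz]
        }
      }
    }
    dist <- counts[n1 + 1, ]
    total <- sum(dist)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1)]) / total
    p_ge <- sum(dist[seq(w2 + 1, smax + 1)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
    p <- max(2 * pnorm(-abs(z)), .Machine$double.xmin)
    method <- "normal"
  }
  tibble::tibble(statistic = w, p = p, n1 = n1, n2 = n2, method = method)
}

#' Pearson chi-square test on a contingency table
#'
#' `X^2 = sum (O - E)^2 / E` with `df = (r - 1)(c - 1)`; no continuity
#' correction by default (a flag provides the Yates correction for 2x2
#' tables).
#'
#' @param table Matrix of non-negative counts with all row/column margins
#'   positive.
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return One-row tibble: `statistic`, `p`, `df`, `n`.
#' @export
#' @examples
#' chi_square(matrix(c(657, 3146, 747, 2346), nrow = 2))
chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0)) {
    abort_invalid_argument("counts must be non-negative.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort_invalid_argument("all table margins must be positive.")
  }
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  dev <- abs(table - expected)
  if (correct && all(dim(table) == c(2, 2))) {
    dev <- pmax(dev - 0.5, 0)
  }
  x2 <- sum(dev^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  p <- max(pchisq(x2, df, lower.tail = FALSE), .Machine$double.xmin)
  tibble::tibble(statistic = x2, p = p, df = df, n = n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; the p-value uses the t approximation
#' with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return One-row tibble: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) {
    abort_invalid_argument("`x` and `y` must have equal length.")
  }
  n <- length(x)
  if (n < 3) abort_invalid_argument("need at least 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort_gutmets("correlation undefined for a constant vector.",
                  "gutmets_undefined_correlation")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- max(2 * pt(-abs(tstat), n - 2), .Machine$double.xmin)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min over j with p_(j) >= p_(i) of (m * p_(j) / j)`, capped at 1.
#' Monotone and order-preserving.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values in the original order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort_invalid_argument("p-values must lie in (0, 1].")
  }
  m <- length(pvals)
  ord <- order(pvals, decreasing = TRUE)
  q_sorted <- cummin(m / seq(m, 1) * pvals[ord])
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' Cohort characteristics summary by gender
#'
#' A cohort-table style summary: per-gender counts and one-decimal
#' percentages for each diagnostic component and for MetS, age as
#' mean +/- SD with a Welch t test, and chi-square tests (no continuity
#' correction) for the component rates.
#'
#' @param cohort Tibble from [generate_cohort()] or any data frame with
#'   `gender`, `age` and the diagnostic columns.
#' @param thresholds,components_required Passed to [diagnose_mets()] when
#'   the component flags are not already present.
#' @return Tibble with one row per characteristic: `variable`, `female`,
#'   `male` (formatted values), `p` (NA when only one gender is present).
#' @export
cohort_summary <- function(cohort, thresholds = mets_thresholds(),
                           components_required = 3) {
  check_columns(cohort, c("gender", "age"), "cohort")
  if (!all(c("flag_waist", "flag_bp", "flag_tg", "flag_hdl", "flag_fbg",
             "mets") %in% names(cohort))) {
    cohort <- diagnose_mets(cohort, thresholds, components_required)
  }
  genders <- unique(cohort$gender)
  two_groups <- length(genders) == 2
  if (!two_groups) {
    warn("single-gender cohort: group comparisons omitted.")
  }
  f <- cohort[cohort$gender == "female", ]
  m <- cohort[cohort$gender == "male", ]
  fmt_group <- function(g, flag) {
    if (nrow(g) == 0) return(NA_character_)
    sprintf("%d (%s)", sum(g[[flag]]), format_prevalence(sum(g[[flag]]),
                                                         nrow(g)))
  }
  flags <- c(waist = "flag_waist", bp = "flag_bp", tg = "flag_tg",
             hdl = "flag_hdl", fbg = "flag_fbg", mets = "mets")
  rows <- purrr::map(names(flags), function(nm) {
    flag <- flags[[nm]]
    p <- NA_real_
    if (two_groups) {
      tab <- rbind(c(sum(f[[flag]]), nrow(f) - sum(f[[flag]])),
                   c(sum(m[[flag]]), nrow(m) - sum(m[[flag]])))
      p <- chi_square(t(tab))$p
    }
    tibble::tibble(variable = nm, female = fmt_group(f, flag),
                   male = fmt_group(m, flag), p = p)
  })
  age_fmt <- function(g) {
    if (nrow(g) == 0) return(NA_character_)
    sprintf("%.1f ± %.1f", round_half_up(mean(g$age), 1),
            round_half_up(sd(g$age), 1))
  }
  age_p <- if (two_groups) t.test(f$age, m$age)$p.value else NA_real_
  age_row <- tibble::tibble(variable = "age", female = age_fmt(f),
                            male = age_fmt(m), p = age_p)
  dplyr::bind_rows(age_row, rows)
}
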