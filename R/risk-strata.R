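# Economic-status, lifestyle and additive-risk analyses: spending-group
# MetS prevalence, spending-lifestyle correlations, and the 4x4
# MetS-index x sedentary-time risk grid.

#' Assign quartile labels
#'
#' Cuts at the empirical 25/50/75 percentiles (midpoint interpolation,
#' quantile type 2); ties at a cut point go to the lower quartile. Labels
#' are invariant under strictly monotone transforms of the values.
#'
#' @param values Numeric vector, `n >= 4`.
#' @return Integer labels 1..4.
#' @export
#' @examples
#' quartilize(1:8)
quartilize <- function(values) {
  if (length(values) < 4) {
    abort_invalid_argument("need at least 4 values to quartilize.")
  }
  cuts <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 2)
  if (cuts[1] == cuts[3]) {
    abort_gutmets("values are too tied to form quartiles.",
                  "gutmets_degenerate_input")
  }
  1L + rowSums(outer(values, cuts, ">"))
}

#' MetS prevalence by group with pairwise tests
#'
#' Per-group prevalence plus all pairwise 2x2 chi-square tests with
#' Benjamini-Hochberg adjustment. Empty groups are excluded with a warning.
#'
#' @param cohort Cohort tibble with `mets`.
#' @param groups Group labels aligned with the cohort rows.
#' @return List of class `gutmets_prevalence`: `groups` tibble (`group`,
#'   `n`, `n_mets`, `prevalence` in percent), `pairwise` tibble (`group1`,
#'   `group2`, `statistic`, `p`, `q`).
#' @export
prevalence_by_group <- function(cohort, groups) {
  check_columns(cohort, "mets", "cohort")
  groups <- as.factor(groups)
  if (length(groups) != nrow(cohort)) {
    abort_invalid_argument("`groups` must align with the cohort rows.")
  }
  tab <- table(groups)
  empty <- names(tab)[tab == 0]
  if (length(empty) > 0) {
    warn(sprintf("excluding empty group(s): %s", paste(empty, collapse = ", ")))
    groups <- droplevels(groups)
  }
  per_group <- tibble::tibble(
    group = levels(groups),
    n = as.integer(table(groups)),
    n_mets = as.integer(tapply(cohort$mets, groups, sum))
  )
  per_group$prevalence <- 100 * per_group$n_mets / per_group$n
  pairwise <- NULL
  if (nrow(per_group) >= 2) {
    pairs <- combn(per_group$group, 2)
    pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      g1 <- per_group[per_group$group == pairs[1, i], ]
      g2 <- per_group[per_group$group == pairs[2, i], ]
      ct <- rbind(c(g1$n_mets, g1$n - g1$n_mets),
                  c(g2$n_mets, g2$n - g2$n_mets))
      test <- chi_square(ct)
      tibble::tibble(group1 = pairs[1, i], group2 = pairs[2, i],
                     statistic = test$statistic, p = test$p)
    })
    pairwise$q <- bh_adjust(pairwise$p)
  }
  structure(list(groups = per_group, pairwise = pairwise),
            class = "gutmets_prevalence")
}

#' @export
print.gutmets_prevalence <- function(x, ...) {
  cat("MetS prevalence by group\n")
  print(x$groups)
  if (!is.null(x$pairwise)) {
    cat("Pairwise chi-square (BH adjusted):\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Spearman correlations of lifestyle variables with spending
#'
#' Correlates each lifestyle column with the target (yearly spending by
#' default), Benjamini-Hochberg adjusted across variables. Constant columns
#' are skipped with a warning.
#'
#' @param cohort Cohort tibble.
#' @param target Target column name.
#' @param variables Lifestyle columns to correlate.
#' @param fdr Significance level on the q-value.
#' @return Tibble with `variable`, `rho`, `p`, `q`, `significant`.
#' @export
lifestyle_correlations <- function(cohort, target = "spending",
                                   variables = c("sedentary", "diet_veg",
                                                 "diet_fruit", "diet_grain",
                                                 "diet_meat", "smoking"),
                                   fdr = 0.05) {
  check_columns(cohort, c(target, variables), "cohort")
  rows <- purrr::map(variables, function(v) {
    x <- as.numeric(cohort[[v]])
    if (sd(x) == 0) {
      warn(sprintf("variable %s is constant; skipped.", v))
      return(NULL)
    }
    res <- spearman_cor(x, cohort[[target]])
    tibble::tibble(variable = v, rho = res$rho, p = res$p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort_gutmets("no variable could be correlated.", "gutmets_empty_result")
  }
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= fdr
  out
}

#' Additive MetS-index x sedentary-time risk grid
#'
#' Quartilizes the MetS index and sedentary time, forming a 4x4 grid of
#' MetS prevalences, with pairwise chi-square q-values between all cell
#' pairs, optional per-spending-level occupancy grids (percent of each
#' spending level's population in each cell), and the corner contrast
#' (high-index/high-sedentary vs the single-high and low/low cells).
#'
#' @param index A `gutmets_index` tibble (or tibble with `sample_id`,
#'   `mets_index`).
#' @param cohort Cohort tibble with `sample_id`, `mets`, `sedentary` and
#'   (optionally) `spending_group`.
#' @return Object of class `gutmets_grid`: `cells` tibble (`index_q`,
#'   `sedentary_q`, `n`, `n_mets`, `prevalence`), `pairwise` tibble with BH
#'   q-values, `occupancy` tibble or NULL, `corners` list of the four
#'   corner prevalences.
#' @export
additive_risk_grid <- function(index, cohort) {
  check_columns(cohort, c("sample_id", "mets", "sedentary"), "cohort")
  merged <- dplyr::inner_join(tibble::as_tibble(index)[c("sample_id",
                                                         "mets_index")],
                              cohort, by = "sample_id")
  merged$index_q <- quartilize(merged$mets_index)
  merged$sedentary_q <- quartilize(merged$sedentary)

  cells <- merged |>
    dplyr::group_by(.data$index_q, .data$sedentary_q) |>
    dplyr::summarise(n = dplyr::n(), n_mets = sum(.data$mets),
                     .groups = "drop") |>
    tidyr::complete(index_q = 1:4, sedentary_q = 1:4,
                    fill = list(n = 0L, n_mets = 0L))
  cells$prevalence <- ifelse(cells$n > 0, 100 * cells$n_mets / cells$n,
                             NA_real_)
  cells$cell <- sprintf("i%d_s%d", cells$index_q, cells$sedentary_q)

  testable <- cells[cells$n > 0, ]
  pairwise <- NULL
  if (nrow(testable) >= 2) {
    pairs <- combn(testable$cell, 2)
    pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      c1 <- testable[testable$cell == pairs[1, i], ]
      c2 <- testable[testable$cell == pairs[2, i], ]
      ct <- rbind(c(c1$n_mets, c1$n - c1$n_mets),
                  c(c2$n_mets, c2$n - c2$n_mets))
      ok <- all(rowSums(ct) > 0) && all(colSums(ct) > 0)
      tibble::tibble(cell1 = pairs[1, i], cell2 = pairs[2, i],
                     statistic = if (ok) chi_square(ct)$statistic else NA_real_,
                     p = if (ok) chi_square(ct)$p else NA_real_)
    })
    tested <- !is.na(pairwise$p)
    pairwise$q <- NA_real_
    if (any(tested)) pairwise$q[tested] <- bh_adjust(pairwise$p[tested])
  }

  occupancy <- NULL
  if ("spending_group" %in% names(cohort)) {
    occupancy <- merged |>
      dplyr::group_by(.data$spending_group, .data$index_q,
                      .data$sedentary_q) |>
      dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
      dplyr::group_by(.data$spending_group) |>
      dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }

  corner <- function(iq, sq) {
    cells$prevalence[cells$index_q == iq & cells$sedentary_q == sq]
  }
  corners <- list(high_high = corner(4, 4), high_index_low_sed = corner(4, 1),
                  low_index_high_sed = corner(1, 4), low_low = corner(1, 1))
  structure(list(cells = cells, pairwise = pairwise, occupancy = occupancy,
                 corners = corners, data = merged),
            class = "gutmets_grid")
}

#' @export
print.gutmets_grid <- function(x, ...) {
  cat("MetS prevalence (%) by index quartile (rows) x sedentary quartile (columns):\n")
  m <- matrix(NA_real_, 4, 4, dimnames = list(paste0("i", 1:4),
                                              paste0("s", 1:4)))
  m[cbind(x$cells$index_q, x$cells$sedentary_q)] <- x$cells$prevalence
  print(round(m, 1))
  cat(sprintf("corner contrast: high/high %.1f%% vs low/low %.1f%%\n",
              x$corners$high_high, x$corners$low_low))
  invisible(x)
}

#' @export
tidy.gutmets_grid <- function(x, ...) x$cells

#' @export
glance.gutmets_grid <- function(x, ...) {
  tibble::tibble(high_high = x$corners$high_high,
                 high_index_low_sed = x$corners$high_index_low_sed,
                 low_index_high_sed = x$corners$low_index_high_sed,
                 low_low = x$corners$low_low,
                 n = sum(x$cells$n))
}

#' Plot the additive risk grid
#'
#' Tile plot of MetS prevalence over the 16 index x sedentary cells.
#'
#' @param object A `gutmets_grid` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gutmets_grid <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$index_q, y = .data$sedentary_q,
                               fill = .data$prevalence)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$prevalence), "-",
                     sprintf("%.1f", .data$prevalence)))) +
    ggplot2::scale_fill_gradient(low = "#fee8c8", high = "#e34a33",
                                 na.value = "grey90") +
    ggplot2::labs(x = "MetS index quartile", y = "sedentary time quartile",
                  fill = "MetS %") +
    ggplot2::theme_minimal()
}
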