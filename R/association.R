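# Confounder-adjusted per-OTU association modelling (MaAsLin-style additive
# linear models on arcsine-square-root transformed relative abundances) and
# the directional taxon network summarisation.

#' Filter OTUs by prevalence
#'
#' Keeps OTUs detected (non-zero count) in at least
#' `ceiling(min_prevalence * n_samples)` samples; the boundary is inclusive
#' ("at least 10% of all samples").
#'
#' @param table A `gutmets_otu` table.
#' @param min_prevalence Fraction in (0, 1].
#' @return The filtered `gutmets_otu` table.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.10) {
  if (min_prevalence <= 0 || min_prevalence > 1) {
    abort_invalid_argument("`min_prevalence` must lie in (0, 1].")
  }
  n <- nrow(table$counts)
  need <- ceiling(min_prevalence * n)
  present <- colSums(table$counts > 0)
  keep <- present >= need
  if (!any(keep)) {
    abort_gutmets("prevalence filter removed every OTU.",
                  "gutmets_empty_result")
  }
  subset_otu(table, otus = colnames(table$counts)[keep])
}

#' Arcsine-square-root transform of relative abundances
#'
#' `y = asin(sqrt(p))` per cell, the variance-stabilising transform used by
#' MaAsLin-style linear models; values lie in \[0, pi/2\].
#'
#' @param table A `gutmets_otu` table (rarefied) or a row-stochastic matrix.
#' @return Numeric matrix of transformed abundances.
#' @export
transform_abundance <- function(table) {
  p <- if (inherits(table, "gutmets_otu")) relative_abundance(table) else
    as.matrix(table)
  asin(sqrt(p))
}

# Componentwise least-squares boosting screen: which covariates are ever
# selected in `iters` steps of step-size `step`?
boosting_screen <- function(y, X, iters = 100, step = 0.1) {
  Xs <- scale(X)
  Xs[is.na(Xs)] <- 0
  r <- y - mean(y)
  selected <- logical(ncol(X))
  ssx <- colSums(Xs^2)
  ssx[ssx == 0] <- 1
  for (it in seq_len(iters)) {
    scores <- abs(crossprod(Xs, r)) / sqrt(ssx)
    j <- which.max(scores)
    b <- sum(Xs[, j] * r) / ssx[j]
    r <- r - step * b * Xs[, j]
    selected[j] <- TRUE
  }
  selected
}

#' Fit per-OTU factor associations with confounder adjustment
#'
#' For every (OTU, factor) pair, fits the additive linear model
#' `y ~ factor + confounders` on the transformed abundance `y` and records
#' the factor coefficient (beta), its two-sided p-value and the
#' Benjamini-Hochberg q-value (adjusted per factor across OTUs by default).
#' Continuous covariates are standardized; geographic region enters as
#' fixed-effect dummies; rank-deficient designs drop aliased covariates
#' with a warning. `selection = "boosted"` first screens the confounders
#' per OTU by componentwise least-squares boosting (100 iterations, step
#' 0.1) and drops never-selected ones; the factor itself is always kept.
#'
#' @param table A `gutmets_otu` table, already prevalence-filtered and
#'   rarefied.
#' @param cohort Cohort tibble with `sample_id`, the factors and the
#'   confounders.
#' @param factors Factors to test (subset of waist, sbp, dbp, tg, hdl, fbg,
#'   mets, income, spending). Diagnostic factors can be modelled as the
#'   binary component flags (default, as diagnostic tables present them) or
#'   continuously via `factor_coding`.
#' @param confounders Confounder columns (default age, gender, region,
#'   Bristol scale).
#' @param selection `"none"` (default: the confounder set is small and
#'   forced) or `"boosted"`.
#' @param fdr Significance level on the q-value.
#' @param factor_coding `"flags"` codes diagnostic factors as their
#'   component flags; `"continuous"` uses the standardized measurements.
#' @param bh_family `"per_factor"` (default) or `"global"` q-value family.
#' @param min_n Minimum complete cases beyond the covariate count.
#' @return Tibble of class `gutmets_associations`: `otu_id`, `taxonomy`,
#'   `factor`, `beta`, `p`, `q`, `n_used`, `direction`, `significant`.
#' @export
fit_associations <- function(table, cohort,
                             factors = c("mets", "waist", "sbp", "dbp",
                                         "tg", "hdl", "fbg"),
                             confounders = c("age", "gender", "region",
                                             "bristol"),
                             selection = c("none", "boosted"),
                             fdr = 0.05,
                             factor_coding = c("flags", "continuous"),
                             bh_family = c("per_factor", "global"),
                             min_n = 10) {
  selection <- match.arg(selection)
  factor_coding <- match.arg(factor_coding)
  bh_family <- match.arg(bh_family)
  bad <- setdiff(factors, MODEL_FACTORS)
  if (length(bad) > 0) {
    abort_invalid_config(sprintf("unknown factor(s): %s.",
                                 paste(bad, collapse = ", ")))
  }
  check_columns(cohort, c("sample_id", confounders), "cohort")
  common <- intersect(rownames(table$counts), cohort$sample_id)
  if (length(common) < min_n) {
    abort_invalid_argument("too few samples shared by table and cohort.")
  }
  cohort <- cohort[match(common, cohort$sample_id), ]
  y_mat <- transform_abundance(subset_otu(table, samples = common))

  factor_value <- function(f) {
    if (factor_coding == "flags" &&
        f %in% c("waist", "sbp", "dbp", "tg", "hdl", "fbg")) {
      thr <- mets_thresholds()
      x <- switch(f,
        waist = cohort$waist >= ifelse(cohort$gender == "male",
                                       thr$waist_male, thr$waist_female),
        sbp = cohort$sbp >= thr$sbp,
        dbp = cohort$dbp >= thr$dbp,
        tg = cohort$tg >= thr$tg,
        # Oriented by HDL level (adequate HDL) so the modelled sign keeps
        # the measurement's valence; the disorder flip happens downstream.
        hdl = cohort$hdl >= thr$hdl,
        fbg = cohort$fbg >= thr$fbg)
      return(standardize(as.numeric(x)))
    }
    x <- cohort[[f]]
    if (f %in% c("income", "spending")) x <- log(x)
    standardize(as.numeric(x))
  }

  confounder_matrix <- function() {
    cols <- list()
    for (cf in confounders) {
      x <- cohort[[cf]]
      if (is.character(x) || is.factor(x) || is.logical(x)) {
        x <- as.factor(x)
        if (nlevels(x) > 1) {
          mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
          colnames(mm) <- paste0(cf, seq_len(ncol(mm)))
          cols[[cf]] <- mm
        }
      } else {
        cols[[cf]] <- matrix(standardize(x), ncol = 1,
                             dimnames = list(NULL, cf))
      }
    }
    do.call(cbind, cols)
  }
  conf_mat <- confounder_matrix()

  fit_factor <- function(f) {
    check_columns(cohort, f, "cohort")
    xf <- factor_value(f)
    X <- cbind(`(Intercept)` = 1, factor = xf, conf_mat)
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      keep <- qr_x$pivot[seq_len(qr_x$rank)]
      dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
      warn(sprintf("dropping aliased covariate(s): %s",
                   paste(dropped, collapse = ", ")))
      X <- X[, keep, drop = FALSE]
      qr_x <- qr(X)
    }
    n <- nrow(X)
    p_cov <- ncol(X)
    if (n < min_n + p_cov) {
      warn(sprintf("factor %s: too few samples for the design; skipped.", f))
      return(NULL)
    }
    if (selection == "none") {
      betas <- qr.coef(qr_x, y_mat)
      resid <- qr.resid(qr_x, y_mat)
      sigma2 <- colSums(resid^2) / (n - p_cov)
      xtx_inv <- chol2inv(chol(crossprod(X)))
      j <- which(colnames(X) == "factor")
      se <- sqrt(sigma2 * xtx_inv[j, j])
      beta <- unname(betas[j, ])
      tstat <- beta / se
      pvals <- 2 * pt(-abs(tstat), n - p_cov)
      # Constant (e.g. all-zero) responses carry no evidence either way.
      pvals[!is.finite(pvals)] <- 1
      tibble::tibble(otu_id = colnames(y_mat), factor = f, beta = beta,
                     p = unname(pmax(pvals, .Machine$double.xmin)), n_used = n)
    } else {
      purrr::map_dfr(seq_len(ncol(y_mat)), function(k) {
        y <- y_mat[, k]
        covs <- X[, setdiff(colnames(X), c("(Intercept)", "factor")),
                  drop = FALSE]
        kept <- if (ncol(covs) > 0) boosting_screen(y, cbind(xf, covs))[-1]
        else logical(0)
        Xk <- cbind(1, xf, covs[, kept, drop = FALSE])
        fit <- stats::lm.fit(Xk, y)
        res <- fit$residuals
        dfree <- n - fit$rank
        sigma2 <- sum(res^2) / dfree
        xtx_inv <- chol2inv(chol(crossprod(Xk)))
        se <- sqrt(sigma2 * xtx_inv[2, 2])
        beta <- unname(fit$coefficients[2])
        pval <- 2 * pt(-abs(beta / se), dfree)
        if (!is.finite(pval)) pval <- 1
        tibble::tibble(otu_id = colnames(y_mat)[k], factor = f, beta = beta,
                       p = max(pval, .Machine$double.xmin), n_used = n)
      })
    }
  }

  records <- purrr::map_dfr(factors, fit_factor)
  if (nrow(records) == 0) {
    abort_gutmets("no associations could be fitted.", "gutmets_empty_result")
  }
  if (bh_family == "per_factor") {
    records <- records |>
      dplyr::group_by(.data$factor) |>
      dplyr::mutate(q = bh_adjust(.data$p)) |>
      dplyr::ungroup()
  } else {
    records$q <- bh_adjust(records$p)
  }
  records$direction <- ifelse(records$beta >= 0, 1, -1)
  records$significant <- records$q <= fdr
  records <- dplyr::left_join(records, table$taxonomy, by = "otu_id")
  records <- records[, c("otu_id", "taxonomy", "factor", "beta", "p", "q",
                         "n_used", "direction", "significant")]
  class(records) <- c("gutmets_associations", class(records))
  attr(records, "fdr") <- fdr
  records
}

#' Directional taxon network summary
#'
#' Counts significant associations by taxon (at a chosen rank) and by
#' factor. Raw per-factor counts keep the modelled sign; in the
#' valence-adjusted (disorder) totals, HDL associations are rescored with
#' the opposite valence, since low HDL is the disorder.
#'
#' @param records A `gutmets_associations` tibble (or any tibble with
#'   `otu_id`, `taxonomy`, `factor`, `direction`, `significant`/`q`).
#' @param rank Taxonomic rank for the per-taxon summary.
#' @param q_threshold Used when a `significant` column is absent.
#' @return Object of class `gutmets_network`: `per_factor` (raw signs),
#'   `per_taxon` (valence-adjusted), `totals` (list with `n_associations`,
#'   `n_negative`, `n_positive`, valence-adjusted).
#' @export
summarize_network <- function(records, rank = "phylum", q_threshold = 0.05) {
  records <- tibble::as_tibble(records)
  if (!"significant" %in% names(records)) {
    records$significant <- records$q <= q_threshold
  }
  sig <- records[records$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    empty <- tibble::tibble(taxon = character(), n_negative = integer(),
                            n_positive = integer(), n_total = integer())
    return(structure(
      list(per_factor = tibble::tibble(factor = character(),
                                       n_negative = integer(),
                                       n_positive = integer()),
           per_taxon = empty,
           totals = list(n_associations = 0L, n_negative = 0L,
                         n_positive = 0L), rank = rank),
      class = "gutmets_network"))
  }
  tax <- sig$taxonomy
  tax[is.na(tax)] <- ""
  sig$taxon <- taxon_at_rank(tax, rank)
  # Disorder valence: flip HDL so that "positive" always means
  # disorder-enriched.
  sig$valence <- ifelse(sig$factor == "hdl", -sig$direction, sig$direction)

  per_factor <- sig |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(n_negative = sum(.data$direction < 0),
                     n_positive = sum(.data$direction > 0),
                     .groups = "drop")
  per_taxon <- sig |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(n_negative = sum(.data$valence < 0),
                     n_positive = sum(.data$valence > 0),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_total))
  totals <- list(n_associations = nrow(sig),
                 n_negative = sum(sig$valence < 0),
                 n_positive = sum(sig$valence > 0))
  structure(list(per_factor = per_factor, per_taxon = per_taxon,
                 totals = totals, rank = rank),
            class = "gutmets_network")
}

#' @export
print.gutmets_network <- function(x, ...) {
  cat(sprintf(
    "Association network summary: %d associations (%d- / %d+ after HDL valence flip)\n",
    x$totals$n_associations, x$totals$n_negative, x$totals$n_positive))
  cat("Per factor (raw modelled sign):\n")
  print(x$per_factor)
  cat(sprintf("Per %s (disorder valence):\n", x$rank))
  print(x$per_taxon)
  invisible(x)
}

#' Plot a directional network summary
#'
#' Stacked bars of negative/positive association counts per taxon.
#'
#' @param object A `gutmets_network` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gutmets_network <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_taxon,
                              c("n_negative", "n_positive"),
                              names_to = "direction", values_to = "n")
  long$direction <- ifelse(long$direction == "n_negative",
                           "negative", "positive")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$taxon, -.data$n),
                                     y = .data$n, fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(negative = "#4575b4",
                                          positive = "#d73027")) +
    ggplot2::labs(x = object$rank, y = "significant associations",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
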