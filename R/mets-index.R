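# The gut microbial MetS index: accumulated relative abundance of
# MetS-associated OTUs weighted by their coefficients and significance,
# standardized across samples; plus its stratified validation and the
# index-economics correlation.

#' Compute the gut microbial MetS index
#'
#' Per-OTU weights default to `w_i = sign(beta_i) |beta_i| (-log10 q_i)`
#' over the significant records of the MetS-related factors (HDL valence
#' flipped so positive always means disorder-enriched); OTUs significant
#' for several factors contribute once, with their weights summed. The
#' per-sample score is `I_s = sum_i r_si w_i` over relative abundances,
#' standardized to mean 0 and SD 1 across samples.
#'
#' @param table A rarefied `gutmets_otu` table.
#' @param records Association records from [fit_associations()].
#' @param factor_set Factors counted as MetS-associated.
#' @param q_threshold Used when `records` has no `significant` column.
#' @param weight_mode `"beta_logq"` (default), `"beta"` (|beta| only) or
#'   `"logq"` (significance only).
#' @param flip_hdl Flip the sign of HDL records when accumulating weights.
#' @param standardize_index Standardize the score across samples.
#' @return Object of class `gutmets_index`: a tibble with `sample_id` and
#'   `mets_index`, carrying the per-OTU weights as attribute `"weights"`.
#' @export
compute_mets_index <- function(table, records,
                               factor_set = c("mets", "waist", "sbp", "dbp",
                                              "tg", "hdl", "fbg"),
                               q_threshold = 0.05,
                               weight_mode = c("beta_logq", "beta", "logq"),
                               flip_hdl = TRUE,
                               standardize_index = TRUE) {
  weight_mode <- match.arg(weight_mode)
  records <- tibble::as_tibble(records)
  check_columns(records, c("otu_id", "factor", "beta", "q"), "records")
  if (!"significant" %in% names(records)) {
    records$significant <- records$q <= q_threshold
  }
  rel <- records[records$significant & records$factor %in% factor_set, ,
                 drop = FALSE]
  if (nrow(rel) == 0) {
    abort_gutmets("no significant MetS-associated records; index undefined.",
                  "gutmets_empty_index")
  }
  sign_beta <- ifelse(rel$beta >= 0, 1, -1)
  if (flip_hdl) {
    sign_beta <- ifelse(rel$factor == "hdl", -sign_beta, sign_beta)
  }
  contribution <- switch(weight_mode,
    beta_logq = sign_beta * abs(rel$beta) * (-log10(rel$q)),
    beta = sign_beta * abs(rel$beta),
    logq = sign_beta * (-log10(rel$q)))
  weights <- tapply(contribution, rel$otu_id, sum)
  w <- tibble::tibble(otu_id = names(weights), weight = as.numeric(weights))

  present <- intersect(w$otu_id, colnames(table$counts))
  if (length(present) == 0) {
    abort_gutmets("no weighted OTU appears in the table; index undefined.",
                  "gutmets_empty_index")
  }
  r <- relative_abundance(table)[, present, drop = FALSE]
  score <- as.numeric(r %*% w$weight[match(colnames(r), w$otu_id)])
  raw <- score
  if (standardize_index) {
    s <- sd(score)
    score <- if (s > 0) (score - mean(score)) / s else score - mean(score)
  }
  out <- tibble::tibble(sample_id = rownames(table$counts),
                        mets_index = score, raw_index = raw)
  class(out) <- c("gutmets_index", class(out))
  attr(out, "weights") <- w
  attr(out, "weight_mode") <- weight_mode
  out
}

#' @export
tidy.gutmets_index <- function(x, ...) attr(x, "weights")

#' @export
glance.gutmets_index <- function(x, ...) {
  w <- attr(x, "weights")
  tibble::tibble(n_samples = nrow(x), n_otus = nrow(w),
                 n_positive_weights = sum(w$weight > 0),
                 n_negative_weights = sum(w$weight < 0),
                 weight_mode = attr(x, "weight_mode"))
}

#' Validate the MetS index within strata
#'
#' Within each level of a stratifying variable (spending group, region,
#' ...), compares the index between MetS and non-MetS subjects with the
#' Wilcoxon rank-sum test; p-values are Benjamini-Hochberg adjusted across
#' strata. Strata containing only one MetS class are skipped and reported.
#'
#' @param index A `gutmets_index` tibble (or tibble with `sample_id`,
#'   `mets_index`).
#' @param cohort Cohort tibble with `sample_id`, `mets` and the strata
#'   variable.
#' @param strata Name of the stratifying column.
#' @return Tibble with one row per stratum: medians by MetS status,
#'   `statistic`, `p`, `q`, `skipped`.
#' @export
stratified_validation <- function(index, cohort, strata = "spending_group") {
  check_columns(cohort, c("sample_id", "mets", strata), "cohort")
  merged <- dplyr::inner_join(tibble::as_tibble(index)[c("sample_id",
                                                         "mets_index")],
                              cohort[c("sample_id", "mets", strata)],
                              by = "sample_id")
  levels_ <- unique(as.character(merged[[strata]]))
  rows <- purrr::map(levels_, function(lev) {
    sub <- merged[as.character(merged[[strata]]) == lev, ]
    a <- sub$mets_index[sub$mets]
    b <- sub$mets_index[!sub$mets]
    if (length(a) == 0 || length(b) == 0) {
      warn(sprintf("stratum %s has a single MetS class; skipped.", lev))
      return(tibble::tibble(stratum = lev, n_mets = length(a),
                            n_non_mets = length(b),
                            median_mets = NA_real_,
                            median_non_mets = NA_real_,
                            statistic = NA_real_, p = NA_real_,
                            skipped = TRUE))
    }
    test <- wilcoxon_rank_sum(a, b)
    tibble::tibble(stratum = lev, n_mets = length(a),
                   n_non_mets = length(b),
                   median_mets = median(a), median_non_mets = median(b),
                   statistic = test$statistic, p = test$p, skipped = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- NA_real_
  tested <- !out$skipped
  if (any(tested)) out$q[tested] <- bh_adjust(out$p[tested])
  out
}

#' Correlate the MetS index with economic status
#'
#' Spearman correlation between the index and yearly spending, within
#' non-MetS subjects (default), MetS subjects, or the whole cohort.
#'
#' @param index A `gutmets_index` tibble.
#' @param cohort Cohort tibble with `sample_id`, `mets`, `spending`.
#' @param subset `"non_mets"`, `"mets"` or `"all"`.
#' @return One-row tibble: `subset`, `rho`, `p`, `n`.
#' @export
index_vs_economics <- function(index, cohort,
                               subset = c("non_mets", "mets", "all")) {
  subset <- match.arg(subset)
  check_columns(cohort, c("sample_id", "mets", "spending"), "cohort")
  merged <- dplyr::inner_join(tibble::as_tibble(index)[c("sample_id",
                                                         "mets_index")],
                              cohort[c("sample_id", "mets", "spending")],
                              by = "sample_id")
  merged <- switch(subset,
                   non_mets = merged[!merged$mets, ],
                   mets = merged[merged$mets, ],
                   all = merged)
  if (nrow(merged) < 3) {
    abort_invalid_argument("subset has fewer than 3 samples.")
  }
  res <- spearman_cor(merged$mets_index, merged$spending)
  tibble::tibble(subset = subset, rho = res$rho, p = res$p, n = res$n)
}

#' Plot the MetS index by MetS status across strata
#'
#' @param object A `gutmets_index` object.
#' @param cohort Cohort tibble with `sample_id`, `mets` and (optionally)
#'   the strata column.
#' @param strata Optional stratifying column name.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gutmets_index <- function(object, cohort, strata = NULL, ...) {
  merged <- dplyr::inner_join(tibble::as_tibble(object),
                              cohort, by = "sample_id")
  merged$status <- ifelse(merged$mets, "MetS", "non-MetS")
  p <- ggplot2::ggplot(merged, ggplot2::aes(x = .data$status,
                                            y = .data$mets_index,
                                            fill = .data$status)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::scale_fill_manual(values = c("MetS" = "#d73027",
                                          "non-MetS" = "#4575b4")) +
    ggplot2::labs(x = NULL, y = "microbial MetS index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(strata)) {
    p <- p + ggplot2::facet_wrap(strata)
  }
  p
}
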