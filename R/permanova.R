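# Permutational multivariate ANOVA (Anderson's pseudo-F on a distance
# matrix) and the subsample significance-saturation procedure: at each
# subsample size, repeated stratified subsamples are tested and the
# smallest size at which every replicate is significant is reported.

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance. The total
#' sum of squared distances is partitioned into within- and between-group
#' parts (`SS_T = sum d_ij^2 / n` over all pairs, `SS_W = sum over groups of
#' within-pair d^2 / n_g`), giving
#' `pseudo-F = (SS_A / (a - 1)) / (SS_W / (n - a))`. Significance comes from
#' label permutations with the add-one correction
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' @param dist A [stats::dist] object or square symmetric matrix.
#' @param groups Group labels aligned with the distance matrix (>= 2 groups,
#'   each with >= 2 members).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @return Object of class `gutmets_permanova` with elements `pseudo_F`,
#'   `p`, `n_permutations`, `n_samples`, `n_groups`, `ss_between`,
#'   `ss_within`, `ss_total`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d)) {
    abort_gutmets("distance matrix must be square.", "gutmets_shape_error")
  }
  n <- nrow(d)
  groups <- as.factor(groups)
  if (length(groups) != n) {
    abort_gutmets("`groups` must align with the distance matrix.",
                  "gutmets_shape_error")
  }
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort_invalid_argument(
      "need >= 2 groups with >= 2 members each (singleton group found).")
  }
  n_perm <- check_scalar_int(n_perm, "n_perm", min = 1)
  d2 <- d^2
  a <- length(sizes)

  ss_total <- sum(d2) / (2 * n)
  within_ss <- function(membership) {
    # membership: n x B 0/1 matrix per group level; within-pair sum via
    # x' D2 x / 2 for each column.
    ss <- 0
    for (lev in levels(groups)) {
      x <- membership[[lev]]
      ss <- ss + colSums(x * (d2 %*% x)) / (2 * sizes[[lev]])
    }
    ss
  }
  obs_membership <- lapply(levels(groups), function(lev) {
    matrix(as.numeric(groups == lev), n, 1)
  })
  names(obs_membership) <- levels(groups)
  ss_within_obs <- within_ss(obs_membership)[1]
  f_of <- function(ssw) ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  f_obs <- f_of(ss_within_obs)

  perms <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
  })
  perm_membership <- lapply(levels(groups), function(lev) {
    base <- as.numeric(groups == lev)
    matrix(base[perms], n, n_perm)
  })
  names(perm_membership) <- levels(groups)
  f_perm <- f_of(within_ss(perm_membership))
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)

  structure(
    list(pseudo_F = f_obs, p = p, n_permutations = n_perm, n_samples = n,
         n_groups = a, ss_between = ss_total - ss_within_obs,
         ss_within = ss_within_obs, ss_total = ss_total),
    class = "gutmets_permanova")
}

#' @export
print.gutmets_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4f, p = %.4g (%d permutations, n = %d, %d groups)\n",
    x$pseudo_F, x$p, x$n_permutations, x$n_samples, x$n_groups))
  invisible(x)
}

#' @export
tidy.gutmets_permanova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within", "total"),
    sum_of_squares = c(x$ss_between, x$ss_within, x$ss_total),
    df = c(x$n_groups - 1, x$n_samples - x$n_groups, x$n_samples - 1),
    statistic = c(x$pseudo_F, NA, NA),
    p.value = c(x$p, NA, NA)
  )
}

#' @export
glance.gutmets_permanova <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, p.value = x$p,
                 n_permutations = x$n_permutations, n = x$n_samples,
                 log10_inv_p = log10(1 / x$p))
}

# Stratified subsample of indices preserving group proportions (largest
# remainder apportionment); retries when a group would lose all members.
stratified_subsample <- function(groups, size, max_tries = 10) {
  n <- length(groups)
  levs <- levels(groups)
  props <- table(groups) / n
  quota <- floor(props * size)
  rem <- size - sum(quota)
  if (rem > 0) {
    frac <- props * size - quota
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    quota[bump] <- quota[bump] + 1
  }
  for (try in seq_len(max_tries)) {
    if (all(quota[props > 0] >= 2)) break
    # Degenerate apportionment: force two members per non-empty group.
    quota[props > 0 & quota < 2] <- 2
    over <- sum(quota) - size
    if (over > 0) {
      donor <- which.max(quota)
      quota[donor] <- quota[donor] - over
    }
  }
  if (any(quota[props > 0] < 2)) {
    abort_invalid_argument("subsample too small to retain every group.")
  }
  idx <- unlist(lapply(levs, function(lev) {
    members <- which(groups == lev)
    sample(members, quota[[lev]])
  }))
  sort(idx)
}

#' Subsample-size significance saturation curve
#'
#' For each subsample size, draws stratified random subsamples (preserving
#' the group ratio), slices the precomputed distance matrix, reruns the
#' PERMANOVA and records the p-value. Reports all replicate p-values, the
#' per-size fraction significant at `alpha`, and the smallest size at which
#' every replicate satisfies `p <= alpha` (the saturation size).
#'
#' @param x A `gutmets_otu` table (Bray-Curtis distances are computed once)
#'   or a precomputed [stats::dist]/matrix.
#' @param groups Per-sample labels aligned with `x`.
#' @param sizes Strictly increasing subsample sizes, `max(sizes) <= n`.
#' @param replicates Subsamples per size.
#' @param alpha Significance level (0.05 reproduces the usual p = 0.05
#'   reference line).
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return Object of class `gutmets_saturation`: `draws` (tibble of size,
#'   replicate, pseudo_F, p), `summary` (per-size fraction significant),
#'   `saturation_size` (NA when not reached), `alpha`.
#' @export
saturation_curve <- function(x, groups, sizes, replicates = 50,
                             alpha = 0.05, n_perm = 999, seed = 1) {
  d <- if (inherits(x, "gutmets_otu")) as.matrix(bray_curtis(x)) else as.matrix(x)
  groups <- as.factor(groups)
  n <- nrow(d)
  if (length(groups) != n) {
    abort_gutmets("`groups` must align with the samples.",
                  "gutmets_shape_error")
  }
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0)) {
    abort_invalid_argument("`sizes` must be strictly increasing.")
  }
  if (max(sizes) > n) {
    abort_invalid_argument("`sizes` cannot exceed the number of samples.")
  }
  replicates <- check_scalar_int(replicates, "replicates", min = 1)

  draws <- with_seed_(seed, {
    purrr::map_dfr(sizes, function(size) {
      purrr::map_dfr(seq_len(replicates), function(rep) {
        idx <- if (size == n) seq_len(n) else stratified_subsample(groups, size)
        fit <- permanova(d[idx, idx], droplevels(groups[idx]),
                         n_perm = n_perm,
                         seed = sample.int(2^30, 1))
        tibble::tibble(size = size, replicate = rep,
                       pseudo_F = fit$pseudo_F, p = fit$p)
      })
    })
  })
  summary <- draws |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(frac_significant = mean(.data$p <= alpha),
                     min_log10_inv_p = min(log10(1 / .data$p)),
                     .groups = "drop")
  saturated <- summary$size[summary$frac_significant == 1]
  structure(
    list(draws = draws, summary = summary,
         saturation_size = if (length(saturated) > 0) min(saturated) else
           NA_integer_,
         alpha = alpha),
    class = "gutmets_saturation")
}

#' @export
print.gutmets_saturation <- function(x, ...) {
  cat("Significance saturation curve\n")
  print(x$summary)
  if (is.na(x$saturation_size)) {
    cat(sprintf("saturation at alpha = %g: not reached\n", x$alpha))
  } else {
    cat(sprintf("saturation at alpha = %g: %d samples\n", x$alpha,
                x$saturation_size))
  }
  invisible(x)
}

#' @export
tidy.gutmets_saturation <- function(x, ...) x$draws

#' @export
glance.gutmets_saturation <- function(x, ...) {
  tibble::tibble(saturation_size = x$saturation_size, alpha = x$alpha,
                 n_sizes = nrow(x$summary))
}

#' Plot a saturation curve
#'
#' Replicate significance (`log10(1/p)`) against subsample size with the
#' `p = alpha` reference line.
#'
#' @param object A `gutmets_saturation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gutmets_saturation <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$size, y = log10(1 / .data$p))) +
    ggplot2::geom_jitter(width = 0.02, height = 0, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = log10(1 / object$alpha),
                        colour = "red", linetype = 2) +
    ggplot2::scale_x_continuous(trans = "log10") +
    ggplot2::labs(x = "subsample size",
                  y = expression(log[10](1 / p)),
                  title = "PERMANOVA significance saturation") +
    ggplot2::theme_minimal()
}
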