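# Internal helpers shared across modules.

abort_gutmets <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "gutmets_error"), ...)
}

abort_invalid_argument <- function(message, ...) {
  abort_gutmets(message, "gutmets_invalid_argument", ...)
}

abort_invalid_config <- function(message, ...) {
  abort_gutmets(message, "gutmets_invalid_config", ...)
}

abort_missing_data <- function(message, field = NULL, ...) {
  abort_gutmets(message, "gutmets_missing_data", field = field, ...)
}

abort_format <- function(message, ...) {
  abort_gutmets(message, "gutmets_format_error", ...)
}

check_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x)) {
    abort_invalid_argument(sprintf("`%s` must be a single integer.", name))
  }
  if (!is.null(min) && x < min) {
    abort_invalid_argument(sprintf("`%s` must be >= %s (got %s).", name, min, x))
  }
  as.integer(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_missing_data(
      sprintf("%s is missing required column(s): %s.", what,
              paste(missing, collapse = ", ")),
      field = missing
    )
  }
  invisible(data)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed_ <- function(seed, expr) {
  seed <- check_scalar_int(seed, "seed")
  withr::with_seed(seed, expr)
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically expands one master seed into per-stage seeds (kept
#' below 2^31) so that each pipeline stage is independently reproducible.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (any string).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "cohort")
derive_seed <- function(seed, stage) {
  seed <- check_scalar_int(seed, "seed")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483587L) + 1L
}

# Round half away from zero at `digits` decimals (Table-1 style percentages).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a count as a one-decimal percentage
#'
#' Percentages are rounded half away from zero and printed with exactly one
#' decimal, the convention used in epidemiological cohort tables
#' (e.g. 657 of 3803 prints as "17.3").
#'
#' @param n Numerator count (vectorised).
#' @param total Denominator count.
#' @return Character vector of formatted percentages.
#' @export
#' @examples
#' format_prevalence(657, 3803)
#' format_prevalence(1404, 6896)
format_prevalence <- function(n, total) {
  if (any(total <= 0)) abort_invalid_argument("`total` must be positive.")
  sprintf("%.1f", round_half_up(100 * n / total, 1))
}

standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

# Truncated normal by rejection-free clamping of the quantile draw.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) abort_invalid_config("standard deviations must be non-negative.")
  if (sd == 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  stats::qnorm(runif(n, lo, hi), mean, sd)
}

format_num6 <- function(x) {
  # Deterministic 6-significant-digit serialisation, "." decimal.
  formatC(signif(x, 6), format = "g", digits = 6)
}
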