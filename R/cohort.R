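# Synthetic cohort generation: metabolic-syndrome diagnostics, demographics,
# economic status and lifestyle, with a shared latent metabolic-risk factor
# so that downstream de-confounding and risk stratification are exercised.

#' Metabolic syndrome diagnostic thresholds
#'
#' The five component cut-offs used for diagnosis: central obesity
#' (waist >= 90 cm in men, >= 85 cm in women), elevated blood pressure
#' (SBP >= 130 or DBP >= 85 mmHg), elevated triglycerides (>= 1.7 mmol/L),
#' low HDL cholesterol (< 1.04 mmol/L) and elevated fasting blood glucose
#' (>= 6.1 mmol/L). All thresholds are inclusive except HDL, which is strict.
#'
#' @param waist_male,waist_female Waist circumference cut-offs (cm).
#' @param sbp,dbp Systolic/diastolic blood pressure cut-offs (mmHg).
#' @param tg Triglyceride cut-off (mmol/L).
#' @param hdl HDL cut-off (mmol/L); values strictly below flag the component.
#' @param fbg Fasting blood glucose cut-off (mmol/L).
#' @return A named list of thresholds.
#' @export
mets_thresholds <- function(waist_male = 90, waist_female = 85,
                            sbp = 130, dbp = 85,
                            tg = 1.7, hdl = 1.04, fbg = 6.1) {
  list(waist_male = waist_male, waist_female = waist_female,
       sbp = sbp, dbp = dbp, tg = tg, hdl = hdl, fbg = fbg)
}

#' Cohort generator configuration
#'
#' Marginal distributions and couplings for [generate_cohort()]. Diagnostic
#' means/SDs are chosen so that, combined with the shared metabolic-risk
#' loading, the five component rates and the ~20% MetS prevalence of a
#' southern-Chinese adult population are reproduced. Spending and sedentary
#' time are coupled through a Gaussian copula; diet variables are coupled to
#' spending with configurable rank correlations.
#'
#' @param p_female Probability that a sample is female.
#' @param age_mean,age_sd Age distribution (years), truncated at
#'   `age_range`.
#' @param age_range Lower/upper truncation for age.
#' @param diagnostics Named list of `c(mean, sd)` pairs for `waist_male`,
#'   `waist_female`, `sbp`, `dbp`, `tg`, `hdl`, `fbg` on their natural scales.
#' @param risk_loading Loading of each diagnostic's latent on the shared
#'   metabolic-risk factor (HDL loads negatively). Controls MetS component
#'   co-occurrence and hence prevalence.
#' @param risk_age,risk_sedentary,risk_spending Weights of standardized age,
#'   sedentary time and log-spending in the metabolic-risk factor.
#' @param spending_meanlog,spending_sdlog Log-normal yearly spending
#'   (currency units/year).
#' @param income_logsd Extra log-normal noise linking income to spending.
#' @param sedentary_mean,sedentary_sd Sedentary time (hours/day), truncated
#'   to `sedentary_range`.
#' @param sedentary_range Truncation bounds for sedentary time.
#' @param sedentary_spending_rho Gaussian-copula correlation between
#'   spending and sedentary time.
#' @param diet Named list of `c(mean, sd, rho)` for `veg`, `fruit`, `grain`,
#'   `meat` (servings/week); `rho` is the coupling to spending.
#' @param smoking_intercept,smoking_male,smoking_spending Logit model for
#'   smoking status.
#' @param bristol_probs Probabilities for Bristol stool scale scores 1..7.
#' @param n_regions Number of sampled geographic regions.
#' @param spending_group_props Proportions of the low/moderate/high spending
#'   strata (defaults follow the 1170/2394/1099 split).
#' @param thresholds Diagnostic thresholds, see [mets_thresholds()].
#' @param components_required Number of positive components (out of 5)
#'   required for a MetS diagnosis.
#' @return A list of class `gutmets_cohort_config`.
#' @export
cohort_config <- function(
    p_female = 0.5515,
    age_mean = 52.7, age_sd = 14.6, age_range = c(18, 95),
    diagnostics = list(
      waist_male = c(82, 10.5), waist_female = c(78, 9.5),
      sbp = c(127.5, 16), dbp = c(75.5, 11),
      tg = c(1.3, 0.55), hdl = c(1.2, 0.27), fbg = c(5.3, 0.86)
    ),
    risk_loading = 0.50,
    risk_age = 0.35, risk_sedentary = 0.20, risk_spending = 0.15,
    spending_meanlog = 9.4, spending_sdlog = 0.9,
    income_logsd = 0.35,
    sedentary_mean = 3.5, sedentary_sd = 2.0, sedentary_range = c(0.25, 16),
    sedentary_spending_rho = 0.3,
    diet = list(
      veg = c(17, 6, 0.25), fruit = c(8, 4, 0.25),
      grain = c(18, 6, -0.25), meat = c(9, 5, 0)
    ),
    smoking_intercept = -2.6, smoking_male = 2.6, smoking_spending = -0.25,
    bristol_probs = c(0.03, 0.08, 0.18, 0.35, 0.20, 0.11, 0.05),
    n_regions = 14,
    spending_group_props = c(low = 0.2509, moderate = 0.5134, high = 0.2357),
    thresholds = mets_thresholds(),
    components_required = 3) {
  cfg <- as.list(environment())
  sds <- c(vapply(cfg$diagnostics, `[`, numeric(1), 2), age_sd,
           spending_sdlog, sedentary_sd,
           vapply(cfg$diet, `[`, numeric(1), 2))
  if (any(sds < 0)) {
    abort_invalid_config("standard deviations must be non-negative.")
  }
  if (abs(risk_loading) > 1) {
    abort_invalid_config("`risk_loading` must lie in [-1, 1].")
  }
  if (abs(sedentary_spending_rho) > 1) {
    abort_invalid_config("`sedentary_spending_rho` must lie in [-1, 1].")
  }
  if (length(bristol_probs) != 7 || any(bristol_probs < 0)) {
    abort_invalid_config("`bristol_probs` must be 7 non-negative weights.")
  }
  structure(cfg, class = "gutmets_cohort_config")
}

#' Diagnose metabolic syndrome from component measurements
#'
#' Applies the five diagnostic component rules (see [mets_thresholds()]) and
#' flags MetS when at least `components_required` components are present
#' (harmonized ">= 3 of 5" criteria by default).
#'
#' @param data Data frame with columns `gender` ("female"/"male"), `waist`,
#'   `sbp`, `dbp`, `tg`, `hdl`, `fbg`.
#' @param thresholds Diagnostic thresholds, see [mets_thresholds()].
#' @param components_required Components needed for a positive diagnosis.
#' @return The input as a tibble with logical columns `flag_waist`,
#'   `flag_bp`, `flag_tg`, `flag_hdl`, `flag_fbg`, integer `n_components`
#'   and logical `mets`.
#' @export
#' @examples
#' diagnose_mets(data.frame(gender = "female", waist = 86, sbp = 131,
#'                          dbp = 70, tg = 1.8, hdl = 1.2, fbg = 5.0))
diagnose_mets <- function(data, thresholds = mets_thresholds(),
                          components_required = 3) {
  fields <- c("gender", "waist", "sbp", "dbp", "tg", "hdl", "fbg")
  check_columns(data, fields, "diagnostic data")
  for (f in fields) {
    if (anyNA(data[[f]])) {
      abort_missing_data(sprintf("field `%s` has missing values.", f),
                         field = f)
    }
  }
  meas <- c("waist", "sbp", "dbp", "tg", "hdl", "fbg")
  for (f in meas) {
    if (any(data[[f]] <= 0)) {
      abort_invalid_argument(sprintf("field `%s` must be strictly positive.", f))
    }
  }
  if (!all(data$gender %in% c("female", "male"))) {
    abort_invalid_argument('`gender` must be "female" or "male".')
  }
  waist_cut <- ifelse(data$gender == "male",
                      thresholds$waist_male, thresholds$waist_female)
  out <- tibble::as_tibble(data)
  out$flag_waist <- data$waist >= waist_cut
  out$flag_bp <- data$sbp >= thresholds$sbp | data$dbp >= thresholds$dbp
  out$flag_tg <- data$tg >= thresholds$tg
  out$flag_hdl <- data$hdl < thresholds$hdl
  out$flag_fbg <- data$fbg >= thresholds$fbg
  out$n_components <- out$flag_waist + out$flag_bp + out$flag_tg +
    out$flag_hdl + out$flag_fbg
  out$mets <- out$n_components >= components_required
  out
}

#' Generate a synthetic MetS cohort
#'
#' Draws `n` participants with demographics, the six diagnostic
#' measurements, economic status and lifestyle variables. A shared latent
#' metabolic-risk factor (loaded by age, sedentary time and spending plus an
#' idiosyncratic part) induces realistic co-occurrence of the diagnostic
#' components, confounding of MetS by age, and prevalence gradients across
#' spending and sedentary strata. The `mets` flag is always computed by
#' [diagnose_mets()] on the generated measurements.
#'
#' @param n Number of participants (>= 2).
#' @param config See [cohort_config()].
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return A tibble with one row per participant: `sample_id`, `age`,
#'   `gender`, the diagnostics, component flags, `mets`, `income`,
#'   `spending`, `spending_group`, `sedentary`, `diet_*`, `smoking`,
#'   `bristol`, `region`.
#' @export
#' @examples
#' cohort <- generate_cohort(200, seed = 1)
#' mean(cohort$mets)
generate_cohort <- function(n, config = cohort_config(), seed = 1) {
  n <- check_scalar_int(n, "n", min = 2)
  if (!inherits(config, "gutmets_cohort_config")) {
    abort_invalid_config("`config` must come from cohort_config().")
  }
  cfg <- config
  with_seed_(seed, {
    gender <- ifelse(runif(n) < cfg$p_female, "female", "male")
    age <- rnorm_trunc(n, cfg$age_mean, cfg$age_sd,
                       cfg$age_range[1], cfg$age_range[2])

    # Economic status and lifestyle (Gaussian copula on spending).
    spend_z <- rnorm(n)
    spending <- exp(cfg$spending_meanlog + cfg$spending_sdlog * spend_z)
    income <- spending * exp(0.4 + cfg$income_logsd * rnorm(n))
    rho <- cfg$sedentary_spending_rho
    sed_z <- rho * spend_z + sqrt(1 - rho^2) * rnorm(n)
    sedentary <- pmin(pmax(cfg$sedentary_mean + cfg$sedentary_sd * sed_z,
                           cfg$sedentary_range[1]), cfg$sedentary_range[2])
    diet <- lapply(cfg$diet, function(par) {
      z <- par[3] * spend_z + sqrt(max(0, 1 - par[3]^2)) * rnorm(n)
      pmax(par[1] + par[2] * z, 0)
    })
    smoke_logit <- cfg$smoking_intercept +
      cfg$smoking_male * (gender == "male") +
      cfg$smoking_spending * spend_z
    smoking <- runif(n) < stats::plogis(smoke_logit)
    bristol <- sample.int(7, n, replace = TRUE,
                          prob = cfg$bristol_probs / sum(cfg$bristol_probs))
    region <- paste0("R", formatC(sample.int(cfg$n_regions, n, replace = TRUE),
                                  width = 2, flag = "0"))

    # Latent metabolic risk: age, sedentary behaviour and spending load on
    # it; the remainder is idiosyncratic. Normalised to unit variance.
    age_z <- if (cfg$age_sd > 0) (age - cfg$age_mean) / cfg$age_sd else rep(0, n)
    w <- c(cfg$risk_age, cfg$risk_sedentary, cfg$risk_spending)
    expl_var <- w[1]^2 + w[2]^2 + w[3]^2 + 2 * w[2] * w[3] * rho
    if (expl_var >= 1) {
      abort_invalid_config("risk factor weights imply variance >= 1.")
    }
    risk <- w[1] * age_z + w[2] * sed_z + w[3] * spend_z +
      sqrt(1 - expl_var) * rnorm(n)

    lam <- cfg$risk_loading
    resid <- sqrt(1 - lam^2)
    draw_diag <- function(par, sign = 1) {
      latent <- sign * lam * risk + resid * rnorm(n)
      pmax(par[1] + par[2] * latent, 0.01)
    }
    dg <- cfg$diagnostics
    waist_par_mean <- ifelse(gender == "male", dg$waist_male[1], dg$waist_female[1])
    waist_par_sd <- ifelse(gender == "male", dg$waist_male[2], dg$waist_female[2])
    waist <- pmax(waist_par_mean + waist_par_sd *
                    (lam * risk + resid * rnorm(n)), 0.01)
    sbp <- draw_diag(dg$sbp)
    dbp <- draw_diag(dg$dbp)
    tg <- draw_diag(dg$tg)
    hdl <- draw_diag(dg$hdl, sign = -1)
    fbg <- draw_diag(dg$fbg)

    cohort <- tibble::tibble(
      sample_id = sprintf("S%05d", seq_len(n)),
      age = age, gender = gender,
      waist = waist, sbp = sbp, dbp = dbp, tg = tg, hdl = hdl, fbg = fbg,
      income = income, spending = spending,
      sedentary = sedentary,
      diet_veg = diet$veg, diet_fruit = diet$fruit,
      diet_grain = diet$grain, diet_meat = diet$meat,
      smoking = smoking, bristol = as.integer(bristol), region = region
    )
    cohort$spending_group <- spending_strata(cohort$spending,
                                             cfg$spending_group_props)
    diagnose_mets(cohort, cfg$thresholds, cfg$components_required)
  })
}

#' Assign spending strata by configured proportions
#'
#' Cuts a spending vector into ordered strata (low/moderate/high by default)
#' at the empirical quantiles implied by the configured group proportions.
#'
#' @param spending Numeric vector of yearly spending.
#' @param props Named proportions summing to 1 (order low to high).
#' @return An ordered factor of stratum labels.
#' @export
spending_strata <- function(spending,
                            props = c(low = 0.2509, moderate = 0.5134,
                                      high = 0.2357)) {
  props <- props / sum(props)
  cuts <- quantile(spending, probs = cumsum(props)[-length(props)],
                   names = FALSE, type = 2)
  labels <- names(props) %||% paste0("G", seq_along(props))
  idx <- 1L + rowSums(outer(spending, cuts, ">"))
  factor(labels[idx], levels = labels, ordered = TRUE)
}
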