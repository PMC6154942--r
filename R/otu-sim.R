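# Synthetic OTU count tables with planted, phylogenetically clustered
# ground-truth effects. Counts follow a Dirichlet-multinomial whose
# per-sample log-scale composition is
#   base + planted effects x standardized factors + confounder terms
#   + community shift + noise,
# so that every downstream stage (filtering, association, index, grid) can
# be tested against known truth.

MODEL_FACTORS <- c("waist", "sbp", "dbp", "tg", "hdl", "fbg", "mets",
                   "income", "spending")

# Phylum inventory with typical gut proportions and a disorder-direction
# prior per taxon: Bacteroidetes and Ruminococcaceae lean protective
# (negative), Proteobacteria and the remaining Firmicutes lean positive.
taxon_inventory <- function() {
  list(
    phyla = c(Bacteroidetes = 0.35, Firmicutes = 0.40, Proteobacteria = 0.12,
              Actinobacteria = 0.05, Verrucomicrobia = 0.02,
              Fusobacteria = 0.02, Tenericutes = 0.02, Euryarchaeota = 0.02),
    families = list(
      Bacteroidetes = c("Bacteroidaceae", "Prevotellaceae", "Rikenellaceae",
                        "Porphyromonadaceae"),
      Firmicutes = c("Ruminococcaceae", "Lachnospiraceae", "Veillonellaceae",
                     "Clostridiaceae", "Peptostreptococcaceae",
                     "Christensenellaceae"),
      Proteobacteria = c("Enterobacteriaceae", "Alcaligenaceae",
                         "Desulfovibrionaceae"),
      Actinobacteria = c("Bifidobacteriaceae", "Coriobacteriaceae"),
      Verrucomicrobia = "Verrucomicrobiaceae",
      Fusobacteria = "Fusobacteriaceae",
      Tenericutes = "RF39",
      Euryarchaeota = "Methanobacteriaceae"
    ),
    classes = c(Bacteroidetes = "Bacteroidia", Firmicutes = "Clostridia",
                Proteobacteria = "Gammaproteobacteria",
                Actinobacteria = "Actinobacteria",
                Verrucomicrobia = "Verrucomicrobiae",
                Fusobacteria = "Fusobacteriia", Tenericutes = "Mollicutes",
                Euryarchaeota = "Methanobacteria"),
    orders = c(Bacteroidetes = "Bacteroidales", Firmicutes = "Clostridiales",
               Proteobacteria = "Enterobacteriales",
               Actinobacteria = "Bifidobacteriales",
               Verrucomicrobia = "Verrucomicrobiales",
               Fusobacteria = "Fusobacteriales", Tenericutes = "RF39",
               Euryarchaeota = "Methanobacteriales"),
    # Probability that a planted effect in this taxon takes the positive
    # (disorder-enriched) direction.
    p_positive = c(Bacteroidetes = 0.05, Proteobacteria = 0.95,
                   Actinobacteria = 1.00, Verrucomicrobia = 0.00,
                   Fusobacteria = 1.00, Tenericutes = 0.00,
                   Euryarchaeota = 0.00),
    p_positive_family = c(Ruminococcaceae = 0.10),
    p_positive_default = 0.90
  )
}

#' OTU simulation configuration
#'
#' @param log_abundance_sd SD of baseline log relative abundances; larger
#'   values give a heavier-tailed, more zero-inflated community. The default
#'   suits analysis-scale tables where most OTUs are prevalent; the
#'   full-inventory emulation of [survey_inventory()] uses 2.6.
#' @param concentration Dirichlet total concentration; smaller values give
#'   stronger compositional overdispersion.
#' @param otu_noise_sd Per-sample, per-OTU log-scale biological noise.
#' @param confounder_fraction Fraction of OTUs whose abundance is driven by
#'   the confounders (age, gender, Bristol scale, region).
#' @param confounder_sd SD of confounder coefficients; defaults to half the
#'   strong planted effect so de-confounding is exercised but identifiable.
#' @param community_shift_sd SD of a per-sample community-level shift along
#'   the planted MetS direction (sample-to-sample dysbiosis severity).
#' @param index_spending_rho Correlation between the community shift and
#'   standardized log spending; a small negative value plants the weak
#'   negative dysbiosis-spending coupling seen in population data.
#' @param dysbiosis_load_coupling Correlation between the community shift
#'   and the standardized metabolic disorder load (number of diagnostic
#'   components). A positive value concentrates abundance into the
#'   disorder-enriched (abundant) OTUs of dysbiotic samples, lowering their
#'   diversity, while leaving unplanted OTUs untouched (the shift direction
#'   is compositionally balanced).
#' @param evenness_loss Per-standard-deviation reduction of the log
#'   Dirichlet concentration with disorder load. Nonzero values lower the
#'   evenness of dysbiotic samples directly, but the dispersion change also
#'   shifts the mean of the variance-stabilised abundances and therefore
#'   confounds per-OTU mean associations; 0 by default.
#' @return A list of class `gutmets_otu_config`.
#' @export
otu_config <- function(log_abundance_sd = 2.2, concentration = 200,
                       otu_noise_sd = 0.6, confounder_fraction = 0.3,
                       confounder_sd = 0.25, community_shift_sd = 0.3,
                       index_spending_rho = 0,
                       dysbiosis_load_coupling = 0.5, evenness_loss = 0) {
  if (log_abundance_sd < 0 || otu_noise_sd < 0 || confounder_sd < 0 ||
      community_shift_sd < 0) {
    abort_invalid_config("SD parameters must be non-negative.")
  }
  if (concentration <= 0) {
    abort_invalid_config("`concentration` must be positive.")
  }
  if (abs(index_spending_rho) > 1) {
    abort_invalid_config("`index_spending_rho` must lie in [-1, 1].")
  }
  if (index_spending_rho^2 + dysbiosis_load_coupling^2 > 1) {
    abort_invalid_config(
      "index_spending_rho^2 + dysbiosis_load_coupling^2 must be <= 1.")
  }
  structure(as.list(environment()), class = "gutmets_otu_config")
}

#' Baseline OTU profile: ids, taxonomy and log abundances
#'
#' @param n_otus Number of OTUs (>= 10).
#' @param config See [otu_config()].
#' @param seed Integer seed.
#' @return Tibble with `otu_id`, `taxonomy`, `phylum`, `family`, `log_base`.
#' @export
otu_profile <- function(n_otus, config = otu_config(), seed = 1) {
  n_otus <- check_scalar_int(n_otus, "n_otus", min = 10)
  inv <- taxon_inventory()
  with_seed_(seed, {
    phylum <- sample(names(inv$phyla), n_otus, replace = TRUE,
                     prob = inv$phyla)
    family <- vapply(phylum, function(p) {
      fams <- inv$families[[p]]
      fams[sample.int(length(fams), 1)]
    }, character(1), USE.NAMES = FALSE)
    taxonomy <- paste0(
      "k__", ifelse(phylum == "Euryarchaeota", "Archaea", "Bacteria"),
      ";p__", phylum,
      ";c__", inv$classes[phylum],
      ";o__", inv$orders[phylum],
      ";f__", ifelse(family == "RF39", "", family),
      ";g__;s__")
    tibble::tibble(
      otu_id = sprintf("OTU_%05d", seq_len(n_otus)),
      taxonomy = taxonomy, phylum = phylum, family = family,
      log_base = rnorm(n_otus, 0, config$log_abundance_sd)
    )
  })
}

#' Plant ground-truth OTU-phenotype effects
#'
#' Selects `n_signal` OTUs from the mid-to-high abundance range of a
#' profile and assigns each one effect on one factor. Effect directions are
#' clustered within taxa (Bacteroidetes and Ruminococcaceae mostly
#' protective, Proteobacteria and other Firmicutes mostly disorder-enriched),
#' mirroring the phylogenetic conservativeness of real MetS associations.
#' HDL effects carry the opposite modelled sign (low HDL is the disorder).
#' Effects are abundance-balanced per factor so the planted signal does not
#' leak into unplanted OTUs through compositional closure.
#'
#' @param profile Tibble from [otu_profile()].
#' @param n_signal Number of OTUs given an effect.
#' @param factors Factors to plant on (subset of the modelled factor set).
#' @param magnitude_range Range of |effect| (log-scale shift per standard
#'   deviation of the factor).
#' @param abundance_window Quantile window of baseline abundance from which
#'   planted OTUs are drawn (rare OTUs carry no detectable signal).
#' @param seed Integer seed.
#' @param balance Balance abundance-weighted effects to zero per factor.
#' @param concentrate Bias disorder-enriched (positive) effects toward
#'   already-abundant OTUs and protective (negative) effects toward less
#'   abundant ones. Off by default: under compositional balancing the bias
#'   mainly costs detection power for the rare negatives; the diversity
#'   loss of dysbiotic samples is modelled by `evenness_loss` /
#'   `dysbiosis_load_coupling` in [otu_config()] instead.
#' @return Tibble with `otu_id`, `factor`, `effect`, `direction` (the
#'   disorder valence of the OTU: +1 enriched in disease, -1 protective).
#' @export
plant_effects <- function(profile, n_signal,
                          factors = c("mets", "waist", "sbp", "dbp", "tg",
                                      "hdl", "fbg"),
                          magnitude_range = c(0.4, 1.0),
                          abundance_window = c(0.50, 0.95),
                          seed = 1, balance = TRUE, concentrate = FALSE) {
  bad <- setdiff(factors, MODEL_FACTORS)
  if (length(bad) > 0) {
    abort_invalid_config(sprintf("unknown factor(s): %s.",
                                 paste(bad, collapse = ", ")))
  }
  inv <- taxon_inventory()
  with_seed_(seed, {
    qs <- quantile(profile$log_base, abundance_window, names = FALSE)
    eligible <- which(profile$log_base >= qs[1] & profile$log_base <= qs[2])
    if (length(eligible) < n_signal) {
      abort_invalid_config("not enough eligible OTUs in the abundance window.")
    }
    # Taxon-consistent direction for every eligible OTU, then sample the
    # planted set: positives biased toward abundant OTUs, negatives toward
    # less abundant ones when `concentrate` is on.
    p_pos <- inv$p_positive[profile$phylum[eligible]]
    fam_override <- inv$p_positive_family[profile$family[eligible]]
    p_pos[!is.na(fam_override)] <- fam_override[!is.na(fam_override)]
    p_pos[is.na(p_pos)] <- inv$p_positive_default
    dir_eligible <- ifelse(runif(length(eligible)) < p_pos, 1, -1)
    pos_pool <- eligible[dir_eligible == 1]
    neg_pool <- eligible[dir_eligible == -1]
    n_pos <- min(length(pos_pool), round(n_signal / 2))
    n_neg <- n_signal - n_pos
    if (n_neg > length(neg_pool)) {
      n_neg <- length(neg_pool)
      n_pos <- n_signal - n_neg
    }
    pool_weight <- function(pool, favor_abundant) {
      r <- rank(profile$log_base[pool]) / length(pool)
      if (!concentrate) rep(1, length(pool))
      else if (favor_abundant) r^2 else (1 - r)^2
    }
    draw_from <- function(pool, n, favor_abundant) {
      pool[sample.int(length(pool), n, prob = pool_weight(pool,
                                                          favor_abundant))]
    }
    idx <- c(draw_from(pos_pool, n_pos, TRUE),
             draw_from(neg_pool, n_neg, FALSE))
    direction <- c(rep(1, n_pos), rep(-1, n_neg))
    ord <- order(idx)
    idx <- idx[ord]
    direction <- direction[ord]
    fac <- sample(factors, n_signal, replace = TRUE)
    mag <- runif(n_signal, magnitude_range[1], magnitude_range[2])
    # Modelled sign: disorder valence, flipped for HDL.
    effect <- ifelse(fac == "hdl", -direction, direction) * mag
    eff <- tibble::tibble(otu_id = profile$otu_id[idx], factor = fac,
                          effect = effect, direction = direction)
    if (balance) {
      w_all <- exp(profile$log_base)
      w_all <- w_all / sum(w_all)
      w <- w_all[idx]
      for (f in unique(eff$factor)) {
        in_f <- eff$factor == f
        drift <- sum(w[in_f] * eff$effect[in_f])
        # Minimal L2 correction so the abundance-weighted effect sums to 0.
        eff$effect[in_f] <- eff$effect[in_f] -
          drift * w[in_f] / sum(w[in_f]^2)
      }
    }
    eff
  })
}

# Standardized factor design matrix from a cohort (n x length(MODEL_FACTORS)).
factor_matrix <- function(cohort) {
  check_columns(cohort, c(setdiff(MODEL_FACTORS, c("mets", "income",
                                                   "spending")),
                          "mets", "income", "spending"), "cohort")
  cols <- lapply(MODEL_FACTORS, function(f) {
    x <- cohort[[f]]
    if (f %in% c("income", "spending")) x <- log(x)
    if (is.logical(x)) x <- as.numeric(x)
    standardize(x)
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- MODEL_FACTORS
  mat
}

#' Generate an OTU count table for a cohort
#'
#' Counts are drawn from a Dirichlet-multinomial whose per-sample log-scale
#' composition is `log_base + effects x standardized factors + confounder
#' terms (age, gender, Bristol scale, region) + community shift + noise`.
#' Every sample sums exactly to `depth`.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param effects Tibble from [plant_effects()] (may have zero rows).
#' @param n_otus Number of OTUs (ignored when `profile` is supplied).
#' @param depth Reads per sample (>= 100).
#' @param seed Integer seed.
#' @param config See [otu_config()].
#' @param profile Optional profile from [otu_profile()]; generated from
#'   `seed` when absent.
#' @param confounder_effects Optional tibble (`otu_id`, `confounder`,
#'   `effect`) planting deterministic confounder effects on chosen OTUs
#'   (confounders: `age`, `gender`, `bristol`), on top of the random
#'   confounder structure; used to study de-confounding.
#' @return A `gutmets_otu` table (samples x OTUs).
#' @export
generate_otu_table <- function(cohort, effects = NULL, n_otus = 1000,
                               depth = 10000, seed = 1,
                               config = otu_config(), profile = NULL,
                               confounder_effects = NULL) {
  depth <- check_scalar_int(depth, "depth", min = 100)
  if (is.null(profile)) {
    profile <- otu_profile(n_otus, config, seed = derive_seed(seed, "profile"))
  }
  n <- nrow(cohort)
  k <- nrow(profile)
  if (is.null(effects) || nrow(effects) == 0) {
    effects <- tibble::tibble(otu_id = character(), factor = character(),
                              effect = numeric(), direction = numeric())
  }
  bad_fac <- setdiff(unique(effects$factor), MODEL_FACTORS)
  if (length(bad_fac) > 0) {
    abort_invalid_config(sprintf("effects reference unknown factor(s): %s.",
                                 paste(bad_fac, collapse = ", ")))
  }
  bad_otu <- setdiff(unique(effects$otu_id), profile$otu_id)
  if (length(bad_otu) > 0) {
    abort_invalid_config(sprintf("effects reference unknown OTU(s): %s.",
                                 paste(head(bad_otu, 3), collapse = ", ")))
  }
  if (anyDuplicated(effects[c("otu_id", "factor")])) {
    abort_invalid_config("at most one effect per (otu_id, factor).")
  }

  X <- factor_matrix(cohort)
  E <- matrix(0, k, length(MODEL_FACTORS),
              dimnames = list(profile$otu_id, MODEL_FACTORS))
  if (nrow(effects) > 0) {
    E[cbind(match(effects$otu_id, profile$otu_id),
            match(effects$factor, MODEL_FACTORS))] <- effects$effect
  }

  with_seed_(seed, {
    # Confounder structure: a fraction of OTUs respond to age, gender,
    # Bristol score and region.
    confounded <- runif(k) < config$confounder_fraction
    n_conf <- sum(confounded)
    gamma <- matrix(0, k, 3)
    gamma[confounded, ] <- rnorm(3 * n_conf, 0, config$confounder_sd)
    regions <- sort(unique(cohort$region))
    region_eff <- matrix(0, k, length(regions))
    region_eff[confounded, ] <- rnorm(length(regions) * n_conf, 0,
                                      config$confounder_sd)
    C <- cbind(standardize(cohort$age), as.numeric(cohort$gender == "male"),
               standardize(cohort$bristol))
    if (!is.null(confounder_effects) && nrow(confounder_effects) > 0) {
      conf_names <- c("age", "gender", "bristol")
      bad_cf <- setdiff(unique(confounder_effects$confounder), conf_names)
      if (length(bad_cf) > 0) {
        abort_invalid_config(sprintf("unknown confounder(s): %s.",
                                     paste(bad_cf, collapse = ", ")))
      }
      bad_id <- setdiff(unique(confounder_effects$otu_id), profile$otu_id)
      if (length(bad_id) > 0) {
        abort_invalid_config("confounder_effects reference unknown OTU(s).")
      }
      gamma[cbind(match(confounder_effects$otu_id, profile$otu_id),
                  match(confounder_effects$confounder, conf_names))] <-
        confounder_effects$effect
    }

    # Community-level dysbiosis severity, optionally coupled to spending.
    rho <- config$index_spending_rho
    lc <- config$dysbiosis_load_coupling
    spend_z <- standardize(log(cohort$spending))
    load_z <- if ("n_components" %in% names(cohort)) {
      standardize(cohort$n_components)
    } else if ("mets" %in% names(cohort)) {
      standardize(as.numeric(cohort$mets))
    } else {
      rep(0, n)
    }
    delta <- config$community_shift_sd *
      (lc * load_z + rho * spend_z + sqrt(1 - lc^2 - rho^2) * rnorm(n))
    # Disorder direction across all planted OTUs (HDL valence flipped).
    valence <- ifelse(MODEL_FACTORS == "hdl", -1, 1)
    u <- as.numeric(E %*% valence)

    log_alpha <- matrix(profile$log_base, n, k, byrow = TRUE) +
      X %*% t(E) + C %*% t(gamma) +
      t(region_eff[, match(cohort$region, regions), drop = FALSE]) +
      delta %*% t(u) +
      matrix(rnorm(n * k, 0, config$otu_noise_sd), n, k)

    # Dirichlet-multinomial draw, rescaled to a per-sample concentration
    # (optionally shrinking with disorder load; see `evenness_loss`).
    conc <- config$concentration * exp(-config$evenness_loss * load_z)
    alpha <- exp(sweep(log_alpha, 1, apply(log_alpha, 1, max), "-"))
    alpha <- alpha / rowSums(alpha) * conc
    g <- matrix(rgamma(n * k, shape = alpha), n, k)
    # Guard against all-zero gamma rows for extremely sparse profiles.
    zero_rows <- rowSums(g) == 0
    if (any(zero_rows)) {
      g[zero_rows, ] <- alpha[zero_rows, , drop = FALSE]
    }
    p <- g / rowSums(g)
    counts <- t(vapply(seq_len(n),
                       function(i) rmultinom(1, depth, p[i, ])[, 1],
                       integer(k)))
    dimnames(counts) <- list(cohort$sample_id, profile$otu_id)
    otu_table(counts, profile[c("otu_id", "taxonomy")])
  })
}

#' Full-inventory OTU table emulating a population 16S survey
#'
#' Generates a table with the full OTU inventory scale of a rarefied
#' population survey (17,083 OTUs at 10,000 reads/sample by default) whose
#' zero-inflation is tuned so that roughly 930 OTUs survive the 10%
#' prevalence filter, matching the prevalent-OTU yield of such surveys.
#'
#' @param n_samples Number of samples (the prevalent fraction is almost
#'   independent of this, so a few hundred samples suffice).
#' @param n_otus Inventory size.
#' @param depth Reads per sample.
#' @param seed Integer seed.
#' @return A list with `cohort` and `table`.
#' @export
survey_inventory <- function(n_samples = 250, n_otus = 17083, depth = 10000,
                           seed = 1) {
  cohort <- generate_cohort(n_samples, seed = derive_seed(seed, "cohort"))
  config <- otu_config(log_abundance_sd = 2.6, confounder_fraction = 0)
  table <- generate_otu_table(cohort, NULL, n_otus = n_otus, depth = depth,
                              seed = derive_seed(seed, "counts"),
                              config = config)
  list(cohort = cohort, table = table)
}

#' Convert ground-truth effects into association-record form
#'
#' Builds pseudo association records from a planted-effects table (beta =
#' planted effect, fixed small p/q), so that index and grid machinery can
#' be exercised against known truth without refitting models.
#'
#' @param effects Tibble from [plant_effects()].
#' @param q Nominal q-value given to every record.
#' @return A tibble shaped like [fit_associations()] output.
#' @export
effects_as_records <- function(effects, q = 1e-4) {
  tibble::tibble(otu_id = effects$otu_id, taxonomy = NA_character_,
                 factor = effects$factor, beta = effects$effect,
                 p = q / 10, q = q, n_used = NA_integer_,
                 direction = ifelse(effects$effect >= 0, 1, -1),
                 significant = TRUE)
}

#' Generate a random rooted phylogeny over OTU ids
#'
#' Random rooted bifurcating tree with strictly positive branch lengths and
#' tips exactly the supplied ids; used for Faith's phylogenetic diversity.
#'
#' @param otu_ids Character vector of >= 2 unique tip ids.
#' @param seed Integer seed.
#' @return An [ape::phylo] tree.
#' @export
generate_tree <- function(otu_ids, seed = 1) {
  if (length(otu_ids) < 2) {
    abort_invalid_argument("need at least 2 OTU ids.")
  }
  if (anyDuplicated(otu_ids)) {
    abort_invalid_argument("OTU ids must be unique.")
  }
  with_seed_(seed, {
    ape::rtree(length(otu_ids), rooted = TRUE, tip.label = otu_ids,
               br = function(n) runif(n, 0.05, 1))
  })
}

#' The default synthetic analysis scenario
#'
#' Bundles the study conditions used throughout the package's validation:
#' a cohort with ~20% MetS prevalence, an OTU table with planted,
#' taxonomically clustered positive and negative effects, the ground-truth
#' effect list and (optionally) a random phylogeny.
#'
#' @param n Cohort size.
#' @param n_otus OTUs in the table.
#' @param n_signal OTUs given a planted effect.
#' @param depth Rarefaction depth (reads/sample).
#' @param seed Master seed (stage seeds are derived from it).
#' @param cohort_config,otu_config Generator configurations.
#' @param magnitude_range Planted |effect| range.
#' @param tree Also generate a phylogeny over the OTU ids.
#' @return List with `cohort`, `profile`, `effects`, `table` and `tree`.
#' @export
mets_scenario <- function(n = 3000, n_otus = 1000, n_signal = 200,
                          depth = 10000, seed = 11,
                          cohort_config = gutmets::cohort_config(),
                          otu_config = gutmets::otu_config(),
                          magnitude_range = c(0.4, 1.0), tree = FALSE) {
  cohort <- generate_cohort(n, cohort_config, seed = derive_seed(seed, "cohort"))
  profile <- otu_profile(n_otus, otu_config, seed = derive_seed(seed, "profile"))
  effects <- plant_effects(profile, n_signal,
                           magnitude_range = magnitude_range,
                           seed = derive_seed(seed, "effects"))
  table <- generate_otu_table(cohort, effects, depth = depth,
                              seed = derive_seed(seed, "counts"),
                              config = otu_config, profile = profile)
  phy <- if (tree) generate_tree(profile$otu_id,
                                 seed = derive_seed(seed, "tree")) else NULL
  list(cohort = cohort, profile = profile, effects = effects,
       table = table, tree = phy)
}
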