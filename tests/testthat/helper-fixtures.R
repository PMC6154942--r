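# Shared fixtures, all built in code. Expensive scenarios are memoised per
# test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Mid-sized scenario shared by diversity / association / index tests.
small_scenario <- function() {
  cached("small_scenario", function() {
    mets_scenario(n = 800, n_otus = 300, n_signal = 60, depth = 5000,
                  seed = 11, tree = TRUE)
  })
}

# Full study-scale scenario used by the acceptance suite (criteria on the
# association engine and the index share it).
study_scenario <- function() {
  cached("study_scenario", function() {
    mets_scenario(n = 3000, n_otus = 1000, n_signal = 200, depth = 10000,
                  seed = 11)
  })
}

study_associations <- function() {
  cached("study_associations", function() {
    sc <- study_scenario()
    filtered <- prevalence_filter(sc$table)
    list(filtered = filtered,
         records = fit_associations(filtered, sc$cohort))
  })
}

# Association records encoding the per-factor direction counts reported for
# a 6896-person southern-Chinese cohort: waist 184-/175+, TG 149-/153+,
# SBP 92-/43+, DBP 72-/29+, FBG 21-/40+, HDL 34+/16- (raw modelled sign),
# MetS 124-/111+; with taxon quotas of 350-/12+ (Bacteroidetes) and
# 230+/21- (Proteobacteria) in disorder-valence space, remainder Firmicutes.
population_network_fixture <- function() {
  raw_counts <- list(
    waist = c(neg = 184, pos = 175), tg = c(neg = 149, pos = 153),
    sbp = c(neg = 92, pos = 43), dbp = c(neg = 72, pos = 29),
    fbg = c(neg = 21, pos = 40), hdl = c(neg = 16, pos = 34),
    mets = c(neg = 124, pos = 111)
  )
  tax <- c(
    Bacteroidetes = "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__;g__;s__",
    Proteobacteria = "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__;f__;g__;s__",
    Firmicutes = "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__;g__;s__"
  )
  # Remaining per-taxon quotas in disorder-valence space.
  quota_neg <- c(Bacteroidetes = 350, Proteobacteria = 21)
  quota_pos <- c(Proteobacteria = 230, Bacteroidetes = 12)
  rows <- list()
  k <- 0
  for (f in names(raw_counts)) {
    for (raw_sign in c(-1, 1)) {
      n_rec <- unname(raw_counts[[f]][if (raw_sign < 0) "neg" else "pos"])
      valence <- if (f == "hdl") -raw_sign else raw_sign
      for (i in seq_len(n_rec)) {
        quota <- if (valence < 0) quota_neg else quota_pos
        taxon <- names(quota)[quota > 0][1]
        if (is.na(taxon)) taxon <- "Firmicutes"
        if (valence < 0 && taxon %in% names(quota_neg)) {
          quota_neg[taxon] <- quota_neg[taxon] - 1
        } else if (valence > 0 && taxon %in% names(quota_pos)) {
          quota_pos[taxon] <- quota_pos[taxon] - 1
        }
        k <- k + 1
        rows[[k]] <- tibble::tibble(
          otu_id = sprintf("FIX_%04d", k), taxonomy = tax[[taxon]],
          factor = f, beta = raw_sign * 0.1, p = 1e-4, q = 1e-3,
          n_used = 6896L, direction = raw_sign, significant = TRUE)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# AUC of a score for a binary label via the rank-sum identity.
auc_score <- function(score, label) {
  w <- wilcoxon_rank_sum(score[label], score[!label])$statistic
  n1 <- sum(label)
  n2 <- sum(!label)
  (w - n1 * (n1 + 1) / 2) / (n1 * n2)
}
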