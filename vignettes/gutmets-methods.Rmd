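---
title: "Models and methods behind gutmets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gutmets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gutmets` implements the analysis chain of population-scale gut
microbiome / metabolic syndrome (MetS) studies: diversity comparison,
PERMANOVA with a subsample-saturation procedure, confounder-adjusted
per-OTU association modelling with FDR control, a weighted microbial MetS
index, and additive lifestyle–dysbiosis risk stratification. This
vignette documents the models, the generator that makes the chain
testable, the numerical conventions, and the design decisions that were
genuinely open.

## The synthetic cohort

Real cohort data of this kind are rarely redistributable, so the package
treats the simulator as a first-class, tested module. `generate_cohort()`
draws, per participant:

* **Demographics.** Gender (female with probability 0.5515), age from a
  truncated normal (52.7 ± 14.6 years, ≥ 18), one of 14 sampling regions,
  and a Bristol stool score (1–7, mode 4).
* **A latent metabolic-risk factor** with unit variance, loaded by
  standardized age (0.35), sedentary time (0.20) and log-spending (0.15),
  the rest idiosyncratic. These loadings create the epidemiological
  structure the downstream analyses must handle: age confounds
  OTU–phenotype associations, and both sedentary time and spending carry
  prevalence gradients.
* **Six diagnostics**, each `μ + σ(λ·risk + √(1−λ²)·ε)` with λ = 0.5
  (HDL loads negatively). The marginal means and SDs were solved from the
  component rates of a published 6896-person cohort table (waist component
  ≈ 23%, SBP ≥ 130 ≈ 44%, TG ≈ 24%, low HDL ≈ 28%, FBG ≈ 18%), and λ was
  then fixed by a one-off Monte-Carlo calibration so that the "≥ 3 of 5
  components" rule yields ≈ 20% MetS prevalence. The `mets` flag is always
  recomputed from the generated measurements by `diagnose_mets()`, never
  drawn directly.
* **Economics and lifestyle.** Log-normal yearly spending and income;
  sedentary time (3.5 ± 2 h/day, truncated) coupled to spending through a
  Gaussian copula (ρ = 0.3, giving a realized Spearman ρ ≈ 0.28);
  vegetable/fruit consumption rising and grain consumption falling with
  spending (|ρ| = 0.25); meat uncoupled; smoking mostly male and
  declining with spending. Spending strata default to proportions
  0.2509/0.5134/0.2357 (low/moderate/high).

All thresholds are inclusive (≥) except HDL, which is strict (<), and the
combining rule (≥ 3 of 5) is exposed as configuration, since harmonized
criteria vary between studies.

## The synthetic OTU table

`generate_otu_table()` draws counts from a Dirichlet-multinomial whose
per-sample log-scale composition is

```
log α_si = base_i + Σ_f e_if · z_sf + γ_i · c_s + δ_s · u_i + ε_si
```

with `base_i ~ N(0, 2.2²)` (heavy-tailed baseline abundances),
standardized factor values `z_sf` (continuous diagnostics, the MetS flag,
log income/spending), confounder terms `γ` on a random 30% of OTUs
(age/gender/Bristol/region coefficients at SD 0.25 — half the typical
planted effect, so de-confounding is exercised but identifiable), a
community-level dysbiosis severity `δ_s` acting along the planted disorder
direction `u`, and per-cell noise (SD 0.6). Each sample's counts sum
exactly to the requested depth. The Dirichlet concentration (200) sets
compositional overdispersion.

Three design points deserve emphasis:

* **Compositional balance.** Planted effects are balanced per factor so
  the abundance-weighted effect sums to zero
  (`Σ w_i e_if = 0`, minimal-L2 correction). Without this, shifting 200
  planted OTUs would move the compositional denominator with the
  phenotype and induce spurious associations in every *unplanted* OTU — at
  n = 3000 even a 3–5% denominator shift is highly significant. With
  balance, the null OTUs stay null and the false-discovery proportion of
  the association stage is governed by the BH procedure alone.
* **Taxon clustering.** Effect directions are drawn per taxon
  (Bacteroidetes and Ruminococcaceae ~90–95% protective; Proteobacteria,
  Actinobacteria and the remaining Firmicutes ~90–95% disorder-enriched),
  mirroring the phylogenetic conservativeness of real MetS associations,
  so network summaries have realistic per-phylum structure. Planted OTUs
  are drawn from the 50th–95th abundance percentile: effects on rarer
  OTUs are undetectable at any realistic depth and would only dilute
  recovery metrics.
* **Diversity loss in disease.** The option `evenness_loss` shrinks the
  per-sample Dirichlet concentration with the standardized disorder load
  (number of positive components), making dysbiotic guts less even and
  less rich — the classic pattern behind lower Shannon and Faith's PD in
  MetS. We keep it at 0 by default and exercise it in a dedicated
  scenario, because dispersion heterogeneity also shifts the *mean* of
  the arcsine-square-root abundances (the transform is concave at small
  proportions) and therefore confounds mean-based per-OTU models. This is
  a real property of such data, not an artifact of the simulator: studies
  combining strong diversity loss with linear association models inherit
  exactly this bias. The default scenario instead couples the community
  shift `δ` to disorder load (correlation 0.5), which perturbs only
  planted OTUs and leaves the null OTUs clean.

`survey_inventory()` emulates a full rarefied 16S survey: 17,083 OTUs at
10,000 reads/sample with `log_abundance_sd = 2.6`, which leaves roughly
930 OTUs (≈ 820–1050 across seeds) detected in at least 10% of samples —
the prevalent-OTU yield this analysis design typically works with.

## Diversity and PERMANOVA

Rarefaction subsamples reads without replacement (multivariate
hypergeometric), drops samples below depth (reported, never padded), and
is seed-deterministic. Shannon uses log base 2 (the QIIME 1 convention;
natural log is a switch). Faith's PD is root-inclusive ("PD whole tree"):
the sum of branch lengths over every edge whose subtree contains an
observed tip. Bray–Curtis is computed through the Manhattan-distance
identity `BC = Σ|u−v| / (Σu + Σv)`. All four are pinned in the test suite
to independent implementations (vegan, picante) and to closed-form or
set-union oracles.

`permanova()` uses Anderson's partition: `SS_T = Σ_pairs d²/n`,
`SS_W = Σ_groups Σ_within-pairs d²/n_g`,
`F = (SS_A/(a−1))/(SS_W/(n−a))`, with significance from label
permutations and the add-one correction `p = (1+#{F* ≥ F})/(1+B)` — so p
is never 0 and the log₁₀(1/p) scale is bounded by the permutation count
(B = 999 by default, α = 0.05). The permutation core is vectorised
(one matrix product per group over all permutations), which is what makes
the saturation procedure and the 2000-replication calibration suite cheap.

`saturation_curve()` implements the subsample-size procedure: for each
size, repeated random subsamples stratified by group (preserving the
group ratio — an assumption we document, since unstratified draws at
small sizes frequently lose a group), distances sliced from the
precomputed matrix (equivalent to recomputation for Bray–Curtis, since
the dissimilarity is pairwise), PERMANOVA per replicate, and the smallest
size at which *all* replicates reach p ≤ α. On the packaged planted
scenario (600 samples, effects 0.3–0.6) the significant fraction rises
monotonically through sizes 30–480 and saturates at 120–240 samples; the
same procedure at a real cohort's effect size and scale is what produces
"all replicates significant from ~1800 samples" curves.

## Core statistics

The Wilcoxon rank-sum, chi-square, Spearman and Benjamini–Hochberg
procedures are implemented in the package (they are the inferential
backbone of every downstream comparison) and verified against brute-force
oracles and the base-R implementations. Conventions: midranks for ties;
exact two-sided rank-sum p by subset-sum enumeration over doubled
midranks for n ≤ 25, otherwise the tie-corrected normal approximation
with continuity correction (worst-case deviation from exact at
n₁ = n₂ = 8 is 0.011, checked exhaustively in the tests); Pearson X²
without Yates correction by default (samples here are large; the flag
exists); Spearman as Pearson of midranks with the t approximation; BH as
the capped step-up `q_(i) = min_{j≥i} m·p_(j)/j`. Cohort summaries print
one-decimal percentages rounded half away from zero, and use Welch's
t test for age (the variance assumption is unstated in such tables;
Welch is the safer default).

## The association engine

`fit_associations()` fits, for every (OTU, factor) pair, the additive
linear model

```
asin√(r_si) ~ z_f + age + gender + region + Bristol
```

on rarefied relative abundances, with region as fixed-effect dummies and
continuous covariates standardized. The arcsine-square-root transform is
the MaAsLin-1 default; log₁₀ of pseudo-counted abundance is available as
configuration. Diagnostic factors enter as their binary component flags
by default (diagnostic tables present flags; continuous coding is a
switch). The HDL flag is oriented by HDL *level* (adequate HDL), so every
record's modelled sign keeps the measurement's valence and the disorder
flip is applied only in aggregate summaries. All OTUs of a factor are fit
through a single QR decomposition, so the study-scale scenario
(1000 OTUs × 7 factors × n = 3000) fits in seconds.

BH families are per factor across OTUs (each factor its own family;
"global" is a switch). We measure the empirical false-discovery
proportion at the record level — a significant (OTU, factor) record is
false iff its OTU carries no planted effect — because that is the
hypothesis family BH controls and the unit in which such studies count
their "N associations". The union of 7 families naturally contains more
false *OTUs* than any single family; that multiplicity is a property of
union-reporting, not of the procedure.

A componentwise least-squares boosting screen (100 iterations, step 0.1,
factor always kept) is available as `selection = "boosted"`; the default
is `"none"` because the confounder set here is small and forced, and the
original gradient-boosting selection adds nothing with four mandatory
covariates.

`summarize_network()` counts significant records per taxon and factor.
Raw per-factor counts keep modelled signs; per-taxon and grand totals are
in disorder valence, i.e. HDL records flipped (a positive HDL association
is protective).

## The microbial MetS index

The per-sample index is the accumulated relative abundance of
MetS-associated OTUs weighted by coefficient and significance:

```
w_i = sign(β_i) · |β_i| · (−log₁₀ q_i)    (summed over factors, HDL flipped)
I_s = Σ_i r_si · w_i                       (standardized to mean 0, SD 1)
```

The exact weighting rule varies between published dysbiosis indices, so
it is isolated behind `weight_mode` (`"beta"` and `"logq"` are the
alternatives); OTUs significant for several factors contribute once with
weights summed; standardization makes quartile cut-offs cohort-relative,
which the risk grid requires. The index is validated by Wilcoxon
rank-sum tests within every spending stratum and region (BH across
strata), and correlated with spending via Spearman within non-MetS
subjects.

For the index–economics coupling experiment the generator's
`index_spending_rho` correlates the community-shift latent δ with
log-spending. The experiment isolates the parameter: the cohort's
spending→risk and sedentary→risk loadings are set to 0 (otherwise
spending reaches the index through the diagnostics and masks the planted
coupling), the community shift is widened (SD 1.5) so δ dominates the
index variance, and 150 of 400 OTUs are planted. Under these conditions
a configured ρ = −0.06 is recovered as a realized Spearman of about
−0.03 to −0.08 at n = 5000 — attenuated, as any signal through two
sampling layers must be.

## Risk stratification

`quartilize()` cuts at the empirical 25/50/75 percentiles with midpoint
interpolation (quantile type 2) and sends ties to the lower quartile —
fixed, documented conventions, since published quartile analyses rarely
state either. `additive_risk_grid()` crosses index and sedentary
quartiles into 16 cells, reports per-cell MetS prevalence, all 120
pairwise chi-square tests with BH, per-spending-level occupancy grids,
and the corner contrast. Summing cells over one axis reproduces the
single-axis quartile prevalences exactly (tested).

The grid emulation scenario uses deliberately *moderate* planted effects
(|e| in 0.1–0.25 over 40 of 150 OTUs, community shift SD 0.8, ground-truth
weights): a dysbiosis index in real cohorts is a weak classifier (top-
vs bottom-quartile prevalences of roughly 26% vs 15%), and only in that
regime is the additive pattern — high/high corner > both single-high
cells > low/low corner — a non-trivial property. With the packaged
settings the ordering holds in ≥ 95% of replicates at n = 4000.

## Problem sizes and reproducibility

The validation suite runs at deliberately chosen scales: the study-scale
association scenario at n = 3000 with 1000 OTUs at depth 10,000 (the
regime where published cohort-scale analyses of this design operate, yet a single scenario
generation takes seconds); PERMANOVA calibration over 2000 null
replications at n = 40 with 199 permutations; the grid emulation over 100
replicates at n = 4000; the inventory emulation at 250 samples (the
prevalent-OTU fraction is nearly independent of sample count). Every
stochastic step takes an explicit seed; `derive_seed()` expands one
master seed into per-stage seeds so stages are independently
reproducible, and `run_pipeline()` writes a manifest with stage seeds and
output hashes — identical configurations yield byte-identical outputs.

## Known limitations

* The generator emulates the *statistical* structure of a real
  population cohort (prevalences, confounding, taxon-clustered planted
  effects, compositional sampling), not its biology: no strain-level
  variation, no longitudinal dynamics, no sequencing-run batch effects,
  and taxonomy strings come from a small fixed inventory. Passing
  recovery tests therefore demonstrates correctness of the machinery
  under the modelled data-generating process, not performance on any
  particular real dataset.
* Evenness–disease coupling biases mean-based association models (see
  above); with `evenness_loss > 0` the FDR guarantees of the association
  stage no longer hold. This mirrors real data.
* The index weight formula is one member of a family; published indices
  differ in exactly this choice, which is why it is configurable and the
  package makes no claim of numerical identity with any specific study's
  supplementary definition.
* PERMANOVA is single-factor (the saturation design needs nothing more);
  multi-factor models and strata/blocking are out of scope, as are
  UniFrac distances and raw 16S read processing.
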