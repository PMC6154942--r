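# Rarefaction, alpha diversity (Shannon, Faith's PD), Bray-Curtis
# dissimilarity and the MetS vs non-MetS diversity comparison.

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples whose total is below `depth` are dropped and reported via
#' the `"dropped"` attribute (and a message).
#'
#' @param table A `gutmets_otu` table.
#' @param depth Target reads/sample (>= 1).
#' @param seed Integer seed; rarefaction is seed-deterministic.
#' @return A rarefied `gutmets_otu` table with constant row sums.
#' @export
rarefy <- function(table, depth, seed = 1) {
  depth <- check_scalar_int(depth, "depth", min = 1)
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  dropped <- rownames(table$counts)[!keep]
  if (length(dropped) > 0) {
    rlang::inform(sprintf(
      "rarefy: dropping %d sample(s) below depth %d: %s",
      length(dropped), depth,
      paste(head(dropped, 5), collapse = ", ")))
  }
  counts <- table$counts[keep, , drop = FALSE]
  k <- ncol(counts)
  out <- with_seed_(seed, {
    t(vapply(seq_len(nrow(counts)), function(i) {
      x <- counts[i, ]
      total <- sum(x)
      if (total == depth) {
        return(as.integer(x))
      }
      # Multivariate hypergeometric draw: sample read positions without
      # replacement and map them back to OTUs.
      picked <- sample.int(total, depth)
      tabulate(findInterval(picked, cumsum(x) - x + 1), nbins = k)
    }, integer(k)))
  })
  dimnames(out) <- dimnames(counts)
  res <- otu_table(out, table$taxonomy)
  attr(res, "dropped") <- dropped
  res
}

#' Shannon diversity of one sample
#'
#' `H = -sum p_i log2 p_i` over the non-zero proportions (log base 2 by
#' default, matching the QIIME 1 convention; `base = exp(1)` switches to
#' nats).
#'
#' @param counts Non-negative count vector with positive total.
#' @param base Logarithm base.
#' @return Shannon index (bits by default).
#' @export
#' @examples
#' shannon(c(5, 5, 5, 5)) # 2 bits
shannon <- function(counts, base = 2) {
  total <- sum(counts)
  if (total <= 0) {
    abort_gutmets("Shannon index undefined for an all-zero sample.",
                  "gutmets_undefined_input")
  }
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Faith's phylogenetic diversity of one sample
#'
#' Sum of the branch lengths of the minimal subtree connecting the root and
#' all observed tips, including the stem path to the root ("PD whole tree"
#' convention).
#'
#' @param counts Named non-negative count vector (names are OTU ids).
#' @param tree Rooted [ape::phylo] tree with branch lengths covering every
#'   observed OTU.
#' @return PD in branch-length units.
#' @export
faith_pd <- function(counts, tree) {
  if (is.null(names(counts))) {
    abort_invalid_argument("`counts` must be named by OTU id.")
  }
  observed <- names(counts)[counts > 0]
  if (length(observed) == 0) {
    abort_gutmets("PD undefined for an all-zero sample.",
                  "gutmets_undefined_input")
  }
  missing <- setdiff(observed, tree$tip.label)
  if (length(missing) > 0) {
    abort_gutmets(sprintf("OTU(s) absent from the tree: %s.",
                          paste(head(missing, 5), collapse = ", ")),
                  "gutmets_tree_mismatch")
  }
  n_tip <- length(tree$tip.label)
  on_path <- logical(n_tip + tree$Nnode)
  on_path[match(observed, tree$tip.label)] <- TRUE
  # Postorder sweep: an edge is on the root-to-observed-tip union iff its
  # child subtree contains an observed tip.
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  lengths <- tree$edge.length[ape::postorder(tree)]
  pd <- 0
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2]
    if (on_path[child]) {
      pd <- pd + lengths[e]
      on_path[edge[e, 1]] <- TRUE
    }
  }
  pd
}

#' Per-sample alpha diversity table
#'
#' @param table A `gutmets_otu` table (typically rarefied).
#' @param tree Optional rooted tree for Faith's PD.
#' @param base Logarithm base for Shannon.
#' @return Tibble with `sample_id`, `shannon` and (when `tree` is given)
#'   `pd`.
#' @export
alpha_diversity <- function(table, tree = NULL, base = 2) {
  out <- tibble::tibble(
    sample_id = rownames(table$counts),
    shannon = apply(table$counts, 1, shannon, base = base)
  )
  if (!is.null(tree)) {
    out$pd <- apply(table$counts, 1, faith_pd, tree = tree)
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(u, v) = 1 - 2 sum min(u_i, v_i) / (sum u + sum v)`, computed for all
#' sample pairs.
#'
#' @param table A `gutmets_otu` table or a numeric sample x OTU matrix.
#' @return A [stats::dist] object labelled by sample id, values in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  x <- if (inherits(table, "gutmets_otu")) table$counts else as.matrix(table)
  if (nrow(x) < 2) abort_invalid_argument("need at least 2 samples.")
  rs <- rowSums(x)
  if (any(rs == 0)) {
    abort_gutmets("Bray-Curtis undefined for a zero-sum sample.",
                  "gutmets_undefined_input")
  }
  # sum min(u,v) = (sum u + sum v - sum |u - v|) / 2, so BC reduces to a
  # Manhattan distance scaled by the total abundance of each pair.
  man <- as.matrix(stats::dist(x, method = "manhattan"))
  bc <- man / outer(rs, rs, "+")
  stats::as.dist(bc)
}

#' Compare alpha diversity between MetS and non-MetS subjects
#'
#' Wilcoxon rank-sum tests of each diversity measure between the two groups
#' with Benjamini-Hochberg adjustment across measures.
#'
#' @param diversity Tibble from [alpha_diversity()].
#' @param cohort Cohort tibble with `sample_id` and `mets`.
#' @return Tibble with one row per measure: group medians, `statistic`,
#'   `p`, `q`.
#' @export
diversity_comparison <- function(diversity, cohort) {
  check_columns(cohort, c("sample_id", "mets"), "cohort")
  merged <- dplyr::inner_join(diversity, cohort[c("sample_id", "mets")],
                              by = "sample_id")
  measures <- setdiff(names(diversity), "sample_id")
  rows <- purrr::map(measures, function(m) {
    test <- wilcoxon_rank_sum(merged[[m]][merged$mets],
                              merged[[m]][!merged$mets])
    tibble::tibble(
      measure = m,
      median_mets = median(merged[[m]][merged$mets]),
      median_non_mets = median(merged[[m]][!merged$mets]),
      statistic = test$statistic, p = test$p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_adjust(out$p)
  out
}
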