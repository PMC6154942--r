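# Light container for a sample x OTU count matrix plus taxonomy.

#' Construct an OTU table
#'
#' @param counts Non-negative integer matrix, samples in rows, OTUs in
#'   columns, both dimensions named.
#' @param taxonomy Tibble with columns `otu_id` and `taxonomy`
#'   (Greengenes-style 7-rank strings `k__...;p__...;...;s__...`).
#' @return An object of class `gutmets_otu`.
#' @export
otu_table <- function(counts, taxonomy) {
  if (!is.matrix(counts)) {
    abort_format("`counts` must be a matrix (samples x OTUs).")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_format("`counts` must have sample (row) and OTU (column) names.")
  }
  if (anyDuplicated(rownames(counts))) {
    abort_format("duplicated sample ids in count matrix.")
  }
  if (anyDuplicated(colnames(counts))) {
    abort_format("duplicated OTU ids in count matrix.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    abort_format(sprintf(
      "counts must be non-negative integers (offending row %d, column %d).",
      bad[1], bad[2]))
  }
  taxonomy <- tibble::as_tibble(taxonomy)
  check_columns(taxonomy, c("otu_id", "taxonomy"), "taxonomy")
  if (!setequal(taxonomy$otu_id, colnames(counts)) ||
      nrow(taxonomy) != ncol(counts)) {
    abort_format("taxonomy must list each OTU of the count matrix exactly once.")
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu_id), ]
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "gutmets_otu")
}

#' @export
print.gutmets_otu <- function(x, ...) {
  cat(sprintf("<gutmets_otu> %d samples x %d OTUs, total reads %s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.gutmets_otu <- function(x) dim(x$counts)

#' Sample and OTU identifiers of an OTU table
#' @param table A `gutmets_otu` object.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
otu_ids <- function(table) colnames(table$counts)

#' Per-sample relative abundances
#' @param table A `gutmets_otu` object.
#' @return Numeric matrix of row-normalised abundances.
#' @export
relative_abundance <- function(table) {
  rs <- rowSums(table$counts)
  if (any(rs == 0)) {
    abort_gutmets("samples with zero total count have undefined composition.",
                  "gutmets_undefined_input")
  }
  sweep(table$counts, 1, rs, "/")
}

#' Long-format view of an OTU table
#'
#' @param x A `gutmets_otu` object.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `otu_id`, `count`, `taxonomy`.
#' @export
as_tibble.gutmets_otu <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(rownames(x$counts), times = ncol(x$counts)),
    otu_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
  dplyr::left_join(long, x$taxonomy, by = "otu_id")
}

# Subset helper used by rarefaction/filtering.
subset_otu <- function(table, samples = NULL, otus = NULL) {
  counts <- table$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(otus)) counts <- counts[, otus, drop = FALSE]
  otu_table(counts, table$taxonomy[table$taxonomy$otu_id %in% colnames(counts), ])
}

#' Split a 7-rank taxonomy string into named ranks
#'
#' Parses Greengenes-style labels (`k__...;p__...;c__...;o__...;f__...;
#' g__...;s__...`) into their seven ranks; missing ranks come back as empty
#' strings. [taxonomy_string()] is the inverse.
#'
#' @param labels Character vector of taxonomy strings.
#' @return Tibble with columns `kingdom`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species`.
#' @export
parse_taxonomy <- function(labels) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  parts <- strsplit(labels, ";", fixed = TRUE)
  rows <- lapply(parts, function(p) {
    p <- trimws(p)
    out <- setNames(rep("", 7), ranks)
    for (piece in p) {
      hit <- startsWith(piece, prefixes)
      if (!any(hit)) {
        abort_format(sprintf("taxonomy piece `%s` lacks a rank prefix.", piece))
      }
      out[which(hit)[1]] <- substring(piece, 4)
    }
    out
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' @rdname parse_taxonomy
#' @param ranks Data frame as produced by [parse_taxonomy()].
#' @export
taxonomy_string <- function(ranks) {
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  cols <- c("kingdom", "phylum", "class", "order", "family", "genus",
            "species")
  check_columns(ranks, cols, "taxonomy ranks")
  apply(as.matrix(ranks[cols]), 1, function(r) {
    paste0(prefixes, r, collapse = ";")
  })
}

# Taxon label at a chosen rank, "Unassigned" when empty or unparseable.
taxon_at_rank <- function(labels, rank = "phylum") {
  ranks <- parse_taxonomy(labels)
  if (!rank %in% names(ranks)) {
    abort_invalid_argument(sprintf("unknown taxonomic rank `%s`.", rank))
  }
  out <- ranks[[rank]]
  out[is.na(out) | out == ""] <- "Unassigned"
  out
}
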