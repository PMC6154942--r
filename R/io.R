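# Readers and writers for the tab-separated formats the pipeline touches
# (OTU tables in native and BIOM-style dense dialects, cohort metadata,
# association records) and Newick trees. Readers validate and reject
# malformed input rather than coercing silently; writers are deterministic
# (fixed column order, 6-significant-digit floats).

#' Write an OTU table as TSV
#'
#' OTUs in rows, samples in columns, a final `taxonomy` column with the
#' 7-rank label; header starts with `#OTU ID` (dense BIOM-style dialect,
#' also accepted by [read_otu_table()]).
#'
#' @param table A `gutmets_otu` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  m <- t(table$counts)
  df <- data.frame(`#OTU ID` = rownames(m), m,
                   taxonomy = table$taxonomy$taxonomy[
                     match(rownames(m), table$taxonomy$otu_id)],
                   check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read an OTU table from TSV
#'
#' Accepts the native dialect written by [write_otu_table()] (leading
#' `#OTU ID` header, trailing `taxonomy` column) or a plain
#' OTU-by-sample/sample-by-OTU matrix whose first header token decides the
#' orientation (`otu_id` or `#OTU ID` means OTUs in rows, `sample_id`
#' means samples in rows). Negative, non-integer or duplicated entries are
#' format errors.
#'
#' @param path File path.
#' @return A validated `gutmets_otu` table (samples x OTUs internally).
#' @export
read_otu_table <- function(path) {
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  first <- header[1]
  df <- suppressMessages(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal"))
  if (anyDuplicated(names(df))) {
    abort_format(sprintf("duplicated column id(s): %s.",
                         paste(names(df)[duplicated(names(df))],
                               collapse = ", ")))
  }
  otus_in_rows <- first %in% c("#OTU ID", "otu_id")
  if (!otus_in_rows && first != "sample_id") {
    abort_format(sprintf(
      "unrecognised leading header token `%s` (expected `#OTU ID`, `otu_id` or `sample_id`).",
      first))
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort_format(sprintf("duplicated row id(s): %s.",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  has_tax <- "taxonomy" %in% names(df)
  value_cols <- setdiff(names(df)[-1], "taxonomy")
  vals <- df[value_cols]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      abort_format(sprintf("non-numeric counts in column `%s`.",
                           value_cols[j]))
    }
    bad <- which(col < 0 | col != round(col))
    if (length(bad) > 0) {
      abort_format(sprintf(
        "negative or non-integer count at row %d, column `%s`.",
        bad[1], value_cols[j]))
    }
  }
  m <- as.matrix(vals)
  if (otus_in_rows) {
    rownames(m) <- ids
    counts <- t(m)
    taxonomy <- tibble::tibble(
      otu_id = ids,
      taxonomy = if (has_tax) as.character(df$taxonomy) else
        "k__;p__;c__;o__;f__;g__;s__")
  } else {
    rownames(m) <- ids
    counts <- m
    taxonomy <- tibble::tibble(
      otu_id = colnames(m),
      taxonomy = "k__;p__;c__;o__;f__;g__;s__")
  }
  storage.mode(counts) <- "integer"
  otu_table(counts, taxonomy)
}

#' Write / read a cohort metadata table
#'
#' Plain TSV, one header row, `sample_id` as the first column.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `path` invisibly (writer); tibble (reader).
#' @export
write_cohort <- function(cohort, path) {
  check_columns(cohort, "sample_id", "cohort")
  readr::write_tsv(dplyr::relocate(cohort, "sample_id"), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- suppressMessages(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  check_columns(df, "sample_id", "cohort file")
  if (anyDuplicated(df$sample_id)) {
    abort_format("duplicated sample_id in cohort file.")
  }
  df
}

# Fixed factor order for association output.
FACTOR_ORDER <- c("waist", "sbp", "dbp", "tg", "hdl", "fbg", "mets",
                  "income", "spending")

#' Write association records as TSV
#'
#' Columns `otu_id`, `taxonomy`, `factor`, `beta`, `p`, `q`, `direction`
#' with a stable sort by (factor, q) and floats serialised at 6 significant
#' digits. Records with non-finite beta are refused.
#'
#' @param records Association records tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(records, path) {
  records <- tibble::as_tibble(records)
  check_columns(records, c("otu_id", "factor", "beta", "p", "q",
                           "direction"), "records")
  bad <- which(!is.finite(records$beta))
  if (length(bad) > 0) {
    abort_format(sprintf(
      "refusing to write non-finite beta for record %d (otu %s, factor %s).",
      bad[1], records$otu_id[bad[1]], records$factor[bad[1]]))
  }
  if (!"taxonomy" %in% names(records)) records$taxonomy <- ""
  fac <- factor(records$factor,
                levels = c(FACTOR_ORDER, setdiff(unique(records$factor),
                                                 FACTOR_ORDER)))
  ord <- order(fac, records$q, records$otu_id, method = "radix")
  out <- records[ord, c("otu_id", "taxonomy", "factor", "beta", "p", "q",
                        "direction")]
  out$beta <- format_num6(out$beta)
  out$p <- format_num6(out$p)
  out$q <- format_num6(out$q)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_associations
#' @export
read_associations <- function(path) {
  df <- suppressMessages(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      otu_id = readr::col_character(),
                      taxonomy = readr::col_character(),
                      factor = readr::col_character(),
                      beta = readr::col_double(),
                      p = readr::col_double(),
                      q = readr::col_double(),
                      direction = readr::col_double())))
  check_columns(df, c("otu_id", "factor", "beta", "p", "q", "direction"),
                "association file")
  df
}

#' Read a rooted Newick tree
#'
#' Single-tree Newick with branch lengths on every edge; unbalanced
#' parentheses, missing lengths or duplicated tip names are parse errors.
#'
#' @param path File path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort_format(
                     sprintf("Newick parse error: %s", conditionMessage(e))),
                   warning = function(w) abort_format(
                     sprintf("Newick parse error: %s", conditionMessage(w))))
  if (is.null(tree)) abort_format("Newick parse error: no tree found.")
  if (inherits(tree, "multiPhylo")) {
    abort_format("expected a single tree, found several.")
  }
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    abort_format("tree is missing branch lengths.")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort_format("duplicated tip names in tree.")
  }
  tree
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write ground-truth effects as TSV
#' @param effects Effects tibble from [plant_effects()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path) {
  readr::write_tsv(effects, path)
  invisible(path)
}

#' Validate that a dataset's pieces fit together
#'
#' Runs the format checks the pipeline needs before analysis: count matrix
#' integrity, sample overlap between table and cohort, required metadata
#' columns, and (when a tree is given) tip coverage of the OTU ids.
#'
#' @param table A `gutmets_otu` table.
#' @param cohort Cohort tibble.
#' @param tree Optional [ape::phylo] tree.
#' @param required_columns Metadata columns the analysis needs.
#' @return Invisibly, a list with counts of shared samples/OTUs.
#' @export
validate_dataset <- function(table, cohort,
                             tree = NULL,
                             required_columns = c("sample_id", "age",
                                                  "gender", "bristol",
                                                  "region", "mets")) {
  check_columns(cohort, required_columns, "cohort")
  shared <- intersect(rownames(table$counts), cohort$sample_id)
  if (length(shared) == 0) {
    abort_format("table and cohort share no sample ids.")
  }
  if (!is.null(tree)) {
    missing <- setdiff(colnames(table$counts), tree$tip.label)
    if (length(missing) > 0) {
      abort_gutmets(sprintf("%d OTU(s) missing from the tree (e.g. %s).",
                            length(missing),
                            paste(head(missing, 3), collapse = ", ")),
                    "gutmets_tree_mismatch")
    }
  }
  invisible(list(n_shared_samples = length(shared),
                 n_otus = ncol(table$counts)))
}
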