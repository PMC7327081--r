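# Readers and writers for the tabular formats the pipeline exchanges:
# expression TSV, stage-label TSV, GMT gene sets, edge lists, feature
# matrices and JSON reports. All readers validate the invariants of the
# objects they return; none impute missing values.

#' Read a gene-by-sample expression matrix from TSV
#'
#' The default dialect is tab-delimited with genes as rows: the first
#' column holds gene identifiers and the header row holds sample
#' identifiers. `orientation = "samples"` transposes input written the
#' other way around. Any missing or non-numeric cell is a hard error;
#' values are never imputed because downstream Pearson correlations on
#' silently imputed data would be misleading.
#'
#' @param path path to a TSV file.
#' @param orientation `"genes"` (rows are genes, default) or `"samples"`.
#' @param delim field delimiter, tab by default.
#' @return a numeric matrix (genes x samples) with gene rownames and
#'   sample colnames, identifiers in file order.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, orientation = c("genes", "samples"),
                                   delim = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(tbl) < 2) {
    abort("expression file needs an identifier column plus at least one value column.")
  }
  ids <- as.character(tbl[[1]])
  vals <- tbl[-1]
  not_num <- !vapply(vals, is.numeric, logical(1))
  if (any(not_num)) {
    col <- names(vals)[which(not_num)[1]]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[which(not_num)[1]]]))))[1]
    abort(sprintf("non-numeric expression value in column \"%s\" (data row %s).",
                  col, ifelse(is.na(row), "?", row)))
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  if (orientation == "samples") {
    mat <- t(mat)
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    abort(sprintf("missing expression value at row \"%s\", column \"%s\"; NA cells are not imputed.",
                  rownames(mat)[bad[1]], colnames(mat)[bad[2]]))
  }
  validate_expression_matrix(mat)
  mat
}

#' Write an expression matrix to TSV
#'
#' Companion writer to [read_expression_matrix()]; a write/read round trip
#' reproduces the matrix exactly (up to numeric text representation).
#'
#' @param expr numeric genes x samples matrix.
#' @param path output path.
#' @param id_column header name for the gene identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, id_column = "gene_id") {
  validate_expression_matrix(expr)
  tbl <- tibble::as_tibble(expr, rownames = id_column)
  readr::write_tsv(tbl, path)
  invisible(path)
}

# Normalization table for the stage vocabulary found in TCGA-style
# annotations: case-insensitive, sub-stages (iia, iiib, ...) collapse to
# the main stage.
.stage_synonyms <- c(
  "control" = "control", "normal" = "control", "healthy" = "control",
  "ctrl" = "control",
  "1" = "1", "i" = "1", "stage1" = "1", "stagei" = "1",
  "2" = "2", "ii" = "2", "stage2" = "2", "stageii" = "2",
  "3" = "3", "iii" = "3", "stage3" = "3", "stageiii" = "3",
  "4" = "4", "iv" = "4", "stage4" = "4", "stageiv" = "4"
)

#' Normalize free-text stage labels
#'
#' Maps the common spellings of stage annotations onto the five canonical
#' categories `control, 1, 2, 3, 4`. Matching is case-insensitive, ignores
#' whitespace and a leading "stage", converts roman numerals, and collapses
#' sub-stages such as "Stage IIA" to their main stage. Unknown labels are a
#' hard error.
#'
#' @param x character vector of raw labels.
#' @return factor with levels `control, 1, 2, 3, 4`.
#' @export
normalize_stage_labels <- function(x) {
  raw <- as.character(x)
  key <- tolower(gsub("[[:space:]_-]", "", raw))
  key <- sub("^stage", "stage", key)
  # strip sub-stage letter suffixes: iia -> ii, stage3b -> stage3
  key <- sub("^((stage)?(i{1,3}v?|iv|[1-4]))[ab]$", "\\1", key)
  out <- .stage_synonyms[key]
  if (anyNA(out)) {
    abort(paste0("unknown stage label(s): ",
                 toString(unique(raw[is.na(out)]))))
  }
  stage_factor(unname(out))
}

#' Read a two-column sample/stage label table
#'
#' @param path TSV with columns sample_id and stage (header optional but
#'   recommended; headerless two-column files are accepted).
#' @param expr optional companion expression matrix; when given, every
#'   labelled sample must exist in it and vice versa.
#' @return tibble with columns `sample_id` (character) and `stage`
#'   (factor with levels control, 1, 2, 3, 4).
#' @export
read_stage_labels <- function(path, expr = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  tbl <- readr::read_tsv(
    path, col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(tbl) < 2) {
    abort("label file must have two tab-separated columns: sample_id, stage.")
  }
  if (nrow(tbl) && grepl("sample", tolower(tbl[[1]][1]))) {
    tbl <- tbl[-1, , drop = FALSE]
  }
  names(tbl)[1:2] <- c("sample_id", "stage")
  out <- tibble(
    sample_id = as.character(tbl$sample_id),
    stage = normalize_stage_labels(tbl$stage)
  )
  validate_labels(out)
  if (!is.null(expr)) {
    validate_expression_matrix(expr)
    missing_lab <- setdiff(colnames(expr), out$sample_id)
    missing_expr <- setdiff(out$sample_id, colnames(expr))
    if (length(missing_lab) || length(missing_expr)) {
      abort(paste0(
        "labels and expression matrix disagree; ",
        if (length(missing_lab)) paste0("unlabelled sample(s): ", toString(head(missing_lab, 10)), "; ") else "",
        if (length(missing_expr)) paste0("label(s) with no sample: ", toString(head(missing_expr, 10))) else ""
      ))
    }
  }
  out
}

#' Write a sample/stage label table
#' @param labels tibble with `sample_id` and `stage`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_stage_labels <- function(labels, path) {
  validate_labels(labels)
  readr::write_tsv(
    tibble(sample_id = labels$sample_id, stage = as.character(labels$stage)),
    path
  )
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one gene set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are collapsed (set semantics). A line with fewer than three fields
#' is a hard error reported with its line number.
#'
#' @param path GMT file path.
#' @return tibble with columns `pathway_id`, `description` and `genes`
#'   (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(pathway_id = character(), description = character(),
                  genes = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.", short[1]))
  }
  out <- tibble(
    pathway_id = vapply(parts, `[[`, character(1), 1L),
    description = vapply(parts, `[[`, character(1), 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
  if (anyDuplicated(out$pathway_id)) {
    abort(paste0("duplicate pathway identifier(s): ",
                 toString(unique(out$pathway_id[duplicated(out$pathway_id)]))))
  }
  if (any(lengths(out$genes) == 0L)) {
    abort("GMT contains a pathway with an empty gene set.")
  }
  out
}

#' Write gene sets in GMT format
#' @param pathways tibble as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- purrr::pmap_chr(
    list(pathways$pathway_id, pathways$description, pathways$genes),
    function(id, desc, genes) paste(c(id, desc, genes), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a co-expression edge list
#' @param path TSV with columns gene_a, gene_b, rho, p_value.
#' @return tibble with those columns, gene pairs in canonical
#'   (lexicographic) order.
#' @export
read_edge_list <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_a = readr::col_character(), gene_b = readr::col_character(),
    rho = readr::col_double(), p_value = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  canonicalize_pairs(tbl)
}

#' Write a co-expression edge list
#' @param edges tibble with columns gene_a, gene_b, rho, p_value.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges[, c("gene_a", "gene_b", "rho", "p_value")], path)
  invisible(path)
}

#' Read a samples-by-positions feature matrix
#' @param path TSV written by [write_feature_matrix()]: first column
#'   `sample_id`, remaining columns one per layout position.
#' @return tibble with `sample_id` plus numeric feature columns.
#' @export
read_feature_matrix <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
}

#' Write a samples-by-positions feature matrix
#' @param features tibble with `sample_id` plus numeric feature columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}

#' Write a report object as JSON
#' @param x a list or tibble-like report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
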