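# Shared internal helpers: stage levels, seed derivation, expression-scale
# handling, layout checksums.

STAGE_LEVELS <- c("control", "1", "2", "3", "4")
CANCER_STAGES <- c("1", "2", "3", "4")

stage_factor <- function(x) {
  factor(as.character(x), levels = STAGE_LEVELS)
}

cancer_stage_factor <- function(x) {
  factor(as.character(x), levels = CANCER_STAGES)
}

assert_stage <- function(stage) {
  stage <- as.character(stage)
  if (length(stage) != 1L || !stage %in% CANCER_STAGES) {
    abort("`stage` must be one of \"1\", \"2\", \"3\", \"4\".")
  }
  stage
}

# Derive independent child seeds from one master seed without consuming the
# caller's RNG stream. Kept below .Machine$integer.max.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Put an expression matrix on the log scale used for correlation
#'
#' Pearson correlations and fold changes are computed on log-scale
#' expression. When the input looks like raw counts (non-negative and
#' integer-valued) it is converted to log2(CPM + 1); log-scale input is
#' passed through unchanged.
#'
#' @param expr numeric genes x samples matrix with dimnames.
#' @param scale `"auto"` (detect counts), `"log"` (no transform) or
#'   `"counts"` (force the CPM transform).
#' @return a numeric matrix on the log2 scale.
#' @export
normalize_log_scale <- function(expr, scale = c("auto", "log", "counts")) {
  scale <- match.arg(scale)
  validate_expression_matrix(expr)
  is_counts <- switch(scale,
    counts = TRUE,
    log = FALSE,
    auto = all(expr >= 0) && all(abs(expr - round(expr)) < 1e-8) && max(expr) > 50
  )
  if (!is_counts) {
    return(expr)
  }
  lib <- colSums(expr)
  if (any(lib == 0)) {
    abort("cannot compute CPM: some samples have zero total counts.")
  }
  log2(sweep(expr, 2, lib / 1e6, "/") + 1)
}

validate_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("expression must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("expression matrix must have gene rownames and sample colnames.")
  }
  dup_g <- rownames(expr)[duplicated(rownames(expr))]
  if (length(dup_g)) {
    abort(paste0("duplicate gene identifier(s): ", toString(unique(dup_g))))
  }
  dup_s <- colnames(expr)[duplicated(colnames(expr))]
  if (length(dup_s)) {
    abort(paste0("duplicate sample identifier(s): ", toString(unique(dup_s))))
  }
  if (!all(is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-finite expression value at gene \"%s\", sample \"%s\".",
      rownames(expr)[bad[1]], colnames(expr)[bad[2]]
    ))
  }
  invisible(expr)
}

validate_labels <- function(labels, expr = NULL) {
  if (!is.data.frame(labels) || !all(c("sample_id", "stage") %in% names(labels))) {
    abort("labels must be a data frame with columns `sample_id` and `stage`.")
  }
  stage <- as.character(labels$stage)
  bad <- setdiff(unique(stage), STAGE_LEVELS)
  if (length(bad)) {
    abort(paste0("unknown stage label(s): ", toString(bad)))
  }
  if (anyDuplicated(labels$sample_id)) {
    abort(paste0(
      "duplicate sample_id in labels: ",
      toString(unique(labels$sample_id[duplicated(labels$sample_id)]))
    ))
  }
  if (!is.null(expr)) {
    missing <- setdiff(labels$sample_id, colnames(expr))
    if (length(missing)) {
      abort(paste0(
        "labelled sample(s) absent from the expression matrix: ",
        toString(head(missing, 10))
      ))
    }
  }
  invisible(labels)
}

# Stable checksum of a feature layout; rlang::hash gives a persistent
# hash of the serialized object.
layout_checksum <- function(layout) {
  rlang::hash(list(
    stage = as.character(layout$stage),
    gene_a = layout$gene_a,
    gene_b = layout$gene_b
  ))
}
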