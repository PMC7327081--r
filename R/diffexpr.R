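# Per-stage differential expression (stage vs control) and the
# variance-balanced DEG selection that equalizes gene-set sizes across the
# four stages before network construction.

#' Identify differentially expressed genes for one stage versus control
#'
#' The built-in test is Welch's two-sample t-test on log2-scale
#' expression, with the log2 fold change taken as the difference of group
#' means on that scale. A gene is called differentially expressed when
#' `|log_fc| > logfc_cut` and `p_value < p_cut`, both strict. No multiple
#' testing correction is applied at this step: the screen is deliberately
#' permissive and downstream network construction applies its own
#' filtering. An externally computed DE table (e.g. from edgeR) can be
#' supplied through `de_table` and is pushed through the identical
#' thresholds.
#'
#' @param expr numeric genes x samples matrix.
#' @param labels tibble with `sample_id`, `stage`.
#' @param stage cancer stage, one of `"1".."4"`.
#' @param logfc_cut fold-change cutoff on the log2 scale (strict `>`).
#' @param p_cut p-value cutoff (strict `<`).
#' @param de_table optional data frame with columns `gene_id`, `log_fc`,
#'   `p_value` replacing the built-in test.
#' @param scale expression scale handling, see [normalize_log_scale()].
#' @return tibble with columns `gene_id`, `log_fc`, `p_value`,
#'   `direction` (`"up"`/`"down"`), containing exactly the genes passing
#'   both cutoffs. Genes constant in both groups are skipped with a
#'   message.
#' @export
identify_degs <- function(expr, labels, stage,
                          logfc_cut = 2.5, p_cut = 0.05,
                          de_table = NULL,
                          scale = c("auto", "log", "counts")) {
  stage <- assert_stage(stage)
  if (is.null(de_table)) {
    validate_labels(labels, expr)
    lx <- normalize_log_scale(expr, scale)
    ctrl <- labels$sample_id[labels$stage == "control"]
    canc <- labels$sample_id[labels$stage == stage]
    if (length(ctrl) < 2 || length(canc) < 2) {
      abort(sprintf(
        "stage \"%s\" needs at least 2 control and 2 stage samples (have %d and %d).",
        stage, length(ctrl), length(canc)
      ))
    }
    tab <- welch_de_table(lx[, canc, drop = FALSE], lx[, ctrl, drop = FALSE])
    n_const <- sum(is.na(tab$p_value))
    if (n_const > 0) {
      inform(sprintf(
        "identify_degs: skipped %d gene(s) constant in both groups (stage %s).",
        n_const, stage
      ))
      tab <- tab[!is.na(tab$p_value), ]
    }
  } else {
    needed <- c("gene_id", "log_fc", "p_value")
    if (!all(needed %in% names(de_table))) {
      abort("`de_table` must have columns gene_id, log_fc, p_value.")
    }
    tab <- tibble(
      gene_id = as.character(de_table$gene_id),
      log_fc = as.numeric(de_table$log_fc),
      p_value = as.numeric(de_table$p_value)
    )
  }
  out <- dplyr::filter(tab, abs(.data$log_fc) > logfc_cut, .data$p_value < p_cut)
  dplyr::mutate(out, direction = ifelse(.data$log_fc > 0, "up", "down"))
}

# Vectorized per-gene Welch t-test of cancer vs control on log-scale
# matrices; returns NA p for genes with zero variance in both groups.
welch_de_table <- function(canc, ctrl) {
  n1 <- ncol(canc); n2 <- ncol(ctrl)
  m1 <- rowMeans(canc); m2 <- rowMeans(ctrl)
  v1 <- rowSums((canc - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[v1 == 0 & v2 == 0] <- NA_real_
  tibble(gene_id = rownames(canc), log_fc = unname(m1 - m2),
         p_value = unname(p))
}

#' Identify DEGs for all four stages
#'
#' Convenience wrapper running [identify_degs()] per stage and binding the
#' results with a `stage` column.
#'
#' @inheritParams identify_degs
#' @return tibble with columns `stage`, `gene_id`, `log_fc`, `p_value`,
#'   `direction`.
#' @export
identify_degs_all <- function(expr, labels, logfc_cut = 2.5, p_cut = 0.05,
                              scale = c("auto", "log", "counts")) {
  purrr::map_dfr(CANCER_STAGES, function(s) {
    dplyr::mutate(
      identify_degs(expr, labels, s, logfc_cut, p_cut, scale = scale),
      stage = s, .before = 1
    )
  })
}

#' Balance DEG set sizes across stages by expression variance
#'
#' To keep the four stage networks comparable in size, every stage keeps
#' the same number of genes: `n`, the smallest per-stage DEG count. Each
#' stage retains its `n` DEGs with the largest expression variance,
#' computed over that stage's cancer samples (optionally restricted via
#' `variance_samples`). Ties in variance break by gene identifier order.
#'
#' @param degs tibble as from [identify_degs_all()] (columns `stage`,
#'   `gene_id`, plus any record columns, e.g. `log_fc`, `direction`).
#' @param expr numeric genes x samples matrix.
#' @param labels tibble with `sample_id`, `stage`.
#' @param variance_samples optional character vector restricting which
#'   samples enter the variance computation (intersected with each
#'   stage's samples); default uses all of the stage's samples.
#' @param scale expression scale handling, see [normalize_log_scale()].
#' @return the input tibble with a logical `selected` column and a
#'   numeric `variance` column; exactly `n` genes are selected per stage.
#' @export
balance_deg_sets <- function(degs, expr, labels, variance_samples = NULL,
                             scale = c("auto", "log", "counts")) {
  validate_labels(labels, expr)
  if (!all(c("stage", "gene_id") %in% names(degs))) {
    abort("`degs` must have columns `stage` and `gene_id`.")
  }
  counts <- table(factor(as.character(degs$stage), levels = CANCER_STAGES))
  if (any(counts == 0)) {
    abort(paste0(
      "stage(s) with zero DEGs: ",
      toString(names(counts)[counts == 0]),
      "; relax `logfc_cut`/`p_cut` or check the labels."
    ))
  }
  n_keep <- min(counts)
  lx <- normalize_log_scale(expr, scale)
  out <- purrr::map_dfr(CANCER_STAGES, function(s) {
    block <- degs[as.character(degs$stage) == s, , drop = FALSE]
    s_samples <- labels$sample_id[labels$stage == s]
    if (!is.null(variance_samples)) {
      s_samples <- intersect(s_samples, variance_samples)
    }
    if (length(s_samples) < 2) {
      abort(sprintf("stage \"%s\": fewer than 2 samples for variance ranking.", s))
    }
    v <- apply(lx[block$gene_id, s_samples, drop = FALSE], 1, var)
    block$variance <- unname(v)
    ord <- order(-block$variance, block$gene_id)
    block$selected <- FALSE
    block$selected[ord[seq_len(n_keep)]] <- TRUE
    block
  })
  stopifnot(all(tapply(out$selected, out$stage, sum) == n_keep))
  as_tibble(out)
}
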