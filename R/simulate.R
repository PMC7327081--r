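# Latent-factor simulator of stage-stratified expression with planted
# stage-specific co-expression modules. Every downstream stage of the
# pipeline is testable against the planted ground truth it returns.

#' Simulate stage-stratified expression with planted co-expression modules
#'
#' Generates a log2-scale expression matrix for five sample groups
#' (control plus stages 1-4). Each cancer stage owns
#' `modules_per_stage` gene modules of `module_size` genes. Within a
#' module, genes load on one shared latent factor per sample, so that for
#' samples of the owning stage the population pairwise correlation between
#' module genes equals `within_module_correlation` in magnitude; loading
#' signs are random, so roughly half the within-module pairs are
#' negatively correlated, as in real co-expression modules. Module genes
#' are also differentially expressed in their stage: each gene's mean is
#' shifted by `de_effect_logfc` log2 units relative to control, with a
#' random direction (up or down) independent of its loading sign. On all
#' other samples (controls and other stages) module genes are independent
#' baseline noise, and non-module genes are independent noise everywhere.
#'
#' With `shared_modules = TRUE` all four stages are assigned the same
#' module genes with the same loadings and shifts, making every cancer
#' stage statistically identical — the negative control under which stage
#' classification must fall to chance.
#'
#' @param n_genes total number of genes.
#' @param samples_per_group samples in each of control, stage 1..4.
#' @param modules_per_stage planted modules per stage.
#' @param module_size genes per module.
#' @param within_module_correlation target |PCC| between module genes on
#'   the owning stage's samples, in (0, 1).
#' @param de_effect_logfc |log2 fold change| of module genes, stage vs
#'   control.
#' @param noise_sd marginal residual standard deviation on the log2 scale.
#' @param baseline_mean baseline log2 expression level.
#' @param shared_modules plant identical modules in all four stages
#'   (uninformative-feature negative control).
#' @param exponentiate emit `2^x` pseudo-counts instead of log2 values.
#' @param seed integer; fixed seed gives byte-identical output.
#' @return a list of class `staged_sim` with elements
#'   \describe{
#'     \item{expr}{genes x samples numeric matrix}
#'     \item{labels}{tibble (`sample_id`, `stage`)}
#'     \item{truth}{list with `modules` (tibble: stage, module, gene_id,
#'       loading_sign, de_direction) and `degs` (tibble: stage, gene_id,
#'       log_fc)}
#'     \item{config}{the resolved simulation parameters}
#'   }
#' @export
simulate_staged_expression <- function(n_genes = 300,
                                       samples_per_group = 60,
                                       modules_per_stage = 2,
                                       module_size = 15,
                                       within_module_correlation = 0.9,
                                       de_effect_logfc = 3,
                                       noise_sd = 0.5,
                                       baseline_mean = 7,
                                       shared_modules = FALSE,
                                       exponentiate = FALSE,
                                       seed = 1L) {
  rho <- within_module_correlation
  if (!(rho > 0 && rho < 1)) {
    abort("`within_module_correlation` must lie strictly between 0 and 1.")
  }
  n_module_genes <- modules_per_stage * module_size *
    (if (shared_modules) 1L else 4L)
  if (n_module_genes > n_genes) {
    abort(sprintf(
      "infeasible config: %d module genes exceed n_genes = %d.",
      n_module_genes, n_genes
    ))
  }
  config <- list(
    n_genes = n_genes, samples_per_group = samples_per_group,
    modules_per_stage = modules_per_stage, module_size = module_size,
    within_module_correlation = rho, de_effect_logfc = de_effect_logfc,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    shared_modules = shared_modules, exponentiate = exponentiate,
    seed = as.integer(seed)
  )

  with_seed(seed, {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    groups <- STAGE_LEVELS
    sample_ids <- unlist(lapply(groups, function(g) {
      sprintf("%s_S%03d", ifelse(g == "control", "ctrl", paste0("st", g)),
              seq_len(samples_per_group))
    }))
    labels <- tibble(
      sample_id = sample_ids,
      stage = stage_factor(rep(groups, each = samples_per_group))
    )
    n_samples <- length(sample_ids)

    # assign module genes
    pool <- sample(gene_ids, n_module_genes)
    assign_stage <- function(genes) {
      m <- matrix(genes, ncol = modules_per_stage)
      purrr::map_dfr(seq_len(modules_per_stage), function(j) {
        tibble(module = j, gene_id = m[, j])
      })
    }
    if (shared_modules) {
      base_assign <- assign_stage(pool)
      base_assign$loading_sign <- sample(c(-1, 1), nrow(base_assign), replace = TRUE)
      base_assign$de_direction <- sample(c(-1, 1), nrow(base_assign), replace = TRUE)
      modules <- purrr::map_dfr(CANCER_STAGES, function(s) {
        dplyr::mutate(base_assign, stage = s, .before = 1)
      })
    } else {
      split_pool <- matrix(pool, ncol = 4)
      modules <- purrr::map_dfr(seq_along(CANCER_STAGES), function(i) {
        a <- assign_stage(split_pool[, i])
        a$loading_sign <- sample(c(-1, 1), nrow(a), replace = TRUE)
        a$de_direction <- sample(c(-1, 1), nrow(a), replace = TRUE)
        dplyr::mutate(a, stage = CANCER_STAGES[i], .before = 1)
      })
    }

    # baseline: independent noise everywhere
    expr <- matrix(
      stats::rnorm(n_genes * n_samples, mean = baseline_mean, sd = noise_sd),
      nrow = n_genes, dimnames = list(gene_ids, sample_ids)
    )

    # overwrite module genes on their owning stage's samples with the
    # factor structure plus the DE shift
    for (s in CANCER_STAGES) {
      s_samples <- labels$sample_id[labels$stage == s]
      mod_s <- modules[modules$stage == s, ]
      for (j in unique(mod_s$module)) {
        genes_j <- mod_s[mod_s$module == j, ]
        f <- stats::rnorm(length(s_samples))                 # latent factor
        eps <- matrix(stats::rnorm(nrow(genes_j) * length(s_samples)),
                      nrow = nrow(genes_j))
        z <- (genes_j$loading_sign * sqrt(rho)) %o% f + sqrt(1 - rho) * eps
        shift <- genes_j$de_direction * de_effect_logfc
        expr[genes_j$gene_id, s_samples] <-
          baseline_mean + shift + noise_sd * z
      }
    }

    degs <- dplyr::transmute(modules,
      stage = .data$stage, gene_id = .data$gene_id,
      log_fc = .data$de_direction * de_effect_logfc
    )

    if (exponentiate) {
      expr <- 2^expr
    }

    structure(
      list(expr = expr, labels = labels,
           truth = list(modules = as_tibble(modules), degs = degs),
           config = config),
      class = "staged_sim"
    )
  })
}

#' @export
print.staged_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<staged_sim> %d genes x %d samples (%d per group), %d module(s)/stage of %d genes\n",
    cfg$n_genes, ncol(x$expr), cfg$samples_per_group,
    cfg$modules_per_stage, cfg$module_size
  ))
  cat(sprintf(
    "  |PCC| target %.2f, |log2FC| %.1f, noise sd %.2f, seed %d%s\n",
    cfg$within_module_correlation, cfg$de_effect_logfc, cfg$noise_sd,
    cfg$seed, if (cfg$shared_modules) ", shared modules" else ""
  ))
  invisible(x)
}
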