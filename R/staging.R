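# The 4-way staging classifier and the full evaluation protocol:
# stratified 30/40/30 split, repeated stratified cross-validation for
# hyperparameter selection, test-set prediction, and per-stage
# sensitivity/specificity, accuracy and Cohen's kappa averaged over
# outer iterations.

#' Stratified reference/training/test split
#'
#' Within each cancer stage, samples are partitioned into reference,
#' training and test sets by a seeded permutation. Reference and test
#' sizes are `floor(fraction * n)`; the remainder goes to training,
#' which benefits most from extra samples.
#'
#' @param labels tibble with `sample_id`, `stage`; control samples are
#'   ignored (they take no part in networks or classification).
#' @param fractions numeric length-3 vector (reference, training, test)
#'   summing to 1.
#' @param seed integer seed for the permutation.
#' @return tibble with columns `sample_id`, `stage`, `role` in
#'   `c("reference", "training", "test")`.
#' @export
split_samples <- function(labels, fractions = c(0.3, 0.4, 0.3), seed = 1L) {
  validate_labels(labels)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three numbers (reference, training, test) summing to 1.")
  }
  cancer <- labels[labels$stage != "control", , drop = FALSE]
  with_seed(seed, {
    purrr::map_dfr(CANCER_STAGES, function(s) {
      ids <- cancer$sample_id[cancer$stage == s]
      n <- length(ids)
      n_ref <- floor(fractions[1] * n)
      n_test <- floor(fractions[3] * n)
      n_train <- n - n_ref - n_test
      if (min(n_ref, n_train, n_test) < 1) {
        abort(sprintf(
          "stage \"%s\" has too few samples (%d) for a %s split.",
          s, n, paste(fractions, collapse = "/")
        ))
      }
      perm <- sample(ids)
      tibble(
        sample_id = perm,
        stage = s,
        role = rep(c("reference", "training", "test"),
                   times = c(n_ref, n_train, n_test))
      )
    })
  })
}

feature_matrix_to_xy <- function(features) {
  if (!"sample_id" %in% names(features)) {
    abort("feature table must have a `sample_id` column.")
  }
  x <- as.matrix(features[, setdiff(names(features), "sample_id"), drop = FALSE])
  rownames(x) <- features$sample_id
  storage.mode(x) <- "double"
  x
}

make_cv_folds <- function(y, k) {
  # stratified folds: spread each class round-robin over a shuffled order
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the stage classifier with repeated cross-validated tuning
#'
#' Hyperparameters are selected from the backend's grid by stratified
#' k-fold cross-validation repeated `cv_repeats` times, maximizing
#' overall accuracy; the winning configuration is refit on all training
#' samples. The fitted handle records the feature-layout checksum so that
#' prediction refuses features built under a different network manifest.
#'
#' @param features feature tibble from [build_feature_matrix()] (or any
#'   tibble with `sample_id` plus numeric columns and a `"checksum"`
#'   attribute).
#' @param truth tibble with `sample_id`, `stage` covering every feature
#'   row.
#' @param backend one of [list_backends()]; default `"boosted_tree"`.
#' @param cv_folds folds per repeat (default 3).
#' @param cv_repeats cross-validation repeats (default 100).
#' @param grid optional data frame overriding the backend's grid.
#' @param seed integer controlling fold assignment and learner seeds.
#' @return an object of class `stage_model`: the refit backend model,
#'   the CV results per grid row, the chosen parameters, and the layout
#'   checksum.
#' @export
train_classifier <- function(features, truth, backend = "boosted_tree",
                             cv_folds = 3, cv_repeats = 100,
                             grid = NULL, seed = 1L) {
  entry <- get_backend(backend)
  x <- feature_matrix_to_xy(features)
  y_map <- setNames(as.character(truth$stage), truth$sample_id)
  missing <- setdiff(rownames(x), names(y_map))
  if (length(missing)) {
    abort(paste0("no stage label for sample(s): ", toString(head(missing, 10))))
  }
  y <- cancer_stage_factor(y_map[rownames(x)])
  if (anyNA(y)) {
    abort("training labels must be cancer stages 1-4.")
  }
  if (nlevels(droplevels(y)) < 2) {
    abort("training set must contain at least 2 stages.")
  }
  if (cv_folds < 2) {
    abort("`cv_folds` must be at least 2.")
  }
  # constant columns carry no signal and break some learners
  keep <- which(apply(x, 2, function(col) diff(range(col)) > 0))
  if (!length(keep)) {
    abort("all feature columns are constant.")
  }
  xk <- x[, keep, drop = FALSE]
  grid <- grid %||% entry$grid
  grid <- as.data.frame(grid)

  seeds <- derive_seeds(seed, cv_repeats + 1L)
  cv <- with_seed(seed, {
    acc <- matrix(NA_real_, nrow = nrow(grid), ncol = cv_repeats)
    for (r in seq_len(cv_repeats)) {
      set.seed(seeds[r])
      fold <- make_cv_folds(y, cv_folds)
      for (g in seq_len(nrow(grid))) {
        hits <- 0L
        for (k in seq_len(cv_folds)) {
          tr <- fold != k
          fit <- entry$fit(xk[tr, , drop = FALSE], droplevels(y[tr]),
                           grid[g, , drop = FALSE], seed = seeds[r] + k)
          pred <- entry$predict(fit, xk[!tr, , drop = FALSE])
          hits <- hits + sum(as.character(pred) == as.character(y[!tr]))
        }
        acc[g, r] <- hits / length(y)
      }
    }
    acc
  })
  cv_results <- dplyr::mutate(
    as_tibble(grid),
    mean_accuracy = rowMeans(cv),
    sd_accuracy = apply(cv, 1, sd)
  )
  best <- which.max(cv_results$mean_accuracy)
  final <- entry$fit(xk, y, grid[best, , drop = FALSE], seed = seeds[cv_repeats + 1L])

  structure(
    list(
      backend = backend,
      fit = final,
      best_params = as_tibble(grid[best, , drop = FALSE]),
      cv_results = cv_results,
      cv_folds = cv_folds,
      cv_repeats = cv_repeats,
      kept_columns = colnames(x)[keep],
      feature_names = colnames(x),
      levels = levels(y),
      layout_checksum = attr(features, "checksum", exact = TRUE),
      seed = as.integer(seed)
    ),
    class = "stage_model"
  )
}

#' @export
print.stage_model <- function(x, ...) {
  cat(sprintf(
    "<stage_model backend=%s> %d features (%d used), CV %d-fold x %d repeats, best accuracy %.3f\n",
    x$backend, length(x$feature_names), length(x$kept_columns),
    x$cv_folds, x$cv_repeats, max(x$cv_results$mean_accuracy)
  ))
  invisible(x)
}

#' @describeIn train_classifier tidy() returns the per-grid-row CV results.
#' @param x a `stage_model`.
#' @param ... unused.
#' @export
tidy.stage_model <- function(x, ...) {
  x$cv_results
}

#' @describeIn train_classifier glance() returns a one-row model summary.
#' @export
glance.stage_model <- function(x, ...) {
  tibble(
    backend = x$backend,
    n_features = length(x$feature_names),
    cv_folds = x$cv_folds,
    cv_repeats = x$cv_repeats,
    cv_accuracy = max(x$cv_results$mean_accuracy)
  )
}

#' Predict the stage of new samples
#'
#' @param model a `stage_model` from [train_classifier()].
#' @param features feature tibble built under the same network manifest
#'   (checksum-verified when both sides carry one).
#' @return tibble with `sample_id` and `predicted_stage` (factor 1-4).
#' @export
predict_stage <- function(model, features) {
  stopifnot(inherits(model, "stage_model"))
  entry <- get_backend(model$backend)
  chk <- attr(features, "checksum", exact = TRUE)
  if (!is.null(chk) && !is.null(model$layout_checksum) &&
      !identical(chk, model$layout_checksum)) {
    abort("feature layout checksum mismatch: features were built under a different network manifest.")
  }
  x <- feature_matrix_to_xy(features)
  missing <- setdiff(model$feature_names, colnames(x))
  if (length(missing)) {
    abort(paste0("features lack position column(s): ", toString(head(missing, 5))))
  }
  pred <- entry$predict(model$fit, x[, model$kept_columns, drop = FALSE])
  tibble(
    sample_id = features$sample_id,
    predicted_stage = cancer_stage_factor(as.character(pred))
  )
}

#' Evaluate stage predictions against annotated stages
#'
#' Builds the 4x4 confusion matrix (rows = predicted, columns =
#' annotated) and derives per-stage one-vs-rest sensitivity and
#' specificity, overall accuracy, and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement from the
#' row/column marginal products.
#'
#' @param predictions tibble with `sample_id`, `predicted_stage`.
#' @param truth tibble with `sample_id`, `stage`.
#' @return an object of class `stage_eval`: `confusion` (matrix),
#'   `per_stage` (tibble: stage, sensitivity, specificity), `accuracy`,
#'   `kappa`, `n`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (!nrow(predictions)) {
    abort("empty prediction set.")
  }
  truth_map <- setNames(as.character(truth$stage), truth$sample_id)
  missing <- setdiff(predictions$sample_id, names(truth_map))
  if (length(missing)) {
    abort(paste0("no truth label for sample(s): ", toString(head(missing, 10))))
  }
  pred <- cancer_stage_factor(predictions$predicted_stage)
  annot <- cancer_stage_factor(truth_map[predictions$sample_id])
  conf <- table(predicted = pred, annotated = annot)
  conf <- unclass(conf)
  metrics_from_confusion(conf)
}

# Shared derivation of the report metrics from a predicted-by-annotated
# count matrix.
metrics_from_confusion <- function(conf) {
  total <- sum(conf)
  acc <- sum(diag(conf)) / total
  per_stage <- purrr::map_dfr(seq_len(nrow(conf)), function(i) {
    tp <- conf[i, i]
    fn <- sum(conf[, i]) - tp       # annotated i, predicted elsewhere
    fp <- sum(conf[i, ]) - tp       # predicted i, annotated elsewhere
    tn <- total - tp - fn - fp
    tibble(
      stage = colnames(conf)[i],
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    )
  })
  p_e <- sum(rowSums(conf) * colSums(conf)) / total^2
  kappa <- if (p_e < 1) (acc - p_e) / (1 - p_e) else 0
  structure(
    list(confusion = conf, per_stage = per_stage, accuracy = acc,
         kappa = kappa, n = total),
    class = "stage_eval"
  )
}

#' @export
print.stage_eval <- function(x, ...) {
  cat(sprintf("<stage_eval> n = %d, accuracy = %.4f, kappa = %.4f\n", x$n,
              x$accuracy, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' @describeIn evaluate_predictions tidy() returns per-stage sensitivity
#'   and specificity.
#' @param x a `stage_eval`.
#' @param ... unused.
#' @export
tidy.stage_eval <- function(x, ...) {
  x$per_stage
}

#' @describeIn evaluate_predictions glance() returns accuracy, kappa and n.
#' @export
glance.stage_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, kappa = x$kappa, n = x$n)
}

#' Run the full staging protocol
#'
#' One iteration performs the complete pipeline: stratified 30/40/30
#' split, per-stage DEG identification (stage vs control) and
#' variance-balanced selection, reference-network construction, feature
#' building for training and test samples, cross-validated training, and
#' test-set evaluation. The protocol repeats this `n_iterations` times
#' with per-iteration seeds derived from `seed` and reports each metric's
#' mean and standard deviation across iterations.
#'
#' By default the DEG step and its variance ranking use all of a stage's
#' samples, mirroring a workflow in which differential expression is
#' established on the full cohort before splitting; `strict_split = TRUE`
#' restricts both to the reference + training samples so that no test
#' sample can influence feature definition.
#'
#' @param expr numeric genes x samples matrix.
#' @param labels tibble with `sample_id`, `stage` (must include control
#'   samples).
#' @param logfc_cut,p_cut DEG cutoffs (log2 scale; strict inequalities).
#' @param tau,network_p_cut co-expression edge cutoffs.
#' @param fractions reference/training/test fractions.
#' @param backend classifier backend, see [list_backends()].
#' @param cv_folds,cv_repeats cross-validation settings.
#' @param n_iterations outer repetitions of the whole pipeline.
#' @param strict_split restrict DEG calling and variance ranking to
#'   reference + training samples.
#' @param scale expression scale handling, see [normalize_log_scale()].
#' @param seed master seed; all per-iteration seeds derive from it.
#' @return an object of class `stage_protocol`: `iterations` (list of
#'   per-iteration results with the `stage_eval`, split and model
#'   summaries), `metrics` (tibble of per-metric mean and sd), `config`.
#' @export
run_protocol <- function(expr, labels,
                         logfc_cut = 2.5, p_cut = 0.05,
                         tau = 0.7, network_p_cut = 0.05,
                         fractions = c(0.3, 0.4, 0.3),
                         backend = "boosted_tree",
                         cv_folds = 3, cv_repeats = 100,
                         n_iterations = 10,
                         strict_split = FALSE,
                         scale = c("auto", "log", "counts"),
                         seed = 1L) {
  scale <- match.arg(scale)
  validate_labels(labels, expr)
  lx <- normalize_log_scale(expr, scale)
  iter_seeds <- derive_seeds(seed, n_iterations)

  iterations <- lapply(seq_len(n_iterations), function(i) {
    run_protocol_once(
      lx, labels, logfc_cut, p_cut, tau, network_p_cut, fractions,
      backend, cv_folds, cv_repeats, strict_split, seed = iter_seeds[i]
    )
  })

  metric_tbl <- purrr::map_dfr(seq_along(iterations), function(i) {
    ev <- iterations[[i]]$eval
    dplyr::bind_rows(
      tibble(metric = "accuracy", value = ev$accuracy),
      tibble(metric = "kappa", value = ev$kappa),
      tibble(
        metric = c(
          paste0("sensitivity_stage", ev$per_stage$stage),
          paste0("specificity_stage", ev$per_stage$stage)
        ),
        value = c(ev$per_stage$sensitivity, ev$per_stage$specificity)
      )
    ) |>
      dplyr::mutate(iteration = i, .before = 1)
  })
  metrics <- metric_tbl |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (dplyr::n() > 1) sd(.data$value, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )

  structure(
    list(
      iterations = iterations,
      iteration_metrics = metric_tbl,
      metrics = metrics,
      config = list(
        logfc_cut = logfc_cut, p_cut = p_cut, tau = tau,
        network_p_cut = network_p_cut, fractions = fractions,
        backend = backend, cv_folds = cv_folds, cv_repeats = cv_repeats,
        n_iterations = n_iterations, strict_split = strict_split,
        seed = as.integer(seed)
      )
    ),
    class = "stage_protocol"
  )
}

run_protocol_once <- function(lx, labels, logfc_cut, p_cut, tau, network_p_cut,
                              fractions, backend, cv_folds, cv_repeats,
                              strict_split, seed) {
  sub_seeds <- derive_seeds(seed, 2L)
  split <- split_samples(labels, fractions, seed = sub_seeds[1])

  non_test <- split$sample_id[split$role != "test"]
  deg_labels <- if (strict_split) {
    dplyr::bind_rows(
      labels[labels$stage == "control", ],
      labels[labels$sample_id %in% non_test, ]
    )
  } else {
    labels
  }
  deg_expr_cols <- deg_labels$sample_id
  degs <- identify_degs_all(lx[, deg_expr_cols, drop = FALSE], deg_labels,
                            logfc_cut, p_cut, scale = "log")
  balanced <- balance_deg_sets(
    degs, lx, labels,
    variance_samples = if (strict_split) non_test else NULL,
    scale = "log"
  )

  networks <- lapply(CANCER_STAGES, function(s) {
    ref <- split$sample_id[split$stage == s & split$role == "reference"]
    genes <- balanced$gene_id[balanced$stage == s & balanced$selected]
    build_stage_network(lx, ref, genes, tau = tau, p_cut = network_p_cut,
                        stage = s, scale = "log")
  })

  train_ids <- split$sample_id[split$role == "training"]
  test_ids <- split$sample_id[split$role == "test"]
  feats_train <- build_feature_matrix(networks, lx, train_ids, scale = "log")
  feats_test <- build_feature_matrix(networks, lx, test_ids, scale = "log")

  truth <- tibble(sample_id = split$sample_id, stage = split$stage)
  model <- train_classifier(feats_train, truth, backend = backend,
                            cv_folds = cv_folds, cv_repeats = cv_repeats,
                            seed = sub_seeds[2])
  preds <- predict_stage(model, feats_test)
  ev <- evaluate_predictions(preds, truth)

  list(
    split = split,
    degs = balanced,
    networks = networks,
    model_summary = glance(model),
    predictions = preds,
    eval = ev,
    seed = seed
  )
}

#' @export
print.stage_protocol <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<stage_protocol> %d iteration(s), backend %s, CV %d x %d\n",
    cfg$n_iterations, cfg$backend, cfg$cv_folds, cfg$cv_repeats
  ))
  main <- x$metrics[x$metrics$metric %in% c("accuracy", "kappa"), ]
  for (i in seq_len(nrow(main))) {
    cat(sprintf("  %s: %.4f (sd %.4f)\n", main$metric[i], main$mean[i],
                main$sd[i]))
  }
  invisible(x)
}

#' @describeIn run_protocol tidy() returns per-iteration metric values.
#' @param x a `stage_protocol`.
#' @param ... unused.
#' @export
tidy.stage_protocol <- function(x, ...) {
  x$iteration_metrics
}

#' @describeIn run_protocol glance() returns one row with mean accuracy
#'   and kappa.
#' @export
glance.stage_protocol <- function(x, ...) {
  m <- x$metrics
  tibble(
    accuracy = m$mean[m$metric == "accuracy"],
    accuracy_sd = m$sd[m$metric == "accuracy"],
    kappa = m$mean[m$metric == "kappa"],
    kappa_sd = m$sd[m$metric == "kappa"],
    n_iterations = x$config$n_iterations
  )
}
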