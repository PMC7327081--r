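make_labels <- function(ns, stages = c("1", "2", "3", "4")) {
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(sum(ns))),
    stage = factor(rep(stages, ns), levels = c("control", "1", "2", "3", "4"))
  )
}

test_that("stratified split honors the 30/40/30 rule with remainder to training", {
  labels <- make_labels(c(100, 10, 11, 20))
  split <- split_samples(labels, seed = 5)
  counts <- table(split$stage, split$role)
  expect_equal(unname(counts["1", c("reference", "training", "test")]),
               c(30, 40, 30))
  expect_equal(unname(counts["2", c("reference", "training", "test")]),
               c(3, 4, 3))
  expect_equal(unname(counts["3", c("reference", "training", "test")]),
               c(3, 5, 3))
  # disjoint and exhaustive within stages
  expect_setequal(split$sample_id, labels$sample_id)
  expect_false(anyDuplicated(split$sample_id) > 0)
  # reproducible from the seed, different under another
  expect_identical(split, split_samples(labels, seed = 5))
  expect_false(identical(split, split_samples(labels, seed = 6)))

  expect_error(split_samples(make_labels(c(100, 100, 100, 2))), "stage")
  expect_error(split_samples(labels, fractions = c(0.5, 0.6, 0.3)), "summing to 1")
})

test_that("evaluation metrics match hand formulas on known confusions", {
  # perfect predictions
  labels <- make_labels(c(5, 5, 5, 5))
  preds <- tibble::tibble(sample_id = labels$sample_id,
                          predicted_stage = labels$stage)
  ev <- evaluate_predictions(preds, labels)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$kappa, 1)
  expect_true(all(ev$per_stage$sensitivity == 1))
  expect_true(all(ev$per_stage$specificity == 1))

  # constant predictor on balanced classes: accuracy 0.25, kappa 0
  preds2 <- tibble::tibble(sample_id = labels$sample_id,
                           predicted_stage = factor("1", levels = c("1", "2", "3", "4")))
  ev2 <- evaluate_predictions(preds2, labels)
  expect_equal(ev2$accuracy, 0.25)
  expect_equal(ev2$kappa, 0)

  # two-class reduction [[8,2],[2,8]]: accuracy 0.8, kappa 0.6
  truth3 <- make_labels(c(10, 10), stages = c("1", "2"))
  pred_stage <- rep(c("1", "2", "2", "1"), c(8, 2, 8, 2))
  preds3 <- tibble::tibble(
    sample_id = truth3$sample_id,
    predicted_stage = factor(pred_stage, levels = c("1", "2", "3", "4"))
  )
  ev3 <- evaluate_predictions(preds3, truth3)
  expect_equal(ev3$accuracy, 0.8)
  expect_equal(ev3$kappa, 0.6)
})

test_that("evaluation agrees with direct formula oracles on random confusions", {
  set.seed(77)
  for (rep in 1:25) {
    conf <- matrix(rpois(16, lambda = sample(3:20, 1)), 4, 4,
                   dimnames = list(c("1", "2", "3", "4"), c("1", "2", "3", "4")))
    if (sum(conf) == 0) conf[1, 1] <- 1
    # expand the confusion into prediction/truth records
    idx <- which(conf > 0, arr.ind = TRUE)
    pred <- rep(rownames(conf)[idx[, 1]], conf[idx])
    annot <- rep(colnames(conf)[idx[, 2]], conf[idx])
    labels <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_along(annot)),
      stage = factor(annot, levels = c("control", "1", "2", "3", "4"))
    )
    preds <- tibble::tibble(
      sample_id = labels$sample_id,
      predicted_stage = factor(pred, levels = c("1", "2", "3", "4"))
    )
    ev <- evaluate_predictions(preds, labels)
    total <- sum(conf)
    expect_equal(ev$accuracy, sum(diag(conf)) / total)
    p_e <- sum(rowSums(conf) * colSums(conf)) / total^2
    expect_equal(ev$kappa, (ev$accuracy - p_e) / (1 - p_e))
    for (i in 1:4) {
      tp <- conf[i, i]
      col <- sum(conf[, i]); row <- sum(conf[i, ])
      sens <- if (col > 0) tp / col else NA_real_
      tn <- total - col - row + tp
      spec <- tn / (total - col)
      expect_equal(ev$per_stage$sensitivity[i], sens)
      expect_equal(ev$per_stage$specificity[i], spec)
    }
  }
})

make_separable_features <- function(n_per_class = 12, p = 8, seed = 1) {
  set.seed(seed)
  stages <- rep(c("1", "2", "3", "4"), each = n_per_class)
  x <- matrix(rnorm(length(stages) * p, sd = 0.05), ncol = p)
  for (i in seq_along(stages)) {
    block <- as.integer(stages[i])
    x[i, (2 * block - 1):(2 * block)] <- x[i, (2 * block - 1):(2 * block)] + 3
  }
  feats <- tibble::as_tibble(x, .name_repair = ~sprintf("p%04d", seq_len(p)))
  feats <- dplyr::mutate(feats, sample_id = sprintf("S%03d", seq_along(stages)),
                         .before = 1)
  truth <- tibble::tibble(
    sample_id = feats$sample_id,
    stage = factor(stages, levels = c("control", "1", "2", "3", "4"))
  )
  list(features = feats, truth = truth)
}

test_that("training on separable blocks reaches perfect training accuracy", {
  fx <- make_separable_features()
  for (backend in c("boosted_tree", "random_forest", "naive_bayes")) {
    model <- train_classifier(fx$features, fx$truth, backend = backend,
                              cv_folds = 3, cv_repeats = 2, seed = 9)
    preds <- predict_stage(model, fx$features)
    ev <- evaluate_predictions(preds, fx$truth)
    expect_equal(ev$accuracy, 1)
  }
})

test_that("training is deterministic for a fixed seed", {
  fx <- make_separable_features(seed = 2)
  m1 <- train_classifier(fx$features, fx$truth, cv_folds = 3, cv_repeats = 3,
                         seed = 123)
  m2 <- train_classifier(fx$features, fx$truth, cv_folds = 3, cv_repeats = 3,
                         seed = 123)
  expect_identical(m1$best_params, m2$best_params)
  expect_identical(m1$cv_results, m2$cv_results)
  expect_identical(predict_stage(m1, fx$features), predict_stage(m2, fx$features))
})

test_that("shuffled labels drive CV accuracy to chance", {
  fx <- make_separable_features(n_per_class = 15, seed = 3)
  shuffled <- fx$truth
  set.seed(55)
  shuffled$stage <- sample(shuffled$stage)
  model <- train_classifier(fx$features, shuffled, backend = "random_forest",
                            cv_folds = 3, cv_repeats = 5, seed = 4)
  cv_acc <- max(model$cv_results$mean_accuracy)
  se <- sqrt(0.25 * 0.75 / nrow(fx$features))
  expect_lt(abs(cv_acc - 0.25), 4 * se)
})

test_that("layout checksum mismatches are refused at prediction time", {
  fx <- make_separable_features()
  feats <- fx$features
  attr(feats, "checksum") <- "layout-A"
  model <- train_classifier(feats, fx$truth, cv_repeats = 2, seed = 1)
  feats2 <- fx$features
  attr(feats2, "checksum") <- "layout-B"
  expect_error(predict_stage(model, feats2), "checksum mismatch")
  # absent checksum on new features is tolerated (manifest unknown)
  expect_s3_class(predict_stage(model, fx$features), "tbl_df")
})

test_that("the full protocol is deterministic and averages per-iteration metrics", {
  sim <- cached_sim("proto", n_genes = 150, samples_per_group = 20,
                    modules_per_stage = 1, module_size = 10, seed = 303L)
  p1 <- run_protocol(sim$expr, sim$labels, cv_repeats = 2, n_iterations = 2,
                     seed = 11)
  p2 <- run_protocol(sim$expr, sim$labels, cv_repeats = 2, n_iterations = 2,
                     seed = 11)
  expect_equal(p1$metrics, p2$metrics)
  expect_equal(glance(p1), glance(p2))
  accs <- p1$iteration_metrics$value[p1$iteration_metrics$metric == "accuracy"]
  expect_equal(glance(p1)$accuracy, mean(accs))
  expect_identical(glance(p1)$n_iterations, 2)
})

test_that("strict split keeps test samples out of DEG selection", {
  sim <- cached_sim("proto", n_genes = 150, samples_per_group = 20,
                    modules_per_stage = 1, module_size = 10, seed = 303L)
  p <- run_protocol(sim$expr, sim$labels, cv_repeats = 2, n_iterations = 1,
                    strict_split = TRUE, seed = 21)
  expect_s3_class(p, "stage_protocol")
  # metrics remain well-formed probabilities
  expect_true(all(p$metrics$mean >= -1 & p$metrics$mean <= 1))
})
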