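# Backend registry for the 4-way stage classifier. Each entry wraps one
# learner family behind a uniform fit/predict pair plus a small default
# hyperparameter grid. The six families mirror the usual co-expression
# staging toolbox: a boosted-tree learner (the C5.0 role), bagged trees,
# random forest, weighted-subspace random forest, a random-ferns-like
# ensemble of shallow randomized trees, and Gaussian naive Bayes.

classifier_registry <- function() {
  list(
    boosted_tree = list(
      label = "gradient-boosted decision trees",
      packages = "xgboost",
      grid = tibble(max_depth = c(2L, 4L), nrounds = c(60L, 60L), eta = 0.3),
      fit = function(x, y, params, seed) {
        ylev <- levels(y)
        dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
        booster <- xgboost::xgb.train(
          params = list(
            objective = "multi:softprob", num_class = length(ylev),
            max_depth = params$max_depth, eta = params$eta,
            nthread = 1L, seed = seed
          ),
          data = dtrain, nrounds = params$nrounds, verbose = 0
        )
        list(booster = booster, levels = ylev)
      },
      predict = function(fit, x) {
        pr <- predict(fit$booster, xgboost::xgb.DMatrix(x))
        if (is.null(dim(pr))) {
          pr <- matrix(pr, ncol = length(fit$levels), byrow = TRUE)
        }
        factor(fit$levels[max.col(pr, ties.method = "first")], levels = fit$levels)
      }
    ),
    random_forest = list(
      label = "random forest",
      packages = "ranger",
      grid = tibble(mtry_frac = c(0.05, 0.33)),
      fit = function(x, y, params, seed) {
        ranger::ranger(
          x = x, y = y, num.trees = 300,
          mtry = max(1L, floor(params$mtry_frac * ncol(x))),
          num.threads = 1L, seed = seed
        )
      },
      predict = function(fit, x) predict(fit, x, num.threads = 1L)$predictions
    ),
    bagged_tree = list(
      label = "bagged decision trees (mtry = all features)",
      packages = "ranger",
      grid = tibble(num_trees = c(100L, 300L)),
      fit = function(x, y, params, seed) {
        ranger::ranger(
          x = x, y = y, num.trees = params$num_trees, mtry = ncol(x),
          num.threads = 1L, seed = seed
        )
      },
      predict = function(fit, x) predict(fit, x, num.threads = 1L)$predictions
    ),
    weighted_subspace_forest = list(
      label = "random forest with variance-weighted feature subspaces",
      packages = "ranger",
      grid = tibble(mtry_frac = c(0.05, 0.33)),
      fit = function(x, y, params, seed) {
        w <- apply(x, 2, var)
        w <- if (sum(w) == 0) rep(1 / ncol(x), ncol(x)) else w / sum(w)
        ranger::ranger(
          x = x, y = y, num.trees = 300,
          mtry = max(1L, floor(params$mtry_frac * ncol(x))),
          split.select.weights = as.numeric(w),
          num.threads = 1L, seed = seed
        )
      },
      predict = function(fit, x) predict(fit, x, num.threads = 1L)$predictions
    ),
    random_ferns = list(
      label = "shallow extremely randomized trees (ferns analog)",
      packages = "ranger",
      grid = tibble(max_depth = c(3L, 5L)),
      fit = function(x, y, params, seed) {
        ranger::ranger(
          x = x, y = y, num.trees = 500, splitrule = "extratrees",
          num.random.splits = 1L, max.depth = params$max_depth,
          num.threads = 1L, seed = seed
        )
      },
      predict = function(fit, x) predict(fit, x, num.threads = 1L)$predictions
    ),
    naive_bayes = list(
      label = "Gaussian naive Bayes",
      packages = "e1071",
      grid = tibble(laplace = 0),
      fit = function(x, y, params, seed) {
        # drop features with near-zero within-class spread: their Gaussian
        # densities degenerate
        keep <- apply(x, 2, function(col) {
          all(tapply(col, y, sd) > 1e-8)
        })
        if (!any(keep)) {
          abort("naive_bayes: all features degenerate within classes.")
        }
        list(
          model = e1071::naiveBayes(x[, keep, drop = FALSE], y,
                                    laplace = params$laplace),
          keep = which(keep)
        )
      },
      predict = function(fit, x) {
        predict(fit$model, x[, fit$keep, drop = FALSE])
      }
    )
  )
}

#' List available classifier backends
#'
#' @return tibble with columns `backend`, `label` and `packages` (the
#'   package each backend requires).
#' @export
list_backends <- function() {
  reg <- classifier_registry()
  tibble(
    backend = names(reg),
    label = vapply(reg, `[[`, character(1), "label"),
    packages = vapply(reg, `[[`, character(1), "packages")
  )
}

get_backend <- function(backend) {
  reg <- classifier_registry()
  if (!backend %in% names(reg)) {
    abort(paste0(
      "unknown backend \"", backend, "\"; available: ",
      toString(names(reg))
    ))
  }
  entry <- reg[[backend]]
  if (!requireNamespace(entry$packages, quietly = TRUE)) {
    abort(paste0("backend \"", backend, "\" needs package ", entry$packages, "."))
  }
  entry
}
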