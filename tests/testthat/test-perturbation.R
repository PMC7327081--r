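# A tiny hand-built network: genes A and B exactly linear over the
# reference samples, plus a weaker pair that a hostile sample can break.

make_perturb_fixture <- function() {
  set.seed(21)
  n <- 10
  f <- rnorm(n)
  ref <- rbind(
    A = 5 + f,
    B = 3 + 2 * f,              # exact linear function of A
    C = 5 + f + 0.3 * rnorm(n),
    D = 5 + f + 0.3 * rnorm(n)
  )
  # new samples: one on the A/B line and consistent elsewhere, one outlier
  good <- c(A = 5 + 1.5, B = 3 + 2 * 1.5, C = 6.4, D = 6.6)
  bad <- c(A = 5 + 1.5, B = 3 + 2 * 1.5, C = 12, D = -2)
  expr <- as_expr(cbind(ref, good = good, bad = bad),
                  genes = rownames(ref),
                  samples = c(sprintf("R%02d", 1:n), "good", "bad"))
  nw <- build_stage_network(expr, sprintf("R%02d", 1:n), rownames(ref),
                            stage = "1", scale = "log")
  list(expr = expr, nw = nw, ref = sprintf("R%02d", 1:n))
}

test_that("a collinear sample preserves a perfect edge at exactly 1.0", {
  fx <- make_perturb_fixture()
  pv <- perturb_network(fx$nw, fx$expr, "good", scale = "log")
  i_ab <- which(pv$edges$gene_a == "A" & pv$edges$gene_b == "B")
  expect_equal(pv$values[i_ab], 1.0)
})

test_that("entries equal the expanded-set correlation or exactly 0 when removed", {
  fx <- make_perturb_fixture()
  for (s in c("good", "bad")) {
    pv <- perturb_network(fx$nw, fx$expr, s, scale = "log")
    expect_length(pv$values, nrow(fx$nw$edges))
    for (i in seq_len(nrow(fx$nw$edges))) {
      ga <- fx$nw$edges$gene_a[i]; gb <- fx$nw$edges$gene_b[i]
      rho_exp <- cor(fx$expr[ga, c(fx$ref, s)], fx$expr[gb, c(fx$ref, s)])
      expected <- if (abs(rho_exp) > fx$nw$tau) rho_exp else 0
      expect_equal(pv$values[i], expected, tolerance = 1e-12)
    }
  }
  # the outlier must actually remove at least one edge the good sample keeps
  v_good <- perturb_network(fx$nw, fx$expr, "good", scale = "log")$values
  v_bad <- perturb_network(fx$nw, fx$expr, "bad", scale = "log")$values
  expect_gt(sum(v_bad == 0), sum(v_good == 0))
})

test_that("perturbation never mutates the stored network", {
  fx <- make_perturb_fixture()
  before <- serialize(fx$nw, NULL)
  invisible(perturb_network(fx$nw, fx$expr, "bad", scale = "log"))
  invisible(perturb_network(fx$nw, fx$expr, "good", scale = "log"))
  expect_identical(serialize(fx$nw, NULL), before)
})

test_that("reference membership and missing genes are hard errors", {
  fx <- make_perturb_fixture()
  expect_error(perturb_network(fx$nw, fx$expr, "R01", scale = "log"),
               "already in the reference set")
  expr2 <- fx$expr[c("A", "B", "C"), ]
  expect_error(perturb_network(fx$nw, expr2, "good", scale = "log"),
               "lacks network gene")
  expect_error(perturb_network(fx$nw, fx$expr, "nope", scale = "log"),
               "not found")
})

test_that("feature vectors concatenate the four blocks in stage order", {
  sim <- small_sim()
  split <- split_samples(sim$labels, seed = 31)
  degs <- identify_degs_all(sim$expr, sim$labels)
  bal <- balance_deg_sets(degs, sim$expr, sim$labels)
  nws <- lapply(c("1", "2", "3", "4"), function(s) {
    build_stage_network(
      sim$expr,
      split$sample_id[split$stage == s & split$role == "reference"],
      bal$gene_id[bal$stage == s & bal$selected],
      stage = s
    )
  })
  counts <- vapply(nws, function(n) nrow(n$edges), integer(1))
  ids <- split$sample_id[split$role == "test"][1:3]
  fv <- build_feature_vector(nws, sim$expr, ids[1])
  expect_length(fv, sum(counts))
  layout <- attr(fv, "layout")
  expect_identical(as.integer(table(factor(layout$stage, levels = c("1","2","3","4")))),
                   counts)
  expect_identical(layout$position, seq_len(sum(counts)))

  fm <- build_feature_matrix(nws, sim$expr, ids)
  expect_identical(dim(fm), c(3L, sum(counts) + 1L))
  expect_identical(attr(fm, "layout"), layout)
  # identical layout, generally different values across samples
  expect_false(identical(as.numeric(fm[1, -1]), as.numeric(fm[2, -1])))
  # networks supplied out of stage order are rejected
  expect_error(build_feature_vector(nws[c(2, 1, 3, 4)], sim$expr, ids[1]),
               "stage order")
})

test_that("the all-pairs layout scores every candidate node pair", {
  fx <- make_perturb_fixture()
  pv <- perturb_network(fx$nw, fx$expr, "good", scale = "log",
                        layout = "all_pairs")
  n_nodes <- length(fx$nw$node_genes)
  expect_length(pv$values, choose(n_nodes, 2))
  # reference edges appear inside the all-pairs layout with equal values
  ref <- perturb_network(fx$nw, fx$expr, "good", scale = "log")
  key_all <- paste(pv$edges$gene_a, pv$edges$gene_b)
  key_ref <- paste(ref$edges$gene_a, ref$edges$gene_b)
  expect_equal(pv$values[match(key_ref, key_all)], ref$values)
  # sub-threshold non-edges score exactly 0
  expect_true(all(pv$values[!key_all %in% key_ref] %in% c(0) |
                    abs(pv$values[!key_all %in% key_ref]) > fx$nw$tau))
})

test_that("determinism: identical inputs yield bit-identical vectors", {
  fx <- make_perturb_fixture()
  a <- perturb_network(fx$nw, fx$expr, "bad", scale = "log")
  b <- perturb_network(fx$nw, fx$expr, "bad", scale = "log")
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("samples retain more edges in their own stage's block", {
  sim <- default_sim()
  split <- split_samples(sim$labels, seed = 17)
  degs <- identify_degs_all(sim$expr, sim$labels)
  bal <- balance_deg_sets(degs, sim$expr, sim$labels)
  nws <- lapply(c("1", "2", "3", "4"), function(s) {
    build_stage_network(
      sim$expr,
      split$sample_id[split$stage == s & split$role == "reference"],
      bal$gene_id[bal$stage == s & bal$selected],
      stage = s
    )
  })
  layout <- layout_manifest(nws)
  test_ids <- split$sample_id[split$role == "test"]
  own <- c(); other <- c()
  for (id in test_ids[1:32]) {
    s <- split$stage[split$sample_id == id]
    v <- build_feature_vector(nws, sim$expr, id)
    ret <- tapply(v != 0, layout$stage, mean)
    own <- c(own, ret[[s]])
    other <- c(other, mean(ret[names(ret) != s]))
  }
  expect_true(all(own > other))
})
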