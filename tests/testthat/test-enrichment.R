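test_that("pair universes count DEG pairs and co-expressed pairs", {
  uni <- build_pair_universe(
    c("a", "b", "c", "d"),
    data.frame(gene_a = c("b", "c"), gene_b = c("a", "d")),
    direction = "up"
  )
  expect_equal(uni$N, 6)          # C(4,2)
  expect_equal(uni$K, 2)
  # canonical, deduplicated pair storage
  expect_identical(uni$ceg_pairs$gene_a, c("a", "c"))

  empty <- build_pair_universe(c("a", "b"), data.frame(gene_a = character(),
                                                       gene_b = character()))
  expect_equal(empty$K, 0)

  expect_error(
    build_pair_universe(c("a", "b"), data.frame(gene_a = "a", gene_b = "z")),
    "universe inconsistency"
  )
})

test_that("pathway scores follow the hypergeometric tail with conventions", {
  uni <- build_pair_universe(
    c("a", "b", "c", "d"),
    data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"))
  )
  # k = 0 leaves the whole support: p = 1
  r0 <- enrich_pathway(uni, c("a", "d"))
  expect_equal(r0$k, 0L)
  expect_equal(r0$p_value, 1)
  # fewer than two effective genes: n = 0, p = 1
  expect_equal(enrich_pathway(uni, c("zz"))$p_value, 1)
  # K = N degenerate universe forces k = n, p = 1
  uni_full <- build_pair_universe(
    c("a", "b", "c"),
    data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"))
  )
  rf <- enrich_pathway(uni_full, c("a", "b", "c"))
  expect_equal(rf$k, rf$n)
  expect_equal(rf$p_value, 1)
})

test_that("the exact example N=6, K=3, n=3, k=3 gives p = 0.05", {
  # universe over genes {a,b,c,d}: N = 6 pairs, 3 of them co-expressed,
  # and a pathway whose 3 pairs are exactly the co-expressed ones
  uni <- build_pair_universe(
    c("a", "b", "c", "d"),
    data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"))
  )
  r <- enrich_pathway(uni, c("a", "b", "c"))
  expect_equal(r$n, 3)
  expect_equal(r$k, 3L)
  expect_equal(r$p_value, choose(3, 3) * choose(3, 0) / choose(6, 3))
  expect_equal(r$p_value, 0.05)
  # point-mass mode reproduces the same value here (single term)
  expect_equal(enrich_pathway(uni, c("a", "b", "c"), point_mass = TRUE)$p_value,
               0.05)
})

test_that("significance is monotone non-increasing in k at fixed (N, K, n)", {
  # five genes -> N = 10; pathway {a,b,c} -> n = 3; hold K = 3 and move
  # k of the co-expressed pairs inside the pathway
  genes <- c("a", "b", "c", "d", "e")
  inside <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"))
  outside <- data.frame(gene_a = c("a", "b", "d"), gene_b = c("d", "e", "e"))
  p_by_k <- vapply(0:3, function(k) {
    ceg <- rbind(head(inside, k), head(outside, 3 - k))
    r <- enrich_pathway(build_pair_universe(genes, ceg), c("a", "b", "c"))
    expect_equal(r$k, k)
    expect_equal(r$N, 10)
    expect_equal(r$K, 3)
    r$p_value
  }, numeric(1))
  expect_true(all(diff(p_by_k) < 0))
  expect_equal(p_by_k[1], 1)
})

test_that("enrich_all applies BH and flags enrichment at alpha", {
  uni <- build_pair_universe(
    c("a", "b", "c", "d"),
    data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"))
  )
  pathways <- tibble::tibble(
    pathway_id = c("hit", "partial", "off"),
    description = "",
    genes = list(c("a", "b", "c"), c("a", "b", "z"), c("x", "y"))
  )
  res <- enrich_all(uni, pathways, alpha = 0.2)
  expect_identical(res$pathway_id, pathways$pathway_id)
  expect_equal(res$adjusted_p, p.adjust(res$p_value, "BH"))
  expect_true(res$enriched[res$pathway_id == "hit"])
  expect_false(res$enriched[res$pathway_id == "off"])
  # pathways disjoint from the DEG set are all p = 1
  off <- enrich_all(uni, pathways[3, ])
  expect_equal(off$p_value, 1)
  # single pathway: BH leaves the raw p untouched
  single <- enrich_all(uni, pathways[1, ])
  expect_equal(single$adjusted_p, single$p_value)
})

test_that("the BH step-up formula matches a direct evaluation", {
  p <- c(0.01, 0.02, 0.5)
  m <- length(p)
  o <- order(p)
  step_up <- pmin(1, rev(cummin(rev(sort(p) * m / seq_len(m)))))
  manual <- numeric(m)
  manual[o] <- step_up
  expect_equal(manual, c(0.03, 0.03, 0.5))
  expect_equal(p.adjust(p, "BH"), manual)
})

test_that("evolution categories follow the set definitions", {
  evo <- evolution_summary(
    control_enriched = c("A", "B", "C"),
    stage_enriched = list(c("A", "B"), "A", "A", "A")
  )
  expect_identical(evo$persistent, "A")
  expect_identical(evo$disappeared_at$stage1, "C")
  expect_identical(evo$disappeared_at$stage2, "B")
  expect_length(evo$intermittent, 0)

  # emergent pathways by earliest enriched phase
  evo2 <- evolution_summary(character(), list(character(), "D", character(), "E"))
  expect_identical(evo2$emergent_early, "D")
  expect_identical(evo2$emergent_advanced, "E")

  # a non-monotone control pathway lands in the intermittent bucket
  evo3 <- evolution_summary("E", list("E", character(), "E", character()))
  expect_identical(evo3$intermittent, "E")
  expect_length(evo3$persistent, 0)
  expect_true(all(lengths(evo3$disappeared_at) == 0))
})

test_that("persistent, disappeared and intermittent partition the control set", {
  set.seed(99)
  pool <- sprintf("PW%03d", 1:40)
  for (i in 1:30) {
    ctrl <- sample(pool, sample(5:25, 1))
    stg <- lapply(1:4, function(s) sample(pool, sample(0:30, 1)))
    evo <- evolution_summary(ctrl, stg)
    parts <- c(evo$persistent, unlist(evo$disappeared_at), evo$intermittent)
    expect_setequal(parts, ctrl)
    expect_equal(length(parts), length(unique(ctrl)))
    expect_length(intersect(evo$persistent, unlist(evo$disappeared_at)), 0)
    expect_length(intersect(c(evo$emergent_early, evo$emergent_advanced),
                            setdiff(ctrl, character())), 0)
  }
})
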