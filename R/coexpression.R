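# Pairwise Pearson co-expression with t-based significance and the
# per-stage reference network construction. Edges are unordered gene
# pairs in canonical (lexicographic) order; a network's edge order is
# fixed at build time and becomes the positional contract for the
# perturbation vectors.

#' Pearson correlation between two expression profiles
#'
#' Plain product-moment correlation,
#' `(E\[XY\] - E\[X\]E\[Y\]) / (sd(X) sd(Y))`. Kept as an explicit
#' primitive because the co-expression edge definition and the
#' single-sample perturbation step are both specified directly in terms
#' of it.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient in \[-1, 1\].
#' @export
pearson_pcc <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.")
  }
  if (length(x) < 3) {
    abort("need at least 3 paired observations.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: constant vector.")
  }
  n <- length(x)
  exy <- mean(x * y)
  num <- exy - mean(x) * mean(y)
  den <- sqrt(mean(x^2) - mean(x)^2) * sqrt(mean(y^2) - mean(y)^2)
  r <- num / den
  # clamp round-off just past the boundary
  max(-1, min(1, r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null transform `t = rho * sqrt(n - 2) / sqrt(1 - rho^2)`
#' referred to Student's t with `n - 2` degrees of freedom.
#'
#' @param rho correlation coefficient.
#' @param n number of paired samples (>= 3).
#' @return two-sided p-value; `|rho| = 1` returns 0.
#' @export
pcc_pvalue <- function(rho, n) {
  if (any(n < 3)) {
    abort("`n` must be at least 3.")
  }
  if (any(abs(rho) > 1)) {
    abort("`rho` must lie in [-1, 1].")
  }
  out <- numeric(length(rho))
  exact <- abs(rho) >= 1
  out[exact] <- 0
  r <- rho[!exact]
  if (length(r)) {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    out[!exact] <- 2 * pt(-abs(tstat), df = n - 2)
  }
  out
}

# Order each pair lexicographically (gene_a < gene_b) and sort rows into
# the canonical edge order.
canonicalize_pairs <- function(edges) {
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
}

#' Build a stage reference co-expression network
#'
#' Computes all pairwise Pearson correlations among `genes` over the
#' reference `samples` and keeps as edges exactly the pairs with
#' `|rho| > tau` and t-based `p_value < p_cut` (both strict). The edge
#' list is returned in canonical lexicographic order; that order is the
#' immutable positional layout later consumed by the perturbation step.
#' Genes constant over the reference samples are dropped from the node
#' set with a message rather than failing the run.
#'
#' @param expr numeric genes x samples matrix.
#' @param samples reference sample identifiers (>= 3).
#' @param genes node genes (the stage's selected DEGs; >= 2).
#' @param tau correlation magnitude threshold (strict `>`), default 0.7.
#' @param p_cut significance cutoff (strict `<`), default 0.05.
#' @param stage optional stage tag carried in the object.
#' @param scale expression scale handling, see [normalize_log_scale()].
#' @return an object of class `stage_network`: list with `stage`,
#'   `reference_samples`, `node_genes`, `edges` (tibble `gene_a`,
#'   `gene_b`, `rho`, `p_value`), `tau`, `p_cut`, `n_samples`.
#' @export
build_stage_network <- function(expr, samples, genes, tau = 0.7, p_cut = 0.05,
                                stage = NA_character_,
                                scale = c("auto", "log", "counts")) {
  validate_expression_matrix(expr)
  samples <- as.character(samples)
  genes <- as.character(genes)
  if (length(samples) < 3) {
    abort("need at least 3 reference samples.")
  }
  if (length(genes) < 2) {
    abort("need at least 2 node genes.")
  }
  missing_s <- setdiff(samples, colnames(expr))
  if (length(missing_s)) {
    abort(paste0("reference sample(s) absent from matrix: ", toString(missing_s)))
  }
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g)) {
    abort(paste0("node gene(s) absent from matrix: ", toString(missing_g)))
  }
  lx <- normalize_log_scale(expr, scale)[genes, samples, drop = FALSE]
  const <- apply(lx, 1, sd) == 0
  if (any(const)) {
    inform(paste0(
      "build_stage_network: dropping constant gene(s) over the reference samples: ",
      toString(genes[const])
    ))
    lx <- lx[!const, , drop = FALSE]
    genes <- genes[!const]
  }
  if (length(genes) < 2) {
    abort("fewer than 2 non-constant node genes over the reference samples.")
  }
  cm <- cor(t(lx))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  rho <- cm[idx]
  edges <- tibble(
    gene_a = genes[idx[, 1]],
    gene_b = genes[idx[, 2]],
    rho = rho,
    p_value = pcc_pvalue(rho, length(samples))
  )
  edges <- edges[abs(edges$rho) > tau & edges$p_value < p_cut, , drop = FALSE]
  edges <- as_tibble(canonicalize_pairs(edges))
  structure(
    list(
      stage = as.character(stage),
      reference_samples = samples,
      node_genes = genes,
      edges = edges,
      tau = tau,
      p_cut = p_cut,
      n_samples = length(samples)
    ),
    class = "stage_network"
  )
}

#' @export
print.stage_network <- function(x, ...) {
  cat(sprintf(
    "<stage_network stage=%s> %d node genes, %d edges (|rho| > %g, p < %g) over %d reference samples\n",
    x$stage, length(x$node_genes), nrow(x$edges), x$tau, x$p_cut, x$n_samples
  ))
  invisible(x)
}

#' @describeIn build_stage_network tidy() returns the canonical edge list
#'   with the stage tag.
#' @param x a `stage_network`.
#' @param ... unused.
#' @export
tidy.stage_network <- function(x, ...) {
  dplyr::mutate(x$edges, stage = x$stage, .before = 1)
}

#' @describeIn build_stage_network glance() returns a one-row summary.
#' @export
glance.stage_network <- function(x, ...) {
  tibble(
    stage = x$stage,
    n_nodes = length(x$node_genes),
    n_edges = nrow(x$edges),
    n_reference_samples = x$n_samples,
    tau = x$tau,
    p_cut = x$p_cut
  )
}

#' Split a network's co-expressed pairs by differential-expression direction
#'
#' Partitions the edges of a stage network into pairs where both genes
#' are up-regulated, pairs where both are down-regulated, and
#' mixed-direction pairs. The up and down sets are the universes of the
#' pair-level enrichment statistic; mixed pairs are reported but belong
#' to neither universe.
#'
#' @param network a `stage_network`.
#' @param deg_records tibble with `gene_id` and `direction`
#'   (`"up"`/`"down"`) covering every node gene.
#' @return the edge tibble with a `pair_direction` column in
#'   `c("up", "down", "mixed")`.
#' @export
ceg_pairs_by_direction <- function(network, deg_records) {
  stopifnot(inherits(network, "stage_network"))
  dir <- setNames(as.character(deg_records$direction), deg_records$gene_id)
  missing <- setdiff(network$node_genes, names(dir))
  if (length(missing)) {
    abort(paste0("node gene(s) with no DEG direction: ", toString(missing)))
  }
  edges <- network$edges
  da <- dir[edges$gene_a]
  db <- dir[edges$gene_b]
  edges$pair_direction <- dplyr::case_when(
    da == "up" & db == "up" ~ "up",
    da == "down" & db == "down" ~ "down",
    TRUE ~ "mixed"
  )
  as_tibble(edges)
}
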