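# Gene-pair hypergeometric pathway enrichment and the stage-evolution
# summary (persistent / disappearing / emergent pathways). The statistic
# treats unordered DEG pairs as the sampling units: out of N DEG pairs of
# one direction, K are co-expressed; a pathway contributing n DEG pairs
# and k co-expressed pairs is scored by the hypergeometric tail
# P(X >= k) with parameters (N, K, n).

#' Build the gene-pair universe for one direction
#'
#' The universe counts all unordered pairs of the direction's DEGs
#' (`N = choose(|genes|, 2)`) and the co-expressed pairs among them
#' (`K`). Every co-expressed pair must lie inside the DEG set, otherwise
#' the universe is inconsistent and the call errors.
#'
#' @param deg_genes character vector of the direction's DEG identifiers.
#' @param ceg_pairs data frame with columns `gene_a`, `gene_b`: the
#'   direction's co-expressed pairs.
#' @param direction `"up"` or `"down"` (carried as metadata).
#' @return an object of class `pair_universe`: list with `direction`,
#'   `N`, `K`, `deg_genes`, `ceg_pairs` (canonical order, deduplicated).
#' @export
build_pair_universe <- function(deg_genes, ceg_pairs, direction = c("up", "down")) {
  direction <- match.arg(direction)
  deg_genes <- unique(as.character(deg_genes))
  pairs <- tibble(
    gene_a = as.character(ceg_pairs$gene_a),
    gene_b = as.character(ceg_pairs$gene_b)
  )
  pairs <- dplyr::distinct(as_tibble(canonicalize_pairs(pairs)))
  outside <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), deg_genes)
  if (length(outside)) {
    abort(paste0(
      "universe inconsistency: co-expressed pair gene(s) outside the ",
      direction, "-regulated DEG set: ", toString(head(outside, 10))
    ))
  }
  structure(
    list(
      direction = direction,
      N = choose(length(deg_genes), 2),
      K = nrow(pairs),
      deg_genes = deg_genes,
      ceg_pairs = pairs
    ),
    class = "pair_universe"
  )
}

#' @export
print.pair_universe <- function(x, ...) {
  cat(sprintf(
    "<pair_universe %s> %d DEGs -> N = %d pairs, K = %d co-expressed\n",
    x$direction, length(x$deg_genes), x$N, x$K
  ))
  invisible(x)
}

#' Score one pathway against a pair universe
#'
#' The pathway's effective gene set is its intersection with the
#' universe's DEGs; `n = choose(|effective|, 2)` is its DEG-pair count
#' and `k` the number of co-expressed pairs falling entirely inside it.
#' Significance is the hypergeometric upper tail `P(X >= k)` for drawing
#' `n` pairs from `N` of which `K` are co-expressed; `point_mass = TRUE`
#' instead returns the single-term probability `P(X = k)`. A pathway
#' with fewer than two effective genes has `n = 0` and p-value 1 by
#' convention.
#'
#' @param universe a `pair_universe`.
#' @param pathway_genes character vector of the pathway's genes.
#' @param point_mass return `P(X = k)` instead of the upper tail.
#' @return one-row tibble with `n`, `k`, `N`, `K`, `p_value`.
#' @export
enrich_pathway <- function(universe, pathway_genes, point_mass = FALSE) {
  stopifnot(inherits(universe, "pair_universe"))
  eff <- intersect(unique(as.character(pathway_genes)), universe$deg_genes)
  n <- choose(length(eff), 2)
  k <- if (n == 0) 0L else sum(
    universe$ceg_pairs$gene_a %in% eff & universe$ceg_pairs$gene_b %in% eff
  )
  p <- if (n == 0) {
    1
  } else if (point_mass) {
    dhyper(k, m = universe$K, n = universe$N - universe$K, k = n)
  } else {
    # P(X >= k)
    phyper(k - 1, m = universe$K, n = universe$N - universe$K, k = n,
           lower.tail = FALSE)
  }
  tibble(n = n, k = as.integer(k), N = universe$N, K = universe$K, p_value = p)
}

#' Score every pathway of a collection against a pair universe
#'
#' Runs [enrich_pathway()] over a pathway collection and applies
#' Benjamini-Hochberg multiplicity correction (or none). A pathway is
#' flagged enriched when its adjusted p-value is below `alpha`.
#'
#' @param universe a `pair_universe`.
#' @param pathways tibble as from [read_gmt()] (`pathway_id`,
#'   `description`, `genes` list-column), or a named list of gene sets.
#' @param alpha enrichment cutoff on the adjusted p-value (default 0.05).
#' @param adjust `"BH"` (default) or `"none"`.
#' @param point_mass see [enrich_pathway()].
#' @return tibble with one row per pathway: `pathway_id`, `n`, `k`, `N`,
#'   `K`, `p_value`, `adjusted_p`, `enriched`.
#' @export
enrich_all <- function(universe, pathways, alpha = 0.05,
                       adjust = c("BH", "none"), point_mass = FALSE) {
  adjust <- match.arg(adjust)
  if (is.list(pathways) && !is.data.frame(pathways)) {
    pathways <- tibble(
      pathway_id = names(pathways),
      description = "",
      genes = unname(pathways)
    )
  }
  if (!nrow(pathways)) {
    abort("empty pathway collection.")
  }
  res <- purrr::map_dfr(seq_len(nrow(pathways)), function(i) {
    dplyr::mutate(
      enrich_pathway(universe, pathways$genes[[i]], point_mass = point_mass),
      pathway_id = pathways$pathway_id[i], .before = 1
    )
  })
  res$adjusted_p <- if (adjust == "BH") p.adjust(res$p_value, "BH") else res$p_value
  res$enriched <- res$adjusted_p < alpha
  res
}

#' Summarize how pathway enrichment evolves across stages
#'
#' Classifies pathways by their enrichment pattern across control and the
#' four stages:
#' \describe{
#'   \item{persistent}{enriched in control and in all four stages}
#'   \item{disappeared_at}{per stage `s`: enriched in control and every
#'     stage before `s`, not enriched at `s` nor any later stage}
#'   \item{intermittent}{control-enriched pathways with a non-monotone
#'     pattern fitting neither of the above}
#'   \item{emergent_early}{not enriched in control, enriched at stage 1
#'     or 2}
#'   \item{emergent_advanced}{not enriched in control, enriched at stage
#'     3 or 4}
#' }
#' Persistent, the four disappeared-at sets and intermittent partition
#' the control-enriched set exactly.
#'
#' @param control_enriched character vector of pathways enriched in
#'   controls.
#' @param stage_enriched list of four character vectors (stages 1-4) of
#'   pathways enriched at each stage.
#' @return an object of class `pathway_evolution`: the sets above plus a
#'   `counts` tibble.
#' @export
evolution_summary <- function(control_enriched, stage_enriched) {
  if (length(stage_enriched) != 4L) {
    abort("`stage_enriched` must be a list of four pathway sets (stages 1-4).")
  }
  ctrl <- unique(as.character(control_enriched))
  stg <- lapply(stage_enriched, function(x) unique(as.character(x)))

  in_stage <- function(p) vapply(stg, function(s) p %in% s, logical(1))
  persistent <- ctrl[vapply(ctrl, function(p) all(in_stage(p)), logical(1))]
  disappeared_at <- setNames(vector("list", 4), paste0("stage", 1:4))
  assigned <- persistent
  for (s in 1:4) {
    hit <- ctrl[vapply(ctrl, function(p) {
      pat <- in_stage(p)
      all(pat[seq_len(s - 1)]) && !any(pat[s:4])
    }, logical(1))]
    disappeared_at[[s]] <- setdiff(hit, assigned)
    assigned <- union(assigned, disappeared_at[[s]])
  }
  intermittent <- setdiff(ctrl, assigned)

  non_ctrl <- setdiff(unique(unlist(stg)), ctrl)
  emergent_early <- non_ctrl[non_ctrl %in% union(stg[[1]], stg[[2]])]
  emergent_advanced <- non_ctrl[non_ctrl %in% union(stg[[3]], stg[[4]])]

  counts <- tibble(
    category = c("control_enriched", "persistent",
                 paste0("disappeared_stage", 1:4), "disappeared_total",
                 "intermittent", "emergent_early", "emergent_advanced"),
    n = c(length(ctrl), length(persistent), lengths(disappeared_at),
          sum(lengths(disappeared_at)), length(intermittent),
          length(emergent_early), length(emergent_advanced))
  )
  structure(
    list(
      persistent = sort(persistent),
      disappeared_at = lapply(disappeared_at, sort),
      intermittent = sort(intermittent),
      emergent_early = sort(emergent_early),
      emergent_advanced = sort(emergent_advanced),
      control_enriched = sort(ctrl),
      counts = counts
    ),
    class = "pathway_evolution"
  )
}

#' @export
print.pathway_evolution <- function(x, ...) {
  cat("<pathway_evolution>\n")
  print(x$counts, n = nrow(x$counts))
  invisible(x)
}

#' @describeIn evolution_summary tidy() returns the category counts.
#' @param x a `pathway_evolution`.
#' @param ... unused.
#' @export
tidy.pathway_evolution <- function(x, ...) {
  x$counts
}
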