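# Single-sample network perturbation: recompute each reference edge's
# correlation over the reference samples plus one new sample, zero out
# edges whose correlation magnitude falls to the threshold or below, and
# concatenate the four per-stage vectors into the fixed-layout feature
# vector the classifier consumes.

#' Perturb a stage network with one new sample
#'
#' For every edge of the reference network, the Pearson correlation is
#' recomputed over the expanded sample set (reference samples plus
#' `new_sample`). An edge whose expanded-set `|rho|` no longer exceeds
#' the network's `tau` is considered removed and its entry is exactly
#' 0.0; a retained edge's entry is the expanded-set correlation itself,
#' which carries the sample-specific signal. Significance is not
#' re-tested on the expanded set: adding a single sample changes the
#' sample size by one, and the threshold relation is the discriminative
#' part of the contract. The stored network is never modified.
#'
#' @param network a `stage_network`.
#' @param expr numeric genes x samples matrix containing `new_sample` and
#'   all network node genes.
#' @param new_sample a sample identifier not in the reference set.
#' @param scale expression scale handling, see [normalize_log_scale()].
#' @param layout `"reference"` (default) scores only the reference
#'   network's edges, keeping the fixed per-run layout; `"all_pairs"`
#'   scores every canonical node-gene pair, so pairs that only become
#'   co-expressed after adding the sample are represented too.
#' @return an object of class `perturbation_vector`: list with
#'   `sample_id`, `stage`, `values` (numeric, aligned one-to-one with the
#'   layout's canonical pair order), and `edges` (the gene pairs).
#' @export
perturb_network <- function(network, expr, new_sample,
                            scale = c("auto", "log", "counts"),
                            layout = c("reference", "all_pairs")) {
  layout <- match.arg(layout)
  stopifnot(inherits(network, "stage_network"))
  validate_expression_matrix(expr)
  new_sample <- as.character(new_sample)
  if (length(new_sample) != 1L || !new_sample %in% colnames(expr)) {
    abort(paste0("sample not found in expression matrix: ", new_sample))
  }
  if (new_sample %in% network$reference_samples) {
    abort(paste0("sample \"", new_sample, "\" is already in the reference set."))
  }
  missing_g <- setdiff(network$node_genes, rownames(expr))
  if (length(missing_g)) {
    abort(paste0("sample matrix lacks network gene(s): ", toString(missing_g)))
  }
  lx <- normalize_log_scale(expr, scale)
  cols <- c(network$reference_samples, new_sample)
  sub <- lx[network$node_genes, cols, drop = FALSE]
  cm <- suppressWarnings(cor(t(sub)))
  pairs <- network_pair_layout(network, layout)
  ia <- match(pairs$gene_a, network$node_genes)
  ib <- match(pairs$gene_b, network$node_genes)
  rho_exp <- cm[cbind(ia, ib)]
  # a gene constant over the expanded set yields NA: treat as removed
  rho_exp[is.na(rho_exp)] <- 0
  values <- ifelse(abs(rho_exp) > network$tau, rho_exp, 0)
  structure(
    list(
      sample_id = new_sample,
      stage = network$stage,
      values = as.numeric(values),
      edges = pairs
    ),
    class = "perturbation_vector"
  )
}

# Canonical pair layout of a network under either layout mode.
network_pair_layout <- function(network, layout = "reference") {
  if (layout == "reference") {
    return(network$edges[, c("gene_a", "gene_b")])
  }
  idx <- which(upper.tri(diag(length(network$node_genes))), arr.ind = TRUE)
  pairs <- tibble(
    gene_a = network$node_genes[idx[, 1]],
    gene_b = network$node_genes[idx[, 2]]
  )
  as_tibble(canonicalize_pairs(pairs))
}

#' @export
print.perturbation_vector <- function(x, ...) {
  cat(sprintf(
    "<perturbation_vector sample=%s stage=%s> %d positions, %d retained edges\n",
    x$sample_id, x$stage, length(x$values), sum(x$values != 0)
  ))
  invisible(x)
}

#' @describeIn perturb_network tidy() returns one row per edge position.
#' @param x a `perturbation_vector`.
#' @param ... unused.
#' @export
tidy.perturbation_vector <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    stage = x$stage,
    position = seq_along(x$values),
    gene_a = x$edges$gene_a,
    gene_b = x$edges$gene_b,
    value = x$values
  )
}

#' Layout manifest of a set of stage networks
#'
#' The concatenated feature layout: one row per position, in stage order
#' then canonical edge order. Identical for every sample of a run; its
#' checksum ties trained models to the networks that produced their
#' features.
#'
#' @param networks list of four `stage_network` objects in stage order
#'   1, 2, 3, 4.
#' @param layout `"reference"` or `"all_pairs"`, see [perturb_network()].
#' @return tibble with columns `position`, `stage`, `gene_a`, `gene_b`.
#' @export
layout_manifest <- function(networks, layout = c("reference", "all_pairs")) {
  layout <- match.arg(layout)
  check_network_list(networks)
  out <- purrr::map_dfr(networks, function(nw) {
    pairs <- network_pair_layout(nw, layout)
    tibble(stage = nw$stage, gene_a = pairs$gene_a, gene_b = pairs$gene_b)
  })
  dplyr::mutate(out, position = dplyr::row_number(), .before = 1)
}

check_network_list <- function(networks) {
  if (!is.list(networks) || length(networks) != 4L ||
      !all(vapply(networks, inherits, logical(1), "stage_network"))) {
    abort("`networks` must be a list of four stage_network objects.")
  }
  stages <- vapply(networks, `[[`, character(1), "stage")
  if (!identical(stages, CANCER_STAGES)) {
    abort("networks must be supplied in stage order \"1\", \"2\", \"3\", \"4\".")
  }
  invisible(networks)
}

#' Build the concatenated feature vector for one sample
#'
#' Runs [perturb_network()] against each of the four stage networks and
#' concatenates the per-network vectors in stage order 1-4.
#'
#' @inheritParams perturb_network
#' @param networks list of four `stage_network` objects in stage order.
#' @param sample the sample identifier to perturb with.
#' @return named numeric vector of length `sum(edge counts)`, with the
#'   layout manifest attached as attribute `"layout"`.
#' @export
build_feature_vector <- function(networks, expr, sample,
                                 scale = c("auto", "log", "counts"),
                                 layout = c("reference", "all_pairs")) {
  layout <- match.arg(layout)
  check_network_list(networks)
  vals <- unlist(lapply(networks, function(nw) {
    perturb_network(nw, expr, sample, scale = scale, layout = layout)$values
  }), use.names = FALSE)
  layout <- layout_manifest(networks, layout)
  names(vals) <- sprintf("s%s_%s|%s", layout$stage, layout$gene_a, layout$gene_b)
  attr(vals, "layout") <- layout
  vals
}

#' Build the feature matrix for a set of samples
#'
#' @inheritParams build_feature_vector
#' @param samples character vector of sample identifiers; none may belong
#'   to any network's reference set.
#' @return tibble with `sample_id` plus one numeric column per layout
#'   position; attributes `"layout"` (the manifest tibble) and
#'   `"checksum"` (its stable hash).
#' @export
build_feature_matrix <- function(networks, expr, samples,
                                 scale = c("auto", "log", "counts"),
                                 layout = c("reference", "all_pairs")) {
  mode <- match.arg(layout)
  check_network_list(networks)
  samples <- as.character(samples)
  lx <- normalize_log_scale(expr, scale)
  layout <- layout_manifest(networks, mode)
  rows <- lapply(samples, function(s) {
    build_feature_vector(networks, lx, s, scale = "log", layout = mode)
  })
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(mat, .name_repair = "minimal")
  names(out) <- sprintf("p%04d", seq_len(ncol(out)))
  out <- dplyr::mutate(out, sample_id = samples, .before = 1)
  attr(out, "layout") <- layout
  attr(out, "checksum") <- layout_checksum(layout)
  out
}
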