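# Shared fixtures: simulations are cached per parameter set so the suite
# generates each dataset once.

.fixtures <- new.env(parent = emptyenv())

cached_sim <- function(key, ...) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, simulate_staged_expression(...), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# the default study conditions (4 x 60 cancer + 60 controls, 300 genes)
default_sim <- function() cached_sim("default", seed = 101L)

# a small, fast dataset for pipeline plumbing tests
small_sim <- function() {
  cached_sim("small", n_genes = 120, samples_per_group = 24,
             modules_per_stage = 1, module_size = 8, seed = 202L)
}

# build a tiny expression matrix from a genes x samples numeric matrix
as_expr <- function(values, genes = NULL, samples = NULL) {
  genes <- genes %||% rownames(values) %||% sprintf("G%02d", seq_len(nrow(values)))
  samples <- samples %||% colnames(values) %||% sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a
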