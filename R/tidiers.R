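#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a truth network into its edge list
#' @param x A `truth_network`.
#' @param ... Unused.
#' @return Tibble with `tf`, `module`, `weight`.
#' @exportS3Method generics::tidy
tidy.truth_network <- function(x, ...) x$edges

#' @rdname tidy.truth_network
#' @exportS3Method generics::glance
glance.truth_network <- function(x, ...) {
  tibble::tibble(n_tfs = x$n_tfs, n_modules = x$n_modules,
                 n_edges = nrow(x$edges),
                 activator_fraction = if (nrow(x$edges)) mean(x$edges$weight > 0) else NA_real_)
}

#' Tidy a module assignment into a gene-module table
#' @param x A `module_assignment`.
#' @param ... Unused.
#' @return Tibble with `gene`, `module`.
#' @exportS3Method generics::tidy
tidy.module_assignment <- function(x, ...) {
  tibble::tibble(gene = names(x$labels),
                 module = sprintf("module_%02d", unname(x$labels)))
}

#' @rdname tidy.module_assignment
#' @exportS3Method generics::glance
glance.module_assignment <- function(x, ...) {
  tibble::tibble(k = x$k, n_genes = length(x$labels),
                 inertia = x$inertia,
                 min_size = min(x$sizes), max_size = max(x$sizes))
}

#' Tidy a BIC sweep into its curve
#' @param x A `bic_sweep`.
#' @param ... Unused.
#' @return Tibble with `k`, `bic`, `inertia`.
#' @exportS3Method generics::tidy
tidy.bic_sweep <- function(x, ...) x$bic_curve

#' @rdname tidy.bic_sweep
#' @exportS3Method generics::glance
glance.bic_sweep <- function(x, ...) {
  tibble::tibble(best_k = x$best_k, n_candidates = nrow(x$bic_curve),
                 min_bic = min(x$bic_curve$bic))
}

#' Tidy a consensus network into its edge table
#' @param x A `consensus_network`.
#' @param ... Unused.
#' @return The edges tibble.
#' @exportS3Method generics::tidy
tidy.consensus_network <- function(x, ...) x$edges

#' @rdname tidy.consensus_network
#' @exportS3Method generics::glance
glance.consensus_network <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$edges),
    n_tfs = length(unique(x$edges$tf)),
    n_modules = length(unique(x$edges$module)),
    n_methods = x$n_methods,
    min_support = x$params$min_support,
    n_activating = sum(grepl("activator", x$edges$class)),
    n_suppressing = sum(grepl("suppressor", x$edges$class)))
}

#' Tidy a pipeline run into its consensus edge table
#' @param x A `grn_pipeline`.
#' @param ... Unused.
#' @return The consensus edges tibble.
#' @exportS3Method generics::tidy
tidy.grn_pipeline <- function(x, ...) x$network$edges

#' @rdname tidy.grn_pipeline
#' @exportS3Method generics::glance
glance.grn_pipeline <- function(x, ...) {
  d <- x$manifest$dims
  tibble::tibble(genes = d$genes, samples = d$samples, degs = d$degs,
                 modules = d$modules, de_tfs = d$de_tfs,
                 inference_rows = d$inference_rows,
                 consensus_edges = d$consensus_edges)
}
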