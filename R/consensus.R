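#' Per-method edge calls by top-fraction rank
#'
#' A method calls a TF-module pair iff the pair's within-method rank
#' (descending score, average ties) is within the top
#' `ceiling(top_fraction * n_pairs)` pairs.
#'
#' @param scores A TF x module score matrix (higher = stronger).
#' @param top_fraction Proportion of pairs called, in `(0, 1]`.
#' @return Logical matrix of the same shape.
#' @export
call_edges <- function(scores, top_fraction = 0.02) {
  check_proportion(top_fraction, "top_fraction", allow_zero = FALSE)
  n_pairs <- length(scores)
  n_call <- ceiling(top_fraction * n_pairs)
  r <- matrix(rank(-as.vector(unclass(scores)), ties.method = "average"),
              nrow(scores), ncol(scores), dimnames = dimnames(scores))
  r <= n_call
}

#' Vote edges across methods
#'
#' @param calls Named list of logical call matrices (one per method, same
#'   shape).
#' @param min_support Minimum number of methods that must call a pair.
#' @return Tibble with `tf`, `module`, `support`, restricted to
#'   `support >= min_support`, ordered by support (desc) then tf, module. If
#'   `min_support` exceeds the number of methods the result is empty with a
#'   warning.
#' @export
consensus_support <- function(calls, min_support) {
  if (!length(calls)) abort("need at least one call matrix")
  min_support <- check_count(min_support, "min_support", min = 0L)
  if (min_support > length(calls)) {
    warn(sprintf("min_support = %d exceeds the %d available methods; empty consensus",
                 min_support, length(calls)))
  }
  support <- Reduce(`+`, lapply(calls, function(m) m * 1L))
  tibble::tibble(
    tf = rep(rownames(support), times = ncol(support)),
    module = rep(colnames(support), each = nrow(support)),
    support = as.integer(as.vector(support))
  ) |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::arrange(dplyr::desc(.data$support), .data$tf, .data$module)
}

#' Signed consensus significance score
#'
#' Per method, scores are mapped to standard-normal quantiles of their
#' within-method ranks (rank-inverse-normal, average ties); the consensus
#' score of a pair is
#' `S = sign(Spearman(tf profile, module profile)) * sum_methods z_method`.
#' `|S|` grows with cross-method agreement; the sign carries the direction of
#' regulation (positive = activation). Negating a module profile negates its
#' pairs' S (the Spearman sign flips, the magnitudes do not).
#'
#' @param scores Named list of TF x module score matrices sharing one pair
#'   universe.
#' @param mat The `inference_matrix` the scores came from (supplies the
#'   profiles for the sign).
#' @return Numeric TF x module matrix of signed scores `S`. Zero-variance
#'   profiles get sign 0 (hence `S = 0`) with a warning.
#' @export
consensus_score <- function(scores, mat) {
  if (!length(scores)) abort("need at least one score matrix")
  shapes <- unique(lapply(scores, dim))
  if (length(shapes) != 1) abort("score matrices must share one pair universe")
  z_sum <- Reduce(`+`, lapply(scores, function(s) {
    matrix(rank_inverse_normal(as.vector(unclass(s))), nrow(s), ncol(s))
  }))
  tf_ids <- rownames(scores[[1]]); mod_ids <- colnames(scores[[1]])
  flat <- apply(mat, 1, stats::sd) == 0
  if (any(flat[c(tf_ids, mod_ids)])) {
    warn("zero-variance profile(s): consensus sign set to 0 for their pairs")
  }
  rho <- suppressWarnings(
    stats::cor(t(mat[tf_ids, , drop = FALSE]),
               t(mat[mod_ids, , drop = FALSE]), method = "spearman"))
  sgn <- sign(rho)
  sgn[!is.finite(rho)] <- 0
  S <- sgn * z_sum
  dimnames(S) <- list(tf_ids, mod_ids)
  S
}

#' Classify consensus edges at the significance thresholds
#'
#' `S >= high` is a highly significant activator; `sig < S < high` an
#' activator; `S <= -high` a highly significant suppressor;
#' `-high < S < -sig` a suppressor; `|S| <= sig` is unclassified.
#'
#' @param S Numeric vector (or matrix) of signed consensus scores.
#' @param sig,high Significance thresholds, `0 < sig < high` (defaults 5
#'   and 10).
#' @return Character vector of class labels, same length as `S`.
#' @export
classify_edges <- function(S, sig = 5, high = 10) {
  check_positive(sig, "sig")
  if (sig >= high) abort("`sig` must be < `high`")
  s <- as.vector(S)
  dplyr::case_when(
    s >= high ~ "highly_significant_activator",
    s > sig ~ "activator",
    s <= -high ~ "highly_significant_suppressor",
    s < -sig ~ "suppressor",
    TRUE ~ "unclassified"
  )
}

#' Assemble the consensus TF-module network
#'
#' Chains [call_edges()], [consensus_support()], [consensus_score()] and
#' [classify_edges()] into a bipartite directed network of TF -> module
#' edges.
#'
#' @param scores Named list of score matrices from [run_all_methods()].
#' @param mat The `inference_matrix` behind the scores.
#' @param top_fraction Per-method call fraction (see [call_edges()]).
#' @param min_support Minimum method support for a consensus edge (default 3).
#' @param sig,high Classification thresholds (see [classify_edges()]).
#' @return A `consensus_network`: list with `edges` (tibble: tf, module,
#'   support, score, sign, class, plus one `score_<method>` column per
#'   method), `nodes` (tibble: id, kind), `n_methods`, `params`.
#' @export
build_consensus_network <- function(scores, mat, top_fraction = 0.02,
                                    min_support = 3, sig = 5, high = 10) {
  calls <- lapply(scores, call_edges, top_fraction = top_fraction)
  edges <- consensus_support(calls, min_support)
  S <- consensus_score(scores, mat)
  idx <- cbind(match(edges$tf, rownames(S)), match(edges$module, colnames(S)))
  edges$score <- if (nrow(edges)) S[idx] else numeric(0)
  edges$sign <- if (nrow(edges)) {
    ifelse(edges$score > 0, "+", ifelse(edges$score < 0, "-", "0"))
  } else character(0)
  edges$class <- classify_edges(edges$score, sig = sig, high = high)
  for (m in names(scores)) {
    edges[[paste0("score_", m)]] <-
      if (nrow(edges)) unclass(scores[[m]])[idx] else numeric(0)
  }
  nodes <- tibble::tibble(
    id = c(rownames(S), colnames(S)),
    kind = c(rep("tf", nrow(S)), rep("module", ncol(S))))
  structure(
    list(edges = edges, nodes = nodes, n_methods = length(scores),
         params = list(top_fraction = top_fraction, min_support = min_support,
                       sig = sig, high = high, methods = names(scores))),
    class = "consensus_network"
  )
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("<consensus_network> %d edges (support >= %d of %d methods); %d activating, %d suppressing\n",
              nrow(x$edges), x$params$min_support, x$n_methods,
              sum(grepl("activator", x$edges$class)),
              sum(grepl("suppressor", x$edges$class))))
  invisible(x)
}

#' Degree table and hub nodes of a consensus network
#'
#' @param net A `consensus_network`.
#' @return List with `degree` (tibble: id, kind, degree; ordered degree desc
#'   then id) and `hubs` (the maximal-degree nodes of each kind).
#' @export
network_stats <- function(net) {
  if (!nrow(net$edges)) {
    empty <- tibble::tibble(id = character(), kind = character(),
                            degree = integer())
    return(list(degree = empty, hubs = empty))
  }
  degree <- dplyr::bind_rows(
    tibble::tibble(id = net$edges$tf, kind = "tf"),
    tibble::tibble(id = net$edges$module, kind = "module")) |>
    dplyr::count(.data$id, .data$kind, name = "degree") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$id)
  hubs <- degree |>
    dplyr::group_by(.data$kind) |>
    dplyr::filter(.data$degree == max(.data$degree)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$kind, .data$id)
  list(degree = degree, hubs = hubs)
}

#' Export a consensus network to TSV, SIF or GraphML
#'
#' TSV columns: `tf`, `module`, `support`, `score`, `class` (round-trips
#' through [read_network_tsv()]); SIF uses the relation `regulates`; GraphML
#' (via igraph) carries the node `kind` and all edge attributes.
#'
#' @param net A `consensus_network`.
#' @param path Output file path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  e <- dplyr::select(net$edges, "tf", "module", "support", "score", "class")
  if (format == "tsv") {
    readr::write_tsv(e, path)
  } else if (format == "sif") {
    writeLines(if (nrow(e)) sprintf("%s\tregulates\t%s", e$tf, e$module) else character(0),
               path)
  } else {
    g <- igraph::graph_from_data_frame(
      e, directed = TRUE,
      vertices = dplyr::filter(net$nodes,
                               .data$id %in% c(e$tf, e$module) | nrow(e) == 0))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back a consensus-edge TSV written by [export_network()]
#'
#' @param path Path to the TSV.
#' @return Tibble with `tf`, `module`, `support`, `score`, `class`.
#' @export
read_network_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(tf = "c", module = "c",
                                          support = "i", score = "d",
                                          class = "c"))
}
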