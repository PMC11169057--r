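#' Pipeline configuration
#'
#' Gathers every tunable of the analysis with validated defaults. Unknown
#' arguments are an error (no silent typos): the function signature is the
#' schema, and [read_config()] round-trips through it.
#'
#' @param lfc_min,p_max DEG filter: minimum |log2 fold change| (inclusive)
#'   and p-value ceiling (strict).
#' @param pseudocount Fold-change pseudocount.
#' @param k_min,k_max,k_step,n_init K-means/BIC sweep grid and restarts.
#' @param standardize_rows Z-score gene rows before clustering? (Makes
#'   modules shape-based.)
#' @param methods Inference methods to run, subset of
#'   `c("aracne", "clr", "lars", "pcor", "spearman")`.
#' @param mi_estimator `"gauss_copula"` or `"binned"`.
#' @param dpi_tolerance ARACNE DPI slack.
#' @param n_resamples,n_steps,subsample_fraction LARS stability-selection
#'   parameters.
#' @param top_fraction Per-method call fraction.
#' @param min_support Consensus vote threshold.
#' @param sig,high Signed-score classification thresholds.
#' @param seed Global seed; stages derive their own seeds by fixed offsets.
#' @return A `pipeline_config` (validated named list).
#' @export
pipeline_config <- function(lfc_min = 1, p_max = 0.05, pseudocount = 1,
                            k_min = 10, k_max = 100, k_step = 5, n_init = 10,
                            standardize_rows = TRUE,
                            methods = c("aracne", "clr", "lars", "pcor"),
                            mi_estimator = "gauss_copula",
                            dpi_tolerance = 0,
                            n_resamples = 200, n_steps = 3,
                            subsample_fraction = 0.8,
                            top_fraction = 0.02, min_support = 3,
                            sig = 5, high = 10, seed = 1) {
  check_positive(lfc_min, "lfc_min")
  check_proportion(p_max, "p_max", allow_zero = FALSE)
  check_nonneg(pseudocount, "pseudocount")
  check_count(k_min, "k_min"); check_count(k_max, "k_max")
  check_count(k_step, "k_step"); check_count(n_init, "n_init")
  if (k_min > k_max) abort("`k_min` must be <= `k_max`")
  bad <- setdiff(methods, c("aracne", "clr", "lars", "pcor", "spearman"))
  if (length(bad)) abort(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  if (!mi_estimator %in% c("gauss_copula", "binned")) {
    abort(sprintf("unknown mi_estimator '%s'", mi_estimator))
  }
  check_nonneg(dpi_tolerance, "dpi_tolerance")
  check_count(n_resamples, "n_resamples"); check_count(n_steps, "n_steps")
  check_proportion(subsample_fraction, "subsample_fraction", allow_zero = FALSE)
  check_proportion(top_fraction, "top_fraction", allow_zero = FALSE)
  check_count(min_support, "min_support")
  check_positive(sig, "sig")
  if (sig >= high) abort("`sig` must be < `high`")
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(lfc_min = lfc_min, p_max = p_max, pseudocount = pseudocount,
         k_min = k_min, k_max = k_max, k_step = k_step, n_init = n_init,
         standardize_rows = standardize_rows,
         methods = methods, mi_estimator = mi_estimator,
         dpi_tolerance = dpi_tolerance,
         n_resamples = n_resamples, n_steps = n_steps,
         subsample_fraction = subsample_fraction,
         top_fraction = top_fraction, min_support = min_support,
         sig = sig, high = high, seed = seed),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration (YAML)
#'
#' The on-disk form round-trips losslessly through [pipeline_config()];
#' unknown keys in the file are fatal.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_config()`: `path` invisibly; `read_config()`: a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read config '%s'", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Validate pipeline inputs
#'
#' Cross-checks the four inputs and returns a tibble of problems; an empty
#' report means the inputs run cleanly.
#'
#' @param counts Gene x sample numeric matrix.
#' @param sample_sheet Tibble with `sample`, `condition`.
#' @param gene_lengths Named numeric vector (bp).
#' @param tf_ids Character vector of regulator gene IDs.
#' @return Tibble with columns `check`, `detail` (one row per problem).
#' @export
validate_inputs <- function(counts, sample_sheet, gene_lengths, tf_ids) {
  problems <- list()
  note <- function(check, detail) {
    problems[[length(problems) + 1]] <<- tibble::tibble(check = check, detail = detail)
  }
  if (!is.matrix(counts) || !is.numeric(counts)) {
    note("counts_numeric", "counts is not a numeric matrix")
    return(dplyr::bind_rows(problems))
  }
  if (anyDuplicated(rownames(counts))) {
    note("duplicate_gene_ids",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    note("duplicate_sample_ids",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    note("negative_counts",
         paste(sprintf("%s/%s", rownames(counts)[neg[, 1]],
                       colnames(counts)[neg[, 2]]), collapse = ", "))
  }
  if (anyNA(counts)) note("missing_counts", sprintf("%d NA cells", sum(is.na(counts))))
  missing_len <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing_len)) {
    note("missing_gene_lengths", paste(head(missing_len, 10), collapse = ", "))
  }
  unmapped <- setdiff(colnames(counts), sample_sheet$sample)
  if (length(unmapped)) note("samples_missing_from_sheet", paste(unmapped, collapse = ", "))
  extra <- setdiff(sample_sheet$sample, colnames(counts))
  if (length(extra)) note("sheet_samples_missing_from_counts", paste(extra, collapse = ", "))
  unknown_tfs <- setdiff(tf_ids, rownames(counts))
  if (length(unknown_tfs)) {
    note("unknown_tf_ids", paste(head(unknown_tfs, 10), collapse = ", "))
  }
  if (!length(problems)) {
    return(tibble::tibble(check = character(), detail = character()))
  }
  dplyr::bind_rows(problems)
}

# stage-seed fan-out: one global seed, fixed offsets per stochastic stage
stage_seed <- function(seed, stage) {
  seed + c(cluster_sweep = 101L, cluster_fit = 202L, infer = 303L)[[stage]]
}

#' Run the full module-network consensus analysis
#'
#' Executes the stages in order: median-of-ratios normalization and FPKM;
#' per-condition DEG tests against the reference (first) condition with the
#' `|log2FC| >= lfc_min & p < p_max` filter; K-means clustering of the
#' condition-averaged log2(FPKM+1) profiles of DEGs with BIC-selected K;
#' module mean profiles and central genes; four-method network inference on
#' the stacked module + DE-TF matrix; consensus voting and signed edge
#' classification.
#'
#' @param counts Gene x sample count matrix.
#' @param sample_sheet Tibble with `sample`, `condition` (first condition in
#'   order of appearance is the DEG reference).
#' @param gene_lengths Named numeric vector (bp) covering all genes.
#' @param tf_ids Regulator gene IDs (must all be rows of `counts`).
#' @param config A [pipeline_config()].
#' @param output_dir If non-NULL, every stage artifact plus a JSON run
#'   manifest is written there.
#' @return A `grn_pipeline` result: list with `size_factors`, `fpkm_log2`,
#'   `qc`, `deg_tables` (one per comparison), `deg_sets`, `sweep`,
#'   `assignment`, `profiles`, `central`, `heatmap`, `inference_matrix`,
#'   `scores`, `network`, `stats`, `manifest`, `config`.
#' @export
run_pipeline <- function(counts, sample_sheet, gene_lengths, tf_ids,
                         config = pipeline_config(), output_dir = NULL) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config")
  report <- validate_inputs(counts, sample_sheet, gene_lengths, tf_ids)
  if (nrow(report)) {
    abort(sprintf("invalid inputs [stage validate]: %s",
                  paste(sprintf("%s (%s)", report$check, report$detail),
                        collapse = "; ")))
  }

  # --- normalize ---
  sf <- size_factors(counts)
  fpkm_lin <- fpkm(counts, gene_lengths, factors = sf)
  fpkm_log <- log2(fpkm_lin + 1)
  attr(fpkm_log, "scale") <- "log2"
  qc <- sample_qc(fpkm_log, sample_sheet)

  # --- DEG: each non-reference condition vs the reference ---
  conds <- unique(sample_sheet$condition)
  if (length(conds) < 2) abort("need at least 2 conditions [stage deg]")
  ref_samples <- sample_sheet$sample[sample_sheet$condition == conds[1]]
  deg_tables <- lapply(conds[-1], function(cc) {
    deg_test(counts,
             group_a = ref_samples,
             group_b = sample_sheet$sample[sample_sheet$condition == cc],
             factors = sf, pseudocount = config$pseudocount,
             lfc_min = config$lfc_min, p_max = config$p_max)
  })
  names(deg_tables) <- paste0(conds[1], "_vs_", conds[-1])
  de_sets <- lapply(deg_tables, filter_degs,
                    lfc_min = config$lfc_min, p_max = config$p_max)
  de_genes <- unique(unlist(lapply(de_sets, `[[`, "all_de")))
  if (length(de_genes) < 2) abort("fewer than 2 DEGs [stage deg]")

  # --- clustering ---
  avg <- average_replicates(fpkm_log, sample_sheet)
  X <- avg[de_genes, , drop = FALSE]
  keep <- apply(X, 1, stats::sd) > 0
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  if (config$standardize_rows) {
    X <- t(scale(t(X)))
  }
  sweep_res <- kmeans_bic_sweep(X, k_min = config$k_min, k_max = config$k_max,
                                k_step = config$k_step, n_init = config$n_init,
                                seed = stage_seed(config$seed, "cluster_sweep"))
  assignment <- assign_modules(X, sweep_res$best_k, n_init = config$n_init,
                               seed = stage_seed(config$seed, "cluster_fit"))
  profiles <- module_profiles(assignment, avg)
  central <- central_genes(assignment, X)
  heat <- heatmap_matrix(profiles)

  # --- inference: columns are the experimental lines (samples), not
  # condition averages, mirroring the module + TF stacked design ---
  de_tfs <- intersect(tf_ids, de_genes)
  profiles_lines <- module_profiles(assignment, fpkm_log)
  tf_expr <- fpkm_log[intersect(tf_ids, rownames(fpkm_log)), , drop = FALSE]
  infmat <- build_inference_matrix(profiles_lines, tf_expr, de_tfs)
  scores <- run_all_methods(infmat, methods = config$methods,
                            mi_estimator = config$mi_estimator,
                            dpi_tolerance = config$dpi_tolerance,
                            n_resamples = config$n_resamples,
                            n_steps = config$n_steps,
                            subsample_fraction = config$subsample_fraction,
                            seed = stage_seed(config$seed, "infer"))

  # --- consensus ---
  network <- build_consensus_network(scores, infmat,
                                     top_fraction = config$top_fraction,
                                     min_support = config$min_support,
                                     sig = config$sig, high = config$high)
  nstats <- network_stats(network)

  manifest <- list(
    package_version = as.character(utils::packageVersion("modnet")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    parameters = unclass(config),
    dims = list(
      genes = nrow(counts), samples = ncol(counts),
      conditions = length(conds),
      degs = length(de_genes), degs_dropped_zero_variance = n_dropped,
      modules = assignment$k, de_tfs = length(de_tfs),
      inference_rows = nrow(infmat), inference_cols = ncol(infmat),
      pair_universe = length(de_tfs) * assignment$k,
      consensus_edges = nrow(network$edges))
  )

  res <- structure(
    list(size_factors = sf, fpkm_log2 = fpkm_log, qc = qc,
         deg_tables = deg_tables, deg_sets = de_sets, deg_genes = de_genes,
         sweep = sweep_res, assignment = assignment, profiles = profiles,
         central = central, heatmap = heat,
         inference_matrix = infmat, scores = scores,
         network = network, stats = nstats,
         manifest = manifest, config = config),
    class = "grn_pipeline")

  if (!is.null(output_dir)) write_pipeline_outputs(res, output_dir)
  res
}

#' @export
print.grn_pipeline <- function(x, ...) {
  d <- x$manifest$dims
  cat(sprintf(paste0("<grn_pipeline> %d genes x %d samples | %d DEGs | ",
                     "%d modules (BIC) | %d DE TFs | inference %d x %d | ",
                     "%d consensus edges\n"),
              d$genes, d$samples, d$degs, d$modules, d$de_tfs,
              d$inference_rows, d$inference_cols, d$consensus_edges))
  invisible(x)
}

#' Write every stage artifact of a pipeline run
#'
#' @param res A `grn_pipeline` result.
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  readr::write_tsv(tibble::as_tibble(res$fpkm_log2, rownames = "gene"), p("fpkm_log2.tsv"))
  readr::write_tsv(dplyr::bind_rows(res$deg_tables, .id = "comparison"),
                   p("deg_table.tsv"))
  readr::write_tsv(tibble::as_tibble(res$qc$correlation, rownames = "sample"),
                   p("qc_correlation.tsv"))
  readr::write_tsv(res$qc$pcoa, p("pcoa.tsv"))
  readr::write_tsv(ma_data(res$deg_tables[[1]]), p("ma_data.tsv"))
  readr::write_tsv(tibble::tibble(gene = names(res$assignment$labels),
                                  module = sprintf("module_%02d", res$assignment$labels)),
                   p("modules.tsv"))
  readr::write_tsv(res$sweep$bic_curve, p("bic_curve.tsv"))
  readr::write_tsv(tibble::as_tibble(res$profiles, rownames = "module"),
                   p("module_profiles.tsv"))
  readr::write_tsv(res$central, p("central_genes.tsv"))
  readr::write_tsv(tibble::as_tibble(res$heatmap$matrix, rownames = "module"),
                   p("heatmap_matrix.tsv"))
  for (m in names(res$scores)) {
    readr::write_tsv(tibble::as_tibble(unclass(res$scores[[m]]), rownames = "tf"),
                     p(sprintf("scores_%s.tsv", m)))
  }
  readr::write_tsv(tidy_scores(res$scores), p("scores.tsv"))
  export_network(res$network, p("consensus_edges.tsv"), "tsv")
  export_network(res$network, p("network.sif"), "sif")
  export_network(res$network, p("network.graphml"), "graphml")
  readr::write_tsv(res$stats$degree, p("degree.tsv"))
  readr::write_tsv(res$stats$hubs, p("hubs.tsv"))
  jsonlite::write_json(res$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}
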