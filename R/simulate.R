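#' Simulate a ground-truth bipartite regulator network
#'
#' Draws a random bipartite network of signed regulatory effects from
#' transcription factors (TFs) onto gene co-expression modules. Edges are
#' sampled without replacement from the full TF x module grid; each edge gets
#' a sign (activator with probability `activator_fraction`, suppressor
#' otherwise) and an effect magnitude on the scale `weight_scale`.
#'
#' @param n_tfs Number of regulators.
#' @param n_modules Number of gene modules.
#' @param edge_density Proportion of the `n_tfs * n_modules` grid carrying an
#'   edge; the realized edge count is `round(edge_density * n_tfs * n_modules)`.
#' @param activator_fraction Probability that an edge is an activator
#'   (positive weight).
#' @param weight_scale Typical absolute effect size; magnitudes are drawn
#'   uniformly from `[0.5, 1.5] * weight_scale`.
#' @param seed Integer seed; identical seeds give identical networks.
#' @return A `truth_network` object: a list with `n_tfs`, `n_modules`,
#'   `tf_ids`, `module_ids`, and `edges`, a tibble with columns `tf`, `module`,
#'   `weight`.
#' @examples
#' net <- simulate_network(5, 3, edge_density = 0.5, seed = 1)
#' net$edges
#' @export
simulate_network <- function(n_tfs, n_modules, edge_density = 0.08,
                             activator_fraction = 0.7, weight_scale = 1,
                             seed = 1) {
  n_tfs <- check_count(n_tfs, "n_tfs")
  n_modules <- check_count(n_modules, "n_modules")
  check_proportion(edge_density, "edge_density")
  check_proportion(activator_fraction, "activator_fraction")
  check_positive(weight_scale, "weight_scale")

  tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
  module_ids <- sprintf("module_%02d", seq_len(n_modules))
  n_pairs <- n_tfs * n_modules
  n_edges <- round(edge_density * n_pairs)

  edges <- withr::with_seed(seed, {
    idx <- sort(sample.int(n_pairs, n_edges))
    tf_i <- ((idx - 1L) %% n_tfs) + 1L
    mod_i <- ((idx - 1L) %/% n_tfs) + 1L
    sign <- ifelse(stats::runif(n_edges) < activator_fraction, 1, -1)
    magnitude <- stats::runif(n_edges, 0.5, 1.5) * weight_scale
    tibble::tibble(
      tf = tf_ids[tf_i],
      module = module_ids[mod_i],
      weight = sign * magnitude
    )
  })

  structure(
    list(n_tfs = n_tfs, n_modules = n_modules,
         tf_ids = tf_ids, module_ids = module_ids, edges = edges),
    class = "truth_network"
  )
}

#' @export
print.truth_network <- function(x, ...) {
  cat(sprintf("<truth_network> %d TFs x %d modules, %d edges (%d activating)\n",
              x$n_tfs, x$n_modules, nrow(x$edges), sum(x$edges$weight > 0)))
  invisible(x)
}

#' Simulate an RNA-seq count dataset from a planted regulator network
#'
#' Generates negative-binomial counts whose log-scale structure follows the
#' planted network: each TF has a latent activity per condition, each module's
#' log-signal is the weighted sum of its regulators' activities, and member
#' genes scatter around the module signal. Replicates share the condition
#' signal and differ only through count noise and library-size variation.
#'
#' The generative model, per condition `c`:
#' \itemize{
#'   \item TF activity `a_t(c) ~ Normal(0, activity_sd^2)`;
#'   \item module log-signal `m_k(c) = sum_t w_tk a_t(c) + Normal(0, module_noise_sd^2)`;
#'   \item member-gene log-signal `= m_k(c) + Normal(0, gene_noise_sd^2)`;
#'   \item TF-gene log-signal `= a_t(c)` (expression tracks activity);
#'   \item counts `~ NegBinomial(mean = exp(base_g + signal) * length_kb * libfactor_s,
#'     Var = mu + mu^2 * nb_dispersion)`.
#' }
#' Gene lengths are drawn log-uniformly on `[500, 5000]` bp so FPKM is
#' exercised nontrivially; library-size factors are log-normal with
#' coefficient of variation `libsize_cv`, normalized to geometric mean 1.
#'
#' @param truth A `truth_network` from [simulate_network()].
#' @param n_conditions,n_replicates Design grid; the dataset has
#'   `n_conditions * n_replicates` sample columns.
#' @param genes_per_module Module size (every module gets the same size).
#' @param activity_sd Standard deviation of latent TF activities across
#'   conditions (log-e scale).
#' @param module_noise_sd,gene_noise_sd Log-scale noise around the module and
#'   gene signals; set both to 0 for a noise-free monotone map from activity
#'   to expression.
#' @param nb_dispersion Negative-binomial dispersion (Var = mu + mu^2 * disp);
#'   must be > 0, use a tiny value (e.g. 1e-8) for near-Poisson counts.
#' @param libsize_cv Coefficient of variation of library-size factors; 0 gives
#'   identical factors.
#' @param base_log_mean Mean of per-gene baseline log-expression (log-e counts
#'   per kb at library factor 1); per-gene baselines scatter around it with
#'   sd 0.5.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A `sim_dataset` object: list with `counts` (integer gene x sample
#'   matrix), `sample_sheet` (tibble: sample, condition, replicate),
#'   `tf_ids`, `gene_lengths` (named, bp), `module_membership` (tibble: gene,
#'   module), `truth`, and `params`.
#' @examples
#' net <- simulate_network(4, 2, edge_density = 0.5, seed = 1)
#' sim <- simulate_expression(net, n_conditions = 2, n_replicates = 3,
#'                            genes_per_module = 5, seed = 1)
#' dim(sim$counts)
#' @export
simulate_expression <- function(truth,
                                n_conditions = 2, n_replicates = 3,
                                genes_per_module = 20,
                                activity_sd = 1,
                                module_noise_sd = 0.1,
                                gene_noise_sd = 0.2,
                                nb_dispersion = 0.05,
                                libsize_cv = 0.1,
                                base_log_mean = log(100),
                                seed = 1) {
  if (!inherits(truth, "truth_network")) abort("`truth` must be a truth_network")
  n_conditions <- check_count(n_conditions, "n_conditions")
  n_replicates <- check_count(n_replicates, "n_replicates")
  genes_per_module <- check_count(genes_per_module, "genes_per_module")
  check_positive(activity_sd, "activity_sd")
  check_nonneg(module_noise_sd, "module_noise_sd")
  check_nonneg(gene_noise_sd, "gene_noise_sd")
  check_positive(nb_dispersion, "nb_dispersion")
  check_nonneg(libsize_cv, "libsize_cv")

  n_tfs <- truth$n_tfs
  n_modules <- truth$n_modules
  module_genes <- unlist(lapply(seq_len(n_modules), function(k) {
    sprintf("%s_G%03d", truth$module_ids[k], seq_len(genes_per_module))
  }))
  gene_ids <- c(truth$tf_ids, module_genes)
  n_genes <- length(gene_ids)
  n_samples <- n_conditions * n_replicates
  condition_ids <- sprintf("C%02d", seq_len(n_conditions))

  # TF x module signed weight matrix from the edge list
  W <- matrix(0, n_tfs, n_modules, dimnames = list(truth$tf_ids, truth$module_ids))
  if (nrow(truth$edges)) {
    W[cbind(match(truth$edges$tf, truth$tf_ids),
            match(truth$edges$module, truth$module_ids))] <- truth$edges$weight
  }

  out <- withr::with_seed(seed, {
    lengths_bp <- round(exp(stats::runif(n_genes, log(500), log(5000))))
    names(lengths_bp) <- gene_ids
    base_g <- stats::rnorm(n_genes, base_log_mean, 0.5)

    activity <- matrix(stats::rnorm(n_tfs * n_conditions, 0, activity_sd),
                       n_tfs, n_conditions,
                       dimnames = list(truth$tf_ids, condition_ids))
    module_signal <- crossprod(W, activity) +
      matrix(stats::rnorm(n_modules * n_conditions, 0, module_noise_sd),
             n_modules, n_conditions)

    # per-gene log-signal by condition
    signal <- matrix(0, n_genes, n_conditions, dimnames = list(gene_ids, condition_ids))
    signal[truth$tf_ids, ] <- activity
    for (k in seq_len(n_modules)) {
      members <- sprintf("%s_G%03d", truth$module_ids[k], seq_len(genes_per_module))
      noise <- matrix(stats::rnorm(genes_per_module * n_conditions, 0, gene_noise_sd),
                      genes_per_module, n_conditions)
      signal[members, ] <- matrix(module_signal[k, ], genes_per_module,
                                  n_conditions, byrow = TRUE) + noise
    }

    if (libsize_cv > 0) {
      sdlog <- sqrt(log(1 + libsize_cv^2))
      libfactor <- exp(stats::rnorm(n_samples, 0, sdlog))
      libfactor <- libfactor / exp(mean(log(libfactor)))
    } else {
      libfactor <- rep(1, n_samples)
    }

    cond_of_sample <- rep(seq_len(n_conditions), each = n_replicates)
    sample_ids <- sprintf("%s_R%d", condition_ids[cond_of_sample],
                          rep(seq_len(n_replicates), times = n_conditions))

    mu <- exp(base_g + signal[, cond_of_sample, drop = FALSE]) *
      (lengths_bp / 1000) *
      matrix(libfactor, n_genes, n_samples, byrow = TRUE)
    counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu,
                                    size = 1 / nb_dispersion),
                     n_genes, n_samples,
                     dimnames = list(gene_ids, sample_ids))
    storage.mode(counts) <- "integer"

    list(counts = counts,
         sample_sheet = tibble::tibble(
           sample = sample_ids,
           condition = condition_ids[cond_of_sample],
           replicate = rep(seq_len(n_replicates), times = n_conditions)),
         lengths_bp = lengths_bp,
         libfactor = stats::setNames(libfactor, sample_ids),
         activity = activity,
         module_signal = module_signal)
  })

  structure(
    list(counts = out$counts,
         sample_sheet = out$sample_sheet,
         tf_ids = truth$tf_ids,
         gene_lengths = out$lengths_bp,
         module_membership = tibble::tibble(
           gene = module_genes,
           module = rep(truth$module_ids, each = genes_per_module)),
         truth = truth,
         lib_factors = out$libfactor,
         tf_activity = out$activity,
         module_signal = out$module_signal,
         params = list(n_conditions = n_conditions, n_replicates = n_replicates,
                       genes_per_module = genes_per_module,
                       activity_sd = activity_sd,
                       module_noise_sd = module_noise_sd,
                       gene_noise_sd = gene_noise_sd,
                       nb_dispersion = nb_dispersion, libsize_cv = libsize_cv,
                       base_log_mean = base_log_mean, seed = seed)),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d genes (%d TFs, %d modules x %d) x %d samples (%d conditions x %d reps)\n",
              nrow(x$counts), length(x$tf_ids), x$truth$n_modules,
              x$params$genes_per_module, ncol(x$counts),
              x$params$n_conditions, x$params$n_replicates))
  invisible(x)
}

#' Write a simulated dataset as the pipeline's standard input files
#'
#' Writes `counts.tsv`, `sample_sheet.tsv`, `gene_lengths.tsv`, `tf_list.txt`,
#' plus the ground-truth files `truth_edges.tsv` and `module_membership.tsv`.
#' The first four are exactly the inputs [run_pipeline()] and
#' [read_dataset()] consume.
#'
#' @param sim A `sim_dataset` from [simulate_expression()].
#' @param dir Output directory, created if needed.
#' @param force Overwrite an existing non-empty directory? Refused otherwise.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, force = FALSE) {
  if (!inherits(sim, "sim_dataset")) abort("`sim` must be a sim_dataset")
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(sprintf("directory '%s' is not empty; use force = TRUE to overwrite", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_df <- tibble::as_tibble(sim$counts, rownames = "gene_id")
  readr::write_tsv(counts_df, file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  readr::write_tsv(tibble::tibble(gene_id = names(sim$gene_lengths),
                                  length_bp = unname(sim$gene_lengths)),
                   file.path(dir, "gene_lengths.tsv"))
  writeLines(sim$tf_ids, file.path(dir, "tf_list.txt"))
  readr::write_tsv(sim$truth$edges, file.path(dir, "truth_edges.tsv"))
  readr::write_tsv(sim$module_membership, file.path(dir, "module_membership.tsv"))
  invisible(dir)
}

#' Read the pipeline's standard input files from a directory
#'
#' Counterpart of [write_dataset()]; reads `counts.tsv`, `sample_sheet.tsv`,
#' `gene_lengths.tsv` and `tf_list.txt`.
#'
#' @param dir Directory containing the files.
#' @return A list with `counts` (integer matrix), `sample_sheet` (tibble),
#'   `gene_lengths` (named numeric) and `tf_ids` (character).
#' @export
read_dataset <- function(dir) {
  list(counts = read_counts(file.path(dir, "counts.tsv")),
       sample_sheet = read_sample_sheet(file.path(dir, "sample_sheet.tsv")),
       gene_lengths = read_gene_lengths(file.path(dir, "gene_lengths.tsv")),
       tf_ids = read_tf_list(file.path(dir, "tf_list.txt")))
}
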